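#' Two-dimensional crown area
#'
#' Occlusal crown area in the traditional paleontological sense: mesiodistal
#' length multiplied by buccolingual breadth, both in mm.
#'
#' @param md_length Mesiodistal crown length (mm), strictly positive.
#' @param bl_breadth Buccolingual crown breadth (mm), strictly positive.
#' @return Crown area in mm^2. Vectorised; `NA` inputs give `NA`.
#' @export
#' @examples
#' crown_area(10, 5)
crown_area <- function(md_length, bl_breadth) {
  bad <- (!is.na(md_length) & md_length <= 0) |
    (!is.na(bl_breadth) & bl_breadth <= 0)
  if (any(bad)) {
    stop("crown_area: md_length and bl_breadth must be strictly positive")
  }
  md_length * bl_breadth
}

#' Molar module component (MMC)
#'
#' Ratio of third-molar to first-molar mesiodistal length. MMC tracks
#' relative size variation within the molar genetic module while excluding
#' the genetic effects on buccolingual breadth that are shared with body
#' size.
#'
#' @param m1_length,m3_length Mesiodistal lengths (mm) of M1 and M3.
#' @return `m3_length / m1_length`; `NA` when either length is missing.
#' @export
compute_mmc <- function(m1_length, m3_length) {
  .length_ratio(m1_length, m3_length, "compute_mmc")
}

#' Premolar-molar module (PMM)
#'
#' Ratio of second-molar to fourth-premolar mesiodistal length, capturing
#' the partial genetic correlation between the premolar and molar modules.
#'
#' @param p4_length,m2_length Mesiodistal lengths (mm) of P4 and M2.
#' @return `m2_length / p4_length`; `NA` when either length is missing.
#' @export
compute_pmm <- function(p4_length, m2_length) {
  .length_ratio(p4_length, m2_length, "compute_pmm")
}

#' Inhibitory cascade trait (IC)
#'
#' Ratio of third-molar to first-molar two-dimensional occlusal area,
#' the developmental activator-inhibitor trait of the molar row.
#'
#' @param area_m1,area_m3 Crown areas (mm^2) of M1 and M3.
#' @return `area_m3 / area_m1`; `NA` when either area is missing.
#' @export
compute_ic <- function(area_m1, area_m3) {
  .length_ratio(area_m1, area_m3, "compute_ic")
}

# denominator-first ratio with missing propagation and positivity guard
.length_ratio <- function(denom, numer, what) {
  if (any(!is.na(denom) & denom <= 0) || any(!is.na(numer) & numer <= 0)) {
    stop(what, ": inputs must be strictly positive")
  }
  out <- numer / denom
  out[is.na(denom) | is.na(numer)] <- NA_real_
  out
}

#' Resolve measurement side per trait for one specimen
#'
#' Applies the left-preferred side rule: each trait is computed from left
#' side teeth when every tooth entering that trait is measured on the left;
#' otherwise the right side is used if complete there. Sides are never mixed
#' within one trait.
#'
#' @param rows A [measurement_table] subset belonging to a single specimen.
#' @return A one-row data frame with the specimen's trait-component metrics
#'   (`p4_len`, `m1_len`, `m2_len`, `m3_len`, `m1_area`, `m2_area`,
#'   `m3_area`) and a `side_used` entry per trait family (`side_mmc`,
#'   `side_pmm`, `side_ic`, `side_areas`), `NA` where neither side is
#'   complete.
#' @export
resolve_side <- function(rows) {
  if (length(unique(rows$specimen_id)) > 1L) {
    stop("resolve_side: rows must belong to a single specimen")
  }
  get <- function(side, tooth, col) {
    i <- which(rows$side == side & rows$tooth == tooth)
    if (length(i) == 0L) return(NA_real_)
    rows[[col]][i[1L]]
  }
  len <- function(side, tooth) get(side, tooth, "md_length")
  area <- function(side, tooth) {
    l <- get(side, tooth, "md_length"); b <- get(side, tooth, "bl_breadth")
    if (is.na(l) || is.na(b)) NA_real_ else l * b
  }
  # a trait's side: L if all components present on L, else R if present there
  pick <- function(vals_l, vals_r) {
    if (!anyNA(vals_l)) "L" else if (!anyNA(vals_r)) "R" else NA_character_
  }
  side_mmc <- pick(c(len("L", "M1"), len("L", "M3")),
                   c(len("R", "M1"), len("R", "M3")))
  side_pmm <- pick(c(len("L", "P4"), len("L", "M2")),
                   c(len("R", "P4"), len("R", "M2")))
  side_ic <- pick(c(area("L", "M1"), area("L", "M3")),
                  c(area("R", "M1"), area("R", "M3")))
  side_areas <- pick(c(area("L", "M1"), area("L", "M2"), area("L", "M3")),
                     c(area("R", "M1"), area("R", "M2"), area("R", "M3")))
  comp <- function(side, f, tooth) if (is.na(side)) NA_real_ else f(side, tooth)
  data.frame(
    specimen_id = rows$specimen_id[1L],
    genus = rows$genus[1L],
    species = rows$species[1L],
    m1_len_mmc = comp(side_mmc, len, "M1"),
    m3_len_mmc = comp(side_mmc, len, "M3"),
    p4_len_pmm = comp(side_pmm, len, "P4"),
    m2_len_pmm = comp(side_pmm, len, "M2"),
    m1_area_ic = comp(side_ic, area, "M1"),
    m3_area_ic = comp(side_ic, area, "M3"),
    m1_area = comp(side_areas, area, "M1"),
    m2_area = comp(side_areas, area, "M2"),
    m3_area = comp(side_areas, area, "M3"),
    side_mmc = side_mmc, side_pmm = side_pmm,
    side_ic = side_ic, side_areas = side_areas,
    stringsAsFactors = FALSE
  )
}

#' Compute specimen-level dental traits
#'
#' Applies [resolve_side()] per specimen and derives MMC, PMM, IC and the
#' three molar crown areas. Ratios are computed within specimens (both
#' component teeth on one side), never as ratios of group means.
#'
#' @param measurements A [measurement_table].
#' @return A data frame, one row per specimen, with columns `specimen_id`,
#'   `genus`, `species`, `area_M1`, `area_M2`, `area_M3`, `IC`, `MMC`,
#'   `PMM` and the per-trait `side_*` columns.
#' @export
specimen_traits <- function(measurements) {
  stopifnot(is.data.frame(measurements))
  parts <- split(measurements, measurements$specimen_id)
  resolved <- do.call(rbind, lapply(parts, resolve_side))
  rownames(resolved) <- NULL
  out <- resolved[, c("specimen_id", "genus", "species")]
  out$area_M1 <- resolved$m1_area
  out$area_M2 <- resolved$m2_area
  out$area_M3 <- resolved$m3_area
  out$IC <- ifelse(is.na(resolved$m1_area_ic) | is.na(resolved$m3_area_ic),
                   NA_real_, resolved$m3_area_ic / resolved$m1_area_ic)
  out$MMC <- ifelse(is.na(resolved$m1_len_mmc) | is.na(resolved$m3_len_mmc),
                    NA_real_, resolved$m3_len_mmc / resolved$m1_len_mmc)
  out$PMM <- ifelse(is.na(resolved$p4_len_pmm) | is.na(resolved$m2_len_pmm),
                    NA_real_, resolved$m2_len_pmm / resolved$p4_len_pmm)
  out$side_mmc <- resolved$side_mmc
  out$side_pmm <- resolved$side_pmm
  out$side_ic <- resolved$side_ic
  out$side_areas <- resolved$side_areas
  out
}

#' Geometric-mean size correction of molar areas
#'
#' Divides each of the M1/M2/M3 areas of an observation by the geometric
#' mean of the three, removing overall size while preserving proportions.
#' Rows with any missing area get all three corrected values missing.
#'
#' @param areas Data frame or matrix with columns `area_M1`, `area_M2`,
#'   `area_M3` (one row per observation).
#' @return Data frame of the same shape with size-corrected areas.
#' @export
size_correct_areas <- function(areas) {
  areas <- as.data.frame(areas)
  cols <- c("area_M1", "area_M2", "area_M3")
  stopifnot(all(cols %in% names(areas)))
  m <- as.matrix(areas[, cols])
  if (any(m <= 0, na.rm = TRUE)) {
    stop("size_correct_areas: areas must be strictly positive")
  }
  gm <- exp(rowMeans(log(m)))   # NA if any area missing
  out <- sweep(m, 1L, gm, "/")
  out[is.na(gm), ] <- NA_real_
  as.data.frame(out)
}

#' Univariate descriptive statistics
#'
#' Sample mean, standard deviation (n-1 denominator), range and Pearson
#' (non-excess) kurtosis m4/m2^2 — the moment-based convention under which a
#' normal sample has kurtosis near 3 and any non-constant sample has
#' kurtosis >= 1.
#'
#' @param values Numeric sample; `NA` dropped.
#' @return An object of class `desc_stats`: list with `n`, `mean`, `sd`,
#'   `min`, `max`, `kurtosis` (NA with `kurtosis_defined = FALSE` for a
#'   constant sample).
#' @export
descriptive_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("descriptive_stats: empty sample")
  n <- length(values)
  m2 <- mean((values - mean(values))^2)
  m4 <- mean((values - mean(values))^4)
  constant <- m2 == 0
  out <- list(
    n = n,
    mean = mean(values),
    sd = if (n > 1L) stats::sd(values) else 0,
    min = min(values),
    max = max(values),
    kurtosis = if (constant) NA_real_ else m4 / m2^2,
    kurtosis_defined = !constant
  )
  class(out) <- "desc_stats"
  out
}

#' @export
print.desc_stats <- function(x, ...) {
  cat(sprintf(
    "n = %d  mean = %.4g  sd = %.4g  range = [%.4g, %.4g]  kurtosis = %s\n",
    x$n, x$mean, x$sd, x$min, x$max,
    if (x$kurtosis_defined) sprintf("%.4g", x$kurtosis) else "undefined"))
  invisible(x)
}

#' Two-level taxonomic trait aggregation
#'
#' Aggregates specimen traits to unweighted species means, then unweighted
#' genus means (each species contributes equally to its genus regardless of
#' sample size), reporting the per-trait n at both levels.
#'
#' @param traits Output of [specimen_traits()].
#' @param level `"genus"` (default) or `"species"` for the intermediate
#'   species-level table.
#' @return Data frame with one row per taxon and, per trait, `<trait>` mean
#'   and `<trait>_n` (number of specimens with the trait non-missing,
#'   summed over species for the genus level).
#' @export
genus_summaries <- function(traits, level = c("genus", "species")) {
  level <- match.arg(level)
  trait_cols <- c("area_M1", "area_M2", "area_M3", "IC", "MMC", "PMM")
  sp_key <- paste(traits$genus, traits$species, sep = "|")
  agg <- function(df, key) {
    out <- data.frame(key = sort(unique(key)), stringsAsFactors = FALSE)
    for (tc in trait_cols) {
      mns <- tapply(df[[tc]], key, function(v) mean(v, na.rm = TRUE))
      ns <- tapply(df[[tc]], key, function(v) sum(!is.na(v)))
      mns[ns == 0] <- NA_real_
      out[[tc]] <- as.numeric(mns[out$key])
      out[[paste0(tc, "_n")]] <- as.integer(ns[out$key])
    }
    out
  }
  species_tab <- agg(traits, sp_key)
  species_tab$genus <- sub("\\|.*$", "", species_tab$key)
  species_tab$species <- sub("^.*\\|", "", species_tab$key)
  species_tab$key <- NULL
  if (level == "species") {
    return(species_tab[, c("genus", "species", setdiff(names(species_tab),
                                                       c("genus", "species")))])
  }
  gen <- data.frame(genus = sort(unique(species_tab$genus)),
                    stringsAsFactors = FALSE)
  for (tc in trait_cols) {
    mns <- tapply(species_tab[[tc]], species_tab$genus,
                  function(v) mean(v, na.rm = TRUE))
    ns <- tapply(species_tab[[paste0(tc, "_n")]], species_tab$genus, sum)
    nsp <- tapply(!is.na(species_tab[[tc]]), species_tab$genus, sum)
    mns[nsp == 0] <- NA_real_
    gen[[tc]] <- as.numeric(mns[gen$genus])
    gen[[paste0(tc, "_n")]] <- as.integer(ns[gen$genus])
  }
  gen
}
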