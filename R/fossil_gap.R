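#' Pair ancestral state estimates with fossil trait values
#'
#' Builds one row per (pairing, trait) joining ASR node estimates to the
#' trait means of candidate fossil genera. Nodes are addressed by the MRCA
#' of a tip set; tip pairings use the observed tip value directly. A genus
#' may appear in several pairings (one fossil can be a candidate ancestor
#' for more than one divergence).
#'
#' @param asr Named list of `asr_result` objects, one per trait (names are
#'   trait labels), from [ml_asr()].
#' @param tip_values Named list (per trait) of named tip value vectors,
#'   used for tip pairings.
#' @param fossil_means Data frame with columns `genus` and one column per
#'   trait holding the fossil genus trait mean.
#' @param spec Data frame with columns `pairing_id`, `node_tips`
#'   (semicolon-separated tip labels; a single label denotes a tip
#'   pairing), `fossil_genus`, `trait`, `include_in_mean`,
#'   `include_in_direction_count`, and optionally `node_age`.
#' @return Pairing rows as for [table8_pairing_rows()].
#' @export
pair_nodes <- function(asr, tip_values, fossil_means, spec) {
  required <- c("pairing_id", "node_tips", "fossil_genus", "trait",
                "include_in_mean", "include_in_direction_count")
  stopifnot(all(required %in% names(spec)))
  bad_genus <- setdiff(unique(spec$fossil_genus), fossil_means$genus)
  if (length(bad_genus) > 0L) {
    stop("pair_nodes: fossil genus missing from fossil_means: ",
         paste(bad_genus, collapse = ", "))
  }
  bad_trait <- setdiff(unique(spec$trait), names(asr))
  if (length(bad_trait) > 0L) {
    stop("pair_nodes: no ASR supplied for trait(s): ",
         paste(bad_trait, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    tr <- spec$trait[i]
    tips <- strsplit(spec$node_tips[i], ";")[[1]]
    a <- asr[[tr]]
    if (length(tips) == 1L) {
      vals <- tip_values[[tr]]
      if (!(tips %in% names(vals))) {
        stop("pair_nodes: unknown tip in pairing ", spec$pairing_id[i],
             ": ", tips)
      }
      asr_value <- unname(vals[tips])
      node_age <- 0
    } else {
      row <- asr_at_mrca(a, tips)
      asr_value <- row$estimate
      depths <- ape::node.depth.edgelength(a$tree)
      node_age <- max(depths[seq_len(ape::Ntip(a$tree))]) - depths[row$node]
    }
    if (!is.null(spec$node_age) && !is.na(spec$node_age[i])) {
      node_age <- spec$node_age[i]
    }
    fossil_value <- fossil_means[[tr]][match(spec$fossil_genus[i],
                                             fossil_means$genus)]
    data.frame(pairing_id = spec$pairing_id[i], trait = tr,
               asr_value = asr_value, fossil_value = fossil_value,
               node_age = node_age,
               fossil_age_mid = if (is.null(spec$fossil_age_mid)) NA_real_
                                else spec$fossil_age_mid[i],
               include_in_mean = spec$include_in_mean[i],
               include_in_direction_count = spec$include_in_direction_count[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Gap statistics between ancestral estimates and fossils
#'
#' Per pairing row: the signed difference `asr_value - fossil_value` and
#' its absolute value. Aggregates: per trait, the mean absolute difference
#' over the rows flagged `include_in_mean`, and the count of pairings with
#' ASR at or above the fossil value over the rows flagged
#' `include_in_direction_count` (ties count as "not lower"). Reported
#' aggregates are also rounded to 3 decimals, half-up.
#'
#' @param rows Pairing rows from [pair_nodes()] or
#'   [table8_pairing_rows()].
#' @return Object of class `gap_report`: list with `rows` (augmented with
#'   `signed_diff`, `abs_diff`), `mean_abs_diff` (named by trait, unrounded),
#'   `mean_abs_diff_rounded`, `n_ge` and `n_direction` (direction-subset
#'   counts per trait).
#' @export
gap_statistics <- function(rows) {
  stopifnot(all(c("trait", "asr_value", "fossil_value") %in% names(rows)))
  rows$signed_diff <- rows$asr_value - rows$fossil_value
  rows$abs_diff <- abs(rows$signed_diff)
  traits <- unique(rows$trait)
  mean_sub <- rows[rows$include_in_mean, ]
  if (nrow(mean_sub) == 0L) stop("gap_statistics: empty mean subset")
  mad_ <- vapply(traits, function(tr) {
    mean(mean_sub$abs_diff[mean_sub$trait == tr])
  }, numeric(1))
  dir_sub <- rows[rows$include_in_direction_count, ]
  n_ge <- vapply(traits, function(tr) {
    sum(dir_sub$signed_diff[dir_sub$trait == tr] >= 0)
  }, numeric(1))
  n_dir <- vapply(traits, function(tr) sum(dir_sub$trait == tr), numeric(1))
  out <- list(rows = rows,
              mean_abs_diff = mad_,
              mean_abs_diff_rounded = round_half_up(mad_, 3),
              n_ge = n_ge,
              n_direction = n_dir)
  class(out) <- "gap_report"
  out
}

# round half away from zero at `digits` decimals (printed-table convention;
# base round() is banker's rounding)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.gap_report <- function(x, ...) {
  cat("ASR-fossil gap report\n")
  for (tr in names(x$mean_abs_diff)) {
    cat(sprintf(
      "  %s: mean |ASR - fossil| = %.4f (%.3f rounded, n = %d); ASR >= fossil in %d of %d direction pairings\n",
      tr, x$mean_abs_diff[tr], x$mean_abs_diff_rounded[tr],
      sum(x$rows$include_in_mean & x$rows$trait == tr),
      x$n_ge[tr], x$n_direction[tr]))
  }
  invisible(x)
}

#' Gap-versus-time table
#'
#' Long-format table of (node_age, trait, abs_diff) for the pairings in a
#' gap report, with the per-trait mean absolute differences attached —
#' the numbers behind a gap-through-time scatter. Rows with missing age
#' are retained in the table but excluded from any plot.
#'
#' @param report A `gap_report`.
#' @return Data frame with columns `pairing_id`, `node_age`, `trait`,
#'   `abs_diff` and attribute `trait_means`.
#' @export
gap_over_time <- function(report) {
  stopifnot(inherits(report, "gap_report"))
  rows <- report$rows[report$rows$include_in_mean, ]
  if (nrow(rows) == 0L) stop("gap_over_time: empty report")
  out <- rows[, c("pairing_id", "node_age", "trait", "abs_diff")]
  rownames(out) <- NULL
  attr(out, "trait_means") <- report$mean_abs_diff
  out
}
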