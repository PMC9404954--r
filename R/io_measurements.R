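#' Read a crown-metric measurement table
#'
#' Long-format table: one row per (specimen, side, tooth) with mesiodistal
#' length and buccolingual breadth in mm. Validation rejects non-positive or
#' non-numeric metrics with row-level diagnostics and duplicate
#' (specimen, side, tooth) keys.
#'
#' @param path CSV file with columns `specimen_id`, `genus`, `species`,
#'   `side` (L/R), `tooth` (P4/M1/M2/M3), `md_length`, `bl_breadth`.
#'   Empty fields and `NA` are read as missing.
#' @return A validated data frame of class `measurement_table`.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("read_measurements: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  for (col in intersect(c("specimen_id", "genus", "species"), names(df))) {
    df[[col]] <- as.character(df[[col]])
  }
  as_measurement_table(df)
}

#' Validate a data frame as a measurement table
#'
#' @param df Data frame with the `read_measurements()` schema.
#' @return `df` with class `measurement_table` prepended.
#' @export
as_measurement_table <- function(df) {
  required <- c("specimen_id", "genus", "species", "side", "tooth",
                "md_length", "bl_breadth")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("measurement table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("md_length", "bl_breadth")) {
    v <- df[[col]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad) > 0L) {
        stop("measurement table integrity error: non-numeric ", col,
             " in row(s) ", paste(bad, collapse = ", "))
      }
      v <- num
    }
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad) > 0L) {
      stop("measurement table integrity error: non-positive ", col,
           " in row(s) ", paste(bad, collapse = ", "))
    }
    df[[col]] <- as.numeric(v)
  }
  if (!all(df$side %in% c("L", "R"))) {
    stop("measurement table integrity error: side must be L or R")
  }
  if (!all(df$tooth %in% c("P4", "M1", "M2", "M3"))) {
    stop("measurement table integrity error: tooth must be P4, M1, M2 or M3")
  }
  key <- paste(df$specimen_id, df$side, df$tooth)
  if (anyDuplicated(key)) {
    stop("measurement table integrity error: duplicate (specimen, side, ",
         "tooth) in row(s) ", paste(which(duplicated(key)), collapse = ", "))
  }
  class(df) <- c("measurement_table", "data.frame")
  df
}

#' Write a measurement table to CSV
#'
#' Missing values are written as empty fields so that
#' `read_measurements(write_measurements(x, f))` is the identity.
#'
#' @param x A `measurement_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a pedigree table
#'
#' Columns `id`, `sire`, `dam`, `sex` (F/M), `age` (years, optional).
#' Founders are marked with `0` or an empty parent field. On load the
#' relation graph is checked for cycles and parental sexes for consistency
#' (every referenced sire is M, every dam F).
#'
#' @param path CSV file.
#' @return A validated data frame of class `pedigree_table` with `sire`/
#'   `dam` set to `NA` for founders and a logical `founder` column.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("read_pedigree: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"),
                        colClasses = "character")
  as_pedigree_table(df)
}

#' Validate a data frame as a pedigree table
#' @param df Data frame with `id`, `sire`, `dam`, `sex` and optional `age`.
#' @return `df` with class `pedigree_table`, founder parents as `NA`.
#' @export
as_pedigree_table <- function(df) {
  required <- c("id", "sire", "dam", "sex")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("pedigree schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  df$id <- as.character(df$id)
  for (col in c("sire", "dam")) {
    v <- as.character(df[[col]])
    v[!is.na(v) & v == "0"] <- NA_character_
    df[[col]] <- v
  }
  if (anyDuplicated(df$id)) stop("pedigree integrity error: duplicate ids")
  if (!all(df$sex %in% c("F", "M"))) {
    stop("pedigree integrity error: sex must be F or M")
  }
  if (!is.null(df$age)) {
    df$age <- as.numeric(df$age)
    if (any(df$age < 0, na.rm = TRUE)) {
      stop("pedigree integrity error: negative age")
    }
  }
  for (col in c("sire", "dam")) {
    ref <- df[[col]][!is.na(df[[col]])]
    unresolved <- setdiff(ref, df$id)
    if (length(unresolved) > 0L) {
      stop("pedigree integrity error: unresolved ", col, "(s): ",
           paste(unique(unresolved), collapse = ", "))
    }
  }
  sex_of <- stats::setNames(df$sex, df$id)
  bad_sire <- df$sire[!is.na(df$sire) & sex_of[df$sire] != "M"]
  if (length(bad_sire) > 0L) {
    stop("pedigree consistency error: sire(s) not male: ",
         paste(unique(bad_sire), collapse = ", "))
  }
  bad_dam <- df$dam[!is.na(df$dam) & sex_of[df$dam] != "F"]
  if (length(bad_dam) > 0L) {
    stop("pedigree consistency error: dam(s) not female: ",
         paste(unique(bad_dam), collapse = ", "))
  }
  if (is.null(pedigree_order(df))) {
    stop("pedigree cycle error: an individual is its own ancestor")
  }
  df$founder <- is.na(df$sire) & is.na(df$dam)
  class(df) <- c("pedigree_table", "data.frame")
  df
}

# topological order (parents before offspring), or NULL if the parent
# relation has a cycle
pedigree_order <- function(ped) {
  ids <- ped$id
  n <- length(ids)
  sire_i <- match(ped$sire, ids)
  dam_i <- match(ped$dam, ids)
  parent <- c(sire_i, dam_i)
  child <- rep(seq_len(n), 2L)
  keep <- !is.na(parent)
  parent <- parent[keep]; child <- child[keep]
  indeg <- tabulate(child, nbins = n)
  children <- split(child, factor(parent, levels = seq_len(n)))
  queue <- integer(n)
  head <- 1L; tail <- 0L
  for (i in which(indeg == 0L)) { tail <- tail + 1L; queue[tail] <- i }
  out <- integer(n); n_out <- 0L
  while (head <= tail) {
    i <- queue[head]; head <- head + 1L
    n_out <- n_out + 1L; out[n_out] <- i
    for (j in children[[i]]) {
      indeg[j] <- indeg[j] - 1L
      if (indeg[j] == 0L) { tail <- tail + 1L; queue[tail] <- j }
    }
  }
  if (n_out < n) NULL else ids[out]
}

#' Write a pedigree table to CSV
#' @param x A `pedigree_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(x, path) {
  df <- as.data.frame(x)
  df$founder <- NULL
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
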