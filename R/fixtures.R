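#' Load a packaged reference table
#'
#' Verbatim transcriptions of the printed reference tables ship with the
#' package: the extant sample composition (`table1`), heritability and
#' covariate results for the pedigreed baboon colony (`table3`), genus
#' descriptive statistics for the ratio traits (`table5`), and the
#' ancestral-state-versus-fossil pairings (`table8`). The fossil sample
#' composition (`table2`) is packaged for documentation; note its printed
#' total (1436) differs from the sum of its rows (1476) in the source.
#'
#' @param name One of `"table1"`, `"table2"`, `"table3"`, `"table5"`,
#'   `"table8"`.
#' @return A typed data frame. `table3` is returned as a
#'   `heritability_table`; `table8` carries logical pairing-subset flags.
#' @export
load_fixture <- function(name = c("table1", "table2", "table3", "table5",
                                  "table8")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "cercodent",
                      mustWork = FALSE)
  if (path == "") {
    # during development, before installation
    path <- file.path("inst", "extdata", paste0(name, ".csv"))
  }
  if (!file.exists(path)) stop("load_fixture: fixture not found: ", name)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (name == "table3") {
    df$significant <- as.logical(df$significant)
    class(df) <- c("heritability_table", "data.frame")
  }
  if (name == "table8") {
    df$include_in_mean <- as.logical(df$include_in_mean)
    df$include_in_direction_count <- as.logical(df$include_in_direction_count)
  }
  df
}

#' Pairing specification from the packaged ASR-fossil table
#'
#' Expands the packaged pairing table to the long per-(pairing, trait) form
#' used by [pair_nodes()] and [gap_statistics()]: one row per pairing and
#' trait (MMC, PMM) with ASR value, fossil value, node age and the two
#' subset flags. The mean subset is the 11 internal-node pairings; the
#' direction-count subset is the 12 pairings of the extant-fossil
#' comparison figure (tip pairings included, the deepest
#' Victoriapithecus pairing excluded).
#'
#' @return Data frame with columns `pairing_id`, `trait`, `asr_value`,
#'   `fossil_value`, `node_age`, `fossil_age_mid`, `include_in_mean`,
#'   `include_in_direction_count`.
#' @export
table8_pairing_rows <- function() {
  t8 <- load_fixture("table8")
  long <- do.call(rbind, lapply(c("MMC", "PMM"), function(tr) {
    data.frame(
      pairing_id = t8$pairing_id,
      trait = tr,
      asr_value = if (tr == "MMC") t8$asr_mmc else t8$asr_pmm,
      fossil_value = if (tr == "MMC") t8$fossil_mmc else t8$fossil_pmm,
      node_age = t8$node_age_ma,
      fossil_age_mid = t8$fossil_age_mid_ma,
      include_in_mean = t8$include_in_mean,
      include_in_direction_count = t8$include_in_direction_count,
      stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  long
}
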