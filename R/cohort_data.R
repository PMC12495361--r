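#' Per-volunteer summary values from the ten-volunteer feedback study
#'
#' Returns the published per-volunteer (mean, SD) summary values recorded
#' under three guidance scenarios — audio feedback without table movement,
#' visual feedback without table movement, and visual feedback with table
#' movement. The DIBH table carries breath-hold plateau amplitude (mm) and
#' intra-breath-hold drift (mm/s); the 4DCT table carries per-cycle
#' breathing amplitude (mm) and cycle duration (s). These values serve as
#' reference inputs for [cohort_summary()], whose aggregation rows can be
#' checked against the published cohort statistics.
#'
#' @param mode `"dibh"` or `"4dct"`.
#' @return A data frame with columns `volunteer`, `scenario` and the
#'   mode-specific `*_mean` / `*_sd` columns.
#' @export
volunteer_summaries <- function(mode = c("dibh", "4dct")) {
  mode <- match.arg(mode)
  path <- system.file("extdata",
                      sprintf("volunteer_%s_summary.csv", mode),
                      package = "breathtrace", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
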