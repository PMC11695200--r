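#' Demographic and clinical group tests from summary statistics
#'
#' Recomputes case-control test statistics from per-group mean/SD/n
#' summaries (Welch or pooled two-sample t, per row) and, when gender
#' counts are given, the Pearson chi-square for the 2x2 gender table.
#' The package ships the summary table of the reference hearing-loss
#' case-control cohort (66 patients, 54 controls) as
#' `extdata/cohort_summary_stats.csv`.
#'
#' @param summary Tibble/data frame with columns `characteristic`,
#'   `mean_case`, `sd_case`, `n_case`, `mean_control`, `sd_control`,
#'   `n_control`, `test` (`"welch"` or `"pooled"`); default: the shipped
#'   reference table.
#' @param gender_counts Optional 2-row data frame with columns `group`,
#'   `female`, `male`; default: the shipped reference counts.
#' @return Tibble with `characteristic`, `test`, `statistic`, `df`, `p`.
#' @export
cohort_summary_tests <- function(summary = NULL, gender_counts = NULL) {
  if (is.null(summary)) {
    summary <- readr::read_csv(
      system.file("extdata", "cohort_summary_stats.csv", package = "dynfnc"),
      show_col_types = FALSE, progress = FALSE)
  }
  if (is.null(gender_counts)) {
    gender_counts <- readr::read_csv(
      system.file("extdata", "cohort_gender_counts.csv", package = "dynfnc"),
      show_col_types = FALSE, progress = FALSE)
  }
  rows <- purrr::pmap(summary, function(characteristic, mean_case, sd_case,
                                        n_case, mean_control, sd_control,
                                        n_control, test) {
    f <- if (test == "welch") welch_t else pooled_t
    res <- f(mean_case, sd_case, n_case, mean_control, sd_control, n_control)
    tibble(characteristic = characteristic, test = test,
           statistic = res$t, df = res$df, p = res$p)
  }) |> purrr::list_rbind()
  if (!is.null(gender_counts)) {
    tab <- as.matrix(gender_counts[, c("female", "male")])
    res <- chi_square_2x2(tab)
    rows <- dplyr::bind_rows(
      rows,
      tibble(characteristic = "gender", test = "chisq",
             statistic = res$chisq, df = res$df, p = res$p))
  }
  rows
}
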