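#' Totals and national prevalence of a survey table
#'
#' Column sums plus the pooled prevalence with 95% binomial confidence
#' intervals, computed both ways practitioners quote them: the normal
#' approximation (Wald) and the exact Clopper-Pearson interval. Works on a
#' community-level survey table or a pre-aggregated regional table — any
#' data.frame with a screened and a cases column.
#'
#' @param df data.frame.
#' @param screened,cases column names (defaults fit both the survey schema
#'   `n_screened`/`n_cases` and the regional fixture schema
#'   `total_surveyed`/`cases`).
#' @return list: `n_rows`, `total_screened`, `total_cases`,
#'   `prevalence_pct` (2 dp), `wald_ci_pct`, `clopper_pearson_ci_pct`
#'   (each length-2, 2 dp).
#' @export
survey_totals <- function(df, screened = NULL, cases = NULL) {
  screened <- screened %||% intersect(c("n_screened", "total_surveyed", "screened"),
                                      names(df))[1]
  cases <- cases %||% intersect(c("n_cases", "cases"), names(df))[1]
  if (is.na(screened) || is.na(cases)) {
    stop("survey_totals: could not locate screened/cases columns", call. = FALSE)
  }
  n <- sum(df[[screened]]); k <- sum(df[[cases]])
  p <- k / n
  wald <- p + c(-1, 1) * stats::qnorm(0.975) * sqrt(p * (1 - p) / n)
  cp <- as.numeric(stats::binom.test(k, n)$conf.int)
  list(n_rows = nrow(df), total_screened = n, total_cases = k,
       prevalence_pct = round(100 * p, 2),
       wald_ci_pct = round(100 * pmax(wald, 0), 2),
       clopper_pearson_ci_pct = round(100 * cp, 2))
}

#' Community-level survey summary
#'
#' The narrative statistics of a community survey table: totals and pooled
#' prevalence (via [survey_totals()]), the number and share of zero-case
#' communities, the mean number screened per community, and the share of
#' communities screening at least 100 individuals.
#'
#' @param surveys survey data.frame with `n_screened` and `n_cases`.
#' @return list extending [survey_totals()] with `zero_case_communities`,
#'   `zero_case_share_pct` (1 dp), `mean_screened`, `share_ge100_pct`.
#' @export
survey_summary <- function(surveys) {
  stopifnot(all(c("n_screened", "n_cases") %in% names(surveys)))
  if (any(surveys$n_cases > surveys$n_screened)) {
    stop("survey_summary: n_cases exceeds n_screened", call. = FALSE)
  }
  tot <- survey_totals(surveys, "n_screened", "n_cases")
  zero <- sum(surveys$n_cases == 0)
  c(tot, list(
    zero_case_communities = zero,
    zero_case_share_pct = round(100 * zero / nrow(surveys), 1),
    mean_screened = round(mean(surveys$n_screened)),
    share_ge100_pct = round(100 * mean(surveys$n_screened >= 100), 1)))
}

#' Read a pre-aggregated regional survey table
#'
#' CSV with columns `region`, `clusters`, `total_surveyed`, `cases` (the
#' layout of a published per-region survey summary).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_region_survey_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("region", "clusters", "total_surveyed", "cases")
  if (!all(req %in% names(df))) {
    stop("read_region_survey_csv: need columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  df
}
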