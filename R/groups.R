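#' Date-defined cohort comparison
#'
#' Policies are partitioned by publication date around a cutoff (e.g. the
#' pandemic onset) and each cohort is summarised by descriptive
#' statistics of its two-decimal display index values: the published
#' comparison consumed rounded values, so the summaries do too.
#'
#' @name cohort_analysis
NULL

#' Split scored policies at a cutoff date
#'
#' @param scores a `pmc_scores` whose coding carried metadata.
#' @param cutoff a `Date` or date string; `pre` takes `pub_date < cutoff`,
#'   `post` takes `pub_date >= cutoff`.
#' @return list with `pre` and `post` data frames (rows of
#'   `scores$results` joined with `pub_date`); disjoint and exhaustive.
#' @export
#' @examples
#' sc <- score_policies(integration_policies()$coding)
#' sp <- split_by_date(sc, "2019-12-01")
#' c(pre = nrow(sp$pre), post = nrow(sp$post))
split_by_date <- function(scores, cutoff) {
  stopifnot(inherits(scores, "pmc_scores"))
  if (is.null(scores$meta)) {
    abort_pmc("scores carry no policy metadata; dates unavailable",
              "pmc_group_error")
  }
  cutoff <- parse_policy_date(cutoff)
  df <- scores$results
  idx <- match(df$code, scores$meta$code)
  if (anyNA(scores$meta$pub_date[idx])) {
    abort_pmc(sprintf("missing publication date for: %s",
                      paste(df$code[is.na(scores$meta$pub_date[idx])],
                            collapse = ", ")), "pmc_group_error")
  }
  df$pub_date <- scores$meta$pub_date[idx]
  list(pre = df[df$pub_date < cutoff, , drop = FALSE],
       post = df[df$pub_date >= cutoff, , drop = FALSE])
}

#' Descriptive summary of one cohort
#'
#' Mean, median (midpoint of the central order statistics for even n),
#' sample standard deviation (n - 1 denominator), minimum and maximum of
#' the members' display index values, each rounded half-up to two
#' decimals. A single-member cohort has no dispersion; its SD is
#' reported as 0 with `sd_defined = FALSE`.
#'
#' @param group data frame with a `pmc_display` column (as produced by
#'   [split_by_date()]), or a numeric vector of display values.
#' @param label cohort label for the output row.
#' @return one-row data frame: `label`, `n`, `mean`, `median`, `sd`,
#'   `min`, `max`, `sd_defined`.
#' @export
cohort_summary <- function(group, label = "cohort") {
  v <- if (is.data.frame(group)) group$pmc_display else as.numeric(group)
  if (length(v) == 0) {
    abort_pmc("cannot summarise an empty cohort", "pmc_group_error")
  }
  sd_defined <- length(v) > 1
  data.frame(
    label = label, n = length(v),
    mean = round_half_up(mean(v), 2),
    median = round_half_up(stats::median(v), 2),
    sd = if (sd_defined) round_half_up(stats::sd(v), 2) else 0,
    min = min(v), max = max(v),
    sd_defined = sd_defined
  )
}

#' Pre/post cohort comparison table
#'
#' @param scores a `pmc_scores` with metadata.
#' @param cutoff partition date, default `"2019-12-01"`.
#' @return data frame with one statistic per row and one column per
#'   cohort, in the published layout.
#' @export
#' @examples
#' sc <- score_policies(integration_policies()$coding)
#' compare_cohorts(sc)
compare_cohorts <- function(scores, cutoff = "2019-12-01") {
  sp <- split_by_date(scores, cutoff)
  pre <- cohort_summary(sp$pre, "pre")
  post <- cohort_summary(sp$post, "post")
  stats_names <- c("Mean", "Median", "Standard deviation (SD)",
                   "Minimum value", "Maximum value")
  data.frame(
    Statistics = stats_names,
    pre = unlist(pre[c("mean", "median", "sd", "min", "max")]),
    post = unlist(post[c("mean", "median", "sd", "min", "max")]),
    row.names = NULL,
    check.names = FALSE
  ) -> out
  names(out)[2:3] <- c(sprintf("Pre (n = %d)", pre$n),
                       sprintf("Post (n = %d)", post$n))
  out
}
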