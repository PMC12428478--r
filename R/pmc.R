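#' Index computation
#'
#' The index of a policy is built in two stages. Each scored primary
#' dimension gets the mean of its binary secondary indicators,
#'
#'   X_t = (1 / T(X_t)) * sum_j X_tj,
#'
#' an exact fraction ones/cardinality in \[0, 1\]. The index is then the
#' plain (equal-weight) sum of the nine scored primaries, a rational in
#' \[0, 9\], and the indentation (concavity) index is its complement
#' 9 - index: the shortfall from the ideal policy. All arithmetic is
#' exact integer numerator/denominator work; decimal rounding (half-up,
#' two places) happens only for display and grade classification.
#'
#' @name pmc_index_model
#' @seealso [score_policies()], [classify_pmc()]
NULL

#' Score of one primary dimension from its indicator bits
#'
#' @param bits integer vector of 0/1 indicator values for one primary.
#' @return the exact fraction as a numeric value, with attributes
#'   `numerator` and `denominator`.
#' @export
#' @examples
#' primary_score(c(0, 1, 0))   # 1/3
primary_score <- function(bits) {
  if (length(bits) == 0) {
    abort_pmc("primary has no indicator bits to score", "pmc_score_error")
  }
  if (anyNA(bits) || !all(bits %in% c(0, 1))) {
    abort_pmc("indicator bits must all be 0 or 1", "pmc_score_error")
  }
  structure(sum(bits) / length(bits),
            numerator = as.integer(sum(bits)),
            denominator = length(bits))
}

# Exact per-policy numerators/denominators over the scored primaries,
# overrides applied. Returns list(num, den): integer matrices
# policies x scored primaries.
primary_fractions <- function(coding, schema) {
  card <- cardinalities(schema)
  codes <- rownames(coding$values)
  num <- matrix(0L, length(codes), length(card),
                dimnames = list(codes, names(card)))
  den <- matrix(rep(card, each = length(codes)), length(codes),
                dimnames = list(codes, names(card)))
  for (t in names(card)) {
    cols <- paste0(t, ":", seq_len(card[[t]]))
    num[, t] <- as.integer(rowSums(coding$values[, cols, drop = FALSE]))
  }
  ov <- coding$overrides
  if (!is.null(ov)) {
    for (i in seq_len(nrow(ov))) {
      if (!ov$code[i] %in% codes || !ov$primary[i] %in% names(card)) next
      num[ov$code[i], ov$primary[i]] <- as.integer(ov$numerator[i])
      den[ov$code[i], ov$primary[i]] <- as.integer(ov$denominator[i])
    }
  }
  storage.mode(den) <- "integer"
  list(num = num, den = den)
}

#' Index of one policy from its primary scores
#'
#' @param scores named numeric vector of primary scores (values in
#'   \[0, 1\]) covering every scored primary of `schema`.
#' @param schema a `pmc_schema`.
#' @return the index value (sum over the scored primaries).
#' @export
#' @examples
#' sch <- default_schema()
#' s <- c(X1 = 1, X2 = 1/3, X3 = 1/3, X4 = 1, X5 = 1, X6 = 1, X7 = 1,
#'        X8 = 1, X9 = 1)
#' pmc_index(s, sch)   # 23/3
pmc_index <- function(scores, schema) {
  miss <- setdiff(schema$scored_ids, names(scores))
  if (length(miss)) {
    abort_pmc(sprintf("missing scored primaries: %s",
                      paste(miss, collapse = ", ")), "pmc_score_error")
  }
  if (any(scores[schema$scored_ids] < 0 | scores[schema$scored_ids] > 1)) {
    abort_pmc("primary scores must lie in [0, 1]", "pmc_score_error")
  }
  sum(scores[schema$scored_ids])
}

#' Indentation (concavity) index
#'
#' The complement of the index on its 0-9 scale: how far the policy
#' falls short of scoring 1 on every dimension.
#'
#' @param pmc index value in \[0, 9\].
#' @return `9 - pmc`.
#' @export
indentation_index <- function(pmc) {
  if (any(pmc < 0 | pmc > 9)) {
    abort_pmc("index values must lie in [0, 9]", "pmc_score_error")
  }
  9 - pmc
}

#' Grade classification of index and indentation values
#'
#' Bands are defined on the two-decimal display value, boundaries
#' inclusive as published: 8.00-9.00 Excellent, 6.00-7.99 Good,
#' 4.00-5.99 Acceptable, below 4.00 Poor. The indentation grades
#' partition \[0, 9\] at 1.00, 3.00 and 5.00.
#'
#' @param x two-decimal display values in \[0, 9\].
#' @return character vector of grades.
#' @export
#' @examples
#' classify_pmc(c(7.67, 5.78, 8.00, 3.99))
classify_pmc <- function(x) {
  if (any(x < 0 | x > 9)) {
    abort_pmc("index values must lie in [0, 9]", "pmc_score_error")
  }
  ifelse(x >= 8, "Excellent",
         ifelse(x >= 6, "Good",
                ifelse(x >= 4, "Acceptable", "Poor")))
}

#' @rdname classify_pmc
#' @export
classify_indentation <- function(x) {
  if (any(x < 0 | x > 9)) {
    abort_pmc("indentation values must lie in [0, 9]", "pmc_score_error")
  }
  ifelse(x <= 1, "Low depression",
         ifelse(x <= 3, "Central depression",
                ifelse(x <= 5, "Acceptable level of indentation",
                       "Unacceptable level of indentation")))
}

#' Score a whole policy set
#'
#' Computes every policy's primary scores, index, indentation index and
#' grades, ranked by descending index (ties broken by policy code), plus
#' the per-primary column means and the overall mean index /
#' indentation used for the radar chart.
#'
#' @param coding a `pmc_coding`.
#' @param schema a `pmc_schema`; defaults to the bundled schema.
#' @return a `pmc_scores` object: list with
#'   \describe{
#'     \item{results}{data frame, one ranked row per policy: `rank`,
#'       `code`, one two-decimal column per scored primary, `pmc`
#'       (unrounded), `pmc_display`, `grade`, `indentation` (unrounded),
#'       `indentation_display`, `indentation_grade`, `disclosed`.}
#'     \item{column_means}{named numeric: unrounded mean of each
#'       primary column plus `pmc` and `indentation` means.}
#'     \item{exact}{integer numerators/denominators behind every value.}
#'     \item{meta}{the policy metadata, if the coding carried any.}
#'   }
#' @export
#' @examples
#' fix <- integration_policies()
#' sc <- score_policies(fix$coding)
#' head(sc$results[, c("rank", "code", "pmc_display", "grade")])
score_policies <- function(coding, schema = default_schema()) {
  stopifnot(inherits(coding, "pmc_coding"))
  fr <- primary_fractions(coding, schema)
  codes <- rownames(fr$num)
  # common denominator across all policies so exact comparison is integer
  L <- lcm_all(unique(as.vector(fr$den)))
  scaled <- fr$num * (L %/% fr$den)          # per-primary num over L
  pmc_num <- as.integer(rowSums(scaled))     # pmc = pmc_num / L
  # ties broken by policy code ascending, numerically where codes carry
  # a numeric suffix (P9 before P25)
  code_num <- suppressWarnings(as.numeric(sub("^\\D*", "", codes)))
  ord <- if (anyNA(code_num)) order(-pmc_num, codes) else
    order(-pmc_num, code_num)

  pmc <- pmc_num / L
  pmc_disp <- rat_display2(pmc_num, L)
  ind_num <- 9L * L - pmc_num
  ind_disp <- rat_display2(ind_num, L)

  prim_disp <- rat_display2(fr$num, fr$den)
  dim(prim_disp) <- dim(fr$num)
  dimnames(prim_disp) <- dimnames(fr$num)

  disclosed <- if (!is.null(coding$meta)) coding$meta$disclosed else
    rep(NA, length(codes))

  results <- data.frame(
    rank = seq_along(codes),
    code = codes[ord],
    prim_disp[ord, , drop = FALSE],
    pmc = pmc[ord],
    pmc_display = pmc_disp[ord],
    grade = classify_pmc(pmc_disp[ord]),
    indentation = (ind_num / L)[ord],
    indentation_display = ind_disp[ord],
    indentation_grade = classify_indentation(ind_disp[ord]),
    disclosed = disclosed[ord],
    check.names = FALSE, row.names = NULL
  )

  col_num <- colSums(scaled)                 # column mean = col_num/(n*L)
  n <- length(codes)
  column_means <- c(col_num / (n * L),
                    pmc = sum(pmc_num) / (n * L),
                    indentation = sum(ind_num) / (n * L))

  structure(list(results = results,
                 column_means = column_means,
                 exact = list(num = fr$num, den = fr$den,
                              pmc_num = stats::setNames(pmc_num, codes),
                              common_den = L),
                 meta = coding$meta,
                 schema_ids = schema$scored_ids),
            class = "pmc_scores")
}

#' Write scored results to CSV
#'
#' Mirrors the published result-table layout: ranking, code, the nine
#' primary columns, index, grade, indentation index, indentation grade.
#'
#' @param scores a `pmc_scores`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  stopifnot(inherits(scores, "pmc_scores"))
  df <- scores$results
  out <- data.frame(
    Ranking = df$rank, Code = df$code,
    df[, scores$schema_ids, drop = FALSE],
    `PMC Index` = sprintf("%.2f", df$pmc_display),
    Evaluation = df$grade,
    `Policy indentation index` = sprintf("%.2f", df$indentation_display),
    `Indentation evaluation` = df$indentation_grade,
    check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Export full-precision results as JSON
#'
#' @param scores a `pmc_scores`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
export_scores_json <- function(scores, path) {
  stopifnot(inherits(scores, "pmc_scores"))
  jsonlite::write_json(
    list(results = scores$results,
         column_means = as.list(scores$column_means)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.pmc_scores <- function(x, ...) {
  cat(sprintf("<pmc_scores>: %d policies, mean index %.2f, mean indentation %.2f\n",
              nrow(x$results),
              round_half_up(x$column_means[["pmc"]], 2),
              round_half_up(x$column_means[["indentation"]], 2)))
  print(utils::head(x$results[, c("rank", "code", "pmc_display", "grade",
                                  "indentation_display")], 10))
  invisible(x)
}
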