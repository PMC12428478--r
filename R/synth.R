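#' Synthetic corpora and codings with known ground truth
#'
#' Generators for testing every pipeline stage without external data:
#' a multi-document corpus whose tokens follow a Zipf law over a
#' controlled vocabulary, and random binary coding matrices whose
#' per-primary fill probabilities give an analytic expected index
#' E\[index\] = sum of fills. The generators return the ground truth
#' alongside the data so tests never re-derive it from generator
#' internals.
#'
#' @name synthetic_data
NULL

#' Configuration for the synthetic generators
#'
#' @param n_policies number of documents / policies.
#' @param vocabulary character vector of distinct terms.
#' @param zipf_exponent positive Zipf exponent `s`; term of rank `r` is
#'   drawn with probability proportional to `r^-s`.
#' @param doc_length tokens per document.
#' @param per_primary_fill named numeric vector of Bernoulli fill
#'   probabilities, one per scored primary.
#' @param seed integer seed fixing all randomness.
#' @param sentence_every insert a sentence break after this many tokens.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_policies = 28,
                         vocabulary = sprintf("term%03d", 1:80),
                         zipf_exponent = 1,
                         doc_length = 400,
                         per_primary_fill = stats::setNames(
                           rep(0.7, 9), paste0("X", 1:9)),
                         seed = 1,
                         sentence_every = 12) {
  if (!length(vocabulary)) {
    abort_pmc("vocabulary must be nonempty", "pmc_synth_error")
  }
  if (anyDuplicated(vocabulary)) {
    abort_pmc("vocabulary terms must be distinct", "pmc_synth_error")
  }
  if (zipf_exponent <= 0) {
    abort_pmc("zipf_exponent must be positive", "pmc_synth_error")
  }
  if (any(per_primary_fill < 0 | per_primary_fill > 1)) {
    abort_pmc("fill probabilities must lie in [0, 1]", "pmc_synth_error")
  }
  structure(list(n_policies = n_policies, vocabulary = vocabulary,
                 zipf_exponent = zipf_exponent, doc_length = doc_length,
                 per_primary_fill = per_primary_fill, seed = seed,
                 sentence_every = sentence_every),
            class = "synth_config")
}

#' Generate a Zipf-distributed synthetic corpus
#'
#' Tokens are drawn i.i.d. with probability proportional to
#' `rank^-zipf_exponent`; a sentence break (". ") is inserted every
#' `sentence_every` tokens. Identical configs (including seed) give
#' bit-identical corpora.
#'
#' @param config a `synth_config`.
#' @return data frame with `doc_id`, `text`, usable wherever a corpus is
#'   expected.
#' @export
synth_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  probs <- seq_along(config$vocabulary)^(-config$zipf_exponent)
  probs <- probs / sum(probs)
  docs <- vapply(seq_len(config$n_policies), function(i) {
    toks <- sample(config$vocabulary, config$doc_length, replace = TRUE,
                   prob = probs)
    groups <- split(toks, ceiling(seq_along(toks) / config$sentence_every))
    paste(vapply(groups, paste, character(1), collapse = " "),
          collapse = ". ")
  }, character(1))
  data.frame(doc_id = sprintf("P%d", seq_len(config$n_policies)),
             text = docs, row.names = NULL)
}

#' Generate a random binary coding matrix with known expected index
#'
#' Each secondary bit of primary `t` is Bernoulli(`per_primary_fill[t]`).
#' The analytic expectation of the index is the sum of the fill
#' probabilities over the scored primaries, returned alongside the
#' matrix.
#'
#' @param config a `synth_config` whose `per_primary_fill` covers every
#'   scored primary of `schema`.
#' @param schema a `pmc_schema`.
#' @return list with `coding` (a `pmc_coding` with synthetic metadata)
#'   and `expected_pmc` (numeric).
#' @export
synth_coding <- function(config, schema = default_schema()) {
  stopifnot(inherits(config, "synth_config"))
  fills <- config$per_primary_fill
  miss <- setdiff(schema$scored_ids, names(fills))
  if (length(miss)) {
    abort_pmc(sprintf("per_primary_fill missing primaries: %s",
                      paste(miss, collapse = ", ")), "pmc_synth_error")
  }
  set.seed(config$seed)
  card <- cardinalities(schema)
  sids <- secondary_ids(schema)
  codes <- sprintf("P%d", seq_len(config$n_policies))
  values <- matrix(0L, config$n_policies, length(sids),
                   dimnames = list(codes, sids))
  for (t in names(card)) {
    cols <- paste0(t, ":", seq_len(card[[t]]))
    values[, cols] <- stats::rbinom(config$n_policies * card[[t]], 1,
                                    fills[[t]])
  }
  meta <- data.frame(
    code = codes,
    name = paste("synthetic policy", codes),
    pub_date = as.Date("2015-01-01") + seq_len(config$n_policies) * 30,
    disclosed = TRUE)
  list(coding = pmc_coding(values, schema, meta = meta),
       expected_pmc = sum(fills[schema$scored_ids]))
}
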