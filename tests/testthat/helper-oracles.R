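# Independent brute-force oracles. Deliberately written as plain nested
# loops over raw inputs, sharing no code with the package internals.

# Index of every policy: mean of bits within each primary, then sum.
oracle_pmc <- function(values, card) {
  out <- numeric(nrow(values))
  for (i in seq_len(nrow(values))) {
    total <- 0
    for (t in names(card)) {
      s <- 0
      for (j in seq_len(card[[t]])) {
        s <- s + values[i, paste0(t, ":", j)]
      }
      total <- total + s / card[[t]]
    }
    out[i] <- total
  }
  names(out) <- rownames(values)
  out
}

# Dictionary count of tokens (post clean/stop/synonym), one doc at a time.
oracle_term_counts <- function(texts, stopwords = character(),
                               synonyms = character()) {
  counts <- new.env(parent = emptyenv())
  for (txt in texts) {
    toks <- tolower(regmatches(txt, gregexpr("[[:alnum:]]+", txt))[[1]])
    for (tok in toks) {
      if (tok %in% names(synonyms)) tok <- unname(synonyms[[tok]])
      if (tok %in% stopwords) next
      counts[[tok]] <- (if (is.null(counts[[tok]])) 0L else counts[[tok]]) + 1L
    }
  }
  out <- vapply(ls(counts), function(k) counts[[k]], integer(1))
  sort(out, decreasing = TRUE)
}

# Pairwise window scan: weight(a, b) = number of sentence windows
# containing both terms.
oracle_cooccurrence <- function(texts, terms, delims = "[.!?;]") {
  k <- length(terms)
  w <- matrix(0L, k, k, dimnames = list(terms, terms))
  for (txt in texts) {
    for (s in strsplit(txt, delims)[[1]]) {
      toks <- tolower(regmatches(s, gregexpr("[[:alnum:]]+", s))[[1]])
      for (a in seq_len(k - 1)) for (b in (a + 1):k) {
        if (terms[a] %in% toks && terms[b] %in% toks) {
          w[a, b] <- w[a, b] + 1L
          w[b, a] <- w[b, a] + 1L
        }
      }
    }
  }
  w
}

# Random binary coding over the default schema, as a pmc_coding.
random_coding <- function(n, schema, seed) {
  set.seed(seed)
  sids <- secondary_ids(schema)
  values <- matrix(sample(0:1, n * length(sids), replace = TRUE), n,
                   dimnames = list(sprintf("R%d", seq_len(n)), sids))
  pmc_coding(values, schema)
}

default_card <- function() cardinalities(default_schema())
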