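test_that("metadata lines are removed, everything else preserved", {
  cfg <- preprocess_config(metadata_patterns = c("^Document number",
                                                 "^Issuing"))
  doc <- "Document number 12\nbody line one\nbody line two"
  expect_equal(clean_text(doc, cfg), "body line one\nbody line two")
  # no matches: identity
  plain <- "body line one\nbody line two"
  expect_equal(clean_text(plain, cfg), plain)
  # three lines, two metadata: one survives
  doc3 <- "Document number 9\nIssuing department X\nonly content"
  expect_equal(clean_text(doc3, cfg), "only content")
  expect_equal(length(strsplit(clean_text(doc3, cfg), "\n")[[1]]), 1L)
})

test_that("tokenization preserves order and matches a regex oracle", {
  expect_equal(tokenize_words("older adult care service"),
               c("older", "adult", "care", "service"))
  expect_equal(tokenize_words(""), character(0))
  messy <- "Care, and: service; (older-adult) CARE!  2025 plans."
  oracle <- tolower(regmatches(messy,
                               gregexpr("[[:alnum:]]+", messy))[[1]])
  expect_equal(tokenize_words(messy), oracle)
})

test_that("term frequencies count, canonicalise and rank correctly", {
  corp <- data.frame(doc_id = "d1", text = "a b b c c c")
  ts <- term_frequencies(corp, preprocess_config(stopwords = "a",
                                                 top_n = 2))
  expect_equal(ts$rank, 1:2)
  expect_equal(ts$term, c("c", "b"))
  expect_equal(ts$frequency, c(3L, 2L))
  expect_equal(attr(ts, "total_tokens"), 5L)

  # synonym variants collapse onto the canonical term before counting
  corp2 <- data.frame(doc_id = "d1", text = "system mechanism")
  ts2 <- term_frequencies(corp2, preprocess_config(
    synonyms = c(mechanism = "system")))
  expect_equal(ts2$term, "system")
  expect_equal(ts2$frequency, 2L)

  # frequency ties break lexicographically
  corp3 <- data.frame(doc_id = "d1", text = "beta alpha")
  ts3 <- term_frequencies(corp3, preprocess_config())
  expect_equal(ts3$term, c("alpha", "beta"))

  # chained synonym maps are rejected up front
  expect_error(preprocess_config(synonyms = c(a = "b", b = "c")),
               "chain", class = "pmc_text_error")
})

test_that("corpus-wide counts equal the dictionary-count oracle", {
  cfg0 <- synth_config(n_policies = 6, doc_length = 300, seed = 42)
  corp <- synth_corpus(cfg0)
  stop <- c("term001", "term007")
  syn <- c(term002 = "term003")
  ts <- term_frequencies(corp, preprocess_config(
    stopwords = stop, synonyms = syn, top_n = 1000))
  expected <- oracle_term_counts(corp$text, stopwords = stop,
                                 synonyms = syn)
  got <- setNames(ts$frequency, ts$term)
  expect_equal(sort(got, decreasing = TRUE)[names(expected)], expected)
  expect_equal(sum(ts$frequency), sum(expected))
})

test_that("co-occurrence windows are sentences and weights count windows", {
  cfg <- preprocess_config()
  corp <- data.frame(doc_id = "d", text = "x y. x z.")
  g <- cooccurrence_network(corp, c("x", "y", "z"), cfg)
  ed <- igraph::as_data_frame(g, "edges")
  key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
  expect_setequal(key, c("x y", "x z"))
  expect_equal(ed$weight, c(1, 1))

  # one sentence containing every term: complete graph, unit weights
  corp2 <- data.frame(doc_id = "d", text = "p q r")
  g2 <- cooccurrence_network(corp2, c("p", "q", "r"), cfg)
  expect_equal(igraph::ecount(g2), 3)
  expect_true(all(igraph::E(g2)$weight == 1))

  # terms that never co-occur stay as isolated vertices
  corp3 <- data.frame(doc_id = "d", text = "only alpha here. beta.")
  g3 <- cooccurrence_network(corp3, c("alpha", "beta", "gamma"), cfg)
  expect_equal(igraph::vcount(g3), 3)
  expect_equal(igraph::degree(g3)[["gamma"]], 0)
  expect_error(cooccurrence_network(corp3, character(0), cfg),
               "nonempty", class = "pmc_text_error")
})

test_that("network weights equal the pairwise window-scan oracle", {
  cfg0 <- synth_config(n_policies = 5, doc_length = 250, seed = 17,
                       vocabulary = sprintf("w%02d", 1:20))
  corp <- synth_corpus(cfg0)
  terms <- sprintf("w%02d", 1:8)
  g <- cooccurrence_network(corp, terms, preprocess_config())
  want <- oracle_cooccurrence(corp$text, terms)
  got <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  expect_equal(got[terms, terms], want)
  # symmetry holds in both representations
  expect_equal(got, t(got))
})

test_that("counts are permutation-invariant and monotone in the corpus", {
  cfg0 <- synth_config(n_policies = 8, doc_length = 200, seed = 3)
  corp <- synth_corpus(cfg0)
  cfg <- preprocess_config(top_n = 50)
  ts <- term_frequencies(corp, cfg)
  set.seed(4)
  shuffled <- corp[sample(nrow(corp)), ]
  expect_equal(term_frequencies(shuffled, cfg), ts)

  terms <- ts$term[1:6]
  g <- cooccurrence_network(corp, terms, cfg)
  g_sh <- cooccurrence_network(shuffled, terms, cfg)
  a <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  expect_equal(igraph::as_adjacency_matrix(g_sh, attr = "weight",
                                           sparse = FALSE)[terms, terms],
               a[terms, terms])

  # adding a document never decreases a count or a weight
  extra <- rbind(corp, data.frame(doc_id = "extra",
                                  text = corp$text[1]))
  ts2 <- term_frequencies(extra, cfg)
  common <- intersect(ts$term, ts2$term)
  f1 <- setNames(ts$frequency, ts$term)
  f2 <- setNames(ts2$frequency, ts2$term)
  expect_true(all(f2[common] >= f1[common]))
  g2 <- cooccurrence_network(extra, terms, cfg)
  a2 <- igraph::as_adjacency_matrix(g2, attr = "weight", sparse = FALSE)
  expect_true(all(a2[terms, terms] >= a[terms, terms]))

  # conservation: retained frequencies never exceed the token total
  expect_lte(sum(ts$frequency), attr(ts, "total_tokens"))
})

test_that("term tables and networks export to standard formats", {
  corp <- data.frame(doc_id = "d", text = "x y. x z. x y.")
  ts <- term_frequencies(corp, preprocess_config())
  csv <- withr::local_tempfile(fileext = ".csv")
  write_term_stats(ts, csv)
  back <- read.csv(csv)
  expect_equal(back$term, ts$term)
  expect_equal(back$frequency, ts$frequency)

  g <- cooccurrence_network(corp, c("x", "y", "z"), preprocess_config())
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(g, gml, "graphml")
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  edges <- withr::local_tempfile(fileext = ".csv")
  write_network(g, edges, "csv")
  el <- read.csv(edges)
  expect_named(el, c("source", "target", "weight"))
  expect_equal(el$weight[el$source == "x" & el$target == "y"], 2)
})
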