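#' Corpus preprocessing and term statistics
#'
#' The text-mining stage that motivates the evaluation dimensions:
#' strip document metadata lines, segment into tokens, canonicalise
#' synonyms, drop stopwords, rank terms by corpus-wide frequency, and
#' build a sentence-window co-occurrence network over the retained
#' high-frequency terms.
#'
#' @name textmine
NULL

#' Read a directory of UTF-8 text files as a corpus
#'
#' One document per `.txt` file; the file name (minus extension) is the
#' document id, conventionally the policy code.
#'
#' @param dir directory path.
#' @return data frame with columns `doc_id`, `text`.
#' @export
read_corpus <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (!length(files)) {
    abort_pmc(sprintf("no .txt files under %s", dir), "pmc_text_error")
  }
  data.frame(
    doc_id = sub("\\.txt$", "", basename(files)),
    text = vapply(files, function(f) {
      paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n")
    }, character(1)),
    row.names = NULL
  )
}

#' Preprocessing configuration
#'
#' @param metadata_patterns character vector of regular expressions; a
#'   line matching any of them is removed by [clean_text()]. Intended
#'   for boilerplate headers (document number, issuing department,
#'   issuing time).
#' @param stopwords character vector of terms dropped before counting.
#' @param synonyms named character vector mapping variant term to
#'   canonical term (e.g. `c(mechanism = "system")`). Chains are
#'   rejected: a canonical target may not itself be a variant.
#' @param min_token_length minimum token length retained.
#' @param top_n number of ranked terms kept by [term_frequencies()].
#' @param sentence_delims characters splitting text into co-occurrence
#'   windows; defaults cover CJK and Latin sentence enders.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(metadata_patterns = character(),
                              stopwords = character(),
                              synonyms = character(),
                              min_token_length = 1,
                              top_n = 30,
                              sentence_delims = "。！？；.!?;") {
  if (top_n < 1) abort_pmc("top_n must be >= 1", "pmc_text_error")
  if (length(synonyms)) {
    if (is.null(names(synonyms)) || any(names(synonyms) == "")) {
      abort_pmc("synonyms must be a named vector (variant -> canonical)",
                "pmc_text_error")
    }
    chained <- intersect(unname(synonyms), names(synonyms))
    if (length(chained)) {
      abort_pmc(sprintf("synonym chains not allowed: %s",
                        paste(chained, collapse = ", ")), "pmc_text_error")
    }
  }
  structure(list(metadata_patterns = metadata_patterns,
                 stopwords = stopwords, synonyms = synonyms,
                 min_token_length = min_token_length, top_n = top_n,
                 sentence_delims = sentence_delims),
            class = "preprocess_config")
}

#' Remove metadata lines from a document
#'
#' @param text raw document text.
#' @param config a `preprocess_config`.
#' @return cleaned text with matching lines dropped, order preserved.
#' @export
clean_text <- function(text, config) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (!length(config$metadata_patterns) || !length(lines)) {
    return(paste(lines, collapse = "\n"))
  }
  drop <- Reduce(`|`, lapply(config$metadata_patterns, grepl, x = lines),
                 accumulate = FALSE)
  paste(lines[!drop], collapse = "\n")
}

#' Default word tokenizer
#'
#' Splits on anything that is not a letter or digit and lowercases.
#' Suitable for space-delimited text; for CJK corpora supply a
#' segmenter via the `tokenizer` argument of the downstream functions.
#'
#' @param text character scalar.
#' @return character vector of tokens, in document order.
#' @export
tokenize_words <- function(text) {
  toks <- regmatches(text, gregexpr("[\\p{L}\\p{N}]+", text, perl = TRUE))[[1]]
  tolower(toks)
}

# clean + tokenize + normalise one document; stopword/synonym handling
# shared by counting and network construction.
normalize_tokens <- function(text, config, tokenizer) {
  toks <- tokenizer(clean_text(text, config))
  toks <- toks[nchar(toks) >= config$min_token_length]
  if (length(config$synonyms)) {
    hit <- toks %in% names(config$synonyms)
    toks[hit] <- unname(config$synonyms[toks[hit]])
  }
  toks[!toks %in% config$stopwords]
}

#' Ranked corpus-wide term frequencies
#'
#' Counts canonicalised, stopword-filtered tokens over the whole corpus,
#' ranks descending with ties broken by lexicographic term order, and
#' truncates to `config$top_n`.
#'
#' @param corpus data frame with `doc_id`, `text` columns.
#' @param config a `preprocess_config`.
#' @param tokenizer function mapping text to a token vector; defaults to
#'   [tokenize_words()].
#' @return a `term_stats` data frame (`rank`, `term`, `frequency`) with
#'   attribute `total_tokens` (token count after stopword removal).
#' @export
#' @examples
#' corp <- data.frame(doc_id = "d1", text = "a b b c c c")
#' term_frequencies(corp, preprocess_config(stopwords = "a", top_n = 2))
term_frequencies <- function(corpus, config = preprocess_config(),
                             tokenizer = tokenize_words) {
  if (anyDuplicated(corpus$doc_id)) {
    abort_pmc("duplicate document ids in corpus", "pmc_text_error")
  }
  toks <- unlist(lapply(corpus$text, normalize_tokens,
                        config = config, tokenizer = tokenizer))
  if (!length(toks)) {
    out <- data.frame(rank = integer(), term = character(),
                      frequency = integer())
    attr(out, "total_tokens") <- 0L
    class(out) <- c("term_stats", "data.frame")
    return(out)
  }
  tab <- table(toks)
  df <- data.frame(term = names(tab), frequency = as.integer(tab))
  df <- df[order(-df$frequency, df$term), , drop = FALSE]
  df <- utils::head(df, config$top_n)
  out <- data.frame(rank = seq_len(nrow(df)), term = df$term,
                    frequency = df$frequency, row.names = NULL)
  attr(out, "total_tokens") <- length(toks)
  class(out) <- c("term_stats", "data.frame")
  out
}

#' Sentence-window co-occurrence network
#'
#' Splits each cleaned document into sentence windows on the configured
#' delimiters and connects two retained terms with weight equal to the
#' number of windows containing both at least once. Terms never
#' co-occurring stay as isolated vertices.
#'
#' @param corpus data frame with `doc_id`, `text`.
#' @param terms character vector of terms to track (typically the
#'   `term` column of [term_frequencies()]).
#' @param config a `preprocess_config` (delimiters, stopwords,
#'   synonyms).
#' @param tokenizer token segmenter, defaults to [tokenize_words()].
#' @return an undirected [igraph::igraph] graph with vertex attribute
#'   `frequency` (total occurrences in windows) and edge attribute
#'   `weight`.
#' @export
#' @examples
#' corp <- data.frame(doc_id = "d", text = "x y. x z.")
#' g <- cooccurrence_network(corp, c("x", "y", "z"), preprocess_config())
#' igraph::as_data_frame(g, "edges")
cooccurrence_network <- function(corpus, terms,
                                 config = preprocess_config(),
                                 tokenizer = tokenize_words) {
  if (!length(terms)) {
    abort_pmc("term set must be nonempty", "pmc_text_error")
  }
  terms <- unique(terms)
  delim_class <- paste0("[", gsub("([\\^\\]\\\\-])", "\\\\\\1",
                                  config$sentence_delims), "]")
  k <- length(terms)
  w <- matrix(0L, k, k, dimnames = list(terms, terms))
  freq <- stats::setNames(integer(k), terms)
  for (txt in corpus$text) {
    sentences <- strsplit(clean_text(txt, config), delim_class,
                          perl = TRUE)[[1]]
    for (s in sentences) {
      toks <- normalize_tokens(s, config, tokenizer)
      toks <- toks[toks %in% terms]
      if (!length(toks)) next
      tab <- table(toks)
      freq[names(tab)] <- freq[names(tab)] + as.integer(tab)
      present <- names(tab)
      if (length(present) > 1) {
        w[present, present] <- w[present, present] + 1L
      }
    }
  }
  diag(w) <- 0L
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  igraph::V(g)$frequency <- as.integer(freq[igraph::V(g)$name])
  g
}

#' Export term statistics and networks
#'
#' @param stats a `term_stats` data frame.
#' @param path output CSV path (`rank,term,frequency`).
#' @return `path`, invisibly.
#' @export
write_term_stats <- function(stats, path) {
  utils::write.csv(as.data.frame(stats)[, c("rank", "term", "frequency")],
                   path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_term_stats
#' @param network an igraph graph from [cooccurrence_network()].
#' @param format `"graphml"` or `"csv"` (edge list
#'   `source,target,weight`).
#' @export
write_network <- function(network, path, format = c("graphml", "csv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    ed <- igraph::as_data_frame(network, what = "edges")
    names(ed)[1:2] <- c("source", "target")
    utils::write.csv(ed, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}
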