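#' Binary coding matrices
#'
#' A coding matrix holds the expert judgement of each policy against
#' every secondary indicator: a policies-by-indicators matrix of 0/1
#' cells. Cells are never imputed — a missing cell is an error, since a
#' silent zero would fabricate a score. A matrix may carry score
#' overrides: explicit numerator/denominator replacements for single
#' (policy, primary) cells whose published value is not expressible as a
#' ones-count over the schema cardinality.
#'
#' @name pmc_coding
#' @seealso [load_coding()], [score_policies()]
NULL

#' Construct a coding matrix object
#'
#' @param values integer matrix of 0/1 cells, rownames = policy codes,
#'   colnames = secondary ids.
#' @param meta optional data frame with columns `code`, `name`,
#'   `pub_date` (and optionally `disclosed`, the policy-level disclosure
#'   boolean for the indicator-only primary).
#' @param schema the `pmc_schema` the matrix is scored against.
#' @param overrides optional data frame with columns `code`, `primary`,
#'   `numerator`, `denominator` replacing the computed ratio for single
#'   cells.
#' @return a `pmc_coding` object.
#' @export
pmc_coding <- function(values, schema, meta = NULL, overrides = NULL) {
  stopifnot(inherits(schema, "pmc_schema"))
  sids <- secondary_ids(schema)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    abort_pmc("coding rows must carry unique policy codes", "pmc_coding_error")
  }
  missing_cols <- setdiff(sids, colnames(values))
  if (length(missing_cols)) {
    abort_pmc(sprintf("coding is missing indicator columns: %s",
                      paste(missing_cols, collapse = ", ")),
              "pmc_coding_error")
  }
  unknown <- setdiff(colnames(values), sids)
  if (length(unknown)) {
    abort_pmc(sprintf("unknown indicator columns: %s",
                      paste(unknown, collapse = ", ")),
              "pmc_coding_error")
  }
  values <- values[, sids, drop = FALSE]
  bad <- which(is.na(values) | !(values %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(bad)) {
    cell <- bad[1, ]
    abort_pmc(sprintf(
      "cell (%s, %s) is %s; coding values must be 0 or 1 and present",
      rownames(values)[cell[1]], colnames(values)[cell[2]],
      format(values[cell[1], cell[2]])), "pmc_coding_error")
  }
  storage.mode(values) <- "integer"
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    if (!all(c("code", "pub_date") %in% names(meta))) {
      abort_pmc("metadata needs columns code and pub_date", "pmc_coding_error")
    }
    meta$pub_date <- parse_policy_date(meta$pub_date)
    if (!"disclosed" %in% names(meta)) meta$disclosed <- TRUE
    extra <- setdiff(rownames(values), meta$code)
    if (length(extra)) {
      abort_pmc(sprintf("policies without metadata: %s",
                        paste(extra, collapse = ", ")), "pmc_coding_error")
    }
    meta <- meta[match(rownames(values), meta$code), , drop = FALSE]
    rownames(meta) <- NULL
  }
  if (!is.null(overrides)) {
    overrides <- as.data.frame(overrides)
    stopifnot(all(c("code", "primary", "numerator", "denominator") %in%
                    names(overrides)))
  }
  structure(list(values = values, meta = meta, overrides = overrides,
                 schema_name = schema$name),
            class = "pmc_coding")
}

#' Parse policy publication dates
#'
#' Accepts the dotted `YYYY.MM.DD` dialect used in policy registries as
#' well as ISO `YYYY-MM-DD`.
#'
#' @param x character or Date vector.
#' @return a `Date` vector; unparseable entries raise an error.
#' @export
parse_policy_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  out <- as.Date(gsub(".", "-", x, fixed = TRUE), format = "%Y-%m-%d")
  if (anyNA(out)) {
    abort_pmc(sprintf("unparseable date(s): %s",
                      paste(x[is.na(out)], collapse = ", ")),
              "pmc_coding_error")
  }
  out
}

#' Load a coding matrix from CSV or JSON
#'
#' CSV layout: first column `code`, remaining columns named by secondary
#' ids (e.g. `X1:1`), cells 0/1. JSON layout: an object mapping policy
#' code to an object of indicator id to 0/1. Every (policy, indicator)
#' cell must be present; values outside \{0, 1\} are rejected with the
#' offending cell named.
#'
#' @param path path to the coding file.
#' @param schema a `pmc_schema`.
#' @param meta optional path to a metadata CSV (`code,name,pub_date`) or
#'   a data frame.
#' @param overrides optional path to a score-override CSV
#'   (`code,primary,numerator,denominator`) or a data frame.
#' @return a `pmc_coding`.
#' @export
load_coding <- function(path, schema, meta = NULL, overrides = NULL) {
  if (!file.exists(path)) {
    abort_pmc(sprintf("coding file not found: %s", path), "pmc_coding_error")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    codes <- names(raw)
    sids <- unique(unlist(lapply(raw, names)))
    values <- matrix(NA_real_, length(codes), length(sids),
                     dimnames = list(codes, sids))
    for (p in codes) for (s in names(raw[[p]])) {
      values[p, s] <- as.numeric(raw[[p]][[s]])
    }
  } else {
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    if (names(df)[1] != "code") {
      abort_pmc("first column of a coding CSV must be 'code'",
                "pmc_coding_error")
    }
    values <- as.matrix(df[, -1, drop = FALSE])
    rownames(values) <- df$code
  }
  if (is.character(meta)) {
    meta <- utils::read.csv(meta, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  }
  if (is.character(overrides)) {
    overrides <- utils::read.csv(overrides, stringsAsFactors = FALSE)
  }
  pmc_coding(values, schema, meta = meta, overrides = overrides)
}

#' Write a coding matrix to CSV or JSON
#'
#' @param coding a `pmc_coding`.
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
save_coding <- function(coding, path) {
  stopifnot(inherits(coding, "pmc_coding"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- lapply(seq_len(nrow(coding$values)), function(i) {
      as.list(coding$values[i, ])
    })
    names(raw) <- rownames(coding$values)
    jsonlite::write_json(raw, path, auto_unbox = TRUE)
  } else {
    df <- data.frame(code = rownames(coding$values), coding$values,
                     check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Check a coding matrix against a published score table
#'
#' Recomputes each scored primary's mean from the raw 0/1 cells, rounds
#' half-up to two decimals, and compares with a reference table of
#' published per-primary scores. Score overrides are deliberately NOT
#' applied here: the point of the check is whether the published cell is
#' reachable from the binary cells at all.
#'
#' @param coding a `pmc_coding`.
#' @param schema a `pmc_schema`.
#' @param reference data frame with column `code` and one column per
#'   scored primary id.
#' @return data frame of discrepancies (`code`, `primary`, `computed`,
#'   `reference`); zero rows when everything matches. Policies present
#'   in the reference but absent from the matrix appear with
#'   `computed = NA`.
#' @export
validate_coding_means <- function(coding, schema, reference) {
  stopifnot(inherits(coding, "pmc_coding"), inherits(schema, "pmc_schema"))
  reference <- as.data.frame(reference, check.names = FALSE)
  prim_ids <- intersect(schema$scored_ids, names(reference))
  out <- list()
  card <- cardinalities(schema)
  for (i in seq_len(nrow(reference))) {
    code <- reference$code[i]
    if (!code %in% rownames(coding$values)) {
      out[[length(out) + 1L]] <- data.frame(
        code = code, primary = NA_character_, computed = NA_real_,
        reference = NA_real_)
      next
    }
    for (t in prim_ids) {
      cols <- paste0(t, ":", seq_len(card[[t]]))
      comp <- rat_display2(sum(coding$values[code, cols]), card[[t]])
      ref <- round_half_up(as.numeric(reference[i, t]), 2)
      if (!isTRUE(all.equal(comp, ref))) {
        out[[length(out) + 1L]] <- data.frame(
          code = code, primary = t, computed = comp, reference = ref)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(code = character(), primary = character(),
                      computed = numeric(), reference = numeric()))
  }
  do.call(rbind, out)
}

#' @export
print.pmc_coding <- function(x, ...) {
  cat(sprintf("<pmc_coding>: %d policies x %d indicators%s%s\n",
              nrow(x$values), ncol(x$values),
              if (!is.null(x$meta)) ", with metadata" else "",
              if (!is.null(x$overrides) && nrow(x$overrides))
                sprintf(", %d score override(s)", nrow(x$overrides)) else ""))
  invisible(x)
}
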