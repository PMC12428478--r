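#' Evaluation variable schemas
#'
#' A variable schema is the two-level hierarchy the index is scored
#' against: primary dimensions (`X1` ... `X10`) each decomposed into
#' binary secondary indicators of equal weight. The bundled default
#' schema has ten primaries with secondary cardinalities
#' (6, 3, 3, 3, 5, 5, 4, 5, 5, 0); `X10` (policy disclosure) carries no
#' secondaries and is flagged `indicator_only`, so it is excluded from
#' the scored set and recorded as a per-policy boolean instead.
#'
#' @name pmc_schema
#' @seealso [load_schema()], [default_schema()], [load_coding()]
NULL

new_pmc_schema <- function(primaries, scored_ids, name = "schema") {
  obj <- structure(
    list(primaries = primaries, scored_ids = scored_ids, name = name),
    class = "pmc_schema"
  )
  validate_pmc_schema(obj)
  obj
}

validate_pmc_schema <- function(schema) {
  pids <- vapply(schema$primaries, `[[`, character(1), "id")
  if (anyDuplicated(pids)) {
    abort_pmc(
      sprintf("duplicate primary variable id: %s",
              paste(unique(pids[duplicated(pids)]), collapse = ", ")),
      "pmc_schema_error"
    )
  }
  sids <- unlist(lapply(schema$primaries, function(p) {
    vapply(p$secondaries, `[[`, character(1), "id")
  }))
  if (anyDuplicated(sids)) {
    abort_pmc(
      sprintf("duplicate secondary variable id: %s",
              paste(unique(sids[duplicated(sids)]), collapse = ", ")),
      "pmc_schema_error"
    )
  }
  if (!all(schema$scored_ids %in% pids)) {
    abort_pmc("scored_ids contains ids not present among the primaries",
              "pmc_schema_error")
  }
  for (p in schema$primaries) {
    scored <- p$id %in% schema$scored_ids
    if (scored && length(p$secondaries) == 0) {
      abort_pmc(
        sprintf("scored primary %s has no secondary indicators", p$id),
        "pmc_schema_error"
      )
    }
    if (!scored && length(p$secondaries) == 0 && !isTRUE(p$indicator_only)) {
      abort_pmc(
        sprintf("primary %s has no secondaries and is not flagged indicator_only",
                p$id),
        "pmc_schema_error"
      )
    }
  }
  invisible(schema)
}

#' Load a variable schema from a YAML or JSON file
#'
#' The file must list `primaries` (each with `id`, `label` and a
#' `secondaries` list of `id`/`label`/`criterion` records) and
#' `scored_ids`, the ordered primary ids that enter the index sum.
#' A primary may omit secondaries only when flagged `indicator_only`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` schema file.
#' @return a validated `pmc_schema` object.
#' @export
#' @examples
#' sch <- default_schema()
#' cardinalities(sch)
load_schema <- function(path) {
  if (!file.exists(path)) {
    abort_pmc(sprintf("schema file not found: %s", path), "pmc_schema_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  primaries <- lapply(raw$primaries, function(p) {
    list(
      id = as.character(p$id),
      label = as.character(p$label %||% p$id),
      indicator_only = isTRUE(p$indicator_only),
      secondaries = lapply(p$secondaries, function(s) {
        list(id = as.character(s$id),
             label = as.character(s$label %||% s$id),
             criterion = as.character(s$criterion %||% ""))
      })
    )
  })
  scored <- as.character(unlist(raw$scored_ids))
  new_pmc_schema(primaries, scored, name = raw$schema_name %||% basename(path))
}

#' The bundled default evaluation schema
#'
#' Ten primary dimensions, 39 binary secondary indicators, scored set
#' `X1`-`X9`; `X10` is the indicator-only disclosure flag.
#'
#' @return a `pmc_schema`.
#' @export
default_schema <- function() {
  load_schema(system.file("extdata", "default_schema.yaml",
                          package = "pmcindex", mustWork = TRUE))
}

#' Write a schema back to YAML or JSON
#'
#' @param schema a `pmc_schema`.
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
save_schema <- function(schema, path) {
  stopifnot(inherits(schema, "pmc_schema"))
  raw <- list(
    schema_name = schema$name,
    scored_ids = schema$scored_ids,
    primaries = lapply(schema$primaries, function(p) {
      out <- list(id = p$id, label = p$label)
      if (isTRUE(p$indicator_only)) out$indicator_only <- TRUE
      out$secondaries <- lapply(p$secondaries, function(s) {
        list(id = s$id, label = s$label, criterion = s$criterion)
      })
      out
    })
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(raw, path)
  }
  invisible(path)
}

#' Secondary-indicator ids of the scored primaries
#'
#' @param schema a `pmc_schema`.
#' @return character vector of secondary ids in schema order.
#' @export
secondary_ids <- function(schema) {
  stopifnot(inherits(schema, "pmc_schema"))
  unlist(lapply(schema$primaries, function(p) {
    vapply(p$secondaries, `[[`, character(1), "id")
  }))
}

#' Secondary cardinality of each scored primary
#'
#' @param schema a `pmc_schema`.
#' @return named integer vector, one entry per scored primary.
#' @export
cardinalities <- function(schema) {
  stopifnot(inherits(schema, "pmc_schema"))
  ids <- schema$scored_ids
  out <- vapply(ids, function(id) {
    p <- schema$primaries[[match(id, vapply(schema$primaries, `[[`,
                                            character(1), "id"))]]
    length(p$secondaries)
  }, integer(1))
  names(out) <- ids
  out
}

#' @export
print.pmc_schema <- function(x, ...) {
  card <- vapply(x$primaries, function(p) length(p$secondaries), integer(1))
  cat(sprintf("<pmc_schema '%s'>: %d primaries, %d secondaries\n",
              x$name, length(x$primaries), sum(card)))
  for (p in x$primaries) {
    tag <- if (p$id %in% x$scored_ids) "scored" else "indicator-only"
    cat(sprintf("  %-4s %-22s %d secondaries (%s)\n",
                p$id, p$label, length(p$secondaries), tag))
  }
  invisible(x)
}
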