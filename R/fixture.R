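#' The bundled 28-policy evaluation set
#'
#' The package ships a worked evaluation of 28 national medical and
#' older-adult-care integration policies (2015-2024): their metadata
#' (code, title, publication date), a binary coding matrix over the 39
#' secondary indicators of the default schema, and the published
#' per-primary reference scores.
#'
#' The binary cells are a synthetic reconstruction: for each policy and
#' primary with cardinality m and published mean v, the first
#' `round(v * m)` indicators are set to 1. This reproduces every
#' published per-primary mean, with one exception carried as an explicit
#' score override: policy P26's X6 value of 0.67 is not expressible as a
#' ones-count over the 5 X6 indicators, so the fixture stores the
#' best binary approximation (3/5) in the matrix and overrides the
#' scored cell to 2/3, which reproduces the published value and the
#' policy's published index of 4.40 exactly. [validate_coding_means()]
#' on this fixture therefore reports exactly that one cell.
#'
#' @return list with
#'   \describe{
#'     \item{coding}{a `pmc_coding` with metadata and the P26/X6 score
#'       override attached.}
#'     \item{reference}{data frame of the published per-primary scores
#'       and index (`code`, `X1`..`X9`, `pmc`).}
#'   }
#' @export
#' @examples
#' fix <- integration_policies()
#' sc <- score_policies(fix$coding)
#' sc$results[1, c("code", "pmc_display", "grade")]
integration_policies <- function() {
  ext <- function(f) system.file("extdata", f, package = "pmcindex",
                                 mustWork = TRUE)
  schema <- default_schema()
  coding <- load_coding(
    ext("integration_policies_coding.csv"), schema,
    meta = ext("integration_policies_meta.csv"),
    overrides = ext("integration_policies_overrides.csv"))
  reference <- utils::read.csv(ext("integration_policies_reference.csv"),
                               check.names = FALSE,
                               stringsAsFactors = FALSE)
  list(coding = coding, reference = reference)
}
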