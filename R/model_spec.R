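# Generalized-linear risk-scoring specifications.
#
# A risk model spec is a logit-link linear predictor over features derived
# from the canonical patient record: intercept + sum of terms, where each
# term is either a category dummy (variable, level, coefficient) or a
# continuous contribution (variable, level = NA, coefficient). Variable
# resolution goes through `variable_map` (model variable -> derived feature),
# so the engine itself is model-agnostic; the shipped SORT, P-POSSUM and SRS
# models are versioned JSON configs transcribed from their original
# publications, with provenance strings.

# features the engine can derive beyond raw record columns
.surgrisk_derived_features <- c(
  "asa_class", "age_band", "highrisk_specialty", "severity_xmajor_complex",
  "malignancy_any", "possum_physiology", "possum_operative", "srs_score"
)

#' Construct a risk model specification
#'
#' @param name Short versioned identifier, e.g. `"sort_v1"`.
#' @param intercept Intercept of the logit-scale linear predictor.
#' @param terms Data frame with columns `variable`, `level` (NA for a
#'   continuous term) and `coefficient`.
#' @param variable_map Named list mapping each model variable to a feature:
#'   either a canonical record column or one of the derived features
#'   (`asa_class`, `age_band`, `highrisk_specialty`,
#'   `severity_xmajor_complex`, `malignancy_any`, `possum_physiology`,
#'   `possum_operative`, `srs_score`).
#' @param provenance Citation string and transcription note.
#' @param link Link function; only `"logit"` is supported.
#' @param urgency_map Optional named list remapping urgency levels before
#'   feature derivation, for models predating the NCEPOD "expedited"
#'   category (e.g. `list(expedited = "elective")`).
#' @param possum_bands Optional banding tables for the POSSUM physiological
#'   and operative sub-scores (see the shipped `ppossum_v1` config).
#' @param srs_maps Optional level-to-points maps for the SRS components.
#' @return An object of class `risk_model_spec`.
#' @export
risk_model_spec <- function(name, intercept, terms, variable_map,
                            provenance = "unspecified", link = "logit",
                            urgency_map = NULL, possum_bands = NULL,
                            srs_maps = NULL) {
  spec <- structure(
    list(name = name, link = link, intercept = as.numeric(intercept),
         terms = terms, variable_map = variable_map,
         urgency_map = urgency_map, possum_bands = possum_bands,
         srs_maps = srs_maps, provenance = provenance),
    class = "risk_model_spec")
  validate_model_spec(spec)
}

#' Validate a risk model specification
#'
#' Enforces the spec invariants: logit link, no duplicate (variable, level)
#' pairs, every term variable resolvable through `variable_map`, and every
#' mapped feature present in the canonical record schema or the engine's
#' derived-feature library.
#'
#' @param spec A `risk_model_spec`.
#' @return The validated spec, invisibly usable in pipelines.
#' @export
validate_model_spec <- function(spec) {
  stopifnot(inherits(spec, "risk_model_spec"))
  if (!identical(spec$link, "logit")) {
    stop("unsupported link '", spec$link, "': only 'logit' is implemented")
  }
  tr <- spec$terms
  if (!is.data.frame(tr) ||
      !all(c("variable", "level", "coefficient") %in% names(tr))) {
    stop("`terms` must be a data frame with variable, level, coefficient")
  }
  if (!is.numeric(tr$coefficient) || anyNA(tr$coefficient)) {
    stop("term coefficients must be numeric and non-missing")
  }
  key <- paste(tr$variable, ifelse(is.na(tr$level), "<numeric>", tr$level))
  if (anyDuplicated(key)) {
    stop("duplicate (variable, level) term(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  unmapped <- setdiff(unique(tr$variable), names(spec$variable_map))
  if (length(unmapped)) {
    stop("term variable(s) not in variable_map: ",
         paste(unmapped, collapse = ", "))
  }
  feats <- unlist(spec$variable_map, use.names = FALSE)
  known <- c(cohort_columns(), .surgrisk_derived_features)
  bad <- setdiff(feats, known)
  if (length(bad)) {
    stop("variable_map points at unknown feature(s): ",
         paste(bad, collapse = ", "))
  }
  spec
}

#' @export
print.risk_model_spec <- function(x, ...) {
  cat(sprintf("<risk_model_spec> %s (link = %s)\n", x$name, x$link))
  cat(sprintf("  intercept: %.4f;  %d term(s) over %d variable(s)\n",
              x$intercept, nrow(x$terms), length(unique(x$terms$variable))))
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Load / save a risk model specification as JSON
#'
#' Model coefficients ship as versioned JSON configs so band or coefficient
#' edits never require code changes. `load_model_spec()` validates the file
#' against the schema and refuses specs whose variables cannot be resolved
#' to canonical record features, listing the offending terms.
#'
#' @param path Path to a spec JSON file.
#' @param spec A `risk_model_spec`.
#' @return `load_model_spec()`: a validated `risk_model_spec`.
#' @export
load_model_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  .spec_from_list(raw, context = path)
}

.spec_from_list <- function(raw, context = "spec list") {
  if (is.null(raw$schema_version) || raw$schema_version != 1) {
    stop("unsupported model-spec schema_version in ", context)
  }
  terms <- do.call(rbind, lapply(raw$terms, function(t) {
    data.frame(variable = t$variable,
               level = if (is.null(t$level)) NA_character_ else t$level,
               coefficient = as.numeric(t$coefficient),
               stringsAsFactors = FALSE)
  }))
  risk_model_spec(
    name = raw$name, intercept = raw$intercept, terms = terms,
    variable_map = lapply(raw$variable_map, as.character),
    provenance = if (is.null(raw$provenance)) "unspecified" else
      raw$provenance,
    link = raw$link,
    urgency_map = raw$urgency_map,
    possum_bands = raw$possum_bands,
    srs_maps = raw$srs_maps)
}

.spec_to_list <- function(spec) {
  terms <- lapply(seq_len(nrow(spec$terms)), function(i) {
    lv <- spec$terms$level[i]
    out <- list(variable = spec$terms$variable[i],
                coefficient = spec$terms$coefficient[i])
    if (!is.na(lv)) out$level <- lv
    out
  })
  out <- list(schema_version = 1, name = spec$name, link = spec$link,
              intercept = spec$intercept, terms = terms,
              variable_map = spec$variable_map,
              urgency_map = spec$urgency_map,
              possum_bands = spec$possum_bands,
              srs_maps = spec$srs_maps,
              provenance = spec$provenance)
  out[!vapply(out, is.null, logical(1))]
}

#' @rdname load_model_spec
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "risk_model_spec"))
  jsonlite::write_json(.spec_to_list(spec), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Shipped risk-model specifications
#'
#' Accessors for the three bundled objective 30-day mortality models:
#' the Surgical Outcome Risk Tool (SORT; 6 variable groups: ASA-PS,
#' urgency, high-risk specialty, procedure severity, malignancy, age band),
#' the Portsmouth-POSSUM equation (logit built from the integer
#' physiological and operative-severity sub-scores), and the Surgical Risk
#' Scale (points sum of CEPOD urgency class, BUPA severity grade and
#' ASA-PS). Coefficients are transcribed from the original publications and
#' carry provenance strings; see each JSON config under
#' `system.file("extdata/models", package = "surgrisk")`.
#'
#' @return A `risk_model_spec`.
#' @export
sort_spec <- function() {
  load_model_spec(system.file("extdata", "models", "sort_v1.json",
                              package = "surgrisk", mustWork = TRUE))
}

#' @rdname sort_spec
#' @export
ppossum_spec <- function() {
  load_model_spec(system.file("extdata", "models", "ppossum_v1.json",
                              package = "surgrisk", mustWork = TRUE))
}

#' @rdname sort_spec
#' @export
srs_spec <- function() {
  load_model_spec(system.file("extdata", "models", "srs_v1.json",
                              package = "surgrisk", mustWork = TRUE))
}
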