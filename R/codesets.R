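# ICD-9-CM code sets and matching semantics.
#
# All selection and ascertainment rules in this package operate on named code
# sets with deterministic matching: a pattern is either an exact code
# ("518.81"), a truncation prefix ("415.1x" matches any 4151*), or an
# inclusive numeric range ("96.70-96.72"). Diagnosis and procedure codes are
# distinct ICD-9-CM namespaces and never share a set.

#' Normalize an ICD-9-CM code
#'
#' Strips dots and surrounding whitespace and lower-cases the code, giving the
#' dot-free token form used throughout for matching. Idempotent.
#'
#' @param code Character vector of raw codes (e.g. `"415.19"`, `"V42.0"`).
#' @return Character vector of normalized tokens (e.g. `"41519"`, `"v420"`).
#' @examples
#' normalize_code(c("415.19", " 96.70", "V42.0"))
#' @export
normalize_code <- function(code) {
  if (!is.character(code)) code <- as.character(code)
  out <- tolower(gsub(".", "", trimws(code), fixed = TRUE))
  if (length(out) == 0L || anyNA(out) || any(!nzchar(out))) {
    stop("invalid code: empty or blank ICD-9-CM code", call. = FALSE)
  }
  out
}

#' Expand a code pattern into exact and prefix tokens
#'
#' Three pattern forms are recognised:
#' * plain codes (`"518.81"`) become one exact token;
#' * `x`-suffixed codes (`"415.1x"`) become a prefix token matching any code
#'   that starts with the normalized stem (the standard ICD-9 truncation
#'   convention);
#' * dash ranges (`"96.70-96.72"`, en dash accepted) enumerate every code
#'   between the inclusive endpoints, which must be all-digit tokens of equal
#'   width.
#'
#' @param pattern A single pattern string.
#' @return A list with character vectors `exact` and `prefix`.
#' @examples
#' expand_pattern("415.1x")
#' expand_pattern("96.70-96.72")
#' @export
expand_pattern <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  if (grepl("[-–]", pattern)) {
    ends <- normalize_code(strsplit(pattern, "[-–]")[[1L]])
    if (length(ends) != 2L || !all(grepl("^[0-9]+$", ends)) ||
        nchar(ends[1L]) != nchar(ends[2L])) {
      stop("malformed range pattern: ", pattern, call. = FALSE)
    }
    lo <- as.integer(ends[1L]); hi <- as.integer(ends[2L])
    if (lo > hi) stop("malformed range pattern (start > end): ", pattern, call. = FALSE)
    return(list(
      exact = formatC(lo:hi, width = nchar(ends[1L]), flag = "0"),
      prefix = character()
    ))
  }
  tok <- normalize_code(pattern)
  if (grepl("x+$", tok)) {
    stem <- sub("x+$", "", tok)
    if (!nzchar(stem)) stop("malformed prefix pattern: ", pattern, call. = FALSE)
    return(list(exact = character(), prefix = stem))
  }
  list(exact = tok, prefix = character())
}

#' Construct a code set
#'
#' @param name Set name (unique within a registry).
#' @param kind `"diagnosis"` or `"procedure"` (the two ICD-9-CM namespaces).
#' @param patterns Character vector of patterns (see [expand_pattern()]).
#' @param provenance Free-text origin of the list.
#' @return An object of class `code_set`.
#' @export
code_set <- function(name, kind = c("diagnosis", "procedure"), patterns,
                     provenance = "unspecified") {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(patterns) == 0L) stop("code set '", name, "' has no patterns", call. = FALSE)
  ex <- lapply(patterns, expand_pattern)
  structure(
    list(
      name = name, kind = kind, patterns = as.character(patterns),
      provenance = provenance,
      exact = unique(unlist(lapply(ex, `[[`, "exact"))),
      prefix = unique(unlist(lapply(ex, `[[`, "prefix")))
    ),
    class = "code_set"
  )
}

#' @export
print.code_set <- function(x, ...) {
  cat(sprintf("<code_set> %s (%s): %d patterns, %d exact / %d prefix tokens\n",
              x$name, x$kind, length(x$patterns), length(x$exact), length(x$prefix)))
  invisible(x)
}

#' Test codes against a code set
#'
#' A code matches when its normalized form equals an exact token of the set or
#' starts with one of the set's prefix tokens.
#'
#' @param code Character vector of codes (raw or normalized).
#' @param set A `code_set`.
#' @return Logical vector, one element per code.
#' @examples
#' reg <- load_registry()
#' code_matches(c("415.19", "415.0"), reg$sets$pe)
#' @export
code_matches <- function(code, set) {
  stopifnot(inherits(set, "code_set"))
  if (length(code) == 0L) return(logical())
  norm <- normalize_code(code)
  hit <- norm %in% set$exact
  if (length(set$prefix)) {
    for (L in unique(nchar(set$prefix))) {
      hit <- hit | substr(norm, 1L, L) %in% set$prefix[nchar(set$prefix) == L]
    }
  }
  hit
}

#' Canonical comorbidity names of the IMPACT rule
#'
#' The eleven claims-coded comorbidities entering the IMPACT linear predictor,
#' in the fixed order used by coefficient files, profiles and registries.
#'
#' @return Character vector of length 11.
#' @export
impact_comorbidities <- function() {
  c("myocardial_infarction", "chronic_lung_disease", "stroke",
    "prior_major_bleeding", "atrial_fibrillation", "cognitive_impairment",
    "heart_failure", "renal_failure", "liver_disease", "coagulopathy",
    "cancer")
}

.required_sets <- function() {
  c("pe", "pe_complication", "pe_complication_procedure", "dvt",
    impact_comorbidities())
}

#' Load a code registry
#'
#' Reads a registry of named code sets from a JSON file. The file must define
#' the sets the pipeline relies on: `pe` (the index PE diagnosis, 415.1x),
#' `pe_complication` (diagnosis codes that qualify a secondary-position PE),
#' `pe_complication_procedure` (thrombolysis / intubation / mechanical
#' ventilation procedure codes with the same role), `dvt` (recurrence
#' ascertainment) and one diagnosis set per IMPACT comorbidity. The default
#' registry shipped with the package carries AHRQ-comorbidity-schema-style
#' lists, with per-set provenance, and can be replaced wholesale to swap in
#' site-specific definitions.
#'
#' @param path Path to a registry JSON file; `NULL` loads the packaged default.
#' @return An object of class `code_registry` with element `sets` (named list
#'   of `code_set`).
#' @export
load_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "code_registry.json", package = "impactpe")
  }
  if (!file.exists(path)) stop("registry file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (is.null(raw$sets)) stop("registry configuration error: no 'sets' element", call. = FALSE)
  sets <- lapply(raw$sets, function(s) {
    code_set(s$name, s$kind, unlist(s$patterns), s$provenance %||% "unspecified")
  })
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(names(sets))) {
    stop("registry configuration error: duplicate set names", call. = FALSE)
  }
  missing <- setdiff(.required_sets(), names(sets))
  if (length(missing)) {
    stop("registry configuration error: missing required set(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(sets = sets, source = path), class = "code_registry")
}

#' Write a code registry to JSON
#'
#' Serializes the pattern lists (not the expanded tokens), so a written
#' registry reloads to an identical object.
#'
#' @param registry A `code_registry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "code_registry"))
  out <- list(sets = lapply(unname(registry$sets), function(s) {
    list(name = s$name, kind = s$kind, patterns = as.list(s$patterns),
         provenance = s$provenance)
  }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.code_registry <- function(x, ...) {
  cat(sprintf("<code_registry> %d sets: %s\n", length(x$sets),
              paste(names(x$sets), collapse = ", ")))
  invisible(x)
}

#' Look up a set in a registry
#'
#' @param registry A `code_registry`.
#' @param name Set name.
#' @return The `code_set`.
#' @export
registry_set <- function(registry, name) {
  stopifnot(inherits(registry, "code_registry"))
  set <- registry$sets[[name]]
  if (is.null(set)) stop("unknown code set: ", name, call. = FALSE)
  set
}

# A concrete claimable code that matches `name` and no other comorbidity set
# (nor the pe/dvt/complication sets). Used by the synthetic generator so that
# every planted claim flags exactly the comorbidity it was planted for.
representative_code <- function(registry, name) {
  set <- registry_set(registry, name)
  others <- setdiff(.required_sets(), name)
  candidates <- unique(c(set$exact,
                         paste0(set$prefix, "0"), paste0(set$prefix, "1"),
                         set$prefix))
  for (cand in candidates) {
    if (!code_matches(cand, set)) next
    clash <- vapply(others, function(o) {
      oset <- registry$sets[[o]]
      oset$kind == set$kind && code_matches(cand, oset)
    }, logical(1))
    if (!any(clash)) return(cand)
  }
  stop("no unambiguous representative code for set: ", name, call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
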