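# Terminology layer: code systems, shipped value sets, label -> concept lookup.
#
# Value sets are plain TSV tables (display, system, code, synonyms) under
# inst/extdata/valuesets/, loaded once per session into a registry. Codes are
# data, not logic: sites/structures carry SNOMED CT codes where a stable SCTID
# exists, everything else (BCA-specific tissue compartments, lateralized bones,
# vertebrae, ribs) lives in a project-local code system. RadLex is configured
# as an additional system for imaging-specific terms; its concepts, like all
# others, come from the editable tables.

#' Configured code-system URIs
#'
#' The terminology layer resolves the shorthand system tokens used in the
#' value-set tables (`sct`, `radlex`, `local`) to these URIs. The local system
#' hosts BCA-specific concepts that have no SNOMED CT or RadLex code.
#'
#' @return Named character vector of code-system URIs.
#' @export
boa_systems <- function() {
  c(
    sct = "http://snomed.info/sct",
    radlex = "http://radlex.org",
    local = paste0(boa_canonical_base(), "/CodeSystem/boa")
  )
}

# lookup priority when a display maps to several systems
system_priority <- function(system) {
  sys <- boa_systems()
  match(system, unname(sys))
}

# terminology systems plus the fixed FHIR infrastructure systems that coded
# elements outside the value sets draw on (categories, security tags, DICOM)
allowed_systems <- function() {
  c(unname(boa_systems()), OBS_CATEGORY_SYSTEM, SECURITY_SYSTEM, DCM_SYSTEM,
    UCUM_SYSTEM)
}

#' Construct a terminology concept
#'
#' A concept is the (system, code, display) triple used everywhere a coded
#' value appears: body sites, tissues, anatomical landmarks, measurement modes.
#'
#' @param system Code-system URI (one of [boa_systems()]).
#' @param code Non-empty token without whitespace.
#' @param display Human-readable label.
#' @return An object of class `boa_concept`.
#' @export
concept <- function(system, code, display) {
  if (!is_string(system) || !system %in% allowed_systems()) {
    abort(paste0("concept system must be a configured code-system URI, got: ", system),
          class = "boa_invalid_concept")
  }
  if (!is_string(code) || !nzchar(code) || grepl("\\s", code)) {
    abort("concept code must be a non-empty token without whitespace",
          class = "boa_invalid_concept")
  }
  structure(list(system = system, code = code, display = display),
            class = "boa_concept")
}

#' @export
format.boa_concept <- function(x, ...) {
  sprintf("<%s> %s \"%s\"", x$system, x$code, x$display)
}

#' @export
print.boa_concept <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

concept_from_row <- function(row) {
  concept(row$system, row$code, row$display)
}

norm_label <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

# -- registry ----------------------------------------------------------------

valueset_registry <- function() {
  if (is.null(.boa_env$valuesets)) {
    .boa_env$valuesets <- list()
    dir <- system.file("extdata", "valuesets", package = "boafhir")
    for (f in list.files(dir, pattern = "\\.tsv$", full.names = TRUE)) {
      id <- sub("\\.tsv$", "", basename(f))
      tab <- read.delim(f, stringsAsFactors = FALSE, colClasses = "character")
      register_valueset(id, tab, title = id)
    }
  }
  .boa_env$valuesets
}

#' Register a value set
#'
#' Adds (or replaces) a value set in the session registry. The five shipped
#' sets are loaded automatically from the package's TSV tables; this function
#' lets deployments add institution-specific sets or swap in updated
#' terminology releases.
#'
#' @param id Value-set id token (e.g. `"BCATissueVS"`).
#' @param table Data frame with columns `display`, `system` (URI or one of the
#'   shorthand tokens `sct`/`radlex`/`local`), `code`, and optional `synonyms`
#'   (pipe-separated alternative labels).
#' @param title Human-readable title; defaults to `id`.
#' @return The registered concept tibble, invisibly.
#' @export
register_valueset <- function(id, table, title = id) {
  stopifnot(is.data.frame(table), all(c("display", "system", "code") %in% names(table)))
  sys <- boa_systems()
  table <- as_tibble(table)
  table$system <- ifelse(table$system %in% names(sys), unname(sys[table$system]), table$system)
  if (!"synonyms" %in% names(table)) table$synonyms <- ""
  table$synonyms[is.na(table$synonyms)] <- ""
  bad <- !table$system %in% unname(sys)
  if (any(bad)) {
    abort(paste0("value set '", id, "' uses unconfigured code systems: ",
                 paste(unique(table$system[bad]), collapse = ", ")),
          class = "boa_invalid_concept")
  }
  if (any(!nzchar(table$code)) || any(grepl("\\s", table$code))) {
    abort(paste0("value set '", id, "' contains empty or whitespace codes"),
          class = "boa_invalid_concept")
  }
  if (anyDuplicated(paste(table$system, table$code))) {
    abort(paste0("value set '", id, "' has duplicate (system, code) pairs"),
          class = "boa_invalid_concept")
  }
  if (is.null(.boa_env$valuesets)) valueset_registry()
  .boa_env$valuesets[[id]] <- list(id = id, title = title,
                                   concepts = table[, c("display", "system", "code", "synonyms")])
  invisible(table)
}

#' List registered value sets
#' @return Character vector of value-set ids.
#' @export
boa_valuesets <- function() names(valueset_registry())

get_valueset <- function(valueset_id) {
  reg <- valueset_registry()
  vs <- reg[[valueset_id]]
  if (is.null(vs)) {
    abort(paste0("unknown value set: '", valueset_id, "'"),
          class = "boa_unknown_valueset", valueset_id = valueset_id)
  }
  vs
}

#' Members of a value set
#'
#' @param valueset_id Id of a shipped or registered value set.
#' @return Tibble with columns `system`, `code`, `display` in the stable
#'   shipped order.
#' @export
#' @examples
#' valueset_members("BCABodySiteVS")
valueset_members <- function(valueset_id) {
  vs <- get_valueset(valueset_id)
  vs$concepts[, c("system", "code", "display")]
}

#' Resolve a label to a concept
#'
#' Case-insensitive, whitespace-normalized match of `label` against the
#' displays and registered synonyms of every registered value set. When the
#' label is known to several systems, `preferred_system` wins if it has a
#' match, otherwise the configured priority (SNOMED CT > RadLex > local).
#'
#' @param label Label to resolve (e.g. `"spleen"`).
#' @param preferred_system Optional code-system URI to prefer.
#' @return A [concept()].
#' @export
#' @examples
#' lookup_concept("abdominal cavity")
lookup_concept <- function(label, preferred_system = NULL) {
  if (!is_string(label) || !nzchar(trimws(label))) {
    abort("label must be a non-empty string", class = "boa_unmapped_label", label = label)
  }
  key <- norm_label(label)
  hits <- lookup_table()
  hits <- hits[hits$key == key, , drop = FALSE]
  if (nrow(hits) == 0) {
    abort(paste0("unmapped label: '", label, "'"),
          class = "boa_unmapped_label", label = label)
  }
  if (!is.null(preferred_system) && any(hits$system == preferred_system)) {
    hits <- hits[hits$system == preferred_system, , drop = FALSE]
  }
  hits <- hits[order(system_priority(hits$system), hits$rank), , drop = FALSE]
  concept_from_row(hits[1, ])
}

# flat lookup table over all sets: one row per (label key, concept)
lookup_table <- function() {
  reg <- valueset_registry()
  if (!is.null(.boa_env$lookup) && identical(.boa_env$lookup_stamp, names(reg))) {
    return(.boa_env$lookup)
  }
  rows <- list()
  rank <- 0L
  for (vs in reg) {
    for (i in seq_len(nrow(vs$concepts))) {
      r <- vs$concepts[i, ]
      rank <- rank + 1L
      labels <- c(r$display, strsplit(r$synonyms, "|", fixed = TRUE)[[1]])
      labels <- labels[nzchar(labels)]
      for (lab in labels) {
        rows[[length(rows) + 1L]] <- tibble(
          key = norm_label(lab), display = r$display, system = r$system,
          code = r$code, rank = rank
        )
      }
    }
  }
  tab <- dplyr::distinct(bind_rows(rows), .data$key, .data$system, .data$code,
                         .keep_all = TRUE)
  .boa_env$lookup <- tab
  .boa_env$lookup_stamp <- names(reg)
  tab
}

#' Test membership of a concept in a value set
#'
#' Membership is decided on the (system, code) pair alone; the display is not
#' consulted, matching FHIR terminology semantics.
#'
#' @param concept A [concept()] (or any list with `system` and `code`).
#' @param valueset_id Id of a registered value set.
#' @return `TRUE` iff the pair appears in the set.
#' @export
validate_membership <- function(concept, valueset_id) {
  vs <- get_valueset(valueset_id)
  any(vs$concepts$system == concept$system & vs$concepts$code == concept$code)
}

#' Serialize a value set as FHIR R4 ValueSet JSON
#'
#' @param valueset_id Id of a registered value set.
#' @return A list ready for JSON serialization (a FHIR `ValueSet` resource with
#'   an inline expansion), canonical URL under [boa_canonical_base()].
#' @export
valueset_to_fhir <- function(valueset_id) {
  vs <- get_valueset(valueset_id)
  members <- vs$concepts
  list(
    resourceType = "ValueSet",
    id = vs$id,
    url = paste0(boa_canonical_base(), "/ValueSet/", vs$id),
    name = vs$id,
    title = vs$title,
    status = "active",
    expansion = list(
      total = nrow(members),
      contains = lapply(seq_len(nrow(members)), function(i) {
        list(system = members$system[i], code = members$code[i],
             display = members$display[i])
      })
    )
  )
}
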