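# Shared low-level helpers: canonical JSON, hashing, FHIR fragments.

#' Canonical base URL for profile and value-set canonicals
#'
#' All canonical URLs (profiles, value sets, the local code system) are minted
#' under this base. It is configuration, not a published canonical: override
#' with `options(boafhir.canonical_base = "https://your.org/fhir")`.
#'
#' @return A length-1 character URL without a trailing slash.
#' @export
boa_canonical_base <- function() {
  base <- getOption("boafhir.canonical_base", "https://boa.example.org/fhir")
  sub("/+$", "", base)
}

# Fixed external code-system URIs used throughout.
UCUM_SYSTEM <- "http://unitsofmeasure.org"
DICOM_UID_SYSTEM <- "urn:dicom:uid"
DCM_SYSTEM <- "http://dicom.nema.org/resources/ontology/DCM"
SECURITY_SYSTEM <- "http://terminology.hl7.org/CodeSystem/v3-ObservationValue"
OBS_CATEGORY_SYSTEM <- "http://terminology.hl7.org/CodeSystem/observation-category"
UCUM_ML <- "mL"
UCUM_HU <- "[hnsf'U]"

# Canonical JSON serialization: one fixed set of jsonlite options so that equal
# R structures always produce byte-identical text (determinism contract).
to_canonical_json <- function(x) {
  as.character(jsonlite::toJSON(
    x, auto_unbox = TRUE, digits = NA, null = "null", na = "null", pretty = 2
  ))
}

read_json_file <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

# Content hash for deterministic resource ids: MD5 over the exact UTF-8 bytes
# (tools::md5sum is file-based, so the bytes pass through a temp file).
content_hash <- function(txt) {
  tmp <- tempfile("boahash")
  on.exit(unlink(tmp))
  writeBin(charToRaw(enc2utf8(txt)), tmp)
  unname(tools::md5sum(tmp))
}

random_uuid <- function() {
  hex <- sprintf("%x", sample(0L:15L, 32, replace = TRUE))
  hex[13] <- "4"
  hex[17] <- sprintf("%x", sample(8L:11L, 1))
  paste0(
    paste(hex[1:8], collapse = ""), "-", paste(hex[9:12], collapse = ""), "-",
    paste(hex[13:16], collapse = ""), "-", paste(hex[17:20], collapse = ""), "-",
    paste(hex[21:32], collapse = "")
  )
}

# FHIR fragment constructors -------------------------------------------------

fhir_coding <- function(concept) {
  list(system = concept$system, code = concept$code, display = concept$display)
}

fhir_codeable_concept <- function(concept, extra_codings = list()) {
  codings <- c(list(fhir_coding(concept)), lapply(extra_codings, fhir_coding))
  list(coding = codings, text = concept$display)
}

fhir_quantity <- function(value, unit, code) {
  list(value = value, unit = unit, system = UCUM_SYSTEM, code = code)
}

fhir_reference <- function(ref) list(reference = ref)

# Path-wise getter on nested lists: get_path(x, c("meta","profile")) -> NULL if absent
get_path <- function(x, path) {
  for (p in path) {
    if (is.null(x)) return(NULL)
    x <- x[[p]]
  }
  x
}

compact_list <- function(x) x[!vapply(x, is.null, logical(1))]

# indexed map that lets conditions raised in `f` propagate untouched
imap_indexed <- function(x, f) lapply(seq_along(x), function(i) f(x[[i]], i))

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x)
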