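# Machine-readable profile definitions for the four BOA profiles. Each is a
# constraint table over top-level elements of its base resource (cardinality,
# fixed value or pattern, required binding) plus named whole-resource rules
# (component layouts, UCUM unit discipline, DICOM identifier grammar) that a
# flat path table cannot express. The set is exportable as
# StructureDefinition-style JSON and re-loadable from it.

# concepts from the project-local code system used as fixed codes
boa_local_concept <- function(code, display) {
  concept(unname(boa_systems()["local"]), code, display)
}

slice_range_concept <- function() boa_local_concept("bca-slice-range", "slice range")
mean_density_concept <- function() boa_local_concept("bca-mean-density", "mean tissue density")
bsv_panel_concept <- function() {
  boa_local_concept("body-structure-volume-panel", "body structure volume panel")
}
report_code_concept <- function() {
  boa_local_concept("boa-analysis-report", "body and organ analysis report")
}
procedure_code_concept <- function() {
  boa_local_concept("ai-image-analysis", "automated image analysis procedure")
}
imaging_category_concept <- function() {
  concept(OBS_CATEGORY_SYSTEM, "imaging", "Imaging")
}

profile_canonical <- function(id) {
  paste0(boa_canonical_base(), "/StructureDefinition/", id)
}

#' Canonical URL of the integrated Read Procedure profile
#'
#' The Procedure resources built by this package reference the Medical
#' Informatics Initiative Procedure profile by canonical URL (it is an external
#' profile, not re-defined here). Override with
#' `options(boafhir.procedure_profile = ...)`.
#' @return A length-1 character URL.
#' @export
read_procedure_canonical <- function() {
  getOption(
    "boafhir.procedure_profile",
    "https://www.medizininformatik-initiative.de/fhir/core/modul-prozedur/StructureDefinition/Procedure"
  )
}

new_constraint <- function(path, min = 0L, max = "*", fixed = NULL,
                           binding_valueset = NA_character_,
                           binding_strength = NA_character_,
                           datatype = NA_character_) {
  tibble(path = path, min = as.integer(min), max = max, fixed = list(fixed),
         binding_valueset = binding_valueset, binding_strength = binding_strength,
         datatype = datatype)
}

new_profile <- function(id, title, base_resource, constraints, rules = character()) {
  bad <- constraints$min > ifelse(constraints$max == "*", Inf,
                                  suppressWarnings(as.numeric(constraints$max)))
  if (any(bad)) abort("profile constraint with min > max", class = "boa_invalid_profile")
  structure(
    list(id = id, title = title, canonical_url = profile_canonical(id),
         base_resource = base_resource, constraints = constraints, rules = rules),
    class = "boa_profile"
  )
}

#' @export
print.boa_profile <- function(x, ...) {
  cat(sprintf("<boa_profile> %s (%s on %s)\n  %s\n  %d constraints, rules: %s\n",
              x$id, x$title, x$base_resource, x$canonical_url,
              nrow(x$constraints), paste(x$rules, collapse = ", ")))
  invisible(x)
}

#' Export the BOA profile definitions
#'
#' Returns the four profiles: BCA Observation (per-region body-composition
#' measurements), Body Structure Volume Observation (one component per organ),
#' Diagnostic Report (the central aggregator), and Imaging Study (only the
#' series used for inference). The Read Procedure profile is referenced by
#' canonical URL ([read_procedure_canonical()]), not re-defined.
#'
#' @return Named list of `boa_profile` objects.
#' @export
export_profile_definitions <- function() {
  base <- boa_canonical_base()
  cached <- .boa_env$profile_cache
  if (!is.null(cached) && identical(attr(cached, "base"), base)) return(cached)
  bca <- new_profile(
    "boa-bca-observation", "BCA Observation", "Observation",
    bind_rows(
      new_constraint("status", 1L, "1", fixed = "final", datatype = "code"),
      new_constraint("category", 1L, "*", fixed = imaging_category_concept(),
                     datatype = "CodeableConcept"),
      new_constraint("code", 1L, "1", binding_valueset = "BCAMeasurementsVS",
                     binding_strength = "required", datatype = "CodeableConcept"),
      new_constraint("bodySite", 1L, "1", binding_valueset = "BCABodySiteVS",
                     binding_strength = "required", datatype = "CodeableConcept"),
      new_constraint("subject", 1L, "1", datatype = "Reference"),
      new_constraint("derivedFrom", 1L, "*", datatype = "Reference"),
      new_constraint("component", 1L, "*")
    ),
    rules = c("bca-components", "ucum-units")
  )
  bsv <- new_profile(
    "boa-body-structure-volume-observation", "Body Structure Volume Observation",
    "Observation",
    bind_rows(
      new_constraint("status", 1L, "1", fixed = "final", datatype = "code"),
      new_constraint("category", 1L, "*", fixed = imaging_category_concept(),
                     datatype = "CodeableConcept"),
      new_constraint("code", 1L, "1", fixed = bsv_panel_concept(),
                     datatype = "CodeableConcept"),
      new_constraint("subject", 1L, "1", datatype = "Reference"),
      new_constraint("derivedFrom", 1L, "*", datatype = "Reference"),
      new_constraint("component", 1L, "*")
    ),
    rules = c("organ-components", "ucum-units")
  )
  report <- new_profile(
    "boa-diagnostic-report", "Diagnostic Report", "DiagnosticReport",
    bind_rows(
      new_constraint("status", 1L, "1", fixed = "final", datatype = "code"),
      new_constraint("identifier", 1L, "*"),
      new_constraint("code", 1L, "1", fixed = report_code_concept(),
                     datatype = "CodeableConcept"),
      new_constraint("subject", 1L, "1", datatype = "Reference"),
      new_constraint("result", 1L, "*", datatype = "Reference"),
      new_constraint("imagingStudy", 1L, "1", datatype = "Reference")
    ),
    rules = c("dicom-identifier", "presented-form-mime")
  )
  study <- new_profile(
    "boa-imaging-study", "Imaging Study", "ImagingStudy",
    bind_rows(
      new_constraint("status", 1L, "1", fixed = "available", datatype = "code"),
      new_constraint("identifier", 1L, "*"),
      new_constraint("subject", 1L, "1", datatype = "Reference"),
      new_constraint("numberOfSeries", 1L, "1"),
      new_constraint("series", 1L, "*")
    ),
    rules = c("dicom-identifier", "series-elements", "number-of-series")
  )
  out <- list(
    "boa-bca-observation" = bca,
    "boa-body-structure-volume-observation" = bsv,
    "boa-diagnostic-report" = report,
    "boa-imaging-study" = study
  )
  attr(out, "base") <- base
  .boa_env$profile_cache <- out
  out
}

#' Serialize a profile definition as StructureDefinition-style JSON
#'
#' @param profile A `boa_profile` from [export_profile_definitions()].
#' @return A list ready for JSON serialization.
#' @export
as_structure_definition <- function(profile) {
  elements <- lapply(seq_len(nrow(profile$constraints)), function(i) {
    r <- profile$constraints[i, ]
    path <- paste0(profile$base_resource, ".", r$path)
    el <- list(id = path, path = path, min = r$min, max = r$max)
    fx <- r$fixed[[1]]
    if (!is.null(fx)) {
      if (identical(r$datatype, "code")) {
        el$fixedCode <- fx
      } else {
        el$patternCodeableConcept <- list(coding = list(fhir_coding(fx)))
      }
    }
    if (!is.na(r$binding_valueset)) {
      el$binding <- list(
        strength = r$binding_strength,
        valueSet = paste0(boa_canonical_base(), "/ValueSet/", r$binding_valueset)
      )
    }
    el
  })
  list(
    resourceType = "StructureDefinition",
    id = profile$id,
    url = profile$canonical_url,
    name = gsub("[^A-Za-z]", "", profile$title),
    title = profile$title,
    status = "active",
    kind = "resource",
    abstract = FALSE,
    type = profile$base_resource,
    baseDefinition = paste0("http://hl7.org/fhir/StructureDefinition/",
                            profile$base_resource),
    derivation = "constraint",
    extension = list(list(
      url = paste0(boa_canonical_base(), "/StructureDefinition/validator-rules"),
      valueString = paste(profile$rules, collapse = " ")
    )),
    differential = list(element = elements)
  )
}

#' Read a profile definition back from StructureDefinition JSON
#'
#' Inverse of [as_structure_definition()]; used by the CLI's `--profile-dir`.
#'
#' @param x File path or parsed list.
#' @return A `boa_profile`.
#' @export
profile_from_json <- function(x) {
  doc <- if (is.list(x)) x else read_json_file(x)
  stopifnot(identical(doc$resourceType, "StructureDefinition"))
  cons <- bind_rows(lapply(doc$differential$element, function(el) {
    fixed <- NULL
    datatype <- NA_character_
    if (!is.null(el$fixedCode)) {
      fixed <- el$fixedCode
      datatype <- "code"
    } else if (!is.null(el$patternCodeableConcept)) {
      cd <- el$patternCodeableConcept$coding[[1]]
      fixed <- concept(cd$system, cd$code, cd$display)
      datatype <- "CodeableConcept"
    }
    vs <- if (!is.null(el$binding)) basename(el$binding$valueSet) else NA_character_
    new_constraint(sub("^[^.]+\\.", "", el$path), el$min, el$max, fixed = fixed,
                   binding_valueset = vs,
                   binding_strength = if (!is.null(el$binding)) el$binding$strength else NA_character_,
                   datatype = datatype)
  }))
  rules <- character()
  for (ext in doc$extension %||% list()) {
    if (grepl("validator-rules$", ext$url)) rules <- strsplit(ext$valueString, " ")[[1]]
  }
  prof <- new_profile(doc$id, doc$title, doc$type, cons, rules)
  prof$canonical_url <- doc$url
  prof
}

#' Write all profile definitions as JSON files
#'
#' @param dir Output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
write_profile_definitions <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- map_chr(export_profile_definitions(), function(p) {
    path <- file.path(dir, paste0(p$id, ".json"))
    writeLines(to_canonical_json(as_structure_definition(p)), path, useBytes = TRUE)
    path
  })
  invisible(paths)
}
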