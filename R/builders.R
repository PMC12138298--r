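# Builders: BOAResult -> profile-conformant FHIR R4 resources and the
# referentially closed transaction Bundle. Resources are nested lists whose
# shape is exactly the FHIR JSON; serialize with fhir_json().

#' Build context for FHIR resource construction
#'
#' @param patient_reference Reference string for the analyzed patient
#'   (e.g. `"Patient/123"`).
#' @param canonical_base Base URL for profile canonicals and entry fullUrls.
#' @param timestamp Optional instant recorded on the DiagnosticReport
#'   (`issued`); omitted when `NULL` so that deterministic builds stay
#'   reproducible.
#' @param id_strategy `"deterministic"` (content-hash ids; identical input
#'   yields a byte-identical Bundle) or `"uuid"` (random version-4 UUIDs).
#' @return An object of class `boa_context`.
#' @export
build_context <- function(patient_reference,
                          canonical_base = boa_canonical_base(),
                          timestamp = NULL,
                          id_strategy = c("deterministic", "uuid")) {
  if (!is_string(patient_reference) || !nzchar(patient_reference)) {
    abort("patient_reference must be a non-empty reference string",
          class = "boa_build_error")
  }
  if (!grepl("^[a-zA-Z][a-zA-Z0-9+.-]*:|^[A-Za-z]+/", canonical_base) ||
      !grepl("^https?://", canonical_base)) {
    abort("canonical_base must be an absolute http(s) URI", class = "boa_build_error")
  }
  structure(
    list(patient_reference = patient_reference,
         canonical_base = sub("/+$", "", canonical_base),
         timestamp = timestamp,
         id_strategy = match.arg(id_strategy)),
    class = "boa_context"
  )
}

build_error <- function(msg, path = NULL) {
  abort(msg, class = "boa_build_error", path = path)
}

# assign a resource id: content hash of the id-less resource, or a random UUID
assign_id <- function(resource, ctx, prefix) {
  resource$id <- if (ctx$id_strategy == "deterministic") {
    paste0(prefix, "-", substr(content_hash(to_canonical_json(resource)), 1, 12))
  } else {
    random_uuid()
  }
  # keep id first for readable JSON
  resource[c("resourceType", "id", setdiff(names(resource), c("resourceType", "id")))]
}

resource_meta <- function(profile_url) list(profile = list(profile_url))

dicom_identifier <- function(uid) {
  list(system = DICOM_UID_SYSTEM, value = paste0("urn:oid:", uid))
}

#' Extract the study UID from a built resource's DICOM identifier
#' @param resource A built ImagingStudy or DiagnosticReport.
#' @return The dotted-decimal study UID, or `NA` if absent.
#' @export
boa_study_uid <- function(resource) {
  for (id in resource$identifier %||% list()) {
    if (identical(id$system, DICOM_UID_SYSTEM)) {
      return(sub("^urn:oid:", "", id$value))
    }
  }
  NA_character_
}

require_member <- function(concept, valueset_id, path) {
  if (!isTRUE(validate_membership(concept, valueset_id))) {
    build_error(sprintf("%s: concept (%s, %s) is not a member of %s",
                        path, concept$system %||% "?", concept$code %||% "?",
                        valueset_id), path = path)
  }
}

#' Build a BCA Observation for one region measurement
#'
#' One Observation per body-site-and-mode region: `code` carries the
#' measurement mode (BCAMeasurementsVS), `bodySite` the cavity (BCABodySiteVS),
#' and each tissue contributes a volume component (UCUM mL) plus, when a mean
#' density is present, a paired density component (UCUM Hounsfield unit) whose
#' code combines the local mean-density concept with the tissue coding. An
#' optional slice-range component carries an integer Range.
#'
#' @param region One region measurement from a [boa_result()].
#' @param ctx A [build_context()].
#' @param study_ref Reference to the Bundle's ImagingStudy.
#' @return An Observation resource (nested list).
#' @export
build_bca_observation <- function(region, ctx, study_ref) {
  require_member(region$body_site, "BCABodySiteVS", "Observation.bodySite")
  require_member(region$mode, "BCAMeasurementsVS", "Observation.code")
  if (length(region$tissues) == 0) build_error("region has no tissue measurements")
  for (t in region$tissues) {
    require_member(t$tissue, "BCATissueVS", "Observation.component.code")
  }

  components <- list()
  for (t in region$tissues) {
    components[[length(components) + 1]] <- list(
      code = fhir_codeable_concept(t$tissue),
      valueQuantity = fhir_quantity(t$volume_ml, "mL", UCUM_ML)
    )
    if (!is.null(t$mean_density_hu)) {
      components[[length(components) + 1]] <- list(
        code = fhir_codeable_concept(mean_density_concept(),
                                     extra_codings = list(t$tissue)),
        valueQuantity = fhir_quantity(t$mean_density_hu, "HU", UCUM_HU)
      )
    }
  }
  if (!is.null(region$slice_range)) {
    components[[length(components) + 1]] <- list(
      code = fhir_codeable_concept(slice_range_concept()),
      valueRange = list(
        low = fhir_quantity(region$slice_range$low, "slice", "1"),
        high = fhir_quantity(region$slice_range$high, "slice", "1")
      )
    )
  }

  obs <- compact_list(list(
    resourceType = "Observation",
    meta = resource_meta(profile_canonical("boa-bca-observation")),
    status = "final",
    category = list(list(coding = list(fhir_coding(imaging_category_concept())))),
    code = fhir_codeable_concept(region$mode),
    subject = fhir_reference(ctx$patient_reference),
    bodySite = fhir_codeable_concept(region$body_site),
    derivedFrom = list(fhir_reference(study_ref)),
    component = components
  ))
  assign_id(obs, ctx, "bca")
}

#' Build the Body Structure Volume Observation
#'
#' A single Observation holding one component per organ: a mandatory
#' CodeableConcept identifying the structure (BodyStructureLandmarkVS) and a
#' Quantity with the UCUM code for millilitres.
#'
#' @param organs Non-empty list of organ volumes from a [boa_result()].
#' @inheritParams build_bca_observation
#' @return An Observation resource.
#' @export
build_body_structure_observation <- function(organs, ctx, study_ref) {
  if (length(organs) == 0) build_error("organ volume collection must be non-empty")
  keys <- map_chr(organs, function(o) paste(o$structure$system, o$structure$code))
  if (anyDuplicated(keys)) build_error("duplicate structure concepts in organ volumes")
  for (o in organs) {
    require_member(o$structure, "BodyStructureLandmarkVS", "Observation.component.code")
  }
  obs <- list(
    resourceType = "Observation",
    meta = resource_meta(profile_canonical("boa-body-structure-volume-observation")),
    status = "final",
    category = list(list(coding = list(fhir_coding(imaging_category_concept())))),
    code = fhir_codeable_concept(bsv_panel_concept()),
    subject = fhir_reference(ctx$patient_reference),
    derivedFrom = list(fhir_reference(study_ref)),
    component = lapply(organs, function(o) list(
      code = fhir_codeable_concept(o$structure),
      valueQuantity = fhir_quantity(o$volume_ml, "mL", UCUM_ML)
    ))
  )
  assign_id(obs, ctx, "bsv")
}

#' Build the Imaging Study resource
#'
#' References only the series used for AI inference: `numberOfSeries` counts
#' the listed inference series, and the study is identified by its DICOM study
#' instance UID under the `urn:dicom:uid` scheme.
#'
#' @param result A [boa_result()].
#' @param ctx A [build_context()].
#' @return An ImagingStudy resource.
#' @export
build_imaging_study <- function(result, ctx) {
  if (!validate_dicom_uid(result$study_uid)) {
    build_error(paste0("invalid study UID: ", result$study_uid),
                path = "ImagingStudy.identifier")
  }
  uids <- map_chr(result$series, function(s) s$series_uid)
  if (anyDuplicated(uids)) build_error("duplicate series UIDs")
  if (!all(validate_dicom_uid(uids))) build_error("invalid series UID")
  study <- compact_list(list(
    resourceType = "ImagingStudy",
    meta = resource_meta(profile_canonical("boa-imaging-study")),
    identifier = list(dicom_identifier(result$study_uid)),
    status = "available",
    subject = fhir_reference(ctx$patient_reference),
    started = result$started,
    numberOfSeries = length(result$series),
    series = lapply(result$series, function(s) compact_list(list(
      uid = s$series_uid,
      modality = list(system = DCM_SYSTEM, code = s$modality %||% "CT"),
      numberOfInstances = s$number_of_instances,
      bodySite = if (!is.null(s$body_site)) fhir_coding(s$body_site)
    )))
  ))
  assign_id(study, ctx, "study")
}

#' Build the Diagnostic Report (central aggregator)
#'
#' Links every built Observation (`result`), the Imaging Study
#' (`imagingStudy`), and carries the rendered reports as `presentedForm`
#' attachments (PDF, JSON, or spreadsheet).
#'
#' @param result A [boa_result()].
#' @param observation_refs Non-empty character vector of Observation references.
#' @param study_ref Reference to the ImagingStudy.
#' @param ctx A [build_context()].
#' @return A DiagnosticReport resource.
#' @export
build_diagnostic_report <- function(result, observation_refs, study_ref, ctx) {
  if (length(observation_refs) == 0) {
    build_error("a diagnostic report must aggregate at least one observation",
                path = "DiagnosticReport.result")
  }
  for (a in result$attachments) {
    if (!(a$content_type %||% "") %in% SUPPORTED_MIMES) {
      build_error(paste0("unsupported presentedForm MIME type: ",
                         a$content_type %||% "<missing>"),
                  path = "DiagnosticReport.presentedForm")
    }
  }
  report <- compact_list(list(
    resourceType = "DiagnosticReport",
    meta = resource_meta(profile_canonical("boa-diagnostic-report")),
    identifier = list(dicom_identifier(result$study_uid)),
    status = "final",
    code = fhir_codeable_concept(report_code_concept()),
    subject = fhir_reference(ctx$patient_reference),
    issued = ctx$timestamp,
    result = lapply(observation_refs, fhir_reference),
    imagingStudy = list(fhir_reference(study_ref)),
    presentedForm = if (length(result$attachments)) {
      lapply(result$attachments, function(a) compact_list(list(
        contentType = a$content_type, data = a$data, url = a$url
      )))
    }
  ))
  assign_id(report, ctx, "report")
}

#' Build the Read Procedure resource
#'
#' Documents the AI model run: name, version, and computational parameters are
#' stored as structured `key=value` annotations, and the procedure's `report`
#' element links back to the Diagnostic Report. The resource targets the base
#' Procedure resource and declares the external Read Procedure profile
#' ([read_procedure_canonical()]) in `meta.profile`.
#'
#' @param model Model metadata list (`name`, `version`, named `parameters`).
#' @param report_ref Reference to the DiagnosticReport.
#' @param ctx A [build_context()].
#' @return A Procedure resource.
#' @export
build_read_procedure <- function(model, report_ref, ctx) {
  if (!is_string(model$name %||% "") || !nzchar(model$name %||% "")) {
    build_error("model name must be non-empty", path = "Procedure.note")
  }
  if (!is_string(model$version %||% "") || !nzchar(model$version %||% "")) {
    build_error("model version must be non-empty", path = "Procedure.note")
  }
  params <- model$parameters %||% character()
  notes <- c(
    paste0("name=", model$name),
    paste0("version=", model$version),
    if (length(params)) paste0("parameter.", names(params), "=", unname(params))
  )
  proc <- list(
    resourceType = "Procedure",
    meta = resource_meta(read_procedure_canonical()),
    status = "completed",
    code = fhir_codeable_concept(procedure_code_concept()),
    subject = fhir_reference(ctx$patient_reference),
    report = list(fhir_reference(report_ref)),
    note = lapply(notes, function(n) list(text = n))
  )
  assign_id(proc, ctx, "read")
}

#' Tag a resource as AI-asserted (AIAST)
#'
#' Adds the HL7 `AIAST` (Artificial Intelligence Asserted) security tag to
#' `meta.security` so consumers can tell AI-generated data from human-entered
#' data. Idempotent: applying it twice leaves exactly one tag, and nothing
#' outside `meta` is touched.
#'
#' @param resource Any built resource.
#' @return The tagged resource.
#' @export
tag_ai_provenance <- function(resource) {
  sec <- resource$meta$security %||% list()
  already <- any(map_lgl(sec, function(s) {
    identical(s$system, SECURITY_SYSTEM) && identical(s$code, "AIAST")
  }))
  if (!already) {
    sec[[length(sec) + 1]] <- list(system = SECURITY_SYSTEM, code = "AIAST",
                                   display = "Artificial Intelligence asserted")
    resource$meta$security <- sec
  }
  resource
}

has_aiast <- function(resource) {
  any(map_lgl(resource$meta$security %||% list(), function(s) {
    identical(s$system, SECURITY_SYSTEM) && identical(s$code, "AIAST")
  }))
}

#' Assemble the transaction Bundle for a BOA result
#'
#' Builds the Imaging Study, one BCA Observation per region, the Body
#' Structure Volume Observation (when organs are present), the Diagnostic
#' Report and the Read Procedure; tags every resource AIAST; and wires all
#' internal references so the Bundle is referentially closed.
#'
#' @param result A [boa_result()].
#' @param ctx A [build_context()]; defaults to a deterministic context whose
#'   patient reference is derived from the result's patient id.
#' @return A Bundle resource (class `boa_bundle`).
#' @export
#' @examples
#' b <- assemble_bundle(generate_synthetic_result(1))
#' length(b$entry)  # 12 under generator defaults
assemble_bundle <- function(result,
                            ctx = build_context(paste0("Patient/", result$patient_id))) {
  stopifnot(inherits(result, "boa_result"))
  study <- build_imaging_study(result, ctx)
  study_ref <- paste0("ImagingStudy/", study$id)

  observations <- lapply(result$regions, function(r) {
    build_bca_observation(r, ctx, study_ref)
  })
  if (length(result$organs)) {
    observations[[length(observations) + 1]] <-
      build_body_structure_observation(result$organs, ctx, study_ref)
  }
  obs_refs <- map_chr(observations, function(o) paste0("Observation/", o$id))

  report <- build_diagnostic_report(result, obs_refs, study_ref, ctx)
  proc <- build_read_procedure(result$model, paste0("DiagnosticReport/", report$id), ctx)

  resources <- c(list(study), observations, list(report, proc))
  resources <- lapply(resources, tag_ai_provenance)

  entries <- lapply(resources, function(res) list(
    fullUrl = paste0(ctx$canonical_base, "/", res$resourceType, "/", res$id),
    resource = res,
    request = list(method = "POST", url = res$resourceType)
  ))
  bundle <- list(
    resourceType = "Bundle",
    id = NULL,
    type = "transaction",
    entry = entries
  )
  bundle$id <- if (ctx$id_strategy == "deterministic") {
    paste0("boa-", substr(content_hash(to_canonical_json(entries)), 1, 12))
  } else {
    random_uuid()
  }
  structure(compact_list(bundle)[c("resourceType", "id", "type", "entry")],
            class = c("boa_bundle", "list"))
}

#' Serialize a resource or Bundle to FHIR R4 JSON
#' @param resource A built resource or Bundle.
#' @return A JSON string.
#' @export
fhir_json <- function(resource) to_canonical_json(unclass(resource))

#' Write a resource or Bundle to a JSON file
#' @param resource A built resource or Bundle.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fhir <- function(resource, path) {
  writeLines(fhir_json(resource), path, useBytes = TRUE)
  invisible(path)
}

#' Write a Bundle as NDJSON (one resource per line)
#' @param bundle A Bundle.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ndjson <- function(bundle, path) {
  lines <- map_chr(bundle$entry, function(e) {
    as.character(jsonlite::toJSON(e$resource, auto_unbox = TRUE, digits = NA,
                                  null = "null", na = "null"))
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.boa_bundle <- function(x, ...) {
  types <- table(map_chr(x$entry, function(e) e$resource$resourceType))
  cat("<boa_bundle>", x$id, "-", length(x$entry), "entries:",
      paste(sprintf("%s x%d", names(types), as.integer(types)), collapse = ", "), "\n")
  invisible(x)
}

#' Push a transaction Bundle to a FHIR server (feature-flagged)
#'
#' Disabled unless `options(boafhir.enable_push = TRUE)` is set: the package's
#' contract is file based and no test or script performs network calls. When
#' enabled, the Bundle is POSTed to `server` with the system `curl` binary.
#'
#' @param bundle A Bundle.
#' @param server FHIR base URL.
#' @return Exit status of the POST, invisibly.
#' @export
push_bundle <- function(bundle, server) {
  if (!isTRUE(getOption("boafhir.enable_push"))) {
    abort("push is disabled; set options(boafhir.enable_push = TRUE) to allow network use",
          class = "boa_push_disabled")
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_fhir(bundle, tmp)
  status <- system2("curl", c("-sf", "-X", "POST",
                              "-H", shQuote("Content-Type: application/fhir+json"),
                              "--data-binary", paste0("@", tmp), shQuote(server)))
  invisible(status)
}
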