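# Data model for one body-and-organ analysis of one CT study, plus its
# canonical JSON form. The JSON schema is shipped at
# inst/extdata/boa-result-schema.json; coded fields are carried as labels and
# resolved through the terminology layer on parse.

#' Validate a DICOM UID
#'
#' A DICOM UID is dotted-decimal: components are non-empty, digits only, have
#' no leading zero (unless the component is exactly "0"), and the whole string
#' is at most 64 characters.
#'
#' @param text Character vector to test.
#' @return Logical vector, `TRUE` where the string is a well-formed UID.
#' @export
#' @examples
#' validate_dicom_uid("1.2.840.10008.1.2")  # TRUE
#' validate_dicom_uid("1.2.04.5")           # FALSE (leading zero)
validate_dicom_uid <- function(text) {
  vapply(text, function(s) {
    if (!is.character(s) || is.na(s) || !nzchar(s) || nchar(s) > 64) return(FALSE)
    comps <- strsplit(s, ".", fixed = TRUE)[[1]]
    # strsplit drops a trailing empty component ("1." -> "1"): reject explicitly
    if (startsWith(s, ".") || endsWith(s, ".") || grepl("..", s, fixed = TRUE)) return(FALSE)
    if (length(comps) == 0) return(FALSE)
    all(vapply(comps, function(p) {
      nzchar(p) && grepl("^[0-9]+$", p) && (p == "0" || !startsWith(p, "0"))
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}

# -- constructors -------------------------------------------------------------

#' Assemble a BOA result
#'
#' The in-memory form of one AI analysis of one CT study. All coded fields are
#' [concept()] objects; `parse_boa_result()` builds them from labels.
#'
#' @param patient_id Opaque patient identifier.
#' @param study_uid DICOM study instance UID.
#' @param series List of series entries, each a list with `series_uid`,
#'   optional `modality` (default `"CT"`), `number_of_instances`, `body_site`.
#' @param regions List of region measurements, each a list with `body_site`
#'   and `mode` concepts, optional `slice_range` (`list(low=, high=)`), and a
#'   non-empty `tissues` list of `list(tissue=, volume_ml=, mean_density_hu=)`.
#' @param organs List of `list(structure = concept, volume_ml = number)`.
#' @param model List with `name`, `version`, and named character `parameters`.
#' @param attachments List of `list(content_type=, data=)` or
#'   `list(content_type=, url=)` report attachments.
#' @param started Optional ISO-8601 timestamp of the acquisition/analysis.
#' @return An object of class `boa_result`.
#' @export
boa_result <- function(patient_id, study_uid, series, regions = list(),
                       organs = list(), model, attachments = list(),
                       started = NULL) {
  x <- structure(
    list(patient_id = patient_id, study_uid = study_uid, started = started,
         series = series, regions = regions, organs = organs, model = model,
         attachments = attachments),
    class = "boa_result"
  )
  issues <- check_boa_result(x)
  if (length(issues)) {
    abort(paste0("invalid BOA result:\n", paste0("  - ", issues, collapse = "\n")),
          class = "boa_invalid_result", issues = issues)
  }
  x
}

SUPPORTED_MIMES <- c(
  "application/pdf", "application/json",
  "application/vnd.openxmlformats-officedocument.spreadsheetml.sheet"
)

# Invariant checks shared by the constructor and the parser; returns a
# character vector of violations (empty when valid). `at` prefixes messages
# with JSON paths for parser errors.
check_boa_result <- function(x, at = function(path, msg) paste0(path, ": ", msg)) {
  iss <- character()
  add <- function(path, msg) iss <<- c(iss, at(path, msg))
  if (!is_string(x$patient_id) || !nzchar(x$patient_id)) {
    add("$.patient_id", "must be a non-empty string")
  }
  if (!is_string(x$study_uid) || !validate_dicom_uid(x$study_uid)) {
    add("$.study_uid", "not a well-formed DICOM UID")
  }
  if (length(x$series) == 0) add("$.series", "at least one series is required")
  uids <- map_chr(x$series, function(s) s$series_uid %||% "")
  for (i in seq_along(x$series)) {
    if (!validate_dicom_uid(uids[i])) {
      add(sprintf("$.series[%d].series_uid", i), "not a well-formed DICOM UID")
    }
  }
  if (anyDuplicated(uids)) add("$.series", "series UIDs must be pairwise distinct")
  if (length(x$regions) == 0 && length(x$organs) == 0) {
    add("$", "at least one of regions/organs must be non-empty")
  }
  for (i in seq_along(x$regions)) {
    r <- x$regions[[i]]
    p <- sprintf("$.regions[%d]", i)
    if (!isTRUE(validate_membership(r$body_site, "BCABodySiteVS"))) {
      add(paste0(p, ".body_site"), "not a member of BCABodySiteVS")
    }
    if (!isTRUE(validate_membership(r$mode, "BCAMeasurementsVS"))) {
      add(paste0(p, ".measurement_mode"), "not a member of BCAMeasurementsVS")
    }
    if (!is.null(r$slice_range)) {
      lo <- r$slice_range$low; hi <- r$slice_range$high
      ok <- is_scalar_number(lo) && is_scalar_number(hi) &&
        lo == round(lo) && hi == round(hi) && lo >= 1 && lo <= hi
      if (!ok) add(paste0(p, ".slice_range"), "requires integers 1 <= low <= high")
    }
    if (length(r$tissues) == 0) add(paste0(p, ".tissues"), "must be non-empty")
    tcodes <- map_chr(r$tissues, function(t) paste(t$tissue$system, t$tissue$code))
    if (anyDuplicated(tcodes)) add(paste0(p, ".tissues"), "duplicate tissue concepts")
    for (j in seq_along(r$tissues)) {
      t <- r$tissues[[j]]
      tp <- sprintf("%s.tissues[%d]", p, j)
      if (!isTRUE(validate_membership(t$tissue, "BCATissueVS"))) {
        add(paste0(tp, ".tissue"), "not a member of BCATissueVS")
      }
      if (!is_scalar_number(t$volume_ml) || t$volume_ml < 0) {
        add(paste0(tp, ".volume_ml"), "must be a non-negative number")
      }
      if (!is.null(t$mean_density_hu) &&
          (!is_scalar_number(t$mean_density_hu) ||
           t$mean_density_hu < -1024 || t$mean_density_hu > 3071)) {
        add(paste0(tp, ".mean_density_hu"), "must lie in [-1024, 3071] HU")
      }
    }
  }
  ocodes <- map_chr(x$organs, function(o) paste(o$structure$system, o$structure$code))
  if (anyDuplicated(ocodes)) add("$.organs", "duplicate structure concepts")
  for (i in seq_along(x$organs)) {
    o <- x$organs[[i]]
    p <- sprintf("$.organs[%d]", i)
    if (!isTRUE(validate_membership(o$structure, "BodyStructureLandmarkVS"))) {
      add(paste0(p, ".structure"), "not a member of BodyStructureLandmarkVS")
    }
    if (!is_scalar_number(o$volume_ml) || o$volume_ml < 0) {
      add(paste0(p, ".volume_ml"), "must be a non-negative number")
    }
  }
  if (!is_string(x$model$name %||% "") || !nzchar(x$model$name %||% "")) {
    add("$.model.name", "must be a non-empty string")
  }
  if (!is_string(x$model$version %||% "") || !nzchar(x$model$version %||% "")) {
    add("$.model.version", "must be a non-empty string")
  }
  for (i in seq_along(x$attachments)) {
    a <- x$attachments[[i]]
    p <- sprintf("$.attachments[%d]", i)
    if (!(a$content_type %||% "") %in% SUPPORTED_MIMES) {
      add(paste0(p, ".content_type"), "unsupported report format")
    }
    if (sum(!is.null(a$data), !is.null(a$url)) != 1) {
      add(p, "exactly one of data/url is required")
    }
  }
  iss
}

# -- parse / serialize --------------------------------------------------------

#' Parse a BOA result JSON document
#'
#' Reads the canonical BOA result JSON (file path, JSON string, or an already
#' parsed list), resolves every coded field through [lookup_concept()], and
#' enforces all model invariants. Unknown top-level keys are ignored with a
#' warning. Violations raise a structured parse error naming the JSON path.
#'
#' @param x File path, JSON string, or list.
#' @return A [boa_result()].
#' @export
parse_boa_result <- function(x) {
  doc <- if (is.list(x)) {
    x
  } else if (is_string(x) && grepl("^\\s*\\{", x)) {
    jsonlite::fromJSON(x, simplifyVector = FALSE)
  } else if (is_string(x) && file.exists(x)) {
    read_json_file(x)
  } else {
    abort("input is neither a JSON object, an existing file, nor a list",
          class = "boa_parse_error", path = "$")
  }

  known <- c("patient_id", "study_uid", "started", "series", "regions",
             "organs", "model", "attachments")
  extra <- setdiff(names(doc), known)
  if (length(extra)) {
    warn(paste0("ignoring unknown top-level keys: ", paste(extra, collapse = ", ")))
  }

  perr <- function(path, msg) {
    abort(paste0("parse error at ", path, ": ", msg),
          class = "boa_parse_error", path = path)
  }
  need <- function(field) {
    if (is.null(doc[[field]])) perr(paste0("$.", field), "required field is missing")
    doc[[field]]
  }
  code_at <- function(label, path, preferred_system = NULL) {
    tryCatch(lookup_concept(label, preferred_system),
             boa_unmapped_label = function(e) perr(path, conditionMessage(e)))
  }

  patient_id <- need("patient_id")
  study_uid <- need("study_uid")
  if (!is_string(study_uid) || !validate_dicom_uid(study_uid)) {
    perr("$.study_uid", "not a well-formed DICOM UID")
  }
  series_in <- need("series")
  series <- imap_indexed(series_in, function(s, i) {
    p <- sprintf("$.series[%d]", i)
    if (is.null(s$series_uid)) perr(paste0(p, ".series_uid"), "required field is missing")
    if (!validate_dicom_uid(s$series_uid)) {
      perr(paste0(p, ".series_uid"), "not a well-formed DICOM UID")
    }
    compact_list(list(
      series_uid = s$series_uid,
      modality = s$modality %||% "CT",
      number_of_instances = if (!is.null(s$number_of_instances)) as.integer(s$number_of_instances),
      body_site = if (!is.null(s$body_site)) code_at(s$body_site, paste0(p, ".body_site"))
    ))
  })
  regions <- imap_indexed(doc$regions %||% list(), function(r, i) {
    p <- sprintf("$.regions[%d]", i)
    if (is.null(r$tissues) || length(r$tissues) == 0) {
      perr(paste0(p, ".tissues"), "required non-empty field is missing")
    }
    compact_list(list(
      body_site = code_at(r$body_site %||% perr(paste0(p, ".body_site"), "required field is missing"),
                          paste0(p, ".body_site")),
      mode = code_at(r$measurement_mode %||% perr(paste0(p, ".measurement_mode"), "required field is missing"),
                     paste0(p, ".measurement_mode")),
      slice_range = if (!is.null(r$slice_range)) {
        list(low = as.numeric(r$slice_range$low), high = as.numeric(r$slice_range$high))
      },
      tissues = imap_indexed(r$tissues, function(t, j) {
        tp <- sprintf("%s.tissues[%d]", p, j)
        compact_list(list(
          tissue = code_at(t$tissue %||% perr(paste0(tp, ".tissue"), "required field is missing"),
                           paste0(tp, ".tissue")),
          volume_ml = as.numeric(t$volume_ml %||% perr(paste0(tp, ".volume_ml"), "required field is missing")),
          mean_density_hu = if (!is.null(t$mean_density_hu)) as.numeric(t$mean_density_hu)
        ))
      })
    ))
  })
  organs <- imap_indexed(doc$organs %||% list(), function(o, i) {
    p <- sprintf("$.organs[%d]", i)
    list(
      structure = code_at(o$structure %||% perr(paste0(p, ".structure"), "required field is missing"),
                          paste0(p, ".structure")),
      volume_ml = as.numeric(o$volume_ml %||% perr(paste0(p, ".volume_ml"), "required field is missing"))
    )
  })
  model_in <- need("model")
  model <- list(
    name = model_in$name %||% "", version = model_in$version %||% "",
    parameters = vapply(model_in$parameters %||% list(), as.character, character(1))
  )
  attachments <- imap_indexed(doc$attachments %||% list(), function(a, i) {
    compact_list(list(content_type = a$content_type, data = a$data, url = a$url))
  })

  res <- tryCatch(
    boa_result(patient_id = patient_id, study_uid = study_uid, series = series,
               regions = regions, organs = organs, model = model,
               attachments = attachments, started = doc$started),
    boa_invalid_result = function(e) {
      abort(paste0("parse error: ", conditionMessage(e)),
            class = "boa_parse_error", path = e$issues[1])
    }
  )
  res
}

#' Serialize a BOA result to canonical JSON
#'
#' Inverse of [parse_boa_result()]: coded fields are written back as their
#' display labels. For a fixed result the output is byte-stable.
#'
#' @param result A [boa_result()].
#' @return A JSON string.
#' @export
boa_result_json <- function(result) {
  stopifnot(inherits(result, "boa_result"))
  doc <- compact_list(list(
    patient_id = result$patient_id,
    study_uid = result$study_uid,
    started = result$started,
    series = lapply(result$series, function(s) compact_list(list(
      series_uid = s$series_uid, modality = s$modality,
      number_of_instances = s$number_of_instances,
      body_site = if (!is.null(s$body_site)) s$body_site$display
    ))),
    regions = lapply(result$regions, function(r) compact_list(list(
      body_site = r$body_site$display,
      measurement_mode = r$mode$display,
      slice_range = r$slice_range,
      tissues = lapply(r$tissues, function(t) compact_list(list(
        tissue = t$tissue$display, volume_ml = t$volume_ml,
        mean_density_hu = t$mean_density_hu
      )))
    ))),
    organs = lapply(result$organs, function(o) list(
      structure = o$structure$display, volume_ml = o$volume_ml
    )),
    model = list(name = result$model$name, version = result$model$version,
                 parameters = as.list(result$model$parameters)),
    attachments = result$attachments
  ))
  to_canonical_json(doc)
}

#' Write a BOA result to a JSON file
#' @param result A [boa_result()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_boa_result <- function(result, path) {
  writeLines(boa_result_json(result), path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.boa_result <- function(x, ...) {
  cat("<boa_result>\n")
  cat("  patient:", x$patient_id, " study:", x$study_uid, "\n")
  cat(sprintf("  %d series, %d regions, %d organ volumes, model %s %s\n",
              length(x$series), length(x$regions), length(x$organs),
              x$model$name, x$model$version))
  invisible(x)
}

# -- tidy accessors -----------------------------------------------------------

#' Tabular views of a BOA result
#'
#' `boa_organs()` returns one row per organ volume; `boa_tissues()` one row per
#' (region, tissue) measurement.
#'
#' @param result A [boa_result()].
#' @return A tibble.
#' @export
boa_organs <- function(result) {
  bind_rows(lapply(result$organs, function(o) tibble(
    structure = o$structure$display, system = o$structure$system,
    code = o$structure$code, volume_ml = o$volume_ml
  )))
}

#' @rdname boa_organs
#' @export
boa_tissues <- function(result) {
  bind_rows(lapply(result$regions, function(r) {
    bind_rows(lapply(r$tissues, function(t) tibble(
      body_site = r$body_site$display, mode = r$mode$display,
      tissue = t$tissue$display, volume_ml = t$volume_ml,
      mean_density_hu = t$mean_density_hu %||% NA_real_
    )))
  }))
}
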