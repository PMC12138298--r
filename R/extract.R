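# Inverse transform: a conformant bundle back to a tidy measurement table
# (one row per region-tissue pair, one per organ component) and all the way
# back to a boa_result, closing the round trip.

measurement_columns <- c(
  "patient_id", "study_uid", "date", "kind", "body_site", "body_site_code",
  "mode", "tissue", "tissue_code", "structure", "structure_code",
  "slice_low", "slice_high", "volume_ml", "mean_density_hu"
)

bundle_resources <- function(bundle, type = NULL) {
  res <- lapply(bundle$entry %||% list(), function(e) e$resource)
  if (!is.null(type)) res <- keep(res, function(r) identical(r$resourceType, type))
  res
}

is_bca_observation <- function(res) {
  identical(res$resourceType, "Observation") && !is.null(res$bodySite)
}

primary_coding <- function(codeable) {
  cds <- as_coding_list(codeable)
  if (length(cds) == 0) NULL else cds[[1]]
}

#' Extract tidy measurement rows from a bundle
#'
#' Produces one row per (region, tissue) component pair and one row per organ
#' component, with values exactly as serialized in the bundle. Region rows are
#' ordered by body site, mode, then tissue display; organ rows by structure
#' display. The bundle must validate cleanly first; a non-conformant bundle is
#' refused with the validator's findings attached.
#'
#' @param bundle A Bundle (built or re-read from JSON).
#' @param validate Set `FALSE` to skip the conformance gate (internal use).
#' @return A tibble of class `boa_measurements` with the documented columns
#'   `patient_id, study_uid, date, kind, body_site, body_site_code, mode,
#'   tissue, tissue_code, structure, structure_code, slice_low, slice_high,
#'   volume_ml, mean_density_hu`.
#' @export
#' @examples
#' rows <- generate_synthetic_result(1) |> assemble_bundle() |> extract_measurements()
#' nrow(rows)  # 168 under generator defaults
extract_measurements <- function(bundle, validate = TRUE) {
  if (validate) {
    iss <- validate_bundle(bundle)
    if (any(iss$severity == "error")) {
      abort(paste0("bundle does not conform to the BOA profiles (",
                   sum(iss$severity == "error"),
                   " errors); run validate_bundle() for details"),
            class = "boa_nonconformant_bundle", issues = iss)
    }
  }
  study <- bundle_resources(bundle, "ImagingStudy")[[1]]
  study_uid <- boa_study_uid(study)
  patient_id <- sub("^Patient/", "",
                    get_path(study, c("subject", "reference")) %||% NA_character_)
  date <- if (!is.null(study$started)) substr(study$started, 1, 10) else NA_character_

  rows <- list()
  for (obs in bundle_resources(bundle, "Observation")) {
    if (is_bca_observation(obs)) {
      site <- primary_coding(obs$bodySite)
      mode <- primary_coding(obs$code)
      slice_low <- slice_high <- NA_real_
      volumes <- list()
      densities <- list()
      for (cmp in obs$component %||% list()) {
        codings <- as_coding_list(cmp$code)
        if (coding_matches(codings, slice_range_concept())) {
          slice_low <- get_path(cmp, c("valueRange", "low", "value"))
          slice_high <- get_path(cmp, c("valueRange", "high", "value"))
        } else if (coding_matches(codings, mean_density_concept())) {
          tissue <- keep(codings, function(cd) !identical(cd$code, mean_density_concept()$code))[[1]]
          densities[[paste(tissue$system, tissue$code)]] <- get_path(cmp, c("valueQuantity", "value"))
        } else {
          volumes[[length(volumes) + 1]] <- list(
            coding = codings[[1]], value = get_path(cmp, c("valueQuantity", "value"))
          )
        }
      }
      for (v in volumes) {
        key <- paste(v$coding$system, v$coding$code)
        rows[[length(rows) + 1]] <- tibble(
          patient_id = patient_id, study_uid = study_uid, date = date,
          kind = "region-tissue",
          body_site = site$display, body_site_code = site$code,
          mode = mode$display,
          tissue = v$coding$display, tissue_code = v$coding$code,
          structure = NA_character_, structure_code = NA_character_,
          slice_low = as.numeric(slice_low), slice_high = as.numeric(slice_high),
          volume_ml = v$value,
          mean_density_hu = densities[[key]] %||% NA_real_
        )
      }
    } else {
      for (cmp in obs$component %||% list()) {
        cd <- primary_coding(cmp$code)
        rows[[length(rows) + 1]] <- tibble(
          patient_id = patient_id, study_uid = study_uid, date = date,
          kind = "organ",
          body_site = NA_character_, body_site_code = NA_character_,
          mode = NA_character_,
          tissue = NA_character_, tissue_code = NA_character_,
          structure = cd$display, structure_code = cd$code,
          slice_low = NA_real_, slice_high = NA_real_,
          volume_ml = get_path(cmp, c("valueQuantity", "value")),
          mean_density_hu = NA_real_
        )
      }
    }
  }
  out <- bind_rows(rows)
  region <- out[out$kind == "region-tissue", , drop = FALSE]
  region <- region[order(region$body_site, region$mode, region$tissue), , drop = FALSE]
  organ <- out[out$kind == "organ", , drop = FALSE]
  organ <- organ[order(organ$structure), , drop = FALSE]
  out <- bind_rows(region, organ)[, measurement_columns]
  class(out) <- c("boa_measurements", class(out))
  out
}

#' Reconstruct a BOA result from a bundle
#'
#' Full inverse of [assemble_bundle()]: recovers the patient id, study and
#' series UIDs, every region and organ measurement, the model metadata from
#' the Procedure annotations, and the report attachments. For any bundle built
#' by this package, serializing the reconstruction reproduces the original
#' result byte for byte.
#'
#' @inheritParams extract_measurements
#' @return A [boa_result()].
#' @export
extract_boa_result <- function(bundle, validate = TRUE) {
  if (validate) {
    iss <- validate_bundle(bundle)
    if (any(iss$severity == "error")) {
      abort("bundle does not conform to the BOA profiles; refusing extraction",
            class = "boa_nonconformant_bundle", issues = iss)
    }
  }
  study <- bundle_resources(bundle, "ImagingStudy")[[1]]
  report <- bundle_resources(bundle, "DiagnosticReport")[[1]]
  proc <- bundle_resources(bundle, "Procedure")[[1]]

  as_concept <- function(cd) concept(cd$system, cd$code, cd$display)
  series <- lapply(study$series %||% list(), function(s) compact_list(list(
    series_uid = s$uid,
    modality = get_path(s, c("modality", "code")) %||% "CT",
    number_of_instances = s$numberOfInstances,
    body_site = if (!is.null(s$bodySite)) as_concept(s$bodySite)
  )))

  regions <- list()
  organs <- list()
  for (obs in bundle_resources(bundle, "Observation")) {
    if (is_bca_observation(obs)) {
      tissues <- list()
      slice <- NULL
      densities <- list()
      order_keys <- character()
      for (cmp in obs$component %||% list()) {
        codings <- as_coding_list(cmp$code)
        if (coding_matches(codings, slice_range_concept())) {
          slice <- list(low = get_path(cmp, c("valueRange", "low", "value")),
                        high = get_path(cmp, c("valueRange", "high", "value")))
        } else if (coding_matches(codings, mean_density_concept())) {
          tcd <- keep(codings, function(cd) !identical(cd$code, mean_density_concept()$code))[[1]]
          densities[[paste(tcd$system, tcd$code)]] <- get_path(cmp, c("valueQuantity", "value"))
        } else {
          cd <- codings[[1]]
          order_keys <- c(order_keys, paste(cd$system, cd$code))
          tissues[[length(tissues) + 1]] <- list(
            tissue = as_concept(cd),
            volume_ml = get_path(cmp, c("valueQuantity", "value"))
          )
        }
      }
      tissues <- lapply(seq_along(tissues), function(j) {
        t <- tissues[[j]]
        d <- densities[[order_keys[j]]]
        if (!is.null(d)) t$mean_density_hu <- d
        t
      })
      regions[[length(regions) + 1]] <- compact_list(list(
        body_site = as_concept(primary_coding(obs$bodySite)),
        mode = as_concept(primary_coding(obs$code)),
        slice_range = slice,
        tissues = tissues
      ))
    } else {
      for (cmp in obs$component %||% list()) {
        organs[[length(organs) + 1]] <- list(
          structure = as_concept(primary_coding(cmp$code)),
          volume_ml = get_path(cmp, c("valueQuantity", "value"))
        )
      }
    }
  }

  notes <- map_chr(proc$note %||% list(), function(n) n$text %||% "")
  kv <- strsplit(notes, "=", fixed = TRUE)
  keys <- map_chr(kv, 1)
  vals <- map_chr(kv, function(x) paste(x[-1], collapse = "="))
  params <- vals[startsWith(keys, "parameter.")]
  names(params) <- sub("^parameter\\.", "", keys[startsWith(keys, "parameter.")])
  model <- list(name = vals[keys == "name"][1], version = vals[keys == "version"][1],
                parameters = params)

  attachments <- lapply(report$presentedForm %||% list(), function(f) {
    compact_list(list(content_type = f$contentType, data = f$data, url = f$url))
  })

  boa_result(
    patient_id = sub("^Patient/", "", get_path(study, c("subject", "reference"))),
    study_uid = boa_study_uid(study),
    series = series,
    regions = regions,
    organs = organs,
    model = model,
    attachments = attachments,
    started = study$started
  )
}

#' Write / read the measurement table as CSV
#'
#' The CSV uses the fixed documented header (see [extract_measurements()]),
#' UTF-8 encoding and the decimal point regardless of locale.
#'
#' @param rows A `boa_measurements` tibble.
#' @param path File path.
#' @return `path` (write) or the re-typed tibble (read).
#' @export
write_measurements_csv <- function(rows, path) {
  write.csv(as.data.frame(rows)[, measurement_columns], path,
            row.names = FALSE, fileEncoding = "UTF-8", quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_measurements_csv
#' @export
read_measurements_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                 colClasses = "character", na.strings = "")
  stopifnot(identical(names(df), measurement_columns))
  for (col in c("slice_low", "slice_high", "volume_ml", "mean_density_hu")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  out <- as_tibble(df)
  class(out) <- c("boa_measurements", class(out))
  out
}

# broom-style verbs on bundles -----------------------------------------------

#' Tidy and summary views of a bundle
#'
#' `tidy()` on a bundle is [extract_measurements()]; `glance()` returns a
#' one-row overview (entry counts, measurement totals, validation status).
#'
#' @param x A `boa_bundle`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy boa_bundle
#' @export
tidy.boa_bundle <- function(x, ...) extract_measurements(x)

#' @rdname tidy.boa_bundle
#' @method glance boa_bundle
#' @export
glance.boa_bundle <- function(x, ...) {
  iss <- validate_bundle(x)
  types <- map_chr(bundle_resources(x), function(r) r$resourceType %||% "?")
  tibble(
    entries = length(x$entry),
    observations = sum(types == "Observation"),
    regions = sum(map_lgl(bundle_resources(x, "Observation"), is_bca_observation)),
    validation_errors = sum(iss$severity == "error"),
    validation_warnings = sum(iss$severity == "warning")
  )
}
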