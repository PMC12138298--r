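# Seeded synthetic BOA results. The generator emulates the analysis document
# of one CT study: well-formed DICOM UIDs, all four BCA body sites in both
# measurement modes (8 regions), draws over all 8 tissue compartments, and one
# volume per anatomical landmark. Value ranges are plausible-by-construction
# configuration defaults, not validated claims about real cohorts.

#' Generation parameters for synthetic BOA results
#'
#' Defaults mirror the shipped terminology: all 4 BCA body sites crossed with
#' both measurement modes (8 regions), all 8 tissues per region, and all 104
#' anatomical landmarks. Ranges are uniform-draw bounds in millilitres (volumes)
#' and Hounsfield units (densities).
#'
#' @param body_sites Displays from `BCABodySiteVS` to include.
#' @param modes Displays from `BCAMeasurementsVS` to include.
#' @param tissues Displays from `BCATissueVS` drawn in every region.
#' @param n_organs Number of landmarks (first `n` of `BodyStructureLandmarkVS`),
#'   0..104.
#' @param n_series Number of image series used for inference.
#' @param organ_volume_range,tissue_volume_range Uniform bounds, mL.
#' @param density_ranges Named list of HU bounds per tissue class; tissues whose
#'   display contains "adipose" use `adipose`, `bone` uses `bone`, everything
#'   else `muscle`.
#' @param slice_count_range Bounds for the number of instances per series.
#' @param with_attachments Emit the PDF + JSON `presentedForm` stubs?
#' @param model_name,model_version Model metadata recorded in the result.
#' @return A list of class `boa_sim_config`.
#' @export
boa_sim_config <- function(body_sites = valueset_members("BCABodySiteVS")$display,
                           modes = valueset_members("BCAMeasurementsVS")$display,
                           tissues = valueset_members("BCATissueVS")$display,
                           n_organs = 104,
                           n_series = 2,
                           organ_volume_range = c(10, 2000),
                           tissue_volume_range = c(20, 4000),
                           density_ranges = list(muscle = c(20, 60),
                                                 bone = c(150, 1200),
                                                 adipose = c(-150, -50)),
                           slice_count_range = c(80, 600),
                           with_attachments = TRUE,
                           model_name = "BOA",
                           model_version = "1.0") {
  cfg <- list(body_sites = body_sites, modes = modes, tissues = tissues,
              n_organs = n_organs, n_series = n_series,
              organ_volume_range = organ_volume_range,
              tissue_volume_range = tissue_volume_range,
              density_ranges = density_ranges,
              slice_count_range = slice_count_range,
              with_attachments = with_attachments,
              model_name = model_name, model_version = model_version)
  ranges <- c(list(cfg$organ_volume_range, cfg$tissue_volume_range,
                   cfg$slice_count_range), cfg$density_ranges)
  for (r in ranges) {
    if (length(r) != 2 || !is.numeric(r) || r[1] > r[2]) {
      abort("inconsistent generation config: every range needs min <= max",
            class = "boa_invalid_config")
    }
  }
  if (cfg$n_organs < 0 || cfg$n_organs > 104 || cfg$n_series < 1) {
    abort("inconsistent generation config: n_organs in 0..104, n_series >= 1",
          class = "boa_invalid_config")
  }
  if (cfg$n_organs == 0 && (length(cfg$body_sites) == 0 || length(cfg$modes) == 0)) {
    abort("inconsistent generation config: need at least one of regions/organs",
          class = "boa_invalid_config")
  }
  structure(cfg, class = "boa_sim_config")
}

density_range_for <- function(display, density_ranges) {
  if (grepl("adipose", display)) density_ranges$adipose
  else if (grepl("bone", display)) density_ranges$bone
  else density_ranges$muscle
}

# dotted-decimal UID under a fixed synthetic root; components drawn without
# leading zeros so every emitted UID passes validate_dicom_uid()
synth_uid <- function(root = "1.2.826.0.1.3680043.9590") {
  paste0(root, ".", paste(sample.int(899999L, 3) + 100000L, collapse = "."))
}

#' Generate a seeded synthetic BOA result
#'
#' Deterministic for a fixed `(seed, config)`: two calls serialize to
#' byte-identical JSON. The global RNG state is left untouched.
#'
#' @param seed Integer seed.
#' @param config A [boa_sim_config()].
#' @return A [boa_result()].
#' @export
#' @examples
#' r <- generate_synthetic_result(1)
#' length(r$regions)  # 8
#' length(r$organs)   # 104
generate_synthetic_result <- function(seed, config = boa_sim_config()) {
  if (!inherits(config, "boa_sim_config")) config <- do.call(boa_sim_config, config)
  withr::with_seed(as.integer(seed), {
    runif_r <- function(range, digits = 1) round(runif(1, range[1], range[2]), digits)

    n_inst <- sample(seq(config$slice_count_range[1], config$slice_count_range[2]), 1)
    series <- lapply(seq_len(config$n_series), function(i) {
      compact_list(list(
        series_uid = synth_uid(),
        modality = "CT",
        number_of_instances = as.integer(n_inst),
        body_site = if (i == 1) lookup_concept("abdominal cavity")
      ))
    })

    regions <- list()
    for (site in config$body_sites) {
      for (mode in config$modes) {
        lo <- sample.int(max(n_inst - 1, 1), 1)
        hi <- lo + sample.int(n_inst - lo, 1)
        regions[[length(regions) + 1]] <- list(
          body_site = lookup_concept(site),
          mode = lookup_concept(mode),
          slice_range = list(low = as.numeric(lo), high = as.numeric(hi)),
          tissues = lapply(config$tissues, function(t) list(
            tissue = lookup_concept(t),
            volume_ml = runif_r(config$tissue_volume_range, 2),
            mean_density_hu = runif_r(density_range_for(t, config$density_ranges), 1)
          ))
        )
      }
    }

    landmarks <- valueset_members("BodyStructureLandmarkVS")$display
    organs <- lapply(utils::head(landmarks, config$n_organs), function(d) list(
      structure = lookup_concept(d),
      volume_ml = runif_r(config$organ_volume_range, 2)
    ))

    started <- format(
      as.POSIXct("2024-01-01 00:00:00", tz = "UTC") +
        sample.int(365L * 24L * 3600L, 1),
      "%Y-%m-%dT%H:%M:%SZ"
    )

    attachments <- if (config$with_attachments) {
      list(
        list(content_type = "application/pdf",
             data = jsonlite::base64_enc(charToRaw(
               "%PDF-1.4 synthetic body-and-organ analysis report stub"))),
        list(content_type = "application/json",
             data = jsonlite::base64_enc(charToRaw(
               '{"report":"synthetic boa summary"}')))
      )
    } else {
      list()
    }

    boa_result(
      patient_id = sprintf("BOA-SYN-%06d", sample.int(999999L, 1)),
      study_uid = synth_uid(),
      series = series,
      regions = regions,
      organs = organs,
      model = list(
        name = config$model_name, version = config$model_version,
        parameters = c(mode = "full-body", windowing = "default",
                       seed = as.character(seed))
      ),
      attachments = attachments,
      started = started
    )
  })
}
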