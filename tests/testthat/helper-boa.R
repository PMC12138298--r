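# Shared fixtures: memoized synthetic results/bundles and the documented
# single-field mutation suite used for fault-injection testing.

.fixtures <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

syn_result <- function(seed = 1, ...) {
  key <- paste0("r", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_synthetic_result(seed, boa_sim_config(...))
  }
  .fixtures[[key]]
}

syn_bundle <- function(seed = 1) {
  key <- paste0("b", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- assemble_bundle(syn_result(seed))
  }
  .fixtures[[key]]
}

entry_index <- function(bundle, type, which_one = 1) {
  idx <- which(vapply(bundle$entry, function(e) e$resource$resourceType, "") == type)
  idx[which_one]
}

local_system <- function() unname(boa_systems()["local"])

# Each mutator flips exactly one field of a conformant bundle and reports the
# element path it touched; the validator must flag an error at (or under) it.
bundle_mutations <- function(bundle) {
  study_i <- entry_index(bundle, "ImagingStudy")
  obs_i <- entry_index(bundle, "Observation") # first BCA observation
  bsv_i <- max(which(vapply(bundle$entry, function(e) e$resource$resourceType, "") == "Observation"))
  rep_i <- entry_index(bundle, "DiagnosticReport")
  proc_i <- entry_index(bundle, "Procedure")
  at <- function(i, ...) sprintf("Bundle.entry[%d].%s", i, paste0(...))

  list(
    non_member_body_site = list(
      path = at(obs_i, "Observation.bodySite"),
      apply = function(b) {
        b$entry[[obs_i]]$resource$bodySite$coding[[1]]$code <- "000"
        b
      }),
    non_member_mode_code = list(
      path = at(obs_i, "Observation.code"),
      apply = function(b) {
        b$entry[[obs_i]]$resource$code$coding[[1]]$code <- "not-a-mode"
        b
      }),
    non_member_tissue = list(
      path = at(obs_i, "Observation.component[1].code"),
      apply = function(b) {
        b$entry[[obs_i]]$resource$component[[1]]$code$coding[[1]]$code <- "granite"
        b
      }),
    volume_unit_litres = list(
      path = at(obs_i, "Observation.component[1].valueQuantity"),
      apply = function(b) {
        b$entry[[obs_i]]$resource$component[[1]]$valueQuantity$code <- "L"
        b
      }),
    non_ucum_unit_system = list(
      path = at(obs_i, "Observation.component[1].valueQuantity"),
      apply = function(b) {
        b$entry[[obs_i]]$resource$component[[1]]$valueQuantity$system <- "http://example.org/units"
        b
      }),
    bad_study_uid = list(
      path = at(study_i, "ImagingStudy.identifier"),
      apply = function(b) {
        b$entry[[study_i]]$resource$identifier[[1]]$value <- "urn:oid:1.2.04.5"
        b
      }),
    bad_series_uid = list(
      path = at(study_i, "ImagingStudy.series[1].uid"),
      apply = function(b) {
        b$entry[[study_i]]$resource$series[[1]]$uid <- "1..2"
        b
      }),
    missing_aiast = list(
      path = at(obs_i, "Observation.meta.security"),
      apply = function(b) {
        b$entry[[obs_i]]$resource$meta$security <- NULL
        b
      }),
    dropped_observation = list(
      path = at(rep_i - 1, "DiagnosticReport.result"), # report shifts down by one
      apply = function(b) {
        b$entry[[obs_i]] <- NULL
        b
      }),
    dropped_imaging_study = list(
      path = "Bundle.entry", # derivedFrom/imagingStudy dangle in several entries
      apply = function(b) {
        b$entry[[study_i]] <- NULL
        b
      }),
    duplicate_organ_component = list(
      path = at(bsv_i, "Observation.component"),
      apply = function(b) {
        comp <- b$entry[[bsv_i]]$resource$component
        comp[[length(comp) + 1]] <- comp[[1]]
        b$entry[[bsv_i]]$resource$component <- comp
        b
      }),
    status_not_final = list(
      path = at(obs_i, "Observation.status"),
      apply = function(b) {
        b$entry[[obs_i]]$resource$status <- "preliminary"
        b
      }),
    meta_profile_stripped = list(
      path = at(obs_i, "Observation.meta.profile"),
      apply = function(b) {
        b$entry[[obs_i]]$resource$meta$profile <- NULL
        b
      }),
    presented_form_html = list(
      path = at(rep_i, "DiagnosticReport.presentedForm[1].contentType"),
      apply = function(b) {
        b$entry[[rep_i]]$resource$presentedForm[[1]]$contentType <- "text/html"
        b
      }),
    number_of_series_wrong = list(
      path = at(study_i, "ImagingStudy.numberOfSeries"),
      apply = function(b) {
        b$entry[[study_i]]$resource$numberOfSeries <- 99
        b
      }),
    slice_range_inverted = list(
      path = at(obs_i, "Observation.component"),
      apply = function(b) {
        comps <- b$entry[[obs_i]]$resource$component
        k <- length(comps) # slice-range component is built last
        lo <- comps[[k]]$valueRange$low$value
        comps[[k]]$valueRange$low$value <- comps[[k]]$valueRange$high$value + 1
        b$entry[[obs_i]]$resource$component <- comps
        b
      }),
    dangling_procedure_report = list(
      path = at(proc_i, "Procedure"),
      apply = function(b) {
        b$entry[[proc_i]]$resource$report[[1]]$reference <- "DiagnosticReport/nonexistent"
        b
      })
  )
}
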