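ctx_for <- function(r) build_context(paste0("Patient/", r$patient_id))

test_that("a BCA observation lays out volume, density and slice-range components", {
  r <- syn_result(1)
  ctx <- ctx_for(r)
  obs <- build_bca_observation(r$regions[[1]], ctx, "ImagingStudy/x")
  # 8 tissues -> 8 volume + 8 density components, plus one slice range
  expect_length(obs$component, 17)
  expect_identical(obs$status, "final")
  expect_true(validate_membership(obs$bodySite$coding[[1]], "BCABodySiteVS"))
  expect_true(validate_membership(obs$code$coding[[1]], "BCAMeasurementsVS"))
  expect_identical(obs$derivedFrom[[1]]$reference, "ImagingStudy/x")
  vols <- Filter(function(c) !is.null(c$valueQuantity) &&
                   identical(c$valueQuantity$code, "mL"), obs$component)
  expect_length(vols, 8)
  hus <- Filter(function(c) !is.null(c$valueQuantity) &&
                  identical(c$valueQuantity$code, "[hnsf'U]"), obs$component)
  expect_length(hus, 8)
  expect_true(all(vapply(c(vols, hus), function(c)
    identical(c$valueQuantity$system, "http://unitsofmeasure.org"), TRUE)))
  rng <- Filter(function(c) !is.null(c$valueRange), obs$component)
  expect_length(rng, 1)
  expect_lte(rng[[1]]$valueRange$low$value, rng[[1]]$valueRange$high$value)
})

test_that("builders reject concepts outside their bound value sets", {
  r <- syn_result(1)
  ctx <- ctx_for(r)
  region <- r$regions[[1]]
  region$body_site <- concept(unname(boa_systems()["local"]), "not-a-site", "nowhere")
  expect_error(build_bca_observation(region, ctx, "ImagingStudy/x"),
               class = "boa_build_error")
  region2 <- r$regions[[1]]
  region2$tissues[[1]]$tissue <- concept(unname(boa_systems()["local"]), "granite", "granite")
  expect_error(build_bca_observation(region2, ctx, "ImagingStudy/x"),
               class = "boa_build_error")
})

test_that("the body-structure observation carries one mL component per organ", {
  r <- syn_result(1)
  ctx <- ctx_for(r)
  one <- list(list(structure = lookup_concept("spleen"), volume_ml = 250))
  obs <- build_body_structure_observation(one, ctx, "ImagingStudy/x")
  expect_length(obs$component, 1)
  expect_identical(obs$component[[1]]$valueQuantity$code, "mL")
  expect_identical(obs$component[[1]]$valueQuantity$value, 250)

  all104 <- build_body_structure_observation(r$organs, ctx, "ImagingStudy/x")
  expect_length(all104$component, 104)

  expect_error(build_body_structure_observation(list(), ctx, "ImagingStudy/x"),
               class = "boa_build_error")
  expect_error(build_body_structure_observation(c(one, one), ctx, "ImagingStudy/x"),
               class = "boa_build_error")
})

test_that("the imaging study counts inference series and keeps the study UID recoverable", {
  r <- syn_result(1)
  study <- build_imaging_study(r, ctx_for(r))
  expect_identical(study$numberOfSeries, 2L)
  expect_length(study$series, 2)
  expect_identical(boa_study_uid(study), r$study_uid)
  expect_identical(study$series[[1]]$uid, r$series[[1]]$series_uid)

  r_dup <- r
  r_dup$series[[2]]$series_uid <- r$series[[1]]$series_uid
  expect_error(build_imaging_study(r_dup, ctx_for(r)), class = "boa_build_error")
})

test_that("the diagnostic report aggregates observations and carries presentedForm", {
  r <- syn_result(1)
  ctx <- ctx_for(r)
  rep <- build_diagnostic_report(r, c("Observation/a", "Observation/b"),
                                 "ImagingStudy/x", ctx)
  expect_identical(rep$status, "final")
  expect_length(rep$presentedForm, 2)
  expect_setequal(vapply(rep$presentedForm, function(f) f$contentType, ""),
                  c("application/pdf", "application/json"))
  expect_identical(boa_study_uid(rep), r$study_uid)
  expect_identical(vapply(rep$result, function(x) x$reference, ""),
                   c("Observation/a", "Observation/b"))

  expect_error(build_diagnostic_report(r, character(), "ImagingStudy/x", ctx),
               class = "boa_build_error")
  r_bad <- r
  r_bad$attachments[[1]]$content_type <- "text/html"
  expect_error(build_diagnostic_report(r_bad, "Observation/a", "ImagingStudy/x", ctx),
               class = "boa_build_error")
})

test_that("the read procedure stores model metadata retrievably and links the report", {
  r <- syn_result(1)
  ctx <- ctx_for(r)
  proc <- build_read_procedure(list(name = "BOA", version = "1.0",
                                    parameters = c(window = "abdomen")),
                               "DiagnosticReport/r1", ctx)
  notes <- vapply(proc$note, function(n) n$text, "")
  expect_true("name=BOA" %in% notes)
  expect_true("version=1.0" %in% notes)
  expect_true("parameter.window=abdomen" %in% notes)
  expect_identical(proc$report[[1]]$reference, "DiagnosticReport/r1")
  expect_error(build_read_procedure(list(name = "", version = "1.0"),
                                    "DiagnosticReport/r1", ctx),
               class = "boa_build_error")
})

test_that("AIAST tagging is idempotent and touches nothing outside meta", {
  r <- syn_result(1)
  obs <- build_bca_observation(r$regions[[1]], ctx_for(r), "ImagingStudy/x")
  count_aiast <- function(res) {
    sum(vapply(res$meta$security %||% list(), function(s)
      identical(s$code, "AIAST"), TRUE))
  }
  strip_meta <- function(res) { res$meta <- NULL; fhir_json(res) }

  expect_identical(count_aiast(obs), 0L)
  once <- tag_ai_provenance(obs)
  expect_identical(count_aiast(once), 1L)
  twice <- tag_ai_provenance(once)
  expect_identical(count_aiast(twice), 1L)
  expect_identical(fhir_json(twice), fhir_json(once))
  expect_identical(strip_meta(once), strip_meta(obs))
})

test_that("assemble_bundle is referentially closed, fully tagged, and deterministic", {
  r <- syn_result(1)
  b <- syn_bundle(1)
  # 8 BCA + 1 body-structure observation + study + report + procedure
  expect_length(b$entry, 12)
  types <- vapply(b$entry, function(e) e$resource$resourceType, "")
  expect_identical(sum(types == "Observation"), 9L)
  expect_identical(sum(types == "ImagingStudy"), 1L)
  expect_identical(sum(types == "DiagnosticReport"), 1L)
  expect_identical(sum(types == "Procedure"), 1L)
  expect_identical(b$type, "transaction")
  for (e in b$entry) {
    expect_true(any(vapply(e$resource$meta$security %||% list(), function(s)
      identical(s$code, "AIAST"), TRUE)), info = e$resource$resourceType)
  }
  expect_identical(fhir_json(assemble_bundle(r)), fhir_json(b))

  ctx_uuid <- build_context(paste0("Patient/", r$patient_id), id_strategy = "uuid")
  b1 <- assemble_bundle(r, ctx_uuid)
  b2 <- assemble_bundle(r, ctx_uuid)
  expect_length(b1$entry, 12)
  expect_false(identical(b1$entry[[1]]$resource$id, b2$entry[[1]]$resource$id))
  expect_match(b1$entry[[1]]$resource$id,
               "^[0-9a-f]{8}-[0-9a-f]{4}-4[0-9a-f]{3}-[89ab][0-9a-f]{3}-[0-9a-f]{12}$")
})

test_that("exported profile definitions cover the four profiles with their bindings", {
  profs <- export_profile_definitions()
  expect_length(profs, 4)
  expect_setequal(vapply(profs, function(p) p$title, ""),
                  c("BCA Observation", "Body Structure Volume Observation",
                    "Diagnostic Report", "Imaging Study"))
  expect_true(all(vapply(profs, function(p) p$base_resource, "") %in%
                    c("Observation", "DiagnosticReport", "ImagingStudy")))
  bca <- profs[["boa-bca-observation"]]
  site_binding <- bca$constraints[bca$constraints$path == "bodySite", ]
  expect_identical(site_binding$binding_valueset, "BCABodySiteVS")
  expect_identical(site_binding$binding_strength, "required")
  code_binding <- bca$constraints[bca$constraints$path == "code", ]
  expect_identical(code_binding$binding_valueset, "BCAMeasurementsVS")
})

test_that("profile definitions survive the StructureDefinition JSON round trip", {
  dir <- withr::local_tempdir()
  write_profile_definitions(dir)
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  expect_length(files, 4)
  for (f in files) {
    back <- profile_from_json(f)
    orig <- export_profile_definitions()[[back$id]]
    expect_identical(back$title, orig$title)
    expect_identical(back$base_resource, orig$base_resource)
    expect_identical(back$rules, orig$rules)
    expect_identical(back$constraints$path, orig$constraints$path)
    expect_identical(back$constraints$min, orig$constraints$min)
    expect_identical(back$constraints$binding_valueset, orig$constraints$binding_valueset)
  }
})
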