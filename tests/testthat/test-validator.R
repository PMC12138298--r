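test_that("every builder output conforms to its own exported profile", {
  b <- syn_bundle(1)
  profs <- export_profile_definitions()
  for (e in b$entry) {
    res <- e$resource
    if (res$resourceType == "Procedure") next # external MII profile, bundle-level checks only
    prof <- switch(res$resourceType,
      ImagingStudy = profs[["boa-imaging-study"]],
      DiagnosticReport = profs[["boa-diagnostic-report"]],
      Observation = if (!is.null(res$bodySite)) profs[["boa-bca-observation"]]
                    else profs[["boa-body-structure-volume-observation"]]
    )
    iss <- validate_resource(res, prof)
    expect_identical(nrow(iss), 0L, info = res$resourceType)
  }
})

test_that("a pristine assembled bundle validates with zero issues", {
  iss <- validate_bundle(syn_bundle(1))
  expect_s3_class(iss, "tbl_df")
  expect_identical(nrow(iss), 0L)
})

test_that("validation is read-only", {
  b <- syn_bundle(1)
  before <- fhir_json(b)
  invisible(validate_bundle(b))
  expect_identical(fhir_json(b), before)
})

test_that("each documented single-field mutation is caught at its path", {
  b <- syn_bundle(1)
  muts <- bundle_mutations(b)
  expect_gte(length(muts), 12)
  for (name in names(muts)) {
    mut <- muts[[name]]
    iss <- validate_bundle(mut$apply(b))
    errs <- iss[iss$severity == "error", ]
    expect_gt(nrow(errs), 0)
    hit <- any(startsWith(errs$path, mut$path) | startsWith(mut$path, errs$path))
    expect_true(hit, info = paste0(name, ": expected an error at ", mut$path,
                                   "; got ", paste(errs$path, collapse = ", ")))
  }
})

test_that("every issue carries a registered rule id and severity", {
  b <- syn_bundle(1)
  reg <- boa_rules()
  all_iss <- dplyr::bind_rows(lapply(bundle_mutations(b), function(m) {
    validate_bundle(m$apply(b))
  }))
  expect_true(all(all_iss$rule_id %in% reg$rule_id))
  expect_identical(unname(reg$severity[match(all_iss$rule_id, reg$rule_id)]),
                   all_iss$severity)
})

test_that("wrong-system codings and missing quantities are flagged precisely", {
  b <- syn_bundle(1)
  obs_i <- entry_index(b, "Observation")
  # binding: correct code, wrong system
  site_code <- b$entry[[obs_i]]$resource$bodySite$coding[[1]]$code
  b$entry[[obs_i]]$resource$bodySite$coding[[1]]$system <- local_system()
  iss <- validate_bundle(b)
  expect_true(any(iss$rule_id == "binding-violation" &
                    grepl("bodySite", iss$path, fixed = TRUE)))

  b2 <- syn_bundle(1)
  b2$entry[[obs_i]]$resource$component[[1]]$valueQuantity <- NULL
  iss2 <- validate_bundle(b2)
  expect_true(any(iss2$rule_id == "component-layout"))
})

test_that("non-BOA resources in a bundle produce a warning, not an error", {
  b <- syn_bundle(1)
  b$entry[[length(b$entry) + 1]] <- list(
    fullUrl = "urn:uuid:patient",
    resource = list(resourceType = "Patient", id = "p1"),
    request = list(method = "POST", url = "Patient")
  )
  iss <- validate_bundle(b)
  expect_identical(sum(iss$severity == "error"), 0L)
  expect_true(any(iss$rule_id == "unknown-resource" & iss$severity == "warning"))
})

test_that("non-bundles and malformed entries yield parse issues", {
  iss <- validate_bundle(list(resourceType = "Observation"))
  expect_identical(iss$rule_id, "parse-error")
  b <- syn_bundle(1)
  b$entry[[1]]$resource <- NULL
  iss2 <- validate_bundle(b)
  expect_true(any(iss2$rule_id == "parse-error"))
})
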