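test_that("shipped value sets have the documented cardinalities and members", {
  expect_setequal(
    valueset_members("BCABodySiteVS")$display,
    c("abdominal cavity", "thoracic cavity", "mediastinum", "pericardium")
  )
  expect_identical(nrow(valueset_members("BodyStructureLandmarkVS")), 104L)
  expect_identical(nrow(valueset_members("BCATissueVS")), 8L)
  expect_identical(nrow(valueset_members("BCARegionVS")), 8L)
  expect_identical(nrow(valueset_members("BCAMeasurementsVS")), 2L)
  expect_match(valueset_members("BCAMeasurementsVS")$display, "extremities", all = TRUE)
})

test_that("every shipped concept satisfies the concept invariants", {
  for (vs in boa_valuesets()) {
    m <- valueset_members(vs)
    expect_true(all(m$system %in% unname(boa_systems())), info = vs)
    expect_true(all(nzchar(m$code)), info = vs)
    expect_false(any(grepl("\\s", m$code)), info = vs)
    expect_identical(anyDuplicated(paste(m$system, m$code)), 0L, info = vs)
    # member order is stable across calls
    expect_identical(m, valueset_members(vs))
  }
})

test_that("lookup is total over shipped displays and round-trips exactly", {
  for (vs in boa_valuesets()) {
    m <- valueset_members(vs)
    for (i in seq_len(nrow(m))) {
      found <- lookup_concept(m$display[i], preferred_system = m$system[i])
      expect_identical(found$system, m$system[i])
      expect_identical(found$code, m$code[i])
      expect_true(validate_membership(found, vs))
    }
  }
})

test_that("lookup normalizes case and whitespace and knows synonyms", {
  a <- lookup_concept("abdominal cavity")
  expect_identical(a$system, "http://snomed.info/sct")
  expect_identical(lookup_concept("  Abdominal   CAVITY "), a)
  expect_identical(lookup_concept("SAT")$display, "subcutaneous adipose tissue")
  expect_identical(lookup_concept("kidney_right")$display, "right kidney")
  expect_identical(lookup_concept("with extremities")$code,
                   lookup_concept("measurement including extremities")$code)
})

test_that("lookup honours the preferred system and the SNOMED > RadLex > local priority", {
  sys <- boa_systems()
  register_valueset("PriorityTestVS", data.frame(
    display = c("test probe", "test probe", "radlex only term"),
    system = c("radlex", "local", "radlex"),
    code = c("RIDTEST", "local-test-probe", "RIDSOLO"),
    synonyms = c("", "", ""),
    stringsAsFactors = FALSE
  ), title = "synthetic priority fixture")
  on.exit({
    # drop the fixture set again so other tests see only shipped sets
    .boa <- asNamespace("boafhir")$.boa_env
    .boa$valuesets[["PriorityTestVS"]] <- NULL
  })
  expect_identical(lookup_concept("test probe")$system, unname(sys["radlex"]))
  expect_identical(lookup_concept("test probe", unname(sys["local"]))$code,
                   "local-test-probe")
  expect_identical(lookup_concept("radlex only term")$code, "RIDSOLO")
  # preferred system without a match falls back to priority order
  expect_identical(lookup_concept("radlex only term", unname(sys["sct"]))$code,
                   "RIDSOLO")
})

test_that("membership is decided on (system, code), never on the display", {
  m <- valueset_members("BCABodySiteVS")
  member <- concept(m$system[1], m$code[1], "totally wrong display")
  expect_true(validate_membership(member, "BCABodySiteVS"))
  expect_false(validate_membership(concept(m$system[1], "000", m$display[1]),
                                   "BCABodySiteVS"))
  # correct code under the wrong system: brute-force scan confirms no member
  wrong_system <- concept(unname(boa_systems()["local"]), m$code[1], m$display[1])
  expect_false(any(m$system == wrong_system$system & m$code == wrong_system$code))
  expect_false(validate_membership(wrong_system, "BCABodySiteVS"))
})

test_that("unknown ids and unmapped labels raise typed errors", {
  expect_error(valueset_members("NoSuchVS"), class = "boa_unknown_valueset")
  expect_error(validate_membership(lookup_concept("spleen"), "NoSuchVS"),
               class = "boa_unknown_valueset")
  expect_error(lookup_concept("xyzzy-nonsense"), class = "boa_unmapped_label")
  err <- tryCatch(lookup_concept("xyzzy-nonsense"), error = function(e) e)
  expect_identical(err$label, "xyzzy-nonsense")
  expect_error(concept("http://snomed.info/sct", "has space", "x"),
               class = "boa_invalid_concept")
})

test_that("value sets serialize to FHIR ValueSet JSON with canonical URLs", {
  vs <- valueset_to_fhir("BCATissueVS")
  expect_identical(vs$resourceType, "ValueSet")
  expect_identical(vs$expansion$total, 8L)
  expect_match(vs$url, "/ValueSet/BCATissueVS$")
  expect_identical(vs$expansion$contains[[1]]$display,
                   valueset_members("BCATissueVS")$display[1])
})
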