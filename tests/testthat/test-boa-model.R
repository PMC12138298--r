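minimal_doc <- function() {
  paste0('{
    "patient_id": "P1",
    "study_uid": "1.2.840.10008.1.1",
    "series": [{"series_uid": "1.2.840.10008.1.2"}],
    "organs": [{"structure": "spleen", "volume_ml": 250}],
    "model": {"name": "BOA", "version": "1.0"}
  }')
}

test_that("a minimal document parses to a valid result with empty regions", {
  r <- parse_boa_result(minimal_doc())
  expect_s3_class(r, "boa_result")
  expect_length(r$regions, 0)
  expect_length(r$organs, 1)
  expect_identical(r$organs[[1]]$structure, lookup_concept("spleen"))
  expect_identical(r$series[[1]]$modality, "CT")
})

test_that("parse errors carry the offending JSON path", {
  bad_uid <- sub('"1.2.840.10008.1.1"', '"1.2.04.5"', minimal_doc(), fixed = TRUE)
  err <- tryCatch(parse_boa_result(bad_uid), error = function(e) e)
  expect_s3_class(err, "boa_parse_error")
  expect_identical(err$path, "$.study_uid")

  bad_label <- sub('"spleen"', '"xyzzy-nonsense"', minimal_doc(), fixed = TRUE)
  err <- tryCatch(parse_boa_result(bad_label), error = function(e) e)
  expect_s3_class(err, "boa_parse_error")
  expect_identical(err$path, "$.organs[1].structure")

  no_model <- sub(',\n    "model": \\{[^}]*\\}', "", minimal_doc())
  err <- tryCatch(parse_boa_result(no_model), error = function(e) e)
  expect_s3_class(err, "boa_parse_error")
  expect_identical(err$path, "$.model")
})

test_that("unknown top-level keys are ignored with a warning", {
  doc <- sub('"patient_id"', '"vendor_extras": {"a": 1}, "patient_id"', minimal_doc(),
             fixed = TRUE)
  expect_warning(r <- parse_boa_result(doc), "vendor_extras")
  expect_s3_class(r, "boa_result")
})

test_that("model invariants are enforced by the constructor", {
  r <- syn_result(1)
  expect_error(
    boa_result(patient_id = r$patient_id, study_uid = r$study_uid,
               series = r$series, regions = list(), organs = list(),
               model = r$model),
    class = "boa_invalid_result"
  )
  dup_series <- c(r$series[1], r$series[1])
  expect_error(
    boa_result(patient_id = r$patient_id, study_uid = r$study_uid,
               series = dup_series, organs = r$organs, model = r$model),
    class = "boa_invalid_result"
  )
  bad_density <- r
  bad_density$regions[[1]]$tissues[[1]]$mean_density_hu <- 5000
  err <- tryCatch(do.call(boa_result, unclass(bad_density)[names(formals(boa_result))]),
                  error = function(e) e)
  expect_s3_class(err, "boa_invalid_result")
  expect_match(err$issues[1], "mean_density_hu")
})

test_that("the generator is deterministic and honours its defaults", {
  r1 <- generate_synthetic_result(42)
  r2 <- generate_synthetic_result(42)
  expect_identical(boa_result_json(r1), boa_result_json(r2))
  expect_length(r1$regions, 8)   # 4 body sites x 2 measurement modes
  expect_length(r1$organs, 104)  # all anatomical landmarks
  expect_false(identical(boa_result_json(r1),
                         boa_result_json(generate_synthetic_result(43))))
  # RNG state of the session is untouched
  set.seed(7); before <- runif(1)
  set.seed(7); invisible(generate_synthetic_result(1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("generator rejects inconsistent configurations", {
  expect_error(boa_sim_config(organ_volume_range = c(10, 2)),
               class = "boa_invalid_config")
  expect_error(boa_sim_config(n_organs = 0, body_sites = character()),
               class = "boa_invalid_config")
  expect_error(boa_sim_config(n_organs = 200), class = "boa_invalid_config")
})

test_that("parse o serialize is the identity on generated results", {
  for (seed in c(1, 7, 23)) {
    r <- generate_synthetic_result(seed)
    json <- boa_result_json(r)
    expect_no_warning(r2 <- parse_boa_result(json))
    expect_identical(boa_result_json(r2), json)
    expect_identical(r2$regions, r$regions)
    expect_identical(r2$organs, r$organs)
  }
})

test_that("generated results survive file round trips and re-validate silently", {
  r <- syn_result(1)
  path <- withr::local_tempfile(fileext = ".json")
  write_boa_result(r, path)
  expect_no_warning(r2 <- parse_boa_result(path))
  expect_identical(boa_result_json(r2), boa_result_json(r))
})

test_that("tidy accessors expose the measurements", {
  r <- syn_result(1)
  org <- boa_organs(r)
  tis <- boa_tissues(r)
  expect_identical(nrow(org), 104L)
  expect_identical(nrow(tis), 64L) # 8 regions x 8 tissues
  expect_true(all(org$volume_ml >= 0))
  expect_true(all(tis$mean_density_hu >= -1024 & tis$mean_density_hu <= 3071))
  expect_setequal(unique(tis$body_site), valueset_members("BCABodySiteVS")$display)
})
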