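# Conformance validator: checks resources against the exported profile
# definitions (cardinality, fixed values, required bindings, unit and UID
# discipline, component layouts) and bundles against cross-resource rules
# (referential integrity, aggregation completeness, AIAST provenance).
# Elements outside the constraint tables are accepted silently (open world).
#
# Issues are accumulated in a plain-list collector and materialized as a
# tibble once per call; membership tables are pre-indexed per validation run.

#' The validator's rule registry
#'
#' Every issue produced by [validate_resource()] / [validate_bundle()] carries
#' a `rule_id` from this registry together with its severity.
#'
#' @return Tibble with columns `rule_id`, `severity`, `description`.
#' @export
boa_rules <- function() {
  tibble::tribble(
    ~rule_id, ~severity, ~description,
    "parse-error", "error", "resource or bundle JSON could not be interpreted",
    "meta-profile-missing", "error", "meta.profile does not list the profile canonical",
    "cardinality-min", "error", "required element is absent or under-populated",
    "cardinality-max", "error", "element repeats beyond its maximum cardinality",
    "fixed-value", "error", "element deviates from the profile's fixed value or pattern",
    "binding-violation", "error", "coding is not a member of the required value set",
    "unit-ucum", "error", "quantity does not use the required UCUM unit",
    "uid-grammar", "error", "DICOM UID violates the dotted-decimal grammar",
    "identifier-dicom-missing", "error", "no identifier under the urn:dicom:uid scheme",
    "component-duplicate", "error", "duplicate component concept within one observation",
    "component-layout", "error", "component lacks its mandatory code or value",
    "slice-range-invalid", "error", "slice range is not an integer range with 1 <= low <= high",
    "number-of-series", "error", "numberOfSeries does not count the listed inference series",
    "attachment-mime", "error", "presentedForm uses an unsupported report format",
    "reference-dangling", "error", "internal reference does not resolve within the bundle",
    "report-result-incomplete", "error", "DiagnosticReport.result does not cover every observation",
    "provenance-missing", "error", "AI-derived resource lacks the AIAST security tag",
    "bundle-cardinality", "error", "more than one ImagingStudy or DiagnosticReport in a bundle",
    "value-range", "error", "measurement value outside its physical range",
    "unknown-resource", "warning", "resource type outside the BOA profile set (ignored)",
    "unknown-coding", "warning", "coding from an unconfigured code system"
  )
}

# issue collector: closures appending to a growing list, tibble at the end
new_collector <- function() {
  items <- vector("list", 64)
  n <- 0L
  reg <- boa_rules()
  list(
    add = function(rule_id, path, message) {
      sev <- reg$severity[match(rule_id, reg$rule_id)]
      stopifnot(!is.na(sev))
      n <<- n + 1L
      items[[n]] <<- list(severity = sev, rule_id = rule_id,
                          path = path, message = message)
    },
    result = function() {
      if (n == 0L) {
        return(tibble(severity = character(), rule_id = character(),
                      path = character(), message = character()))
      }
      got <- items[seq_len(n)]
      tibble(
        severity = map_chr(got, "severity"), rule_id = map_chr(got, "rule_id"),
        path = map_chr(got, "path"), message = map_chr(got, "message")
      )
    }
  )
}

# membership index: named character sets "system\tcode" per value set
membership_index <- function() {
  idx <- .boa_env$membership_index
  stamp <- names(valueset_registry())
  if (!is.null(idx) && identical(attr(idx, "stamp"), stamp)) return(idx)
  idx <- lapply(stats::setNames(nm = stamp), function(vs) {
    m <- valueset_members(vs)
    paste(m$system, m$code, sep = "\t")
  })
  attr(idx, "stamp") <- stamp
  .boa_env$membership_index <- idx
  idx
}

coding_in_valueset_fast <- function(codings, valueset_id, idx) {
  members <- idx[[valueset_id]]
  if (is.null(members)) return(FALSE)
  any(map_lgl(codings, function(cd) {
    paste(cd$system %||% "", cd$code %||% "", sep = "\t") %in% members
  }))
}

# count element repeats: NULL -> 0, unnamed list -> length, scalar/object -> 1
elem_count <- function(x) {
  if (is.null(x)) return(0L)
  if (is.list(x) && (is.null(names(x)) || all(names(x) == ""))) return(length(x))
  1L
}

as_coding_list <- function(codeable) {
  if (is.null(codeable)) return(list())
  codeable$coding %||% list()
}

coding_matches <- function(codings, concept) {
  any(map_lgl(codings, function(cd) {
    identical(cd$system, concept$system) && identical(cd$code, concept$code)
  }))
}

check_quantity <- function(col, q, expected_code, path, what) {
  if (is.null(q)) {
    col$add("component-layout", path, paste0(what, " quantity is missing"))
    return(invisible())
  }
  if (!identical(q$system, UCUM_SYSTEM)) {
    col$add("unit-ucum", path, paste0(what, " quantity system is not UCUM"))
  }
  if (!identical(q$code, expected_code)) {
    col$add("unit-ucum", path, sprintf("%s unit code '%s' (expected '%s')",
                                       what, q$code %||% "<none>", expected_code))
  }
  if (!is_scalar_number(q$value)) {
    col$add("component-layout", path, paste0(what, " quantity has no numeric value"))
  }
  invisible()
}

# -- whole-resource rules -----------------------------------------------------

rule_bca_components <- function(col, resource, root, idx) {
  slice_cpt <- slice_range_concept()
  dens_cpt <- mean_density_concept()
  tissue_keys <- character()
  n_slice <- 0L
  comps <- resource$component %||% list()
  for (i in seq_along(comps)) {
    cmp <- comps[[i]]
    p <- sprintf("%s.component[%d]", root, i)
    codings <- as_coding_list(cmp$code)
    if (length(codings) == 0) {
      col$add("component-layout", paste0(p, ".code"), "component without coded concept")
      next
    }
    if (coding_matches(codings, slice_cpt)) {
      n_slice <- n_slice + 1L
      rng <- cmp$valueRange
      lo <- get_path(rng, c("low", "value"))
      hi <- get_path(rng, c("high", "value"))
      ok <- is_scalar_number(lo) && is_scalar_number(hi) &&
        lo == round(lo) && hi == round(hi) && lo >= 1 && lo <= hi
      if (!ok) {
        col$add("slice-range-invalid", paste0(p, ".valueRange"),
                "slice range must satisfy 1 <= low <= high (integers)")
      }
      if (n_slice > 1L) {
        col$add("cardinality-max", p, "at most one slice-range component")
      }
    } else if (coding_matches(codings, dens_cpt)) {
      others <- keep(codings, function(cd) {
        !(identical(cd$code, dens_cpt$code) && identical(cd$system, dens_cpt$system))
      })
      if (!coding_in_valueset_fast(others, "BCATissueVS", idx)) {
        col$add("binding-violation", paste0(p, ".code"),
                "density component lacks a BCATissueVS tissue coding")
      }
      check_quantity(col, cmp$valueQuantity, UCUM_HU,
                     paste0(p, ".valueQuantity"), "density")
      v <- get_path(cmp, c("valueQuantity", "value"))
      if (is_scalar_number(v) && (v < -1024 || v > 3071)) {
        col$add("value-range", paste0(p, ".valueQuantity.value"),
                "mean density outside [-1024, 3071] HU")
      }
    } else {
      if (!coding_in_valueset_fast(codings, "BCATissueVS", idx)) {
        col$add("binding-violation", paste0(p, ".code"),
                "tissue component coding is not in BCATissueVS")
      } else {
        key <- paste(codings[[1]]$system, codings[[1]]$code)
        if (key %in% tissue_keys) {
          col$add("component-duplicate", p, "duplicate tissue volume component")
        }
        tissue_keys <- c(tissue_keys, key)
      }
      check_quantity(col, cmp$valueQuantity, UCUM_ML,
                     paste0(p, ".valueQuantity"), "volume")
      v <- get_path(cmp, c("valueQuantity", "value"))
      if (is_scalar_number(v) && v < 0) {
        col$add("value-range", paste0(p, ".valueQuantity.value"),
                "negative tissue volume")
      }
    }
  }
}

rule_organ_components <- function(col, resource, root, idx) {
  keys <- new.env(parent = emptyenv())
  comps <- resource$component %||% list()
  for (i in seq_along(comps)) {
    cmp <- comps[[i]]
    p <- sprintf("%s.component[%d]", root, i)
    codings <- as_coding_list(cmp$code)
    if (length(codings) == 0) {
      col$add("component-layout", paste0(p, ".code"),
              "organ component without coded concept")
      next
    }
    if (!coding_in_valueset_fast(codings, "BodyStructureLandmarkVS", idx)) {
      col$add("binding-violation", paste0(p, ".code"),
              "structure coding is not in BodyStructureLandmarkVS")
    } else {
      key <- paste(codings[[1]]$system, codings[[1]]$code)
      if (!is.null(keys[[key]])) {
        col$add("component-duplicate", p, "duplicate structure component")
      }
      keys[[key]] <- TRUE
    }
    check_quantity(col, cmp$valueQuantity, UCUM_ML,
                   paste0(p, ".valueQuantity"), "volume")
  }
}

rule_ucum_units <- function(col, resource, root, idx) {
  walk <- function(x, path) {
    if (!is.list(x)) return()
    nms <- names(x) %||% rep("", length(x))
    for (i in seq_along(x)) {
      nm <- nms[i]
      child_path <- if (nzchar(nm)) paste0(path, ".", nm) else sprintf("%s[%d]", path, i)
      if (nm %in% c("valueQuantity", "low", "high") && is.list(x[[i]])) {
        q <- x[[i]]
        if (!identical(q$system, UCUM_SYSTEM)) {
          col$add("unit-ucum", child_path, "quantity system must be UCUM")
        }
        if (!is_string(q$code %||% "") || !nzchar(q$code %||% "")) {
          col$add("unit-ucum", child_path, "quantity lacks a coded UCUM unit")
        }
      }
      walk(x[[i]], child_path)
    }
  }
  walk(resource, root)
}

rule_dicom_identifier <- function(col, resource, root, idx) {
  ids <- resource$identifier %||% list()
  dicom <- keep(ids, function(id) identical(id$system, DICOM_UID_SYSTEM))
  if (length(dicom) == 0) {
    col$add("identifier-dicom-missing", paste0(root, ".identifier"),
            "no identifier under the urn:dicom:uid scheme")
    return(invisible())
  }
  for (d in dicom) {
    val <- d$value %||% ""
    uid <- sub("^urn:oid:", "", val)
    if (!startsWith(val, "urn:oid:") || !validate_dicom_uid(uid)) {
      col$add("uid-grammar", paste0(root, ".identifier.value"),
              paste0("malformed DICOM identifier: ", val))
    }
  }
}

rule_series_elements <- function(col, resource, root, idx) {
  series <- resource$series %||% list()
  uids <- character()
  for (i in seq_along(series)) {
    s <- series[[i]]
    p <- sprintf("%s.series[%d]", root, i)
    if (!is_string(s$uid %||% "") || !validate_dicom_uid(s$uid %||% "")) {
      col$add("uid-grammar", paste0(p, ".uid"),
              "series uid is not a well-formed DICOM UID")
    }
    if ((s$uid %||% "") %in% uids) {
      col$add("component-duplicate", paste0(p, ".uid"), "duplicate series uid")
    }
    uids <- c(uids, s$uid %||% "")
    if (!is_string(get_path(s, c("modality", "code")) %||% "")) {
      col$add("component-layout", paste0(p, ".modality"),
              "series modality code is missing")
    }
  }
}

rule_number_of_series <- function(col, resource, root, idx) {
  n <- resource$numberOfSeries
  listed <- length(resource$series %||% list())
  if (!is_scalar_number(n) || n != listed) {
    col$add("number-of-series", paste0(root, ".numberOfSeries"),
            sprintf("numberOfSeries is %s but %d inference series are listed",
                    n %||% "<absent>", listed))
  }
}

rule_presented_form_mime <- function(col, resource, root, idx) {
  forms <- resource$presentedForm %||% list()
  for (i in seq_along(forms)) {
    f <- forms[[i]]
    p <- sprintf("%s.presentedForm[%d]", root, i)
    if (!(f$contentType %||% "") %in% SUPPORTED_MIMES) {
      col$add("attachment-mime", paste0(p, ".contentType"),
              paste0("unsupported report format: ", f$contentType %||% "<missing>"))
    }
    if (sum(!is.null(f$data), !is.null(f$url)) != 1) {
      col$add("attachment-mime", p, "exactly one of data/url is required")
    }
  }
}

rule_registry_impl <- function() {
  list(
    "bca-components" = rule_bca_components,
    "organ-components" = rule_organ_components,
    "ucum-units" = rule_ucum_units,
    "dicom-identifier" = rule_dicom_identifier,
    "series-elements" = rule_series_elements,
    "number-of-series" = rule_number_of_series,
    "presented-form-mime" = rule_presented_form_mime
  )
}

# -- resource validation ------------------------------------------------------

validate_resource_into <- function(col, resource, profile, idx) {
  root <- resource$resourceType %||% "?"
  if (!is.list(resource) || is.null(resource$resourceType)) {
    col$add("parse-error", "?", "not a FHIR resource (resourceType missing)")
    return(invisible())
  }
  if (!identical(root, profile$base_resource)) {
    col$add("parse-error", root,
            sprintf("resource type %s does not match profile base %s",
                    root, profile$base_resource))
    return(invisible())
  }
  profiles <- unlist(resource$meta$profile %||% list())
  if (!profile$canonical_url %in% profiles) {
    col$add("meta-profile-missing", paste0(root, ".meta.profile"),
            paste0("missing canonical ", profile$canonical_url))
  }

  for (i in seq_len(nrow(profile$constraints))) {
    r <- profile$constraints[i, ]
    el <- resource[[r$path]]
    path <- paste0(root, ".", r$path)
    n <- elem_count(el)
    if (n < r$min) {
      col$add("cardinality-min", path,
              sprintf("element requires min %d, found %d", r$min, n))
      next
    }
    if (r$max != "*" && n > as.numeric(r$max)) {
      col$add("cardinality-max", path,
              sprintf("element allows max %s, found %d", r$max, n))
    }
    fx <- r$fixed[[1]]
    if (!is.null(fx) && n > 0) {
      if (identical(r$datatype, "code")) {
        if (!identical(el, fx)) {
          col$add("fixed-value", path,
                  sprintf("expected fixed value '%s', found '%s'",
                          fx, as.character(el)))
        }
      } else {
        cc_list <- if (is.list(el) && is.null(names(el))) el else list(el)
        ok <- any(map_lgl(cc_list, function(cc) coding_matches(as_coding_list(cc), fx)))
        if (!ok) {
          col$add("fixed-value", path,
                  sprintf("no coding matches pattern (%s, %s)", fx$system, fx$code))
        }
      }
    }
    if (!is.na(r$binding_valueset) && n > 0) {
      if (!coding_in_valueset_fast(as_coding_list(el), r$binding_valueset, idx)) {
        col$add("binding-violation", path,
                paste0("coding is not a member of ", r$binding_valueset))
      }
    }
  }

  impl <- rule_registry_impl()
  for (rule in profile$rules) {
    impl[[rule]](col, resource, root, idx)
  }
  invisible()
}

#' Validate one resource against a profile definition
#'
#' Checks cardinalities, fixed values/patterns, required bindings (via the
#' terminology layer), unit and UID discipline, component layouts, and that
#' `meta.profile` lists the profile canonical. An empty tibble means the
#' resource conforms.
#'
#' @param resource A built resource (or one re-read from FHIR JSON).
#' @param profile A `boa_profile` from [export_profile_definitions()].
#' @return Tibble of issues (see [boa_rules()]); zero rows when conformant.
#' @export
validate_resource <- function(resource, profile) {
  col <- new_collector()
  validate_resource_into(col, resource, profile, membership_index())
  col$result()
}

# -- bundle validation --------------------------------------------------------

# profile selection: meta.profile first, resource type as fallback heuristic
match_profile <- function(resource, profiles) {
  urls <- map_chr(profiles, function(p) p$canonical_url)
  declared <- unlist(resource$meta$profile %||% list())
  hit <- which(urls %in% declared)
  if (length(hit)) return(profiles[[hit[1]]])
  cand <- keep(profiles, function(p) identical(p$base_resource, resource$resourceType))
  if (length(cand) == 1) return(cand[[1]])
  if (length(cand) > 1) {
    # two Observation profiles: bodySite separates the BCA layout
    if (!is.null(resource$bodySite)) {
      return(cand[[which(map_chr(cand, "id") == "boa-bca-observation")]])
    }
    return(cand[[which(map_chr(cand, "id") == "boa-body-structure-volume-observation")]])
  }
  NULL
}

collect_references <- function(x) {
  refs <- character()
  walk <- function(x) {
    if (!is.list(x)) return()
    if (!is.null(x$reference) && is.character(x$reference)) {
      refs <<- c(refs, x$reference)
    }
    for (el in x) walk(el)
  }
  walk(x)
  refs
}

#' Validate an assembled bundle
#'
#' Runs [validate_resource()] on every entry (profile chosen from
#' `meta.profile`) and adds the cross-resource rules: internal references must
#' resolve, `DiagnosticReport.result` must cover exactly the contained
#' Observations, every AI-derived resource must carry the AIAST tag, and a
#' bundle holds at most one ImagingStudy and one DiagnosticReport. Non-BOA
#' resources are ignored with a warning issue.
#'
#' @param bundle A Bundle (built or re-read from JSON).
#' @return Tibble of issues; zero rows when the bundle conforms.
#' @export
validate_bundle <- function(bundle) {
  col <- new_collector()
  if (!is.list(bundle) || !identical(bundle$resourceType, "Bundle")) {
    col$add("parse-error", "Bundle", "not a FHIR Bundle")
    return(col$result())
  }
  idx <- membership_index()
  profiles <- export_profile_definitions()
  boa_types <- c("Observation", "DiagnosticReport", "ImagingStudy", "Procedure")
  entries <- bundle$entry %||% list()

  local_ids <- character()
  obs_refs <- character()
  report_entry <- NULL
  n_study <- 0L
  n_report <- 0L

  for (i in seq_along(entries)) {
    res <- entries[[i]]$resource
    root <- sprintf("Bundle.entry[%d]", i)
    if (is.null(res)) {
      col$add("parse-error", root, "entry without resource")
      next
    }
    rt <- res$resourceType %||% "?"
    local_ids <- c(local_ids, paste0(rt, "/", res$id %||% ""))
    if (!rt %in% boa_types) {
      col$add("unknown-resource", paste0(root, ".", rt),
              paste0("resource type ", rt, " is outside the BOA profile set"))
      next
    }
    if (rt == "ImagingStudy") n_study <- n_study + 1L
    if (rt == "DiagnosticReport") {
      n_report <- n_report + 1L
      report_entry <- list(res = res, root = root)
    }
    if (rt == "Observation") obs_refs <- c(obs_refs, paste0("Observation/", res$id %||% ""))

    if (rt == "Procedure") {
      # external MII profile: structural checks only
      if (length(res$report %||% list()) == 0) {
        col$add("cardinality-min", paste0(root, ".Procedure.report"),
                "procedure must link its diagnostic report")
      }
    } else {
      prof <- match_profile(res, profiles)
      if (is.null(prof)) {
        col$add("parse-error", paste0(root, ".", rt),
                "no BOA profile matches this resource")
        next
      }
      sub <- new_collector()
      validate_resource_into(sub, res, prof, idx)
      found <- sub$result()
      for (j in seq_len(nrow(found))) {
        col$add(found$rule_id[j], paste0(root, ".", found$path[j]), found$message[j])
      }
    }
    if (!has_aiast(res)) {
      col$add("provenance-missing", paste0(root, ".", rt, ".meta.security"),
              paste0(rt, "/", res$id %||% "?", " lacks the AIAST provenance tag"))
    }
  }

  if (n_study > 1L || n_report > 1L) {
    col$add("bundle-cardinality", "Bundle.entry",
            "at most one ImagingStudy and one DiagnosticReport per bundle")
  }

  # referential integrity: references to BOA resource types must resolve locally
  internal_pattern <- paste0("^(", paste(boa_types, collapse = "|"), ")/")
  for (i in seq_along(entries)) {
    res <- entries[[i]]$resource
    if (is.null(res) || !(res$resourceType %||% "") %in% boa_types) next
    refs <- collect_references(res)
    internal <- refs[grepl(internal_pattern, refs)]
    for (m in setdiff(internal, local_ids)) {
      col$add("reference-dangling",
              sprintf("Bundle.entry[%d].%s", i, res$resourceType),
              paste0("reference ", m, " does not resolve within the bundle"))
    }
  }

  # the report aggregates every observation in the bundle
  if (!is.null(report_entry)) {
    listed <- map_chr(report_entry$res$result %||% list(),
                      function(r) r$reference %||% "")
    for (u in setdiff(obs_refs, listed)) {
      col$add("report-result-incomplete",
              paste0(report_entry$root, ".DiagnosticReport.result"),
              paste0("observation ", u, " is not listed in result"))
    }
  }
  col$result()
}
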