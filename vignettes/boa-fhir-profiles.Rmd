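---
title: "Representing AI-derived CT body composition as FHIR R4: the BOA profile set"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representing AI-derived CT body composition as FHIR R4}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boafhir)
```

## The problem

Automated segmentation models for routine CT — body-composition analysis (BCA)
combined with whole-body organ segmentation, together "body and organ analysis"
(BOA) — produce a rich set of quantitative biomarkers: tissue volumes and mean
Hounsfield-unit densities per body region, and volumes for about a hundred
anatomical landmarks. These numbers support opportunistic screening (sarcopenia,
osteoporosis, cardiovascular risk) but typically live in vendor-specific JSON or
PDF reports, invisible to the clinical record.

`boafhir` turns one such analysis result into a set of interlinked, profile-
conformant HL7 FHIR R4 resources so the measurements can be stored, exchanged
and queried like any other clinical observation:

* **BCA Observation** — one per body region and measurement mode, carrying
  tissue volumes/densities as components;
* **Body Structure Volume Observation** — a single observation with one
  component per segmented organ;
* **Diagnostic Report** — the central aggregator referencing every observation
  and carrying the rendered reports (PDF/JSON/spreadsheet) as `presentedForm`;
* **Imaging Study** — referencing *only* the series used for AI inference,
  identified by DICOM UIDs under the `urn:dicom:uid` scheme.

A fifth resource, a Procedure conforming to the externally published Read
Procedure profile of the German Medical Informatics Initiative (MII), documents
the model name, version and computational parameters; it is referenced by
canonical URL and not re-profiled here.

Every resource the package emits is tagged with the HL7 `AIAST` ("Artificial
Intelligence Asserted") security tag, so downstream consumers can always tell
AI-generated measurements from human-entered data — in mixed repositories this
provenance is what keeps AI output interpretable.

## Terminology

All coded elements resolve through five shipped value sets, stored as editable
TSV tables (`display`, `system`, `code`, `synonyms`) under
`inst/extdata/valuesets/` and loaded at first use:

| id | members | binds |
|---|---|---|
| `BCABodySiteVS` | 4 | `Observation.bodySite` of the BCA profile |
| `BCAMeasurementsVS` | 2 | `Observation.code` of the BCA profile |
| `BCATissueVS` | 8 | tissue component codes |
| `BodyStructureLandmarkVS` | 104 | organ component codes |
| `BCARegionVS` | 8 | shipped for region-level analyses; not bound by a profile |

Design notes, in decreasing order of external grounding:

* The four body sites (abdominal cavity, thoracic cavity, mediastinum,
  pericardium) carry SNOMED CT codes, as do organs with stable, widely
  documented SCTIDs (spleen, liver, kidneys, ...). Terminology releases evolve,
  so codes are *data*, not logic: deployments should review the tables against
  their SNOMED CT / RadLex release and may replace any code without touching
  package code. RadLex is a configured system with lookup priority
  SNOMED CT > RadLex > local; the shipped tables currently map no concept to
  it rather than invent RIDs.
* The 104 landmarks are the public TotalSegmentator v1 class inventory — the
  only public enumeration matching that cardinality for whole-body CT
  segmentation. Vertebrae, ribs and lateralized structures use project-local
  codes (`ts-*`) because per-side SCTIDs could not be confirmed reliably.
* The 8 tissue compartments (muscle, bone, subcutaneous / visceral /
  intramuscular / intermuscular adipose tissue, epicardial and paracardial
  adipose tissue) are BCA-specific pseudo-tissues and live in the project-local
  code system: FHIR requires *some* system for every coding, and inventing
  SNOMED codes would be worse than honestly local ones.
* The relationship between "8 body regions" and the 4 bodySite cavities is
  genuinely open. This package realizes the 8 regions as
  4 cavities × 2 measurement modes ("measurement including/excluding
  extremities"), which is what the generator produces by default, and
  additionally ships an 8-member `BCARegionVS` (whole body, the four cavities,
  pelvic cavity, retroperitoneum, extremities) as a package decision for
  region-level analyses.

`lookup_concept()` is case- and whitespace-insensitive and consults synonyms
(e.g. `"SAT"`, `"kidney_right"`), so vendor labels map without a shim layer.

## The input model and its canonical JSON

A `boa_result` holds: patient identifier, DICOM study UID, the inference series
(UID, modality, instance count, optional body site), per-region tissue
measurements (volume in mL, optional mean density in HU, optional 1-based
inclusive slice range interpreted as DICOM InstanceNumber positions), organ
volumes in mL, model metadata (name, version, key→value parameters) and report
attachments (PDF, JSON or XLSX; exactly one of base64 `data` / `url`). The
canonical JSON schema ships at `inst/extdata/boa-result-schema.json`; coded
fields are carried as labels and resolved on parse, and `parse_boa_result()`
rejects any invariant violation with the offending JSON path (`$.study_uid`,
`$.regions[2].tissues[1].volume_ml`, ...).

DICOM UIDs are validated against the dotted-decimal grammar (digit-only
components, no leading zeros except the component "0", total length ≤ 64); the
test suite pins the implementation to a brute-force regular-grammar oracle on
an exhaustive enumeration of short strings plus a curated 50-case edge list.

## Builder decisions

Where the profile layout left room, the package decides as follows:

* **One BCA Observation per (body site, mode)** — bodySite is a scalar element
  of Observation, so a single observation cannot carry several regions.
* **Density components**: HU densities are a first-class BOA output but have no
  dedicated slot in the profile sketch; each tissue's density becomes a paired
  component whose code combines the local `mean tissue density` concept with
  the tissue coding, keeping the representation lossless and self-describing.
* **sliceRange** is an integer `Range` (`low`/`high`, UCUM unit `1`) on a
  dedicated component; the component is named in the profile but its datatype
  is not, and an integer range is the minimal faithful encoding.
* **DICOM identifiers**: `identifier.system = "urn:dicom:uid"`,
  `identifier.value = "urn:oid:" + UID`, on both ImagingStudy and
  DiagnosticReport (the report reuses the study UID; a report-specific UID
  would require minting identifiers the input does not contain).
* **numberOfSeries counts the listed inference series**, not the original
  study's full series count — the resource intentionally references only what
  the model saw.
* **Fixed values**: `Observation.status = "final"`, category `imaging`,
  `ImagingStudy.status = "available"`, `Procedure.status = "completed"`.
* **Model metadata as annotations**: `name=...`, `version=...`,
  `parameter.<key>=...` notes on the Procedure keep the MII profile untouched;
  custom extensions would have required re-profiling an external artifact.
* **Deterministic ids by default**: resource ids are MD5 content hashes of the
  id-less resource JSON, so identical inputs yield byte-identical bundles —
  valuable for deduplication and for reproducing any reported artifact.
  Version-4 UUIDs are available via `id_strategy = "uuid"`.
* **Canonical base URL** (`https://boa.example.org/fhir` by default) is
  configuration via `options(boafhir.canonical_base = ...)`; no canonical has
  been published for these profiles.

## Validation semantics

`validate_resource()` checks a resource against the machine-readable constraint
table of its profile — cardinalities, fixed values/patterns, required bindings
(membership on the (system, code) pair, never the display), `meta.profile` —
plus whole-resource rules a flat path table cannot express: component layouts,
UCUM unit discipline (`mL` for volumes, `[hnsf'U]` for densities), UID grammar
on DICOM identifiers, physical ranges. `validate_bundle()` adds the
cross-resource rules: internal references resolve, the report covers every
observation, AIAST on all resources, at most one ImagingStudy and one
DiagnosticReport.

Binding strength follows the "fixed binding" language of the profile set: all
named bindings are `required`, so violations are errors. Everything outside the
constraint tables is accepted silently (open-world), matching FHIR profiling
semantics; resource types outside the BOA set produce warnings, not errors.
Every issue carries a `rule_id` from the documented registry (`boa_rules()`),
its severity, and an element path, so findings are machine-actionable.
Validation never mutates its input.

## What the synthetic generator does and does not emulate

`generate_synthetic_result(seed)` emulates the *document*, not the biology: it
emits well-formed UIDs, all 4 body sites × both modes, draws over all 8 tissues
and all 104 landmarks, and attaches PDF/JSON report stubs. Volumes and
densities are uniform draws from plausible ranges (organ volumes 10–2000 mL,
tissue volumes 20–4000 mL, muscle 20–60 HU, bone 150–1200 HU, adipose −150 to
−50 HU) chosen once as generator configuration — they are explicitly *not*
claims about any cohort. There is no anatomical correlation structure, no
left/right symmetry, no pathology, and no vendor-dialect noise.

Passing tests therefore demonstrate contract correctness — schema, terminology
binding, referential closure, information preservation, determinism — on the
full structural envelope of real BOA outputs. They do not demonstrate clinical
plausibility of values, and a real deployment still needs an adapter from the
vendor's output dialect to the canonical schema.

Problem sizes used by the test suite and the acceptance script are the
package's own choices: conformance closure over 100 seeded results, round-trip
fidelity over 20 seeds, fault injection with 17 documented single-field
mutations, and exhaustive UID-grammar agreement on all 5460 strings of length
≤ 6 over `{0, 1, ., a}`.

## Numerical and degenerate-input choices

* Measurement values round-trip exactly because serialization uses full-
  precision JSON and the generator emits values with ≤ 2 decimals; no epsilon
  comparisons are needed anywhere.
* A result must contain at least one region or organ; a region must contain at
  least one tissue, with pairwise-distinct tissue concepts; series UIDs must be
  pairwise distinct. These are constructor errors, not validator findings,
  so malformed objects cannot exist in memory.
* Slice ranges require integers `1 ≤ low ≤ high`; densities must lie in the
  physical CT range [−1024, 3071] HU.
* `lookup_concept()` ties are broken by system priority, then by shipped table
  order, making resolution stable across sessions.

## Limitations

This is not a general-purpose FHIR validator: it checks the BOA profile set
and its cross-links only. There is no XML serialization, no terminology-server
client ($expand/$validate-code), and no FHIR R5 `ImagingSelection` /
`BodyStructure` variants — R5 offers leaner alternatives for series references
and anatomical coding that a future revision could adopt. The `push`
subcommand (HTTP transaction POST) is feature-flagged off and untested by
design; the package's contract ends at conformant files.
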