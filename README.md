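# boafhir

Automated CT segmentation models ("body and organ analysis", BOA) quantify
body composition — tissue volumes and mean Hounsfield-unit densities per body
region — and the volumes of about a hundred anatomical structures from routine
scans. Those biomarkers power opportunistic screening (sarcopenia,
osteoporosis, cardiometabolic risk), but they usually stay trapped in
vendor-specific JSON or PDF reports. `boafhir` is for imaging-informatics and
data-integration teams who need those results inside the clinical record: it
serializes one analysis result into profile-conformant **HL7 FHIR R4**
resources, validates conformance, and extracts tidy tables back out.

The core is a set of four interlinked FHIR profiles plus an external
procedure profile:

* **BCA Observation** — one `Observation` per body region (bodySite bound to
  `BCABodySiteVS`, code bound to `BCAMeasurementsVS`): one component per
  tissue with a UCUM `mL` quantity, a paired mean-density component
  (UCUM `[hnsf'U]`), and an integer-`Range` slice-range component;
* **Body Structure Volume Observation** — one component per organ
  (code bound to the 104-member `BodyStructureLandmarkVS`, value in `mL`);
* **Diagnostic Report** — the central aggregator: DICOM identifier under the
  `urn:dicom:uid` scheme, references to every observation and the imaging
  study, rendered reports as `presentedForm` (PDF/JSON/XLSX);
* **Imaging Study** — only the series used for AI inference, with DICOM
  study/series UIDs;
* **Read Procedure** (external MII profile, referenced by canonical URL) —
  model name, version and parameters as structured annotations.

Every emitted resource carries the HL7 **AIAST** ("Artificial Intelligence
Asserted") security tag, and assembled transaction bundles are referentially
closed: `DiagnosticReport.result` covers every observation, `derivedFrom`
points at the imaging study, `Procedure.report` at the report.

## Worked example

```r
library(boafhir)

r <- generate_synthetic_result(1)   # seeded synthetic analysis document
r
#> <boa_result>
#>   patient: BOA-SYN-274741  study: 1.2.826.0.1.3680043.9590.439558.216048.986526
#>   2 series, 8 regions, 104 organ volumes, model BOA 1.0

b <- assemble_bundle(r)             # five resource types, AIAST-tagged
b
#> <boa_bundle> boa-3d7c39da81da - 12 entries: DiagnosticReport x1, ImagingStudy x1,
#>   Observation x9, Procedure x1

glance(b)                           # validation gate + shape at a glance
#> # A tibble: 1 × 5
#>   entries observations regions validation_errors validation_warnings
#>     <int>        <int>   <int>             <int>               <int>
#> 1      12            9       8                 0                   0

rows <- extract_measurements(b)     # 8x8 region-tissue rows + 104 organ rows
rows[c(1:2, 65:66), c("kind", "body_site", "tissue", "structure",
                      "volume_ml", "mean_density_hu")]
#> # A tibble: 4 × 6
#>   kind          body_site        tissue    structure volume_ml mean_density_hu
#>   <chr>         <chr>            <chr>     <chr>         <dbl>           <dbl>
#> 1 region-tissue abdominal cavity bone      <NA>          2900.           582.
#> 2 region-tissue abdominal cavity epicardi… <NA>          2935.           -80.7
#> 3 organ         <NA>             <NA>      aorta         1714.            NA
#> 4 organ         <NA>             <NA>      brain          624.            NA
```

The 12 bundle entries are the imaging study, 8 BCA observations (4 body
sites × 2 measurement modes), the organ-volume observation, the diagnostic
report and the procedure. Volumes are millilitres, densities Hounsfield
units; every value in `rows` equals the serialized FHIR value exactly, and
`extract_boa_result(b)` reproduces `r` byte for byte.

Seeding a single fault shows the validator's machine-readable findings:

```r
bad <- b
bad$entry[[2]]$resource$bodySite$coding[[1]]$code <- "000"
validate_bundle(bad)[, c("severity", "rule_id", "path")]
#> # A tibble: 1 × 3
#>   severity rule_id           path
#>   <chr>    <chr>             <chr>
#> 1 error    binding-violation Bundle.entry[2].Observation.bodySite
```

A command-line front end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "boa-fhir", package = "boafhir"))')
Rscript $CLI generate --seed 1 -o boa.json
Rscript $CLI convert boa.json -o bundle.json
Rscript $CLI validate bundle.json            # exit 0 iff no errors
Rscript $CLI extract bundle.json -o table.csv
```

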