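# fracturepathways

Post-fracture management patterns from administrative claims.

## What this package is for

After a first nontraumatic fracture, a woman aged 50 or older is at very
high risk of fracturing again — yet osteoporosis (OP) is persistently
underdiagnosed and undertreated in exactly this population. Health-plan
claims (enrollment spans, medical claims with diagnosis/procedure codes,
pharmacy claims with days of supply) are the standard substrate for
describing what actually happens after the fracture. `fracturepathways`
implements that descriptive pharmacoepidemiology pipeline for analysts
working with such data:

* **Fracture ascertainment** across nine anatomic sites (hip, femur,
  pelvis, vertebral, humerus, radius/ulna, tibia/fibula, ankle, clavicle).
  An inpatient diagnosis suffices; an outpatient diagnosis needs a same-site
  fracture-treatment procedure within a ±7-day pairing window, except
  vertebral fractures, where an evaluation-and-management visit suffices.
  Same-day multi-site events resolve by the site hierarchy above (hip
  first); across days, the earliest event is the index.
* **Cohort eligibility and attrition**: female, age ≥ 50 at index,
  continuous medical+pharmacy enrollment over the 365 days before and 183
  days after index, no same-day trauma, no prior fracture, no
  Paget's/other/metabolic bone disease, no cancer (non-melanoma skin
  cancer exempt) — applied in fixed order with a step-by-step attrition
  table.
* **Baseline profiling** over `[index−365, index−1]`, including the
  Charlson comorbidity index (weights summed over *distinct* categories).
* **Six-month management measures**: index hospitalization with
  nights-based length of stay, 30-day all-cause readmission
  (`[discharge+1, discharge+30]`), OP diagnosis, DXA and time to first
  scan, orthopedic surgery (index day included), rehabilitation, skilled
  nursing facility, durable medical equipment.
* **Medication persistence** at 6/12/24-month landmarks. A fill on day
  *f* with *s* days supply covers `[f, f+s−1]`; with run end *e*, a refill
  gap `f − e − 1 > 60` days discontinues the class, dated at the last
  covered day *e*; re-initiation is a same-class fill afterwards.
  Discontinuation is reported at a landmark only when the full 61-day gap
  is observable before it. Months on treatment exclude gaps
  (covered days / 30.4375).
* **Subsequent fractures**: a post-index event qualifies at a never-yet
  fractured site at any gap, or at a previously fractured site after a
  gap strictly over 90 days, with per-site state updated only by accepted
  events.
* **A label-first synthetic claims generator** with per-member ground
  truth, because the real databases this design targets are proprietary.
  The packaged `scenario_paper()` is calibrated to published headline
  values; the pipeline must recover every planted label member-for-member
  and every planted aggregate within Monte-Carlo tolerance.

All tables are descriptive (N, %, mean, SD) — no inferential statistics.
Codes are fully registry-driven: the shipped registry is a synthetic
vocabulary, and licensees drop in real ICD/CPT/NDC lists via one YAML file.

## Worked example

```r
library(fracturepathways)

registry <- load_registry()          # packaged synthetic code registry
config   <- analysis_config()        # 2014–2019 study, 2015–2019.5 index

gen <- generate_population(scenario_paper(n_members = 5000), registry, config)
res <- run_pipeline(gen$bundle, registry, config)

res$attrition
#>                                                           step n_remaining
#>  1:                                          members in bundle        5000
#>  2:            qualified nontraumatic fracture in index period        4888
#>  3:                                                     female        4828
#>  4:                                         age >= 50 at index        4692
#>  5:  continuous pre-index enrollment (365 d, medical+pharmacy)        4510
#>  6: continuous post-index enrollment (183 d, medical+pharmacy)        4343
#>  7:                          no trauma diagnosis on index date        4225
#>  8:                             no prior nontraumatic fracture        4063
#>  9:          no Paget's/other/metabolic bone disease pre-index        3994
#> 10:      no pre-index cancer (non-melanoma skin cancer exempt)        3809
```

The attrition starts from all simulated members and ends at the analysis
cohort (n = 3,809 here). Six-month management measures, stratified:

```r
res$table3[stratum %in% c("overall", "hip") &
           measure %in% c("hospitalized_for_index", "ortho_surgery_6mo")]
#>    stratum                measure  kind numerator denominator    value
#> 1:     hip hospitalized_for_index   pct       456         474 96.20253
#> 2: overall hospitalized_for_index   pct      1327        3809 34.83854
#> 3:     hip      ortho_surgery_6mo   pct       427         474 90.08439
#> 4: overall      ortho_surgery_6mo   pct      1654        3809 43.42347
```

Read: 96.2% of the 474 hip-index members were hospitalized for the index
fracture and 90.1% had orthopedic surgery within six months, against 34.8%
and 43.4% in the overall cohort — hip fractures carry by far the heaviest
acute burden. Treatment and subsequent-fracture landmarks:

```r
res$table4[landmark == "6mo" & stratum == "overall" & measure == "any_op_med"]
#>    landmark stratum    measure  kind numerator denominator    value
#> 1:      6mo overall any_op_med   pct       423        3809 11.10528
res$table5[landmark == "6mo" & stratum == "overall" & measure == "any_subsequent"]
#>    landmark stratum        measure numerator denominator    value
#> 1:      6mo overall any_subsequent       255        3809 6.694671
```

Only 11.1% of the cohort received any OP medication within six months of
the fracture, and 6.7% had already fractured again. `emit_reports(res,
"reports")` writes the attrition and all five aggregate tables (plus
member-level files and a run manifest) as CSV, every percentage cell
carrying its numerator and denominator.

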