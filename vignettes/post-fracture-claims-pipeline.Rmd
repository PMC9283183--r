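---
title: "Post-fracture management patterns from administrative claims: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-fracture management patterns from administrative claims: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracturepathways)
library(data.table)
```

## The problem

Osteoporosis is persistently underdiagnosed and undertreated after a first
nontraumatic fracture, even though such a fracture marks a woman as being at
very high risk of a subsequent one. Administrative claims — enrollment spans,
medical claims carrying diagnosis and procedure codes, and pharmacy claims
carrying days of supply — are the standard observational substrate for
describing what actually happens after the fracture: whether the patient is
hospitalized and for how long, whether she receives a bone-density (DXA)
scan or an osteoporosis diagnosis, whether she starts an osteoporosis
medication and stays on it, and whether she fractures again.

`fracturepathways` implements that descriptive pipeline end to end for women
aged 50 and older with a first nontraumatic fracture of the hip, femur,
pelvis, vertebra, humerus, radius/ulna, tibia/fibula, ankle, or clavicle.
It is purely descriptive: means, standard deviations, frequencies and
percentages. No inferential statistics are computed anywhere, by design.

## Conventions shared by every stage

* Dates are calendar dates at day resolution. **Every interval is closed on
  both ends**; durations are day counts (`end - start`).
* The study period (default 2014-01-01 to 2019-12-31) bounds all claims; the
  index period (2015-01-01 to 2019-06-30) is nested inside it so that a full
  1-year look-back and at least a 6-month follow-up fit within the data.
* Landmarks are 183 / 365 / 730 days ("6 / 12 / 24 months"). A member enters
  a landmark's denominator only with continuous medical + pharmacy
  enrollment through that day, which is why landmark denominators shrink.
* Months are counted as covered days / 30.4375.

## Fracture ascertainment and the index event

A fracture event at a site on a date qualifies through one of three routes:

1. an **inpatient** claim carrying a fracture diagnosis for the site (dated
   at admission when present, else at service);
2. an **outpatient** claim with a site diagnosis plus a fracture-treatment
   procedure *for the same site* on an outpatient claim within ±7 days
   (configurable `pairing_window_days`); the event is dated at the
   diagnosis. The window exists because outpatient fracture care may bill
   the diagnosis and the treatment on different days; requiring same-day
   billing would silently drop legitimate outpatient fractures.
3. **vertebral only**: an outpatient vertebral diagnosis with an evaluation
   & management (E&M) procedure within the same window — vertebral
   fractures are frequently managed without a site-specific procedure.

The index fracture is the *earliest* qualified event in the index period;
the earliest date always beats the site hierarchy. Only among same-day
events does the hierarchy (hip, femur, pelvis, vertebral, humerus,
radius/ulna, tibia/fibula, ankle, clavicle) decide, lower rank winning.

## Eligibility and attrition

Criteria are applied in a fixed order, each member stopping at her first
failure (so the attrition table decrements are interpretable): female; age
≥ 50 at index (year arithmetic — claims carry birth year only, so this is
the resolution the data support); continuous medical + pharmacy enrollment
over `[index-365, index-1]` and over `[index+1, index+183]`; no trauma
diagnosis on the index date; no qualified fracture event before the index;
no Paget's/other/metabolic bone-disease diagnosis anywhere pre-index within
the study period; and no cancer diagnosis in the 365-day look-back, with
non-melanoma skin cancer explicitly exempt.

Two deliberate interpretations, both configurable: continuous enrollment
tolerates **zero** gap days (`allowed_gap_days = 0`) — the sources this
design follows are silent on gap tolerance, and zero is the strictest,
reproducible reading; and the 6-month post-index requirement starts **the
day after** index, so an enrollment span ending exactly at `index + 183`
qualifies and one ending at `index + 182` does not.

## Baseline profiling

All baseline flags are computed over `[index-365, index-1]`: the index day
belongs to post-index context, never to baseline, so the index fracture's
own claims cannot pollute baseline flags. Corticosteroid use looks back 183
days. The Charlson comorbidity index sums weights over *distinct* Charlson
categories present (a category counts once no matter how many claims carry
it). Comorbidity flags require one mapped claim (`min_claims = 1`; a
two-claim confirmation rule is a config knob, not the default). The
"days since last DXA/surgery" bands are half-open (≤30, >30–60, >60–180,
>180–360); values of 361–365 days are possible within the look-back and are
reported as `out_of_range` rather than silently clipped into the last band.

## Six-month management measures

All post-index windows are closed `[index, index+183]` — "on or within six
months" includes day 0, so surgery on the index date counts. Inpatient
claims are merged into stays when contiguous (`admission ≤ prior
discharge + 1`); the index hospitalization is the merged stay admitted
within `[index, index+7]` carrying an index-site fracture diagnosis,
preferring admission on the index day. Length of stay counts nights
(`discharge - admission`), minimum 1 for same-day stays — the claims
convention, and it avoids zero-LOS artifacts in means. Readmission is any
inpatient admission (any cause) in `[discharge+1, discharge+30]`: a
same-day rebill or transfer is not a readmission, and an admission on
`discharge+1` merges into the stay rather than counting. Rehabilitation is
any claim with a rehabilitation code *or* a home-health claim.
Readmission percentages use the hospitalized members as denominator; all
other percentages use the stratum size.

## Medication persistence

With day 0 = index, a fill on day *f* with *s* days supply covers
`[f, f+s-1]`. Overlapping or abutting coverage merges end-to-end (an
optional `stockpile` mode instead shifts a refill to start after the
previous supply ends). With current run end *e*, the refill gap to a fill
on day *f* is `f - e - 1`; the run survives iff the gap is ≤ 60 days. The
boundary is exact and strict: supply ending day 29, refill day 90 (gap 60)
continues; refill day 91 (gap 61) discontinues, dated at day 29 — the last
covered day is the discontinuation date. Re-initiation is a same-class fill
after the discontinuation day; both are defined at drug-class level for the
first class initiated post-index.

At a landmark *L*, discontinuation is reported only when the full 61-day
gap is observable on or before *L* (`e + 61 ≤ L`). Without this rule a
member whose run simply reaches the landmark would be misclassified as
discontinued by censoring. Months on treatment count gap-excluded covered
days clipped to `[0, L]`, divided by 30.4375. Time to initiation is
summarized among treatment-naïve members only (no OP fill in the 365-day
look-back). A same-day first-fill tie across classes is broken anabolic
before antiresorptive, then canonical class order.

## Subsequent fractures

Scanning qualified events strictly after the index in date order, an event
is a new fracture iff its site has never fractured (relative to the index
and previously *accepted* subsequents) or the gap from the most recent
fracture at that site strictly exceeds 90 days. Accepted events update the
per-site state; rejected events (continuing-care claims) do not. The gap is
measured against the most recent accepted fracture at the site, not only
the index — "a previous fracture" is plural in scope. Subsequent events
must pass the same identification algorithm as the index (outpatient events
need their paired procedure). A known limitation inherited from claims
data: ongoing vertebral care billing can overestimate vertebral subsequent
fractures; no deduplication beyond the 90-day rule is attempted.

## The synthetic claims generator

Real claims databases of this kind are proprietary, so the package ships a
seeded generator with a **label-first** design: per-member truth labels
(eligibility category, index site and setting, hospitalization and LOS,
readmission, six-month care flags, treatment episode shape by landmark,
subsequent fracture day) are sampled first, and claims are then written so
that the corresponding pipeline rule provably detects each label. Planted
negatives violate exactly one clause of their rule. This makes member-level
recovery *exact by construction* and is what the end-to-end tests assert at
100% agreement.

The packaged `scenario_paper()` calibration plants published headline
values for commercially insured postmenopausal women (index-site mix with
vertebral 30.6%, radius/ulna 24.9%, hip 12.1%; 34.8% inpatient
ascertainment; 96.7% hip hospitalization, mean LOS 5.5 days (SD 4.1);
14.3% 30-day readmission; surgery 43.1% overall and 90.0% for hip; 41.4%
hip SNF admission; 13.6% DXA; 76% with neither OP diagnosis nor treatment
at 6 months; 11.2/14.3/17.6% treated and 7.4/9.9/13.2% with a subsequent
fracture by 6/12/24 months). These are **calibration inputs** to the
simulator, not independent reproductions of proprietary-data results; the
acceptance machinery checks that the pipeline *recovers* them within
binomial Monte-Carlo tolerance. Where the sources print only group-level
values, the generator needs per-site choices: the 32.4% of index fractures
not covered by the three printed sites is split across the remaining six
NHNV sites in plausible field proportions (humerus 10.0%, ankle 8.0%,
tibia/fibula 6.0%, pelvis 4.4%, femur 2.4%, clavicle 1.6%); LOS is
`1 + NegBin(mu = 4.5, size = 1.645)`, an integer distribution with mean 5.5
and SD 4.1 exactly; the 12/24-month denominators arise from calendar
truncation at the study end plus an exponential disenrollment tail (rate
8.545e-4/day) fitted to the published denominator ratios.

What the generator deliberately does **not** emulate: realistic code
frequency distributions (each semantic tag uses a handful of synthetic
codes), correlated comorbidity structure, provider/cost fields, claim-level
noise such as miscoded sites, or care processes (claims are written from
labels, not simulated encounter by encounter). Passing tests therefore
demonstrate that the *rules* are implemented exactly and that aggregates
are recovered at scale — not that the pipeline is robust to real-world
coding idiosyncrasies, which only a licensed code registry and real data
can exercise.

## Numerical and engineering choices

* Interval algebra (enrollment coverage, fill coverage) is integer day
  arithmetic on sorted intervals with cumulative-maximum scans; the test
  suite checks it against brute-force day-grid oracles (1,000 random fill
  histories and 1,000 random enrollment windows) for exact agreement.
* Percentages are reported with numerator and denominator alongside; the
  one-decimal rendering rounds half away from zero. Empty strata yield
  `NA`, never `0%`.
* All generator randomness flows from a single seed; identical seeds give
  byte-identical bundles and reports.
* Problem sizes in the packaged evaluation: member-level recovery at
  n = 5,000 and aggregate recovery at n = 50,000 — the latter matches the
  scale at which three binomial standard errors separate the planted
  percentages from their neighbors while the whole suite stays fast on a
  single CPU.

## Worked example

```{r example, eval = FALSE}
library(fracturepathways)

registry <- load_registry()              # synthetic default vocabulary
config <- analysis_config()

gen <- generate_population(scenario_paper(n_members = 5000), registry, config)
res <- run_pipeline(gen$bundle, registry, config)

res$attrition
res$table3[stratum == "hip" & measure == "ortho_surgery_6mo"]
emit_reports(res, "reports")
```

## Known limitations

* The shipped registry is a synthetic placeholder vocabulary; real ICD/CPT/
  NDC lists are licensed content and must be supplied by the user. Every
  rule is registry-driven, so no code changes are needed.
* Recurrent-index (multiple index events per member) designs are out of
  scope; the cohort is strictly first-event.
* SNF length of stay, therapy intensity, costs, and inferential comparisons
  are out of scope.
* Whether a fracture diagnosis must appear in the primary position on the
  index hospitalization is not modeled (any position counts), and the
  vertebral continuing-care overestimation noted above applies.
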