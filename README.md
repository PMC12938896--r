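# ranobm

Longitudinal treatment-response assessment for brain metastases.

Patients with brain metastases are followed with serial MRI while receiving
stereotactic radiosurgery (SRS/FSRT), whole-brain radiotherapy, surgery, and
systemic therapy, often sequentially. The standard way to classify how the
disease is responding is the RANO-BM scheme: up to five measurable lesions
(longest diameter ≥ 10 mm, perpendicular ≥ 5 mm) are designated *target*
lesions and followed through the sum of their longest diameters (SLD), while
all other lesions are assessed qualitatively. At each scan the patient is
assigned one overall category:

| | CR | PR | SD | PD |
|---|---|---|---|---|
| Target lesions | none | ≥ 30 % ↓ in SLD vs baseline | not PR, not PD | ≥ 20 % ↑ in SLD vs nadir **and** ≥ 5 mm ↑ in ≥ 1 lesion |
| Non-target lesions | none | stable or improved | stable or improved | unequivocal progression |
| New lesions | none | none | none | present (confirmed) |
| Corticosteroids | none | stable or decreased | stable or decreased | n/a |
| Clinical status | stable or improved | stable or improved | stable or improved | worse |
| Requirement | all | all | all | any |

`ranobm` implements this classification as a deterministic, auditable engine
for longitudinal patient courses, together with the extensions a
sum-of-diameters rule cannot express:

- **Per-lesion and mixed-response reporting** — each lesion is classified by
  the same thresholds applied to its own diameter, and the report carries the
  fraction of lesions per final category plus a *discrepancy flag* when the
  overall category masks a progressing lesion (or masks control of most
  lesions in an overall-PD course).
- **Pluggable target designation** — policy **A1** (classic fixed baseline
  targets), **A2** (measurable new lesions are added, or replace the smallest
  current target), and **A-Rx** (every *treated* lesion is target from its
  pre-treatment scan, no count limit, no size gate). Under A2/A-Rx the
  baseline and nadir SLD reset whenever target composition changes.
- **Distant brain failure (DBF) metrics** — new-lesion events with count and
  volume (measured, or the sphere proxy πd³/6), DBF latency
  (last-event time ÷ number of events), and brain metastasis velocity
  BMV = new lesions / year and vBMV = new-lesion volume / year.
- **Clinical status** — the RANO-BM KPS deterioration clauses plus a 0–5
  brain-specific-symptoms (BSS) scale, with declines attributable to non-CNS
  causes discounted.
- **Scenario fixtures and a seeded simulator** — twelve programmatic
  hypothetical courses exercising every limitation above, and a stochastic
  course generator (exponential lesion kinetics, Poisson new-lesion
  arrivals, truncated Gaussian measurement noise).

Intended users are methodologists and trialists studying response-assessment
criteria, and anyone needing a reproducible RANO-BM implementation for
retrospective cohorts.

## Worked example

A patient with five treated lesions: four respond (one completely), one
progresses. The SLD-based overall category is PD, but the per-lesion report
shows the treatment controlled 4/5 lesions:

```r
library(ranobm)
course <- build_scenario("fig3_p2")
report <- assess_course(course, assessment_config(policy = "A1"))
print(report)
#> <assessment_report> fig3_p2 under policy A1
#>  assessment_index day target_category nontarget_state ... overall
#>                 0   0              SD            none ...      SD
#>                 1  91              PR            none ...      PR
#>                 2 183              PR            none ...      PR
#>                 3 274              PR            none ...      PR
#>                 4 365              PD            none ...      PD
#> best overall: PR; time to progression: 365 days; discrepancy: TRUE
#> final per-lesion fractions: CR 0.20, PR 0.60, PD 0.20
```

Reading: the course progresses at day 365 (the fifth lesion grew ≥ 20 % over
its nadir with a ≥ 5 mm gain, dragging the SLD with it), yet one lesion ended
in complete response and three in partial response — the `discrepancy: TRUE`
flag and the 0.20/0.60/0.20 fractions surface exactly the mixed response the
single overall label conceals.

DBF rate metrics distinguish courses the binary PD label cannot:

```r
ev <- detect_dbf_events(build_scenario("fig6_p1"), reference_day = 0)
days_to_months(dbf_latency(ev, 0))   # 3.997 months (one new lesion / 4 months)
bmv(dbf_extent(ev), 0, 365)          # 3.002 new lesions per year
```

## Command line

```sh
inst/cli/bmrs assess --course course.json --policy arx --out report_dir
inst/cli/bmrs scenario fig8 --out fig8.json
inst/cli/bmrs simulate --seed 7 --out sim.json
inst/cli/bmrs compare-policies --course fig8.json
```

## Documentation

See the methods vignette (`vignettes/response-assessment.Rmd`) for the model,
its assumptions, the designation policies, numerical conventions, what the
simulator does and does not emulate, and known limitations.
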