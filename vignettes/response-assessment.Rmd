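---
title: "Methods: response classification, lesion designation, and DBF metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: response classification, lesion designation, and DBF metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ranobm)
```

## The model

A patient course is a discrete time series over scan days $t_0 = 0 < t_1 <
\dots < t_{T-1}$ (integer day offsets from the baseline MRI). At each scan,
every known lesion carries a longest diameter $d_{i,t}$ in mm (0 when the
lesion has resolved; absent lesions keep their identity), optionally a
perpendicular diameter and a volume, and a qualitative state. Treatments are
events with a modality and, for focal modalities (SRS, FSRT, surgery), an
explicit set of targeted lesions. Clinical observations carry a Karnofsky
performance score (KPS), a brain-specific-symptoms score (BSS, 0–5), a
corticosteroid state, and a flag marking declines attributable to non-CNS
causes.

The engine classifies each scan with the five-row grid: target lesions via
the sum of longest diameters $S_t = \sum_{i \in \mathrm{targets}(t)}
d_{i,t}$, non-target lesions qualitatively, new lesions (confirmed on a
repeat scan by default), corticosteroids, and clinical status. CR/PR/SD
require *all* of their column conditions; PD requires *any* of its
triggers. PR is $S_t \le (1-0.30)\,S_{\mathrm{base}}$; PD is $S_t \ge
(1+0.20)\,S_{\mathrm{nadir}}$ *and* some target lesion at least 5 mm above
its own nadir. Under the alternative absolute rule
(`pd_rule = "absolute_2p5mm"`), a single-lesion gain of 2.5 mm over nadir
defines PD on its own — a variant proposed to sharpen sensitivity after
repeated radiosurgery. The measurability gate (10 × 5 mm by default) may be
lowered to 5 mm for thin-slice MRI cohorts via `measurable_longest_mm`.

All baselines and nadirs are *epoch-local*: under the designation policies
that can change target-set composition (A2, A-Rx), both $S_{\mathrm{base}}$
and $S_{\mathrm{nadir}}$ — and the per-lesion nadirs feeding the 5 mm
clause — restart at every composition change. Within an epoch the target
set is constant, so these quantities are well defined.

## Designation policies

* **A1** fixes up to `max_targets` measurable lesions on the baseline scan,
  largest first; everything later is non-target. It is the cheapest policy
  but blind to lesions treated later.
* **A2** starts as A1. When measurable new lesions appear they are added
  while fewer than five targets exist; otherwise each (largest first)
  replaces the smallest current target if strictly larger *at the current
  assessment*. Replaced lesions are followed qualitatively thereafter.
* **A-Rx** makes every treated lesion a target from the scan preceding (or
  coinciding with) its treatment start, with no count limit and no size
  gate. Non-focal treatments (WBRT, systemic) target every lesion present at
  their start and every lesion appearing while the treatment is ongoing; a
  non-focal treatment is considered ongoing until the next one starts. The
  treatment-to-scan mapping uses the scan grid because scans are the only
  time axis in the data model.

Deterministic tie-breaks, where the designation text is silent, are part of
this package's contract: baseline selection ties break by lexicographic
lesion id; the A2 replacement victim among equally small targets is the
lexicographically greatest id; a target lesion that disappears stays a
target at 0 mm (disappearance is response, not re-designation — so a
resolved target *can* be replaced by any measurable new lesion, since its
current diameter is 0).

## Per-lesion and mixed response

Each lesion is additionally classified on its own trajectory with the same
thresholds (baseline = first recorded diameter, nadir = running minimum);
for a single-lesion patient this coincides with the target category. The
report carries the fractions of lesions per final category and a
*discrepancy flag*: overall never PD while some lesion ends PD (masked
progression), or overall PD while at least half the lesions end CR/PR
(masked control). The one-half threshold is a reporting convention, not a
clinical claim.

## New lesions, DBF, and rates

A lesion first seen after baseline is a new-lesion candidate; by default it
must persist on the next scan to be confirmed, and the progression/DBF event
is then dated at first appearance. A lesion appearing only at the terminal
scan stays *pending*: it does not trigger PD, and — because the grid's
CR/PR/SD columns all require "no new lesions" — the scan is reported NE
rather than silently classified. The same reading makes a steroid increase
without progression NE: the grid has no column for it, and an explicit NE is
preferable to a silent misclassification.

Simultaneous confirmed appearances merge into one DBF event with a count and
a volume (recorded volume, else the sphere proxy $\pi d^3/6$, taken at first
appearance — extent is measured *at the time of progression*, not at peak).
DBF latency is the mean inter-event interval anchored at the reference day,
equivalently $\mathrm{day}_{\mathrm{last}}/k$ for $k$ events: a course with
one new lesion every 4 months for a year has latency 4 months; a course
with six lesions at 12 months, latency 12 months. BMV and vBMV divide
cumulative count and volume by years of follow-up (365.25 d/yr). The
reference day is an explicit parameter — anchoring at baseline versus at a
particular therapy start is an analysis choice the cohort literature does
not fix, so the package does not guess.

## Clinical status

Deterioration is judged against the course (or window) baseline observation,
not the previous visit, because the KPS clauses are phrased against a
starting score and a fixed reference makes retrospective replay
deterministic. KPS deteriorates when 90–100 falls to ≤ 70, when ≤ 80 falls
by ≥ 20, or when any score falls to ≤ 50. BSS worsens on a rise of
`bss_worsen_delta` points (default 1 — the minimal detectable change on a
6-level ordinal scale; the scale itself defines no delta). When both scores
are present either suffices (OR): BSS is meant to supplement KPS, and OR is
the conservative composition. Any worsening flagged as attributable to a
non-CNS cause is discounted, which is what keeps a transiently bed-bound
patient with a hip fracture from being misread as neurologic progression.

## Windowed assessment

`windowed_assessment()` re-anchors the course at any scan day: lesions
present there become the window's initial lesions, lesions appearing inside
it are new, earlier treatments are dropped, and clinical status re-references
to the window-start observation. Windows are anchored at scans (the
assessment on or just before a therapy start) because scans are the only
time grid; a window must contain at least two scans.

## Synthetic data

The simulator draws baseline lesions from a log-normal diameter distribution
(median 12 mm, σ_log 0.4 — a typical SRS-eligible burden), treats them with
SRS at day 0, shrinks them at −12 %/month for a 6-month response phase, then
lets each regrow exponentially at a per-lesion rate (mean +5 %/month, SD
4 %). New lesions arrive as a Poisson process (default 2/patient-year,
thinned to scan days, so interval counts sum to the exact Poisson total)
with log-normal detection diameters (median 7 mm). Measurements add Gaussian
noise (SD 1 mm) truncated at zero. Scans are 3-monthly, six in total. Random
numbers are consumed in a fixed order (baseline diameters, growth rates,
baseline noise; then per scan: arrival count, new diameters, new growth
rates, noise), so seeds are stable across refactors.

What this emulates: the shapes the worked scenarios need —
shrink-then-regrow kinetics, staggered new-lesion arrivals, noisy diameters.
What it does not: measurement error correlated across readers or scanners,
pseudo-progression and radiation necrosis, lesion coalescence, anatomy,
non-exponential kinetics, informative censoring. A green simulator test
therefore establishes internal consistency of the engine and the stated
arrival/growth laws, not clinical realism.

## Numerical conventions

Months convert at 30.44 d/month and years at 365.25 d/yr, fixed, so
latencies and velocities are reproducible from integer day grids. Threshold
comparisons carry a 1e-9 tolerance so that exact boundary cases (a 30.0 %
drop, a +20.0 % rise, a 5.0 mm gain) classify as the grid intends despite
binary floating point. Report JSON is written with sorted keys and
6-significant-digit floats for byte-stable diffs. Fixture diameters are
frozen constants chosen to satisfy each scenario's stated relations;
`check_scenario()` re-verifies those relations mechanically, and the
relation set — not the constants — is the fixture's contract.

## Design choices on genuinely open points

* A resolved lesion that reappears is regrowth of the same lesion (a gain
  over a 0 mm nadir, hence local progression), not a new-lesion event; its
  identity and `is_new_on_study` are fixed at first appearance.
* Overall PR accepts a target category of CR (residual non-target disease or
  steroids then decide CR vs PR), following the response-criteria lineage;
  without this, a patient whose targets resolved while on stable steroids
  would be unclassifiable.
* PD from target growth needs no repeat-scan confirmation; only new-lesion
  PD does — repetition is tied to new-lesion detection, where slice
  thickness makes single-scan calls unreliable.
* No minimum duration is imposed for SD, and assessment continues after PD
  (the scenarios follow patients through multiple failures), so
  time-to-progression is the *first* PD day.
* Best overall response ignores NE scans: NE carries no ordering
  information.

## Known limitations

Modality attribution across concurrent treatments is out of scope: windowed
assessment isolates periods, but crediting local versus systemic control
within a period is an open methodological question. Pseudo-progression and
radiation necrosis enter only as qualitative input flags. The BSS scale is
novel and unvalidated; inter-rater reliability is explicitly outside this
package. Volumetric inputs are passed through (or proxied by spheres), not
segmented.
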