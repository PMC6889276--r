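---
title: "Methods: response criteria, kinetics and surrogacy in radresponse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: response criteria, kinetics and surrogacy in radresponse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radresponse)
```

# Scope and data model

`radresponse` analyses longitudinal target-lesion measurements from
serial CT in slow-growing solid tumours: per lesion and scan, the
longest diameter (mm) and the mean arterial-phase attenuation (HU,
possibly missing), plus per-patient outcome data (death day or last
follow-up). Time is kept internally as integer days from treatment
start (day 0 = first dose) and converted to months by the 365.25/12 =
30.4375-day convention only for reporting. The baseline scan is the
assessment with the largest non-positive day and must fall within the
four weeks before treatment (window [−28, 0] days); series violating
this, or with no measurable baseline lesion or fewer than two
assessments, are reported by `validate_cohort()` and excluded in strict
mode rather than silently repaired.

# Response classification

Target lesions are chosen at baseline by descending diameter, at most
five overall and two per organ, with deterministic tie-breaks (organ
label, then lesion id). Because the constraint family "≤ 5 total, ≤ 2
per organ" is a truncated partition matroid, the greedy choice
maximises the selected total diameter; the test suite checks this
against subset enumeration. The sum of diameters is arithmetic over
target lesions (a vanished lesion must be recorded as 0 mm, not
dropped); the mean attenuation is the unweighted mean over target
lesions with an HU value, since no weighting scheme is part of the
criteria definitions.

**RECIST v1.1** labels each follow-up: PD if a new lesion or
unequivocal non-target progression is present, or the sum has grown vs
the nadir (smallest sum so far, baseline included) by at least +20% and
at least 5 mm; otherwise CR if the sum is 0, PR if the change vs
baseline is ≤ −30%, else SD. Progression-vs-nadir is checked *before*
PR-vs-baseline: a deep responder who regrows ≥ 20% and ≥ 5 mm from the
nadir is PD even while still 30% below baseline, which is the standard
reading of the criteria; the alternative (PR masks PD) would make the
label non-monotone in the follow-up sum.

**Choi** labels: PD for new lesions/non-target progression; CR for sum
0; PR if mean attenuation dropped ≥ 15% vs baseline *or* the sum
dropped ≥ 10% vs baseline; PD if the sum grew ≥ 10% vs the configured
reference *and* the attenuation-PR condition is not met; else SD. The
attenuation clause is checked before size-PD, so a tumour that grows
but hypo-attenuates ≥ 15% is a responder — the defining nuance of the
criteria. All threshold comparisons are inclusive (−30.0% is PR; +20.0%
with +5.0 mm is PD).

Two points in the published material are not operationally pinned down,
so they are configuration rather than constants
(`criterion_config()`): the reference for the Choi PD size change
(default **baseline**, the first-named convention in published
descriptions of the criteria; `"nadir"` available) and the attenuation handling when HU is
missing at a follow-up (the clause is treated as *not met* and the row
is flagged `hu_unavailable`; a missing baseline HU downgrades the whole
patient to size-only classification with a warning). Both criteria stop
a patient's series at the first PD; later scans are never evaluated.

Landmark labels (`response_at()`, default day 183 ± 60 days) take the
assessment closest to the landmark inside the window, carrying an
earlier PD forward. The ±60-day window is a design choice: scans were
protocol-scheduled only to within 3–6 months, so some explicit window
is unavoidable, and 60 days keeps a 3-month-late scan usable without
letting a 9-month scan masquerade as a 6-month one. The transition
table folds CR into PR (CR is rare in this setting and both are
response), and Cohen's κ is the unweighted
\((p_o - p_e)/(1 - p_e)\).

`reconstruct_transition_table()` rebuilds a full 3×3 table from
published summaries: category marginals as percentages (converted to
counts by nearest-integer rounding), the two off-diagonal cells of the
middle (SD) row, and the structural implication that a ≥ 30% shrinkage
always satisfies the 10% Choi size criterion, which zeroes the
PR-row off-diagonals; the PD row then follows from the column margins.
The function refuses inconsistent inputs rather than adjusting them.

# Kinetics

Tumour growth is summarised on the volume log scale:
\(\mathrm{TG} = 3\,\ln(D_t/D_0)/t\) with \(t\) in months (the factor 3
converts a diameter ratio to a volume ratio under the sphere
approximation; the logarithm is natural, as the inverse transform
\(\mathrm{TGR} = 100(e^{\mathrm{TG}}-1)\) requires), and the variation
rates \(\mathrm{DVR}, \mathrm{AVR} = 100\,(X_t-X_0)/X_0/t\) divide the
relative size/attenuation change by elapsed time. Rates from baseline
use day 0 as the time origin even when the baseline scan preceded
treatment by up to four weeks — the quantity of interest is change per
month *of treatment* — while the baseline measurement values themselves
come from the baseline scan. Per-interval rates (previous scan as
origin) are emitted alongside, flagged by `interval_type`. Undefined
rates (non-positive diameters, missing HU) are `NA`, never
extrapolated. At a common \(t\), TGR is a strictly increasing transform
of DVR, so their Kendall correlation is exactly 1 — a useful algebraic
test anchor.

# Endpoints and surrogacy statistics

PFS runs to the first criterion-specific PD or death (death without
documented progression is an event at death time); event-free patients
are censored at the last adequate imaging assessment, not last contact,
because the endpoint is imaging-defined. OS is standard.
`pair_endpoints()` enforces the semi-competing structure PFS ≤ OS,
clipping a PFS *censoring* that outruns OS to the OS time (inheriting
its event status) and rejecting a PFS *event* after OS as a data error.

**Clayton copula.** Dependence between PFS and OS is summarised by
Kendall's \(\tau = \theta/(\theta+2)\) from a Clayton copula fitted in
two stages: Kaplan–Meier margins transform each observation to the
survival-uniform scale, and \(\theta\) maximises the censored-data
pseudo-likelihood with the four censoring-pattern contributions (both
events → copula density; one censored → partial derivative of the
copula; both censored → the copula itself). Two numerical choices
matter. First, the margins use the *left-continuous* KM value
\(S(t^-)\): the right-continuous version assigns \(u = 0\) to the
largest fully-observed time, and that single boundary point visibly
biases \(\hat\theta\) downward. Second, death-first pairs (PFS = OS,
both events) enter the both-event contribution at equal uniforms
without jittering; being exactly diagonal they pull \(\hat\theta\) up,
which is why the pair *simulator* (below) defaults to margins that make
them rare. The optimiser is a bounded golden-section search on
\(\theta \in [10^{-6}, 50]\); hitting the upper bound (comonotone
degeneracy) sets `converged = FALSE`. The SE of \(\hat\tau\) comes from
B = 200 nonparametric bootstrap resamples of patients under a fixed
seed — the published analyses report an SE for \(\tau\) and a resampling
SE is the assumption-light choice when the margins are themselves
estimated.

**Landmark analysis.** Conditional Kaplan–Meier from a landmark
(default 6 months) among patients event-free and in follow-up at the
landmark, grouped by their response label there (same ±60-day window as
the transition table), reported at the horizon (default 24 months) with
log-log 95% CIs. With landmark 0 this reduces to the unconditional KM
evaluated at the horizon, which the tests exploit.

**Mantel–Byar.** The responder/non-responder comparison uses response
as a time-dependent state: each patient contributes to the unexposed
risk set until their transition time and to the exposed set after it.
At each event time the exposed event count is compared with its
hypergeometric expectation; \( (O-E)^2/V \) is \(\chi^2_1\). Exposure
at time \(t\) means transition strictly before \(t\), matching the
(start, stop] counting-process convention, so with all transitions at 0
the statistic equals the ordinary two-group log-rank (the tests require
agreement with `survival::survdiff` to 1e−8).

**Time-dependent Cox.** The single binary switch covariate admits a
closed bookkeeping: per event time only the exposed/unexposed risk-set
sizes and the dying subject's state matter. The scalar Newton iteration
on the Breslow partial likelihood runs to gradient tolerance 1e−8
(at most 50 iterations), with a Wald 95% CI on the log-HR. A covariate
with no contrast over the risk sets, or a monotone likelihood, raises
an error rather than returning a boundary estimate.
`survival::coxph` on the counting-process representation serves as the
independent oracle in the tests (agreement to 4 decimals), never as the
implementation.

**Paired Wilcoxon** delegates to `stats::wilcox.test`, forced exact for
≤ 25 non-zero differences and normal-with-continuity-correction above,
with the all-zero-difference case returned as degenerate (p = 1). No
multiplicity adjustment is applied anywhere in the battery: each
comparison answers its own question and the battery is descriptive,
not confirmatory.

# The synthetic cohort generator

`simulation_config()` encodes the study conditions the analyses assume:
85 patients; 1–6 lesions each, liver-dominant organ mix; log-normal
baseline diameters (median 25 mm); normal baseline attenuation
(110 ± 20 HU, arterial-phase hypervascular); scans every ~105 ± 15 days
with a pre-treatment baseline in [−21, −3] days; log-linear lesion
growth with slow rates (median TGR a few percent per month);
an attenuation-responder phenotype (45%) whose mean HU drops by
28 ± 8% at the first on-treatment scan while diameters change little; a
deep-response subset (28% of responders) whose shrinkage reaches the
RECIST PR range; 10% growing-but-hypoattenuating patients who are Choi
responders on a RECIST progression track; latent progression
(log-normal, median 9 months, doubled for responders) that accelerates
growth, spawns a new lesion with probability 0.5, and is followed by
death after an exponential lag (mean 14 months, floored at 4.5 months
so every patient has at least one on-treatment scan); administrative
censoring uniform over 24–42 months; and measurement noise of 1.5 mm /
5 HU. The responder and deep-response fractions were set so the
6-month Choi and RECIST PR fractions land near 0.45 and 0.13 — a
qualitative emulation of the reported response mix, not a fit — and the
remaining values are what a practitioner would call realistic for this
disease; they are fixed defaults, not tuning knobs.

All randomness flows from one master seed through per-patient
sub-streams, so output is reproducible and insensitive to patient
order. What the generator does *not* emulate: reader variability and
multi-reader consensus, interval-censored progression times (scans are
jittered but progression is classified only at scans, as in reality),
organ-specific growth, non-proportional post-progression hazards, and
loss to follow-up beyond administrative censoring. Tests passing on
these cohorts therefore validate the *machinery* — rule logic,
estimator consistency, pipeline plumbing — not the clinical
conclusions of any particular study.

`simulate_clayton_pairs()` is a separate, smaller harness for the
copula fitter: a Clayton(\(\theta\)) pair by conditional inversion
mapped through exponential margins, with PFS = min(latent progression,
death) so PFS ≤ OS holds by construction, and exponential censoring
calibrated to a target OS-margin censoring fraction. Its default
margins are progression-dominant (means 3 and 90 months): the min()
construction makes death-first pairs perfectly concordant ties, which
inflate dependence above \(\theta/(\theta+2)\), and the wide separation
keeps that contamination near 1% so parameter-recovery checks remain
meaningful. These margins are a property of the test harness, not a
clinical claim.

# Problem sizes and numerical tolerances in the test suite

The suite works at deliberately modest sizes: copula recovery at
n ∈ {100, 500, 2000} (B = 200 bootstrap only in the end-to-end check),
Mantel–Byar size calibration over 1000 null replicates of n = 80,
Cox-HR recovery at n = 1000, the rule grid over every sign/magnitude
combination around the −30/−15/−10/+10/+20% and 5-mm boundaries, and
the RECIST-PR ⇒ Choi-PR implication over 10⁴ random series. Exact
identities (TGR∘TG, κ, product-limit values, log-rank equivalence) are
asserted to 1e−8 or tighter; stochastic recoveries use tolerances set
from the estimator's sampling variability at the stated n, chosen
before the tests were first run and not revisited.

# Known limitations

Lymph-node short-axis rules are omitted (the data model carries longest
diameters only); non-target disease is a single assessment-level
boolean; mRECIST/PERCIST/volumetric criteria are out of scope; the
copula family is Clayton only (no Gumbel/Frank comparison); the
landmark estimator is unadjusted for covariates; and the time-dependent
Cox model handles exactly one binary covariate. The published
patient-level results of the motivating study (median PFS, cohort τ
values, landmark OS rates) are not reproducible from first principles
because the underlying data are not deposited; the package instead
reproduces the in-paper arithmetic that *is* recomputable and validates
everything else by construction on synthetic data.
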