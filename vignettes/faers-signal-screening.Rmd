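---
title: "Disproportionality screening of spontaneous reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality screening of spontaneous reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The screening problem

Spontaneous reporting databases collect suspected drug–event associations
without exposure denominators, so incidence cannot be estimated; what can be
estimated is whether a pair is reported *disproportionately* often relative
to the rest of the database. `faersignal` implements the standard
pharmacovigilance screen for one target drug: each deduplicated report either
does or does not carry the target drug as primary suspect (PS), and does or
does not mention a given event, giving the 2×2 table `(a, b, c, d)` with
`n = a + b + c + d`. The counting unit is the report: a report mentioning an
event on three REAC rows, or several PTs of the same SOC, contributes one
count. Cell `b` counts target-drug reports with other events and `c`
non-target reports with the event — the layout under which the PRR below is
the usual proportional reporting ratio.

Assumptions worth keeping in mind: reports are treated as independent;
reporting propensity is taken as homogeneous across drugs for a given event
(violations — stimulated reporting, channeling — bias any disproportionality
method); and a signal is a statistical flag, not a causal claim.

## The four algorithms

All four are deterministic functions of the table.

* **Reporting odds ratio.** `ROR = ad/(bc)` with the Wald interval
  `exp(ln ROR ± 1.96·√(1/a + 1/b + 1/c + 1/d))`. Undefined when any cell is
  zero; no Haldane/continuity correction is applied (a correction changes
  every borderline decision; an undefined estimate simply fails its
  criterion, which is conservative).
* **Proportional reporting ratio.** `PRR = (a/(a+b)) / (c/(c+d))`, paired
  with the uncorrected Pearson statistic
  `χ² = n(ad − bc)² / ((a+b)(c+d)(a+c)(b+d))` (no Yates term).
* **BCPNN information component.** The point value is
  `IC = log₂(a·n / ((a+b)(a+c)))`, the log₂ observed-to-expected ratio of
  the joint reporting probability. Shrinkage uses the classical closed-form
  moments of the posterior under Beta priors: with prior constants
  `α₁ = β₁ = 1`, `α = β = 2`, `γ₁₁ = 1` and the joint prior strength `γ`
  recomputed from each table so the prior IC is centred at zero,

  `E(IC) = log₂[(a+γ₁₁)(n+α)(n+β) / ((n+γ)(a+b+α₁)(a+c+β₁))]`

  and the matching variance form `V(IC)`; the decision bound is
  `IC025 = E(IC) − 2·√V(IC)`, a normal-approximation lower bound rather than
  a sampled posterior quantile. The prior constants are exposed via
  `bcpnn_priors()` because published analyses vary them. With `a = 0` the
  shrunken moments remain defined while the point IC does not.
* **EBGM (closed form).** `EBGM = a·n/((a+b)(a+c))` — the relative reporting
  ratio, with bounds `exp(ln EBGM ± 1.96·√(1/a+1/b+1/c+1/d))`, the lower one
  being EBGM05. This is deliberately *not* the DuMouchel multi-item gamma
  Poisson shrinker: there is no EM-fitted gamma-mixture prior here, and at
  small `a` this closed form does not shrink toward 1. It is the form used
  by a large family of published FAERS screens, and it obeys the exact
  identity `IC = log₂(EBGM)`, which the test suite asserts for every table.

A pair is a **consensus signal** when all four flags hold simultaneously —
ROR CI lower bound > 1; PRR ≥ 2 and χ² ≥ 4; IC025 > 0; EBGM05 > 2 — plus the
minimum-evidence rule `a ≥ 3`. Requiring the conjunction trades sensitivity
for a markedly lower false-positive rate, which is the point of a screen.
Thresholds are arguments (`evaluate_criteria()`, `screen_signals()`), with
these defaults.

At SOC level the same machinery runs on SOC-mapped events. Note that SOC
aggregation dilutes PT-level signals: a strongly disproportionate PT sitting
in a SOC with many unremarkable PTs may leave the SOC below threshold, which
is visible in the worked example (`analysis/04_signals.R`).

## Preprocessing rules

* **Deduplication.** Cases accumulate report versions; within each CASEID the
  surviving version is the one with the latest FDA_DT, ties broken by the
  numerically highest PRIMARYID. Rows with a blank CASEID survive as
  singletons and are counted. The operation is idempotent and is checked
  against a brute-force group-by oracle.
* **Cohort rule.** A report is target-exposed iff some drug row matches a
  name pattern (case-insensitive substring over DRUGNAME and PROD_AI — free
  text in practice, hence substring rather than exact match, which also
  catches suffixed biologic names) *and* that row's role is PS. Matches in
  SS/C/I roles never qualify.
* **Dates.** FAERS dates may be 8-, 6- or 4-digit. Partial dates are kept
  with their precision rather than padded: padding a month-precision date to
  its first day would silently convert an unusable onset interval into a
  plausible-looking one. The therapy start is the earliest full-precision
  START_DT among matching PS drug rows (the natural reading of "treatment
  initiation" when several therapy episodes exist).
* **Seriousness.** A report is serious iff it carries any outcome code
  (DE/LT/HO/DS/CA/RI/OT); codes are tallied individually and a report may
  carry several, so outcome tallies legitimately exceed the serious-report
  count. Unknown codes count as serious under an `unknown` label rather than
  being dropped.
* **Ages** are harmonized to years from AGE/AGE_COD (YR, MON/12, WK/52.14,
  DY/365.25); any other unit yields missing. Descriptive percentages use the
  total report count as denominator (the convention under which
  single-assignment sections sum to 100%) and round half-up at two decimals,
  matching how such tables are conventionally printed.

## Time to onset

Onset is `EVENT_DT − START_DT` in calendar days; day 0 is valid. Every
target report resolves to exactly one of: an onset value, or one of four
exclusion reasons (`missing_start`, `missing_event`, `partial_date`,
`negative_interval` — the last covering events dated before therapy start,
i.e. incorrect or irrelevant dating). The partition is asserted in the
tests; nothing is dropped silently. Quartiles use linear interpolation
between order statistics (`stats::quantile` type 7) — published per-event
onset tables show fractional quartiles, which rules out nearest-rank; the
method is an argument for sensitivity analysis. Day bins are 0–30, 31–90,
91–180, 181–360, >360, ends inclusive. The overall summary counts one
observation per report; the per-PT table counts one per (report, PT) pair.

## The synthetic generator

`synthetic_config()` / `simulate_raw()` emulate the relational structure the
pipeline consumes: DEMO/DRUG/REAC/THER/OUTC/INDI keyed by PRIMARYID, CASEID
shared across versions, a deleted-case list, PS/C drug roles (including a
small fraction of non-target reports carrying the target drug in a
concomitant role, to exercise the role filter), and dates with configurable
missing/partial fractions. Background PT frequencies are one symmetric
Dirichlet(0.5) draw — deliberately non-uniform, so rare events and zero
cells occur. Planted signals multiply chosen PTs' rates by a relative rate
`R` in target reports only; planted PTs are pinned at the mean background
frequency so that `R`, not a freak tail of the Dirichlet draw, determines
detectability. Each report draws `1 + Poisson(λ)` events.

Reference conditions (the package defaults): 50,000 reports, 2% target
prevalence, 200 PTs, three planted PTs at `R = 10`, `λ = 1.5`, 5% duplicate
versions (10% of them FDA_DT ties, to exercise the tie-break), 1% deleted,
~35% missing start and event dates plus 5% partial each (leaving ~40% of
reports onset-evaluable, a realistic fraction for this kind of database),
onset delay log-normal with median 14 days and σ = 1.1. All randomness flows
from the single configuration seed; `expected_table()` re-derives the same
Dirichlet draw, so closed-form expectations refer to the realized
frequencies and observed cells sit within Poisson error of them.

What passing tests on these data do and do not show: they validate the
*mechanics* — counting, deduplication, formula evaluation, exclusion
accounting, threshold logic — under a model where reports are independent
and drug assignment is random. Real spontaneous data violate independence
(duplicate submissions beyond versioning, stimulated reporting waves),
carry free-text drug-name noise, and have correlated co-prescription; none
of that is modelled, so recovery rates here are an upper bound on real-data
behaviour.

### What EBGM recovers, exactly

The closed-form EBGM estimates the ratio of *per-report event probabilities*
between target and background reports, not the planted per-draw rate `R`
itself. Three mechanisms attenuate it: multinomial renormalization (planting
mass on some PTs removes it from others, so the effective rate is `R/Z` with
`Z` the normalizer), report-level saturation (a PT drawn twice in one report
counts once: the event probability is `1 − (1−p)e^{−λp}`, concave in `p`),
and the target reports' own contribution to the `a+c` margin. At the
reference conditions (`R = 10` on three PTs of mean mass) these compound to
a predictable ≈20–25% downward bias — visible in the acceptance output,
where the mean planted EBGM is ≈8 against `R = 10`. The parameter-recovery
property test therefore runs where the theory says the bias is small
(`R = 5`, one planted PT among 100 near-uniform PTs, `λ = 0.5`): there EBGM
recovers `R` within ±15%. This is arithmetic of the estimand, not an
estimator defect; `expected_table()` gives the exact attenuated target for
any configuration.

## Problem sizes and runtime choices

The validation suite uses 1,000 random tables for the formula oracles, 2,000
multinomial replicates for ROR interval coverage (enough for ±2% Monte-Carlo
resolution at 95%), 20 seeded runs at the full reference conditions for
signal recovery, and 3–10 seeds for the cheaper distributional checks —
sizes chosen so each property is decisively powered while the whole suite
stays comfortably runnable on a laptop.

## Known limitations

* The EBGM is the closed form discussed above, not the EM-fitted gamma
  Poisson shrinker; at very small `a` it is anti-conservative relative to
  true MGPS (mitigated by the `a ≥ 3` rule and the four-way conjunction).
* No stratification or adjustment (age, sex, year) and no multiple-testing
  correction beyond the consensus rule — both deliberate, matching standard
  screening practice for a single-drug safety profile.
* IC025 is a moment-based lower bound, not a posterior quantile; at tiny
  counts the two can differ noticeably.
* Record linkage beyond the CASEID/FDA_DT/PRIMARYID rule (probabilistic
  duplicate detection across cases) is out of scope.
* The MedDRA PT→SOC mapping is user-supplied (the dictionary is licensed);
  unmapped PTs surface under an `UNMAPPED` pseudo-SOC rather than being
  dropped, and each PT maps to exactly one (primary) SOC.
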