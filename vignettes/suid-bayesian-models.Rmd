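---
title: "Bayesian decision models for SUID categorization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian decision models for SUID categorization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suidbn)
```

## The problem

Sudden unexpected infant death (SUID) is certified under three ICD-10 code
groups — SIDS (R95), accidental asphyxia (W75/W78/W79) and unknown causes
(R96/R98/R99) — and the boundary between them is drawn inconsistently: the
inter-region coefficient of variation of the SIDS-specific mortality rate
is several times that of the total SUID rate, evidence that regions agree
on *how many* infants die suddenly but not on *what to call it*. `suidbn`
implements two Bayesian decision aids built from a small, richly
documented forensic autopsy cohort — a diagnostic classifier and an
onset-risk predictor — together with the surveillance statistics that
motivate them, and synthetic-data generators that make the whole pipeline
testable without access to the original case records.

## Diagnostic support models

### Model

A discrete Bayesian network over the 16 coded risk factors plus a
`cause_of_death` node. The joint factorizes as
$P(x_1,\dots,x_n) = \prod_i P(x_i \mid \mathrm{pa}(x_i))$, each conditional
stored as a CPT. Training estimates every CPT row from a labeled cohort by

$$\hat P(s \mid \text{parents}=r) = \frac{n_{rs} + \alpha}{n_{r\cdot} + \alpha k},$$

with $k$ states and pseudo-count $\alpha \ge 0$. A diagnosis is the exact
posterior $P(\text{cause} \mid \text{observed factors})$, computed by
variable elimination; a brute-force enumeration twin serves as its oracle
in the test suite.

Three structures are shipped as editable JSON. Model 1 is *causal*: age
band, death during sleep and co-sleeping are the proximal parents of the
outcome, with distal factors (breastfeeding, maternal age, gestational
age, passive smoking) acting through intermediates. Models 2 and 3 are
*retrospective*: the outcome is the single root and each factor a child,
with the structural edges `death_during_sleep → co_sleeping` and
`death_during_sleep → sleep_position` retained. Models 1–2 use the
two-state outcome SIDS/non-SIDS; Model 3 separates SIDS, other internal,
and external causes. The topologies are the package's own transcription —
the source figures are not machine-readable — and nothing downstream
depends on one topology: any valid DAG whose nodes map onto cohort
variables trains and scores identically through the same code path.

### Parameters that matter

* `alpha` (default 0, dimensionless pseudo-count). With 64 training cases
  several CPT rows are deterministic — every SIDS case is a sleep-related
  death — so $\alpha = 0$ reproduces count-based tables exactly but makes
  some posteriors hard 0/1 (a non-sleep death can never be diagnosed
  SIDS). Any $\alpha > 0$ keeps all posteriors strictly inside $(0,1)$;
  the default reproduces first and regularizes only on request.
* `unknown_policy` (default `as_state` for diagnosis). The training tables
  report "unknown" as a category of its own for sleeping position,
  breastfeeding, passive smoking and vaccination, so the diagnostic models
  treat it as an informative state. The alternative `exclude` drops
  unknown records from the affected CPT and enters unknown evidence as
  neutral (marginalized) — the convention the onset model uses, because
  its published case proportions are computed over known values only
  (passive smoking 21/30, not 21/41).
* Structural not-applicability is its own state `na`: co-sleeping and
  sleeping position are only defined for sleep-related deaths, and the
  `na` state carries exactly the information "did not die during sleep".

Ties in the posterior argmax are broken by declared state order and
flagged; evidence with zero probability raises an error rather than
returning NaN.

### What validation can and cannot show

The published per-case validation posteriors (e.g. 0.71–0.87 for
concordant SIDS cases) were computed from the original 64-case joint
distribution, which is not public: no reimplementation can reproduce them
from marginal tables, and this package does not claim to. What the tests
assert is structural: all eight packaged validation cases are scored by
all three models, two-state posteriors sum to one, and concordance
counting is permutation-invariant. The qualitative concordance on
replicate-trained models (typically 4–6 of the 6 SIDS cases, varying with
the replicate seed) is *reported* by `scripts/acceptance.R` but not
asserted.

## The onset-predictive model

### Model

Annual SIDS incidence in the general population, $\lambda_0 = 0.3$ per
1000 live births, is derived as the total SUID rate (0.49) times the SIDS
fraction (0.64), rounded to one decimal. The age-band prior reweights
$\lambda_0$ by the case age distribution against the uniform-by-month
population convention ($3/12, 4/12, 5/12$ for 0–2, 3–6, 7–11 months):

$$\lambda(a) = \lambda_0 \frac{P(a \mid \text{case})}{P(a \mid \text{pop})},
\qquad \sum_a P(a \mid \text{pop})\,\lambda(a) = \lambda_0 .$$

Each assigned factor level multiplies by its likelihood ratio
$\mathrm{LR} = P(\text{level} \mid \text{case}) / P(\text{level} \mid
\text{pop})$; unassigned factors are neutral (ratio 1), so prediction is
exactly multiplicative. This rate-space update is the first-order
approximation of the posterior-odds form
$\mathrm{odds} = \frac{p}{1-p}\prod \mathrm{LR}$ with
$p = \lambda(a)/1000$; both are implemented
(`predict_incidence(method =)`), they agree within 1% relative for rates
below 5/1000, and the LR form is the default because it reproduces the
published grid. The approximation treats the published population
proportions as non-case proportions, which is accurate to $O(p)$ for an
event this rare.

Co-sleeping and breastfeeding are age-stratified; sex, gestational age,
birth weight and passive smoking use a single stratum — exactly the strata
in which the control sources publish. Display rounding is 1 decimal at or
above 0.25 and 2 decimals below, and the D/A and D/general ratio columns
are computed *from the rounded cells*; this is the only rule under which
the printed ratio 120.0 (= 2.4/0.02) is recoverable.

### Known numerical deviations

Recomputing the grid from the packaged tables reproduces 10 of the 12
incidence cells exactly and all 12 within one unit in the last printed
digit. The deviations, documented rather than tuned away:

* 3–6 months, group A: computed 0.15 vs printed 0.14;
* 7–11 months, group C: computed 0.08 vs printed 0.09;
* the 3–6-month D/A ratio prints 11.0, not derivable from either rounded
  (1.5/0.15 = 10.0) or unrounded (10.1) cells; the 7–11-month D/A prints
  10.0 where the rounded cells give 0.21/0.02 = 10.5.

These are consistent with the original values having been produced inside
a proprietary inference engine whose exact rounding and posterior
arithmetic are not described. Two source ambiguities are resolved as
follows: the 0–2-month co-sleeping case column prints counts 12/1 with
percents 91.7/8.3 (which imply 11/12); the counts are taken as
authoritative. The subgroup summary values "10.0 and 124.5" for
non-breastfed low-birth-weight males are referenced too ambiguously to
operationalize and are not reproduced; the subgroup grid itself is
available via `incidence_grid(model, c(sex = "male", birth_weight =
"<2500", breastfeeding = "no"))` and is checked only for the qualitative
property that every young-band cell rises.

## Surveillance statistics

Regional rates are deaths per 1000 live births; the variability table
reports the arithmetic mean, the sample SD ($n-1$ denominator — the
source does not state which form it used; at the printed precision both
forms round identically for all four rows) and the CV in percent. One
printed CV (unknown causes, 0.10/0.31 = 32.26 vs printed 32.2) is not
exactly recoverable from the printed mean/SD, indicating it was computed
upstream from unrounded rates; the tests therefore assert exact agreement
for the other three rows and one-unit agreement there. The Fisher exact
test (2×2) and Freeman–Halton exact test (R×C) are exposed through the
package surface and delegate to R's `fisher.test` (point-probability
two-sided rule); the test suite validates both against an independent
brute-force enumeration of all tables with fixed margins, and large
tables use a seeded Monte-Carlo fallback.

## Synthetic data: what it emulates, and what it does not

`generate_replicate_cohort()` produces cohorts whose per-factor,
per-group level counts equal the published cohort tables *exactly, for
every seed*: within each diagnosis group each factor column is an
independent seeded permutation, subject only to the published structural
nesting (co-sleeping/position exist only for the 54 sleep-related deaths)
and the 11/12 internal/external split. Because only marginals were
published, the generator deliberately asserts **no** other joint
dependence — so tests that pass on replicate cohorts certify the
pipeline's bookkeeping and arithmetic, not the clinical performance of
models trained on real, correlated data. Parameter-recovery testing uses
the complementary generator `sample_cohort_from_bn()` (ancestral
sampling), for which ground-truth CPTs exist: estimation at
$n = 10{,}000$ recovers every CPT entry of parent rows with at least 10%
visit mass within ±0.02 (rarer rows carry too few effective samples for
that tolerance by binomial concentration).

`generate_regions()` draws per-region latent rates from a gamma
distribution with the stated mean and CV and observed counts as Poisson —
a standard overdispersed surveillance model chosen because no generative
detail is published; dispersion 0 collapses to constant rates (CV ≈ 0 up
to Poisson noise).

All generators are pure functions of (spec, seed), draw from one seeded
generator per call, and restore the caller's RNG state.

## Numerical and engineering choices

* Exact inference only; enumeration guards its state space (≤ 2×10⁶
  assignments) and variable elimination uses a greedy smallest-factor
  elimination order — ample for 17-node diagnostic networks.
* Zero-count CPT rows become uniform (they are unreachable under the
  training distribution but must remain valid distributions).
* CPT rows must sum to 1 within 1e-9; posteriors renormalize once at the
  end; the VE-vs-enumeration property is enforced at 1e-9 over 200 random
  networks (≤ 8 nodes, ≤ 3 states).
* Problem sizes in the test suite — 200 random networks, 10,000-record
  recovery samples, exhaustive small-margin contingency sweeps plus seeded
  random tables to total ≤ 40 — were chosen so the full suite completes in
  well under a minute while still exercising every property at scales
  where failures would be visible.
* Cohort CSVs distinguish informational missingness (literal `unknown`)
  from structural not-applicability (literal `NA`), because the source
  tables mix both.

## Limitations

Sixty-four training cases spread over networks of this size leave many
CPT rows estimated from a handful of observations; the models are a proof
of concept, not a calibrated clinical tool. The onset model's controls
come from heterogeneous published sources (different years, designs and
denominators) and are treated as the non-case population; no confidence
intervals are produced because the sources publish none. Nothing in this
package should be used to certify individual deaths.
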