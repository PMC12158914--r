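---
title: "Counterfactual survival queries for HCC treatment decisions"
author: "hccbn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual survival queries for HCC treatment decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hccbn)
```

## The problem

Hepatocellular carcinoma (HCC) has many treatment options — resection,
transplant, ablation, TACE, SIRT, systemic medical therapy, supportive
care — and the Barcelona Clinic Liver Cancer (BCLC) flowchart routes broad
patient groups to recommended options using performance status (PS), BCLC
stage and solitary tumour size.  Real multidisciplinary meetings (MDMs)
frequently and reasonably depart from the flowchart.  Two questions then
arise for any individual case: *was this decision guideline-compliant*,
and *what survival would this patient most likely have had under the
alternative*?  `hccbn` answers the first with a declarative rule engine and
the second with case-level counterfactual inference on a small discrete
Bayesian network.

## The model

Four observed variables form the network: guideline compliance
$C \in \{\mathrm{No}, \mathrm{Yes}\}$, treatment group $Y$ (7 options),
waiting time $T$ from MDM to first treatment (integer months, 0–24), and
survival from MDM $S$ (integer months, capped at 40, the cohort censoring
horizon).  The expert-specified structure is

$$P(C, Y, T, S) = P(C)\, P(Y \mid C)\, P(T)\, P(S \mid Y, T),$$

i.e. the decision whether to comply determines the treatment, and both the
treatment and the waiting time affect survival.  Two exogenous
personalisation variables are attached for counterfactual work: $U_t \to T$
and $U_s \to S$, each with 12 states and a uniform prior — they absorb the
individual deviation of a case from the population-level conditionals.

### Parameter learning and the smoothing prior

CPTs are learned by Dirichlet-smoothed maximum likelihood: for child state
$k$ under parent configuration $j$,

$$\hat p_{jk} = \frac{n_{jk} + w}{n_j + wK},$$

with pseudo-count $w$ per cell (default $w = 0.001$).  The default keeps
observed data at 99.9% weight while removing structural zeros: a zero cell
usually reflects the difficulty of observing a combination (e.g. supportive
care for a fit young patient with a small tumour), not its impossibility,
and a hard zero would make the corresponding counterfactual query
ill-defined.  `smoothing_sensitivity()` re-learns the network over a sweep
of weights and reports the Shannon entropy of a reference survival
posterior per weight; because each smoothed row is a convex combination of
the empirical row and the uniform distribution with mixing weight
increasing in $w$, that entropy is non-decreasing in $w$, and at the small
end of the sweep predictions become insensitive to the exact value — which
is what motivates the default.

### Exact inference

Posteriors are computed exactly by variable elimination with a greedy
min-fill ordering; ordering affects cost only, never the answer.  Factors
are kept in linear space with renormalisation at the end of each query —
the network is small enough (largest clique ≈ $41 \times 25 \times 12$)
that log-space bookkeeping would add complexity without benefit.  Every
returned distribution is checked against enumeration oracles in the test
suite at $10^{-10}$.

## The compliance rule engine

The BCLC flowchart ships as an ordered, first-match YAML rule table
(`inst/extdata/bclc2022_rules.yaml`): PS 3–4 or stage D route to
supportive care; stage C or PS 1–2 to medical therapy; then stage and the
2 cm size threshold separate very-early routing (ablation/resection) from
early (resection/transplant/ablation) and intermediate (TACE/transplant)
options.  Design choices that the flowchart itself leaves open, made once
and fixed here:

* **Three-level routing** (PS, then stage, then size) is the default,
  matching the 2022 reading of the flowchart; a single-level 2018-style
  table can be supplied as a custom rule file.
* **Unknown PS** routes by stage alone.  PS is missing rarely (~1.6%), and
  dropping such cases would bias the audit.
* **First-match semantics** make routing deterministic; the validator
  rejects non-exhaustive tables before any classification runs, probing
  every PS × stage combination on both sides of every size bound.
* Each non-compliant case is attributed to the decision point of its
  routing leaf (e.g. `PS=0→BCLC=0`, `BCLC=C→medical therapy`), so the
  per-point counts always partition the non-compliant total.

The exact recommended set per leaf is the main lever on compliance counts;
it is deliberately configuration, not code, so an audit is always
reproducible *under a stated rule file*.

## Cohort cleaning and waiting-time imputation

Missing tumour sizes are filled with the population mean (unrounded, in
millimetres; a config switch accepts centimetre input).  Missing PS
becomes an explicit `"unknown"` level rather than being dropped.  Durations
are rounded half-up to whole months and survival is capped at 40.

Waiting time is missing for a large fraction of records — typically cases
given supportive care, where there is no active treatment to wait for.
Dropping them would under-represent exactly the group counterfactual
reasoning can serve, so the package imputes: a two-pass protocol first
learns CPTs from the rows available to each table (rows missing the
waiting time still inform every other table), then fills each missing
waiting time with the **exact posterior mode** given the row's treatment,
survival and compliance, then re-learns on the completed table.  The mode
(ties to the smaller month) rather than the mean is the default because it
keeps imputed values in the observed state space; the rounded posterior
mean is available via `statistic = "mean"`, and every filled cell is
logged per row so the two can be compared.  Missingness is assumed missing
at random given the observed fields.

## The counterfactual algorithm

`counterfactual()` implements the three-step abduction–action–prediction
scheme for one case with factual profile
$(C^{\mathrm{f}}, Y^{\mathrm{f}}, T^{\mathrm{f}}, S^{\mathrm{f}})$:

1. **Abduction** — compute the exact joint posterior of $(U_s, U_t)$ given
   all four factual values, and replace each noise prior with its
   posterior marginal.  Replacing the *marginals* per node is the default;
   a `joint = TRUE` option preserves the joint instead (by making $U_t$ a
   child of $U_s$), which matters only when the factual evidence leaves
   the two noises dependent — with all four observed variables given, the
   noise posterior factorises, so the two options coincide on the clinical
   network and differ only on structures where both noises feed one
   observed collider.
2. **Action** — graph surgery (`do_intervention()`): each intervened
   variable loses its incoming edges and its CPT becomes a point mass.
3. **Prediction** — the posterior of survival, retaining factual evidence
   on variables that are neither intervened, nor the outcome, nor
   downstream of an intervened variable in the mutilated graph.  The
   factual outcome itself is always dropped: it enters only through
   abduction.  The point prediction is the maximum-a-posteriori month,
   with ties broken toward the smaller month (the conservative survival
   claim).

The evidence-retention rule deserves a note: when intervening only on the
treatment, the factual waiting time is kept as evidence (it is not
downstream of the treatment in this structure), which is what makes
"same patient, different treatment" queries hold the waiting time fixed.

### The noise mechanism: `copy` vs `quantile`

How the learned conditional $P(S \mid Y, T)$ should be split across the 12
$U_s$ states is underdetermined by observational data that never records
$U_s$.  Two constructions bracket the plausible readings:

* **copy** (default): the learned conditional is replicated for every
  noise state.  The noise is then a priori uninformative, abduction leaves
  it uniform, and predictions reduce to the learned conditional at the
  intervened/factual parent values.  Identical interventions therefore
  yield identical predicted months across cases — the behaviour to expect
  when the network's personalisation is carried entirely by the retained
  factual evidence.
* **quantile**: given its parents, the child is the
  $(u - 0.5)/12$-quantile of the learned conditional, making $U$ a
  rank-preserving individual effect: a patient whose factual survival sat
  in the upper tail of their treatment's distribution is predicted in the
  upper tail under the alternative too.  A purely deterministic mechanism
  with 12 levels can explain at most 12 child states, so the construction
  keeps a small residual mass ($\varepsilon = 0.02$, a tunable parameter)
  on the learned conditional; this guarantees every factual value has
  positive likelihood and abduction is always well defined.  Marginalising
  a uniform noise then recovers the learned conditional up to 12-bin
  discretisation (Kolmogorov distance below $1/12$).

Every report records which mechanism produced it.

## The synthetic cohort generator

`cohort_spec()` defines a full generative model used by the tests and the
acceptance script: demographic marginals mimicking the clinical cohort's
descriptive table (77% male, 71% cirrhosis, mean age 71, the observed
aetiology and presentation mix), a stage/PS/size model, an MDM that
follows the shipped rule table with probability 0.16, truncated-Poisson
waiting conditionals and negative-binomial survival conditionals (capped
at 40) — both realised through 12-level latent ranks via the inverse-CDF
construction, so quantile-mode abduction is *exactly* correct on synthetic
data and copy mode is a measurable approximation.  Potential survival
outcomes under all seven treatments are recorded per case, with the
factual arm equal to the observed survival by construction.  Missingness
defaults are 4% (size), 1.6% (PS) and 62% (waiting time), masked
completely at random.

A `deterministic = TRUE` variant makes the waiting and survival
conditionals point masses (waiting fixed at 3 months for every treatment,
so every treatment–waiting combination that occurs is observed); on it the
full pipeline must reproduce the hidden potential outcomes exactly, which
is the strongest end-to-end correctness check in the suite.

What the generator does **not** emulate: the real cohort's joint
distribution (correlations between demographics and outcome beyond the
modelled paths), informative censoring, site effects, or
missingness-not-at-random.  Passing recovery tests therefore demonstrates
the pipeline's internal correctness under the stated assumptions, not
clinical validity on real data.

### Problem sizes used by the checks

The test suite and `scripts/acceptance.R` use: 100 random networks (≤5
nodes, ≤4 states) against enumeration oracles; 50 random networks for the
do-operator; synthetic cohorts of 190 (the study-scale pipeline run), 600
(classifier and smoothing sweep; the sweep's reference evidence is a
well-populated treatment/waiting configuration), 600 deterministic and
5000 stochastic cases for recovery, and 10000 for CPT recovery.  These
sizes put Monte-Carlo noise well below the asserted tolerances while
keeping a full run in tens of seconds.

## Numerical choices and degenerate inputs

* Probabilities in linear space; rows validated to sum to 1 within
  $10^{-12}$ at learning, $10^{-9}$ at prior replacement.
* Evidence with zero joint probability raises an explicit "impossible
  evidence" error; with the default smoothing it cannot occur.
* `w = 0` is allowed (exact empirical frequencies; rows with no
  observations fall back to uniform) and is used by the deterministic
  recovery tests.
* Half-up rounding for months; MAP ties toward the smaller month;
  serialisation prints probabilities at 17 significant digits so YAML
  round-trips are bit-exact.
* All randomness flows through explicit integer seeds; sampling restores
  the caller's RNG state.

## Known limitations

* The identification assumptions are inherited from the study design:
  ignorability of the compliance–waiting relationship, SUTVA, and
  positivity only up to the smoothing prior.  Rarely observed
  treatment–waiting combinations yield near-uniform survival rows whose
  MAP (ties to month 0) reflects ignorance, not prognosis — visible in
  small-cohort runs and intrinsic to the positivity problem.
* Copy mode cannot personalise beyond the retained evidence; quantile
  mode personalises by rank but rests on an untestable rank-preservation
  assumption.  Reporting both is the honest envelope.
* The AUC validation treats the network as a classifier of a dichotomised
  survival; which variable the original validation dichotomised is not
  fixed by the design, so target and split seed are exposed as parameters.
* Survival is modelled as a capped discrete variable without censoring
  adjustment; average treatment effects are deliberately out of scope —
  queries are per-case.
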