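---
title: "Benchmarking hospitals by template matching: models, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking hospitals by template matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Conventional hospital profiling is indirect standardization: a system-wide
regression predicts how an average hospital would fare with hospital A's
patients, and A is judged against that extrapolation. When hospitals see
very different patients, the extrapolation is exactly the part of the model
with no data behind it. Template matching is the direct-standardization
alternative: fix one representative sample of hospitalizations (the
*template*), find in every hospital a sample of admissions matched 1:1 to
that template, and compare hospitals on the outcomes of those matched
samples. Every hospital is then measured on the same yardstick, and the
yardstick is inspectable.

`templatebench` implements the full procedure — template selection, optimal
constrained matching, match-quality audits, and mixed-model ranking on
30-day mortality — together with a synthetic multi-hospital generator with
*known* hospital quality effects, so the whole chain can be validated as a
measurement instrument: does the benchmark recover the truth it was built
to estimate?

## Pipeline and models

### Risk model

The illness-severity covariate is the predicted probability of 30-day
mortality from a maximum-likelihood logistic regression (IRLS, tolerance
1e-8, at most 100 iterations) on age, sex, race/ethnicity, surgical
indicator, admission route, principal-diagnosis terms, 29 comorbidity
indicators and 11 admission laboratory values (as z-scores against fixed
population centers). In place of indicator sets derived from external
diagnosis-code groupers, the model uses the 7 broad diagnosis categories
plus indicators for the 20 most common fine categories of the training
cohort; this preserves the rank structure of diagnostic risk without any
code-mapping machinery. Separation (non-convergence or exploding
coefficients) triggers a weak-ridge refit (lambda = 1e-4) with a flag.
Discrimination is summarised by the c-statistic, computed from mid-ranks
(ties count one half).

### Eligibility cascade

Exclusions are applied in a fixed order: system transfers, organ
transplants, missing principal diagnosis, rare principal diagnoses (fine
category with frequency strictly below 1 in 300 of the remaining cohort),
hospitals below the matching-ratio volume floor
(`template_size * ratio`, e.g. 300 × 3 = 900), and hospitals with more
than 90% psychiatric/substance-abuse admissions. Two points were genuinely
open and are resolved as follows. First, narrative descriptions of such
cascades sometimes order the row-level counts differently than they are
reported; the order here follows the methodological description
(transfers before diagnosis rules before hospital rules) and the log makes
every step auditable. Second, the denominator of the 1-in-300 rule is the
cohort remaining after the row-level exclusions (steps 1–3), which is what
"remaining eligible" most naturally means; it is configurable
(`rare_denominator = "input"`) for sensitivity analysis.

### Template selection

Candidates are simple random samples of m = 300 hospitalizations drawn
without replacement (1000 candidates by default); the selected template
minimizes the Mahalanobis distance between the candidate mean and the
cohort mean over a selection roster (predicted mortality, observed
mortality, sex, race/ethnicity, surgical indicator, the 7 broad diagnosis
categories, and seven major comorbidities). "Observed mortality" enters as
the 30-day outcome indicator of the sampled rows. Categorical variables
enter as one-hot indicators with a reference level dropped, which keeps
the covariance better conditioned; the covariance is estimated from the
full eligible cohort and inverted by Moore–Penrose pseudo-inverse, since
indicator rosters are routinely rank-deficient. Zero-variance columns are
dropped with a warning. Ties break by candidate index, so selection is
deterministic under a seed.

In tiered mode one template is selected per critical-care tier, and the
template's surgical proportion can be fixed to that of the tier's median
hospital; hospitals whose surgical or non-surgical pools cannot support
the matching ratio in either stratum are flagged ineligible (a template of
50 surgical / 250 non-surgical cases requires pools of 150 and 750).

### Optimal matching with near-exact and fine-balance constraints

Each hospital's m matched admissions minimize the total pair distance over
all 1:1 assignments of template cases to the hospital's pool, solved as
min-cost network flow (successive shortest paths with Dijkstra and node
potentials, implemented in C++). The pair distance is the Mahalanobis
distance over the distance roster (pooled-cohort covariance,
pseudo-inverse) plus a penalty per mismatched near-exact variable. The
default penalty, `(m + 1) * max(base distance)` recomputed per hospital,
makes near-exact agreement lexicographically dominant: if any
zero-mismatch assignment exists, the optimum has zero mismatches.

Fine balance — the matched sample's category counts must equal the
template's exactly — is encoded as capacitated category nodes between the
pool and the sink. With several fine-balance variables, layers are nested
by interaction in priority order, and each layer carries overflow arcs
whose penalties decrease with depth, so the first variable is balanced
most strictly and later ones as well as possible given the earlier layers.
Costs are scaled to integers with a per-instance scale chosen so that
(a) base distances keep about nine significant digits and (b) the largest
penalty times the flow stays within exact int64/double range; this caps
the penalty hierarchy at the documented layer depths. Whether balance was
attained is always re-verified by recounting categories from the matched
rows, independently of the solver; unattained balance is reported with the
highest-priority binding variable named, never silently absorbed.

Two practical notes. For large pools the network can be thinned to each
template case's q nearest pool rows; the solver automatically widens the
neighborhood whenever the thinned network is infeasible *or* uses any
overflow capacity, so thinning can cost a little distance but can never
fabricate imbalance. And a configurable node/arc budget turns oversized
networks into an explicit "non-converged" result rather than an open-ended
computation — mirroring how high-dimensional matching runs fail in
practice. Ties among optimal assignments resolve by the deterministic arc
order (rows sorted as given).

### Match-quality audits

The cross-match test pools the m template cases with the m matched
admissions, pairs all 2m subjects to minimize total Mahalanobis distance
(exact non-bipartite minimum-weight perfect matching via the blossom
algorithm, delegated to networkx through a batched subprocess), and counts
cross-group pairs A1. Under the null that both groups occupy the same
covariate distribution, all pairings of labels are equally likely, giving
the closed-form pmf
P(A1 = a) = C(m,a) C(n,a) a! (m−a−1)!! (n−a−1)!! / (m+n−1)!!
on values of a with the parity of the group sizes. The reported p-value is
P(A1 ≤ a1), exact for groups up to 30 (log-space factorials), with a
normal approximation (continuity correction 1, since the support steps by
2) above. One consequence worth stating plainly: the exact test is
discrete, so its attained size sits *below* any nominal level — at
n = 20 per group the largest attainable size under 0.05 is about 0.0075.
Calibration checks therefore compare the empirical rejection rate with the
exact attained size, not with the nominal 5%. "Poorly matched" is flagged
at p < 0.05 by default; the cut is configurable, as is the balance cut
below, since neither has a canonical published value.

Omnibus balance uses Kruskal–Wallis (continuous) and Pearson chi-square
(categorical) tests of each matching variable across all hospitals'
matched samples, with `balanced` meaning p ≥ 0.05 by default. Constant
variables are reported as degenerate-balanced with a warning rather than
producing 0/0 statistics.

### Ranking and the regression comparator

The matched benchmark stacks all matched samples and fits a hierarchical
logistic model: 30-day death on a fixed effect per hospital (centred to
sum to zero, so an effect is a deviation from the average hospital) plus
the logit of predicted mortality, with a random intercept per template
case — each template case indexes the cluster of its matched admissions,
one per hospital. That is the most literal reading of "clustering on the
template matched patient"; the model statement is genuinely ambiguous and
the chosen hierarchy is recorded here rather than guessed about further.
Estimation is by Laplace approximation (`lme4::glmer`); when the
template-case variance degenerates to zero or the fit fails, the model
falls back to conditional logistic regression on template-case strata,
which conditions the cluster effects out. The conditional estimator can
also be requested directly (`estimator = "conditional"`): it is the
classical estimator for 1:1 matched designs and an order of magnitude
faster, which is why the simulation studies below use it. Hospitals with
no deaths (or no survivors) among matched rows would separate the
likelihood; they receive two half-weight pseudo-observations (one death,
one survival) — a weak ridge toward the average — and are flagged.

The comparator is indirect standardization: a random-intercept-per-hospital
logistic model on the entire eligible cohort, adjusted for the logit of
predicted mortality, ranked by empirical-Bayes intercepts. Hospitals are
categorized top / median / bottom with the top and bottom quintiles each
holding `ceiling(H / 5)` hospitals (ties in estimates break by hospital
id), and two benchmarks are compared by the Pearson chi-square of the
3 × 3 category table plus the share of identically categorized hospitals.

## The synthetic generator

The generator emulates the structure that makes this benchmarking problem
hard: many hospitals, skewed volumes, and case-mix that differs between
hospitals far more than sampling noise. Its defaults are fixed once:

* 40 hospitals, volumes log-uniform on 300–3,000 (a scaled-down version of
  a national system's 267–16,253 range; tiers 1–5 assigned by volume
  quintile, largest = tier 1).
* Between-hospital heterogeneity on every case-mix block, all multiplied
  by one `heterogeneity` scale (default 1): hospital age means N(65, 4²);
  logit-normal spreads for female share (base 6%), surgical share (base
  8%, sd 1.0 — spanning roughly 1–35%), ED admission share (base 60%,
  sd 2.2 — spanning nearly 0–99%), nursing-facility share, and the 29
  comorbidity prevalences (sd 0.4); Dirichlet diagnosis mixes
  (concentration 12, psychiatric/substance base 18%, giving
  single-digit-to-majority psychiatric shares across hospitals); small
  per-hospital lab shifts (0.15 SD). Setting the scale to 0 makes all
  hospitals exchangeable — a property the test suite exploits.
* 72 fine diagnosis categories refined from the 7 broad ones with
  Zipf-like within-category weights (exponent 1.3), so a 1-in-300 rarity
  rule genuinely removes a tail.
* Labs drawn from a fixed multivariate normal on the z-scale with a small
  plausible correlation structure (renal pair −0.6, blood-gas pair −0.45,
  nutrition pair +0.25) plus diagnosis-linked shifts. Only ranks and
  balance of labs matter downstream, so no attempt is made at clinical
  realism beyond location/scale/correlation.
* A true outcome model: logistic in the generated covariates with
  invented but clinically signed coefficients (no published set exists for
  synthetic data), intercept −3.6, yielding pooled 30-day mortality
  around 5–9% depending on case-mix; and a hospital quality effect
  N(0, `quality_sd`²) (default 0.3) added to every admission's log-odds.
  The quality effect is the estimand of the whole exercise.
* Reproducibility: one master seed; hospital profiles from the master
  stream, each hospital's rows from a deterministically derived
  per-hospital substream.

What the generator does *not* emulate: diagnosis-code semantics,
longitudinal structure, missing data, and within-hospital time trends.
Passing tests on this generator therefore shows the machinery measures
what it claims under known, well-behaved data-generating processes — not
that any real system can be balanced; indeed the heterogeneity experiment
below reproduces the opposite.

## Validation studies and problem sizes

The test suite certifies each optimizer against an independent oracle:
assignment totals against exhaustive dynamic programming (templates up to
6, pools up to 10, 200 instances), the Hungarian algorithm on square
instances, blossom pairings against full pairing enumeration (up to 12
subjects) and a greedy comparator, the cross-match pmf against complete
enumeration, and Kruskal–Wallis / chi-square against hand-derived values
(H = 27/7 for {1,2,3} vs {4,5,6}; 20/3 for the 20/10/10/20 table).

The recovery study runs 100 replicates of the full pipeline on the default
40-hospital system (quality SD 0.3, template 300, 50 candidate templates,
near-exact sex, thinned networks, conditional estimator): hospitals below
the 900-row floor are excluded exactly as in production, and the Spearman
correlation between true quality effects and each method's ranks averages
well above 0.6 for both template matching and regression. A 500-replicate
two-hospital experiment (effects 0 vs +1, pools at the 3:1 floor) checks
raw separation. The heterogeneity experiment runs 50 paired replicates of
a 10-hospital system at heterogeneity 0.25 vs 1.25 (template 50, fine
balance on diagnosis category, with and without labs in the distance
roster): more heterogeneity yields more unbalanced variables after
matching and no better cross-method category agreement. These problem
sizes are the package's documented validation conditions; the generator's
scientific defaults are never tuned to them.

## Known limitations

* The pair distance is plain Mahalanobis; rank-based robust variants used
  by some matching tools are a documented configuration point left
  unimplemented.
* Fine-balance layering uses nested category interactions; marginal
  balance of a later variable can be attainable in principle yet
  unattained under the layering, which is reported honestly per variable.
* The blossom step requires a Python interpreter with networkx on PATH;
  everything else is pure R/C++.
* No standardized-mean-difference balance metrics, caliper or
  variable-ratio matching, O/E ratios, or multi-year pooling.
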