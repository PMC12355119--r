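---
title: "Estimating and probing symptom networks from ordinal questionnaire data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and probing symptom networks from ordinal questionnaire data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`symptomnet` implements a complete symptom-network workflow for two
co-occurring psychological constructs measured with ordinal
questionnaires — the motivating application is fear of cancer recurrence
(FCR, measured by the 42-item FCRI across 7 dimensions) and pain
catastrophizing (PC, the 13-item PCS) in breast-cancer patients. The
network nodes are the 7 FCRI dimension scores (F1–F7) and the 13
individual PCS items (P1–P13), giving a 20-node, two-community network.
This vignette explains each model in the pipeline, the tunable
parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical choices behind the implementation.

## Scoring and sample size

Items are scored 0–4; reverse-scored items are transformed as
$v' = \max + \min - v$ before summation. Reliability is summarized by
Cronbach's $\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_i s_i^2}{s_T^2}\right)$
on raw item covariances. Missing data are handled by listwise deletion
only — an incomplete questionnaire is treated as invalid, matching field
practice for short self-report batteries; imputation is deliberately not
offered because the downstream polychoric likelihood assumes complete
response patterns.

A Gaussian graphical model over $p$ nodes has $p$ threshold parameters
and $p(p-1)/2$ pairwise parameters; `network_sample_size()` implements
the rule that the sample should at least exceed this total
(210 cases for $p = 20$), inflated by an anticipated attrition rate
(263 at 20%).

The FCRI item-to-dimension layout ships as an editable YAML file
(`inst/extdata/fcri.yaml`), since local adaptations of the instrument
occasionally renumber items. Dimension scores enter the network as raw
sums by default; `standardize = TRUE` is available, and because both
the polychoric and Pearson correlations are location/scale invariant at
the node level, the choice only matters when mixing node types.

## Input correlations

Ordinal items violate the Gaussian assumption of a partial-correlation
network, so the input matrix uses polychoric correlations: each
variable is modeled as a discretized latent standard normal, thresholds
are estimated from the marginal category proportions
($\tau_k = \Phi^{-1}(\hat F_k)$, the two-step estimator), and the
latent correlation maximizes the bivariate-normal contingency-table
likelihood. The rectangle probabilities come from a 6/12/20-point
Gauss–Legendre scheme (the standard Drezner–Wesolowsky/Genz algorithm,
accurate to ~1e-15); the one-dimensional likelihood search uses
golden-section to a 1e-6 tolerance on $\rho \in (-0.999, 0.999)$, with
perfect association clamped and warned. `method = "auto"` chooses
polychoric exactly when every variable is integer-valued with at most 7
distinct levels, Pearson otherwise — dimension sums (range 0–36) are
therefore treated as continuous, single items as ordinal.

Pairwise polychoric matrices need not be positive semi-definite; when
needed the matrix is smoothed by clipping negative eigenvalues and
rescaling to a unit diagonal. Pearson/Spearman matrices are Gram
matrices and never need smoothing.

Redundancy screening (`goldbricker()`) flags node pairs that correlate
strongly (default $|r| \ge 0.50$) *and* relate to the rest of the
network near-identically: for each third node the two correlations are
compared with the Hittner et al. back-transformed-average-$z$ test for
dependent overlapping correlations, and a pair is flagged when fewer
than 25% of those comparisons differ at $p < 0.05$. The three
thresholds are package conventions (the applied literature rarely
states them) and are exposed as arguments. Flagged pairs are reported
with a suggested member to drop (the one with weaker remaining
connectivity); nothing is removed automatically.

## Regularized network estimation

The network is the Gaussian graphical model estimated by graphical
lasso: maximize
$\log\det K - \mathrm{tr}(SK) - \lambda \sum_{i \ne j} |K_{ij}|$
over positive-definite precision matrices (diagonal unpenalized),
solved by block coordinate descent with lasso subproblems. Convergence
is declared when the largest change in the working covariance falls
below `tol` (default 1e-4) times the mean absolute off-diagonal of
$S$; the coordinate updates produce exact zeros. Edge weights are
partial correlations $w_{ij} = -K_{ij}/\sqrt{K_{ii}K_{jj}}$.

The penalty is selected by the extended BIC over a descending
log-spaced path of 100 values from $\lambda_{\max} = \max_{i<j}|S_{ij}|$
down to $0.01\,\lambda_{\max}$:
$\mathrm{EBIC} = -2\,\ell(K) + E \log n + 4 E \gamma \log p$,
with $E$ the number of nonzero upper-triangle edges and $\gamma = 0.5$
by default ($\gamma = 0$ recovers plain BIC). Two documented choices
follow the reference implementations of this estimator: the
log-likelihood uses the penalized $K$ directly rather than a refit
(this changes selection slightly, in the liberal direction at large
$n$), and the same $\gamma$ is used for the separate 7- and 13-node
community networks as for the combined 20-node network.

Centrality follows the standard conventions: strength
$\sum_j |w_{ij}|$, one-step expected influence $\sum_j w_{ij}$,
betweenness and closeness on shortest paths with edge length
$1/|w_{ij}|$ (betweenness over unordered pairs with fractional credit
for ties; closeness as the *unnormalized* inverse total distance, which
matches the small magnitudes conventionally reported, e.g. 0.030 for a
7-node graph). On disconnected graphs closeness is computed within the
node's component and flagged; isolated nodes get `NA`. Bridge strength
is the cross-community restriction of strength; bridge expected
influence its signed analog.

## Stability, accuracy and group comparison

Edge accuracy uses the nonparametric bootstrap (`B = 1000` by
default): respondents are resampled with replacement, the entire
correlation + EBIC-glasso pipeline is re-run, and percentile 2.5/97.5%
bounds are reported per edge. Centrality stability uses the
case-dropping bootstrap: for each drop proportion $q$ in
$\{0.05, \dots, 0.75\}$, subsamples retaining $\lceil (1-q) n \rceil$
respondents are re-estimated and the centrality vector is correlated
(Spearman by default, robust to scale; Pearson by flag) with the
full-sample vector. The CS coefficient is the largest $q$ for which
that correlation reaches 0.7 in at least 95% of subsamples; 0.25 is the
conventional floor and 0.5 the comfortable level. Degenerate subsample
centralities (e.g. an all-zero strength vector on a null network) have
undefined correlations and count as failures, which makes the CS of
pure-noise data collapse to 0 rather than being undefined.

The network comparison test (NCT) is a permutation test between two
groups (here: early- vs. advanced-stage patients). Observed statistics
are $S$, the absolute difference in global strength — the *signed*
(expected-influence) variant by default, matching how the global
quantity is usually reported for all-positive symptom networks, with
the unsigned variant by flag — and $M$, the maximum absolute
edge-weight difference. The null distribution pools all respondents
and re-splits them at the original group sizes, re-estimating both
networks each time; $p = (1 + \#\{\text{perm} \ge \text{obs}\})/(K+1)$
never returns 0. Optional edge-level and centrality-level tests
(strength and bridge expected influence by default) are Holm-corrected.
Because the test is permutation-exact under exchangeability, its
type-I calibration does not depend on the input-correlation estimator;
the package's calibration checks exploit this by using the faster
Spearman input on 50-value paths.

## Directed structure: Bayesian network averaging

Directionality is explored with score-based structure learning on the
(approximately Gaussian) node scores: greedy hill climbing over
add/delete/reverse moves maximizing the decomposable linear-Gaussian
BIC, with local scores
$\ell_j - \tfrac{|\mathrm{pa}(j)| + 2}{2}\log n$ (coefficients,
intercept, noise variance). Candidate moves are scanned in a fixed
order with first-arrival tie-breaking: members of a score-equivalence
class tie exactly, and a deterministic rule keeps their orientation
consistent across bootstrap resamples — with random tie-breaking the
direction-consistency filter below would discard genuinely present
edges. Randomness enters only through seeded restart perturbations
(default 10 restarts on full data, fewer inside the bootstrap).

The reported graph averages `B = 200` bootstrap searches: an edge is
retained when it appears (in either direction) in at least 50% of
resamples *and* its majority direction holds in at least 75% of its
appearances — the direction-consistency rule; the presence threshold
is the package's own addition, since a direction rule alone would admit
edges that rarely appear at all. Retained edges are inserted in
decreasing presence order, skipping any that would create a cycle (the
skips are logged). Edge strength is the change in the full-data network
score when the edge is removed: negative values mean the edge improves
fit. Complexity is summarized by the mean Markov-blanket size (parents,
children, co-parents), the branching factor (mean out-degree), the
total BIC score, and the parent nodes (out-degree > 0, in-degree 0).
Ordinal scores are treated as continuous Gaussian variables here, the
standard practice behind this analysis; a discretized alternative is
out of scope.

## Simulated interventions under an Ising model

For intervention ranking the data are dichotomized at $> 0$ (any
endorsement counts as symptom presence) and an Ising model is fitted by
eLasso: per-node $L_1$-penalized logistic regressions with per-node
EBIC selection ($\mathrm{EBIC} = \mathrm{dev} + k \log n + 2\gamma k
\log(p-1)$, $\gamma = 0.25$, the conservative convention), couplings
combined by the AND rule by default (both directed estimates nonzero,
averaged; OR by flag). Nodewise predictability is classification-based:
$(\mathrm{acc} - \mathrm{maj})/(1 - \mathrm{maj})$ floored at 0, where
`maj` is the marginal majority-class rate.

An intervention on node $i$ shifts its threshold by $\pm 2$ standard
deviations *of the fitted threshold vector* (the perturbation unit of
the cited procedure; not of the edge weights), amplification raising
the activation probability. Baseline and perturbed models are
Gibbs-sampled (single chain, 1000 burn-in sweeps, default 10,000
recorded responses) with a shared seed stream, so the reported
$\Delta$sum-score and per-node prevalence changes are common-random-
number contrasts with exact zeros under a null perturbation.
Aggravation targets are ranked by descending $\Delta$score under
amplification, alleviation targets by ascending $\Delta$score under
attenuation; relative influence normalizes by the total absolute effect
per direction. The clinical-relevance flags (defaults 0.01 for
aggravation, 1.0 for alleviation) are reporting conventions exposed as
arguments, not model logic, and the rank-1 consistency across seed
replicates is offered as a reconstruction of bootstrap validation.

## The synthetic generator: what it emulates, and what it does not

Because questionnaire data of this kind are not publicly shareable, the
package ships a generator with known ground truth. Ordinal responses
arise by discretizing a latent multivariate Gaussian whose precision
matrix has unit diagonal, off-diagonal support only on planted
within-community pairs and a few planted cross-community bridges, and
is made positive definite by scaling all off-diagonals down until the
smallest eigenvalue exceeds 0.01 (simple and reproducible; the
*realized*, post-shrinkage partial correlations are recorded as the
truth). Defaults: communities of 7 and 13 nodes; within-community
density 0.65, mirroring the dense within-community connectivity
reported for fitted FCR/PC networks and giving planted support that is
identifiable at moderate sample sizes (the positive-definiteness
shrinkage then brings the realized partial correlations down to
roughly the scale of reported symptom-network edge weights); 2 bridge
edges between seeded random
cross-community pairs, whose incident nodes are the recorded "true"
bridge nodes; planted weights drawn from (0.2, 0.4); 5 response
categories with right-skewed cuts (≈ 40/28/17/10/5% marginals,
mimicking symptom data where most respondents endorse low categories);
and n = 346 respondents, the motivating study's analytic sample size.

The generator emulates the *structure* relied on by the estimators —
ordinal margins, latent Gaussian dependence, two communities, sparse
bridges — and deliberately not other features of real questionnaire
data: no differential item functioning, no local dependence beyond the
Gaussian copula, no response styles or careless responding, no
missingness unless requested. Passing recovery tests therefore shows
the estimators work when their assumptions hold; it cannot certify
performance under model violations. The companion Ising sampler is a
plain Gibbs chain whose conditional logits are
$\tau_i + \sum_j \beta_{ij} x_j$, consistent with the eLasso
parameterization it is used to validate.

## Numerical choices and problem sizes

All resampling procedures accept a seed and are byte-reproducible;
`run_all()` fans one global seed out to fixed per-stage offsets (+100
edge bootstrap, +200 case-dropping, +300 NCT, +400 Bayesian network,
+500 Ising), so stages can be reproduced in isolation. Degenerate
inputs fail loudly and early: constant columns are named in the error,
out-of-range or missing responses abort scoring, attrition ≥ 1 and
single-community bridge analyses are rejected.

The validation suite sizes its simulations to what the checks need
rather than to the motivating study: oracle-equivalence checks run on
3-node problems (where exhaustive enumeration and general-purpose
optimization are exact); support recovery uses n = 2000 so that the
planted partial correlations are comfortably identifiable (median F1
across 10 replicates); bridge recovery uses 50 replicates; Ising
parameter recovery uses n = 5000 on a 2-node model with known Gibbs
truth; the NCT type-I calibration uses 500 null replicates of
two n = 300 groups at K = 200 permutations with Spearman inputs on a
50-value path (see above for why calibration is estimator-agnostic);
and the pure-noise CS check uses 20 replicates at n = 300. Where a
published worked example fixes numbers exactly (210/263 cases, 190
possible edges, 52-point PCS ceiling, 4.7%/95.3% retention, 23.81%/
37.18% zero-edge shares), the tests assert them exactly.

## Known limitations

- The polychoric estimator is two-step, not full ML; with very sparse
  cells (rare categories at small n) thresholds are noisy and the
  likelihood can flatten near the boundary.
- EBIC on the penalized likelihood is mildly liberal at large n
  (documented above); users wanting maximal specificity should raise
  `gamma`.
- The Bayesian network treats ordinal scores as Gaussian; with 5-level
  items the local linear models are approximations, and directions
  within a score-equivalence class are identified only by the
  bootstrap consistency rule, not by the data.
- The Ising intervention simulates manipulation of a model parameter;
  it is a computational probe of the fitted joint distribution, not a
  causal effect estimate.
- One grouping variable with exactly two levels is supported in the
  comparison stage; paired designs and k > 2 groups are out of scope.
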