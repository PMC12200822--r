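---
title: "Ranking health-domain interventions with causal Bayesian networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking health-domain interventions with causal Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalrank)
```

## The model

`causalrank` treats a two-wave ordinal panel as observations from a
structural causal model over `2K` temporal variables: `K` health domains,
each measured at baseline (`_t0`) and follow-up (`_t1`) on the ordinal scale
`poor < fair < healthy` (codes 0, 1, 2). The causal structure is a DAG over
these variables, constrained only by the arrow of time: no edge may point
from a follow-up node into a baseline node, while edges within either slice
and from baseline to follow-up are allowed.

Because the causal structure in this domain is genuinely uncertain, the
package never commits to a single DAG. It computes decision quantities
marginalized over the structure posterior

$$ P(G \mid D) \;\propto\; P(D \mid G) $$

under a uniform prior over admissible DAGs. Everything downstream —
expected utilities, treatment effects, optimal-target probabilities — is an
average over DAG samples from this posterior, so structural uncertainty
propagates into the recommendations and into their standard errors.

### Scoring: the BGe marginal likelihood

`P(D | G)` is the Bayesian Gaussian equivalent (BGe) score evaluated on the
ordinal codes after per-column standardization. Scoring ordinal data as
Gaussian keeps the order information that a multinomial score would discard,
at the cost of a distributional approximation (see *Limitations*). The score
of node $j$ with parent set $P$ is a ratio of set marginals of the conjugate
normal-Wishart model,

$$ s(j \mid P) = \log p(d_{P \cup j}) - \log p(d_P), $$

with the set marginal of $l$ columns

$$ \log p(d_A) = -\tfrac{lN}{2}\log\pi + \tfrac{l}{2}\log\tfrac{\alpha_\mu}{\alpha_\mu+N}
   + \log\frac{\Gamma_l\!\big(\tfrac{N+\alpha_w-n+l}{2}\big)}{\Gamma_l\!\big(\tfrac{\alpha_w-n+l}{2}\big)}
   + \tfrac{\alpha_w-n+l}{2}\log|T_0{}_{A}| - \tfrac{N+\alpha_w-n+l}{2}\log|R_A|, $$

where $R = T_0 + S_N + \tfrac{N\alpha_\mu}{N+\alpha_\mu}\,\bar x \bar x^\top$
(data centered, so the mean term vanishes) and $\Gamma_l$ is the
multivariate gamma function. Because the score is a ratio of set functions
it is constant across Markov-equivalent DAGs; the test suite asserts this to
`1e-8` and pins the formula against an independently coded normal-gamma
closed form for the univariate case. Hyperparameter defaults follow the
structure-learning literature: $\alpha_\mu = 1$, $\alpha_w = n + 2$, prior
mean 0, prior scale $t\,I$ with
$t = \alpha_\mu(\alpha_w - n - 1)/(\alpha_\mu + 1)$, which gives every
standardized column prior variance 1. These are exposed through
`bge_hyper()`; they are a genuinely open choice since no single setting is
canonical, and the defaults make the prior as uninformative as the conjugate
family allows while keeping it proper.

Constant data columns are rejected at scoring time with a named error: a
constant column carries no ordering information and makes edge direction
ill-posed.

### Sampling: partition MCMC

The sampler walks over *labelled partitions*: ordered blocks of nodes. A DAG
is compatible with a partition when every node's parents lie in strictly
earlier blocks and every node outside the first block has at least one
parent in the immediately preceding block. Under this rule each DAG belongs
to exactly one partition, so partitions tile DAG space; a partition's score
is the log-sum of its DAGs' scores, computed per node as a sum over
admissible parent sets (never by DAG enumeration), and one DAG is drawn per
retained partition state proportionally to its score. The temporal
constraint enters as a hard admissibility filter on parent sets; partitions
that leave a baseline node without any admissible parent set score $-\infty$
and are never accepted.

The proposal kernel mixes three moves (probabilities 0.6 / 0.25 / 0.15):

* **relocate** one node into another block or a new singleton block, with an
  exact Hastings correction equal to the ratio of neighbour counts — this
  single move family also realizes block splits and merges, since relocating
  a node out of or into a block changes the block count;
* **swap two nodes** across blocks (block sizes preserved, hence symmetric);
* **swap two adjacent blocks** (block count preserved, hence symmetric).

Every chain starts from the single-block partition (the empty DAG, always
admissible). Runs are reproducible: chain $c$ of a run with master seed $s$
uses the seed $(48271\,s + 7919\,c) \bmod (2^{31}-19)$, recorded in the
output. Defaults are 8 chains, 60,000 iterations, 20,000 burn-in, thinning
40, and a parent-set cap of 4, which keeps the per-node sums exact and cheap
(at 14 nodes, at most 1,093 parent sets per node). The cap is a modelling
choice as much as a computational one: with roughly 600 observations,
conditional tables beyond four parents are not estimable anyway.

Correctness of the sampler is tested against exhaustive enumeration
(`enumerate_posterior()`, all 25 DAGs at 3 nodes) at three Monte-Carlo
standard errors, and every retained draw is checked for acyclicity and
temporal admissibility.

### Convergence

`convergence_report()` compares per-chain edge probabilities and passes when
the largest cross-chain spread is below 0.05. At large `n` the posterior
over *within-slice* edge orientations can be genuinely multimodal with
near-equal mode weights (Markov-equivalent orientations score identically);
single-node moves cross between such modes through low-score intermediate
partitions, so chains can disagree on those orientations long after the
presence probabilities have stabilized. The pipeline therefore treats a
failed spread check as a prominent warning rather than an error — the
cross-time edges that drive the decision layer are oriented by the temporal
constraint and are not affected by this multimodality, but reported
within-slice orientation probabilities should then be read with care and the
run repeated with more iterations.

## Networks, interventions, decisions

Each sampled DAG is fitted as a categorical Bayesian network with
Dirichlet-MAP tables: cell probability
`(count + pseudocount) / (row total + 3 * pseudocount)`, default
pseudocount 1 (the mode of a symmetric Dirichlet(2) posterior). Smoothing is
essential, not cosmetic: a node with four parents has 81 rows against ~600
observations, so many parent configurations are sparse or unobserved;
unobserved rows become uniform. The pseudocount is exposed because no
canonical value exists; sensitivity to it can be probed through the
pipeline configuration.

Inference is exact. Given a baseline profile, all `3^K` follow-up
configurations are enumerated (2,187 at K = 7) and the joint is the product
of follow-up CPT entries with baseline nodes clamped. Baseline CPTs are
fitted but unused in follow-up inference — baselines are always evidence.
The do-operation on target `d` removes all edges into `d`'s follow-up node
and replaces its table by a point mass on *healthy*; it is idempotent and
never modifies its input. The ranking fast path evaluates all `K + 1`
actions from one enumeration pass using leave-one-out prefix/suffix
products, which is algebraically identical to enumerating each mutilated
network (and is asserted equal to the plain path in tests, since
zero-probability entries make naive division invalid).

Utilities are `U(s) = Σ_d w_d u(level_d)` with presets
*default* `(0, 0.75, 1)` (moderately risk-averse), *risk_neutral*
`(0, 0.5, 1)` and *risk_averse* `(0, 1, 1)`; weights default to 1. Rankings
are invariant to positive affine transformations of `u` (tested), so only
the curvature of the subutility and the weight ratios matter. Reported per
action: posterior-mean EU; a Monte-Carlo standard error `sd/sqrt(ESS)` with
the effective sample size taken from the autocorrelation of the per-sample
EU series (the plain posterior SD is reported alongside, since either
reading of "SE" is defensible); and the ATE as the per-sample-paired
difference against doing nothing. Optimality (`p_opt`, `p_rec(N)`) is
resolved per posterior sample — not on posterior-mean EUs — so the reported
probabilities are genuine posterior probabilities of being optimal,
marginalized over the empirical baseline-state distribution (unobserved
states get weight 0, a deliberate design choice over modelling the state
distribution). Ties are broken by the fixed registry order
(functioning, distress, nutrition, activity, sleep, social, substance), and
`rank_targets()` reports when a tie-break fires. Doing nothing is excluded
from `p_opt`/`p_rec` tabulations but always reported alongside, since a
short-list recommender chooses among targets.

The shipped up-weighting sensitivity (weight 2 on psychological distress and
personal functioning) is illustrative only; elicited weights should replace
it in any real use.

## The synthetic-data generator

The generator (`generator_config()`, `sample_scm()`, `simulate_panel()`)
emulates the data regime the method is designed for:

* about 600 individuals, 7 domains, 3 ordinal levels at two time points;
* strong same-domain persistence: probability `ar_strength = 0.6` of staying
  at the baseline level, remainder biased toward adjacent levels;
* a sparse set of cross-domain effects: 2 lagged and 4 within-follow-up
  edges by default, matching the scale of structure typically detectable at
  this sample size;
* ordinal effects as monotone probability-mass shifts (`effect_size = 0.25`
  of remaining mass per level of parent deviation from *fair*), so healthier
  parents always shift children toward healthier levels — the by-construction
  monotonicity is asserted over every generated table;
* baseline category marginals copied from a published two-wave well-being
  cohort table (e.g. physical activity 75% healthy, social support 43%
  poor), giving realistic state frequencies at zero cost;
* follow-up gaps log-normal around a 55-day median, truncated to the 7–183
  day selection window.

`effect_size` has no empirical anchor (the motivating analyses report edge
probabilities, not effect magnitudes), so 0.25 was chosen once as a
moderate, clearly detectable-at-n=5000 effect and left alone. Within-baseline
dependence is off by default: baseline dependence is plausibly dense in real
data but its parameters are unknown, and independent baselines make the
empirical state distribution maximally spread, which is the harder case for
state-weighted summaries.

What the generator does *not* emulate: questionnaire items below the domain
level, missingness (the target data are complete by construction), selection
between app registration and analysis eligibility, cyclic within-slice
feedback, and unmeasured confounders. Passing recovery tests therefore shows
the chain is correct and identifiable under its own assumptions — not that
those assumptions hold in any particular cohort.

## Numerical choices and degenerate inputs

* Log-domain throughout; partition and enumeration sums use log-sum-exp.
* Set-marginal determinants via Cholesky with memoization per subset mask.
* CPT rows sum to 1 within 1e-12; follow-up distributions within 1e-9
  (asserted).
* Ties in rankings: registry order, logged. Ties in per-sample optimality:
  earliest registry index.
* Degenerate inputs rejected with named errors: constant columns, duplicate
  individual ids, unknown level labels (with row and column), unsorted visit
  logs, empty selection windows, backward-in-time whitelist entries in
  pipeline configurations.
* `compatible_dags()` refuses more than 8 nodes and `enumerate_posterior()`
  more than 5 — they are oracles, not production paths.

## Problem sizes used by the test suite

The suite favours exactness over scale: oracle comparisons run at 2–4 nodes
where exhaustive enumeration is available; sampler-versus-enumeration
agreement uses 3 nodes, n = 500, 4 chains; CPT and marginal recovery use
n = 5,000; the end-to-end recovery runs use the 3-domain generator
(n = 5,000, where single baseline states carry > 5% empirical mass, making
per-state recovery checks substantive) and the full 7-domain generator
(n = 5,000, 4 chains × 6,000 iterations), which recovers every
autoregressive edge above 0.8 posterior probability and agrees with the
ground-truth optimal target on over 80% of the baseline-state mass. These
sizes are the package's own validation choices; production runs should use
the larger MCMC defaults.

## Limitations

* **Ordinal-as-Gaussian.** The BGe score treats coded levels as Gaussian;
  with 3-level data this is a working approximation that can admit spurious
  edges at very large n and does not model floor/ceiling effects.
* **Acyclicity within a slice.** Real contemporaneous feedback loops are
  projected onto acyclic structures, which can understate cross-domain
  intervention effects.
* **Single decision epoch.** One baseline, one follow-up, one intervention;
  no sequential policies.
* **Idealized interventions.** `do(d = healthy)` assumes a perfectly
  effective, side-effect-free intervention at follow-up; costs and partial
  efficacy are outside the utility as shipped.
* **Orientation multimodality.** Within-slice edge orientations can mix
  slowly at large n (see *Convergence*); presence probabilities and
  cross-time structure are robust to this, orientation probabilities less so.
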