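---
title: "Estimating significance thresholds for bootstrap edge confidences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating significance thresholds for bootstrap edge confidences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnstrength)
```

## The problem

Structure learning infers the graph of a graphical model — here a discrete
Bayesian network — from data. A single learned graph carries no measure of
how robust each edge is to sampling noise, so the standard remedy is
bootstrap model averaging: resample the data with replacement $m$ times,
learn one structure per replicate, and record for every unordered node pair
$e_i$ its *confidence* (arc strength)

$$\hat{p}_i = \frac{1}{m}\sum_{b=1}^{m} \mathbf{1}\{e_i \in E_b\},$$

the fraction of replicate graphs containing the edge in either orientation.
With $N$ nodes there are $k = N(N-1)/2$ such pairs. The practical question
is where to cut: which confidences are large enough to call the edge
significant? Fixed cut-offs such as 0.8 or 0.95 are common, but they ignore
both the data and the learner, and high cut-offs in particular trade many
false negatives for few false positives.

## The estimator

Sort the confidences into the order statistic
$\hat{p}_{(1)} \le \dots \le \hat{p}_{(k)}$. A consistent learner given
unlimited data would learn the same structure on every replicate, so the
confidences would reach the *ideal configuration*: a vector of 0s (absent
edges) and 1s (present edges). Its CDF is a one-step function that equals
$t$ — the fraction of non-significant edges — on $[0, 1)$ and jumps to 1 at
1. At finite sample sizes the empirical CDF $F_{\hat{p}}$ of the observed
confidences is a staircase in between.

The estimator chooses the $t$ whose ideal one-step CDF is closest to the
observed staircase in $L_1$ distance,

$$\hat{t} = \arg\min_{t \in [0,1]} \int \left| F_{\hat{p}}(x) -
F_{\tilde{p}}(x; t) \right| \, dx .$$

Both CDFs are piecewise constant, so the integral collapses to a weighted
sum of $|F_{\hat{p}}(x_i) - t|$ over the constant segments of the
staircase, with weights equal to the segment widths — computable in one
linear pass (`l1_distance()`). As a function of $t$ this is convex
piecewise-linear, and its exact minimiser is the **weighted median** of the
segment CDF values under those width weights; no numerical optimiser is
involved (`estimate_threshold()`). The estimated fraction is converted to a
confidence scale through the quantile function
$F^{-1}_{\hat{p}}(\hat{t}) = \inf\{x : F_{\hat{p}}(x) \ge \hat{t}\}$
(`cdf_quantile()`), and an edge is significant exactly when its confidence
is *strictly greater* than that cut-off. Because $\hat{t}$ depends on the
whole confidence vector, edges are not judged in isolation: a group of
edges with moderate confidences can be recognised jointly where a fixed
0.8-style cut-off would discard them all.

The $L_2$ distance (whose minimiser is the width-weighted mean) and the
$L_\infty$ distance (midrange) are available for comparison; $L_1$ is the
default because it does not inflate large deviations and so tolerates a
wide variety of staircase shapes.

A six-pair worked example, whose confidence table ships with the package:

```{r example}
conf <- read_strength(system.file("extdata", "example1_strength.tsv",
                                  package = "bnstrength"))
estimate_threshold(conf)
```

## The surrounding machinery

**Sampling and scoring.** `forward_sample()` draws i.i.d. observations by
ancestral sampling. Structures are learned by greedy hill climbing
(`hill_climb()`) over single-edge additions, deletions and reversals under
the BDeu score — the log marginal likelihood of the data under symmetric
Dirichlet priors whose total weight is the *equivalent sample size* `ess`.
BDeu is score equivalent: Markov-equivalent DAGs score identically (the
test suite verifies this exhaustively on four nodes), which is why
significance is assessed on the skeleton, with directions recovered
afterwards by majority vote over the bootstrap replicates
(`build_averaged_network()`; exact ties are flagged undirected).

**Thresholding is learner-agnostic.** `bootstrap_confidences()` accepts any
function `(data, seed) -> bn_graph`; `hc_learner()` is the shipped default.
Confidence tables can also be read from TSV (`read_strength()`), so
thresholds can be estimated for confidences produced by any external
learner.

**Noise floor.** As an alternative cut-off, `noise_floor()` permutes every
column independently (destroying all dependence, preserving marginals),
learns one structure per permutation replicate, and records how often each
pair appears; `select_by_noise_floor()` keeps edges whose bootstrap
confidence strictly exceeds the maximum floor. One structure is learned
per permutation replicate (not a nested bootstrap); this is the cheaper of
the two readings of the original recipe and is the package's documented
interpretation.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `m` | 500 | bootstrap replicates; 200 gives very similar confidences at half the cost, and the simulation harness uses 100 at desk scale |
| `ess` | 10 | BDeu prior weight; larger values smooth CPT estimates and are known to favour denser graphs |
| `max_parents` | unbounded | runtime guard for dense problems only |
| `restarts` | 0 | plain greedy search by default; restarts mitigate local optima at a linear cost |
| `permutations` | 100 | noise-floor replicates; the floor is a maximum, so it stabilises quickly |
| `avg_neighbours` | — | expected degree of generated fixtures; 2.3–3.8 matches the classical benchmarks' 1.17–1.92 edges per node |
| `cpt_concentration` | 0.25 | symmetric-Dirichlet concentration for fixture CPT rows; 0.25 reproduces the strongly informative rows of the classical benchmarks (binary rows: mean max-probability ≈ 0.88, majority above 0.9), whereas 1 (uniform on the simplex) yields much weaker dependencies than any published benchmark |

## Numerical and convention choices

* **Right-continuity.** The empirical CDF uses the right-continuous
  convention ($F(x)$ counts values $\le x$), which is what makes the
  worked example's cut-off land on the third jump point.
* **Flat optima.** $L_1(t)$ can be minimised on a closed interval (when a
  cumulative segment weight hits exactly $1/2$); the midpoint is returned.
* **Quantile at 0.** $\inf\{x : F(x) \ge 0\}$ is $-\infty$ over the reals;
  0 is returned, the infimum of the confidence scale. Combined with the
  strict selection rule this gives the correct degenerate limits: all-ones
  confidences select everything, all-zeros select nothing.
* **Strictness.** The selection rule is strictly greater-than throughout,
  including the noise-floor rule; results also report the equivalent
  "minimum significant confidence" for readability.
* **Determinism.** Every stochastic operation takes one integer seed;
  nested draws (bootstrap replicates, permutation replicates, simulation
  cells) use seeds derived from the master seed by sampling without
  replacement, so replicates are order-independent and each recorded cell
  can be reproduced in isolation. Hill-climbing ties are broken by
  canonical move order (lexicographic pair; addition, then deletion, then
  reversal) and search starts from the empty graph.
* **Degenerate inputs.** Empty datasets score 0 under BDeu (the Gamma
  terms cancel); `n = 0` sampling yields a typed empty dataset;
  single-valued confidence vectors produce all-or-nothing selections.

## The fixture generator, and what passing tests do not show

`random_network()` emulates the *shape* of the classical discrete
benchmarks: a sparse DAG with a chosen average degree, multinomial nodes,
and strongly informative Dirichlet CPT rows. It does not emulate their
semantics — no latent clinical structure, no deterministic logic nodes, no
shared parameters — and real molecular data add measurement noise,
normalisation artefacts and unmeasured confounders that no fixture here
represents. Passing the simulation harness therefore shows that the
estimator behaves as designed *given* a learner whose confidences separate
signal from noise; it does not certify recovery rates on experimental
data.

One scale-down effect deserves emphasis. The published benchmarks are
large and sparse: their true edges are 7–15% of all possible pairs, so
specificity denominators are in the hundreds and a handful of spurious
edges barely dents specificity — this is precisely why near-1 specificity
is reported there. A 10-node fixture with the same *per-node* density has
~29% of its pairs as true edges; each spurious edge then costs about 3% of
specificity. Moreover, with strongly informative CPTs, greedy hill
climbing under BDeu (`ess = 10`) retains several score-justified extra
edges even at $n = 5000$ (restarted search finds structures scoring above
the true DAG that keep most of them). At this scale those extra edges
carry confidence near 1, so *no* thresholding policy — estimated or ad hoc
— reaches 0.9 specificity, and the estimated threshold, which is
deliberately more liberal than a 0.95 cut-off, shows a larger specificity
gap than it does on large sparse networks. The simulation harness in the
test suite runs at sizes $n \in \{100, 500, 2000, 5000\}$ with $m = 100$
and 10 repetitions on a 10-node fixture; the sensitivity trends (increasing
in $n$; the estimated threshold dominating high ad hoc cut-offs at small
$n$) reproduce cleanly, while the close-to-1 specificity figures should be
read as a property of large sparse networks, not of dense miniatures.

## Known limitations

* Greedy hill climbing has no optimality guarantee; one of the fixed
  3-node test problems is a verified single-move local optimum, and the
  test suite asserts exactly that.
* BDeu's `ess` controls sparseness; `ess = 10` (the conventional choice
  used throughout) is on the dense side for small samples.
* Complete data only; rows with missing values are rejected, not imputed.
* Discrete networks only; the threshold estimator itself is
  distribution-free and applies to any confidence vector via
  `read_strength()`, but no Gaussian learner ships here.
* No confidence intervals on $\hat{t}$ are provided; its sampling
  variability is substantial and does not shrink much with $n$, which is
  one more reason to prefer it over a fixed cut-off only jointly with the
  whole confidence vector.
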