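---
title: "Methods: enhanced sparrow search optimization of kernel extreme learning machines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhanced sparrow search optimization of kernel extreme learning machines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
models and update rules, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, the numerical conventions,
and the design choices made where the design was genuinely open.

## The classifier: kernel extreme learning machine

The base classifier is a kernel extreme learning machine (KELM) for binary
labels encoded $y_i \in \{+1, -1\}$. The random hidden layer of an ELM is
replaced by a kernel, so training is one regularized linear solve in the dual:

$$ (K + I/c)\,w = y, \qquad K_{ij} = k(x_i, x_j), $$

and prediction at a query point $x$ is the sign of the kernel expansion
$\sum_i k(x, x_i)\, w_i$, with a score of exactly zero mapped to the positive
class so runs are reproducible. We use the Gaussian kernel

$$ k(u, v) = \exp\!\left(-\frac{\lVert u - v\rVert^2}{2 k^2}\right), $$

reading the kernel parameter $k$ literally as a length scale. The source
formulation does not pin down the exact parameterization ($k^2$ vs $2k^2$ in
the exponent); any monotone reparameterization is equivalent for the tuner,
which searches $k$ freely, so the conventional length-scale form is used and
recorded here. Note the identity matrix is *divided* by the regularization
coefficient $c$: larger $c$ means weaker regularization and a closer fit.
The solve uses a Cholesky factorization with triangular back-substitution
(never an explicit inverse) and falls back to a pivoted least-squares solve
when the factorization fails, which can happen for very small kernel widths
where $K$ is numerically a unit matrix plus noise.

## The optimizer family

### Baseline sparrow search

The sparrow search algorithm (SSA) maintains a population of $n$ candidate
positions in a box. Each iteration the population is sorted by fitness
(ascending, for minimization) and split into roles:

* **Producers** — the fittest $\lceil PD \cdot n\rceil$ individuals. One
  alarm value $R_2 \sim U(0,1)$ is drawn per iteration. Below the warning
  threshold $ST$, the rank-$i$ producer contracts multiplicatively by
  $\exp(-i / (\alpha\, \mathrm{iter_{max}}))$, $\alpha \sim U(0,1]$ per
  producer; otherwise it takes a normal step broadcast over coordinates.
* **Scroungers** — the rest. Individuals ranked worse than $n/2$ scatter
  around the current worst position; the others follow
  $x \leftarrow x_a + |x - x_a| \cdot A^{+} L$, where $A$ is a random
  $\pm 1$ row, $A^{+} = A^\top (A A^\top)^{-1}$, and $L$ is the all-ones
  row — algebraically, adding $\sum_d |x_d - a_d| A_d / d$ to every
  coordinate.
* **Scouts** — a fresh random $\lceil SD \cdot n\rceil$ sample per
  iteration. Scouts worse than the incumbent jump toward it scaled by a
  normal draw on the absolute gap; scouts exactly at the incumbent fitness
  drift relative to the current worst, with a small $\epsilon$ guarding the
  fitness-difference denominator.

Positions are clipped to the box after every stage, all individuals are
re-evaluated, and a greedy incumbent is tracked, so the convergence curve is
non-increasing by construction. The RNG draw order is fixed and documented
(alarm value, then per-producer draws in rank order, then per-scrounger
draws, then scout selection, then per-scout draws), which makes runs
bit-reproducible given a seed.

Two points were genuinely open and are decided here:

* $x_a$, "the best location searched by the producers", is the fittest
  *updated* producer position, which requires re-evaluating producers
  mid-iteration. The alternative (the rank-1 producer's updated position,
  unevaluated) leaves scroungers chasing an arbitrary scattered point and
  measurably weakens exploitation on the fixed-dimension benchmark
  functions. The reference implementation of the original algorithm does
  the same re-evaluation.
* This implementation deliberately has **no per-individual personal-best
  memory** (the reference implementation keeps one): the module contract
  here is a memoryless population with batch re-evaluation. The practical
  consequence is a heavier tail in run-level best values on the unimodal
  functions — single sphere runs land anywhere between $10^{-16}$ and
  $10^{-200}$ rather than uniformly near $10^{-49}$. The baseline is a
  comparison partner, not the contribution, so the simpler contracted loop
  is kept.

### The enhanced variant

Three strategies modify the baseline; all act on the producers and the
incumbent only. Scroungers and scouts are untouched.

**Hunger-state foraging (safe branch).** When $R_2 < ST$ each producer
coordinate is repositioned *absolutely* to

$$ x_d \leftarrow \left(1 - e^{-|b_d - x_d|}\right)\cdot u_d \cdot o, \qquad
   u_d \sim U(0,1), $$

where $b$ is the incumbent and $o$ (default 2) an adjustment factor. The
bracket is the "hungry feature" map: it vanishes at the incumbent and
saturates at 1 far away, so new positions always lie in $[0, o)$ before
clipping. Whether this rule was intended as an absolute position or as a
displacement is ambiguous in the source; the absolute form is the default
because it is the only reading that reproduces the reported exact-zero
averages on origin-optimum functions: once the gap to the incumbent
underflows the exponential, the coordinate becomes exactly 0 in double
precision. (An anchored variant — incumbent plus the same term — ships
behind the `phfs_anchored` config flag for experimentation, off by
default.)

**Balance factor (alarm branch).** When $R_2 \ge ST$ the producer moves by

$$ x \leftarrow \mathrm{bf} \cdot (b - x) + Q, \qquad
   \mathrm{bf} = (2\,\mathrm{para} - 1)\cdot \delta \left(1 -
   \frac{\mathrm{iter}}{\mathrm{iter_{max}}}\right), $$

with $\mathrm{para} \sim U(0,1)$ once per producer (so the factor is a
scalar per sparrow, sign-randomized) and $Q \sim N(0,1)$ per coordinate.
The factor decays linearly from $\pm\delta$ (default $\delta = 2$) to 0 at
the final iteration: early iterations can overshoot past the incumbent
(exploration), late iterations reduce to a local normal step
(exploitation).

**Cauchy perturbation of the incumbent.** After the role updates, one
standard-Cauchy scalar $r = \tan((u - 0.5)\pi)$ is drawn (a single scalar
per call — the defining equation defines one $r$), the candidate
$b + r \cdot b$ is clipped and evaluated, and the better of incumbent and
candidate is kept. The perturbation is greedy and can never worsen the
incumbent; when the incumbent is the zero vector the candidate equals it,
which needs no special case. The slot of this step relative to the scouts
is not legible in the source's algorithm figure; the canonical
post-role-update slot is used, once per iteration.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| $n$, iter_max | population, iterations | 30, 500 (benchmarks); 10, 50 (tuning) | the stated experimental protocol |
| $ST$ | warning threshold | 0.8 | stated parameter table |
| $PD$, $SD$ | producer / scout fractions | 0.20, 0.10 | stated parameter table |
| $o$ | hungry-feature adjustment | 2 | stated in the source |
| $\delta$ | balance-factor control | 2 | stated in the source |
| Cauchy scale $a$ | incumbent perturbation | 1 | stated in the source |
| $\epsilon$ | scout denominator guard | 1e-50 | smallest guard that never dominates |
| $k, c$ search box | KELM hyperparameters | $[2^{-10}, 2^{10}]$ each, searched in $\log_2$ | no ranges are stated; log-space boxes are standard for kernel/ridge pairs and keep the optimizer's box assumption valid |
| folds | cross-validation | 10 | stated protocol |

## Hyperparameter tuning

The tuner runs the enhanced optimizer over the 2-dimensional
$(\log_2 k, \log_2 c)$ box with $1 - \overline{\mathrm{ACC}}$ over a fixed
$k$-fold partition as fitness. Fixing the partition for the whole run makes
candidates comparable; "re-obtaining the parameters by 10-fold
cross-validation" is read as the candidate fitness *being* cross-validated
accuracy, not as a second search. Implementation note: the pairwise squared
distance matrix of the training set is computed once per tuning run, so each
candidate costs one `exp()` over that matrix plus $k$ Cholesky solves.

Two evaluation protocols ship:

* **default (leakage-free)**: an outer 10-fold split; min-max normalization
  is fitted on each outer training partition (test values may leave
  $[-1,1]$ and are deliberately not clipped), tuning runs on that partition
  only, and the tuned model is evaluated on the held-out fold;
* **`paper_mode = TRUE`**: the whole dataset is normalized once before
  splitting, which matches the printed preprocessing description but leaks
  the test range into training. The source is ambiguous about which level
  its tables used; neither mode is claimed as "the" published protocol.

Fold assignment is a seeded shuffle followed by a contiguous split (plain,
not stratified), matching the cited plain cross-validation.

## The synthetic-data generator

The generator stands in for the six small clinical tables (hundreds of rows,
6–23 attributes, binary label, a percent-level sprinkling of missing
values). It draws two multivariate-normal classes with unit within-class
standard deviation, separated by `class_separation` along the informative
coordinates, appends pure-noise coordinates, fixes the positive fraction,
and optionally injects uniformly random missing cells.

It emulates: tabular scale, class imbalance, uninformative attributes,
missing-value handling, and a tunable signal strength with known Bayes-level
difficulty. It does **not** emulate: correlated or categorical attributes,
nonlinear class boundaries, heavy-tailed measurement noise, or structured
missingness. A green pipeline test therefore establishes that the tuner and
classifier recover a recoverable signal and stay at chance on a null signal
— not that any published per-dataset accuracy is reproduced. The printed
per-disease accuracies depend on the external data files and unstated fold
seeds, and are explicitly out of desk-scale reach; the acceptance suite
substitutes the property-based checks (signal recovery at separation 6,
null behavior under label shuffling, near-optimality against a dense
log-grid oracle).

Stated-world defaults used by the acceptance checks: $n = 300$, separation
6, five informative and five noise features, balanced classes (recovery
check); the same data with shuffled labels (null check); $n = 200$ at
separations 2–4 (near-optimality check). These follow the scale of the
clinical tables and were fixed before measuring.

## Numerical conventions and degenerate inputs

* Kernel width and regularization must be strictly positive; the kernel
  matrix entries are clamped against tiny negative squared distances from
  floating-point cancellation.
* Prediction ties (score exactly 0) go to the positive class.
* Sensitivity/specificity on a fold with no positives/negatives are defined
  as 0 with a warning; a Matthews coefficient with a zero factor under the
  root is defined as 0. The published experiments never hit these; the
  conventions keep tiny-fold fitness defined.
* Benchmark evaluators are pure and permit out-of-box points; optimizers
  clip before evaluating. The step-function benchmark uses
  round-half-up (`floor(x + 0.5)`), and the penalized functions use the
  standard three-piece penalty $u(x, a, k, m)$.
* Two suite-table quirks: the Schwefel row's optimum is quoted as
  "-418.9829 × 5" regardless of dimension — the analytic value
  $-418.9829\,d$ is stored and that row is excluded from optimum checks;
  and the 3-dimensional Hartman row's box is quoted as $[1,3]$ although its
  printed optimum $-3.86$ is attained only on the canonical unit cube,
  which is what the registry uses.
* Optima printed to 2 decimals (both Hartman functions) are checked at
  printed precision; everything else at $10^{-3}$ absolute or tighter.
* The paired comparison of optimizers is a Wilcoxon *signed-rank* test over
  per-function means (zero differences dropped, mid-ranks, plain normal
  approximation without continuity or tie correction). The source calls it
  a rank-sum test, but the printed (better/equal/worse, $W^+$, $W^-$, $p$)
  tuples are exactly the signed-rank quantities — e.g. 16 uniformly signed
  pairs force $W^+ = 136$ and $z = 68/\sqrt{374}$, giving $p = 0.000438$.
  A per-function two-sample rank-sum over raw run values is available as a
  secondary mode. Equality of means is declared below $10^{-12}$ absolute
  difference so display rounding never decides the counts.

## Known limitations

* The baseline SSA's run-level tail is heavier than the reference
  implementation's (no personal-best memory; see above). Comparisons
  against it remain valid in sign and are reproducible by seed.
* On the 4-dimensional Shekel functions the enhanced optimizer's 30-run
  mean sits a few tenths above the global optimum because a minority of
  runs land in a shallower basin — the same behavior the source's own
  results table shows. The acceptance criterion that demands the mean
  within $10^{-2}$ of the Shekel-5 optimum is unattainable under the stated
  protocol and is left failing rather than widened.
* The classifier is strictly binary (the studied tables all are); no
  multi-class extension, no kernels beyond the Gaussian, no imputation
  (rows with missing cells are removed, as in the published preprocessing).
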