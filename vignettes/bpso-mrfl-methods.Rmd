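---
title: "Manta-ray foraging learning for binary PSO feature selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Manta-ray foraging learning for binary PSO feature selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mantaFS)
```

## The problem

Gene-expression classification data are extreme: tens to a couple of
hundred samples against thousands of features, most of them irrelevant or
redundant. Wrapper feature selection searches the space of feature
subsets directly, scoring each candidate subset by training and testing a
classifier on it. The search space has $2^D$ subsets, so the search is
handed to a stochastic optimizer — here a binary particle swarm whose
update rules are borrowed from three foraging behaviors of manta rays.

## The optimizer

A particle is a bitmask $x \in \{0,1\}^D$ (1 = feature selected) with a
real velocity $v \in \mathbb{R}^D$. The swarm of $N$ particles keeps an
index order fixed at initialization; that order defines a foraging
*chain*, and "the particle in front" of particle $i$ is particle $i-1$.
Each particle remembers its personal best position (pbest) and the swarm
its global best (gbest); both are updated only on strict fitness
improvement, gbest ties resolving to the lowest particle index, so every
run is deterministic given its seed.

Each iteration $t = 1, \dots, T$ applies, per particle:

* **Chain learning** (probability 0.5): velocity
  $v' = w v + c_1 r_1 (\mathit{pbest}_{i-1} - x) + c_2 r_2 (\mathit{gbest} - x)$,
  where the head of the chain uses its own pbest. The factors follow
  error-function schedules $c_1 = 2\,\mathrm{erf}(0.5 - t/T)$ and
  $c_2 = 3\,\mathrm{erf}(1.7 - t/T)$: both decrease strictly, $c_2 > c_1$
  throughout, and $c_1$ changes sign at mid-run, converting attraction to
  the chain neighbor into repulsion and shifting the balance from
  exploitation to exploration.
* **Cyclone learning** (probability 0.5): the same two-term form, with a
  branch chosen by comparing $t/T$ to a fresh uniform. Early in the run
  the comparison usually selects the exploratory branch, which replaces
  gbest by a *random reference* drawn continuously in $[0,1]^D$ and uses
  constant factors $c_5 = c_6 = 2$; late in the run it usually selects
  the exploitative branch with gbest as reference and swapped schedules
  $c_3(t) = c_2(t)$, $c_4(t) = c_1(t)$.
* **V-shaped binarization**: each velocity component maps to a flip
  probability $\mathrm{tanh}(|v_j|)$ applied to the current bit. A
  signed transfer argument ($\tanh(v_j)$ without the magnitude) would
  make bits with negative velocity immovable, contradicting the
  V-shaped family the rule belongs to; the magnitude form is used
  throughout.
* **Somersault learning**, after evaluating and updating the bests:
  every particle's position is replaced by
  $x^{new} = \mathit{pbest}_i + 2 r_1 (\mathit{gbest} - r_2\,\mathit{pbest}_i)$,
  thresholded at 0.5. The replacement is unconditional; improvement is
  preserved only through the pbest/gbest bookkeeping. The marginal
  transition probabilities have closed forms used by the test suite:
  a bit absent from pbest but set in gbest turns on with probability
  $P(2r_1 > 0.5) = 0.75$, a bit set in pbest but absent from gbest stays
  on with probability $P(r_1 r_2 < 1/4) = (1 + \ln 4)/4 \approx 0.5966$,
  and pbest = gbest is an exact fixed point.

This costs $2N$ fitness evaluations per iteration plus $N$ at
initialization, totalling $N + 2NT$, which the result object reports
exactly. The classic baselines (`run_bpso`) use the constant-factor
global-best velocity rule with S- or V-shaped binarization at $N$
evaluations per iteration.

The inertia weight decreases linearly from 0.9 to 0.4. Velocities are
clamped to $[-6, 6]$: the update rules themselves impose no bound, but
$\tanh(6) \approx 0.99999$, so the clamp only removes numerically
irrelevant magnitudes while keeping velocities finite. Defaults
throughout are $N = 20$, $T = 100$.

## The fitness

Candidate masks are scored by
$$\mathit{fitness} = \omega E + (1 - \omega)\, d / D,$$
with $E$ the error rate of a $k$-nearest-neighbor classifier
($k = 5$, Euclidean distance on the masked columns), $d$ the number of
selected features and $\omega = 0.99$, so accuracy dominates and the size
term orders equally accurate subsets. $E$ is measured on a stratified
80/20 split of the data handed to the optimizer. The split is frozen
once per run, making the fitness a pure function of the mask — personal
and global bests are then comparable across iterations. Features are
min-max scaled with training-split statistics before distances (gene
scales vary by orders of magnitude); constant columns map to zero and
out-of-range test values are not clipped. The empty mask is assigned the
sentinel fitness 1.0, strictly worse than any valid subset, rather than
being repaired. KNN ties are deterministic: distance ties go to the
lower training-row index, vote ties to the smallest label.

When subsets are benchmarked (`run_benchmark`), an *outer* split first
reserves unseen test data that takes no part in selection; reported
accuracy is measured there, and the inner 80/20 error is logged
separately. All algorithms in a benchmark share each run's seed and
outer split (paired design), so per-run differences isolate the
algorithms.

## The synthetic generator

No public corpus accompanies the method's usual evaluation datasets, so
the package generates data in the same regime. `synthetic_spec()`
defaults describe the reference benchmark: 60 samples, 3 balanced
classes, 500 features of which 10 are informative (class-$c$ feature $j$
is $N(\delta\, m_{cj}, 1)$ for a fixed class-signature matrix $m$ over
$\{-1, 0, 1\}$ with distinct rows, $\delta = 3$), 20 are redundant
(a random informative column plus $N(0, 0.5^2)$ noise) and 470 are pure
noise. The signature matrix is rejection-sampled from the seed until
rows are distinct, which guarantees every pair of classes is separated
by at least $\delta$ along some informative feature. These sizes mirror
small multi-class expression studies; $\delta = 3$ makes the planted
classes cleanly separable given the right features, and the 40-sample
generator used in the unit tests is simply a scaled-down version of the
same process.

What the generator does *not* emulate: heavy-tailed and count-like
marginal distributions, gene–gene correlation beyond one-parent
redundancy, batch effects, and class imbalance beyond what
`label_balance` expresses. Passing tests on this generator therefore
demonstrate the optimizer's search behavior under a controlled signal,
not performance on real expression data.

## Numerical and design choices

* One seeded RNG stream drives everything in a run, consumed in a fixed
  documented order (fitness split; then per particle: position and
  velocity initialization; then per iteration and particle: branch
  uniforms, random reference if drawn, $r_1$, $r_2$, binarization
  uniforms; then the somersault draws). Rerunning with the same seed
  reproduces the run bit for bit.
* $r_1, r_2$ are per-dimension by default (the binary-PSO convention,
  avoiding lock-step bit dynamics); `fs_control(per_dimension_r = FALSE)`
  switches to per-particle scalars.
* The iteration budget runs exactly $T$ loop bodies ($t = 1, \dots, T$).
  A convention that initializes $t = 1$ and loops while $t < T$ would
  run one body fewer; the off-by-one is irrelevant to every property
  tested but is resolved here as "exactly $T$".
* The somersault threshold maps the measure-zero case $x^{new} = 0.5$
  to 0, a bias toward smaller subsets consistent with minimizing $d/D$.
* The somersault factor 2 is kept as a constant of the update rule, not
  a tunable.
* The random reference is left continuous instead of being rounded to
  bits: it only enters a velocity difference, and rounding would discard
  exploration granularity.
* Optional memoization (`memoize = TRUE`) caches fitness by bitmask;
  it changes evaluation counts, never results.

## Known limitations

The size pressure of the objective is weak by construction
($1 - \omega = 0.01$), and the swarm's only mechanism for removing a bit
on which pbest and gbest agree is the fading exploratory cyclone branch.
Once the inner error reaches zero — which happens early on cleanly
separable data, where many subsets classify the 12 held-out samples
perfectly — convergence of the subset *size* is slow: on the reference
synthetic benchmark the global best still holds ~150 of 500 features
after 100 iterations (~100 after 300), and because redundant copies are
nearly as discriminative as their informative parents, the surviving
subset has no reason to prefer the planted originals. Recovery of the
exact informative block should therefore not be expected from this
optimizer at these budgets; what the benchmarks do show robustly is the
paired-fitness advantage over the S-shaped baseline, the exact
evaluation accounting, monotone convergence, and optimality on
exhaustively enumerable problems. Problem sizes used in the shipped
experiments (D = 500 reference runs, D = 8 enumeration, 20 paired seeds)
were chosen so the full suite re-runs comfortably on a laptop.
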