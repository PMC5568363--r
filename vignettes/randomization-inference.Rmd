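---
title: "Assumption violations, permutation inference and p-value error bounds in two-arm trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assumption violations, permutation inference and p-value error bounds in two-arm trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permtrial)
```

## The problem

Parametric analysis of a two-arm randomized trial rests on a chain of
assumptions: subject responses are independent and identically distributed,
the normalized difference of arm means
$z = (A_1 - A_0)/\sqrt{s_1^2/n_1 + s_0^2/n_0}$ is approximately standard
normal under the null, and the sample size is what the plan said it would be.
Each link can fail in ways that are invisible in the data: heterogeneity
across latent response categories, dependence between relatives or otherwise
clustered subjects, sample sizes that are in reality random, and the
randomization actually performed being ignored at analysis time.

`permtrial` makes each failure mode *constructible* — you simulate a
population in which the violation is present by design — and *measurable*:
the type-I error or power of a chosen p-value method is estimated by Monte
Carlo, and the distance between the parametric reference distribution and the
truth is bounded analytically.

## The population model

A cohort is a mixture of latent **response categories**, each with its own
response law per arm (any of six families, or a deterministic value — the
deterministic paradigm is a degenerate distribution, not a separate code
path). The category structure itself can be random: the number of categories
$K$ is drawn from a positive-integer law and the weights from a symmetric
Dirichlet. The package defaults are $K = 1 + \mathrm{Poisson}(\lambda)$ and
$\mathrm{Dirichlet}(\alpha = 1)$: the simplest laws with support on "a large
yet unknown number of categories" and fully random weights. Neither choice is
estimable from trial data, which is precisely the point; both are
configurable.

Dependence is induced constructively. Within a cluster (twins, siblings), a
normal response with mean $\mu$ and standard deviation $\sigma$ is generated
as
$$Y = \mu + \sigma\left(\sqrt{r}\,G_{\text{cluster}} +
\sqrt{1-r}\,E_{\text{subject}}\right),$$
which leaves the marginal law unchanged and gives every within-cluster pair
correlation exactly $r$. The construction is exact only for the normal
family; requesting $r > 0$ for a bounded family is an error naming the
family, because the additive effect would distort its marginal law.

Every subject's two potential outcomes are drawn once. Re-randomizing a
cohort never re-draws outcomes — this allocation-invariance is what makes
sharp-null permutation inference well defined.

## Trials and randomization

`trial_design()` supports complete-balanced, simple-coin and permuted-block
allocation, and four sample-size regimes (fixed; Poisson total; independent
dropout with retention $q$; event-driven, where an event is a control-arm
potential outcome exceeding a threshold — the observed arm is unknown before
allocation, so the control outcome is the natural event variable).

Two numerical choices deserve a note:

* **Partial permuted blocks.** When the subject count is not a multiple of
  the block length, the final partial block is the truncation of a random
  balanced block. Distinct truncated patterns are *not* equally likely, so
  the exact enumeration keeps duplicate truncations — the multiset carries
  the scheme's true probabilities, and exact p-values stay exact.
* **Randomization unit.** `randomization_unit = "cluster"` assigns intact
  clusters to arms (both twins together). An analysis that then treats
  subjects as independent underestimates $\mathrm{Var}(A_1)$ by the factor
  $1 + r$ for pairs. This is the mechanism of the package's
  dependence-distortion experiments: under subject-level randomization of
  correlated pairs, the within-arm variance inflation and the across-arm
  covariance cancel in $\mathrm{Var}(\Delta)$ on average, and simulation
  confirms the parametric test stays approximately calibrated — the
  distortion requires the allocation to respect the clusters. With $r = 0.5$
  pairs the predicted two-sided type-I error at nominal 0.05 is
  $2\Phi(-1.96/\sqrt{1.5}) \approx 0.11$, which the simulations reproduce.

## Four p-values

With observed responses held fixed (the sharp null: every subject responds
identically under either assignment), the package computes:

1. **Parametric**: the standard-normal tail of the observed $z$; refuses when
   a degenerate arm leaves $z$ undefined.
2. **Exact permutation**: the fraction of admissible allocations — of the
   scheme actually used, enumerated exactly — whose statistic is at least as
   extreme as observed. Ties count as extreme (conservative, keeps the test
   exact). The default statistic is $\Delta$, which is defined for every
   allocation; $z$ is available but undefined on degenerate allocations.
   Two-sided extremeness is $|\text{stat}| \ge |\text{observed}|$ by default,
   with a double-the-smaller-tail option.
3. **Monte-Carlo permutation**: `m` allocations sampled iid from the scheme,
   with the add-one estimator $p = (b+1)/(m+1)$, so $p$ is never 0 and
   validity is unconditional.
4. **Permutation-averaged parametric**: the mean over admissible allocations
   of each allocation's parametric tail p-value. Allocations with a
   degenerate arm are dropped and counted by default; imputing $p = 1$ is
   available (`degenerate = "one"`). The drop default reflects that a
   degenerate re-allocation simply has no parametric p-value to average; the
   report always discloses the count.

Exact enumeration switches to Monte-Carlo sampling beyond a configurable
limit (default $10^6$ allocations), flagged in the report.

## Berry–Esseen error bounds

For iid summands with moment ratio $C = E|X-\mu|^3/\sigma^3 \ge 1$, the KS
distance between the law of the standardized sample mean and the standard
normal is at most $0.5\,C\,n^{-1/2}$. Because a p-value is a tail
probability, its error is bounded by the KS distance of the statistic's law
from its normal reference, and for the difference of two independent arm
means the package uses the **sum** of per-arm bounds: for independent $U, V$
and any $t$,
$$|P(U+V \le t) - P(U'+V \le t)| \le \sup_u |F_U(u) - F_{U'}(u)|$$
(condition on $V$ and integrate), so replacing each arm mean by its normal
limit in turn costs at most $\varepsilon_1 + \varepsilon_0$. The sum is an
upper bound; its tightness is not claimed.

From this follow three calculators:

* `combined_pvalue_uncertainty()`: $[\max(0, p-\varepsilon),
  \min(1, p+\varepsilon)]$, with a flag when the interval contains the
  significance threshold.
* `guaranteed_decimal_digits()`: the largest $k$ with $\varepsilon \le 0.5
  \cdot 10^{-k}$ — the half-ulp reading of "correct after rounding". With
  $C = 1$ the combined bound reaches $0.05$ at exactly $n = 400$ per arm, so
  "a few hundred to a few thousand subjects" guarantees one decimal digit.
* `min_n_for_tolerance()`: the smallest equal per-arm $n$ with combined bound
  $\le$ tolerance; $0.005$ (keeping $\alpha = 0.05$ correct after rounding)
  gives $n = 40{,}000$ per arm. The tolerance interval is closed at 1 so the
  degenerate case (bound exactly 1 at $n = 1$, $C = 1$) returns 1.

The generalized bound for independent non-identical summands,
$\text{const}\cdot\sum\rho_3 / (\sum\sigma^2)^{3/2}$, uses a configurable
constant with default 0.56, since the classical 0.5 is stated only for the
iid case; both constants are surfaced in every report.
`empirical_ks_distance()` verifies the bounds by simulation; the lower bound
of 1000 replicates keeps the MC noise (about $0.5/\sqrt{\text{reps}}$) below
anything the bound comparisons care about.

## What the generator emulates — and what a green test establishes

The synthetic cohorts reproduce the *mechanisms* under study: latent-category
heterogeneity with random composition, exact equicorrelation within clusters,
random sample sizes, deterministic responses. They do not emulate real
clinical data: no covariates, no informative dropout (the dropout regime is
response-independent by design; informative censoring is named but
unspecified in the source critique and left unimplemented), no measurement
error, no biological fidelity in the shipped "dormancy-like" illustrative
config. A green operating-characteristics test therefore establishes that a
method behaves as claimed *under the stated mechanism*, not that any real
trial satisfies or violates the mechanism.

Scaled-down defaults: scenario grids stay desk-scale (n ≤ 2,000 subjects,
reps ≤ 20,000). In the acceptance suite the clustered permutation arm runs
4,000 replicates of an m = 199 Monte-Carlo randomization test instead of the
infeasible exact test over $\binom{200}{100}$ cluster allocations; its
validity band is computed at 4,000 replicates.

## Numerical choices and degenerate inputs

* Moment ratios use closed forms (normal, bernoulli/two-point, uniform) or
  quadrature at relative tolerance $10^{-12}$ (truncated normal); exact
  summation for tabulated laws. Quadrature round-off is clamped at the
  theoretical floor $C = 1$.
* Permutation tie comparisons use a relative tolerance of $10^{-12}$ so exact
  ties survive floating point.
* Vectorized per-allocation variances (one-pass sums) cancel catastrophically
  for near-constant arms; variances below $10^{-12}(1 + |m_1|^2 + |m_0|^2)$
  are treated as zero, and an allocation with a zero-variance arm is
  *degenerate*: it has $\Delta$ but no $z$.
* Random draws inside every exported operation run under a local seed; the
  caller's RNG state is restored, and `seed = NULL` draws from the current
  stream so nested simulations stay reproducible from one top-level seed.
* Between-replication irreproducibility is measured with one realized
  category composition per experiment replication — each replication models
  an independent trial program sampling its own realized population. Redrawn
  per-trial compositions would make rejections iid Bernoulli and hide the
  effect.

## Known limitations

* Dependence bounds: no Berry–Esseen analogue is offered for dependent
  summands, and no probability metrics beyond Kolmogorov–Smirnov are
  implemented (extension points, not features).
* The correlation construction covers the normal family only.
* No multi-arm designs, stratified randomization, adaptive stopping,
  confidence-interval inversion or multiplicity corrections.
* The 0.4·C·n^{-1/2} impossibility remark is documented here, not
  implemented: constructing extremal distributions is out of scope.
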