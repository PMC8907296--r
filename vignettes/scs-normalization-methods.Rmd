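---
title: "Shape-constrained spline normalization of clonal diversity: model and methods"
author: "scsEntropy authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-constrained spline normalization of clonal diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scsEntropy)
```

## The problem

In hematopoietic stem-cell gene therapy, each transduced clone is labelled by
its vector integration site (IS), and the Shannon entropy
$h = -\sum_i p_i \log p_i$ of the clone relative abundances is the standard
proxy for clonal diversity. The measured entropy, however, depends strongly
on technical variables: the amount of genomic DNA used for IS retrieval, the
vector copy number (VCN), the sequencing depth (SD, total reads of the IS
library) and, in pooled longitudinal designs, the pool size (PS, number of
animals contributing blood). Deeper sequencing and larger DNA input detect
more rare clones, so raw entropies from heterogeneous libraries are not
comparable.

`scsEntropy` removes these confounding effects by regression instead of
subsampling. Log-entropies are modelled as

$$\log h_i = \beta_0 + \sum_{k=1}^K \mathbf{C}^k_i \boldsymbol\beta_c^k
  + \sum_{j=1}^J \mathbf{F}^j_i \boldsymbol\beta_f^j + \varepsilon_i,
  \qquad \varepsilon_i \sim N(0, \sigma^2),$$

where each $\mathbf{C}^k$ is a B-spline basis in one technical confounder and
each $\mathbf{F}^j$ carries a factor of interest (e.g. lineage-by-vector
time decay). The confounder-free diversity is the rescaled entropy

$$h^{res} = \exp\!\big(\log h - \mathbf{C}\hat{\boldsymbol\beta}_c\big),$$

which deliberately keeps the factor terms: they are the biology.

## Shape constraints

Detection mechanics dictate the shape of every confounder effect: more DNA,
more vector copies or more reads can only reveal more diversity (monotone
nondecreasing), with diminishing returns (concave), and a plateau once
everything present has been found (saturation: zero slope at the right
boundary knot). Quadratic B-splines are the default degree. Boundary knots
sit at the observed minimum and maximum of each predictor, interior knots
are equidistant, and the basis is clamped (boundary knots repeated to
multiplicity degree + 1) so that it spans constants and evaluation is exact
at the boundaries. No extrapolation is performed outside the boundary knots.

For evenly spaced knots, monotonicity and concavity reduce to sign
conditions on raw coefficient differences (the `V` and `W` matrices of
`constraintMatrices()`; when both are imposed, all but the last monotonicity
row are redundant, giving the stacked matrix `Z` — verified by brute force
in the test suite). Clamped knot vectors are *not* evenly spaced at the
boundaries, and the raw second-difference condition there genuinely admits
convex fits: the slope attached to coefficient $j$ is
$(\beta_j-\beta_{j-1})/(k_{j+deg+1}-k_j)$ and the denominators shrink near
the boundary. The fitting therefore uses `basisConstraintMatrices()`, which
builds the concavity rows from these knot-spacing-aware slopes. The rows
reduce exactly to `W` for even spacing, and the redundancy argument
carries over unchanged (nonincreasing slopes plus a nonnegative last slope
make every slope nonnegative). This was a genuinely open design point: we
chose correctness of the stated shape over the literal uniform-spacing
matrices, and the package's property tests check the fitted curves directly
(first differences $\ge -10^{-8}$, second differences $\le 10^{-8}$ on a
1000-point grid).

Saturation is an equality constraint $\partial B(\xi_R)\beta = 0$ absorbed
by an affine transform $A$ that eliminates the last coefficient
(`saturationTransform()`); it is on by default for every confounder and can
be switched off per term. For longitudinal decay factors the steady state
is placed at the *second-right* distinct knot: the derivative is pinned to
zero at both ends of the final knot interval, which for a quadratic spline
(piecewise-linear derivative) makes the fit constant on that whole interval
— after the last pooled animal dies nothing more can change. Decreasing
terms are fitted by negating the block's design columns under the
increasing-shape cone, so "decreasing" keeps
concave-in-the-modelled-direction semantics and double negation is the
identity.

## Identifiability

A clamped B-spline basis spans constants, so every spline block competes
with the global intercept for the level. We anchor each shape-constrained
block by fixing its first coefficient to zero (dropping the first
transformed column): each effect is exactly zero at its left boundary knot
and the intercept carries the level. A centering convention was the obvious
alternative, but centering the columns annihilates precisely the constant
coefficient direction and leaves the quadratic program singular, while
anchoring keeps the cone geometry intact and makes coefficient
nonnegativity a consequence of monotonicity. Rescaled entropies are
therefore anchored at the left boundary: adding a constant to all
log-entropies moves only the intercept and multiplies all $h^{res}$ by a
common factor (a tested invariant). In the lineage-by-vector factor design
the same anchoring removes the vector-specific intercept — both treatment
arms start from the shared per-lineage baseline at the earliest time — and
per-lineage intercepts are reference-coded against the global intercept.

## Estimation

The constrained least-squares problem
$\min_\theta \|y - X\theta\|^2$ s.t. $G\theta \ge 0$ is a convex quadratic
program, solved with an active-set solver (`pracma::quadprog`) followed by a
KKT polishing step: the constraints active at the numerical solution are
treated as equalities and the fit is re-solved exactly on that face,
accepted when feasible and at least as good. Polishing makes the solution
reproducible to near machine precision and the landing face unambiguous;
the implementation is checked against exhaustive active-set enumeration on
random instances (max coefficient discrepancy $< 10^{-6}$).

The *cone-face dimension* $d$ — the number of independent directions
spanning the face the projection lands on, computed as the parameter count
minus the rank of the active constraint rows (tolerance $10^{-8}$, ties
resolved by a rank-revealing decomposition) — acts as the effective number
of parameters: the variance estimate is $\hat\sigma^2 = RSS/(n - 1.5d)$ and
$d$ is the $p$ in the information criteria.

Pointwise confidence intervals follow the cone-projection construction:
simulate responses around the fitted values with variance $\hat\sigma^2$,
refit, and record which face each projection lands on; the covariance
factor $\hat G$ is the face-probability-weighted average of the per-face
inverse information matrices, zero-padded outside the face span (on a face
spanned by coordinate directions this is literally $(X_I'X_I)^{-1}$ padded
with zeros). The default number of face simulations is 1000 with an
explicit seed (at least 100 is enforced); singular faces are skipped with a
warning and the weights renormalized. The interval uses $z_{\alpha/2}$
half-widths, i.e. conventional two-sided $1-\alpha$ coverage; source
descriptions of this construction sometimes phrase the coverage as
"$1-\alpha/2$", and we document the discrepancy rather than follow the
phrasing. Calibration is checked by simulation: with truth strictly inside
the cone, empirical coverage of the nominal 95% interval over 500 datasets
falls in $[0.90, 0.99]$.

## Model selection and averaging

Candidate models are all $2^K - 1$ nonempty confounder subsets, each keeping
the factor block. AICc
($-2\log L + 2p + 2p(p+1)/(n-p)$, Gaussian likelihood with profiled
variance, $p = d$) is reported for selection; BIC ($-2\log L + p\log n$)
drives the frequentist model-averaging weights
$\lambda_l = \exp(-BIC_l/2)/\sum_j \exp(-BIC_j/2)$, computed with
max-subtraction and interpretable as approximate posterior model
probabilities under a uniform prior. The averaged coefficient vector embeds
absent confounder blocks as zero, so the model-averaged rescaling is well
defined across subsets, and marginal inclusion probabilities are the
weight sums over subsets containing each confounder. The BIC uses $p = d$
for internal consistency with the AICc; exact marginal likelihoods
(Laplace or thermodynamic integration) are out of scope.

## Competitor normalizations

Rarefaction (RAR) subsamples every library without replacement
(multivariate hypergeometric, via `vegan::rrarefy`) to the total count of
the shallowest sample, 1000 replicates by default; the per-sample rescaled
entropy is the *mean* over replicates (a median would differ negligibly;
the aggregator is a documented choice). Scaling with ranked subsampling
(SRS) scales counts to the target, keeps integer parts, and fills the
deficit by descending fractional part with seeded uniform tie-breaking; the
output always sums exactly to the target and never inverts the input rank
order. Non-integer abundance estimates are rounded with a warning before
either method, which are defined on counts.

## Residual-confounding assessment

The efficiency of a rescaling method is measured by two-sided Spearman
rank-correlation tests between (rescaled) entropies and each confounder:
low p-values indicate unresolved confounding. Ties are handled by average
ranks; p-values are exact (full permutation distribution) for $n \le 9$
without ties and use the t-approximation otherwise — the exact branch is
validated against an exhaustive $7!$-permutation oracle. No
multiple-testing correction is applied across the method-by-confounder
grid; raw p-values are reported.

## What the synthetic data emulate

The generator reproduces the mechanisms the model is built for, with known
ground truth:

* **Transduction**: per-cell integration counts are Poisson(MOI); the
  untransduced fraction is $e^{-m}$. VCN is the mean integration count.
  Clone sizes are log-normal (sd 1) by default, giving realistic dominance;
  a uniform option exists for maximal-entropy checks.
* **Detection**: an IS library is a two-stage multinomial — a DNA aliquot
  samples `round(dna_ng * 152)` genomes (a diploid mammalian genome weighs
  about 6.6 pg, hence 152 genomes/ng; a documented constant, not a fitted
  quantity), then sequencing draws `depth` reads from the sampled genomes.
  Observed entropy rises with DNA and depth and saturates at the pool
  entropy.
* **In-vitro assay**: three MOI levels crossed with DNA amounts 5/20/100 ng
  and three technical replicates; sequencing depth scales with input DNA
  and VCN times log-normal pooling noise, so DNA, VCN and SD all confound
  the observed entropy — mirroring how library yield grows with template in
  real pooled sequencing.
* **Entropy-level simulation**: log-entropies drawn directly from the model
  with Michaelis–Menten effects $a\,x/(b+x)$ (monotone, concave,
  saturating by construction), default noise sd 0.1 on the log scale and
  default $n = 200$.
* **Mouse study**: pools of 2–3 mice per arm, monthly bleeds, earlier
  deaths in the genotoxic arm (so PS is nonincreasing and sampling stops
  with the pool), four lineages by two vectors (eight decay blocks), decay
  amplitudes steeper for the genotoxic vector except in the B compartment.

The generator does **not** simulate read sequences, PCR chemistry, IS
genomic-position biology, collision artifacts or abundance-estimation error
(e.g. fragment-length-based correction). Passing tests therefore show that
the estimator removes the confounding it models under correctly specified
shapes and Gaussian log-scale noise — not that it corrects every artifact
of real IS pipelines.

## Numerical choices and problem sizes

Active-constraint tolerance $10^{-8}$; KKT stationarity residuals are
checked below $10^{-7}$ in tests; degenerate predictors (constant
confounders), rank-deficient designs and $n \le 1.5d$ raise errors rather
than warnings. The test suite and the reproduction script use problem sizes
chosen to make the stochastic checks sharp yet quick: 100 seeded datasets
($n = 200$) for confounder removal, 50 seeds of a 27-sample in-vitro assay
with 400-cell pools and 50 rarefaction replicates for the competitor
comparison, 500 datasets with 100 face simulations each for CI calibration,
and $10^5$ draws for the constraint-reduction brute force. The package
defaults (1000 rarefaction replicates, 1000 face simulations) are larger.

## Limitations

Spline regression needs enough distinct confounder values to support the
basis: with only three distinct DNA amounts, one interior knot is the most
the design can carry, and a single sample cannot be rescaled at all without
parameters learned elsewhere. Errors are assumed independent Gaussian on
the log scale; longitudinal correlation within pools is not modelled.
Entropies of zero (single-clone samples) have no logarithm and are dropped
with a warning rather than pseudocounted. Penalized/smoothing variants are
intentionally not offered for the quadratic default.

## A worked example

```{r example}
et <- simulateEntropyDataset(n = 120, seed = 1)
model <- scsModel(list(scsTerm("dna_ng", 2), scsTerm("vcn", 2),
                       scsTerm("sd", 2)))
fit <- fitScs(et, model)
fit
hres <- rescaleEntropies(fit)
sapply(c("dna_ng", "vcn", "sd"), function(v)
  spearmanTest(unname(hres), et[[v]])$p_value)
```

High p-values mean no detectable residual dependence of the rescaled
entropies on any confounder.
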