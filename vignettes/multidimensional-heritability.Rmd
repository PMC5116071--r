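---
title: "Heritability of multidimensional traits: models, estimators and the shape-descriptor pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heritability of multidimensional traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiherit)
```

## The model

`multiherit` estimates how much of the variation of a *vector-valued*
phenotype is attributable to additive genetic effects. An M-dimensional
trait on N individuals, collected in an N×M matrix Y, is modelled as

$$Y = G + C + E,$$

where the three terms are matrix-normal random effects:
$\mathrm{vec}(G) \sim N(0, \Sigma_A \otimes K)$,
$\mathrm{vec}(C) \sim N(0, \Sigma_C \otimes \Lambda)$ and
$\mathrm{vec}(E) \sim N(0, \Sigma_E \otimes I)$. Here K is the genetic
similarity matrix (an empirical SNP-based GRM for unrelated samples, or
twice the kinship matrix in pedigrees), Λ encodes shared environment
(household membership), and Σ_A, Σ_C, Σ_E are M×M genetic, shared- and
unique-environment covariance matrices. Both the genetic effects and the
environmental factors may be correlated across trait dimensions.

Heritability is defined as the trace ratio

$$h^2 = \frac{\mathrm{tr}[\Sigma_A]}
             {\mathrm{tr}[\Sigma_A + \Sigma_C + \Sigma_E]},$$

the proportion of total phenotypic variance explained by additive genetic
variance. Two properties make this definition well behaved and are
enforced by tests rather than assumed:

* **Rotation invariance.** For orthogonal T, the trait YT has the same
  h² — the covariances transform as $T^\top \Sigma T$ and traces are
  invariant under conjugation by an orthogonal matrix.
* **Weighted-average decomposition.** h² equals
  $\sum_m \gamma_m h^2_m$ with $\gamma_m$ the share of component m in the
  total phenotypic variance. The multivariate h² is thus a
  variance-weighted average of per-component (or, after rotation,
  per-principal-component) heritabilities.

## The moment-matching estimator for unrelated samples

With unrelated individuals Λ vanishes and
$\mathrm{cov}[y_r, y_s] = \Sigma_{A,rs} K + \Sigma_{E,rs} I$. Regressing
each empirical cross-product matrix $y_r y_s^\top$ on (K, I) by ordinary
least squares — the multivariate generalisation of Haseman–Elston
regression — has the closed form implemented in `fit_moment_matching()`:

$$\hat\Sigma_A = \frac{Y^\top (K - \bar k I) Y}{v_K}, \qquad
  \hat\Sigma_E = \frac{Y^\top (\kappa I - \bar k K) Y}{v_K},$$

with $\bar k = \mathrm{tr}[K]/N$, $\kappa = \mathrm{tr}[K^2]/N$ and
$v_K = \mathrm{tr}[K^2] - \mathrm{tr}^2[K]/N$. The estimates are
unbiased; for M = 1 the estimator reduces exactly to the classical scalar
Haseman–Elston regression (the test suite checks this against a
brute-force elementwise OLS oracle). The estimator is reported clamped to
[0, 1]; the unclamped value is retained because the inference machinery
needs the raw statistic. When K has no relatedness contrast
($v_K/N < 10^{-8}\,\kappa$, e.g. K = cI) the estimator is undefined and
an error is raised rather than a garbage number returned.

Likelihood-based (REML) fitting of the *multivariate* model for unrelated
samples is deliberately out of scope: it is computationally expensive at
moderate M and the moment estimator with its analytic standard error is
what the downstream inference is calibrated for.

### Standard error

`sampling_variance()` applies the delta method to
$f(t) = t_A/(t_A + t_E)$. The covariance of the trace estimates is
simplified under two approximations that are standard for
unrelated-sample GRMs: off-diagonal entries of K are small (K ≈ I inside
the trace products), and the phenotypic covariance is replaced by its
empirical estimate. The result,

$$\mathrm{var}[\hat h^2] \approx \frac{2}{v_K}\,
  \frac{\mathrm{tr}[\hat\Sigma_P^2]}{\mathrm{tr}^2[\hat\Sigma_P]},$$

depends, given K, only on the sample size and the phenotypic covariance
structure. In eigenvalue form the ratio is
$\sum_m \lambda_m^2 / (\sum_m \lambda_m)^2$: it equals 1 for a scalar
trait (var = 2/v_K, the known scalar result), equals 1 iff the M
components are perfectly correlated, and equals 1/M for M independent
equal-variance components. Combining traits therefore never increases,
and usually reduces, the sampling variance — the main statistical payoff
of analysing a multidimensional descriptor instead of M separate scalars.
Monte-Carlo experiments in the acceptance suite confirm the empirical
spread of the estimator matches this approximation to within a few
percent at N = 500.

### Covariates

Fixed effects (X, an N×q full-rank design including the intercept) are
removed by rotating onto the null space of $X^\top$: with U any
N×(N−q) orthonormal basis satisfying $U^\top X = 0$,
`project_out_covariates()` replaces Y by $U^\top Y$ and K by
$U^\top K U$. The projected model has the same variance-component
structure, and all downstream estimates are provably independent of which
basis is chosen (the estimator depends on U only through
$UU^\top = I - X(X^\top X)^{-1}X^\top$); the test suite verifies this
with QR- and SVD-derived bases and with X-span noise injected into Y.
Rank-deficient covariates are rejected with the collinear columns named.

### Inference

Under the null h² = 0 the parameter sits on the boundary of its space, so
the Wald statistic $W = (\hat h^2/\mathrm{se})^2$ follows a half–half
mixture of a point mass at zero and $\chi^2_1$; `wald_test()` returns
$p = \tfrac12 P(\chi^2_1 \ge W)$, i.e. p = 0.5 at W = 0. The
nonparametric alternative, `permutation_test()`, jointly shuffles the
rows and columns of the (projected) similarity matrix and recomputes the
estimate, with the add-one convention
$p = (1 + \#\{\hat h^2_r \ge \hat h^2\})/(N_{perm}+1)$ — never exactly
zero, super-uniform under the null. Two conventions required decisions:

* Permutations are applied *after* covariate projection (shuffling K̃
  rather than re-projecting each permutation). This matches the notion of
  shuffling the genetic similarity structure while keeping the traits and
  their covariate adjustment fixed, and costs O(N²M) per permutation.
* Comparisons use the *unclamped* estimate, so boundary ties cannot
  distort the null distribution.

On well-powered simulated data the two p-values are nearly identical
(median absolute difference well below 0.05 at 1,000 permutations), which
is the practical check that the analytic standard errors are accurate.
Families of tests are adjusted by Benjamini–Hochberg FDR
(`fdr_adjust()`, a thin wrapper over `p.adjust`).

## Familial (twin/sibling) designs

With family structure, K = 2Φ and Λ are strongly correlated, which makes
the moment estimator inefficient; the package instead fits each trait
component by REML (`fit_ace_component()`): cov[y] = σ²_A·2Φ + σ²_C·Λ +
σ²_E·I with fixed effects profiled out. Kinship uses the twin-design
coefficients φ = 1/2 (MZ) and 1/4 (DZ and full siblings); Λ is 1 within a
family — twins and their non-twin siblings share the environment — and is
configurable through a `household` column. The restricted likelihood is
maximised on the log-variance scale (enforcing nonnegativity; components
driven to the boundary are reported as 0). Internally the likelihood is
evaluated block-wise: families are independent blocks and identical
family types share one small Cholesky factorization per evaluation, so a
400-subject twin study fits in well under a second without approximation.
An input with no relatedness contrast (K = I) leaves σ²_A unidentifiable
and is flagged rather than silently fitted.

Component fits are combined by `combine_components()` as a
variance-weighted average — the same decomposition that underlies the
trace-ratio definition, so for uncorrelated components the combined value
matches the multivariate definition. Uncertainty comes from the
family-block bootstrap (`block_bootstrap_se()`): whole families are
resampled with replacement to the original family count, everything is
refitted, and the standard deviation across replicates is the standard
error. 1,000 replicates is the publication-grade default; bootstrap
replicates in which no component converges are dropped and counted, since
retrying would bias the resampling distribution.

## The shape-descriptor pipeline

The package's motivating application is treating the *shape* of an
anatomical structure as a multidimensional trait. The descriptor is the
truncated Laplace–Beltrami spectrum ("Shape-DNA") of the structure's
boundary surface:

1. **Surface extraction** (`extract_surface()`): the binary-label
   isosurface at 0.5 is triangulated on the voxel-corner grid with
   outward winding — watertight by construction — and scaled to mm.
2. **Geometric smoothing** (`smooth_mesh()`, default 3 iterations):
   Taubin-style alternating λ/μ relaxation, which removes the voxel
   staircase while limiting the shrinkage of plain Laplacian smoothing.
   The tests verify that smoothing moves a voxelized ball's spectrum
   toward the analytic sphere spectrum.
3. **Spectrum** (`compute_spectrum()`, default 50 nonzero modes): linear
   FEM with the cotangent stiffness matrix and the *consistent*
   linear-element mass matrix (the Shape-DNA reference choice; a lumped
   mass is available behind a flag). The generalized eigenproblem
   A f = λ B f is solved by dense Cholesky reduction below ~700 vertices
   and by shift-invert block subspace iteration on sparse factors above.
   On a 10,242-vertex icosphere the first nonzero eigenvalue is within
   0.04% of the analytic value 2, with the spherical-harmonic
   multiplicities 1, 3, 5, … reproduced.
4. **Zero-mode removal and re-weighting** (`reweight_eigenvalues()`): a
   closed surface contributes one zero eigenvalue per connected component
   (threshold |λ| < 10⁻⁸·λ_{M/2}), which carries no shape information.
   Because eigenvalues of a 2D surface grow linearly in their index
   (Weyl's law) and their variance grows quadratically, the m-th nonzero
   eigenvalue is divided by m so that low and high modes contribute
   comparably to the phenotypic covariance.
5. **Volume normalization** (`volume_normalize()`): multiplying
   eigenvalues by η rescales the manifold by η^(−1/2), so multiplying by
   V^(2/3) maps every subject to a unit-volume shape. The exponent is
   verified by the scale-invariance test (descriptors of a shape and its
   uniformly scaled copy agree to 10⁻⁶) rather than assumed. The
   structure volume is kept as a covariate so heritability of shape is
   measured over and above size.
6. **Bilateral assembly** (`assemble_descriptor()`): left/right
   descriptors are concatenated (2M components) and their volumes
   averaged into one covariate; unilateral structures pass through. Which
   structures count as unilateral is configuration, not hard-coded.

Defaults of 50 eigenvalues and 3 smoothing iterations are the
standard operating point of this descriptor; both are exposed because
sensitivity analyses around them are a routine robustness check.

## Principal modes

`decompose()` and `pc_heritability()` rotate the (covariate-residualized)
descriptors onto their principal axes. Because PCA is a rotation and h²
is rotation invariant, the variance-weighted average of per-PC
heritabilities reproduces the multivariate estimate *exactly*; this
identity is the module's keystone test and holds to numerical precision
on every input. The PCs are computed on the projected data precisely so
that the identity is exact rather than approximate. The first PC carries
the largest variance weight and thus dominates the overall estimate;
image-space rendering of the principal mode (template registration,
probability maps) is out of scope — only the PC mathematics is provided.

## Synthetic data

All tests and the acceptance script run on synthetic data with known
ground truth: Hardy–Weinberg genotypes at uniform allele frequencies
(`simulate_genotypes()`), matrix-normal traits drawn via the factorization
$L_K Z L_\Sigma^\top$ so the NM×NM Kronecker covariance is never formed
(`simulate_traits()`), twin pedigrees (`simulate_twin_pedigree()`,
defaulting to an extended-twin design of 72 MZ + 69 DZ pairs, 253
siblings, 55 singletons), and analytic meshes with known spectra and
volumes (`make_test_mesh()`). What the generators deliberately do *not*
emulate: linkage disequilibrium, population stratification, assortative
mating, and realistic brain geometry. Passing tests therefore validate
the estimators under their own model assumptions — they do not certify
behaviour under model misspecification on real cohorts.

## Numerical choices and problem sizes

* GRM: allele-frequency-standardized cross-products with per-variant mean
  imputation of missing genotypes; monomorphic variants are an error
  (divide-by-zero guard) and should be removed by `qc_filter()`
  (call rate ≥ 0.97, MAF ≥ 0.01, HWE mid-p ≥ 10⁻⁶ by default; all
  thresholds configurable). The HWE test is a mid-p exact test, which is
  better calibrated at low minor-allele counts.
* Estimator guard: undefined when $v_K/N < 10^{-8} \kappa$.
* Eigensolver: subspace dimension k + max(10, k/2), shift
  σ ≈ 0.5·(trA/trB)·(k/n), eigenvalue convergence tolerance 10⁻¹⁰; the
  deterministic start vector makes spectra reproducible bit-for-bit.
* REML: Nelder–Mead on log σ² (relative tolerance 10⁻¹⁰), variance floor
  10⁻⁸·var(y) below which a component is reported as 0.
* Simulation scales used by the acceptance script — chosen as the
  smallest sizes at which the asymptotic approximations visibly hold:
  N = 500 / S = 5,000 / M = 5 with 500 trait replicates for recovery and
  calibration; 50 datasets × 1,000 permutations for Wald/permutation
  agreement; 200 twin studies of 100 MZ + 100 DZ pairs with 150-replicate
  bootstraps for the familial branch; a 10,242-vertex icosphere for
  spectral accuracy. Trait replicates share one genotype panel because
  both the estimator's unbiasedness and its analytic standard error are
  conditional on K — redrawing genotypes would test a different (and
  weaker) statement.

## Known limitations

* The analytic standard error inherits the K ≈ I approximation: in
  samples with appreciable cryptic relatedness it will be optimistic;
  the permutation test remains valid there.
* The ACE implementation covers twin/sibling structures (MZ/DZ/full-sib
  kinship); general pedigrees, dominance and multivariate REML are out of
  scope.
* Surface extraction assumes a filled, single-label structure; no
  non-manifold repair is attempted beyond degenerate-face rejection.
* Estimates from unrelated samples capture only variance tagged by the
  genotyped SNPs and are expected to sit below familial estimates of the
  same traits; on matched simulations the familial branch indeed returns
  systematically larger values.
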