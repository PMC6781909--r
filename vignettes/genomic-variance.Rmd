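---
title: "Predicting the random additive genomic variance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting the random additive genomic variance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The model and the quantity being predicted

`gblupvar` works in the standard whole-genome regression setting.  For $n$
individuals genotyped at $p$ biallelic markers with allele dosages
$x_{ij} \in \{0,1,2\}$, the phenotype model is

$$ y = \mu 1_n + PX\beta + \varepsilon, \qquad
   \beta_j \sim N(0, \sigma_\beta^2), \qquad
   \varepsilon \sim N(0, \sigma_\varepsilon^2 I_n), $$

where $P = I_n - 1_n 1_n^\top/n$ centres the genotype columns.  The
equivalent individual-level form is $y = \mu 1_n + g + \varepsilon$ with
$g = PX\beta \sim N(0, \sigma_g^2 G)$, $G = PXX^\top P/c$ the VanRaden
genomic relationship matrix, $c = 2\sum_j p_j(1-p_j)$, and
$\sigma_\beta^2 = \sigma_g^2/c$.  Fitting happens in the equivalent form
(it is $n$-dimensional); marker-level quantities are recovered exactly
afterwards.

The object of interest is the **additive genomic variance**

$$ s_{g,B}^2 = \frac{1}{n-1}\, g^\top B g
            = \frac{1}{n-1}\, \beta^\top X^\top P B P X \beta , $$

the sample variance of the genomic values ($B = I_n$, *current
population*) or of the decorrelated genomic values $g^* = R^{-1/2} g$
($B = R^{-1/2} P R^{-1/2}$, *base population*) for a relationship matrix
$R$.  Because $\beta$ is random, $s_{g,B}^2$ is a **random variable**, and
an estimator of it is really a predictor of a random target.  Two
predictors are implemented:

* **Unconditional expectation (V family).**
  $V_B = E[s_{g,B}^2] = \sigma_g^2\,\mathrm{tr}(BG)/(n-1)$; for $B = I$
  this is $\sigma_\beta^2\,\mathrm{tr}(\hat\Sigma_X)$ with
  $\hat\Sigma_X = X^\top P X/(n-1)$ the sample marker covariance.  This is
  the quantity GREML-style software reports.  Only the *diagonal* of
  $\hat\Sigma_X$ enters: the i.i.d. prior on $\beta$ makes
  $E[\beta\beta^\top]$ diagonal, so all marker covariances — linkage
  disequilibrium — are discarded.

* **Best predictor (W family).**
  $W_B = E[s_{g,B}^2 \mid y]
       = \mathrm{tr}(B[\mu_{g|y}\mu_{g|y}^\top + \Sigma_{g|y}])/(n-1)$,
  the conditional expectation given the phenotypes, which minimises the
  mean squared error of prediction among all functions of $y$ and is
  unbiased for the random target.  Here $\mu_{g|y} = E[g\mid y]$ is the
  BLUP and $\Sigma_{g|y} = \mathrm{Cov}(g\mid y)$.  The conditional second
  moment $E[\beta\beta^\top\mid y] = \mu_{\beta|y}\mu_{\beta|y}^\top +
  \Sigma_{\beta|y}$ is *not* diagonal, so every entry of $\hat\Sigma_X$ is
  weighted and LD contributes.

The two are linked by the exact decomposition $W_B = V_B + L(y)$, where

$$ L(y) = \sum_{j} M_{jj} (\hat\Sigma_X)_{jj}
        + \sum_{i \neq j} M_{ij} (\hat\Sigma_X)_{ij},
   \qquad M = \mu_{\beta|y}\mu_{\beta|y}^\top -
              \mathrm{Cov}(\mu_{\beta|y}). $$

`ld_contribution()` evaluates $L(y)$ as $W - V$ by default (exact,
$O(n^2)$, valid at any $p$) and keeps the explicit double sum — including
the split into the variance-weighted diagonal part and the LD-weighted
off-diagonal part — as the cross-checking route for panels small enough to
materialise $p \times p$ matrices (cap: 20 000 markers, configurable).
Note the sign convention: $L(y)$ weights use
$\mathrm{Cov}(\mu_{\beta|y})$ (the covariance of the BLUP), while
$\Sigma_{\beta|y} = \sigma_\beta^2 I - \mathrm{Cov}(\mu_{\beta|y})$ is the
conditional covariance; conflating the two flips signs, so both are
exposed separately by `marker_blups()`.

## REML fitting

`gblup()` uses spectral profile REML.  $G$ is eigendecomposed once,
$G = UDU^\top$; $y$ and $1_n$ are rotated into the eigenbasis; and for a
candidate variance ratio $\lambda = \sigma_g^2/\sigma_\varepsilon^2$ the
intercept and $\sigma_\varepsilon^2$ have closed-form profile solutions,
leaving a one-dimensional restricted log-likelihood in $\log\lambda$.
That function is scanned on a 200-point log-grid over
$\lambda \in [10^{-8}, 10^8]$ and the bracketing cell is refined with
derivative-free golden-section search to a tolerance of $10^{-10}$ in
$\log\lambda$.  With exactly two variance components this procedure is
exact (same surface as explicit-$V$ REML, verified against a dense
implementation in the tests), fast, and free of convergence pathologies;
$\hat\sigma_g^2 = 0$ is reported as a flagged boundary solution rather
than an error.

All conditional quantities use the REML projection
$Q = V^{-1} - V^{-1}1(1^\top V^{-1}1)^{-1}1^\top V^{-1}$, i.e. they
account for estimating the intercept: $\mu_{g|y} = \hat\sigma_g^2 G Q y$,
$\mathrm{Cov}(\mu_{g|y}) = \hat\sigma_g^4 G Q G$,
$\Sigma_{g|y} = \hat\sigma_g^2 G - \mathrm{Cov}(\mu_{g|y})$.  Under this
convention two identities hold at the REML optimum to machine precision,
and the package's validation leans on both:

* $W + \hat\sigma_\varepsilon^2 = \hat\sigma_y^2$: the best predictor and
  the residual variance partition the phenotypic sample variance exactly,
  which is what makes $\tilde h^2_W = W/(W + \hat\sigma_\varepsilon^2)$ a
  self-consistent heritability definition in the current population.
  (With the ML projection instead of $Q$ this identity degrades to
  $O(1/n)$.)
* With the GRM itself used for the base-population transform, the
  pseudo-inverse collapse $G^{-1/2} P\, G^{-1/2} = G^{+}$ (valid because
  $G1 = 0$) combined with the REML estimating equation makes
  $W_s^* = \hat\sigma_g^2 \cdot \mathrm{rank}(G)/(n-1)$ — numerically
  indistinguishable from $V_s^* = \hat\sigma_g^2$ whenever
  $\mathrm{rank}(G) = n-1$, i.e. whenever $p \ge n$.  Reported gaps
  between $V_s^*$ and $W_s^*$ from iterative general-purpose REML fitters
  are therefore convergence artefacts under this reading of the
  (singular) GRM transform; the supplied-$R$ route is the informative
  base-population analysis.

Heritability is deliberately defined only in the current population: the
residual variance is a property of the observed individuals and does not
transfer to the hypothetical unrelated founders, so `heritability()`
rejects base-population inputs.

## Base-population transform

`matrix_inv_sqrt()` computes $R^{-1/2}$ by eigendecomposition with
Moore-Penrose handling of rank deficiency: eigenvalues below
`rank_tol` $\times \lambda_{\max}$ (default $n \cdot$ machine epsilon,
standard pseudo-inverse practice) are inverted to zero.  For full-rank
$R$, $R^{-1/2}RR^{-1/2} = I$; for singular $R$ the product is the
orthogonal projector onto $\mathrm{range}(R)$, and raising the tolerance
can only lower the rank used (tested as a monotonicity property).  The
base-population marker matrix $X^* = R^{-1/2}PX$ is never formed at
marker dimension; all base-population traces are evaluated through the
$n \times n$ representation so that panels of hundreds of thousands of
markers remain feasible.

## The Bayesian route as an independent cross-check

`brr()` implements the Gibbs sampler for Bayesian ridge regression: the
same Gaussian prior on $\beta$, scalar conjugate-normal updates per
marker effect, a flat prior on $\mu$, and scaled-inverse-$\chi^2$ full
conditionals for the variance components.  Priors default to 5 degrees of
freedom with scales that split the phenotypic variance equally between
the genomic and residual sides — a common weakly informative choice; both
are configurable.  The posterior-mean variance
$M2 = \frac{1}{M}\sum_m \beta^{(m)\top} \hat\Sigma_X \beta^{(m)}$
(evaluated per draw as $\lVert PX\beta^{(m)}\rVert^2/(n-1)$) is the
Bayesian counterpart of $W$.  With the variance components *fixed* at the
REML estimates (`fix_vc`), the posterior of $\beta$ is exactly the
conditional Gaussian behind $W$, so $E[M2] = W$ exactly and the sampler
is a genuinely independent numerical route to the same number; without
fixing, variance-component uncertainty makes $M2$ differ from the plug-in
$W$ systematically, which is why the cross-check mode exists.  Default
chain settings (12 000 iterations, 2 000 burn-in, thinning 10) suit
desk-scale panels; Monte-Carlo standard errors are estimated by batch
means (20 batches), which stays honest under residual autocorrelation.

## What the synthetic-data generator does and does not emulate

`simulate_genotypes()` produces dosage matrices under two regimes.  The
`independent` model draws Binomial(2, $p_j$) dosages — Hardy-Weinberg,
linkage equilibrium.  The `ar1_haplotype` model builds each individual
from two independent haplotypes, each a first-order Markov chain of 0/1
alleles whose stationary marginal at marker $j$ is the simulated MAF and
whose adjacent-locus correlation is $\rho$; summing independent
haplotypes leaves the adjacent-marker *genotype* correlation equal to
$\rho$, giving the generator an analytic target that the sampling tests
verify.  This construction was preferred over thresholded multivariate
normals because it has exact $\{0,1,2\}$ support and a closed-form
correlation.  Transition probabilities are clipped into $[0,1]$; clipping
is inactive when neighbouring MAFs are similar, hence the default narrow
MAF band (0.1–0.5, uniform).

`simulate_phenotypes()` draws $\beta$ and $\varepsilon$ at user-chosen
$\sigma_\beta^2$ and $\sigma_\varepsilon^2$ and stores the *realised*
random target $s_g^2 = \beta^\top\hat\Sigma_X\beta$ (and $s_{g^*}^2$ when
a relationship matrix is attached), so predictor calibration can be
checked against the quantity actually realised in each replicate.
Validation defaults put $\sigma_g^2 = \sigma_\varepsilon^2 = 0.5$ — a
heritability of one half, typical of the traits this methodology is
applied to — by setting $\sigma_\beta^2 = 0.5/c$ for the simulated panel.
`make_relationship()` provides identity and block-family
compound-symmetry structures, PSD by construction.

What the generator does **not** emulate: coalescent-realistic LD decay,
allele-frequency/effect-size coupling, selection, population structure
beyond family blocks, genotyping error, and incomplete LD between causal
loci and markers (the gap between genetic and genomic variance).  Passing
tests therefore demonstrate correctness of the estimators under the
random-effects model's own assumptions, not robustness to violations of
them.

## Numerical choices and degenerate inputs

* Allele frequencies come from the sample, $\hat p_j = \bar x_{\cdot j}/2$,
  folded to the minor allele for the scaling constant (VanRaden
  convention); an external reference panel is not consulted.
* Monomorphic markers are dropped with a warning and recorded; an
  all-monomorphic panel is an error ($c = 0$).
* Missing dosages error by default; optional mean imputation keeps the
  centred column sum at zero and so perturbs no downstream identity.
* Dense $p \times p$ objects ($\hat\Sigma_X$, marker-effect covariances,
  the explicit LD sum) are materialised only below a 20 000-marker cap;
  every estimator also has an $n$-dimensional route, which is the default.
* Sample variances use the $n-1$ denominator throughout; there is no
  $n$-denominator option.
* Relationship matrices must be symmetric within $10^{-10}$ relative and
  PSD up to $-10^{-8}\lambda_{\max}$; the GRM is symmetrised explicitly
  after the cross-product to remove accumulation noise.
* Phenotype scaling to unit sample variance is an explicit flag
  (`scale_phenotype`), never silent; under it the variance estimates read
  directly as heritabilities.

## Validation problem sizes

The shipped tests and the acceptance script regenerate everything from
code: identity checks on fixtures of 20–50 individuals; REML validated
against a $2\times10^4$-point independent grid search and a dense
explicit-inversion REML; variance-component recovery over 200 replicates
at $n = 500$, $p = 1000$; best-predictor calibration (unbiasedness for
the realised $s_g^2$ within Monte-Carlo error, MSE no worse than $V$)
over 500 replicates at $n = 300$, $p = 50$; Bayesian equivalence at
$10^4$ retained draws on a $50 \times 8$ fixture; and the
phenotypic-variance partition $|W + \hat\sigma_\varepsilon^2 -
\hat\sigma_y^2|/\hat\sigma_y^2 < 10^{-3}$ across 100 scaled fits.  These
sizes were chosen as the smallest at which the Monte-Carlo bands are
informative for the properties being asserted.

## Known limitations

Intercept-only fixed effects (general $X\gamma$ designs are out of
scope); a single genomic variance component (no multi-kernel or
dominance/epistasis terms); no standard errors for $W$ (none exist in
closed form; the Bayesian route provides posterior spread if needed); and
the GRM-based base-population transform inherits the interpretive caveat
discussed above — when a pedigree or external relationship matrix is
available, prefer it.
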