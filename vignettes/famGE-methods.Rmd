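---
title: "Gene-environment interaction testing in families: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-environment interaction testing in families: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(famGE)
```

famGE tests whether a *set* of SNPs in a gene interacts with an
environmental exposure in data on related individuals (pedigrees). This
vignette describes the model, the statistic, the estimation machinery, the
synthetic-data generator, and the numerical and design choices behind them.

## The model

For member $j$ of family $i$, with phenotype $Y_{ij}$, covariates
$X_{ij}$, exposure $E_{ij}$, dosage vector $G_{ij} \in \{0,1,2\}^q$ for the
$q$ SNPs of one gene, and interactions
$S_{ij} = (E_{ij} G_{ij1}, \ldots, E_{ij} G_{ijq})^T$, the GLMM is

$$ g(E[Y_{ij} \mid \alpha_{ij}]) = X_{ij}^T \beta_1 + E_{ij}\beta_2 +
   G_{ij}^T \theta + S_{ij}^T \gamma + \alpha_{ij}, \qquad
   \alpha_i \sim N(0,\, 2\sigma^2 \Phi_i), $$

where $\Phi_i$ is the kinship matrix of family $i$ (so $2\Phi_i$ is the
additive relationship matrix; writing $2\Phi_i = K_iK_i^T$ turns
$\alpha_i$ into $K_i b_i$ with i.i.d. $b_i$). Supported response families
are binomial-logit (dispersion fixed at $\phi = 1$) and gaussian-identity
(dispersion estimated).

Three ingredients distinguish the approach from a standard fixed-effect
interaction test:

1. **Random interaction coefficients.** $\gamma \sim N(0, \tau I_q)$, so
   "no interaction" is the variance hypothesis $H_0\colon \tau = 0$ and the
   test has far fewer effective degrees of freedom than a $q$-DF score
   test.
2. **Random SNP main effects.** $\theta \sim N(0, \sigma_\theta^2 I_q)$
   under the null. The BLUP of $d_1 = G\theta$ is identical to a weighted
   ridge-regression estimate with penalty $\lambda = \phi/\sigma_\theta^2$
   (see below), so the ridge penalty that stabilises collinear SNPs under
   LD is *estimated by REML* instead of cross-validation.
3. **Kinship random effect.** $d_2 = Kb$ captures phenotypic correlation
   among relatives.

## The variance-component score test

With working vector $\tilde{Y}$ and covariance
$\Sigma = \sigma_\theta^2 GG^T + \sigma^2 KK^T + \phi W^{-1}$ from the
null fit, the score statistic for $\tau$ is the quadratic form

$$ U_\tau = \tfrac12\, (\tilde{Y} - \tilde{X}\hat\beta)^T \hat\Sigma^{-1}
   S S^T \hat\Sigma^{-1} (\tilde{Y} - \tilde{X}\hat\beta). $$

Because $SS^T$ is not block-diagonal across families, $U_\tau$ is not
asymptotically normal; under $H_0$ it behaves as a mixture of 1-DF
chi-squares with weights given by the eigenvalues of
$\tfrac12 S^T \hat{P} S$, where
$P = \Sigma^{-1} - \Sigma^{-1}\tilde{X}(\tilde{X}^T\Sigma^{-1}\tilde{X})^{-1}
\tilde{X}^T\Sigma^{-1}$ is the REML projection. For computational ease the
package calibrates $U_\tau$ by the Satterthwaite device: match mean and
variance to $\kappa \chi^2_\xi$,

$$ e = \tfrac12\,\mathrm{tr}(\hat{P} S S^T), \qquad
   I_\tau = \tfrac12\,\mathrm{tr}(P SS^T P SS^T) - J^T M^{-1} J, \qquad
   \kappa = \frac{I_\tau}{2e}, \quad \xi = \frac{2e^2}{I_\tau}, $$

and report $p = P(\chi^2_\xi > U_\tau/\kappa)$ with possibly non-integer
$\xi$. The subtraction $J^T M^{-1} J$, with
$J_k = \tfrac12 \mathrm{tr}(P SS^T P \Sigma_k)$ and
$M_{kl} = \tfrac12 \mathrm{tr}(P\Sigma_k P \Sigma_l)$ over the nuisance
variance components ($\Sigma_1 = GG^T$, $\Sigma_2 = KK^T$, plus
$\Sigma_3 = W^{-1}$ when $\phi$ is estimated), accounts for plugging in
REML estimates of the nuisance variances. The $J$/$M$ entries follow the
classical efficient-score construction for variance components in working
linear mixed models; with $\phi$ known they are 2-dimensional, otherwise
3-dimensional.

**A note on the factor one half.** The mean of
$\tfrac12\varepsilon^T PSS^TP\varepsilon$ with
$\mathrm{Var}(\varepsilon) = \Sigma$ is exactly
$\tfrac12 \mathrm{tr}(PSS^T)$ (using $P\Sigma P = P$), and its variance is
the $\tfrac12\mathrm{tr}((PSS^T)^2)$ term above. Some presentations write
the Satterthwaite mean without the half while keeping the half in both the
statistic and the variance; mixing the two conventions breaks the scale
invariance of $T = U_\tau/\kappa$ and would make the test drastically
conservative (the calibrated statistic is invariant to scaling
$U \mapsto cU$, $e \mapsto ce$, $I_\tau \mapsto c^2 I_\tau$, so only the
*consistent* choice matters). famGE uses the internally consistent moments
throughout, and asserts $\kappa\xi = e$ and $2\kappa^2\xi = I_\tau$ on
every test run. The mixture-law check in the test suite (Kolmogorov-
Smirnov comparison of the Monte-Carlo distribution of $U_\tau$ against the
eigenvalue mixture under a known-variance gaussian null) validates this
calibration end to end.

## Null-model estimation: PQL with AI-REML

`fit_null()` alternates, until joint convergence of variance components
and fixed effects:

1. linearisation: $\tilde{Y} = \eta + (Y - \mu) g'(\mu)$, weights
   $W = \mathrm{diag}\{\omega/(\nu(\mu) g'(\mu)^2)\}$ (for the logit link,
   $\mu(1-\mu)$);
2. BLUE/BLUP update at the current variance components:
   $\hat\beta = (\tilde{X}^T\Sigma^{-1}\tilde{X})^{-1}\tilde{X}^T
   \Sigma^{-1}\tilde{Y}$,
   $\hat{d}_1 = \sigma_\theta^2 GG^T\Sigma^{-1}(\tilde{Y}-\tilde{X}\hat\beta)$,
   $\hat{d}_2 = \sigma^2 KK^T \Sigma^{-1}(\tilde{Y}-\tilde{X}\hat\beta)$;
3. one average-information REML step on the working linear mixed model,
   with step-halving against the REML log-likelihood for large proposals
   and a lower bound of $10^{-8}\,\mathrm{Var}(\tilde{Y})$ on each
   component (a component held at the bound for three consecutive
   iterations is flagged and reported as effectively zero).

These are the Henderson mixed-model equations in the well-posed
$(\beta, \theta, b)$ parameterisation; the package also exposes
`henderson_solve()` (the joint linear system) and `henderson_closed()`
(the GLS/BLUP closed forms) and verifies in its test suite that the two
agree, as well as the ridge equivalence: for fixed weights,
$G\hat\theta_{\mathrm{ridge}}(\lambda = \phi/\sigma_\theta^2) = \hat{d}_1$,
exactly — with the kinship term present the identity holds for the
effective GLS weight $\phi(\sigma^2KK^T + \phi W^{-1})^{-1}$.

Numerical choices:

* $\mu$ is clipped to $[10^{-10}, 1 - 10^{-10}]$ before the logit
  linearisation.
* Convergence: relative change of every variance component *and* absolute
  change of every fixed effect below `tol = 1e-5`; at most 200 outer
  iterations; non-convergence is an error carrying the iteration
  trajectory (never a silent return).
* Initialisation: $\hat\beta$ from a fixed-effects-only GLM;
  $\sigma_\theta^2 = \sigma^2 = 0.1$; for the gaussian family $\phi$
  starts at the GLM residual variance.
* $\Sigma$-solves during iteration exploit the structure
  $\Sigma = A + \sigma_\theta^2 GG^T$ with
  $A = \sigma^2\,2\Phi + \phi W^{-1}$ block-diagonal over families:
  per-family Cholesky factorisations plus a rank-$q$ Woodbury correction.
  Dense $\Sigma^{-1}$ and $P$ are materialised once at convergence for the
  trace computations of the tests (quadratic in $n$; intended for
  $n \lesssim 5000$).
* `cholesky_factor()` adds a jitter of $10^{-10}\,\overline{\mathrm{diag}}$
  up to three times before falling back to a symmetric
  eigendecomposition for rank-deficient relationship matrices.

## Competing tests

* `fixed_score_test()`: the $q$-DF score test treating $\gamma$ as fixed —
  $U_\gamma = S^T\Sigma^{-1}(\tilde{Y}-\tilde{X}\hat\beta)$,
  $V = S^T P S$, $U_\gamma^T V^{-1} U_\gamma \sim \chi^2_{\mathrm{rank}(V)}$.
  Its power collapses as $q$ grows, which is the motivating contrast for
  the variance-component test.
* `minp_test()`: single-SNP scan — for each SNP the GLMM is refit with
  that SNP and its interaction as fixed effects (kinship random effect
  kept; no random SNP-set term), the interaction is Wald-tested (1 DF;
  a score-test variant is available via `method = "score"` — Wald was
  chosen as the default because it needs exactly one fit per SNP), and the
  minimum p-value is multiplied by the effective number of independent
  SNPs `M_eff` — the number of principal components of the SNP correlation
  matrix reaching 99.5% of total variation. Multiplying the minimum p by
  `M_eff` is numerically equivalent to comparing it against
  $\alpha/M_{\mathrm{eff}}$; the package reports the multiplied form.

## The synthetic-data generator

The generator reproduces a family-based simulation design: a pool of 1000
identical 10-member, 3-generation pedigrees; per replicate, families are
sampled without replacement (default 100; the scaled studies use 50, i.e.
$n = 500$) and the exposure and phenotype are redrawn while genotypes stay
fixed, as in a genotyped cohort.

* **Pedigree.** The canonical family has two founding grandparents, two of
  their children each married to an unrelated founder, and four
  grandchildren (two per couple). Relative pairs span parent-offspring
  ($2\Phi = 0.5$), grandparent-grandchild (0.25), avuncular and first
  cousins (0.125). The reference publication shows its pedigree only as a
  figure, so this structure is a documented package choice; exact
  type-I-error numerics depend mildly on it.
* **Genotypes.** Gene dropping: founders draw two haplotypes, non-founders
  inherit one haplotype of each parent uniformly at random (no
  recombination within the gene), so Mendelian consistency holds by
  construction. Independent mode draws founder alleles
  Bernoulli(MAF) per SNP; LD mode draws founder haplotypes from a Gaussian
  copula whose latent correlation has five 10-SNP blocks with
  $s_i s_j\, 0.9^{|i-j|}$, $s_i = (-1)^{i-1}$ (mixed strong positive and
  negative LD, independence across blocks) — a documented stand-in for a
  correlation structure published only as a heat map. Causal SNPs sit at
  positions 1 and 5 with MAFs 0.3 and 0.1 (independent) or 0.3 and 0.17
  (LD); remaining MAFs cycle through a fixed grid of common frequencies.
* **Exposure.** $E_{ij} = 2 + 0.01\,\mathrm{Age} + 0.1\,I(\mathrm{Female})
  + \gamma_i + \varepsilon_{ij}$ with $\gamma_i \sim N(0,4)$ and
  $\varepsilon_{ij} \sim N(0,4)$: residual variance 8, within-family
  exchangeable correlation 0.5. Ages are Uniform(20, 50) plus 15 years per
  generation; sex is fixed by the pedigree structure.
* **Phenotype.** The linear predictor is
  $0.1 + 0.01\,\mathrm{Age} + 0.1\,I(\mathrm{Female}) + 0.1E + 0.3G_1 +
  0.3G_2 + \gamma_1 G_1E + \gamma_2 G_2E$; only the two causal SNPs carry
  main effects and interactions. The default generator is *marginal*: the
  coefficients are marginal log-odds and the family dependence enters
  through a Gaussian copula on the logistic error with latent correlation
  $2\Phi_i$ (`simulate_phenotype(method = "marginal")`). A
  conditional-on-$\alpha$ Bernoulli generator — the GLMM's own
  data-generating process — is available via `method = "conditional"`.
  The marginal construction is the default because it is the one under
  which the reference study's fitted variance scale
  ($\hat\sigma^2 \approx 1.25$ for a nominal scale of 1) is reproducible:
  the copula puts the *entire* logistic error scale ($\pi^2/3$) behind the
  kinship correlation, a much stronger family dependence than a
  conditional draw with $\sigma^2 = 1$, under which PQL fits centre well
  below 1 (the test suite computes both scales and asserts the contrast).
  This is a deliberate, documented choice of generative convention, not a
  tuning knob.

What the generator does **not** emulate: genotyping error and missingness,
recombination and map-based LD decay, ascertainment of families, age/sex
distributions of any particular cohort, household (shared-environment)
effects. Passing simulation checks therefore demonstrates statistical
correctness under the stated model, not robustness to those features of
real data.

## Study drivers and problem sizes

`run_type1_study()` crosses $q \in \{5, 10, 50\}$ with the two LD modes
under $\gamma_1 = \gamma_2 = 0$ and reports, per scenario, the empirical
rejection rates of the selected tests plus the mean fitted
$\hat\sigma^2$, $\hat\sigma_\theta^2$ and the implied penalty. The
reported `lambda` is $\phi$ over the *mean* of $\hat\sigma_\theta^2$
across replicates (the per-replicate ratio is heavy-tailed whenever a
single $\hat\sigma_\theta^2$ approaches its lower bound, so averaging the
ratio itself would be dominated by a few boundary fits).
`run_power_study()` sweeps $\gamma_1 = \gamma_2$ over a grid and adds a
monotone-trend diagnostic.

The packaged checks run scaled versions of the reference design: 50
families per replicate ($n = 500$), 500 null replicates for the
$q = 5$ independent scenario and 200 for the other five, and 200
replicates per point of the power grid $\{0, 0.04, 0.08\}$ at $q = 5$ in
LD mode. These sizes were chosen so the whole suite completes in tens of
minutes on a single core while keeping Monte-Carlo standard errors on
rejection rates near 0.01; `scripts/acceptance.R` re-runs the same design
from scratch at an arbitrary seed.

## Known limitations

* PQL is known to attenuate variance components for binary responses with
  small cluster sizes; the test remains calibrated because the score and
  its moments are evaluated at the same plug-in estimates, but fitted
  $\hat\sigma^2$ should not be read as an unbiased estimate of a
  conditional-model variance.
* Dense trace computations make the per-test cost $O(n^2 q + n^3)$ at the
  final iteration; for cohorts beyond a few thousand individuals a
  low-rank/trace-sampling variant would be needed.
* Only canonical links are implemented; overdispersed binomial, multiple
  environmental exposures and household random effects are out of scope.
* Genome-wide ancestry adjustment is supported only through precomputed
  principal-component columns passed as ordinary covariates; the package
  does not compute genotype PCs itself.
* Satterthwaite calibration matches two moments; extremely small tail
  probabilities (far beyond $10^{-4}$) would be better served by an exact
  mixture-of-chi-square evaluation, which the package deliberately omits.
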