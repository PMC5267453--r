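---
title: "Purity-aware methylation analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Purity-aware methylation analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MethylPurity)
```

## The problem

A solid tumor specimen contains a fraction $\lambda \in (0, 1]$ of
cancer cells mixed with normal stroma and infiltrating immune cells.
The beta value of a CpG site measured on a 450k-style array is a
per-molecule average, so the observed tumor methylome is a
$\lambda$-weighted blend of the cancer and normal methylomes. Two
consequences drive everything in this package:

1. at sites where cancer and normal differ strongly, the observed beta
   value carries direct information about $\lambda$;
2. ignoring $\lambda$ in tumor-vs-normal tests both attenuates effect
   estimates and inflates within-tumor variance, because samples with
   different purities genuinely have different expected values.

## Purity estimation

`select_idmcs()` screens CpG sites for use as purity markers
("informative differentially methylated CpGs", iDMCs) by a two-sided
Wilcoxon rank-sum test of tumor versus a normal control panel, keeping
sites whose tumor beta variance exceeds `var_min` and retaining the
`n_top` smallest p-values. The high tumor variance is itself a
signature of mixing: across samples with different purities, a true
iDMC sweeps a wide range of beta values.

For a tumor sample, `transform_idmc_betas()` flips hypo-methylated
iDMCs ($\beta \mapsto 1-\beta$) so that every iDMC reads out the cancer
fraction, and `density_mode()` takes the mode of a Gaussian kernel
density of those values as $\hat\lambda$. The mode, rather than a mean
or median, is robust to the minority of mis-selected markers and to
asymmetric contamination.

Parameter choices:

* `var_min = 0.005` (beta-scale variance) and `n_top = 1000` are the
  method's standard operating point; estimation is insensitive over a
  wide band of `n_top`, and `estimate_purity()` reports a diagnostic
  message when the density has substantial secondary modes so users can
  vary `n_top` and check stability.
* Bandwidth is Silverman's rule of thumb with a floor of 0.01 (beta
  units). The floor exists for degenerate inputs (for example a
  point-mass of identical values) where the rule collapses to zero; it
  is written out explicitly rather than through `bw.nrd0()`, whose
  internal fallbacks would otherwise replace a zero bandwidth with a
  data-location-dependent value.
* The density is an unbounded Gaussian KDE evaluated on 1001 equispaced
  grid points of $[0,1]$ (resolution $\approx 0.001$ purity), without
  boundary correction; the estimate is the grid point of global maximum,
  ties resolving to the smallest point, and is clamped to $[0,1]$.
  Boundary correction was considered and rejected: iDMC modes sit in
  the interior for any sample with non-trivial purity, and a
  deterministic grid rule keeps results bit-reproducible.
* Ties in the rank-sum p-value are broken by larger absolute centred
  statistic, then site id; equal tumor/control means classify as
  `hyper`. Both rules are arbitrary but deterministic.
* The rank-sum test uses the normal approximation with tie and
  continuity corrections at every sample size. At tiny $n$ the
  approximation deviates from exact enumeration by up to about 0.09 in
  p (the test suite measures this against a brute-force enumeration
  oracle); for marker *ranking* this is immaterial, since the ordering
  agrees with the exact ordering essentially everywhere.

## Differential methylation with normal controls

Beta values are transformed by $f(\beta)=\arcsin(2\beta-1)$, which
stabilizes variance for beta-distributed proportions, behaves well at
the boundaries 0 and 1 (both map to finite values, so no clipping is
needed), and is close enough to linear that a mixture that is a weighted
average on the beta scale remains approximately one after transform.

For site $i$: normals $X_i \sim N(m_i, \sigma_i^2)$; pure-cancer
difference $\delta_i \sim N(\mu_i, \tau_i^2)$; an observed tumor with
purity $\lambda_s$ gives $Y'_{is} = X_{is} + \lambda_s\delta_{is}$.
Purity therefore multiplies the effect. The stacked response
$Z = (X_1,\dots,X_{n_0}, Y'_1,\dots,Y'_{n_1})$ follows a linear model
with design $W = [\mathbf{1}, a]$, $a_s = 0$ for normals and
$\lambda_s$ for tumors, and $\beta = (m, \mu)$:

$$\hat\beta = (W^TW)^{-1}W^TZ, \qquad
\mathrm{var}(\hat\beta) = H_1\Sigma H_1^T + H_2\Sigma' H_2^T,$$

with $\Sigma = \sigma^2 I_{n_0}$, $\Sigma' = \sigma'^2 I_{n_1}$
estimated from the group-wise residual sums of squares with
denominators $n_0-2$ and $n_1-2$. The Wald statistic
$t=\hat\mu/\mathrm{se}(\hat\mu)$ is referred to $t(n_0+n_1-2)$,
two-sided, and BH-adjusted across sites. Purities enter as known
constants; their estimation uncertainty is not propagated. The
variance of $\delta_i$ ($\tau_i^2$) and any correlation between $X_i$
and $\delta_i$ are absorbed into $\sigma'^2$ — the generator exposes
them as knobs, the fitted model does not distinguish them.

Numerical and design choices:

* **Variance shrinkage.** Residual variances are shrunk linearly on the
  log scale toward the mean log variance (the geometric mean),
  separately within the normal-group and tumor-group vectors, default
  weight `shrink_weight = 0.2`. This preserves each vector's geometric
  mean exactly at every weight, returns the input at $w=0$ and the
  geometric mean at $w=1$. Separate pools were chosen because the two
  groups estimate different population variances; pooling them would
  let systematic tumor-normal variance differences leak into both.
  The degrees of freedom remain $n_0+n_1-2$ after shrinkage — no
  moderated-df adjustment — which makes the test mildly conservative
  when shrinkage stabilizes the variance estimates (see Limitations).
* **Degenerate sites.** If both groups have (numerically) zero residual
  variance, the site is flagged `degenerate` and $p$ is set by the sign
  convention $p=1$ if $\hat\mu=0$, else $p=0$; "zero" is judged at
  machine-epsilon scale because an exact fit leaves rounding residue of
  order $10^{-16}$. Zero variances entering the shrinkage are floored
  at machine epsilon.
* The per-site solve is vectorized: one $2\times(n_0+n_1)$ hat matrix
  serves every site, so genome-scale matrices fit in seconds.

## Control-free differential methylation

With no normals, $E[Y'_{is}] = m_i + \lambda_s\mu_i$: a simple
regression of a site's transformed tumor values on purity estimates
$\mu_i$ as the slope (`regress_on_purity()`); the slope's $t$ is
algebraically the Pearson-correlation test statistic. Ranking uses the
plug-in posterior $\mu \sim N(\hat\mu, \mathrm{se}^2)$,

$$\Pr(|\mu|>c) = \Phi\!\left(\tfrac{-c-\hat\mu}{se}\right) +
1 - \Phi\!\left(\tfrac{c-\hat\mu}{se}\right),$$

which demotes sites whose statistic is large only because the standard
error is tiny. The posterior construction is the minimal Bayesian
reading (flat prior, plug-in standard error); nothing richer is implied.

* `c = 0.1` by default, **on the arcsine scale** — the scale on which
  $\mu$ is defined — not beta units; users thinking in beta differences
  should note that near mid-range methylation an arcsine difference of
  0.1 is roughly a beta difference of 0.05.
* At $c=0$ the probability is identically 1 (returned exactly as 1; a
  naive evaluation of $p + 1 - p$ in floating point lands one ulp off
  and would scramble the ranking), so ranking falls through to the
  $|t|$ tie-break, which coincides exactly with ranking by $|r|$.
* Ranking is by descending posterior probability with $|t|$ then site
  id as tie-breaks. Posterior-primary ranking was chosen over blending
  the statistic in, as the simplest rule consistent with using the
  posterior at all; the optional `p_values = TRUE` column restores
  $t$-based p-values for users who need them.
* Guards: error below 4 tumors, warning below 20; purity dispersion
  floor `sd(lambda) >= 0.05` (configurable) operationalizes the
  requirement that purities be "dispersed enough" for the regression to
  be informative. A site with exactly constant response returns
  $t=0, r=0$; an exactly collinear response hits a guarded
  infinite-$t$ path (residual sums below $100\,\epsilon$ relative are
  treated as exact fits).

## The synthetic-data generator

`simulate_methylation()` produces the structure the methods assume:

* **Bimodal baseline methylome**: per-site baseline means drawn around
  arcsine-transformed modes at beta 0.1 and 0.9 (sd 0.15 on the
  transformed scale), mimicking the unmethylated/methylated bimodality
  of real methylomes.
* **Mixture signal**: by default mixing is a weighted average on the
  *beta* scale — the physically literal reading, since molecules
  average at the original scale — with `scale = "arcsine"` available
  where the linear model should hold exactly (e.g. algebraic identity
  checks).
* **Effects**: true DMCs get $|\delta| \sim N(2.0, 0.2^2)$ truncated at
  0 on the arcsine scale (a swing of roughly 0.1 to 0.9 in beta —
  "iDMC-grade"), with sign opposing the baseline state with probability
  $(1-\rho)/2$ where `x_delta_corr` $=\rho=-0.3$ by default. This
  sign-level encoding reproduces the observed tendency of unmethylated
  sites to gain and methylated sites to lose methylation, and induces
  the negative baseline-effect correlation seen in real data. Effects
  are clamped so the pure-cancer methylome stays in range; the truth
  table records *realized* effects after clamping.
* **Noise**: i.i.d. Gaussian on the arcsine scale (default sd 0.05 —
  a clean array experiment), added to the mixed signal, clamped to the
  valid range and mapped back to beta.
* **Purities**: uniform on (0.3, 0.9) by default, the dispersed regime
  the methods are designed for.

What it does *not* emulate: probe-specific biases and batch effects,
spatially correlated neighboring CpGs, site-specific variance
heterogeneity beyond the bimodal baseline, subclonal heterogeneity
(every cancer cell shares one methylome), and real methylomes' full
marginal distribution. Passing tests on this generator therefore
demonstrate correctness of the algorithms under the model's own
assumptions, not robustness to everything real arrays do.

## Validation design and problem sizes

The test suite validates each stage against independent oracles:
brute-force enumeration for the rank-sum test, an explicit
adjugate-inverse least-squares solver for the site fit, closed-form
normal CDF values for the posterior, and simulated ground truth for
recovery. Simulation sizes were chosen as the smallest that make the
statistical assertions stable: 2000 sites x 70 samples for purity
recovery (asserting mean absolute error at most 0.05 and Spearman rank
correlation at least 0.95 against truth), 5000 null sites at
$n_0=n_1=30$ for type-I calibration (asserting the empirical rate lies
in the 99% binomial band around 0.05), and 2000 sites with 10% true
DMCs for power and discrimination checks. The power comparison against
a purity-ignoring $t$-test runs at a moderate signal-to-noise ratio
(arcsine effect 0.5, noise sd 0.3, baselines at beta 0.25/0.75):
at very high SNR both tests saturate at full sensitivity and the
comparison is uninformative, while this regime exercises the
intermediate-power region where handling purity should and does matter.
`scripts/acceptance.R` recomputes the same quantities from scratch for
any seed.

## Known limitations

* **Purity bias from marker baselines.** An iDMC whose normal methylome
  sits at beta $b_0$ and cancer methylome at $b_1$ reads
  $b_0 + \lambda(b_1-b_0)$, so the density mode estimates
  $b_0 + \lambda(b_1-b_0)$ rather than $\lambda$; with realistic marker
  baselines near 0.1/0.9 this bounds the systematic error at roughly
  $|0.1 - 0.16\lambda|$. The mean absolute error the suite measures
  includes this bias. It is a property of the estimator, not of the
  implementation.
* **Mild conservatism of the Wald test.** The $n_0-2$/$n_1-2$ variance
  denominators slightly over-estimate the per-group variances (the
  design spends less than one degree of freedom per group block), and
  referring a shrinkage-stabilized statistic to $t(n_0+n_1-2)$ thins
  the tails further; together the realized null rejection at
  $\alpha=0.05$ sits a few thousandths below nominal. Conservative, so
  FDR control is not endangered.
* **Rank-sum approximation with heavy ties.** The $\pm 0.5$ continuity
  correction is tuned to the unit rank lattice; with many midranks at
  tiny $n$ the approximate p can deviate further from the exact value,
  though orderings still agree.
* **Control-free mode is a ranking.** Without controls there is no
  calibrated null, so no FDR is attached by default; the optional
  p-value column inherits all caveats of the purity regression.
* Purity estimates below the dispersion floor, cohorts under 20
  tumors, or cancer types whose iDMCs are dominated by heterogeneity
  rather than mixing will degrade all downstream guarantees; the
  guards turn the first two into warnings/errors, the third is
  invisible to the software.
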