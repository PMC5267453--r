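# MethylPurity

Solid tumor specimens are mixtures: a fraction λ (the *tumor purity*) of
cancer cells diluted with stromal and immune cells. DNA methylation
read out as 450k-style beta values therefore reflects a weighted average
of the cancer and normal methylomes, which biases naive tumor-vs-normal
comparisons and hides real differential methylation behind
purity-driven variance. MethylPurity is for epigenomics analysts working
with population-scale methylation cohorts who need to (i) estimate λ per
sample from the beta values themselves — no copy-number or expression
data — and (ii) call differentially methylated CpGs (DMCs) with purity
handled correctly, including when no normal controls were profiled.

## The model

**Purity estimation.** Informative differentially methylated CpGs
(iDMCs) are selected by a Wilcoxon rank-sum test of tumor vs a normal
control panel, requiring tumor beta-value variance > 0.005 and keeping
the top 1000 sites by p-value. At an iDMC the normal and cancer
methylomes sit near opposite ends of the beta scale, so after flipping
hypo-methylated sites (β → 1 − β) every iDMC in a tumor sample reads out
the cancer fraction. The per-sample purity estimate is the mode of a
Gaussian kernel density over these transformed values.

**DM calling with controls.** Beta values are variance-stabilized with
f(β) = arcsin(2β − 1). For CpG i with normal-sample values
X<sub>i</sub> ~ N(m<sub>i</sub>, σ<sub>i</sub>²) and pure-cancer
difference δ<sub>i</sub> ~ N(μ<sub>i</sub>, τ<sub>i</sub>²), an observed
tumor with purity λ<sub>s</sub> satisfies the mixture identity

    Y'_is = (1 − λ_s) X_is + λ_s Y_is = X_is + λ_s δ_is

so purity acts *multiplicatively* on the effect — not as an additive
covariate. Stacking normals then tumors into Z, the design W has an
intercept column and a purity column (0 for normals, λ<sub>s</sub> for
tumors); β̂ = (WᵀW)⁻¹WᵀZ, with group-specific residual variances
σ̂² = Σ<sub>normals</sub> ε̂²/(n₀−2) and σ̂′² = Σ<sub>tumors</sub>
ε̂²/(n₁−2) assembled into var(β̂) = H₁ΣH₁ᵀ + H₂Σ′H₂ᵀ. Variances are
shrunk toward their geometric mean across sites (log-linear, weight 0.2
by default), and H₀: μ = 0 is tested by the Wald statistic
t = μ̂/se(μ̂) against t(n₀+n₁−2), with Benjamini–Hochberg FDR.

**Control-free DM calling.** Since E[Y'] = m + λμ, regressing each
site's transformed tumor values on λ estimates μ as the slope (its t
statistic is exactly the Pearson-correlation statistic
r·√((n−2)/(1−r²))). Sites are ranked by the plug-in posterior
probability Pr(|μ| > c) under μ ~ N(μ̂, se²), with c = 0.1 by default,
which demotes sites that are statistically certain but biologically
tiny. This needs > 20 tumors and dispersed purities.

A synthetic-data generator (`simulate_methylation()`) produces beta
matrices with bimodal baselines, known purities, known DMC truth, and
beta-scale mixing, so every stage is testable against ground truth.

## Worked example

```r
library(MethylPurity)

sim <- simulate_methylation(synth_config(n_tumor = 40, n_normal = 15,
                                         frac_dmc = 0.2, seed = 7))
idmc   <- select_idmcs(sim$beta, sim$groups, n_top = 250)
purity <- estimate_purity(sim$beta, sim$groups, idmc)
purity
#> Tumor purity estimates for 40 sample(s)
#>   purity: median 0.607, range [0.338, 0.876]
#>  sample_id purity n_idmc_used peak_height
#>       T001  0.824         250    7.828864
#>       T002  0.740         250    7.593777
#>       T003  0.629         250    7.287020
#>       ...

mean(abs(purity$purity - sim$truth$purity[purity$sample_id]))
#> 0.0216   # mean absolute purity error against the simulated truth

dm <- call_dm(sim$beta, sim$groups, purity)
summary(dm)
#> Purity-aware DM test: 2000 sites, 15 normal vs 40 tumor samples (shrinkage weight 0.2)
#>  fdr_cutoff n_dmc
#>        0.01   401
#>        0.05   419
#>        0.10   436

cf <- call_dm_control_free(sim$beta, tumor_ids = sim$groups$tumor_ids,
                           purity = purity)
cf
#> Control-free differential methylation: 2000 sites, 40 tumor samples, effect threshold c = 0.1
#>   sites with Pr(|mu| > c) > 0.95: 400
#>   site_id mu_hat      se      t pearson_r post_prob rank
#>  cg001631  2.205 0.03762  58.63    0.9945         1    1
#>  ...
```

The 400 simulated true DMCs are recovered almost exactly (401 calls at
FDR < 0.01; 400 sites with posterior probability > 0.95 in control-free
mode), and estimated purities track the simulated λ to ~0.02 mean
absolute error.

The same pipeline is available from the shell via the installed
`exec/methylpurity` script (`simulate`, `idmc`, `purity`, `dm`, `dmfree`
subcommands); every output file carries a `#` header with version,
parameters, and seed.

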