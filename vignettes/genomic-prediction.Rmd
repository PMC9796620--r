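---
title: "Genomic prediction with GBLUP, BayesC and BayesGC: models, priors and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction with GBLUP, BayesC and BayesGC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the three prediction models, the prior-partitioning calculus
that connects them, how repeated records are weighted, how predictions are
scored, what the synthetic-data generator does and does not emulate, and
every numerical choice a maintainer might want to revisit.

## Setting

The target application is genomic prediction of maternal traits in a sow
nucleus population: heritabilities roughly 0.09–0.34, one yield deviation
(YD) per parity with at most six parities per sow, phenotypes already
adjusted for fixed effects by an upstream routine evaluation, and forward
validation on the youngest ~10% of animals whose records are masked during
fitting. Variance components ($\sigma_u^2$, $\sigma_e^2$) and the
permanent-environment ratio $\lambda$ are **inputs** here, as they come
from a pedigree-based REML analysis in routine practice; the package does
not estimate them.

## Repeated records: the effective number of records

An animal with $n$ parity records shares a permanent-environment effect
across them, so its record mean carries less information than $n$
independent observations. The collapsed phenotype is the arithmetic mean of
the parity YDs, and its residual precision is scaled by the effective
number of records

$$n_{\mathrm{eff}} = \frac{n(1+\lambda)}{n+\lambda}, \qquad
  \lambda = \sigma_e^2/\sigma_{pe}^2 ,$$

which is 1 at $n=1$ and saturates at $1+\lambda$: beyond a point, more
parities add almost nothing. The residual covariance used by every fitter
is $\mathbf{D}\sigma_e^2$ with $d_{jj} = 1/n_{\mathrm{eff},j}$. The mean is
unweighted across parities; the information content is carried entirely by
$n_{\mathrm{eff}}$ (weighting inside the mean is not part of the record
model here, and nothing downstream depends on it). $\lambda = \infty$
(no permanent environment) is accepted and gives $n_{\mathrm{eff}} = n$.

## The three models

With $\mathbf{y}$ the collapsed phenotypes and
$\mathbf{e} \sim N(0, \mathbf{D}\sigma_e^2)$:

**GBLUP.** $\mathbf{y} = \mathbf{1}\mu + \mathbf{u} + \mathbf{e}$ with
$\mathbf{u} \sim N(0, \mathbf{G}\sigma_u^2)$. $\mathbf{G}$ is VanRaden
method 1, $\mathbf{G} = \mathbf{Z}\mathbf{Z}'/(2\sum_i p_i(1-p_i))$, where
$\mathbf{Z}$ holds dosages centred by $2p_i$ and $p_i$ is computed from
all genotyped animals of the current run (reference and validation
together — standard VanRaden practice, and it keeps the centring of
prediction animals consistent with the training animals). The solver
builds the mixed-model equations over *all* animals in the GRM; animals
without phenotypes (or masked ones) get residual weight 0, which makes
their solutions the conditional means given the observed animals — no
separate prediction equation is needed, and the same convention is used by
the samplers.

**BayesC.** $\mathbf{y} = \mathbf{1}\mu + \sum_i I_i \mathbf{x}_i s_i +
\mathbf{e}$, $I_i \sim \mathrm{Bern}(\pi)$,
$s_i \mid I_i = 1 \sim N(0, \sigma_m^2)$, $\mathbf{x}_i$ the centred
genotype vector of SNP $i$.

**BayesGC.** Both terms at once:
$\mathbf{y} = \mathbf{1}\mu + \mathbf{u} + \sum_i I_i \mathbf{x}_i s_i +
\mathbf{e}$ with $\mathbf{u} \sim N(0, \mathbf{G}\sigma_{pol}^2)$. A few
SNPs with real effects are fitted explicitly while the polygenic remainder
flows through the relationship matrix.

The GEBV is the genetic part only — $\hat{u}$, the posterior mean of
$\sum_i I_i \mathbf{x}_i s_i$, or their sum — never including $\mu$;
accuracy is translation-invariant but the dispersion regression is not,
and excluding the intercept matches EBV convention.

## Prior partitioning

Let $F_r$ be the fraction of the total genetic variance one fitted SNP is
assumed to explain, and $q$ the fraction of $\sigma_u^2$ assigned to the
marker term ($q=1$ recovers BayesC, $q=0$ GBLUP). With the average
heterozygosity $\overline{HET} = 2\sum_i p_i(1-p_i)/N_{loci}$:

$$\pi_C = \frac{1/F_r}{N_{loci}}, \quad \pi_{GC} = q\,\pi_C, \quad
  \sigma_m^2 = \frac{F_r\,\sigma_u^2}{\overline{HET}}, \quad
  \sigma_{pol}^2 = (1-q)\,\sigma_u^2 .$$

These satisfy $\sigma_{pol}^2 + \pi N_{loci}\overline{HET}\sigma_m^2 =
\sigma_u^2$ identically: however the variance is split, the prior total is
preserved. `make_prior_spec()` assembles the set and enforces the
identity; $\pi > 1$ (more expected SNPs than loci) is a hard error rather
than a clip, because it always signals an inconsistent $(F_r, N_{loci})$
configuration. Tests reproduce the published prior tables for the 429,403
SNP maternal-trait panel at their printed rounding (half a unit in the
last printed digit). Two table-reproduction caveats found on the way, both
attributable to the source tables being printed rounded: the heritability
column recomputed from its own (3-decimal) variance components is off by
up to one unit in the third decimal for one trait, so it is checked at one
unit in the last digit; and no single value of $\overline{HET}$ reproduces
every per-SNP-variance cell at five decimals, so only two independent
cells (which pin $\overline{HET} \approx 0.3282$) and the exact factor-10
row structure are asserted. $\overline{HET}$ of the real panel is never
hard-coded anywhere in the implementation — it is always computed from the
panel at hand.

## The Gibbs samplers

Full conditionals are standard but spelled out here because the package
implements them from scratch (the hot loop is RcppArmadillo C++). Write
$\mathbf{W} = \mathrm{diag}(w)$ with $w_j = n_{\mathrm{eff},j}$ (0 for
masked animals), $\lambda_m = \sigma_e^2/\sigma_m^2$, and let $\mathbf{r}$
be the current residual.

*Intercept* (flat prior):
$\mu \mid \cdot \sim N\!\big(\sum_j w_j(r_j+\mu)/\sum_j w_j,\;
\sigma_e^2/\sum_j w_j\big)$.

*SNP $i$*: with $v_i = \mathbf{x}_i'\mathbf{W}\mathbf{x}_i$ (constant, so
precomputed once) and $rhs_i = \mathbf{x}_i'\mathbf{W}\mathbf{r}_{-i}$
(residual excluding SNP $i$'s own contribution), integrating $s_i$ out of
the indicator's conditional gives

$$\log\frac{P(I_i=1\mid\cdot)}{P(I_i=0\mid\cdot)}
 = \log\frac{\pi}{1-\pi}
 + \tfrac12\log\frac{\lambda_m}{\lambda_m+v_i}
 + \frac{rhs_i^2}{2\sigma_e^2(\lambda_m+v_i)} ,$$

and on acceptance $s_i \mid I_i{=}1 \sim
N\!\big(rhs_i/(v_i+\lambda_m),\; \sigma_e^2/(v_i+\lambda_m)\big)$.
Sampling the indicator with the effect integrated out (rather than
conditional on the old $s_i$) is what makes the chain mix at small $\pi$.

*Polygenic vector* (BayesGC): the full conditional is multivariate normal
with precision $\mathbf{P} = \mathbf{G}^{-1}/\sigma_{pol}^2 +
\mathbf{W}/\sigma_e^2$ — constant across cycles. Its Cholesky factor is
computed once; each cycle costs two triangular solves for the mean plus
one for the noise, i.e. $O(n^2)$ rather than $O(n^3)$. This exact joint
draw avoids the slow mixing of single-site polygenic updates.

Update order within a cycle is $\mu$, SNPs in index order, then
$\mathbf{u}$ — deterministic given the seed; the order does not affect the
stationary distribution, and SNP-permutation exchangeability is tested
statistically. All variance parameters stay fixed, as in the study design
this package follows; estimating them by MCMC would dominate the chain
length needed and is deliberately out of scope.

Residuals are updated incrementally whenever any effect changes and
recomputed from scratch every 1000 cycles; the maximum drift observed is
returned in the fit (`max_residual_drift`, asserted `< 1e-8` in tests).
Chains $c = 1, \dots, C$ are seeded `seed + c` through R's RNG (the C++
code draws from R's generator), so every run is reproducible and chain 1
of a 2-chain run equals chain 1 of a 1-chain run. Defaults are the study's
settings: 20,000 cycles, 4,000 burn-in, two chains, with convergence
declared when the per-chain posterior-mean GEBVs correlate above 0.9999.
At the package's desk scales (hundreds of animals, 1,000–5,000 SNPs) the
observed two-chain correlation at full chain length is ~0.99996; unit
tests on smaller/shorter runs use the scaled threshold 0.999.

## Validation statistics

Accuracy is $r_{pred} = \mathrm{cor}(\mathrm{GEBV}, \mathrm{YD})/\sqrt{h^2}$
with $h^2 = \sigma_u^2/(\sigma_u^2+\sigma_e^2)$: the YD is a noisy proxy
of genetic merit, and $\sqrt{h^2}$ rescales the correlation to the
accuracy of predicting the breeding value itself. Small validation sets
can push the estimate above 1; it is reported unclipped. Dispersion bias
is the OLS slope of YD on GEBV ($b=1$ unbiased, $b<1$ over-dispersed
GEBVs). The standard error of the accuracy is a nonparametric bootstrap
over validation animals (1000 resamples, seeded) — the reference analyses
report an SE without stating its estimator, and the bootstrap is the
assumption-light choice; it reproduces the order of magnitude (~0.05–0.10
at ~1000 validation animals) but is not guaranteed to match any particular
closed form. The reference/validation split takes the `n` animals with the
largest birth keys; ties are broken by animal id (lexicographically last
into validation) so the split is deterministic.

## The synthetic-data generator

The generator exists so that every pipeline stage is testable without the
proprietary study data. It emulates: allele frequencies from a Beta
distribution (default Beta(2,2)); Hardy–Weinberg genotypes, by default in
linkage equilibrium; an additive architecture of `n_qtl` discrete QTL
carrying `qtl_var_fraction` of $\sigma_u^2$ plus a polygenic tail spread
over all remaining SNPs; a per-animal permanent-environment deviate; and
1–6 parity records per animal of the form tbv + pe + residual. Yield
deviations are simulated directly rather than via litter records and a
fixed-effects evaluation, because the pipeline's input boundary is the YD.
By default each QTL carries an equal share `qtl_var_fraction/n_qtl`
(random sign) — the architectures of interest are specified that way
("$k$ QTL of $x$% each"), and equal shares make recovery properties sharp;
`qtl_effect_dist = "normal"` gives randomly sized effects instead.

Linkage equilibrium keeps the oracles exact but removes the very feature
that makes variable selection useful, so an LD mode generates each
haplotype by thresholding an AR(1) latent Gaussian (`ld_rho`), preserving
marginal frequencies while inducing local LD (adjacent-dosage correlation
$\approx (2/\pi)\arcsin(\rho)$ for intermediate frequencies). The
qualitative-property tests use `ld_rho = 0.95`.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: genome-scale LD structure and recombination
maps, family/pedigree structure and selection over generations,
genotyping/imputation error, across-chip density differences, non-additive
variance, and fixed-effect contamination of the YDs. Absolute accuracies
on synthetic data therefore do not transfer; what is checked is the
internal consistency of the machinery and the *qualitative* architecture
result: with few large QTL in LD, BayesGC's accuracy is at least GBLUP's,
and on purely polygenic traits the two are statistically
indistinguishable.

## Numerical choices and degenerate inputs

* **Ridge.** $\mathbf{G}$ from $m < n$ SNPs is singular; a diagonal ridge
  (default `1e-6`) is added only where an inverse/Cholesky is needed. The
  GBLUP-vs-SNP-BLUP equivalence test uses `1e-8` because the ridge itself
  perturbs the equivalence at about its own magnitude.
* **Missing genotypes** are imputed to the column mean $2p_i$ (count
  reported), preserving exact centring; missing VCF records that are not
  biallelic SNPs are skipped with a warning count.
* **MAF filtering** is strict (`min(p, 1-p) > threshold`); removing every
  SNP is an explicit error, as is a monomorphic-only GRM (denominator 0).
* **Duplicate (animal, parity) pairs** are an error naming the pair;
  collapse order is deterministic (sorted animal id).
* **Monte-Carlo assertions** compare a sampler to an oracle within 3 MC
  standard errors, with the SE estimated across chains; because that SE is
  itself estimated from $C$ chains, the criterion uses the matching
  $t_{C-1}$ quantile, requires 95% of animals within it, and none beyond
  twice it.
* **Table reproduction** asserts agreement to half a unit in the last
  printed digit (one unit where the inputs are themselves printed
  rounded).
* **Grid tie-breaks**: equal accuracies resolve to the smaller model
  (larger $F_r$; GBLUP counts as the smallest model of all).
* **Problem sizes in the test suite** are desk-scale choices: the
  two-chain agreement check runs the full 20,000-cycle protocol at
  300 animals × 1,000 SNPs; the architecture comparison uses 5 seeds ×
  (800 × 1,500) with 3,000-cycle chains; oracle comparisons use 50–200
  animals. The whole suite completes in a few minutes on one CPU.

## Known limitations

Single-trait only; variance components are inputs, never estimated;
no single-step (pedigree + genomic) matrices; no BayesA/B/R samplers; the
polygenic draw's one-off Cholesky is $O(n^3)$ in memory-resident $n$, fine
to a few thousand animals but not for national evaluations; VCF input
assumes biallelic SNPs with GT fields and takes the ALT allele as the
counted dosage. The pipeline's `manifest.yaml` records config, seeds and
file digests; report files are byte-reproducible for a given seed, the
manifest's wall times of course are not.
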