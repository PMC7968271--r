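---
title: "Multi-source prediction of milk protein traits: models, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-source prediction of milk protein traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectrakin)
```

## The problem

Milk protein composition (casein and whey-protein fractions, expressed as
% of total milk nitrogen) is expensive to measure by chromatography, but
milk FTIR spectra, SNP genotypes, pedigree and routine on-farm records
(herd, days in milk, parity) are cheap and widely available. `spectrakin`
predicts the nine protein traits by combining these sources in a single
mixed-model framework and quantifies how much each source contributes
under two cross-validation designs.

## Models

### Multiple kernel learning

The core model regresses the phenotype on one or two kernel-structured
random effects plus on-farm fixed effects:

$$\mathbf{y} = \mathbf{Xb} + \mathbf{u}_{IR} + \mathbf{u}_g + \mathbf{e},
\qquad
\mathbf{u}_{IR} \sim N(\mathbf{0}, \mathbf{S}\sigma^2_{u_{IR}}),\;
\mathbf{u}_g \sim N(\mathbf{0}, \mathbf{G}\sigma^2_{u_g}),\;
\mathbf{e} \sim N(\mathbf{0}, \mathbf{I}\sigma^2_e).$$

Three relationship matrices are supported:

* **S** (spectral): $\mathbf{S} = \mathbf{W}_{IR}\mathbf{W}_{IR}'/m_{IR}$
  from the column-centered, unit-variance wavenumber matrix — the same
  construction as a genomic relationship matrix, with spectra in place of
  markers.
* **G** (genomic): VanRaden method 1,
  $\mathbf{G} = \mathbf{Z}\mathbf{Z}'/(2\sum_j p_j(1-p_j))$ with
  $\mathbf{Z}$ the allele-frequency-centered dosages.
* **A** (pedigree): the numerator relationship matrix by the recursive
  tabular method; restriction to the phenotyped cows happens only *after*
  the full recursion, so excluded ancestors still transmit relationship.

Fitting is by Gibbs sampling. Each kernel is eigendecomposed once
($\mathbf{K} = \mathbf{U}\mathbf{D}\mathbf{U}'$) and the random vector is
sampled as independent regressions on eigenvectors, which makes the full
conditional diagonal; variances have scaled-inverse-chi-square full
conditionals and fixed effects a flat prior. Test-set phenotypes are
predicted by the conditional expectation
$\mathbf{K}_{tst,trn}\mathbf{K}_{trn,trn}^{-1}\hat{\mathbf{u}}$, one term
per kernel, plus $\mathbf{X}_{tst}\hat{\mathbf{b}}$ for every model except
the spectra-only M1 (whose prediction is the kernel term alone; R² and
slope are unaffected by the omitted constant). Marker effects are
recovered from a genomic fit by the GBLUP back-solution
$\hat{\mathbf{a}} = \mathbf{Z}'\mathbf{G}^{-1}\hat{\mathbf{u}}_g /
(2\sum_j p_j(1-p_j))$.

### Multilayer BayesB

For variable selection the same phenotype is regressed directly on the
wavenumber and SNP columns, each layer with its own point-mass +
scaled-t mixture prior:

$$p(a_i \mid \pi, df, S) = \pi\, t(a_i \mid df, S) + (1-\pi)\,\delta_0.$$

The scaled-t slab is implemented hierarchically (normal effect with
scaled-inverse-chi-square variance). The inclusion probability
$\pi$ of each layer has a Beta hyper-prior parameterised by its mean
(`probin = 0.5`) and concentration (`counts = 10`), giving prior variance
$0.5 \times 0.5 / 11 = 0.023$. The indicator update integrates the effect
out (Bernoulli draw from the marginal likelihood ratio) and then draws the
effect when included — the standard construction with good mixing.
Whether the spectra layer's $\pi$ should be Beta-updated or fixed is not
observable from the protocol we follow; both are supported and the
Beta-updated version (identical to the SNP layer) is the default.
Fixed effects receive a Gaussian prior with variance $10^8$.

Default hyperparameters follow a partition rule: a prior $R^2$ of 0.5 is
split equally across layers, and each layer's t-scale is chosen so that
$\pi_0 \cdot \sum_j \mathrm{var}(w_j) \cdot E[\sigma^2_a]$ equals the
layer's share of $R^2\,\mathrm{var}(y)$, with the residual prior mode at
$(1-R^2)\,\mathrm{var}(y)$.

### PLS baseline

Partial least squares (NIPALS) on the column-concatenated predictor
blocks is the chemometric baseline. Genomic and pedigree information
enters as principal-component scores of **G** or **A** (eigenvectors
scaled by root eigenvalues, smallest count explaining > 80% of the
variance). The latent-variable count minimises 10-fold inner-CV RMSE on
the training set, capped at 50. One-hot herd/parity columns are
standardized like every other column; the alternative (raw 0/1 coding)
was considered and rejected for symmetry of the column weights.

### The catalogue

Seven covariate sets are defined (M1 spectra only; M2 + herd; M3 + herd,
DIM, parity; M4 + genomics; M5 top-3 markers as fixed covariates instead
of **G**; M6 both, with **G** rebuilt excluding the top 3; M7 pedigree
instead of genomics). Kernel learning fits all seven; BayesB fits M1-M4
(it selects markers internally); PLS fits M1-M4 and M7. The top-3 markers
are selected inside each training fold from the M4 fit by largest
absolute back-solved effect, ties broken by panel order.

## Cross-validation

* **Repeated random sub-sampling**: uniform cow-level splits (716/250 at
  the full cohort scale), 10 repeats.
* **Herd-blocked**: herds are sampled into 65 training / 20 testing (so no
  herd spans both sets), the herd effect is dropped from every model, and
  M2 is not admissible.

Metrics are the squared Pearson correlation between observed and
predicted test phenotypes and the slope of observed on predicted;
repeats are aggregated as the mean of per-repeat metrics, never pooled.
One master seed spawns independent per-repeat streams. Standardization
statistics (spectra and SNP layers) are computed on the training rows of
each fold by default (`standardize_scope = "train"`); the full-data
alternative is one switch away since protocols differ on this point.
Genotype imputation uses full-data allele frequencies once, before
cross-validation, reflecting a workflow where imputation precedes model
comparison; a per-fold alternative would change third-decimal results at
most because imputation touches ~1% of calls.

## The synthetic cohort generator

No cow-level dataset is distributed, so every component is exercised on
synthetic cohorts calibrated to the study population the package targets:
966 cows in 85 herds (11.4 ± 2.4 cows per herd), DIM 169.8 ± 101.8,
parity 2.4 ± 1.2, 1060 wavenumbers spanning 5011-925 cm⁻¹, and the nine
trait means/SDs in `milk_protein_traits()`. The generator produces:

* a pedigree (founder sires/dams + one offspring generation, random
  mating) with genotypes gene-dropped from founder haplotypes at
  Uniform(0.05, 0.5) frequencies — relatedness therefore induces
  founder-block LD, but no map-based recombination model is attempted;
* traits as mean + herd + DIM/parity + genetic value + a latent
  milk-composition factor + residual, with configurable variance shares
  (defaults: h² 0.5, herd 0.20, DIM 0.03, parity 0.02, milk 0.10);
* spectra as a smooth baseline plus three structured signals —
  herd-specific smooth signature curves, a genetic loading curve and a
  milk-factor loading curve — plus AR(1) channel noise (ρ = 0.9, chosen
  to mimic the strong correlation of adjacent FTIR channels).

The genetic value is rescaled to realized unit variance (founder-block
sharing would otherwise inflate it), so the configured h² is the share
actually simulated; trait scaling uses *theoretical* component variances,
so realized means and SDs fluctuate naturally around the targets.

Two generator choices deserve comment. First, the herd fingerprint: each
herd imprints its own signature curve on the spectra while an independent
scalar herd effect moves the trait. Under random splits a kernel model
"memorises" these fingerprints through herdmates in the training set;
under herd-blocked splits the fingerprints are novel and that shortcut
disappears — which reproduces the optimism gap between the two designs,
and makes the gap vanish when `spectra_herd_loading = 0`. Second, the
genetic loading on the spectra is deliberately partial
(`spectra_genetic_loading = 0.3` against channel noise SD 1.0): spectra
measure milk composition, which expresses only part of genetic merit, so
adding genomic or pedigree kernels genuinely improves prediction — the
regime the package is designed to study. With a large loading the spectra
would already contain the genetic signal and genomics could not help;
that regime is available but is not the default.

What passing tests on this generator do **not** show: performance on real
FTIR spectra (instrument artefacts, water-absorption regions, nonlinear
concentration effects), real LD structure, or genotype-by-environment
interaction. The generator exists to verify the estimation machinery and
the structural behaviour of the CV designs, not to forecast real-data
accuracy.

## Numerical choices

* Kernel eigenvalues below 1e-10 are treated as zero (their regression
  coefficients are pinned to 0); eigenvalues below −1e-8·max are an
  error.
* Training-block kernel inverses get one 1e-8 diagonal jitter attempt
  before failing. This also covers rank-deficient **S** when the channel
  count is below the training size.
* Column standardization uses the unbiased (n−1) SD; constant columns are
  dropped with a warning (monomorphic SNPs should already have been
  removed by the MAF filter).
* QC thresholds are strict-less-than removals: call rate ≥ 0.95 and
  MAF ≥ 0.05 are kept.
* Tie-breaks in top-marker selection follow panel order; PLS component
  ties take the smaller count.
* MCMC defaults are 50,000 burn-in + 50,000 kept, thinning 10. Posterior
  means use every post-burn-in draw; thinning affects only stored chains.
  The test-suite and example chains are much shorter (hundreds to a few
  thousand draws) and the suite verifies that short and long chains give
  posterior means correlating above 0.95 on a fixed fit. Effect-wise
  Gibbs updates scan predictors in column order, so permuting columns
  changes the chain realisation; permutation equivariance holds to Monte
  Carlo error, not bitwise.
* The synthetic problem sizes used by tests and the acceptance script
  (300-400 cows, 500 SNPs, 50-200 channels, chains of 2,000-5,000
  iterations) were chosen as the smallest at which the estimators are
  statistically stable; the generator scales to the full cohort
  dimensions with one argument.

## Known limitations

* Single-trait models only; no multi-trait covariance, no REML.
* The spectral kernel is unweighted; weighted variants would need a
  wavenumber-relevance model.
* BayesB top-marker models (M5/M6) are intentionally absent — mixture
  priors already perform selection.
* The CLI's `fit` command refuses M5/M6 outside cross-validation because
  top-marker selection is defined per training fold.

## A worked example

```{r example, eval = FALSE}
library(spectrakin)

sim <- simulate_dataset(sim_config(desk = TRUE, seed = 1))
bundle <- sim$bundle

cv <- random_subsampling_cv(
  bundle, traits = "kappa_CN", methods = "kernel",
  models = c("M1", "M4"), n_test = 75, repeats = 10, seed = 7,
  mcmc = mcmc_control(2000, 2000, 5))
summarize_cv(cv)
```
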