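---
title: "Models and methods behind ratoonGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ratoonGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratoonGS)
```

# The scientific problem

Sugarcane is planted once and then harvested repeatedly: the plant-cane (PC)
crop is followed by ratoon crops (first ratoon FR, second ratoon SR, ...)
that regrow from the stubble. Yields decline across ratoons, so breeders
select for *ratooning ability* (RA): for a trait with plant-cane value $P$
and ratoon values $R_1,\dots,R_N$,

$$A = \frac{\sum_{n=1}^{N} R_n}{P \cdot N} \times 100,$$

the average ratoon performance as a percentage of plant cane. `ratoonGS`
derives RA for five sugar/yield traits — economic index (EI), stalk
population (SP), stalk weight (SW), cane yield (TCH) and sucrose yield
(TSH) — from plot-level component measurements, estimates its genetic
architecture with mixed models and a kinship-corrected GWAS, and benchmarks
four genomic-prediction models under repeated cross-validation.

# Trait derivation

Component measurements per plot are stalk population SP (stalks ha⁻¹),
stalk weight SW (kg stalk⁻¹), Brix (%), Pol (%), fiber (%) and moisture
(%). Derived traits:

* Sugar content: $SC = \mathrm{Pol} \times 26 \,/\, [105.811 + (\mathrm{Brix} - 15) \times 0.444]$.
  The printed form of this industry formula is typographically ambiguous
  about whether the bracket divides; we default to the denominator reading
  (the alternative is available via `reading = "product"`, and the choice is
  recorded on the output) because it yields percent-scale values for
  field-realistic Brix/Pol.
* Cane yield: $TCH = SW \times SP / 1000$ (Mg ha⁻¹).
* Commercial recoverable sugar: $CRS = 0.86 \times TRS$. The theoretical
  recoverable sucrose TRS is lab-derived from juice data and fiber; its
  published formula is not printed in the sources we implement against, so
  the package accepts TRS as an input column or computes it from a
  configurable linear plug-in in Pol, Brix and fiber
  (`theoretical_recoverable_sucrose()`). We treat CRS in kg per Mg cane so
  that $TSH = TCH \times CRS / 1000$ has Mg ha⁻¹ units; the alternative
  kg ha⁻¹ reading would make the TSH formula dimensionally inconsistent.
* Economic index: $EI = \text{price} \times TSH - (c_{harvest} + c_{haul} +
  c_{mill}) \times TCH$, a linear profit form whose coefficients are
  configuration with neutral defaults — the published index is defined only
  through its inputs.

RA values above 100% are legitimate (SP often ratoons above plant cane) and
are preserved. A zero plant-cane value leaves RA undefined; such records
are dropped with a warning rather than imputed.

# The univariate field model

Plot-level values from the augmented row-column trial are analyzed with

$$y = \mu + \text{population}_i + \gamma_j + r_{jh} + c_{jk} + g_a + \varepsilon,$$

where the population class (test clone vs each check cultivar) and the
intercept are fixed; replicate, row-within-replicate, column-within-replicate
and genotype are independent random effects; and the residual variance is
heterogeneous with one variance per population class (diagonal $R$). The
class-level grouping is our reading of "heterogeneous error variance": checks
are highly replicated cultivars whose plot-to-plot noise need not match the
test clones', and class is the coarsest grouping that is estimable from 2
replicates. Replicate is treated as random; with two levels the shrinkage is
strong and the choice is immaterial for the genotype BLUPs, but it keeps all
design terms on the same footing.

Estimation is Average-Information REML with an EM fallback (`reml_lvc()`):
AI steps are accepted only if they stay in the parameter space and do not
decrease the restricted likelihood (step-halving, then an EM step), so the
log-likelihood trace is monotone. Variances are floored at $10^{-8}
\mathrm{var}(y)$ — boundary estimates are reported, not fatal. Defaults:
relative tolerance $10^{-8}$, 100 iterations.

Entry-mean heritability uses the genotype and *test-clone* residual
variances with the clone replication $R$ (2 by default):
$H^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2 / R)$.

# The multivariate multi-cycle model

Because ratoons regrow from the same stubble, a plot is the repeated unit
across crop cycles. For one trait over $K$ cycles we fit

$$y = Xb + Zu + e,$$

with per-cycle fixed effects (intercept plus population class), clone
effects $u \sim N(0,\, U \otimes I_c)$ with unstructured $K \times K$
genetic covariance $U$, and plot residuals correlated across cycles,
$e_{plot} \sim N(0, E)$ with unstructured $E$. Per-cycle predicted clone
values (fixed part + BLUP) feed the RA formula.

Estimation is an expectation-conditional-maximization algorithm on the
exact marginal likelihood. Clones with the same replication share identical
posterior gain and covariance matrices, so the E-step reduces to a few
matrix products per replication group — this is what makes 400+-clone fits
take fractions of a second. The M-step's closed forms keep $U$ and $E$
positive semidefinite by construction; a final eigenvalue clip (with a
warning) guards against numerical indefiniteness. The conditional M-step
for the fixed effects maximizes the ordinary (ML) likelihood rather than a
restricted one; with ~430 clones and three fixed parameters per cycle the
REML correction is an $O(p/n)$ effect, far below the sampling noise of a
genetic correlation, and the simulation suite verifies recovery of the
generative correlation within its tolerance. EM on covariance structures
converges slowly near the optimum, so the default cap is 1000 iterations at
relative tolerance $10^{-8}$; estimates used in the package's checks are
insensitive beyond ~250 iterations.

# Relationship matrix, PCA, and gene-action codings

Sugarcane here is treated as pseudo-diploid: genotype calls are
$\{0, 1, 2\}$ because sequencing depth cannot resolve decaploid allele
dosage. The additive relationship matrix is VanRaden method 1 on those
dosages: columns centered by $2\hat p$, scaled by $2\sum \hat p(1-\hat p)$.
Missing genotypes are column-mean imputed (deterministic and adequate at
the low missingness this pipeline expects). Population structure is read
from the SVD of the centered genotype matrix (`pca_population()`).

Gene-action codings for the scan: additive (dosage as-is), `1-dom-ref`
(carrier of ≥1 alternate allele, $\{0,1,1\}$) and `1-dom-alt` (carrier of
≥1 reference allele, $\{1,1,0\}$) — the two dominance directions of a
pseudo-diploid simplex-dominance model. Reports always label the direction
explicitly.

# The GWAS engine

`gwas_scan()` is a P3D ("population parameters previously determined")
mixed-model scan. For each chromosome the null model $y = \mu + g + e$,
$g \sim N(0, \sigma_g^2 K_{LOCO})$, is fit once by REML on the
eigendecomposition of the leave-one-chromosome-out kinship (so the tested
marker's own chromosome never contributes to its polygenic correction).
With the variance ratio fixed, the data are whitened and every marker is
tested by weighted least squares with a two-sided t (Wald) test. This
construction makes the scan with $K = I$ *numerically identical* to
ordinary regression — the property the oracle tests assert — and keeps
permutation type-I error at its nominal level. Markers that become constant
under a coding are flagged with $p = 1$ rather than dropped, so output rows
stay aligned across codings.

Marker QC retains biallelic SNPs with MAF ≥ 0.02 whose most frequent
genotype class stays below $1 - 5/N$ (0.988 at $N = 432$) — i.e. at least
five clones outside the modal class. Significance is Benjamini–Hochberg at
FDR 0.1, applied separately per trait × coding combination; BH was chosen
as the standard deterministic step-up procedure consistent with
per-combination thresholds. Significant SNPs within 5 Mb on a chromosome
merge into putative QTL by single linkage (a gap strictly greater than the
window splits); the peak is the smallest p-value, ties broken by lower
position.

# Genomic-prediction models

All four models accept optional unpenalized fixed covariates (used for the
top-GWAS-SNP mode) and share a `predict()` that computes cross-kernels and
centerings from training statistics only.

* **RR-BLUP** — ridge marker regression solved exactly through its GBLUP
  dual: one 1-D REML on the VanRaden kernel gives the shrinkage, and
  marker effects are back-transformed. The equivalence is asserted to 1e-8.
* **Bayes A** — Gibbs sampler (compiled) with per-marker normal effects and
  marker-specific scaled-inverse-$\chi^2$ variances, flat priors on fixed
  effects. The source publications state no hyperparameters, so defaults
  are standard practice: $df = 5$ with the prior scale solved so the
  prior-mode total marker variance equals half the phenotypic variance;
  5,000 iterations with 1,000 burn-in by default (tests use shorter chains
  at small $p$, where mixing is fast). The sampler uses R's RNG, so a seed
  fully reproduces the chain.
* **RKHS** — Gaussian kernel $\exp(-D / (h \cdot \mathrm{median}(D)))$ on
  squared Euclidean marker distances; $h$ selected from the grid
  $\{0.2, 1, 5\}$ by REML likelihood (likelihood-weighted kernel averaging
  is available as a config option). No bandwidth is stated in the sources,
  so the grid brackets the median-distance heuristic by a factor of five
  each way.
* **ADE** — three-variance-component kernel model: VanRaden additive kernel
  $A$; dominance kernel from heterozygosity indicators centered at
  $2pq$; epistasis restricted to the additive×additive Hadamard product
  $A \circ A$ (the smallest faithful reading of
  "additive–dominance–epistasis"). Variance components by the same AI/EM
  engine as the field model; with the D and E components dropped the model
  collapses exactly to GBLUP, which the tests assert. One identifiability
  caveat is worth knowing: on a panel of nearly unrelated clones the
  Hadamard kernel approaches the identity matrix, so epistatic and residual
  variance become confounded and the reported epistatic share is
  untrustworthy. On panels with LD and relatedness — the situation this
  package targets, and what its generator produces — the partition is
  identifiable, and the additive-simulation checks are run under those
  conditions.

# Cross-validation benchmark

5-fold cross-validation repeated 25 times; the repeat index seeds the fold
randomization, so every model, trait and fixed-effect arm trains on
identical folds. Metrics per cell: Pearson accuracy, coincidence index
(share of the observed top 20% recovered in the predicted top 20%, top-set
size $\lceil 0.2n \rceil$, ties resolved by stable order), and the slope
and intercept of predicted-on-observed regression (1 and 0 when unbiased).

In the `top_gwas_snp` mode an additive-only scan runs on the *training*
clones of each repeat × fold; the most significant SNP (ties broken by
ascending chromosome then position) enters all models of that cell as a
fixed covariate, and selection frequencies are tabulated. Validation
phenotypes are never visible to selection or fitting — a canary test
corrupts them and requires the identical choice. Failed cells are recorded
and excluded from summaries with an explicit count, never imputed.

# The synthetic-population generator

`sim_config()` defaults encode the study conditions the pipeline is built
for: 432 test clones and two checks (each check totalling 17 plots) in a
two-replicate augmented row–column design; 10,435 biallelic pseudo-diploid
SNPs on 10 chromosomes with MAF ≥ 0.02; three crop cycles with cross-cycle
genetic correlation 0.7 (a moderately high value consistent with clone
effects that persist across ratoons) and entry-mean heritability 0.65 per
cycle, inside the 0.58–0.71 band the trait family exhibits.

Genotypes come from a Gaussian copula: a latent AR(1) process within blocks
of 10 SNPs, thresholded to Hardy–Weinberg genotype classes. SNPs in a block
share an allele frequency (a haplotype-block reading), and the latent
correlation is inflated to $\sin(\rho \pi / 2)$ so the *genotype-scale*
adjacent correlation lands near the configured `ld_rho`; discretization
otherwise attenuates it by ~20%. Genetic values are marker-based: QTL split
between two latent factors, per-QTL effects drawn jointly across cycles
with the configured correlation, dominance deviations on heterozygotes for
a configurable fraction of QTL. Component traits are linear combinations of
the two standardized factors on natural scales (SP ≈ 95,000 stalks ha⁻¹,
SW ≈ 1.1 kg, ...), which induces the configured negative SP–SW genetic
correlation (−0.13 by default: heavy-stalk clones tiller less).

Residual noise is calibrated per cycle as $\sigma_e^2 = R\,\sigma_g^2 (1 -
h^2)/h^2$ with $R$ the clone replication, so the *entry-mean* $H^2$
estimated downstream converges to `cycle_h2`; checks get their own residual
scale, making the heterogeneous-R structure real rather than cosmetic.

What the generator does **not** emulate: recombination-based LD decay and
coalescent ancestry (the copula is block-local), true polysomic dosage,
genotype-by-year interaction beyond the cycle correlation structure,
spatially autocorrelated field trends (row/column effects are exchangeable),
and selection or pedigree structure among clones. Passing tests therefore
demonstrate statistical correctness of the machinery under the stated
generative model, not robustness to every pathology of real trials.

# Numerical choices and problem sizes

Variance floors at $10^{-8}\mathrm{var}(y)$; PSD projections by eigenvalue
clipping at $10^{-8}$; BH thresholds computed by `p.adjust`; QTL-window
boundary is strict (`gap > window` splits); CI cutoff ties resolved by
stable order; fold sizes differ by at most one. All randomness flows from
explicit seeds through a deterministic fan-out (`derive_seed()`), making
every simulation, chain and fold assignment reproducible bit-for-bit.

The test and acceptance suites run the statistical checks at the panel size
the design targets (432 clones) but with reduced marker counts (240–2,000
SNPs) and 10–20 simulation seeds per check — sizes chosen so the whole
verification cycle completes comfortably on a single CPU while keeping
Monte-Carlo error well inside each stated tolerance.

# Known limitations

* The multivariate engine assumes every plot is observed in all cycles;
  incomplete plots are dropped with a warning rather than handled by a
  missing-at-random EM extension.
* Spatial correlation (AR1×AR1) structures and polysomic dosage models are
  out of scope; the pseudo-diploid reading is baked into the codings and
  kernels.
* The economic index and TRS plug-in are linear stand-ins whose
  coefficients must come from local industry data; their defaults are
  neutral placeholders.
* Bayes A chain-length defaults are conservative for the panel sizes here;
  much larger marker panels deserve longer chains and a convergence check
  on the stored diagnostic chain.
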