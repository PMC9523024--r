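---
title: "Mixed-model GWAS of genotype-by-environment interaction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-model GWAS of genotype-by-environment interaction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxescan)
```

## The scientific problem

Seed germination in rice is strongly temperature-dependent, and the loci
controlling germination can act in one thermal environment but not another.
A standard single-environment GWAS cannot distinguish a locus with a
*common* effect (equally active at 15 °C and 30 °C) from a locus whose
effect is *environment-specific*. `gxescan` implements the mixed-model
machinery for making that distinction in an inbred diversity panel
phenotyped under two environments: a per-marker likelihood-ratio test of
genotype-by-environment (G×E) interaction, flanked by the standard
preprocessing (variant filtering and multi-allelic decomposition), kinship
and structure estimation, per-environment scans, and downstream haplotype
analyses.

## Models

### Stacked two-environment mixed model

Let $y$ be the $n$-vector of stacked phenotypic records (here $n \le 2m$
for $m$ varieties and two environments). The **null model** gives the
tested marker one common effect $\alpha$:

$$ y = T t + S s + x\,\alpha + u_G + u_{GE} + \varepsilon $$

where $T$ ($n \times 2$) assigns records to environments and $t$ holds the
environment means; $S$ holds the first five principal components of the
genotype matrix with effects $s$; $x$ is the marker genotype coded
$\{-1, +1\}$ = {REF/REF, ALT/ALT} (heterozygotes are masked in this inbred
panel); and the random terms are

$$ u_G \sim \mathrm{MVN}\!\left(0,\; [Z_G G Z_G'] \sigma^2_G\right), \qquad
   u_{GE} \sim \mathrm{MVN}\!\left(0,\; [Z_G G Z_G'] \circ [Z_E Z_E']\,
   \sigma^2_{GE}\right), \qquad
   \varepsilon \sim N(0, I\sigma^2_\varepsilon), $$

with $Z_G$ ($n \times m$) and $Z_E$ ($n \times 2$) the variety and
environment incidence matrices, $G$ the genomic relationship matrix and
$\circ$ the Hadamard product. The Hadamard mask $Z_E Z_E'$ is 1 exactly
where two records share an environment, so the G×E kernel contributes
kinship-structured covariance *within* an environment and nothing across
environments — the polygenic term is re-drawn per environment, which is
what "polygenic G×E" means operationally.

The **alternative model** replaces $x\alpha$ with one effect per
environment, $\sum_{l=1}^{2} (\pi_l \circ x)\,\zeta_l$, where $\pi_l$
indicates records from environment $l$. The models are nested with one
extra parameter, and the marker's G×E signal is the deviance

$$ D = -2\,(\mathrm{LL}_{\text{null}} - \mathrm{LL}_{\text{alt}})
   \sim \chi^2_1 \text{ under } H_0 . $$

### Kinship, structure, heritability

`compute_grm()` uses the VanRaden normalization
$G = WW' / \sum_j 2p_j(1-p_j)$ on the mean-imputed, column-centered code
matrix; for a fully homozygous panel the mean diagonal is $\approx 2$
(inbreeding-scaled, $1+f$ with $f=1$). `pca_covariates()` decomposes the
same imputed, centered matrix, so $S$ and $G$ are mutually consistent;
eigenvector signs are fixed by making the largest-magnitude loading
positive, which makes all outputs reproducible.

Per-environment narrow-sense heritability is
$\hat h^2 = \hat\sigma^2_G / (\hat\sigma^2_G + \hat\sigma^2_\varepsilon)$
from the single-kernel model $V = G\sigma^2_G + I\sigma^2_\varepsilon$,
fitted EMMA-style: one spectral decomposition of $G$, then a 1-D
golden-section search over $\log \delta$, $\delta =
\sigma^2_\varepsilon/\sigma^2_G \in [10^{-6}, 10^6]$, tolerance $10^{-8}$,
with fixed effects profiled by GLS at each ratio.

## Estimation choices

**REML for variance components, ML deviances for the LRT.** The two-kernel
fit profiles the fixed effects and the residual scale analytically and
optimizes the two variance ratios
$(\sigma^2_G/\sigma^2_\varepsilon,\ \sigma^2_{GE}/\sigma^2_\varepsilon)$ by
Nelder–Mead on the log scale (bounds $[10^{-6}, 10^6]$), seeded from a
coarse profile-likelihood grid and restarted when an optimum lands on a
bound. During development we found — and confirmed against a brute-force
direct-likelihood grid, so it is a property of the likelihood, not of the
optimizer — that *full-ML* variance estimation can collapse onto the
$\sigma^2_\varepsilon = 0$ boundary when the kinship spectrum is weakly
informative (many independent markers make the GRM bulk approach a scaled
identity, which the genetic kernel can then mimic). REML does not exhibit
this collapse. The package therefore:

* estimates the marker-free variance components by **REML** (this is also
  what the classical mixed-model solvers default to), and
* computes per-marker LRTs under those *fixed* ratios as generalized
  least-squares deviances $D = n \log(\mathrm{RSS}_0/\mathrm{RSS}_1)$ on
  whitened data — the P3D ("population parameters previously determined")
  strategy. Because the ratios are held fixed, the null and alternative
  likelihoods remain directly comparable even though their fixed effects
  differ; full-ML per-marker refitting is available via
  `strategy = "exact"`, which is the statistically pure reading when REML
  likelihoods would not be comparable across fixed-effect structures.

P3D makes a 2000-marker scan a matter of seconds (two OLS fits per marker
after one Cholesky factorization) and, as the calibration suite shows,
costs essentially nothing in type-I accuracy: at 2000 null markers the
empirical rejection rate at $\alpha = 0.05$ is within [0.03, 0.075] and
the Kolmogorov–Smirnov distance of the deviances from $\chi^2_1$ is below
0.05.

**Degenerate markers.** A marker monomorphic overall yields an `NA` row; a
marker monomorphic within one environment loses that environment's effect
and the test's degrees of freedom are reduced accordingly (flagged
`env_monomorphic`). Negative deviances within $10^{-6}$ (optimizer
tolerance) are clipped to zero; anything larger is flagged as an optimizer
failure. A constant response is rejected as degenerate.

**Per-environment scans.** `run_env_gwas()` estimates the single-kernel
variance ratio once by REML on the marker-free model, then tests each
marker by GLS with a two-sided Wald $t$ on $n_{\text{obs}} - q$ degrees of
freedom, re-estimating the residual scale per marker. In the
identity-kinship, no-covariate limit this reduces *exactly* to ordinary
least-squares regression, which the test suite checks to $10^{-8}$.
Markers with missing calls are tested on their observed subset (the
covariance is re-whitened on the subset) rather than imputed, avoiding
effect attenuation.

## The synthetic-data generator

Raw sequencing data for the motivating panel are deposited as reads and
are not re-processed here; instead, every analysis is exercised on
synthetic data with exactly the statistical structure the models assume.

* **Genotypes.** A Balding–Nichols model: ancestral minor allele
  frequencies uniform on (0.05, 0.5), subpopulation frequencies
  $\mathrm{Beta}(f_0(1-F_{ST})/F_{ST}, (1-f_0)(1-F_{ST})/F_{ST})$, one
  homozygous draw per variety (inbred lines; heterozygotes never enter the
  internal matrix). Defaults: $m = 164$ varieties — the size of the
  motivating japonica panel — $p = 1000$ markers, $k = 3$ subpopulations,
  $F_{ST} = 0.1$, choices a rice population geneticist would call a
  moderately structured landrace panel. The leading principal component
  separates two simulated subpopulations at $F_{ST} = 0.3$ with ≥95 %
  accuracy.
* **Phenotypes.** The forward model is *exactly* the null model when every
  focal marker has $\zeta_1 = \zeta_2$ and exactly the alternative
  otherwise: environment means (40, 70) trait units for 15 °C/30 °C
  (cool-temperature germination is the harder assay), focal-marker fixed
  effects, $u_G$ drawn once from $\mathrm{MVN}(0, G\sigma^2_G)$, $u_{GE}$
  drawn independently per environment from
  $\mathrm{MVN}(0, G\sigma^2_{GE})$, iid residuals. Default variances
  $(\sigma^2_G, \sigma^2_{GE}, \sigma^2_\varepsilon) = (1, 0.5, 0.5)$.
  Phenotypes are continuous and unbounded, matching the linear-Gaussian
  assumption of the models; they are *not* clipped to [0, 100] %
  (germination rates near the boundaries would violate it — see
  limitations).
* **VCF fixtures.** `write_vcf_fixture()` emits VCF 4.2 with a configurable
  fraction of tri-allelic records (second ALT alleles created by recoding
  half of the ALT-homozygous varieties), injected heterozygotes, and `MQ`
  annotations spanning both sides of 40 — so the masking, splitting and
  filtering rules all have work to do on every fixture.

What the generator does **not** emulate: linkage disequilibrium decay along
chromosomes (markers are exchangeable given the subpopulation), genotyping
error, shared-environment (plot/year) effects, and the bounded, often
U-shaped empirical distribution of germination percentages. Passing tests
therefore demonstrate correctness of the estimators under the models'
own assumptions, not robustness to these real-data features.

## Preprocessing rules

The pipeline order is mask → split → filter:

1. **Heterozygote masking** sets every call whose two allele indices differ
   to missing — in a highly inbred panel residual heterozygosity is mostly
   artefactual.
2. **Tri-allelic decomposition** turns a site with alleles (REF, ALT1,
   ALT2) into the three allele-pair contrasts (REF, ALT1), (REF, ALT2),
   (ALT1, ALT2); within each derived record, carriers of the excluded
   third allele are set missing, and all other fields are duplicated from
   the parent. This is the $\binom{3}{2}$ reading of "three bi-allelic
   variants": each pairwise contrast can pick up an association that the
   forced REF-vs-major-ALT encoding would dilute — the motivation is
   allelic heterogeneity, where functionally distinct alleles at one locus
   weaken a single bi-allelic test. Records with more than three alleles
   are dropped with a warning.
3. **Filters**: minor allele frequency ≥ 0.05 (computed on allele counts
   over non-missing homozygous calls), mapping quality ≥ 40, call rate
   ≥ 0.40. "Minimum count" is read as a minimum non-missing call rate;
   all three thresholds are inclusive. Filtering is idempotent.

## Haplotype analyses

`call_haplotypes()` groups accessions by identical *translated* sequence
(synonymous changes collapse), with a minimum group size of three ("more
than two varieties"); smaller groups are reported unassigned. Sequences
that cannot be translated — explicit deletion alleles, gapped alignments —
are grouped by their exact nucleotide string, so loss-of-function deletion
haplotypes are accepted as explicit labels rather than inferred.
`build_msn()` computes the ε = 0 minimum spanning network: a minimum
spanning tree (Hamming distance on equal-length keys, edit distance with
single-event indels otherwise) augmented with every non-tree edge whose
weight ties the maximum on the tree path between its endpoints. The MSN
edge set is invariant to how spanning-tree ties are broken, which makes
the output deterministic. `chi2_independence()` is the Pearson test
without continuity correction, `df = (r-1)(c-1)`, warning when expected
cells fall below 5.

## Linkage disequilibrium

For a homozygous panel the squared genotype correlation equals the
haplotype $r^2$, so `r2_matrix()` needs no EM haplotype-frequency
estimation. Block annotation is a deliberately simple threshold-contiguity
rule (maximal runs with adjacent $r^2 \ge 0.7$), not a Gabriel-style
confidence-interval caller; the matrix itself is the primary output.

## Problem sizes and reproducibility

The simulation studies in the test suite and in `scripts/acceptance.R`
use: null calibration at $m = 100$ with 2000 markers; variance-component
recovery at $m = 200$ with 50 phenotype replicates over a fixed genotype
panel; heritability recovery at $m = 300$ with 100 replicates;
specificity at the panel's own size $m = 164$ with 1000 markers and 20
replicates — sizes at which each Monte-Carlo band is comfortably wider
than its standard error while a full run stays in the minutes range on one
CPU. The planted effects in the specificity study make both loci
major-effect QTLs of per-environment magnitude 2, differing only in
environment specificity, which mirrors the empirical contrast between a
G×E peak detected only at 30 °C and a cool-germination QTL with a common
effect. Every random draw flows from an explicit integer seed, and the
whole pipeline is bit-reproducible end to end.

## Known limitations

* Two environments only; the covariance construction generalizes to more,
  but nothing beyond two is tested.
* The LMM treats percentages as unbounded Gaussian; traits pinned near 0 %
  or 100 % call for a transformed or censored model.
* P3D holds variance ratios fixed across markers; loci explaining a large
  fraction of variance slightly violate this (use `strategy = "exact"`
  for final candidate regions).
* Variance-component identifiability degrades when the GRM spectrum
  approaches a scaled identity (very many independent markers relative to
  panel size); REML protects the point estimates but their sampling
  variance remains large in that regime.
* The tri-allelic decomposition follows the pairwise-contrast reading;
  sites with four or more alleles are dropped rather than decomposed.
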