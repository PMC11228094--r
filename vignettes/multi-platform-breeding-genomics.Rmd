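---
title: "Multi-platform genotype integration, inbreeding-aware GWAS and genomic prediction for clonal crop breeding populations"
author: "orchardGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-platform breeding genomics with orchardGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orchardGS)
```

# The problem

Long-running breeding programs for clonally propagated fruit crops
accumulate genotype data from several marker platforms: an older SNP array
covers the whole historical population, while a newer sequencing-based
assay covers only the parents and the most recent families. Selection
decisions, however, need one coherent marker matrix. orchardGS implements
the full analysis chain for this situation:

1. **merge** the two panels on their shared physical coordinate system,
2. **phase and impute** the families that lack one platform's genotypes,
   using their phased parents,
3. quantify **inbreeding** from pedigree and from runs of homozygosity
   (ROH), and locate ROH islands,
4. run linear-mixed-model **GWAS** (single-SNP and SNP-set kernel tests),
5. fit **GBLUP genomic prediction** models with additive and dominance
   kernels and a directional inbreeding (inbreeding depression) fixed
   effect.

Because real multi-platform breeding data are rarely public, the package
ships a pedigreed population simulator whose ground truth (haplotypes,
identity-by-descent, QTL effects) is retained, so every step can be
evaluated against a known answer.

# The simulator and what it does (and does not) emulate

`simulate_study()` draws founders at allele frequencies uniform on
[0.05, 0.95], breeds a parental population for a configurable number of
generations with preferential reuse of a few "leading cultivar" parents
(which makes inbreeding rise over time, as in real programs), and then
creates full-sib families. Meiosis uses a Poisson crossover count per
chromosome (mean `recomb_rate`, default 1.5) with uniform crossover
positions and no interference. Every founder haplotype carries a unique
label that is propagated through each meiosis, so the *true* genomic
inbreeding of any individual is simply the fraction of markers at which
its two haplotypes carry the same label.

The default configuration is a desk-scale (about 1/10) rendition of a
two-platform apple program: 17 chromosomes of 30 Mb; platform A
(array-like) with 1,100 markers and 0.5% missing calls covering everyone;
platform B (sequencing-based) with 1,050 markers, 1.6% missing calls,
and 9 markers shared with A, covering the parents and 5 of 21 families.
Phenotypes are built as

$$y_{iy} = g^{(a)}_i + g^{(d)}_i + b\,F_i + \mathrm{year}_y + e_{iy},$$

with additive and dominance components rescaled to their target
variances, $F_i$ the true autozygosity, and an unbalanced year design
(parents evaluated in several years, offspring usually in one).

Two features of real data are deliberately *not* emulated by default:
genotype-calling error (a hook exists, default rate 0) and
population-level linkage disequilibrium older than the simulated
pedigree. Consequences of that choice are flagged below where they
matter.

# Platform merging and the masking evaluation design

`merge_platforms()` joins panels on (chromosome, position). When both
platforms assay the same position, the copy from the platform with the
higher overall missing rate is dropped — generalising the common practice
of trusting the cleaner assay — after recording the per-marker genotype
consistency of the duplicated markers. Merging a matrix with an empty
panel is exactly the identity, so the operation is idempotent.

Imputation accuracy is measured with a three-dataset masking design.
Datasets 1 and 2 contain the parents and the dual-genotyped families;
platform B (Dataset 1) or platform A (Dataset 2) genotypes of those
families are withheld and then reconstructed. Dataset 3 applies the
Dataset-2 masking inside the full population, in which the remaining
families only ever had platform-A data. Accuracy is the fraction of
masked cells whose reconstructed dosage (scored 1/0/−1 for AA/Aa/aa)
equals the truth.

A caveat that falls out of the error-free default: in real data the
sequencing-based platform is noisier, which depresses the *apparent*
accuracy of recovering its genotypes (its observed calls serve as the
evaluation reference), so recovering array genotypes from a sequencing
scaffold looks more accurate than the reverse. With error-free truth as
the reference, the two maskings are nearly symmetric, and the slightly
denser, cleaner platform-A scaffold in fact makes Dataset 1 marginally
*more* accurate (by about 0.1–0.5 percentage points at the default
configuration). The package reports what it measures; users comparing to
noisy-reference numbers should enable the genotyping-error hook.

# Family phasing, parental origin and imputation

`phase_family()` phases each offspring against its two phased parents by
dynamic programming over the four parental-origin states (dam haplotype
1/2 × sire haplotype 1/2) along each chromosome, minimising genotype
mismatches under a per-crossover penalty. The penalty (2.5 mismatch
units) makes one crossover cheaper than three isolated mismatches but
dearer than two — a deliberate trade-off between typical genotyping-error
and recombination rates. Missing genotypes are free to the objective, so
the same pass imputes them from the selected parental alleles
(`impute_from_origin()`); ties are broken deterministically in favour of
not recombining. Markers whose offspring genotype is Mendelian-impossible
given the parents are treated as missing, with a warning above 5% per
offspring.

In the evaluation pipelines the parents' haplotypes are taken from the
simulation truth: phasing *parentless* founders from population LD is a
different problem (normally delegated to an LD-based phaser) and outside
this package's scope.

`estimate_parental_origin()` implements window-voting origin
classification for externally phased haplotypes: repeatedly (default 100
times) draw a window of 30 consecutive markers, correlate the offspring
haplotype with each of the four parental haplotypes over the window, and
let each repetition vote for the parent owning the best-correlated
haplotype; the majority decides, ties return "unknown", and
zero-variance windows are redrawn (up to ten times the repetition
count). The window is defined in *markers*, not base pairs: at realistic
marker densities (one marker per ~14 kb here) a base-pair window of
similar nominal size would rarely contain two markers, so a fixed marker
count is the only workable reading. Windows are drawn within chromosomes
on the 0/1 allele coding.

Phasing accuracy is scored as maternal-assignment concordance: over an
individual's truly heterozygous markers, the fraction at which the
allele on the dam-labelled haplotype equals the truly maternally
transmitted allele. (This metric has no universally agreed definition;
concordance at heterozygous sites is the strictest choice that does not
reward trivially correct homozygous positions.)

# Inbreeding and ROH

`pedigree_inbreeding()` uses the tabular additive-relationship recursion
(F = A_ii − 1), with founders assumed non-inbred and unrelated — which is
why pedigree F understates genomic F in populations whose founders were
already related, a bias the simulator reproduces.

`detect_roh()` is a consecutive-SNP scanner: a run is a maximal stretch
of consecutive SNPs with at most `max_opp_run` heterozygous and
`max_miss_run` missing calls *in total*, no inter-SNP gap above
`max_gap`, at least `min_snp` SNPs and `min_length` bp (defaults 1, 1,
1 Mb, 100, 1 Mb). All *maximal* qualifying windows are emitted — the
implementation is verified against a brute-force enumerator — which means
two runs can overlap around a heterozygote that exhausts the budget.
`froh()` therefore divides the *union* of an individual's run intervals
by the SNP-covered genome length (per-chromosome span of first to last
SNP), keeping F_ROH within [0, 1]. `roh_islands()` computes the
percentage of individuals whose runs cover each SNP, thresholds at the
85th percentile of those incidences (ties included — i.e. the top 15% of
SNP incidence values), and reports maximal consecutive SNP intervals at
or above the threshold.

# GWAS

Both scans correct for relatedness with the VanRaden genomic relationship
matrix and for structure with 3 genotype principal components; markers
below MAF 0.025 are normally removed first (`filter_maf()`); significance
uses Benjamini–Hochberg FDR at 0.05.

The single-SNP test is P3D/EMMAX: variance components are REML-estimated
once under the null (spectral decomposition of the kinship, 1-D profile
over the variance ratio), then each SNP gets a generalized-least-squares
Wald t-test in the whitened basis. The exact per-SNP REML refit is
available as `method = "exact"` and doubles as the accuracy reference —
on test instances, −log10 p differs by well under 0.2.

The SNP-set scan slides a window of `2 * window_half + 1` SNPs (default
41) one focal SNP at a time and tests a window-specific random effect
whose covariance is the linear kernel of the window's standardized
genotypes. Two test statistics are offered:

* **Score test (default).** A variance-component score statistic referred
  to its exact weighted-chi-square null distribution (Imhof integration,
  Liu moment-matching as fallback). Its null p-values are continuous and
  uniform, which makes genome-wide FDR control and calibration checks
  clean.
* **Restricted LRT (`test = "lrt"`).** The REML likelihood-ratio
  statistic against the 0.5·χ²₀ + 0.5·χ²₁ boundary mixture. Because the
  variance-ratio estimate sits on the boundary for about half of null
  windows, these p-values have an atom at 1: valid, but *not* uniform,
  so distribution-shaped diagnostics (QQ plots, KS tests) will flag
  them. The LRT concentrates evidence better and is the more powerful
  choice when a window truly carries several causal variants.

The default is the score test precisely because a boundary LRT cannot
deliver uniform null p-values — the two goals (the classical mixture
test and calibration-grade uniformity) are mutually exclusive, and we
resolve the conflict in favour of calibration, keeping the LRT as an
option.

One empirical observation from the simulator is worth recording: inside
family-structured LD (full-sib families segregate chromosome-scale
haplotype blocks), a *single-SNP* scan almost always attains a smaller
minimum p than the windowed test, because any one marker in phase with
the local haplotype tags the entire block. The windowed test earns its
keep when causal variants inside a window are individually weak and not
strongly tagged — the classic multi-variant regime, which is how the
package's power comparison is constructed (unlinked markers, five causal
SNPs of about 2.4% variance each inside one 41-SNP window).

# Genomic prediction

`fit_gblup()` fits four models: additive (A), additive + inbreeding
fixed effect (AF), additive + dominance (AD), and all three (ADF).
Additive covariance is the VanRaden matrix; dominance uses the
heterozygosity-coded matrix H_ik = het − 2p_k q_k normalised by
Σ 2p_k q_k (1 − 2p_k q_k). Note that this dominance parameterisation is
orthogonal to the additive coding only at allele frequency 1/2; away
from it the two matrices are mildly positively correlated, which is a
property of the coding, not a bug. Single-kernel fits use the spectral
REML; two-kernel fits optimise the two variance ratios numerically
(Nelder–Mead, started from the single-kernel solutions). Both are
stabilised with a 1e-6 diagonal ridge. BLUPs for unphenotyped
individuals come from their kernel rows, which is how test sets are
predicted. Estimated single-kernel BLUPs coincide with ridge regression
on centered markers (RR-BLUP equivalence), a property the test suite
checks numerically.

The inbreeding slope b (phenotype units per unit F; "inbreeding
depression parameter" in the directional-dominance literature) is a
fixed effect on a *marker-based* inbreeding coefficient — F_ROH in the
standard pipeline. Identifiability deserves a warning: F is itself
structured along families, so b competes with the additive random
effect. In shallow two-generation pedigrees the REML fit attenuates b
noticeably; with four or more generations of parental crossing (more
inbreeding loops, more Mendelian-sampling variance in realised F) the
slope is recovered essentially unbiasedly — the parameter-recovery
study uses such a design (about 500 individuals, five chromosomes,
twenty replicates). The projection of an estimated inbreeding effect
onto descendants simply halves per generation
(`project_inbreeding_effect()`).

`run_train_scenarios()` reproduces the three-design comparison: Train 1
(parents, platform-B markers), Train 2 (parents, merged markers), Train 3
(parents plus all non-test families, merged markers), always predicting
the dual-genotyped families. Training sets never contain test
individuals; accuracy is Pearson r (negative estimates reported as 0,
matching the field's convention) and RMSE. On simulated data with
heritability 0.5, Train 3 clearly beats Train 1 on average — population
size matters more than the platform-B marker difference.

# Numerical choices and degenerate inputs

* REML profile searches bracket log-ratio grids ([−10, 10] in 41 steps)
  then refine with `optimize`; residual variances are floored at 1e-12
  (constant response gives a warning, not an error).
* Zero-variance markers are excluded from kernels with a warning;
  missing genotypes are mean-imputed per marker for kernels, PCs and
  association testing (typical pipelines impute before GWAS, so
  this path only handles residual missingness).
* Monomorphic SNP-set windows have a zero kernel and return p = 1;
  SNPs collinear with covariates are flagged and given p = 1.
* Imhof integration is clamped to [1e-300, 1] and falls back to the Liu
  approximation if the integral misbehaves.
* The family DP breaks cost ties toward fewer crossovers, making results
  deterministic.

# Problem sizes used in the checks

The shipped tests run the full chain at desk scale: the default
simulated study (about 250 individuals × 2,141 merged markers), null
calibrations with 2,000 single-SNP tests and 2,000 non-overlapping
windows at n = 200, twenty-replicate recovery studies at n ≈ 500, and
ROH verification on 200 random instances of up to 500 SNPs. These sizes
were chosen so the whole suite completes in minutes on a laptop while
every statistical check retains enough resolution to fail loudly if an
estimator is wrong.

# Known limitations

* No genotyping-error model beyond missingness is enabled by default;
  the masking evaluation is correspondingly optimistic and symmetric
  between platforms (see above).
* Founder phasing relies on simulation truth (or an external phaser);
  population-LD imputation of parentless individuals is out of scope.
* Pedigree F assumes non-inbred, unrelated founders.
* The dominance matrix follows the heterozygosity coding; genotypic
  dominance variance estimated under it is not directly comparable to
  breeding-value parameterisations.
* Single fixed hold-out evaluation (the dual-genotyped families); no
  cross-validation folds.
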