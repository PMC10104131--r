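---
title: "Methods: duplex energetics, two-locus genetics and blood-pressure association for the linked AGT variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: duplex energetics, two-locus genetics and blood-pressure association for the linked AGT variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agtlink)
```

`agtlink` analyses the two tightly linked angiotensinogen (*AGT*)
variants rs699 A>G (a missense change in exon 2, U>C on the mRNA) and
rs5051 C>T (a promoter variant that raises transcription). The two
sit in strong linkage disequilibrium, so their individual effects on
microRNA regulation and blood pressure can only be separated in the
rare subjects who carry more of one variant allele than the other.
The package provides the four analysis layers needed to study that
question, plus a seeded cohort generator so the whole pipeline can be
exercised and validated without access to restricted biobank data.

## 1. Duplex energetics

### Model

`fold_duplex()` computes the minimum free energy (MFE) of an
intermolecular RNA:RNA duplex under the nearest-neighbor model:
structures are chains of canonical pairs (AU, GC and the G-U wobble)
between the two strands, hybridizing antiparallel (pairs sorted by
position on the miRNA have strictly decreasing positions on the
target). The energy of a structure is

* one duplex **initiation** penalty (default 4.09 kcal/mol),
* a **stacking** energy for each adjacent pair doublet, from the
  published 37 °C nearest-neighbor table covering all Watson-Crick and
  wobble doublets,
* a **loop** penalty for each bulge or interior loop between
  consecutive pairs, tabulated by total unpaired length with a
  logarithmic tail, plus a Ninio-style asymmetry term for interior
  loops (0.6 kcal/mol per unpaired-length difference, capped at 3.0),
* a **terminal AU/GU** penalty (0.45 kcal/mol) at each end of the
  duplex whose closing pair is AU, UA, GU or UG.

Only intermolecular structure is considered: no intramolecular
folding of either strand, no ensembles or partition functions. This
matches the scope of a duplex-MFE scan, and its known blind spots
(target-site accessibility, RNA-binding-protein competition, base
modifications) are the reasons duplex predictions should be read
conservatively.

The dynamic program is exact over this structure space. It is written
in C++ because the scramble null (below) folds thousands of targets;
the recursion is over the suffix energies `R[i,j]` of a duplex whose
leftmost pair is `(i, j)`, with transitions limited to loops of total
span at most `max_loop_span` (default 30 nt).

### Numerical choices

* **No canonical pair at all** returns the no-interaction sentinel:
  `delta_g = 0` with an empty structure. A weak single-pair "duplex"
  has positive energy (initiation plus terminal penalties, no stacks)
  and is reported as such; scrambled targets can therefore legitimately
  show positive MFEs.
* **Co-optimal structures** are resolved deterministically: the
  reported structure is the one whose pair list is lexicographically
  smallest. This makes outputs bit-reproducible across runs.
* **Single-nucleotide bulges** retain the stacking energy of their
  flanking pairs, as in the reference nearest-neighbor treatment;
  consequently the bulge penalty table alone is not monotone from size
  1 to 2, but effective loop costs are. All other loops are scored by
  length and asymmetry only.
* **DNA input** (T residues) is transcribed to U on ingest, with a
  message.
* Dangling ends and terminal mismatches are not scored. This is a
  deliberate simplification of the full Turner model; energies are
  therefore expected to differ by fractions of a kcal/mol from tools
  that score them. For this reason the published −11.3/−12.3 kcal/mol
  energies of the real *AGT* window are treated as context, not as a
  gating test (the assayed oligo sequence, which includes cloning
  primer ends, is also not redistributable here; the package ships a
  clearly labelled synthetic stand-in window instead, see
  `synthetic_agt_window()`).

`duplex_energy_of_structure()` re-scores an explicit pair list by
plain summation, independent of the search; every returned structure
re-scores to its reported energy to within 1e-9 kcal/mol, and the test
suite also checks the DP against exhaustive enumeration of all
structures for short sequences.

### The scramble null and the percent-of-range statistic

A raw ΔΔG between two alleles has no natural scale. `scramble_null()`
builds the package's contextualization: the target is permuted
uniformly at random (Fisher-Yates; composition preserved) `n` times
(default 2000, default seed 699), each permutation is folded, and the
*weakest* (least negative) scramble MFE becomes the upper end of the
plausible binding range; the lower end is the energy of a perfectly
complementary siRNA (`perfect_match_dg()`). `percent_of_range()` then
expresses `dg_ref − dg_var` as a percentage of that span, with an
integer rounding that rounds halves away from zero. The statistic is
invariant to shifting all four energies by a constant, and both the
minimum and maximum scramble energies are retained so either reading
of "smallest ΔG" is recoverable; the weakest-binding reading is the
default because it is the one used as the highest plausible value.

## 2. Two-locus genetics

Genotypes are reduced to effect-allele counts, rs699 G and rs5051 T,
both on the positive genomic strand. `assign_group()` encodes the
nine genotype combinations into the ordinal groups 1-9, ranked first
by allele imbalance `t5051 − g699` (groups 1-3 carry more promoter T,
4-6 are balanced, 7-9 carry more missense G) and within an imbalance
level by total variant-allele count; the five-level binned form
({1}, {2,3}, {4,5,6}, {7,8}, {9}) isolates the unbalanced classes.
Missing genotypes propagate to missing groups and are excluded
listwise downstream, with counts reported.

`em_haplotype_frequencies()` estimates the four haplotype frequencies
(GT, GC, AT, AC) from unphased group counts by
expectation-maximization. Only the double heterozygote (group 5) is
phase-ambiguous; each iteration splits it between the GT/AC and GC/AT
configurations in proportion to the current products
`f_GT·f_AC : f_GC·f_AT`. Iteration stops when the multinomial
log-likelihood improves by less than 1e-10 (cap 1000 iterations); the
likelihood is non-decreasing by construction and the suite checks the
converged value against an independent simplex grid search (coarse
0.01 grid refined locally to 0.001).

From haplotype frequencies the package derives: `ld_stats()` (D, D′
and r²), `expected_group_frequencies()` (the Hardy-Weinberg
push-forward onto the nine groups, which always sums to 1), and
`discordant_fraction()` (both the allele-level fraction `f_AT + f_GC`
and the expected fraction of *people* in the unbalanced groups; the
two denominators are reported separately because summaries in the
field mix them). `table1_haplotype_frequencies()` back-solves the
default frequencies from the published all-populations combination
table (homozygote classes give f_GT and f_AC, the rare cross terms
give f_AT and f_GC; renormalized). These imply r² ≈ 0.97; published
r² values near 0.94 come from different 1000 Genomes extracts, so no
equality is asserted.

Dosage handling follows the best-guess convention: `round_dosage()`
rounds imputed dosages in [0, 2] to the nearest whole count with
halves away from zero. `read_genotypes()` reads VCF (via `vcfR`) and
PLINK `.raw` tables, flips counts when the file's orientation differs
from the declared effect alleles, and logs the flip.

## 3. Blood-pressure association

`clean_phenotypes()` averages systolic/diastolic readings over up to
four visit instances, excluding individual readings outside
plausibility bounds (defaults 60-270 mmHg systolic, 30-160 diastolic
-- these bounds are this package's decision, stated here because the
upstream cleaning conventions of biobank analyses are not fully
standardized), derives `mean_bp = (sbp + dbp)/2`, and drops (and
counts) subjects with no valid reading.

`fit_linear()`/`fit_logistic()` fit the phenotype on an intercept,
one genotype encoding and the eleven lifestyle/biomarker covariates
(sex, age, BMI, smoking 0-2, physical activity 0-2, alcohol 1-6 with
6 = never, salt-adding 1-4, CRP, apolipoproteins A and B, education
score), all on their raw scales. The fits are ordinary least squares
and maximum-likelihood logit (IRLS) via base R's `lm()`/`glm()`; the
test suite checks them against a normal-equations oracle and the
closed-form 2×2 log odds ratio. The ordinal group (1-9) and binned
group (1-5) encodings enter as single numeric covariates so that each
model reports one slope per encoding, matching how a single estimate
per genotype grouping is interpreted; a categorical encoding is also
exposed for factor-style contrasts, and the two give identical
predictions whenever only two genotype classes are present. Analysis
is complete-case with conserved row accounting; rank-deficient designs
fail with the collinear terms named, and suspected separation in the
logit fit is warned about. Normality is not formally tested;
`phenotype_diagnostics()` logs skewness/kurtosis instead, non-gating.

`zscore_normalize()` divides estimates by the full-cohort phenotype
standard deviation (computed on the cleaned cohort before any
stratification), making effects comparable across phenotypes;
`stratified_fits()` refits the identical specification within strata
(age bands, medication use, race/ethnicity group) and reports
per-stratum sample sizes. Age of diagnosis is modeled as a linear
outcome among diagnosed subjects only. No multiple-testing adjustment
is applied; p-values are nominal.

## 4. qPCR expression statistics

`ddct_fold_changes()` implements comparative-Ct analysis with a fixed
amplification efficiency of 2 (no standard-curve correction): per
sample ΔCt = Ct(AGT) − Ct(GAPDH); ΔΔCt subtracts the mean ΔCt of the
wild-type construct group, so the wild-type group mean ΔΔCt is 0 by
construction; relative expression is 2^−ΔΔCt. Both replicate
conventions are provided, because published analyses vary: technical
replicates averaged within biological replicate first
(`averaged_tech`) or entered separately (`separate_tech`). Group
comparisons use the two-sided Welch t-test (`two_sample_ttest()`),
chosen over the pooled test because equal variances across transfected
constructs should not be assumed; with equal group sizes the two
statistics coincide anyway. Degenerate zero-variance inputs follow
fixed conventions (equal means: t = 0, p = 1; unequal: t = ±Inf,
p = 0) so that noiseless fixtures are analysable. No outlier-Ct rule
is applied by default. `junction_usage_fraction()` is the plain
percentage of non-canonical junction reads among all junction reads at
an exon boundary; read extraction from alignments is out of scope.

## 5. The synthetic cohort generator

`simulate_cohort()` generates data with exactly the structure the
analysis assumes, so that every estimator above can be tested as a
round trip against known truth:

* **Genetics.** Each subject's population is drawn by proportion;
  two haplotypes are drawn i.i.d. from that population's frequencies,
  i.e. Hardy-Weinberg at the haplotype level with LD carried by the
  haplotype frequencies themselves. The default is a two-population
  mixture mirroring the reported ancestry contrast: a 94% stratum with
  rs5051 T frequency 0.40 and a 6% stratum with T frequency 0.88, both
  in strong LD.
* **Covariates.** Age ~ U(40, 70) years, sex ~ Bernoulli(0.5),
  BMI ~ N(27, 4.5) kg/m², ordinal covariates uniform over their
  declared ranges, CRP ~ logN(log 1.5, 0.9) mg/L,
  apoA ~ logN(log 1.5, 0.15) g/L, apoB ~ logN(log 1.0, 0.2) g/L,
  education score ~ U(7, 20). These distributions are this package's
  documented defaults; they are deliberately simple (independent
  covariates, no age-BMI correlation, no measurement error).
* **Phenotypes.** Systolic BP is the linear predictor under the
  default coefficient set `default_bp_coefficients()` — the
  covariate-adjusted estimates reported by a large biobank analysis,
  used here as *generative inputs* — plus N(0, 18 mmHg) noise; the
  default genotype effect is 0.35 mmHg per rs5051 T allele, with the
  default populations overriding it to 0.25 and 1.17 mmHg so that
  stratified analyses have a real contrast to find. Diastolic BP is
  0.6·SBP + N(0, 8); hypertension is the indicator SBP ≥ 140 mmHg,
  with an age of diagnosis drawn for cases. The 18 mmHg residual SD,
  the diastolic coupling and the threshold are package defaults, not
  published quantities.
* **Missingness** is applied last, independently per field.

Everything is reproducible bit-for-bit from the spec's seed, and the
global RNG state is restored afterwards. `write_fixtures()` emits
VCF, PLINK `.raw`, phenotype CSV and a truth JSON that regenerates the
cohort; `simulate_qpcr()` does the analogous job for Ct tables (GAPDH
Ct ~ N(18, ct_sd) per well, AGT Ct offset by the baseline ΔCt minus
log2 of the true fold), with defaults anchored to a liver-like
near-1.8-fold contrast.

What passing tests on these cohorts do **not** show: recovery of the
actual biobank estimates (those require the restricted individual-level
data), robustness to covariate measurement error, population
stratification beyond the two-stratum mixture, genotyping or
imputation error beyond simple missingness, or real qPCR artifacts
such as efficiency drift. The printed effect sizes
(0.11/0.10/0.36/0.35/−0.25/0.25/1.17 mmHg, the 1.8/2.0/1.1-fold
changes, the 10% splice fraction) appear in this package only as
generative defaults and documentation.

## Problem sizes and tolerances used in validation

The shipped validation uses: exhaustive duplex enumeration for
sequence pairs up to 8 nt (500 random pairs in the acceptance suite);
2000-scramble nulls; EM round trips at 10,000 subjects (tolerance
±0.01 on frequencies) with grid-oracle likelihood agreement within
1e-4 on 100-subject tables; association recovery on 50,000-subject
cohorts. Because a 2-standard-error band has ~95% coverage per
coefficient, recovery across the 13 coefficients is judged as a
coverage property over several seeded cohorts (the count of
deviations beyond 2 SE must stay within its binomial bound, and no
deviation may exceed 4 SE), rather than demanding every coefficient
of a single draw to land inside 2 SE, which a correct generator fails
for roughly half of seeds. The qPCR null holds its nominal 0.05 size
within binomial error over 200 seeded replicates.

## Known limitations

The duplex model omits dangling-end/terminal-mismatch terms and all
intramolecular structure; energies are comparable within this package
but not identical to full-featured folding engines. The EM treats the
two loci only (no multi-locus phasing) and assumes HWE within the
sample supplied to it — applying it to a mixed cohort estimates
pooled-pool frequencies and inherits Wahlund-type distortion of r².
The association layer is deliberately plain OLS/logit: no mixed
models, kinship or ancestry principal components, so it reproduces the
analysis style it models rather than state-of-the-art GWAS practice.
The generator's covariates are independent by construction, which
makes covariate confounding tests conservative.
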