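# agtlink

Analysis toolkit for the two tightly linked angiotensinogen (*AGT*)
variants **rs699 A>G** (missense, exon 2; U>C on the mRNA) and
**rs5051 C>T** (promoter). Angiotensinogen is the liver-secreted
precursor of angiotensin II, so even small shifts in its expression
matter for blood pressure. The two variants sit in strong linkage
disequilibrium (r² near 0.95), which means their individual effects —
a candidate microRNA-binding change at rs699 versus increased
transcription from rs5051 — can only be separated in the rare
subjects carrying more of one variant allele than the other. The
package is aimed at statistical geneticists and molecular biologists
who want to analyse (or simulate) exactly that situation.

It provides four analysis layers plus a generator:

1. **Duplex energetics** — intermolecular RNA:RNA minimum free energy
   by nearest-neighbor dynamic programming. For a miRNA *m* and
   target *t*, structures are antiparallel chains of canonical pairs
   (AU, GC, G·U) and

   ΔG = ΔG_init + Σ stacks + Σ loop(ℓ₁, ℓ₂) + terminal AU/GU ends,

   with the published 37 °C stacking table embedded. A scrambled-target
   null (`scramble_null()`, default 2000 Fisher–Yates permutations) and
   the perfectly complementary siRNA bound (`perfect_match_dg()`)
   define a plausible binding range, and a variant's ΔΔG is expressed
   as a percent of that span:
   `100 · (ΔG_ref − ΔG_var) / (ΔG_weakest-scramble − ΔG_perfect-match)`.
2. **Two-locus genetics** — EM estimation of the four haplotype
   frequencies (GT, GC, AT, AC) from unphased genotypes, LD statistics
   (D, D′, r²), the Hardy–Weinberg push-forward onto the nine
   combined-genotype groups, and the ordinal 1–9 / binned 1–5 group
   encodings ranked by allele imbalance t5051 − g699.
3. **Association** — covariate-adjusted OLS/logistic models of
   blood-pressure phenotypes on genotype encodings, with z-score-like
   scaling (estimate ÷ cohort SD) and stratified refits.
4. **Expression statistics** — comparative-Ct qPCR fold changes
   (2^−ΔΔCt, GAPDH-normalized, wild-type-referenced) with Welch
   t-tests, and the non-canonical splice-junction usage percentage.
5. **Synthetic cohorts** — seeded biobank-style genotype + phenotype
   tables (haplotypes in LD, eleven covariates, linear SBP model,
   hypertension labels, qPCR Ct tables) with a truth record, so the
   full pipeline is testable without restricted data.

## Worked example

```r
library(agtlink)

## mirSNP energetics: miR-122-5p vs the packaged synthetic AGT-like
## window (the assayed oligo is not redistributable); the rs699-style
## U>C change converts a G-U wobble into G-C
win <- synthetic_agt_window()
compare_alleles(mir122_5p(), win$target, win$offset, win$alt)
#> Reference: -36.16 kcal/mol (22 pairs)  Variant: -38.46 kcal/mol (22 pairs)
#> ddG = -2.30 kcal/mol; pairs +0 (-1 G-U)

scramble_null(mir122_5p(), win$target, n = 2000, seed = 699)
#> Scramble null (n = 2000, seed = 699): weakest -3.6, strongest -23.2, perfect match -38.5 kcal/mol
#> Plausible range: -3.6 to -38.5 kcal/mol

## the percent-of-range statistic on published duplex energies:
## a 1 kcal/mol strengthening over the (-7.1, -39.3) range
str(percent_of_range(-11.3, -12.3, -7.1, -39.3))
#> List of 3
#>  $ percent        : num 3.11
#>  $ span           : num 32.2
#>  $ percent_rounded: int 3

## two-locus genetics from the back-solved haplotype frequencies
hf <- table1_haplotype_frequencies()
round(hf, 4)
#>     GT     GC     AT     AC
#> 0.7059 0.0018 0.0045 0.2878
round(ld_stats(hf)$r2, 3)
#> [1] 0.97
round(expected_group_frequencies(hf), 4)
#>      1      2      3      4      5      6      7      8      9
#> 0.0000 0.0064 0.0026 0.4983 0.4063 0.0828 0.0025 0.0010 0.0000

## association on a simulated 50,000-subject cohort generated with a
## 0.35 mmHg-per-T-allele genotype effect
co <- simulate_cohort(cohort_spec(n_subjects = 50000, seed = 1,
  populations = list(list(label = "all", proportion = 1, hap_freq = hf)),
  genotype_effect = 0.35))
rec <- clean_phenotypes(co$phenotypes)
fit <- fit_linear("sbp", rec, co$genotypes, encoding = "allele_dosage_rs5051")
fit[fit$term == "t5051", ]
#>   term estimate    se statistic p_value
#>  t5051    0.249 0.126      1.98  0.0481
```

Reading the output: the variant allele strengthens miRNA binding by
2.3 kcal/mol on the synthetic window; on the published energies the
strengthening is 3% of the 32.2 kcal/mol plausible span. The
back-solved haplotype frequencies imply r² ≈ 0.97 and reproduce the
heterozygous combination frequencies (0.0064, 0.0026, 0.0025, 0.0010).
The cohort regression recovers the generating 0.35 mmHg effect to
within its standard error (0.25 ± 0.13 at this seed).

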