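#' Specification for a synthetic biobank-style cohort
#'
#' Collects every parameter of the cohort generator: sample size, one
#' or more ancestry populations (each with its own two-locus haplotype
#' frequencies and, optionally, its own genotype effect on systolic
#' blood pressure), the linear-model coefficients for systolic blood
#' pressure, the residual noise, the hypertension threshold and
#' per-field missingness.  The default coefficients are the
#' covariate-adjusted systolic-blood-pressure estimates observed in a
#' large biobank analysis; the default genotype effect is 0.35 mmHg per
#' rs5051 T allele.  The default populations mirror a European-ancestry
#' majority (rs5051 T frequency 0.40, genotype effect 0.25 mmHg) with
#' an African-ancestry minority (T frequency 0.88, effect 1.17 mmHg),
#' so stratified analyses have structure to find.
#'
#' @param n_subjects number of subjects.
#' @param populations list of populations, each a list with `label`,
#'   `proportion`, `hap_freq` (four frequencies GT, GC, AT, AC) and
#'   optional `genotype_effect` overriding the global one.
#' @param coefficients named vector of linear-model terms for systolic
#'   blood pressure (intercept + 11 covariates), mmHg per unit.
#' @param genotype_effect mmHg per rs5051 T allele (global default,
#'   overridable per population).
#' @param noise_sd residual SD of systolic blood pressure, mmHg.
#' @param dbp_slope,dbp_noise_sd diastolic pressure is
#'   `dbp_slope * sbp + N(0, dbp_noise_sd)`.
#' @param htn_threshold systolic threshold (mmHg) defining the
#'   hypertension label.
#' @param missingness per-field missingness probability, applied last
#'   to genotypes and covariates.
#' @param seed RNG seed; the cohort is bit-identical for identical
#'   specs.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 10000L,
                        populations = default_populations(),
                        coefficients = default_bp_coefficients(),
                        genotype_effect = 0.35,
                        noise_sd = 18,
                        dbp_slope = 0.6,
                        dbp_noise_sd = 8,
                        htn_threshold = 140,
                        missingness = 0,
                        seed = 1L) {
  props <- vapply(populations, `[[`, numeric(1), "proportion")
  if (abs(sum(props) - 1) > 1e-9) stop("population proportions must sum to 1")
  for (p in populations) as_hap_freq(p$hap_freq)
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (missingness < 0 || missingness >= 1) stop("missingness must be in [0, 1)")
  structure(list(n_subjects = as.integer(n_subjects),
                 populations = populations,
                 coefficients = coefficients,
                 genotype_effect = genotype_effect,
                 noise_sd = noise_sd, dbp_slope = dbp_slope,
                 dbp_noise_sd = dbp_noise_sd,
                 htn_threshold = htn_threshold,
                 missingness = missingness, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_bp_coefficients <- function() {
  c(intercept = 73.825, sex = -6.450, age = 0.6715, bmi = 0.7195,
    smoking = -0.889, activity = 0.759, alcohol = -0.497, salt = -0.818,
    crp = 0.0653, apo_a = 7.250, apo_b = 7.966, education = 0.0294)
}

#' @rdname cohort_spec
#' @export
default_populations <- function() {
  list(list(label = "White", proportion = 0.94,
            hap_freq = c(GT = 0.395, GC = 0.005, AT = 0.005, AC = 0.595),
            genotype_effect = 0.25),
       list(label = "Black", proportion = 0.06,
            hap_freq = c(GT = 0.87, GC = 0.01, AT = 0.01, AC = 0.11),
            genotype_effect = 1.17))
}

#' Simulate a synthetic cohort
#'
#' Generates genotypes and phenotypes with the statistical structure
#' the association analysis assumes.  Per subject: a population is
#' sampled by proportion; two haplotypes are drawn i.i.d. from that
#' population's frequencies (Hardy-Weinberg at the haplotype level);
#' covariates are drawn from documented defaults (age U(40, 70), sex
#' Bernoulli(0.5), BMI N(27, 4.5), ordinal covariates uniform over
#' their declared ranges, biomarkers log-normal, education U(7, 20));
#' systolic blood pressure is the linear predictor plus N(0, noise_sd);
#' diastolic pressure is coupled to systolic; the hypertension label is
#' a systolic threshold, with an age of diagnosis for cases; field
#' missingness is applied last.  Fully reproducible from the spec's
#' seed; the global RNG state is restored on exit.
#'
#' @param spec a [cohort_spec()].
#' @return Object of class `synthetic_cohort`: list with `genotypes`
#'   (subject_id, g699, t5051, dosage_source), `phenotypes`
#'   (subject_id, sbp_0, dbp_0, covariates, htn, age_of_diagnosis,
#'   on_bp_med, race_group) and `truth` (the spec plus the generating
#'   coefficients and haplotype frequencies).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)

  n <- spec$n_subjects
  labs <- vapply(spec$populations, `[[`, character(1), "label")
  props <- vapply(spec$populations, `[[`, numeric(1), "proportion")
  pop <- sample.int(length(labs), n, replace = TRUE, prob = props)

  g699 <- integer(n); t5051 <- integer(n); gt_eff <- numeric(n)
  for (k in seq_along(labs)) {
    idx <- which(pop == k)
    if (!length(idx)) next
    p <- as_hap_freq(spec$populations[[k]]$hap_freq)
    h1 <- sample.int(4, length(idx), replace = TRUE, prob = p)
    h2 <- sample.int(4, length(idx), replace = TRUE, prob = p)
    # haplotypes: 1 = GT, 2 = GC, 3 = AT, 4 = AC
    g699[idx] <- (h1 <= 2) + (h2 <= 2)
    t5051[idx] <- (h1 %in% c(1, 3)) + (h2 %in% c(1, 3))
    ge <- spec$populations[[k]]$genotype_effect
    gt_eff[idx] <- if (is.null(ge)) spec$genotype_effect else ge
  }

  cov <- data.frame(
    sex = stats::rbinom(n, 1, 0.5),
    age = stats::runif(n, 40, 70),
    bmi = stats::rnorm(n, 27, 4.5),
    smoking = sample(0:2, n, replace = TRUE),
    activity = sample(0:2, n, replace = TRUE),
    alcohol = sample(1:6, n, replace = TRUE),
    salt = sample(1:4, n, replace = TRUE),
    crp = stats::rlnorm(n, log(1.5), 0.9),
    apo_a = stats::rlnorm(n, log(1.5), 0.15),
    apo_b = stats::rlnorm(n, log(1.0), 0.2),
    education = stats::runif(n, 7, 20))

  b <- spec$coefficients
  lin <- b["intercept"] +
    as.matrix(cov) %*% b[colnames(cov)] +
    gt_eff * t5051
  sbp <- as.numeric(lin) + stats::rnorm(n, 0, spec$noise_sd)
  dbp <- spec$dbp_slope * sbp + stats::rnorm(n, 0, spec$dbp_noise_sd)

  htn <- as.integer(sbp >= spec$htn_threshold)
  age_dx <- ifelse(htn == 1, pmax(20, cov$age - stats::runif(n, 0, 10)), NA)
  on_bp_med <- as.integer(htn == 1 & stats::runif(n) < 0.7)

  subject_id <- sprintf("S%06d", seq_len(n))
  genotypes <- data.frame(subject_id = subject_id,
                          g699 = g699, t5051 = t5051,
                          dosage_source = "hard_call")
  phenotypes <- data.frame(subject_id = subject_id,
                           sbp_0 = sbp, dbp_0 = dbp, cov,
                           htn = htn, age_of_diagnosis = age_dx,
                           on_bp_med = on_bp_med,
                           race_group = labs[pop])

  if (spec$missingness > 0) {
    miss_fields <- c("g699", "t5051")
    for (f in miss_fields)
      genotypes[[f]][stats::runif(n) < spec$missingness] <- NA
    for (f in c("sbp_0", "dbp_0", names(cov)))
      phenotypes[[f]][stats::runif(n) < spec$missingness] <- NA
  }

  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 truth = list(spec = spec,
                              coefficients = b,
                              genotype_effects = stats::setNames(
                                vapply(spec$populations, function(p) {
                                  if (is.null(p$genotype_effect))
                                    spec$genotype_effect else p$genotype_effect
                                }, numeric(1)), labs),
                              hap_freq = lapply(stats::setNames(
                                spec$populations, labs), `[[`, "hap_freq"),
                              seed = spec$seed)),
            class = "synthetic_cohort")
}

#' Simulate a qPCR well table
#'
#' Generates GAPDH and AGT cycle thresholds for a transfection
#' experiment with known true fold changes relative to the wild-type
#' construct: GAPDH Ct is N(18, ct_sd) per well; the same well's AGT Ct
#' is its GAPDH Ct plus a baseline delta-Ct, minus `log2(fold)`, plus
#' N(0, ct_sd).  With `ct_sd = 0` the ddCt analysis recovers the true
#' folds exactly.
#'
#' @param fold_changes named vector of true fold changes per construct;
#'   must include `AGT_A = 1` (added if absent).  Default anchors a
#'   liver-like near-2-fold increase.
#' @param n_bio,n_tech biological and technical replicates per
#'   construct.
#' @param ct_sd per-well Ct noise, cycles.
#' @param baseline_dct wild-type `ct_AGT - ct_GAPDH`, cycles.
#' @param seed RNG seed.
#' @return Data frame of qPCR wells (`bio_rep`, `tech_rep`,
#'   `construct`, `gene`, `ct`) suitable for [ddct_fold_changes()].
#' @export
simulate_qpcr <- function(fold_changes = c(AGT_A = 1, AGT_G = 1.8),
                          n_bio = 4L, n_tech = 3L, ct_sd = 0.3,
                          baseline_dct = 5, seed = 1L) {
  if (any(fold_changes <= 0)) stop("fold changes must be positive")
  if (n_bio < 2L) stop("need n_bio >= 2")
  if (n_tech < 1L) stop("need n_tech >= 1")
  if (!"AGT_A" %in% names(fold_changes))
    fold_changes <- c(AGT_A = 1, fold_changes)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  grid <- expand.grid(tech_rep = seq_len(n_tech), bio_rep = seq_len(n_bio),
                      construct = names(fold_changes),
                      stringsAsFactors = FALSE)
  gapdh <- stats::rnorm(nrow(grid), 18, ct_sd)
  agt <- gapdh + baseline_dct - log2(fold_changes[grid$construct]) +
    stats::rnorm(nrow(grid), 0, ct_sd)
  rbind(data.frame(bio_rep = paste0(grid$construct, "_b", grid$bio_rep),
                   tech_rep = paste0("t", grid$tech_rep),
                   construct = grid$construct, gene = "GAPDH", ct = gapdh),
        data.frame(bio_rep = paste0(grid$construct, "_b", grid$bio_rep),
                   tech_rep = paste0("t", grid$tech_rep),
                   construct = grid$construct, gene = "AGT", ct = agt))
}

#' Write a synthetic cohort to disk as analysis fixtures
#'
#' Emits a two-variant VCF (rs699 REF A / ALT G, rs5051 REF C / ALT T,
#' unphased hard-call genotypes), a PLINK-style `.raw` dosage table, a
#' phenotype CSV and a truth JSON sufficient to regenerate the cohort.
#' Re-reading the genotype files through [read_genotypes()] reproduces
#' the in-memory table.
#'
#' @param cohort a `synthetic_cohort`.
#' @param out_dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(cohort, out_dir) {
  if (!inherits(cohort, "synthetic_cohort")) stop("cohort must be a synthetic_cohort")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(out_dir, "genotypes.vcf"),
             raw = file.path(out_dir, "genotypes.raw"),
             pheno = file.path(out_dir, "phenotypes.csv"),
             truth = file.path(out_dir, "truth.json"))

  g <- cohort$genotypes
  gt_str <- function(x) ifelse(is.na(x), "./.",
                               c("0/0", "0/1", "1/1")[x + 1L])
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", g$subject_id), collapse = "\t"))
  row699 <- paste(c("1", "230710048", "rs699", "A", "G", ".", "PASS", ".",
                    "GT", gt_str(g$g699)), collapse = "\t")
  row5051 <- paste(c("1", "230714139", "rs5051", "C", "T", ".", "PASS", ".",
                     "GT", gt_str(g$t5051)), collapse = "\t")
  writeLines(c(hdr, row699, row5051), paths["vcf"])

  raw <- data.frame(FID = g$subject_id, IID = g$subject_id,
                    PAT = 0L, MAT = 0L, SEX = 0L, PHENOTYPE = -9L,
                    rs699_G = g$g699, rs5051_T = g$t5051,
                    check.names = FALSE)
  utils::write.table(raw, paths["raw"], sep = " ", quote = FALSE,
                     row.names = FALSE, na = "NA")

  utils::write.csv(cohort$phenotypes, paths["pheno"], row.names = FALSE,
                   na = "")

  tr <- cohort$truth
  jsonlite::write_json(
    list(seed = tr$seed,
         n_subjects = tr$spec$n_subjects,
         coefficients = as.list(tr$coefficients),
         genotype_effects = as.list(tr$genotype_effects),
         hap_freq = lapply(tr$hap_freq, as.list),
         noise_sd = tr$spec$noise_sd,
         htn_threshold = tr$spec$htn_threshold,
         missingness = tr$spec$missingness),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
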