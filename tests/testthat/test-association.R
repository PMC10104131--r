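# small helper: genotype table with one row per record
toy_genotypes <- function(ids, g699, t5051) {
  data.frame(subject_id = ids, g699 = g699, t5051 = t5051,
             dosage_source = "hard_call")
}

test_that("phenotype cleaning averages instances and derives mean BP", {
  raw <- data.frame(subject_id = c("a", "b", "c"),
                    sbp_0 = c(140, 120, NA), sbp_1 = c(150, NA, NA),
                    sbp_2 = NA_real_, sbp_3 = NA_real_,
                    dbp_0 = c(90, 80, NA), dbp_1 = c(92, NA, NA),
                    age = c(50, 60, 70))
  expect_message(cl <- clean_phenotypes(raw), "1 subject\\(s\\) dropped")
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$sbp, c(145, 120))
  expect_equal(cl$dbp, c(91, 80))
  expect_equal(cl$mean_bp, (cl$sbp + cl$dbp) / 2)
  expect_identical(attr(cl, "n_dropped"), 1L)
})

test_that("out-of-range readings are excluded before averaging", {
  raw <- data.frame(subject_id = "a",
                    sbp_0 = 140, sbp_1 = 150, sbp_2 = 20, sbp_3 = 300,
                    dbp_0 = 80, dbp_1 = 500)
  cl <- clean_phenotypes(raw)
  expect_equal(cl$sbp, 145)          # 20 and 300 fall outside the bounds
  expect_equal(cl$dbp, 80)
  expect_identical(attr(cl, "n_readings_excluded"), 3L)
})

test_that("a noiseless linear relationship is interpolated exactly", {
  g <- expand.grid(g699 = 0:2, t5051 = 0:2)
  ids <- sprintf("s%d", seq_len(nrow(g)))
  geno <- toy_genotypes(ids, g$g699, g$t5051)
  bins <- assign_group(g$g699, g$t5051)$binned
  rec <- data.frame(subject_id = ids, sbp = 71.86 + 0.22 * bins)
  # lm warns that the fit is essentially perfect - that is the point here
  fit <- suppressWarnings(
    fit_linear("sbp", rec, geno, encoding = "group_binned",
               covariates = character(0)))
  expect_equal(fit$estimate[fit$term == "(Intercept)"], 71.86,
               tolerance = 1e-10)
  expect_equal(fit$estimate[fit$term == "binned"], 0.22, tolerance = 1e-10)
})

test_that("OLS coefficients, SEs and p-values match the normal-equations oracle", {
  set.seed(17)
  n <- 20L
  ids <- sprintf("s%d", 1:n)
  geno <- toy_genotypes(ids, sample(0:2, n, TRUE), sample(0:2, n, TRUE))
  rec <- data.frame(subject_id = ids,
                    sbp = rnorm(n, 130, 15),
                    age = runif(n, 40, 70), bmi = rnorm(n, 27, 4))
  fit <- fit_linear("sbp", rec, geno, encoding = "group_ordinal",
                    covariates = c("age", "bmi"))
  gg <- assign_group(geno$g699, geno$t5051)$group
  X <- cbind(1, gg, rec$age, rec$bmi)
  o <- ols_oracle(X, rec$sbp)
  expect_equal(fit$estimate, o$beta, tolerance = 1e-9)
  expect_equal(fit$se, o$se, tolerance = 1e-9)
  expect_equal(fit$statistic, o$t, tolerance = 1e-9)
  expect_equal(fit$p_value, o$p, tolerance = 1e-9)
  expect_identical(attr(fit, "n_used"), n)
})

test_that("complete-case accounting conserves rows and collinearity is named", {
  set.seed(3)
  n <- 30L
  ids <- sprintf("s%d", 1:n)
  geno <- toy_genotypes(ids, sample(0:2, n, TRUE), sample(0:2, n, TRUE))
  rec <- data.frame(subject_id = ids, sbp = rnorm(n, 130, 10),
                    age = runif(n, 40, 70))
  rec$sbp[c(2, 9)] <- NA
  rec$age[5] <- NA
  fit <- fit_linear("sbp", rec, geno, encoding = "group_ordinal",
                    covariates = "age")
  expect_identical(attr(fit, "n_used") + attr(fit, "complete_case_dropped"),
                   n)
  expect_identical(attr(fit, "complete_case_dropped"), 3L)
  rec$age2 <- rec$age   # exact copy: rank-deficient design
  expect_error(fit_linear("sbp", rec, geno, encoding = "group_ordinal",
                          covariates = c("age", "age2")),
               "collinear.*age2")
})

test_that("logistic coefficient on a 2x2 design equals the closed-form log odds ratio", {
  counts <- c(n00 = 40, n01 = 25, n10 = 15, n11 = 35) # (exposure, outcome)
  y <- c(rep(0, 40), rep(1, 25), rep(0, 15), rep(1, 35))
  x <- c(rep(0, 65), rep(1, 50))
  ids <- sprintf("s%d", seq_along(y))
  geno <- toy_genotypes(ids, x, rep(0L, length(y)))   # rs699 carries exposure
  rec <- data.frame(subject_id = ids, htn = y)
  fit <- fit_logistic("htn", rec, geno, encoding = "allele_dosage_rs699",
                      covariates = character(0))
  log_or <- log((counts["n11"] * counts["n00"]) /
                  (counts["n10"] * counts["n01"]))
  expect_equal(fit$estimate[fit$term == "g699"], unname(log_or),
               tolerance = 1e-6)
})

test_that("a balanced outcome independent of predictors fits a null model", {
  set.seed(8)
  n <- 400
  ids <- sprintf("s%d", 1:n)
  geno <- toy_genotypes(ids, sample(0:2, n, TRUE), sample(0:2, n, TRUE))
  rec <- data.frame(subject_id = ids, htn = rep(c(0, 1), n / 2),
                    age = runif(n, 40, 70))
  fit <- fit_logistic("htn", rec, geno, encoding = "group_ordinal",
                      covariates = "age")
  expect_true(all(fit$p_value[fit$term != "(Intercept)"] > 0.01))
})

test_that("ordinal and categorical encodings agree on a binary genotype contrast", {
  set.seed(21)
  n <- 200
  ids <- sprintf("s%d", 1:n)
  # only two genotype classes present: groups 4 and 6
  g <- sample(c(0L, 2L), n, TRUE)
  geno <- toy_genotypes(ids, g, g)
  rec <- data.frame(subject_id = ids, sbp = rnorm(n, 130 + 0.5 * g, 5))
  f_ord <- fit_linear("sbp", rec, geno, encoding = "group_ordinal",
                      covariates = character(0))
  f_cat <- fit_linear("sbp", rec, geno, encoding = "group_categorical",
                      covariates = character(0))
  pred_ord <- fitted(attr(f_ord, "model"))
  pred_cat <- fitted(attr(f_cat, "model"))
  expect_equal(unname(pred_ord), unname(pred_cat), tolerance = 1e-9)
})

test_that("z-scaling divides estimates by the cohort SD and round-trips", {
  set.seed(4)
  n <- 50
  ids <- sprintf("s%d", 1:n)
  geno <- toy_genotypes(ids, sample(0:2, n, TRUE), sample(0:2, n, TRUE))
  rec <- data.frame(subject_id = ids, sbp = rnorm(n, 130, 18))
  fit <- fit_linear("sbp", rec, geno, encoding = "group_ordinal",
                    covariates = character(0))
  z <- zscore_normalize(fit, sd(rec$sbp))
  expect_equal(z$z_like * sd(rec$sbp), z$estimate, tolerance = 1e-12)
  expect_equal(zscore_normalize(fit, 18.7)$z_like, fit$estimate / 18.7)
  expect_error(zscore_normalize(fit, 0), "positive")
})

test_that("stratifying by a constant column reproduces the unstratified fit", {
  set.seed(13)
  n <- 60
  ids <- sprintf("s%d", 1:n)
  geno <- toy_genotypes(ids, sample(0:2, n, TRUE), sample(0:2, n, TRUE))
  rec <- data.frame(subject_id = ids, sbp = rnorm(n, 130, 10),
                    age = runif(n, 40, 70), strat = "all")
  whole <- fit_linear("sbp", rec, geno, encoding = "group_ordinal",
                      covariates = "age")
  sf <- stratified_fits("sbp", rec, geno, "strat",
                        encoding = "group_ordinal", covariates = "age")
  expect_named(sf, "all")
  expect_equal(sf$all$estimate, whole$estimate, tolerance = 1e-12)
  expect_identical(attr(sf$all, "n_used"), attr(whole, "n_used"))
})

test_that("disjoint strata partition the subjects", {
  set.seed(14)
  n <- 80L
  ids <- sprintf("s%d", 1:n)
  geno <- toy_genotypes(ids, sample(0:2, n, TRUE), sample(0:2, n, TRUE))
  rec <- data.frame(subject_id = ids, sbp = rnorm(n, 130, 10),
                    age = runif(n, 40, 70))
  lab <- ifelse(rec$age < 50, "under50", "over50")
  sf <- stratified_fits("sbp", rec, geno, lab,
                        encoding = "group_ordinal", covariates = character(0))
  expect_identical(sum(vapply(sf, attr, integer(1), "n_used")), n)
})

test_that("stratified fits recover population-specific genotype effects", {
  pops <- list(list(label = "White", proportion = 0.7,
                    hap_freq = c(GT = 0.395, GC = 0.005, AT = 0.005,
                                 AC = 0.595), genotype_effect = 0.25),
               list(label = "Black", proportion = 0.3,
                    hap_freq = c(GT = 0.87, GC = 0.01, AT = 0.01,
                                 AC = 0.11), genotype_effect = 1.17))
  spec <- cohort_spec(n_subjects = 30000, populations = pops, seed = 106)
  co <- simulate_cohort(spec)
  rec <- clean_phenotypes(co$phenotypes)
  sf <- stratified_fits("sbp", rec, co$genotypes, "race_group",
                        encoding = "allele_dosage_rs5051")
  truth <- c(White = 0.25, Black = 1.17)
  for (lab in names(truth)) {
    est <- sf[[lab]]$estimate[sf[[lab]]$term == "t5051"]
    se <- sf[[lab]]$se[sf[[lab]]$term == "t5051"]
    expect_lt(abs(est - truth[[lab]]), 2 * se)
  }
})

test_that("phenotype diagnostics flag skewed distributions", {
  set.seed(2)
  d <- phenotype_diagnostics(rnorm(5000))
  expect_lt(abs(d$skewness), 0.15)
  expect_lt(abs(d$excess_kurtosis), 0.3)
  expect_gt(phenotype_diagnostics(rlnorm(5000))$skewness, 1)
})
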