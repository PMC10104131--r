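#' Clean a biobank-style phenotype table
#'
#' Collapses instance-suffixed blood-pressure columns to per-subject
#' means, derives mean blood pressure, and applies plausibility bounds.
#' Systolic and diastolic pressures are averaged over the non-missing
#' visit instances (columns `sbp_0`..`sbp_3`, `dbp_0`..`dbp_3`, any
#' subset present); individual readings outside the declared bounds are
#' excluded before averaging.  Blood-biochemistry covariates are taken
#' from the table as given (first-instance columns by convention).
#' Subjects with no valid blood-pressure reading are dropped and
#' counted.
#'
#' @param raw data frame with a `subject_id` column, instance-suffixed
#'   `sbp_*`/`dbp_*` columns, and covariate columns (any of `sex`,
#'   `age`, `bmi`, `smoking`, `activity`, `alcohol`, `salt`, `crp`,
#'   `apo_a`, `apo_b`, `education`, `htn`, `age_of_diagnosis`,
#'   `on_bp_med`, `race_group`; all optional, carried through).
#' @param sbp_bounds,dbp_bounds plausibility ranges in mmHg for a
#'   single reading.
#' @return Data frame of one row per retained subject with `sbp`,
#'   `dbp`, `mean_bp` and the covariates; attributes `n_dropped`
#'   (subjects with no valid BP) and `n_readings_excluded`
#'   (out-of-range readings).
#' @export
clean_phenotypes <- function(raw, sbp_bounds = c(60, 270),
                             dbp_bounds = c(30, 160)) {
  if (!"subject_id" %in% names(raw)) stop("raw needs a subject_id column")
  inst_mean <- function(prefix, bounds) {
    cols <- grep(paste0("^", prefix, "_[0-9]+$"), names(raw), value = TRUE)
    if (!length(cols)) return(list(x = rep(NA_real_, nrow(raw)), excl = 0L))
    m <- as.matrix(raw[cols])
    bad <- !is.na(m) & (m < bounds[1] | m > bounds[2])
    m[bad] <- NA
    list(x = rowMeans(m, na.rm = TRUE), excl = sum(bad))
  }
  s <- inst_mean("sbp", sbp_bounds)
  d <- inst_mean("dbp", dbp_bounds)
  sbp <- s$x; dbp <- d$x
  sbp[is.nan(sbp)] <- NA; dbp[is.nan(dbp)] <- NA

  keep <- !(is.na(sbp) & is.na(dbp))
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " subject(s) dropped: no valid blood-pressure reading")

  extra <- setdiff(names(raw), grep("^(sbp|dbp)_[0-9]+$", names(raw),
                                    value = TRUE))
  out <- raw[keep, extra, drop = FALSE]
  out$sbp <- sbp[keep]
  out$dbp <- dbp[keep]
  out$mean_bp <- (out$sbp + out$dbp) / 2
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  attr(out, "n_readings_excluded") <- s$excl + d$excl
  out
}

default_covariates <- c("sex", "age", "bmi", "smoking", "activity",
                        "alcohol", "salt", "crp", "apo_a", "apo_b",
                        "education")

# build the model frame for a genotype encoding
encode_predictor <- function(records, genotypes, encoding) {
  gg <- assign_group(genotypes$g699, genotypes$t5051)
  switch(encoding,
         allele_dosage_rs699 = data.frame(g699 = genotypes$g699),
         allele_dosage_rs5051 = data.frame(t5051 = genotypes$t5051),
         group_ordinal = data.frame(group = gg$group),
         group_binned = data.frame(binned = gg$binned),
         group_categorical = data.frame(group = factor(gg$group,
                                                       levels = 1:9)),
         stop("unknown predictor encoding: ", encoding))
}

#' Covariate-adjusted genotype association models
#'
#' Fits a blood-pressure phenotype on a genotype encoding plus
#' covariates.  `fit_linear()` is ordinary least squares (via
#' [stats::lm()]); `fit_logistic()` is a maximum-likelihood logit fit
#' (via [stats::glm()], IRLS) for binary outcomes such as hypertension
#' diagnosis.  The ordinal group encodings enter as single numeric
#' covariates so that one slope per model is reported; the categorical
#' encoding enters as a factor.  Analysis is complete-case; the number
#' of dropped rows is reported and conserved.
#'
#' @param phenotype outcome column name in `records` (e.g. `"sbp"`,
#'   `"dbp"`, `"mean_bp"`, `"age_of_diagnosis"`; binary `"htn"` for
#'   `fit_logistic`).
#' @param records cleaned phenotype data frame (see
#'   [clean_phenotypes()]) with a `subject_id` column.
#' @param genotypes data frame with `subject_id`, `g699`, `t5051`
#'   (matched to `records` by `subject_id`).
#' @param encoding one of `"allele_dosage_rs699"`,
#'   `"allele_dosage_rs5051"`, `"group_ordinal"`, `"group_binned"`,
#'   `"group_categorical"`.
#' @param covariates character vector of covariate column names.
#' @return Object of class `fit_result`: data frame of per-term
#'   `estimate`, `se`, `statistic`, `p_value`, with attributes
#'   `n_used`, `complete_case_dropped`, `phenotype`, `family` and the
#'   fitted model in `model`.
#' @export
fit_linear <- function(phenotype, records, genotypes,
                       encoding = "group_ordinal",
                       covariates = default_covariates) {
  fit_bp_model(phenotype, records, genotypes, encoding, covariates,
               family = "linear")
}

#' @rdname fit_linear
#' @export
fit_logistic <- function(phenotype, records, genotypes,
                         encoding = "group_ordinal",
                         covariates = default_covariates) {
  fit_bp_model(phenotype, records, genotypes, encoding, covariates,
               family = "logistic")
}

fit_bp_model <- function(phenotype, records, genotypes, encoding,
                         covariates, family = c("linear", "logistic")) {
  family <- match.arg(family)
  if (!phenotype %in% names(records))
    stop("phenotype column '", phenotype, "' not in records")
  missing_cov <- setdiff(covariates, names(records))
  if (length(missing_cov))
    stop("missing covariate column(s): ", paste(missing_cov, collapse = ", "))

  idx <- match(records$subject_id, genotypes$subject_id)
  geno <- genotypes[idx, , drop = FALSE]
  pred <- encode_predictor(records, geno, encoding)
  df <- cbind(y = records[[phenotype]], pred, records[covariates])

  n_input <- nrow(df)
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  n_used <- nrow(df)
  if (n_used < ncol(df) + 2L)
    stop("too few complete cases (", n_used, ") for ", ncol(df), " terms")

  form <- stats::as.formula(paste("y ~", paste(names(df)[-1], collapse = " + ")))
  if (family == "linear") {
    fit <- stats::lm(form, data = df)
    if (fit$rank < length(stats::coef(fit))) {
      bad <- names(which(is.na(stats::coef(fit))))
      stop("rank-deficient design; collinear term(s): ",
           paste(bad, collapse = ", "))
    }
    sm <- summary(fit)$coefficients
  } else {
    if (length(unique(df$y)) < 2L)
      stop("logistic fit needs both outcome classes present")
    fit <- withCallingHandlers(
      stats::glm(form, data = df, family = stats::binomial(),
                 control = stats::glm.control(epsilon = 1e-10, maxit = 50)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          warning("possible separation in logistic fit", call. = FALSE)
        invokeRestart("muffleWarning")
      })
    big <- abs(stats::coef(fit)) > 15
    if (any(big[-1], na.rm = TRUE))
      warning("possible separation: diverging coefficient(s) ",
              paste(names(which(big[-1])), collapse = ", "), call. = FALSE)
    sm <- summary(fit)$coefficients
  }

  out <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                    statistic = sm[, 3], p_value = sm[, 4],
                    row.names = NULL)
  structure(out, class = c("fit_result", "data.frame"),
            n_used = n_used, complete_case_dropped = n_input - n_used,
            phenotype = phenotype, family = family, encoding = encoding,
            model = fit)
}

#' Normalize effect estimates to phenotype standard deviations
#'
#' Divides each regression estimate by the full-cohort standard
#' deviation of the phenotype, yielding z-score-like values that are
#' comparable across phenotypes measured in different units (systolic,
#' diastolic, mean blood pressure, age of diagnosis).
#'
#' @param fit a `fit_result`.
#' @param phenotype_sd full-cohort phenotype standard deviation
#'   (computed before any stratification).
#' @return The fit table with an added `z_like` column and a
#'   `phenotype_sd` attribute.
#' @export
zscore_normalize <- function(fit, phenotype_sd) {
  if (!is.numeric(phenotype_sd) || length(phenotype_sd) != 1L ||
      is.na(phenotype_sd) || phenotype_sd <= 0)
    stop("phenotype_sd must be a positive number")
  fit$z_like <- fit$estimate / phenotype_sd
  attr(fit, "phenotype_sd") <- phenotype_sd
  fit
}

#' Stratified association fits
#'
#' Re-fits the same model specification independently within each level
#' of a stratifying variable (e.g. age below/at-or-above 50, blood
#' pressure medication use, race/ethnicity group).  Strata that fail
#' the fit preconditions are skipped with a message.
#'
#' @inheritParams fit_linear
#' @param strata either a column name in `records` or a vector/factor
#'   of stratum labels aligned with `records` rows.
#' @param family `"linear"` or `"logistic"`.
#' @return Named list of `fit_result`s, one per stratum level; each
#'   carries its own `n_used`.
#' @export
stratified_fits <- function(phenotype, records, genotypes, strata,
                            encoding = "group_ordinal",
                            covariates = default_covariates,
                            family = "linear") {
  lab <- if (is.character(strata) && length(strata) == 1L) {
    if (!strata %in% names(records)) stop("stratum column '", strata,
                                          "' not in records")
    records[[strata]]
  } else {
    if (length(strata) != nrow(records))
      stop("strata vector must align with records rows")
    strata
  }
  out <- list()
  for (lev in unique(as.character(lab[!is.na(lab)]))) {
    sub <- records[!is.na(lab) & as.character(lab) == lev, , drop = FALSE]
    fit <- tryCatch(
      fit_bp_model(phenotype, sub, genotypes, encoding, covariates,
                   family = family),
      error = function(e) {
        message("stratum '", lev, "' skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(fit)) out[[lev]] <- fit
  }
  out
}

#' Distribution diagnostics for a phenotype
#'
#' Logged (non-gating) skewness and excess-kurtosis diagnostics used in
#' place of visual normality checks.
#'
#' @param x numeric vector.
#' @return List with `n`, `skewness` and `excess_kurtosis`.
#' @export
phenotype_diagnostics <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  z <- (x - mean(x)) / stats::sd(x)
  list(n = n, skewness = mean(z^3), excess_kurtosis = mean(z^4) - 3)
}
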