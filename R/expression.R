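#' Delta-delta-Ct relative expression
#'
#' Classic comparative-Ct analysis of a transfection qPCR experiment.
#' Each sample's AGT cycle threshold is normalized to its GAPDH
#' housekeeping Ct (`dct = ct_AGT - ct_GAPDH`); samples are then
#' normalized to the mean delta-Ct of the wild-type construct group
#' (`AGT_A`), and relative expression is `2^-ddct` (amplification
#' efficiency fixed at 2).  Under `"averaged_tech"` the technical
#' replicates of each biological replicate are averaged before the
#' computation; under `"separate_tech"` every well enters on its own.
#' A two-sided Welch t-test compares each non-wild-type construct's
#' delta-Ct values against the wild-type group.
#'
#' @param wells data frame with columns `bio_rep`, `tech_rep`,
#'   `construct` (`"AGT_A"`, `"AGT_G"`, `"vector"`, ...), `gene`
#'   (`"AGT"` or `"GAPDH"`) and `ct` (> 0 cycles).
#' @param replicate_mode `"averaged_tech"` or `"separate_tech"`.
#' @return Object of class `fold_change_result`: list with `per_sample`
#'   (data frame of `construct`, `bio_rep`, optionally `tech_rep`,
#'   then `dct`, `ddct`, `fold`), `group_means` (mean fold per
#'   construct), `tests`
#'   (per non-wild-type construct: `t`, `df`, `p_value`) and
#'   `replicate_mode`.
#' @export
ddct_fold_changes <- function(wells,
                              replicate_mode = c("averaged_tech",
                                                 "separate_tech")) {
  replicate_mode <- match.arg(replicate_mode)
  need <- c("bio_rep", "tech_rep", "construct", "gene", "ct")
  if (!all(need %in% names(wells)))
    stop("wells needs columns ", paste(need, collapse = ", "))
  if (any(wells$ct <= 0, na.rm = TRUE)) stop("ct values must be positive")
  if (!any(wells$construct == "AGT_A"))
    stop("need at least one wild-type (AGT_A) sample")

  if (replicate_mode == "averaged_tech") {
    agg <- stats::aggregate(ct ~ construct + bio_rep + gene, data = wells,
                            FUN = mean)
    wide <- stats::reshape(agg, idvar = c("construct", "bio_rep"),
                           timevar = "gene", direction = "wide")
    id_cols <- c("construct", "bio_rep")
  } else {
    wide <- stats::reshape(wells[need], idvar = c("construct", "bio_rep",
                                                  "tech_rep"),
                           timevar = "gene", direction = "wide")
    id_cols <- c("construct", "bio_rep", "tech_rep")
  }
  if (!all(c("ct.AGT", "ct.GAPDH") %in% names(wide)))
    stop("each sample needs both an AGT and a GAPDH Ct")
  incomplete <- is.na(wide$ct.AGT) | is.na(wide$ct.GAPDH)
  if (any(incomplete)) {
    message(sum(incomplete),
            " sample(s) dropped: missing AGT or housekeeping Ct")
    wide <- wide[!incomplete, , drop = FALSE]
  }

  wide$dct <- wide$ct.AGT - wide$ct.GAPDH
  wt_mean <- mean(wide$dct[wide$construct == "AGT_A"])
  wide$ddct <- wide$dct - wt_mean
  wide$fold <- 2^(-wide$ddct)

  group_means <- tapply(wide$fold, wide$construct, mean)
  tests <- list()
  for (cons in setdiff(unique(wide$construct), "AGT_A")) {
    a <- wide$dct[wide$construct == cons]
    b <- wide$dct[wide$construct == "AGT_A"]
    if (length(a) >= 2 && length(b) >= 2)
      tests[[cons]] <- two_sample_ttest(a, b)
  }

  structure(list(per_sample = wide[c(id_cols, "dct", "ddct", "fold")],
                 group_means = group_means,
                 tests = tests,
                 replicate_mode = replicate_mode),
            class = "fold_change_result")
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat("ddCt fold changes (", x$replicate_mode, "):\n", sep = "")
  print(round(x$group_means, 3))
  for (nm in names(x$tests))
    cat(sprintf("  %s vs AGT_A: t = %.3f, p = %.4g\n",
                nm, x$tests[[nm]]$t, x$tests[[nm]]$p_value))
  invisible(x)
}

#' Two-sample two-sided t-test
#'
#' Welch (unequal-variance) two-sided t-test by default, with
#' conventions for the degenerate noiseless case: two groups with zero
#' variance give `t = 0, p = 1` when their means are equal and
#' `t = +-Inf, p = 0` when they differ (the limit of the statistic as
#' noise vanishes).
#'
#' @param group_a,group_b numeric vectors, each with at least 2 values.
#' @param var_equal pooled-variance test instead of Welch.
#' @return List with `t`, `df` and `p_value`.
#' @export
two_sample_ttest <- function(group_a, group_b, var_equal = FALSE) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 values")
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    df0 <- length(group_a) + length(group_b) - 2
    if (mean(group_a) == mean(group_b))
      return(list(t = 0, df = df0, p_value = 1))
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf,
                df = df0, p_value = 0))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Non-canonical splice-junction usage fraction
#'
#' Percentage of exon-junction reads that splice to a non-canonical
#' acceptor, out of all junction reads at the exon boundary.
#'
#' @param canonical_reads,noncanonical_reads nonnegative read counts
#'   (vectorized; per-subject vectors give per-subject fractions).
#' @return Percent values `100 * noncanonical / (canonical +
#'   noncanonical)`.
#' @export
junction_usage_fraction <- function(canonical_reads, noncanonical_reads) {
  if (any(canonical_reads < 0) || any(noncanonical_reads < 0))
    stop("read counts must be nonnegative")
  total <- canonical_reads + noncanonical_reads
  if (any(total == 0))
    stop("junction fraction undefined when total reads are zero")
  100 * noncanonical_reads / total
}
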