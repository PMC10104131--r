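#' Round an imputed dosage to a hard genotype call
#'
#' Imputed allele dosages in `[0, 2]` are converted to best-guess
#' genotypes by rounding to the nearest whole allele count, halves
#' rounding away from zero (0.5 -> 1, 1.5 -> 2).  Vectorized; `NA`
#' propagates.
#'
#' @param dosage numeric vector in `[0, 2]`.
#' @return Integer vector in `{0, 1, 2}`.
#' @export
round_dosage <- function(dosage) {
  if (any(dosage < 0 | dosage > 2, na.rm = TRUE))
    stop("dosage must lie in [0, 2]")
  as.integer(floor(dosage + 0.5))
}

# Table of the nine combined-genotype classes, ranked by allele
# imbalance (t5051 - g699) and then by total variant-allele count:
# group 1 = AA/TT (maximal excess of rs5051 T) ... group 9 = GG/CC
# (maximal excess of rs699 G).
group_code_table <- function() {
  g <- expand.grid(g699 = 0:2, t5051 = 0:2)
  key1 <- -(g$t5051 - g$g699)
  key2 <- -(g$t5051 + g$g699)
  g$group <- rank(key1 * 10 + key2, ties.method = "first")
  g <- g[order(g$group), ]
  g$binned <- c(1L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 5L)[g$group]
  rownames(g) <- NULL
  g
}

#' Assign combined-genotype groups
#'
#' Maps per-subject rs699 G-allele and rs5051 T-allele counts to the
#' nine-group ordinal combined-genotype encoding: groups 1-3 carry more
#' rs5051 T than rs699 G alleles, 4-6 are balanced, 7-9 carry more
#' rs699 G.  Within an imbalance level, groups are ordered by
#' decreasing total variant-allele count.  A five-level binned form
#' (\{1\}, \{2,3\}, \{4,5,6\}, \{7,8\}, \{9\}) is attached, which isolates
#' the unbalanced classes.  Missing genotypes yield missing groups.
#'
#' @param g699 rs699 G-allele counts in `{0, 1, 2}` (vectorized).
#' @param t5051 rs5051 T-allele counts in `{0, 1, 2}`.
#' @return Data frame with columns `g699`, `t5051`, `group` (1-9),
#'   `binned` (1-5) and `imbalance` (`t5051 - g699`).
#' @export
assign_group <- function(g699, t5051) {
  if (length(g699) != length(t5051))
    stop("g699 and t5051 must have equal length")
  ok <- is.na(g699) | g699 %in% 0:2
  ok2 <- is.na(t5051) | t5051 %in% 0:2
  if (!all(ok) || !all(ok2)) stop("allele counts must be 0, 1, 2 or NA")
  tab <- group_code_table()
  idx <- match(paste(g699, t5051), paste(tab$g699, tab$t5051))
  n_miss <- sum(is.na(idx))
  if (n_miss > 0)
    message(n_miss, " subject(s) with missing genotype excluded from grouping")
  data.frame(g699 = g699, t5051 = t5051,
             group = tab$group[idx], binned = tab$binned[idx],
             imbalance = t5051 - g699)
}

haplotype_names <- c("GT", "GC", "AT", "AC")

# haplotype-pair composition of each genotype class; group 5 (double
# heterozygote) is the only phase-ambiguous class
group_haplotype_pairs <- function() {
  list(`1` = c("AT", "AT"), `2` = c("GT", "AT"), `3` = c("AT", "AC"),
       `4` = c("GT", "GT"), `5` = NULL, `6` = c("AC", "AC"),
       `7` = c("GT", "GC"), `8` = c("GC", "AC"), `9` = c("GC", "GC"))
}

# HWE class probabilities for the nine groups given haplotype
# frequencies p = c(GT, GC, AT, AC)
group_probs_from_hf <- function(p) {
  names(p) <- haplotype_names
  c(`1` = unname(p["AT"]^2),
    `2` = unname(2 * p["GT"] * p["AT"]),
    `3` = unname(2 * p["AT"] * p["AC"]),
    `4` = unname(p["GT"]^2),
    `5` = unname(2 * (p["GT"] * p["AC"] + p["GC"] * p["AT"])),
    `6` = unname(p["AC"]^2),
    `7` = unname(2 * p["GT"] * p["GC"]),
    `8` = unname(2 * p["GC"] * p["AC"]),
    `9` = unname(p["GC"]^2))
}

#' Two-locus haplotype frequencies by EM
#'
#' Maximum-likelihood estimation of the four (rs699 allele, rs5051
#' allele) haplotype frequencies - GT, GC, AT, AC - from unphased
#' combined-genotype counts.  Only the double-heterozygote class (group
#' 5) is phase-ambiguous; each EM iteration splits it between GT/AC and
#' GC/AT in proportion to the current estimates `f_GT f_AC` versus
#' `f_GC f_AT`, then re-normalizes haplotype counts.  Iteration stops
#' when the multinomial log-likelihood improves by less than `tol` or
#' after `max_iter` iterations.
#'
#' @param group_counts numeric vector of nine genotype-class counts
#'   (named "1".."9" or in that order).
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @return Object of class `haplotype_frequencies`: list with
#'   `frequencies` (named numeric, sums to 1), `loglik`, `n_iter` and
#'   `loglik_trace`.
#' @export
em_haplotype_frequencies <- function(group_counts, tol = 1e-10,
                                     max_iter = 1000L) {
  counts <- as.numeric(group_counts)
  if (length(counts) != 9L || any(counts < 0) || anyNA(counts))
    stop("group_counts must be nine nonnegative counts")
  if (sum(counts) <= 0) stop("total count must be >= 1")
  names(counts) <- as.character(1:9)

  # phase-unambiguous haplotype contributions
  fixed <- c(GT = 0, GC = 0, AT = 0, AC = 0)
  hp <- group_haplotype_pairs()
  for (g in names(hp)) {
    if (is.null(hp[[g]])) next
    for (h in hp[[g]]) fixed[h] <- fixed[h] + counts[g]
  }
  n_hap <- 2 * sum(counts)

  ll_of <- function(p) {
    pr <- group_probs_from_hf(p)
    sum(counts[counts > 0] * log(pr[counts > 0]))
  }

  p <- rep(0.25, 4); names(p) <- haplotype_names
  ll <- ll_of(p)
  trace <- ll
  for (it in seq_len(max_iter)) {
    w_cis <- p["GT"] * p["AC"]
    w_trans <- p["GC"] * p["AT"]
    split_cis <- if (w_cis + w_trans > 0) w_cis / (w_cis + w_trans) else 0.5
    cnt <- fixed
    cnt["GT"] <- cnt["GT"] + counts["5"] * split_cis
    cnt["AC"] <- cnt["AC"] + counts["5"] * split_cis
    cnt["GC"] <- cnt["GC"] + counts["5"] * (1 - split_cis)
    cnt["AT"] <- cnt["AT"] + counts["5"] * (1 - split_cis)
    p <- cnt / n_hap
    ll_new <- ll_of(p)
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) < tol) { ll <- ll_new; break }
    ll <- ll_new
  }
  structure(list(frequencies = p, loglik = ll, n_iter = length(trace) - 1L,
                 loglik_trace = trace),
            class = "haplotype_frequencies")
}

#' @export
print.haplotype_frequencies <- function(x, ...) {
  cat("Two-locus haplotype frequencies (rs699 allele, rs5051 allele):\n")
  print(round(x$frequencies, 5))
  cat(sprintf("log-likelihood %.4f after %d EM iteration(s)\n",
              x$loglik, x$n_iter))
  invisible(x)
}

as_hap_freq <- function(hf) {
  p <- if (inherits(hf, "haplotype_frequencies")) hf$frequencies else
    as.numeric(hf)
  if (length(p) != 4L) stop("need four haplotype frequencies (GT, GC, AT, AC)")
  names(p) <- haplotype_names
  if (any(p < -1e-9) || abs(sum(p) - 1) > 1e-6)
    stop("haplotype frequencies must be nonnegative and sum to 1")
  pmax(p, 0) / sum(pmax(p, 0))
}

#' Linkage-disequilibrium statistics for the two loci
#'
#' Computes `D = f_GT - f_G f_T` (the haplotype-frequency covariance),
#' `r2 = D^2 / (f_G f_A f_T f_C)` and `D' = |D| / D_max`, where
#' `D_max = min(f_G f_C, f_A f_T)` when `D > 0` and
#' `min(f_G f_T, f_A f_C)` otherwise.
#'
#' @param hf a `haplotype_frequencies` object or numeric vector of the
#'   four frequencies in order GT, GC, AT, AC.
#' @return List with `D`, `D_prime`, `r2` and the marginal allele
#'   frequencies.
#' @export
ld_stats <- function(hf) {
  p <- as_hap_freq(hf)
  f_G <- p["GT"] + p["GC"]; f_A <- 1 - f_G
  f_T <- p["GT"] + p["AT"]; f_C <- 1 - f_T
  if (f_G <= 0 || f_G >= 1 || f_T <= 0 || f_T >= 1)
    stop("LD statistics undefined at a monomorphic locus")
  D <- unname(p["GT"] - f_G * f_T)
  d_max <- if (D > 0) min(f_G * f_C, f_A * f_T) else min(f_G * f_T, f_A * f_C)
  list(D = D,
       D_prime = unname(if (D == 0) 0 else abs(D) / d_max),
       r2 = unname(D^2 / (f_G * f_A * f_T * f_C)),
       f_G = unname(f_G), f_A = unname(f_A),
       f_T = unname(f_T), f_C = unname(f_C))
}

#' Expected combined-genotype frequencies under Hardy-Weinberg
#'
#' Pushes haplotype frequencies forward through random union of
#' haplotypes: homozygous classes get squared frequencies, heterozygous
#' classes the usual cross terms, and the double-heterozygote class
#' collects both phase configurations.  The nine frequencies sum to 1.
#'
#' @inheritParams ld_stats
#' @return Named numeric vector of length 9 (groups "1".."9").
#' @export
expected_group_frequencies <- function(hf) {
  p <- as_hap_freq(hf)
  group_probs_from_hf(p)
}

#' Fraction of discordant haplotypes and of unbalanced subjects
#'
#' Haplotypes carrying exactly one of the two variant alleles (AT or
#' GC) break the usual coupling of rs699 G with rs5051 T.  Returns both
#' the allele-level fraction `f_AT + f_GC` and the expected HWE fraction
#' of subjects in the unbalanced groups \{1, 2, 3, 7, 8, 9\}.
#'
#' @inheritParams ld_stats
#' @return List with `allele_fraction` and `person_fraction`.
#' @export
discordant_fraction <- function(hf) {
  p <- as_hap_freq(hf)
  freqs <- group_probs_from_hf(p)
  list(allele_fraction = unname(p["AT"] + p["GC"]),
       person_fraction = unname(sum(freqs[c("1", "2", "3", "7", "8", "9")])))
}

#' Back-solved haplotype frequencies from published combination counts
#'
#' The default two-locus haplotype frequencies used throughout the
#' package, back-solved from the homozygote and heterozygote
#' combined-genotype frequencies reported for the all-populations 1000
#' Genomes extract (f_GT from the balanced GG/TT class, f_AC from
#' AA/CC, the rare discordant haplotypes from the GT/AT and GT/GC cross
#' terms) and re-normalized to sum to 1.
#'
#' @return Named numeric vector (GT, GC, AT, AC).
#' @export
table1_haplotype_frequencies <- function() {
  f_gt <- sqrt(0.4921)
  f_ac <- sqrt(0.0818)
  f_at <- 0.0063 / (2 * f_gt)
  f_gc <- 0.0025 / (2 * f_gt)
  p <- c(GT = f_gt, GC = f_gc, AT = f_at, AC = f_ac)
  p / sum(p)
}

#' Read rs699/rs5051 genotypes from VCF or PLINK raw files
#'
#' Extracts per-subject allele counts for the two loci with respect to
#' the declared effect alleles (rs699 G, rs5051 T).  For VCF input the
#' variant records are located by ID; if the effect allele is the
#' file's REF rather than ALT, counts are flipped (and a message
#' emitted).  For PLINK `.raw` input the counted allele is taken from
#' the `SNP_A` column-name suffix; dosages are rounded through
#' [round_dosage()] when `hard_calls = TRUE`, otherwise passed through.
#'
#' @param path file path.
#' @param format `"vcf"` or `"plink_raw"`.
#' @param rs699_id,rs5051_id variant IDs as they appear in the file.
#' @param hard_calls round dosages to `{0, 1, 2}`?
#' @return Data frame with columns `subject_id`, `g699`, `t5051` and
#'   `dosage_source`.
#' @export
read_genotypes <- function(path, format = c("vcf", "plink_raw"),
                           rs699_id = "rs699", rs5051_id = "rs5051",
                           hard_calls = TRUE) {
  format <- match.arg(format)
  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    ids <- vcf@fix[, "ID"]
    get_counts <- function(id, effect) {
      row <- which(ids == id)
      if (length(row) != 1L)
        stop("variant '", id, "' not found (or duplicated) in ", path)
      ref <- vcf@fix[row, "REF"]; alt <- vcf@fix[row, "ALT"]
      gt <- vcfR::extract.gt(vcf)[row, ]
      alleles <- strsplit(gt, "[/|]")
      counts <- vapply(alleles, function(a) {
        if (length(a) == 0 || anyNA(a) || any(a == ".")) return(NA_real_)
        sum(a == "1")
      }, numeric(1))
      eff_dna <- chartr("U", "T", effect)
      if (toupper(alt) == eff_dna) {
        counts
      } else if (toupper(ref) == eff_dna) {
        message("effect allele ", effect, " is REF for ", id,
                "; flipping allele counts")
        2 - counts
      } else {
        stop("effect allele ", effect, " matches neither REF nor ALT for ", id)
      }
    }
    g699 <- get_counts(rs699_id, "G")
    t5051 <- get_counts(rs5051_id, "T")
    data.frame(subject_id = colnames(vcf@gt)[-1],
               g699 = as.integer(g699), t5051 = as.integer(t5051),
               dosage_source = "hard_call", row.names = NULL)
  } else {
    raw <- utils::read.table(path, header = TRUE, check.names = FALSE)
    find_col <- function(id) {
      hits <- grep(paste0("^", id, "(_[ACGT])?$"), names(raw))
      if (length(hits) != 1L)
        stop("variant '", id, "' not found (or ambiguous) in ", path)
      hits
    }
    counted_allele <- function(col) sub(".*_", "", names(raw)[col])
    pull <- function(id, effect) {
      col <- find_col(id)
      x <- raw[[col]]
      if (grepl("_[ACGT]$", names(raw)[col]) &&
          counted_allele(col) != effect) {
        message("counted allele for ", id, " is ", counted_allele(col),
                "; flipping to effect allele ", effect)
        x <- 2 - x
      }
      x
    }
    g699 <- pull(rs699_id, "G")
    t5051 <- pull(rs5051_id, "T")
    is_dosage <- any(g699 %% 1 != 0, na.rm = TRUE) ||
      any(t5051 %% 1 != 0, na.rm = TRUE)
    if (hard_calls) {
      g699 <- round_dosage(g699)
      t5051 <- round_dosage(t5051)
    }
    data.frame(subject_id = as.character(raw$IID),
               g699 = g699, t5051 = t5051,
               dosage_source = if (is_dosage) "imputed_dosage" else "hard_call",
               row.names = NULL)
  }
}
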