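# Independent oracles used across the test files.

# --- duplex: exhaustive enumeration of antiparallel chain structures ---

.canonical_pair <- function(x, y) {
  paste0(x, y) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
}

.pair_type_chr <- function(x, y) {
  match(paste0(x, y), c("CG", "GC", "GU", "UG", "AU", "UA"))
}

# Minimum energy over every non-empty chain of canonical pairs, scored
# incrementally with the same parameter tables but independently of the
# dynamic program (plain depth-first enumeration).  Returns 0 when no
# canonical pair exists, matching the fold_duplex sentinel.
brute_force_dg <- function(s1, s2, params = duplex_params()) {
  s1c <- strsplit(toupper(s1), "")[[1]]
  s2c <- strsplit(toupper(s2), "")[[1]]
  n <- length(s1c); m <- length(s2c)
  P <- params
  term <- function(t) if (t >= 3) P$terminal_au_gu else 0
  stk <- function(i, j, k, l)
    P$stack[paste0(s1c[i], s2c[j]), paste0(s2c[l], s1c[k])]
  join <- function(i, j, k, l) {
    a <- k - i - 1; b <- j - l - 1; t <- a + b
    if (t > P$max_loop_span) return(Inf)
    if (t == 0) return(stk(i, j, k, l))
    if (a == 0 || b == 0)
      return(P$bulge_init[t] + if (t == 1) stk(i, j, k, l) else 0)
    P$interior_init[t] + min(P$ninio_max, P$ninio_per_nt * abs(a - b))
  }
  best <- Inf
  found <- FALSE
  rec <- function(i, j, e) {
    tot <- e + term(.pair_type_chr(s1c[i], s2c[j]))
    if (tot < best) best <<- tot
    if (i < n && j > 1) {
      for (k in (i + 1):n) {
        for (l in 1:(j - 1)) {
          if (!.canonical_pair(s1c[k], s2c[l])) next
          cst <- join(i, j, k, l)
          if (is.finite(cst)) rec(k, l, e + cst)
        }
      }
    }
  }
  for (i in 1:n) {
    for (j in 1:m) {
      if (!.canonical_pair(s1c[i], s2c[j])) next
      found <- TRUE
      rec(i, j, P$init_penalty + term(.pair_type_chr(s1c[i], s2c[j])))
    }
  }
  if (!found) 0 else best
}

random_rna <- function(len) paste(sample(c("A", "C", "G", "U"), len,
                                         replace = TRUE), collapse = "")

# --- association: normal-equations OLS oracle ---

ols_oracle <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tstat <- beta / se
  list(beta = as.numeric(beta), se = as.numeric(se),
       t = as.numeric(tstat),
       p = as.numeric(2 * stats::pt(abs(tstat), df, lower.tail = FALSE)))
}

# --- genetics: grid-search multinomial-likelihood oracle over the
# haplotype-frequency simplex (coarse pass then local refinement down
# to step 0.001) ---

.grid_ll <- function(counts, P) {
  # P: matrix with columns GT, GC, AT, AC
  probs <- cbind(P[, 3]^2,                       # 1: AT/AT
                 2 * P[, 1] * P[, 3],            # 2: GT/AT
                 2 * P[, 3] * P[, 4],            # 3: AT/AC
                 P[, 1]^2,                       # 4: GT/GT
                 2 * (P[, 1] * P[, 4] + P[, 2] * P[, 3]),  # 5
                 P[, 4]^2,                       # 6: AC/AC
                 2 * P[, 1] * P[, 2],            # 7: GT/GC
                 2 * P[, 2] * P[, 4],            # 8: GC/AC
                 P[, 2]^2)                       # 9: GC/GC
  keep <- counts > 0
  lp <- log(probs[, keep, drop = FALSE])
  lp[!is.finite(lp)] <- -1e12
  as.numeric(lp %*% counts[keep])
}

grid_loglik_oracle <- function(counts) {
  counts <- as.numeric(counts)
  simplex_grid <- function(lo, hi, step) {
    v <- lapply(1:3, function(k) seq(max(0, lo[k]), min(1, hi[k]), by = step))
    g <- as.matrix(expand.grid(v))
    g <- g[rowSums(g) <= 1 + 1e-12, , drop = FALSE]
    cbind(g, pmax(0, 1 - rowSums(g)))
  }
  # coarse pass over the whole simplex (free parameters GT, GC, AT)
  G <- simplex_grid(c(0, 0, 0), c(1, 1, 1), 0.01)
  ll <- .grid_ll(counts, G)
  best <- G[which.max(ll), 1:3]
  # refinement at step 0.001 around the coarse optimum
  G2 <- simplex_grid(best - 0.012, best + 0.012, 0.001)
  ll2 <- .grid_ll(counts, G2)
  i <- which.max(ll2)
  list(loglik = ll2[i],
       frequencies = stats::setNames(as.numeric(G2[i, ]),
                                     c("GT", "GC", "AT", "AC")))
}
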