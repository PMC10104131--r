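#' Fold a microRNA against a target window
#'
#' Computes the minimum free energy over all intermolecular-only duplex
#' structures between two RNA strands: chains of canonical pairs (AU,
#' GC, GU) joined by stacks, bulges and interior loops whose total
#' unpaired span does not exceed `params$max_loop_span`.  The energy is
#' the sum of stack/loop terms plus a duplex initiation penalty and
#' terminal AU/GU penalties at both helix ends.  Hybridization is
#' antiparallel, so pairs sorted by position on the first strand have
#' strictly decreasing positions on the second.
#'
#' Among co-optimal structures, the one whose pair list is
#' lexicographically smallest is reported, which makes the output
#' deterministic.  If the two sequences admit no canonical pair at all,
#' the no-interaction sentinel (`delta_g = 0`, empty structure) is
#' returned.
#'
#' @param mirna,target `rna_seq` objects (or character scalars), each of
#'   length >= 3, both written 5' to 3'.
#' @param params a [duplex_params()] parameter set.
#' @return An object of class `duplex_result`: a list with `delta_g`
#'   (kcal/mol), `structure` (list with a two-column `pairs` matrix and
#'   `dotbracket` notation), `n_pairs`, `n_gu_pairs`, `target_window`
#'   (half-open 0-based interval on the target spanned by the duplex)
#'   and the sequences.
#' @examples
#' fold_duplex(mir122_5p(), synthetic_agt_window()$target)
#' @export
fold_duplex <- function(mirna, target, params = duplex_params()) {
  mirna <- rna_seq(mirna, name = "mirna", origin = "mirna")
  target <- rna_seq(target, name = "target")
  stopifnot(inherits(params, "duplex_params"))
  if (nchar(mirna) < 3L || nchar(target) < 3L)
    stop("sequences must be at least 3 nt for folding")

  res <- .duplex_fold_cpp(seq_codes(mirna), seq_codes(target),
                          params$stack, params$bulge_init,
                          ifelse(is.na(params$interior_init), 1e9,
                                 params$interior_init),
                          params$init_penalty, params$terminal_au_gu,
                          params$ninio_per_nt, params$ninio_max,
                          params$max_loop_span)
  pairs <- res$pairs
  colnames(pairs) <- c("i", "j")
  window <- if (nrow(pairs) == 0L) c(0L, 0L) else
    c(min(pairs[, "j"]) - 1L, max(pairs[, "j"]))
  structure(list(delta_g = res$dg,
                 structure = list(pairs = pairs,
                                  dotbracket = duplex_dotbracket(
                                    nchar(mirna), nchar(target), pairs)),
                 n_pairs = res$n_pairs,
                 n_gu_pairs = res$n_gu_pairs,
                 target_window = window,
                 mirna = mirna, target = target),
            class = "duplex_result")
}

#' @export
print.duplex_result <- function(x, ...) {
  cat(sprintf("Duplex MFE: %.2f kcal/mol  (%d pairs, %d G-U)\n",
              x$delta_g, x$n_pairs, x$n_gu_pairs))
  cat(" ", x$structure$dotbracket, "\n")
  invisible(x)
}

# RNAduplex-style two-strand dot-bracket: '(' on strand 1, ')' on
# strand 2, '&' separator
duplex_dotbracket <- function(n1, n2, pairs) {
  d1 <- rep(".", n1); d2 <- rep(".", n2)
  if (nrow(pairs)) {
    d1[pairs[, 1]] <- "("
    d2[pairs[, 2]] <- ")"
  }
  paste0(paste(d1, collapse = ""), "&", paste(d2, collapse = ""))
}

#' Re-score a duplex structure under a parameter set
#'
#' Independent summation of the energy of an explicit pair list: duplex
#' initiation, stack/loop terms between consecutive pairs, and terminal
#' AU/GU penalties.  Validates the structure (canonical pairs, each
#' position used at most once, non-crossing/antiparallel, loop spans
#' within `max_loop_span`).  This is a plain re-scorer, independent of
#' the dynamic-programming search, so it can audit [fold_duplex()]
#' output or score enumerated structures.
#'
#' @param mirna,target sequences as in [fold_duplex()].
#' @param pairs two-column integer matrix of (i, j) 1-based positions;
#'   zero rows means the empty structure (energy 0 by the sentinel
#'   convention).
#' @param params a [duplex_params()] set.
#' @return Energy in kcal/mol.
#' @export
duplex_energy_of_structure <- function(mirna, target, pairs,
                                       params = duplex_params()) {
  mirna <- rna_seq(mirna, name = "mirna", origin = "mirna")
  target <- rna_seq(target, name = "target")
  s1 <- seq_chars(mirna); s2 <- seq_chars(target)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) == 0L) return(0)
  ord <- order(pairs[, 1])
  pairs <- pairs[ord, , drop = FALSE]
  if (anyDuplicated(pairs[, 1]) || anyDuplicated(pairs[, 2]))
    stop("each position may occur in at most one pair")
  if (any(pairs[, 1] < 1 | pairs[, 1] > length(s1) |
          pairs[, 2] < 1 | pairs[, 2] > length(s2)))
    stop("pair index out of range")
  if (is.unsorted(rev(pairs[, 2]), strictly = TRUE))
    stop("pairs must be non-crossing (j strictly decreasing in i)")

  ptype <- function(x, y) {
    key <- paste0(x, y)
    match(key, c("CG", "GC", "GU", "UG", "AU", "UA"))
  }
  types <- ptype(s1[pairs[, 1]], s2[pairs[, 2]])
  if (anyNA(types)) stop("non-canonical pair in structure")

  term <- function(t) if (t >= 3) params$terminal_au_gu else 0
  e <- params$init_penalty + term(types[1]) + term(types[length(types)])
  if (nrow(pairs) > 1L) {
    for (q in seq_len(nrow(pairs) - 1L)) {
      i <- pairs[q, 1]; j <- pairs[q, 2]
      k <- pairs[q + 1, 1]; l <- pairs[q + 1, 2]
      a <- k - i - 1L; b <- j - l - 1L
      t <- a + b
      if (t > params$max_loop_span)
        stop("loop span ", t, " exceeds max_loop_span")
      stk <- params$stack[paste0(s1[i], s2[j]), paste0(s2[l], s1[k])]
      if (t == 0L) {
        e <- e + stk
      } else if (a == 0L || b == 0L) {
        e <- e + params$bulge_init[t] + if (t == 1L) stk else 0
      } else {
        e <- e + params$interior_init[t] +
          min(params$ninio_max, params$ninio_per_nt * abs(a - b))
      }
    }
  }
  unname(e)
}

#' Free energy of the perfectly matching duplex
#'
#' Folds the miRNA against its exact reverse complement - the energy a
#' perfectly matching siRNA would achieve - which serves as the
#' strongest-binding bound of the plausible range.
#'
#' @inheritParams fold_duplex
#' @return A `duplex_result`; its structure pairs every position.
#' @export
perfect_match_dg <- function(mirna, params = duplex_params()) {
  mirna <- rna_seq(mirna, name = "mirna", origin = "mirna")
  fold_duplex(mirna, reverse_complement(mirna), params = params)
}

#' Scrambled-target null distribution of duplex energies
#'
#' Contextualizes an observed miRNA:target energy by folding the miRNA
#' against `n` uniform random permutations (Fisher-Yates, via
#' [sample()]) of the target residues - composition is preserved - and
#' recording all energies, the weakest (least negative) and strongest,
#' together with the perfect-match bound.  The plausible binding range
#' runs from the weakest scramble energy to the perfect-match energy.
#'
#' @inheritParams fold_duplex
#' @param n number of scrambles (default 2000).
#' @param seed RNG seed; the result is bit-identical for identical
#'   `(seed, n)`.  The global RNG state is left untouched.
#' @return An object of class `scramble_null`: list with `n_scrambles`,
#'   `seed`, `per_scramble_dg`, `weakest_dg`, `strongest_dg`,
#'   `perfect_match_dg` and `plausible_range = c(upper = weakest,
#'   lower = perfect_match)`.
#' @export
scramble_null <- function(mirna, target, n = 2000L, seed = 699L,
                          params = duplex_params()) {
  mirna <- rna_seq(mirna, name = "mirna", origin = "mirna")
  target <- rna_seq(target, name = "target")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  chars <- seq_chars(target)
  dgs <- vapply(seq_len(n), function(k) {
    scr <- rna_seq(paste(sample(chars), collapse = ""),
                   name = sprintf("scramble_%d", k), origin = "scramble")
    fold_duplex(mirna, scr, params = params)$delta_g
  }, numeric(1))

  pm <- perfect_match_dg(mirna, params = params)$delta_g
  structure(list(n_scrambles = n, seed = as.integer(seed),
                 per_scramble_dg = dgs,
                 weakest_dg = max(dgs),
                 strongest_dg = min(dgs),
                 perfect_match_dg = pm,
                 plausible_range = c(upper = max(dgs), lower = pm)),
            class = "scramble_null")
}

#' @export
print.scramble_null <- function(x, ...) {
  cat(sprintf(paste0("Scramble null (n = %d, seed = %d): weakest %.1f, ",
                     "strongest %.1f, perfect match %.1f kcal/mol\n"),
              x$n_scrambles, x$seed, x$weakest_dg, x$strongest_dg,
              x$perfect_match_dg))
  cat(sprintf("Plausible range: %.1f to %.1f kcal/mol\n",
              x$plausible_range["upper"], x$plausible_range["lower"]))
  invisible(x)
}

#' Express a variant energy change as a percent of the plausible range
#'
#' The change in binding energy between reference and variant alleles,
#' `dg_ref - dg_var`, expressed as a percentage of the plausible binding
#' span `range_upper - range_lower` (weakest-scramble to perfect-match
#' energies, both negative by convention).
#'
#' @param dg_ref,dg_var reference and variant duplex energies, kcal/mol.
#' @param range_upper,range_lower bounds of the plausible range
#'   (`range_lower < range_upper`), kcal/mol.
#' @return List with `percent` (signed, 100 x (dg_ref - dg_var) / span),
#'   `span` (kcal/mol) and `percent_rounded` (integer, half away from
#'   zero).
#' @examples
#' percent_of_range(-11.3, -12.3, -7.1, -39.3)  # span 32.2, 3 percent
#' @export
percent_of_range <- function(dg_ref, dg_var, range_upper, range_lower) {
  if (!(range_lower < range_upper)) stop("need range_lower < range_upper")
  span <- range_upper - range_lower
  if (span == 0) stop("zero plausible-range span")
  pct <- 100 * (dg_ref - dg_var) / span
  list(percent = pct, span = span,
       percent_rounded = as.integer(sign(pct) * floor(abs(pct) + 0.5)))
}

#' Compare reference and variant alleles of a target window
#'
#' Applies a single-residue substitution to the target (mRNA-sense; the
#' rs699 A>G variant, reported on the positive genomic strand, is a U>C
#' change in the AGT mRNA) and folds both alleles against the miRNA.
#'
#' @inheritParams fold_duplex
#' @param target_ref reference-allele target window.
#' @param variant_offset 0-based index of the substituted position.
#' @param variant_residue the variant residue (must differ from the
#'   reference residue at that position).
#' @return List of class `allele_comparison` with both `duplex_result`s
#'   (`ref`, `var`), `ddg = delta_g_var - delta_g_ref`, `n_pairs_diff`
#'   and `n_gu_pairs_diff`.
#' @export
compare_alleles <- function(mirna, target_ref, variant_offset,
                            variant_residue, params = duplex_params()) {
  mirna <- rna_seq(mirna, name = "mirna", origin = "mirna")
  target_ref <- rna_seq(target_ref, name = "target_ref")
  chars <- seq_chars(target_ref)
  k <- as.integer(variant_offset) + 1L
  if (is.na(k) || k < 1L || k > length(chars))
    stop("variant_offset out of bounds")
  variant_residue <- toupper(variant_residue)
  if (identical(variant_residue, "T")) variant_residue <- "U"
  if (!variant_residue %in% c("A", "C", "G", "U"))
    stop("variant_residue must be one of A, C, G, U")
  if (identical(chars[k], variant_residue))
    stop("variant residue equals the reference residue at this offset")
  chars_var <- chars
  chars_var[k] <- variant_residue
  target_var <- rna_seq(paste(chars_var, collapse = ""),
                        name = paste0(attr(target_ref, "name"), "_var"))

  ref <- fold_duplex(mirna, target_ref, params = params)
  var <- fold_duplex(mirna, target_var, params = params)
  structure(list(ref = ref, var = var,
                 ddg = var$delta_g - ref$delta_g,
                 n_pairs_diff = var$n_pairs - ref$n_pairs,
                 n_gu_pairs_diff = var$n_gu_pairs - ref$n_gu_pairs),
            class = "allele_comparison")
}

#' @export
print.allele_comparison <- function(x, ...) {
  cat(sprintf("Reference: %.2f kcal/mol (%d pairs)  Variant: %.2f kcal/mol (%d pairs)\n",
              x$ref$delta_g, x$ref$n_pairs, x$var$delta_g, x$var$n_pairs))
  cat(sprintf("ddG = %.2f kcal/mol; pairs %+d (%+d G-U)\n",
              x$ddg, x$n_pairs_diff, x$n_gu_pairs_diff))
  invisible(x)
}
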