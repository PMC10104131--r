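#' Nearest-neighbor duplex energy parameters
#'
#' Builds the energy parameter set used by [fold_duplex()] and friends:
#' the Turner 2004 nearest-neighbor stacking table for all Watson-Crick
#' and G-U doublets at 37 degrees C, a duplex initiation penalty, a
#' terminal AU/GU penalty applied at both helix ends, and bulge/interior
#' loop initiation penalties with a Ninio-style asymmetry term.  Values
#' are in kcal/mol.
#'
#' The stack table is indexed by the two base pairs of a doublet: entry
#' `stack[p1, p2]` is the free energy of the motif `5'-W X-3'` over
#' `3'-Y Z-5'` where `p1` names the pair W-Y and `p2` names the pair Z-X
#' (the second pair read bottom-to-top, the standard duplex-reversal
#' symmetric layout, so the matrix is symmetric).
#'
#' Single-nucleotide bulges retain the stack of their flanking pairs, as
#' in the reference nearest-neighbor treatment; larger loops are scored
#' by length alone plus the asymmetry term.  Loop sizes beyond
#' `max_loop_span` are disallowed.
#'
#' @param init_penalty duplex initiation penalty, kcal/mol.
#' @param terminal_au_gu penalty added for each terminal AU or GU pair,
#'   kcal/mol.
#' @param max_loop_span maximum total number of unpaired nucleotides
#'   between two consecutive pairs.
#' @param ninio_per_nt,ninio_max interior-loop asymmetry penalty per
#'   nucleotide of asymmetry, and its cap, kcal/mol.
#' @param stack optional replacement 6x6 stack matrix with dimnames
#'   `c("CG","GC","GU","UG","AU","UA")`.
#'
#' @return An object of class `duplex_params`.
#' @seealso [read_stack_table()], [write_stack_table()]
#' @export
duplex_params <- function(init_penalty = 4.09, terminal_au_gu = 0.45,
                          max_loop_span = 30L, ninio_per_nt = 0.6,
                          ninio_max = 3.0, stack = NULL) {
  pr <- c("CG", "GC", "GU", "UG", "AU", "UA")
  if (is.null(stack)) {
    stack <- matrix(c(
      -2.40, -3.30, -2.10, -1.40, -2.10, -2.10,
      -3.30, -3.40, -2.50, -1.50, -2.20, -2.40,
      -2.10, -2.50,  1.30, -0.50, -1.40, -1.30,
      -1.40, -1.50, -0.50,  0.30, -0.60, -1.00,
      -2.10, -2.20, -1.40, -0.60, -1.10, -0.90,
      -2.10, -2.40, -1.30, -1.00, -0.90, -1.30),
      nrow = 6, byrow = TRUE, dimnames = list(pr, pr))
  } else {
    stack <- as.matrix(stack)
    if (!identical(dim(stack), c(6L, 6L)))
      stop("stack table must be 6x6 (CG, GC, GU, UG, AU, UA)")
    dimnames(stack) <- list(pr, pr)
    if (max(abs(stack - t(stack))) > 1e-9)
      stop("stack table must be symmetric under duplex reversal")
  }
  max_loop_span <- as.integer(max_loop_span)
  if (max_loop_span < 1L || max_loop_span > 30L)
    stop("max_loop_span must be in 1..30")

  # loop initiation penalties by total unpaired size 1..30 (kcal/mol)
  bulge <- c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4, 4.6, 4.7, 4.8, 4.9,
             5.0, 5.1, 5.2, 5.3, 5.4, 5.4, 5.5, 5.5, 5.6, 5.7,
             5.7, 5.8, 5.8, 5.8, 5.9, 5.9, 6.0, 6.0, 6.0, 6.1)
  interior <- c(NA, 1.0, 1.0, 1.1, 2.0, 2.0, 2.1, 2.3, 2.4, 2.5,
                2.6, 2.7, 2.8, 2.9, 2.9, 3.0, 3.1, 3.1, 3.2, 3.3,
                3.3, 3.4, 3.4, 3.5, 3.5, 3.5, 3.6, 3.6, 3.7, 3.7)

  structure(list(stack = stack,
                 bulge_init = bulge,
                 interior_init = interior,
                 init_penalty = init_penalty,
                 terminal_au_gu = terminal_au_gu,
                 ninio_per_nt = ninio_per_nt,
                 ninio_max = ninio_max,
                 max_loop_span = max_loop_span,
                 temperature_C = 37),
            class = "duplex_params")
}

#' @export
print.duplex_params <- function(x, ...) {
  cat("Duplex nearest-neighbor parameters (37 C, kcal/mol)\n")
  cat("  initiation:", x$init_penalty,
      " terminal AU/GU:", x$terminal_au_gu,
      " max loop span:", x$max_loop_span, "nt\n")
  cat("  stack table:\n")
  print(x$stack)
  invisible(x)
}

#' Read or write a stacking table as plain text
#'
#' The serialized form is a three-column whitespace-separated table
#' (`pair1`, `pair2`, `kcal_per_mol`), one row per doublet, so that
#' alternative parameter sets can be swapped in.
#'
#' @param path file path.
#' @param params a `duplex_params` object (for writing).
#' @return `read_stack_table()` returns a 6x6 matrix suitable for the
#'   `stack` argument of [duplex_params()]; `write_stack_table()` returns
#'   `path` invisibly.
#' @export
read_stack_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("pair1", "pair2", "kcal_per_mol") %in% names(tab)))
    stop("stack table file needs columns pair1, pair2, kcal_per_mol")
  pr <- c("CG", "GC", "GU", "UG", "AU", "UA")
  m <- matrix(NA_real_, 6, 6, dimnames = list(pr, pr))
  m[cbind(match(tab$pair1, pr), match(tab$pair2, pr))] <- tab$kcal_per_mol
  m[is.na(m)] <- t(m)[is.na(m)]  # fill from the symmetric partner
  if (anyNA(m)) stop("stack table file does not cover all doublets")
  m
}

#' @rdname read_stack_table
#' @export
write_stack_table <- function(params, path) {
  stopifnot(inherits(params, "duplex_params"))
  s <- params$stack
  idx <- which(upper.tri(s, diag = TRUE), arr.ind = TRUE)
  tab <- data.frame(pair1 = rownames(s)[idx[, 1]],
                    pair2 = colnames(s)[idx[, 2]],
                    kcal_per_mol = s[idx])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
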