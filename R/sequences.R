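#' RNA sequence constructor
#'
#' Validates and normalizes a nucleotide sequence for duplex folding.
#' Input is uppercased and DNA thymine is transcribed to uracil (with a
#' message, so silent DNA input is visible in logs).
#'
#' @param residues character scalar over A, C, G, U (T accepted and
#'   converted).
#' @param name identifier.
#' @param origin one of `"mirna"`, `"target"`, `"scramble"`,
#'   `"complement"`.
#' @return An object of class `rna_seq`: a character scalar with `name`
#'   and `origin` attributes.
#' @export
rna_seq <- function(residues, name = "seq", origin = c("mirna", "target",
                                                       "scramble", "complement")) {
  origin <- match.arg(origin)
  if (inherits(residues, "rna_seq")) return(residues)
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues))
    stop("residues must be a nonempty character scalar")
  x <- toupper(residues)
  if (grepl("T", x)) {
    message("DNA input: converting T to U in '", name, "'")
    x <- gsub("T", "U", x)
  }
  if (grepl("[^ACGU]", x))
    stop("invalid residues in '", name, "': only A, C, G, U (or T) allowed")
  structure(x, name = name, origin = origin, class = "rna_seq")
}

seq_chars <- function(x) strsplit(unclass(x)[1L], "")[[1L]]

# integer codes for the C++ engine: A=0, C=1, G=2, U=3
seq_codes <- function(x) {
  match(seq_chars(x), c("A", "C", "G", "U")) - 1L
}

#' Reverse complement of an RNA sequence
#'
#' @param x an `rna_seq` or character scalar.
#' @return An `rna_seq` with origin `"complement"`.
#' @export
reverse_complement <- function(x) {
  x <- rna_seq(x, name = paste0(attr(x, "name"), "_rc"))
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  rc <- paste(rev(comp[seq_chars(x)]), collapse = "")
  rna_seq(rc, name = attr(x, "name"), origin = "complement")
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper around Biostrings; returns `rna_seq` objects (DNA is
#' transcribed on ingest).  By convention the first record is the miRNA
#' when a file holds both strands of an analysis.
#'
#' @param path FASTA file.
#' @param origin origin tag applied to all records.
#' @return Named list of `rna_seq`.
#' @export
read_fasta_seqs <- function(path, origin = "target") {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA requires the Biostrings package")
  ss <- Biostrings::readBStringSet(path)
  out <- lapply(seq_along(ss), function(i)
    rna_seq(as.character(ss[[i]]), name = names(ss)[i], origin = origin))
  names(out) <- names(ss)
  out
}

#' hsa-miR-122-5p
#'
#' The mature hsa-miR-122-5p sequence (miRBase MIMAT0000421), the
#' liver-enriched microRNA that binds the AGT mRNA near rs699.
#'
#' @return An `rna_seq`.
#' @export
mir122_5p <- function() {
  rna_seq("UGGAGUGUGACAAUGGUGUUUG", name = "hsa-miR-122-5p", origin = "mirna")
}

#' Synthetic AGT-like target window for the rs699 U>C substitution
#'
#' The target window actually assayed in the reporter experiments (a
#' cloning oligo with primer ends) is not redistributable here, so the
#' package ships a SYNTHETIC stand-in: a window whose core is
#' complementary to miR-122-5p except that the reference allele carries a
#' U opposite a miRNA G (a G-U wobble).  The mRNA-sense U>C substitution
#' (rs699 is reported A>G on the positive genomic strand; AGT is
#' transcribed from the negative strand) converts that wobble into a
#' Watson-Crick G-C pair, strengthening the duplex - the qualitative
#' behaviour of a binding-site-strengthening mirSNP.
#'
#' @return A list with elements `target` (reference-allele `rna_seq`),
#'   `offset` (0-based index of the variant position) and `alt` (the
#'   variant residue, `"C"`).
#' @export
synthetic_agt_window <- function() {
  # 8-nt primer ends flank the 22-nt miR-122-5p complement; position 18
  # of the core (0-based offset 8 + 17 = 25) is U in the reference.
  core <- seq_chars(reverse_complement(mir122_5p()))
  ref_core <- core
  ref_core[18] <- "U"                       # reference wobble position
  ref <- paste0("GGACUAGC", paste(ref_core, collapse = ""), "CGAUCAGG")
  list(target = rna_seq(ref, name = "AGT_rs699_window_synthetic",
                        origin = "target"),
       offset = 25L,
       alt = "C")
}
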