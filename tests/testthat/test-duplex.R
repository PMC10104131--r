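test_that("sequence ingestion validates, uppercases and transcribes DNA", {
  expect_equal(unclass(rna_seq("acgu"))[1], "ACGU")
  expect_message(s <- rna_seq("ACGT"), "converting T to U")
  expect_equal(unclass(s)[1], "ACGU")
  expect_error(rna_seq("ACGX"), "invalid residues")
  expect_error(rna_seq(""), "nonempty")
  expect_equal(unclass(reverse_complement(rna_seq("GAAC")))[1], "GUUC")
})

test_that("folding two incompatible homopolymers returns the no-interaction sentinel", {
  r <- fold_duplex("AAAAA", "AAAAA")
  expect_identical(r$delta_g, 0)
  expect_identical(r$n_pairs, 0L)
  expect_identical(nrow(r$structure$pairs), 0L)
})

test_that("zero-stack and hand-summed stack energies match the embedded table", {
  p <- duplex_params()
  # single AU pair: initiation + terminal penalty at both helix ends
  r1 <- fold_duplex("AGG", "GGU", params = p)
  expect_equal(r1$delta_g, p$init_penalty + 2 * p$terminal_au_gu)
  expect_identical(r1$n_pairs, 1L)
  # GGG vs CCC: full helix, initiation + two 5'GG3'/3'CC5' stacks
  r2 <- fold_duplex("GGG", "CCC", params = p)
  expect_equal(r2$delta_g,
               p$init_penalty + 2 * p$stack["GC", "CG"])
  expect_identical(r2$n_pairs, 3L)
  expect_identical(r2$n_gu_pairs, 0L)
})

test_that("DP energies equal exhaustive enumeration on short random pairs", {
  set.seed(2024)
  p <- duplex_params()
  for (rep in 1:200) {
    s1 <- random_rna(sample(3:8, 1))
    s2 <- random_rna(sample(3:8, 1))
    got <- suppressMessages(fold_duplex(s1, s2, params = p))$delta_g
    want <- brute_force_dg(s1, s2, p)
    expect_equal(got, want, tolerance = 1e-12,
                 label = sprintf("fold(%s, %s)", s1, s2))
  }
})

test_that("returned structures are valid and re-score to the reported energy", {
  set.seed(11)
  p <- duplex_params()
  for (rep in 1:50) {
    s1 <- random_rna(sample(4:15, 1))
    s2 <- random_rna(sample(4:20, 1))
    r <- fold_duplex(s1, s2, params = p)
    if (r$n_pairs == 0L) next
    pairs <- r$structure$pairs
    # antiparallel, non-crossing, within range
    expect_true(all(diff(pairs[, 1]) > 0))
    expect_true(all(diff(pairs[, 2]) < 0))
    expect_lte(r$n_gu_pairs, r$n_pairs)
    # independent re-scoring reproduces delta_g
    expect_equal(duplex_energy_of_structure(s1, s2, pairs, p), r$delta_g,
                 tolerance = 1e-9)
    # target window is the half-open j-interval of the duplex
    expect_equal(r$target_window,
                 c(min(pairs[, 2]) - 1L, max(pairs[, 2])))
  }
})

test_that("the structure re-scorer rejects invalid structures", {
  p <- duplex_params()
  expect_error(duplex_energy_of_structure("GGG", "CCC",
                                          rbind(c(1, 1), c(2, 2)), p),
               "non-crossing")
  expect_error(duplex_energy_of_structure("GGG", "CCC",
                                          rbind(c(1, 3), c(1, 2)), p),
               "at most one pair")
  expect_error(duplex_energy_of_structure("AGG", "CCA", cbind(1, 3), p),
               "non-canonical")
})

test_that("perfect-match energy bounds any same-length target fold", {
  set.seed(5)
  p <- duplex_params()
  mir <- mir122_5p()
  pm <- perfect_match_dg(mir, params = p)
  expect_identical(pm$n_pairs, nchar(mir))
  for (rep in 1:10) {
    tgt <- random_rna(nchar(mir))
    expect_lte(pm$delta_g, fold_duplex(mir, tgt, params = p)$delta_g)
  }
})

test_that("scramble null is seed-deterministic and composition-preserving", {
  mir <- mir122_5p()
  tgt <- synthetic_agt_window()$target
  a <- scramble_null(mir, tgt, n = 25, seed = 699)
  b <- scramble_null(mir, tgt, n = 25, seed = 699)
  expect_identical(a$per_scramble_dg, b$per_scramble_dg)
  c <- scramble_null(mir, tgt, n = 25, seed = 700)
  expect_false(identical(a$per_scramble_dg, c$per_scramble_dg))
  expect_equal(a$weakest_dg, max(a$per_scramble_dg))
  expect_equal(a$strongest_dg, min(a$per_scramble_dg))
  expect_lte(a$perfect_match_dg, a$strongest_dg)
  expect_equal(unname(a$plausible_range),
               c(a$weakest_dg, a$perfect_match_dg))
})

test_that("scrambling a homopolymer leaves the energy unchanged", {
  sn <- scramble_null("GGGAGG", "CCCCCC", n = 8, seed = 1)
  base <- fold_duplex("GGGAGG", "CCCCCC")$delta_g
  expect_true(all(sn$per_scramble_dg == base))
  expect_equal(sn$weakest_dg, sn$strongest_dg)
})

test_that("scramble energies match independently folded permutations", {
  set.seed(42)
  p <- duplex_params()
  mir <- random_rna(6)
  tgt <- "GCAUGC"
  sn <- scramble_null(mir, tgt, n = 10, seed = 77, params = p)
  # regenerate the same permutations and fold each through the oracle
  chars <- strsplit(tgt, "")[[1]]
  set.seed(77)
  for (k in 1:10) {
    scr <- paste(sample(chars), collapse = "")
    expect_equal(sn$per_scramble_dg[k], brute_force_dg(mir, scr, p),
                 tolerance = 1e-12)
  }
})

test_that("percent-of-range is linear, shift-invariant and rounds half away from zero", {
  r <- percent_of_range(-11.3, -12.3, -7.1, -39.3)
  expect_equal(r$span, 32.2)
  expect_equal(r$percent, 100 * 1 / 32.2, tolerance = 1e-12)
  expect_identical(r$percent_rounded, 3L)
  expect_equal(percent_of_range(-10, -10, -7.1, -39.3)$percent, 0)
  expect_equal(percent_of_range(-10, -20, -7.1, -39.3)$percent,
               100 * 10 / 32.2, tolerance = 1e-12)
  # invariance to adding a constant to all four energies
  for (shift in c(-3.7, 1.4, 10)) {
    expect_equal(percent_of_range(-11.3 + shift, -12.3 + shift,
                                  -7.1 + shift, -39.3 + shift)$percent,
                 r$percent, tolerance = 1e-12)
  }
  expect_identical(percent_of_range(-10, -10.8, -5, -55)$percent_rounded, 2L)
  expect_error(percent_of_range(-10, -11, -5, -5), "range_lower < range_upper")
})

test_that("allele comparison applies mRNA-sense substitutions and reports deltas", {
  win <- synthetic_agt_window()
  cmp <- compare_alleles(mir122_5p(), win$target, win$offset, win$alt)
  expect_equal(cmp$ddg, cmp$var$delta_g - cmp$ref$delta_g)
  # the U>C substitution turns a G-U wobble into G-C: stronger binding,
  # one wobble fewer
  expect_lt(cmp$ddg, 0)
  expect_equal(cmp$n_gu_pairs_diff, -1L)
  expect_error(compare_alleles(mir122_5p(), win$target, 999, "C"),
               "out of bounds")
  expect_error(compare_alleles(mir122_5p(), win$target, win$offset, "U"),
               "equals the reference")
})

test_that("a substitution away from the duplex window leaves the energy unchanged", {
  p <- duplex_params()
  # strong GC helix at the 5' end of the target; position 11 never pairs
  mir <- "GGGGGG"
  tgt <- "CCCCCCAAAAA"
  cmp <- compare_alleles(mir, tgt, 10, "U", params = p)
  expect_equal(cmp$ddg, 0)
  expect_identical(cmp$n_pairs_diff, 0L)
})

test_that("co-optimal tie-break reports the lexicographically smallest pair list", {
  # two disjoint CC sites on the target give co-optimal single-helix
  # structures; the leftmost (smallest j) must be reported
  r <- fold_duplex("GGG", "CCAAACC")
  expect_equal(r$structure$pairs[, 2], c(2, 1))
})

test_that("energy parameter tables round-trip through the plain-text form", {
  p <- duplex_params()
  tf <- tempfile(fileext = ".tsv")
  write_stack_table(p, tf)
  m <- read_stack_table(tf)
  expect_equal(m, p$stack)
  p2 <- duplex_params(stack = m)
  expect_equal(p2$stack, p$stack)
})

test_that("stack table is symmetric and loop penalties behave", {
  p <- duplex_params()
  expect_equal(p$stack, t(p$stack))
  # nondecreasing from size 2 upwards (single-nt bulges are scored with
  # their flanking stack and are a documented special case)
  expect_true(all(diff(p$bulge_init[-1]) >= 0))
  expect_true(all(diff(p$interior_init[-1]) >= 0))
  expect_true(all(p$bulge_init > 0))
  expect_true(all(p$interior_init[-1] > 0))
})

test_that("FASTA round trip preserves sequences", {
  skip_if_not_installed("Biostrings")
  tf <- tempfile(fileext = ".fa")
  writeLines(c(">mir", "UGGAGUGUGA", ">win", "ACGUACGUAC"), tf)
  seqs <- read_fasta_seqs(tf)
  expect_named(seqs, c("mir", "win"))
  expect_equal(unclass(seqs$mir)[1], "UGGAGUGUGA")
})
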