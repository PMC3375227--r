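test_that("read_alignment builds the reference column map", {
  # reference without gaps: identity mapping
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ref", "ACDEF", ">s2", "ACDEF", ">s3", "AC-EF"), f)
  aln <- read_alignment(f, "ref")
  expect_equal(aln$column_map, 1:5)

  # reference gap at column 2: column 3 maps to position 2
  writeLines(c(">ref", "A-DEF", ">s2", "ACDEF"), f)
  aln <- read_alignment(f, "ref")
  expect_equal(aln$column_map, c(1L, NA, 2L, 3L, 4L))

  aln <- toy5_alignment()
  expect_equal(aln$n_seq, 5L)
  expect_equal(aln$width, 12L)
})

test_that("malformed alignments and missing references are rejected", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ref", "ACDEF", ">s2", "ACDE"), f)
  expect_error(read_alignment(f, "ref"), "unequal")
  writeLines(c(">ref", "ACDEF", ">s2", "ACDEF"), f)
  expect_error(read_alignment(f, "nope"), "not found")
})

test_that("select_subalignment partitions by the signature residue", {
  aln <- toy5_alignment()
  parts <- select_subalignment(aln, signature_criterion(4, "H", "P"))
  expect_equal(parts$n_sub, 2L)
  expect_equal(parts$n_complement, 3L)
  expect_setequal(parts$sub$members, c("seq4", "seq5"))

  # residue set covering everything observed: sub = whole alignment
  all_parts <- select_subalignment(aln, signature_criterion(4, c("H", "P"), "G"))
  expect_equal(all_parts$n_sub, 5L)
  expect_equal(all_parts$n_complement, 0L)

  # residue never observed at the position: empty-perturbation error
  expect_error(select_subalignment(aln, signature_criterion(4, "W", "P")),
               "empty perturbation")
})

test_that("positional frequencies count residues with pseudocount", {
  aln <- new_alignment(c(ref = "AC", s2 = "AC", s3 = "AC", s4 = "CC"), "ref")
  f0 <- positional_frequencies(aln, pseudocount = 0)
  expect_equal(unname(f0$freq[1, "A"]), 0.75)
  expect_equal(unname(f0$freq[1, "C"]), 0.25)
  expect_equal(unname(f0$freq[2, "C"]), 1)
  expect_equal(sum(f0$freq[2, ] > 0), 1L)

  f1 <- positional_frequencies(aln, pseudocount = 1)
  expect_equal(unname(f1$freq[1, "A"]), 4 / 24)
  expect_equal(unname(f1$freq[1, "C"]), 2 / 24)
  expect_equal(unname(f1$freq[1, "W"]), 1 / 24)
  # every position sums to one regardless of pseudocount
  expect_equal(rowSums(f0$freq), c(`1` = 1, `2` = 1), tolerance = 1e-9)
  expect_equal(rowSums(f1$freq), c(`1` = 1, `2` = 1), tolerance = 1e-9)
})

test_that("gap columns are excluded from normalisation and flagged", {
  aln <- new_alignment(c(ref = "AC", s2 = "-C", s3 = "-C", s4 = "-C"), "ref")
  ft <- positional_frequencies(aln, pseudocount = 0)
  expect_equal(unname(ft$n_eff[1]), 1)
  expect_equal(unname(ft$freq[1, "A"]), 1)
  expect_true(ft$flagged[1])
  expect_false(ft$flagged[2])
})

test_that("SCA energy vanishes when the subalignment is the full alignment", {
  aln <- toy5_alignment()
  crit <- signature_criterion(4, c("H", "P"), "G")
  sca <- suppressWarnings(
    sca_statistical_energy(aln, crit, force = TRUE))
  expect_true(all(abs(sca$ddG) < 1e-12))
})

test_that("a planted shifted column attains the top SCA energy and sigma", {
  aln <- toy5_alignment()
  crit <- signature_criterion(4, "H", "P")
  for (method in c("binomial", "logratio")) {
    sca <- suppressWarnings(
      sca_statistical_energy(aln, crit, method = method, force = TRUE))
    expect_equal(sca$position[which.max(sca$ddG)], 8)
    expect_equal(sca$position[which.max(sca$sigma)], 8)
  }
  sig <- suppressWarnings(covariance_sigma(aln, crit, force = TRUE))
  expect_equal(sig$position[which.max(sig$sigma)], 8)
})

test_that("small subalignments are refused unless forced", {
  aln <- toy5_alignment()
  crit <- signature_criterion(4, "H", "P")
  expect_error(sca_statistical_energy(aln, crit), "min_sub_size|only 2")
  expect_warning(sca_statistical_energy(aln, crit, force = TRUE),
                 "below min_sub_size")
})

test_that("SCA energies are invariant to record order and relabeling", {
  spec <- msa_spec(60, 20, signature_position = 3,
                   signature_fraction = 0.5,
                   planted = data.frame(position = 7, baseline = "A",
                                        shifted = "V", shift = 0.8),
                   seed = 42)
  aln <- generate_msa(spec)
  crit <- signature_criterion(3, "H", "P")
  sca1 <- sca_statistical_energy(aln, crit)
  recs <- aln$records
  perm <- c("ref", sample(setdiff(names(recs), "ref")))
  shuffled <- recs[perm]
  names(shuffled) <- c("ref", paste0("renamed", seq_len(length(recs) - 1)))
  sca2 <- sca_statistical_energy(new_alignment(shuffled, "ref"), crit)
  expect_equal(sca1$ddG, sca2$ddG, tolerance = 1e-12)
  expect_equal(sca1$sigma, sca2$sigma, tolerance = 1e-12)
})

test_that("gamma score is zero on identical tables, positive on the planted
           shift, and antisymmetric under subalignment swap", {
  aln <- toy5_alignment()
  parts <- select_subalignment(aln, signature_criterion(4, "H", "P"))
  fs <- positional_frequencies(parts$sub)
  fc <- positional_frequencies(parts$complement)
  # identical frequency tables: any shift measure must vanish
  expect_equal(gamma_score(fs, fs, 1, ec = "A", x = "C"), 0)
  expect_equal(gamma_score(fc, fc, 8, ec = "W", x = "Y"), 0)
  # planted column 8: His subalignment shifts W -> Y
  g <- gamma_score(fs, fc, 8, ec = "W", x = "Y")
  expect_gt(g, 0)
  expect_equal(gamma_score(fc, fs, 8, ec = "W", x = "Y"), -g)
  expect_error(gamma_score(fs, fc, 8, ec = "W", x = "W"), "must differ")
})

test_that("candidate selection keeps positive-score mutations in rank order", {
  pl <- data.frame(position = c(5, 20, 33, 41, 48, 55),
                   baseline = c("A", "A", "A", "A", "Y", "Y"),
                   shifted  = c("V", "Y", "R", "L", "V", "T"),
                   shift = 0.6,
                   ref = c("A", "A", "A", "A", "V", "T"))
  spec <- msa_spec(400, 60, signature_position = 10, planted = pl, seed = 2)
  aln <- generate_msa(spec)
  crit <- signature_criterion(10, "H", "P")
  cand <- top_candidate_mutations(aln, crit, n_top = 6)
  # the four positively-shifted columns are returned, the two columns
  # shifting toward the reference residue are dropped (Gamma < 0)
  expect_setequal(cand$position, c(5, 20, 33, 41))
  expect_true(all(cand$gamma > 0))
  expect_equal(cand$sca_energy, sort(cand$sca_energy, decreasing = TRUE))
  expect_equal(cand$rank, seq_len(4))
  expect_true(all(cand$x != cand$ec))
  # X really is the most frequent non-reference residue in the signature
  # subalignment (checked against raw counts)
  parts <- select_subalignment(aln, crit)
  fs <- positional_frequencies(parts$sub)
  for (r in seq_len(nrow(cand))) {
    counts <- fs$counts[match(cand$position[r], fs$positions), ]
    counts <- counts[names(counts) != cand$ec[r]]
    expect_equal(cand$x[r], names(counts)[which.max(counts)])
  }
  expect_equal(nrow(top_candidate_mutations(aln, crit, n_top = 0)), 0L)
})
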