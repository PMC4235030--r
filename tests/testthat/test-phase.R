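two_panels <- function(seed = 71, n = 80, m = 60) {
  spec <- synthetic_spec(n_markers = m, chrom_length_bp = m * 1e5,
                         n_individuals = n, Ne = n, seed = seed)
  suppressMessages(gen_diverged_populations(spec, list(A = 0, B = 0)))
}

test_that("common markers intersect on position with allele-set checks and flips", {
  mk <- function(pos, a0, a1) {
    hap <- matrix(rep(c(0L, 1L), length(pos) * 2), nrow = length(pos))
    make_panel(hap, pos = pos, allele0 = a0, allele1 = a1)
  }
  pA <- mk(c(1e5, 2e5, 3e5), c("A", "A", "A"), c("C", "C", "C"))
  pB <- mk(c(2e5, 3e5, 4e5), c("A", "C", "A"), c("C", "A", "C"))
  pC <- mk(c(2e5, 3e5, 5e5), c("A", "A", "A"), c("C", "C", "C"))
  cms <- common_markers(list(pA, pB, pC), scenario = "I")
  expect_equal(cms$table$pos, c(2e5, 3e5))
  # marker at 3e5 has swapped labels in panel B -> flip flag there only
  expect_equal(cms$table$flip_2, c(FALSE, TRUE))
  expect_equal(cms$table$flip_3, c(FALSE, FALSE))
  # Scenario II on the pair (A, B)
  cms2 <- common_markers(list(pA, pB), scenario = "II")
  expect_equal(cms2$table$pos, c(2e5, 3e5))
  # allele-set mismatch is dropped with a message
  pD <- mk(c(2e5, 3e5), c("A", "G"), c("C", "T"))
  expect_message(cmsD <- common_markers(list(pA, pD), scenario = "II"),
                 "mismatched allele sets")
  expect_equal(cmsD$table$pos, 2e5)
  expect_error(common_markers(list(pA, mk(9e5, "A", "C")), "II"), "no markers shared")
})

test_that("Scenario-I marker sets are subsets of every pairwise Scenario-II set", {
  panels <- suppressMessages(gen_diverged_populations(
    synthetic_spec(n_markers = 120, chrom_length_bp = 1.2e7, n_individuals = 40,
                   Ne = 40, seed = 77),
    list(A = 2, B = 2, C = 30)))
  cms1 <- common_markers(panels, scenario = "I")
  key1 <- paste(cms1$table$chrom, cms1$table$pos)
  for (pr in list(c(1, 2), c(1, 3), c(2, 3))) {
    cms2 <- common_markers(panels[pr], scenario = "II")
    key2 <- paste(cms2$table$chrom, cms2$table$pos)
    expect_true(all(key1 %in% key2))
  }
})

test_that("phase_correlation reproduces hand Pearson values and edge cases", {
  rA <- c(0.1, 0.5, 0.9)
  rB <- c(0.2, 0.4, 1.0)
  # hand computation: centred cross-product 0.32 over sd product 0.33307
  expect_equal(phase_correlation(rA, rB), 0.32 / sqrt(0.32 * 0.34666667),
               tolerance = 1e-7)
  expect_equal(phase_correlation(rA, rB), 0.9608, tolerance = 1e-4)
  expect_equal(phase_correlation(rA, rA), 1)
  expect_equal(phase_correlation(rA, -rA), -1)
  expect_warning(out <- phase_correlation(c(1, 1, 1), rA), "zero variance")
  expect_true(is.na(out))
  expect_error(phase_correlation(rA, rB[1:2]), "equal length")
})

test_that("identical panels give unit phase correlation in every populated bin and window", {
  panels <- two_panels()
  pA <- panels$A
  cms <- common_markers(list(pA, pA), scenario = "II")
  curve <- binned_phase_decay(pA, pA, cms, max_distance = 5)
  expect_true(all(abs(curve$cor_r[!is.na(curve$cor_r)] - 1) < 1e-12))
  trk <- local_phase(pA, pA, cms, N = 10)
  expect_true(all(abs(trk$cor_r[!is.na(trk$cor_r)] - 1) < 1e-12))
  expect_equal(nrow(trk), nrow(cms$table) - 10 + 1)
})

test_that("relabeling every allele of one panel leaves phase correlations unchanged", {
  panels <- two_panels(seed = 73)
  pA <- panels$A; pB <- panels$B
  flipped <- pB
  flipped$haplotypes <- 1L - flipped$haplotypes
  a0 <- flipped$markers$allele0
  flipped$markers$allele0 <- flipped$markers$allele1
  flipped$markers$allele1 <- a0
  cms <- common_markers(list(pA, pB), scenario = "II")
  cms_f <- common_markers(list(pA, flipped), scenario = "II")
  expect_true(all(cms_f$table$flip_2))
  c1 <- binned_phase_decay(pA, pB, cms, max_distance = 3)
  c2 <- binned_phase_decay(pA, flipped, cms_f, max_distance = 3)
  expect_equal(c1$cor_r, c2$cor_r, tolerance = 1e-12)
})

test_that("local phase windows slide by one matched marker and flag degenerate windows", {
  panels <- two_panels(seed = 79, m = 40)
  pA <- panels$A; pB <- panels$B
  cms <- common_markers(list(pA, pB), scenario = "II")
  n_matched <- nrow(cms$table)
  trk <- local_phase(pA, pB, cms, N = 12)
  expect_equal(nrow(trk), n_matched - 12 + 1)
  expect_equal(trk$n_pairs, rep(12 * 11 / 2, nrow(trk)))
  expect_equal(trk$mid_pos, cms$table$pos[seq_len(nrow(trk)) + 6])
})
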