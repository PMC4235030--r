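test_that("sample missingness filter removes exactly the samples above threshold", {
  hap <- matrix(0L, nrow = 10, ncol = 10)  # 5 samples
  hap[, 6] <- c(rep(NA_integer_, 2), rep(0L, 8))   # sample 3: 2/10 missing
  hap[1, 9] <- NA_integer_                         # sample 5: 1/10 missing
  hap[, 2] <- 1L  # keep markers polymorphic-ish (not required here)
  panel <- make_panel(hap)
  res <- filter_samples_by_missingness(panel, max_missing_frac = 0.10)
  expect_equal(res$panel$sample_ids, c("s1", "s2", "s4", "s5"))
  expect_equal(unname(res$report$removed_by_rule["sample_missingness"]), 1L)
  # exactly at the threshold is kept (sample 5: 0.10)
  expect_true("s5" %in% res$panel$sample_ids)
})

test_that("toy missingness report matches a hand count", {
  set.seed(11)
  hap <- matrix(rbinom(10 * 10, 1L, 0.5), nrow = 10)
  hap[c(1, 3, 5), 1] <- NA  # sample 1: 3/10 -> removed
  hap[2, 4] <- NA           # sample 2: 1/10 -> kept
  panel <- make_panel(hap)
  res <- filter_samples_by_missingness(panel, 0.10)
  expect_equal(res$report$n_samples_in, 5L)
  expect_equal(res$report$n_samples_out, 4L)
})

test_that("marker filters apply call rate, MAF and HWE in order with first-rule attribution", {
  set.seed(7)
  n_ind <- 40
  hap <- matrix(rbinom(20 * 2 * n_ind, 1L, 0.5), nrow = 20)
  # marker 1: called in 85% of samples -> call-rate failure
  miss <- sample(n_ind, ceiling(0.15 * n_ind))
  hap[1, c(2 * miss - 1, 2 * miss)] <- NA
  # marker 2: MAF 0.04 -> removed; marker 3: MAF exactly 0.05 -> kept
  hap[2, ] <- 0L; hap[2, seq_len(round(0.04 * 2 * n_ind))] <- 1L
  hap[3, ] <- 0L; hap[3, seq_len(0.05 * 2 * n_ind)] <- 1L
  # marker 4: extreme heterozygote excess -> HWE failure
  hap[4, seq(1, 2 * n_ind, 2)] <- 0L
  hap[4, seq(2, 2 * n_ind, 2)] <- 1L
  panel <- make_panel(hap)
  res <- filter_markers(panel)
  expect_false("m1" %in% res$panel$markers$id)
  expect_false("m2" %in% res$panel$markers$id)
  expect_true("m3" %in% res$panel$markers$id)
  expect_false("m4" %in% res$panel$markers$id)

  # surviving set equals an independent re-implementation of all three rules
  keep_oracle <- vapply(seq_len(20), function(i) {
    a <- hap[i, seq(1, 2 * n_ind, 2)]
    b <- hap[i, seq(2, 2 * n_ind, 2)]
    ok <- !is.na(a) & !is.na(b)
    if (mean(ok) < 0.9) return(FALSE)
    alleles <- c(a[ok], b[ok])
    maf <- min(mean(alleles), 1 - mean(alleles))
    if (maf < 0.05) return(FALSE)
    g <- (a + b)[ok]
    oracle_hwe(sum(g == 0), sum(g == 1), sum(g == 2)) >= 1e-7
  }, logical(1))
  expect_setequal(res$panel$markers$id, paste0("m", which(keep_oracle)))
  expect_equal(res$report$n_markers_in - res$report$n_markers_out,
               sum(res$report$removed_by_rule))
})

test_that("filtering is idempotent", {
  set.seed(3)
  panel <- random_panel(30, 60)
  once <- filter_markers(panel)$panel
  twice <- filter_markers(once)$panel
  expect_identical(once, twice)
})

test_that("the exact HWE test matches enumeration, is symmetric, and stays in (0, 1]", {
  expect_equal(hwe_exact_test(25, 50, 25), 1.0)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-7)
  expect_equal(hwe_exact_test(10, 0, 0), 1.0)  # monomorphic
  cases <- list(c(5, 10, 5), c(12, 3, 9), c(0, 7, 30), c(2, 2, 2), c(40, 12, 1))
  for (cs in cases) {
    p <- hwe_exact_test(cs[1], cs[2], cs[3])
    expect_equal(p, oracle_hwe(cs[1], cs[2], cs[3]), tolerance = 1e-12)
    expect_equal(p, hwe_exact_test(cs[3], cs[2], cs[1]), tolerance = 1e-12)
    expect_gt(p, 0)
    expect_lte(p, 1)
  }
})

test_that("HWE p-values agree with a small-n permutation null", {
  # place 2n alleles into n genotypes at random; empirical two-sided p
  set.seed(21)
  n_AA <- 3; n_Aa <- 0; n_aa <- 2
  n <- 5; na <- 2 * n_AA + n_Aa
  alleles <- c(rep(1L, na), rep(0L, 2 * n - na))
  het_obs_prob <- function(h, draws) mean(draws == h)
  draws <- replicate(20000, {
    perm <- sample(alleles)
    sum(perm[seq(1, 2 * n, 2)] != perm[seq(2, 2 * n, 2)])
  })
  p_emp <- {
    tab <- table(draws) / length(draws)
    p_obs <- het_obs_prob(n_Aa, draws)
    sum(tab[tab <= p_obs + 1e-9])
  }
  expect_equal(hwe_exact_test(n_AA, n_Aa, n_aa), p_emp, tolerance = 0.02)
})

test_that("pruning removes parents then keeps one full sib per family, reproducibly", {
  ped <- data.frame(
    individual = c("sire1", "dam1", "kid1", "kid2", "kid3", "solo", "kidX", "kidY"),
    sire = c(NA, NA, "sire1", "sire1", "sire1", NA, "sire2", "sire2"),
    dam = c(NA, NA, "dam1", "dam1", "dam1", NA, NA, "damY"),
    stringsAsFactors = FALSE)
  ids <- ped$individual
  kept <- prune_relatives(ids, ped, seed = 99)
  # hand-derived: sire1/dam1 are parents of sampled kids -> removed;
  # kid1-3 are full sibs -> exactly one kept; kidX has unknown dam -> kept;
  # kidY's parents not both in the full-sib rule group with kidX -> kept
  expect_false(any(c("sire1", "dam1") %in% kept))
  expect_equal(sum(c("kid1", "kid2", "kid3") %in% kept), 1L)
  expect_true(all(c("solo", "kidX", "kidY") %in% kept))
  expect_identical(kept, prune_relatives(ids, ped, seed = 99))
  # trio: child kept, parents dropped
  trio <- data.frame(individual = c("c", "s", "d"), sire = c("s", NA, NA),
                     dam = c("d", NA, NA), stringsAsFactors = FALSE)
  expect_identical(prune_relatives(c("c", "s", "d"), trio, 1), "c")
  # empty pedigree is the identity
  expect_identical(prune_relatives(c("a", "b"), NULL, 1), c("a", "b"))
})
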