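test_that("noise-free decay data recovers alpha to machine-level accuracy", {
  d <- seq(0.1, 10, by = 0.1)
  for (a in c(0.5, 1, 2, 5, 10)) {
    fit <- fit_alpha(d, 1 / (1 + a * d))
    expect_true(fit$converged)
    expect_lt(abs(fit$alpha_hat - a) / a, 1e-6)
  }
})

test_that("pairs with r2 = 0 are excluded before fitting", {
  d <- c(0.5, 1, 2, 3, 4)
  r2 <- c(1 / (1 + 2 * d[1:3]), 0, 0)
  fit <- fit_alpha(d, r2)
  expect_equal(fit$n_used, 3L)
  expect_equal(fit$n_excluded_zero, 2L)
  expect_error(fit_alpha(c(1, 2), c(0, 0)), "r2 > 0")
})

test_that("the deviance fit agrees with the IRLS Gamma GLM on noisy data", {
  gp <- gen_glm_pairs(alpha = 5, n = 4000, gamma_shape = 1, seed = 31)
  keep <- gp$r2 > 1e-12
  fit <- fit_alpha(gp$d, gp$r2)
  ref <- stats::glm(r2 ~ 0 + d, family = stats::Gamma(link = "inverse"),
                    offset = rep(1, sum(keep)), data = gp[keep, ])
  expect_equal(fit$alpha_hat, unname(coef(ref)), tolerance = 1e-7)
  expect_equal(fit$std_err, unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
})

test_that("fit_alpha is invariant to pair order and to duplicating the pair set", {
  gp <- gen_glm_pairs(alpha = 2, n = 500, seed = 17)
  base <- fit_alpha(gp$d, gp$r2)$alpha_hat
  perm <- sample(nrow(gp))
  expect_equal(fit_alpha(gp$d[perm], gp$r2[perm])$alpha_hat, base,
               tolerance = 1e-9)
  expect_equal(fit_alpha(rep(gp$d, 2), rep(gp$r2, 2))$alpha_hat, base,
               tolerance = 1e-9)
})

test_that("expected_r2 and Sved's formula agree under alpha = 4 Ne c-per-Mb", {
  expect_equal(expected_r2(7, 0), 1)
  expect_equal(expected_r2(0, 3.2), 1)
  expect_equal(expected_r2(9, 1), 0.1)
  expect_error(expected_r2(-2, 1), "undefined")
  expect_equal(sved_expected_r2(0, 50), 1)
  expect_equal(sved_expected_r2(0.25, 1), 0.5)
  expect_equal(sved_expected_r2(0.5, 100), 1 / 201)
  # substitution check at sampled points: d Mb at c_mb Morgans/Mb
  for (c_mb in c(0.005, 0.01, 0.02)) {
    for (d in c(0.5, 2, 8)) {
      Ne <- 120
      expect_equal(expected_r2(4 * Ne * c_mb, d), sved_expected_r2(c_mb * d, Ne),
                   tolerance = 1e-12)
    }
  }
  # strictly decreasing in d for alpha > 0
  d_grid <- seq(0, 10, by = 0.5)
  expect_true(all(diff(expected_r2(3, d_grid)) < 0))
})

test_that("ld_map slides one marker per step and records the upper-middle marker", {
  set.seed(41)
  panel <- random_panel(12, 60, spacing_bp = 1e5)
  track <- suppressWarnings(ld_map(panel, N = 10, d_fixed = 10))
  expect_equal(nrow(track), 12 - 10 + 1)
  expect_equal(track$mid_pos, panel$markers$pos[(1:3) + 5])
  exact <- make_panel(matrix(rbinom(10 * 40, 1, 0.5), nrow = 10))
  exact$haplotypes[rowSums(exact$haplotypes) %in% c(0, 40), 1] <- 1L
  one <- suppressWarnings(ld_map(exact, N = 10))
  expect_equal(nrow(one), 1L)
})

test_that("a high-recombination mid-segment elevates the alpha track over the flanks", {
  set.seed(55)
  m <- 150
  pos <- seq(2e5, by = 2e5, length.out = m)          # 30 Mb, even spacing
  # distort the map: intervals in the middle third behave 15x longer
  gaps <- diff(pos) / 1e6
  hot <- seq_len(m - 1) > m / 3 & seq_len(m - 1) <= 2 * m / 3
  eff <- cumsum(c(pos[1] / 1e6, gaps * ifelse(hot, 15, 1))) * 1e6
  founders <- matrix(rbinom(6 * m, 1, 0.5), nrow = 6)
  pool <- ldscape:::mosaic_pool(founders, eff, rho = 1, n_hap = 160)
  keep <- !(rowMeans(pool) %in% c(0, 1))
  panel <- make_panel(pool[keep, ], pos = pos[keep])
  track <- ld_map(panel, N = 30, d_fixed = 10)
  mid_lo <- quantile(pos, 1 / 3)
  mid_hi <- quantile(pos, 2 / 3)
  in_mid <- track$mid_pos > mid_lo & track$mid_pos <= mid_hi
  expect_gt(median(track$alpha_hat[in_mid], na.rm = TRUE),
            median(track$alpha_hat[!in_mid], na.rm = TRUE))
})

test_that("chromosome_alpha is deterministic and exact on noise-free panels", {
  set.seed(61)
  panel <- random_panel(120, 50, spacing_bp = 2e5)
  a1 <- chromosome_alpha(panel, "1", n_pairs = 500, n_replicates = 10, seed = 5)
  a2 <- chromosome_alpha(panel, "1", n_pairs = 500, n_replicates = 10, seed = 5)
  expect_identical(a1$alphas, a2$alphas)
  expect_false(identical(
    a1$alphas,
    chromosome_alpha(panel, "1", n_pairs = 500, n_replicates = 10, seed = 6)$alphas))
  # when all pairs satisfy r2 = 1/(1 + alpha d) exactly, every subsample
  # recovers alpha and the replicate spread collapses
  d <- seq(0.05, 10, length.out = 400)
  alphas <- vapply(1:20, function(k) {
    idx <- sample(length(d), 200)
    fit_alpha(d[idx], 1 / (1 + 3 * d[idx]))$alpha_hat
  }, numeric(1))
  expect_lt(max(abs(alphas - 3)), 1e-6)
  expect_lt(sd(alphas), 1e-7)
})

test_that("windows too small or incomplete panels are rejected", {
  panel <- random_panel(5, 20)
  expect_warning(expect_error(ld_map(panel, N = 10), "no chromosome"),
                 "skipped")
  panel$haplotypes[1, 1] <- NA
  expect_error(ld_map(panel, N = 3), "complete")
})
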