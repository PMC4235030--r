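#' @title Local LD maps via a Gamma GLM with inverse link
#' @description The decay of r-squared with physical distance d (Mb) is
#'   modelled as `E(r2) = 1 / (1 + alpha * d)`: a Gamma generalized linear
#'   model with inverse link whose linear predictor `eta = 1 + alpha * d`
#'   has its intercept fixed at 1 (an offset), leaving a single regression
#'   parameter alpha, the per-Mb LD decay rate. alpha conflates local
#'   recombination rate and local effective population size and is the
#'   quantity mapped along chromosomes by the sliding-window functions.
#'   Fitting minimises the Gamma deviance in alpha alone (the dispersion
#'   cancels from the point estimate); pairs with r2 = 0 are excluded
#'   before fitting.
#' @name local_ld
NULL

#' Fit the LD decay rate alpha
#'
#' Maximum-likelihood fit of `E(r2) = 1/(1 + alpha d)` by minimising the
#' Gamma deviance in the single parameter alpha. Because the inverse link is
#' canonical for the Gamma family, the score equation is
#' `sum(d * (r2 - mu)) = 0` with `mu = 1/(1 + alpha d)`; the deviance is
#' convex in alpha on the admissible region `1 + alpha d > 0`, so Newton
#' steps with a bisection fallback on the bracket
#' `(-1/max(d) + eps, 1e4)` always terminate. Pairs with r2 = 0 (within a
#' 1e-12 guard) are excluded before fitting. The dispersion is estimated by
#' the Pearson moment estimator and used only for the standard error.
#'
#' @param d distances in Mb (or a 2-column data.frame/list with elements
#'   `d` and `r2`)
#' @param r2 observed r-squared values, same length as `d`
#' @return an `alpha_fit` list: `alpha_hat`, `std_err`, `converged`,
#'   `n_used` (pairs after zero-exclusion), `n_excluded_zero`, `deviance`,
#'   `dispersion`, `iterations`
#' @export
#' @examples
#' d <- seq(0.1, 10, by = 0.1)
#' fit_alpha(d, 1 / (1 + 2 * d))$alpha_hat  # recovers 2 exactly
fit_alpha <- function(d, r2 = NULL) {
  if (is.null(r2)) {
    r2 <- d$r2
    d <- d$d
  }
  stopifnot(length(d) == length(r2), all(d >= 0), all(r2 >= 0))
  nz <- r2 > 1e-12
  n_excluded <- sum(!nz)
  d <- d[nz]; y <- r2[nz]
  if (length(y) < 2L || length(unique(d)) < 2L) {
    stop("fit_alpha needs >= 2 pairs with r2 > 0 at >= 2 distinct distances")
  }
  d_max <- max(d)
  lo <- -1 / d_max + 1e-9
  hi <- 1e4
  # score g(a) = d deviance / d alpha / 2 = sum(d * (y - 1/(1 + a d)))
  score <- function(a) sum(d * (y - 1 / (1 + a * d)))
  info <- function(a) sum(d^2 / (1 + a * d)^2)
  g_lo <- score(lo); g_hi <- score(hi)
  if (g_lo >= 0) {           # minimum at (or beyond) the lower boundary
    a <- lo
    return(finish_alpha_fit(a, d, y, n_excluded, converged = FALSE,
                            iterations = 0L))
  }
  if (g_hi <= 0) {           # flat-to-increasing LD: boundary at the cap
    a <- hi
    return(finish_alpha_fit(a, d, y, n_excluded, converged = FALSE,
                            iterations = 0L))
  }
  # moment start: solve mean(y) = 1/(1 + a * mean(d))
  a <- (1 / mean(y) - 1) / mean(d)
  if (a <= lo || a >= hi) a <- (lo + hi) / 2
  converged <- FALSE
  it <- 0L
  blo <- lo; bhi <- hi
  while (it < 100L) {
    it <- it + 1L
    g <- score(a)
    if (g > 0) bhi <- a else blo <- a
    step <- g / info(a)
    a_new <- a - step
    if (a_new <= blo || a_new >= bhi) a_new <- (blo + bhi) / 2  # bisection fallback
    if (abs(a_new - a) < 1e-10) {
      a <- a_new
      converged <- TRUE
      break
    }
    a <- a_new
  }
  finish_alpha_fit(a, d, y, n_excluded, converged, it)
}

finish_alpha_fit <- function(a, d, y, n_excluded, converged, iterations) {
  eta <- 1 + a * d
  mu <- 1 / eta
  dev <- 2 * sum(-log(y / mu) + (y - mu) / mu)
  n <- length(y)
  phi <- sum(((y - mu) / mu)^2) / max(n - 1L, 1L)   # Pearson dispersion
  se <- sqrt(phi / sum(d^2 / eta^2))
  structure(list(alpha_hat = a, std_err = se, converged = converged,
                 n_used = n, n_excluded_zero = n_excluded, deviance = dev,
                 dispersion = phi, iterations = iterations),
            class = "alpha_fit")
}

#' @export
print.alpha_fit <- function(x, ...) {
  cat(sprintf("alpha_fit: alpha_hat = %.6g (se %.3g), n_used = %d, %s\n",
              x$alpha_hat, x$std_err, x$n_used,
              if (x$converged) sprintf("converged in %d iteration(s)", x$iterations)
              else "NOT converged"))
  invisible(x)
}

#' Expected r-squared at a distance under the fitted decay model
#'
#' @param alpha per-Mb decay rate
#' @param d distance in Mb (vectorised)
#' @return `1 / (1 + alpha * d)`; errors when `1 + alpha d <= 0`
#' @export
expected_r2 <- function(alpha, d) {
  eta <- 1 + alpha * d
  if (any(eta <= 0)) stop("expected_r2 undefined: 1 + alpha*d <= 0")
  1 / eta
}

#' Sved's expected r-squared under drift-recombination equilibrium
#'
#' For an isolated random-mating population, the expectation of r-squared at
#' recombination fraction `c` with effective population size `Ne` is
#' `1 / (1 + 4 c Ne)`. The physical-distance decay model used throughout
#' this package borrows this functional form, replacing `4 c Ne` by
#' `alpha * d`.
#'
#' @param c recombination fraction (>= 0)
#' @param Ne effective population size (> 0)
#' @return expected r-squared
#' @export
sved_expected_r2 <- function(c, Ne) {
  stopifnot(all(c >= 0), all(Ne > 0))
  1 / (1 + 4 * c * Ne)
}

# All within-chromosome banded pairs (index offset < N) with d and r2;
# shared by ld_map. Returns list(i, j, d, r2) in window-scan order.
banded_pairs <- function(h, pos, N) {
  m <- length(pos)
  cnt <- pmin(N - 1L, m - seq_len(m))
  ii <- rep.int(seq_len(m), cnt)
  jj <- sequence(cnt) + ii
  r <- pair_r_vec(h, ii, jj)
  list(i = ii, j = jj, d = (pos[jj] - pos[ii]) / 1e6, r2 = r * r)
}

#' Sliding-window local LD map
#'
#' Slides a window of `N` consecutive markers along each chromosome, one
#' marker per step. In each window all `N(N-1)/2` marker pairs are formed and
#' [fit_alpha()] estimates the local decay rate; the fitted alpha is then
#' transformed to an expected r-squared at the fixed distance `d_fixed` and
#' both are recorded at the physical position of the window's middle marker
#' (index `floor(N/2)`, 0-based, i.e. the upper-middle marker for even `N`).
#' Chromosomes with fewer than `N` markers are skipped with a warning;
#' window fit failures are flagged and the track continues.
#'
#' @param panel a QC'd, complete [haplotype_panel()]
#' @param N window size in markers (default 100)
#' @param d_fixed distance in Mb at which expected r-squared is reported
#'   (default 10)
#' @return an `ld_map_track`: data.frame with columns `chrom`, `window`,
#'   `mid_id`, `mid_pos`, `alpha_hat`, `std_err`, `expected_r2` (`NA` where
#'   `1 + alpha d_fixed <= 0`), `converged`, `n_used`
#' @export
ld_map <- function(panel, N = 100, d_fixed = 10) {
  stopifnot(N >= 3, d_fixed > 0)
  if (anyNA(panel$haplotypes)) stop("ld_map requires a complete panel")
  m <- panel$markers
  tracks <- lapply(split(seq_len(nrow(m)), m$chrom), function(rows) {
    mm <- length(rows)
    if (mm < N) {
      warning(sprintf("chromosome %s has %d < N = %d markers; skipped",
                      m$chrom[rows[1L]], mm, N))
      return(NULL)
    }
    h <- panel$haplotypes[rows, , drop = FALSE]
    pos <- m$pos[rows]
    bp <- banded_pairs(h, pos, N)
    n_win <- mm - N + 1L
    res <- vector("list", n_win)
    for (s in seq_len(n_win)) {
      e <- s + N - 1L
      sel <- bp$i >= s & bp$j <= e
      mid <- s + N %/% 2L            # 0-based floor(N/2) within the window
      fit <- tryCatch(fit_alpha(bp$d[sel], bp$r2[sel]), error = function(err) NULL)
      res[[s]] <- data.frame(
        chrom = m$chrom[rows[1L]], window = s,
        mid_id = m$id[rows[mid]], mid_pos = m$pos[rows[mid]],
        alpha_hat = if (is.null(fit)) NA_real_ else fit$alpha_hat,
        std_err = if (is.null(fit)) NA_real_ else fit$std_err,
        expected_r2 = if (is.null(fit) || 1 + fit$alpha_hat * d_fixed <= 0) {
          NA_real_
        } else 1 / (1 + fit$alpha_hat * d_fixed),
        converged = if (is.null(fit)) FALSE else fit$converged,
        n_used = if (is.null(fit)) 0L else fit$n_used,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, res)
  })
  tracks <- tracks[!vapply(tracks, is.null, logical(1))]
  if (!length(tracks)) stop("no chromosome has >= N markers")
  out <- do.call(rbind, tracks)
  rownames(out) <- NULL
  structure(out, class = c("ld_map_track", "data.frame"),
            N = N, d_fixed = d_fixed, population = panel$population)
}

#' Chromosome-level decay rate by replicate subsampling
#'
#' Estimates a chromosome's decay rate alpha by repeatedly drawing a random
#' sample of `n_pairs` marker pairs (uniformly, without replacement) from
#' all within-chromosome pairs, fitting [fit_alpha()] to each replicate, and
#' reporting the mean and standard deviation of the replicate estimates.
#' Fully reproducible given `seed`.
#'
#' @param panel a QC'd, complete [haplotype_panel()]
#' @param chrom chromosome to analyse
#' @param n_pairs pairs per replicate (default 10000); when the chromosome
#'   has fewer candidate pairs, all are used with a warning
#' @param n_replicates number of replicates (default 1000)
#' @param seed integer seed
#' @param max_distance optional distance cap in Mb on the candidate pairs
#'   (default `Inf`: all within-chromosome pairs)
#' @return a `chromosome_alpha` list: `chrom`, `mean_alpha`, `sd_alpha`,
#'   `alphas` (replicate vector), `n_pairs`, `n_replicates`, `seed`
#' @export
chromosome_alpha <- function(panel, chrom, n_pairs = 10000, n_replicates = 1000,
                             seed = 1L, max_distance = Inf) {
  rows <- which(panel$markers$chrom == chrom)
  if (length(rows) < 2L) stop("chromosome ", chrom, " has < 2 markers")
  sub <- subset_panel(panel, markers = rows)
  cap <- if (is.finite(max_distance)) max_distance else
    diff(range(sub$markers$pos)) / 1e6 + 1
  tab <- pairwise_ld(sub, max_distance = cap)
  usable <- tab$r2 > 1e-12
  if (!any(usable)) stop("no polymorphic pair with r2 > 0 on chromosome ", chrom)
  n_avail <- nrow(tab)
  k <- n_pairs
  if (n_avail < n_pairs) {
    warning(sprintf("only %d candidate pairs (< %d requested); using all",
                    n_avail, n_pairs))
    k <- n_avail
  }
  alphas <- with_seed(seed, {
    vapply(seq_len(n_replicates), function(rep_i) {
      idx <- sample.int(n_avail, k)
      fit_alpha(tab$d[idx], tab$r2[idx])$alpha_hat
    }, numeric(1))
  })
  structure(list(chrom = chrom, mean_alpha = mean(alphas),
                 sd_alpha = stats::sd(alphas), alphas = alphas,
                 n_pairs = k, n_replicates = n_replicates, seed = seed),
            class = "chromosome_alpha")
}

#' @export
print.chromosome_alpha <- function(x, ...) {
  cat(sprintf("chromosome_alpha: chrom %s, mean(alpha) = %.4g, sd(alpha) = %.3g (%d x %d pairs)\n",
              x$chrom, x$mean_alpha, x$sd_alpha, x$n_replicates, x$n_pairs))
  invisible(x)
}
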