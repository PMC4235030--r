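#' @title Genome-wide LD decay summaries
#' @description Pools marker pairs from all autosomal chromosomes, groups
#'   them into even distance intervals (100 kb by default, from 0 up to
#'   10 Mb) and averages r-squared within each group, yielding the classic
#'   LD-decay curve. Also summarises adjacent-pair LD, tabulates mean
#'   r-squared at selected distances per chromosome, and compares
#'   adjacent-pair LD between two populations with a Welch t-test.
#' @name decay
NULL

#' Binned LD decay curve
#'
#' Bins are half-open `[lo, hi)`: a pair at exactly the cap distance is
#' excluded, and a pair at an interior bin edge is counted in the upper bin.
#'
#' @param pairs an `ld_pair_table` from [pairwise_ld()], or a list of such
#'   tables (e.g. one per chromosome) which are pooled
#' @param bin_width bin width in Mb (default 0.1, i.e. 100 kb)
#' @param max_distance upper cap in Mb (default 10)
#' @return a `decay_curve`: data.frame with columns `bin_lo`, `bin_hi`,
#'   `mid` (Mb), `mean_r2` (`NA` for empty bins), `n_pairs`
#' @export
binned_decay <- function(pairs, bin_width = 0.1, max_distance = 10) {
  if (is.data.frame(pairs)) pairs <- list(pairs)
  d <- unlist(lapply(pairs, `[[`, "d"), use.names = FALSE)
  r2 <- unlist(lapply(pairs, `[[`, "r2"), use.names = FALSE)
  keep <- d < max_distance
  d <- d[keep]; r2 <- r2[keep]
  edges <- seq(0, max_distance, by = bin_width)
  nb <- length(edges) - 1L
  bin <- findInterval(d, edges, rightmost.closed = FALSE)
  n_pairs <- tabulate(bin, nbins = nb)
  sums <- vapply(seq_len(nb), function(b) sum(r2[bin == b]), numeric(1))
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
                    mid = (edges[-length(edges)] + edges[-1L]) / 2,
                    mean_r2 = ifelse(n_pairs > 0L, sums / pmax(n_pairs, 1L), NA_real_),
                    n_pairs = n_pairs)
  structure(out, class = c("decay_curve", "data.frame"),
            bin_width = bin_width, max_distance = max_distance)
}

#' Summary statistics for adjacent-pair LD
#'
#' @param pairs an `ld_pair_table` from [adjacent_pairs()]
#' @return an `adjacent_summary` list: `n_pairs`, `median_spacing_kb`,
#'   `mean_spacing_kb`, `mean_r2`, `sd_r2`, `prop_r2_gt_03`, `prop_r2_gt_02`
#' @export
adjacent_summary <- function(pairs) {
  if (nrow(pairs) == 0L) stop("adjacent_summary: no pairs supplied")
  structure(list(
    n_pairs = nrow(pairs),
    median_spacing_kb = stats::median(pairs$d) * 1000,
    mean_spacing_kb = mean(pairs$d) * 1000,
    mean_r2 = mean(pairs$r2),
    sd_r2 = stats::sd(pairs$r2),
    prop_r2_gt_03 = mean(pairs$r2 > 0.3),
    prop_r2_gt_02 = mean(pairs$r2 > 0.2)), class = "adjacent_summary")
}

#' @export
print.adjacent_summary <- function(x, ...) {
  cat(sprintf(paste0("adjacent-pair LD over %d pairs\n",
                     "  spacing: median %.1f kb, mean %.1f kb\n",
                     "  r2: mean %.3f (sd %.3f); P(r2>0.3) = %.2f, P(r2>0.2) = %.2f\n"),
              x$n_pairs, x$median_spacing_kb, x$mean_spacing_kb,
              x$mean_r2, x$sd_r2, x$prop_r2_gt_03, x$prop_r2_gt_02))
  invisible(x)
}

#' Mean r-squared at selected distances, per chromosome
#'
#' For each chromosome and target distance D, averages r-squared over pairs
#' with `d` in the half-open window `[D - tolerance, D)`; an empty window
#' yields `NA`.
#'
#' @param pairs an `ld_pair_table` covering the chromosomes of interest
#' @param targets target distances in Mb (default `c(0.5, 1, 5)`)
#' @param tolerance window width in Mb below each target (default 0.1)
#' @return data.frame with columns `chrom` and one `mean r2` column per
#'   target (named `at_<D>Mb`), plus an `All` row pooling chromosomes
#' @export
ld_at_distances <- function(pairs, targets = c(0.5, 1, 5), tolerance = 0.1) {
  stopifnot(tolerance > 0, all(targets > 0))
  chroms <- unique(pairs$chrom)
  cell <- function(d, r2, D) {
    sel <- d >= (D - tolerance) & d < D
    if (!any(sel)) NA_real_ else mean(r2[sel])
  }
  rows <- lapply(c(chroms, "All"), function(ch) {
    sel <- if (ch == "All") rep(TRUE, nrow(pairs)) else pairs$chrom == ch
    vals <- vapply(targets, function(D) cell(pairs$d[sel], pairs$r2[sel], D),
                   numeric(1))
    as.data.frame(c(list(chrom = ch), stats::setNames(as.list(vals),
                                                      paste0("at_", targets, "Mb"))))
  })
  do.call(rbind, rows)
}

#' Welch t-test comparing adjacent-pair LD between two populations
#'
#' Two-sample t-test with unequal variances on the adjacent-pair r-squared
#' values of two populations. Degenerate inputs (both groups constant) are
#' handled directly: equal means give `t = 0, p = 1`, different means
#' `t = Inf, p = 0`.
#'
#' @param r2_a,r2_b numeric vectors of adjacent-pair r-squared values (or
#'   `ld_pair_table`s, whose `r2` column is used); each of length >= 2
#' @return list with `t`, `df`, `p_value`, `mean_a`, `mean_b`
#' @export
compare_adjacent_ld <- function(r2_a, r2_b) {
  if (is.data.frame(r2_a)) r2_a <- r2_a$r2
  if (is.data.frame(r2_b)) r2_b <- r2_b$r2
  if (length(r2_a) < 2L || length(r2_b) < 2L) {
    stop("need at least 2 values per group")
  }
  if (stats::var(r2_a) == 0 && stats::var(r2_b) == 0) {
    same <- isTRUE(all.equal(mean(r2_a), mean(r2_b)))
    return(list(t = if (same) 0 else Inf * sign(mean(r2_a) - mean(r2_b)),
                df = NA_real_, p_value = if (same) 1 else 0,
                mean_a = mean(r2_a), mean_b = mean(r2_b)))
  }
  tt <- stats::t.test(r2_a, r2_b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(r2_a), mean_b = mean(r2_b))
}
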