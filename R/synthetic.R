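#' @title Synthetic haplotype panels with controllable LD structure
#' @description Generators for all of the package's test inputs, at three
#'   levels: (a) distribution-level (d, r2) pairs with a known decay rate
#'   alpha for exercising the Gamma-GLM fitter; (b) single-population
#'   haplotype panels from a founder-mosaic model, in which each sample
#'   haplotype is a recombinant patchwork of K founder haplotypes and LD
#'   therefore decays with physical distance at a rate controlled by the
#'   switch intensity rho; (c) sets of diverged populations obtained by
#'   evolving a common base population forward under Wright-Fisher
#'   reproduction with recombination, so that persistence of phase between
#'   daughters decays with their divergence time. All generators are
#'   deterministic given the seed.
#' @name synthetic_data
NULL

#' Parameters of the synthetic panel generator
#'
#' Defaults describe a desk-scale panel mimicking a livestock 60K-chip
#' chromosome: 3000 markers on one 300-Mb chromosome (about 100 kb mean
#' spacing), 100 diploids, 4 founder haplotypes and one expected founder
#' switch per Mb. The founder count sets the short-range LD plateau
#' (approximately `1/(K-1)` for random founders), so small K mimics the
#' strong adjacent-marker LD of intensively selected livestock populations.
#'
#' @param n_markers number of biallelic markers
#' @param chrom_length_bp chromosome length in bp
#' @param spacing `"uniform"` (positions uniform on the chromosome) or
#'   `"exponential"` (inter-marker gaps exponential)
#' @param n_founders K, number of founder haplotypes (>= 2); plays the role
#'   of an effective-size knob (more founders, less LD)
#' @param rho founder-mosaic switch intensity: expected switches per Mb,
#'   controlling how fast LD decays with distance
#' @param n_individuals diploids sampled per population
#' @param Ne Wright-Fisher population size (diploids) used when evolving
#'   diverged daughter populations
#' @param rec_rate_mb meiotic recombination rate in Morgans per Mb used in
#'   Wright-Fisher reproduction (default 0.01, i.e. 1 cM/Mb)
#' @param chrom chromosome name
#' @param seed integer seed; fixed seed gives byte-identical output
#' @return a `synthetic_spec` list
#' @export
synthetic_spec <- function(n_markers = 3000, chrom_length_bp = 3e8,
                           spacing = c("uniform", "exponential"),
                           n_founders = 4, rho = 1, n_individuals = 100,
                           Ne = 100, rec_rate_mb = 0.01, chrom = "1",
                           seed = 1L) {
  spacing <- match.arg(spacing)
  stopifnot(n_markers >= 2, chrom_length_bp > n_markers, n_founders >= 2,
            rho >= 0, n_individuals >= 1, Ne >= 2, rec_rate_mb >= 0)
  structure(list(n_markers = as.integer(n_markers),
                 chrom_length_bp = as.numeric(chrom_length_bp),
                 spacing = spacing, n_founders = as.integer(n_founders),
                 rho = rho, n_individuals = as.integer(n_individuals),
                 Ne = as.integer(Ne), rec_rate_mb = rec_rate_mb,
                 chrom = as.character(chrom), seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Distance/r-squared pairs from the decay model with Gamma noise
#'
#' Draws distances uniformly on `d_range` and r-squared values from a Gamma
#' distribution with shape `gamma_shape` and mean `1/(1 + alpha d)` — the
#' noise model under which the local-LD fitter is the maximum-likelihood
#' estimator. With `noise_free = TRUE` the r-squared values equal the mean
#' exactly (the infinite-shape limit).
#'
#' @param alpha per-Mb decay rate; must satisfy `1 + alpha d > 0` on the range
#' @param n number of pairs
#' @param d_range length-2 Mb interval
#' @param gamma_shape Gamma shape parameter (default 1)
#' @param seed integer seed
#' @param noise_free if `TRUE`, return the noiseless mean curve
#' @return data.frame with columns `d`, `r2`
#' @export
gen_glm_pairs <- function(alpha, n, d_range = c(0.01, 10), gamma_shape = 1,
                          seed = 1L, noise_free = FALSE) {
  stopifnot(length(d_range) == 2L, d_range[1] >= 0, d_range[2] > d_range[1],
            gamma_shape > 0, n >= 0)
  if (1 + alpha * d_range[1] <= 0 || 1 + alpha * d_range[2] <= 0) {
    stop("1 + alpha*d must be positive over d_range")
  }
  if (n == 0L) return(data.frame(d = numeric(), r2 = numeric()))
  with_seed(seed, {
    d <- stats::runif(n, d_range[1], d_range[2])
    mu <- 1 / (1 + alpha * d)
    r2 <- if (noise_free) mu else stats::rgamma(n, shape = gamma_shape,
                                                rate = gamma_shape / mu)
    data.frame(d = d, r2 = r2)
  })
}

# Marker map for a spec: sorted unique integer positions.
draw_marker_map <- function(spec) {
  m <- spec$n_markers
  pos <- switch(spec$spacing,
    uniform = sort(sample.int(spec$chrom_length_bp, m)),
    exponential = {
      gaps <- stats::rexp(m, rate = m / spec$chrom_length_bp)
      p <- cumsum(pmax(1, round(gaps)))
      p
    })
  pos <- as.integer(pos)
  while (anyDuplicated(pos)) pos <- as.integer(sort(pos + cumsum(duplicated(pos))))
  alle <- t(vapply(seq_len(m), function(i) sample(c("A", "C", "G", "T"), 2L),
                   character(2)))
  data.frame(id = sprintf("snp%05d", seq_len(m)), chrom = spec$chrom,
             pos = pos, allele0 = alle[, 1L], allele1 = alle[, 2L],
             stringsAsFactors = FALSE)
}

# One mosaic haplotype pool: n_hap haplotypes over founder matrix F
# (n_founders x m); switch prob per interval = 1 - exp(-rho * gap_mb).
mosaic_pool <- function(founders, pos, rho, n_hap) {
  m <- length(pos)
  K <- nrow(founders)
  p_switch <- 1 - exp(-rho * diff(pos) / 1e6)
  pool <- matrix(0L, nrow = m, ncol = n_hap)
  for (g in seq_len(n_hap)) {
    sw <- stats::rbinom(m - 1L, 1L, p_switch) == 1L
    f <- integer(m)
    f[1L] <- sample.int(K, 1L)
    cur <- f[1L]
    pts <- which(sw)
    if (length(pts)) {
      bounds <- c(1L, pts + 1L, m + 1L)
      picks <- c(cur, sample.int(K, length(pts), replace = TRUE))
      f <- rep(picks, diff(bounds))
    } else {
      f <- rep(cur, m)
    }
    pool[, g] <- founders[cbind(f, seq_len(m))]
  }
  pool
}

#' Simulate a single population as a founder mosaic
#'
#' K founder haplotypes are drawn i.i.d. Bernoulli(0.5) per site; each
#' sample haplotype copies a founder and switches to a uniformly chosen
#' founder between consecutive markers with probability
#' `1 - exp(-rho * gap_Mb)`. Phased diploids are assembled from independent
#' haplotypes. Markers monomorphic in the sample are dropped with a message.
#'
#' @param spec a [synthetic_spec()]
#' @return a [haplotype_panel()]
#' @export
gen_mosaic_population <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    map <- draw_marker_map(spec)
    founders <- matrix(stats::rbinom(spec$n_founders * nrow(map), 1L, 0.5),
                       nrow = spec$n_founders)
    pool <- mosaic_pool(founders, map$pos, spec$rho, 2L * spec$n_individuals)
    panel <- haplotype_panel(map, pool,
                             sample_ids = sprintf("ind%04d", seq_len(spec$n_individuals)),
                             population = "synthetic")
    drop_monomorphic(panel)
  })
}

drop_monomorphic <- function(panel) {
  p <- rowMeans(panel$haplotypes)
  mono <- p == 0 | p == 1
  if (any(mono)) {
    message(sprintf("dropped %d monomorphic marker(s)", sum(mono)))
    panel <- subset_panel(panel, markers = !mono)
  }
  panel
}

# One gamete per parent: recombine the parent's two haplotypes with
# per-interval crossover probability 0.5 * (1 - exp(-2 * c_morgan_mb * gap)).
# Vectorised over all gametes of a generation.
wf_gametes <- function(pool, parent_idx, p_cross) {
  m <- nrow(pool)
  G <- length(parent_idx)
  hapA <- pool[, 2L * parent_idx - 1L, drop = FALSE]
  hapB <- pool[, 2L * parent_idx, drop = FALSE]
  start <- stats::rbinom(G, 1L, 0.5)
  sw <- matrix(stats::rbinom((m - 1L) * G, 1L, p_cross), nrow = m - 1L)
  path <- (rbind(start, apply(sw, 2L, cumsum) + rep(start, each = m - 1L))) %% 2L
  out <- hapA
  useB <- path == 1L
  out[useB] <- hapB[useB]
  out
}

# Evolve a haplotype pool (m x 2*Ne) forward t generations of Wright-Fisher
# reproduction with Ne diploids; returns the final pool.
wf_evolve <- function(pool, pos, rec_rate_mb, Ne, t) {
  if (t == 0L) return(pool)
  p_cross <- 0.5 * (1 - exp(-2 * rec_rate_mb * diff(pos) / 1e6))
  for (gen in seq_len(t)) {
    sires <- sample.int(Ne, Ne, replace = TRUE)
    dams <- sample.int(Ne, Ne, replace = TRUE)
    g1 <- wf_gametes(pool, sires, p_cross)
    g2 <- wf_gametes(pool, dams, p_cross)
    nxt <- matrix(0L, nrow = nrow(pool), ncol = 2L * Ne)
    nxt[, seq(1L, 2L * Ne, 2L)] <- g1
    nxt[, seq(2L, 2L * Ne, 2L)] <- g2
    pool <- nxt
  }
  pool
}

#' Simulate diverged populations from a common base
#'
#' A base population of `Ne` diploids is generated by the founder-mosaic
#' model; each daughter population then evolves independently from the base
#' by `t` generations of Wright-Fisher reproduction (size `Ne`, random
#' mating with recombination at `rec_rate_mb` Morgans/Mb, no mutation —
#' markers therefore stay matched across daughters by construction). Finally
#' `n_individuals` diploids are sampled from each daughter (offspring of a
#' final reproduction round, so `n_individuals` may exceed `Ne`). A split
#' time of 0 samples the base directly. Markers monomorphic within a
#' daughter are dropped from that daughter's panel, so daughter panels may
#' have different (overlapping) marker sets, as real per-population QC'd
#' panels do.
#'
#' @param spec a [synthetic_spec()]
#' @param split_design named numeric vector or list: population label ->
#'   split time in generations
#' @return named list of [haplotype_panel()] objects
#' @export
gen_diverged_populations <- function(spec, split_design) {
  stopifnot(inherits(spec, "synthetic_spec"), length(split_design) >= 1)
  if (spec$Ne < 2L) stop("Ne must be >= 2")
  labels <- names(split_design)
  if (is.null(labels) || any(labels == "")) stop("split_design must be named")
  times <- as.integer(unlist(split_design))
  if (any(times < 0L)) stop("split times must be >= 0")
  with_seed(spec$seed, {
    map <- draw_marker_map(spec)
    founders <- matrix(stats::rbinom(spec$n_founders * nrow(map), 1L, 0.5),
                       nrow = spec$n_founders)
    base <- mosaic_pool(founders, map$pos, spec$rho, 2L * spec$Ne)
    panels <- vector("list", length(labels))
    names(panels) <- labels
    for (k in seq_along(labels)) {
      pool <- wf_evolve(base, map$pos, spec$rec_rate_mb, spec$Ne, times[k])
      # final reproduction round to draw the sampled individuals
      p_cross <- 0.5 * (1 - exp(-2 * spec$rec_rate_mb * diff(map$pos) / 1e6))
      g1 <- wf_gametes(pool, sample.int(spec$Ne, spec$n_individuals, TRUE), p_cross)
      g2 <- wf_gametes(pool, sample.int(spec$Ne, spec$n_individuals, TRUE), p_cross)
      hap <- matrix(0L, nrow = nrow(map), ncol = 2L * spec$n_individuals)
      hap[, seq(1L, ncol(hap), 2L)] <- g1
      hap[, seq(2L, ncol(hap), 2L)] <- g2
      panel <- haplotype_panel(map, hap,
                               sample_ids = sprintf("%s_%04d", labels[k],
                                                    seq_len(spec$n_individuals)),
                               population = labels[k])
      panels[[k]] <- drop_monomorphic(panel)
    }
    panels
  })
}
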