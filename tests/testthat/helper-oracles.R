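# Shared fixtures and independent oracles. Oracles deliberately use naive
# counting / closed forms, never the package's vectorised code paths.

# Build a panel from a 0/1 haplotype matrix (rows = markers).
make_panel <- function(hap, pos = NULL, chrom = "1", population = "pop",
                       allele0 = NULL, allele1 = NULL) {
  hap <- as.matrix(hap)
  m <- nrow(hap)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (length(chrom) == 1L) chrom <- rep(chrom, m)
  if (is.null(allele0)) allele0 <- rep("A", m)
  if (is.null(allele1)) allele1 <- rep("C", m)
  markers <- data.frame(id = paste0("m", seq_len(m)), chrom = chrom,
                        pos = as.integer(pos), allele0 = allele0,
                        allele1 = allele1, stringsAsFactors = FALSE)
  haplotype_panel(markers, hap, sample_ids = paste0("s", seq_len(ncol(hap) / 2)),
                  population = population)
}

# Random polymorphic panel: every marker has both alleles present.
random_panel <- function(n_markers, n_hap, chrom = "1", spacing_bp = 1e5) {
  hap <- matrix(rbinom(n_markers * n_hap, 1L, runif(n_markers, 0.2, 0.8)),
                nrow = n_markers)
  mono <- rowSums(hap) %in% c(0L, n_hap)
  hap[mono, 1L] <- 1L - hap[mono, 1L]
  hap[rowSums(hap) %in% c(0L, n_hap), ] <- rep(c(0L, 1L), length.out = n_hap)
  pos <- cumsum(1L + rpois(n_markers, spacing_bp))
  make_panel(hap, pos = pos, chrom = chrom)
}

# Naive Eq-1 oracle: haplotype-class counting with explicit loops.
oracle_r <- function(x, y) {
  n <- length(x)
  n11 <- 0; n1x <- 0; nx1 <- 0
  for (k in seq_len(n)) {
    if (x[k] == 1 && y[k] == 1) n11 <- n11 + 1
    if (x[k] == 1) n1x <- n1x + 1
    if (y[k] == 1) nx1 <- nx1 + 1
  }
  p_i <- n1x / n; p_j <- nx1 / n; p_ij <- n11 / n
  (p_ij - p_i * p_j) / sqrt(p_i * (1 - p_i) * p_j * (1 - p_j))
}

# Closed-form conditional probability of a heterozygote count given allele
# counts, via lchoose (independent route from the package's recurrence-free
# lgamma formulation).
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- 2 * n_AA + n_Aa
  h_parity <- na %% 2
  h_vals <- seq(h_parity, min(na, 2 * n - na), by = 2)
  logp <- vapply(h_vals, function(h) {
    nAA <- (na - h) / 2
    naa <- n - nAA - h
    lchoose(n, nAA) + lchoose(n - nAA, h) + h * log(2) -
      lchoose(2 * n, na)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_Aa, h_vals)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-12)]))
}

# Phase correlation over pooled pairs closer than `cap` Mb (single group).
short_distance_phase <- function(pA, pB, cms, which, cap = 1) {
  curve <- binned_phase_decay(pA, pB, cms, which = which, bin_width = cap,
                              max_distance = cap)
  curve$cor_r[1L]
}
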