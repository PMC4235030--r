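#' @title Sample and marker quality control
#' @description Filtering rules for SNP panels prior to LD analysis: sample
#'   missingness, marker call rate, minor allele frequency, and an exact
#'   Hardy-Weinberg equilibrium test, plus pedigree-based pruning of parents
#'   and full sibs. Each filter returns the reduced panel together with a
#'   `qc_report` stating how many samples/markers each rule removed. A marker
#'   removed by several rules is attributed to the first failing rule, in the
#'   order call rate, MAF, HWE.
#' @name qc
NULL

new_qc_report <- function(n_samples_in, n_samples_out, n_markers_in,
                          n_markers_out, removed_by_rule, thresholds) {
  structure(list(n_samples_in = n_samples_in, n_samples_out = n_samples_out,
                 n_markers_in = n_markers_in, n_markers_out = n_markers_out,
                 removed_by_rule = removed_by_rule, thresholds = thresholds),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: samples %d -> %d, markers %d -> %d\n",
              x$n_samples_in, x$n_samples_out, x$n_markers_in, x$n_markers_out))
  for (rule in names(x$removed_by_rule)) {
    cat(sprintf("  removed by %-16s %d\n", paste0(rule, ":"),
                x$removed_by_rule[[rule]]))
  }
  invisible(x)
}

# Per-individual fraction of markers with a missing genotype (either allele NA).
sample_missing_fraction <- function(panel) {
  h <- panel$haplotypes
  a <- is.na(h[, seq(1L, ncol(h), 2L), drop = FALSE])
  b <- is.na(h[, seq(2L, ncol(h), 2L), drop = FALSE])
  colMeans(a | b)
}

#' Remove samples with excessive missingness
#'
#' An individual whose genotype (either haplotype allele) is missing at more
#' than `max_missing_frac` of the markers is excluded from the panel.
#'
#' @param panel a [haplotype_panel()]
#' @param max_missing_frac maximum tolerated missing-genotype fraction
#'   (default 0.10; the rule is strict: a fraction exactly at the threshold
#'   is kept)
#' @return list with elements `panel` and `report` (a `qc_report`)
#' @export
filter_samples_by_missingness <- function(panel, max_missing_frac = 0.10) {
  frac <- sample_missing_fraction(panel)
  keep <- frac <= max_missing_frac
  if (!any(keep)) stop("all samples exceed the missingness threshold")
  out <- subset_panel(panel, samples = keep)
  report <- new_qc_report(
    n_samples_in = n_samples(panel), n_samples_out = sum(keep),
    n_markers_in = n_markers(panel), n_markers_out = n_markers(panel),
    removed_by_rule = c(sample_missingness = sum(!keep)),
    thresholds = list(max_missing_frac = max_missing_frac))
  list(panel = out, report = report)
}

# Genotype counts (n00, n01, n11) per marker from phased haplotypes,
# counting only individuals with both alleles observed.
genotype_counts <- function(panel) {
  h <- panel$haplotypes
  a <- h[, seq(1L, ncol(h), 2L), drop = FALSE]
  b <- h[, seq(2L, ncol(h), 2L), drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  g <- a + b
  cbind(n00 = rowSums(g == 0L & ok, na.rm = TRUE),
        n01 = rowSums(g == 1L & ok, na.rm = TRUE),
        n11 = rowSums(g == 2L & ok, na.rm = TRUE))
}

#' Filter markers by call rate, MAF and Hardy-Weinberg equilibrium
#'
#' Rules are applied in order: call rate (fraction of individuals with a
#' non-missing genotype) below `min_call_rate`; minor allele frequency below
#' `min_maf` (a MAF exactly at the threshold is kept); exact HWE test p-value
#' below `hwe_p_threshold`. MAF is computed from non-missing alleles and the
#' HWE test from non-missing genotypes. Each removed marker is attributed to
#' the first rule that fails it.
#'
#' @param panel a [haplotype_panel()]
#' @param min_call_rate minimum genotype call rate (default 0.90)
#' @param min_maf minimum minor allele frequency (default 0.05)
#' @param hwe_p_threshold HWE exact-test p-value threshold (default 1e-7)
#' @return list with elements `panel` and `report`
#' @export
filter_markers <- function(panel, min_call_rate = 0.90, min_maf = 0.05,
                           hwe_p_threshold = 1e-7) {
  gc <- genotype_counts(panel)
  n_ind <- n_samples(panel)
  call_rate <- rowSums(gc) / n_ind
  n1 <- gc[, "n01"] + 2L * gc[, "n11"]
  n_alleles <- 2L * rowSums(gc)
  p1 <- ifelse(n_alleles > 0L, n1 / n_alleles, NA_real_)
  maf <- pmin(p1, 1 - p1)
  hwe_p <- vapply(seq_len(nrow(gc)), function(i) {
    if (sum(gc[i, ]) == 0L) return(1.0)
    hwe_exact_test(gc[i, "n00"], gc[i, "n01"], gc[i, "n11"])
  }, numeric(1))

  fail_call <- call_rate < min_call_rate
  fail_maf <- !fail_call & (is.na(maf) | maf < min_maf)
  fail_hwe <- !fail_call & !fail_maf & hwe_p < hwe_p_threshold
  keep <- !(fail_call | fail_maf | fail_hwe)
  if (!any(keep)) stop("no markers survive filtering")
  out <- subset_panel(panel, markers = keep)
  report <- new_qc_report(
    n_samples_in = n_ind, n_samples_out = n_ind,
    n_markers_in = n_markers(panel), n_markers_out = sum(keep),
    removed_by_rule = c(call_rate = sum(fail_call), maf = sum(fail_maf),
                        hwe = sum(fail_hwe)),
    thresholds = list(min_call_rate = min_call_rate, min_maf = min_maf,
                      hwe_p_threshold = hwe_p_threshold))
  list(panel = out, report = report)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact conditional test: given the observed allele counts, the
#' p-value is the sum of probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count.
#' Monomorphic markers return 1.
#'
#' @param n_AA,n_Aa,n_aa nonnegative genotype counts (total >= 1)
#' @return p-value in (0, 1]
#' @export
#' @examples
#' hwe_exact_test(25, 50, 25)   # modal heterozygote count: p = 1
#' hwe_exact_test(50, 0, 50)    # extreme heterozygote deficit: p << 1e-7
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1L) stop("at least one genotype required")
  n_a <- n_Aa + 2L * n_aa                 # minor-or-not, symmetry handled below
  n_rare <- min(n_a, 2L * n - n_a)
  if (n_rare == 0L) return(1.0)
  # heterozygote counts share the parity of the rare-allele count
  h_obs <- n_Aa
  h_vals <- seq.int(n_rare %% 2L, n_rare, by = 2L)
  # log conditional probability up to a constant:
  # P(h) proportional to n! / (nAA! nAa! naa!) * 2^h  with
  # nAa = h, n_rare_hom = (n_rare - h)/2, n_common_hom = n - h - n_rare_hom
  rare_hom <- (n_rare - h_vals) / 2
  common_hom <- n - h_vals - rare_hom
  logp <- h_vals * log(2) - lgamma(h_vals + 1) - lgamma(rare_hom + 1) -
    lgamma(common_hom + 1)
  logp <- logp - max(logp)
  prob <- exp(logp) / sum(exp(logp))
  p_obs <- prob[match(h_obs, h_vals)]
  if (is.na(p_obs)) stop("observed heterozygote count inconsistent with allele counts")
  min(1.0, sum(prob[prob <= p_obs * (1 + 1e-12)]))
}

#' Prune parents and full sibs from a sample
#'
#' Mirrors a standard family-structure removal: first any sample that is
#' recorded as the sire or dam of another sample is excluded; then the
#' remaining samples are grouped by their (sire, dam) pair when both parents
#' are known, and one member per full-sib group is kept uniformly at random.
#' Samples absent from the pedigree are treated as founders with unknown
#' parents and are always kept.
#'
#' @param sample_ids character vector of candidate sample ids
#' @param pedigree data.frame from [read_pedigree()]
#' @param seed integer seed making the full-sib draw reproducible
#' @return character vector of kept sample ids (original order)
#' @export
prune_relatives <- function(sample_ids, pedigree, seed = 1L) {
  if (is.null(pedigree) || nrow(pedigree) == 0L) return(sample_ids)
  idx <- match(sample_ids, pedigree$individual)
  sire <- pedigree$sire[idx]
  dam <- pedigree$dam[idx]
  parents <- unique(stats::na.omit(c(sire, dam)))
  keep <- !(sample_ids %in% parents)
  ids <- sample_ids[keep]
  sire <- sire[keep]
  dam <- dam[keep]
  fam <- ifelse(!is.na(sire) & !is.na(dam), paste(sire, dam, sep = "\r"), NA)
  chosen <- with_seed(seed, {
    vapply(split(ids[!is.na(fam)], fam[!is.na(fam)]),
           function(g) g[sample.int(length(g), 1L)], character(1))
  })
  kept <- c(ids[is.na(fam)], unname(chosen))
  sample_ids[sample_ids %in% kept]
}

# Run an expression under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
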