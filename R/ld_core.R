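#' @title Pairwise haplotype LD (signed r and r-squared)
#' @description Linkage disequilibrium between two biallelic markers is
#'   computed directly from phased haplotype counts:
#'   `r = (p_ij - p_i p_j) / sqrt(p_i(1-p_i) p_j(1-p_j))`, where `p_i`,
#'   `p_j` are the frequencies of allele 1 (the alternate allele) at each
#'   marker and `p_ij` the frequency of the (1,1) haplotype. The sign of `r`
#'   follows the alternate-allele convention and is needed for
#'   persistence-of-phase comparisons; `r2 = r^2` measures LD strength.
#' @name ld_core
NULL

#' Signed r and r-squared for one marker pair
#'
#' @param panel a [haplotype_panel()] with complete (non-missing) haplotypes
#'   at the two markers
#' @param i,j marker row indices
#' @return named numeric vector `c(r = , r2 = )`
#' @export
#' @examples
#' m <- data.frame(id = c("a", "b"), chrom = "1", pos = c(1L, 2L),
#'                 allele0 = "A", allele1 = "C")
#' h <- rbind(c(1L, 1L, 0L, 0L), c(1L, 1L, 0L, 0L))
#' signed_r(haplotype_panel(m, h, c("i1", "i2")), 1, 2)  # perfect LD: r = 1
signed_r <- function(panel, i, j) {
  x <- panel$haplotypes[i, ]
  y <- panel$haplotypes[j, ]
  if (anyNA(x) || anyNA(y)) {
    stop("signed_r requires complete haplotype data at both markers")
  }
  n <- length(x)
  p_i <- sum(x) / n
  p_j <- sum(y) / n
  if (p_i == 0 || p_i == 1 || p_j == 0 || p_j == 1) {
    stop("monomorphic marker: r is undefined (zero denominator)")
  }
  p_ij <- sum(x == 1L & y == 1L) / n
  r <- (p_ij - p_i * p_j) / sqrt(p_i * (1 - p_i) * p_j * (1 - p_j))
  c(r = r, r2 = r * r)
}

# Vectorised signed r over index pairs (ii, jj) of one complete 0/1 matrix.
# Processed in blocks so that the intermediate pair x haplotype products
# stay within a fixed memory footprint even for millions of pairs.
pair_r_vec <- function(h, ii, jj) {
  n <- ncol(h)
  p <- rowSums(h) / n
  out <- numeric(length(ii))
  block <- max(1L, as.integer(2e7 / n))
  for (start in seq(1L, length(ii), by = block)) {
    idx <- start:min(start + block - 1L, length(ii))
    bi <- ii[idx]; bj <- jj[idx]
    p11 <- rowSums(h[bi, , drop = FALSE] * h[bj, , drop = FALSE]) / n
    denom <- sqrt(p[bi] * (1 - p[bi]) * p[bj] * (1 - p[bj]))
    out[idx] <- (p11 - p[bi] * p[bj]) / denom
  }
  out
}

new_ld_pair_table <- function(df, population, max_distance) {
  structure(df, class = c("ld_pair_table", "data.frame"),
            population = population, max_distance = max_distance)
}

#' All within-chromosome marker pairs up to a distance cap
#'
#' Enumerates every marker pair on the same chromosome separated by at most
#' `max_distance` Mb and computes signed r and r-squared for each. Pairs are
#' never formed across chromosomes. The panel must be complete (no missing
#' alleles) and every marker polymorphic; run [filter_markers()] first.
#'
#' @param panel a QC'd, complete [haplotype_panel()]
#' @param max_distance distance cap in Mb (default 10)
#' @return an `ld_pair_table`: data.frame with columns `chrom`, `i`, `j`
#'   (panel row indices, `i < j`), `id_i`, `id_j`, `pos_i`, `pos_j`,
#'   `d` (Mb), `r`, `r2`, ordered by (chrom, i, j), with attributes
#'   `population` and `max_distance`
#' @export
pairwise_ld <- function(panel, max_distance = 10) {
  stopifnot(max_distance > 0)
  if (anyNA(panel$haplotypes)) {
    stop("pairwise_ld requires a complete panel (no missing alleles)")
  }
  m <- panel$markers
  parts <- lapply(split(seq_len(nrow(m)), m$chrom), function(rows) {
    mm <- length(rows)
    if (mm < 2L) return(NULL)
    pos <- m$pos[rows]
    # markers are sorted, so candidate j's for each i are a contiguous run
    hi <- findInterval(pos + max_distance * 1e6, pos)
    cnt <- hi - seq_len(mm)
    cnt[cnt < 0L] <- 0L
    if (sum(cnt) == 0L) return(NULL)
    ii <- rep.int(seq_len(mm), cnt)
    jj <- sequence(cnt) + ii
    keep <- (pos[jj] - pos[ii]) <= max_distance * 1e6
    ii <- ii[keep]; jj <- jj[keep]
    if (!length(ii)) return(NULL)
    data.frame(chrom = m$chrom[rows[1L]], i = rows[ii], j = rows[jj],
               stringsAsFactors = FALSE)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) {
    df <- data.frame(chrom = character(), i = integer(), j = integer(),
                     id_i = character(), id_j = character(), pos_i = integer(),
                     pos_j = integer(), d = numeric(), r = numeric(),
                     r2 = numeric(), stringsAsFactors = FALSE)
    return(new_ld_pair_table(df, panel$population, max_distance))
  }
  df <- do.call(rbind, parts)
  df <- df[order(df$chrom, df$i, df$j), , drop = FALSE]
  p <- rowMeans(panel$haplotypes)
  if (any(p == 0 | p == 1)) {
    stop("panel contains monomorphic markers; filter them before pairwise_ld")
  }
  r <- pair_r_vec(panel$haplotypes, df$i, df$j)
  out <- data.frame(chrom = df$chrom,
                    i = df$i, j = df$j,
                    id_i = panel$markers$id[df$i], id_j = panel$markers$id[df$j],
                    pos_i = panel$markers$pos[df$i],
                    pos_j = panel$markers$pos[df$j],
                    d = marker_distance_mb(panel$markers$pos[df$i],
                                           panel$markers$pos[df$j]),
                    r = r, r2 = r * r, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  new_ld_pair_table(out, panel$population, max_distance)
}

#' LD between adjacent marker pairs
#'
#' One pair per consecutive marker couple within each chromosome; a
#' chromosome with fewer than two markers contributes nothing.
#'
#' @param panel a QC'd, complete [haplotype_panel()]
#' @return an `ld_pair_table` (see [pairwise_ld()]) with no distance cap
#'   attribute (`max_distance = Inf`)
#' @export
adjacent_pairs <- function(panel) {
  if (anyNA(panel$haplotypes)) {
    stop("adjacent_pairs requires a complete panel")
  }
  m <- panel$markers
  rows_by_chrom <- split(seq_len(nrow(m)), m$chrom)
  ii <- unlist(lapply(rows_by_chrom, function(rows) {
    if (length(rows) < 2L) integer(0) else rows[-length(rows)]
  }), use.names = FALSE)
  if (!length(ii)) {
    return(new_ld_pair_table(
      data.frame(chrom = character(), i = integer(), j = integer(),
                 id_i = character(), id_j = character(), pos_i = integer(),
                 pos_j = integer(), d = numeric(), r = numeric(),
                 r2 = numeric(), stringsAsFactors = FALSE),
      panel$population, Inf))
  }
  jj <- ii + 1L
  ord <- order(m$chrom[ii], ii)
  ii <- ii[ord]; jj <- jj[ord]
  r <- pair_r_vec(panel$haplotypes, ii, jj)
  out <- data.frame(chrom = m$chrom[ii], i = ii, j = jj,
                    id_i = m$id[ii], id_j = m$id[jj],
                    pos_i = m$pos[ii], pos_j = m$pos[jj],
                    d = marker_distance_mb(m$pos[ii], m$pos[jj]),
                    r = r, r2 = r * r, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  new_ld_pair_table(out, panel$population, Inf)
}
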