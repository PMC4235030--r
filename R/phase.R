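#' @title Persistence of LD phase between populations
#' @description For a set of markers shared by two populations, persistence
#'   of phase is the Pearson correlation between the signed r values of the
#'   same marker pairs in the two populations: a value near 1 means the
#'   populations share LD phase, so a marker-QTL association found in one is
#'   expected to hold in the other. Two common-marker scenarios are
#'   supported: Scenario I uses the markers shared by all three populations
#'   of a triple, Scenario II the markers shared by each specific pair.
#' @name phase
NULL

#' Match markers across panels
#'
#' Markers are matched on (chrom, pos); allele pairs must agree as sets.
#' When the allele0/allele1 labels of a matched marker are swapped between
#' panels the marker is kept with a sign-flip flag (its r values in that
#' panel change sign); allele-set mismatches are dropped with a message.
#'
#' @param panels list of 2 (Scenario II) or 3 (Scenario I)
#'   [haplotype_panel()] objects
#' @param scenario `"I"` (intersection over all three panels) or `"II"`
#'   (intersection over a pair)
#' @return a `common_marker_set`: list with `scenario`, `populations`, and
#'   `table` — a data.frame with columns `chrom`, `pos`, and per panel k
#'   `idx_k` (marker row in panel k) and `flip_k` (logical; flips are
#'   relative to panel 1, whose `flip_1` is all `FALSE`)
#' @export
common_markers <- function(panels, scenario = c("I", "II")) {
  scenario <- match.arg(scenario)
  k_needed <- if (scenario == "I") 3L else 2L
  if (length(panels) != k_needed) {
    stop(sprintf("scenario %s needs exactly %d panels, got %d", scenario,
                 k_needed, length(panels)))
  }
  keys <- lapply(panels, function(p) paste(p$markers$chrom, p$markers$pos))
  shared <- Reduce(intersect, keys)
  if (!length(shared)) stop("no markers shared by the panels")
  idx <- lapply(keys, match, x = shared)
  ref <- panels[[1L]]$markers[idx[[1L]], ]
  flip <- vector("list", length(panels))
  flip[[1L]] <- rep(FALSE, length(shared))
  keep <- rep(TRUE, length(shared))
  for (k in seq_along(panels)[-1L]) {
    mk <- panels[[k]]$markers[idx[[k]], ]
    same <- mk$allele0 == ref$allele0 & mk$allele1 == ref$allele1
    swapped <- mk$allele0 == ref$allele1 & mk$allele1 == ref$allele0
    keep <- keep & (same | swapped)
    flip[[k]] <- swapped
  }
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("common_markers: dropped %d marker(s) with mismatched allele sets",
                    n_dropped))
  }
  if (!any(keep)) stop("no shared markers with matching allele sets")
  tab <- data.frame(chrom = ref$chrom[keep], pos = ref$pos[keep])
  for (k in seq_along(panels)) {
    tab[[paste0("idx_", k)]] <- idx[[k]][keep]
    tab[[paste0("flip_", k)]] <- flip[[k]][keep]
  }
  tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(scenario = scenario,
                 populations = vapply(panels, `[[`, character(1), "population"),
                 table = tab),
            class = "common_marker_set")
}

#' Correlation of signed r between two populations
#'
#' Plain Pearson correlation of two equal-length vectors of signed r values
#' computed over the same marker pairs in two populations.
#'
#' @param rA,rB numeric vectors, equal length >= 3
#' @return the correlation; `NA` (with a warning) when either vector has
#'   zero variance
#' @export
phase_correlation <- function(rA, rB) {
  if (length(rA) != length(rB)) stop("rA and rB must have equal length")
  if (length(rA) < 3L) stop("need at least 3 marker pairs")
  if (stats::sd(rA) == 0 || stats::sd(rB) == 0) {
    warning("zero variance in r values; phase correlation undefined")
    return(NA_real_)
  }
  stats::cor(rA, rB)
}

# Signed r for pairs (ii, jj) of matched-set rows in panel k, with sign
# flips applied: relabelling one marker of a pair negates its r.
matched_pair_r <- function(panel, cms, k, ii, jj) {
  tab <- cms$table
  idx <- tab[[paste0("idx_", k)]]
  flip <- tab[[paste0("flip_", k)]]
  r <- pair_r_vec(panel$haplotypes, idx[ii], idx[jj])
  sgn <- ifelse(xor(flip[ii], flip[jj]), -1, 1)
  r * sgn
}

# Enumerate within-chromosome pairs of matched-set rows with d <= cap (Mb).
matched_pair_index <- function(cms, max_distance) {
  tab <- cms$table
  parts <- lapply(split(seq_len(nrow(tab)), tab$chrom), function(rows) {
    mm <- length(rows)
    if (mm < 2L) return(NULL)
    pos <- tab$pos[rows]
    hi <- findInterval(pos + max_distance * 1e6, pos)
    cnt <- pmax(hi - seq_len(mm), 0L)
    if (sum(cnt) == 0L) return(NULL)
    ii <- rep.int(seq_len(mm), cnt)
    jj <- sequence(cnt) + ii
    keep <- (pos[jj] - pos[ii]) <= max_distance * 1e6
    list(ii = rows[ii[keep]], jj = rows[jj[keep]])
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  list(ii = unlist(lapply(parts, `[[`, "ii"), use.names = FALSE),
       jj = unlist(lapply(parts, `[[`, "jj"), use.names = FALSE))
}

#' Distance-binned persistence-of-phase curve
#'
#' Enumerates within-chromosome pairs of matched markers up to
#' `max_distance`, computes signed r for each pair in both populations
#' (sign flips applied), bins pairs by distance exactly as [binned_decay()]
#' does, and reports the per-bin [phase_correlation()]. Bins with fewer than
#' 3 pairs are flagged `NA`. Distances come from the shared physical map
#' (matched positions are identical by construction).
#'
#' @param panelA,panelB the two panels, in the order they appear in `cms`
#'   (panels 1 and 2 of the matched set by default; use `which` to pick)
#' @param cms a [common_markers()] result covering both panels
#' @param which integer pair: which panel slots of `cms` the two panels
#'   occupy (default `c(1, 2)`)
#' @param bin_width bin width in Mb (default 0.1)
#' @param max_distance cap in Mb (default 10)
#' @return a `phase_curve`: data.frame with `bin_lo`, `bin_hi`, `mid`,
#'   `cor_r`, `n_pairs`
#' @export
binned_phase_decay <- function(panelA, panelB, cms, which = c(1L, 2L),
                               bin_width = 0.1, max_distance = 10) {
  pr <- matched_pair_index(cms, max_distance)
  if (!length(pr$ii)) stop("no matched marker pairs within the distance cap")
  tab <- cms$table
  d <- (tab$pos[pr$jj] - tab$pos[pr$ii]) / 1e6
  rA <- matched_pair_r(panelA, cms, which[1L], pr$ii, pr$jj)
  rB <- matched_pair_r(panelB, cms, which[2L], pr$ii, pr$jj)
  edges <- seq(0, max_distance, by = bin_width)
  nb <- length(edges) - 1L
  keep <- d < max_distance
  bin <- findInterval(d[keep], edges)
  rA <- rA[keep]; rB <- rB[keep]
  cor_r <- rep(NA_real_, nb)
  n_pairs <- tabulate(bin, nbins = nb)
  for (b in which(n_pairs >= 3L)) {
    sel <- bin == b
    if (stats::sd(rA[sel]) > 0 && stats::sd(rB[sel]) > 0) {
      cor_r[b] <- stats::cor(rA[sel], rB[sel])
    }
  }
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
                    mid = (edges[-length(edges)] + edges[-1L]) / 2,
                    cor_r = cor_r, n_pairs = n_pairs)
  structure(out, class = c("phase_curve", "data.frame"),
            populations = c(panelA$population, panelB$population),
            scenario = cms$scenario)
}

#' Sliding-window local persistence of phase
#'
#' Slides a window of `N` consecutive matched markers along each chromosome
#' (step one marker); within each window the Pearson correlation of signed r
#' over all `N(N-1)/2` pairs is computed between the two populations and
#' recorded at the middle matched marker's position. Zero-variance windows
#' are flagged `NA`.
#'
#' @inheritParams binned_phase_decay
#' @param N window size in matched markers (default 50)
#' @return a `local_phase_track`: data.frame with `chrom`, `window`,
#'   `mid_pos`, `cor_r`, `n_pairs`
#' @export
local_phase <- function(panelA, panelB, cms, N = 50, which = c(1L, 2L)) {
  stopifnot(N >= 3)
  tab <- cms$table
  tracks <- lapply(split(seq_len(nrow(tab)), tab$chrom), function(rows) {
    mm <- length(rows)
    if (mm < N) return(NULL)
    # banded pairs among matched rows of this chromosome
    cnt <- pmin(N - 1L, mm - seq_len(mm))
    ii_l <- rep.int(seq_len(mm), cnt)
    jj_l <- sequence(cnt) + ii_l
    ii <- rows[ii_l]; jj <- rows[jj_l]
    rA <- matched_pair_r(panelA, cms, which[1L], ii, jj)
    rB <- matched_pair_r(panelB, cms, which[2L], ii, jj)
    n_win <- mm - N + 1L
    res <- data.frame(chrom = tab$chrom[rows[1L]], window = seq_len(n_win),
                      mid_pos = tab$pos[rows[seq_len(n_win) + N %/% 2L]],
                      cor_r = NA_real_, n_pairs = 0L,
                      stringsAsFactors = FALSE)
    for (s in seq_len(n_win)) {
      sel <- ii_l >= s & jj_l <= s + N - 1L
      res$n_pairs[s] <- sum(sel)
      a <- rA[sel]; b <- rB[sel]
      if (stats::sd(a) > 0 && stats::sd(b) > 0) res$cor_r[s] <- stats::cor(a, b)
    }
    res
  })
  tracks <- tracks[!vapply(tracks, is.null, logical(1))]
  if (!length(tracks)) stop("no chromosome has >= N matched markers")
  out <- do.call(rbind, tracks)
  rownames(out) <- NULL
  structure(out, class = c("local_phase_track", "data.frame"),
            N = N, populations = c(panelA$population, panelB$population),
            scenario = cms$scenario)
}
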