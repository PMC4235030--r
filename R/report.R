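#' @title Figures and run orchestration
#' @description ggplot2 figures for the decay curves, LD-map tracks,
#'   persistence-of-phase curves and the triangular pairwise-r2 heatmap,
#'   plus a YAML-driven pipeline runner used by the command-line script in
#'   `inst/cli/ldscape.R`. Plots are side artifacts; all downstream
#'   comparisons work from the TSV tables.
#' @name cli_report
NULL

#' Plot a binned LD decay curve
#'
#' @param curves a `decay_curve` or named list of them (one per population)
#' @return a ggplot object (mean r-squared vs bin midpoint)
#' @export
plot_decay_curve <- function(curves) {
  if (is.data.frame(curves)) curves <- list(population = curves)
  df <- do.call(rbind, lapply(names(curves), function(nm) {
    cbind(curves[[nm]], population = nm)
  }))
  df <- df[!is.na(df$mean_r2), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$mean_r2,
                                   colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance (Mb)", y = expression(mean ~ r^2),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a local LD-map track
#'
#' @param track an `ld_map_track` from [ld_map()]
#' @param what `"alpha"` for the decay-rate track or `"expected_r2"` for the
#'   transformed LD track
#' @return a ggplot object
#' @export
plot_ld_map <- function(track, what = c("expected_r2", "alpha")) {
  what <- match.arg(what)
  ycol <- if (what == "alpha") "alpha_hat" else "expected_r2"
  df <- as.data.frame(track)
  df <- df[!is.na(df[[ycol]]), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid_pos / 1e6, y = .data[[ycol]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position of window middle marker (Mb)",
                  y = if (what == "alpha") expression(hat(alpha)) else
                    expression(E(r^2))) +
    ggplot2::theme_minimal()
}

#' Plot persistence-of-phase curves
#'
#' @param curves a `phase_curve` or named list of them (one per breed pair)
#' @return a ggplot object (correlation of r vs bin midpoint)
#' @export
plot_phase_curve <- function(curves) {
  if (is.data.frame(curves)) curves <- list(pair = curves)
  df <- do.call(rbind, lapply(names(curves), function(nm) {
    cbind(curves[[nm]], pair = nm)
  }))
  df <- df[!is.na(df$cor_r), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$cor_r,
                                   colour = .data$pair)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance (Mb)", y = "correlation of r", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot local persistence-of-phase tracks
#'
#' @param tracks a `local_phase_track` or named list of them
#' @return a ggplot object
#' @export
plot_local_phase <- function(tracks) {
  if (is.data.frame(tracks)) tracks <- list(pair = tracks)
  df <- do.call(rbind, lapply(names(tracks), function(nm) {
    cbind(as.data.frame(tracks[[nm]]), pair = nm)
  }))
  df <- df[!is.na(df$cor_r), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid_pos / 1e6, y = .data$cor_r,
                                   colour = .data$pair)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position of window middle marker (Mb)",
                  y = "correlation of r", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Per-chromosome mean decay-rate chart
#'
#' @param chrom_alphas list of `chromosome_alpha` results (possibly across
#'   populations: a named list of lists)
#' @return a ggplot object of mean(alpha) per chromosome
#' @export
plot_chromosome_alpha <- function(chrom_alphas) {
  if (inherits(chrom_alphas, "chromosome_alpha")) chrom_alphas <- list(chrom_alphas)
  if (!is.null(chrom_alphas$mean_alpha)) chrom_alphas <- list(chrom_alphas)
  flat <- list()
  for (nm in names(chrom_alphas)) {
    el <- chrom_alphas[[nm]]
    if (inherits(el, "chromosome_alpha")) el <- list(el)
    for (ca in el) {
      flat[[length(flat) + 1L]] <- data.frame(
        population = nm, chrom = ca$chrom, mean_alpha = ca$mean_alpha,
        sd_alpha = ca$sd_alpha)
    }
  }
  df <- do.call(rbind, flat)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chrom, y = .data$mean_alpha,
                                   group = .data$population,
                                   colour = .data$population)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "chromosome", y = expression(mean(hat(alpha))),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Triangular pairwise-r2 heatmap
#'
#' Classic rotated LD triangle: each marker pair of a region is drawn as a
#' diamond at x = midpoint of the two marker positions, depth proportional
#' to their separation, shaded by r-squared (darker = higher LD).
#'
#' @param pairs an `ld_pair_table` holding the region's pairs
#' @param chrom chromosome to draw (default: the first in `pairs`)
#' @return a ggplot object
#' @export
plot_triangular_heatmap <- function(pairs, chrom = NULL) {
  if (nrow(pairs) == 0L) stop("empty region: no pairs to draw")
  if (is.null(chrom)) chrom <- pairs$chrom[1L]
  df <- pairs[pairs$chrom == chrom, , drop = FALSE]
  if (nrow(df) == 0L) stop("no pairs on chromosome ", chrom)
  df$x <- (df$pos_i + df$pos_j) / 2 / 1e6
  df$y <- -(df$pos_j - df$pos_i) / 2 / 1e6
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$r2)) +
    ggplot2::geom_point(shape = 23, colour = NA, size = 1.5) +
    ggplot2::scale_fill_gradient(low = "white", high = "black", limits = c(0, 1)) +
    ggplot2::labs(x = "position (Mb)", y = "pair depth (Mb)",
                  fill = expression(r^2)) +
    ggplot2::theme_minimal()
}

#' Run the full LD analysis from a configuration
#'
#' Orchestrates the pipeline the package exposes piecewise: read phased
#' panels, QC them, compute adjacent-pair and binned decay summaries, the
#' local LD map, chromosome-level alpha, and (for two or more populations)
#' persistence-of-phase curves and local tracks. All tables are written as
#' TSV with provenance headers into `out_dir`.
#'
#' @param config named list, typically from `yaml::read_yaml()`: see the
#'   package vignette for the accepted fields (`populations`: named list of
#'   VCF paths; `qc`, `ld_map`, `phase`, `chromosome_alpha` parameter
#'   blocks; `seed`; `max_distance`; `bin_width`)
#' @param out_dir output directory, created if absent
#' @return named list of the computed objects, invisibly
#' @export
run_ld_analysis <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  cap <- config$max_distance %||% 10
  bw <- config$bin_width %||% 0.1
  qc_cfg <- config$qc %||% list()
  meta <- list(seed = seed, config = paste(deparse(config), collapse = ""))

  panels <- lapply(names(config$populations), function(nm) {
    p <- read_phased_vcf(config$populations[[nm]], nm)
    p <- filter_samples_by_missingness(
      p, qc_cfg$max_missing_frac %||% 0.10)$panel
    filter_markers(p,
                   min_call_rate = qc_cfg$min_call_rate %||% 0.90,
                   min_maf = qc_cfg$min_maf %||% 0.05,
                   hwe_p_threshold = qc_cfg$hwe_p_threshold %||% 1e-7)$panel
  })
  names(panels) <- names(config$populations)

  out <- list(panels = panels)
  out$pairs <- lapply(panels, pairwise_ld, max_distance = cap)
  out$adjacent <- lapply(panels, adjacent_pairs)
  out$decay <- lapply(out$pairs, binned_decay, bin_width = bw,
                      max_distance = cap)
  for (nm in names(panels)) {
    write_result_tsv(as.data.frame(out$decay[[nm]]),
                     file.path(out_dir, paste0("decay_", nm, ".tsv")),
                     c(meta, population = nm))
    write_result_tsv(as.data.frame(out$adjacent[[nm]]),
                     file.path(out_dir, paste0("adjacent_", nm, ".tsv")),
                     c(meta, population = nm))
  }
  lm_cfg <- config$ld_map %||% list()
  out$ld_map <- lapply(panels, function(p) {
    # "window" is the YAML-facing spelling: a bare N parses as boolean FALSE
    tryCatch(ld_map(p, N = lm_cfg$window %||% lm_cfg$N %||% 100,
                    d_fixed = lm_cfg$d_fixed %||% 10),
             error = function(e) NULL)
  })
  for (nm in names(panels)) {
    if (!is.null(out$ld_map[[nm]])) {
      write_result_tsv(as.data.frame(out$ld_map[[nm]]),
                       file.path(out_dir, paste0("ld_map_", nm, ".tsv")),
                       c(meta, population = nm))
    }
  }
  ca_cfg <- config$chromosome_alpha %||% list()
  out$chrom_alpha <- lapply(panels, function(p) {
    lapply(unique(p$markers$chrom), function(ch) {
      chromosome_alpha(p, ch, n_pairs = ca_cfg$n_pairs %||% 10000,
                       n_replicates = ca_cfg$n_replicates %||% 1000,
                       seed = seed)
    })
  })
  ca_df <- do.call(rbind, lapply(names(out$chrom_alpha), function(nm) {
    do.call(rbind, lapply(out$chrom_alpha[[nm]], function(ca) {
      data.frame(population = nm, chrom = ca$chrom, mean_alpha = ca$mean_alpha,
                 sd_alpha = ca$sd_alpha, n_pairs = ca$n_pairs,
                 n_replicates = ca$n_replicates)
    }))
  }))
  write_result_tsv(ca_df, file.path(out_dir, "chromosome_alpha.tsv"), meta)

  if (length(panels) >= 2L) {
    ph_cfg <- config$phase %||% list()
    combs <- utils::combn(names(panels), 2L, simplify = FALSE)
    out$phase <- list()
    for (pr in combs) {
      cms <- common_markers(panels[pr], scenario = "II")
      curve <- binned_phase_decay(panels[[pr[1L]]], panels[[pr[2L]]], cms,
                                  bin_width = bw, max_distance = cap)
      key <- paste(pr, collapse = "-")
      out$phase[[key]] <- curve
      write_result_tsv(as.data.frame(curve),
                       file.path(out_dir, paste0("phase_", key, ".tsv")),
                       c(meta, pair = key, scenario = "II"))
      trk <- tryCatch(local_phase(panels[[pr[1L]]], panels[[pr[2L]]], cms,
                                  N = ph_cfg$window %||% ph_cfg$N %||% 50),
                      error = function(e) NULL)
      if (!is.null(trk)) {
        write_result_tsv(as.data.frame(trk),
                         file.path(out_dir, paste0("local_phase_", key, ".tsv")),
                         c(meta, pair = key, scenario = "II"))
      }
    }
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
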