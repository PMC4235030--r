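#' Construct a phased haplotype panel
#'
#' A `haplotype_panel` is the central data structure of the package: a set of
#' biallelic markers with a physical map, together with the phased haplotypes
#' of a sample of diploid individuals from one population. Alleles are coded
#' 0 (reference, `allele0`) and 1 (alternate, `allele1`); `NA` marks a
#' missing allele. The matrix has one row per marker and two columns per
#' individual (maternal and paternal haplotype, in input order).
#'
#' @param markers data.frame with columns `id`, `chrom`, `pos` (1-based bp),
#'   `allele0`, `allele1`. Rows must be sorted by (`chrom`, `pos`).
#' @param haplotypes integer matrix of 0/1/NA with `nrow(markers)` rows and
#'   two columns per individual.
#' @param sample_ids character vector of individual ids, one per diploid.
#' @param population single string labelling the population.
#'
#' @return An object of class `haplotype_panel`: a list with elements
#'   `markers`, `haplotypes`, `sample_ids`, `population`.
#' @export
#' @examples
#' m <- data.frame(id = c("s1", "s2"), chrom = "1", pos = c(100L, 200L),
#'                 allele0 = "A", allele1 = "C")
#' h <- matrix(c(0L, 1L, 1L, 0L), nrow = 2)
#' haplotype_panel(m, h, sample_ids = "ind1", population = "popA")
haplotype_panel <- function(markers, haplotypes, sample_ids, population = "pop") {
  markers <- as.data.frame(markers)
  required <- c("id", "chrom", "pos", "allele0", "allele1")
  missing_cols <- setdiff(required, names(markers))
  if (length(missing_cols)) {
    stop("markers is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  markers$id <- as.character(markers$id)
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.integer(markers$pos)
  markers$allele0 <- as.character(markers$allele0)
  markers$allele1 <- as.character(markers$allele1)
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  obj <- structure(
    list(markers = markers, haplotypes = haplotypes,
         sample_ids = as.character(sample_ids),
         population = as.character(population)[1]),
    class = "haplotype_panel")
  validate_panel(obj)
  obj
}

validate_panel <- function(panel) {
  m <- panel$markers
  h <- panel$haplotypes
  if (nrow(m) != nrow(h)) {
    stop("marker table has ", nrow(m), " rows but haplotype matrix has ",
         nrow(h))
  }
  if (ncol(h) %% 2 != 0) stop("haplotype matrix must have an even column count")
  if (length(panel$sample_ids) != ncol(h) / 2) {
    stop("expected ", ncol(h) / 2, " sample ids, got ", length(panel$sample_ids))
  }
  if (any(m$pos < 1L, na.rm = TRUE)) stop("marker positions must be >= 1")
  if (anyDuplicated(m$id)) stop("marker ids must be unique within a panel")
  if (any(m$allele0 == m$allele1)) stop("allele0 and allele1 must differ")
  ord <- order(m$chrom, m$pos)
  if (!identical(ord, seq_len(nrow(m)))) {
    stop("markers must be sorted by (chrom, pos)")
  }
  bad <- h[!is.na(h) & h != 0L & h != 1L]
  if (length(bad)) stop("haplotype codes must be 0, 1 or NA")
  invisible(panel)
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel '%s': %d markers x %d diploids (%d haplotypes)\n",
              x$population, nrow(x$markers), length(x$sample_ids),
              ncol(x$haplotypes)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$markers$chrom), collapse = ", ")))
  n_miss <- sum(is.na(x$haplotypes))
  cat(sprintf("  missing alleles: %d (%.2f%%)\n", n_miss,
              100 * n_miss / length(x$haplotypes)))
  invisible(x)
}

#' Number of markers / samples in a panel
#' @param panel a [haplotype_panel()]
#' @return integer count
#' @export
n_markers <- function(panel) nrow(panel$markers)

#' @rdname n_markers
#' @export
n_samples <- function(panel) length(panel$sample_ids)

#' Subset a panel by marker and/or sample index
#'
#' @param panel a [haplotype_panel()]
#' @param markers integer or logical index into the marker rows (default all)
#' @param samples integer or logical index into the individuals (default all)
#' @return a new `haplotype_panel`
#' @export
subset_panel <- function(panel, markers = NULL, samples = NULL) {
  if (is.null(markers)) markers <- seq_len(n_markers(panel))
  if (is.logical(markers)) markers <- which(markers)
  if (is.null(samples)) samples <- seq_len(n_samples(panel))
  if (is.logical(samples)) samples <- which(samples)
  hap_cols <- as.vector(rbind(2L * samples - 1L, 2L * samples))
  haplotype_panel(panel$markers[markers, , drop = FALSE],
                  panel$haplotypes[markers, hap_cols, drop = FALSE],
                  panel$sample_ids[samples], panel$population)
}

#' Read a phased VCF into a haplotype panel
#'
#' Retains biallelic SNP records whose GT fields are all phased (`|`
#' separator). Multiallelic, non-SNP and unphased records are skipped and the
#' skip counts reported in a message. Missing alleles (`.`) become `NA`.
#'
#' @param path path to a VCF (plain text or bgzip)
#' @param population_label population name stored in the panel
#' @return a [haplotype_panel()] sorted by (chrom, pos)
#' @export
read_phased_vcf <- function(path, population_label = "pop") {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcf@gt
  if (ncol(gt) < 2L) stop("VCF has no sample columns: ", path)
  sample_ids <- colnames(gt)[-1]
  n_rec <- nrow(fix)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_snp <- !is.na(ref) & !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    !grepl(",", alt, fixed = TRUE)
  gt_field <- sub(":.*$", "", gt[, -1, drop = FALSE])
  phased <- matrix(grepl("^[01.]\\|[01.]$", gt_field), nrow = n_rec)
  all_phased <- rowSums(phased) == length(sample_ids)
  keep <- is_snp & all_phased
  n_multi <- sum(!is_snp)
  n_unphased <- sum(is_snp & !all_phased)
  if (n_multi + n_unphased > 0) {
    message(sprintf("read_phased_vcf: skipped %d non-biallelic-SNP and %d unphased record(s)",
                    n_multi, n_unphased))
  }
  if (!any(keep)) stop("no phased biallelic SNP records retained from ", path)
  gt_field <- gt_field[keep, , drop = FALSE]
  a0 <- substr(gt_field, 1L, 1L)
  a1 <- substr(gt_field, 3L, 3L)
  hap <- matrix(NA_integer_, nrow = sum(keep), ncol = 2L * length(sample_ids))
  hap[, seq(1L, ncol(hap), by = 2L)] <- suppressWarnings(as.integer(a0))
  hap[, seq(2L, ncol(hap), by = 2L)] <- suppressWarnings(as.integer(a1))
  ids <- fix[keep, "ID"]
  need_id <- is.na(ids) | ids == "."
  ids[need_id] <- paste0(fix[keep, "CHROM"][need_id], "_", fix[keep, "POS"][need_id])
  markers <- data.frame(id = ids, chrom = fix[keep, "CHROM"],
                        pos = as.integer(fix[keep, "POS"]),
                        allele0 = ref[keep], allele1 = alt[keep],
                        stringsAsFactors = FALSE)
  ord <- order(markers$chrom, markers$pos)
  haplotype_panel(markers[ord, , drop = FALSE], hap[ord, , drop = FALSE],
                  sample_ids, population_label)
}

#' Write a haplotype panel as a phased VCF
#'
#' Emits a minimal VCF 4.2 file with phased GT fields that
#' [read_phased_vcf()] inverts exactly.
#'
#' @param panel a non-empty [haplotype_panel()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_phased_vcf <- function(panel, path) {
  validate_panel(panel)
  if (n_markers(panel) == 0L) stop("cannot write an empty panel")
  if (n_samples(panel) == 0L) stop("cannot write a panel with no samples")
  m <- panel$markers
  h <- panel$haplotypes
  hc <- matrix(as.character(h), nrow = nrow(h))
  hc[is.na(hc)] <- "."
  gt <- matrix(paste0(hc[, seq(1L, ncol(hc), 2L), drop = FALSE], "|",
                      hc[, seq(2L, ncol(hc), 2L), drop = FALSE]),
               nrow = nrow(hc))
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=ldscape %s", as.character(utils::packageVersion("ldscape"))),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_ids), collapse = "\t"),
    paste(m$chrom, m$pos, m$id, m$allele0, m$allele1, ".", "PASS", ".", "GT",
          apply(gt, 1L, paste, collapse = "\t"), sep = "\t"))
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open for writing: ", path)
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a pedigree table
#'
#' Expects a 3-column TSV (individual, sire, dam), with unknown parents coded
#' `"0"`. A header line is accepted if its first field is `individual` or
#' `id`.
#'
#' @param path TSV file path
#' @return data.frame with character columns `individual`, `sire`, `dam`;
#'   unknown parents are `NA`
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("^(individual|id)\\b", tolower(first))
  ped <- utils::read.table(path, sep = "\t", header = has_header,
                           colClasses = "character",
                           col.names = c("individual", "sire", "dam"))
  names(ped) <- c("individual", "sire", "dam")
  if (anyDuplicated(ped$individual)) {
    stop("duplicate individual id(s) in pedigree: ",
         paste(unique(ped$individual[duplicated(ped$individual)]), collapse = ", "))
  }
  ped$sire[ped$sire == "0"] <- NA_character_
  ped$dam[ped$dam == "0"] <- NA_character_
  ped
}

# Mb distance between two marker rows; the map is 1-based bp.
marker_distance_mb <- function(pos_i, pos_j) abs(pos_j - pos_i) / 1e6

#' Write a data frame as TSV with a provenance header
#'
#' All result tables in the package are written in this form: comment lines
#' (`# key: value`) followed by a header line and tab-separated rows.
#'
#' @param df data.frame to write
#' @param path output path
#' @param meta named list written as `# name: value` comment lines
#' @return `path`, invisibly
#' @export
write_result_tsv <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(list(package = paste0("ldscape ",
                                  as.character(utils::packageVersion("ldscape")))),
            meta)
  for (k in names(meta)) writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
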