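#' Construct a polarized haplotype matrix
#'
#' The central container for phased, outgroup-polarized variation data:
#' a binary matrix with one row per haploid genome and one column per
#' segregating site, 0 = ancestral allele, 1 = derived allele, NA = missing.
#'
#' @param entries numeric/integer matrix of 0/1/NA, haplotypes x sites.
#' @param positions 1-based bp positions, strictly increasing, one per column.
#' @param chrom chromosome/contig label.
#' @param populations character vector of population labels, one per row.
#' @param polarized logical; TRUE when 0/1 encode ancestral/derived states
#'   assigned from an outgroup. Statistics that need the derived-allele
#'   frequency spectrum (Fay and Wu's H, Thomson's TMRCA) refuse
#'   unpolarized matrices.
#' @return object of class `hap_matrix`.
#' @export
hap_matrix <- function(entries, positions, chrom = "chr0",
                       populations = NULL, polarized = TRUE) {
  entries <- as.matrix(entries)
  if (ncol(entries) != length(positions))
    stop("positions length must match number of sites")
  if (ncol(entries) > 0) {
    if (is.unsorted(positions, strictly = TRUE))
      stop("positions must be strictly increasing")
    obs <- colSums(!is.na(entries))
    if (any(obs == 0)) stop("every site must have >= 1 observed allele")
  }
  vals <- entries[!is.na(entries)]
  if (length(vals) && !all(vals %in% c(0, 1)))
    stop("entries must be 0 (ancestral), 1 (derived) or NA")
  if (is.null(populations)) populations <- rep("pop0", nrow(entries))
  if (length(populations) != nrow(entries))
    stop("one population label per haplotype required")
  structure(
    list(entries = entries, positions = as.integer(positions),
         chrom = chrom, populations = as.character(populations),
         polarized = isTRUE(polarized)),
    class = "hap_matrix"
  )
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf("hap_matrix: %d haplotypes x %d sites on %s%s\n",
              nrow(x$entries), ncol(x$entries), x$chrom,
              if (x$polarized) " (polarized)" else " (unpolarized)"))
  invisible(x)
}

#' @export
dim.hap_matrix <- function(x) dim(x$entries)

#' Number of haplotypes / sites in a hap_matrix
#' @param x a `hap_matrix`.
#' @return integer count.
#' @export
n_haplotypes <- function(x) nrow(x$entries)

#' @rdname n_haplotypes
#' @export
n_sites <- function(x) ncol(x$entries)

#' Subset a hap_matrix to a genomic window
#'
#' @param x a `hap_matrix`.
#' @param start,end window in 0-based half-open coordinates
#'   (sites with start < pos <= end in 1-based terms).
#' @return a `hap_matrix` restricted to sites inside the window.
#' @export
subset_window <- function(x, start, end) {
  keep <- x$positions > start & x$positions <= end
  sub_sites(x, which(keep))
}

sub_sites <- function(x, idx) {
  structure(
    list(entries = x$entries[, idx, drop = FALSE],
         positions = x$positions[idx], chrom = x$chrom,
         populations = x$populations, polarized = x$polarized),
    class = "hap_matrix"
  )
}

#' Subset a hap_matrix to a set of haplotypes
#'
#' @param x a `hap_matrix`.
#' @param idx row indices or logical mask.
#' @param drop_monomorphic drop sites with no observed copy of one allele
#'   after subsetting (fixed-derived sites are kept; they matter for
#'   Thomson's estimator).
#' @return a `hap_matrix`.
#' @export
subset_haplotypes <- function(x, idx, drop_monomorphic = FALSE) {
  m <- x$entries[idx, , drop = FALSE]
  out <- structure(
    list(entries = m, positions = x$positions, chrom = x$chrom,
         populations = x$populations[idx], polarized = x$polarized),
    class = "hap_matrix"
  )
  if (drop_monomorphic && ncol(m)) {
    dc <- colSums(m == 1, na.rm = TRUE)
    out <- sub_sites(out, which(dc > 0))
  }
  out
}

#' Filter sites by minor allele frequency
#'
#' Retains sites whose minor allele frequency (among observed calls) is
#' strictly greater than `threshold`, mirroring the common ">10% MAF"
#' inclusion rule for LD analyses where low-frequency variants are
#' uninformative about linkage.
#'
#' @param x a `hap_matrix`.
#' @param threshold MAF threshold in `[0, 0.5)`; a site at exactly the
#'   threshold is removed (strict inequality).
#' @return filtered `hap_matrix`; warns when no site survives.
#' @export
maf_filter <- function(x, threshold = 0.10) {
  if (threshold < 0 || threshold >= 0.5)
    stop("threshold must be in [0, 0.5)")
  if (ncol(x$entries) == 0) return(x)
  p <- colMeans(x$entries == 1, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  keep <- maf > threshold
  if (!any(keep)) warning("maf_filter removed every site")
  sub_sites(x, which(keep))
}

#' Write a hap_matrix as a plain TSV matrix
#'
#' One row per haplotype; first columns `haplotype` and `population`,
#' then one 0/1 column per site named `<chrom>_<pos>`.
#'
#' @param x a `hap_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hap_tsv <- function(x, path) {
  df <- as.data.frame(x$entries)
  names(df) <- paste0(x$chrom, "_", x$positions)
  df <- cbind(haplotype = paste0("hap", seq_len(nrow(df))),
              population = x$populations, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a hap_matrix as a minimal phased VCF
#'
#' Haplotypes are paired in row order into pseudo-diploid samples (an odd
#' trailing haplotype becomes a haploid sample). REF is the ancestral
#' allele (A), ALT the derived allele (T); GT is phased.
#'
#' @param x a `hap_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hap_vcf <- function(x, path) {
  n <- nrow(x$entries)
  pair_of <- split(seq_len(n), ceiling(seq_len(n) / 2))
  ids <- vapply(seq_along(pair_of), function(i) paste0("sample", i), "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=sdpopgen",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  ), con)
  fmt_gt <- function(v) {
    v <- ifelse(is.na(v), ".", as.character(v))
    v
  }
  for (j in seq_len(ncol(x$entries))) {
    gts <- vapply(pair_of, function(idx) {
      paste(fmt_gt(x$entries[idx, j]), collapse = "|")
    }, "")
    writeLines(paste(c(x$chrom, x$positions[j], ".", "A", "T", ".", "PASS",
                       ".", "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}
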