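#' Parse a region string in reporting style
#'
#' Accepts `"chr7:143,501,000-143,521,000"` with thousands commas and
#' either an ASCII hyphen or an en-dash; the 1-based inclusive interval is
#' converted to internal 0-based half-open coordinates. The conversion is
#' lossless both ways (see [format_region()]).
#'
#' @param s region string.
#' @return data.frame with chrom, start, end (0-based half-open).
#' @export
#' @examples
#' parse_region("chr7:143,501,000-143,521,000")
parse_region <- function(s) {
  s <- gsub(",", "", s)
  s <- gsub("–", "-", s)  # en-dash
  m <- regmatches(s, regexec("^([^:]+):([0-9]+)-([0-9]+)$", s))[[1]]
  if (length(m) != 4) stop("cannot parse region string: ", s)
  start1 <- as.numeric(m[3]); end1 <- as.numeric(m[4])
  if (start1 < 1 || end1 < start1) stop("invalid interval in: ", s)
  data.frame(chrom = m[2], start = start1 - 1, end = end1)
}

#' @rdname parse_region
#' @param region data.frame row with chrom, start, end (0-based half-open).
#' @export
format_region <- function(region) {
  sprintf("%s:%s-%s", region$chrom,
          format(region$start + 1, big.mark = ",", scientific = FALSE,
                 trim = TRUE),
          format(region$end, big.mark = ",", scientific = FALSE,
                 trim = TRUE))
}

#' Read / write windows as BED
#'
#' BED is 0-based half-open, matching the internal convention, so no
#' coordinate shift is applied.
#'
#' @param path BED path (3+ columns; extra columns ignored on read).
#' @return data.frame chrom/start/end for the reader; `path` invisibly for
#'   the writer.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(df[, 1:3], c("chrom", "start", "end"))
}

#' @rdname read_bed
#' @param windows data.frame with chrom, start, end.
#' @export
write_bed <- function(windows, path) {
  utils::write.table(windows[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read phased genotypes from a VCF
#'
#' Thin wrapper over vcfR that extracts the fixed fields and the per-sample
#' phased GT strings, computes each SNV's distance to the nearest indel in
#' the file, and drops multiallelic records with a logged count.
#'
#' @param path VCF path (plain text or bgzip).
#' @return list with `chrom`, `pos`, `ref`, `alt`, `qual`, `gt` (variant x
#'   sample character matrix), `samples`, `indel_dist` (bp distance to the
#'   nearest indel; Inf when the file has none).
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi))
    message(sum(multi), " multiallelic records dropped")
  is_indel <- nchar(fix$REF) != 1 | (nchar(fix$ALT) != 1 & !multi)
  pos <- as.numeric(fix$POS)
  indel_pos <- pos[is_indel]
  indel_dist <- if (length(indel_pos)) {
    vapply(pos, function(p) min(abs(p - indel_pos)), numeric(1))
  } else rep(Inf, length(pos))
  keep <- !multi & !is_indel
  list(chrom = fix$CHROM[keep], pos = pos[keep], ref = fix$REF[keep],
       alt = fix$ALT[keep],
       qual = suppressWarnings(as.numeric(fix$QUAL[keep])),
       gt = gt[keep, , drop = FALSE], samples = colnames(gt),
       indel_dist = indel_dist[keep])
}

#' Variant-level quality filters
#'
#' Drops records with QUAL below `min_qual` (strict <: a record at exactly
#' the threshold is retained) or lying within `indel_radius` bp of an
#' indel (distance <= radius removed). Counts of removed records are
#' reported via `message`.
#'
#' @param records data.frame/list with fields `qual` and `indel_dist`
#'   (and any parallel per-variant fields, all subset together), e.g. from
#'   [read_vcf_genotypes()].
#' @param min_qual QUAL threshold.
#' @param indel_radius removal radius around indels, bp.
#' @return records with failing variants removed.
#' @export
filter_variants <- function(records, min_qual = 20, indel_radius = 10) {
  qual <- records$qual
  qual[is.na(qual)] <- Inf  # missing QUAL ('.') passes
  low_q <- qual < min_qual
  near_indel <- records$indel_dist <= indel_radius
  drop <- low_q | near_indel
  message(sum(low_q), " variants below QUAL ", min_qual, "; ",
          sum(near_indel), " within ", indel_radius, " bp of an indel")
  keep <- !drop
  subset_records(records, keep)
}

subset_records <- function(records, keep) {
  n <- length(keep)
  out <- lapply(records, function(f) {
    if (is.matrix(f) && nrow(f) == n) f[keep, , drop = FALSE]
    else if (!is.matrix(f) && length(f) == n) f[keep]
    else f
  })
  out
}

#' Sample-level missingness filter
#'
#' Drops samples whose fraction of missing genotype calls exceeds
#' `max_missing` (strict >: a sample at exactly the threshold is
#' retained).
#'
#' @param gt character genotype matrix (variants x samples); missing calls
#'   are `"."`, `"./."`, `".|."` or NA.
#' @param max_missing maximum tolerated missing fraction.
#' @return list with `gt` (filtered matrix) and `dropped` (sample names).
#' @export
filter_samples <- function(gt, max_missing = 0.10) {
  miss <- is.na(gt) | gt %in% c(".", "./.", ".|.")
  frac <- colMeans(miss)
  drop <- frac > max_missing
  if (all(drop)) stop("all samples exceed the missingness threshold")
  if (any(drop))
    message("dropping ", sum(drop), " sample(s): ",
            paste(colnames(gt)[drop], collapse = ", "))
  list(gt = gt[, !drop, drop = FALSE], dropped = colnames(gt)[drop])
}
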