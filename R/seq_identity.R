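#' Windowed pairwise sequence-identity profile of an alignment
#'
#' Slides a window (default 500 columns, step 100) along a pairwise
#' alignment and reports the fraction of matching columns per window.
#' Columns where either sequence carries a gap count as mismatches under
#' the default `"gap-mismatch"` policy (conservative for gene-conversion
#' detection: insertions break identity); `"gap-exclude"` drops them from
#' the denominator instead. Identity is computed exactly (no rounding), so
#' a window is 1.0 only when every counted column matches.
#'
#' @param seq_a,seq_b equal-length aligned sequences (character scalars;
#'   `-` is the gap character). Case-insensitive.
#' @param window window size in alignment columns.
#' @param step step size in columns (<= window).
#' @param gap_policy `"gap-mismatch"` or `"gap-exclude"`.
#' @return object of class `identity_profile`: data.frame with `start`,
#'   `end` (0-based half-open alignment-column coordinates) and `identity`,
#'   plus attributes `window`, `step`, `gap_policy`, `length`.
#' @export
#' @examples
#' p <- plant_igc(5000, 0.02, tract = c(2000, 3500), seed = 2)
#' prof <- identity_profile(p$donor, p$acceptor)
#' detect_igc_tracts(prof)
identity_profile <- function(seq_a, seq_b, window = 500, step = 100,
                             gap_policy = c("gap-mismatch", "gap-exclude")) {
  gap_policy <- match.arg(gap_policy)
  a <- toupper(strsplit(seq_a, "")[[1]])
  b <- toupper(strsplit(seq_b, "")[[1]])
  if (length(a) != length(b))
    stop("aligned sequences must have equal length")
  if (window < step) stop("window must be >= step")
  L <- length(a)
  if (L < window) stop("alignment shorter than one window")
  gap <- a == "-" | b == "-"
  match_col <- a == b & !gap
  starts <- seq(0, L - window, by = step)
  csum_m <- cumsum(c(0L, match_col))
  csum_g <- cumsum(c(0L, gap))
  nm <- csum_m[starts + window + 1L] - csum_m[starts + 1L]
  ng <- csum_g[starts + window + 1L] - csum_g[starts + 1L]
  denom <- if (gap_policy == "gap-mismatch") rep(window, length(starts)) else
    window - ng
  ident <- ifelse(denom == 0, NA_real_, nm / denom)
  structure(
    data.frame(start = starts, end = starts + window, identity = ident),
    window = window, step = step, gap_policy = gap_policy, length = L,
    class = c("identity_profile", "data.frame")
  )
}

#' Detect empirical interlocus gene-conversion tracts
#'
#' A tract is a maximal run of more than two consecutive windows at
#' exactly 100% identity (a 2-window run is not enough — the comparison is
#' to literal 1.0, no epsilon). The tract span runs from the first window's
#' start to the last window's end, in alignment-column coordinates.
#'
#' @param profile an [identity_profile()].
#' @return data.frame with `start`, `end`, `n_windows` (0 rows when no
#'   tract qualifies).
#' @export
detect_igc_tracts <- function(profile) {
  is_one <- !is.na(profile$identity) & profile$identity == 1
  r <- rle(is_one)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  keep <- r$values & r$lengths > 2
  if (!any(keep))
    return(data.frame(start = integer(0), end = integer(0),
                      n_windows = integer(0)))
  data.frame(
    start = profile$start[starts_i[keep]],
    end = profile$end[ends_i[keep]],
    n_windows = r$lengths[keep]
  )
}

#' Project alignment-column spans back onto an ungapped sequence
#'
#' Maps 0-based half-open alignment-column intervals to coordinates on one
#' of the aligned sequences, skipping its gap columns.
#'
#' @param spans data.frame with `start`, `end` in alignment columns.
#' @param aligned_seq the gapped sequence the spans should be projected on.
#' @return data.frame with `start`, `end` in 0-based half-open ungapped
#'   coordinates.
#' @export
project_to_sequence <- function(spans, aligned_seq) {
  chars <- strsplit(aligned_seq, "")[[1]]
  # ungapped bases consumed before each alignment column
  offset <- cumsum(c(0L, as.integer(chars != "-")))
  data.frame(start = offset[spans$start + 1L], end = offset[spans$end + 1L])
}

#' Read an aligned FASTA pair
#'
#' @param path aligned FASTA with exactly two records of equal length.
#' @return list with `seq_a`, `seq_b`, `names`.
#' @export
read_aligned_pair <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) != 2) stop("expected exactly two FASTA records")
  nm <- sub("^>\\s*", "", lines[hdr])
  block <- function(i) {
    from <- hdr[i] + 1
    to <- if (i < length(hdr)) hdr[i + 1] - 1 else length(lines)
    paste(lines[from:to], collapse = "")
  }
  list(seq_a = block(1), seq_b = block(2), names = nm)
}

#' Assign full-length transcript reads to duplicate haplotypes
#'
#' Filters candidate alignments of full-length non-chimeric (FLNC) cDNA
#' reads against paralogous haplotype contigs using the thresholds
#' appropriate for near-identical duplicates: identity strictly above
#' `min_identity`, overlap of at least `min_overlap`, ORF of at least
#' `min_orf`. Reads mapping to several haplotypes are kept on every
#' placement whose identity is within `multimap_tol` of the read's best
#' placement. Isoform/haplotype combinations supported by strictly more
#' than `min_reads` reads are reported as retained.
#'
#' @param records data.frame with columns `read`, `target`, `identity`
#'   (fraction in `[0,1]`), `overlap` (bp), `orf_len` (aa).
#' @param min_identity identity threshold (strict >; default 0.99).
#' @param min_overlap minimum alignment overlap in bp (>=).
#' @param multimap_tol maximum identity gap to the best placement for a
#'   secondary placement to be retained (strict <; default 1e-4, i.e.
#'   0.01 percentage points).
#' @param min_reads isoforms need strictly more than this many reads.
#' @param min_orf minimum ORF length in amino acids (>=).
#' @return list with `assignments` (retained read placements) and
#'   `isoforms` (data.frame target / n_reads of retained isoforms).
#' @export
assign_flnc_reads <- function(records, min_identity = 0.99,
                              min_overlap = 200, multimap_tol = 1e-4,
                              min_reads = 10, min_orf = 200) {
  need <- c("read", "target", "identity", "overlap", "orf_len")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  keep <- records$identity > min_identity &
    records$overlap >= min_overlap &
    records$orf_len >= min_orf
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec)) {
    best <- tapply(rec$identity, rec$read, max)
    rec <- rec[rec$identity > best[rec$read] - multimap_tol, , drop = FALSE]
  }
  iso <- if (nrow(rec)) {
    counts <- table(rec$target)
    data.frame(target = names(counts), n_reads = as.integer(counts))
  } else data.frame(target = character(0), n_reads = integer(0))
  iso <- iso[iso$n_reads > min_reads, , drop = FALSE]
  rownames(iso) <- NULL
  list(assignments = rec, isoforms = iso)
}
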