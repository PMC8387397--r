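#' Tile genomic regions into fixed-size windows
#'
#' Regions (0-based half-open) are tiled left to right with non-overlapping
#' windows. A terminal partial window is retained when it covers at least
#' half the window size and is otherwise merged into the preceding window
#' (a region shorter than half a window still yields one window).
#'
#' @param regions data.frame with columns chrom, start, end (0-based
#'   half-open); regions must be non-overlapping.
#' @param window_size window size in bp (> 0).
#' @return data.frame chrom, start, end, one row per window.
#' @export
#' @examples
#' window_partition(data.frame(chrom = "chr7", start = 0, end = 20000), 2000)
window_partition <- function(regions, window_size) {
  if (window_size <= 0) stop("window_size must be > 0")
  out <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    len <- r$end - r$start
    if (len <= 0) stop("empty region at row ", i)
    n_full <- len %/% window_size
    rem <- len - n_full * window_size
    starts <- r$start + window_size * seq_len(max(n_full, 1)) - window_size
    ends <- pmin(starts + window_size, r$end)
    if (n_full == 0) {
      # region shorter than one window: keep as a single window
      starts <- r$start; ends <- r$end
    } else if (rem > 0) {
      if (rem >= window_size / 2) {
        starts <- c(starts, r$start + n_full * window_size)
        ends <- c(ends[seq_len(n_full)], r$end)
      } else {
        ends[n_full] <- r$end  # merge the short tail into the last window
      }
    }
    out[[i]] <- data.frame(chrom = r$chrom, start = starts, end = ends)
  }
  do.call(rbind, out)
}

#' Derived-allele site-frequency spectrum of a window
#'
#' Counts, for each derived-allele count i in 1..n-1, the number of sites
#' at that count. Sites fixed for the derived allele (count n) are excluded
#' from the spectrum and from S but reported separately; they still matter
#' for Thomson's TMRCA estimator.
#'
#' @param x a polarized [hap_matrix()] (unpolarized input is refused).
#' @param window optional `c(start, end)` 0-based half-open; default all sites.
#' @return list with `spectrum` (length n-1), `S`, `n`, `fixed_derived`.
#' @export
sfs <- function(x, window = NULL) {
  if (!x$polarized)
    stop("sfs requires a polarized matrix (ancestral/derived encoding)")
  if (!is.null(window)) x <- subset_window(x, window[1], window[2])
  n <- nrow(x$entries)
  spec <- integer(max(n - 1, 0))
  fixed <- 0L
  if (ncol(x$entries)) {
    dc <- colSums(x$entries == 1, na.rm = TRUE)
    fixed <- sum(dc == n)
    dc <- dc[dc > 0 & dc < n]
    if (length(dc)) spec <- tabulate(dc, nbins = n - 1)
  }
  list(spectrum = spec, S = sum(spec), n = n, fixed_derived = fixed)
}

#' Diversity estimators from a derived-allele spectrum
#'
#' `theta_pi` is the mean number of pairwise differences
#' (sum over sites of i(n-i)/C(n,2)); `theta_w` is Watterson's S/a1 with
#' a1 = sum_{i=1}^{n-1} 1/i; `theta_h` is the homozygosity-weighted
#' estimator sum 2 i^2 S_i / (n(n-1)) that emphasizes high-frequency
#' derived alleles.
#'
#' @param spectrum integer vector S_1..S_{n-1} of site counts by derived
#'   allele count.
#' @param n number of haplotypes.
#' @return numeric scalar (per window, i.e. summed over sites).
#' @export
theta_pi <- function(spectrum, n) {
  i <- seq_along(spectrum)
  sum(spectrum * i * (n - i)) / choose(n, 2)
}

#' @rdname theta_pi
#' @export
theta_w <- function(spectrum, n) {
  sum(spectrum) / sum(1 / seq_len(n - 1))
}

#' @rdname theta_pi
#' @export
theta_h <- function(spectrum, n) {
  i <- seq_along(spectrum)
  sum(2 * i^2 * spectrum) / (n * (n - 1))
}

#' Tajima's D from a derived-allele spectrum
#'
#' D = (theta_pi - theta_W) / sqrt(e1 S + e2 S (S-1)) with the standard
#' Tajima (1989) variance constants derived from n. Windows with S = 0
#' return NA (the statistic is a 0/0 form, not zero).
#'
#' @inheritParams theta_pi
#' @return numeric scalar, or NA when S = 0.
#' @export
tajima_d <- function(spectrum, n) {
  if (n < 4) stop("Tajima's D requires n >= 4")
  if (length(spectrum) != n - 1)
    stop("spectrum must have length n - 1")
  S <- sum(spectrum)
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (theta_pi(spectrum, n) - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Fay and Wu's H from a derived-allele spectrum
#'
#' Unnormalized H = theta_pi - theta_H (the original definition); negative
#' values indicate an excess of high-frequency derived alleles, a positive-
#' selection signature that purifying selection does not produce. The
#' normalized variant (dividing by the standard-deviation form of Zeng et
#' al. 2006) is available behind `normalized = TRUE`. Requires a polarized
#' spectrum; fixed-derived sites (count n) must have been excluded.
#'
#' @inheritParams theta_pi
#' @param normalized return the variance-normalized statistic.
#' @param theta_input optional theta estimate used by the normalization
#'   (defaults to Watterson's from the spectrum).
#' @return numeric scalar, or NA when S = 0.
#' @export
fay_wu_h <- function(spectrum, n, normalized = FALSE, theta_input = NULL) {
  if (n < 2) stop("Fay and Wu's H requires n >= 2")
  if (length(spectrum) != n - 1)
    stop("spectrum must have length n - 1 (fixed sites pre-excluded)")
  S <- sum(spectrum)
  if (S == 0) return(NA_real_)
  h <- theta_pi(spectrum, n) - theta_h(spectrum, n)
  if (!normalized) return(h)
  a1 <- sum(1 / seq_len(n - 1))
  bn1 <- sum(1 / seq_len(n)^2)  # sum to n, per Zeng et al.
  th <- theta_input %||% (S / a1)
  th2 <- S * (S - 1) / (a1^2 + sum(1 / seq_len(n - 1)^2))
  varh <- (n - 2) / (6 * (n - 1)) * th +
    (18 * n^2 * (3 * n + 2) * bn1 - (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
      (9 * n * (n - 1)^2) * th2
  h / sqrt(varh)
}

#' Per-window diversity and selection statistics
#'
#' For each window: complete-case haplotype set (haplotypes with any
#' missing call inside the window are dropped for that window), then S,
#' theta_pi, theta_W, theta_H, Tajima's D and Fay and Wu's H from the
#' derived-allele spectrum. Windows with S = 0 carry NA for D and H.
#'
#' @param x a polarized [hap_matrix()].
#' @param windows data.frame chrom/start/end (0-based half-open), e.g. from
#'   [window_partition()].
#' @return data.frame of per-window records.
#' @export
windowed_stats <- function(x, windows) {
  if (nrow(windows) == 0) stop("empty window list")
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    xm <- subset_window(x, w$start, w$end)
    keep <- if (ncol(xm$entries)) !apply(is.na(xm$entries), 1, any) else
      rep(TRUE, nrow(xm$entries))
    xm <- subset_haplotypes(xm, keep)
    sp <- sfs(xm)
    n <- sp$n
    data.frame(
      chrom = w$chrom, start = w$start, end = w$end, n = n, S = sp$S,
      fixed_derived = sp$fixed_derived,
      pi = if (n >= 2) theta_pi(sp$spectrum, n) else NA_real_,
      theta_w = if (n >= 2) theta_w(sp$spectrum, n) else NA_real_,
      theta_h = if (n >= 2) theta_h(sp$spectrum, n) else NA_real_,
      tajima_d = if (n >= 4) tajima_d(sp$spectrum, n) else NA_real_,
      faywu_h = if (n >= 2) fay_wu_h(sp$spectrum, n) else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Thomson's TMRCA estimator
#'
#' T-hat = (1/n) sum_i d_i / (mu * L), where d_i is the number of derived
#' mutations carried by haplotype i, including sites fixed for the derived
#' allele in the sample (every derived mutation on a lineage counts).
#'
#' @param x a polarized [hap_matrix()].
#' @param mu per-bp per-generation mutation rate (> 0).
#' @param length sequence length in bp over which the matrix was called.
#' @param generation_time optional years per generation for a years-scale
#'   estimate.
#' @return list with `tmrca_generations`, `tmrca_years` (NULL unless
#'   `generation_time` given), `d` (per-haplotype derived counts), `mu_l`.
#' @export
thomson_tmrca <- function(x, mu, length, generation_time = NULL) {
  if (!x$polarized) stop("Thomson's estimator requires a polarized matrix")
  if (mu <= 0) stop("mu must be > 0")
  if (length <= 0) stop("length must be > 0")
  d <- rowSums(x$entries == 1, na.rm = TRUE)
  est <- mean(d) / (mu * length)
  list(tmrca_generations = est,
       tmrca_years = if (is.null(generation_time)) NULL else
         est * generation_time,
       d = unname(d), mu_l = mu * length)
}

#' Pairwise linkage disequilibrium between two sites
#'
#' From haplotype counts at two biallelic sites: D = p_AB - p_A p_B,
#' Lewontin's D' = D / D_max, and r^2 = D^2 / (p_A q_A p_B q_B).
#' Haplotypes with a missing call at either site are excluded.
#'
#' @param x a [hap_matrix()] (polarization not required; LD is invariant
#'   under a simultaneous allele-label swap at both sites).
#' @param site_a,site_b column indices.
#' @return list with `D`, `Dprime`, `r2`, `p_a`, `p_b`, `maf_a`, `maf_b`.
#' @export
ld_pair <- function(x, site_a, site_b) {
  a <- x$entries[, site_a]
  b <- x$entries[, site_b]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1))
    stop("ld_pair requires both sites polymorphic among observed haplotypes")
  pab <- mean(a == 1 & b == 1)
  D <- pab - pa * pb
  dmax <- if (D >= 0) min(pa * (1 - pb), (1 - pa) * pb) else
    min(pa * pb, (1 - pa) * (1 - pb))
  list(D = D,
       Dprime = if (dmax == 0) NA_real_ else D / dmax,
       r2 = D^2 / (pa * (1 - pa) * pb * (1 - pb)),
       p_a = pa, p_b = pb,
       maf_a = min(pa, 1 - pa), maf_b = min(pb, 1 - pb))
}

#' LD table for all site pairs of a matrix
#'
#' @param x a [hap_matrix()]; monomorphic sites are skipped.
#' @return data.frame pos_a, pos_b, D, Dprime, r2.
#' @export
ld_table <- function(x) {
  p <- colMeans(x$entries == 1, na.rm = TRUE)
  poly <- which(p > 0 & p < 1)
  if (length(poly) < 2) return(data.frame())
  pairs <- utils::combn(poly, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    r <- ld_pair(x, pairs[1, k], pairs[2, k])
    data.frame(pos_a = x$positions[pairs[1, k]],
               pos_b = x$positions[pairs[2, k]],
               D = r$D, Dprime = r$Dprime, r2 = r$r2)
  })
  do.call(rbind, rows)
}

#' Find SNVs perfectly separating two haplotype groups
#'
#' Returns the sites (ordered by position) where one allele is carried by
#' every haplotype of group 1 and by none of group 2 — the tagging-variant
#' definition used to distinguish structurally divergent super haplogroups.
#'
#' @param x a [hap_matrix()].
#' @param group1,group2 disjoint, non-empty row-index vectors.
#' @return integer vector of column indices (possibly empty).
#' @export
find_tagging_snvs <- function(x, group1, group2) {
  if (length(group1) == 0 || length(group2) == 0)
    stop("both groups must be non-empty")
  if (length(intersect(group1, group2)))
    stop("groups must not overlap")
  m1 <- x$entries[group1, , drop = FALSE]
  m2 <- x$entries[group2, , drop = FALSE]
  sep <- (colSums(m1 == 1) == length(group1) & colSums(m2 == 1) == 0) |
    (colSums(m1 == 0) == length(group1) & colSums(m2 == 0) == 0)
  sep[is.na(sep)] <- FALSE
  idx <- which(sep)
  idx[order(x$positions[idx])]
}

#' Bootstrap test comparing derived-allele counts to a reference pool
#'
#' Draws `n_boot` bootstrap samples of size |target| (with replacement)
#' from the per-sample derived-allele counts of a reference pool, and
#' reports the add-one empirical p-value for the target mean being at
#' least as extreme as the bootstrap means (tail selectable).
#'
#' @param target_counts per-sample derived-allele counts of the target set.
#' @param reference_pool per-sample counts of the reference pool (size >=
#'   target size).
#' @param n_boot number of bootstrap draws.
#' @param seed integer seed.
#' @param tail `"less"`: p = fraction of bootstrap means <= target mean;
#'   `"greater"`: >=.
#' @return list with `p`, `target_mean`, `boot_means`.
#' @export
derived_allele_bootstrap <- function(target_counts, reference_pool,
                                     n_boot = 1000, seed = NULL,
                                     tail = c("less", "greater")) {
  tail <- match.arg(tail)
  if (length(reference_pool) == 0) stop("empty reference pool")
  if (length(reference_pool) < length(target_counts))
    stop("pool must be at least as large as the target")
  if (!is.null(seed)) set.seed(seed)
  tm <- mean(target_counts)
  bm <- vapply(seq_len(n_boot), function(i) {
    mean(sample(reference_pool, length(target_counts), replace = TRUE))
  }, numeric(1))
  r <- if (tail == "less") sum(bm <= tm) else sum(bm >= tm)
  list(p = (r + 1) / (n_boot + 1), target_mean = tm, boot_means = bm)
}
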