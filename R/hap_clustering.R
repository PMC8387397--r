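#' Encode phased genotypes as a polarized haplotype matrix
#'
#' Recodes haplotype alleles as 0 = ancestral / 1 = derived using an
#' outgroup allele table (the chimpanzee in human applications). Sites
#' whose outgroup allele matches neither REF nor ALT, or with no outgroup
#' call, are dropped with a logged count.
#'
#' @param gt character matrix of phased genotypes (`"a|b"`), variants x
#'   samples; unphased separators (`/`) are refused. Haploid single-allele
#'   genotypes are accepted.
#' @param ref,alt allele character vectors, one per variant.
#' @param pos 1-based positions, one per variant.
#' @param outgroup data.frame with columns `pos` and `allele` (ancestral
#'   base per position); positions absent from it are dropped.
#' @param chrom chromosome label.
#' @param populations population label per *sample*; each diploid sample
#'   contributes two haplotypes with its label.
#' @return a polarized [hap_matrix()]; attribute `n_dropped` counts sites
#'   removed for outgroup mismatch or missing outgroup call.
#' @export
encode_haplotypes <- function(gt, ref, alt, pos, outgroup,
                              chrom = "chr0", populations = NULL) {
  gt <- as.matrix(gt)
  if (any(grepl("/", gt, fixed = TRUE)))
    stop("unphased genotypes (\"/\" separator) are not accepted")
  og <- stats::setNames(as.character(outgroup$allele),
                        as.character(outgroup$pos))
  anc <- og[as.character(pos)]
  usable <- !is.na(anc) & (anc == ref | anc == alt)
  n_dropped <- sum(!usable)
  if (n_dropped > 0)
    message(n_dropped,
            " sites dropped (missing or mismatching outgroup allele)")
  gt <- gt[usable, , drop = FALSE]
  pos <- pos[usable]; ref <- ref[usable]; alt <- alt[usable]
  anc <- anc[usable]
  # split "a|b" into haplotype columns
  split_gt <- strsplit(gt, "|", fixed = TRUE)
  ploidy <- lengths(split_gt)[1]
  n_hap_per_sample <- max(1L, ploidy)
  n_samp <- ncol(gt)
  ent <- matrix(NA_integer_, nrow = n_samp * n_hap_per_sample,
                ncol = nrow(gt))
  for (v in seq_len(nrow(gt))) {
    alleles <- unlist(strsplit(gt[v, ], "|", fixed = TRUE))
    alleles[alleles == "."] <- NA
    dosage <- as.integer(alleles)  # 0 = REF, 1 = ALT
    # derived = allele differing from the outgroup state
    derived_is_alt <- anc[v] == ref[v]
    ent[, v] <- if (derived_is_alt) dosage else 1L - dosage
  }
  hap_pops <- if (is.null(populations)) NULL else
    rep(populations, each = n_hap_per_sample)
  out <- hap_matrix(ent, pos, chrom = chrom, populations = hap_pops,
                    polarized = TRUE)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Greedy LD pruning of a haplotype matrix
#'
#' Left-to-right scan: for each retained site, later sites within `window`
#' bp whose r-squared with it exceeds `r2_threshold` are dropped. Duplicate
#' columns therefore keep a single survivor.
#'
#' @param x a [hap_matrix()].
#' @param r2_threshold r-squared threshold in (0, 1] (strict >).
#' @param window maximum pair distance in bp considered (Inf = all pairs).
#' @return pruned `hap_matrix`.
#' @export
ld_prune <- function(x, r2_threshold = 0.4, window = Inf) {
  if (r2_threshold <= 0 || r2_threshold > 1)
    stop("r2_threshold must be in (0, 1]")
  p <- colMeans(x$entries == 1, na.rm = TRUE)
  keep <- rep(TRUE, ncol(x$entries))
  for (i in seq_len(ncol(x$entries))) {
    if (!keep[i] || p[i] %in% c(0, 1)) next
    j <- i + 1
    while (j <= ncol(x$entries) &&
           x$positions[j] - x$positions[i] <= window) {
      if (keep[j] && !(p[j] %in% c(0, 1))) {
        if (ld_pair(x, i, j)$r2 > r2_threshold) keep[j] <- FALSE
      }
      j <- j + 1
    }
  }
  sub_sites(x, which(keep))
}

#' Haplotype-based principal component analysis
#'
#' Columns (sites) are centered and the scores come from the singular
#' value decomposition of the centered matrix; variance fractions are the
#' normalized squared singular values. `n_informative` is the smallest N
#' whose leading components jointly explain more than 90% of the variance.
#'
#' @param x a [hap_matrix()] with >= 2 distinct haplotypes and no missing
#'   calls.
#' @param var_explained cumulative variance-fraction cutoff for
#'   `n_informative` (default 0.9).
#' @return object of class `hap_pca`: list with `scores` (haplotypes x
#'   components), `loadings`, `var_frac`, `n_informative`.
#' @export
haplotype_pca <- function(x, var_explained = 0.9) {
  m <- x$entries
  if (anyNA(m)) stop("haplotype_pca requires a complete matrix")
  mc <- scale(m, center = TRUE, scale = FALSE)
  if (all(mc == 0)) stop("all haplotypes identical: zero variance")
  sv <- svd(mc)
  var_frac <- sv$d^2 / sum(sv$d^2)
  n_inf <- which(cumsum(var_frac) > var_explained)[1]
  structure(
    list(scores = sv$u %*% diag(sv$d, nrow = length(sv$d)),
         loadings = sv$v, var_frac = var_frac, n_informative = n_inf),
    class = "hap_pca"
  )
}

#' @export
print.hap_pca <- function(x, ...) {
  cat(sprintf("hap_pca: %d haplotypes, %d informative PCs (>%.0f%% variance)\n",
              nrow(x$scores), x$n_informative,
              100 * cumsum(x$var_frac)[x$n_informative]))
  invisible(x)
}

# k-means++ seeding: first center uniform, then each next center drawn
# with probability proportional to squared distance to the nearest chosen
# center.
kmeanspp_centers <- function(scores, k) {
  n <- nrow(scores)
  centers <- matrix(NA_real_, k, ncol(scores))
  idx <- sample.int(n, 1)
  centers[1, ] <- scores[idx, ]
  if (k > 1) {
    d2 <- rowSums((scores - matrix(centers[1, ], n, ncol(scores),
                                   byrow = TRUE))^2)
    for (j in 2:k) {
      probs <- if (sum(d2) == 0) rep(1, n) else d2
      idx <- sample.int(n, 1, prob = probs)
      centers[j, ] <- scores[idx, ]
      d2 <- pmin(d2, rowSums((scores - matrix(centers[j, ], n,
                                              ncol(scores),
                                              byrow = TRUE))^2))
    }
  }
  centers
}

kmeans_best <- function(scores, k, restarts = 10, init_centers = NULL) {
  best <- NULL
  if (k >= nrow(unique(scores))) {
    km <- suppressWarnings(stats::kmeans(scores, centers =
                                           unique(scores)[seq_len(min(k, nrow(unique(scores)))), , drop = FALSE]))
    return(km)
  }
  for (r in seq_len(restarts)) {
    cen <- kmeanspp_centers(scores, k)
    cen <- unique(cen)
    km <- tryCatch(
      suppressWarnings(stats::kmeans(scores, centers = cen,
                                     iter.max = 50)),
      error = function(e) NULL
    )
    if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss))
      best <- km
  }
  if (!is.null(init_centers)) {
    km <- tryCatch(
      suppressWarnings(stats::kmeans(scores, centers = init_centers,
                                     iter.max = 50)),
      error = function(e) NULL
    )
    if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss))
      best <- km
  }
  best
}

#' Choose the number of haplotype clusters by the WSS elbow rule
#'
#' For k = 1..k_max, k-means (k-means++ seeding, `restarts` restarts,
#' best within-group sum of squares kept) is run on the informative PC
#' scores; the chosen k is the smallest k whose WSS drop to k+1 falls
#' below `delta`. To keep the WSS trace non-increasing, clustering at k+1
#' additionally tries an initialization built from the best k-solution's
#' centers plus the worst-fit point.
#'
#' @param scores numeric matrix of PC scores (haplotypes x components),
#'   typically `pca$scores[, 1:pca$n_informative]`.
#' @param k_max largest k tried.
#' @param delta WSS-drop threshold. The data-scale value used at the
#'   original locus was 500; `delta = NULL` uses a scale-aware default of
#'   0.5% of WSS(1).
#' @param seed integer seed.
#' @param restarts k-means restarts per k.
#' @return object of class `cluster_model`: list with `k`, `assignment`,
#'   `wss` (trace for k = 1..k_max), `delta`, `centers`.
#' @export
choose_k <- function(scores, k_max = 20, delta = NULL, seed = NULL,
                     restarts = 10) {
  scores <- as.matrix(scores)
  if (any(!is.finite(scores))) stop("non-finite PC scores")
  if (nrow(scores) < k_max + 1)
    warning("fewer than k_max + 1 haplotypes; large k values are degenerate")
  if (!is.null(seed)) set.seed(seed)
  wss1 <- sum(scale(scores, scale = FALSE)^2)
  if (is.null(delta)) delta <- 0.005 * wss1
  k_max <- min(k_max, nrow(unique(scores)))
  wss <- numeric(k_max)
  fits <- vector("list", k_max)
  wss[1] <- wss1
  fits[[1]] <- list(cluster = rep(1L, nrow(scores)),
                    centers = matrix(colMeans(scores), 1))
  prev <- NULL
  for (k in seq_len(k_max)[-1]) {
    init <- if (!is.null(prev)) {
      d2 <- rowSums((scores - prev$centers[prev$cluster, , drop = FALSE])^2)
      rbind(prev$centers, scores[which.max(d2), ])
    } else NULL
    km <- kmeans_best(scores, k, restarts, init_centers = init)
    wss[k] <- km$tot.withinss
    fits[[k]] <- km
    prev <- km
  }
  chosen <- k_max
  for (k in seq_len(k_max - 1)) {
    if (wss[k] - wss[k + 1] < delta) { chosen <- k; break }
  }
  structure(
    list(k = chosen, assignment = fits[[chosen]]$cluster, wss = wss,
         delta = delta, centers = fits[[chosen]]$centers),
    class = "cluster_model"
  )
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: k = %d (delta = %.3g); cluster sizes: %s\n",
              x$k, x$delta,
              paste(table(x$assignment), collapse = ", ")))
  invisible(x)
}

#' Haplotype heterozygosity
#'
#' h = (n/(n-1)) (1 - sum p_i^2) over haplotype class frequencies p_i: the
#' probability that two randomly drawn haplotypes belong to different
#' classes, with the unbiased small-sample correction (switch it off with
#' `corrected = FALSE`).
#'
#' @param assignments vector of class labels, one per haplotype.
#' @param corrected apply the n/(n-1) correction.
#' @return numeric scalar in `[0, 1]`.
#' @export
haplotype_heterozygosity <- function(assignments, corrected = TRUE) {
  n <- length(assignments)
  if (n < 2) stop("need >= 2 haplotypes")
  p <- as.numeric(table(assignments)) / n
  h <- 1 - sum(p^2)
  if (corrected) h <- h * n / (n - 1)
  h
}

#' Permutation test of archaic-cluster homogeneity
#'
#' Under panmixia, how often would m haplotypes drawn from the modern
#' pool all fall into a single cluster? Draws are with or without
#' replacement from the pooled cluster assignments; the add-one empirical
#' p-value is the fraction of draws that are single-cluster. With
#' replacement the closed form is sum_c p_c^m.
#'
#' @param assignments cluster label per haplotype in the modern pool.
#' @param m number of haplotypes drawn per permutation (the archaic sample
#'   size).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param mode `"without_replacement"` (default) or `"with_replacement"`.
#' @return list with `p`, `n_perm`, `mode`.
#' @export
homogeneity_permutation <- function(assignments, m = 8, n_perm = 10000,
                                    seed = NULL,
                                    mode = c("without_replacement",
                                             "with_replacement")) {
  mode <- match.arg(mode)
  if (m < 1) stop("m must be >= 1")
  pool <- as.vector(assignments)
  if (mode == "without_replacement" && m > length(pool))
    stop("m exceeds pool size for without-replacement draws")
  if (!is.null(seed)) set.seed(seed)
  if (length(unique(pool)) == 1)
    return(list(p = 1, n_perm = n_perm, mode = mode))
  hits <- sum(vapply(seq_len(n_perm), function(i) {
    draw <- sample(pool, m, replace = (mode == "with_replacement"))
    length(unique(draw)) == 1L
  }, logical(1)))
  list(p = (hits + 1) / (n_perm + 1), n_perm = n_perm, mode = mode)
}
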