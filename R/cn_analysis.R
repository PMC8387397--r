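#' V_ST copy-number differentiation between two populations
#'
#' V_ST = (V_T - V_S) / V_T, where V_T is the variance of the pooled
#' copy-number values and V_S the sample-size-weighted mean of the
#' within-population variances. Population variance (divide by n) is used
#' consistently for both terms, which is what bounds V_ST <= 1. V_T = 0
#' (no variation at all) is defined as V_ST = 0.
#'
#' @param cn a [cn_matrix()].
#' @param locus locus column name or index.
#' @param pop_a,pop_b population labels (>= 2 samples each).
#' @return list with `vst`, `v_t`, `v_s`, `n_a`, `n_b`.
#' @export
vst <- function(cn, locus, pop_a, pop_b) {
  va <- cn$values[cn$populations == pop_a, locus]
  vb <- cn$values[cn$populations == pop_b, locus]
  if (length(va) < 2 || length(vb) < 2)
    stop("vst requires >= 2 samples per population")
  vst_values(va, vb)
}

# core arithmetic on two value vectors (shared with the permutation test)
vst_values <- function(va, vb) {
  popvar <- function(x) mean((x - mean(x))^2)
  pooled <- c(va, vb)
  v_t <- popvar(pooled)
  v_s <- (length(va) * popvar(va) + length(vb) * popvar(vb)) /
    (length(va) + length(vb))
  list(vst = if (v_t == 0) 0 else (v_t - v_s) / v_t,
       v_t = v_t, v_s = v_s, n_a = length(va), n_b = length(vb))
}

#' Permutation test of copy-number differentiation (on V_ST)
#'
#' Population labels are permuted `n_perm` times; the add-one p-value is
#' the fraction of permutations with V_ST at least as large as observed.
#'
#' @inheritParams vst
#' @param n_perm number of label permutations (error below 10, warning
#'   below 100).
#' @param seed integer seed.
#' @param m Bonferroni factor (number of population pairs tested).
#' @return list with `vst`, `p`, `p_bonferroni`, `n_perm`.
#' @export
cn_differentiation_test <- function(cn, locus, pop_a, pop_b,
                                    n_perm = 1000, seed = NULL, m = 1) {
  if (n_perm < 10) stop("n_perm must be >= 10")
  if (n_perm < 100) warning("n_perm < 100: permutation p is very coarse")
  va <- cn$values[cn$populations == pop_a, locus]
  vb <- cn$values[cn$populations == pop_b, locus]
  if (length(va) < 2 || length(vb) < 2)
    stop("requires >= 2 samples per population")
  if (!is.null(seed)) set.seed(seed)
  obs <- vst_values(va, vb)$vst
  pooled <- c(va, vb)
  na <- length(va)
  perm_vst <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pooled), na)
    vst_values(pooled[idx], pooled[-idx])$vst
  }, numeric(1))
  p <- (sum(perm_vst >= obs) + 1) / (n_perm + 1)
  list(vst = obs, p = p, p_bonferroni = bonferroni(p, m), n_perm = n_perm)
}

#' Latitude regression of copy number with PC covariates
#'
#' Fits `copy_number ~ latitude + PC_1 + ... + PC_k` by least squares and
#' reports the latitude coefficient with its t-test p-value, alongside the
#' unadjusted Pearson correlation — the comparison that separates a
#' latitudinal cline from confounding by population structure. With
#' `n_pcs = 0` this reduces exactly to simple linear regression.
#'
#' @param cn_values copy-number value per observation (sample or
#'   population mean).
#' @param latitude latitude per observation, degrees; absolute value is
#'   taken when `absolute = TRUE` (default), matching the convention that
#'   distance from the equator is the covariate of interest.
#' @param pcs matrix of principal components (observations x components),
#'   centered; may be NULL when `n_pcs = 0`.
#' @param n_pcs number of leading PCs to include as covariates.
#' @param absolute use |latitude|.
#' @return list with `coef` (latitude slope), `p_adjusted` (its t-test p
#'   in the PC-adjusted model), `raw_r`, `p_raw` (unadjusted Pearson),
#'   `fit` (the lm object).
#' @export
latitude_regression <- function(cn_values, latitude, pcs = NULL,
                                n_pcs = 10, absolute = TRUE) {
  lat <- if (absolute) abs(latitude) else latitude
  n <- length(cn_values)
  if (n < n_pcs + 3)
    stop("need >= n_pcs + 3 observations")
  df <- data.frame(cn = cn_values, latitude = lat)
  if (n_pcs > 0) {
    if (is.null(pcs) || ncol(pcs) < n_pcs)
      stop("pcs must provide at least n_pcs components")
    pcs <- as.matrix(pcs)[, seq_len(n_pcs), drop = FALSE]
    colnames(pcs) <- paste0("PC", seq_len(n_pcs))
    X <- cbind(latitude = lat, pcs)
    qr_rank <- qr(cbind(1, X))$rank
    if (qr_rank < ncol(X) + 1) {
      # name the first component whose addition does not raise the rank
      for (j in seq_len(ncol(X))) {
        if (qr(cbind(1, X[, seq_len(j), drop = FALSE]))$rank < j + 1)
          stop("collinear covariate: ", colnames(X)[j])
      }
    }
    df <- cbind(df, as.data.frame(pcs))
  }
  fit <- stats::lm(cn ~ ., data = df)
  sm <- summary(fit)$coefficients
  ct <- stats::cor.test(cn_values, lat)
  list(coef = sm["latitude", "Estimate"],
       p_adjusted = sm["latitude", "Pr(>|t|)"],
       raw_r = unname(ct$estimate), p_raw = ct$p.value, fit = fit)
}

#' Empirical p-value of a correlation against a genomic-shuffle background
#'
#' Compares the absolute target correlation with absolute correlations
#' observed at random background loci (e.g. random segmental-duplication
#' loci across the genome), with the add-one convention.
#'
#' @param target_correlation observed correlation coefficient at the locus
#'   of interest.
#' @param background_correlations correlations at n random background loci
#'   (error when empty, warning below 1,000; >= 100 recommended).
#' @return list with `p`, `n_background`.
#' @export
genomic_shuffle_null <- function(target_correlation, background_correlations) {
  bg <- background_correlations[!is.na(background_correlations)]
  if (length(bg) == 0) stop("empty background")
  if (length(bg) < 100)
    warning("background has fewer than 100 loci; p is very coarse")
  else if (length(bg) < 1000)
    warning("background has fewer than 1,000 loci")
  r <- sum(abs(bg) >= abs(target_correlation))
  list(p = (r + 1) / (length(bg) + 1), n_background = length(bg))
}

#' Donor/acceptor reciprocal copy-number correlation
#'
#' Pearson correlation of paired per-sample copy numbers at a donor and an
#' acceptor locus; a significantly negative correlation is the reciprocal
#' signature expected when interlocus gene conversion copies donor sequence
#' over the acceptor. Optionally stratified by population.
#'
#' @param cn a [cn_matrix()] containing both loci.
#' @param donor_locus,acceptor_locus column names or indices.
#' @param by_population also return per-population correlations.
#' @return list with `r`, `p` and optionally `by_population`
#'   (data.frame population/r/p; populations with < 3 samples or zero
#'   variance are skipped).
#' @export
donor_acceptor_correlation <- function(cn, donor_locus, acceptor_locus,
                                       by_population = FALSE) {
  d <- cn$values[, donor_locus]
  a <- cn$values[, acceptor_locus]
  if (stats::sd(d) == 0 || stats::sd(a) == 0)
    stop("zero copy-number variance at one of the loci")
  ct <- stats::cor.test(d, a)
  out <- list(r = unname(ct$estimate), p = ct$p.value)
  if (by_population) {
    pops <- unique(cn$populations)
    rows <- lapply(pops, function(p) {
      i <- cn$populations == p
      if (sum(i) < 3 || stats::sd(d[i]) == 0 || stats::sd(a[i]) == 0)
        return(NULL)
      cc <- stats::cor.test(d[i], a[i])
      data.frame(population = p, r = unname(cc$estimate), p = cc$p.value)
    })
    out$by_population <- do.call(rbind, rows)
  }
  out
}
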