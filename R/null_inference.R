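#' Construct a null distribution of a window statistic
#'
#' Holds one value per null window (genome-background mode) or per
#' simulated replicate-window (simulation mode). At least 100 values are
#' required before p-values are issued; below 1,000 a warning is emitted
#' because empirical tails are then coarse.
#'
#' @param values numeric vector of null statistic values (NAs dropped with
#'   a message).
#' @param statistic statistic name (e.g. "tajima_d").
#' @param source `"genome_background"` or `"simulation"`.
#' @param provenance free-form provenance string (model hash, seed, ...).
#' @return object of class `null_distribution`.
#' @export
null_distribution <- function(values, statistic,
                              source = c("genome_background", "simulation"),
                              provenance = "") {
  source <- match.arg(source)
  n_na <- sum(is.na(values))
  if (n_na > 0) {
    message("dropping ", n_na, " missing null values")
    values <- values[!is.na(values)]
  }
  if (length(values) < 100)
    stop("need >= 100 null values before p-values can be issued (have ",
         length(values), ")")
  if (length(values) < 1000)
    warning("fewer than 1,000 null values; empirical tail is coarse")
  structure(list(values = values, statistic = statistic, source = source,
                 provenance = provenance),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null_distribution: %s, %d values (%s)\n",
              x$statistic, length(x$values), x$source))
  invisible(x)
}

#' Empirical one-tailed test of a window-set statistic against a null
#'
#' The target windows are aggregated by their median; the null is built by
#' drawing `n_resample` random window sets of the same size (with
#' replacement) from the null values and taking each set's median. The
#' add-one empirical p-value is the fraction of null medians at least as
#' extreme as the observed one in the requested tail.
#'
#' @param target_stats statistic values over the target windows (NAs
#'   dropped).
#' @param null a [null_distribution()].
#' @param tail `"negative"` (observed at least as small) or `"positive"`.
#' @param n_resample number of null window-set draws.
#' @param seed integer seed.
#' @param m Bonferroni correction factor (number of groups tested).
#' @return object of class `selection_test`: list with `observed` (target
#'   median), `tail`, `p`, `p_bonferroni`, `n_target_windows`, `n_null`.
#' @export
empirical_p_windowset <- function(target_stats, null,
                                  tail = c("negative", "positive"),
                                  n_resample = 10000, seed = NULL, m = 1) {
  tail <- match.arg(tail)
  stopifnot(inherits(null, "null_distribution"))
  target_stats <- target_stats[!is.na(target_stats)]
  if (length(target_stats) == 0) stop("all target windows are missing")
  if (!is.null(seed)) set.seed(seed)
  obs <- stats::median(target_stats)
  k <- length(target_stats)
  null_medians <- vapply(seq_len(n_resample), function(i) {
    stats::median(sample(null$values, k, replace = TRUE))
  }, numeric(1))
  r <- if (tail == "negative") sum(null_medians <= obs) else
    sum(null_medians >= obs)
  p <- (r + 1) / (n_resample + 1)
  structure(list(observed = obs, tail = tail, p = p,
                 p_bonferroni = bonferroni(p, m),
                 n_target_windows = k, n_null = length(null$values)),
            class = "selection_test")
}

#' @export
print.selection_test <- function(x, ...) {
  cat(sprintf("selection_test: median = %.4f (%s tail), p = %.4g, Bonferroni p = %.4g (%d windows vs %d null values)\n",
              x$observed, x$tail, x$p, x$p_bonferroni,
              x$n_target_windows, x$n_null))
  invisible(x)
}

#' Simulate null distributions of Tajima's D and Fay and Wu's H
#'
#' Runs `n_replicates` x `windows_per_replicate` independent coalescent
#' windows under the demographic model and computes per-window D and H.
#' Windows with S = 0 are dropped with a logged count — the statistics are
#' undefined there.
#'
#' @param model a [demog_model()].
#' @param n_replicates number of replicates.
#' @param windows_per_replicate windows simulated per replicate (each an
#'   independent genealogy; within-window recombination is not modelled).
#' @param window_size window size in bp.
#' @param seed integer seed.
#' @return list with `d` and `h` ([null_distribution()]s), and `windows`
#'   (data.frame of all per-window statistics).
#' @export
simulate_null_distribution <- function(model, n_replicates,
                                       windows_per_replicate = 1,
                                       window_size = 2000, seed = NULL) {
  stopifnot(inherits(model, "demog_model"))
  if (!is.null(seed)) set.seed(seed)
  total <- n_replicates * windows_per_replicate
  dd <- numeric(total); hh <- numeric(total); ss <- integer(total)
  for (i in seq_len(total)) {
    rep_i <- simulate_coalescent(model, window_size)
    sp <- sfs(rep_i$haplotypes)
    ss[i] <- sp$S
    dd[i] <- if (sp$n >= 4) tajima_d(sp$spectrum, sp$n) else NA_real_
    hh[i] <- fay_wu_h(sp$spectrum, sp$n)
  }
  n_zero <- sum(ss == 0)
  if (n_zero > 0)
    message(n_zero, " null windows with S = 0 dropped")
  prov <- sprintf("model:%dpop;reps:%d;win:%d", nrow(model$populations),
                  n_replicates, window_size)
  list(
    d = null_distribution(dd[!is.na(dd)], "tajima_d", "simulation", prov),
    h = null_distribution(hh[!is.na(hh)], "faywu_h", "simulation", prov),
    windows = data.frame(S = ss, tajima_d = dd, faywu_h = hh)
  )
}

#' Bonferroni correction
#'
#' @param p p-value in (0, 1].
#' @param m number of tests (>= 1).
#' @return min(1, m * p).
#' @export
bonferroni <- function(p, m) {
  if (m < 1) stop("m must be >= 1")
  if (any(p <= 0 | p > 1)) stop("p must be in (0, 1]")
  pmin(1, m * p)
}

#' Joint quadrant comparison of (D, H) pairs against a simulated cloud
#'
#' Computes the fraction of observed (D, H) window pairs falling in a sign
#' quadrant (default D < 0 and H < 0, the joint positive-selection
#' signature), the same fraction for the simulated cloud, and an add-one
#' empirical p-value for observing at least the observed fraction among
#' same-size draws (with replacement) from the simulated pairs.
#'
#' @param observed data.frame/matrix with columns D and H (one row per
#'   window; NAs dropped pairwise).
#' @param simulated same layout for the simulated null cloud.
#' @param quadrant two-element character vector of signs for (D, H), each
#'   `"neg"` or `"pos"`; `c("any", "any")` covers the whole plane.
#' @param n_resample resampling draws for the p-value.
#' @param seed integer seed.
#' @return list with `frac_observed`, `frac_simulated`, `p`, `n_observed`.
#' @export
joint_dh_comparison <- function(observed, simulated,
                                quadrant = c("neg", "neg"),
                                n_resample = 10000, seed = NULL) {
  obs <- as.matrix(observed)[, 1:2, drop = FALSE]
  sim <- as.matrix(simulated)[, 1:2, drop = FALSE]
  obs <- obs[stats::complete.cases(obs), , drop = FALSE]
  sim <- sim[stats::complete.cases(sim), , drop = FALSE]
  if (nrow(obs) == 0) stop("need >= 1 observed (D, H) pair")
  if (nrow(sim) == 0) stop("empty simulated cloud")
  if (!is.null(seed)) set.seed(seed)
  in_quad <- function(m) {
    keep <- rep(TRUE, nrow(m))
    for (j in 1:2) {
      keep <- keep & switch(quadrant[j],
                            neg = m[, j] < 0,
                            pos = m[, j] > 0,
                            any = TRUE,
                            stop("quadrant sign must be neg/pos/any"))
    }
    mean(keep)
  }
  f_obs <- in_quad(obs)
  f_sim_flags <- {
    keep <- rep(TRUE, nrow(sim))
    for (j in 1:2) {
      keep <- keep & switch(quadrant[j], neg = sim[, j] < 0,
                            pos = sim[, j] > 0, any = TRUE)
    }
    keep
  }
  k <- nrow(obs)
  r <- sum(vapply(seq_len(n_resample), function(i) {
    mean(sample(f_sim_flags, k, replace = TRUE)) >= f_obs
  }, logical(1)))
  list(frac_observed = f_obs, frac_simulated = mean(f_sim_flags),
       p = (r + 1) / (n_resample + 1), n_observed = k)
}

#' Load a genome-background null from a window-statistics TSV
#'
#' Accepts any TSV with a column named after the statistic (e.g. the
#' output of [windowed_stats()] written with `write.table`), for use as a
#' genome-wide empirical background.
#'
#' @param path TSV path.
#' @param statistic column name to extract.
#' @return a [null_distribution()] with source `"genome_background"`.
#' @export
read_background_null <- function(path, statistic = "tajima_d") {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!statistic %in% names(df))
    stop("no column '", statistic, "' in ", path)
  null_distribution(df[[statistic]], statistic, "genome_background",
                    provenance = path)
}
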