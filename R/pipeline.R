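#' Run the synthetic end-to-end analysis pipeline
#'
#' Chains the stages on self-generated data: coalescent simulation of
#' target and null windows, per-window selection statistics, the
#' empirical window-set tests, the copy-number differentiation stage, the
#' identity-profile/IGC stage and haplotype clustering. Writes TSV/JSON
#' results plus a provenance manifest (config, seed) into `out_dir`.
#'
#' Config fields (all optional except `seed`): `window_size` (bp, default
#' 2000), `n_windows` (target windows, default 10), `n_haplotypes`
#' (default 20), `ne` (default 10000), `mutation_rate` (default chosen so
#' that theta = 10 per window), `n_null` (null windows, default 1000),
#' `n_resample` (default 999), `seed` (integer, required), plus optional
#' stage switches `run_cn`, `run_igc`, `run_clustering` (default TRUE).
#'
#' @param config named list (or path to a YAML file with the same fields).
#' @param out_dir output directory, created if needed.
#' @return named list of result objects, invisibly; files are the primary
#'   output.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config$seed is mandatory")
  cfg <- utils::modifyList(list(
    window_size = 2000, n_windows = 10, n_haplotypes = 20, ne = 10000,
    mutation_rate = NULL, n_null = 1000, n_resample = 999,
    run_cn = TRUE, run_igc = TRUE, run_clustering = TRUE
  ), config)
  if (is.null(cfg$mutation_rate))
    cfg$mutation_rate <- 10 / (4 * cfg$ne * cfg$window_size)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  model <- constant_size_model(cfg$n_haplotypes, cfg$ne,
                               mutation_rate = cfg$mutation_rate)

  results$target <- stage("windowed_stats", {
    rows <- lapply(seq_len(cfg$n_windows), function(i) {
      r <- simulate_coalescent(model, cfg$window_size)
      sp <- sfs(r$haplotypes)
      data.frame(window = i, S = sp$S,
                 pi = theta_pi(sp$spectrum, sp$n),
                 theta_w = theta_w(sp$spectrum, sp$n),
                 theta_h = theta_h(sp$spectrum, sp$n),
                 tajima_d = tajima_d(sp$spectrum, sp$n),
                 faywu_h = fay_wu_h(sp$spectrum, sp$n))
    })
    do.call(rbind, rows)
  })
  utils::write.table(results$target, file.path(out_dir, "target_windows.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  results$null <- stage("null_simulation",
    simulate_null_distribution(model, cfg$n_null,
                               window_size = cfg$window_size))
  utils::write.table(results$null$windows,
                     file.path(out_dir, "null_windows.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  results$test_d <- stage("selection_test_d",
    empirical_p_windowset(results$target$tajima_d, results$null$d,
                          tail = "negative", n_resample = cfg$n_resample))
  results$test_h <- stage("selection_test_h",
    empirical_p_windowset(results$target$faywu_h, results$null$h,
                          tail = "negative", n_resample = cfg$n_resample))

  if (isTRUE(cfg$run_cn)) {
    results$cn <- stage("cn_analysis", {
      am <- list(popA = c("1" = 0.2, "2" = 0.6, "3" = 0.2),
                 popB = c("1" = 0.7, "2" = 0.3))
      cnm <- simulate_cn_genotypes(am, c(popA = 40, popB = 40))
      list(vst = vst(cnm, 1, "popA", "popB"),
           test = cn_differentiation_test(cnm, 1, "popA", "popB",
                                          n_perm = 999))
    })
  }

  if (isTRUE(cfg$run_igc)) {
    results$igc <- stage("igc_detection", {
      pair <- plant_igc(20000, divergence = 0.02, tract = c(5000, 12000))
      prof <- identity_profile(pair$donor, pair$acceptor)
      list(tracts = detect_igc_tracts(prof), truth = pair$truth)
    })
    utils::write.table(cbind(chrom = "alignment", results$igc$tracts),
                       file.path(out_dir, "igc_tracts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (isTRUE(cfg$run_clustering)) {
    results$clustering <- stage("hap_clustering", {
      m <- two_group_model(n_modern = 30, n_archaic = 8,
                           ne_modern = cfg$ne, ne_archaic = cfg$ne / 5,
                           t_split = 12 * cfg$ne, t_archaic = cfg$ne / 10,
                           mutation_rate = cfg$mutation_rate)
      r <- simulate_two_group_model(m, cfg$window_size * 5)
      pca <- haplotype_pca(r$haplotypes)
      cl <- choose_k(pca$scores[, seq_len(pca$n_informative), drop = FALSE],
                     k_max = 8)
      list(model = cl,
           heterozygosity = haplotype_heterozygosity(cl$assignment),
           populations = r$haplotypes$populations)
    })
    utils::write.table(
      data.frame(haplotype = seq_along(results$clustering$model$assignment),
                 population = results$clustering$populations,
                 cluster = results$clustering$model$assignment),
      file.path(out_dir, "cluster_assignments.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  summary <- list(
    selection = list(
      tajima_d = list(median = results$test_d$observed, p = results$test_d$p),
      faywu_h = list(median = results$test_h$observed, p = results$test_h$p)
    ),
    cn = if (!is.null(results$cn))
      list(vst = results$cn$vst$vst, p = results$cn$test$p),
    igc = if (!is.null(results$igc))
      list(n_tracts = nrow(results$igc$tracts)),
    clustering = if (!is.null(results$clustering))
      list(k = results$clustering$model$k,
           heterozygosity = results$clustering$heterozygosity)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(list(config = cfg, package = "sdpopgen",
                            r_version = as.character(getRversion())),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
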