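# Three well-separated Gaussian blobs in 2D, used by several tests.
make_blobs <- function(n_per = 30, sd = 0.3, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6))
  scores <- do.call(rbind, lapply(1:3, function(i) {
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))
  }))
  list(scores = scores, truth = rep(1:3, each = n_per))
}

test_that("genotype encoding polarizes against the outgroup and drops mismatches", {
  gt <- rbind(c("0|1", "1|1"),
              c("0|0", "0|1"),
              c("1|0", "0|0"),
              c("0|1", "1|0"))
  ref <- c("A", "C", "G", "T")
  alt <- c("T", "G", "A", "C")
  outgroup <- data.frame(pos = c(100, 200, 300, 400),
                         allele = c("A", "G", "G", "X"))
  # site 1: ancestral = REF, dosage kept; site 2: ancestral = ALT, flipped;
  # site 4: outgroup matches neither allele -> dropped
  expect_message(
    x <- encode_haplotypes(gt, ref, alt, pos = c(100, 200, 300, 400),
                           outgroup = outgroup,
                           populations = c("a", "b")),
    "1 sites dropped"
  )
  expect_equal(attr(x, "n_dropped"), 1)
  expect_equal(x$positions, c(100L, 200L, 300L))
  expect_equal(x$populations, c("a", "a", "b", "b"))
  # sample1 haps: site1 0,1; site2 flipped from 0,0 -> 1,1; site3 1,0
  expect_equal(unname(x$entries[1:2, ]), rbind(c(0L, 1L, 1L), c(1L, 1L, 0L)))
  # sample2 haps: site1 1,1; site2 flipped 0,1 -> 1,0; site3 0,0
  expect_equal(unname(x$entries[3:4, ]), rbind(c(1L, 1L, 0L), c(1L, 0L, 0L)))
  expect_true(x$polarized)

  expect_error(
    encode_haplotypes(matrix("0/1", 1, 1), "A", "T", 1,
                      data.frame(pos = 1, allele = "A")),
    "unphased"
  )
})

test_that("LD pruning keeps one copy of duplicated columns", {
  set.seed(5)
  col <- rbinom(20, 1, 0.5)
  other <- rbinom(20, 1, 0.5)
  x <- hap_matrix(cbind(col, col, other, col),
                  positions = c(10, 20, 30, 40))
  pruned <- ld_prune(x, r2_threshold = 0.99)
  # the three identical columns (r2 = 1) collapse to the first
  expect_equal(pruned$positions, c(10L, 30L))

  # a window shorter than the duplicate spacing disables pruning
  expect_equal(n_sites(ld_prune(x, r2_threshold = 0.99, window = 5)), 4)

  # 3-site toy: site B in strong LD with A, site C independent
  a <- rep(c(0, 1), each = 10)
  b <- a; b[1] <- 1  # r2 with a is high but < 1
  cc <- rep(c(0, 1), 10)
  y <- hap_matrix(cbind(a, b, cc), positions = c(1, 2, 3))
  r2_ab <- ld_pair(y, 1, 2)$r2
  expect_gt(r2_ab, 0.4)
  got <- ld_prune(y, r2_threshold = 0.4)
  expect_equal(got$positions, c(1L, 3L))
  # with a threshold above the observed r2, nothing is pruned
  expect_equal(n_sites(ld_prune(y, r2_threshold = 0.99)), 3)

  expect_error(ld_prune(y, r2_threshold = 0), "r2_threshold")
})

test_that("haplotype PCA matches an eigendecomposition oracle", {
  set.seed(7)
  m <- matrix(rbinom(30 * 12, 1, 0.4), nrow = 30)
  m <- m[, colSums(m) > 0 & colSums(m) < 30, drop = FALSE]
  x <- hap_matrix(m, positions = seq_len(ncol(m)))
  p <- haplotype_pca(x)

  mc <- scale(m, center = TRUE, scale = FALSE)
  eg <- eigen(mc %*% t(mc), symmetric = TRUE)
  n_pos <- sum(eg$values > 1e-9)
  # variance fractions agree
  expect_equal(p$var_frac[seq_len(n_pos)],
               (eg$values / sum(eg$values))[seq_len(n_pos)],
               tolerance = 1e-9)
  expect_equal(sum(p$var_frac), 1, tolerance = 1e-12)
  # scores agree up to per-component sign
  for (j in seq_len(n_pos)) {
    ev <- eg$vectors[, j] * sqrt(eg$values[j])
    expect_true(
      isTRUE(all.equal(p$scores[, j], ev, tolerance = 1e-6)) ||
        isTRUE(all.equal(p$scores[, j], -ev, tolerance = 1e-6))
    )
  }
  # n_informative is the smallest PC count explaining > 90%
  cum <- cumsum(p$var_frac)
  expect_gt(cum[p$n_informative], 0.9)
  if (p$n_informative > 1) expect_lte(cum[p$n_informative - 1], 0.9)

  # reconstruction: scores %*% t(loadings) recovers the centered matrix
  expect_equal(p$scores %*% t(p$loadings), unname(mc),
               ignore_attr = TRUE, tolerance = 1e-9)

  expect_error(haplotype_pca(hap_matrix(matrix(c(1, 1, NA, 1), 2, 2),
                                        positions = 1:2)), "complete")
  expect_error(haplotype_pca(hap_matrix(rbind(c(0, 1), c(0, 1)),
                                        positions = 1:2)), "identical")
})

test_that("the WSS elbow rule picks k as specified", {
  bl <- make_blobs()
  # infinite delta: the first drop is always below it, so k = 1
  cm1 <- choose_k(bl$scores, k_max = 6, delta = Inf, seed = 1)
  expect_equal(cm1$k, 1)
  expect_equal(cm1$assignment, rep(1L, nrow(bl$scores)))

  cm <- choose_k(bl$scores, k_max = 8, seed = 2)
  # WSS trace is non-increasing and starts at the total sum of squares
  expect_true(all(diff(cm$wss) <= 1e-8))
  expect_equal(cm$wss[1], sum(scale(bl$scores, scale = FALSE)^2))
  # three separated blobs -> k = 3
  expect_equal(cm$k, 3)
  expect_equal(rand_index(cm$assignment, bl$truth), 1)

  # delta default is 0.5% of WSS(1)
  expect_equal(cm$delta, 0.005 * cm$wss[1])

  expect_error(choose_k(matrix(c(1, NA), 2, 1)), "non-finite")
})

test_that("blob recovery at k = 3 is reliable across seeds", {
  ok <- 0
  for (s in 1:30) {
    bl <- make_blobs(n_per = 20, sd = 0.4, seed = s)
    cm <- choose_k(bl$scores, k_max = 6, seed = s + 100)
    if (cm$k == 3 && rand_index(cm$assignment, bl$truth) > 0.99)
      ok <- ok + 1
  }
  expect_gte(ok, 29)
})

test_that("haplotype heterozygosity matches its closed form", {
  # frequencies 0.5 / 0.3 / 0.2 over n = 10
  a <- rep(c("x", "y", "z"), c(5, 3, 2))
  raw <- 1 - (0.5^2 + 0.3^2 + 0.2^2)
  expect_equal(haplotype_heterozygosity(a, corrected = FALSE), raw,
               tolerance = 1e-12)
  expect_equal(haplotype_heterozygosity(a), raw * 10 / 9,
               tolerance = 1e-12)
  # limits: a single class gives 0, all-distinct gives 1 (corrected)
  expect_equal(haplotype_heterozygosity(rep("a", 6)), 0)
  expect_equal(haplotype_heterozygosity(letters[1:6]), 1, tolerance = 1e-12)
  expect_error(haplotype_heterozygosity("a"), ">= 2")
})

test_that("homogeneity permutation matches closed forms", {
  # with replacement: pool half/half, m = 2 -> P(single class) = 0.5^2 * 2
  pool <- rep(c(1, 2), each = 50)
  g <- homogeneity_permutation(pool, m = 2, n_perm = 40000, seed = 1,
                               mode = "with_replacement")
  expect_equal(g$p, 0.5, tolerance = 4 * sqrt(0.25 / 40000) + 1e-3)

  # m = 3, frequencies 0.25 / 0.75: sum p_c^3 = 0.4375
  pool2 <- rep(c(1, 2), c(25, 75))
  g2 <- homogeneity_permutation(pool2, m = 3, n_perm = 40000, seed = 2,
                                mode = "with_replacement")
  exact <- 0.25^3 + 0.75^3
  expect_equal(g2$p, exact, tolerance = 4 * sqrt(exact * (1 - exact) / 40000) + 1e-3)

  # without replacement: hypergeometric closed form
  # P(all m from one class) = sum_c C(n_c, m) / C(n, m)
  g3 <- homogeneity_permutation(pool2, m = 3, n_perm = 40000, seed = 3)
  exact3 <- (choose(25, 3) + choose(75, 3)) / choose(100, 3)
  expect_equal(g3$p, exact3,
               tolerance = 4 * sqrt(exact3 * (1 - exact3) / 40000) + 1e-3)

  # a single-class pool is trivially homogeneous: p = 1 exactly
  expect_equal(homogeneity_permutation(rep(1, 30), m = 5)$p, 1)

  expect_error(homogeneity_permutation(pool, m = 200), "exceeds")
  expect_error(homogeneity_permutation(pool, m = 0), "m must be")
})

test_that("two diverged groups separate on PC1 and cluster cleanly", {
  # Two populations with an old split; a single non-recombining genealogy
  # can be dominated by deep within-group coalescences, so concatenate
  # several independent loci (as recombining data would provide) before
  # the PCA.
  model <- two_group_model(n_modern = 12, n_archaic = 12,
                           ne_modern = 10000, ne_archaic = 10000,
                           t_split = 60000, t_archaic = 100,
                           mutation_rate = 1e-8)
  reps <- lapply(1:8, function(i) simulate_coalescent(model, 5000,
                                                      seed = 2100 + i))
  ent <- do.call(cbind, lapply(reps, function(r) r$haplotypes$entries))
  x <- hap_matrix(ent, positions = seq_len(ncol(ent)),
                  populations = reps[[1]]$haplotypes$populations)
  x <- maf_filter(x, 0.05)
  p <- haplotype_pca(x)
  truth <- as.integer(factor(x$populations))
  km2 <- stats::kmeans(p$scores[, 1], centers = 2, nstart = 10)
  expect_gt(rand_index(km2$cluster, truth), 0.9)
  # the elbow rule finds at least the two population clusters
  sc <- p$scores[, seq_len(p$n_informative), drop = FALSE]
  cm <- choose_k(sc, k_max = 6, seed = 4)
  expect_gte(cm$k, 2)
})
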