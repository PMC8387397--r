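test_that("window tiling follows the half-window retention rule", {
  w <- window_partition(data.frame(chrom = "c", start = 0, end = 20000), 2000)
  expect_equal(nrow(w), 10)
  expect_equal(w$start, seq(0, 18000, by = 2000))
  expect_equal(w$end, seq(2000, 20000, by = 2000))

  # terminal partial window of exactly half the size is retained
  w <- window_partition(data.frame(chrom = "c", start = 0, end = 5000), 2000)
  expect_equal(nrow(w), 3)
  expect_equal(w$end[3], 5000)

  # a shorter tail is merged into the previous window
  w <- window_partition(data.frame(chrom = "c", start = 0, end = 4900), 2000)
  expect_equal(nrow(w), 2)
  expect_equal(w$end[2], 4900)

  # a region shorter than one window still yields one window
  w <- window_partition(data.frame(chrom = "c", start = 0, end = 1500), 2000)
  expect_equal(nrow(w), 1)

  # three-region layout: 20 kb + 12 kb + 20 kb at 2 kb windows
  regs <- data.frame(chrom = "chr7",
                     start = c(0, 100000, 200000),
                     end = c(20000, 112000, 220000))
  expect_equal(nrow(window_partition(regs, 2000)), 26)

  expect_error(window_partition(regs, 0), "window_size")
})

test_that("the spectrum is the per-site derived-count histogram", {
  # single site with derived count 3 of n = 6
  m <- hap_matrix(matrix(c(1, 1, 1, 0, 0, 0), ncol = 1), positions = 5)
  sp <- sfs(m)
  expect_equal(sp$spectrum, c(0, 0, 1, 0, 0))
  expect_equal(sp$S, 1)

  # monomorphic window
  m0 <- hap_matrix(matrix(0, 4, 2), positions = c(1, 2))
  expect_equal(sfs(m0)$spectrum, c(0, 0, 0))

  # fixed-derived sites are excluded from S but reported
  mf <- hap_matrix(cbind(c(1, 1, 1, 1), c(1, 0, 0, 0)), positions = c(1, 2))
  spf <- sfs(mf)
  expect_equal(spf$S, 1)
  expect_equal(spf$fixed_derived, 1)

  # random matrices: spectrum equals a direct column-sum histogram
  set.seed(1)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    x <- random_hap_matrix(n, 20)
    dc <- colSums(x$entries)
    dc <- dc[dc > 0 & dc < n]
    expect_equal(sfs(x)$spectrum, tabulate(dc, n - 1))
  }

  # unpolarized input is refused
  up <- hap_matrix(matrix(c(0, 1), 2, 1), positions = 1, polarized = FALSE)
  expect_error(sfs(up), "polarized")
})

test_that("D and H match brute-force oracles on random small instances", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(4:8, 1)
    x <- random_hap_matrix(n, 20)
    sp <- sfs(x)
    expect_equal(theta_pi(sp$spectrum, n),
                 brute_pi(x$entries[, colSums(x$entries) < n, drop = FALSE]),
                 tolerance = 1e-12)
    expect_equal(theta_w(sp$spectrum, n), brute_theta_w(x$entries),
                 tolerance = 1e-12)
    expect_equal(theta_h(sp$spectrum, n), brute_theta_h(x$entries),
                 tolerance = 1e-12)
    expect_equal(tajima_d(sp$spectrum, n), brute_tajima_d(x$entries),
                 tolerance = 1e-12)
    expect_equal(fay_wu_h(sp$spectrum, n), brute_faywu_h(x$entries),
                 tolerance = 1e-12)
  }
})

test_that("D and H have the expected sign and missingness behaviour", {
  n <- 10
  expect_true(is.na(tajima_d(rep(0L, n - 1), n)))
  expect_true(is.na(fay_wu_h(rep(0L, n - 1), n)))
  expect_error(tajima_d(c(1, 0), 3), "n >= 4")
  expect_error(fay_wu_h(rep(0L, n), n), "length n - 1")

  # all singletons -> negative D
  spec <- c(12, rep(0L, n - 2))
  expect_lt(tajima_d(spec, n), 0)
  # high-frequency derived alleles -> negative H
  spec <- c(rep(0L, n - 2), 8)
  expect_lt(fay_wu_h(spec, n), 0)
})

test_that("D and H are invariant under haplotype permutation", {
  set.seed(7)
  x <- random_hap_matrix(8, 15)
  sp1 <- sfs(x)
  xp <- subset_haplotypes(x, sample(1:8))
  sp2 <- sfs(xp)
  expect_equal(tajima_d(sp1$spectrum, 8), tajima_d(sp2$spectrum, 8))
  expect_equal(fay_wu_h(sp1$spectrum, 8), fay_wu_h(sp2$spectrum, 8))
})

test_that("windowed statistics compose and handle per-window missingness", {
  set.seed(9)
  m <- constant_size_model(12, 10000, mutation_rate = 2.5e-7)
  r <- simulate_coalescent(m, 8000, seed = 4)
  x <- r$haplotypes
  wins <- window_partition(data.frame(chrom = "sim", start = 0, end = 8000),
                           2000)
  ws <- windowed_stats(x, wins)
  expect_equal(nrow(ws), 4)
  # restricting the matrix to one window reproduces that window's stats
  w2 <- subset_window(x, wins$start[2], wins$end[2])
  sp <- sfs(w2)
  expect_equal(ws$tajima_d[2], tajima_d(sp$spectrum, sp$n))
  expect_equal(ws$faywu_h[2], fay_wu_h(sp$spectrum, sp$n))

  # a haplotype with a missing call in one window is dropped there only
  x$entries[3, which(x$positions > wins$start[1] &
                       x$positions <= wins$end[1])[1]] <- NA
  ws2 <- windowed_stats(x, wins)
  expect_equal(ws2$n[1], 11)
  expect_equal(ws2$n[2], 12)
  expect_equal(ws2$tajima_d[2], ws$tajima_d[2])

  expect_error(windowed_stats(x, wins[0, ]), "empty window")
})

test_that("Thomson's estimator follows its closed form and recovers tmrca", {
  # every haplotype carrying exactly 2 derived alleles forces T = 2/(mu L)
  m <- hap_matrix(rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1)),
                  positions = c(10, 20, 30))
  res <- thomson_tmrca(m, mu = 1e-6, length = 1000)
  expect_equal(res$tmrca_generations, 2 / (1e-6 * 1000))
  expect_equal(res$d, c(2, 2, 2))

  # no derived alleles -> 0
  m0 <- hap_matrix(matrix(0, 3, 1), positions = 1)
  m0$entries <- m0$entries[, 0, drop = FALSE]; m0$positions <- integer(0)
  expect_equal(thomson_tmrca(m0, 1e-6, 1000)$tmrca_generations, 0)

  expect_error(thomson_tmrca(m, mu = 0, length = 1000), "mu")

  # fixed-derived sites count towards d_i
  mf <- hap_matrix(cbind(c(1, 1, 1), c(1, 0, 0)), positions = c(1, 2))
  expect_equal(thomson_tmrca(mf, 1e-3, 1000)$d, c(2, 1, 1))

  # simulation recovery: mean relative bias below 10% at n = 20
  mu <- 10 / (4 * 10000 * 2000)
  mod <- constant_size_model(20, 10000, mutation_rate = mu)
  set.seed(13)
  rel <- replicate(300, {
    r <- simulate_coalescent(mod, 2000)
    est <- thomson_tmrca(r$haplotypes, mu, 2000)$tmrca_generations
    (est - r$tmrca) / r$tmrca
  })
  expect_lt(abs(mean(rel)), 0.10)
})

test_that("LD measures match direct arithmetic and its invariances", {
  # two identical columns -> D' = 1, r2 = 1
  x <- hap_matrix(cbind(c(1, 1, 0, 0), c(1, 1, 0, 0)), positions = c(1, 2))
  r <- ld_pair(x, 1, 2)
  expect_equal(r$Dprime, 1)
  expect_equal(r$r2, 1)

  # exact linkage equilibrium -> D = 0
  a <- rep(c(1, 1, 0, 0), 25)
  b <- rep(c(1, 0, 1, 0), 25)
  xe <- hap_matrix(cbind(a, b), positions = c(1, 2))
  expect_equal(ld_pair(xe, 1, 2)$D, 0)

  # the 40/10/10/40 two-locus table against hand arithmetic
  a <- c(rep(1, 50), rep(0, 50))
  b <- c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40))
  xt <- hap_matrix(cbind(a, b), positions = c(1, 2))
  got <- ld_pair(xt, 1, 2)
  want <- brute_ld(a, b)
  expect_equal(got$D, want$D, tolerance = 1e-12)
  expect_equal(got$Dprime, want$Dprime, tolerance = 1e-12)
  expect_equal(got$r2, want$r2, tolerance = 1e-12)

  # invariance under simultaneous allele-label swap at both sites
  xs <- hap_matrix(cbind(1 - a, 1 - b), positions = c(1, 2))
  got2 <- ld_pair(xs, 1, 2)
  expect_equal(got2$Dprime, got$Dprime, tolerance = 1e-12)
  expect_equal(got2$r2, got$r2, tolerance = 1e-12)

  expect_error(ld_pair(hap_matrix(cbind(c(1, 1), c(1, 0)),
                                  positions = c(1, 2)), 1, 2),
               "polymorphic")
})

test_that("MAF filtering uses a strict threshold", {
  # site at exactly 10% MAF is removed
  m <- hap_matrix(cbind(c(1, rep(0, 9)), c(1, 1, rep(0, 8))),
                  positions = c(1, 2))
  f <- maf_filter(m, 0.10)
  expect_equal(n_sites(f), 1)
  expect_equal(f$positions, 2L)

  # threshold 0 removes only monomorphic sites
  mm <- hap_matrix(cbind(rep(1, 4), c(1, 0, 0, 0)), positions = c(1, 2))
  expect_equal(n_sites(maf_filter(mm, 0)), 1)

  expect_warning(maf_filter(m, 0.4), "every site")
  expect_error(maf_filter(m, 0.5), "threshold")
})

test_that("tagging SNVs are exactly the perfectly separating sites", {
  set.seed(3)
  base <- matrix(rbinom(8 * 10, 1, 0.5), 8, 10)
  # plant 4 separating sites between rows 1:4 and 5:8
  base[, c(2, 5, 7, 9)] <- rep(c(1, 1, 1, 1, 0, 0, 0, 0), 4)
  # ensure no accidental separators elsewhere
  base[1, c(1, 3, 4, 6, 8, 10)] <- 0
  base[5, c(1, 3, 4, 6, 8, 10)] <- 0
  x <- hap_matrix(base, positions = seq(10, 100, by = 10))
  got <- find_tagging_snvs(x, 1:4, 5:8)
  expect_equal(got, c(2, 5, 7, 9))
  # groups with identical content share every allele: no separator
  dup <- hap_matrix(rbind(base[1:4, ], base[1:4, ]),
                    positions = seq(10, 100, by = 10))
  expect_length(find_tagging_snvs(dup, 1:4, 5:8), 0)
  expect_error(find_tagging_snvs(x, 1:4, 4:8), "overlap")
  expect_error(find_tagging_snvs(x, integer(0), 5:8), "non-empty")
})

test_that("the derived-allele bootstrap matches exhaustive enumeration", {
  pool <- c(0, 2, 7)
  target <- c(2, 2)
  # exhaustive: all 3^2 equally likely draws of size 2 with replacement
  draws <- expand.grid(pool, pool)
  exact <- mean(rowMeans(draws) <= mean(target))
  got <- derived_allele_bootstrap(target, pool, n_boot = 40000, seed = 1)
  se <- sqrt(exact * (1 - exact) / 40000)
  expect_lt(abs(got$p - exact), 4 * se + 1 / 40001)

  # extreme target above the pool maximum
  ext <- derived_allele_bootstrap(c(100), pool, n_boot = 999, seed = 1,
                                  tail = "greater")
  expect_equal(ext$p, 1 / 1000)

  expect_error(derived_allele_bootstrap(1, numeric(0)), "empty")
})
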