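# Independent brute-force oracles used to pin the statistics code.
# These deliberately avoid the package's spectrum-based computation paths.

# mean pairwise differences summed over sites, by enumerating all C(n,2)
# haplotype pairs on the raw matrix
brute_pi <- function(m) {
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + sum(m[i, ] != m[j, ])
    }
  }
  tot / choose(n, 2)
}

brute_theta_w <- function(m) {
  n <- nrow(m)
  dc <- colSums(m)
  S <- sum(dc > 0 & dc < n)
  S / sum(1 / seq_len(n - 1))
}

brute_theta_h <- function(m) {
  n <- nrow(m)
  dc <- colSums(m)
  dc <- dc[dc > 0 & dc < n]
  sum(2 * dc^2 / (n * (n - 1)))
}

brute_tajima_d <- function(m) {
  n <- nrow(m)
  dc <- colSums(m)
  S <- sum(dc > 0 & dc < n)
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  seg <- m[, dc > 0 & dc < n, drop = FALSE]
  (brute_pi(seg) - S / a1) /
    sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

brute_faywu_h <- function(m) {
  n <- nrow(m)
  dc <- colSums(m)
  seg <- m[, dc > 0 & dc < n, drop = FALSE]
  if (ncol(seg) == 0) return(NA_real_)
  brute_pi(seg) - brute_theta_h(m)
}

# direct 2x2-table LD arithmetic from haplotype vectors
brute_ld <- function(a, b) {
  n <- length(a)
  pa <- sum(a) / n; pb <- sum(b) / n
  pab <- sum(a == 1 & b == 1) / n
  D <- pab - pa * pb
  dmax <- if (D >= 0) min(pa * (1 - pb), (1 - pa) * pb) else
    min(pa * pb, (1 - pa) * (1 - pb))
  list(D = D, Dprime = D / dmax,
       r2 = D^2 / (pa * (1 - pa) * pb * (1 - pb)))
}

brute_vst <- function(va, vb) {
  pv <- function(x) sum((x - mean(x))^2) / length(x)
  vt <- pv(c(va, vb))
  vs <- (length(va) * pv(va) + length(vb) * pv(vb)) / (length(va) + length(vb))
  if (vt == 0) 0 else (vt - vs) / vt
}

# random polarized matrix with given haplotype count and up to max_s
# polymorphic sites (plus occasional fixed-derived columns)
random_hap_matrix <- function(n, max_s, allow_fixed = TRUE) {
  s <- sample.int(max_s, 1)
  cols <- lapply(seq_len(s), function(j) {
    hi <- if (allow_fixed && stats::runif(1) < 0.1) n else
      sample.int(n - 1, 1)
    sample(c(rep(1L, hi), rep(0L, n - hi)))
  })
  m <- do.call(cbind, cols)
  hap_matrix(m, positions = seq_len(s) * 10L)
}

sample_skewness <- function(x) {
  mean((x - mean(x))^3) / stats::sd(x)^3
}

rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}
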