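#' Simulate population-structured diploid copy-number genotypes
#'
#' Diploid copy numbers at a duplicated cassette are modelled as the sum of
#' two independently drawn haploid cassette-count alleles, with per-
#' population haploid class frequencies. An ancestral-like population fixed
#' for one cassette per haplotype (class frequencies `{1: 1}`) yields every
#' sample at diploid copy number 2, the state observed in archaic hominins
#' and nonhuman apes at such loci.
#'
#' @param allele_model named list: one element per population, each a named
#'   numeric vector mapping haploid cassette count (as name, integer >= 0)
#'   to frequency; frequencies must sum to 1 (tolerance 1e-9).
#' @param n_samples integer vector (recycled/named per population) of
#'   diploid sample counts.
#' @param seed integer seed.
#' @return a [cn_matrix()] with one locus column `locus1`.
#' @export
#' @examples
#' am <- list(ARC = c("1" = 1), HUM = c("1" = 0.3, "2" = 0.5, "3" = 0.2))
#' cn <- simulate_cn_genotypes(am, n_samples = c(ARC = 4, HUM = 30), seed = 1)
#' table(cn$populations, cn$values[, 1])
simulate_cn_genotypes <- function(allele_model, n_samples, seed = NULL) {
  if (length(allele_model) < 1) stop("need >= 1 population")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(n_samples)))
    names(n_samples) <- names(allele_model)
  vals <- integer(0); pops <- character(0)
  for (p in names(allele_model)) {
    freqs <- allele_model[[p]]
    if (length(freqs) == 0) stop("empty haploid class map for ", p)
    if (abs(sum(freqs) - 1) > 1e-9)
      stop("haploid class frequencies for ", p, " do not sum to 1")
    classes <- as.integer(names(freqs))
    if (any(is.na(classes)) || any(classes < 0))
      stop("haploid class counts must be non-negative integers")
    n <- n_samples[[p]]
    hap1 <- sample(classes, n, replace = TRUE, prob = freqs)
    hap2 <- sample(classes, n, replace = TRUE, prob = freqs)
    vals <- c(vals, hap1 + hap2)
    pops <- c(pops, rep(p, n))
  }
  cn_matrix(matrix(vals, ncol = 1, dimnames = list(NULL, "locus1")),
            populations = pops)
}

#' Construct a copy-number matrix
#'
#' @param values numeric matrix, samples x loci, of diploid copy-number
#'   estimates (non-negative; read-depth genotypes may be non-integer).
#' @param populations population label per sample.
#' @param loci optional data.frame (chrom, start, end, 1-based inclusive)
#'   with one row per locus.
#' @return object of class `cn_matrix`.
#' @export
cn_matrix <- function(values, populations, loci = NULL) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("copy numbers must be non-negative")
  if (length(populations) != nrow(values))
    stop("one population label per sample required")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("locus", seq_len(ncol(values)))
  structure(list(values = values, populations = as.character(populations),
                 loci = loci),
            class = "cn_matrix")
}

#' @export
print.cn_matrix <- function(x, ...) {
  cat(sprintf("cn_matrix: %d samples x %d loci (%d populations)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$populations))))
  invisible(x)
}

#' Read / write a copy-number matrix as TSV
#'
#' Layout: header `sample`, `population`, then one column per locus.
#'
#' @param path file path.
#' @return [cn_matrix()] for the reader; `path` invisibly for the writer.
#' @export
read_cn_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  cn_matrix(as.matrix(df[, -(1:2), drop = FALSE]),
            populations = df$population)
}

#' @rdname read_cn_tsv
#' @param x a `cn_matrix`.
#' @export
write_cn_tsv <- function(x, path) {
  df <- data.frame(sample = paste0("sample", seq_len(nrow(x$values))),
                   population = x$populations, check.names = FALSE)
  df <- cbind(df, as.data.frame(x$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a diverged duplicate sequence pair with a planted IGC tract
#'
#' Two paralogous sequences are generated at a given background divergence
#' (mismatches placed independently per site), then an interlocus
#' gene-conversion event is emulated by copying the donor over the acceptor
#' inside the tract, leaving the pair 100% identical there. The truth
#' coordinates are returned for detector-recovery tests.
#'
#' @param seq_length alignment length in bp (no indels are introduced, so
#'   sequence and alignment coordinates coincide).
#' @param divergence per-bp substitution probability outside the tract, in
#'   `[0, 1]`.
#' @param tract integer vector `c(start, end)`, 1-based inclusive, or NULL
#'   for a pure-divergence negative control.
#' @param seed integer seed.
#' @return list with `donor`, `acceptor` (character scalars, A/C/G/T),
#'   and `truth` (data.frame start/end, or NULL).
#' @export
#' @examples
#' pair <- plant_igc(2000, divergence = 0.02, tract = c(500, 1500), seed = 1)
#' substr(pair$donor, 500, 520) == substr(pair$acceptor, 500, 520)
plant_igc <- function(seq_length, divergence, tract = NULL, seed = NULL) {
  if (seq_length < 1) stop("seq_length must be >= 1")
  if (divergence < 0 || divergence > 1)
    stop("divergence must be in [0, 1]")
  if (!is.null(tract)) {
    if (length(tract) != 2 || tract[1] < 1 || tract[2] > seq_length ||
        tract[1] > tract[2])
      stop("tract must lie within the sequence")
  }
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  donor <- sample(bases, seq_length, replace = TRUE)
  acceptor <- donor
  mism <- stats::runif(seq_length) < divergence
  if (any(mism)) {
    # substitute with a uniformly drawn different base
    acceptor[mism] <- vapply(donor[mism], function(b) {
      sample(setdiff(bases, b), 1)
    }, "")
  }
  if (!is.null(tract)) {
    idx <- tract[1]:tract[2]
    acceptor[idx] <- donor[idx]
  }
  list(donor = paste(donor, collapse = ""),
       acceptor = paste(acceptor, collapse = ""),
       truth = if (is.null(tract)) NULL else
         data.frame(start = tract[1], end = tract[2]))
}
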