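#' Simulate a coalescent genealogy with mutations under a demographic model
#'
#' Structured-coalescent simulation backwards in time with population
#' splits, piecewise-exponential size trajectories, backwards migration and
#' ancient (nonzero-time) sampling. Mutations follow the infinite-sites
#' model: Poisson-distributed on each branch with mean
#' branch length x mu x sequence length, placed uniformly and discretized
#' to unique integer positions (collisions resolved by rejection).
#'
#' Each call simulates a single non-recombining genealogy; windows of a
#' larger region are simulated as independent replicates.
#'
#' @param model a [demog_model()].
#' @param sequence_length simulated sequence length in bp (> 0).
#' @param seed integer seed; identical seed and model give identical output.
#' @param keep_tree also return the genealogy as newick text.
#' @return object of class `sim_replicate`: list with `haplotypes`
#'   (a [hap_matrix()]), `tmrca` (coalescent time of the full sample, in
#'   generations; 0 for a single haplotype) and `tree` (newick or NULL).
#' @export
#' @examples
#' m <- constant_size_model(n_haplotypes = 10, ne = 10000)
#' rep <- simulate_coalescent(m, sequence_length = 2000, seed = 1)
#' n_sites(rep$haplotypes)
simulate_coalescent <- function(model, sequence_length, seed = NULL,
                                keep_tree = FALSE) {
  stopifnot(inherits(model, "demog_model"))
  if (sequence_length <= 0) stop("sequence_length must be > 0")
  if (!is.null(seed)) set.seed(seed)

  gen <- simulate_genealogy(model)
  hm <- drop_mutations(gen, model$mutation_rate, sequence_length)
  structure(
    list(haplotypes = hm, tmrca = gen$tmrca,
         tree = if (keep_tree) genealogy_newick(gen) else NULL),
    class = "sim_replicate"
  )
}

#' @export
print.sim_replicate <- function(x, ...) {
  cat(sprintf("sim_replicate: %d haplotypes, %d segregating sites, tmrca = %.1f generations\n",
              n_haplotypes(x$haplotypes), n_sites(x$haplotypes), x$tmrca))
  invisible(x)
}

# Backwards-in-time structured coalescent. Waiting times to coalescence in
# an exponentially changing population use the closed-form inverse of the
# integrated hazard; migration is a competing constant-hazard process, so
# the minimum of the independently sampled candidate times has the correct
# law.
simulate_genealogy <- function(model) {
  pops <- model$populations$name
  npop <- length(pops)
  pstate <- list(
    active = stats::setNames(rep(TRUE, npop), pops),
    n_ref = stats::setNames(model$populations$size, pops),
    t_ref = stats::setNames(rep(0, npop), pops),
    growth = stats::setNames(model$populations$growth, pops)
  )
  mig <- matrix(0, npop, npop, dimnames = list(pops, pops))

  # expand sampling into leaf nodes; leaves numbered in sampling-row order
  samp <- model$sampling
  leaf_pop <- rep(samp$population, samp$n)
  leaf_time <- rep(samp$time, samp$n)
  n_leaf <- length(leaf_pop)
  n_nodes_max <- 2L * n_leaf - 1L
  node_time <- numeric(n_nodes_max)
  node_child <- vector("list", n_nodes_max)
  node_time[seq_len(n_leaf)] <- leaf_time
  next_node <- n_leaf + 1L

  # event queue: model events + one sampling event per distinct time
  queue <- lapply(model$events, function(e) e)
  for (tt in unique(leaf_time)) {
    queue[[length(queue) + 1L]] <- list(time = tt, kind = "sample",
                                        leaves = which(leaf_time == tt))
  }
  qt <- vapply(queue, `[[`, numeric(1), "time")
  queue <- queue[order(qt)]

  lin_node <- integer(0)   # active lineage -> node id
  lin_pop <- character(0)  # active lineage -> population
  t <- 0
  qi <- 1L

  repeat {
    t_next <- if (qi <= length(queue)) queue[[qi]]$time else Inf
    k_tot <- length(lin_node)
    if (k_tot <= 1L && qi > length(queue)) break

    # candidate coalescence per active population
    best_tau <- Inf; best_kind <- NA_character_; best_pop <- NA_character_
    if (k_tot >= 2L) {
      for (p in pops[pstate$active]) {
        k <- sum(lin_pop == p)
        if (k < 2L) next
        tau <- coal_waiting_time(k, pstate$n_ref[p], pstate$t_ref[p],
                                 pstate$growth[p], t)
        if (tau < best_tau) { best_tau <- tau; best_kind <- "coal"; best_pop <- p }
      }
    }
    # candidate migration (constant rates within the interval)
    if (k_tot >= 1L && any(mig > 0)) {
      rates <- vapply(lin_pop, function(p) sum(mig[p, ]), numeric(1))
      rtot <- sum(rates)
      if (rtot > 0) {
        tau <- stats::rexp(1, rtot)
        if (tau < best_tau) { best_tau <- tau; best_kind <- "mig" }
      }
    }

    if (t + best_tau < t_next) {
      t <- t + best_tau
      if (best_kind == "coal") {
        idx <- which(lin_pop == best_pop)
        pair <- if (length(idx) == 2L) idx else sample(idx, 2L)
        node <- next_node; next_node <- next_node + 1L
        node_time[node] <- t
        node_child[[node]] <- lin_node[pair]
        lin_node <- c(lin_node[-pair], node)
        lin_pop <- c(lin_pop[-pair], best_pop)
      } else {
        rates <- vapply(lin_pop, function(p) sum(mig[p, ]), numeric(1))
        l <- sample.int(length(lin_node), 1L, prob = rates)
        dest <- sample(pops, 1L, prob = mig[lin_pop[l], ])
        lin_pop[l] <- dest
      }
    } else {
      if (!is.finite(t_next))
        stop("genealogy failed to coalesce (model allows no further events)")
      t <- t_next
      ev <- queue[[qi]]; qi <- qi + 1L
      if (ev$kind == "sample") {
        lin_node <- c(lin_node, ev$leaves)
        lin_pop <- c(lin_pop, leaf_pop[ev$leaves])
      } else if (ev$kind == "split") {
        lin_pop[lin_pop == ev$derived] <- ev$ancestral
        pstate$active[ev$derived] <- FALSE
        mig[ev$derived, ] <- 0
        mig[, ev$derived] <- 0
      } else if (ev$kind == "size_change") {
        pstate$n_ref[ev$population] <- ev$size
        pstate$t_ref[ev$population] <- ev$time
        pstate$growth[ev$population] <- ev$growth %||% 0
      } else if (ev$kind == "migration_change") {
        mig[ev$from, ev$to] <- ev$rate
      }
    }
  }

  root <- if (n_leaf == 1L) 1L else next_node - 1L
  list(n_leaf = n_leaf, node_time = node_time[seq_len(next_node - 1L)],
       node_child = node_child[seq_len(next_node - 1L)],
       root = root, tmrca = if (n_leaf == 1L) 0 else node_time[root],
       leaf_pop = leaf_pop)
}

# Waiting time to the next coalescence among k lineages in a population of
# (backwards) size N(t) = n_ref * exp(-g * (t - t_ref)); inverse of the
# integrated hazard for an Exp(1) draw. Declining backward size (g < 0) can
# make coalescence escape to infinity, which the caller caps at the next
# demographic event.
coal_waiting_time <- function(k, n_ref, t_ref, g, t0) {
  a <- k * (k - 1) / (4 * n_ref)
  e <- stats::rexp(1)
  if (g == 0) return(e / a)
  b <- exp(g * (t0 - t_ref)) + g * e / a
  if (b <= 0) return(Inf)
  log(b) / g - (t0 - t_ref)
}

# Infinite-sites mutation dropping: Poisson mutations per branch, uniform
# placement, discretized to unique integer positions in 1..L.
drop_mutations <- function(gen, mu, L) {
  n <- gen$n_leaf
  n_nodes <- length(gen$node_time)
  # parent pointers from child lists
  parent <- rep(NA_integer_, n_nodes)
  for (v in seq_len(n_nodes)) {
    for (ch in gen$node_child[[v]]) parent[ch] <- v
  }
  # descendant leaves per node (children always have smaller ids)
  leafset <- vector("list", n_nodes)
  for (v in seq_len(n_nodes)) {
    leafset[[v]] <- if (v <= n) v else
      unlist(leafset[gen$node_child[[v]]], use.names = FALSE)
  }
  branch_nodes <- setdiff(seq_len(n_nodes), gen$root)
  blen <- gen$node_time[parent[branch_nodes]] - gen$node_time[branch_nodes]
  nmut <- stats::rpois(length(branch_nodes), blen * mu * L)
  total <- sum(nmut)
  if (total > floor(L))
    stop("more mutations than integer positions; increase sequence_length")
  pos <- integer(0)
  if (total > 0) {
    pos <- unique(floor(stats::runif(total, 0, L)) + 1L)
    while (length(pos) < total) {
      extra <- floor(stats::runif(total - length(pos), 0, L)) + 1L
      pos <- unique(c(pos, extra))
    }
    pos <- pos[seq_len(total)]
  }
  mut_branch <- rep(branch_nodes, nmut)
  ord <- order(pos)
  pos <- pos[ord]; mut_branch <- mut_branch[ord]
  m <- matrix(0L, nrow = n, ncol = total)
  for (j in seq_along(pos)) m[leafset[[mut_branch[j]]], j] <- 1L
  hap_matrix(m, pos, chrom = "sim", populations = gen$leaf_pop,
             polarized = TRUE)
}

genealogy_newick <- function(gen) {
  rec <- function(v) {
    if (v <= gen$n_leaf) return(paste0("hap", v))
    ch <- gen$node_child[[v]]
    inner <- vapply(ch, function(c) {
      paste0(rec(c), ":",
             format(gen$node_time[v] - gen$node_time[c], digits = 15))
    }, "")
    paste0("(", paste(inner, collapse = ","), ")")
  }
  paste0(rec(gen$root), ";")
}

#' Simulate under a modern/archaic two-group model
#'
#' Wrapper around [simulate_coalescent()] for models with an archaic-like
#' split and ancient sampling (see [two_group_model()]); it checks that at
#' least one sampling time is strictly positive (fossil-style sampling) and
#' that the model contains a split, then simulates. Population labels of
#' the two groups are preserved on the output haplotypes, and archaic
#' lineages carry no mutations younger than their sampling time by
#' construction (their branches begin at the sampling time).
#'
#' @inheritParams simulate_coalescent
#' @return a `sim_replicate`.
#' @export
simulate_two_group_model <- function(model, sequence_length, seed = NULL,
                                     keep_tree = FALSE) {
  stopifnot(inherits(model, "demog_model"))
  if (!any(model$sampling$time > 0))
    stop("two-group model requires an ancient (time > 0) sampling event")
  if (!any(vapply(model$events, function(e) e$kind == "split", logical(1))))
    stop("two-group model requires a population split")
  simulate_coalescent(model, sequence_length, seed, keep_tree)
}
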