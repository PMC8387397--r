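#' Construct a demographic model for coalescent simulation
#'
#' A demographic model describes the populations, their effective sizes and
#' growth rates, the demographic events connecting them (splits, size
#' changes, migration-rate changes), the mutation and recombination rates,
#' and the sampling scheme. All times are in generations before present;
#' conversion to years happens only at reporting, via `generation_time`.
#'
#' @param populations data.frame with columns `name` (character), `size`
#'   (effective size in diploids, > 0) and optionally `growth` (per-generation
#'   exponential growth rate, forward in time; default 0).
#' @param sampling data.frame with columns `population`, `n` (number of
#'   haploid genomes sampled) and optionally `time` (generations before
#'   present; default 0 = contemporary).
#' @param events list of event lists. Each event has `time` (generations) and
#'   `kind`, one of `"split"` (fields `derived`, `ancestral`: backwards in
#'   time lineages of `derived` move into `ancestral`), `"size_change"`
#'   (fields `population`, `size`, optional `growth`) or `"migration_change"`
#'   (fields `from`, `to`, `rate`: backwards per-lineage migration rate).
#' @param mutation_rate per-bp per-generation mutation rate.
#' @param recombination_rate per-bp per-generation recombination rate. The
#'   simulator treats each window as a single non-recombining genealogy, so
#'   this is carried as metadata only (see the methods vignette).
#' @param generation_time generation time in years (reporting only).
#'
#' @return object of class `demog_model`.
#' @export
#' @examples
#' m <- demog_model(
#'   populations = data.frame(name = "pop0", size = 10000),
#'   sampling = data.frame(population = "pop0", n = 20)
#' )
demog_model <- function(populations, sampling, events = list(),
                        mutation_rate = 1.25e-8, recombination_rate = 0,
                        generation_time = 29) {
  stopifnot(is.data.frame(populations), nrow(populations) >= 1)
  if (!"growth" %in% names(populations)) populations$growth <- 0
  populations$name <- as.character(populations$name)
  if (anyDuplicated(populations$name))
    stop("duplicated population names")
  if (any(populations$size <= 0))
    stop("all population sizes must be > 0")

  stopifnot(is.data.frame(sampling), nrow(sampling) >= 1)
  if (!"time" %in% names(sampling)) sampling$time <- 0
  sampling$population <- as.character(sampling$population)
  if (any(sampling$n < 1)) stop("sampling n must be >= 1")
  if (any(sampling$time < 0)) stop("sampling times must be non-negative")
  bad <- setdiff(sampling$population, populations$name)
  if (length(bad)) stop("sampling refers to unknown population: ", bad[1])

  if (mutation_rate < 0) stop("mutation_rate must be non-negative")
  if (recombination_rate < 0) stop("recombination_rate must be non-negative")
  if (generation_time <= 0) stop("generation_time must be positive")

  events <- lapply(events, validate_event, populations = populations)
  ord <- order(vapply(events, `[[`, numeric(1), "time"))
  events <- events[ord]

  model <- structure(
    list(populations = populations, sampling = sampling, events = events,
         mutation_rate = mutation_rate,
         recombination_rate = recombination_rate,
         generation_time = generation_time),
    class = "demog_model"
  )
  check_model_connectivity(model)
  model
}

validate_event <- function(ev, populations) {
  if (is.null(ev$time) || ev$time < 0)
    stop("event with missing or negative time: ", deparse1(ev))
  if (is.null(ev$kind) || !ev$kind %in% c("split", "size_change", "migration_change"))
    stop("unknown event kind: ", deparse1(ev$kind))
  pops <- populations$name
  if (ev$kind == "split") {
    if (is.null(ev$derived) || is.null(ev$ancestral) ||
        !ev$derived %in% pops || !ev$ancestral %in% pops ||
        ev$derived == ev$ancestral)
      stop("invalid split event (derived=", ev$derived,
           ", ancestral=", ev$ancestral, ")")
  } else if (ev$kind == "size_change") {
    if (is.null(ev$population) || !ev$population %in% pops)
      stop("size_change names unknown population: ", ev$population)
    if (is.null(ev$size) || ev$size <= 0)
      stop("size_change at time ", ev$time, " has non-positive size")
    if (is.null(ev$growth)) ev$growth <- 0
  } else {
    if (is.null(ev$from) || is.null(ev$to) ||
        !ev$from %in% pops || !ev$to %in% pops || ev$from == ev$to)
      stop("invalid migration_change event at time ", ev$time)
    if (is.null(ev$rate) || ev$rate < 0)
      stop("migration_change at time ", ev$time, " has invalid rate")
  }
  ev
}

# The split events must merge all populations into a single root so the
# sample is guaranteed to find a common ancestor; also each population may
# be split away (as `derived`) at most once, and samples must be taken
# before their population is absorbed.
check_model_connectivity <- function(model) {
  pops <- model$populations$name
  if (length(pops) == 1) return(invisible(TRUE))
  splits <- Filter(function(e) e$kind == "split", model$events)
  derived <- vapply(splits, `[[`, character(1), "derived")
  if (anyDuplicated(derived))
    stop("population split away more than once: ",
         derived[duplicated(derived)][1])
  surviving <- setdiff(pops, derived)
  if (length(surviving) != 1)
    stop("population tree implied by splits is not connected; ",
         "populations never merged: ", paste(surviving, collapse = ", "))
  # sampling must precede the population's terminal (absorption) time
  term <- stats::setNames(rep(Inf, length(pops)), pops)
  for (e in splits) term[e$derived] <- e$time
  for (i in seq_len(nrow(model$sampling))) {
    s <- model$sampling[i, ]
    if (s$time >= term[s$population])
      stop("sampling in '", s$population, "' at time ", s$time,
           " is not before the population's split at ", term[s$population])
  }
  invisible(TRUE)
}

#' @export
print.demog_model <- function(x, ...) {
  cat("Demographic model:", nrow(x$populations), "population(s),",
      length(x$events), "event(s)\n")
  cat("  mu =", x$mutation_rate, "/bp/gen; r =", x$recombination_rate,
      "/bp/gen; generation time =", x$generation_time, "y\n")
  for (i in seq_len(nrow(x$populations)))
    cat(sprintf("  %s: N = %g, growth = %g\n", x$populations$name[i],
                x$populations$size[i], x$populations$growth[i]))
  n <- tapply(x$sampling$n, x$sampling$population, sum)
  cat("  sampling:", paste(names(n), n, sep = ":", collapse = ", "), "\n")
  invisible(x)
}

#' Read a demographic model from a YAML config file
#'
#' The config mirrors the [demog_model()] arguments:
#' ```yaml
#' mutation_rate: 1.25e-8
#' generation_time: 29
#' populations:
#'   - {name: AFR, size: 14000}
#'   - {name: OOA, size: 1800, growth: 0.004}
#' sampling:
#'   - {population: AFR, n: 20}
#' events:
#'   - {time: 2000, kind: split, derived: OOA, ancestral: AFR}
#' ```
#'
#' @param path path to a YAML file.
#' @return a `demog_model`.
#' @export
read_demog_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  to_df <- function(x) {
    # YAML 1.1 parses the bare keys n/y as booleans; map them back
    x <- lapply(x, function(e) {
      names(e)[names(e) == "FALSE"] <- "n"
      e
    })
    keys <- unique(unlist(lapply(x, names)))
    rows <- lapply(x, function(e) {
      e[setdiff(keys, names(e))] <- NA
      as.data.frame(e[keys])
    })
    df <- do.call(rbind, rows)
    if ("growth" %in% keys) df$growth[is.na(df$growth)] <- 0
    if ("time" %in% keys) df$time[is.na(df$time)] <- 0
    df
  }
  demog_model(
    populations = to_df(cfg$populations),
    sampling = to_df(cfg$sampling),
    events = if (is.null(cfg$events)) list() else cfg$events,
    mutation_rate = cfg$mutation_rate %||% 1.25e-8,
    recombination_rate = cfg$recombination_rate %||% 0,
    generation_time = cfg$generation_time %||% 29
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convenience constructor: one constant-size population
#'
#' @param n_haplotypes number of sampled haploid genomes.
#' @param ne diploid effective population size.
#' @param mutation_rate per-bp per-generation mutation rate.
#' @param ... passed to [demog_model()].
#' @return a `demog_model`.
#' @export
constant_size_model <- function(n_haplotypes, ne, mutation_rate = 1.25e-8, ...) {
  demog_model(
    populations = data.frame(name = "pop0", size = ne),
    sampling = data.frame(population = "pop0", n = n_haplotypes),
    mutation_rate = mutation_rate, ...
  )
}

#' Convenience constructor: modern + archaic-like population pair
#'
#' Two populations that split `t_split` generations ago, with the archaic
#' group sampled `t_archaic` generations before present (e.g. fossil
#' samples). After the split (backwards in time) all lineages sit in the
#' ancestral population, whose size defaults to the modern size.
#'
#' @param n_modern,n_archaic haploid sample sizes.
#' @param ne_modern,ne_archaic,ne_ancestral diploid effective sizes.
#' @param t_split split time, generations before present.
#' @param t_archaic archaic sampling time, generations before present
#'   (must be positive and before the split).
#' @param mutation_rate per-bp per-generation mutation rate.
#' @param ... passed to [demog_model()].
#' @return a `demog_model`.
#' @export
two_group_model <- function(n_modern, n_archaic, ne_modern, ne_archaic,
                            t_split, t_archaic,
                            ne_ancestral = ne_modern,
                            mutation_rate = 1.25e-8, ...) {
  if (t_archaic <= 0) stop("archaic sampling time must be > 0")
  if (t_archaic >= t_split)
    stop("archaic sampling time must be before the split")
  demog_model(
    populations = data.frame(
      name = c("modern", "archaic"),
      size = c(ne_modern, ne_archaic)
    ),
    sampling = data.frame(
      population = c("modern", "archaic"),
      n = c(n_modern, n_archaic),
      time = c(0, t_archaic)
    ),
    events = list(
      list(time = t_split, kind = "split",
           derived = "archaic", ancestral = "modern"),
      list(time = t_split, kind = "size_change",
           population = "modern", size = ne_ancestral)
    ),
    mutation_rate = mutation_rate, ...
  )
}
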