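#' Reduced stem-compartment simulation (lattice-free cross-check)
#'
#' Event-driven birth-death model of the stem compartment alone.  Because a
#' stem division's type depends only on the current stem-cell census (not on
#' the transit lattice), the succession dynamics of the full lattice model
#' with a stem-count feedback census can be reproduced without simulating
#' transit cells.  This implementation is deliberately independent of the
#' lattice engine: it tracks per-lineage cell counts and division times in
#' R and is used as an oracle in the test suite.
#'
#' Timing mirrors the lattice model's realised cycle: a cell born at step
#' `s` divides at `s + tg1 + tsg2 + 3` steps (one step to leave quiescence
#' plus one transition step per phase), and the founding cells start in G1
#' with a uniformly drawn elapsed phase, so within a lineage divisions stay
#' synchronised while lineages are staggered.
#'
#' @param n0 Number of founding stem lineages.
#' @param ps,bias Per-lineage symmetric-division probability and bias
#'   factor; scalars are recycled, so per-lineage vectors express a marked
#'   mutant lineage.
#' @param tc,tg1 Stem cycle and G1 times in hours; per-lineage, recycled.
#' @param dt Time step in hours.
#' @param mutation_prob Per-stem-product second-hit probability; with a
#'   positive value the run reports the first hit iteration (all lineages
#'   are treated as heterozygous, as in the familial-mutation setting).
#' @param seed Integer seed, `NULL` to use the current RNG state.
#' @param max_iterations,max_stem_cells Run guards as in [crypt_params()].
#'
#' @return A list: `succession_iteration` (`NULL` if none),
#'   `succession_days`, `winner` (lineage label), `n_events` (number of
#'   lineage division epochs before succession), `second_hit_iteration`,
#'   `outcome`, and the `ns` series sampled at each division epoch.
#' @examples
#' stem_only_sim(ps = 0.2, seed = 1)$succession_days
#' @export
stem_only_sim <- function(n0 = 10, ps = 0.1, bias = 1, tc = 24, tg1 = 12,
                          dt = 0.5, mutation_prob = 0, seed = NULL,
                          max_iterations = 500000L, max_stem_cells = 200L) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n0 >= 1, all(ps >= 0 & ps <= 1), all(bias > 0), all(tg1 < tc))
  ps <- rep_len(ps, n0)
  bias <- rep_len(bias, n0)
  tg1_steps <- vapply(rep_len(tg1, n0), steps_of, integer(1), dt, "tg1")
  tsg2_steps <- vapply(rep_len(tc, n0) - rep_len(tg1, n0), steps_of,
                       integer(1), dt, "tc - tg1")
  cycle <- tg1_steps + tsg2_steps + 3L

  u <- vapply(tg1_steps, function(g) sample.int(g, 1L) - 1L, integer(1))
  cnt <- rep(1L, n0)
  # first division: remaining G1 + transition + S+G2 + transition
  nextdiv <- (tg1_steps - u) + tsg2_steps + 2L
  second_hit <- NULL
  n_events <- 0L
  ns_series <- integer(0)
  outcome <- "max_iterations"
  t <- 0L

  repeat {
    alive <- cnt > 0L
    if (!any(alive)) { outcome <- "extinction"; break }
    if (sum(cnt) > max_stem_cells) { outcome <- "stem_overflow"; break }
    if (sum(alive) == 1L && mutation_prob == 0) { outcome <- "succession"; break }
    t <- min(nextdiv[alive])
    if (t > max_iterations) break
    ns <- sum(cnt)
    for (i in which(alive & nextdiv == t)) {
      pd <- biased_differentiation_probability(
        corrected_differentiation_probability(ns, n0), bias[i])
      n <- cnt[i]
      sym <- runif(n) < ps[i]
      diffd <- sym & (runif(n) < pd)
      selfd <- sym & !diffd
      cnt[i] <- n - sum(diffd) + sum(selfd)
      nextdiv[i] <- t + cycle[i]
      n_events <- n_events + 1L
      if (mutation_prob > 0 && is.null(second_hit)) {
        # one draw per stem product: asymmetric keeps one stem daughter,
        # self-renewing symmetric keeps two
        n_draws <- sum(!sym) + 2L * sum(selfd)
        if (n_draws > 0 && any(runif(n_draws) < mutation_prob))
          second_hit <- t
      }
    }
    ns_series <- c(ns_series, sum(cnt))
    if (!is.null(second_hit)) { outcome <- "second_hit"; break }
  }

  succ <- if (outcome == "succession") t
  list(succession_iteration = succ,
       succession_days = if (!is.null(succ)) iterations_to_days(succ, dt),
       winner = if (outcome == "succession")
         paste0("SC", which(cnt > 0L) - 1L),
       n_events = n_events,
       second_hit_iteration = second_hit,
       ns = ns_series,
       outcome = outcome)
}

#' Succession-period ensemble from the reduced stem-compartment model
#'
#' @param ps,bias Symmetric-division probability and bias factor (scalars
#'   or per-lineage vectors, see [stem_only_sim()]).
#' @param n0 Number of founding lineages.
#' @param n_reps Number of replicates.
#' @param master_seed Master seed; per-replicate seeds derive from it via
#'   [replicate_seeds()].
#' @param ... Passed to [stem_only_sim()].
#' @return A data frame with one row per replicate: `seed`, `outcome`,
#'   `succession_days`, `n_events`, `winner`.
#' @examples
#' mean(stem_only_succession(ps = 0.2, n_reps = 5, master_seed = 1)$succession_days)
#' @export
stem_only_succession <- function(ps = 0.1, bias = 1, n0 = 10, n_reps = 20,
                                 master_seed = 1, ...) {
  seeds <- replicate_seeds(master_seed, n_reps)
  rows <- lapply(seeds, function(s) {
    r <- stem_only_sim(n0 = n0, ps = ps, bias = bias, seed = s, ...)
    data.frame(seed = s, outcome = r$outcome,
               succession_days = r$succession_days %||% NA_real_,
               n_events = r$n_events,
               winner = r$winner %||% NA_character_)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
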