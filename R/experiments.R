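#' Derive per-replicate seeds from a master seed
#'
#' Stable scheme: the master seed initialises R's RNG once and `n` integer
#' seeds are drawn from it.  Replicate `i` of a given master seed is the
#' same in every run and package version.
#'
#' @param master_seed Integer master seed.
#' @param n Number of replicate seeds.
#' @return Integer vector of length `n`.
#' @examples
#' replicate_seeds(1, 3)
#' @export
replicate_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run a seeded replicate ensemble of the lattice model
#'
#' @param params A [crypt_params()] object.
#' @param mutation A [mutation_config()] object.
#' @param n_reps Number of replicates.
#' @param master_seed Master seed (see [replicate_seeds()]).
#' @param ... Passed to [simulate_crypt()] (e.g. `stop_on_succession`).
#' @return A data frame, one row per replicate: `replicate`, `seed`,
#'   `outcome`, `n_iter`, `succession_iteration`, `succession_days`,
#'   `winner`, `marked`, `second_hit_stem`, `second_hit_any`, `mean_ns`,
#'   `final_ns`.
#' @examples
#' run_replicates(crypt_params(ps = 0.2), n_reps = 2, master_seed = 1)
#' @export
run_replicates <- function(params = crypt_params(),
                           mutation = mutation_config("NORMAL"),
                           n_reps = 20, master_seed = 1, ...) {
  seeds <- replicate_seeds(master_seed, n_reps)
  rows <- lapply(seq_along(seeds), function(i) {
    r <- simulate_crypt(params, mutation, seed = seeds[i],
                        record = "summary", ...)
    data.frame(
      replicate = i, seed = seeds[i], outcome = r$outcome, n_iter = r$n_iter,
      succession_iteration = r$succession$iteration %||% NA_integer_,
      succession_days = r$succession$days %||% NA_real_,
      winner = r$succession$ancestor,
      marked = r$marked_ancestor,
      second_hit_stem = r$second_hit$stem_iteration %||% NA_integer_,
      second_hit_any = r$second_hit$any_iteration %||% NA_integer_,
      mean_ns = mean(r$ns), final_ns = r$ns[length(r$ns)],
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mean niche-succession period across symmetric-division probabilities
#'
#' Runs a replicate ensemble at each `ps` (unbiased, `B = 1`) and reports
#' the mean succession period in days.  Replicates that end without
#' succession (overflow or iteration cap) are censored: excluded from the
#' mean and counted.
#'
#' @param ps_values Symmetric-division probabilities to sweep.
#' @param n_reps Replicates per value.
#' @param master_seed Master seed.
#' @param params Base parameters (its `ps` is overridden).
#' @return A data frame: `ps`, `mean_days`, `sd_days`, `n`, `n_censored`.
#' @examples
#' succession_period_vs_ps(c(0.1, 0.2), n_reps = 3, master_seed = 1)
#' @export
succession_period_vs_ps <- function(ps_values, n_reps = 20, master_seed = 1,
                                    params = crypt_params()) {
  rows <- lapply(ps_values, function(ps) {
    params$ps <- ps
    params$bias <- 1
    reps <- run_replicates(params, n_reps = n_reps, master_seed = master_seed)
    ok <- !is.na(reps$succession_days)
    data.frame(ps = ps,
               mean_days = mean(reps$succession_days[ok]),
               sd_days = sd(reps$succession_days[ok]),
               n = sum(ok), n_censored = sum(!ok))
  })
  do.call(rbind, rows)
}

#' Stem-cell count dynamics under a given bias
#'
#' Summarises the stem-cell count over a fixed horizon: mean, 5th-95th
#' percentile band, and a growth classification -- `"unbounded"` when any
#' replicate trips the stem-overflow guard, `"elevated"` when the mean sits
#' more than one cell above the target `n0`, `"homeostatic"` otherwise.
#'
#' @param ps,bias Division parameters.
#' @param n_reps Number of replicates.
#' @param horizon Iterations per replicate.
#' @param master_seed Master seed.
#' @param params Base parameters.
#' @return A list: `mean_ns`, `p5`, `p95`, `classification`, `n_overflow`.
#' @examples
#' stem_count_dynamics(ps = 0.1, bias = 1, n_reps = 2, horizon = 2000)
#' @export
stem_count_dynamics <- function(ps = 0.1, bias = 1, n_reps = 20,
                                horizon = 5000, master_seed = 1,
                                params = crypt_params()) {
  params$ps <- ps
  params$bias <- bias
  params$max_iterations <- as.integer(horizon)
  seeds <- replicate_seeds(master_seed, n_reps)
  all_ns <- integer(0)
  n_overflow <- 0L
  for (s in seeds) {
    r <- simulate_crypt(params, seed = s, stop_on_succession = FALSE,
                        record = "summary")
    if (r$outcome == "stem_overflow") n_overflow <- n_overflow + 1L
    all_ns <- c(all_ns, r$ns)
  }
  band <- quantile(all_ns, c(0.05, 0.95), names = FALSE, type = 1)
  cls <- if (n_overflow > 0) "unbounded"
         else if (mean(all_ns) > params$n0 + 1) "elevated"
         else "homeostatic"
  list(mean_ns = mean(all_ns), p5 = band[1], p95 = band[2],
       classification = cls, n_overflow = n_overflow)
}

#' Fixation probability of a marked (heterozygous) stem-cell lineage
#'
#' Sporadic-mutation setting: one seed-chosen founding stem cell is
#' heterozygous, the other `n0 - 1` are wild type, second hits are disabled,
#' and each replicate runs until niche succession.  The estimate is the
#' fraction of replicates whose succession winner is the marked lineage;
#' replicates ending in multi-lineage survival (overflow guard) or at the
#' iteration cap count as non-fixation and are reported as flags.
#'
#' @param het_ps,het_bias,het_cycle_mult Heterozygous phenotype effect (see
#'   [mutation_config()]); all defaults mean a phenotypically neutral mark.
#' @param n_reps Number of replicates.
#' @param master_seed Master seed.
#' @param params Control parameters (wild-type cells).
#' @return A list: `prob` (fixation fraction), `wins`, `n`, and
#'   `outcome_flags` (a table of terminal outcomes).
#' @examples
#' fixation_probability(n_reps = 4, master_seed = 1)$prob
#' @export
fixation_probability <- function(het_ps = NA_real_, het_bias = NA_real_,
                                 het_cycle_mult = 1, n_reps = 100,
                                 master_seed = 1, params = crypt_params()) {
  mut <- mutation_config("SPORADIC", mutation_prob = 0,
                         het_ps = het_ps, het_bias = het_bias,
                         het_cycle_mult = het_cycle_mult)
  reps <- run_replicates(params, mut, n_reps = n_reps,
                         master_seed = master_seed)
  wins <- sum(!is.na(reps$winner) & reps$winner == reps$marked)
  list(prob = wins / n_reps, wins = wins, n = n_reps,
       outcome_flags = table(reps$outcome))
}

#' Mean waiting time to the second APC hit
#'
#' Familial (FAP) setting: every founding stem cell is heterozygous and the
#' remaining wild-type allele mutates at division with probability `mu` per
#' daughter.  Each replicate stops at the first second hit within the
#' configured scope (stem cells by default); replicates reaching the
#' iteration cap first are censored and excluded from the mean.
#'
#' @param het_ps,het_bias,het_cycle_mult Heterozygous phenotype effect.
#' @param mu Second-hit probability per daughter per division.
#' @param n_reps Number of replicates.
#' @param master_seed Master seed.
#' @param params Base parameters.
#' @param second_hit_scope `"STEM_ONLY"` or `"ANY_CELL"`.
#' @return A list: `mean_iterations` over uncensored replicates, `sd`,
#'   `n`, `n_censored`.
#' @examples
#' time_to_second_hit(mu = 0.01, n_reps = 2, master_seed = 1)$mean_iterations
#' @export
time_to_second_hit <- function(het_ps = NA_real_, het_bias = NA_real_,
                               het_cycle_mult = 1, mu = 0.001, n_reps = 20,
                               master_seed = 1, params = crypt_params(),
                               second_hit_scope = "STEM_ONLY") {
  mut <- mutation_config("FAP", mutation_prob = mu,
                         het_ps = het_ps, het_bias = het_bias,
                         het_cycle_mult = het_cycle_mult,
                         second_hit_scope = second_hit_scope)
  reps <- run_replicates(params, mut, n_reps = n_reps,
                         master_seed = master_seed,
                         stop_on_succession = FALSE)
  hit <- if (second_hit_scope == "STEM_ONLY") reps$second_hit_stem
         else reps$second_hit_any
  ok <- !is.na(hit)
  list(mean_iterations = mean(hit[ok]), sd = sd(hit[ok]),
       n = sum(ok), n_censored = sum(!ok))
}
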