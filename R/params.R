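#' Simulation parameters for the crypt lattice model
#'
#' Collects and validates the lattice and cell-cycle parameters.  The
#' defaults are the reference parameterisation of the model: a 10 x 50
#' grid holding on the order of 500 cells, 10 founding stem cells, a 24 h
#' stem-cell cycle (12 h of it in G1), a 12 h transit-cell cycle (4 h G1),
#' at most 6 transit divisions before terminal differentiation, and a 30 min
#' time step.
#'
#' @param n_cols,n_rows Lattice dimensions (columns wrap; row 0 is the
#'   niche, row `n_rows - 1` the luminal top row).
#' @param n0 Initial number of stem cells, one per niche column
#'   (`n0 <= n_cols`).
#' @param tc_stem,tc_transit Total cell-cycle time in hours for stem and
#'   transit-amplifying cells.
#' @param tg1_stem,tg1_transit Time spent in G1 in hours; must be less than
#'   the corresponding cycle time.
#' @param num_div_max Maximum number of transit divisions before terminal
#'   differentiation; stemness is quantised in steps of `1/num_div_max`.
#' @param dt Time step in hours.  All durations must be integer multiples
#'   of `dt`.
#' @param ps Symmetric-division probability for stem cells, in `[0, 1]`.
#' @param bias Bias factor applied to the corrected differentiation
#'   probability during symmetric division (`bias < 1` favours stem-cell
#'   progeny); must be positive.
#' @param max_iterations Hard iteration cap for a run.
#' @param max_stem_cells Stem-cell overflow guard: a run stops (flagged, not
#'   an error) when the stem count exceeds this, mirroring the unbounded
#'   growth regime at strong bias.
#' @param ns_feedback Which census feeds the homeostatic correction of the
#'   differentiation probability: `"stem_count"` (default) reads the number
#'   of stem cells, `"niche_occupancy"` reads the total number of cells
#'   resident in the niche row (an environmental-crowding variant kept for
#'   sensitivity analysis; see the methods vignette).
#'
#' @return An object of class `crypt_params` (a validated list).
#' @examples
#' p <- crypt_params()
#' p
#' crypt_params(ps = 0.2, bias = 0.6)
#' @export
crypt_params <- function(n_cols = 10L, n_rows = 50L, n0 = 10L,
                         tc_stem = 24, tc_transit = 12,
                         tg1_stem = 12, tg1_transit = 4,
                         num_div_max = 6L, dt = 0.5,
                         ps = 0.1, bias = 1,
                         max_iterations = 500000L, max_stem_cells = 200L,
                         ns_feedback = c("stem_count", "niche_occupancy")) {
  ns_feedback <- match.arg(ns_feedback)
  p <- list(n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
            n0 = as.integer(n0), tc_stem = tc_stem, tc_transit = tc_transit,
            tg1_stem = tg1_stem, tg1_transit = tg1_transit,
            num_div_max = as.integer(num_div_max), dt = dt,
            ps = ps, bias = bias,
            max_iterations = as.integer(max_iterations),
            max_stem_cells = as.integer(max_stem_cells),
            ns_feedback = ns_feedback)
  class(p) <- "crypt_params"
  validate_crypt_params(p)
  p
}

steps_of <- function(hours, dt, what) {
  s <- hours / dt
  if (abs(s - round(s)) > 1e-9)
    stop(sprintf("%s (%g h) is not an integer multiple of dt = %g h",
                 what, hours, dt), call. = FALSE)
  as.integer(round(s))
}

validate_crypt_params <- function(p) {
  stopifnot(is.list(p))
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(p$n_cols >= 1 && p$n_rows >= 2, "lattice must have >= 1 column and >= 2 rows")
  chk(p$n0 >= 1, "n0 must be at least 1")
  chk(p$n0 <= p$n_cols, "n0 must not exceed n_cols (one stem cell per niche column)")
  chk(p$dt > 0, "dt must be positive")
  chk(p$ps >= 0 && p$ps <= 1, "ps must lie in [0, 1]")
  chk(p$bias > 0, "bias must be positive")
  chk(p$num_div_max >= 1, "num_div_max must be at least 1")
  chk(p$tg1_stem < p$tc_stem, "tg1_stem must be less than tc_stem")
  chk(p$tg1_transit < p$tc_transit, "tg1_transit must be less than tc_transit")
  chk(p$max_iterations >= 0, "max_iterations must be non-negative")
  chk(p$max_stem_cells > p$n0, "max_stem_cells must exceed n0")
  for (f in c("tc_stem", "tc_transit", "tg1_stem", "tg1_transit"))
    steps_of(p[[f]], p$dt, f)
  invisible(p)
}

#' @export
print.crypt_params <- function(x, ...) {
  cat("Crypt lattice parameters\n")
  cat(sprintf("  grid: %d columns x %d rows (niche row 0), %d founding stem cells\n",
              x$n_cols, x$n_rows, x$n0))
  cat(sprintf("  cycle: stem %g h (G1 %g h), transit %g h (G1 %g h), dt %g h\n",
              x$tc_stem, x$tg1_stem, x$tc_transit, x$tg1_transit, x$dt))
  cat(sprintf("  stemness quantum 1/%d; Ps = %g, bias B = %g\n",
              x$num_div_max, x$ps, x$bias))
  cat(sprintf("  feedback census: %s; guards: %d iterations, %d stem cells\n",
              x$ns_feedback, x$max_iterations, x$max_stem_cells))
  invisible(x)
}

#' Mutation-layer configuration
#'
#' Configures the two-allele APC genotype layer.  `"NORMAL"` runs carry no
#' mutations.  In `"FAP"` mode every founding stem cell starts with one
#' mutated allele (germline heterozygosity); in `"SPORADIC"` mode exactly
#' one seed-chosen founding stem cell does.  The remaining wild-type allele
#' of a heterozygous cell can mutate at division (the "second hit"), with an
#' independent Bernoulli draw of probability `mutation_prob` per daughter
#' per division.  First hits in wild-type cells are not modelled; the
#' simulated experiments start from a pre-existing heterozygote.
#'
#' A heterozygous phenotype effect may override the symmetric-division
#' probability and/or bias factor of mutated cells, and/or rescale their
#' cell-cycle time (e.g. `het_cycle_mult = 0.5` doubles the division rate).
#' `NA` means "inherit the base value" (no phenotype change).
#'
#' @param mode One of `"NORMAL"`, `"FAP"`, `"SPORADIC"`.
#' @param mutation_prob Second-hit probability per daughter per division.
#' @param het_ps,het_bias Overrides of `ps` / `bias` for heterozygous cells
#'   (`NA` = no change).
#' @param het_cycle_mult Multiplier applied to both cycle-time parameters of
#'   heterozygous cells (1 = no change).
#' @param second_hit_scope Which cells count for the second-hit endpoint:
#'   `"STEM_ONLY"` (default; only hits in stem cells end a run, since only
#'   stem-cell lineages persist) or `"ANY_CELL"`.
#' @return An object of class `mutation_config`.
#' @examples
#' mutation_config("FAP", mutation_prob = 0.001)
#' mutation_config("SPORADIC", het_ps = 0.2, het_bias = 0.5)
#' @export
mutation_config <- function(mode = c("NORMAL", "FAP", "SPORADIC"),
                            mutation_prob = 0,
                            het_ps = NA_real_, het_bias = NA_real_,
                            het_cycle_mult = 1,
                            second_hit_scope = c("STEM_ONLY", "ANY_CELL")) {
  mode <- match.arg(mode)
  second_hit_scope <- match.arg(second_hit_scope)
  if (mutation_prob < 0 || mutation_prob > 1)
    stop("mutation_prob must lie in [0, 1]", call. = FALSE)
  if (!is.na(het_ps) && (het_ps < 0 || het_ps > 1))
    stop("het_ps must lie in [0, 1]", call. = FALSE)
  if (!is.na(het_bias) && het_bias <= 0)
    stop("het_bias must be positive", call. = FALSE)
  if (het_cycle_mult <= 0)
    stop("het_cycle_mult must be positive", call. = FALSE)
  het_active <- !is.na(het_ps) || !is.na(het_bias) || het_cycle_mult != 1
  if (mode == "NORMAL" && (het_active || mutation_prob > 0))
    stop("NORMAL mode carries no mutated alleles; heterozygous effects and ",
         "mutation_prob do not apply", call. = FALSE)
  m <- list(mode = mode, mutation_prob = mutation_prob,
            het_ps = as.numeric(het_ps), het_bias = as.numeric(het_bias),
            het_cycle_mult = het_cycle_mult,
            second_hit_scope = second_hit_scope)
  class(m) <- "mutation_config"
  m
}

#' @export
print.mutation_config <- function(x, ...) {
  cat(sprintf("APC mutation layer: mode %s, second-hit probability %g per daughter\n",
              x$mode, x$mutation_prob))
  if (x$mode != "NORMAL") {
    eff <- c(
      if (!is.na(x$het_ps)) sprintf("Ps -> %g", x$het_ps),
      if (!is.na(x$het_bias)) sprintf("B -> %g", x$het_bias),
      if (x$het_cycle_mult != 1) sprintf("cycle time x %g", x$het_cycle_mult))
    cat("  heterozygous effect:",
        if (length(eff)) paste(eff, collapse = ", ") else "none", "\n")
    cat("  second-hit endpoint scope:", x$second_hit_scope, "\n")
  }
  invisible(x)
}
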