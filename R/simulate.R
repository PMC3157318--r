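#' Run the crypt lattice simulation
#'
#' Executes the agent-based model: every iteration advances each cell's
#' cycle state synchronously from the start-of-step snapshot, commits the
#' resulting divisions in a seeded random order, resolves mitotic-pressure
#' migration column by column, and sheds cells pushed past the top row.
#' Stem-cell divisions draw their type (asymmetric / both-differentiate /
#' both-stem) from the symmetric-division probability and the bias-corrected
#' differentiation probability evaluated on the start-of-iteration niche
#' census.
#'
#' @param params A [crypt_params()] object.
#' @param mutation A [mutation_config()] object.
#' @param seed Integer seed; the run is fully reproducible from it.  `NULL`
#'   uses the current RNG state.
#' @param stop_on_succession Stop when all stem cells share one founding
#'   ancestor.
#' @param stop_on_second_hit Stop at the first homozygous APC mutant within
#'   the configured scope (defaults to `TRUE` when the mutation layer has a
#'   positive second-hit probability).
#' @param record `"trace"` keeps the per-iteration per-ancestor stem-count
#'   matrix; `"summary"` drops it (cheaper for long replicate sweeps).
#'
#' @return A `crypt_run` object: per-iteration series (`ns`,
#'   `niche_occupancy`, `population`, `births`, `shed`, and with
#'   `record = "trace"` the `ancestor_counts` matrix), the `succession`
#'   result (iteration, winning ancestor, period in days), `second_hit`
#'   iterations, the terminal `outcome` (one of `"succession"`,
#'   `"second_hit"`, `"stem_overflow"`, `"extinction"`,
#'   `"max_iterations"`), and the final cell table `cells`.
#' @examples
#' run <- simulate_crypt(crypt_params(ps = 0.2), seed = 1)
#' run
#' @export
simulate_crypt <- function(params = crypt_params(),
                           mutation = mutation_config("NORMAL"),
                           seed = NULL,
                           stop_on_succession = TRUE,
                           stop_on_second_hit = mutation$mutation_prob > 0,
                           record = c("trace", "summary")) {
  stopifnot(inherits(params, "crypt_params"), inherits(mutation, "mutation_config"))
  validate_crypt_params(params)
  record <- match.arg(record)
  if (!is.null(seed)) set.seed(seed)

  p <- params
  dt <- p$dt
  het_tc_stem <- p$tc_stem * mutation$het_cycle_mult
  het_tg1_stem <- p$tg1_stem * mutation$het_cycle_mult
  het_tc_transit <- p$tc_transit * mutation$het_cycle_mult
  het_tg1_transit <- p$tg1_transit * mutation$het_cycle_mult

  par <- list(
    n_cols = p$n_cols, n_rows = p$n_rows, n0 = p$n0,
    num_div_max = p$num_div_max,
    tg1_stem_steps = steps_of(p$tg1_stem, dt, "tg1_stem"),
    tsg2_stem_steps = steps_of(p$tc_stem - p$tg1_stem, dt, "tc_stem - tg1_stem"),
    tg1_transit_steps = steps_of(p$tg1_transit, dt, "tg1_transit"),
    tsg2_transit_steps = steps_of(p$tc_transit - p$tg1_transit, dt,
                                  "tc_transit - tg1_transit"),
    het_tg1_stem_steps = steps_of(het_tg1_stem, dt, "het tg1_stem"),
    het_tsg2_stem_steps = steps_of(het_tc_stem - het_tg1_stem, dt,
                                   "het tc_stem - tg1_stem"),
    het_tg1_transit_steps = steps_of(het_tg1_transit, dt, "het tg1_transit"),
    het_tsg2_transit_steps = steps_of(het_tc_transit - het_tg1_transit, dt,
                                      "het tc_transit - tg1_transit"),
    ps = p$ps, bias = p$bias,
    het_ps = mutation$het_ps, het_bias = mutation$het_bias,
    mode = match(mutation$mode, c("NORMAL", "FAP", "SPORADIC")) - 1L,
    mutation_prob = mutation$mutation_prob,
    hit_scope = match(mutation$second_hit_scope, c("STEM_ONLY", "ANY_CELL")) - 1L,
    max_iterations = p$max_iterations,
    max_stem_cells = p$max_stem_cells,
    stop_on_succession = isTRUE(stop_on_succession),
    stop_on_second_hit = isTRUE(stop_on_second_hit),
    record_trace = record == "trace",
    ns_feedback = match(p$ns_feedback, c("stem_count", "niche_occupancy")) - 1L)

  raw <- .cpp_simulate(par, dt)

  anc_names <- paste0("SC", seq_len(p$n0) - 1L)
  lab <- function(i) if (is.null(i) || i < 0) NA_character_ else anc_names[i + 1L]
  outcome <- c("max_iterations", "succession", "second_hit",
               "stem_overflow", "extinction")[raw$stop_reason + 1L]

  run <- list(
    params = p, mutation = mutation, seed = seed,
    n_iter = raw$n_iter,
    ns = raw$ns,
    niche_occupancy = raw$niche_occupancy,
    population = raw$population,
    births = raw$births,
    shed = raw$shed,
    ancestor_counts = if (!is.null(raw$ancestor_counts)) {
      m <- raw$ancestor_counts
      colnames(m) <- anc_names
      m
    },
    succession = list(
      iteration = if (raw$succession_iteration >= 0) raw$succession_iteration,
      ancestor = lab(raw$winner),
      days = if (raw$succession_iteration >= 0)
        iterations_to_days(raw$succession_iteration, dt)),
    second_hit = list(
      stem_iteration = if (raw$second_hit_stem >= 0) raw$second_hit_stem,
      any_iteration = if (raw$second_hit_any >= 0) raw$second_hit_any),
    marked_ancestor = lab(raw$marked),
    outcome = outcome,
    cells = raw$cells)
  class(run) <- "crypt_run"
  run
}

#' @export
print.crypt_run <- function(x, ...) {
  cat(sprintf("Crypt simulation: %d iterations (%.1f days), outcome: %s\n",
              x$n_iter, iterations_to_days(x$n_iter, x$params$dt), x$outcome))
  n <- length(x$ns)
  if (n > 0)
    cat(sprintf("  final: %d stem cells, %d cells total\n",
                x$ns[n], x$population[n]))
  if (!is.null(x$succession$iteration))
    cat(sprintf("  niche succession by %s at iteration %d (%.1f days)\n",
                x$succession$ancestor, x$succession$iteration,
                x$succession$days))
  if (!is.null(x$second_hit$stem_iteration))
    cat(sprintf("  second APC hit in a stem cell at iteration %d\n",
                x$second_hit$stem_iteration))
  if (!is.na(x$marked_ancestor))
    cat(sprintf("  marked (heterozygous) founding lineage: %s\n",
                x$marked_ancestor))
  invisible(x)
}

#' @export
summary.crypt_run <- function(object, ...) {
  ns <- object$ns
  out <- list(
    n_iter = object$n_iter,
    outcome = object$outcome,
    mean_ns = mean(ns),
    ns_band = stats::quantile(ns, c(0.05, 0.95), names = FALSE, type = 1),
    total_births = sum(object$births),
    total_shed = sum(object$shed),
    succession = object$succession,
    second_hit = object$second_hit)
  class(out) <- "summary.crypt_run"
  out
}

#' @export
print.summary.crypt_run <- function(x, ...) {
  cat(sprintf("%d iterations, outcome %s\n", x$n_iter, x$outcome))
  cat(sprintf("stem cells: mean %.2f, 5th-95th percentile band %d-%d\n",
              x$mean_ns, x$ns_band[1], x$ns_band[2]))
  cat(sprintf("births %d, shed %d\n", x$total_births, x$total_shed))
  if (!is.null(x$succession$iteration))
    cat(sprintf("succession by %s after %.1f days\n",
                x$succession$ancestor, x$succession$days))
  invisible(x)
}

#' Plot a crypt run
#'
#' With a recorded trace, draws the per-lineage stem-cell counts over time
#' and the total stem count; otherwise just the stem count.
#'
#' @param x A `crypt_run`.
#' @param ... Passed to [graphics::matplot()] / [graphics::plot()].
#' @export
plot.crypt_run <- function(x, ...) {
  days <- iterations_to_days(seq_along(x$ns), x$params$dt)
  if (!is.null(x$ancestor_counts)) {
    graphics::matplot(days, x$ancestor_counts, type = "l", lty = 1,
                      xlab = "time (days)", ylab = "stem cells per lineage",
                      main = "Founding-lineage stem-cell counts", ...)
    graphics::lines(days, x$ns, lwd = 2, col = "black")
  } else {
    graphics::plot(days, x$ns, type = "l", xlab = "time (days)",
                   ylab = "stem cells", main = "Stem-cell count", ...)
  }
  invisible(x)
}
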