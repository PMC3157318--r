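#' Corrected differentiation probability
#'
#' Homeostatic correction of the symmetric-division differentiation
#' probability.  At the target pool size (`ns == n0`) the probability is
#' 0.5, so the two kinds of symmetric division balance; it falls linearly
#' to 0 at `ns/n0 = 0.5` and rises to 1 at `ns/n0 = 1.5`, clipped outside
#' that range:
#' `pd = clip(ns/n0 - 0.5, 0, 1)`.
#'
#' @param ns Current size of the stem-cell compartment census (vectorised).
#' @param n0 Target (initial) stem-cell number; must be positive.
#' @return Differentiation probabilities in `[0, 1]`.
#' @examples
#' corrected_differentiation_probability(c(5, 10, 12, 15), 10)
#' @export
corrected_differentiation_probability <- function(ns, n0) {
  if (length(n0) != 1L || !is.finite(n0) || n0 <= 0)
    stop("n0 must be a single positive number", call. = FALSE)
  if (any(ns < 0)) stop("ns must be non-negative", call. = FALSE)
  pmin(pmax(ns / n0 - 0.5, 0), 1)
}

#' Biased differentiation probability
#'
#' Multiplies an already-corrected differentiation probability by the bias
#' factor `B` and clips the product to `[0, 1]`.  For `B <= 1` the
#' attainable range is `[0, B]`, so a bias below one tilts symmetric
#' divisions towards stem-cell progeny.
#'
#' @param pd_corrected Corrected differentiation probability in `[0, 1]`.
#' @param bias Positive bias factor `B`.
#' @return Biased differentiation probabilities in `[0, 1]`.
#' @examples
#' biased_differentiation_probability(0.5, 1)
#' biased_differentiation_probability(c(0, 0.5, 1), 0.6)
#' @export
biased_differentiation_probability <- function(pd_corrected, bias) {
  if (length(bias) != 1L || !is.finite(bias) || bias <= 0)
    stop("bias must be a single positive number", call. = FALSE)
  if (any(pd_corrected < 0 | pd_corrected > 1))
    stop("pd_corrected must lie in [0, 1] (clip it first)", call. = FALSE)
  pmin(pmax(bias * pd_corrected, 0), 1)
}

#' Division-outcome probabilities
#'
#' Probabilities that a stem-cell division produces 0, 1 or 2 stem-cell
#' daughters, given the symmetric-division probability `ps` and the (biased)
#' differentiation probability `pd`:
#' `p0 = ps * pd` (both daughters differentiate), `p1 = 1 - ps`
#' (asymmetric), `p2 = ps * (1 - pd)` (both daughters remain stem cells).
#' The three always sum to one.
#'
#' @param ps Symmetric-division probability in `[0, 1]` (vectorised).
#' @param pd Biased differentiation probability in `[0, 1]` (vectorised).
#' @return A data frame with columns `p0`, `p1`, `p2`.
#' @examples
#' division_outcome_probs(ps = 0.2, pd = 0.6)
#' @export
division_outcome_probs <- function(ps, pd) {
  if (any(ps < 0 | ps > 1) || any(pd < 0 | pd > 1))
    stop("ps and pd must lie in [0, 1]", call. = FALSE)
  data.frame(p0 = ps * pd, p1 = 1 - ps, p2 = ps * (1 - pd))
}

#' Sample stem-cell division types
#'
#' Draws division types with the same two-stage scheme the simulator uses:
#' a first uniform draw below `ps` makes the division symmetric, and a
#' second draw below `pd` then makes both daughters differentiate.
#'
#' @param n Number of divisions to draw.
#' @param ps Symmetric-division probability.
#' @param pd Biased differentiation probability.
#' @return A factor with levels `ASYMMETRIC`, `SYM_DIFF`, `SYM_SELF`.
#' @examples
#' set.seed(1)
#' table(sample_division_type(1000, ps = 0.2, pd = 0.5))
#' @export
sample_division_type <- function(n, ps, pd) {
  if (ps < 0 || ps > 1 || pd < 0 || pd > 1)
    stop("ps and pd must lie in [0, 1]", call. = FALSE)
  sym <- runif(n) < ps
  diff <- runif(n) < pd   # drawn for every division; used only when symmetric
  out <- ifelse(!sym, "ASYMMETRIC", ifelse(diff, "SYM_DIFF", "SYM_SELF"))
  factor(out, levels = c("ASYMMETRIC", "SYM_DIFF", "SYM_SELF"))
}

#' Detect niche succession from per-lineage stem counts
#'
#' Succession has occurred when exactly one founding lineage still has a
#' positive stem-cell count.
#'
#' @param counts Named vector of stem-cell counts per founding ancestor.
#' @return The name of the surviving ancestor, or `NA_character_` when more
#'   than one lineage is alive.  A total count of zero is niche extinction,
#'   a degenerate outcome flagged with a warning, not a succession.
#' @examples
#' detect_succession(c(SC0 = 0, SC1 = 11, SC2 = 0))
#' detect_succession(c(SC0 = 5, SC3 = 5))
#' @export
detect_succession <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  alive <- counts > 0
  if (!any(alive)) {
    warning("no stem cells left: niche extinction, not a succession")
    return(NA_character_)
  }
  if (sum(alive) == 1L) names(counts)[alive] else NA_character_
}

#' Convert an iteration count to days
#'
#' @param iterations Number of simulation iterations.
#' @param dt Time step in hours.
#' @return Elapsed time in days.
#' @examples
#' iterations_to_days(2880, dt = 0.5)  # 60 days
#' @export
iterations_to_days <- function(iterations, dt) iterations * dt / 24

#' One step of the cell-cycle state machine
#'
#' Reference R implementation of the per-step transition rules used by the
#' simulator: a quiescent cell with positive stemness enters G1; G1 and
#' S+G2 accumulate time until their phase duration is reached and then
#' advance (G1 lasts `tg1`, S+G2 lasts `tc - tg1`); the transition into
#' mitosis flags the cell for division.  Terminally differentiated cells
#' (stemness 0) stay quiescent.  Age always advances by `dt`.
#'
#' @param cell A list with fields `state` (one of `"QUIESCENT"`, `"G1"`,
#'   `"S_G2"`, `"MITOSIS"`), `time_in_state` (hours), `age` (hours) and
#'   `stemness`.
#' @param tc,tg1 Cycle and G1 durations (hours) for this cell's class.
#' @param dt Time step (hours).
#' @return The updated cell; a cell that has just entered `"MITOSIS"` is
#'   divided by the simulator within the same step.
#' @examples
#' step_cell_cycle(list(state = "G1", time_in_state = 12, age = 30,
#'                      stemness = 1), tc = 24, tg1 = 12, dt = 0.5)
#' @export
step_cell_cycle <- function(cell, tc, tg1, dt = 0.5) {
  stopifnot(tg1 < tc, dt > 0)
  cell$age <- cell$age + dt
  switch(cell$state,
    QUIESCENT = {
      if (cell$stemness > 0) {
        cell$state <- "G1"
        cell$time_in_state <- 0
      }
    },
    G1 = {
      if (cell$time_in_state >= tg1) {
        cell$state <- "S_G2"
        cell$time_in_state <- 0
      } else cell$time_in_state <- cell$time_in_state + dt
    },
    S_G2 = {
      if (cell$time_in_state >= tc - tg1) {
        cell$state <- "MITOSIS"
        cell$time_in_state <- 0
      } else cell$time_in_state <- cell$time_in_state + dt
    },
    MITOSIS = {
      # resolved by the division step within the iteration it was entered
    },
    stop("unknown cell state: ", cell$state, call. = FALSE)
  )
  cell
}
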