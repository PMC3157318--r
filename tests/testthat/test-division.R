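# Division-probability model: homeostatic correction, bias, outcome
# probabilities and type sampling.

test_that("corrected differentiation probability passes through its anchors", {
  expect_equal(corrected_differentiation_probability(10, 10), 0.5)
  expect_equal(corrected_differentiation_probability(5, 10), 0)
  expect_equal(corrected_differentiation_probability(15, 10), 1)
  # linear interpolation forced by the three anchors: cross-check against a
  # brute-force least-squares line through them
  fit <- lm(y ~ x, data.frame(x = c(0.5, 1, 1.5), y = c(0, 0.5, 1)))
  pred <- unname(predict(fit, data.frame(x = 1.2)))
  expect_equal(corrected_differentiation_probability(12, 10), pred)
  expect_equal(corrected_differentiation_probability(12, 10), 0.7)
})

test_that("corrected differentiation probability clips and validates", {
  ns <- 0:40
  pd <- corrected_differentiation_probability(ns, 10)
  expect_true(all(pd >= 0 & pd <= 1))
  expect_true(all(diff(pd) >= 0))           # monotone in ns
  expect_equal(pd[ns <= 5], rep(0, sum(ns <= 5)))
  expect_equal(pd[ns >= 15], rep(1, sum(ns >= 15)))
  expect_error(corrected_differentiation_probability(5, 0), "n0")
  expect_error(corrected_differentiation_probability(-1, 10), "ns")
})

test_that("bias multiplies after clipping, giving attainable range [0, B]", {
  expect_equal(biased_differentiation_probability(0.5, 1), 0.5)
  pd_corr <- corrected_differentiation_probability(0:30, 10)
  for (B in c(0.4, 0.5, 0.6, 0.8, 1)) {
    pd_b <- biased_differentiation_probability(pd_corr, B)
    expect_equal(range(pd_b), c(0, B))
  }
  # bias above one still clips at 1
  expect_equal(biased_differentiation_probability(0.9, 2), 1)
  expect_error(biased_differentiation_probability(0.5, 0), "bias")
  expect_error(biased_differentiation_probability(1.2, 0.5), "clip")
})

test_that("division-outcome probabilities are exact products summing to one", {
  p <- division_outcome_probs(0.2, 0.6)
  expect_equal(p$p0, 0.12)
  expect_equal(p$p1, 0.8)
  expect_equal(p$p2, 0.08)
  expect_equal(division_outcome_probs(0, 0.3), data.frame(p0 = 0, p1 = 1, p2 = 0))
  expect_equal(division_outcome_probs(1, 0), data.frame(p0 = 0, p1 = 0, p2 = 1))
  grid <- expand.grid(ps = seq(0, 1, 0.1), pd = seq(0, 1, 0.1))
  pr <- division_outcome_probs(grid$ps, grid$pd)
  expect_true(all(pr >= 0))
  expect_equal(pr$p0 + pr$p1 + pr$p2, rep(1, nrow(grid)))
  expect_equal(pr$p1, 1 - grid$ps)
})

test_that("P2's range dominates P0's under strong stem-progeny bias", {
  # over the attainable corrected-pd range, min P2 > max P0 whenever B < 0.5
  pd_corr <- seq(0, 1, 0.01)
  for (ps in c(0.02, 0.05, 0.1, 0.2)) {
    for (B in c(0.3, 0.45, 0.49)) {
      pr <- division_outcome_probs(ps, biased_differentiation_probability(pd_corr, B))
      expect_gt(min(pr$p2), max(pr$p0))
    }
    # at B = 0.6 the ranges overlap but do not coincide
    pr <- division_outcome_probs(ps, biased_differentiation_probability(pd_corr, 0.6))
    expect_lt(min(pr$p2), max(pr$p0))
    expect_gt(max(pr$p2), max(pr$p0))
  }
})

test_that("sampled division types converge to the outcome probabilities", {
  set.seed(401)
  expect_true(all(sample_division_type(500, 0, 0.5) == "ASYMMETRIC"))
  expect_true(all(sample_division_type(500, 1, 1) == "SYM_DIFF"))
  expect_true(all(sample_division_type(500, 1, 0) == "SYM_SELF"))
  n <- 1e5
  tab <- table(sample_division_type(n, 0.2, 0.5)) / n
  # three-standard-error binomial bounds around (0.1, 0.8, 0.1)
  se <- sqrt(c(0.1, 0.8, 0.1) * c(0.9, 0.2, 0.9) / n)
  expect_lt(abs(tab[["SYM_DIFF"]] - 0.1), 3 * se[1])
  expect_lt(abs(tab[["ASYMMETRIC"]] - 0.8), 3 * se[2])
  expect_lt(abs(tab[["SYM_SELF"]] - 0.1), 3 * se[3])
})

test_that("succession detection requires exactly one surviving lineage", {
  expect_equal(detect_succession(c(SC0 = 0, SC1 = 11, SC2 = 0)), "SC1")
  expect_true(is.na(detect_succession(c(SC0 = 5, SC3 = 5))))
  expect_equal(detect_succession(c(SC0 = 1)), "SC0")
  expect_warning(out <- detect_succession(c(SC0 = 0, SC1 = 0)), "extinction")
  expect_true(is.na(out))
  expect_error(detect_succession(c(SC0 = -1)), "non-negative")
})

test_that("iteration counts convert to days at the configured time step", {
  expect_equal(iterations_to_days(2880, 0.5), 60)
  expect_equal(iterations_to_days(0, 0.5), 0)
  expect_equal(iterations_to_days(2200, 0.5), 2200 / 48)
})

test_that("cell-cycle state machine follows the per-step rules", {
  stem <- function(state, t) list(state = state, time_in_state = t,
                                  age = 100, stemness = 1)
  # G1 accumulates dt until TG1 is reached, then advances
  c1 <- step_cell_cycle(stem("G1", 11.5), tc = 24, tg1 = 12)
  expect_equal(c1$state, "G1")
  expect_equal(c1$time_in_state, 12)
  c2 <- step_cell_cycle(stem("G1", 12), tc = 24, tg1 = 12)
  expect_equal(c2$state, "S_G2")
  expect_equal(c2$time_in_state, 0)
  # S+G2 lasts TC - TG1; a transit cell at 8 h (= 12 - 4) enters mitosis
  c3 <- step_cell_cycle(list(state = "S_G2", time_in_state = 8, age = 10,
                             stemness = 5 / 6), tc = 12, tg1 = 4)
  expect_equal(c3$state, "MITOSIS")
  # quiescent cells with positive stemness are promoted to G1
  c4 <- step_cell_cycle(list(state = "QUIESCENT", time_in_state = 3, age = 1,
                             stemness = 0.5), tc = 12, tg1 = 4)
  expect_equal(c4$state, "G1")
  expect_equal(c4$time_in_state, 0)
  # terminally differentiated cells never re-enter the cycle
  c5 <- list(state = "QUIESCENT", time_in_state = 0, age = 0, stemness = 0)
  for (i in 1:10) c5 <- step_cell_cycle(c5, tc = 12, tg1 = 4)
  expect_equal(c5$state, "QUIESCENT")
  expect_equal(c5$age, 5)
  expect_error(step_cell_cycle(stem("LIMBO", 0), 24, 12), "unknown cell state")
})
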