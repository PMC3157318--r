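# Lattice core: initialisation, daughter insertion, migration, shedding,
# and whole-run conservation/confinement invariants.

test_that("initial crypt holds n0 staggered G1 stem cells in the niche row", {
  cells <- init_state(crypt_params(), seed = 1)
  expect_equal(nrow(cells), 10)
  expect_true(all(cells$y == 0))
  expect_equal(cells$x, 0:9)
  expect_true(all(cells$state == 1))          # G1
  expect_true(all(cells$stemness == 1))
  expect_equal(sort(cells$ancestor), 0:9)     # distinct founding lineages
  expect_true(all(cells$age == 0))
  # elapsed G1 phase drawn from {0, dt, ..., TG1 - dt}
  expect_true(all(cells$time_in_state >= 0 & cells$time_in_state <= 11.5))
  expect_true(all(cells$time_in_state %% 0.5 == 0))
  expect_gt(length(unique(cells$time_in_state)), 1)
})

test_that("different seeds change only the G1 phases, not the layout", {
  a <- init_state(crypt_params(), seed = 1)
  b <- init_state(crypt_params(), seed = 2)
  expect_equal(a$x, b$x)
  expect_equal(a$y, b$y)
  expect_equal(a$stemness, b$stemness)
  expect_false(identical(a$time_in_state, b$time_in_state))
})

test_that("invalid lattice configurations are rejected", {
  expect_error(crypt_params(n0 = 12, n_cols = 10), "n0")
  expect_error(crypt_params(n_cols = 0), "lattice")
  expect_error(crypt_params(ps = 1.5), "ps")
  expect_error(crypt_params(bias = -1), "bias")
  expect_error(crypt_params(tg1_stem = 30), "tg1_stem")
  expect_error(crypt_params(dt = 0.7), "multiple")
})

test_that("daughter insertion follows the empty-north priority ladder", {
  M <- 5; N <- 5
  # mother at (2,2); north empty, everything else around occupied
  around <- grid_cells(x = c(2, 1, 3, 2), y = c(2, 2, 2, 1), age = 10)
  expect_equal(choose_site(around, N, M, 2, 2), c(x = 2, y = 3))

  # north occupied, east and west empty: uniform random between them
  occ_n <- grid_cells(x = c(2, 2), y = c(2, 3), age = 10)
  set.seed(7)
  picks <- t(replicate(200, choose_site(occ_n, N, M, 2, 2)))
  expect_true(all(picks[, "y"] == 2))
  expect_setequal(unique(picks[, "x"]), c(1, 3))
  expect_gt(min(table(picks[, "x"])), 60)   # both sides used, roughly evenly

  # only south empty
  no_sew <- grid_cells(x = c(2, 1, 3, 2), y = c(2, 2, 2, 3), age = 10)
  expect_equal(choose_site(no_sew, N, M, 2, 2), c(x = 2, y = 1))

  # everything occupied: uniform over occupied north/east/west, never south
  full <- grid_cells(x = c(2, 1, 3, 2, 2), y = c(2, 2, 2, 3, 1), age = 10)
  set.seed(8)
  picks <- t(replicate(300, choose_site(full, N, M, 2, 2)))
  expect_false(any(picks[, "x"] == 2 & picks[, "y"] == 1))  # south excluded
  key <- paste(picks[, "x"], picks[, "y"])
  expect_setequal(unique(key), c("2 3", "1 2", "3 2"))
})

test_that("stem daughters go east or west in the niche row regardless of occupancy", {
  full_niche <- grid_cells(x = 0:4, y = rep(0, 5), age = 10, stem = TRUE)
  set.seed(9)
  picks <- t(replicate(200, choose_site(full_niche, 5, 5, 2, 0,
                                        stem_daughter = TRUE)))
  expect_true(all(picks[, "y"] == 0))
  expect_setequal(unique(picks[, "x"]), c(1, 3))
})

test_that("columns wrap laterally", {
  # mother at column 0: west neighbour is the last column
  cells <- grid_cells(x = c(0, 0, 1), y = c(0, 1, 0), age = 10)
  expect_equal(choose_site(cells, 5, 5, 0, 0), c(x = 4, y = 0))
})

test_that("migration moves the oldest resident up and pushes the column", {
  # all sites singly occupied: identity
  single <- grid_cells(x = c(0, 1, 2), y = c(0, 1, 2), age = c(5, 6, 7))
  out <- migrate_probe(single, 3, 5)
  expect_equal(out$n_shed, 0)
  expect_equal(out$cells$y, c(0, 1, 2))

  # site (3,5) holds ages 240 and 48; (3,6) and (3,7) occupied above.
  # the 240 h cell moves to (3,6) and the residents above shift up one.
  stack <- grid_cells(x = rep(3, 4), y = c(5, 5, 6, 7), age = c(240, 48, 10, 11))
  out <- migrate_probe(stack, 8, 10)
  got <- out$cells[order(out$cells$age), ]
  expect_equal(out$n_shed, 0)
  expect_equal(got$y[got$age == 240], 6)
  expect_equal(got$y[got$age == 48], 5)
  expect_equal(got$y[got$age == 10], 7)
  expect_equal(got$y[got$age == 11], 8)
})

test_that("a transit newborn sharing a niche site with a stem cell is evicted", {
  pair <- data.frame(x = c(4L, 4L), y = c(0L, 0L), age = c(500L, 0L),
                     stem = c(TRUE, FALSE))
  out <- migrate_probe(pair, 10, 5)
  stem_row <- out$cells[out$cells$stem, ]
  transit_row <- out$cells[!out$cells$stem, ]
  expect_equal(stem_row$y, 0)     # stems are never displaced
  expect_equal(transit_row$y, 1)  # the only non-stem is the one pushed up
})

test_that("a full column sheds exactly one cell per push from below", {
  M <- 6
  col <- grid_cells(x = rep(0, M + 1), y = c(0, 0:(M - 1)),
                    age = c(9, 10, 8, 7, 6, 5, 4))
  out <- migrate_probe(col, 1, M)
  expect_equal(out$n_shed, 1)
  expect_equal(nrow(out$cells), M)
  expect_equal(sort(out$cells$y), 0:(M - 1))
  # no cell at the top beforehand, no multi-occupancy: nothing shed
  quiet <- grid_cells(x = rep(0, 3), y = 0:2, age = 1:3)
  expect_equal(migrate_probe(quiet, 1, M)$n_shed, 0)
})

test_that("population is conserved: births minus sheddings equals growth", {
  run <- simulate_crypt(crypt_params(ps = 0.1, max_iterations = 5000),
                        seed = 11, stop_on_succession = FALSE,
                        record = "summary")
  expect_equal(run$n_iter, 5000)
  pop <- run$population
  expect_equal(diff(pop), (run$births - run$shed)[-1])
  expect_equal(pop[length(pop)], nrow(run$cells))
  expect_equal(pop[1], 10 + run$births[1] - run$shed[1])
})

test_that("stem cells stay confined to the niche row and stemness is quantised", {
  for (seed in c(3, 17)) {
    run <- simulate_crypt(crypt_params(ps = 0.2, max_iterations = 3000),
                          seed = seed, stop_on_succession = FALSE,
                          record = "summary")
    cells <- run$cells
    expect_true(all(cells$y[cells$stemness == 1] == 0))
    expect_true(all(cells$y >= 0 & cells$y < 50))
    expect_true(all(cells$x >= 0 & cells$x < 10))
    # stemness lives on the 1/num_div_max ladder
    expect_true(all(abs(cells$stemness * 6 - round(cells$stemness * 6)) < 1e-12))
    # terminally differentiated cells are quiescent
    expect_true(all(cells$state[cells$stemness == 0] == 0))
    # stem census equals the bottom-row stemness-1 population
    expect_equal(run$ns[run$n_iter],
                 sum(cells$stemness == 1 & cells$y == 0))
  }
})

test_that("pure asymmetric division preserves every founding lineage", {
  run <- simulate_crypt(crypt_params(ps = 0, max_iterations = 10000),
                        seed = 5, stop_on_succession = TRUE)
  expect_equal(run$outcome, "max_iterations")   # no succession can occur
  expect_true(all(run$ns == 10))
  expect_true(all(run$ancestor_counts == 1))    # each lineage keeps one stem
})

test_that("identical parameters and seed reproduce a run bit-for-bit", {
  p <- crypt_params(ps = 0.2, max_iterations = 2000)
  a <- simulate_crypt(p, seed = 99)
  b <- simulate_crypt(p, seed = 99)
  expect_identical(a$ns, b$ns)
  expect_identical(a$ancestor_counts, b$ancestor_counts)
  expect_identical(a$cells, b$cells)
  expect_identical(a$succession, b$succession)
})

test_that("a single founding lineage is monoclonal at iteration zero", {
  p <- crypt_params(n0 = 1, max_iterations = 1000)
  run <- simulate_crypt(p, seed = 4)
  expect_equal(run$outcome, "succession")
  expect_equal(run$succession$iteration, 0)
  expect_equal(run$succession$ancestor, "SC0")
  expect_equal(run$succession$days, 0)
})
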