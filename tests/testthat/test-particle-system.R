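test_that("cell list equals the brute-force oracle on randomized clouds", {
  set.seed(7)
  for (k in 1:50) {
    n <- sample(20:200, 1)
    side <- 2
    x <- runif(n, 0, side)
    y <- runif(n, 0, side)
    ps <- particle_system(x = x, y = y, vx = 0 * x, vy = 0 * x, rho = 1000,
                          mass = 1, phase = PHASE[["FLUID"]], dx = 0.05,
                          bounds = c(0, side, 0, side), check_spacing = FALSE)
    cutoff <- runif(1, 0.1, 0.6)
    cell <- build_cell_list(ps, cutoff)
    ref <- oracle_neighbors(x, y, cutoff)
    expect_identical(lapply(cell, as.integer), ref)
    # symmetry of the neighbor relation, checked in one pass
    pairs <- cbind(rep(seq_len(n), lengths(cell)), unlist(cell))
    expect_true(length(pairs) == 0 ||
                  all(mapply(function(i, j) i %in% cell[[j]],
                             pairs[, 1], pairs[, 2])))
  }
})

test_that("neighbor search edge cases behave", {
  ps2 <- particle_system(x = c(0, 1.05), y = c(0, 0), vx = c(0, 0),
                         vy = c(0, 0), rho = 1000, mass = 1,
                         phase = PHASE[["FLUID"]], dx = 0.5,
                         bounds = c(-1, 2, -1, 1))
  expect_identical(lengths(build_cell_list(ps2, 1)), c(0L, 0L))
  ps1 <- particle_system(x = 0.5, y = 0.5, vx = 0, vy = 0, rho = 1000,
                         mass = 1, phase = PHASE[["FLUID"]], dx = 0.5,
                         bounds = c(0, 1, 0, 1))
  expect_identical(build_cell_list(ps1, 1)[[1]], integer(0))
  expect_error(build_cell_list(ps1, 0), "positive")
  expect_error(build_cell_list(ps1, -1), "positive")
})

test_that("phase census counts every particle and handles the empty ratio", {
  ps <- particle_system(x = 1:7 / 10, y = rep(0.5, 7), vx = rep(0, 7),
                        vy = rep(0, 7), rho = 1000, mass = 1,
                        phase = PHASE[["FLUID"]], dx = 0.1,
                        bounds = c(0, 1, 0, 1))
  pc <- phase_counts(ps)
  expect_identical(unname(pc$counts), c(7L, 0L, 0L, 0L))
  expect_identical(pc$total, 7L)
  expect_true(is.na(pc$live_dead_ratio))
  ps <- set_phase(ps, 1:2, PHASE[["LIVE_CORAL"]])
  ps <- set_phase(ps, 1, PHASE[["DEAD_CORAL"]])
  pc <- phase_counts(ps)
  expect_identical(sum(pc$counts), 7L)
  expect_equal(pc$live_dead_ratio, 1)
})

test_that("only ecological phase transitions are permitted", {
  ps <- particle_system(x = c(0.25, 0.75), y = c(0.5, 0.5), vx = c(0.1, 0),
                        vy = c(0, 0), rho = 1000, mass = 2,
                        phase = c(PHASE[["FLUID"]], PHASE[["WALL"]]),
                        dx = 0.5, bounds = c(0, 1, 0, 1))
  grown <- set_phase(ps, 1, PHASE[["LIVE_CORAL"]])
  expect_identical(grown$phase[1], PHASE[["LIVE_CORAL"]])
  expect_identical(grown$vx[1], 0)          # velocity zeroed at conversion
  expect_identical(grown$mass, ps$mass)     # mass never changes
  dead <- set_phase(grown, 1, PHASE[["DEAD_CORAL"]])
  expect_identical(dead$phase[1], PHASE[["DEAD_CORAL"]])
  expect_error(set_phase(ps, 2, PHASE[["LIVE_CORAL"]]), "illegal")
  expect_error(set_phase(dead, 1, PHASE[["LIVE_CORAL"]]), "illegal")
  expect_error(set_phase(ps, 1, PHASE[["DEAD_CORAL"]]), "illegal")
})

test_that("construction invariants are enforced", {
  expect_error(particle_system(x = c(0, 0.01), y = c(0, 0), vx = c(0, 0),
                               vy = c(0, 0), rho = 1000, mass = 1,
                               phase = PHASE[["FLUID"]], dx = 0.5,
                               bounds = c(0, 1, 0, 1)),
               "closer than")
  expect_error(particle_system(x = 0, y = 0, vx = 0.2, vy = 0, rho = 1000,
                               mass = 1, phase = PHASE[["WALL"]], dx = 0.1,
                               bounds = c(0, 1, 0, 1)),
               "zero velocity")
  expect_error(particle_system(x = 0, y = 0, vx = 0, vy = 0, rho = -5,
                               mass = 1, phase = PHASE[["FLUID"]], dx = 0.1,
                               bounds = c(0, 1, 0, 1)),
               "positive")
  expect_error(particle_system(x = 0, y = 0, vx = 0, vy = 0, rho = 1000,
                               mass = 1, phase = PHASE[["FLUID"]],
                               streak = 3L, dx = 0.1, bounds = c(0, 1, 0, 1)),
               "streak")
})
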