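test_that("steady-state detector follows its definition", {
  expect_true(steady_state_reached(rep(5, 100), 0.05, 20))
  expect_false(steady_state_reached(2^(1:100), 0.05, 20))
  expect_false(steady_state_reached(numeric(0), 0.05, 20))
  expect_false(steady_state_reached(rep(5, 30), 0.05, 20))  # too short
  # exponential decay to a plateau: first steady index matches a direct scan
  ke <- 10 * exp(-(1:400) / 40) + 2
  window <- 25L
  tol <- 0.01
  scan <- vapply(seq_along(ke), function(k) {
    if (k < 2 * window) return(FALSE)
    m2 <- mean(ke[(k - window + 1):k])
    m1 <- mean(ke[(k - 2 * window + 1):(k - window)])
    abs(m2 - m1) / max(abs(m1), abs(m2)) < tol
  }, logical(1))
  first_ref <- which(scan)[1]
  first_pkg <- which(vapply(seq_along(ke), function(k)
    steady_state_reached(ke[1:k], tol, window), logical(1)))[1]
  expect_identical(first_pkg, first_ref)
})

test_that("frozen fixture: band AND proximity select exactly one conversion", {
  fx <- frozen_growth_fixture()
  ge <- growth_event(fx$system, fx$mean_speed, fx$config)
  expect_identical(ge$converted, fx$expected_converted)
  expect_length(ge$converted, 1L)
  # the convert is the particle at 1.4 dx with 0.045 m/s
  d <- sqrt((fx$system$x - fx$system$x[1])^2 +
              (fx$system$y - fx$system$y[1])^2)
  expect_equal(d[ge$converted] / fx$system$dx, 1.4, tolerance = 1e-9)
  expect_equal(fx$mean_speed[ge$converted], 0.045)
  # particle count is conserved by the event
  expect_identical(ge$system$n, fx$system$n)
  expect_identical(sum(phase_counts(ge$system)$counts), fx$system$n)
})

test_that("widening the band or shrinking proximity changes the conversion set", {
  wide <- frozen_growth_fixture(band = c(0.01, 0.10))
  ge <- growth_event(wide$system, wide$mean_speed, wide$config)
  # all fluid particles within proximity convert (1.0 and 1.4 dx)
  expect_length(ge$converted, 2L)
  near <- frozen_growth_fixture(proximity_dx = 0.5)
  ge0 <- growth_event(near$system, near$mean_speed, near$config)
  expect_length(ge0$converted, 0L)
})

test_that("local mean speeds respect the proximity radius", {
  fx <- frozen_growth_fixture()
  ms <- local_mean_speed(fx$system, fx$mean_speed, 1, fx$config)
  d_dx <- sqrt((fx$system$x - fx$system$x[1])^2 +
                 (fx$system$y - fx$system$y[1])^2) / fx$system$dx
  expect_setequal(as.integer(names(ms)), which(d_dx > 0 & d_dx <= 1.5))
  expect_false(any(abs(ms - 0.07) < 1e-12))  # the 1.6 dx particle is excluded
})

test_that("band widening can only grow the conversion set (monotone band)", {
  set.seed(11)
  for (k in 1:10) {
    n <- 40
    ps <- random_system(n = n, dx = 0.05, seed = 100 + k)
    ps$phase[sample(n, 5)] <- PHASE[["LIVE_CORAL"]]
    ps$vx[ps$phase != PHASE[["FLUID"]]] <- 0
    ps$vy[ps$phase != PHASE[["FLUID"]]] <- 0
    speeds <- runif(n, 0, 0.12)
    narrow <- goldilocks_config(v_opt_min = 0.03, v_opt_max = 0.06)
    wide <- goldilocks_config(v_opt_min = 0.02, v_opt_max = 0.08)
    a <- growth_event(ps, speeds, narrow)$converted
    b <- growth_event(ps, speeds, wide)$converted
    expect_true(all(a %in% b))
  }
})

test_that("the death rule increments, resets, and kills on streaks", {
  # one live coral with a single adjacent fluid particle
  dx <- 0.05
  ps <- particle_system(x = c(0.5, 0.55), y = c(0.5, 0.5), vx = c(0, 0.01),
                        vy = c(0, 0), rho = 1000, mass = 2.5,
                        phase = c(PHASE[["LIVE_CORAL"]], PHASE[["FLUID"]]),
                        dx = dx, bounds = c(0, 1, 0, 1))
  cfg <- goldilocks_config(death_interval = 5)
  sub <- c(NA, 0.1)    # adjacent speed above the band: suboptimal
  opt <- c(NA, 0.045)  # in band: optimal
  s <- ps
  for (k in 1:4) {
    de <- death_event(s, sub, cfg)
    s <- de$system
    expect_identical(s$streak[1], k)
    expect_length(de$died, 0L)
  }
  # a single optimal evaluation resets the streak
  s2 <- death_event(s, opt, cfg)$system
  expect_identical(s2$streak[1], 0L)
  expect_identical(s2$phase[1], PHASE[["LIVE_CORAL"]])
  # the fifth consecutive suboptimal event kills
  de <- death_event(s, sub, cfg)
  expect_identical(de$died, 1L)
  expect_identical(de$system$phase[1], PHASE[["DEAD_CORAL"]])
  # interior coral with no adjacent fluid is suboptimal by construction
  lone <- particle_system(x = 0.5, y = 0.5, vx = 0, vy = 0, rho = 1000,
                          mass = 2.5, phase = PHASE[["LIVE_CORAL"]],
                          dx = dx, bounds = c(0, 1, 0, 1))
  expect_identical(death_event(lone, NA_real_, cfg)$system$streak[1], 1L)
  # K = Inf: streaks accumulate but nothing ever dies
  cfg_inf <- goldilocks_config(death_interval = Inf)
  s <- ps
  for (k in 1:20) s <- death_event(s, sub, cfg_inf)$system
  expect_identical(s$phase[1], PHASE[["LIVE_CORAL"]])
  expect_identical(s$streak[1], 20L)
  # accumulate-without-reset sensitivity mode never resets
  cfg_acc <- goldilocks_config(death_interval = 10, reset_streak = FALSE)
  s <- ps
  s <- death_event(s, sub, cfg_acc)$system
  s <- death_event(s, opt, cfg_acc)$system
  expect_identical(s$streak[1], 1L)
})

test_that("a per-event cap recovers the one-particle-per-step reading", {
  wide <- frozen_growth_fixture(band = c(0.01, 0.10))
  cfg1 <- goldilocks_config(v_opt_min = 0.01, v_opt_max = 0.10,
                            cap_per_event = 1)
  ge <- growth_event(wide$system, wide$mean_speed, cfg1)
  expect_length(ge$converted, 1L)
})
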