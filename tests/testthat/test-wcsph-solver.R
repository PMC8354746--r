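test_that("Tait equation of state matches direct arithmetic", {
  fp <- fluid_properties(rho0 = 1000, cs = 10, gamma = 7)
  expect_equal(fp$B, 1000 * 10^2 / 7)       # about 14285.7 Pa
  expect_identical(tait_pressure(1000, fp), 0)
  expect_equal(tait_pressure(1010, fp), (1000 * 100 / 7) * (1.01^7 - 1))
  # strictly increasing in density
  rho <- seq(950, 1050, by = 10)
  expect_true(all(diff(tait_pressure(rho, fp)) > 0))
  expect_error(tait_pressure(-1, fp), "blow-up")
  expect_error(tait_pressure(0, fp), "blow-up")
})

test_that("pair sums match all-pairs oracle evaluation to 1e-12 relative", {
  fp <- fluid_properties()
  for (seed in 1:3) {
    ps <- random_system(n = 50, dx = 0.1, seed = seed, props = fp)
    ks <- kernel_spec(1.3 * ps$dx)
    dr <- continuity_rhs(ps, ks)
    dr_ref <- oracle_continuity(ps, ks$h)
    expect_equal(dr, dr_ref, tolerance = 1e-12)
    mom <- momentum_rhs(ps, fp, ks)
    mom_ref <- oracle_momentum(ps, ks$h, fp$mu)
    expect_equal(mom$ax, mom_ref$ax, tolerance = 1e-12)
    expect_equal(mom$ay, mom_ref$ay, tolerance = 1e-12)
    sm <- smooth_density(ps, ks, epsilon = 0.01)
    sm_ref <- oracle_smooth(ps, ks$h, 0.01)
    expect_equal(sm, sm_ref, tolerance = 1e-12)
  }
})

test_that("continuity responds to compression and ignores uniform motion", {
  fp <- fluid_properties()
  ps <- random_system(n = 30, dx = 0.1, seed = 4, props = fp)
  ks <- kernel_spec(1.3 * ps$dx)
  ps$vx <- rep(0.3, ps$n); ps$vy <- rep(-0.1, ps$n)
  expect_equal(continuity_rhs(ps, ks), rep(0, ps$n), tolerance = 1e-14)
  # two particles approaching head-on compress: drho/dt > 0 for both
  two <- particle_system(x = c(0, 0.1), y = c(0, 0), vx = c(0.1, -0.1),
                         vy = c(0, 0), rho = 1000, mass = 2.5,
                         phase = PHASE[["FLUID"]], dx = 0.05,
                         bounds = c(-1, 1, -1, 1))
  expect_true(all(continuity_rhs(two, kernel_spec(0.065)) > 0))
})

test_that("momentum interaction is pairwise antisymmetric and conservative", {
  fp <- fluid_properties(mu = 0)
  two <- random_system(n = 2, dx = 0.1, seed = 5, props = fp)
  ks <- kernel_spec(1.3 * two$dx)
  m <- momentum_rhs(two, fp, ks)
  expect_equal(two$mass[1] * m$ax[1], -two$mass[2] * m$ax[2])
  expect_equal(two$mass[1] * m$ay[1], -two$mass[2] * m$ay[2])
  # uniform pressure and velocity, no body force: zero acceleration where
  # the kernel support is symmetric (lattice interior; a constant field has
  # no SPH gradient only over balanced neighborhoods)
  g <- expand.grid(x = (1:10 - 0.5) * 0.1, y = (1:10 - 0.5) * 0.1)
  ps <- particle_system(x = g$x, y = g$y, vx = rep(0.2, nrow(g)),
                        vy = rep(0.2, nrow(g)), rho = 1000,
                        mass = 10, phase = PHASE[["FLUID"]], dx = 0.1,
                        bounds = c(0, 1, 0, 1))
  ps$p <- rep(500, ps$n)
  m <- momentum_rhs(ps, fp, kernel_spec(1.3 * ps$dx))
  interior <- g$x > 0.3 & g$x < 0.7 & g$y > 0.3 & g$y < 0.7
  expect_lt(max(abs(m$ax[interior])), 1e-9)
  expect_lt(max(abs(m$ay[interior])), 1e-9)
  # closed random system: total momentum rate is zero to machine precision
  ps <- random_system(n = 50, dx = 0.1, seed = 7, props = fluid_properties())
  m <- momentum_rhs(ps, fluid_properties(), kernel_spec(1.3 * ps$dx))
  scale <- max(abs(ps$mass * m$ax)) + max(abs(ps$mass * m$ay))
  expect_lt(abs(sum(ps$mass * m$ax)) / scale, 1e-12)
  expect_lt(abs(sum(ps$mass * m$ay)) / scale, 1e-12)
})

test_that("density filter is the identity for uniform fields and eps = 0", {
  ps <- random_system(n = 30, dx = 0.1, seed = 8)
  ks <- kernel_spec(1.3 * ps$dx)
  expect_identical(smooth_density(ps, ks, epsilon = 0), ps$rho)
  ps$rho <- rep(1000, ps$n)
  expect_equal(smooth_density(ps, ks, epsilon = 0.01), ps$rho)
  expect_error(smooth_density(ps, ks, epsilon = 1), "epsilon")
})

test_that("time-step control uses the most restrictive cap", {
  fp <- fluid_properties(cs = 10, mu = 1e-9)
  ps <- particle_system(x = c(0.25, 0.75), y = c(0.5, 0.5), vx = c(0.5, 0),
                        vy = c(0, 0), rho = 1000, mass = 2.5,
                        phase = PHASE[["FLUID"]], dx = 0.05,
                        bounds = c(0, 1, 0, 1))
  ks <- kernel_spec(0.065)
  # acoustic-limited: cfl * h / (cs + vmax)
  expect_equal(compute_dt(ps, fp, ks), 0.25 * 0.065 / 10.5)
  # doubling cs strictly decreases dt
  expect_lt(compute_dt(ps, fluid_properties(cs = 20, mu = 1e-9), ks),
            compute_dt(ps, fp, ks))
  # a strong body force binds through the sqrt(h / f) cap
  fpF <- fluid_properties(cs = 10, mu = 1e-9, body_force = c(0, -1e7))
  expect_equal(compute_dt(ps, fpF, ks), 0.25 * sqrt(0.065 / 1e4))
})

test_that("Verlet integration reproduces ballistic motion and respects walls", {
  # single free particle under constant F/rho = g for 1 s
  g <- 9.81
  fp <- fluid_properties(mu = 0, epsilon = 0, body_force = c(0, -1000 * g))
  ps <- particle_system(x = 0, y = 0, vx = 0, vy = 0, rho = 1000, mass = 1,
                        phase = PHASE[["FLUID"]], dx = 0.1,
                        bounds = c(-100, 100, -100, 100))
  ks <- kernel_spec(0.13)
  st <- advance(ps, fp, ks, n_steps = 100, dt = 0.01, smooth_every = 0)
  expect_equal(st$system$y, -0.5 * g * 1^2, tolerance = 1e-4)
  expect_equal(st$system$vy, -g, tolerance = 1e-4)
  # a wall particle under the same force does not move
  wall <- particle_system(x = 0, y = 0, vx = 0, vy = 0, rho = 1000, mass = 1,
                          phase = PHASE[["WALL"]], dx = 0.1,
                          bounds = c(-100, 100, -100, 100))
  stw <- advance(wall, fp, ks, n_steps = 100, dt = 0.01, smooth_every = 0)
  expect_identical(stw$system$x, 0)
  expect_identical(stw$system$y, 0)
  # dt = 0 leaves the state unchanged
  st0 <- verlet_step(ps, fp, ks, dt = 0)
  expect_identical(st0$system$x, ps$x)
  expect_identical(st0$system$vx, ps$vx)
})
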