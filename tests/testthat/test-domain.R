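test_that("default domain lattice holds 20 000 fluid sites", {
  props <- fluid_properties()
  # without a seed the interior is exactly (width/dx) * (height/dx) fluid
  d0 <- domain_spec(seed_radius = 0)
  ps0 <- build_domain(d0, props)
  pc0 <- phase_counts(ps0)
  expect_identical(pc0$counts[["FLUID"]], 20000L)
  # with the seed, conversions keep the interior total at 20 000
  d1 <- domain_spec()
  ps1 <- build_domain(d1, props)
  pc1 <- phase_counts(ps1)
  expect_identical(pc1$counts[["FLUID"]] + pc1$counts[["LIVE_CORAL"]], 20000L)
  expect_gt(pc1$counts[["LIVE_CORAL"]], 0L)
  expect_identical(pc1$counts[["DEAD_CORAL"]], 0L)
  # every particle has mass rho0 dx^2
  expect_true(all(ps1$mass == props$rho0 * 0.05^2))
})

test_that("small lattice and geometric seed oracle", {
  props <- fluid_properties()
  d <- domain_spec(width = 1, height = 1, dx = 0.5, wall_layers = 3,
                   seed_radius = 0)
  pc <- phase_counts(build_domain(d, props))
  expect_identical(pc$counts[["FLUID"]], 4L)   # 2 x 2 lattice
  # live-coral count equals direct point-in-half-disc enumeration
  d <- domain_spec(width = 2, height = 1, dx = 0.05, seed_radius = 0.25)
  ps <- build_domain(d, props)
  gx <- (seq_len(40) - 0.5) * 0.05
  gy <- (seq_len(20) - 0.5) * 0.05
  pts <- expand.grid(x = gx, y = gy)
  n_expected <- sum((pts$x - 1)^2 + pts$y^2 <= 0.25^2)
  expect_identical(phase_counts(ps)$counts[["LIVE_CORAL"]],
                   as.integer(n_expected))
  # a seed smaller than the spacing cannot hold a particle
  expect_error(build_domain(domain_spec(seed_radius = 0.01), props),
               "seed")
  expect_error(domain_spec(width = 1.03, dx = 0.05), "integer multiples")
})

test_that("inlet profile is anchored at the seabed and peaks at the lid", {
  d <- domain_spec()
  expect_identical(inlet_profile(0, d), 0)
  expect_equal(inlet_profile(d$height, d), d$lid_speed)
  expect_equal(inlet_profile(d$height / 2, d), d$lid_speed * 0.75)
  # monotone increasing with height
  y <- seq(0, d$height, length.out = 50)
  expect_true(all(diff(inlet_profile(y, d)) >= 0))
})

test_that("boundary conditions prescribe bands and recycle the outflow", {
  props <- fluid_properties()
  d <- domain_spec(width = 2, height = 1, dx = 0.05, seed_radius = 0.25)
  ps <- build_domain(d, props)
  solid <- ps$phase != PHASE[["FLUID"]]
  expect_true(all(ps$vx[solid] == 0 & ps$vy[solid] == 0))
  inlet <- ps$phase == PHASE[["FLUID"]] & ps$x < d$inlet_cols * d$dx
  lid <- ps$phase == PHASE[["FLUID"]] & !inlet &
    ps$y > d$height - d$lid_rows * d$dx
  expect_true(all(ps$vx[lid] == d$lid_speed))
  expect_equal(ps$vx[inlet], inlet_profile(ps$y[inlet], d))
  # recycling: push a particle past the outlet, reapply, count unchanged
  n0 <- ps$n
  i <- which(!solid & !lid & !inlet)[1]
  ps$x[i] <- d$width + 0.01
  ps2 <- apply_boundary_conditions(ps, d, rho0 = props$rho0)
  expect_identical(ps2$n, n0)
  expect_true(all(ps2$x[ps2$phase == PHASE[["FLUID"]]] <= d$width))
  expect_equal(ps2$vx[i], inlet_profile(ps2$y[i], d))
  expect_equal(ps2$rho[i], props$rho0)
})

test_that("flow past the colony is sheltered in its wake", {
  # short spin-up of the reduced scenario; speeds adjacent to the coral fall
  # below the free stream (the colony baffles the current)
  cfg <- reduced_scenario_config()
  spec <- cfg$domain
  ks <- kernel_spec(1.3 * spec$dx)
  ps <- build_domain(spec, cfg$fluid, ks)
  st <- advance(ps, cfg$fluid, ks, n_steps = 1500, flow = scenario_flow(spec),
                avg_window = 300)
  ps <- st$system
  coral <- which(ps$phase == PHASE[["LIVE_CORAL"]])
  nb <- build_cell_list(ps, 1.5 * spec$dx)
  adj <- setdiff(unique(unlist(nb[coral])), coral)
  adj <- adj[ps$phase[adj] == PHASE[["FLUID"]]]
  expect_gt(length(adj), 0)
  free_stream <- spec$lid_speed
  expect_lt(max(st$mean_speed[adj]), free_stream)
  expect_lt(mean(st$mean_speed[adj]), 0.5 * free_stream)
})
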