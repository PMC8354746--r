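test_that("kernel spec enforces its invariants", {
  ks <- kernel_spec(0.065)
  expect_equal(ks$support, 0.13)
  expect_equal(ks$alpha2d, 7 / (4 * pi))
  expect_error(kernel_spec(-1), "positive")
  expect_error(kernel_spec(c(1, 2)), "scalar")
  expect_error(wendland_value(c(NaN, 0), ks), "non-finite")
  expect_error(wendland_gradient(c(Inf, 0), ks), "non-finite")
})

test_that("kernel value matches the closed form and has compact support", {
  ks <- kernel_spec(1)
  expect_equal(wendland_value(c(0, 0), ks), 7 / (4 * pi))
  # zero branch: |r| = 2.5 h and exactly at the support edge
  expect_identical(wendland_value(c(2.5, 0), ks), 0)
  expect_identical(wendland_value(c(0, 2), ks), 0)
  g <- wendland_gradient(c(2.5, 0), ks)
  expect_identical(as.numeric(g), c(0, 0))
  # positive inside the support
  expect_gt(wendland_value(c(1, 0.5), ks), 0)
})

test_that("unity condition holds to 1e-6 across smoothing lengths", {
  for (h in c(0.05, 0.065, 0.1)) {
    ks <- kernel_spec(h)
    f <- function(r) vapply(r, function(ri)
      wendland_value(c(ri, 0), ks) * 2 * pi * ri, numeric(1))
    q <- integrate(f, 0, 2 * h, rel.tol = 1e-10)
    expect_equal(q$value, 1, tolerance = 1e-6)
  }
})

test_that("kernel-weighted average converges to the point value as h shrinks", {
  # quadratic test function; midpoint-rule quadrature of f * W over the
  # support approximates f at the centre with error shrinking in h
  f <- function(x, y) 2 + 3 * x + x^2 - 0.5 * y^2
  centre <- c(0.3, 0.4)
  errs <- vapply(c(0.2, 0.1, 0.05), function(h) {
    ks <- kernel_spec(h)
    g <- seq(-2 * h, 2 * h, length.out = 81)
    dg <- g[2] - g[1]
    gx <- outer(g, rep(1, length(g)))
    gy <- t(gx)
    w <- matrix(wendland_value(cbind(as.numeric(gx), as.numeric(gy)), ks),
                nrow = length(g))
    est <- sum(w * f(centre[1] + gx, centre[2] + gy)) * dg^2
    abs(est - f(centre[1], centre[2]))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
})

test_that("gradient is antisymmetric, inward, and matches finite differences", {
  ks <- kernel_spec(0.8)
  expect_identical(as.numeric(wendland_gradient(c(0, 0), ks)), c(0, 0))
  set.seed(42)
  for (k in 1:25) {
    r <- runif(2, -1.5, 1.5) * ks$h
    if (sqrt(sum(r^2)) < 1e-3 || sqrt(sum(r^2)) >= 2 * ks$h) next
    g <- wendland_gradient(r, ks)
    # antisymmetry under r -> -r
    expect_equal(as.numeric(wendland_gradient(-r, ks)), -as.numeric(g))
    # radial component non-positive (monotone decreasing kernel)
    expect_lte(sum(g * r), 0)
    # central finite difference of the value
    eps <- 1e-7
    fd <- c((wendland_value(r + c(eps, 0), ks) -
               wendland_value(r - c(eps, 0), ks)) / (2 * eps),
            (wendland_value(r + c(0, eps), ks) -
               wendland_value(r - c(0, eps), ks)) / (2 * eps))
    expect_equal(as.numeric(g), fd, tolerance = 1e-6)
  }
})
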