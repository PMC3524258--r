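test_that("raft counting follows the geometry", {
  p <- default_params()
  g <- raft_geometry(p)
  expect_equal(g$n_rafts, round(0.3 * 8e-6 / (pi * (1e-5)^2)))
  # coverage recovered within one raft's area
  expect_lt(abs(g$n_rafts * pi * g$radius_cm^2 / g$area - g$coverage),
            pi * g$radius_cm^2 / g$area)
  expect_gt(g$outer_cm, g$radius_cm)
  expect_error(raft_geometry(radius = -1, coverage = 0.3, area = 8e-6),
               "radius")
  expect_error(raft_geometry(radius = 100, coverage = 0, area = 8e-6),
               "coverage")
})

test_that("the partition relation converts rho to entry rates", {
  # rho = 0.85, lambda = 10 s: ~1.8 s spent outside rafts per cycle
  expect_equal(1 / entry_rate_from_partition(0.85, 10), 10 * 0.15 / 0.85)
  # rho = 1/2: mean time outside equals the raft lifetime
  expect_equal(1 / entry_rate_from_partition(0.5, 7), 7)
  expect_equal(1 / entry_rate_from_partition(0.30, 10), 10 * 0.7 / 0.3)
  expect_error(entry_rate_from_partition(1, 10), "infinite")
  expect_error(entry_rate_from_partition(0.5, 0), "lambda")
})

test_that("the entry rate round-trips through two-state exchange", {
  for (rho in c(0.06, 0.3, 0.5, 0.85, 0.99)) for (lam in c(0.1, 1, 10)) {
    kN <- entry_rate_from_partition(rho, lam)
    expect_equal(kN / (kN + 1 / lam), rho, tolerance = 1e-12)
  }
})

test_that("the transient-trap Bessel closed form matches a finite-difference solution", {
  g <- raft_geometry(default_params())
  s <- g$radius_cm; b <- g$outer_cm; D <- 1e-8
  fd_ubar <- function(lambda, n = 3000) {
    r <- seq(s, b, length.out = n); h <- r[2] - r[1]
    M <- matrix(0, n, n); rhs <- numeric(n)
    M[1, 1] <- 1; rhs[1] <- 1
    for (i in 2:(n - 1)) {
      M[i, i - 1] <- D * (1 / h^2 - 1 / (2 * r[i] * h))
      M[i, i] <- -2 * D / h^2 - 1 / lambda
      M[i, i + 1] <- D * (1 / h^2 + 1 / (2 * r[i] * h))
    }
    M[n, n - 1] <- 2 * D / h^2
    M[n, n] <- -2 * D / h^2 - 1 / lambda
    u <- solve(M, rhs)
    2 * sum(u * r) * h / (b^2 - s^2)
  }
  for (lam in c(0.003, 0.015, 0.1, 1)) {
    expect_equal(raftsig:::capture_probability(s, b, lam, D), fd_ubar(lam),
                 tolerance = 1e-3)
  }
})

test_that("the permanent-trap limit recovers the annulus mean capture time", {
  g <- raft_geometry(default_params())
  s <- g$radius_cm; b <- g$outer_cm; D <- 1e-8
  # closed-form mean first-passage time, absorbing disk in reflecting
  # annulus: T(r) = (b^2/(2D)) ln(r/s) - (r^2 - s^2)/(4D), area-averaged
  Tr <- function(r) (b^2 / (2 * D)) * log(r / s) - (r^2 - s^2) / (4 * D)
  r <- seq(s, b, length.out = 20000)
  Tbar <- 2 * sum(Tr(r) * r) * (r[2] - r[1]) / (b^2 - s^2)
  kN_inf <- diffusion_limited_rate(g, 1e9, D) * g$density
  expect_equal(1 / kN_inf, Tbar, tolerance = 1e-3)
})

test_that("the diffusion-limited rate is monotone in lifetime and linear in D", {
  g <- raft_geometry(default_params())
  lams <- 10^seq(-3, 2, length.out = 30)
  k <- vapply(lams, function(l) diffusion_limited_rate(g, l, 1e-8), 0)
  expect_true(all(diff(k) <= 1e-12))  # shorter-lived traps capture faster
  # linear scaling in D at fixed dimensionless groups (s/b, s^2/(D lambda))
  k1 <- diffusion_limited_rate(g, 0.015, 1e-8)
  k2 <- diffusion_limited_rate(g, 0.0015, 1e-7)
  expect_equal(k2 / k1, 10, tolerance = 1e-10)
})

test_that("the minimum lifetime scales with raft area at fixed coverage", {
  p <- default_params()
  l100 <- min_raft_lifetime(raft_geometry(p), 0.85, p$d_raft)
  l1000 <- min_raft_lifetime(raft_geometry(p, radius = 1000), 0.85,
                             p$d_raft)
  # exact s^2 scaling up to integer rounding of the raft count
  expect_equal(l1000 / l100, 100, tolerance = 0.02)
  # a smaller partition coefficient demands less and shifts the limit down
  l_small <- min_raft_lifetime(raft_geometry(p), 0.3, p$d_raft)
  expect_lt(l_small, l100)
})

test_that("detergent extrapolation reproduces the aggregated-receptor rho", {
  # independent arithmetic: line through (0.06, 65.6), (0.1, 52.9)
  slope <- (52.9 - 65.6) / (0.1 - 0.06)
  expect_equal(extrapolate_partition(), 65.6 - slope * 0.06,
               tolerance = 1e-10)
})

test_that("the Syk off-rate change shortens the complex lifetime by 35%", {
  expect_equal(syk_lifetime_reduction(0.13, 0.2), 0.35)
  expect_equal(syk_lifetime_reduction(0.2, 0.2), 0)
})

test_that("the kinetics report flags physical consistency", {
  df <- suppressMessages(withr::with_output_sink(
    tempfile(), raft_report(default_params())))
  expect_true(all(df$within_diffusion_limit))
  expect_setequal(df$class, c("monomer", "dimer", "lyn", "lat"))
})
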