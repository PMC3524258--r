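test_that("half-life interpolation is exact on analytic decays", {
  t <- seq(0, 30, by = 0.5)
  for (k in c(0.05, 0.1, 0.7)) {
    expect_equal(half_life(t, exp(-k * t)), log(2) / k, tolerance = 1e-9)
  }
  expect_true(is.na(half_life(t, rep(1, length(t)))))
  expect_equal(half_life(t, c(0.4, exp(-0.1 * t[-1]))), 0)
})

test_that("normalized dephosphorylation curves start at one and stay in range", {
  cv <- cached_curves()
  for (a in names(cv)) {
    w <- cv[[a]]
    for (o in setdiff(names(w), "time")) {
      expect_equal(w[[o]][1], 1)
      expect_true(all(w[[o]] >= 0 & w[[o]] <= 1 + 1e-8))
      # monotone loss of phosphorylation after receptor disaggregation
      expect_lt(w[[o]][nrow(w)], 0.5)
    }
  }
})

test_that("steady-state phosphorylation decreases with raft PTPase access", {
  # larger alpha = more dephosphorylation in rafts, all else equal
  o <- sapply(c("0.1", "0.5", "1"), function(a)
    observables(cached_ss(as.numeric(a), 1e-9)$state,
                cached_net(as.numeric(a))))
  for (obs in c("beta", "gamma", "syk", "lat"))
    expect_true(all(diff(o[obs, ]) < 0))
})

test_that("hapten inhibition fails fast when nothing is phosphorylated", {
  expect_error(
    hapten_inhibition(alphas = 0.2, times = c(0, 1), ligand = 0),
    "zero phosphorylation")
})

test_that("raft lifetime shifts dephosphorylation as the exchange clock", {
  cv10 <- cached_curves()
  p100 <- default_params(raft_lifetime = 100)
  p1 <- default_params(raft_lifetime = 1)
  c100 <- dephos_curves(0.2, p100, times = seq(0, 180, by = 0.5),
                        observables = c("gamma", "lat"))[["0.2"]]
  c1 <- dephos_curves(c(0.2, 1), p1, times = seq(0, 180, by = 0.5),
                      observables = c("gamma", "lat"))
  hl <- function(w, o) half_life(w$time, w[[o]])
  ref <- cv10[["0.2"]]
  # longer-lived rafts slow gamma and LAT dephosphorylation
  expect_gt(hl(c100, "gamma"), hl(ref, "gamma"))
  expect_gt(hl(c100, "lat"), hl(ref, "lat"))
  # short-lived rafts push curves toward the no-protection case
  gap_1 <- abs(hl(c1[["0.2"]], "lat") - hl(c1[["1"]], "lat"))
  gap_10 <- abs(hl(ref, "lat") -
                  hl(cached_curves()[["1"]], "lat"))
  expect_lt(gap_1, gap_10)
})

test_that("the lifetime sweep rejects lifetimes beyond the diffusion limit", {
  sw <- lifetime_sweep(lambdas = c(0.005), alphas = 0.2,
                       times = c(0, 1))
  expect_true(is.character(sw[["0.005"]]))
  expect_match(sw[["0.005"]], "diffusion limit")
})

test_that("identical Lyn partitioning yields no mutation effect", {
  m <- lyn_mutation(alpha = 0.2, rho_wt = 0.32, rho_ca = 0.32,
                    params = default_params(lyn_mutant = FALSE))
  # same rho; the only difference left is the mutant monomer rule
  expect_true(all(abs(m$reduction_pct) < 15))
  expect_error(lyn_mutation(rho_wt = 0, rho_ca = 0.06), "rho_wt")
})

test_that("dose-response reports fold changes at the dose nearest 5 nM", {
  doses <- default_dose_grid()
  ref <- doses[which.min(abs(doses - 5e-9))]
  expect_equal(ref, 10^0.75 * 1e-9, tolerance = 1e-9)
})
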