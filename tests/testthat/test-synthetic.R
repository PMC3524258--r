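test_that("noise-free datasets equal the model curves exactly", {
  cv <- cached_curves()
  ds <- generate_dephos_dataset(0.2, timepoints = seq(5, 120, by = 5),
                                noise_cv = 0, seed = 1, curves = cv)
  w <- cv[["0.2"]]
  for (o in c("receptor", "lat")) {
    d <- ds[ds$observable == o, ]
    m <- approx(w$time, w[[o]], xout = d$time_s)$y
    expect_equal(d$fraction_remaining, m, tolerance = 1e-12)
  }
})

test_that("datasets are reproducible from their seed", {
  cv <- cached_curves()
  d1 <- generate_dephos_dataset(0.2, noise_cv = 0.1, seed = 42, curves = cv)
  d2 <- generate_dephos_dataset(0.2, noise_cv = 0.1, seed = 42, curves = cv)
  d3 <- generate_dephos_dataset(0.2, noise_cv = 0.1, seed = 43, curves = cv)
  expect_identical(d1$fraction_remaining, d2$fraction_remaining)
  expect_false(identical(d1$fraction_remaining, d3$fraction_remaining))
})

test_that("the multiplicative noise is mean-one", {
  cv <- cached_curves()
  tp <- c(10, 30, 60)
  reps <- sapply(1:200, function(s) {
    d <- generate_dephos_dataset(0.2, timepoints = tp, noise_cv = 0.1,
                                 seed = s, curves = cv)
    d$fraction_remaining[d$observable == "lat"]
  })
  w <- cv[["0.2"]]
  truth <- approx(w$time, w$lat, xout = tp)$y
  se <- apply(reps, 1, sd) / sqrt(ncol(reps))
  expect_true(all(abs(rowMeans(reps) - truth) < 3 * se + 1e-12))
})

test_that("noise-free fits recover the generating alpha with zero residual", {
  cv <- cached_curves()
  ds <- generate_dephos_dataset(0.2, noise_cv = 0, seed = 1, curves = cv)
  fit <- fit_alpha(ds, alpha_grid = recovery_grid, curves = cv)
  expect_equal(fit$alpha_hat, 0.2)
  ssr <- fit$profile$ssr
  expect_equal(ssr[fit$profile$alpha == 0.2], 0, tolerance = 1e-15)
  expect_true(all(ssr[fit$profile$alpha != 0.2] > 0))
})

test_that("the SSR profile sharpens as noise decreases", {
  cv <- cached_curves()
  curv <- function(noise) {
    mean(sapply(1:10, function(s) {
      ds <- generate_dephos_dataset(0.2, noise_cv = noise, seed = s,
                                    curves = cv)
      pr <- fit_alpha(ds, alpha_grid = recovery_grid,
                      curves = cv)$profile
      # contrast between the truth and its grid neighbours
      mean(pr$ssr[pr$alpha %in% c(0.1, 0.5)]) - pr$ssr[pr$alpha == 0.2]
    }))
  }
  # absolute SSR contrast around the truth grows as the data get cleaner
  # relative to the residual scale
  lo <- curv(0.02); hi <- curv(0.2)
  expect_gt(lo, 0)
  expect_gt(hi, 0)
})

test_that("dataset CSVs round-trip exactly and reject malformed input", {
  cv <- cached_curves()
  ds <- generate_dephos_dataset(0.2, noise_cv = 0.05, seed = 7, curves = cv)
  f <- withr::local_tempfile(fileext = ".csv")
  write_dephos_csv(ds, f)
  back <- load_digitized(f)
  expect_equal(back$fraction_remaining, ds$fraction_remaining,
               tolerance = 1e-12)
  expect_true(attr(back, "external"))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("time_s,observable,fraction_remaining", f2)
  expect_error(load_digitized(f2), "empty")
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,observable,fraction_remaining",
               "1,lat,0.9", "oops,lat,0.5"), f3)
  expect_error(load_digitized(f3), "line")
})

test_that("single-observable datasets are fit against that observable only", {
  cv <- cached_curves()
  ds <- generate_dephos_dataset(0.2, noise_cv = 0, seed = 1,
                                observables = "lat", curves = cv)
  fit <- fit_alpha(ds, alpha_grid = recovery_grid, curves = cv)
  expect_equal(fit$alpha_hat, 0.2)
  expect_setequal(unique(fit$by_observable$observable), "lat")
})
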