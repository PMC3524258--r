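#' Generate a synthetic dephosphorylation dataset
#'
#' Emulates a hapten-inhibition immunoblot experiment: the model's
#' normalized dephosphorylation curves at a known raft protection level
#' `alpha_true` are sampled at discrete timepoints and multiplied by
#' independent lognormal mean-one factors with coefficient of variation
#' `noise_cv` (densitometry noise is ratio-scale, so the noise is
#' multiplicative). The generating configuration and seed are recorded so
#' datasets are exactly reproducible.
#'
#' @param alpha_true generating raft protection level.
#' @param timepoints sampling times (s) within the simulated range.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer RNG seed.
#' @param params base parameter set.
#' @param observables observables to include; the default mirrors the
#'   receptor/LAT readout of the hapten-inhibition immunoblots.
#' @param curves optional precomputed model curves from [dephos_curves()]
#'   (avoids re-simulation).
#' @return object of class `raft_dataset`: data.frame (`time_s`,
#'   `observable`, `fraction_remaining`) with attributes `alpha_true`,
#'   `noise_cv`, `seed`, `external = FALSE`.
#' @export
generate_dephos_dataset <- function(alpha_true, timepoints = seq(5, 120, by = 5),
                                    noise_cv = 0.1, seed = 1,
                                    params = default_params(),
                                    observables = c("receptor", "lat"),
                                    curves = NULL) {
  stopifnot(noise_cv >= 0, all(timepoints >= 0))
  if (is.null(curves))
    curves <- dephos_curves(alpha_true, params, observables = observables)
  cv <- curves[[as.character(alpha_true)]]
  if (is.null(cv))
    stop("curves do not contain alpha = ", alpha_true)
  df <- do.call(rbind, lapply(observables, function(o) {
    v <- stats::approx(cv$time, cv[[o]], xout = timepoints)$y
    if (anyNA(v)) stop("timepoints outside the simulated range")
    data.frame(time_s = timepoints, observable = o, fraction_remaining = v)
  }))
  set.seed(seed)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    fac <- stats::rlnorm(nrow(df), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    df$fraction_remaining <- df$fraction_remaining * fac
  }
  structure(df, alpha_true = alpha_true, noise_cv = noise_cv, seed = seed,
            external = FALSE, class = c("raft_dataset", "data.frame"))
}

#' Simulate normalized dephosphorylation curves for a set of alphas
#'
#' Convenience wrapper around [hapten_inhibition()] returning, per alpha, a
#' data.frame of time plus one column per observable. Used by
#' [generate_dephos_dataset()] and [fit_alpha()]; precompute once when
#' fitting many datasets.
#'
#' @param alphas raft protection levels.
#' @param params base parameter set.
#' @param times simulation grid (s).
#' @param observables observables to keep.
#' @return named list (by alpha) of data.frames.
#' @export
dephos_curves <- function(alphas, params = default_params(),
                          times = seq(0, 180, by = 0.5),
                          observables = c("receptor", "lat")) {
  h <- hapten_inhibition(alphas = alphas, params = params, times = times,
                         observables_keep = observables)
  out <- list()
  for (a in alphas) {
    sub <- h[h$alpha == a, ]
    w <- data.frame(time = times)
    for (o in observables)
      w[[o]] <- sub$value[sub$observable == o]
    out[[as.character(a)]] <- w
  }
  out
}

#' Grid-search fit of the raft protection level alpha
#'
#' Simulates the hapten-inhibition experiment at every alpha on the grid
#' and scores the sum of squared residuals against the dataset over shared
#' timepoints, pooling all observables with equal weights; the estimate is
#' the grid argmin. Mirrors the discrete curve-matching used to select the
#' protection level against dephosphorylation time courses.
#'
#' @param dataset a `raft_dataset` (or the data.frame layout of
#'   [load_digitized()]).
#' @param alpha_grid candidate alphas in `[0, 1]`.
#' @param params base parameter set.
#' @param curves optional precomputed [dephos_curves()] for `alpha_grid`.
#' @return object of class `raft_alpha_fit`: list with `alpha_hat`,
#'   `profile` (data.frame alpha/ssr), `by_observable` residual breakdown,
#'   `alpha_true` when known.
#' @export
fit_alpha <- function(dataset, alpha_grid = c(0, 0.05, 0.1, 0.2, 0.5, 1),
                      params = default_params(), curves = NULL) {
  stopifnot(length(alpha_grid) > 0, all(alpha_grid >= 0 & alpha_grid <= 1))
  obs <- unique(dataset$observable)
  if (is.null(curves))
    curves <- dephos_curves(alpha_grid, params, observables = obs)
  missing_a <- setdiff(as.character(alpha_grid), names(curves))
  if (length(missing_a))
    stop("curves missing for alpha = ", paste(missing_a, collapse = ", "))
  miss <- setdiff(obs, colnames(curves[[as.character(alpha_grid[1])]]))
  if (length(miss))
    stop("model curves lack dataset observable(s): ",
         paste(miss, collapse = ", "))
  prof <- data.frame(alpha = alpha_grid, ssr = NA_real_)
  byo <- list()
  for (i in seq_along(alpha_grid)) {
    cv <- curves[[as.character(alpha_grid[i])]]
    ssr_o <- vapply(obs, function(o) {
      d <- dataset[dataset$observable == o, ]
      m <- stats::approx(cv$time, cv[[o]], xout = d$time_s)$y
      sum((d$fraction_remaining - m)^2)
    }, 0)
    prof$ssr[i] <- sum(ssr_o)
    byo[[i]] <- data.frame(alpha = alpha_grid[i], observable = obs,
                           ssr = unname(ssr_o))
  }
  structure(list(alpha_hat = prof$alpha[which.min(prof$ssr)],
                 profile = prof, by_observable = do.call(rbind, byo),
                 alpha_true = attr(dataset, "alpha_true")),
            class = "raft_alpha_fit")
}

#' @export
print.raft_alpha_fit <- function(x, ...) {
  cat("Raft protection grid fit: alpha_hat =", x$alpha_hat)
  if (!is.null(x$alpha_true)) cat("  (generating alpha =", x$alpha_true, ")")
  cat("\n")
  print(x$profile, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Read or write a dephosphorylation dataset CSV
#'
#' The dialect is a three-column CSV `time_s, observable,
#' fraction_remaining`. Loaded files are flagged as external (no known
#' generating alpha) and are usable by [fit_alpha()].
#'
#' @param path CSV file path.
#' @param dataset for `write_dephos_csv`, a `raft_dataset`.
#' @return `load_digitized` returns a `raft_dataset` with
#'   `external = TRUE`.
#' @export
load_digitized <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop("malformed CSV ", path, ": ", conditionMessage(e)))
  need <- c("time_s", "observable", "fraction_remaining")
  if (!all(need %in% names(df)))
    stop("expected columns ", paste(need, collapse = ", "))
  if (nrow(df) == 0) stop("empty dataset: ", path)
  bad <- which(!is.finite(df$time_s) | !is.finite(df$fraction_remaining))
  if (length(bad))
    stop("malformed rows (line ", paste(bad + 1L, collapse = ", "), ") in ",
         path)
  structure(df[need], alpha_true = NULL, external = TRUE,
            class = c("raft_dataset", "data.frame"))
}

#' @rdname load_digitized
#' @export
write_dephos_csv <- function(dataset, path) {
  utils::write.csv(
    dataset[c("time_s", "observable", "fraction_remaining")], path,
    row.names = FALSE, quote = FALSE)
  invisible(path)
}
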