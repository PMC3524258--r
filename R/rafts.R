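#' Raft geometry
#'
#' Derived geometry of the raft-studded membrane: the number of rafts
#' `n_rafts = round(coverage * area / (pi s^2))`, the raft density `N`, and
#' the outer radius `b = 1/sqrt(pi N)` of the annular nonraft region
#' associated with each raft.
#'
#' @param params a `raft_params` list, or individual values below.
#' @param radius raft radius (nm).
#' @param coverage fraction of the membrane covered by rafts.
#' @param area cell surface area (cm^2).
#' @return list with `radius_cm`, `outer_cm`, `coverage`, `area`,
#'   `n_rafts`, `density` (rafts/cm^2).
#' @examples
#' raft_geometry(default_params())$n_rafts   # ~8000 rafts per cell
#' @export
raft_geometry <- function(params = NULL, radius = NULL, coverage = NULL,
                          area = NULL) {
  if (!is.null(params)) {
    radius <- radius %||% params$raft_radius
    coverage <- coverage %||% params$raft_coverage
    area <- area %||% params$cell_area
  }
  if (radius <= 0 || area <= 0 || coverage <= 0 || coverage >= 1)
    stop("need radius > 0, area > 0 and coverage in (0, 1)")
  s <- radius * 1e-7   # nm -> cm
  n <- round(coverage * area / (pi * s^2))
  dens <- n / area
  b <- 1 / sqrt(pi * dens)
  if (b <= s) stop("geometry error: outer radius b <= raft radius s")
  list(radius_cm = s, outer_cm = b, coverage = coverage, area = area,
       n_rafts = n, density = dens)
}

#' Number of rafts per cell
#'
#' @inheritParams raft_geometry
#' @return integer raft count, `round(coverage * area / (pi s^2))`.
#' @export
raft_count <- function(params = NULL, radius = NULL, coverage = NULL,
                       area = NULL)
  raft_geometry(params, radius, coverage, area)$n_rafts

#' Raft entry rate implied by a partition coefficient
#'
#' At equilibrium the fraction of a protein in the raft compartment equals
#' the fraction of time it spends there: `rho = lambda / (lambda + 1/(k+N))`,
#' so the lumped nonraft-to-raft transition rate is
#' `k+N = rho / (lambda (1 - rho))`, and `1/(k+N)` is the mean time spent
#' diffusing through the nonraft region between successive raft captures.
#'
#' @param rho partition coefficient in (0, 1).
#' @param lambda mean raft lifetime (s).
#' @return the entry rate `k+N` (/s).
#' @examples
#' 1 / entry_rate_from_partition(0.85, 10)  # ~1.8 s outside per cycle
#' @export
entry_rate_from_partition <- function(rho, lambda) {
  if (any(lambda <= 0)) stop("lambda must be positive")
  if (any(rho <= 0)) stop("rho must be positive")
  if (any(rho >= 1)) stop("rho >= 1 implies an infinite entry rate")
  rho / (lambda * (1 - rho))
}

## capture probability before trap turnover, averaged over a uniform start
## in the annulus s < r < b:  D (u'' + u'/r) = u/lambda, u(s)=1, u'(b)=0.
## Closed form in modified Bessel functions, exponentially scaled to stay
## finite for small D*lambda.
capture_probability <- function(s, b, lambda, D) {
  beta <- 1 / sqrt(D * lambda)
  bs <- beta * s; bb <- beta * b
  I0s <- besselI(bs, 0, expon.scaled = TRUE)
  I1s <- besselI(bs, 1, expon.scaled = TRUE)
  I1b <- besselI(bb, 1, expon.scaled = TRUE)
  K0s <- besselK(bs, 0, expon.scaled = TRUE)
  K1s <- besselK(bs, 1, expon.scaled = TRUE)
  K1b <- besselK(bb, 1, expon.scaled = TRUE)
  e <- exp(bb - bs)  # unscale I(bb)K(bs) ~ e, K(bb)I(bs) ~ 1/e
  Z <- I1b * K0s * e + K1b * I0s / e
  num <- I1b * K1s * e - K1b * I1s / e
  2 * s * num / (beta * (b^2 - s^2) * Z)
}

#' Diffusion-limited 2D capture rate for transient disk traps
#'
#' The highest physically permissible rate at which a membrane protein can
#' be captured by disk-shaped traps (rafts) of radius `s` and finite mean
#' lifetime `lambda`, following the transient-trap formulation of
#' Goldstein, Griego and Wofsy (1984, Biophys J 46:573). Each raft owns an
#' annular nonraft region of outer radius `b = 1/sqrt(pi N)`. When a raft
#' dissolves, a new one forms at a random location, so the protein's
#' position relative to its trap renews; the capture probability per raft
#' generation, `u`, solves `D grad^2 u = u/lambda` with `u(s) = 1`,
#' `u'(b) = 0` (modified Bessel functions of argument scaled by
#' `1/sqrt(D lambda)`), averaged over a uniform start in the annulus. The
#' mean time to capture is `T = (1 - u) lambda / u` and the rate constant
#' is `k+diff = 1/(T N)`. The raft diffusion coefficient dominates protein
#' diffusion, so a single `D = d_raft` applies to all membrane proteins.
#'
#' @param geometry a list from [raft_geometry()].
#' @param lambda mean raft lifetime (s).
#' @param D relative diffusion coefficient (cm^2/s).
#' @return the 2D forward rate constant `k+diff` (cm^2/s).
#' @export
diffusion_limited_rate <- function(geometry, lambda, D) {
  s <- geometry$radius_cm; b <- geometry$outer_cm
  if (s >= b) stop("geometry error: raft radius s must be < outer radius b")
  if (any(lambda <= 0) || D <= 0) stop("lambda and D must be positive")
  u <- capture_probability(s, b, lambda, D)
  kN <- u / ((1 - u) * lambda)        # capture rate per protein (/s)
  kN / geometry$density               # 2D rate constant (cm^2/s)
}

#' Minimum physically consistent raft lifetime
#'
#' As the raft lifetime decreases at fixed partition coefficient, the
#' required nonraft-to-raft entry rate `rho/(lambda (1-rho))` grows; below
#' a critical lifetime it exceeds the diffusion-limited capture rate
#' `k+diff * N` and the model becomes physically inconsistent. The crossing
#' is found by bracketed root search on log-spaced lifetimes in
#' `[1e-4, 1e3]` s (relative tolerance 1e-4).
#'
#' @inheritParams diffusion_limited_rate
#' @param rho partition coefficient in (0, 1).
#' @return the critical lifetime (s).
#' @examples
#' g <- raft_geometry(default_params())
#' min_raft_lifetime(g, 0.85, 1e-8)   # ~0.017 s for 100 nm rafts
#' @export
min_raft_lifetime <- function(geometry, rho, D) {
  if (rho <= 0 || rho >= 1) stop("rho must lie in (0, 1)")
  gap <- function(lam)
    entry_rate_from_partition(rho, lam) -
      diffusion_limited_rate(geometry, lam, D) * geometry$density
  lo <- 1e-4; hi <- 1e3
  glo <- gap(lo); ghi <- gap(hi)
  if (glo * ghi > 0)
    stop(sprintf(
      "no diffusion-limit crossing in [%g, %g] s (gap %g to %g)",
      lo, hi, glo, ghi))
  stats::uniroot(gap, c(lo, hi), tol = 1e-4 * lo,
                 extendInt = "no")$root
}

#' Extrapolate a detergent-resistance series to zero detergent
#'
#' Raft association measured by Triton X-100 solubilization depends on the
#' detergent concentration; the model's partition coefficient for
#' crosslinked receptor aggregates is the linear extrapolation of the
#' measured percent raft association to 0% detergent. With the published
#' series (65.6% at 0.06% and 52.9% at 0.1% Triton; Kovarova et al. 2001)
#' this gives ~85%.
#'
#' @param triton detergent concentrations (percent).
#' @param percent measured percent raft association.
#' @return extrapolated percent raft association at zero detergent.
#' @examples
#' extrapolate_partition()  # 84.65
#' @export
extrapolate_partition <- function(triton = c(0.06, 0.1),
                                  percent = c(65.6, 52.9)) {
  fit <- stats::lm(percent ~ triton)
  unname(stats::predict(fit, data.frame(triton = 0)))
}

#' Average active Lyn per raft
#'
#' @param params a `raft_params` list.
#' @return Lyn copies per raft (~3.5 at defaults).
#' @export
lyn_per_raft <- function(params = default_params())
  params$lyn_total / raft_count(params)

#' Relative reduction of the receptor-Syk complex lifetime
#'
#' Increasing the receptor-Syk dissociation rate from `from` to `to`
#' shortens the mean complex lifetime `1/koff` by `1 - from/to` (35% for
#' 0.13 -> 0.2 /s).
#'
#' @param from,to dissociation rates (/s).
#' @return fractional lifetime reduction.
#' @export
syk_lifetime_reduction <- function(from = 0.13, to = 0.2)
  1 - from / to

#' Geometry and kinetics report
#'
#' Aligned-text summary of the raft geometry, the per-class entry rates and
#' mean nonraft sojourns, the diffusion-limit check at the current lifetime
#' and the minimum permissible lifetime.
#'
#' @param params a `raft_params` list.
#' @return invisibly, a data.frame with the per-class kinetics.
#' @export
raft_report <- function(params = default_params()) {
  g <- raft_geometry(params)
  lam <- params$raft_lifetime
  entry <- entry_rates_by_class(params)
  kdiff <- diffusion_limited_rate(g, lam, params$d_raft)
  lmin <- min_raft_lifetime(g, max(params$rho_monomer, params$rho_dimer,
                                   params$rho_lyn, params$rho_lat),
                            params$d_raft)
  cat(sprintf("rafts/cell: %d  (radius %g nm, coverage %.0f%%, area %g cm^2)\n",
              g$n_rafts, params$raft_radius, 100 * g$coverage, g$area))
  cat(sprintf("raft lifetime lambda: %g s;  active Lyn per raft: %.2f\n",
              lam, lyn_per_raft(params)))
  cat(sprintf("diffusion-limited capture: k+diff*N = %.4g /s at lambda\n",
              kdiff * g$density))
  cat(sprintf("minimum permissible lifetime (largest rho): %.4g s\n", lmin))
  df <- data.frame(
    class = names(entry), rho = c(params$rho_monomer, params$rho_dimer,
                                  params$rho_lyn, params$rho_lat),
    entry_rate = unname(entry),
    mean_nonraft_s = 1 / unname(entry),
    within_diffusion_limit = unname(entry) <= kdiff * g$density)
  print(df, row.names = FALSE, digits = 4)
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
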