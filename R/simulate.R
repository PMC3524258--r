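#' Default initial state of a network
#'
#' All receptors start as free, unphosphorylated monomers; Lyn and LAT are
#' free; Syk and Grb2 are cytosolic and unphosphorylated. Membrane species
#' are pre-equilibrated between raft and nonraft compartments according to
#' their class partition coefficient.
#'
#' @param network a `raft_network`.
#' @return a numeric state vector (molecules/cell) named by species label.
#' @export
initial_state <- function(network) {
  p <- network$params
  st <- network$species
  x <- stats::setNames(numeric(nrow(st)), st$label)
  put <- function(chem_lab, total, rho) {
    rows <- which(st$chem == chem_lab)
    if (!length(rows)) return()
    if (length(rows) == 1L) { x[rows] <<- total; return() }
    r <- rows[st$loc[rows] == "raft"]
    n <- rows[st$loc[rows] == "nonraft"]
    x[r] <<- total * rho
    x[n] <<- total * (1 - rho)
  }
  put("R(0;Y;Y)", p$rec_total, p$rho_monomer)
  put("Lyn", p$lyn_total, p$rho_lyn)
  put("LAT(U)", p$lat_total, p$rho_lat)
  put("Syk(00)", p$syk_total, 0)
  put("Grb2", p$grb2_total, 0)
  x
}

# precompute fast ODE machinery for given bath concentrations (molar)
ode_system <- function(network, ligand = 0, hapten = 0) {
  rx <- network$reactions
  k <- rx$k
  k[rx$class == "bath_lig"] <- k[rx$class == "bath_lig"] * ligand
  k[rx$class == "bath_hapten"] <- k[rx$class == "bath_hapten"] * hapten
  mm <- rx$class == "mm"
  ma <- !mm
  i1 <- rx$i1[ma]; i2 <- rx$i2[ma]
  bi <- i2 > 0L
  S <- network$S[, c(which(ma), which(mm)), drop = FALSE]
  m_cat <- rx$i1[mm]; m_sub <- rx$i2[mm]
  m_k <- k[mm]; m_km <- rx$km[mm]
  k_ma <- k[ma]
  nspec <- nrow(network$species)
  nma <- sum(ma); nmm <- sum(mm)

  rates <- function(x) {
    v <- k_ma * x[i1]
    v[bi] <- v[bi] * x[i2[bi]]
    if (nmm) {
      u <- x[m_sub]
      v <- c(v, m_k * x[m_cat] * u / (m_km + u))
    }
    v
  }
  rhs <- function(t, x, parms) {
    list(as.vector(S %*% rates(x)))
  }
  jac <- function(t, x, parms) {
    ri <- c(seq_len(nma), seq_len(nma)[bi])
    ci <- c(i1, i2[bi])
    xv <- c(k_ma * ifelse(bi, x[pmax(i2, 1L)], 1), k_ma[bi] * x[i1[bi]])
    if (nmm) {
      u <- x[m_sub]
      ri <- c(ri, nma + seq_len(nmm), nma + seq_len(nmm))
      ci <- c(ci, m_cat, m_sub)
      xv <- c(xv, m_k * u / (m_km + u),
              m_k * x[m_cat] * m_km / (m_km + u)^2)
    }
    Dv <- Matrix::sparseMatrix(i = ri, j = ci, x = xv,
                               dims = c(nma + nmm, nspec))
    as.matrix(S %*% Dv)
  }
  list(rhs = rhs, jac = jac, rates = rates)
}

#' Integrate the network ODEs
#'
#' Stiff integration (`deSolve::lsoda` with an analytically assembled dense
#' Jacobian) of the compartmental mass-action / Michaelis-Menten system.
#' Abundances are molecules per cell; bath species (ligand, hapten) are held
#' at fixed molar concentrations and folded into pseudo-first-order rate
#' constants.
#'
#' @param network a `raft_network`.
#' @param init initial state vector, see [initial_state()].
#' @param times numeric time grid (s), strictly increasing from its start.
#' @param ligand,hapten bath concentrations (M).
#' @param rtol,atol integrator tolerances (atol in molecules/cell).
#' @return matrix of states (rows = times), with a `times` attribute.
#' @export
integrate_network <- function(network, init, times, ligand = 0, hapten = 0,
                              rtol = 1e-8, atol = 1e-3) {
  sys <- ode_system(network, ligand, hapten)
  out <- deSolve::lsoda(y = init, times = times, func = sys$rhs,
                        jacfunc = sys$jac, jactype = "fullusr",
                        parms = NULL, rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("integrator failure at t = ", max(out[, 1]),
         " (see deSolve diagnostics)")
  x <- out[, -1, drop = FALSE]
  colnames(x) <- network$species$label
  attr(x, "times") <- out[, 1]
  x
}

#' Integrate to steady state
#'
#' Integrates over expanding horizons until the relative derivative norm
#' `||dx/dt|| / ||x||` falls below `tol_dxdt` (default 1e-8 /s) or
#' `max_time` is reached; non-convergence is flagged, not an error.
#'
#' @inheritParams integrate_network
#' @param tol_dxdt relative derivative-norm convergence threshold (/s).
#' @param max_time integration horizon cap (s).
#' @return list with `state` (named vector), `converged`, `time`,
#'   `dxdt_norm`.
#' @export
steady_state <- function(network, init = initial_state(network),
                         ligand = 0, hapten = 0, tol_dxdt = 1e-8,
                         max_time = 1e4, rtol = 1e-8, atol = 1e-3) {
  sys <- ode_system(network, ligand, hapten)
  x <- init
  t0 <- 0
  horizons <- c(10, 100, 1000, max_time)
  horizons <- horizons[horizons <= max_time]
  if (!length(horizons) || max(horizons) < max_time)
    horizons <- c(horizons, max_time)
  conv <- FALSE; dn <- NA_real_
  for (h in horizons) {
    out <- deSolve::lsoda(y = x, times = c(t0, h), func = sys$rhs,
                          jacfunc = sys$jac, jactype = "fullusr",
                          parms = NULL, rtol = rtol, atol = atol)
    x <- out[nrow(out), -1]
    t0 <- h
    dn <- sqrt(sum(sys$rhs(h, x, NULL)[[1]]^2)) / sqrt(sum(x^2))
    if (is.finite(dn) && dn < tol_dxdt) { conv <- TRUE; break }
  }
  list(state = stats::setNames(pmax(x, 0), network$species$label),
       converged = conv, time = t0, dxdt_norm = dn)
}

#' Named phospho-fraction observables
#'
#' Fractions of each protein in the phosphorylated state:
#' `beta` and `gamma` are phosphorylated receptor ITAM fractions (a
#' phosphorylated-and-bound site counts as phosphorylated), `syk` the
#' fraction of Syk phosphorylated on its activation loop, `lat` the
#' phosphorylated LAT fraction, and `receptor` pools beta and gamma
#' phosphotyrosines over both ITAMs. Observables sum over raft and nonraft
#' locations.
#'
#' @param state a state vector or a matrix of states (rows = times).
#' @param network the `raft_network` the state belongs to.
#' @return a named vector of fractions, or a matrix (rows = times).
#' @export
observables <- function(state, network) {
  p <- network$params
  W <- network$obs_counts
  den <- c(beta = p$rec_total, gamma = p$rec_total, syk = p$syk_total,
           lat = p$lat_total, receptor = 2 * p$rec_total)
  one <- function(x) {
    x <- pmax(x, 0)
    num <- as.vector(x %*% W)
    names(num) <- colnames(W)
    c(num, receptor = unname(num["beta"] + num["gamma"])) / den
  }
  if (is.matrix(state)) {
    out <- t(apply(state, 1, one))
    rownames(out) <- NULL
    out
  } else one(state)
}

#' Conserved protein totals of a state
#'
#' @inheritParams observables
#' @return named vector of receptor, Lyn, Syk, LAT and Grb2 molecule totals.
#' @export
conserved_totals <- function(state, network) {
  M <- network$moieties
  if (is.matrix(state)) {
    out <- state %*% M
    colnames(out) <- colnames(M)
    out
  } else {
    stats::setNames(as.vector(state %*% M), colnames(M))
  }
}

#' Raft fraction per chemistry species
#'
#' For a compartmental state, the fraction of each membrane chemistry
#' species currently in the raft compartment (NA where the total is zero).
#'
#' @inheritParams observables
#' @return named vector over membrane chemistry species.
#' @export
raft_fractions <- function(state, network) {
  st <- network$species
  mem <- st$chem[st$loc == "raft"]
  vapply(mem, function(ch) {
    r <- state[st$chem == ch & st$loc == "raft"]
    n <- state[st$chem == ch & st$loc == "nonraft"]
    tot <- r + n
    if (tot <= 0) NA_real_ else unname(r / tot)
  }, 0)
}
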