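test_that("without ligand or hapten no phosphorylation ever occurs", {
  net <- cached_net(0.2)
  tc <- integrate_network(net, initial_state(net), c(0, 10, 100))
  ob <- observables(tc, net)
  # trans-phosphorylation requires ligand-induced dimers; anything left is
  # integrator round-off far below one molecule per cell
  expect_lt(max(ob[, c("beta", "gamma", "syk", "lat")]), 1e-10)
})

test_that("protein totals are conserved through stimulation", {
  net <- cached_net(0.2)
  tc <- integrate_network(net, initial_state(net), seq(0, 50, by = 10),
                          ligand = 1e-9)
  tot <- conserved_totals(tc, net)
  ref <- conserved_totals(initial_state(net), net)
  for (m in colnames(tot))
    expect_lt(max(abs(tot[, m] - ref[m])) / ref[m], 1e-6)
})

test_that("steady state is flagged and reproducible across initial paths", {
  ss1 <- cached_ss(0.2, 1e-9)
  expect_true(ss1$converged)
  expect_lt(ss1$dxdt_norm, 1e-8)
  # different integration path: start from a perturbed partitioning
  net <- cached_net(0.2)
  x0 <- initial_state(net)
  st <- net$species
  for (ch in c("R(0;Y;Y)", "Lyn", "LAT(U)")) {
    r <- which(st$chem == ch & st$loc == "raft")
    n <- which(st$chem == ch & st$loc == "nonraft")
    tot <- x0[r] + x0[n]
    x0[r] <- 0.5 * tot; x0[n] <- 0.5 * tot
  }
  ss2 <- steady_state(net, init = x0, ligand = 1e-9)
  expect_lt(max(abs(ss2$state - ss1$state)) /
              max(ss1$state), 1e-6)
})

test_that("observables count bound phosphosites as phosphorylated", {
  net <- cached_net(0.2)
  st <- net$species
  x <- setNames(numeric(nrow(st)), st$label)
  # every LAT phosphorylated and Grb2-bound: LAT fraction is 1
  x[st$chem == "LAT(PG)" & st$loc == "raft"] <- net$params$lat_total
  expect_equal(unname(observables(x, net)["lat"]), 1)
  # fractions are invariant under the raft/nonraft split of the same totals
  y <- setNames(numeric(nrow(st)), st$label)
  y[st$chem == "LAT(PG)" & st$loc == "nonraft"] <- net$params$lat_total
  expect_equal(observables(x, net), observables(y, net))
})

test_that("indistinguishable rafts collapse to one compartment", {
  # rafts carry no information when protection is absent, Lyn activity is
  # uniform and every class partitions at the raft area fraction; the
  # co-confinement scaling then makes the two-location fluxes sum exactly
  # to the one-compartment fluxes
  p <- default_params(alpha = 1, lyn_nonraft_activity = 1,
                      rho_monomer = 0.3, rho_dimer = 0.3, rho_lyn = 0.3,
                      rho_lat = 0.3)
  net <- generate_network(build_model(p))
  col <- collapse_compartments(net)
  times <- seq(0, 40, by = 5)
  tc2 <- integrate_network(net, initial_state(net), times, ligand = 1e-9)
  tc1 <- integrate_network(col, initial_state(col), times, ligand = 1e-9)
  o2 <- observables(tc2, net)
  o1 <- observables(tc1, col)
  expect_lt(max(abs(o2 - o1)), 1e-6)
})

test_that("reported observables are insensitive to tighter tolerances", {
  net <- cached_net(0.2)
  x0 <- cached_ss(0.2, 1e-9)$state
  times <- seq(0, 20, by = 5)
  a <- observables(integrate_network(net, x0, times, ligand = 1e-9,
                                     hapten = 1e-4), net)
  b <- observables(integrate_network(net, x0, times, ligand = 1e-9,
                                     hapten = 1e-4, rtol = 5e-9,
                                     atol = 5e-4), net)
  expect_lt(max(abs(a - b)), 1e-4)
})

test_that("halving the raft lifetime at fixed rho leaves exchange equilibria unchanged", {
  p1 <- exchange_only_params()
  p2 <- exchange_only_params(raft_lifetime = 5)
  f1 <- raftsig:::entry_rates_by_class(p1) * p1$raft_lifetime
  f2 <- raftsig:::entry_rates_by_class(p2) * p2$raft_lifetime
  expect_equal(f1, f2)  # rho/(1-rho) is lifetime-free
})
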