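test_that("toy ligand+receptor model matches exhaustive enumeration", {
  p <- default_params()
  toy <- build_model(p, include = character(0))
  net <- generate_network(toy)
  # independent hand enumeration: a receptor is free, ligand-bound via one
  # arm, or in the unique symmetric dimer
  expect_setequal(net$chem$species$label,
                  c("R(0;Y;Y)", "R(L;Y;Y)", "D(Y;Y)(Y;Y)"))
  r <- net$chem$reactions
  expect_equal(nrow(r), 4L)
  # the two indistinguishable crosslink bonds of the symmetric dimer merge
  # into one breakup channel at twice the bond dissociation rate
  brk <- r[r$r1 == "D(Y;Y)(Y;Y)", ]
  expect_equal(nrow(brk), 1L)
  expect_equal(brk$k, 2 * p$koff_x)
  # bivalent ligand binds through either arm
  lig_on <- r[r$class == "bath_lig", ]
  expect_equal(lig_on$k, 2 * p$kon_lig)
})

test_that("adding the monovalent hapten extends the toy model minimally", {
  net <- generate_network(build_model(default_params(),
                                      include = "hapten"))
  expect_setequal(net$chem$species$label,
                  c("R(0;Y;Y)", "R(L;Y;Y)", "R(H;Y;Y)", "D(Y;Y)(Y;Y)"))
  expect_equal(nrow(net$chem$reactions), 6L)
})

test_that("network generation is deterministic", {
  n1 <- generate_network(build_model(default_params()))
  n2 <- generate_network(build_model(default_params()))
  expect_identical(n1$chem$species$label, n2$chem$species$label)
  expect_identical(n1$chem$reactions, n2$chem$reactions)
})

test_that("stoichiometry conserves every protein moiety", {
  net <- cached_net(0.2)
  V <- as.matrix(Matrix::t(net$S) %*% net$moieties)
  expect_lt(max(abs(V)), 1e-12)
})

test_that("SH2-occupied phosphosites have no dephosphorylation channel", {
  r <- cached_net(0.2)$chem$reactions
  dp <- r[r$class == "dephos_mem", ]
  # a dephosphorylation step never touches a bound site: the counts of
  # Lyn-SH2-bound beta, Syk-bound gamma and Grb2-bound LAT are unchanged
  nocc <- function(x) {
    vapply(gregexpr("PL|S[01][01]|PG", x), function(g)
      sum(g > 0), 0L)
  }
  expect_identical(nocc(dp$r1), nocc(dp$p1))
  expect_false(any(dp$r1 == "LAT(PG)"))
})

test_that("every naked membrane phosphosite is covered by one alpha-scaled rule", {
  net <- cached_net(0.2)
  r <- net$chem$reactions
  dp <- r[r$class == "dephos_mem", ]
  # per species, the number of dephosphorylation channels equals the number
  # of naked phosphosites on membrane complexes (receptor ITAMs and LAT)
  naked <- function(lab) {
    sp <- raftsig:::parse_label(lab)
    switch(sp$type,
      mono  = (sp$b == "P") + (sp$g == "P"),
      dimer = (sp$b1 == "P") + (sp$g1 == "P") +
              (sp$b2 == "P") + (sp$g2 == "P"),
      lat   = as.integer(identical(sp$y, "P")),
      0L)
  }
  sp <- net$chem$species
  mem <- sp$label[sp$membrane]
  # symmetric dimers merge their two equivalent channels into one reaction
  # at twice the rate, so count rate-weighted channels per species
  w <- tapply(dp$k / net$params$k_dephos, factor(dp$r1, levels = mem),
              sum, default = 0)
  cnt_sites <- vapply(mem, naked, 0L)
  expect_equal(unname(as.vector(w)), as.numeric(unname(cnt_sites)))
  # and in the compartmental expansion the raft copy runs at alpha * rate
  rx <- net$reactions
  st <- net$species
  raft_dp <- rx$class == "dephos_mem" & st$loc[rx$i1] == "raft"
  non_dp <- rx$class == "dephos_mem" & st$loc[rx$i1] == "nonraft"
  expect_equal(sum(raft_dp), sum(non_dp))
  expect_equal(sort(rx$k[raft_dp]),
               sort(rx$k[non_dp]) * net$params$alpha)
})

test_that("exchange-only dynamics equilibrate every class to its rho", {
  p <- exchange_only_params()
  net <- generate_network(build_model(p))
  x0 <- initial_state(net)
  # perturb: move everything out of the rafts
  st <- net$species
  for (ch in unique(st$chem[st$loc == "raft"])) {
    r <- which(st$chem == ch & st$loc == "raft")
    n <- which(st$chem == ch & st$loc == "nonraft")
    x0[n] <- x0[n] + x0[r]
    x0[r] <- 0
  }
  tc <- integrate_network(net, x0, c(0, 500), rtol = 1e-10, atol = 1e-8)
  fr <- raft_fractions(tc[nrow(tc), ], net)
  fr <- fr[!is.na(fr)]
  rho <- vapply(names(fr), function(l) assign_partition(l, p), 0)
  expect_lt(max(abs(fr - rho)), 1e-6)
})

test_that("collapsing the compartments halves the membrane species", {
  net <- cached_net(0.2)
  col <- collapse_compartments(net)
  n_mem <- sum(net$chem$species$membrane)
  expect_equal(nrow(col$species),
               nrow(net$species) - n_mem)
  expect_false(col$compartmental)
  expect_error(collapse_compartments(col), "raft attributes")
})

test_that("a species cap aborts runaway expansion informatively", {
  expect_error(generate_network(build_model(default_params()),
                                max_species = 50),
               "species cap")
})

test_that("configurations beyond the diffusion limit are rejected", {
  p <- default_params(raft_lifetime = 0.005)
  expect_error(generate_network(build_model(p)), "diffusion limit")
})
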