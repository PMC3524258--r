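#' Generate the reaction network from a model definition
#'
#' Expands the rule set by iterative application from the seed species
#' (free receptor, free Lyn, unphosphorylated cytosolic Syk, LAT, Grb2)
#' to closure, enumerating every reachable complex (bond graph plus site
#' states) and every unidirectional mass-action or Michaelis-Menten event.
#' Species carry a canonical label unique under graph isomorphism, so the
#' resulting species and reaction counts are deterministic functions of the
#' model. The chemistry-level network is then duplicated over the raft and
#' nonraft membrane compartments: location-dependent rates are scaled
#' (`alpha` on raft dephosphorylation, `lyn_nonraft_activity` on nonraft Lyn
#' catalysis, co-confinement factors on membrane-membrane association), and
#' raft-exchange reactions are attached (raft to nonraft at `1/lambda`,
#' nonraft to raft at the class entry rate from the partition relation).
#'
#' At build time the implied per-raft capture rate constant of every
#' partition class is checked against the two-dimensional diffusion limit
#' for transient disk traps ([diffusion_limited_rate()]); a configuration
#' demanding a faster-than-diffusion entry rate is rejected.
#'
#' @param model a `raft_model` from [build_model()].
#' @param compartmental duplicate membrane species over raft/nonraft
#'   locations (`TRUE`, the default) or return the single-compartment
#'   chemistry network.
#' @param max_species safety cap on the number of enumerated complexes.
#' @return An object of class `raft_network`.
#' @examples
#' toy <- build_model(default_params(), include = character(0))
#' net <- generate_network(toy)
#' network_size(net)
#' @export
generate_network <- function(model, compartmental = TRUE,
                             max_species = 2000) {
  stopifnot(inherits(model, "raft_model"))
  chem <- enumerate_chemistry(model, max_species = max_species)
  build_kinetic_network(chem, model$params, compartmental = compartmental)
}

## ---- chemistry enumeration (single compartment) -----------------------

enumerate_chemistry <- function(model, max_species = 2000) {
  p <- model$params
  inc <- model$include
  has <- function(x) x %in% inc

  species <- new.env(parent = emptyenv())   # label -> species record
  apps    <- new.env(parent = emptyenv())   # application id -> TRUE
  rxns    <- new.env(parent = emptyenv())   # reaction key -> record
  queue   <- character(0)
  n_seen  <- 0L
  last_rule <- ""

  add_species <- function(sp) {
    lab <- canonical_label(sp)
    if (is.null(species[[lab]])) {
      if (n_seen + 1L > max_species)
        stop("species cap (", max_species, ") exceeded; last rule: ",
             last_rule)
      species[[lab]] <- sp
      n_seen <<- n_seen + 1L
      queue <<- c(queue, lab)
    }
    lab
  }

  emit <- function(id, reactants, products, k, class) {
    if (!is.null(apps[[id]])) return(invisible())
    apps[[id]] <- TRUE
    last_rule <<- class
    for (pr in products) add_species(pr)
    key <- paste(paste(sort(vapply(reactants, identity, "")), collapse = "+"),
                 paste(sort(vapply(products, canonical_label, "")),
                       collapse = "+"),
                 class, sep = " -> ")
    rec <- rxns[[key]]
    if (is.null(rec)) {
      rxns[[key]] <- list(
        r = unlist(reactants),
        p = sort(vapply(products, canonical_label, "")),
        class = class, k = k)
    } else {
      rec$k <- rec$k + k
      rxns[[key]] <- rec
    }
    invisible()
  }

  # pairing registries for bimolecular rules whose partners both grow
  reg <- list(monoL = character(0), mono0 = character(0),
              sykfree = character(0), gP = character(0))

  unit_states <- function(sp) {
    if (sp$type == "mono") list(c(sp$b, sp$g))
    else list(c(sp$b1, sp$g1), c(sp$b2, sp$g2))
  }
  # rebuild a receptor complex with unit `i` replaced
  with_unit <- function(sp, i, b, g) {
    if (sp$type == "mono") sp_mono(sp$a, b, g)
    else if (i == 1L) sp_dimer(b, g, sp$b2, sp$g2)
    else sp_dimer(sp$b1, sp$g1, b, g)
  }

  crosslink <- function(labL, lab0) {
    sL <- species[[labL]]; s0 <- species[[lab0]]
    emit(paste("xl", labL, lab0), list(labL, lab0),
         list(sp_dimer(sL$b, sL$g, s0$b, s0$g)), p$kx_lig, "bind2d")
  }
  syk_bind <- function(labR, labS) {
    spR <- species[[labR]]; spS <- species[[labS]]
    us <- unit_states(spR)
    for (i in seq_along(us)) {
      if (us[[i]][2] == "P")
        emit(paste("sykon", labR, i, labS), list(labR, labS),
             list(with_unit(spR, i, us[[i]][1],
                            paste0("S", spS$l, spS$a))),
             p$kon_syk, "bind3d")
    }
  }

  derive <- function(lab) {
    sp <- species[[lab]]

    if (sp$type == "mono") {
      if (sp$a == "0") {
        emit(paste("lig_on", lab), list(lab),
             list(sp_mono("L", sp$b, sp$g)), 2 * p$kon_lig, "bath_lig")
        if (has("hapten"))
          emit(paste("hap_on", lab), list(lab),
               list(sp_mono("H", sp$b, sp$g)), p$kon_hapten, "bath_hapten")
      }
      if (sp$a == "L")
        emit(paste("lig_off", lab), list(lab),
             list(sp_mono("0", sp$b, sp$g)), p$koff_lig, "unbind")
      if (sp$a == "H")
        emit(paste("hap_off", lab), list(lab),
             list(sp_mono("0", sp$b, sp$g)), p$koff_hapten, "unbind")
    }

    if (sp$type == "dimer") {
      # breakup: either crosslink bond breaks; the ligand stays on one side
      emit(paste("brk", lab, 1), list(lab),
           list(sp_mono("L", sp$b1, sp$g1), sp_mono("0", sp$b2, sp$g2)),
           p$koff_x, "unbind")
      emit(paste("brk", lab, 2), list(lab),
           list(sp_mono("L", sp$b2, sp$g2), sp_mono("0", sp$b1, sp$g1)),
           p$koff_x, "unbind")
      # trans-catalysis between the two receptors
      us <- unit_states(sp)
      for (kin in 1:2) {
        sub <- 3L - kin
        kb <- us[[kin]][1]; kg <- us[[kin]][2]
        sb <- us[[sub]][1]; sg <- us[[sub]][2]
        if (kb %in% c("YL", "PL")) {
          anch <- if (kb == "YL") "u" else "s"
          kbeta  <- if (anch == "u") p$p_beta_u  else p$p_beta_s
          kgamma <- if (anch == "u") p$p_gamma_u else p$p_gamma_s
          klink  <- if (anch == "u") p$p_syk_u   else p$p_syk_s
          if (sb == "Y")
            emit(paste("tpb", lab, kin), list(lab),
                 list(with_unit(sp, sub, "P", sg)), kbeta, "lyncat")
          if (sg == "Y")
            emit(paste("tpg", lab, kin), list(lab),
                 list(with_unit(sp, sub, sb, "P")), kgamma, "lyncat")
          if (startsWith(sg, "S") && substr(sg, 2, 2) == "0")
            emit(paste("tpl", lab, kin), list(lab),
                 list(with_unit(sp, sub, sb,
                                paste0("S1", substr(sg, 3, 3)))),
                 klink, "lyncat")
        }
        if (startsWith(kg, "S") && startsWith(sg, "S") &&
            substr(sg, 3, 3) == "0") {
          rate <- if (substr(kg, 3, 3) == "0") p$p_aloop else p$p_aloop_a
          emit(paste("tpa", lab, kin), list(lab),
               list(with_unit(sp, sub, sb,
                              paste0("S", substr(sg, 2, 2), "1"))),
               rate, "sykcat")
        }
      }
    }

    if (sp$type %in% c("mono", "dimer")) {
      us <- unit_states(sp)
      for (i in seq_along(us)) {
        b <- us[[i]][1]; g <- us[[i]][2]
        # Lyn binding/unbinding (free Lyn is a seed when present)
        if (has("lyn")) {
          if (b == "Y")
            emit(paste("lynu_on", lab, i), list(lab, "Lyn"),
                 list(with_unit(sp, i, "YL", g)), p$kon_lyn_u, "bind2d")
          if (b == "P")
            emit(paste("lyns_on", lab, i), list(lab, "Lyn"),
                 list(with_unit(sp, i, "PL", g)), p$kon_lyn_sh2, "bind2d")
          if (b == "YL")
            emit(paste("lynu_off", lab, i), list(lab),
                 list(with_unit(sp, i, "Y", g), sp_lyn()),
                 p$koff_lyn_u, "unbind")
          if (b == "PL")
            emit(paste("lyns_off", lab, i), list(lab),
                 list(with_unit(sp, i, "P", g), sp_lyn()),
                 p$koff_lyn_sh2, "unbind")
        }
        if (has("syk") && startsWith(g, "S"))
          emit(paste("syk_off", lab, i), list(lab),
               list(with_unit(sp, i, b, "P"),
                    sp_syk(substr(g, 2, 2), substr(g, 3, 3))),
               p$koff_syk, "unbind")
        # dephosphorylation of naked membrane phosphosites
        if (b == "P")
          emit(paste("dpb", lab, i), list(lab),
               list(with_unit(sp, i, "Y", g)), p$k_dephos, "dephos_mem")
        if (g == "P")
          emit(paste("dpg", lab, i), list(lab),
               list(with_unit(sp, i, b, "Y")), p$k_dephos, "dephos_mem")
        # Syk's own phosphosites dephosphorylate on free cytosolic Syk
        # only: receptor-bound Syk dephosphorylation kinetics are set by
        # receptor-Syk dissociation, matching the reported raft
        # insensitivity of Syk dephosphorylation
      }
      # Michaelis-Menten LAT phosphorylation by receptor-bound activated Syk
      if (has("lat") && has("syk")) {
        m <- sum(vapply(us, function(u)
          u[2] %in% c("S01", "S11"), logical(1)))
        if (m > 0)
          emit(paste("mm", lab), list(lab, "LAT(U)"),
               list(sp_lat("P")), m * p$kcat_lat, "mm")
      }
    }

    if (sp$type == "syk") {
      if (sp$l == "1")
        emit(paste("dcl", lab), list(lab), list(sp_syk("0", sp$a)),
             p$k_dephos_cyt, "dephos_cyt")
      if (sp$a == "1")
        emit(paste("dca", lab), list(lab), list(sp_syk(sp$l, "0")),
             p$k_dephos_cyt, "dephos_cyt")
    }

    if (sp$type == "lat") {
      if (sp$y == "P") {
        emit(paste("dpLAT", lab), list(lab), list(sp_lat("U")),
             p$k_dephos, "dephos_mem")
        if (has("grb2"))
          emit(paste("grb_on", lab), list(lab, "Grb2"),
               list(sp_lat("PG")), p$kon_grb2, "bind3d")
      }
      if (sp$y == "PG")
        emit(paste("grb_off", lab), list(lab),
             list(sp_lat("P"), sp_grb2()), p$koff_grb2, "unbind")
    }

    # growing-partner bimolecular rules (crosslinking, Syk recruitment)
    if (sp$type == "mono" && sp$a == "L") {
      for (x in reg$mono0) crosslink(lab, x)
      reg$monoL <<- c(reg$monoL, lab)
    }
    if (sp$type == "mono" && sp$a == "0") {
      for (x in reg$monoL) crosslink(x, lab)
      reg$mono0 <<- c(reg$mono0, lab)
    }
    if (has("syk")) {
      if (sp$type == "syk") {
        for (x in reg$gP) syk_bind(x, lab)
        reg$sykfree <<- c(reg$sykfree, lab)
      }
      if (sp$type %in% c("mono", "dimer") &&
          any(vapply(unit_states(sp), function(u) u[2] == "P",
                     logical(1)))) {
        for (x in reg$sykfree) syk_bind(lab, x)
        reg$gP <<- c(reg$gP, lab)
      }
    }
    invisible()
  }

  ## seeds
  add_species(sp_mono("0", "Y", "Y"))
  if (has("lyn"))  add_species(sp_lyn())
  if (has("syk"))  add_species(sp_syk("0", "0"))
  if (has("lat"))  add_species(sp_lat("U"))
  if (has("grb2")) add_species(sp_grb2())

  while (length(queue)) {
    lab <- queue[1]
    queue <- queue[-1]
    derive(lab)
  }

  labs <- sort(ls(species))
  sps <- lapply(labs, function(l) species[[l]])
  mo <- t(vapply(sps, moiety_counts, c(R = 0L, Lyn = 0L, Syk = 0L,
                                       LAT = 0L, Grb2 = 0L)))
  ob <- t(vapply(sps, phospho_counts, c(beta = 0L, gamma = 0L, syk = 0L,
                                        lat = 0L)))
  sdf <- data.frame(
    label = labs,
    type = vapply(sps, `[[`, "", "type"),
    membrane = vapply(sps, is_membrane_species, logical(1)),
    pclass = vapply(sps, function(s) {
      cls <- partition_class(s, p)
      if (is.na(cls)) "" else cls
    }, ""),
    stringsAsFactors = FALSE)
  sdf <- cbind(sdf, as.data.frame(mo), as.data.frame(ob))

  rkeys <- sort(ls(rxns))
  rl <- lapply(rkeys, function(k) rxns[[k]])
  rdf <- data.frame(
    r1 = vapply(rl, function(x) x$r[1], ""),
    r2 = vapply(rl, function(x) if (length(x$r) > 1) x$r[2] else "", ""),
    p1 = vapply(rl, function(x) x$p[1], ""),
    p2 = vapply(rl, function(x) if (length(x$p) > 1) x$p[2] else "", ""),
    class = vapply(rl, `[[`, "", "class"),
    k = vapply(rl, `[[`, 0, "k"),
    stringsAsFactors = FALSE)

  structure(list(species = sdf, reactions = rdf, model = model),
            class = "raft_chem")
}

## ---- compartmental expansion ------------------------------------------

entry_rates_by_class <- function(params) {
  lam <- params$raft_lifetime
  rho <- c(monomer = params$rho_monomer, dimer = params$rho_dimer,
           lyn = params$rho_lyn, lat = params$rho_lat)
  vapply(rho, entry_rate_from_partition, 0, lambda = lam)
}

build_kinetic_network <- function(chem, params, compartmental = TRUE) {
  sdf <- chem$species
  rdf <- chem$reactions
  # partition classes depend on params (wild-type vs mutant Lyn), so they
  # are re-derived at expansion time rather than taken from the chemistry
  sdf$pclass <- vapply(sdf$label, function(l) {
    cls <- partition_class(parse_label(l), params)
    if (is.na(cls)) "" else cls
  }, "")
  f_raft <- params$raft_coverage
  f_non  <- 1 - params$raft_coverage

  if (compartmental) {
    check_diffusion_limit(params)
    reps <- ifelse(sdf$membrane, 2L, 1L)
    state <- data.frame(
      chem = rep(sdf$label, reps),
      loc = unlist(lapply(sdf$membrane, function(m)
        if (m) c("raft", "nonraft") else "cyt")),
      stringsAsFactors = FALSE)
  } else {
    state <- data.frame(chem = sdf$label,
                        loc = ifelse(sdf$membrane, "mem", "cyt"),
                        stringsAsFactors = FALSE)
  }
  state$label <- paste0(state$chem, "@", substr(state$loc, 1, 1))
  idx <- stats::setNames(seq_len(nrow(state)), state$label)
  chem_row <- stats::setNames(seq_len(nrow(sdf)), sdf$label)
  mem_of <- function(lab) sdf$membrane[chem_row[lab]]
  sid <- function(lab, loc) {
    if (!nzchar(lab)) return(0L)
    if (mem_of(lab)) idx[[paste0(lab, "@", substr(loc, 1, 1))]]
    else idx[[paste0(lab, "@c")]]
  }

  loc_set <- if (compartmental) c("raft", "nonraft") else "mem"
  area_frac <- function(loc) switch(loc, raft = f_raft, nonraft = f_non, 1)

  out <- vector("list", nrow(rdf) * length(loc_set))
  n_out <- 0L
  push <- function(i1, i2, p1, p2, k, class, km = NA_real_) {
    n_out <<- n_out + 1L
    out[[n_out]] <<- list(i1 = i1, i2 = i2, p1 = p1, p2 = p2, k = k,
                          class = class, km = km)
  }

  for (i in seq_len(nrow(rdf))) {
    r <- rdf[i, ]
    r1m <- mem_of(r$r1)
    anchored <- r1m || (nzchar(r$r2) && mem_of(r$r2))
    if (!anchored) {  # purely cytosolic (free Syk dephosphorylation)
      push(sid(r$r1, "cyt"), if (nzchar(r$r2)) sid(r$r2, "cyt") else 0L,
           sid(r$p1, "cyt"), if (nzchar(r$p2)) sid(r$p2, "cyt") else 0L,
           r$k, r$class)
      next
    }
    for (loc in loc_set) {
      k <- r$k
      if (compartmental) {
        if (r$class == "bind2d" && isTRUE(params$scale_bimolecular))
          k <- k / area_frac(loc)
        if (r$class == "lyncat" && loc == "nonraft")
          k <- k * params$lyn_nonraft_activity
        if (r$class == "dephos_mem" && loc == "raft")
          k <- k * params$alpha
      }
      km <- if (r$class == "mm") {
        params$km_lat * (if (compartmental &&
                             isTRUE(params$scale_bimolecular))
          area_frac(loc) else 1)
      } else NA_real_
      push(sid(r$r1, loc), if (nzchar(r$r2)) sid(r$r2, loc) else 0L,
           sid(r$p1, loc), if (nzchar(r$p2)) sid(r$p2, loc) else 0L,
           k, r$class, km)
    }
  }

  if (compartmental) {
    entry <- entry_rates_by_class(params)
    mem_labs <- sdf$label[sdf$membrane]
    for (lab in mem_labs) {
      cls <- sdf$pclass[chem_row[lab]]
      push(sid(lab, "raft"), 0L, sid(lab, "nonraft"), 0L,
           1 / params$raft_lifetime, "exchange")
      push(sid(lab, "nonraft"), 0L, sid(lab, "raft"), 0L,
           unname(entry[cls]), "exchange")
    }
  }

  out <- out[seq_len(n_out)]
  rx <- data.frame(
    i1 = vapply(out, `[[`, 0L, "i1"),
    i2 = vapply(out, `[[`, 0L, "i2"),
    p1 = vapply(out, `[[`, 0L, "p1"),
    p2 = vapply(out, `[[`, 0L, "p2"),
    k = vapply(out, `[[`, 0, "k"),
    class = vapply(out, `[[`, "", "class"),
    km = vapply(out, `[[`, 0, "km"))

  ## stoichiometry matrix (species x reactions); MM handled in rate law,
  ## its stoichiometry is LAT(U) -> LAT(P) with the catalyst unchanged
  nr <- nrow(rx)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  add_trip <- function(sidx, ridx, v) {
    keep <- sidx > 0L
    trip_i <<- c(trip_i, sidx[keep])
    trip_j <<- c(trip_j, ridx[keep])
    trip_x <<- c(trip_x, v[keep])
  }
  is_mm <- rx$class == "mm"
  is_bath <- rx$class %in% c("bath_lig", "bath_hapten")
  # reactants consumed (bath pseudo-reactant i2 = 0 already)
  add_trip(ifelse(is_mm, 0L, rx$i1), seq_len(nr), rep(-1, nr))
  add_trip(ifelse(is_mm, rx$i2, rx$i2), seq_len(nr),
           rep(-1, nr))
  add_trip(rx$p1, seq_len(nr), rep(1, nr))
  add_trip(ifelse(is_mm, 0L, rx$p2), seq_len(nr), rep(1, nr))
  S <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(nrow(state), nr))

  mo <- as.matrix(sdf[chem_row[state$chem],
                      c("R", "Lyn", "Syk", "LAT", "Grb2")])
  ob <- as.matrix(sdf[chem_row[state$chem],
                      c("beta", "gamma", "syk", "lat")])
  rownames(mo) <- rownames(ob) <- NULL

  structure(list(
    chem = chem, species = state, reactions = rx, S = S, moieties = mo,
    obs_counts = ob, params = params, compartmental = compartmental),
    class = "raft_network")
}

check_diffusion_limit <- function(params) {
  geom <- raft_geometry(params)
  lam <- params$raft_lifetime
  kdiffN <- diffusion_limited_rate(geom, lam, params$d_raft) * geom$density
  entry <- entry_rates_by_class(params)
  bad <- names(entry)[entry > kdiffN]
  if (length(bad))
    stop("raft entry rate exceeds the 2D diffusion limit for class(es) ",
         paste(bad, collapse = ", "),
         sprintf(" (lambda = %g s < lambda_min; k+diff*N = %.3g /s)",
                 lam, kdiffN))
  invisible(TRUE)
}

#' Merge the raft/nonraft compartments of a generated network
#'
#' Returns the single-compartment network obtained by identifying the
#' raft/nonraft twins of every membrane species, removing the protection
#' factor `alpha`, the co-confinement scaling and the exchange reactions,
#' and setting Lyn activity to its raft value. With `alpha = 1` and
#' `lyn_nonraft_activity = 1` (and co-confinement scaling disabled) the
#' compartmental network's observables coincide with this network's.
#'
#' @param network a compartmental `raft_network`.
#' @return a `raft_network` with `compartmental = FALSE`.
#' @export
collapse_compartments <- function(network) {
  stopifnot(inherits(network, "raft_network"))
  if (!network$compartmental)
    stop("network was not generated with raft attributes")
  build_kinetic_network(network$chem, network$params, compartmental = FALSE)
}

#' Species and reaction counts of a generated network
#'
#' Reports the size of the network under the conventions used in the
#' rule-based FcERI literature: `receptor_species_ligand` counts distinct
#' receptor-containing complexes reachable in the bivalent-ligand
#' (stimulation) phase — the convention under which the base-model
#' combinatorics give 348 — plus total chemistry-level species/reactions
#' (with the monovalent hapten reachable) and the compartment-expanded
#' counts actually integrated.
#'
#' @param network a `raft_network`.
#' @return a named list of counts.
#' @export
network_size <- function(network) {
  stopifnot(inherits(network, "raft_network"))
  sdf <- network$chem$species
  rdf <- network$chem$reactions
  rec <- sdf$R > 0
  hap <- sdf$type == "mono" &
    vapply(strsplit(sdf$label, ";"), function(x)
      grepl("H", x[1], fixed = TRUE), logical(1))
  hap <- hap | (sdf$type == "mono" & startsWith(sdf$label, "R(H"))
  hap_rx <- rdf$r1 %in% sdf$label[hap] | rdf$p1 %in% sdf$label[hap] |
    rdf$p2 %in% sdf$label[hap] | rdf$class == "bath_hapten"
  list(
    receptor_species_ligand = sum(rec & !hap),
    receptor_species = sum(rec),
    chem_species_ligand = sum(!hap),
    chem_species = nrow(sdf),
    chem_reactions_ligand = sum(!hap_rx),
    chem_reactions = nrow(rdf),
    state_species = nrow(network$species),
    state_reactions = nrow(network$reactions))
}

#' @export
print.raft_network <- function(x, ...) {
  ns <- network_size(x)
  cat("FcERI raft reaction network\n")
  cat(sprintf("  receptor complexes (ligand phase): %d\n",
              ns$receptor_species_ligand))
  cat(sprintf("  chemistry species / reactions:     %d / %d\n",
              ns$chem_species, ns$chem_reactions))
  if (x$compartmental)
    cat(sprintf("  compartmental states / reactions:  %d / %d\n",
                ns$state_species, ns$state_reactions))
  else
    cat("  single-compartment (collapsed) network\n")
  invisible(x)
}
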