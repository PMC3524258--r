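#' Build the FcERI raft model definition
#'
#' Assembles the declarative model: molecule types (bivalent ligand,
#' monovalent hapten, receptor with beta/gamma ITAMs, Lyn, Syk, LAT, Grb2),
#' the binding/catalytic/dephosphorylation rule set, and the parameter set.
#' The chemistry follows Faeder et al. (2003): constitutive Lyn unique-domain
#' association with unphosphorylated beta; ligand binding and crosslinking
#' into receptor dimers; trans-phosphorylation of the partner receptor's beta
#' and gamma ITAMs by receptor-anchored Lyn (distinct rates for unique-domain
#' vs SH2-anchored Lyn); Lyn-SH2 recruitment to phospho-beta and Syk
#' recruitment to phospho-gamma; Lyn phosphorylation of the linker of
#' partner-bound Syk and Syk trans-autophosphorylation of the partner Syk's
#' activation loop; Michaelis-Menten phosphorylation of LAT by receptor-bound
#' activated Syk; Grb2 binding to phospho-LAT; and dephosphorylation of every
#' naked phosphosite, scaled by `alpha` inside rafts. SH2-bound
#' phosphotyrosines (Lyn-SH2 on beta, Syk on gamma, Grb2 on LAT) have no
#' dephosphorylation channel while bound.
#'
#' @param params a `raft_params` list, see [default_params()].
#' @param include character vector of optional molecule modules to include;
#'   any of `"lyn"`, `"syk"`, `"lat"`, `"grb2"`, `"hapten"`. The default is
#'   all of them; a reduced set (e.g. `character(0)` for the bare
#'   ligand-receptor binding model) is useful for enumeration checks.
#' @return An object of class `raft_model`.
#' @examples
#' m <- build_model(default_params())
#' m$molecules$receptor$components
#' @export
build_model <- function(params = default_params(),
                        include = c("lyn", "syk", "lat", "grb2", "hapten")) {
  validate_params(params)
  include <- as.character(include)
  allowed <- c("lyn", "syk", "lat", "grb2", "hapten")
  if (!all(include %in% allowed))
    stop("include must be a subset of: ", paste(allowed, collapse = ", "))
  if (("grb2" %in% include) && !("lat" %in% include))
    stop("grb2 requires lat (Grb2 binds phospho-LAT)")

  molecules <- list(
    ligand = list(
      name = "ligand", localization = "extracellular",
      components = list(list(site = "arm1", states = NULL, bindable = TRUE),
                        list(site = "arm2", states = NULL, bindable = TRUE))),
    receptor = list(
      name = "receptor", localization = "membrane",
      copy_number = params$rec_total,
      components = list(
        list(site = "alpha", states = NULL, bindable = TRUE),
        list(site = "beta",  states = c("U", "P"), bindable = TRUE),
        list(site = "gamma", states = c("U", "P"), bindable = TRUE)))
  )
  if ("hapten" %in% include)
    molecules$hapten <- list(
      name = "hapten", localization = "extracellular",
      components = list(list(site = "dnp", states = NULL, bindable = TRUE)))
  if ("lyn" %in% include)
    molecules$lyn <- list(
      name = "lyn", localization = "membrane", copy_number = params$lyn_total,
      components = list(
        list(site = "unique", states = NULL, bindable = TRUE),
        list(site = "sh2", states = NULL, bindable = TRUE)))
  if ("syk" %in% include)
    molecules$syk <- list(
      name = "syk", localization = "cytosolic", copy_number = params$syk_total,
      components = list(
        list(site = "tsh2", states = NULL, bindable = TRUE),
        list(site = "linker", states = c("U", "P"), bindable = FALSE),
        list(site = "aloop", states = c("U", "P"), bindable = FALSE)))
  if ("lat" %in% include)
    molecules$lat <- list(
      name = "lat", localization = "membrane", copy_number = params$lat_total,
      components = list(
        list(site = "tyr", states = c("U", "P"), bindable = TRUE)))
  if ("grb2" %in% include)
    molecules$grb2 <- list(
      name = "grb2", localization = "cytosolic",
      copy_number = params$grb2_total,
      components = list(list(site = "sh2", states = NULL, bindable = TRUE)))

  for (m in molecules) {
    sn <- vapply(m$components, `[[`, "", "site")
    if (anyDuplicated(sn))
      stop("duplicate site names in molecule ", m$name)
  }

  structure(list(molecules = molecules, params = params, include = include),
            class = "raft_model")
}

#' @export
print.raft_model <- function(x, ...) {
  cat("FcERI raft model:", length(x$molecules), "molecule types (",
      paste(names(x$molecules), collapse = ", "), ")\n")
  cat("alpha =", x$params$alpha, " lambda =", x$params$raft_lifetime, "s\n")
  invisible(x)
}

## ---- species records --------------------------------------------------
## Aggregates never exceed dimers, so complexes are represented as small
## typed records with a canonical label; the label is invariant under
## permutation of the two receptors of a dimer (sorted unit states).

# receptor unit: beta in {"Y","YL","P","PL"}, gamma in
# {"Y","P","S00","S01","S10","S11"} (Syk bound, linker/aloop flags)
BETA_STATES  <- c("Y", "YL", "P", "PL")
GAMMA_STATES <- c("Y", "P", "S00", "S01", "S10", "S11")

sp_mono  <- function(a, b, g) list(type = "mono", a = a, b = b, g = g)
sp_dimer <- function(b1, g1, b2, g2) {
  u <- c(paste(b1, g1, sep = "|"), paste(b2, g2, sep = "|"))
  o <- order(u)
  us <- list(c(b1, g1), c(b2, g2))[o]
  list(type = "dimer", b1 = us[[1]][1], g1 = us[[1]][2],
       b2 = us[[2]][1], g2 = us[[2]][2])
}
sp_lyn  <- function() list(type = "lyn")
# l, a are "0"/"1" flags for linker / activation-loop phosphorylation
sp_syk  <- function(l, a) list(type = "syk", l = l, a = a)
sp_lat  <- function(y) list(type = "lat", y = y)  # y in {"U","P","PG"}
sp_grb2 <- function() list(type = "grb2")

#' Canonical species label
#'
#' Labels are equal iff the complexes are isomorphic: for dimers the two
#' receptor unit states are sorted, so relabeling molecule instances never
#' changes the label.
#'
#' @param sp a species record.
#' @return a character scalar.
#' @keywords internal
canonical_label <- function(sp) {
  switch(sp$type,
    mono  = sprintf("R(%s;%s;%s)", sp$a, sp$b, sp$g),
    dimer = sprintf("D(%s;%s)(%s;%s)", sp$b1, sp$g1, sp$b2, sp$g2),
    lyn   = "Lyn",
    syk   = sprintf("Syk(%s%s)", sp$l, sp$a),
    lat   = sprintf("LAT(%s)", sp$y),
    grb2  = "Grb2",
    stop("unknown species type ", sp$type))
}

# per-species moiety counts (receptor, lyn, syk, lat, grb2)
moiety_counts <- function(sp) {
  unit_lyn <- function(b) as.integer(b %in% c("YL", "PL"))
  unit_syk <- function(g) as.integer(startsWith(g, "S"))
  switch(sp$type,
    mono  = c(R = 1L, Lyn = unit_lyn(sp$b), Syk = unit_syk(sp$g),
              LAT = 0L, Grb2 = 0L),
    dimer = c(R = 2L, Lyn = unit_lyn(sp$b1) + unit_lyn(sp$b2),
              Syk = unit_syk(sp$g1) + unit_syk(sp$g2), LAT = 0L, Grb2 = 0L),
    lyn   = c(R = 0L, Lyn = 1L, Syk = 0L, LAT = 0L, Grb2 = 0L),
    syk   = c(R = 0L, Lyn = 0L, Syk = 1L, LAT = 0L, Grb2 = 0L),
    lat   = c(R = 0L, Lyn = 0L, Syk = 0L, LAT = 1L,
              Grb2 = as.integer(identical(sp$y, "PG"))),
    grb2  = c(R = 0L, Lyn = 0L, Syk = 0L, LAT = 0L, Grb2 = 1L))
}

is_membrane_species <- function(sp)
  sp$type %in% c("mono", "dimer", "lyn", "lat")

# per-species phosphosite counts feeding the named observables; a
# phosphorylated-and-bound site counts as phosphorylated
phospho_counts <- function(sp) {
  unit_bP <- function(b) as.integer(b %in% c("P", "PL"))
  unit_gP <- function(g) as.integer(g == "P" || startsWith(g, "S"))
  unit_sP <- function(g) as.integer(g %in% c("S01", "S11"))
  switch(sp$type,
    mono  = c(beta = unit_bP(sp$b), gamma = unit_gP(sp$g),
              syk = unit_sP(sp$g), lat = 0L),
    dimer = c(beta = unit_bP(sp$b1) + unit_bP(sp$b2),
              gamma = unit_gP(sp$g1) + unit_gP(sp$g2),
              syk = unit_sP(sp$g1) + unit_sP(sp$g2), lat = 0L),
    syk   = c(beta = 0L, gamma = 0L, syk = as.integer(sp$a == "1"),
              lat = 0L),
    lat   = c(beta = 0L, gamma = 0L, syk = 0L,
              lat = as.integer(sp$y %in% c("P", "PG"))),
    c(beta = 0L, gamma = 0L, syk = 0L, lat = 0L))
}

#' Raft partition coefficient of a complex
#'
#' Total on membrane-containing complexes, depending only on the membrane
#' part, by precedence: a complex containing a receptor dimer partitions as
#' an aggregate (`rho_dimer`); wild-type Lyn bound to a non-aggregated
#' receptor confers its own partitioning (`rho_lyn`, palmitoylation-driven),
#' as does free Lyn; complexes containing LAT use `rho_lat`; any other
#' non-aggregated receptor (including one bound by palmitoylation-mutant
#' Lyn, which is equally likely to be anywhere in the membrane) uses
#' `rho_monomer`. Cytosolic binders (Syk, Grb2) never change the coefficient.
#'
#' @param sp a species record (or canonical label) of a membrane complex.
#' @param params a `raft_params` list.
#' @return the partition coefficient rho in (0, 1).
#' @export
assign_partition <- function(sp, params = default_params()) {
  if (is.character(sp)) sp <- parse_label(sp)
  cls <- partition_class(sp, params)
  if (is.na(cls))
    stop("cytosolic or extracellular species have no partition coefficient: ",
         canonical_label(sp))
  unname(c(monomer = params$rho_monomer, dimer = params$rho_dimer,
           lyn = params$rho_lyn, lat = params$rho_lat)[cls])
}

partition_class <- function(sp, params) {
  switch(sp$type,
    dimer = "dimer",
    lyn   = "lyn",
    lat   = "lat",
    mono  = {
      has_lyn <- sp$b %in% c("YL", "PL")
      if (has_lyn && !isTRUE(params$lyn_mutant)) "lyn" else "monomer"
    },
    syk   = NA_character_,
    grb2  = NA_character_)
}

# inverse of canonical_label, for user-facing entry points
parse_label <- function(lab) {
  if (lab == "Lyn") return(sp_lyn())
  if (lab == "Grb2") return(sp_grb2())
  m <- regmatches(lab, regexec("^LAT\\((U|P|PG)\\)$", lab))[[1]]
  if (length(m)) return(sp_lat(m[2]))
  m <- regmatches(lab, regexec("^Syk\\(([01])([01])\\)$", lab))[[1]]
  if (length(m)) return(sp_syk(m[2], m[3]))
  m <- regmatches(lab, regexec("^R\\(([0LH]);([A-Z]+);([A-Z0-9]+)\\)$",
                               lab))[[1]]
  if (length(m)) return(sp_mono(m[2], m[3], m[4]))
  m <- regmatches(lab, regexec(
    "^D\\(([A-Z]+);([A-Z0-9]+)\\)\\(([A-Z]+);([A-Z0-9]+)\\)$", lab))[[1]]
  if (length(m)) return(sp_dimer(m[2], m[3], m[4], m[5]))
  stop("cannot parse species label: ", lab)
}
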