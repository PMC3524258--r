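# run every file to completion even when acceptance blocks are red
options(testthat.progress.max_fails = Inf)

# heavy simulation objects shared across test files (built once per run)
.raft_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.raft_test_cache[[key]]))
    assign(key, force(expr), envir = .raft_test_cache)
  get(key, envir = .raft_test_cache)
}

cached_chem <- function()
  cached("chem", raftsig:::enumerate_chemistry(build_model(default_params())))

cached_net <- function(alpha = 0.2, ...) {
  key <- paste("net", alpha, paste(c(...), collapse = "|"))
  cached(key, raftsig:::build_kinetic_network(
    cached_chem(), default_params(alpha = alpha, ...)))
}

cached_ss <- function(alpha = 0.2, ligand = 1e-9) {
  key <- paste("ss", alpha, ligand)
  cached(key, steady_state(cached_net(alpha), ligand = ligand))
}

# normalized dephosphorylation curves at default parameters over the
# alpha grid used for recovery, 0-180 s
recovery_grid <- c(0, 0.05, 0.1, 0.2, 0.5, 1)

cached_curves <- function()
  cached("curves", dephos_curves(
    recovery_grid, default_params(), times = seq(0, 180, by = 0.5),
    observables = c("beta", "gamma", "receptor", "lat")))

# all rate processes off: pure raft/nonraft exchange
exchange_only_params <- function(...) {
  default_params(
    kon_lig = 0, koff_lig = 0, kx_lig = 0, koff_x = 0, kon_hapten = 0,
    koff_hapten = 0, kon_lyn_u = 0, koff_lyn_u = 0, kon_lyn_sh2 = 0,
    koff_lyn_sh2 = 0, kon_syk = 0, koff_syk = 0, kon_grb2 = 0,
    koff_grb2 = 0, p_beta_u = 0, p_beta_s = 0, p_gamma_u = 0,
    p_gamma_s = 0, p_syk_u = 0, p_syk_s = 0, p_aloop = 0, p_aloop_a = 0,
    kcat_lat = 0, k_dephos = 0, k_dephos_cyt = 0, ...)
}

half_lives_from_curves <- function(curves, observable) {
  vapply(names(curves), function(a)
    half_life(curves[[a]]$time, curves[[a]][[observable]]), 0)
}
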