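# shared scenario builders and a memoisation cache reused across test files;
# simulations are deterministic, so caching never changes results

.test_cache <- new.env(parent = emptyenv())

protein_scenario <- function(...) {
  sc <- scenario(
    agent = agent_spec(),
    tissue = tissue_spec(),
    target = target_spec(),
    regimen = make_regimen("single", peak = 1e-6, half_life = 2.55),
    n_shells = 100, t_end = 72
  )
  mods <- list(...)
  for (nm in names(mods)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    sc[[parts[1]]][[parts[2]]] <- mods[[nm]]
  }
  sc
}

peptide_scenario <- function(...) {
  protein_scenario("agent.molecular_weight" = 3.5,
                   "agent.plasma_half_life" = 0.28, ...)
}

run_cached <- function(sc) run_scenario(sc, cache = .test_cache)

# independent well-mixed oracle: the same reaction network written as a
# 6-species lumped ODE with its own unit conversions, integrated by radau
# (a different stiff method than the PDE path uses)
well_mixed_oracle <- function(agent, tissue, target, peak, t_end,
                              times = seq(0, t_end, by = 0.25)) {
  NA_CONST <- 6.02214076e23
  aV <- 2 * tissue$capillary_radius /
    (tissue$krogh_radius^2 - tissue$capillary_radius^2)   # area/volume, 1/um
  P <- tissue$vascular_permeability *
    (tissue$reference_mw / agent$molecular_weight)^(2 / 3) * 1e4 * 3600  # um/h
  eps <- tissue$void_fraction
  kon <- agent$kon_receptor * 3600
  koff <- kon * agent$kd_receptor
  ke <- tissue$k_internalize * 60
  R0 <- tissue$receptors_per_cell * tissue$cell_density * 1e3 / NA_CONST
  fesc <- agent$escape_fraction
  phi <- tissue$cell_density * 1e3 * target$cytosol_volume_per_cell * 1e-12
  kdeg_a <- log(2) / agent$cytosolic_half_life
  kon_t <- agent$kon_target * 3600
  koff_t <- kon_t * agent$kd_target
  kcat <- agent$k_cat * 60
  T0 <- target$copies_per_cell / (NA_CONST * target$cytosol_volume_per_cell * 1e-12)
  kdeg_T <- log(2) / target$target_half_life
  ksyn <- T0 * kdeg_T
  rhs <- function(t, y, p) {
    A <- y[1]; R <- y[2]; C <- y[3]; Ac <- y[4]; Tf <- y[5]; B <- y[6]
    Cp <- peak * 2^(-t / agent$plasma_half_life)
    bind <- kon * (A / eps) * R - koff * C
    intern <- ke * C
    cap <- kon_t * Ac * Tf - koff_t * B
    list(c(
      P * aV * (Cp - A / eps) - bind,
      -bind + intern,
      bind - intern,
      fesc * intern / phi - kdeg_a * Ac - cap + kcat * B,
      ksyn - kdeg_T * Tf - cap,
      cap - kcat * B
    ))
  }
  y0 <- c(A = 0, R = R0, C = 0, Ac = 0, Tf = T0, B = 0)
  deSolve::radau(y0, times, rhs, parms = NULL, rtol = 1e-10, atol = 1e-14)
}

# build a synthetic trajectory object with prescribed fields (for outcome
# metric oracles on analytically known profiles)
synthetic_trajectory <- function(grid, times, T_free, A_int = NULL, T0, phi = 0.29) {
  n <- grid$n_shells
  nt <- length(times)
  conc <- array(0, dim = c(6, n, nt),
                dimnames = list(c("A_int", "R_free", "RC_surf", "A_cyt",
                                  "T_free", "TC_cyt"), NULL, NULL))
  conc["T_free", , ] <- T_free
  if (!is.null(A_int)) conc["A_int", , ] <- A_int
  structure(
    list(times = times, conc = conc, grid = grid,
         params = list(T0 = T0, phi = phi),
         regimen = make_regimen("single", peak = 0, half_life = 1)),
    class = "trajectory"
  )
}
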