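state0 <- function(agent = agent_spec(), tissue = tissue_spec(),
                   target = target_spec(), cold = FALSE) {
  nm <- c("A_int", "R_free", "RC_surf", "A_cyt", "T_free", "TC_cyt")
  if (cold) nm <- c(nm, "A_int_cold", "RC_surf_cold")
  s <- stats::setNames(rep(0, length(nm)), nm)
  s["R_free"] <- receptors_to_molar(tissue$receptors_per_cell, tissue$cell_density)
  s["T_free"] <- copies_to_molar(target$copies_per_cell,
                                 target$cytosol_volume_per_cell)
  s
}

test_that("pre-dose steady state has zero net rates", {
  d <- reaction_terms(state0(), agent_spec(), tissue_spec(), target_spec())
  expect_equal(max(abs(d)), 0)
})

test_that("catalytic mode with vanishing k_cat reduces to binder mode", {
  ag_b <- agent_spec(mode = "binder")
  # the constructor forbids k_cat = 0 in catalytic mode (type invariant), so
  # build the degenerate object directly to check the rate equations
  ag_c <- unclass(ag_b); ag_c$mode <- "catalytic"; ag_c$k_cat <- 0
  class(ag_c) <- "agent_spec"
  s <- state0()
  s[] <- abs(sin(seq_along(s))) * 1e-8  # arbitrary positive state
  expect_identical(
    reaction_terms(s, ag_b, tissue_spec(), target_spec()),
    reaction_terms(s, ag_c, tissue_spec(), target_spec())
  )
})

test_that("binder-mode target mass balance closes on the rate equations", {
  ag <- agent_spec()
  ti <- tissue_spec(); tg <- target_spec()
  T0 <- copies_to_molar(tg$copies_per_cell, tg$cytosol_volume_per_cell)
  kdeg_T <- log(2) / tg$target_half_life
  set.seed(11)
  for (i in 1:20) {
    s <- state0()
    s[] <- runif(6) * 1e-7
    d <- reaction_terms(s, ag, ti, tg)
    # d(T_free + TC_cyt)/dt == synthesis - decay of free target, exactly
    resid <- (d["T_free"] + d["TC_cyt"]) -
      (T0 * kdeg_T - kdeg_T * s["T_free"])
    expect_lt(abs(resid) / T0, 1e-8)
  }
})

test_that("a single isolated cell layer matches an independent stiff solve", {
  # one shell, transport off, interstitial agent clamped at 1 uM free:
  # integrate the surface/cytosolic cascade with radau, independently written
  ag <- agent_spec(kd_receptor = 1e-9)
  ti <- tissue_spec()
  tg <- target_spec()
  kon <- ag$kon_receptor * 3600; koff <- kon * ag$kd_receptor
  ke <- ti$k_internalize * 60
  R0 <- receptors_to_molar(ti$receptors_per_cell, ti$cell_density)
  Af <- 1e-6  # clamped free interstitial concentration
  # recycling returns internalized receptor to the surface (steady state)
  oracle <- deSolve::radau(
    c(R = R0, C = 0), seq(0, 48, by = 0.5),
    function(t, y, p) list(c(-kon * Af * y[1] + koff * y[2] + ke * y[2],
                             kon * Af * y[1] - koff * y[2] - ke * y[2])),
    parms = NULL, rtol = 1e-10, atol = 1e-14
  )
  # package path: same clamped shell via reaction_terms + lsoda
  rhs <- function(t, y, p) {
    s <- state0(ag, ti, tg)
    s["R_free"] <- y[1]; s["RC_surf"] <- y[2]
    s["A_int"] <- Af * ti$void_fraction
    d <- reaction_terms(s, ag, ti, tg)
    list(c(d["R_free"], d["RC_surf"]))
  }
  ours <- deSolve::lsoda(c(R0, 0), seq(0, 48, by = 0.5), rhs, parms = NULL,
                         rtol = 1e-10, atol = 1e-14)
  expect_equal(ours[, 2], unname(oracle[, 2]), tolerance = 1e-6)
  expect_equal(ours[, 3], unname(oracle[, 3]), tolerance = 1e-6)
  # long-time occupancy: saturation-shaped, reduced by internalization
  C_inf <- R0 * kon * Af / (kon * Af + koff + ke)
  expect_equal(unname(ours[nrow(ours), 3]), C_inf, tolerance = 1e-3)
})

test_that("initial state is the receptor/target steady state", {
  ti <- tissue_spec(); tg <- target_spec()
  g <- build_grid(ti, 50)
  y <- initial_state(ti, tg, g)
  expect_equal(dim(y), c(6, 50))
  expect_equal(unique(y["R_free", ]), receptors_to_molar(5.4e5, 2.9e8))
  expect_equal(unique(y["T_free", ]), copies_to_molar(1e4, 1))
  expect_true(all(y[c("A_int", "A_cyt", "TC_cyt", "RC_surf"), ] == 0))
  y2 <- initial_state(ti, tg, g, cold = TRUE)
  expect_equal(nrow(y2), 8)
})
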