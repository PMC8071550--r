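test_that("a zero dose leaves the tissue at its pre-dose steady state", {
  sc <- protein_scenario()
  sc$regimen <- make_regimen("single", peak = 0, half_life = 2.55)
  sc$n_shells <- 40; sc$t_end <- 24
  tr <- run_cached(sc)
  y0 <- initial_state(sc$tissue, sc$target, tr$grid)
  dev <- apply(tr$conc, 3, function(m) max(abs(m - y0)))
  expect_lt(max(dev) / max(y0), 1e-8)
})

test_that("all species stay non-negative and receptors are conserved", {
  tr <- run_cached(protein_scenario())
  expect_gt(min(tr$conc), -1e-12)
  Rtot <- species_field(tr, "R_free") + species_field(tr, "RC_surf")
  expect_lt(max(abs(Rtot - tr$params$R_tot)) / tr$params$R_tot, 1e-6)
})

test_that("receptor conservation holds with a cold competitor in the mix", {
  sc <- protein_scenario()
  sc$regimen <- make_regimen("single", peak = 1e-6, half_life = 2.55,
                             cold_offset = 0)
  sc$n_shells <- 50; sc$t_end <- 48
  tr <- run_cached(sc)
  expect_equal(dim(tr$conc)[1], 8)
  Rtot <- species_field(tr, "R_free") + species_field(tr, "RC_surf") +
    species_field(tr, "RC_surf_cold")
  expect_lt(max(abs(Rtot - tr$params$R_tot)) / tr$params$R_tot, 1e-6)
  expect_gt(min(tr$conc), -1e-12)
})

test_that("global agent mass accounting closes within 0.1 percent", {
  sc <- protein_scenario()
  sc$dt_out <- 0.01; sc$t_end <- 48
  au <- mass_audit(run_cached(sc))
  expect_lt(au$relative_residual, 1e-3)
  # and with convective outflow active
  scv <- protein_scenario("tissue.fluid_velocity_at_wall" = 0.5)
  scv$dt_out <- 0.01; scv$t_end <- 48
  auv <- mass_audit(run_cached(scv))
  expect_lt(auv$relative_residual, 1e-3)
  expect_gt(auv$outflow, 0)
})

test_that("the well-mixed limit matches an independent lumped ODE", {
  sc <- protein_scenario("tissue.interstitial_diffusivity" = 1e-4)  # 1e4 x
  sc$t_end <- 48
  tr <- run_cached(sc)
  orc <- well_mixed_oracle(sc$agent, sc$tissue, sc$target, peak = 1e-6,
                           t_end = 48)
  nm <- c("A_int", "R_free", "RC_surf", "A_cyt", "T_free", "TC_cyt")
  for (i in seq_along(nm)) {
    ours <- volume_average(species_field(tr, nm[i]), tr$grid)
    ref <- orc[, i + 1]
    expect_lt(max(abs(ours - ref)) / max(abs(ref)), 5e-3)
  }
})

test_that("the interstitial profile decreases monotonically without convection", {
  tr <- run_cached(protein_scenario())
  A <- species_field(tr, "A_int")
  viol <- apply(A[, -1, drop = FALSE], 2,
                function(col) max(c(diff(col), 0)))
  expect_lt(max(viol), 1e-6 * max(A))
})

test_that("metrics converge under grid and output-step refinement", {
  sc <- protein_scenario()
  m100 <- max_inhibition(run_cached(sc))
  sc2 <- protein_scenario(); sc2$n_shells <- 200; sc2$dt_out <- 0.125
  m200 <- max_inhibition(run_cached(sc2))
  expect_lt(abs(m200 - m100) / m100, 0.01)
})

test_that("maximum inhibition is monotone in the administered dose", {
  m <- vapply(c(3e-7, 1e-6, 3e-6), function(pk) {
    sc <- protein_scenario()
    sc$regimen <- make_regimen("single", peak = pk, half_life = 2.55)
    max_inhibition(run_cached(sc))
  }, numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("dose times restart the integration without artefacts", {
  sc <- protein_scenario()
  sc$regimen <- make_regimen("repeated", peak = 5e-7, half_life = 2.55,
                             interval = 11.9, n_doses = 3)
  sc$t_end <- 48
  tr <- run_cached(sc)
  cp <- plasma_concentration(tr$regimen, "warm", tr$times)
  # plasma jumps by the peak at each dose; tissue state stays continuous
  A <- volume_average(species_field(tr, "A_int"), tr$grid)
  expect_true(all(is.finite(A)))
  expect_gt(min(tr$conc), -1e-12)
  expect_equal(max(cp), plasma_concentration(tr$regimen, "warm", 23.8),
               tolerance = 0.05)
})

test_that("trajectories export as tidy long tables", {
  sc <- protein_scenario(); sc$n_shells <- 40; sc$t_end <- 4
  tr <- run_cached(sc)
  df <- as.data.frame(tr)
  expect_named(df, c("time_h", "radius_um", "species", "concentration_M"))
  expect_equal(nrow(df), 6 * 40 * length(tr$times))
  one <- df[df$time_h == 2 & df$species == "T_free", ]
  expect_equal(one$concentration_M, species_field(tr, "T_free")[, match(2, tr$times)])
})
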