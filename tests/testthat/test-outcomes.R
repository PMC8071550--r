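test_that("inhibition field is the clipped fractional target depression", {
  g <- build_grid(tissue_spec(), 50)
  T0 <- copies_to_molar(1e4, 1)
  # pre-dose: target at baseline everywhere -> zero inhibition
  tr <- synthetic_trajectory(g, 0:10, T_free = T0, T0 = T0)
  expect_true(all(inhibition_field(tr) == 0))
  # fully depleted target -> full inhibition
  tr2 <- synthetic_trajectory(g, 0:10, T_free = 0, T0 = T0)
  expect_true(all(inhibition_field(tr2) == 1))
  # overshoot above baseline clips to zero rather than going negative
  tr3 <- synthetic_trajectory(g, 0:10, T_free = 1.2 * T0, T0 = T0)
  expect_true(all(inhibition_field(tr3) == 0))
  tr4 <- synthetic_trajectory(g, 0:10, T_free = T0, T0 = 0)
  expect_error(inhibition_field(tr4), "zero baseline")
})

test_that("inhibitory effect integrates to the duration under full inhibition", {
  g <- build_grid(tissue_spec(), 50)
  T0 <- copies_to_molar(1e4, 1)
  tr <- synthetic_trajectory(g, seq(0, 36, by = 0.25), T_free = 0, T0 = T0)
  expect_equal(inhibitory_effect(tr), 36)
  tr0 <- synthetic_trajectory(g, seq(0, 36, by = 0.25), T_free = T0, T0 = T0)
  expect_equal(inhibitory_effect(tr0), 0)
  expect_equal(max_inhibition(tr), 1)
  expect_equal(max_inhibition(tr0), 0)
})

test_that("inhibitory effect is monotone in the simulated horizon", {
  sc <- protein_scenario(); sc$n_shells <- 50
  tr <- run_cached(sc)
  trunc_ie <- vapply(c(24, 48, 72), function(tend) {
    keep <- tr$times <= tend
    tt <- tr
    tt$times <- tr$times[keep]
    tt$conc <- tr$conc[, , keep, drop = FALSE]
    inhibitory_effect(tt)
  }, numeric(1))
  expect_true(all(diff(trunc_ie) > 0))
})

test_that("time of maximal delivery flags the degenerate zero-dose case", {
  sc <- protein_scenario()
  sc$regimen <- make_regimen("single", peak = 0, half_life = 2.55)
  sc$n_shells <- 40; sc$t_end <- 12
  expect_true(is.na(time_of_max_delivery(run_cached(sc))))
})

test_that("penetration depth matches the closed-form annulus oracle", {
  g <- build_grid(tissue_spec(), 100)
  T0 <- copies_to_molar(1e4, 1)
  # uniform agent: half the annular volume sits within
  # sqrt((r_cap^2 + R_K^2)/2) - r_cap = 68.58 um of the wall
  tr <- synthetic_trajectory(g, 0:4, T_free = 0.5 * T0, A_int = 1e-8, T0 = T0)
  d50 <- penetration_depth(tr, 0.5, t = 2)
  expect_lt(abs(d50 - (sqrt((8^2 + 108^2) / 2) - 8)), 1.5)
  # the whole mass lies within the full tissue depth
  expect_equal(penetration_depth(tr, 1, t = 2), 100)
  # exponentially confined profile: oracle by direct cumulative sum
  prof <- 1e-8 * exp(-(g$centers - 8) / 10)
  tr2 <- synthetic_trajectory(g, 0:4, T_free = 0.5 * T0, A_int = prof, T0 = T0)
  m <- prof * g$volumes
  k <- which(cumsum(m) / sum(m) >= 0.5)[1]
  expect_equal(penetration_depth(tr2, 0.5, t = 0), g$edges[k + 1] - 8)
  # no agent anywhere -> sentinel
  tr3 <- synthetic_trajectory(g, 0:4, T_free = 0.5 * T0, T0 = T0)
  expect_true(is.na(penetration_depth(tr3, 0.5, t = 2)))
})

test_that("metrics are stable under output-time refinement", {
  sc <- protein_scenario(); sc$n_shells <- 50
  a <- run_cached(sc)
  sc2 <- protein_scenario(); sc2$n_shells <- 50; sc2$dt_out <- 0.125
  b <- run_cached(sc2)
  expect_lt(abs(max_inhibition(a) - max_inhibition(b)) / max_inhibition(a), 0.01)
  expect_lt(abs(inhibitory_effect(a) - inhibitory_effect(b)) /
              inhibitory_effect(a), 0.01)
  expect_lt(abs(time_of_max_delivery(a) - time_of_max_delivery(b)), 0.3)
})

test_that("volume weighting agrees with an independent annulus integral", {
  g <- build_grid(tissue_spec(), 200)
  T0 <- copies_to_molar(1e4, 1)
  # prescribed linear inhibition profile: inh(r) = 1 - (r - 8)/100
  inh_prof <- 1 - (g$centers - 8) / 100
  tr <- synthetic_trajectory(g, 0:2, T_free = (1 - inh_prof) * T0, T0 = T0)
  analytic <- stats::integrate(function(r) (1 - (r - 8) / 100) * 2 * pi * r,
                               8, 108)$value / (pi * (108^2 - 8^2))
  expect_equal(max_inhibition(tr), analytic, tolerance = 1e-4)
})

test_that("the outcome report gathers the scalar metrics", {
  sc <- protein_scenario(); sc$n_shells <- 50
  rep <- outcome_report(run_cached(sc))
  expect_s3_class(rep, "outcome_report")
  expect_true(rep$max_inhibition > 0 && rep$max_inhibition <= 1)
  expect_lte(rep$inhibitory_effect, sc$t_end)
  expect_gt(rep$t_max_delivery, 0)
  expect_output(print(rep), "max inhibition")
})
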