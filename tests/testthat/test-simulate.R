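test_that("the calibrated equilibrium is stationary", {
  p <- ref_params()
  m <- chip_model(p)
  # derivative at equilibrium vanishes
  d <- chipgraft:::chip_rhs(0, p$u_star,
                            list(model = m,
                                 pre = chipgraft:::prepare_model(m)))[[1]]
  expect_lt(max(abs(d) / pmax(p$u_star, 1)), 1e-8)
  # ten simulated years without drift
  tr <- simulate_dynamics(m, horizon = 3650, dt = 50)
  dev <- sweep(tr$u[, 1, ], 2, p$u_star, "/") - 1
  expect_lt(max(abs(dev)), 1e-4)
})

test_that("a depleted mature compartment regenerates under feedback", {
  p <- ref_params()
  m <- chip_model(p)
  st <- p$u_star
  st[p$n_stages + 2] <- st[p$n_stages + 2] / 2
  pre <- chipgraft:::prepare_model(m)
  d <- chipgraft:::chip_rhs(0, st, list(model = m, pre = pre))[[1]]
  # mature derivative positive, proliferation rates above homeostatic
  expect_gt(d[length(d)], 0)
  s_p <- feedback_signal(sum(st[p$n_stages + 2]), p$k_p)
  expect_gt(s_p, p$s_p_star)
})

test_that("the homeostatic state is stable under perturbations", {
  p <- ref_params()
  m <- chip_model(p)
  # HSC perturbations relax on the slow stem-cell timescale (decades),
  # downstream perturbations within months
  horizons <- c(40 * 365.25, 3650, 3650)
  for (k in seq_along(horizons)) {
    idx <- c(1L, 8L, p$n_stages + 2L)[k]
    st <- matrix(p$u_star, nrow = 1)
    st[idx] <- st[idx] * 1.2
    tr <- simulate_dynamics(m, init = st, horizon = horizons[k], dt = 100)
    final <- tr$u[length(tr$times), 1, ]
    expect_lt(max(abs(final / p$u_star - 1)), 0.01)
  }
})

test_that("clone aggregation is symmetric", {
  p <- ref_params()
  wt2 <- list(clone_spec(clone_id = "wt_a"), clone_spec(clone_id = "wt_b"))
  m1 <- chip_model(p)
  m3 <- chip_model(p, clones = wt2)
  init1 <- matrix(p$u_star, nrow = 1)
  init3 <- rbind(p$u_star / 3, p$u_star / 3, p$u_star / 3)
  tr1 <- simulate_dynamics(m1, init = init1, horizon = 365, dt = 5)
  tr3 <- simulate_dynamics(m3, init = init3, horizon = 365, dt = 5)
  tot1 <- apply(tr1$u, c(1, 3), sum)
  tot3 <- apply(tr3$u, c(1, 3), sum)
  expect_lt(max(abs(tot3 / tot1 - 1)), 1e-8)
})

test_that("reference transplantation engrafts in the clinical window", {
  tr <- ref_transplant()
  et <- engraftment_time(tr)
  expect_gte(et, 10)
  expect_lte(et, 20)
  # all concentrations nonnegative
  expect_true(all(tr$u >= 0))
  # recovery approaches the homeostatic mature count without ringing:
  # monotone rise to the maximum, then no drop below 90% of it
  M <- mature_series(tr)
  i_max <- which.max(M)
  expect_true(all(diff(M[1:i_max]) >= -1e-6 * max(M)))
  expect_true(all(M[i_max:length(M)] >= 0.9 * M[i_max]))
})

test_that("engraftment time is robust to solver tolerances", {
  init <- apply_homing(make_graft(4.7e6, ref_composition()))
  m <- chip_model(ref_params())
  t1 <- engraftment_time(simulate_dynamics(m, init = init, horizon = 40,
                                           dt = 0.25))
  t2 <- engraftment_time(simulate_dynamics(m, init = init, horizon = 40,
                                           dt = 0.25, atol = 2e-3,
                                           rtol = 2e-6))
  expect_lt(abs(t1 - t2), 0.01)
})

test_that("engraftment extraction handles edge cases", {
  p <- ref_params()
  m <- chip_model(p)
  # starts engrafted at equilibrium
  tr <- simulate_dynamics(m, horizon = 10, dt = 1)
  expect_identical(engraftment_time(tr), 0)
  # never engrafts: tiny graft, short horizon
  init <- apply_homing(make_graft(10, ref_composition()))
  tr2 <- simulate_dynamics(m, init = init, horizon = 5, dt = 0.5)
  expect_true(is.na(engraftment_time(tr2)))
  # threshold unit conversion: 5e8/l at 5 l / 80 kg = 3.125e7/kg
  expect_equal(5e8 * 5 / 80, 3.125e7)
})

test_that("simulate_dynamics validates its inputs", {
  m <- chip_model(ref_params())
  expect_error(simulate_dynamics(m, horizon = -1), "horizon")
  expect_error(simulate_dynamics(m, init = matrix(1, 2, 3)), "matrix")
  bad <- matrix(ref_params()$u_star, nrow = 1); bad[1] <- -5
  expect_error(simulate_dynamics(m, init = bad), "nonnegative")
})
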