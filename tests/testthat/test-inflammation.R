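test_that("the QSS burden and its saturating effect are algebraic", {
  ip <- inflammation_params(mode = "mutant_boost", host_baseline = 2)
  expect_equal(inflammatory_burden(1e8, ip, alpha = 0), 2)
  ip0 <- inflammation_params(mode = "mutant_boost", host_baseline = 0)
  expect_equal(inflammatory_burden(0, ip0, alpha = 1e-8), 0)
  expect_equal(inflammatory_burden(1e8, ip0, alpha = 1e-8), 1)
  expect_equal(inflammation_effect(1, 1), 0.5)
  expect_equal(inflammation_effect(0, 1), 0)
  expect_equal(inflammation_effect(2, 1), 2 / 3)
  e <- inflammation_effect(seq(0, 50, by = 1), 1)
  expect_true(all(diff(e) > 0) && all(e < 1))
  expect_error(inflammation_effect(-1, 1), ">= 0")
})

test_that("coupling factors act on the right clone and targets", {
  p <- ref_params()
  rates <- regulated_rates(p$s_star, p$s_star, p)
  boost <- inflammation_params(mode = "mutant_boost",
                               lambda_selfrenewal = 0.4, lambda_prolif = 0.2)
  # zero effect, zero disadvantage: rates unchanged
  r0 <- apply_inflammation(rates, 0, boost)
  expect_equal(r0$p, unname(rates$p))
  expect_equal(r0$a, unname(rates$a))
  # positive effect boosts the responsive mutant clone
  r1 <- apply_inflammation(rates, 0.5, boost)
  expect_equal(r1$a[1], min(1, rates$a[1] * 1.2))
  expect_equal(r1$p, unname(rates$p) * 1.1)
  # wildtype untouched in mutant-boost mode
  rw <- apply_inflammation(rates, 0.5, boost, is_wildtype = TRUE)
  expect_equal(rw$a, unname(rates$a))
  # exhaustion reduces wildtype self-renewal and amplification only
  exh <- inflammation_params(mode = "wildtype_exhaustion",
                             mu_selfrenewal = 0.4, mu_amplification = 0.2)
  re <- apply_inflammation(rates, 0.5, exh, is_wildtype = TRUE)
  expect_equal(re$a[1], rates$a[1] * 0.8)
  expect_equal(re$a[-1], unname(rates$a[-1]) * 0.9)
  expect_equal(re$p, unname(rates$p))
  rm <- apply_inflammation(rates, 0.5, exh, is_wildtype = FALSE)
  expect_equal(rm$a, unname(rates$a))
  # probabilities stay clipped in [0, 1]
  big <- inflammation_params(mode = "mutant_boost", lambda_selfrenewal = 50)
  rb <- apply_inflammation(rates, 0.9, big)
  expect_true(all(rb$a <= 1))
})

test_that("zero-effect inflammation coupling reproduces the plain model", {
  cl <- clone_spec(sens_hsc = 2, sens_hpc = 2)
  tr_off <- run_recipient(cl, horizon = 200, dt = 1)
  # mutant_boost with nothing to couple: identical trajectories
  ip <- inflammation_params(mode = "mutant_boost")
  tr_null <- run_recipient(cl, horizon = 200, dt = 1, inflammation = ip)
  expect_equal(tr_null$u, tr_off$u, tolerance = 1e-12)
  # burden is constant in time when alpha = 0 and reported alongside
  ip2 <- inflammation_params(mode = "mutant_boost", host_baseline = 3)
  tr_b <- run_recipient(cl, horizon = 200, dt = 1, inflammation = ip2)
  expect_true(all(tr_b$burden == 3))
})

test_that("CHIP-driven inflammation sustains mutant expansion", {
  cl <- clone_spec(infl_production = 1e-7)
  ip <- inflammation_params(mode = "mutant_boost", hill_theta = 1,
                            lambda_selfrenewal = 0.25, lambda_prolif = 0.25)
  tr <- run_recipient(cl, horizon = 6 * 365.25, dt = 5, inflammation = ip)
  expect_equal(classify_pattern(tr$times, vaf_series(tr), 0.05),
               "persistent")
  # burden grows with the mutant load
  expect_gt(tr$burden[length(tr$burden)], tr$burden[50])
})

test_that("wildtype exhaustion gives the mutant a relative advantage", {
  cl <- clone_spec(infl_production = 1e-7)
  ip <- inflammation_params(mode = "wildtype_exhaustion", hill_theta = 1,
                            mu_selfrenewal = 0.15, mu_amplification = 0.1)
  tr <- run_recipient(cl, horizon = 6 * 365.25, dt = 5, inflammation = ip)
  expect_equal(classify_pattern(tr$times, vaf_series(tr), 0.05),
               "persistent")
})

test_that("the host burden decides an inflammation-dependent clone's fate", {
  # fitness deficit without inflammation; no mediator secretion
  cl0 <- clone_spec()
  ip_dec <- inflammation_params(mode = "mutant_boost", hill_theta = 1,
                                lambda_selfrenewal = 0.25,
                                lambda_prolif = 0.25,
                                lambda_amplification = 0.25,
                                disadvantage_delta = 0.05,
                                host_baseline = 0)
  tr_lo <- run_recipient(cl0, donor_vaf = 0.02, horizon = 3 * 365.25,
                         dt = 5, inflammation = ip_dec)
  v_lo <- vaf_series(tr_lo)
  expect_lt(v_lo[length(v_lo)], 0.02 * 0.7)
  # the same clone in a high-baseline-burden host expands
  ip_hi <- inflammation_params(mode = "mutant_boost", hill_theta = 1,
                               lambda_selfrenewal = 0.25,
                               lambda_prolif = 0.25,
                               lambda_amplification = 0.25,
                               disadvantage_delta = 0.05,
                               host_baseline = 5)
  tr_hi <- run_recipient(cl0, donor_vaf = 0.02, horizon = 3 * 365.25,
                         dt = 5, inflammation = ip_hi)
  v_hi <- vaf_series(tr_hi)
  expect_gt(v_hi[length(v_hi)], 0.025)
})

test_that("self-sustaining clones need a critical graft VAF", {
  # mediator-secreting clone with a fitness deficit at zero burden: its
  # own mature cells must supply enough burden to sustain the advantage
  cl <- clone_spec(infl_production = 1e-7)
  ip <- inflammation_params(mode = "mutant_boost", hill_theta = 10,
                            lambda_selfrenewal = 0.25,
                            lambda_prolif = 0.25,
                            lambda_amplification = 0.25,
                            disadvantage_delta = 0.05,
                            host_baseline = 0)
  end_vaf <- function(v0) {
    tr <- run_recipient(cl, donor_vaf = v0, horizon = 2.5 * 365.25,
                        dt = 5, inflammation = ip)
    v <- vaf_series(tr); v[length(v)]
  }
  lo <- 0.02; hi <- 0.2
  expect_lt(end_vaf(lo), lo)   # small clone declines
  expect_gt(end_vaf(hi), hi)   # large clone self-sustains and expands
  for (k in 1:3) {             # bisection brackets the critical VAF
    mid <- (lo + hi) / 2
    if (end_vaf(mid) < mid) lo <- mid else hi <- mid
  }
  expect_lt(hi - lo, (0.2 - 0.02) / 8)
  # the bisection invariant still holds at the narrowed bracket
  expect_lt(end_vaf(lo), lo)
  expect_gt(end_vaf(hi), hi)
})
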