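test_that("VAF algebra follows the heterozygous allele-count formula", {
  expect_equal(vaf(1e8, 0), 0.5)            # all neutrophils mutated
  expect_equal(vaf(0, 1e8), 0)
  expect_equal(vaf(1e8, 1e8), 0.25)
  expect_equal(vaf(1e8, 0, zygosity = "homozygous"), 1)
  expect_equal(vaf(3e7, 7e7, zygosity = "homozygous"), 0.3)
  expect_error(vaf(0, 0), "undefined")
  expect_error(vaf(-1, 1), ">= 0")
})

test_that("mutant sensitivity steepens the response around the fixed point", {
  s_star <- 0.5
  # identity at sigma = 1 and at the homeostatic point for any sigma
  s <- seq(0.05, 1, by = 0.05)
  expect_equal(mutant_signal(s, s_star, 1), s)
  expect_equal(mutant_signal(s_star, s_star, 5), s_star)
  # steepening above/below the fixed point
  expect_gt(mutant_signal(0.7, s_star, 2), 0.7)
  expect_lt(mutant_signal(0.3, s_star, 2), 0.3)
  # clipping keeps the transformed signal in (0, 1]
  expect_equal(mutant_signal(0.9, s_star, 10), 1)
  expect_gt(mutant_signal(0.1, s_star, 10), 0)
  # composition with a monotone response function
  p <- ref_params()
  base <- function(x) chipgraft:::prolif_response(x, p$s_p_star,
                                                  p$prolif_fold_max,
                                                  p$prolif_floor)
  expect_equal(mutant_response(p$s_p_star, p$s_p_star, 7, base), base(p$s_p_star))
  expect_gt(mutant_response(0.5, p$s_p_star, 2, base), base(0.5))
})

test_that("a fully neutral clone keeps a constant VAF for a decade", {
  p <- ref_params()
  cl <- clone_spec()
  frac <- 2 * 0.07
  init <- rbind(p$u_star * (1 - frac), p$u_star * frac)
  m <- chip_model(p, clones = list(cl))
  tr <- simulate_dynamics(m, init = init, horizon = 3652.5, dt = 50)
  v <- vaf_series(tr)
  expect_lt(max(abs(v / 0.07 - 1)), 1e-6)
})

test_that("heterozygous VAF never exceeds one half", {
  tr <- run_recipient(clone_spec(sens_hsc = 4, sens_hpc = 4,
                                 mult_selfrenewal_hsc = 1.3),
                      donor_vaf = 0.12, horizon = 3 * 365.25, dt = 5)
  expect_true(all(vaf_series(tr) <= 0.5 + 1e-12))
})

test_that("trajectory patterns are classified by their shape", {
  t <- seq(0, 6 * 365.25, by = 10)
  yr <- 365.25
  expect_equal(classify_pattern(t, rep(0.05, length(t)), 0.05), "none")
  expect_equal(classify_pattern(t, 0.05 + 0.01 * t / yr, 0.05),
               "persistent")
  plateau <- 0.05 + 0.05 * (1 - exp(-t / 60))
  expect_equal(classify_pattern(t, plateau, 0.05), "saturated")
  bump <- 0.05 + 0.08 * exp(-(t - 150)^2 / 2e4)
  expect_equal(classify_pattern(t, bump, 0.05), "transient")
  expect_error(classify_pattern(t[t < 500], rep(0.05, sum(t < 500)), 0.05),
               "2 years")
})

test_that("simulated expansion mechanisms land in their regimes", {
  # permanent HSC self-renewal advantage: persistent expansion
  tr_p <- run_recipient(clone_spec(mult_selfrenewal_hsc = 1.1))
  expect_equal(classify_pattern(tr_p$times, vaf_series(tr_p), 0.05),
               "persistent")
  # HPC-only sensitivity: no stem-cell advantage, transient rise
  tr_t <- run_recipient(clone_spec(sens_hpc = 3))
  expect_equal(classify_pattern(tr_t$times, vaf_series(tr_t), 0.05),
               "transient")
  v <- vaf_series(tr_t)
  expect_gt(max(v), 0.06)            # it does rise first
  expect_lt(v[length(v)], max(v) / 3) # and falls back towards the donor VAF
})

test_that("expansion metrics interpolate at the exact horizons", {
  yr <- 365.25
  # constructed donor course: linear growth 0.04 -> 0.05 over the year
  dt <- seq(0, 2 * yr, length.out = 200)
  dv <- 0.03 + 0.01 * dt / yr
  rt <- seq(0, 1.2 * yr, length.out = 120)
  m <- expansion_metrics(dt, dv, rt, rep(0.05, length(rt)),
                         donation_time = 2 * yr)
  expect_equal(m$delta_D_1y, 0.01, tolerance = 1e-10)
  expect_equal(m$pi_D_1y, 1.25, tolerance = 1e-10)
  expect_equal(m$delta_R_100d, 0)
  expect_equal(m$pi_R_100d, 1)
  # identical constant donor and recipient
  m2 <- expansion_metrics(dt, rep(0.04, length(dt)), rt,
                          rep(0.04, length(rt)), donation_time = 2 * yr)
  expect_equal(m2$delta_R_100d, 0)
  expect_equal(m2$pi_R_100d, 1)
  expect_error(expansion_metrics(dt[dt < 100], dv[dt < 100], rt,
                                 rep(0.04, length(rt)),
                                 donation_time = 2 * yr), "1 year")
  expect_error(expansion_metrics(dt, dv, rt[rt < 300],
                                 rep(0.04, sum(rt < 300)),
                                 donation_time = 2 * yr), "1 year")
})

test_that("homing-only differences give monotone converging VAFs", {
  # randomized sweep over homing parameters; kinetics fully neutral
  set.seed(11)
  combos <- cbind(hsc = runif(4, 0.3, 0.95), hpc = runif(4, 0.3, 0.95))
  for (k in seq_len(nrow(combos))) {
    tr <- run_recipient(clone_spec(homing_hsc = combos[k, 1],
                                   homing_hpc = combos[k, 2]),
                        horizon = 3 * 365.25, dt = 5)
    v <- vaf_series(tr)
    keep <- tr$times >= 30          # past the engraftment transient
    dv <- diff(v[keep])
    # monotone: all increments share one sign (up to numerical noise)
    expect_true(all(dv >= -1e-7) || all(dv <= 1e-7))
    # converged: late slope vanishes
    expect_lt(abs(dv[length(dv)]) / 5, 1e-6)
  }
  # quantitative check of the homing arithmetic: wildtype 50%, mutant 80%
  # homing of a VAF 0.05 graft gives marrow fraction 0.08/0.53
  g <- make_graft(4.7e6, ref_composition(), donor_vaf = 0.05,
                  clones = list(clone_spec(homing_hsc = 0.8,
                                           homing_hpc = 0.8)))
  init <- apply_homing(g)
  frac <- sum(init[2, ]) / sum(init)
  expect_equal(frac, 0.08 / 0.53, tolerance = 1e-10)
  tr <- run_recipient(clone_spec(homing_hsc = 0.8, homing_hpc = 0.8),
                      horizon = 2.1 * 365.25, dt = 5)
  v <- vaf_series(tr)
  expect_equal(v[length(v)], 0.0755, tolerance = 2e-3)
})

test_that("saturated-expansion trajectories stabilize", {
  tr <- run_recipient(clone_spec(sens_hsc = 3, sens_hpc = 1.5))
  v <- vaf_series(tr); t <- tr$times
  early <- t <= 100 & t >= 10
  slope_early_max <- max(abs(diff(v[early]) / diff(t[early])))
  at5y <- which.min(abs(t - 5 * 365.25))
  slope_5y <- abs((v[at5y + 1] - v[at5y - 1]) / (t[at5y + 1] - t[at5y - 1]))
  expect_lt(slope_5y, 0.01 * slope_early_max)
  expect_equal(classify_pattern(t, v, 0.05), "saturated")
})
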