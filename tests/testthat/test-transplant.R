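test_that("graft construction conserves the dose and splits by VAF", {
  comp <- ref_composition()
  expect_equal(sum(comp), 1)
  g <- make_graft(4.7e6, comp, donor_vaf = 0.005,
                  clones = list(clone_spec()))
  expect_equal(sum(g$cells), 4.7e6)
  # mature compartment of the graft is discarded
  expect_true(all(g$cells[, ncol(g$cells)] == 0))
  # reference composition carries about 1e5 HSCs per 80 kg graft
  hsc_total <- sum(g$cells[, 1]) * 80
  expect_equal(hsc_total, 1e5, tolerance = 0.01)
  # donor VAF 0.005, heterozygous: >= 1000 mutated HSCs in the transplant
  mut_hsc <- g$cells[2, 1] * 80
  expect_gte(mut_hsc, 1000 * 0.99)
  expect_equal(g$cells[2, 2] / sum(g$cells[, 2]), 0.01, tolerance = 1e-10)
  # wildtype-only graft for donor VAF zero
  g0 <- make_graft(4.7e6, comp, donor_vaf = 0)
  expect_equal(nrow(g0$cells), 1L)
  expect_error(make_graft(0, comp), "dose")
  expect_error(make_graft(1e6, comp * 2), "sum to 1")
})

test_that("homing conserves cells and zeroes the mature compartment", {
  comp <- ref_composition()
  cl <- clone_spec(homing_hsc = 0.8, homing_hpc = 0.6)
  g <- make_graft(4.7e6, comp, donor_vaf = 0.05, clones = list(cl))
  init <- apply_homing(g)
  n <- ncol(init) - 2L
  # homed + non-homed = graft, exactly, per clone and compartment class
  expect_equal(init[1, 1], g$cells[1, 1] * 0.5)
  expect_equal(init[2, 1], g$cells[2, 1] * 0.8)
  expect_equal(init[1, 2:(n + 1)], g$cells[1, 2:(n + 1)] * 0.5)
  expect_equal(init[2, 2:(n + 1)], g$cells[2, 2:(n + 1)] * 0.6)
  expect_true(all(init[, n + 2] == 0))
})

test_that("a graft sampled from a donor state inherits clonal fractions", {
  p <- ref_params()
  cl <- clone_spec(mult_selfrenewal_hsc = 1.08)
  m <- chip_model(p, clones = list(cl))
  dc <- donor_course(m, initial_vaf = 0.05, years_before_donation = 1)
  g <- make_graft(4.7e6, ref_composition(), donor_state = dc$state_at_donation,
                  clones = list(cl))
  expect_equal(sum(g$cells), 4.7e6)
  # per-compartment mutant fractions match the donor state
  fr_graft <- g$cells[2, 1] / sum(g$cells[, 1])
  fr_donor <- dc$state_at_donation[2, 1] / sum(dc$state_at_donation[, 1])
  expect_equal(fr_graft, fr_donor, tolerance = 1e-10)
})

test_that("larger transplant doses engraft earlier", {
  p <- ref_params()
  m <- chip_model(p)
  comp <- ref_composition()
  ets <- vapply(c(1e6, 4.7e6, 1.5e7), function(dose) {
    init <- apply_homing(make_graft(dose, comp))
    engraftment_time(simulate_dynamics(m, init = init, horizon = 120,
                                       dt = 0.5))
  }, numeric(1))
  expect_true(all(diff(ets) < 0))
})

test_that("the global homing percentage shifts timing, not the pattern", {
  cl30 <- clone_spec(sens_hsc = 2, sens_hpc = 1.5, homing_hsc = 0.3,
                     homing_hpc = 0.3)
  cl70 <- clone_spec(sens_hsc = 2, sens_hpc = 1.5, homing_hsc = 0.7,
                     homing_hpc = 0.7)
  wt30 <- clone_spec(clone_id = "wildtype", homing_hsc = 0.3,
                     homing_hpc = 0.3)
  wt70 <- clone_spec(clone_id = "wildtype", homing_hsc = 0.7,
                     homing_hpc = 0.7)
  p <- ref_params()
  run <- function(cl, wt) {
    g <- make_graft(4.7e6, ref_composition(), donor_vaf = 0.05,
                    clones = list(cl))
    m <- chip_model(p, clones = list(cl), wildtype = wt)
    simulate_dynamics(m, init = apply_homing(g, wildtype = wt),
                      horizon = 5 * 365.25, dt = 4)
  }
  tr30 <- run(cl30, wt30); tr70 <- run(cl70, wt70)
  e30 <- engraftment_time(tr30); e70 <- engraftment_time(tr70)
  expect_gt(e30, e70)  # fewer homed cells, later engraftment
  expect_equal(classify_pattern(tr30$times, vaf_series(tr30), 0.05),
               classify_pattern(tr70$times, vaf_series(tr70), 0.05))
})

test_that("donor course is flat for neutral clones, rising for drivers", {
  p <- ref_params()
  m0 <- chip_model(p, clones = list(clone_spec()))
  dc0 <- donor_course(m0, initial_vaf = 0.06, years_before_donation = 2)
  v0 <- vaf_series(dc0$trajectory)
  expect_lt(max(abs(v0 - 0.06)), 1e-6)
  m1 <- chip_model(p, clones = list(clone_spec(mult_selfrenewal_hsc = 1.1)))
  dc1 <- donor_course(m1, initial_vaf = 0.06, years_before_donation = 2)
  expect_gt(dc1$vaf_at_donation, 0.06)
  # donor with a baseline burden above the clone's threshold: VAF rises
  ip <- inflammation_params(mode = "mutant_boost", hill_theta = 1,
                            lambda_selfrenewal = 0.25, lambda_prolif = 0.25,
                            lambda_amplification = 0.25,
                            disadvantage_delta = 0.05, host_baseline = 5)
  m2 <- chip_model(p, clones = list(clone_spec()), inflammation = ip)
  dc2 <- donor_course(m2, initial_vaf = 0.06, years_before_donation = 2)
  expect_gt(dc2$vaf_at_donation, 0.06)
})
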