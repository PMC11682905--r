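#' Scenario presets
#'
#' Named parameter bundles encoding the canonical clonal-dynamics regimes
#' of the model, each with the qualitative pattern its recipient VAF
#' trajectory is expected to show (see [classify_pattern()]):
#'
#' * `reference_engraftment`: wildtype-only reference transplantation
#'   (4.7e6 CD34+ cells/kg, 50% homing, no growth factor).
#' * `sensitivity_saturated`: mutant HSCs and HPCs respond more
#'   sensitively to feedback-signal perturbations; identical kinetics at
#'   homeostasis.  Saturated expansion.
#' * `homing_saturated`: mutant cells differ only in their homing
#'   fraction (80% vs 50%).  Monotone VAF convergence above the donor
#'   VAF.
#' * `homing_hsc_vs_hpc`: mutant HSCs home better than mutant HPCs (90%
#'   vs 70%, wildtype 50%); the PB VAF rises monotonically to a constant.
#' * `hpc_sensitivity_transient`: only mutant HPCs are hypersensitive;
#'   without a stem-cell advantage the VAF rise is temporary.
#' * `selfrenewal_persistent`: permanently increased mutant HSC
#'   self-renewal; persistent expansion.
#' * `inflammation_boost_persistent`: mutant mature cells secrete
#'   pro-inflammatory mediators which boost mutant HSC self-renewal and
#'   proliferation; persistent expansion.
#' * `exhaustion_persistent`: the CHIP-driven burden exhausts wildtype
#'   HSC self-renewal and HPC amplification; persistent expansion.
#' * `inflammation_threshold`: an inflammation-dependent clone
#'   (fitness deficit without burden) transplanted into a low-burden
#'   host declines; the donor's burden sustains it.
#'
#' @param name preset name; `preset_names()` lists all.
#' @return list with components `params`, `clones`, `inflammation`,
#'   `donor_vaf`, `dose`, `horizon_days` and `expected_pattern`.
#' @export
scenario_preset <- function(name) {
  name <- match.arg(name, preset_names())
  base <- list(params = chip_params(), dose = 4.7e6, donor_vaf = 0.05,
               horizon_days = 8 * 365.25, inflammation = inflammation_params(),
               expected_pattern = NA_character_)
  pre <- switch(name,
    reference_engraftment = list(clones = list(), donor_vaf = 0,
                                 horizon_days = 60),
    sensitivity_saturated = list(
      clones = list(clone_spec(sens_hsc = 3, sens_hpc = 1.5)),
      expected_pattern = "saturated"),
    homing_saturated = list(
      clones = list(clone_spec(homing_hsc = 0.8, homing_hpc = 0.8)),
      expected_pattern = "saturated"),
    homing_hsc_vs_hpc = list(
      clones = list(clone_spec(homing_hsc = 0.9, homing_hpc = 0.7)),
      expected_pattern = "saturated"),
    hpc_sensitivity_transient = list(
      clones = list(clone_spec(sens_hpc = 3)),
      expected_pattern = "transient"),
    selfrenewal_persistent = list(
      clones = list(clone_spec(mult_selfrenewal_hsc = 1.1)),
      expected_pattern = "persistent"),
    inflammation_boost_persistent = list(
      clones = list(clone_spec(infl_production = 1e-7)),
      inflammation = inflammation_params(mode = "mutant_boost",
                                         hill_theta = 1,
                                         lambda_selfrenewal = 0.25,
                                         lambda_prolif = 0.25),
      expected_pattern = "persistent"),
    exhaustion_persistent = list(
      clones = list(clone_spec(infl_production = 1e-7)),
      inflammation = inflammation_params(mode = "wildtype_exhaustion",
                                         hill_theta = 1,
                                         mu_selfrenewal = 0.15,
                                         mu_amplification = 0.1),
      expected_pattern = "persistent"),
    inflammation_threshold = list(
      clones = list(clone_spec(infl_production = 1e-7)),
      inflammation = inflammation_params(mode = "mutant_boost",
                                         hill_theta = 30,
                                         lambda_selfrenewal = 0.25,
                                         lambda_prolif = 0.25,
                                         lambda_amplification = 0.25,
                                         disadvantage_delta = 0.05,
                                         host_baseline = 0),
      expected_pattern = "transient")
  )
  out <- utils::modifyList(base, pre)
  out$name <- name
  out
}

#' @rdname scenario_preset
#' @export
preset_names <- function() {
  c("reference_engraftment", "sensitivity_saturated", "homing_saturated",
    "homing_hsc_vs_hpc", "hpc_sensitivity_transient",
    "selfrenewal_persistent", "inflammation_boost_persistent",
    "exhaustion_persistent", "inflammation_threshold")
}

#' Run a scenario preset
#'
#' Builds the preset's model, constructs the graft (reference dose and
#' composition, the preset's donor VAF), applies homing, simulates the
#' recipient and classifies the VAF pattern.
#'
#' @param name preset name (see [scenario_preset()]).
#' @param horizon_days override of the preset horizon.
#' @param dt output grid spacing, days.
#' @return list with `trajectory`, `engraftment_days`, and, when the
#'   preset carries a mutant clone, `vaf` (series), `pattern` and
#'   `expected_pattern`.
#' @export
run_preset <- function(name, horizon_days = NULL, dt = 2) {
  ps <- scenario_preset(name)
  horizon <- horizon_days %||% ps$horizon_days
  params <- calibrate_homeostasis(ps$params)$params
  comp <- graft_composition(params)
  g <- make_graft(ps$dose, comp, donor_vaf = ps$donor_vaf,
                  clones = ps$clones)
  init <- apply_homing(g)
  model <- chip_model(params, clones = ps$clones,
                      inflammation = ps$inflammation)
  traj <- simulate_dynamics(model, init = init, horizon = horizon,
                            dt = if (horizon <= 100) 0.25 else dt)
  out <- list(name = name, trajectory = traj,
              engraftment_days = engraftment_time(traj))
  if (length(ps$clones)) {
    out$vaf <- vaf_series(traj)
    if (horizon >= 2 * 365.25)
      out$pattern <- classify_pattern(traj$times, out$vaf, ps$donor_vaf)
    out$expected_pattern <- ps$expected_pattern
  }
  out
}
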