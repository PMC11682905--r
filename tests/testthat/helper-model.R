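# Shared fixtures: the reference calibration is reused across test files.
.fixtures <- new.env(parent = emptyenv())

ref_params <- function() {
  if (is.null(.fixtures$params))
    .fixtures$params <- calibrate_homeostasis(chip_params())$params
  .fixtures$params
}

ref_composition <- function() {
  if (is.null(.fixtures$comp))
    .fixtures$comp <- graft_composition(ref_params())
  .fixtures$comp
}

# Reference transplantation trajectory (wildtype only), cached.
ref_transplant <- function(horizon = 60, dt = 0.25) {
  key <- sprintf("ref_%s_%s", horizon, dt)
  if (is.null(.fixtures[[key]])) {
    init <- apply_homing(make_graft(4.7e6, ref_composition()))
    .fixtures[[key]] <- simulate_dynamics(chip_model(ref_params()),
                                          init = init, horizon = horizon,
                                          dt = dt)
  }
  .fixtures[[key]]
}

# Recipient simulation with one mutant clone at the reference dose.
run_recipient <- function(clone, donor_vaf = 0.05, horizon = 6 * 365.25,
                          dt = 2, inflammation = inflammation_params(),
                          pk = NULL, dose = 4.7e6, params = ref_params()) {
  g <- make_graft(dose, graft_composition(params), donor_vaf = donor_vaf,
                  clones = list(clone))
  m <- chip_model(params, clones = list(clone),
                  inflammation = inflammation, pk = pk)
  simulate_dynamics(m, init = apply_homing(g), horizon = horizon, dt = dt)
}
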