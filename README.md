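# chipgraft

Mechanistic modeling of neutrophil reconstitution and donor-derived
CHIP-clone dynamics after allogeneic hematopoietic stem cell
transplantation (HSCT).

A relevant share of stem cell donors carry clonal hematopoiesis of
indeterminate potential (CHIP): a mutated hematopoietic stem cell (HSC)
clone producing a measurable variant allele frequency (VAF) in blood.
After transplantation, such donor clones behave very differently across
recipients — some expand quickly and plateau, some keep expanding for
years, some never move.  `chipgraft` implements a feedback-regulated
compartment model of the neutrophil lineage (HSC, 15 progenitor stages,
circulating neutrophils; per-clone copies competing through shared
feedback) that reproduces these regimes from explicit mechanisms, plus a
virtual-clinical-trial engine for dose, graft-composition,
growth-factor and donor–recipient correlation experiments.

The core dynamics, per clone and stage ($a_i$ self-renewal probability,
$p_i$ division rate):

```
du_0/dt = (2 a_0 - 1) p_0 u_0
du_i/dt = (2 a_i - 1) p_i u_i + 2 (1 - a_{i-1}) p_{i-1} u_{i-1}
du_m/dt = 2 (1 - a_n) p_n u_n - d u_m
```

with first-order Hill feedback signals `s = 1/(1 + k x)` of the mature
(systemic) and HSC (niche) counts regulating `a_i` and `p_i`, mutant
clones modifying parameters and/or responding more sensitively to signal
deviations, an optional quasi-steady-state inflammation coupling, and a
pegfilgrastim-like PK submodel feeding into the same signals.  See the
methods vignette (`vignettes/clone-dynamics.Rmd`) for the full model
account.

## Worked example

```r
library(chipgraft)

# calibrated wildtype physiology: 3.1e8 neutrophils/kg, 1250 HSCs/kg
params <- calibrate_homeostasis(chip_params())$params

# a CHIP clone that over-responds to feedback-signal perturbations
clone <- clone_spec(sens_hsc = 3, sens_hpc = 1.5)

# reference transplantation: 4.7e6 CD34+ cells/kg, donor VAF 5%
graft <- make_graft(4.7e6, graft_composition(params),
                    donor_vaf = 0.05, clones = list(clone))
model <- chip_model(params, clones = list(clone))
traj <- simulate_dynamics(model, init = apply_homing(graft),
                          horizon = 6 * 365.25, dt = 2)

engraftment_time(traj)
#> [1] 11.60911
v <- vaf_series(traj)
round(stats::approx(traj$times, v, xout = c(100, 365.25, 5 * 365.25))$y, 4)
#> [1] 0.1235 0.0691 0.0850
classify_pattern(traj$times, v, donor_vaf = 0.05)
#> [1] "saturated"
```

Neutrophils recover in 11.6 days (clinical window 10–20 days).  The
hypersensitive clone more than doubles its VAF during the stress phase
(0.124 at day 100 against a donor VAF of 0.05), dips as the overshoot
clears, and settles near 0.085 — the "saturated expansion" pattern
(with initial overshoot).  A permanent HSC
self-renewal advantage (`clone_spec(mult_selfrenewal_hsc = 1.1)`)
instead yields ongoing ("persistent") expansion; `preset_names()` lists
ready-made scenarios for all regimes, runnable via `run_preset()` or the
`exec/chipgraft` command line.

Cohort-level experiments:

```r
cohort <- sample_cohort(200, clone_ranges = clone_archetype("saturated"),
                        seed = 1)
tab <- run_dose_trial(cohort, doses = c(1e6, 5e6, 1e7, 1.5e7))
correlate_trial(tab[tab$dose == 5e6, ])
```

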