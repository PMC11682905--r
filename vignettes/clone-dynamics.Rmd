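---
title: "Feedback-regulated hematopoiesis and donor-clone dynamics after allogeneic HSCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feedback-regulated hematopoiesis and donor-clone dynamics after allogeneic HSCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipgraft)
```

## The modeling problem

After allogeneic hematopoietic stem cell transplantation (HSCT) the
recipient's blood formation is rebuilt from a graft of donor CD34+ stem
and progenitor cells.  A substantial share of eligible donors carry
clonal hematopoiesis of indeterminate potential (CHIP): a mutated
hematopoietic stem cell (HSC) clone contributing measurably to blood
production.  Longitudinal studies of such transplants show strikingly
heterogeneous post-transplant behavior of the donor clone — rapid early
expansion that plateaus ("saturated"), steady expansion over many years
("persistent"), temporary excursions, or no change at all.  This package
implements a mechanistic, feedback-regulated compartment model of the
neutrophil lineage that can generate all of these patterns from explicit
cellular mechanisms, and a virtual-clinical-trial engine that asks how
controllable transplant parameters — CD34+ dose, graft composition,
growth-factor support — shape the expansion of the donor clone.

Neutrophils dominate the white-cell pool from which variant allele
frequencies (VAF) are measured in peripheral blood, so the model is
restricted to the neutrophil lineage.

## Model structure

Each clone (wildtype, plus any number of mutant clones) occupies one HSC
compartment, `n_stages = 15` progenitor/precursor (HPC) stages and a
circulating mature pool, all in cells per kg of body weight.  With
self-renewal probability $a_i$ and division rate $p_i$ of stage $i$, the
per-clone dynamics are the standard self-renewal/differentiation form

$$\frac{du_0}{dt} = (2a_0 - 1)\,p_0\,u_0,\qquad
\frac{du_i}{dt} = (2a_i - 1)\,p_i\,u_i + 2(1 - a_{i-1})\,p_{i-1}\,u_{i-1},$$

with the mature pool fed by the last mitotic stage and cleared at rate
$d$.  A division produces two daughters; each independently keeps the
parental identity with probability $a_i$, so a stage at flux equilibrium
amplifies throughput by $r_i = 2(1-a_i)/(1-2a_i)$ (for $a_i < 1/2$).

### Feedback loops

Regulation is phenomenological, motivated by G-CSF biology: shortage of
mature cells increases HSC self-renewal, division rates, and the number
of divisions progenitors perform before terminal differentiation
("amplification").  Every signal is a first-order Hill function of a
cell count, $s = 1/(1 + k\,x)$, with the loops:

* **HSC self-renewal**: $a_0(s) = a_{0,\max}\, s$ with
  $a_{0,\max} = 0.75$ and the gain set so the homeostatic signal is
  $s^* = 0.5/a_{0,\max} = 2/3$ — the HSC steady state forces
  $a_0(s^*) = 1/2$.  Keeping $a_{0,\max} < 1$ bounds the
  differentiation fraction $1 - a_0$ away from zero even under maximal
  stimulation, so no clone can ever fully stop exporting progenitors.
* **HPC amplification**: $a_i(s) = a_{hpc,\max}\,s$ with its own gain
  chosen so the loop passes through the calibrated homeostatic
  self-renewal $a_{hpc}^{hom}$; `a_hpc_max` (default 0.50) sets how much
  an empty system can push progenitor amplification; together with the
  graft composition it calibrates the reconstitution speed and the
  dose-dependence of engraftment.
* **Proliferation**: $p_i(s) = p_i^{hom}\, g(s)$ with a piecewise-linear
  $g$, $g(s_p^*) = 1$, $g(1) = 4$ (the experimentally motivated maximal
  fold-stimulation) and a floor of 0.25 under over-supply.  This loop
  carries a deliberately strong gain (`s_p_star = 0.002`): circulating
  G-CSF rises steeply only in deep neutropenia, so division rates sit
  near their homeostatic schedule through most of a reconstitution and
  the full four-fold acceleration is reached only near aplasia or under
  exogenous growth factor.

Two model variants move HSC regulation to the niche (a Hill signal of
the HSC count): `niche_selfrenewal` and
`niche_selfrenewal_proliferation`.  All qualitative conclusions of the
trial engine hold in all three variants (this is asserted by tests).

Giving each regulated property its own gain — rather than one shared
systemic gain — was the central open design choice.  We adopted
per-loop gains because a single moderate gain leaves every loop
saturated ($s \approx 1$) throughout reconstitution: the cascade then
amplifies a graft to the engraftment threshold within ~5 days, exogenous
growth factor has no headroom to act, and all feedback-mediated clonal
selection is compressed into days instead of the clinically observed
months.  With the strong proliferation gain, recovery is transit-limited
through the cascade (engraftment 10–20 days at the reference dose),
pegfilgrastim gains a real ~3-day effect, the HSC pool needs years to
recover (as reported clinically), and signal elevations that drive
mutant selection persist over months to years.

### Homeostatic calibration

`calibrate_homeostasis()` solves the stationary state in closed form
against the physiological anchors: $M^* = 3.1\times10^8$ neutrophils/kg
(5×10⁹ per litre at 5 l blood, 80 kg), $H^* = 1250$ HSCs/kg (10⁵ per
body), clearance $d = 2.3$/day (blood half-life ≈ 7 h), HSC division
rate 2/year rising arithmetically to 1/day at the last mitotic stage.
The uniform homeostatic HPC self-renewal (≈ 0.294) is the root of the
total amplification requirement
$\prod_i r_i = d\,M^*/(p_0\,H^*) \approx 10^8$, and stage concentrations
follow by flux balance.  Calibration is exact: integrating from the
computed state shows relative drift below $10^{-6}$ over years.

## Transplantation

A graft is `dose` CD34+ cells/kg allocated across compartments.  The
progenitor part samples the donor's marrow proportionally to the
homeostatic stage profile over the immature stages; true HSCs are
`hsc_fraction = 2.66e-4` of the graft, which
puts ≈ 10⁵ HSCs into a reference 4.7×10⁶ cells/kg graft for an 80 kg
recipient — consistent with the rarity of primitive HSCs among CD34+
cells, and with the observation that a donor VAF of 0.005 already
implies ≥ 1000 mutated HSCs in the transplant.  The composition, `hsc_fraction` and the
amplification headroom `a_hpc_max` are the calibration degrees of
freedom that published counts do not pin down; they were fixed once so
that the reference transplantation (50% homing, no growth factor)
engrafts in the clinical 10–20 day window with a clinically plausible
dose dependence, and never revisited.

Homing is instantaneous (marrow migration takes under a day): a clone-
and compartment-class-specific fraction (default 50%) of infused cells
seeds the marrow; graft neutrophils are discarded as they are cleared
within days.  Engraftment is the first crossing of 5×10⁸ neutrophils
per litre (3.125×10⁷/kg under the 5 l / 80 kg convention), located by
linear interpolation on the output grid.

## Mutant clones

A `clone_spec()` modifies a clone relative to wildtype by

* multiplicative factors on proliferation, self-renewal and clearance —
  self-renewal factors act on the maximal probability with the
  *evaluated* probability clipped at 1, so a factor $m > 1$ raises the
  homeostatic mutant HSC self-renewal to $m/2 > 1/2$ and yields
  persistent expansion;
* aberrant signal sensitivity: the clone experiences
  $s^* + \sigma\,(s - s^*)$ for each loop (linear amplification of the
  deviation, clipped to the valid range — the minimal monotone
  steepening that preserves the homeostatic fixed point).  Such clones
  are neutral at homeostasis and expand only under hematopoietic
  stress, producing saturated expansion after HSCT;
* homing fractions, which act once at transplantation.  Homing-only
  differences change the VAF monotonically towards a new constant; no
  overshoot is possible (asserted over randomized homing sweeps);
* inflammation couplings (below).

VAF in peripheral blood is $c^M/(c^M + c^{WT})/2$ for heterozygous
clones (maximum 0.5), without the factor ½ for homozygous ones.

### Pattern classification

`classify_pattern()` makes the qualitative regimes operational:
excluding the first 30 days (when the mature pool is refilling and the
PB VAF is dominated by the engraftment transient), a trajectory is
"none" if it never leaves ±0.005 of the donor VAF; "persistent" if the
mean slope over years 2–5 exceeds 0.005 VAF/year; "transient" if it
rose clearly above the donor VAF, has returned at least half-way back
and is still declining; "saturated" if it has plateaued (late slope
under 10% of the maximal early slope) above the donor VAF — so an early
overshoot that settles at an elevated level counts as saturated, as in
the clinical descriptions; otherwise "transient".  The thresholds are explicit,
configurable arguments; the defaults were chosen once to separate the
canonical presets and are not fitted quantities.

## CHIP-driven inflammation

Mutated mature cells may secrete short-lived pro-inflammatory mediators.
Under a quasi-steady-state argument the systemic burden is
$I = B_0 + \alpha\,c^M_{mature}$, with $B_0$ a CHIP-independent host
baseline (inflammaging, atherosclerosis) that is constant in time.  The
impact saturates through $e = I/(I + \theta)$; burden units are
arbitrary and $\theta$ normalizes them.  Two coupling modes:

* `mutant_boost`: responsive mutant clones have their HSC self-renewal,
  proliferation and HPC amplification multiplied by
  $1 - \delta + \lambda_x\,e$ (clipped to valid ranges); wildtype cells
  are unaffected.  $\delta > 0$ encodes a fitness deficit without
  inflammation, so the host's burden — or the clone's own mediator
  production — decides between decline and expansion, with a critical
  graft VAF separating the fates in the self-sustaining configuration.
* `wildtype_exhaustion`: wildtype HSC self-renewal and HPC amplification
  are multiplied by $1 - \mu_x\,e$ (an optional `mu_prolif` additionally
  raises wildtype proliferation, default off).

The multiplicative form is our reconstruction; directions and the
saturation are the constrained content.  Coupling composes *after* the
feedback-signal evaluation, so homeostatic calibration is untouched when
the mode is off.

## Growth-factor support

Pegfilgrastim-like kinetics: a subcutaneous depot absorbed at rate
$k_a$, plasma elimination at $k_e$, closed-form superposition over
doses.  `calibrate_pk()` solves $(k_a, k_e)$ for a peak ≈ 2 days after
injection and decay to half-peak 3–4 days later, giving
$k_a = 0.668$/day, $k_e = 0.363$/day.  The plasma concentration adds to
each systemic feedback signal as $\min(1, s + \gamma C)$ for wildtype
and mutant clones alike; mutant sensitivity applies to the combined
signal since it passes through the same response functions.  The potency
$\gamma = 0.33$ (dose normalized to 1) was calibrated once so a single
dose on day 3 shortens the cohort's median engraftment by ≈ 3 days.
Because the drug acts symmetrically on all clones, it accelerates
engraftment without materially changing recipient VAFs.

## The virtual cohort

`sample_cohort()` is the package's synthetic-data generator: each
virtual patient multiplies reference parameters by independent uniform
factors (see `cohort_widths()`), is recalibrated to their own
homeostatic state, and draws a donor clone from an archetype —
"saturated" (sensitivity factors σ_HSC ~ U(1.1, 1.5),
σ_HPC ~ U(1.5, 2.5)) or "persistent" (HSC self-renewal factor ~
U(1.04, 1.12)) — with donor PB VAF ~
U(0.005, 0.125).  The widths were fixed by a one-time calibration loop
so that the 1000-patient cohort's engraftment times at the reference
dose match the clinically reported 11–25 day range with a median near
14 days; the dominant width, on `a_hpc_max`, is asymmetric because
recovery time scales roughly inversely with the amplification headroom
and the clinical distribution is right-skewed.  Per-patient random
substreams are derived from the root seed, so the same patients are
reused across arms and enlarging a cohort never changes existing
patients.

What the generator emulates: inter-individual variation in recovery
kinetics and clone properties under one archetypal mechanism at a time.
What it does not: measurement noise in VAF assays, multiple concurrent
clones per donor, de-novo mutation, stochastic extinction of small
clones, immune control, or correlations between patient physiology and
clone biology.  Passing trials therefore demonstrate mechanistic
consistency, not clinical effect sizes.

Trials: `run_dose_trial()` transplants each patient at 1–15×10⁶ CD34+
cells/kg (with or without pegfilgrastim), `run_composition_trial()`
varies HSC and HPC content separately (1:5:10:15; graft 2 ≡ graft 6 by
construction), and `correlate_trial()` reports Spearman rank
correlations (average-rank ties) for the six donor/recipient pairs.

## Numerical choices

Stiff integration uses `deSolve::ode` (lsoda) at `rtol = 1e-6`,
`atol = 1e-3` cells/kg, with output on a uniform grid (0.25 days for
engraftment extraction, 1–5 days for multi-year runs; growth-factor
dose times are inserted into the grid).  Concentrations within
100·atol of zero are clipped to zero; larger negativity raises an
error.  Engraftment time is robust to doubling either tolerance to
within 0.01 days.  Donor pre-donation courses run 2 years at a 5-day
grid.  Routine tests use 5–8-patient cohorts and the acceptance script
1000 patients (growth-factor contrast on 250); these sizes were chosen
as the smallest that make the monotonicity and correlation sign
patterns stable.

## Known limitations

* The engraftment window and the cohort spread rest on a few constants
  (`a_hpc_max`, `s_p_star`, `a_hsc_max`, graft composition) that
  published counts do not identify; different combinations reproducing
  the same window would shift quantitative VAF trajectories somewhat.
* The maximal HSC self-renewal `a_hsc_max = 0.75` bounds the mutant
  differentiation fraction away from zero; with `a_hsc_max = 1` a
  hypersensitive clone stops differentiating entirely during prolonged
  recoveries and its blood VAF collapses, which contradicts the
  monotone dose dependence the trials rely on.
* PB VAF equals the neutrophil clonal fraction; contributions of
  lymphoid and monocytic cells to measured VAFs are outside the model.
* The inflammation coupling form (multiplicative, shared deficit δ) is
  one of several algebraic forms consistent with the qualitative
  constraints.
* ODE dynamics assume clone sizes large enough to ignore stochastic
  extinction (donor VAF ≥ 0.005 guarantees ≥ 1000 mutated HSCs per
  graft).
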