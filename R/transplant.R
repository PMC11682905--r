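#' Default CD34+ graft stage composition
#'
#' Allocation of a CD34+ peripheral-blood graft across the immature
#' compartments.  The progenitor part samples the donor's marrow
#' proportionally to the calibrated homeostatic stage profile over the
#' first `n_cd34_stages` HPC stages (all stages by default; smaller
#' values model a graft depleted of the most mature precursors).  A
#' fraction `hsc_fraction` of the graft are true HSCs — primitive HSCs
#' are a small minority of CD34+ cells; the default 2.66e-4 puts about
#' 1e5 HSCs into a reference graft of 4.7e6 CD34+ cells/kg for an 80 kg
#' recipient.  Mature neutrophils contained in the graft are discarded
#' (they are cleared within days and do not contribute).
#'
#' The stage profile and `hsc_fraction` are the calibration degrees of
#' freedom that the printed constants do not pin down; together with the
#' stimulated amplification headroom (`a_hpc_max`) they were fixed once
#' such that the reference transplantation (4.7e6 CD34+ cells/kg, 50%
#' homing, no growth factor) engrafts in the clinically observed 10-20
#' day window.
#'
#' @param params calibrated [chip_params()]; `NULL` uses the reference
#'   calibration.
#' @param hsc_fraction fraction of graft cells that are HSCs.
#' @param n_cd34_stages number of HPC stages contributing to the graft.
#' @return numeric vector of length `n_stages + 1` (HSC, then HPC stages)
#'   summing to 1.
#' @export
graft_composition <- function(params = NULL, hsc_fraction = 2.66e-4,
                              n_cd34_stages = 15L) {
  if (is.null(params))
    params <- calibrate_homeostasis(chip_params())$params
  stopifnot(inherits(params, "chip_params"), isTRUE(params$calibrated),
            hsc_fraction > 0, hsc_fraction < 1,
            n_cd34_stages >= 1, n_cd34_stages <= params$n_stages)
  w <- numeric(params$n_stages + 1L)
  w[2:(n_cd34_stages + 1)] <- params$u_star[2:(n_cd34_stages + 1)]
  w <- w / sum(w) * (1 - hsc_fraction)
  w[1] <- hsc_fraction
  w
}

#' Construct a stem cell graft
#'
#' Allocates a transplant dose of CD34+ cells per kg of body weight across
#' the HSC and HPC compartments according to a stage composition, and
#' splits each compartment between the wildtype clone and mutant clones.
#' If only the donor's peripheral-blood VAF is given, the mutant cell
#' fraction is assumed uniform across compartments and equals `2 * VAF`
#' for a heterozygous clone (`VAF` for homozygous).  Alternatively a full
#' donor state (per-clone, per-compartment concentrations, e.g. from
#' [donor_course()]) provides per-compartment clonal fractions.
#'
#' @param dose_cd34_per_kg transplanted CD34+ cells per kg (> 0).
#' @param composition per-stage allocation from [graft_composition()]
#'   (length `n_stages + 1`, summing to 1).
#' @param donor_vaf VAF in the donor's peripheral blood at donation
#'   (ignored when `donor_state` is given).
#' @param donor_state optional matrix (clones x compartments) of donor
#'   concentrations at donation.
#' @param clones list of mutant [clone_spec()]s in the graft (may be
#'   empty); zygosity of the first clone is used for the VAF conversion.
#' @return object of class `chip_graft`: per-clone, per-compartment cell
#'   numbers before homing (mature column zero).
#' @export
make_graft <- function(dose_cd34_per_kg, composition = graft_composition(),
                       donor_vaf = 0, donor_state = NULL,
                       clones = list()) {
  if (dose_cd34_per_kg <= 0)
    stop("dose must be > 0", call. = FALSE)
  if (abs(sum(composition) - 1) > 1e-8)
    stop("composition must sum to 1", call. = FALSE)
  if (inherits(clones, "clone_spec")) clones <- list(clones)
  n_stages <- length(composition) - 1L
  J <- 1L + length(clones)
  cells <- dose_cd34_per_kg * composition   # HSC + HPC stages
  g <- matrix(0, nrow = J, ncol = n_stages + 2L,
              dimnames = list(c("wildtype",
                                vapply(clones, `[[`, "", "clone_id")),
                              compartment_names(n_stages)))
  if (!is.null(donor_state)) {
    frac <- donor_state[, 1:(n_stages + 1), drop = FALSE]
    frac <- sweep(frac, 2, colSums(frac), "/")
    frac[, colSums(donor_state[, 1:(n_stages + 1), drop = FALSE]) == 0] <- 0
    g[, 1:(n_stages + 1)] <- sweep(frac, 2, cells, "*")
  } else {
    if (donor_vaf < 0 || donor_vaf > 0.5 + 1e-12)
      stop("donor_vaf must lie in [0, 0.5]", call. = FALSE)
    mut_frac <- 0
    if (length(clones)) {
      zyg <- clones[[1]]$zygosity
      mut_frac <- if (zyg == "heterozygous") 2 * donor_vaf else donor_vaf
      if (length(clones) > 1)
        mut_frac <- rep(mut_frac / length(clones), length(clones))
    }
    g[1, 1:(n_stages + 1)] <- cells * (1 - sum(mut_frac))
    for (k in seq_along(clones))
      g[1 + k, 1:(n_stages + 1)] <- cells * mut_frac[[min(k, length(mut_frac))]]
  }
  out <- list(cells = g, dose_cd34_per_kg = dose_cd34_per_kg,
              composition = composition, donor_vaf = donor_vaf,
              clones = clones)
  class(out) <- "chip_graft"
  out
}

#' @export
print.chip_graft <- function(x, ...) {
  cat(sprintf("CD34+ graft: %.3g cells/kg (%d clone(s), donor VAF %.4g)\n",
              x$dose_cd34_per_kg, nrow(x$cells), x$donor_vaf))
  cat(sprintf("  HSC: %.3g /kg, HPC: %.3g /kg\n",
              sum(x$cells[, 1]), sum(x$cells[, -c(1, ncol(x$cells))])))
  invisible(x)
}

#' Apply marrow homing to a graft
#'
#' Only a fraction of the infused cells lodges in the bone marrow and
#' contributes to blood cell formation (about 50% by default); homing is
#' treated as instantaneous since marrow migration completes in under a
#' day.  Homing fractions are clone- and compartment-class-specific
#' (`homing_hsc`, `homing_hpc` on each [clone_spec()]).  The mature
#' compartment of the recipient starts at zero.
#'
#' @param graft a [make_graft()] object.
#' @param wildtype optional wildtype [clone_spec()] carrying the wildtype
#'   homing fractions (default 0.5 / 0.5).
#' @return initial state matrix (clones x compartments) for
#'   [simulate_dynamics()].
#' @export
apply_homing <- function(graft, wildtype = NULL) {
  stopifnot(inherits(graft, "chip_graft"))
  if (is.null(wildtype)) wildtype <- wildtype_clone()
  specs <- c(list(wildtype), graft$clones)
  g <- graft$cells
  n_stages <- ncol(g) - 2L
  init <- g
  for (j in seq_len(nrow(g))) {
    s <- specs[[min(j, length(specs))]]
    init[j, 1] <- g[j, 1] * s$homing_hsc
    init[j, 2:(n_stages + 1)] <- g[j, 2:(n_stages + 1)] * s$homing_hpc
  }
  init[, n_stages + 2] <- 0
  init
}

#' Simulate the donor's pre-donation course
#'
#' Initializes the donor at the calibrated homeostatic equilibrium with
#' the mutant clone occupying the compartment fraction consistent with an
#' assigned peripheral-blood VAF, then simulates forward (same dynamics,
#' no transplant) up to the time of donation.  For a neutral clone the
#' VAF stays constant; clones with kinetic advantages or
#' inflammation-dependent fitness drift, producing the donor's
#' pre-donation VAF trajectory.  The final state can seed [make_graft()]
#' via its `donor_state` argument.
#'
#' @param model a [chip_model()] with exactly one mutant clone; the
#'   model's `inflammation$host_baseline` is the donor's burden.
#' @param initial_vaf the donor's PB VAF at the start of the course.
#' @param years_before_donation length of the simulated course, years.
#' @param dt output grid spacing, days.
#' @return list: `trajectory` (`chip_trajectory`), `state_at_donation`
#'   (clones x compartments matrix) and `vaf_at_donation`.
#' @export
donor_course <- function(model, initial_vaf, years_before_donation = 2,
                         dt = 5) {
  stopifnot(inherits(model, "chip_model"), length(model$clones) == 2L,
            initial_vaf >= 0, initial_vaf <= 0.5)
  p <- model$params
  zyg <- model$clones[[2]]$zygosity
  frac <- if (zyg == "heterozygous") 2 * initial_vaf else initial_vaf
  init <- rbind(p$u_star * (1 - frac), p$u_star * frac)
  traj <- simulate_dynamics(model, init = init,
                            horizon = years_before_donation * 365.25,
                            dt = dt)
  nt <- length(traj$times)
  state <- traj$u[nt, , ]
  list(trajectory = traj,
       state_at_donation = state,
       vaf_at_donation = vaf_series(traj)[nt])
}
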