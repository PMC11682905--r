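#' Perturbation widths of the virtual patient cohort
#'
#' Each virtual patient carries an individual parameter set obtained by
#' multiplying reference parameters with independent uniform factors.
#' The default widths were fixed once by a calibration loop so that the
#' 1000-patient cohort's times to neutrophil engraftment at the reference
#' transplantation (4.7e6 CD34+ cells/kg, no growth factor) match the
#' clinically reported range of 11-25 days with a median near 14 days.
#'
#' Each entry is a length-2 vector `c(lo, hi)`: the multiplicative factor
#' is drawn from U(lo, hi).  The factor on `a_hpc_max` perturbs the
#' stimulated amplification headroom, the dominant determinant of the
#' reconstitution speed, and is deliberately asymmetric: recovery time
#' scales roughly with the inverse headroom, so an asymmetric factor
#' range maps onto the right-skewed clinical engraftment distribution.
#'
#' @return named list of length-2 numeric vectors.
#' @export
cohort_widths <- function() {
  list(
    a_hpc_max = c(0.84, 1.02),
    p_hsc_hom = c(0.90, 1.10),
    p_last_hom = c(0.95, 1.05),
    d_mature = c(0.95, 1.05),
    M_star = c(0.95, 1.05),
    H_star = c(0.95, 1.05),
    homing = c(0.95, 1.05)
  )
}

#' Mutant-clone archetype ranges for cohort sampling
#'
#' Per-cohort uniform sampling ranges of the CHIP clone properties.  The
#' `"saturated"` archetype draws aberrant signal-sensitivity factors
#' (clones that expand only under hematopoietic stress and stabilize once
#' the feedback signals normalize); the `"persistent"` archetype draws a
#' permanent HSC self-renewal advantage accompanied by a proliferation
#' advantage (clones that keep expanding at roughly constant rate for
#' years).  Donor PB VAFs are drawn uniformly
#' from `vaf_range` (default 0.005-0.125).
#'
#' @param archetype `"saturated"` or `"persistent"`.
#' @param vaf_range donor PB VAF sampling range.
#' @return named list describing the sampling ranges.
#' @export
clone_archetype <- function(archetype = c("saturated", "persistent"),
                            vaf_range = c(0.005, 0.125)) {
  archetype <- match.arg(archetype)
  ranges <- switch(archetype,
    saturated = list(sens_hsc = c(1.1, 1.5), sens_hpc = c(1.5, 2.5)),
    persistent = list(mult_selfrenewal_hsc = c(1.04, 1.12),
                      mult_prolif_hsc = c(1.5, 3)))
  list(archetype = archetype, vaf_range = vaf_range, ranges = ranges)
}

patient_seed <- function(root_seed, i) {
  # deterministic per-patient substream; adding patients never changes
  # earlier ones
  (as.integer(root_seed) + 104729L * (i %% 20000L)) %% 2147483587L
}

#' Sample a calibrated virtual patient cohort
#'
#' Generates `n` virtual patients by multiplicative uniform perturbation
#' of a reference parameter set (see [cohort_widths()]), recalibrating
#' the homeostatic state per patient, and drawing each patient's donor
#' CHIP clone from a [clone_archetype()].  The same seed always
#' reproduces the same cohort, and patient `i` only depends on
#' `(seed, i)`, so cohorts of different sizes share their initial
#' patients.
#'
#' @param n number of virtual patients.
#' @param reference reference [chip_params()] (uncalibrated is fine).
#' @param widths perturbation widths, as [cohort_widths()].
#' @param clone_ranges archetype from [clone_archetype()], or `NULL` for
#'   a wildtype-only cohort.
#' @param seed integer root seed.
#' @return object of class `chip_cohort`: list of patients, each with
#'   calibrated `params`, `clone` (or `NULL`), `donor_vaf`, `homing` and
#'   `patient_id`.
#' @export
sample_cohort <- function(n, reference = chip_params(),
                          widths = cohort_widths(),
                          clone_ranges = clone_archetype("saturated"),
                          seed = 1L) {
  stopifnot(n >= 1)
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(patient_seed(seed, i))
    pp <- reference
    for (nm in names(widths)) {
      if (nm == "homing") next
      w <- widths[[nm]]
      pp[[nm]] <- pp[[nm]] * stats::runif(1, w[1], w[2])
    }
    homing <- 0.5
    if ("homing" %in% names(widths)) {
      w <- widths[["homing"]]
      homing <- min(1, 0.5 * stats::runif(1, w[1], w[2]))
    }
    params <- calibrate_homeostasis(pp)$params
    clone <- NULL
    donor_vaf <- 0
    if (!is.null(clone_ranges)) {
      donor_vaf <- stats::runif(1, clone_ranges$vaf_range[1],
                                clone_ranges$vaf_range[2])
      args <- lapply(clone_ranges$ranges,
                     function(r) stats::runif(1, r[1], r[2]))
      args$clone_id <- sprintf("chip_%04d", i)
      args$homing_hsc <- homing
      args$homing_hpc <- homing
      clone <- do.call(clone_spec, args)
    }
    patients[[i]] <- list(patient_id = i, params = params, clone = clone,
                          donor_vaf = donor_vaf, homing = homing)
  }
  out <- list(patients = patients, seed = seed,
              archetype = if (is.null(clone_ranges)) "wildtype"
                          else clone_ranges$archetype)
  class(out) <- "chip_cohort"
  out
}

#' @export
print.chip_cohort <- function(x, ...) {
  cat(sprintf("Virtual patient cohort: n = %d, archetype = %s, seed = %d\n",
              length(x$patients), x$archetype, x$seed))
  invisible(x)
}

patient_wildtype <- function(pat) {
  clone_spec(clone_id = "wildtype", homing_hsc = pat$homing,
             homing_hpc = pat$homing)
}

# Simulate one transplantation for one virtual patient.
# Returns the recipient chip_trajectory.
simulate_patient <- function(pat, dose, gcsf_day = NULL, horizon = 150,
                             dt = 0.25, graft_cells = NULL,
                             donor_state = NULL, gamma = NULL) {
  comp <- graft_composition(pat$params)
  clones <- if (is.null(pat$clone)) list() else list(pat$clone)
  g <- if (is.null(graft_cells)) {
    make_graft(dose, comp, donor_vaf = pat$donor_vaf,
               donor_state = donor_state, clones = clones)
  } else graft_cells
  wt <- patient_wildtype(pat)
  init <- apply_homing(g, wildtype = wt)
  pk <- NULL
  if (!is.null(gcsf_day)) {
    pk <- pk_params(dose_times = gcsf_day)
    if (!is.null(gamma)) pk$gamma <- gamma
  }
  model <- chip_model(pat$params, clones = clones, pk = pk, wildtype = wt)
  simulate_dynamics(model, init = init, horizon = horizon, dt = dt)
}

#' Cohort engraftment times
#'
#' Simulates the reference transplantation for every cohort patient and
#' returns the time to neutrophil engraftment (threshold 5e8 cells per
#' litre), optionally under a single pegfilgrastim dose.
#'
#' @param cohort a [sample_cohort()] object.
#' @param dose transplanted CD34+ cells per kg.
#' @param gcsf_day day of a single pegfilgrastim dose, or `NULL` for no
#'   growth-factor support.
#' @param horizon simulation horizon, days.
#' @return numeric vector of engraftment times (days; `NA` if not
#'   reached within the horizon).
#' @export
cohort_engraftment <- function(cohort, dose = 4.7e6, gcsf_day = NULL,
                               horizon = 150) {
  vapply(cohort$patients, function(pat) {
    tr <- simulate_patient(pat, dose, gcsf_day = gcsf_day,
                           horizon = horizon)
    engraftment_time(tr)
  }, numeric(1))
}

trial_row <- function(pat, arm, dose, gcsf, tr, donor) {
  v <- vaf_series(tr)
  t <- tr$times
  vaf100 <- stats::approx(t, v, xout = 100)$y
  vaf1y <- stats::approx(t, v, xout = 365.25)$y
  data.frame(
    patient_id = pat$patient_id, arm = arm, dose = dose, gcsf = gcsf,
    donor_vaf = donor$vaf_at_donation,
    vaf_100d = vaf100, vaf_1y = vaf1y,
    engraftment_days = engraftment_time(tr),
    delta_R_100d = vaf100 - donor$vaf_at_donation,
    pi_R_100d = vaf100 / donor$vaf_at_donation,
    delta_D_1y = donor$delta_D_1y, pi_D_1y = donor$pi_D_1y
  )
}

# Donor pre-donation course for one patient; returns state at donation
# and the donor expansion metrics over the final pre-donation year.
patient_donor_course <- function(pat, years = 2) {
  model <- chip_model(pat$params, clones = list(pat$clone))
  dc <- donor_course(model, initial_vaf = pat$donor_vaf,
                     years_before_donation = years, dt = 5)
  tr <- dc$trajectory
  v <- vaf_series(tr)
  t_don <- max(tr$times)
  v_don <- dc$vaf_at_donation
  v_prior <- stats::approx(tr$times, v, xout = t_don - 365.25)$y
  list(state = dc$state_at_donation, vaf_at_donation = v_don,
       delta_D_1y = v_don - v_prior,
       pi_D_1y = if (v_prior > 0) v_don / v_prior else NA_real_)
}

#' Run the transplant-dose trial
#'
#' For every cohort patient the donor's pre-donation course is simulated
#' once; the resulting graft (sampled from the donor state at donation)
#' is then transplanted at each dose, with and/or without one
#' pegfilgrastim dose on day 3, and the recipient is followed for one
#' year.  Unlike a clinical trial, the very same virtual patient is
#' transplanted under every arm.
#'
#' @param cohort a [sample_cohort()] cohort with clones.
#' @param doses CD34+ doses per kg (default 1e6, 5e6, 1e7, 1.5e7).
#' @param gcsf logical vector of growth-factor arms to run (default
#'   without support only; use `c(FALSE, TRUE)` for both).
#' @param gcsf_day day of the pegfilgrastim dose.
#' @param horizon recipient follow-up, days (>= 1 year for the VAF
#'   metrics).
#' @return data.frame with one row per patient x dose x gcsf arm:
#'   recipient VAF at 100 days and 1 year, engraftment time and the
#'   donor/recipient expansion metrics.
#' @export
run_dose_trial <- function(cohort, doses = c(1e6, 5e6, 1e7, 1.5e7),
                           gcsf = FALSE, gcsf_day = 3, horizon = 380) {
  rows <- list()
  for (pat in cohort$patients) {
    donor <- patient_donor_course(pat)
    for (dose in doses) for (gc in gcsf) {
      tr <- simulate_patient(pat, dose,
                             gcsf_day = if (gc) gcsf_day else NULL,
                             horizon = horizon, dt = 1,
                             donor_state = donor$state)
      rows[[length(rows) + 1]] <-
        trial_row(pat, arm = sprintf("dose_%g%s", dose,
                                     if (gc) "_gcsf" else ""),
                  dose, gc, tr, donor)
    }
  }
  do.call(rbind, rows)
}

#' Run the graft-composition trial
#'
#' Two arms of four grafts each.  Arm A (grafts 1-4): transplanted HSC
#' numbers in ratio 1:5:10:15 (the HSC content of 1e6, 5e6, 1e7 and
#' 1.5e7 CD34+/kg grafts) at the fixed HPC content of a 5e6 CD34+/kg
#' graft.  Arm B (grafts 5-8): HPC numbers in ratio 1:5:10:15 at the
#' fixed HSC content of a 5e6 CD34+/kg graft.  Graft 2 and graft 6 are
#' identical by construction.
#'
#' @param cohort a [sample_cohort()] cohort with clones.
#' @param base_dose dose whose composition anchors the fixed component
#'   (default 5e6).
#' @param ratios scaling of the varied component (default
#'   `c(1, 5, 10, 15) / 5` relative to `base_dose`).
#' @param horizon recipient follow-up, days.
#' @return data.frame as in [run_dose_trial()], with arms
#'   `graft_1` ... `graft_8`.
#' @export
run_composition_trial <- function(cohort, base_dose = 5e6,
                                  ratios = c(1, 5, 10, 15) / 5,
                                  horizon = 380) {
  rows <- list()
  for (pat in cohort$patients) {
    donor <- patient_donor_course(pat)
    comp <- graft_composition(pat$params)
    n_comp <- length(comp) + 1L
    base <- make_graft(base_dose, comp, donor_state = donor$state,
                       clones = list(pat$clone))
    for (k in seq_along(ratios)) {
      for (arm_class in c("A", "B")) {
        g <- base
        scale_cols <- if (arm_class == "A") 1L else 2:(n_comp - 1L)
        g$cells[, scale_cols] <- g$cells[, scale_cols] * ratios[k]
        g$dose_cd34_per_kg <- sum(g$cells)
        arm_id <- if (arm_class == "A") k else 4L + k
        tr <- simulate_patient(pat, dose = g$dose_cd34_per_kg,
                               horizon = horizon, dt = 1, graft_cells = g)
        rows[[length(rows) + 1]] <-
          trial_row(pat, arm = sprintf("graft_%d", arm_id),
                    dose = g$dose_cd34_per_kg, gcsf = FALSE, tr, donor)
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$arm, out$patient_id), ]
}

#' Spearman correlations of donor and recipient clonal dynamics
#'
#' Rank correlations (average-rank ties) of the six donor/recipient
#' quantity pairs: donor VAF vs recipient VAF at 100 days, vs the
#' absolute expansion `delta_R_100d`, vs the relative expansion
#' `pi_R_100d`; pre-donation donor expansion `delta_D_1y` vs
#' `delta_R_100d` and vs recipient VAF at 100 days; and `pi_D_1y` vs
#' `pi_R_100d`.
#'
#' @param trial_table a single-arm subset of a [run_dose_trial()] /
#'   [run_composition_trial()] table.
#' @return named numeric vector of Spearman rho values.
#' @export
correlate_trial <- function(trial_table) {
  stopifnot(nrow(trial_table) >= 3)
  pairs <- list(
    donor_vs_recipient100d = c("donor_vaf", "vaf_100d"),
    donor_vs_delta_R = c("donor_vaf", "delta_R_100d"),
    donor_vs_pi_R = c("donor_vaf", "pi_R_100d"),
    delta_D_vs_delta_R = c("delta_D_1y", "delta_R_100d"),
    pi_D_vs_pi_R = c("pi_D_1y", "pi_R_100d"),
    delta_D_vs_recipient100d = c("delta_D_1y", "vaf_100d")
  )
  vapply(pairs, function(p) {
    x <- trial_table[[p[1]]]; y <- trial_table[[p[2]]]
    ok <- is.finite(x) & is.finite(y)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      stop("undefined correlation: constant input vector (", p[1], " vs ",
           p[2], ")", call. = FALSE)
    stats::cor(x[ok], y[ok], method = "spearman")
  }, numeric(1))
}
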