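#' Model parameters for feedback-regulated neutrophil hematopoiesis
#'
#' Constructs the parameter set of the compartmental model of the neutrophil
#' lineage: one hematopoietic stem cell (HSC) compartment, `n_stages`
#' progenitor/precursor (HPC) stages and one mature polymorphonuclear
#' neutrophil (PMN) compartment.  All concentrations are expressed in cells
#' per kg of body weight and all rates in 1/day.
#'
#' Homeostatic per-stage proliferation rates increase by equal arithmetic
#' increments from `p_hsc_hom` (HSC) to `p_last_hom` (last mitotic stage).
#' Feedback signals are first-order Hill functions of the total mature count
#' (systemic signal) and of the total HSC count (niche signal); see
#' [feedback_signal()].  Which signal regulates which cell property is
#' selected by `variant`:
#'
#' * `"baseline"`: all regulated properties respond to the systemic signal;
#' * `"niche_selfrenewal"`: HSC self-renewal responds to the niche signal,
#'   everything else to the systemic signal;
#' * `"niche_selfrenewal_proliferation"`: HSC self-renewal and HSC
#'   proliferation respond to the niche signal, HPC properties to the
#'   systemic signal.
#'
#' The object returned by `chip_params()` is not yet calibrated: the
#' feedback gains, the homeostatic HPC self-renewal probability and the
#' equilibrium stage concentrations are filled in by
#' [calibrate_homeostasis()].
#'
#' @param n_stages number of immature non-HSC compartments (default 15).
#' @param p_hsc_hom homeostatic HSC proliferation rate, 1/day (default
#'   2/365.25, i.e. two divisions per year).
#' @param p_last_hom homeostatic proliferation rate of the last mitotic
#'   stage, 1/day (default 1).
#' @param prolif_fold_max maximal fold-increase of proliferation under full
#'   stimulation (default 4).
#' @param prolif_floor lower bound of the proliferation response for
#'   signals below the homeostatic value (default 0.25).
#' @param a_hsc_max maximal HSC self-renewal probability (default 0.75).
#'   [calibrate_homeostasis()] sets the homeostatic self-renewal signal to
#'   `s* = 0.5 / a_hsc_max` so the HSC steady state sits at self-renewal
#'   1/2; values below 1 bound the differentiation fraction `1 - a` away
#'   from zero even under maximal stimulation.
#' @param a_hpc_max maximal HPC self-renewal probability under full
#'   stimulation (default 0.50; must exceed the homeostatic value solved
#'   by [calibrate_homeostasis()], about 0.294 at the reference targets).
#'   The headroom between the two sets how strongly an empty system can
#'   boost progenitor amplification; together with the graft composition
#'   it calibrates the post-transplant recovery speed and is fixed once.
#' @param s_p_star homeostatic value of the proliferation-loop feedback
#'   signal (default 0.002).  The proliferation loop carries its own
#'   strong Hill gain `k_p = (1/s_p_star - 1)/M_star`: circulating G-CSF
#'   rises steeply only in deep neutropenia, so division rates stay close
#'   to their homeostatic schedule during most of the reconstitution and
#'   reach the full `prolif_fold_max` only near-complete aplasia (or
#'   under exogenous growth factor).  This constant calibrates the
#'   post-transplant recovery speed and is fixed once.
#' @param d_mature clearance rate of circulating neutrophils, 1/day
#'   (default 2.3, a blood half-life of roughly 7 hours).
#' @param M_star homeostatic mature neutrophil concentration, cells/kg
#'   (default 3.1e8, i.e. 5e9 cells per litre at 5 l blood / 80 kg).
#' @param H_star homeostatic HSC concentration, cells/kg (default
#'   1e5 HSCs / 80 kg = 1250).
#' @param variant feedback wiring, see Details.
#' @return an object of class `chip_params`.
#' @seealso [calibrate_homeostasis()], [chip_model()]
#' @examples
#' p <- calibrate_homeostasis(chip_params())$params
#' p
#' @export
chip_params <- function(n_stages = 15L,
                        p_hsc_hom = 2 / 365.25,
                        p_last_hom = 1,
                        prolif_fold_max = 4,
                        prolif_floor = 0.25,
                        a_hsc_max = 0.75,
                        a_hpc_max = 0.50,
                        s_p_star = 0.002,
                        d_mature = 2.3,
                        M_star = 3.1e8,
                        H_star = 1e5 / 80,
                        variant = c("baseline", "niche_selfrenewal",
                                    "niche_selfrenewal_proliferation")) {
  variant <- match.arg(variant)
  n_stages <- as.integer(n_stages)
  stopifnot(n_stages >= 1L)
  if (!(p_hsc_hom > 0 && p_last_hom > 0 && d_mature > 0 &&
        M_star > 0 && H_star > 0 && prolif_fold_max >= 1 &&
        prolif_floor > 0 && prolif_floor <= 1))
    stop("all rates and targets must be strictly positive; ",
         "prolif_fold_max >= 1, 0 < prolif_floor <= 1", call. = FALSE)
  if (p_hsc_hom >= p_last_hom)
    stop("p_hsc_hom must be smaller than p_last_hom", call. = FALSE)
  if (!is.na(a_hpc_max) && (a_hpc_max <= 0 || a_hpc_max > 1))
    stop("a_hpc_max must lie in (0, 1]", call. = FALSE)
  if (is.na(a_hsc_max) || a_hsc_max <= 0.5 || a_hsc_max > 1)
    stop("a_hsc_max must lie in (0.5, 1]", call. = FALSE)
  if (s_p_star <= 0 || s_p_star >= 1)
    stop("s_p_star must lie in (0, 1)", call. = FALSE)
  obj <- list(
    n_stages = n_stages,
    p_hsc_hom = p_hsc_hom,
    p_last_hom = p_last_hom,
    prolif_fold_max = prolif_fold_max,
    prolif_floor = prolif_floor,
    a_hsc_max = a_hsc_max,
    a_hpc_max = a_hpc_max,
    s_p_star = s_p_star,
    a_hpc_hom = NA_real_,
    d_mature = d_mature,
    M_star = M_star,
    H_star = H_star,
    k_sys = NA_real_,
    k_p = NA_real_,
    k_amp = NA_real_,
    k_niche = NA_real_,
    k_p_niche = NA_real_,
    s_amp_star = NA_real_,
    s_star = NA_real_,
    variant = variant,
    calibrated = FALSE,
    u_star = NULL
  )
  class(obj) <- "chip_params"
  obj
}

#' @export
print.chip_params <- function(x, ...) {
  cat("Feedback-regulated neutrophil hematopoiesis parameters\n")
  cat(sprintf("  compartments: HSC + %d HPC stages + mature PMN\n",
              x$n_stages))
  cat(sprintf("  variant: %s\n", x$variant))
  cat(sprintf("  p_hsc_hom = %.4g /day, p_last_hom = %.4g /day\n",
              x$p_hsc_hom, x$p_last_hom))
  cat(sprintf("  d_mature = %.3g /day, M* = %.3g /kg, H* = %.4g /kg\n",
              x$d_mature, x$M_star, x$H_star))
  if (isTRUE(x$calibrated)) {
    cat(sprintf("  calibrated: a_hsc_max = %.4g, a_hpc_hom = %.6g, s* = %.3g\n",
                x$a_hsc_max, x$a_hpc_hom, x$s_star))
  } else {
    cat("  not calibrated (run calibrate_homeostasis())\n")
  }
  invisible(x)
}

#' Hill-type feedback signal
#'
#' First-order Hill function of a cell count: `s = 1 / (1 + gain * total)`.
#' The signal is 1 for an empty system (maximal stimulation) and decreases
#' monotonically towards 0 as the regulating population grows.
#'
#' @param total_cells regulating cell concentration, cells/kg (>= 0).
#' @param gain feedback gain, 1/(cells/kg) (> 0).
#' @return signal in (0, 1].
#' @examples
#' feedback_signal(0, 1e-8)          # 1: empty system
#' feedback_signal(3.1e8, 1 / 3.1e8) # 0.5 at the half-saturation count
#' @export
feedback_signal <- function(total_cells, gain) {
  if (any(!is.finite(total_cells)) || any(total_cells < 0))
    stop("total_cells must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(gain)) || any(gain <= 0))
    stop("gain must be finite and > 0", call. = FALSE)
  1 / (1 + gain * total_cells)
}

# Piecewise-linear proliferation response g(s): g(s_star) = 1,
# g(1) = fold_max, and a positive floor for under-stimulation (s < s_star).
prolif_response <- function(s, s_star, fold_max, floor = 0.25) {
  up <- 1 + (fold_max - 1) * (s - s_star) / (1 - s_star)
  dn <- pmax(floor, floor + (1 - floor) * s / s_star)
  ifelse(s >= s_star, up, dn)
}

#' Feedback-regulated rate schedule
#'
#' Evaluates the per-stage proliferation rates and self-renewal
#' probabilities at given values of the systemic and niche feedback
#' signals.  Self-renewal of stage i is `a_i(x) = a_i_max * x`, clipped to
#' `[0, a_i_max]`; proliferation is `p_i(x) = p_i_hom * g(x)` with the
#' piecewise-linear response `g` satisfying `g(s*) = 1` and
#' `g(1) = prolif_fold_max`.  The HPC self-renewal (amplification) loop
#' uses its own Hill gain `k_amp`; `s_sys` (the proliferation-loop signal)
#' is converted internally to the amplification-loop signal of the same
#' underlying mature count, so `s_sys = s*` reproduces the homeostatic
#' schedule and `s_sys = 1` (empty system) gives the fully stimulated one.
#' Which signal is used for which property is decided by `params$variant`
#' (see [chip_params()]).
#'
#' @param s_sys systemic feedback signal in (0, 1].
#' @param s_niche niche feedback signal in (0, 1].
#' @param params calibrated [chip_params()] object.
#' @return list with components `p` (length `n_stages + 1`: HSC followed by
#'   the HPC stages) and `a` (same layout), plus the homeostatic schedule
#'   `p_hom` and `a_max`.
#' @export
regulated_rates <- function(s_sys, s_niche, params) {
  stopifnot(inherits(params, "chip_params"))
  if (!isTRUE(params$calibrated))
    stop("params must be calibrated first (calibrate_homeostasis)",
         call. = FALSE)
  for (s in c(s_sys, s_niche))
    if (!is.finite(s) || s <= 0 || s > 1)
      stop("feedback signals must lie in (0, 1]", call. = FALSE)
  n <- params$n_stages
  sig_sr_hsc <- switch(params$variant,
                       baseline = s_sys,
                       niche_selfrenewal = s_niche,
                       niche_selfrenewal_proliferation = s_niche)
  p_hom <- params$p_hom
  a_max <- params$a_max_vec
  # loop-specific signals of the same underlying cell counts
  M <- (1 / s_sys - 1) / params$k_sys
  s_p <- feedback_signal(M, params$k_p)
  s_amp <- feedback_signal(M, params$k_amp)
  s_p_hsc <- if (params$variant == "niche_selfrenewal_proliferation") {
    H <- (1 / s_niche - 1) / params$k_niche
    feedback_signal(H, params$k_p_niche)
  } else s_p
  g_hpc <- prolif_response(s_p, params$s_p_star, params$prolif_fold_max,
                           params$prolif_floor)
  g_hsc <- prolif_response(s_p_hsc, params$s_p_star, params$prolif_fold_max,
                           params$prolif_floor)
  p <- p_hom * c(g_hsc, rep(g_hpc, n))
  sig_a <- c(sig_sr_hsc, rep(s_amp, n))
  a <- pmin(pmax(a_max * sig_a, 0), a_max)
  list(p = p, a = a, p_hom = p_hom, a_max = a_max)
}

#' Calibrate the model to its homeostatic state
#'
#' Solves for the feedback gains, the maximal HSC self-renewal probability,
#' the uniform homeostatic HPC self-renewal probability and the equilibrium
#' stage concentrations such that the assembled ODE system has a steady
#' state with mature neutrophil concentration `M_star` and HSC
#' concentration `H_star`.
#'
#' The calibration fixes the homeostatic signal at `s* = 0.5` by setting
#' `k_sys = 1/M_star` and `k_niche = 1/H_star`; the HSC steady state
#' `du/dt = (2a - 1) p u = 0` then forces `a_hsc(s*) = 1/2`, i.e.
#' `a_hsc_max = 1`.  Stage-wise flux balance gives the per-stage
#' amplification `r = 2(1 - a)/(1 - 2a)` for a homeostatic HPC self-renewal
#' probability `a < 1/2`; the uniform `a_hpc_hom` is solved from the
#' required total amplification `d_mature * M_star / (p_hsc_hom * H_star)`
#' over the `n_stages` HPC stages, and the stage concentrations are
#' back-solved from the flux balance.
#'
#' @param params a [chip_params()] object.
#' @return list with components `params` (calibrated `chip_params`) and
#'   `state` (the homeostatic state matrix with one wildtype clone, as used
#'   by [simulate_dynamics()]).
#' @examples
#' cal <- calibrate_homeostasis(chip_params())
#' cal$params$a_hpc_hom
#' @export
calibrate_homeostasis <- function(params) {
  stopifnot(inherits(params, "chip_params"))
  n <- params$n_stages
  # HSC equilibrium forces a_hsc(s*) = 1/2, so s* = 0.5 / a_hsc_max
  s_star <- 0.5 / params$a_hsc_max
  params$s_star <- s_star
  params$k_sys <- (1 / s_star - 1) / params$M_star
  params$k_niche <- (1 / s_star - 1) / params$H_star
  # homeostatic per-stage proliferation rates: arithmetic progression
  params$p_hom <- seq(params$p_hsc_hom, params$p_last_hom, length.out = n + 1)
  # required total amplification between HSC outflux and mature influx:
  # outflux from HSC = 2 (1 - a_hsc*) p_hsc H* = p_hsc H*  (a_hsc* = 1/2)
  flux_hsc <- 2 * (1 - 0.5) * params$p_hsc_hom * params$H_star
  A_req <- params$d_mature * params$M_star / flux_hsc
  r_req <- A_req^(1 / n)
  if (r_req <= 1)
    stop("calibration error: required per-stage amplification <= 1 ",
         "(targets imply net attenuation)", call. = FALSE)
  # r = 2(1-a)/(1-2a)  =>  a = (r-2)/(2(r-1)); feasible only for a < 1/2
  a_hpc <- (r_req - 2) / (2 * (r_req - 1))
  if (a_hpc >= 0.5 || a_hpc < 0)
    stop(sprintf(paste0("calibration error: homeostatic HPC self-renewal ",
                        "a = %.4f violates 0 <= a < 0.5"), a_hpc),
         call. = FALSE)
  if (is.na(params$a_hpc_max))
    params$a_hpc_max <- min(1, a_hpc / s_star)
  if (params$a_hpc_max <= a_hpc)
    stop(sprintf(paste0("calibration error: a_hpc_max = %.3f must exceed ",
                        "the homeostatic HPC self-renewal %.4f"),
                 params$a_hpc_max, a_hpc), call. = FALSE)
  params$a_hpc_hom <- a_hpc
  # amplification loop: Hill gain passing through the homeostatic point
  params$s_amp_star <- a_hpc / params$a_hpc_max
  params$k_amp <- (1 / params$s_amp_star - 1) / params$M_star
  # proliferation loop: strong gain, homeostatic signal value s_p_star
  params$k_p <- (1 / params$s_p_star - 1) / params$M_star
  params$k_p_niche <- (1 / params$s_p_star - 1) / params$H_star
  params$a_max_vec <- c(params$a_hsc_max, rep(params$a_hpc_max, n))
  # back-solve equilibrium stage concentrations from flux balance:
  # 0 = (2a - 1) p_i u_i + F_{i-1},  F_i = 2 (1 - a) p_i u_i
  u <- numeric(n + 2)
  u[1] <- params$H_star
  flux <- flux_hsc
  for (i in seq_len(n)) {
    u[i + 1] <- flux / ((1 - 2 * a_hpc) * params$p_hom[i + 1])
    flux <- flux * 2 * (1 - a_hpc) / (1 - 2 * a_hpc) # equivalently 2(1-a) p u
  }
  u[n + 2] <- flux / params$d_mature
  params$u_star <- u
  params$calibrated <- TRUE
  state <- matrix(u, nrow = 1,
                  dimnames = list("wildtype", compartment_names(n)))
  list(params = params, state = state)
}

compartment_names <- function(n_stages) {
  c("hsc", paste0("hpc", seq_len(n_stages)), "mature")
}
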