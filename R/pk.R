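#' Pegfilgrastim-like pharmacokinetic parameters
#'
#' Two-compartment first-order kinetics: the drug is injected into a
#' subcutaneous depot, enters the plasma at rate `ka` proportional to the
#' depot content, and is eliminated from plasma at rate `ke` proportional
#' to the plasma concentration.  Dose amounts are normalized to 1 per
#' injection; only the potency `gamma` (stimulus units per concentration
#' unit) carries the strength of the coupling into the feedback stimulus
#' (see [stimulus_coupling()]).
#'
#' The default rates come from [calibrate_pk()] with the calibration
#' targets of a long-acting G-CSF analog: peak plasma concentration about
#' 2 days after injection, decay to half of the peak 3-4 days later.
#'
#' @param ka absorption rate from the subcutaneous depot, 1/day.
#' @param ke plasma elimination rate, 1/day.
#' @param dose_times injection times, days (dose amount 1 each).
#' @param gamma stimulus potency per unit plasma concentration.
#' @return object of class `pk_params`.
#' @export
pk_params <- function(ka = 0.6680, ke = 0.3629, dose_times = numeric(0),
                      gamma = 0.33) {
  stopifnot(ka > 0, ke > 0, gamma >= 0)
  obj <- list(ka = ka, ke = ke, dose_times = sort(as.numeric(dose_times)),
              gamma = gamma)
  class(obj) <- "pk_params"
  obj
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf("PK: ka = %.4g /day, ke = %.4g /day, gamma = %.3g\n",
              x$ka, x$ke, x$gamma))
  if (length(x$dose_times))
    cat("  doses at days:", paste(x$dose_times, collapse = ", "), "\n")
  else cat("  no doses scheduled\n")
  invisible(x)
}

#' Plasma concentration after subcutaneous dosing
#'
#' Closed-form superposition of the first-order depot/plasma solution over
#' all scheduled doses:
#' `C(t) = sum_d ka/(ka - ke) * (exp(-ke dt) - exp(-ka dt))` for
#' `dt = t - t_dose >= 0` (0 before the dose); in the degenerate equal-rate
#' case `ka = ke` the limit `ka * dt * exp(-ka dt)` is used.
#'
#' @param t time, days (scalar or vector).
#' @param params a [pk_params()] object.
#' @return plasma concentration >= 0 (arbitrary units; dose amount 1).
#' @examples
#' pk <- pk_params(dose_times = 0)
#' t_peak <- log(pk$ka / pk$ke) / (pk$ka - pk$ke) # closed-form peak time
#' plasma_concentration(t_peak, pk)
#' @export
plasma_concentration <- function(t, params) {
  ka <- params$ka; ke <- params$ke
  out <- numeric(length(t))
  for (td in params$dose_times) {
    dt <- t - td
    pos <- dt >= 0
    if (!any(pos)) next
    if (abs(ka - ke) < 1e-12) {
      out[pos] <- out[pos] + ka * dt[pos] * exp(-ka * dt[pos])
    } else {
      out[pos] <- out[pos] +
        ka / (ka - ke) * (exp(-ke * dt[pos]) - exp(-ka * dt[pos]))
    }
  }
  out
}

# single-dose peak time, closed form
pk_tmax <- function(ka, ke) {
  if (abs(ka - ke) < 1e-12) return(1 / ka)
  log(ka / ke) / (ka - ke)
}

# time from peak to half-peak for a single dose, found numerically
pk_half_decay <- function(ka, ke) {
  p <- pk_params(ka = ka, ke = ke, dose_times = 0)
  tm <- pk_tmax(ka, ke)
  cmax <- plasma_concentration(tm, p)
  f <- function(t) plasma_concentration(tm + t, p) - cmax / 2
  stats::uniroot(f, c(1e-6, 200 / ke), tol = 1e-10)$root
}

#' Calibrate the PK rates to peak-time and decay targets
#'
#' Solves numerically for `(ka, ke)` such that the single-dose plasma peak
#' occurs at `target_tmax` (within 0.05 days) and the time from the peak
#' to half of the peak concentration falls inside
#' `target_half_decay_window`.
#'
#' @param target_tmax target peak time, days (default 2).
#' @param target_half_decay_window numeric length-2 window, days (default
#'   `c(3, 4)`).
#' @param gamma potency to store on the returned object.
#' @return a calibrated [pk_params()] object (no doses scheduled).
#' @examples
#' pk <- calibrate_pk()
#' log(pk$ka / pk$ke) / (pk$ka - pk$ke) # ~ 2 days
#' @export
calibrate_pk <- function(target_tmax = 2,
                         target_half_decay_window = c(3, 4),
                         gamma = 0.33) {
  stopifnot(target_tmax > 0, length(target_half_decay_window) == 2,
            all(target_half_decay_window > 0),
            diff(target_half_decay_window) >= 0)
  t_half <- mean(target_half_decay_window)
  # outer solve over ke: for each ke, pick ka hitting the tmax target,
  # then drive the half-decay time to the window midpoint.
  ka_for_ke <- function(ke) {
    f <- function(ka) pk_tmax(ka, ke) - target_tmax
    stats::uniroot(f, c(ke * (1 + 1e-6), ke + 50), tol = 1e-12)$root
  }
  g <- function(ke) pk_half_decay(ka_for_ke(ke), ke) - t_half
  # the peak time cannot exceed 1/ke (the equal-rate limit), so the
  # feasible elimination rates for a given tmax are ke < 1/tmax
  sol <- tryCatch(
    stats::uniroot(g, c(0.01, 0.98 / target_tmax), tol = 1e-10),
    error = function(e)
      stop("PK calibration error: targets infeasible (", conditionMessage(e),
           ")", call. = FALSE))
  ke <- sol$root
  ka <- ka_for_ke(ke)
  # self-consistency check against the stated targets
  if (abs(pk_tmax(ka, ke) - target_tmax) > 0.05)
    stop("PK calibration error: peak-time target missed", call. = FALSE)
  hd <- pk_half_decay(ka, ke)
  if (hd < target_half_decay_window[1] - 1e-6 ||
      hd > target_half_decay_window[2] + 1e-6)
    stop("PK calibration error: half-decay target missed", call. = FALSE)
  pk_params(ka = ka, ke = ke, gamma = gamma)
}

#' Couple exogenous growth factor into the feedback stimulus
#'
#' Exogenous cytokine analogs act like the endogenous feedback signal:
#' the effective systemic stimulus is `min(1, s_endo + gamma * C)`,
#' saturating at the maximal stimulation 1.  The effective stimulus is
#' used wherever the systemic signal regulates cell properties, for
#' wildtype and mutated clones alike.
#'
#' @param s_endo endogenous systemic signal in (0, 1].
#' @param C plasma concentration >= 0.
#' @param gamma potency (stimulus per concentration unit).
#' @return effective stimulus in (0, 1].
#' @export
stimulus_coupling <- function(s_endo, C, gamma) {
  if (any(C < 0)) stop("plasma concentration must be >= 0", call. = FALSE)
  pmin(1, s_endo + gamma * C)
}
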