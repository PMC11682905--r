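#' CHIP-driven systemic inflammation parameters
#'
#' Mutated mature cells can secrete pro-inflammatory mediators.  The
#' mediators are assumed short-lived and degraded cell-independently, so a
#' quasi-steady-state approximation gives the systemic inflammatory burden
#' as a linear function of the mutated mature cell concentration,
#' `I = B0 + alpha * c_mut` (see [inflammatory_burden()]); `B0` is a
#' CHIP-independent host baseline (e.g. inflammaging or atherosclerosis).
#' The impact on cell kinetics saturates via a first-order Hill function
#' `e = I / (I + theta)` (see [inflammation_effect()]).
#'
#' Two coupling modes are supported:
#'
#' * `"mutant_boost"`: the burden confers a growth advantage to clones
#'   with `infl_responsive = TRUE`; their HSC self-renewal, proliferation
#'   and HPC amplification terms are multiplied by
#'   `1 - disadvantage_delta + lambda_x * e` (clipped to valid ranges).
#'   A positive `disadvantage_delta` encodes a fitness deficit of the
#'   clone in the absence of inflammation, so such clones decline in
#'   low-burden hosts and expand in high-burden hosts.  Wildtype cells are
#'   unaffected.
#' * `"wildtype_exhaustion"`: the burden exhausts wildtype cells; wildtype
#'   HSC self-renewal and HPC amplification are multiplied by
#'   `1 - mu_x * e`.  Optionally (`mu_prolif > 0`) wildtype proliferation
#'   is additionally increased by `1 + mu_prolif * e`, which accelerates
#'   the exhaustion dynamics.
#'
#' Burden units are arbitrary; `hill_theta` normalizes them.
#'
#' @param mode `"off"`, `"mutant_boost"` or `"wildtype_exhaustion"`.
#' @param host_baseline CHIP-independent burden B0 >= 0 of the individual
#'   carrying the cells (donor or recipient), constant in time.
#' @param hill_theta half-saturation burden theta > 0.
#' @param lambda_selfrenewal,lambda_prolif,lambda_amplification effect
#'   magnitudes >= 0 for the mutant-boost mode.
#' @param mu_selfrenewal,mu_amplification exhaustion magnitudes in
#'   \[0, 1\] for the wildtype-exhaustion mode.
#' @param mu_prolif optional wildtype proliferation boost (>= 0, default
#'   0 = off) in the exhaustion mode.
#' @param disadvantage_delta fitness deficit >= 0 of responsive clones in
#'   the absence of inflammation.
#' @return object of class `inflammation_params`.
#' @export
inflammation_params <- function(mode = c("off", "mutant_boost",
                                         "wildtype_exhaustion"),
                                host_baseline = 0,
                                hill_theta = 1,
                                lambda_selfrenewal = 0,
                                lambda_prolif = 0,
                                lambda_amplification = 0,
                                mu_selfrenewal = 0,
                                mu_amplification = 0,
                                mu_prolif = 0,
                                disadvantage_delta = 0) {
  mode <- match.arg(mode)
  stopifnot(host_baseline >= 0, hill_theta > 0,
            lambda_selfrenewal >= 0, lambda_prolif >= 0,
            lambda_amplification >= 0,
            mu_selfrenewal >= 0, mu_selfrenewal <= 1,
            mu_amplification >= 0, mu_amplification <= 1,
            mu_prolif >= 0, disadvantage_delta >= 0)
  obj <- list(mode = mode, host_baseline = host_baseline,
              hill_theta = hill_theta,
              lambda_selfrenewal = lambda_selfrenewal,
              lambda_prolif = lambda_prolif,
              lambda_amplification = lambda_amplification,
              mu_selfrenewal = mu_selfrenewal,
              mu_amplification = mu_amplification,
              mu_prolif = mu_prolif,
              disadvantage_delta = disadvantage_delta)
  class(obj) <- "inflammation_params"
  obj
}

#' Quasi-steady-state systemic inflammatory burden
#'
#' `I = B0 + alpha * c_mut_mature`: the steady state of linear mediator
#' production by mutated mature cells and first-order decay, plus the
#' host's CHIP-independent baseline.
#'
#' @param c_mut_mature concentration of mediator-producing (mutated)
#'   mature cells, cells/kg; the per-cell production coefficients alpha
#'   live on the clone specs ([clone_spec()] field `infl_production`),
#'   `alpha` here is their aggregate contribution
#'   `sum(alpha_j * c_j)` when called with a single pooled value.
#' @param params an [inflammation_params()] object.
#' @param alpha per-cell production coefficient (burden per cells/kg).
#' @return burden I >= 0 (arbitrary units).
#' @export
inflammatory_burden <- function(c_mut_mature, params, alpha = 0) {
  if (any(c_mut_mature < 0)) stop("cell counts must be >= 0", call. = FALSE)
  params$host_baseline + alpha * c_mut_mature
}

#' Saturating effect of the inflammatory burden
#'
#' First-order Hill function `e = I / (I + theta)`; 0 at zero burden,
#' approaching 1 for burdens far above the half-saturation theta.
#'
#' @param I burden >= 0.
#' @param theta half-saturation burden > 0.
#' @return effect in \[0, 1).
#' @export
inflammation_effect <- function(I, theta) {
  if (any(I < 0) || theta <= 0)
    stop("I must be >= 0 and theta > 0", call. = FALSE)
  I / (I + theta)
}

# Coupling factors applied to a clone's rate schedule given effect e.
# Returns multiplicative factors for (selfrenewal_hsc, prolif, amplification).
# For non-responsive clones in mutant_boost mode, and for all mutant clones
# in wildtype_exhaustion mode, all factors are 1.
inflammation_factors <- function(ip, e, is_wildtype, responsive) {
  f <- c(selfrenewal = 1, prolif = 1, amplification = 1)
  if (ip$mode == "off") return(f)
  if (ip$mode == "mutant_boost") {
    if (!is_wildtype && responsive) {
      base <- 1 - ip$disadvantage_delta
      f["selfrenewal"] <- max(0, base + ip$lambda_selfrenewal * e)
      f["prolif"] <- max(0, base + ip$lambda_prolif * e)
      f["amplification"] <- max(0, base + ip$lambda_amplification * e)
    }
  } else { # wildtype_exhaustion
    if (is_wildtype) {
      f["selfrenewal"] <- max(0, 1 - ip$mu_selfrenewal * e)
      f["amplification"] <- max(0, 1 - ip$mu_amplification * e)
      f["prolif"] <- 1 + ip$mu_prolif * e
    }
  }
  f
}

#' Apply inflammation coupling to a rate schedule
#'
#' Modifies a clone's per-stage rate schedule (as returned by
#' [regulated_rates()]) according to the inflammation mode and the current
#' saturated effect `e`.  The coupling composes after the feedback-signal
#' evaluation, so the homeostatic calibration is unaffected when the mode
#' is `"off"`.  Self-renewal probabilities are clipped to \[0, 1\] after
#' modification.
#'
#' @param rates list with components `p` and `a` (length `n_stages + 1`,
#'   HSC first).
#' @param e saturated inflammatory effect in \[0, 1).
#' @param params an [inflammation_params()] object.
#' @param is_wildtype logical; is this the wildtype clone?
#' @param responsive logical; does this clone respond to the burden?
#' @return modified rates list.
#' @export
apply_inflammation <- function(rates, e, params, is_wildtype = FALSE,
                               responsive = TRUE) {
  f <- inflammation_factors(params, e, is_wildtype, responsive)
  p <- rates$p * f["prolif"]
  a <- rates$a
  a[1] <- a[1] * f["selfrenewal"]
  if (length(a) > 1)
    a[-1] <- a[-1] * f["amplification"]
  a <- pmin(pmax(a, 0), 1)
  if (any(p <= 0))
    stop("configuration error: inflammation coupling drove a proliferation ",
         "rate to <= 0", call. = FALSE)
  list(p = unname(p), a = unname(a))
}
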