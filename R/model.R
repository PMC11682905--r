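#' Assemble a multi-clone hematopoiesis model
#'
#' Bundles calibrated wildtype parameters, the clone set, the inflammation
#' coupling and the growth-factor pharmacokinetics into one simulation
#' object.  Clone 0 is always wildtype; `clones` lists the mutant clones
#' (possibly none).
#'
#' @param params a [chip_params()] object (calibrated automatically if
#'   not yet calibrated).
#' @param clones list of mutant [clone_spec()] objects.
#' @param inflammation an [inflammation_params()] object; the
#'   `host_baseline` describes the individual being simulated.
#' @param pk a [pk_params()] object with scheduled doses, or `NULL` for no
#'   growth-factor support.
#' @param wildtype optional [clone_spec()] for the wildtype clone (used
#'   for its homing fractions); defaults to all-neutral.
#' @return object of class `chip_model`.
#' @examples
#' m <- chip_model(chip_params())
#' m
#' @export
chip_model <- function(params = chip_params(), clones = list(),
                       inflammation = inflammation_params(),
                       pk = NULL, wildtype = NULL) {
  stopifnot(inherits(params, "chip_params"))
  if (!isTRUE(params$calibrated))
    params <- calibrate_homeostasis(params)$params
  if (inherits(clones, "clone_spec")) clones <- list(clones)
  stopifnot(all(vapply(clones, inherits, logical(1), "clone_spec")))
  stopifnot(inherits(inflammation, "inflammation_params"))
  if (!is.null(pk)) stopifnot(inherits(pk, "pk_params"))
  if (is.null(wildtype)) wildtype <- wildtype_clone()
  obj <- list(params = params,
              clones = c(list(wildtype), clones),
              inflammation = inflammation,
              pk = pk)
  class(obj) <- "chip_model"
  obj
}

#' @export
print.chip_model <- function(x, ...) {
  cat("Multi-clone hematopoiesis model\n")
  cat(sprintf("  %d clone(s): %s\n", length(x$clones),
              paste(vapply(x$clones, `[[`, "", "clone_id"), collapse = ", ")))
  cat(sprintf("  feedback variant: %s; inflammation mode: %s; growth factor: %s\n",
              x$params$variant, x$inflammation$mode,
              if (is.null(x$pk) || !length(x$pk$dose_times)) "none"
              else paste0(length(x$pk$dose_times), " dose(s)")))
  invisible(x)
}

n_compartments <- function(params) params$n_stages + 2L

# Precompute per-clone constant vectors used in the RHS.
prepare_model <- function(model) {
  p <- model$params
  n <- p$n_stages
  cl <- model$clones
  J <- length(cl)
  list(
    n = n, J = J,
    mult_p = t(vapply(cl, function(c)
      c(c$mult_prolif_hsc, rep(c$mult_prolif_hpc, n)), numeric(n + 1))),
    a_max_eff = t(vapply(cl, function(c)
      p$a_max_vec * c(c$mult_selfrenewal_hsc,
                      rep(c$mult_selfrenewal_hpc, n)), numeric(n + 1))),
    d = p$d_mature * vapply(cl, `[[`, numeric(1), "mult_clearance"),
    sens_hsc = vapply(cl, `[[`, numeric(1), "sens_hsc"),
    sens_hpc = vapply(cl, `[[`, numeric(1), "sens_hpc"),
    alpha = vapply(cl, `[[`, numeric(1), "infl_production"),
    responsive = vapply(cl, `[[`, logical(1), "infl_responsive"),
    is_wt = seq_len(J) == 1L
  )
}

# Time derivative of the flattened state (deSolve interface).
# State layout: J x (n+2) matrix flattened column-major
# (clones vary fastest within a compartment).
chip_rhs <- function(t, y, parms) {
  model <- parms$model; pre <- parms$pre
  p <- model$params
  n <- pre$n; J <- pre$J
  if (any(!is.finite(y)))
    stop("integration error: non-finite state encountered", call. = FALSE)
  u <- matrix(y, nrow = J)
  u_pos <- pmax(u, 0)
  M <- sum(u_pos[, n + 2])
  H <- sum(u_pos[, 1])
  s_sys <- feedback_signal(M, p$k_sys)      # HSC self-renewal loop
  s_p <- feedback_signal(M, p$k_p)          # proliferation loop
  s_amp <- feedback_signal(M, p$k_amp)      # HPC amplification loop
  s_niche <- feedback_signal(H, p$k_niche)
  if (!is.null(model$pk) && length(model$pk$dose_times)) {
    C <- plasma_concentration(t, model$pk)
    s_sys <- stimulus_coupling(s_sys, C, model$pk$gamma)
    s_p <- stimulus_coupling(s_p, C, model$pk$gamma)
    s_amp <- stimulus_coupling(s_amp, C, model$pk$gamma)
  }
  ip <- model$inflammation
  e <- 0
  if (ip$mode != "off") {
    I <- ip$host_baseline + sum(pre$alpha * u_pos[, n + 2])
    e <- inflammation_effect(I, ip$hill_theta)
  }
  # which raw signal regulates which property class
  sig_sr_hsc_raw <- if (p$variant == "baseline") s_sys else s_niche
  sig_p_hsc_raw <- if (p$variant == "niche_selfrenewal_proliferation")
    feedback_signal(H, p$k_p_niche) else s_p
  du <- matrix(0, nrow = J, ncol = n + 2)
  for (j in seq_len(J)) {
    # clone-specific aberrant sensitivity, per property class and loop
    s_hsc_sr <- mutant_signal(sig_sr_hsc_raw, p$s_star, pre$sens_hsc[j])
    s_hsc_p <- mutant_signal(sig_p_hsc_raw, p$s_p_star, pre$sens_hsc[j])
    s_hpc_p <- mutant_signal(s_p, p$s_p_star, pre$sens_hpc[j])
    s_hpc_a <- mutant_signal(s_amp, p$s_amp_star, pre$sens_hpc[j])
    g <- prolif_response(c(s_hsc_p, s_hpc_p), p$s_p_star, p$prolif_fold_max,
                         p$prolif_floor)
    pr <- p$p_hom * c(g[1], rep(g[2], n)) * pre$mult_p[j, ]
    a <- pre$a_max_eff[j, ] * c(s_hsc_sr, rep(s_hpc_a, n))
    a <- pmin(pmax(a, 0), 1)
    if (ip$mode != "off") {
      f <- inflammation_factors(ip, e, pre$is_wt[j], pre$responsive[j])
      pr <- pr * f[["prolif"]]
      a[1] <- min(1, a[1] * f[["selfrenewal"]])
      a[-1] <- pmin(1, a[-1] * f[["amplification"]])
    }
    uj <- u_pos[j, ]
    self <- (2 * a - 1) * pr * uj[1:(n + 1)]
    influx <- c(0, 2 * (1 - a[1:n]) * pr[1:n] * uj[1:n])
    du[j, 1:(n + 1)] <- self + influx
    du[j, n + 2] <- 2 * (1 - a[n + 1]) * pr[n + 1] * uj[n + 1] -
      pre$d[j] * uj[n + 2]
  }
  list(as.vector(du))
}

#' Simulate the model forward in time
#'
#' Integrates the stiff ODE system with `deSolve::ode` (lsoda) from a
#' given initial state and returns the trajectory on a uniform output
#' grid.  Small negative concentrations (within `100 * atol` of zero,
#' an inevitable consequence of finite solver tolerances) are clipped to
#' zero; larger negativity raises an integration error.
#'
#' @param model a [chip_model()] object.
#' @param init initial state: matrix with one row per clone (wildtype
#'   first) and `n_stages + 2` columns (HSC, HPC stages, mature), cells/kg.
#'   Defaults to the calibrated homeostatic state held entirely by the
#'   wildtype clone.
#' @param horizon simulation horizon, days.
#' @param dt output grid spacing, days (default 1).
#' @param rtol,atol relative / absolute solver tolerances (defaults 1e-6
#'   and 1e-3 cells/kg).
#' @return object of class `chip_trajectory`: times, a
#'   `time x clone x compartment` concentration array, the inflammatory
#'   burden series, and the model.
#' @export
simulate_dynamics <- function(model, init = NULL, horizon = 365,
                              dt = 1, rtol = 1e-6, atol = 1e-3) {
  stopifnot(inherits(model, "chip_model"), horizon > 0)
  p <- model$params
  J <- length(model$clones)
  nc <- n_compartments(p)
  if (is.null(init)) {
    if (J != 1L)
      stop("default (homeostatic) init is only available for the ",
           "single-clone model; supply an init matrix", call. = FALSE)
    init <- matrix(p$u_star, nrow = 1)
  }
  init <- as.matrix(init)
  if (nrow(init) != J || ncol(init) != nc)
    stop(sprintf("init must be a %d x %d matrix (clones x compartments)",
                 J, nc), call. = FALSE)
  if (any(init < 0)) stop("initial state must be nonnegative", call. = FALSE)
  times <- seq(0, horizon, by = dt)
  if (times[length(times)] < horizon) times <- c(times, horizon)
  if (!is.null(model$pk))
    times <- sort(unique(c(times,
      model$pk$dose_times[model$pk$dose_times <= horizon])))
  pre <- prepare_model(model)
  sol <- deSolve::ode(y = as.vector(init), times = times, func = chip_rhs,
                      parms = list(model = model, pre = pre),
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0)
    stop("integration error: solver failed (istate ",
         attr(sol, "istate")[1], ")", call. = FALSE)
  y <- sol[, -1, drop = FALSE]
  neg <- y < 0
  if (any(y < -100 * atol))
    stop(sprintf("integration error: negative concentration %.3g beyond ",
                 min(y)), "tolerance", call. = FALSE)
  y[neg] <- 0
  arr <- array(y, dim = c(nrow(y), J, nc),
               dimnames = list(NULL,
                               vapply(model$clones, `[[`, "", "clone_id"),
                               compartment_names(p$n_stages)))
  burden <- NULL
  if (model$inflammation$mode != "off") {
    mut_mat <- arr[, , nc, drop = FALSE]
    dim(mut_mat) <- c(nrow(y), J)
    burden <- model$inflammation$host_baseline +
      as.vector(mut_mat %*% pre$alpha)
  }
  out <- list(times = sol[, 1], u = arr, burden = burden, model = model)
  class(out) <- "chip_trajectory"
  out
}

#' @export
print.chip_trajectory <- function(x, ...) {
  cat(sprintf("Hematopoiesis trajectory: %d time points over %.1f days, %d clone(s)\n",
              length(x$times), max(x$times), dim(x$u)[2]))
  M <- mature_series(x)
  cat(sprintf("  mature neutrophils: %.3g -> %.3g cells/kg\n",
              M[1], M[length(M)]))
  invisible(x)
}

#' Trajectory accessors
#'
#' `mature_series()` returns the total (or per-clone) circulating mature
#' neutrophil concentration; `hsc_series()` the HSC concentration;
#' `vaf_series()` the peripheral-blood VAF time course of a mutant clone
#' (and `vaf_series(..., compartment = "hsc")` the VAF in the stem cell
#' compartment).
#'
#' @param traj a `chip_trajectory`.
#' @param by_clone return a matrix with one column per clone instead of
#'   the clone-summed total.
#' @return numeric vector (or matrix) along `traj$times`.
#' @export
mature_series <- function(traj, by_clone = FALSE) {
  nc <- dim(traj$u)[3]
  m <- traj$u[, , nc, drop = FALSE]
  dim(m) <- dim(traj$u)[1:2]
  colnames(m) <- dimnames(traj$u)[[2]]
  if (by_clone) m else rowSums(m)
}

#' @rdname mature_series
#' @export
hsc_series <- function(traj, by_clone = FALSE) {
  m <- traj$u[, , 1, drop = FALSE]
  dim(m) <- dim(traj$u)[1:2]
  colnames(m) <- dimnames(traj$u)[[2]]
  if (by_clone) m else rowSums(m)
}

#' @rdname mature_series
#' @param clone clone index (>= 2; clone 1 is wildtype) or clone id.
#' @param compartment `"mature"` (peripheral blood) or `"hsc"`.
#' @export
vaf_series <- function(traj, clone = 2L, compartment = c("mature", "hsc")) {
  compartment <- match.arg(compartment)
  if (is.character(clone))
    clone <- match(clone, dimnames(traj$u)[[2]])
  if (is.na(clone) || clone < 2 || clone > dim(traj$u)[2])
    stop("clone must identify a mutant clone", call. = FALSE)
  idx <- if (compartment == "mature") dim(traj$u)[3] else 1L
  cm <- traj$u[, clone, idx]
  cw <- rowSums(traj$u[, -clone, idx, drop = FALSE])
  zyg <- traj$model$clones[[clone]]$zygosity
  f <- cm / pmax(cm + cw, .Machine$double.xmin)
  if (zyg == "heterozygous") f / 2 else f
}

#' @export
plot.chip_trajectory <- function(x, what = c("mature", "vaf"), clone = 2L,
                                 ...) {
  what <- match.arg(what)
  if (what == "mature") {
    per_l <- mature_series(x) * 80 / 5  # cells per litre of blood
    graphics::plot(x$times, per_l, type = "l", log = "y",
                   xlab = "days since transplantation",
                   ylab = "neutrophils per litre", ...)
    graphics::abline(h = 5e8, lty = 2)
  } else {
    graphics::plot(x$times, vaf_series(x, clone = clone), type = "l",
                   xlab = "days since transplantation", ylab = "PB VAF", ...)
  }
  invisible(x)
}

#' Time to neutrophil engraftment
#'
#' First time the total circulating neutrophil concentration crosses the
#' engraftment threshold from below, located by linear interpolation
#' between output grid points.  The threshold is given per litre of blood
#' and converted to cells/kg with the blood-volume convention (default
#' 5 l of blood for an 80 kg body, so 5e8/l corresponds to 3.125e7/kg).
#'
#' @param traj a `chip_trajectory`.
#' @param threshold_per_l engraftment threshold, cells per litre (default
#'   5e8).
#' @param blood_l litres of blood (default 5).
#' @param body_kg body weight in kg (default 80).
#' @return days to engraftment; 0 if already engrafted at the start;
#'   `NA_real_` if the threshold is never reached within the trajectory.
#' @export
engraftment_time <- function(traj, threshold_per_l = 5e8,
                             blood_l = 5, body_kg = 80) {
  stopifnot(inherits(traj, "chip_trajectory"))
  if (length(traj$times) < 2)
    stop("trajectory is empty or too short", call. = FALSE)
  thr <- threshold_per_l * blood_l / body_kg
  M <- mature_series(traj)
  if (M[1] >= thr) return(0)
  above <- which(M >= thr)
  if (!length(above)) return(NA_real_)
  i <- above[1]
  t0 <- traj$times[i - 1]; t1 <- traj$times[i]
  m0 <- M[i - 1]; m1 <- M[i]
  t0 + (thr - m0) / (m1 - m0) * (t1 - t0)
}
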