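#' Specification of a hematopoietic clone
#'
#' Describes how one clone deviates from wildtype cell kinetics.  Mutant
#' effects are represented as (i) multiplicative modifications of the cell
#' parameters (proliferation rates, self-renewal, mature-cell clearance),
#' (ii) an aberrant sensitivity to perturbations of the feedback signals,
#' (iii) clone-specific homing fractions, and (iv) optional coupling to the
#' systemic inflammatory burden (see [inflammation_params()]).
#'
#' Self-renewal multipliers act on the maximal self-renewal probability;
#' the evaluated probability is clipped to `[0, 1]`, so a multiplier above
#' 1 raises the homeostatic mutant self-renewal above the wildtype value
#' of 1/2 and produces net clonal growth (persistent expansion).
#'
#' Sensitivity factors `sens_hsc`/`sens_hpc` steepen the response to
#' signal deviations around the homeostatic point: the clone experiences
#' the transformed signal `s* + sigma * (s - s*)` (see [mutant_signal()]).
#' At homeostasis (`s = s*`) mutant and wildtype kinetics coincide for any
#' sigma, so such clones expand only under hematopoietic stress.
#'
#' @param clone_id label; `"wildtype"` is reserved for clone 0.
#' @param mult_prolif_hsc,mult_prolif_hpc multiplicative factors (> 0) on
#'   HSC / HPC proliferation rates.
#' @param mult_selfrenewal_hsc,mult_selfrenewal_hpc multiplicative factors
#'   on maximal self-renewal (evaluated probability clipped to 1).
#' @param mult_clearance factor on the mature-cell clearance rate.
#' @param sens_hsc,sens_hpc signal-sensitivity factors sigma >= 0
#'   (1 = wildtype response).
#' @param homing_hsc,homing_hpc fractions in \[0, 1\] of transplanted cells
#'   of this clone that home to the marrow.
#' @param zygosity `"heterozygous"` (default) or `"homozygous"`; used by
#'   [vaf()] and by the graft arithmetic.
#' @param infl_production per-cell contribution of this clone's mature
#'   cells to the systemic inflammatory burden (alpha >= 0); 0 for clones
#'   that do not secrete pro-inflammatory mediators.
#' @param infl_responsive logical; whether this clone's kinetics respond to
#'   the inflammatory burden (mutant-boost mode) or, for the wildtype
#'   clone, are exhausted by it (wildtype-exhaustion mode).
#' @return an object of class `clone_spec`.
#' @export
clone_spec <- function(clone_id = "mutant",
                       mult_prolif_hsc = 1, mult_prolif_hpc = 1,
                       mult_selfrenewal_hsc = 1, mult_selfrenewal_hpc = 1,
                       mult_clearance = 1,
                       sens_hsc = 1, sens_hpc = 1,
                       homing_hsc = 0.5, homing_hpc = 0.5,
                       zygosity = c("heterozygous", "homozygous"),
                       infl_production = 0,
                       infl_responsive = TRUE) {
  zygosity <- match.arg(zygosity)
  num <- c(mult_prolif_hsc, mult_prolif_hpc, mult_selfrenewal_hsc,
           mult_selfrenewal_hpc, mult_clearance)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("clone multipliers must be finite and > 0", call. = FALSE)
  if (sens_hsc < 0 || sens_hpc < 0)
    stop("sensitivity factors must be >= 0", call. = FALSE)
  if (homing_hsc < 0 || homing_hsc > 1 || homing_hpc < 0 || homing_hpc > 1)
    stop("homing fractions must lie in [0, 1]", call. = FALSE)
  obj <- list(clone_id = clone_id,
              mult_prolif_hsc = mult_prolif_hsc,
              mult_prolif_hpc = mult_prolif_hpc,
              mult_selfrenewal_hsc = mult_selfrenewal_hsc,
              mult_selfrenewal_hpc = mult_selfrenewal_hpc,
              mult_clearance = mult_clearance,
              sens_hsc = sens_hsc, sens_hpc = sens_hpc,
              homing_hsc = homing_hsc, homing_hpc = homing_hpc,
              zygosity = zygosity,
              infl_production = infl_production,
              infl_responsive = infl_responsive)
  class(obj) <- "clone_spec"
  obj
}

#' @export
print.clone_spec <- function(x, ...) {
  cat(sprintf("clone '%s' (%s)\n", x$clone_id, x$zygosity))
  cat(sprintf("  prolif x(%.3g, %.3g)  selfren x(%.3g, %.3g)  clear x%.3g\n",
              x$mult_prolif_hsc, x$mult_prolif_hpc,
              x$mult_selfrenewal_hsc, x$mult_selfrenewal_hpc,
              x$mult_clearance))
  cat(sprintf("  sensitivity (HSC %.3g, HPC %.3g); homing (HSC %.2g, HPC %.2g)\n",
              x$sens_hsc, x$sens_hpc, x$homing_hsc, x$homing_hpc))
  if (x$infl_production > 0)
    cat(sprintf("  inflammatory production alpha = %.3g per mature cell/kg\n",
                x$infl_production))
  invisible(x)
}

wildtype_clone <- function() clone_spec(clone_id = "wildtype")

#' Aberrant signal sensitivity of mutated cells
#'
#' Mutated cells can respond more sensitively than wildtype cells to
#' perturbations of the feedback signals: the signal experienced by the
#' clone is the linear amplification of the deviation around the
#' homeostatic point, `s_star + sigma * (s - s_star)`, clipped to the
#' valid signal range (0, 1].  For `s = s_star` the transformed signal
#' equals `s_star` for any sigma, so mutant and wildtype kinetics are
#' identical at homeostasis.
#'
#' @param s observed signal in (0, 1].
#' @param s_star homeostatic signal value in (0, 1).
#' @param sigma sensitivity factor >= 0 (1 = wildtype).
#' @return transformed signal in (0, 1].
#' @export
mutant_signal <- function(s, s_star, sigma) {
  if (any(sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  if (any(s <= 0) || any(s > 1) || s_star <= 0 || s_star >= 1)
    stop("signals must lie in (0, 1]", call. = FALSE)
  pmin(pmax(s_star + sigma * (s - s_star), .Machine$double.eps), 1)
}

#' @rdname mutant_signal
#' @param base_response function of the signal (a rate or probability
#'   response); `mutant_response()` evaluates it at the transformed signal.
#' @export
mutant_response <- function(s, s_star, sigma, base_response) {
  base_response(mutant_signal(s, s_star, sigma))
}

#' Variant allele frequency of a clone in peripheral blood
#'
#' `VAF = c_mut / (c_wt + c_mut) / 2` for a heterozygous mutation (every
#' mutated cell carries one mutated and one wildtype allele); the factor
#' 1/2 is dropped for homozygous mutations.  The maximal heterozygous VAF
#' is 0.5, attained when all circulating neutrophils carry the mutation.
#'
#' @param c_mut_mature mutated mature cell concentration, cells/kg.
#' @param c_wt_mature wildtype mature cell concentration, cells/kg.
#' @param zygosity `"heterozygous"` or `"homozygous"`.
#' @return VAF in \[0, 0.5\] (heterozygous) or \[0, 1\] (homozygous).
#' @examples
#' vaf(1e8, 0)    # 0.5: all neutrophils mutated, heterozygous
#' vaf(1e8, 1e8)  # 0.25
#' @export
vaf <- function(c_mut_mature, c_wt_mature,
                zygosity = c("heterozygous", "homozygous")) {
  zygosity <- match.arg(zygosity)
  if (any(c_mut_mature < 0) || any(c_wt_mature < 0))
    stop("cell concentrations must be >= 0", call. = FALSE)
  tot <- c_mut_mature + c_wt_mature
  if (any(tot == 0))
    stop("VAF undefined: no mature cells", call. = FALSE)
  f <- c_mut_mature / tot
  if (zygosity == "heterozygous") f / 2 else f
}

#' Classify the post-transplant VAF trajectory pattern
#'
#' Rule-based classification of a recipient VAF time course into the
#' patterns observed after transplantation:
#'
#' * `"none"`: the VAF stays within `tol_none` of the donor VAF throughout;
#' * `"persistent"`: the mean VAF slope over years 2-5 exceeds
#'   `slope_persistent` (VAF per year);
#' * `"transient"`: the VAF rose clearly above the donor value and has
#'   returned at least half-way back towards it (or matches no other
#'   rule);
#' * `"saturated"`: the trajectory plateaus (late slope below
#'   `plateau_frac` of the maximal early slope) at a level above the donor
#'   VAF.
#'
#' @param times trajectory times, days.
#' @param vafs VAF values at `times`.
#' @param donor_vaf VAF in the donor's peripheral blood at donation.
#' @param tol_none absolute VAF tolerance for "no expansion" (default 0.005).
#' @param slope_persistent late-window slope threshold, VAF/year (default
#'   0.005).
#' @param plateau_frac late/early slope ratio below which the trajectory
#'   counts as plateaued (default 0.1).
#' @param settle_days initial window excluded from classification (default
#'   30): while the mature compartment refills after transplantation the
#'   PB VAF is dominated by the engraftment transient.
#' @return one of `"saturated"`, `"persistent"`, `"transient"`, `"none"`.
#' @export
classify_pattern <- function(times, vafs, donor_vaf,
                             tol_none = 0.005,
                             slope_persistent = 0.005,
                             plateau_frac = 0.1,
                             settle_days = 30) {
  stopifnot(length(times) == length(vafs), length(times) > 2)
  if (max(times) < 2 * 365.25)
    stop("trajectory must cover at least 2 years", call. = FALSE)
  keep <- times >= settle_days
  times <- times[keep]; vafs <- vafs[keep]
  if (max(abs(vafs - donor_vaf)) < tol_none) return("none")
  # late-window slope (years 2 .. min(5, horizon)), VAF per year
  t_hi <- min(max(times), 5 * 365.25)
  late <- times >= 2 * 365.25 & times <= t_hi
  slope_late <- stats::coef(stats::lm(vafs[late] ~ times[late]))[2] * 365.25
  if (is.finite(slope_late) && slope_late > slope_persistent)
    return("persistent")
  # maximal early slope (first 100 days), VAF per year
  early <- times <= 100
  d_early <- diff(vafs[early]) / diff(times[early]) * 365.25
  slope_early_max <- max(abs(d_early))
  final <- vafs[length(vafs)]
  # transient: rose clearly above the donor VAF, has returned at least
  # half-way back towards it and is still declining (an early overshoot
  # that settles at an elevated plateau counts as saturated instead)
  peak <- max(vafs)
  if (peak > donor_vaf + tol_none &&
      final < peak - 0.5 * (peak - donor_vaf) &&
      slope_late < 0) return("transient")
  plateaued <- abs(slope_late) < plateau_frac * slope_early_max
  if (plateaued && final > donor_vaf + tol_none) return("saturated")
  "transient"
}

#' Donor and recipient clonal expansion metrics
#'
#' Computes the expansion summary used to relate donor and recipient
#' clonal dynamics: the recipient VAF at 100 days and 1 year after
#' transplantation, the absolute transplant-related expansion
#' `delta_R_100d` (recipient VAF at day 100 minus donor VAF at donation),
#' the relative expansion `pi_R_100d` (their ratio), and the pre-donation
#' expansion in the donor, `delta_D_1y` (donor VAF at donation minus donor
#' VAF one year prior) and `pi_D_1y` (their ratio).  Values at the exact
#' horizons are obtained by linear interpolation on the trajectory grid.
#'
#' @param donor_times,donor_vafs donor VAF time course (days; time of
#'   donation = `donation_time`), covering at least one year before
#'   donation.
#' @param recipient_times,recipient_vafs recipient VAF time course, days
#'   since transplantation, covering at least one year.
#' @param donation_time time of donation on the donor clock, days.
#' @return object of class `expansion_metrics` (a named list).
#' @export
expansion_metrics <- function(donor_times, donor_vafs,
                              recipient_times, recipient_vafs,
                              donation_time = max(donor_times)) {
  yr <- 365.25
  if (min(donor_times) > donation_time - yr ||
      max(donor_times) < donation_time - 1e-9)
    stop("donor trajectory must cover the donation time and >= 1 year ",
         "before it", call. = FALSE)
  if (max(recipient_times) < yr)
    stop("recipient trajectory must cover >= 1 year", call. = FALSE)
  d_at <- function(t) stats::approx(donor_times, donor_vafs, xout = t,
                                    rule = 2)$y
  r_at <- function(t) stats::approx(recipient_times, recipient_vafs,
                                    xout = t, rule = 2)$y
  vaf_donor <- d_at(donation_time)
  vaf_prior <- d_at(donation_time - yr)
  vaf_100d <- r_at(100)
  vaf_1y <- r_at(yr)
  out <- list(
    vaf_donor = vaf_donor,
    vaf_100d = vaf_100d,
    vaf_1y = vaf_1y,
    delta_R_100d = vaf_100d - vaf_donor,
    pi_R_100d = if (vaf_donor > 0) vaf_100d / vaf_donor else NA_real_,
    delta_D_1y = vaf_donor - vaf_prior,
    pi_D_1y = if (vaf_prior > 0) vaf_donor / vaf_prior else NA_real_
  )
  class(out) <- "expansion_metrics"
  out
}

#' @export
print.expansion_metrics <- function(x, ...) {
  cat("Clonal expansion metrics\n")
  cat(sprintf("  donor VAF %.4f  ->  recipient VAF 100d %.4f, 1y %.4f\n",
              x$vaf_donor, x$vaf_100d, x$vaf_1y))
  cat(sprintf("  delta_R,100d = %+.4f   pi_R,100d = %.3f\n",
              x$delta_R_100d, x$pi_R_100d))
  cat(sprintf("  delta_D,1y   = %+.4f   pi_D,1y   = %.3f\n",
              x$delta_D_1y, x$pi_D_1y))
  invisible(x)
}
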