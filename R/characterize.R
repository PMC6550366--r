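#' Construct a fluorophore calibration
#'
#' Linear calibration converting released 4-methylumbelliferone (MU)
#' concentration to fluorescence: `RFU = slope * conc + intercept`.
#'
#' @param slope RFU per uM MU; must be > 0.
#' @param intercept RFU at zero product.
#' @param buffer_id Optional buffer label (calibrations are buffer-specific).
#' @return A `calibration` object.
#' @export
calibration <- function(slope, intercept = 0, buffer_id = NA_character_) {
  if (!is.numeric(slope) || slope <= 0)
    stop("calibration slope must be > 0", call. = FALSE)
  cal <- list(slope = slope, intercept = intercept, buffer_id = buffer_id)
  class(cal) <- "calibration"
  cal
}

#' Fit an MU calibration curve
#'
#' Ordinary least-squares line through standard points of known MU
#' concentration measured in the assay buffer.
#'
#' @param mu_conc MU concentrations (uM); >= 3 points, >= 2 distinct values.
#' @param rfu Measured fluorescence (RFU).
#' @param buffer_id Optional buffer label.
#' @return A [calibration()] object.
#' @export
fit_calibration <- function(mu_conc, rfu, buffer_id = NA_character_) {
  if (length(mu_conc) < 3 || length(rfu) != length(mu_conc))
    stop("calibration requires >= 3 (conc, rfu) points", call. = FALSE)
  if (length(unique(mu_conc)) < 2)
    stop("calibration requires >= 2 distinct concentrations", call. = FALSE)
  fit <- stats::lm(rfu ~ mu_conc)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0)
    stop("fitted calibration slope is not positive; calibration unusable",
         call. = FALSE)
  calibration(slope = slope, intercept = unname(stats::coef(fit)[1]),
              buffer_id = buffer_id)
}

#' Estimate an initial rate from a time course
#'
#' Converts fluorescence to product via the calibration, keeps exactly the
#' early points with `P(t) <= 0.10 * conc0` (initial rates within 10% of
#' substrate consumption), and fits a least-squares line with free
#' intercept; the slope, converted to uM/min, is the rate. If fewer than
#' three points qualify the time course is flagged `"depleted"` rather than
#' raising an error. When the time course carries an OD600 the rate is
#' divided by it (per-cell-density normalization).
#'
#' @param tc A `timecourse` object (see [simulate_timecourse()]).
#' @param cal A [calibration()] object.
#' @param depletion_limit Fraction of `conc0` defining the initial-rate
#'   window (default 0.10).
#' @param normalize_od Divide by OD600 when available (default TRUE).
#' @return Rate in uM/min, or the character flag `"depleted"`.
#' @export
estimate_initial_rate <- function(tc, cal, depletion_limit = 0.10,
                                  normalize_od = TRUE) {
  p <- (tc$rfu - cal$intercept) / cal$slope
  keep <- p <= depletion_limit * tc$conc0
  if (sum(keep) < 3) return("depleted")
  fit <- stats::lm(p[keep] ~ tc$times[keep])
  rate <- unname(stats::coef(fit)[2]) * 60   # uM/s -> uM/min
  if (normalize_od && !is.null(tc$od600) && is.finite(tc$od600) && tc$od600 > 0)
    rate <- rate / tc$od600
  rate
}

#' Optimal substrate of a clone
#'
#' Argmax over the eight-substrate MU panel; ties broken by panel order,
#' and a clone with no measurable activity (all rates zero, missing or
#' depleted-flagged) gets the label `"none"`. Invariant under positive
#' scaling of all rates.
#'
#' @param rates Named numeric (or list) mapping panel substrate to initial
#'   rate; `"depleted"` flags and NAs are ignored.
#' @return A substrate label, or `"none"`.
#' @export
substrate_preference <- function(rates) {
  panel <- substrate_panel()
  r <- vapply(panel, function(s) {
    v <- if (s %in% names(rates)) rates[[s]] else NULL
    if (is.null(v) || !is.numeric(v) || !is.finite(v)) NA_real_ else v
  }, numeric(1))
  if (all(is.na(r)) || all(r[!is.na(r)] <= 0)) return("none")
  panel[which.max(r)]   # which.max returns the first (earliest panel) maximum
}

#' pH optimum from primary and extension buffer series
#'
#' The optimum is the grid pH with maximal velocity in the primary
#' (citrate-phosphate, pH 4-7.7) series. If that maximum sits on the top
#' grid point of the primary range the measurement is censored and the
#' glycyl-glycine extension series (pH 7-9.8) is required; the global
#' argmax over both series is then returned. Ties break towards lower pH.
#'
#' @param profile_primary data.frame with columns `ph`, `rate` (nonempty).
#' @param profile_extension Optional data.frame with the same columns.
#' @return The optimum pH (a grid point).
#' @export
ph_optimum <- function(profile_primary, profile_extension = NULL) {
  stopifnot(nrow(profile_primary) > 0)
  prim <- profile_primary[order(profile_primary$ph), , drop = FALSE]
  i <- which.max(prim$rate)   # first maximum = lowest pH on ties
  if (i < nrow(prim)) return(prim$ph[i])
  if (is.null(profile_extension) || nrow(profile_extension) == 0)
    stop("pH optimum at range boundary; extension series needed", call. = FALSE)
  both <- rbind(prim, profile_extension[, c("ph", "rate")])
  both <- both[order(both$ph), , drop = FALSE]
  both$ph[which.max(both$rate)]
}

#' Fit a two-state van't Hoff denaturation curve
#'
#' Nonlinear least-squares fit of residual activity after pre-incubation,
#' \deqn{v(T) = v_0 / (1 + \exp[(\Delta H_{vH}/R)(1/T_m - 1/T)])}
#' with temperatures in kelvin internally and `Tm` reported in degrees C.
#' Initialization is multi-start: `Tm` at each observed temperature
#' bracketing the half-maximal rate, `dH` at 100, 200 and 400 kJ/mol; the
#' best converged fit by residual sum of squares wins.
#'
#' @param thermal_curve data.frame with columns `temperature` (degrees C)
#'   and `rate`; >= 4 points spanning a rate decrease.
#' @return A list with `tm` (degrees C), `dh_vh` (kJ/mol), `v0`, `rss`, and
#'   `extrapolated` (TRUE when `tm` falls outside the grid +/- 10 C).
#' @export
fit_vant_hoff <- function(thermal_curve) {
  tc <- thermal_curve[order(thermal_curve$temperature), , drop = FALSE]
  if (nrow(tc) < 4)
    stop("van't Hoff fit requires >= 4 temperature points", call. = FALSE)
  if (max(tc$rate) <= 0 || min(tc$rate) > 0.75 * max(tc$rate))
    stop("no clear rate decrease across the temperature grid; Tm unidentifiable",
         call. = FALSE)
  half <- max(tc$rate) / 2
  below <- which(tc$rate < half)
  brack <- if (length(below) > 0) {
    unique(c(tc$temperature[min(below)],
             tc$temperature[max(1, min(below) - 1)]))
  } else stats::median(tc$temperature)
  starts <- expand.grid(tm = brack, dh = c(100, 200, 400))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        rate ~ v0 * vant_hoff_fraction(temperature, tm, dh),
        data = tc,
        start = list(v0 = max(tc$rate), tm = starts$tm[k], dh = starts$dh[k]),
        lower = c(v0 = 0, tm = -100, dh = 1),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- c(as.list(stats::coef(fit)), list(rss = rss))
  }
  if (is.null(best))
    stop("van't Hoff fit did not converge from any start", call. = FALSE)
  list(tm = best$tm, dh_vh = best$dh, v0 = best$v0, rss = best$rss,
       extrapolated = best$tm < min(tc$temperature) - 10 ||
         best$tm > max(tc$temperature) + 10)
}

#' Classify glycosidase mechanism from a 2-fluoroglycoside inhibition pair
#'
#' A retaining glycosidase forms a stable 2-deoxy-2-fluoroglycosyl enzyme
#' intermediate and is inactivated; an inverting enzyme is not. The call is
#' `retaining` when the residual/control rate ratio is below 0.5.
#'
#' @param residual_rate Rate after 2-fluoroglycoside treatment.
#' @param control_rate Rate of the paired uninhibited control; must be > 0.
#' @return A list with `mechanism` (`"retaining"` or `"inverting"`) and
#'   `ratio`.
#' @export
classify_mechanism <- function(residual_rate, control_rate) {
  if (!is.numeric(control_rate) || control_rate <= 0)
    stop("control rate must be > 0 (uninterpretable inhibition pair)",
         call. = FALSE)
  ratio <- residual_rate / control_rate
  list(mechanism = if (ratio < 0.5) "retaining" else "inverting",
       ratio = ratio)
}

#' Full plate-based characterization of one active clone
#'
#' Drives the forward models and estimators end-to-end for a simulated
#' clone: panel time courses -> initial rates -> optimal substrate; pH
#' series -> pH optimum; thermal series -> van't Hoff Tm; inactivation
#' pair -> mechanism. Convenience wrapper used by the analysis drivers and
#' recovery tests.
#'
#' @param clone An active `gh_clone`.
#' @param config A [simulation_config()] object.
#' @param cal A [calibration()] object.
#' @param conc0 Assay substrate concentration (uM; default 240).
#' @param times Sampling times (s); the default log-spaced grid keeps at
#'   least three samples inside the 10%-consumption window across the
#'   plausible activity range.
#' @param noise_sd Additive RFU noise for time courses.
#' @param series_noise Relative noise for pH/thermal/inactivation series.
#' @param ph_grid_primary,ph_grid_extension pH grids of the two buffer
#'   systems.
#' @param thermal_grid Pre-incubation temperatures (degrees C).
#' @return A list (class `activity_profile`) with `clone_id`, `rates`,
#'   `optimal_substrate`, `ph_optimum`, `tm`, `dh_vh`, `mechanism`.
#' @export
characterize_clone <- function(clone, config, cal = calibration(2, 0),
                               conc0 = 240,
                               times = c(0, 1, 2, 5, 10, 20, 50, 100, 200,
                                         500, 1000, 2000, 3600),
                               noise_sd = 0, series_noise = 0,
                               ph_grid_primary = seq(4, 7.7, by = 0.3),
                               ph_grid_extension = seq(7, 9.8, by = 0.4),
                               thermal_grid = seq(37, 90, by = 4)) {
  stopifnot(is_active(clone))
  panel <- substrate_panel()
  rates <- stats::setNames(vector("list", length(panel)), panel)
  for (s in panel) {
    tc <- simulate_timecourse(clone$enzymes, s, conc0, times, cal,
                              noise_sd = noise_sd,
                              enzyme_conc_um = config$lysate_enzyme_conc_um,
                              clone_id = clone$clone_id)
    rates[[s]] <- estimate_initial_rate(tc, cal)
  }
  opt <- substrate_preference(rates)
  lead <- clone$enzymes[[1]]
  ph_prim <- simulate_ph_series(lead, ph_grid_primary, series_noise)
  ph_ext <- simulate_ph_series(lead, ph_grid_extension, series_noise)
  opt_ph <- ph_optimum(ph_prim, ph_ext)
  therm <- simulate_thermal_series(lead, thermal_grid, series_noise)
  vh <- fit_vant_hoff(therm)
  inact <- simulate_inactivation(lead, control_rate = 1, noise = series_noise)
  mech <- classify_mechanism(inact$residual_rate, inact$control_rate)
  out <- list(clone_id = clone$clone_id, rates = rates,
              optimal_substrate = opt, ph_optimum = opt_ph,
              tm = vh$tm, dh_vh = vh$dh_vh, mechanism = mech$mechanism)
  class(out) <- "activity_profile"
  out
}
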