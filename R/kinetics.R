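#' Assemble a rate dataset for Michaelis-Menten fitting
#'
#' Initial rates of a purified enzyme measured over a substrate
#' concentration series (typical assay range 0.5 uM - 1 mM), one column per
#' replicate.
#'
#' @param conc_um Substrate concentrations (uM), positive, >= 5 distinct
#'   values.
#' @param rates Numeric matrix (or vector) of initial rates (uM/s), one
#'   column per replicate, rows matching `conc_um`.
#' @param enzyme_conc_um Enzyme concentration in the assay (uM).
#' @param substrate Optional substrate label.
#' @return A `rate_dataset` object.
#' @export
rate_dataset <- function(conc_um, rates, enzyme_conc_um,
                         substrate = NA_character_) {
  rates <- as.matrix(rates)
  if (any(conc_um <= 0)) stop("concentrations must be positive", call. = FALSE)
  if (nrow(rates) != length(conc_um))
    stop("rates must have one row per concentration", call. = FALSE)
  if (length(unique(conc_um)) < 5)
    warning("fewer than 5 distinct substrate concentrations; Km may be poorly determined")
  ds <- list(conc_um = conc_um, rates = rates,
             enzyme_conc_um = enzyme_conc_um, substrate = substrate)
  class(ds) <- "rate_dataset"
  ds
}

# single-replicate Michaelis-Menten fit; concentrations in uM, Km reported in mM
fit_mm_one <- function(conc_um, v) {
  if (all(v <= 0)) stop("all rates are zero; Michaelis-Menten fit cannot converge",
                        call. = FALSE)
  vmax0 <- max(v)
  # Km0: substrate concentration at half of Vmax0 by interpolation
  ord <- order(conc_um)
  km0 <- tryCatch(stats::approx(v[ord], conc_um[ord], xout = vmax0 / 2,
                                ties = mean)$y,
                  error = function(e) NA_real_)
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(conc_um)
  df <- data.frame(s = conc_um, v = v)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ vmax * s / (km + s), data = df,
                      start = list(vmax = vmax0, km = km0),
                      lower = c(vmax = 0, km = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop(sprintf("Michaelis-Menten fit did not converge: %s", conditionMessage(e)),
           call. = FALSE))
  cf <- stats::coef(fit)
  list(vmax = unname(cf["vmax"]), km_um = unname(cf["km"]),
       rss = sum(stats::residuals(fit)^2))
}

#' Fit Michaelis-Menten kinetics across replicates
#'
#' Nonlinear least squares of `v = Vmax * S / (Km + S)` fitted per
#' replicate; reported parameters are the mean across replicates with the
#' sample SD as uncertainty. Turnover number `kcat = Vmax / [E]`. A fitted
#' Km more than 10x above the largest assayed concentration is flagged
#' poorly determined.
#'
#' @param data A [rate_dataset()].
#' @param pooled Fit all replicates jointly instead (single fit; SDs from
#'   the fit covariance). Default FALSE.
#' @return An `mm_fit` object: `kcat`, `kcat_sd` (1/s); `km`, `km_sd` (mM);
#'   `kcat_over_km`, `kcat_over_km_sd` (1/mM/s); `vmax` (uM/s);
#'   `enzyme_conc` (uM); `n_replicates`; `poorly_determined` flag.
#' @export
fit_michaelis_menten <- function(data, pooled = FALSE) {
  stopifnot(inherits(data, "rate_dataset"))
  e <- data$enzyme_conc_um
  if (pooled) {
    s_all <- rep(data$conc_um, ncol(data$rates))
    fit <- fit_mm_one(s_all, as.vector(data$rates))
    kcat <- fit$vmax / e
    km_mm <- fit$km_um / 1000
    kcat_sd <- km_sd <- NA_real_
    vmax <- fit$vmax
  } else {
    fits <- lapply(seq_len(ncol(data$rates)), function(j)
      fit_mm_one(data$conc_um, data$rates[, j]))
    kcats <- vapply(fits, function(f) f$vmax / e, numeric(1))
    kms <- vapply(fits, function(f) f$km_um / 1000, numeric(1))
    kcat <- mean(kcats); km_mm <- mean(kms)
    kcat_sd <- if (length(kcats) > 1) stats::sd(kcats) else NA_real_
    km_sd <- if (length(kms) > 1) stats::sd(kms) else NA_real_
    vmax <- mean(vapply(fits, `[[`, numeric(1), "vmax"))
  }
  ratio <- specificity_constant(kcat, km_mm,
                                kcat_sd = kcat_sd, km_sd = km_sd)
  out <- list(kcat = kcat, kcat_sd = kcat_sd, km = km_mm, km_sd = km_sd,
              kcat_over_km = ratio$value, kcat_over_km_sd = ratio$sd,
              vmax = vmax, enzyme_conc = e, substrate = data$substrate,
              n_replicates = ncol(data$rates),
              poorly_determined = km_mm * 1000 > 10 * max(data$conc_um))
  class(out) <- "mm_fit"
  out
}

#' Specificity constant kcat/Km with propagated uncertainty
#'
#' The second-order rate constant for the enzyme-substrate reaction,
#' `kcat/Km` (1/mM/s), with first-order error propagation:
#' `sd = ratio * sqrt((sd_kcat/kcat)^2 + (sd_km/km)^2)`.
#'
#' @param kcat Turnover number (1/s).
#' @param km Michaelis constant (mM); must be > 0.
#' @param kcat_sd,km_sd Optional SDs.
#' @return A list with `value` and `sd` (NA when either SD is missing).
#' @export
specificity_constant <- function(kcat, km, kcat_sd = NA, km_sd = NA) {
  if (!is.numeric(km) || km <= 0) stop("Km must be > 0", call. = FALSE)
  value <- kcat / km
  sd <- if (is.finite(kcat_sd) && is.finite(km_sd))
    value * sqrt((kcat_sd / kcat)^2 + (km_sd / km)^2) else NA_real_
  list(value = value, sd = sd)
}

#' Protein concentration from A280
#'
#' Beer-Lambert: `conc = A280 / (epsilon * path)`, returned in uM.
#'
#' @param a280 Absorbance at 280 nm (>= 0).
#' @param epsilon Molar extinction coefficient (1/M/cm); default 128480,
#'   the calculated coefficient for the characterized GH1 enzyme.
#' @param path_cm Path length (cm).
#' @return Concentration in uM.
#' @export
protein_conc_from_a280 <- function(a280, epsilon = 128480, path_cm = 1) {
  if (epsilon <= 0 || path_cm <= 0)
    stop("epsilon and path length must be > 0", call. = FALSE)
  if (a280 < 0) stop("absorbance must be >= 0", call. = FALSE)
  a280 / (epsilon * path_cm) * 1e6
}
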