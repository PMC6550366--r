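#' The eight-substrate fluorogenic panel
#'
#' Ordered labels of the 4-methylumbelliferyl (MU) glycoside substrates used
#' for substrate-preference profiling: cellobioside, lactoside, glucoside,
#' galactoside, xyloside, arabinofuranoside, mannoside and
#' N-acetyl-glucosaminide. The order is fixed; ties in substrate preference
#' are broken towards the earlier panel member.
#'
#' @return Character vector of length 8.
#' @export
substrate_panel <- function() {
  c("MU-C", "MU-Lac", "MU-Glc", "MU-Gal", "MU-Xyl", "MU-Ara", "MU-Man",
    "MU-GlcNAc")
}

#' Simulation configuration for a synthetic fosmid screen
#'
#' Builds a validated configuration object describing the latent study
#' conditions of a simulated functional screen: library sizes, the fraction
#' of clones carrying at least one active glycoside hydrolase, plate
#' geometry, fluorescence noise, and the ranges from which per-enzyme
#' kinetic and stability parameters are drawn.
#'
#' Defaults reflect a large-insert fosmid screen: 384-well plates, 0.5 mM
#' (500 uM) screening substrate, inserts of 35,047 +/- 4,852 bp at one gene
#' per kb, denaturation midpoints spanning 38-74 degrees C, and 58% of
#' enzymes using the retaining mechanism.
#'
#' @param n_libraries Number of libraries to simulate.
#' @param clones_per_library Clones per library.
#' @param active_fraction Probability that a clone carries >= 1 active enzyme.
#' @param plate_rows,plate_cols Plate geometry (default 16 x 24 = 384 wells).
#' @param screening_substrate_conc Screening substrate concentration (uM).
#' @param background_rfu_mean,background_rfu_sd Additive background
#'   fluorescence (RFU).
#' @param signal_cv Coefficient of variation of the multiplicative
#'   (lognormal) noise on active-well signal.
#' @param kcat_range Log-uniform bounds for per-substrate kcat (1/s).
#' @param km_range Log-uniform bounds for per-substrate Km (mM).
#' @param tm_range Uniform bounds for the denaturation midpoint (degrees C).
#' @param dh_vh_range Uniform bounds for the van't Hoff enthalpy (kJ/mol).
#' @param ph_opt_range Uniform bounds for the pH optimum.
#' @param ph_width Width (pH units) of the Gaussian pH-activity profile.
#' @param retaining_fraction Probability an enzyme is retaining.
#' @param extra_enzyme_lambda Poisson mean of additional enzymes on an active
#'   clone (active clones carry 1 + Poisson(lambda) enzymes).
#' @param insert_len_mean,insert_len_sd Insert length distribution (bp).
#' @param gene_density Genes per kb on the insert.
#' @param pul_fraction Probability a clone carries a planted SusC-SusD-GH3
#'   cassette.
#' @param lysate_enzyme_conc_um Effective expressed-enzyme concentration in a
#'   screening well (uM); converts kcat into a well velocity.
#' @param calibration_slope RFU per uM of released fluorophore.
#' @param calibration_intercept RFU at zero product.
#' @param row_effect_sd,col_effect_sd Optional additive plate row/column
#'   effects (RFU) used to stress the robust plate statistic; default 0.
#' @param seed Integer RNG seed fixing all stochastic output.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
simulation_config <- function(n_libraries = 1L,
                              clones_per_library = 384L,
                              active_fraction = 1 / 239,
                              plate_rows = 16L,
                              plate_cols = 24L,
                              screening_substrate_conc = 500,
                              background_rfu_mean = 100,
                              background_rfu_sd = 10,
                              signal_cv = 0.1,
                              kcat_range = c(1, 100),
                              km_range = c(0.02, 2),
                              tm_range = c(38, 74),
                              dh_vh_range = c(150, 400),
                              ph_opt_range = c(4.5, 7.5),
                              ph_width = 1.0,
                              retaining_fraction = 0.58,
                              extra_enzyme_lambda = 0.5,
                              insert_len_mean = 35047,
                              insert_len_sd = 4852,
                              gene_density = 1.0,
                              pul_fraction = 0.07,
                              lysate_enzyme_conc_um = 0.01,
                              calibration_slope = 2,
                              calibration_intercept = 0,
                              row_effect_sd = 0,
                              col_effect_sd = 0,
                              seed = 1L) {
  cfg <- list(
    n_libraries = as.integer(n_libraries),
    clones_per_library = as.integer(clones_per_library),
    active_fraction = active_fraction,
    plate_rows = as.integer(plate_rows),
    plate_cols = as.integer(plate_cols),
    screening_substrate_conc = screening_substrate_conc,
    background_rfu_mean = background_rfu_mean,
    background_rfu_sd = background_rfu_sd,
    signal_cv = signal_cv,
    kcat_range = kcat_range,
    km_range = km_range,
    tm_range = tm_range,
    dh_vh_range = dh_vh_range,
    ph_opt_range = ph_opt_range,
    ph_width = ph_width,
    retaining_fraction = retaining_fraction,
    extra_enzyme_lambda = extra_enzyme_lambda,
    insert_len_mean = insert_len_mean,
    insert_len_sd = insert_len_sd,
    gene_density = gene_density,
    pul_fraction = pul_fraction,
    lysate_enzyme_conc_um = lysate_enzyme_conc_um,
    calibration_slope = calibration_slope,
    calibration_intercept = calibration_intercept,
    row_effect_sd = row_effect_sd,
    col_effect_sd = col_effect_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stop_cfg <- function(field, why) {
    stop(sprintf("invalid configuration: field '%s' %s", field, why),
         call. = FALSE)
  }
  probs <- c("active_fraction", "retaining_fraction", "pul_fraction")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop_cfg(p, "must be a probability in [0, 1]")
  }
  ranges <- c("kcat_range", "km_range", "tm_range", "dh_vh_range",
              "ph_opt_range")
  for (r in ranges) {
    v <- cfg[[r]]
    if (!is.numeric(v) || length(v) != 2 || any(is.na(v)) || v[1] > v[2])
      stop_cfg(r, "must be an ordered pair (low <= high)")
  }
  for (pos in c("plate_rows", "plate_cols", "clones_per_library",
                "n_libraries")) {
    if (cfg[[pos]] < 1) stop_cfg(pos, "must be positive")
  }
  for (nn in c("screening_substrate_conc", "insert_len_mean", "gene_density",
               "lysate_enzyme_conc_um", "calibration_slope", "ph_width")) {
    if (cfg[[nn]] <= 0) stop_cfg(nn, "must be positive")
  }
  for (nn in c("background_rfu_sd", "signal_cv", "insert_len_sd",
               "row_effect_sd", "col_effect_sd")) {
    if (cfg[[nn]] < 0) stop_cfg(nn, "must be non-negative")
  }
  if (cfg$kcat_range[1] <= 0 || cfg$km_range[1] <= 0)
    stop("invalid configuration: field 'kcat_range'/'km_range' must be strictly positive (log-uniform draw)",
         call. = FALSE)
  invisible(cfg)
}

#' Read or write a simulation configuration as YAML
#'
#' @param cfg A `sim_config` object.
#' @param path File path.
#' @return `read_config` returns a `sim_config`; `write_config` returns the
#'   path invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(simulation_config, vals)
}
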