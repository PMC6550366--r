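# Independent numerical oracle for the integrated Michaelis-Menten progress
# curve: explicit fine-step RK4 integration of dP/dt = Vmax (S0-P)/(Km+S0-P).
oracle_progress <- function(times, vmax, km_um, s0, dt = 0.01) {
  f <- function(p) vmax * (s0 - p) / (km_um + s0 - p)
  out <- numeric(length(times))
  p <- 0; t <- 0
  for (i in seq_along(times)) {
    while (t < times[i] - 1e-12) {
      h <- min(dt, times[i] - t)
      k1 <- f(p); k2 <- f(p + h * k1 / 2)
      k3 <- f(p + h * k2 / 2); k4 <- f(p + h * k3)
      p <- min(p + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6, s0)
      t <- t + h
    }
    out[i] <- p
  }
  out
}

# Independent identity oracle: count matching columns of the aligned strings
# character by character (vs the implementation's nmatch-based count).
oracle_alignment_identity <- function(seq_a, seq_b) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1),
    gapOpening = 4, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  sum(pa == sa & pa != "-") / length(pa)
}

# A fully specified enzyme for recovery tests (no random draws).
make_enzyme <- function(kcat = c("MU-C" = 10), km = 0.1, ph_opt = 6,
                        ph_width = 1, tm = 50, dh = 200,
                        mechanism = "retaining", family = "GH3") {
  panel <- substrate_panel()
  kv <- stats::setNames(numeric(length(panel)), panel)
  kmv <- stats::setNames(rep(NA_real_, length(panel)), panel)
  kv[names(kcat)] <- kcat
  kmv[names(kcat)] <- km
  enz <- list(gh_family = family, kcat = kv, km = kmv, ph_optimum = ph_opt,
              ph_width = ph_width, tm = tm, dh_vh = dh, mechanism = mechanism)
  class(enz) <- "gh_enzyme"
  enz
}

make_clone <- function(id = "LIB01_01_A01", enzymes = list(),
                       library_id = "LIB01", plate = 1L, well = "A01") {
  cl <- list(clone_id = id, library_id = library_id, plate = plate,
             well = well, enzymes = enzymes, insert_sequence = NULL,
             annotation = NULL)
  class(cl) <- "gh_clone"
  cl
}

# A plate of inactive clones with n_active planted strong actives whose
# noiseless signal is `effect_mads` scaled MADs of background above it.
planted_plate <- function(config, n_active = 1, effect_mads = 20,
                          incubation_time = 3600) {
  n <- config$plate_rows * config$plate_cols
  clones <- lapply(seq_len(n), function(i)
    make_clone(sprintf("LIB01_01_W%03d", i), well = sprintf("W%03d", i)))
  # choose kcat so v0 * t * slope = effect_mads * background_sd, below the
  # full-conversion cap (Km negligible at the screening concentration)
  target_rfu <- effect_mads * config$background_rfu_sd
  s <- config$screening_substrate_conc
  v0 <- target_rfu / config$calibration_slope / incubation_time
  kcat <- v0 / config$lysate_enzyme_conc_um / (s / (0.001 * 1000 + s))
  act <- sample(n, n_active)
  for (i in act)
    clones[[i]]$enzymes <- list(make_enzyme(kcat = c("MU-C" = kcat), km = 0.001))
  list(clones = clones, active = sort(act),
       plate = simulate_screen_plate(clones, "MU-C",
                                     incubation_time = incubation_time,
                                     config = config))
}
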