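GH_FAMILY_POOL <- c(
  GH3 = 0.20, GH5 = 0.12, GH1 = 0.10, GH2 = 0.08, GH43 = 0.08, GH16 = 0.06,
  GH9 = 0.05, GH10 = 0.05, GH30 = 0.05, GH13 = 0.05, GH78 = 0.04,
  GH115 = 0.04, GH67 = 0.04, GH144 = 0.04, GH51 = 0.04
)

SUBSTRATE_WEIGHTS <- c(
  "MU-C" = 0.30, "MU-Glc" = 0.25, "MU-Ara" = 0.12, "MU-Xyl" = 0.08,
  "MU-Gal" = 0.07, "MU-Lac" = 0.07, "MU-Man" = 0.06, "MU-GlcNAc" = 0.05
)

runif_log <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))

#' Draw one synthetic glycoside hydrolase
#'
#' Samples the latent parameters of a single enzyme: a CAZy GH family, a
#' primary substrate from the MU-glycoside panel (with optional weaker side
#' activities), per-substrate kcat (1/s) and Km (mM), a Gaussian pH-activity
#' profile, a two-state thermal denaturation midpoint with van't Hoff
#' enthalpy, and a retaining or inverting mechanism.
#'
#' @param config A [simulation_config()] object.
#' @return An object of class `gh_enzyme`.
#' @export
simulate_enzyme <- function(config) {
  panel <- substrate_panel()
  primary <- sample(names(SUBSTRATE_WEIGHTS), 1, prob = SUBSTRATE_WEIGHTS)
  kcat <- stats::setNames(numeric(length(panel)), panel)
  km <- stats::setNames(rep(NA_real_, length(panel)), panel)
  kcat[primary] <- runif_log(1, config$kcat_range)
  km[primary] <- runif_log(1, config$km_range)
  for (s in setdiff(panel, primary)) {
    if (stats::runif(1) < 0.25) {
      kcat[s] <- kcat[primary] * stats::runif(1, 0.05, 0.5)
      km[s] <- runif_log(1, config$km_range)
    }
  }
  enz <- list(
    gh_family = sample(names(GH_FAMILY_POOL), 1, prob = GH_FAMILY_POOL),
    kcat = kcat,
    km = km,
    ph_optimum = stats::runif(1, config$ph_opt_range[1], config$ph_opt_range[2]),
    ph_width = config$ph_width,
    tm = stats::runif(1, config$tm_range[1], config$tm_range[2]),
    dh_vh = stats::runif(1, config$dh_vh_range[1], config$dh_vh_range[2]),
    mechanism = if (stats::runif(1) < config$retaining_fraction) "retaining" else "inverting"
  )
  class(enz) <- "gh_enzyme"
  enz
}

well_labels <- function(rows, cols) {
  rn <- LETTERS[seq_len(rows)]
  as.vector(t(outer(rn, seq_len(cols), function(r, c) sprintf("%s%02d", r, c))))
}

#' Simulate fosmid libraries with known ground truth
#'
#' Generates `n_libraries * clones_per_library` clones arrayed onto 384-well
#' plates. Each clone is active (carries `1 + Poisson(extra_enzyme_lambda)`
#' enzymes drawn by [simulate_enzyme()]) with probability `active_fraction`,
#' otherwise carries none. Clone IDs follow the `library_plate_well`
#' convention (e.g. `"LIB01_02_C11"`). Insert sequences are not generated
#' here (only validated hits are typically sequenced); see
#' [simulate_insert_and_annotation()].
#'
#' Output is deterministic given the configuration (including its `seed`).
#'
#' @param config A [simulation_config()] object.
#' @return A list of `gh_clone` objects.
#' @export
simulate_library <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  wells_per_plate <- config$plate_rows * config$plate_cols
  labels <- well_labels(config$plate_rows, config$plate_cols)
  clones <- vector("list", config$n_libraries * config$clones_per_library)
  k <- 0L
  for (lib in seq_len(config$n_libraries)) {
    library_id <- sprintf("LIB%02d", lib)
    active <- stats::runif(config$clones_per_library) < config$active_fraction
    for (i in seq_len(config$clones_per_library)) {
      plate <- (i - 1L) %/% wells_per_plate + 1L
      well <- labels[(i - 1L) %% wells_per_plate + 1L]
      enzymes <- list()
      if (active[i]) {
        n_enz <- 1L + stats::rpois(1, config$extra_enzyme_lambda)
        enzymes <- lapply(seq_len(n_enz), function(j) simulate_enzyme(config))
      }
      cl <- list(
        clone_id = sprintf("%s_%02d_%s", library_id, plate, well),
        library_id = library_id,
        plate = plate,
        well = well,
        enzymes = enzymes,
        insert_sequence = NULL,
        annotation = NULL
      )
      class(cl) <- "gh_clone"
      k <- k + 1L
      clones[[k]] <- cl
    }
  }
  clones
}

is_active <- function(clone) length(clone$enzymes) > 0

#' Michaelis-Menten well velocity of a clone lysate
#'
#' Initial velocity (uM/s) of the combined enzymes of a clone on one
#' substrate: `sum(kcat_i * E * S / (1000 * Km_i + S))` with `S` in uM and
#' `Km` in mM.
#'
#' @param enzymes List of `gh_enzyme` objects (or a single one).
#' @param substrate Panel substrate label.
#' @param s_um Substrate concentration (uM).
#' @param e_um Effective enzyme concentration (uM).
#' @return Velocity in uM/s.
#' @export
clone_velocity <- function(enzymes, substrate, s_um, e_um) {
  if (inherits(enzymes, "gh_enzyme")) enzymes <- list(enzymes)
  v <- 0
  for (enz in enzymes) {
    kc <- enz$kcat[[substrate]]
    if (is.null(kc) || is.na(kc) || kc == 0) next
    km_um <- enz$km[[substrate]] * 1000
    v <- v + kc * e_um * s_um / (km_um + s_um)
  }
  v
}

#' Simulate one endpoint screening plate
#'
#' Forward model of the fluorogenic endpoint screen. Every well draws
#' additive Gaussian background (plus optional row/column effects); an
#' active well adds signal `calibration_slope * min(v0 * time, conc)` --
#' the initial-velocity product capped at full conversion of the substrate
#' -- under multiplicative lognormal noise with coefficient of variation
#' `signal_cv`.
#'
#' @param clones List of `gh_clone` objects, at most one plate's worth;
#'   wells map 1:1 to clones.
#' @param substrate Panel substrate label.
#' @param conc Substrate concentration (uM).
#' @param incubation_time Incubation time (s).
#' @param config A [simulation_config()] object.
#' @param plate_id Optional plate label.
#' @return A `plate_read` object (see [plate_read()]).
#' @export
simulate_screen_plate <- function(clones, substrate,
                                  conc = config$screening_substrate_conc,
                                  incubation_time = 3600,
                                  config = simulation_config(),
                                  plate_id = NULL) {
  panel <- substrate_panel()
  if (!substrate %in% panel)
    stop(sprintf("unknown substrate '%s'; configured panel: %s", substrate,
                 paste(panel, collapse = ", ")), call. = FALSE)
  n_wells <- config$plate_rows * config$plate_cols
  if (length(clones) > n_wells)
    stop("more clones than wells on the plate", call. = FALSE)
  labels <- well_labels(config$plate_rows, config$plate_cols)[seq_along(clones)]
  row_idx <- match(substr(labels, 1, 1), LETTERS)
  col_idx <- as.integer(substring(labels, 2))

  row_eff <- if (config$row_effect_sd > 0)
    stats::rnorm(config$plate_rows, 0, config$row_effect_sd) else numeric(config$plate_rows)
  col_eff <- if (config$col_effect_sd > 0)
    stats::rnorm(config$plate_cols, 0, config$col_effect_sd) else numeric(config$plate_cols)

  bg <- config$background_rfu_mean +
    (if (config$background_rfu_sd > 0)
       stats::rnorm(length(clones), 0, config$background_rfu_sd) else 0) +
    row_eff[row_idx] + col_eff[col_idx]

  signal <- vapply(seq_along(clones), function(i) {
    cl <- clones[[i]]
    if (!is_active(cl)) return(0)
    v0 <- clone_velocity(cl$enzymes, substrate, conc, config$lysate_enzyme_conc_um)
    if (v0 <= 0) return(0)
    product <- min(v0 * incubation_time, conc)
    noise <- if (config$signal_cv > 0)
      stats::rlnorm(1, -0.5 * log(1 + config$signal_cv^2),
                    sqrt(log(1 + config$signal_cv^2))) else 1
    config$calibration_slope * product * noise
  }, numeric(1))

  wells <- data.frame(
    well = labels,
    row = row_idx,
    col = col_idx,
    clone_id = vapply(clones, `[[`, character(1), "clone_id"),
    fluorescence = pmax(bg + signal, 0),
    stringsAsFactors = FALSE
  )
  plate_read(
    plate_id = plate_id %||% sprintf("%s_%02d", clones[[1]]$library_id, clones[[1]]$plate),
    library_id = clones[[1]]$library_id,
    substrate = substrate,
    wells = wells
  )
}

#' Simulate the full endpoint screen of a clone set
#'
#' Splits clones by library and plate and calls [simulate_screen_plate()]
#' on each group.
#'
#' @inheritParams simulate_screen_plate
#' @return A list of `plate_read` objects.
#' @export
simulate_screen <- function(clones, substrate = "MU-C",
                            conc = config$screening_substrate_conc,
                            incubation_time = 3600,
                            config = simulation_config()) {
  key <- vapply(clones, function(cl) sprintf("%s_%02d", cl$library_id, cl$plate),
                character(1))
  groups <- split(clones, factor(key, levels = unique(key)))
  lapply(groups, simulate_screen_plate, substrate = substrate, conc = conc,
         incubation_time = incubation_time, config = config)
}

# Integrated single-substrate Michaelis-Menten progress curve.
# Solves Vmax * t = P + Km * log(S0 / (S0 - P)) for P by bisection;
# exact at all depletion levels.
mm_progress <- function(t, vmax, km_um, s0) {
  vapply(t, function(tt) {
    if (tt <= 0 || vmax <= 0) return(0)
    f <- function(p) vmax * tt - p - km_um * log(s0 / (s0 - p))
    lo <- 0
    hi <- s0 * (1 - 1e-12)
    if (f(hi) >= 0) return(s0)            # numerically full conversion
    for (iter in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
      if (hi - lo < s0 * 1e-12) break
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' Simulate a product time course for one enzyme and substrate
#'
#' Product concentration follows the integrated single-substrate
#' Michaelis-Menten progress curve (implicit closed form solved by bisection
#' at each time point), so the trajectory is exact at all depletion levels
#' and never exceeds full conversion. Fluorescence is
#' `calibration$slope * P(t) + calibration$intercept` plus additive Gaussian
#' noise.
#'
#' @param enzyme A `gh_enzyme` (or list of them, summed).
#' @param substrate Panel substrate label.
#' @param conc0 Initial substrate concentration (uM), > 0.
#' @param times Strictly increasing sampling times (s).
#' @param cal A [calibration()] object (RFU per uM).
#' @param noise_sd Additive fluorescence noise sd (RFU).
#' @param enzyme_conc_um Enzyme concentration (uM).
#' @param clone_id,od600,condition Metadata carried on the result.
#' @return A `timecourse` object.
#' @export
simulate_timecourse <- function(enzyme, substrate, conc0, times,
                                cal = calibration(slope = 2, intercept = 0),
                                noise_sd = 0, enzyme_conc_um = 0.01,
                                clone_id = NA_character_, od600 = NULL,
                                condition = NULL) {
  stopifnot(conc0 > 0, length(times) >= 1)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (inherits(enzyme, "gh_enzyme")) enzyme <- list(enzyme)
  vmax <- 0
  km_um <- Inf
  # combined lysate trajectory: for multi-enzyme clones use the
  # rate-weighted harmonic combination of a single effective enzyme
  active <- Filter(function(e) {
    k <- e$kcat[[substrate]]; !is.null(k) && !is.na(k) && k > 0
  }, enzyme)
  if (length(active) > 0) {
    vmax <- sum(vapply(active, function(e) e$kcat[[substrate]] * enzyme_conc_um,
                       numeric(1)))
    # effective Km: matches the combined initial velocity at conc0
    v0 <- clone_velocity(active, substrate, conc0, enzyme_conc_um)
    km_um <- vmax * conc0 / v0 - conc0
    km_um <- max(km_um, 1e-9)
  }
  p <- if (vmax > 0) mm_progress(times, vmax, km_um, conc0) else rep(0, length(times))
  rfu <- cal$slope * p + cal$intercept
  if (noise_sd > 0) rfu <- rfu + stats::rnorm(length(rfu), 0, noise_sd)
  tc <- list(clone_id = clone_id, substrate = substrate, conc0 = conc0,
             times = times, rfu = rfu, od600 = od600, condition = condition)
  class(tc) <- "timecourse"
  tc
}

# two-state van't Hoff folded fraction; temperatures in Celsius, dH in kJ/mol
vant_hoff_fraction <- function(temp_c, tm_c, dh_kj) {
  R <- 8.314462618e-3   # kJ/(mol K)
  t_k <- temp_c + 273.15
  tm_k <- tm_c + 273.15
  1 / (1 + exp((dh_kj / R) * (1 / tm_k - 1 / t_k)))
}

#' Simulate a pH-activity series
#'
#' The rate at each pH is the enzyme's reference rate scaled by a Gaussian
#' profile `exp(-(pH - ph_optimum)^2 / (2 * ph_width^2))`, with optional
#' multiplicative Gaussian noise.
#'
#' @param enzyme A `gh_enzyme`.
#' @param grid Numeric pH grid (nonempty).
#' @param noise Relative noise (sd of the multiplicative factor minus one).
#' @param rate_ref Reference (optimal-pH) rate; default 1.
#' @return A data.frame with columns `ph` and `rate`.
#' @export
simulate_ph_series <- function(enzyme, grid, noise = 0, rate_ref = 1) {
  stopifnot(length(grid) > 0)
  rate <- rate_ref * exp(-(grid - enzyme$ph_optimum)^2 / (2 * enzyme$ph_width^2))
  if (noise > 0) rate <- rate * (1 + stats::rnorm(length(rate), 0, noise))
  data.frame(ph = grid, rate = rate)
}

#' Simulate a thermal-stability series
#'
#' Residual activity after pre-incubation at each temperature: the unheated
#' rate scaled by the two-state van't Hoff folded fraction with parameters
#' `(tm, dh_vh)`. At `T = tm` the rate is exactly half the unheated rate.
#'
#' @param enzyme A `gh_enzyme`.
#' @param grid Pre-incubation temperatures (degrees C, nonempty).
#' @param noise Relative noise.
#' @param rate_ref Unheated reference rate; default 1.
#' @return A data.frame with columns `temperature` and `rate`.
#' @export
simulate_thermal_series <- function(enzyme, grid, noise = 0, rate_ref = 1) {
  stopifnot(length(grid) > 0)
  rate <- rate_ref * vant_hoff_fraction(grid, enzyme$tm, enzyme$dh_vh)
  if (noise > 0) rate <- rate * (1 + stats::rnorm(length(rate), 0, noise))
  data.frame(temperature = grid, rate = rate)
}

#' Simulate a 2-fluoroglycoside inactivation assay
#'
#' A retaining glycosidase is trapped by the 2-deoxy-2-fluoroglycoside and
#' retains ~0 residual activity; an inverting enzyme is untouched and keeps
#' the control rate, before noise.
#'
#' @param enzyme A `gh_enzyme`.
#' @param control_rate Rate of the paired uninhibited control.
#' @param noise Relative noise.
#' @return A list with `residual_rate` and `control_rate`.
#' @export
simulate_inactivation <- function(enzyme, control_rate = 1, noise = 0) {
  residual <- if (enzyme$mechanism == "retaining") 0 else control_rate
  if (noise > 0) {
    residual <- residual * (1 + stats::rnorm(1, 0, noise)) +
      abs(stats::rnorm(1, 0, noise * control_rate * 0.05))
    control_rate <- control_rate * (1 + stats::rnorm(1, 0, noise))
  }
  list(residual_rate = residual, control_rate = control_rate)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Apply random substitutions to a DNA sequence
#'
#' Each base is replaced by one of the three other bases independently with
#' probability `rate`. Used to plant redundant clone pairs below the
#' clustering identity threshold.
#'
#' @param seq DNA string.
#' @param rate Per-base substitution probability.
#' @return Mutated DNA string.
#' @export
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(bases)) < rate)
  for (i in hit) bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
  paste(bases, collapse = "")
}

#' Simulate an insert sequence and ORF annotation for a clone
#'
#' Insert length is Normal(`insert_len_mean`, `insert_len_sd`) truncated
#' positive; non-overlapping ORFs are laid down at about `gene_density`
#' genes per kb. Active clones receive GH ORFs matching their enzymes'
#' families; with probability `pul_fraction` an adjacent same-strand
#' SusC-SusD-GH3 cassette (in transcriptional order) is planted. Background
#' ORFs are mostly unannotated with a sprinkling of GH/CE/CBM labels; SusC
#' and SusD never occur outside planted cassettes.
#'
#' @param clone A `gh_clone`.
#' @param config A [simulation_config()] object.
#' @param force_pul Logical; override the `pul_fraction` coin flip.
#' @return The clone with `insert_sequence` and `annotation` (data.frame
#'   with columns start, end, strand, family; 1-based inclusive, sorted by
#'   start) filled in.
#' @export
simulate_insert_and_annotation <- function(clone, config, force_pul = NULL) {
  len <- 0
  while (len < 2000) len <- round(stats::rnorm(1, config$insert_len_mean,
                                               config$insert_len_sd))
  n_genes <- max(3L, stats::rpois(1, len / 1000 * config$gene_density))
  slot <- len / n_genes
  starts <- ends <- integer(n_genes)
  strands <- character(n_genes)
  for (i in seq_len(n_genes)) {
    s0 <- floor((i - 1) * slot) + 1
    glen <- max(90L, round(stats::runif(1, 0.55, 0.85) * slot))
    starts[i] <- s0 + sample.int(max(1L, floor(slot - glen)), 1) - 1L
    ends[i] <- min(starts[i] + glen - 1L, len)
    strands[i] <- sample(c("+", "-"), 1)
  }
  family <- rep("unannotated", n_genes)
  u <- stats::runif(n_genes)
  bg_gh <- u < 0.04
  family[bg_gh] <- sample(names(GH_FAMILY_POOL), sum(bg_gh), replace = TRUE,
                          prob = GH_FAMILY_POOL)
  bg_ce <- u >= 0.04 & u < 0.055
  family[bg_ce] <- paste0("CE", sample(c(1, 4, 6), sum(bg_ce), replace = TRUE))
  bg_cbm <- u >= 0.055 & u < 0.065
  family[bg_cbm] <- paste0("CBM", sample(c(6, 32, 48), sum(bg_cbm), replace = TRUE))

  free <- which(family == "unannotated")
  for (enz in clone$enzymes) {
    if (length(free) == 0) break
    pick <- free[sample.int(length(free), 1)]
    family[pick] <- enz$gh_family
    free <- setdiff(free, pick)
  }

  plant <- if (is.null(force_pul)) stats::runif(1) < config$pul_fraction else force_pul
  if (plant && n_genes >= 3) {
    i0 <- sample.int(n_genes - 2L, 1)
    idx <- i0:(i0 + 2L)
    strand <- sample(c("+", "-"), 1)
    strands[idx] <- strand
    cassette <- c("SusC", "SusD", "GH3")
    # transcriptional order SusC -> SusD -> GH3; on minus strand the
    # coordinate order is reversed
    family[idx] <- if (strand == "+") cassette else rev(cassette)
  }

  ord <- order(starts)
  clone$insert_sequence <- random_dna(len)
  clone$annotation <- data.frame(start = starts[ord], end = ends[ord],
                                 strand = strands[ord], family = family[ord],
                                 stringsAsFactors = FALSE)
  clone
}

#' Plant redundant duplicate pairs in a clone set
#'
#' Copies the insert (and annotation) of each of `n_pairs` source clones
#' onto a distinct partner clone, applying a per-base substitution rate, so
#' the resulting pairs have a known expected identity.
#'
#' @param clones List of `gh_clone` objects with inserts already simulated.
#' @param n_pairs Number of duplicate pairs to plant.
#' @param substitution_rate Per-base substitution probability applied to
#'   the copy.
#' @return The clone list with duplicates planted; pairs recorded in
#'   `attr(, "duplicate_pairs")` (two-column matrix of indices).
#' @export
plant_duplicates <- function(clones, n_pairs, substitution_rate = 0) {
  stopifnot(2 * n_pairs <= length(clones))
  idx <- sample(seq_along(clones), 2 * n_pairs)
  src <- idx[seq_len(n_pairs)]
  dst <- idx[n_pairs + seq_len(n_pairs)]
  for (i in seq_len(n_pairs)) {
    clones[[dst[i]]]$insert_sequence <-
      mutate_sequence(clones[[src[i]]]$insert_sequence, substitution_rate)
    clones[[dst[i]]]$annotation <- clones[[src[i]]]$annotation
  }
  attr(clones, "duplicate_pairs") <- cbind(src, dst)
  clones
}

#' Simulate a sequenced hit set with planted catalog structure
#'
#' Builds the fosmid set a sequencing-and-cataloging stage consumes:
#' `n_fosmids` validated hits with simulated inserts and annotations, into
#' which three kinds of ground-truth structure are planted on disjoint
#' fosmid subsets: `n_dup_pairs` redundant duplicate pairs (copies at
#' `dup_substitution_rate` per-base substitutions), `n_pul` SusC-SusD-GH3
#' cassettes, and `n_multi_gh` fosmids carrying at least `min_gh` GH genes.
#' All other fosmids receive no cassette and at most background GH content.
#'
#' @param config A [simulation_config()] object; its `seed` drives all
#'   randomness.
#' @param n_fosmids Total fosmids.
#' @param n_dup_pairs Planted duplicate pairs (so the expected nonredundant
#'   count is `n_fosmids - n_dup_pairs`).
#' @param n_pul Fosmids with a planted PUL cassette.
#' @param n_multi_gh Fosmids with >= `min_gh` GH ORFs planted.
#' @param min_gh GH count defining a multi-GH fosmid (default 5).
#' @param dup_substitution_rate Per-base substitution rate applied to
#'   duplicate copies (default 0.02, comfortably above the 95% identity
#'   threshold).
#' @return List of `fosmid_record` objects with attributes
#'   `duplicate_pairs` (two-column matrix of fosmid IDs), `pul_ids`,
#'   `multi_gh_ids`.
#' @export
simulate_catalog_study <- function(config = simulation_config(),
                                   n_fosmids = 164, n_dup_pairs = 49,
                                   n_pul = 11, n_multi_gh = 25, min_gh = 5,
                                   dup_substitution_rate = 0.02) {
  stopifnot(n_pul + n_multi_gh + 2 * n_dup_pairs <= n_fosmids)
  validate_config(config)
  set.seed(config$seed)
  ids <- sprintf("HIT_%02d_%s", seq_len(n_fosmids) %/% 24 + 1,
                 well_labels(16, 24)[(seq_len(n_fosmids) - 1) %% 384 + 1])
  ids <- make.unique(ids, sep = "r")
  pul_idx <- seq_len(n_pul)
  mgh_idx <- n_pul + seq_len(n_multi_gh)
  dup_idx <- n_pul + n_multi_gh + seq_len(2 * n_dup_pairs)

  clones <- lapply(seq_len(n_fosmids), function(i) {
    cl <- list(clone_id = ids[i], library_id = sub("_.*", "", ids[i]),
               plate = 1L, well = "A01", enzymes = list(),
               insert_sequence = NULL, annotation = NULL)
    class(cl) <- "gh_clone"
    repeat {
      cl <- simulate_insert_and_annotation(cl, config,
                                           force_pul = i %in% pul_idx)
      if (!(i %in% mgh_idx) || nrow(cl$annotation) >= min_gh) break
    }
    if (i %in% mgh_idx) {
      free <- which(!cl$annotation$family %in% c("SusC", "SusD"))
      pick <- free[seq_len(min_gh)]
      cl$annotation$family[pick] <- sample(names(GH_FAMILY_POOL), min_gh,
                                           replace = TRUE,
                                           prob = GH_FAMILY_POOL)
    }
    cl
  })
  src <- dup_idx[seq_len(n_dup_pairs)]
  dst <- dup_idx[n_dup_pairs + seq_len(n_dup_pairs)]
  for (k in seq_len(n_dup_pairs)) {
    clones[[dst[k]]]$insert_sequence <-
      mutate_sequence(clones[[src[k]]]$insert_sequence, dup_substitution_rate)
    clones[[dst[k]]]$annotation <- clones[[src[k]]]$annotation
  }
  fosmids <- as_fosmid_records(clones)
  attr(fosmids, "duplicate_pairs") <- cbind(ids[src], ids[dst])
  attr(fosmids, "pul_ids") <- ids[pul_idx]
  attr(fosmids, "multi_gh_ids") <- ids[mgh_idx]
  fosmids
}

`%||%` <- function(a, b) if (is.null(a)) b else a
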