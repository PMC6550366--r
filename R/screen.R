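#' Construct a plate read
#'
#' Container for one plate of endpoint fluorescence measurements.
#'
#' @param plate_id,library_id,substrate Labels.
#' @param wells data.frame with at least columns `well`, `clone_id`,
#'   `fluorescence`; well labels unique, fluorescence finite and >= 0.
#' @param controls Optional character vector of control well labels,
#'   excluded from hit calling but included in plate statistics.
#' @return A `plate_read` object.
#' @export
plate_read <- function(plate_id, library_id = NA_character_,
                       substrate = NA_character_, wells, controls = character()) {
  stopifnot(is.data.frame(wells),
            all(c("well", "clone_id", "fluorescence") %in% names(wells)))
  if (anyDuplicated(wells$well))
    stop("well labels must be unique", call. = FALSE)
  if (any(!is.finite(wells$fluorescence)) || any(wells$fluorescence < 0))
    stop("fluorescence must be finite and >= 0", call. = FALSE)
  pr <- list(plate_id = plate_id, library_id = library_id,
             substrate = substrate, wells = wells, controls = controls)
  class(pr) <- "plate_read"
  pr
}

#' Per-plate robust Z-scores
#'
#' The outlier-resistant hit statistic of high-throughput screening:
#' \deqn{z_i = (x_i - \mathrm{median}(x)) / (1.4826 \cdot \mathrm{MAD}(x))}
#' with `MAD = median(|x - median(x)|)`. Computed per plate, never pooled
#' across plates. The statistic is invariant to affine transforms of the
#' plate and resistant to contamination by strong actives (breakdown point
#' 50%), unlike a mean/SD Z-score.
#'
#' @param plate A [plate_read()] object (>= 8 wells), or a bare numeric
#'   vector of fluorescence values.
#' @return Named numeric vector of Z-scores, one per well.
#' @export
robust_zscore <- function(plate) {
  is_plate <- inherits(plate, "plate_read")
  x <- if (is_plate) plate$wells$fluorescence else plate
  nm <- if (is_plate) plate$wells$well else names(plate)
  # the >= 8 well requirement applies to plates used for hit calling; the
  # bare statistic is defined for any vector with >= 2 finite values
  if (sum(is.finite(x)) < (if (is_plate) 8 else 2))
    stop("robust Z-score requires >= 8 wells with finite values", call. = FALSE)
  med <- stats::median(x)
  mad0 <- stats::median(abs(x - med))
  if (mad0 == 0)
    stop("degenerate plate: MAD is zero (constant fluorescence)", call. = FALSE)
  z <- (x - med) / (1.4826 * mad0)
  if (!is.null(nm)) names(z) <- nm
  z
}

#' Call hits on one or more plates
#'
#' One `HitCall` row per well: `passed` is a strict comparison
#' `zscore > threshold` (primary screens use threshold 10; secondary
#' rescreens, e.g. with an azido-modified substrate, use 3).
#'
#' @param plates A `plate_read` or list of them.
#' @param threshold Positive Z-score threshold.
#' @return data.frame with columns `clone_id`, `plate_id`, `well`, `zscore`,
#'   `threshold`, `passed`, `validated` (initialized FALSE).
#' @export
call_hits <- function(plates, threshold = 10) {
  stopifnot(threshold > 0)
  if (inherits(plates, "plate_read")) plates <- list(plates)
  res <- lapply(plates, function(pl) {
    z <- robust_zscore(pl)
    keep <- !(pl$wells$well %in% pl$controls)
    data.frame(clone_id = pl$wells$clone_id[keep],
               plate_id = pl$plate_id,
               well = pl$wells$well[keep],
               zscore = unname(z[keep]),
               threshold = threshold,
               passed = unname(z[keep]) > threshold,
               validated = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Validate primary hits by triplicate rescreen
#'
#' Each primary hit must carry exactly three replicate measurements; a hit
#' is validated when the median of its replicate Z-scores exceeds the same
#' threshold used for calling.
#'
#' @param primary_hits data.frame from [call_hits()], restricted to
#'   `passed` rows (non-passed rows are dropped with a warning).
#' @param replicate_plates List of three `plate_read` objects containing
#'   the rearrayed candidates.
#' @param threshold Z-score threshold (default: the one on `primary_hits`).
#' @return `primary_hits` with `validated` set and a `replicate_zscores`
#'   list-column added.
#' @export
validate_hits <- function(primary_hits, replicate_plates, threshold = NULL) {
  if (length(replicate_plates) != 3)
    stop("triplicate validation requires exactly 3 replicate plates", call. = FALSE)
  if (any(!primary_hits$passed)) {
    warning("dropping candidates that did not pass the primary threshold")
    primary_hits <- primary_hits[primary_hits$passed, , drop = FALSE]
  }
  threshold <- threshold %||% primary_hits$threshold[1]
  zmat <- lapply(replicate_plates, function(pl) {
    z <- robust_zscore(pl)
    stats::setNames(unname(z), pl$wells$clone_id)
  })
  missing <- primary_hits$clone_id[!vapply(primary_hits$clone_id, function(id)
    all(vapply(zmat, function(z) id %in% names(z), logical(1))), logical(1))]
  if (length(missing) > 0)
    stop(sprintf("missing replicate measurements for: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  reps <- lapply(primary_hits$clone_id, function(id)
    vapply(zmat, function(z) z[[id]], numeric(1)))
  primary_hits$validated <- vapply(reps, function(z)
    stats::median(z) > threshold, logical(1))
  primary_hits$replicate_zscores <- reps
  primary_hits
}
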