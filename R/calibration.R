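# Unit-intensity calibration from the equidistant peaks of a spot-intensity
# distribution, and conversion of spot integrals to integer molecule counts.

# Topographic prominence of each local maximum of a curve y: height above the
# higher of the two saddle minima separating it from larger values.
# min_prominence may be a vector (per-position threshold).
curve_peaks <- function(x, y, min_prominence) {
  n <- length(y)
  if (n < 3) return(numeric())
  if (length(min_prominence) == 1) min_prominence <- rep(min_prominence, n)
  is_max <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  out <- numeric()
  for (i in is_max) {
    left <- y[1:i]
    higher_l <- which(left > y[i])
    saddle_l <- if (length(higher_l)) min(y[max(higher_l):i]) else min(left)
    right <- y[i:n]
    higher_r <- which(right > y[i])
    saddle_r <- if (length(higher_r)) min(y[i:(i + min(higher_r) - 1)]) else min(right)
    prom <- y[i] - max(saddle_l, saddle_r)
    if (prom >= min_prominence[i]) out <- c(out, x[i])
  }
  sort(out)
}

#' Detect equidistant peaks in a spot-intensity distribution
#'
#' Builds a kernel-density estimate (or histogram) of the spot integrals and
#' returns the positions of local maxima whose prominence is at least
#' `min_prominence_frac` of the global maximum. For a calibration sample in
#' which most spots hold 1, 2, 3, ... molecules, the peaks sit near integer
#' multiples of the single-molecule intensity.
#'
#' @param intensities numeric vector of background-free spot integrals
#'   (>= 50 recommended).
#' @param binwidth KDE bandwidth / histogram bin width in intensity units.
#'   `NULL` chooses a Silverman bandwidth, refined after a first pass so that
#'   the bandwidth lies in `[u/10, u/2]` of the provisional peak spacing `u`.
#' @param min_prominence_frac prominence threshold as a fraction of the
#'   density maximum (default 0.05).
#' @param method `"kde"` (default) or `"histogram"`.
#' @param min_peaks minimum number of peaks required (default 4); fewer
#'   raises a calibration-failure error.
#' @return numeric vector of peak positions, ascending.
#' @export
detect_peaks <- function(intensities, binwidth = NULL,
                         min_prominence_frac = 0.05,
                         method = c("kde", "histogram"), min_peaks = 4L) {
  method <- match.arg(method)
  intensities <- intensities[is.finite(intensities) & intensities > 0]
  if (length(intensities) < 5) {
    stop_pf("too few spot intensities for calibration",
            class = "pf_calibration_failure")
  }
  n <- length(intensities)
  # A candidate peak must rise above both a fixed fraction of the global
  # maximum and 3x the local sampling noise of the estimator (KDE height
  # SE ~ sqrt(f * R(K) / (n h)), histogram counts ~ Poisson), so chance
  # undulations of a single broad cluster are not mistaken for peaks.
  one_pass <- function(bw) {
    if (method == "kde") {
      d <- density(intensities, bw = bw, n = 2048, from = 0,
                   to = max(intensities) * 1.15)
      thr <- pmax(min_prominence_frac * max(d$y),
                  3 * sqrt(d$y * 0.2821 / (n * bw)))
      curve_peaks(d$x, d$y, thr)
    } else {
      breaks <- seq(0, max(intensities) + bw, by = bw)
      h <- graphics::hist(intensities, breaks = breaks, plot = FALSE)
      thr <- pmax(min_prominence_frac * max(h$counts), 3 * sqrt(h$counts))
      curve_peaks(h$mids, h$counts, thr)
    }
  }
  bw <- binwidth
  if (is.null(bw)) {
    # Bandwidth selection: Silverman's rule spans the whole multi-peak
    # mixture and oversmooths the minor peaks, so refine it from the
    # provisional peak spacing u: the final bandwidth u/8 resolves peaks
    # while still averaging ~n*binwidth/u spots per peak.
    bw0 <- stats::bw.nrd0(intensities)
    bw <- bw0
    for (div in c(1, 3, 9, 27)) {
      peaks <- one_pass(bw0 / div)
      if (length(peaks) >= 2) break
    }
    if (length(peaks) >= 2) {
      u_est <- min(diff(peaks))
      bw <- u_est / 8
    }
  }
  if (bw <= 0) stop_pf("binwidth must be positive", class = "pf_bad_input")
  peaks <- one_pass(bw)
  if (length(peaks) < min_peaks) {
    stop_pf("calibration failure: only ", length(peaks), " peak(s) found; ",
            "at least ", min_peaks, " equidistant peaks are needed - use a ",
            "lower-copy calibration sample (e.g. a low-copy backbone or ",
            "weak induction) so that 1..4-molecule spots dominate",
            class = "pf_calibration_failure")
  }
  peaks
}

#' Single-molecule unit intensity from detected peaks
#'
#' The unit intensity is the mean of the three successive distances among the
#' first four peaks, i.e. `(p4 - p1) / 3`.
#'
#' @param peaks numeric vector of peak positions, strictly increasing,
#'   length >= 4.
#' @return unit intensity (intensity units per molecule).
#' @export
unit_from_peaks <- function(peaks) {
  if (length(peaks) < 4) {
    stop_pf("need at least four peaks to calibrate",
            class = "pf_calibration_failure")
  }
  if (any(diff(peaks) <= 0)) {
    stop_pf("peak positions must be strictly increasing",
            class = "pf_bad_input")
  }
  (peaks[4] - peaks[1]) / 3
}

#' Calibrate the unit intensity from spot integrals
#'
#' Convenience wrapper: [detect_peaks()] then [unit_from_peaks()].
#'
#' @inheritParams detect_peaks
#' @return object of class `calibration_result`: `unit_intensity`,
#'   `peak_positions`, `n_spots_used`, `binwidth`, `method`.
#' @export
calibrate_unit_intensity <- function(intensities, binwidth = NULL,
                                     min_prominence_frac = 0.05,
                                     method = c("kde", "histogram")) {
  method <- match.arg(method)
  peaks <- detect_peaks(intensities, binwidth = binwidth,
                        min_prominence_frac = min_prominence_frac,
                        method = method)
  spacings <- diff(peaks[1:4])
  if (max(spacings) / min(spacings) > 1.8) {
    stop_pf("calibration failure: the first four peaks are not equidistant ",
            "(spacings ", paste(round(spacings), collapse = ", "), "); the ",
            "spot sample is too sparse or multi-modal for a reliable unit",
            class = "pf_calibration_failure")
  }
  structure(list(unit_intensity = unit_from_peaks(peaks),
                 peak_positions = peaks,
                 n_spots_used = sum(is.finite(intensities) & intensities > 0),
                 binwidth = binwidth, method = method),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Unit-intensity calibration\n")
  cat("  unit intensity :", format(x$unit_intensity, digits = 5), "\n")
  cat("  peaks          :", paste(format(head(x$peak_positions, 6), digits = 5),
                                  collapse = ", "), "\n")
  cat("  spots used     :", x$n_spots_used, "\n")
  invisible(x)
}

#' Convert spot integrals to integer molecule counts
#'
#' Each spot's count is its integral divided by the unit intensity, rounded
#' to the nearest integer with ties away from zero. Spots rounding to zero
#' (integral below half a unit) are treated as noise and discarded; a cell
#' whose spots are all discarded has a true count of zero.
#'
#' @param integrals numeric vector of background-free spot integrals.
#' @param unit_intensity intensity of a single molecule (> 0).
#' @return list with `per_spot` (integer counts, 0 = discarded), `retained`
#'   (logical), and `total` (sum of retained counts).
#' @export
counts_from_spots <- function(integrals, unit_intensity) {
  stopifnot(unit_intensity > 0)
  # round half away from zero (integrals are nonnegative in practice)
  k <- as.integer(floor(integrals / unit_intensity + 0.5))
  retained <- k >= 1
  list(per_spot = ifelse(retained, k, 0L), retained = retained,
       total = sum(k[retained]))
}

#' Per-cell molecule counts from a spot table
#'
#' Applies [counts_from_spots()] within each cell of one channel and returns
#' a per-cell table. Cells present in `cell_ids` but without retained spots
#' get a count of zero (these populate the zero class of the copy-number
#' distribution).
#'
#' @param spots data.frame with at least `cell_id` and `integral` columns
#'   (one channel).
#' @param unit_intensity single-molecule intensity.
#' @param cell_ids full set of cell labels to report (defaults to the labels
#'   present in `spots`).
#' @return data.frame (cell_id, count).
#' @export
counts_per_cell <- function(spots, unit_intensity, cell_ids = NULL) {
  if (is.null(cell_ids)) cell_ids <- sort(unique(spots$cell_id))
  counts <- vapply(cell_ids, function(cid) {
    ints <- spots$integral[spots$cell_id == cid]
    if (length(ints) == 0) return(0L)
    as.integer(counts_from_spots(ints, unit_intensity)$total)
  }, integer(1))
  data.frame(cell_id = cell_ids, count = counts)
}

#' Empirical copy-number distribution with optional random subsampling
#'
#' Selects `n_subsample` cells uniformly without replacement (all cells when
#' `NULL`) and summarizes the count distribution: mean, standard deviation
#' and the fraction of cells with zero molecules (e.g. the plasmid-loss
#' fraction).
#'
#' @param counts integer vector of per-cell counts.
#' @param n_subsample cells to draw without replacement; `NULL` = all.
#' @param seed integer seed for the subsample.
#' @return list: `counts` (the subsample), `mean`, `sd`, `zero_fraction`,
#'   `n`, `table` (count frequencies).
#' @export
population_distribution <- function(counts, n_subsample = NULL, seed = NULL) {
  stopifnot(all(counts >= 0))
  if (!is.null(n_subsample)) {
    if (n_subsample > length(counts)) {
      stop_pf("cannot subsample ", n_subsample, " from ", length(counts),
              " cells without replacement", class = "pf_bad_input")
    }
    counts <- with_seed(seed, counts[sample.int(length(counts), n_subsample)])
  }
  list(counts = counts, mean = mean(counts), sd = sd(counts),
       zero_fraction = mean(counts == 0), n = length(counts),
       table = table(counts))
}
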