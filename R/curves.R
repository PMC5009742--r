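#' Construct a fluorescence curve
#'
#' A single well's time-ordered fluorescence readout: either a real-time
#' amplification trace (time in minutes) or a melt trace (temperature in
#' degrees Celsius).
#'
#' @param well well identifier (character scalar).
#' @param times strictly increasing numeric vector: minutes for
#'   amplification curves, degrees C for melt curves.
#' @param rfu relative fluorescence units, same length as `times`.
#' @param kind `"amplification"` or `"melt"`.
#' @return An object of class `fluorescence_curve`.
#' @export
fluorescence_curve <- function(well, times, rfu,
                               kind = c("amplification", "melt")) {
  kind <- match.arg(kind)
  if (!is.numeric(times) || !is.numeric(rfu) ||
      length(times) != length(rfu)) {
    stop_input("times and rfu must be numeric vectors of equal length")
  }
  if (length(times) < 10L) {
    stop_input("curve for well '%s' has %d points; at least 10 required",
               as.character(well), length(times))
  }
  if (anyNA(times) || anyNA(rfu)) {
    stop_input("curve for well '%s' contains missing values",
               as.character(well))
  }
  if (any(diff(times) <= 0)) {
    stop_input("times must be strictly increasing for well '%s'",
               as.character(well))
  }
  structure(list(well = as.character(well), times = as.numeric(times),
                 rfu = as.numeric(rfu), kind = kind),
            class = "fluorescence_curve")
}

#' @export
print.fluorescence_curve <- function(x, ...) {
  cat(sprintf("<fluorescence_curve> well %s (%s), %d points, %s %.3g-%.3g\n",
              x$well, x$kind, length(x$times),
              if (x$kind == "melt") "temp" else "t", min(x$times),
              max(x$times)))
  invisible(x)
}

# Savitzky-Golay first derivative on a (near-)uniform grid.
sg_derivative <- function(values, times, smooth_window, poly_order) {
  if (smooth_window %% 2L == 0L) {
    stop_input("smooth_window must be odd (got %d)", smooth_window)
  }
  if (smooth_window < poly_order + 2L) {
    stop_input("smooth_window must be >= poly_order + 2")
  }
  if (smooth_window > length(values)) {
    stop_input("smooth_window (%d) exceeds curve length (%d)",
               smooth_window, length(values))
  }
  dt <- median(diff(times))
  signal::sgolayfilt(values, p = poly_order, n = smooth_window, m = 1,
                     ts = dt)
}

# Parabolic refinement of a grid argmax: vertex of the parabola through
# (i-1, i, i+1). Falls back to the grid point at the boundary or when the
# three points are collinear.
refine_peak <- function(times, y, i) {
  n <- length(y)
  if (i <= 1L || i >= n) return(times[i])
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (denom >= 0 || abs(denom) < .Machine$double.eps) return(times[i])
  offset <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
  offset <- max(-1, min(1, offset))
  dt <- if (i < n) times[i + 1L] - times[i] else times[i] - times[i - 1L]
  times[i] + offset * dt
}

#' Extract the point of inflection (POI) from an amplification curve
#'
#' The POI is the time of maximum slope of the sigmoidal real-time
#' fluorescence curve -- the isothermal analogue of qPCR's Cq. The first
#' derivative is estimated by Savitzky-Golay local polynomial smoothing and
#' its grid maximum refined by parabolic interpolation. A well is declared
#' non-amplifying when the maximal slope does not exceed `min_slope`.
#'
#' @param curve a [fluorescence_curve()] of kind `"amplification"`.
#' @param smooth_window odd window length (points) of the local polynomial
#'   derivative filter.
#' @param poly_order polynomial order of the filter.
#' @param min_slope minimum slope excess (RFU/min) over the trace's median
#'   derivative required to call a well amplifying. Default `NULL` uses 5x
#'   the robust dispersion (MAD) of the derivative, i.e. five baseline
#'   standard deviations for traces that are mostly flat; both the excess
#'   and the default threshold scale with the fluorescence axis, so the
#'   call is invariant to affine rescaling of RFU.
#' @return An object of class `poi_result`: list with `poi` (minutes, `NA`
#'   when not amplified), `max_slope` (RFU/min), `amplified` (logical), and
#'   `qc_notes` (character).
#' @export
extract_poi <- function(curve, smooth_window = 7L, poly_order = 2L,
                        min_slope = NULL) {
  stopifnot(inherits(curve, "fluorescence_curve"))
  if (curve$kind != "amplification") {
    stop_input("extract_poi requires an amplification curve (got '%s')",
               curve$kind)
  }
  n <- length(curve$times)
  deriv <- sg_derivative(curve$rfu, curve$times, smooth_window, poly_order)
  notes <- character(0)
  # a sigmoid is quiescent over most of its span, so the median/MAD of the
  # derivative estimate the baseline slope level and its noise
  base_level <- median(deriv)
  if (is.null(min_slope)) {
    min_slope <- 5 * stats::mad(deriv)
    if (!is.finite(min_slope)) min_slope <- 0
  }
  i <- which.max(deriv)             # ties resolve to the earliest time
  max_slope <- deriv[i]
  # numeric floor: slopes indistinguishable from float noise on the RFU
  # scale never count as amplification
  slope_floor <- 1e-9 * max(abs(curve$rfu)) / median(diff(curve$times))
  amplified <- is.finite(max_slope) && max_slope > slope_floor &&
    (max_slope - base_level) > min_slope
  poi <- NA_real_
  if (amplified) {
    poi <- refine_peak(curve$times, deriv, i)
    if (i <= smooth_window %/% 2L || i > n - smooth_window %/% 2L) {
      notes <- c(notes, "max slope at curve boundary; POI unreliable")
    }
  } else {
    notes <- c(notes, "no amplification above slope threshold")
  }
  structure(list(well = curve$well, poi = poi, max_slope = max_slope,
                 amplified = amplified, min_slope = min_slope,
                 qc_notes = notes),
            class = "poi_result")
}

#' @export
print.poi_result <- function(x, ...) {
  if (x$amplified) {
    cat(sprintf("<poi_result> well %s: POI %.2f min (max slope %.3g RFU/min)\n",
                x$well, x$poi, x$max_slope))
  } else {
    cat(sprintf("<poi_result> well %s: not amplified\n", x$well))
  }
  invisible(x)
}

# Topographic prominence of local maxima in y at indices `peaks`.
peak_prominence <- function(y, peaks) {
  vapply(peaks, function(i) {
    h <- y[i]
    left_min <- h
    j <- i - 1L
    while (j >= 1L && y[j] <= h) {
      left_min <- min(left_min, y[j])
      j <- j - 1L
    }
    if (j < 1L) left_min <- min(y[seq_len(i)])
    right_min <- h
    j <- i + 1L
    while (j <= length(y) && y[j] <= h) {
      right_min <- min(right_min, y[j])
      j <- j + 1L
    }
    if (j > length(y)) right_min <- min(y[i:length(y)])
    h - max(left_min, right_min)
  }, numeric(1))
}

#' Call melting temperatures from a melt curve
#'
#' Tm values are read as the peaks of the negative derivative -dF/dT of the
#' dye fluorescence with respect to temperature. Peaks are required to
#' exceed a prominence threshold; positions are refined by parabolic
#' interpolation.
#'
#' @param curve a [fluorescence_curve()] of kind `"melt"` (times hold
#'   temperature in degrees C).
#' @param smooth_window,poly_order Savitzky-Golay derivative filter
#'   parameters.
#' @param min_prominence minimum peak prominence, as a fraction of the
#'   global -dF/dT maximum (default 0.1).
#' @return Numeric vector of Tm values (degrees C) sorted by decreasing
#'   prominence, with attribute `"prominence"`; empty when nothing
#'   qualifies.
#' @export
call_tm <- function(curve, smooth_window = 7L, poly_order = 2L,
                    min_prominence = 0.1) {
  stopifnot(inherits(curve, "fluorescence_curve"))
  if (curve$kind != "melt") {
    stop_input("call_tm requires a melt curve (got '%s')", curve$kind)
  }
  neg <- -sg_derivative(curve$rfu, curve$times, smooth_window, poly_order)
  n <- length(neg)
  top <- max(neg)
  # slopes indistinguishable from float noise on the RFU scale are no melt
  slope_floor <- 1e-9 * max(abs(curve$rfu)) / median(diff(curve$times))
  if (!is.finite(top) || top <= slope_floor) {
    return(structure(numeric(0), prominence = numeric(0)))
  }
  idx <- which(diff(sign(diff(neg))) < 0) + 1L   # strict local maxima
  idx <- idx[neg[idx] > 0]
  if (length(idx) == 0L) {
    return(structure(numeric(0), prominence = numeric(0)))
  }
  prom <- peak_prominence(neg, idx)
  keep <- prom >= min_prominence * top
  idx <- idx[keep]
  prom <- prom[keep]
  if (length(idx) == 0L) {
    return(structure(numeric(0), prominence = numeric(0)))
  }
  ord <- order(prom, decreasing = TRUE)
  tms <- vapply(idx[ord], function(i) refine_peak(curve$times, neg, i),
                numeric(1))
  structure(tms, prominence = prom[ord])
}

#' Subtract a linear baseline from an amplification curve
#'
#' Fits a straight line to the initial pre-amplification region (the early
#' points whose slope stays below a fraction of the maximal slope) and
#' subtracts it from the whole trace, removing both static background and
#' linear drift. Idempotent on curves whose baseline is already flat at
#' zero.
#'
#' @param curve a [fluorescence_curve()] of kind `"amplification"`.
#' @param smooth_window,poly_order derivative filter parameters used to
#'   locate the flat region.
#' @param slope_frac slope threshold as a fraction of the maximal derivative
#'   (default 0.2); points before the first crossing form the baseline.
#' @param min_points minimum number of baseline points (default 5).
#' @return The corrected `fluorescence_curve`.
#' @export
baseline_correct <- function(curve, smooth_window = 7L, poly_order = 2L,
                             slope_frac = 0.2, min_points = 5L) {
  stopifnot(inherits(curve, "fluorescence_curve"))
  if (curve$kind != "amplification") {
    stop_input("baseline_correct requires an amplification curve")
  }
  n <- length(curve$times)
  if (n < min_points) {
    stop_input("need at least %d points for baseline estimation", min_points)
  }
  deriv <- sg_derivative(curve$rfu, curve$times, smooth_window, poly_order)
  thresh <- slope_frac * max(abs(deriv))
  rising <- which(abs(deriv) > thresh)
  k <- if (length(rising) == 0L) n else rising[1L] - 1L
  k <- max(k, min_points)
  k <- min(k, n)
  idx <- seq_len(k)
  fit <- lm(rfu ~ times, data = data.frame(times = curve$times[idx],
                                           rfu = curve$rfu[idx]))
  baseline <- coef(fit)[1] + coef(fit)[2] * curve$times
  fluorescence_curve(curve$well, curve$times, curve$rfu - baseline,
                     kind = curve$kind)
}
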