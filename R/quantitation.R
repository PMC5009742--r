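#' Fit a log-linear POI calibration
#'
#' Ordinary least squares of POI (minutes) on log10(input copies). EXPAR
#' calibrations are straight lines in this space; for a well-behaved assay
#' the slope is negative (more input, earlier inflection).
#'
#' @param copies input copy numbers, `> 0`.
#' @param poi observed POI values, minutes, same length.
#' @return An object of class `calibration_fit`: `intercept`, `slope`
#'   (minutes per log10 copies, regression convention
#'   `POI = intercept + slope * log10(copies)`), `r` (Pearson correlation,
#'   `NA` for degenerate data), `range` (`[copies_min, copies_max]` of the
#'   fitted points), `n_points`, and `degenerate` flag.
#' @export
#' @examples
#' cp <- 10^(0:11)
#' fit <- fit_calibration(cp, 28.3 - 2.09 * log10(cp))
#' fit$slope     # -2.09
fit_calibration <- function(copies, poi) {
  if (length(copies) != length(poi)) {
    stop_input("copies and poi must have equal length")
  }
  if (length(copies) < 3L) {
    stop_input("at least 3 calibration points required (got %d)",
               length(copies))
  }
  if (any(!is.finite(copies)) || any(copies <= 0)) {
    stop_input("all copy numbers must be positive and finite")
  }
  lg <- log10(copies)
  fit <- lm(poi ~ lg)
  r <- suppressWarnings(stats::cor(lg, poi))
  degenerate <- !is.finite(r) || var(poi) == 0
  structure(list(intercept = unname(coef(fit)[1]),
                 slope = unname(coef(fit)[2]),
                 r = if (degenerate) NA_real_ else r,
                 range = range(copies),
                 n_points = length(copies),
                 degenerate = degenerate),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<calibration_fit> POI = %s %+s * lg(copies)",
              format(x$intercept, digits = digits),
              format(x$slope, digits = digits)))
  if (!is.na(x$r)) cat(sprintf("  (r = %s)", format(x$r, digits = digits)))
  if (x$degenerate) cat("  [degenerate]")
  cat(sprintf("\n  valid range: %.3g - %.3g copies, %d points\n",
              x$range[1], x$range[2], x$n_points))
  invisible(x)
}

#' Predicted POI at a given input
#'
#' @param fit a `calibration_fit`.
#' @param copies input copies.
#' @return Predicted POI, minutes.
#' @export
predict_poi <- function(fit, copies) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (any(copies <= 0)) stop_input("copies must be positive")
  fit$intercept + fit$slope * log10(copies)
}

#' Fit a two-segment (piecewise linear) POI calibration
#'
#' Standard-template EXPAR calibrations can show two linear regimes with
#' different slopes. The breakpoint is chosen over candidate knots (every
#' interior data abscissa in log10 space plus midpoints between neighbours)
#' minimising the total residual sum of squares, with at least 3 points per
#' segment.
#'
#' @param copies,poi calibration points; at least 6 points spanning at least
#'   4 decades of input.
#' @return An object of class `piecewise_fit`: `lower` and `upper`
#'   [fit_calibration()] segments, `breakpoint` (log10 copies), `rss`, and a
#'   `degenerate` flag set when a single line already explains the data.
#' @export
fit_piecewise <- function(copies, poi) {
  if (length(copies) < 6L) {
    stop_input("at least 6 points required for a two-segment fit")
  }
  if (any(copies <= 0)) stop_input("all copy numbers must be positive")
  lg <- log10(copies)
  if (diff(range(lg)) < 4) {
    stop_input("points must span at least 4 decades (span %.2f)",
               diff(range(lg)))
  }
  ord <- order(lg)
  lg <- lg[ord]
  poi <- poi[ord]
  copies <- copies[ord]
  seg_rss <- function(idx) {
    f <- lm(poi[idx] ~ lg[idx])
    sum(resid(f)^2)
  }
  u <- sort(unique(lg))
  cand <- sort(unique(c(u[-c(1, length(u))],
                        (u[-1] + u[-length(u)]) / 2)))
  best <- NULL
  for (bp in cand) {
    left <- which(lg <= bp)
    right <- which(lg >= bp)
    if (length(left) < 3L || length(right) < 3L) next
    if (length(unique(lg[left])) < 2L || length(unique(lg[right])) < 2L) next
    rss <- seg_rss(left) + seg_rss(right)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(bp = bp, left = left, right = right, rss = rss)
    }
  }
  if (is.null(best)) stop_input("no admissible breakpoint with >= 3 points per segment")
  single <- lm(poi ~ lg)
  single_rss <- sum(resid(single)^2)
  scale <- max(var(poi) * (length(poi) - 1), .Machine$double.eps)
  degenerate <- (single_rss - best$rss) / scale < 1e-6
  if (degenerate) {
    seg <- fit_calibration(copies, poi)
    lower <- upper <- seg
  } else {
    lower <- fit_calibration(copies[best$left], poi[best$left])
    upper <- fit_calibration(copies[best$right], poi[best$right])
  }
  structure(list(lower = lower, upper = upper, breakpoint = best$bp,
                 rss = if (degenerate) single_rss else best$rss,
                 degenerate = degenerate),
            class = "piecewise_fit")
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat(sprintf("<piecewise_fit> breakpoint at lg(copies) = %.3f%s\n",
              x$breakpoint, if (x$degenerate) " [degenerate: single line]" else ""))
  cat("  lower: "); print(x$lower)
  cat("  upper: "); print(x$upper)
  invisible(x)
}

#' Inverse prediction: copy number from an observed POI
#'
#' @param fit a `calibration_fit`.
#' @param poi observed POI, minutes.
#' @return Estimated input copies, `10^((poi - intercept) / slope)`. Warns
#'   when the estimate falls outside the calibration's fitted range.
#' @export
#' @examples
#' fit <- fit_calibration(10^(0:11), 28.3 - 2.09 * log10(10^(0:11)))
#' invert_poi(fit, 7.4)   # 1e10 copies
invert_poi <- function(fit, poi) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$degenerate || fit$slope == 0) {
    stop_domain("calibration slope is zero; POI carries no copy information")
  }
  copies <- 10^((poi - fit$intercept) / fit$slope)
  out_of_range <- copies < fit$range[1] | copies > fit$range[2]
  if (any(out_of_range)) {
    warning(sprintf("%d estimate(s) outside the calibrated range [%.3g, %.3g]",
                    sum(out_of_range), fit$range[1], fit$range[2]),
            call. = FALSE)
  }
  copies
}

# Avogadro constant, per mole.
AVOGADRO <- 6.022e23

#' Convert between molecule counts and molar amounts
#'
#' `copies_from_amount(1e-14)` (10 fmol) gives 6.02e9 copies;
#' `copies_from_amount(1e-23)` (0.01 zmol) gives about 6 molecules.
#'
#' @param amount amount of substance, moles, `>= 0`.
#' @param copies molecule count, `>= 0`.
#' @return The corresponding copy number / molar amount.
#' @export
copies_from_amount <- function(amount) {
  if (any(amount < 0)) stop_domain("amount must be non-negative")
  amount * AVOGADRO
}

#' @rdname copies_from_amount
#' @export
amount_from_copies <- function(copies) {
  if (any(copies < 0)) stop_domain("copies must be non-negative")
  copies / AVOGADRO
}

#' Estimate the extensible-duplex fraction from a quenching experiment
#'
#' When a doubly dye-labelled template is incubated with a doubly
#' quencher-labelled trigger, the fractional fluorescence drop at the
#' template's 3' terminus reports trigger bound there, and likewise at the
#' 5' terminus. The extensible fraction is the 3' share of the total bound
#' signal: `phi = drop_3 / (drop_3 + drop_5)`.
#'
#' @param drop_3prime fluorescence drop at the 3'-terminal label, percent.
#' @param drop_5prime fluorescence drop at the 5'-terminal label, percent.
#' @return phi in `[0, 1]`.
#' @export
#' @examples
#' estimate_phi_from_quench(51, 54)      # symmetric template, ~0.49
#' estimate_phi_from_quench(93.1, 36.8)  # biotin-tagged template, ~0.72
estimate_phi_from_quench <- function(drop_3prime, drop_5prime) {
  for (d in c(drop_3prime, drop_5prime)) {
    if (!is.numeric(d) || length(d) != 1L || d < 0 || d > 100) {
      stop_domain("drops must be single percentages in [0, 100]")
    }
  }
  if (drop_3prime + drop_5prime == 0) {
    stop_domain("both drops are zero; phi is undefined")
  }
  drop_3prime / (drop_3prime + drop_5prime)
}

#' Relative error of a measurement against a reference
#'
#' @param measured measured concentration(s).
#' @param reference reference concentration(s), `> 0`.
#' @return `(measured - reference) / reference * 100`, percent.
#' @export
relative_error <- function(measured, reference) {
  if (any(reference <= 0)) stop_domain("reference must be positive")
  (measured - reference) / reference * 100
}

#' Relative standard deviation of replicate measurements
#'
#' @param values at least two replicate values with non-zero mean.
#' @return Sample standard deviation over mean, percent.
#' @export
rsd <- function(values) {
  if (length(values) < 2L) stop_input("rsd needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop_domain("mean of values is zero; RSD undefined")
  sd(values) / m * 100
}

#' Published inter-method let-7a quantitation of tissue RNA
#'
#' Reference table of let-7a levels (1e6 copies per microlitre) in total-RNA
#' extracts from lung and cervical cancer tissues, measured by RT-qPCR
#' (reference method) and by EXPAR on a biotin-tagged and a toehold/biotin
#' template, with per-method replicate RSDs. Used as the fixed input for
#' inter-method accuracy accounting.
#'
#' @return A data frame with columns `sample`, `rtqpcr_mean`, `rtqpcr_rsd`,
#'   `biotin_mean`, `biotin_rsd`, `toehold_mean`, `toehold_rsd`.
#' @export
let7a_tissue_levels <- function() {
  data.frame(
    sample = c("Lung cancer 1", "Lung cancer 2", "Lung cancer 3",
               "Cervical cancer 1", "Cervical cancer 2"),
    rtqpcr_mean = c(4.05, 0.418, 3.98, 0.406, 4.30),
    rtqpcr_rsd = c(2.42, 25.6, 2.54, 48.5, 3.56),
    biotin_mean = c(4.33, 0.373, 4.33, 0.385, 4.09),
    biotin_rsd = c(1.69, 23.3, 1.76, 31.2, 1.83),
    toehold_mean = c(4.17, 0.361, 4.09, 0.413, 4.87),
    toehold_rsd = c(0.89, 27.1, 2.03, 12.3, 1.62),
    stringsAsFactors = FALSE
  )
}
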