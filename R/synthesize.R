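#' Phenomenological model of a sigmoidal amplification curve
#'
#' Real-time EXPAR traces are sigmoidal: a flat (possibly drifting)
#' baseline, an exponential-looking rise, and a plateau set by dye/dNTP
#' saturation. The generator uses a logistic in time,
#' `RFU(t) = baseline + drift * t + amplitude / (1 + exp(-k (t - poi_true)))
#' + N(0, noise_sd)`, whose midpoint is exactly the point of maximum slope,
#' matching the POI definition.
#'
#' @param baseline background fluorescence (RFU).
#' @param amplitude plateau rise above baseline (RFU), `> 0`.
#' @param k logistic steepness (per minute), `> 0`.
#' @param poi_true true inflection time (minutes).
#' @param noise_sd Gaussian read noise (RFU), `>= 0`.
#' @param drift linear baseline drift (RFU per minute).
#' @return An object of class `curve_model`.
#' @export
curve_model <- function(baseline = 100, amplitude = 100, k = 1.2,
                        poi_true = 12, noise_sd = 0, drift = 0) {
  if (amplitude <= 0) stop_domain("amplitude must be positive")
  if (k <= 0) stop_domain("steepness k must be positive")
  if (noise_sd < 0) stop_domain("noise_sd must be non-negative")
  structure(list(baseline = baseline, amplitude = amplitude, k = k,
                 poi_true = poi_true, noise_sd = noise_sd, drift = drift),
            class = "curve_model")
}

#' Generate one synthetic amplification curve
#'
#' @param model a [curve_model()].
#' @param t_grid increasing time grid, minutes.
#' @param seed RNG seed (NULL uses the current stream).
#' @param well well label for the resulting curve.
#' @return A [fluorescence_curve()] of kind `"amplification"`.
#' @export
#' @examples
#' cm <- curve_model(poi_true = 7.19, noise_sd = 0)
#' cv <- generate_curve(cm, seq(0, 30, 0.1))
#' extract_poi(cv)
generate_curve <- function(model, t_grid, seed = NULL, well = "A1") {
  stopifnot(inherits(model, "curve_model"))
  if (any(diff(t_grid) <= 0)) stop_input("t_grid must be increasing")
  clean <- model$baseline + model$drift * t_grid +
    model$amplitude / (1 + exp(-model$k * (t_grid - model$poi_true)))
  noise <- if (model$noise_sd > 0) {
    with_seed(seed, rnorm(length(t_grid), 0, model$noise_sd))
  } else {
    0
  }
  fluorescence_curve(well, t_grid, clean + noise, kind = "amplification")
}

#' Log-linear calibration truth used by the plate generator
#'
#' Encodes the assay's calibration law `POI = a - b * log10(copies)` and the
#' copy-number range over which it is valid.
#'
#' @param a intercept, minutes.
#' @param b decadic slope magnitude, minutes per log10(copies); positive `b`
#'   means POI decreases with increasing input (the usual behaviour).
#' @param range length-2 numeric, valid `[copies_min, copies_max]`.
#' @return An object of class `calibration_truth`.
#' @export
calibration_truth <- function(a = 28.3, b = 2.09, range = c(0.602, 6.02e11)) {
  if (length(range) != 2L || range[1] >= range[2]) {
    stop_input("range must be [copies_min, copies_max] with min < max")
  }
  if (b == 0) stop_domain("slope b must be non-zero")
  structure(list(a = a, b = b, range = as.numeric(range)),
            class = "calibration_truth")
}

#' Plate layout specification for the simulator
#'
#' @param wells data frame with columns `well` (unique ids), `species`,
#'   `copies` (input copies, `>= 0`), and optionally `template`
#'   (`"standard"`, `"biotin"` or `"toehold_biotin"`) and `replicate`.
#' @param read_interval fluorescence read interval, minutes (instrument
#'   default: one read per 60 s).
#' @param duration run length, minutes.
#' @param seed plate-level RNG seed.
#' @return An object of class `plate_spec`.
#' @export
plate_spec <- function(wells, read_interval = 1, duration = 40, seed = 1L) {
  need <- c("well", "species", "copies")
  if (!is.data.frame(wells) || !all(need %in% names(wells))) {
    stop_input("wells must be a data.frame with columns: %s",
               paste(need, collapse = ", "))
  }
  if (anyDuplicated(wells$well)) stop_input("well ids must be unique")
  if (any(wells$copies < 0)) stop_input("copies must be non-negative")
  if (read_interval <= 0 || duration <= 0) {
    stop_input("read_interval and duration must be positive")
  }
  if (!"template" %in% names(wells)) wells$template <- "biotin"
  if (!"replicate" %in% names(wells)) wells$replicate <- 1L
  structure(list(wells = wells, read_interval = read_interval,
                 duration = duration, seed = seed),
            class = "plate_spec")
}

#' Simulate a full plate of amplification curves with known truth
#'
#' Each well's true POI follows the calibration law applied to its
#' effective input `copies * fraction`, where `fraction` is the species'
#' cross-reactivity with the assay (1 for the target, small for
#' interferents, 0 for non-triggering species). Wells whose effective input
#' falls below `floor_copies` stay flat; between the floor and one molecule
#' Poisson presence sampling decides whether the well amplifies at all.
#'
#' @param spec a [plate_spec()].
#' @param truth a [calibration_truth()].
#' @param curve_defaults a [curve_model()]; its `poi_true` field is
#'   overridden per well.
#' @param cross_reactivity named numeric vector or list mapping every
#'   species in the plate to its effective-trigger fraction in `[0, 1]`.
#' @param floor_copies no-amplification floor, copies (default 0.1).
#' @return An object of class `plate_run`: list with `curves` (named list of
#'   [fluorescence_curve()]), `truth` (data frame: well, species, copies,
#'   fraction, eff_copies, poi_true, amplifies), `spec`, and `seed`.
#' @export
generate_plate <- function(spec, truth, curve_defaults = curve_model(),
                           cross_reactivity = c(target = 1),
                           floor_copies = 0.1) {
  stopifnot(inherits(spec, "plate_spec"), inherits(truth, "calibration_truth"),
            inherits(curve_defaults, "curve_model"))
  cr <- unlist(cross_reactivity)
  wells <- spec$wells
  unknown <- setdiff(unique(wells$species), names(cr))
  if (length(unknown) > 0L) {
    stop_input("species without cross-reactivity entry: %s",
               paste(unknown, collapse = ", "))
  }
  t_grid <- seq(0, spec$duration, by = spec$read_interval)
  curves <- vector("list", nrow(wells))
  names(curves) <- wells$well
  info <- wells
  info$fraction <- as.numeric(cr[wells$species])
  info$eff_copies <- info$copies * info$fraction
  info$poi_true <- NA_real_
  info$amplifies <- FALSE
  with_seed(spec$seed, {
    for (i in seq_len(nrow(wells))) {
      eff <- info$eff_copies[i]
      amplifies <- eff >= floor_copies
      if (amplifies && eff < 1) {
        n_mol <- rpois(1L, eff)       # single-molecule occupancy
        amplifies <- n_mol > 0
        if (amplifies) eff <- n_mol
      }
      m <- curve_defaults
      if (amplifies) {
        poi <- truth$a - truth$b * log10(eff)
        poi <- min(max(poi, 0), spec$duration)
        m$poi_true <- poi
        info$poi_true[i] <- poi
        info$amplifies[i] <- TRUE
      } else {
        m$amplitude <- .Machine$double.eps   # effectively flat
        m$poi_true <- 2 * spec$duration      # rise pushed past the run
      }
      curves[[i]] <- generate_curve(m, t_grid, seed = NULL,
                                    well = wells$well[i])
    }
  })
  structure(list(curves = curves, truth = info, spec = spec,
                 seed = spec$seed),
            class = "plate_run")
}

#' @export
print.plate_run <- function(x, ...) {
  cat(sprintf("<plate_run> %d wells, %g min at %g-min reads, seed %s\n",
              length(x$curves), x$spec$duration, x$spec$read_interval,
              format(x$seed)))
  invisible(x)
}

#' Generate a synthetic melt curve
#'
#' Each duplex contributes a two-state (logistic-in-temperature) melting
#' transition; the dye signal is the sum of the still-hybridised fractions,
#' so `-dF/dT` has a local maximum near each Tm.
#'
#' @param tms melting temperatures, degrees C.
#' @param widths transition widths, degrees C (recycled; default 1.5).
#' @param amplitudes fluorescence contribution of each transition, RFU
#'   (recycled; default 100).
#' @param T_grid increasing temperature grid within `[45, 95]` degrees C.
#' @param noise_sd Gaussian noise, RFU.
#' @param seed RNG seed.
#' @param well well label.
#' @return A [fluorescence_curve()] of kind `"melt"`.
#' @export
generate_melt_curve <- function(tms, widths = 1.5, amplitudes = 100,
                                T_grid = seq(45, 95, 0.2), noise_sd = 0,
                                seed = NULL, well = "M1") {
  if (any(diff(T_grid) <= 0)) stop_input("T_grid must be increasing")
  if (min(T_grid) < 45 || max(T_grid) > 95) {
    stop_input("T_grid must lie within [45, 95] degrees C")
  }
  k <- length(tms)
  widths <- rep_len(widths, k)
  amplitudes <- rep_len(amplitudes, k)
  rfu <- rep(0, length(T_grid))
  for (i in seq_len(k)) {
    rfu <- rfu + amplitudes[i] / (1 + exp((T_grid - tms[i]) / widths[i]))
  }
  if (noise_sd > 0) {
    rfu <- rfu + with_seed(seed, rnorm(length(T_grid), 0, noise_sd))
  }
  fluorescence_curve(well, T_grid, rfu, kind = "melt")
}

#' Generate a paired method-comparison table
#'
#' Emulates quantifying the same samples by a reference method and a test
#' method, each with lognormal multiplicative replicate noise at a given
#' coefficient of variation, and summarises per sample the replicate means,
#' relative standard deviations, and the test method's relative error
#' against the reference mean.
#'
#' @param true_levels true concentrations, one per sample.
#' @param cv_ref,cv_test replicate coefficient of variation, percent.
#' @param n_reps replicates per method per sample (default 3).
#' @param seed RNG seed.
#' @param sample_names optional sample labels.
#' @return A data frame with one row per sample: `sample`, `true_level`,
#'   `ref_mean`, `ref_rsd`, `test_mean`, `test_rsd`, `re_pct`.
#' @export
generate_method_comparison <- function(true_levels, cv_ref = 10,
                                       cv_test = 10, n_reps = 3L,
                                       seed = NULL, sample_names = NULL) {
  if (cv_ref < 0 || cv_test < 0) stop_domain("cv must be non-negative")
  if (n_reps < 2L) stop_input("n_reps must be >= 2")
  if (is.null(sample_names)) {
    sample_names <- paste0("sample_", seq_along(true_levels))
  }
  draw <- function(level, cv_pct, n) {
    if (cv_pct == 0) return(rep(level, n))
    sdlog <- sqrt(log(1 + (cv_pct / 100)^2))
    level * rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  with_seed(seed, {
    rows <- lapply(seq_along(true_levels), function(i) {
      ref <- draw(true_levels[i], cv_ref, n_reps)
      tst <- draw(true_levels[i], cv_test, n_reps)
      data.frame(
        sample = sample_names[i],
        true_level = true_levels[i],
        ref_mean = mean(ref),
        ref_rsd = if (cv_ref == 0) 0 else rsd(ref),
        test_mean = mean(tst),
        test_rsd = if (cv_test == 0) 0 else rsd(tst),
        re_pct = relative_error(mean(tst), mean(ref))
      )
    })
    do.call(rbind, rows)
  })
}
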