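#' Flatten a simulated plate to instrument-export form
#'
#' @param x a `plate_run`.
#' @param ... unused.
#' @return Long data frame with columns `well`, `time_min`, `rfu`.
#' @export
as.data.frame.plate_run <- function(x, ...) {
  df <- do.call(rbind, lapply(x$curves, function(cv) {
    data.frame(well = cv$well, time_min = cv$times, rfu = cv$rfu)
  }))
  rownames(df) <- NULL
  df
}

#' Write plate / melt curves as CSV
#'
#' Amplification plates are written with columns `well, time_min, rfu`;
#' melt series with `well, temp_c, rfu` (UTF-8, '.' decimal).
#'
#' @param x a `plate_run`, a single [fluorescence_curve()], or a list of
#'   curves of one kind.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(x, path) {
  curves <- if (inherits(x, "plate_run")) x$curves
  else if (inherits(x, "fluorescence_curve")) list(x)
  else x
  kinds <- unique(vapply(curves, `[[`, "", "kind"))
  if (length(kinds) != 1L) stop_input("curves must share one kind")
  tcol <- if (kinds == "melt") "temp_c" else "time_min"
  df <- do.call(rbind, lapply(curves, function(cv) {
    out <- data.frame(well = cv$well, t = cv$times, rfu = cv$rfu)
    names(out)[2] <- tcol
    out
  }))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the truth sidecar of a simulated plate
#'
#' @param plate a `plate_run`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(plate, path) {
  stopifnot(inherits(plate, "plate_run"))
  truth <- plate$truth
  truth$seed <- plate$seed
  write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plate or melt CSV into fluorescence curves
#'
#' Accepts the export dialect written by [write_plate_csv()]: exact headers
#' `well,time_min,rfu` (amplification) or `well,temp_c,rfu` (melt). Rows
#' may arrive in any order; curves are grouped by well and time-sorted.
#' Duplicate (well, time) pairs and non-numeric cells are rejected with the
#' offending row numbers.
#'
#' @param path CSV file.
#' @return Named list of [fluorescence_curve()] objects.
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (identical(sort(names(df)), sort(c("well", "time_min", "rfu")))) {
    tcol <- "time_min"; kind <- "amplification"
  } else if (identical(sort(names(df)), sort(c("well", "temp_c", "rfu")))) {
    tcol <- "temp_c"; kind <- "melt"
  } else {
    stop_input("unrecognised headers (%s); expected well,time_min,rfu or well,temp_c,rfu",
               paste(names(df), collapse = ","))
  }
  tv <- suppressWarnings(as.numeric(df[[tcol]]))
  rv <- suppressWarnings(as.numeric(df$rfu))
  bad <- which(is.na(tv) | is.na(rv))
  if (length(bad) > 0L) {
    stop_input("non-numeric cells at data row(s): %s",
               paste(head(bad, 5), collapse = ", "))
  }
  key <- paste(df$well, tv, sep = "@")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop_input("duplicate (well, %s) pairs at data row(s): %s", tcol,
               paste(head(dup, 5), collapse = ", "))
  }
  curves <- lapply(split(seq_len(nrow(df)), df$well), function(idx) {
    o <- idx[order(tv[idx])]
    fluorescence_curve(df$well[o[1]], tv[o], rv[o], kind = kind)
  })
  curves[unique(df$well)]
}

#' Write per-well analysis results as CSV
#'
#' @param results data frame (list columns are joined with `;`).
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path) {
  df <- as.data.frame(results)
  for (nm in names(df)) {
    if (is.list(df[[nm]])) {
      df[[nm]] <- vapply(df[[nm]], function(v) paste(v, collapse = ";"), "")
    }
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read named sequences from a FASTA file
#'
#' @param path FASTA file with at least one record; `U` is allowed
#'   (RNA records are kept as-is, uppercased).
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_input("cannot parse FASTA: %s",
                                                 conditionMessage(e)))
  if (length(set) == 0L) stop_input("FASTA file has no records: %s", path)
  nms <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(nms)) {
    stop_input("duplicate FASTA record names: %s",
               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- nms
  seqs
}

#' Extract POIs from every curve of a plate
#'
#' @param x a `plate_run`, or a (named) list of amplification
#'   [fluorescence_curve()] objects, e.g. from [read_plate_csv()].
#' @param ... passed to [extract_poi()].
#' @return Data frame with one row per well: `well`, `poi`, `max_slope`,
#'   `amplified`, plus `species` and `copies` when `x` carries truth
#'   metadata.
#' @export
analyze_plate <- function(x, ...) {
  curves <- if (inherits(x, "plate_run")) x$curves else x
  rows <- lapply(curves, function(cv) {
    p <- extract_poi(cv, ...)
    data.frame(well = cv$well, poi = p$poi, max_slope = p$max_slope,
               amplified = p$amplified)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (inherits(x, "plate_run")) {
    res <- merge(res, x$truth[, c("well", "species", "copies")],
                 by = "well", sort = FALSE)
  }
  res
}

#' Assemble a pipeline run configuration
#'
#' Collects every tunable of the simulate-and-analyse pipeline: the
#' calibration truth driving the generator, plate geometry, noise, curve
#' shape, smoothing, thresholds, the specificity challenge, and the
#' method-comparison design.
#'
#' @param seed master RNG seed; stage seeds are derived from it.
#' @param read_interval fluorescence read interval, minutes.
#' @param duration run length, minutes; must exceed 10 read intervals.
#' @param calibration_a,calibration_b calibration truth
#'   `POI = a - b * lg(copies)`.
#' @param cal_range valid copy range of the truth.
#' @param decades log10(copies) levels of the calibration dilution series.
#' @param replicates wells per dilution level.
#' @param noise_sd curve noise, RFU.
#' @param curve a [curve_model()] supplying baseline/amplitude/steepness
#'   /drift defaults.
#' @param smooth_window,poly_order POI derivative filter settings.
#' @param min_slope amplification threshold (NULL = data-driven).
#' @param melt_prominence melt peak prominence fraction.
#' @param floor_copies no-amplification floor, copies.
#' @param template template kind label carried into the report.
#' @param cross_reactivity named fractions for the specificity plate
#'   (NULL skips the specificity stage).
#' @param specificity_copies input copies of each specificity well.
#' @param comparison_levels true levels for the method-comparison stage
#'   (NULL skips it).
#' @param cv_ref,cv_test method CVs, percent.
#' @param comparison_reps replicates per method and sample.
#' @param plate_csv,truth_csv input paths for analyze-only mode.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, read_interval = 1, duration = 40,
                       calibration_a = 28.3, calibration_b = 2.09,
                       cal_range = c(0.602, 6.02e11),
                       decades = 1:10, replicates = 1L, noise_sd = 0,
                       curve = curve_model(),
                       smooth_window = 7L, poly_order = 2L,
                       min_slope = NULL, melt_prominence = 0.1,
                       floor_copies = 0.1, template = "biotin",
                       cross_reactivity = NULL, specificity_copies = 6.02e9,
                       comparison_levels = NULL, cv_ref = 10, cv_test = 10,
                       comparison_reps = 3L,
                       plate_csv = NULL, truth_csv = NULL) {
  if (duration <= 10 * read_interval) {
    stop_input("duration must exceed 10 read intervals")
  }
  if (melt_prominence <= 0 || floor_copies <= 0) {
    stop_input("thresholds must be positive")
  }
  structure(as.list(environment()), class = "run_config")
}

#' Parse a plain-text key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values that parse
#' as numbers become numeric; comma-separated values become vectors.
#' Recognised keys are passed to [run_config()].
#'
#' @param path configuration file.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop_input("malformed config line: '%s'", ln)
    key <- trimws(parts[1])
    raw <- trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(raw))
    kv[[key]] <- if (all(!is.na(num))) num else raw
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(kv), known)
  if (length(unknown) > 0L) {
    stop_input("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(run_config, kv)
}

#' Run the simulate-and-analyse pipeline end to end
#'
#' Chains the package's stages into one deterministic report: simulate a
#' calibration dilution plate (or read one from disk), extract every well's
#' POI, fit the log-linear calibration (plus a two-segment fit when the
#' series spans at least four decades and two slope regimes genuinely
#' separate), then optionally run a specificity
#' challenge plate through the cross-reactivity report and a paired
#' method-comparison table with RE/RSD columns.
#'
#' @param config a [run_config()].
#' @param mode `"simulate"` (generate inputs from the config truth) or
#'   `"analyze_only"` (read `config$plate_csv` / `config$truth_csv`).
#' @return An object of class `expar_report`: list with elements
#'   `per_well`, `calibration`, `piecewise` (or NULL), `specificity`
#'   (or NULL), `comparison` (or NULL), `config`, and `mode`.
#' @export
run_pipeline <- function(config, mode = c("simulate", "analyze_only")) {
  stopifnot(inherits(config, "run_config"))
  mode <- match.arg(mode)
  truth <- calibration_truth(config$calibration_a, config$calibration_b,
                             config$cal_range)
  stage_fail <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop_input("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e))
    })
  }
  if (mode == "simulate") {
    wells <- expand.grid(rep = seq_len(config$replicates),
                         lg = config$decades)
    layout <- data.frame(
      well = sprintf("C%02d", seq_len(nrow(wells))),
      species = "let-7a",
      copies = 10^wells$lg,
      template = config$template,
      replicate = wells$rep
    )
    cm <- config$curve
    cm$noise_sd <- config$noise_sd
    plate <- stage_fail("simulate", generate_plate(
      plate_spec(layout, config$read_interval, config$duration,
                 seed = config$seed),
      truth, cm, cross_reactivity = c("let-7a" = 1),
      floor_copies = config$floor_copies))
    per_well <- stage_fail("analyze", analyze_plate(
      plate, smooth_window = config$smooth_window,
      poly_order = config$poly_order, min_slope = config$min_slope))
  } else {
    if (is.null(config$plate_csv)) {
      stop_input("analyze_only mode requires config$plate_csv")
    }
    curves <- stage_fail("ingest", read_plate_csv(config$plate_csv))
    per_well <- stage_fail("analyze", analyze_plate(
      curves, smooth_window = config$smooth_window,
      poly_order = config$poly_order, min_slope = config$min_slope))
    if (!is.null(config$truth_csv)) {
      tr <- read.csv(config$truth_csv)
      per_well <- merge(per_well, tr[, intersect(c("well", "species", "copies"),
                                                 names(tr))],
                        by = "well", sort = FALSE)
    }
  }
  cal <- NULL
  pw <- NULL
  if ("copies" %in% names(per_well)) {
    ok <- per_well$amplified & !is.na(per_well$poi) & per_well$copies > 0
    if (sum(ok) >= 3L) {
      cal <- stage_fail("calibrate",
                        fit_calibration(per_well$copies[ok],
                                        per_well$poi[ok]))
      span <- diff(range(log10(per_well$copies[ok])))
      if (sum(ok) >= 6L && span >= 4) {
        pw <- stage_fail("calibrate",
                         fit_piecewise(per_well$copies[ok],
                                       per_well$poi[ok]))
        # report a second regime only when its slopes genuinely separate
        if (pw$degenerate ||
            abs(pw$lower$slope - pw$upper$slope) <
              0.15 * abs(cal$slope)) {
          pw <- NULL
        }
      }
    }
  }
  specificity <- NULL
  if (!is.null(config$cross_reactivity) && !is.null(cal)) {
    cr <- unlist(config$cross_reactivity)
    layout <- data.frame(well = sprintf("S%02d", seq_along(cr)),
                         species = names(cr),
                         copies = config$specificity_copies,
                         template = config$template, replicate = 1L)
    cm <- config$curve
    cm$noise_sd <- config$noise_sd
    sp_plate <- stage_fail("specificity", generate_plate(
      plate_spec(layout, config$read_interval, config$duration,
                 seed = config$seed + 1L),
      truth, cm, cross_reactivity = cr,
      floor_copies = config$floor_copies))
    sp_res <- analyze_plate(sp_plate, smooth_window = config$smooth_window,
                            poly_order = config$poly_order,
                            min_slope = config$min_slope)
    specificity <- stage_fail("specificity", cross_reactivity_report(
      sp_res, cal, config$specificity_copies, target = "let-7a"))
  }
  comparison <- NULL
  if (!is.null(config$comparison_levels)) {
    comparison <- stage_fail("comparison", generate_method_comparison(
      config$comparison_levels, cv_ref = config$cv_ref,
      cv_test = config$cv_test, n_reps = config$comparison_reps,
      seed = config$seed + 2L))
  }
  structure(list(per_well = per_well, calibration = cal, piecewise = pw,
                 specificity = specificity, comparison = comparison,
                 config = config, mode = mode),
            class = "expar_report")
}

#' @export
print.expar_report <- function(x, ...) {
  cat(sprintf("<expar_report> (%s mode, seed %s)\n", x$mode,
              format(x$config$seed)))
  cat(sprintf("  wells analysed: %d (%d amplified)\n", nrow(x$per_well),
              sum(x$per_well$amplified)))
  if (!is.null(x$calibration)) {
    cat("  calibration: "); print(x$calibration)
  }
  if (!is.null(x$piecewise)) {
    cat(sprintf("  piecewise breakpoint: lg(copies) = %.2f\n",
                x$piecewise$breakpoint))
  }
  if (!is.null(x$specificity)) {
    cat(sprintf("  specificity: %d species challenged\n",
                nrow(x$specificity)))
  }
  if (!is.null(x$comparison)) {
    cat(sprintf("  method comparison: %d samples, max |RE| %.2f%%\n",
                nrow(x$comparison), max(abs(x$comparison$re_pct))))
  }
  invisible(x)
}
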