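#' Interference of a cross-reacting species, percent of input
#'
#' An interferent that triggers amplification produces a POI; reading that
#' POI through the target calibration yields the apparent copy number the
#' signal corresponds to. Interference is the apparent copies as a
#' percentage of the actual input copies of the interferent: a perfectly
#' cross-reacting species scores 100, a non-amplifying one 0.
#'
#' @param poi_interferent observed POI of the interferent well, minutes;
#'   `NA` for a non-amplifying well.
#' @param fit the target's `calibration_fit`.
#' @param input_copies interferent input, copies, `> 0`.
#' @return Interference, percent. Non-amplifying wells return 0.
#' @export
interference_percent <- function(poi_interferent, fit, input_copies) {
  if (input_copies <= 0) stop_input("input_copies must be positive")
  if (is.na(poi_interferent)) return(0)
  apparent <- suppressWarnings(invert_poi(fit, poi_interferent))
  apparent / input_copies * 100
}

#' Cross-reactivity report for a specificity plate
#'
#' Converts per-well POI results from a plate challenged with the target
#' and its family interferents (each at the same input) into an
#' interference table via the target calibration.
#'
#' @param results data frame with columns `well`, `species`, `poi`
#'   (minutes, `NA` when not amplified), `amplified` (logical), e.g. as
#'   produced by [analyze_plate()]. Replicate rows per species are averaged
#'   on the interference scale.
#' @param fit the target `calibration_fit`.
#' @param input_copies common input copy number of every challenged well.
#' @param target name of the target species (default `"let-7a"`); the plate
#'   must contain at least one target well.
#' @return A data frame of class `interference_table`, one row per species
#'   sorted by decreasing interference: `species`, `poi` (mean over
#'   amplified replicates, `NA` if none), `apparent_copies`,
#'   `interference_pct`, `n_wells`, `n_amplified`.
#' @export
cross_reactivity_report <- function(results, fit, input_copies,
                                    target = "let-7a") {
  need <- c("species", "poi", "amplified")
  if (!is.data.frame(results) || !all(need %in% names(results))) {
    stop_input("results must contain columns: %s", paste(need, collapse = ", "))
  }
  if (!target %in% results$species) {
    stop_input("plate has no reference well for target '%s'", target)
  }
  species <- unique(results$species)
  rows <- lapply(species, function(sp) {
    sub <- results[results$species == sp, , drop = FALSE]
    amp <- sub[sub$amplified & !is.na(sub$poi), , drop = FALSE]
    if (nrow(amp) == 0L) {
      data.frame(species = sp, poi = NA_real_, apparent_copies = 0,
                 interference_pct = 0, n_wells = nrow(sub), n_amplified = 0L)
    } else {
      ints <- vapply(amp$poi, interference_percent, numeric(1),
                     fit = fit, input_copies = input_copies)
      data.frame(species = sp, poi = mean(amp$poi),
                 apparent_copies = mean(ints) / 100 * input_copies,
                 interference_pct = mean(ints), n_wells = nrow(sub),
                 n_amplified = nrow(amp))
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$interference_pct), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interference_table", "data.frame")
  out
}

#' @export
print.interference_table <- function(x, ...) {
  cat("Cross-reactivity report (% of input recovered as apparent target)\n")
  df <- as.data.frame(x)
  df$interference_pct <- signif(df$interference_pct, 3)
  df$apparent_copies <- signif(df$apparent_copies, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
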