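# Shared fixtures for the exparkit test suite. Everything is generated in
# code; no binary data.

# Calibration law of the biotin-template assay used throughout as the
# generator truth: POI = 28.3 - 2.09 * lg(copies).
biotin_truth <- function() calibration_truth(28.3, 2.09, c(0.602, 6.02e11))

# Independent logistic evaluator (kept separate from curve_model /
# generate_curve so generator tests have an external oracle).
logistic_rfu <- function(t, baseline, amplitude, k, midpoint, drift = 0) {
  baseline + drift * t + amplitude / (1 + exp(-k * (t - midpoint)))
}

# Simple central-difference derivative, an oracle for the Savitzky-Golay
# filter path.
central_diff <- function(y, t) {
  n <- length(y)
  c(NA, (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)]), NA)
}

# A noiseless dilution plate on a fine grid, reused by calibration tests.
make_dilution_plate <- function(decades = 0:11, read_interval = 0.1,
                                duration = 40, seed = 1,
                                noise_sd = 0, k = 1.2) {
  wells <- data.frame(well = sprintf("W%02d", seq_along(decades)),
                      species = "let-7a", copies = 10^decades)
  generate_plate(plate_spec(wells, read_interval, duration, seed = seed),
                 biotin_truth(),
                 curve_model(noise_sd = noise_sd, k = k),
                 cross_reactivity = c("let-7a" = 1))
}

# run code under a local seed without touching the suite's RNG stream
with_seed_test <- getFromNamespace("with_seed", "exparkit")

# scratch file inside the session tempdir (cleaned up with the session)
temp_path <- function(name) tempfile(fileext = paste0("-", name))

random_dna <- function(n, seed) {
  with_seed_test(seed, paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = ""))
}
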