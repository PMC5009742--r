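let7a_rna <- "UGAGGUAGUAGGUUGUAUAGUU"
let7a_xprime <- "AACTATACAACCTACTACCTCA"

test_that("reverse complement handles DNA and RNA, and is an involution", {
  expect_identical(reverse_complement("ACGT"), "ACGT")   # palindrome
  expect_identical(reverse_complement(let7a_rna, "RNA"), let7a_xprime)
  expect_identical(reverse_complement("acgttg"), "CAACGT")  # case-folding
  for (s in 1:10) {
    x <- random_dna(25, seed = s)
    expect_identical(reverse_complement(reverse_complement(x)), x)
    expect_identical(nchar(reverse_complement(x)), nchar(x))
  }
  expect_error(reverse_complement("ACGU"), "position 4")
  expect_error(reverse_complement("ACXT"), "position 3")
})

test_that("template assembly follows the two-copy architecture", {
  d <- build_template(let7a_rna, kind = "standard", alphabet = "RNA")
  n <- nchar(let7a_xprime)
  expect_identical(substr(d$core, 1, n), let7a_xprime)
  expect_identical(substr(d$core, nchar(d$core) - n + 1, nchar(d$core)),
                   let7a_xprime)
  expect_true(is.na(d$biotin_position))
  expect_identical(d$full_template, d$core)

  b <- build_template(let7a_rna, kind = "biotin", alphabet = "RNA")
  expect_identical(b$core, d$core)        # same sequence, tag only
  expect_identical(b$biotin_position, 2L)

  tb <- build_template(let7a_rna, kind = "toehold_biotin", alphabet = "RNA")
  expect_identical(nchar(tb$toehold$invading) - nchar(tb$toehold$incumbent),
                   6L)
  expect_identical(tb$biotin_position, 2L)
  # hairpin arm pairs the template's 3' terminus
  expect_identical(reverse_complement(tb$toehold$incumbent),
                   substr(tb$core, nchar(tb$core) - 9, nchar(tb$core)))

  expect_warning(build_template("ACGUACGUACGU", alphabet = "RNA"), "18-25")
  expect_error(build_template("ACGUACGUACGU", alphabet = "RNA",
                              strict = TRUE), "18-25")
})

test_that("nicking-site validation counts sites and checks the cut register", {
  d <- build_template(let7a_rna, kind = "biotin", alphabet = "RNA")
  v <- validate_nease_site(d)
  expect_true(v$ok)
  expect_identical(v$n_sites, 1L)
  expect_identical(v$released_length, nchar(let7a_rna))

  scrambled <- d
  scrambled$core <- gsub("GACTC", "GCTAC", d$core, fixed = TRUE)
  vs <- validate_nease_site(scrambled)
  expect_false(vs$ok)
  expect_identical(vs$n_sites, 0L)
  expect_gt(length(vs$findings), 0)

  middle <- reverse_complement(paste0("GAGTC", d$spacer))
  doubled <- d
  doubled$core <- paste0(d$x_prime, middle, middle, d$x_prime)
  vd <- validate_nease_site(doubled)
  expect_false(vd$ok)
  expect_identical(vd$n_sites, 2L)
})

test_that("nearest-neighbor Tm is deterministic and ranks duplexes sanely", {
  a <- "TGAGGTAGTAGGTTGTATAGTT"
  b <- reverse_complement(a)
  tm1 <- nn_duplex_tm(a, b)
  expect_identical(nn_duplex_tm(a, b), tm1)
  expect_true(tm1 > 20 && tm1 < 90)

  # any single internal mismatch destabilises
  for (pos in c(5, 11, 17)) {
    mm <- a
    substr(mm, pos, pos) <- ifelse(substr(a, pos, pos) == "A", "C", "A")
    expect_lt(nn_duplex_tm(mm, b), tm1)
  }

  # complementary extension stabilises
  short <- "TGAGGTAGTA"
  long <- "TGAGGTAGTAGGTTG"
  expect_gt(nn_duplex_tm(long, reverse_complement(long)),
            nn_duplex_tm(short, reverse_complement(short)))

  expect_error(nn_duplex_tm("ACGTACGT", "ACGTACGTA"), "equal length")
  expect_error(nn_duplex_tm("AAAAAAAAAA", "AAAAAAAAAA"),
               "complementary core")
})

test_that("interference percentages follow the calibration arithmetic", {
  copies <- 10^(0:11)
  fit <- fit_calibration(copies, 28.3 - 2.09 * log10(copies))
  target_poi <- predict_poi(fit, 6.02e9)
  expect_equal(interference_percent(target_poi, fit, 6.02e9), 100,
               tolerance = 1e-9)
  expect_identical(interference_percent(NA, fit, 6.02e9), 0)
  # two decades later in POI terms = 1% apparent input
  expect_equal(interference_percent(target_poi + 2.09 * 2, fit, 6.02e9), 1,
               tolerance = 1e-9)
  expect_error(interference_percent(10, fit, 0), "positive")
})

test_that("cross-reactivity fractions round-trip through a noiseless plate", {
  fractions <- c("let-7a" = 1, "let-7e" = 0.0993, "let-7d" = 0.00044,
                 "let-7f" = 0.00023, "let-7b" = 0.00012)
  wells <- data.frame(well = sprintf("S%d", seq_along(fractions)),
                      species = names(fractions), copies = 6.02e9)
  plate <- generate_plate(plate_spec(wells, 0.5, 40, seed = 2),
                          biotin_truth(), curve_model(noise_sd = 0),
                          cross_reactivity = fractions)
  res <- analyze_plate(plate)
  fit <- fit_calibration(10^(0:11), 28.3 - 2.09 * log10(10^(0:11)))
  rep <- cross_reactivity_report(res, fit, 6.02e9, target = "let-7a")
  expect_identical(rep$species[1], "let-7a")
  got <- rep$interference_pct[match(names(fractions), rep$species)]
  expect_true(all(abs(got - fractions * 100) / (fractions * 100) < 0.01))
  expect_true(all(diff(rep$interference_pct) <= 0))   # sorted descending
})

test_that("cross-reactivity report handles edge plates", {
  fit <- fit_calibration(10^(0:11), 28.3 - 2.09 * log10(10^(0:11)))
  solo <- data.frame(species = "let-7a", poi = predict_poi(fit, 6.02e9),
                     amplified = TRUE)
  rep <- cross_reactivity_report(solo, fit, 6.02e9)
  expect_identical(nrow(rep), 1L)
  expect_equal(rep$interference_pct, 100, tolerance = 1e-9)

  expect_error(cross_reactivity_report(
    data.frame(species = "let-7e", poi = 20, amplified = TRUE),
    fit, 6.02e9), "reference well")

  dead <- data.frame(species = c("let-7a", "let-7e", "let-7d"),
                     poi = c(predict_poi(fit, 6.02e9), NA, NA),
                     amplified = c(TRUE, FALSE, FALSE))
  rep2 <- cross_reactivity_report(dead, fit, 6.02e9)
  expect_equal(rep2$interference_pct[rep2$species != "let-7a"], c(0, 0))
})
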