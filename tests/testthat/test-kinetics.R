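test_that("beta growth rate matches hand-computed instances", {
  # gamma*lam^2/(eps*(lam+1)) - (1-phi)/(phi*(lam+1)) - alpha, times c_T0
  p0 <- rate_params(gamma = 1, epsilon = 1, lam = 1, alpha = 0, phi = 0.5,
                    c_T0 = 1)
  expect_equal(beta_growth_rate(p0), 0)

  p1 <- rate_params(gamma = 2, epsilon = 1, lam = 2, alpha = 0.1, phi = 0.8,
                    c_T0 = 0.5)
  expect_equal(beta_growth_rate(p1), (8 / 3 - 0.2 / 2.4 - 0.1) * 0.5,
               tolerance = 1e-12)
})

test_that("phi = 1 removes the inextensible-duplex penalty exactly", {
  for (s in 1:5) {
    gamma <- s; eps <- 0.5 * s; lam <- 0.3 * s; alpha <- 0.01 * s
    p <- rate_params(gamma = gamma, epsilon = eps, lam = lam, alpha = alpha,
                     phi = 1, c_T0 = 2)
    expect_identical(beta_growth_rate(p),
                     (gamma * lam^2 / (eps * (lam + 1)) - alpha) * 2)
  }
})

test_that("beta rejects parameters that break the formula's domain", {
  expect_error(rate_params(phi = -0.1), "phi")
  expect_error(rate_params(phi = 1.2), "phi")
  expect_error(rate_params(lam = 0), "lam")
  p <- rate_params(phi = 0.5)
  p$phi <- 0
  expect_error(beta_growth_rate(p), "phi")
  p <- rate_params()
  p$epsilon <- 0
  expect_error(beta_growth_rate(p), "epsilon")
})

test_that("beta is monotone non-decreasing in phi", {
  phis <- seq(0.05, 1, length.out = 20)
  for (gamma in c(0.1, 1, 10)) {
    for (lam in c(0.2, 1, 5)) {
      for (alpha in c(0, 0.5, 2)) {
        betas <- vapply(phis, function(ph) {
          beta_growth_rate(rate_params(gamma = gamma, lam = lam,
                                       alpha = alpha, phi = ph, c_T0 = 1))
        }, numeric(1))
        expect_true(all(diff(betas) >= 0))
      }
    }
  }
})

test_that("amplicon concentration follows the exponential law", {
  p <- rate_params(gamma = 1, epsilon = 1, lam = 1, alpha = 0, phi = 0.5,
                   c_T0 = 1, c_X0 = 3e-15)
  expect_equal(amplicon_concentration(p, 0), 3e-15)        # t = 0
  expect_equal(amplicon_concentration(p, c(1, 5, 50)),
               rep(3e-15, 3))                              # beta = 0, flat
  # doubling time arithmetic: beta = ln 2 -> 8x after 3 minutes
  pd <- rate_params(gamma = 2 * log(2), epsilon = 1, lam = 1, alpha = 0,
                    phi = 1, c_T0 = 1, c_X0 = 1e-15)
  expect_equal(beta_growth_rate(pd), log(2))
  expect_equal(amplicon_concentration(pd, 3), 8e-15, tolerance = 1e-12)
  expect_error(amplicon_concentration(p, -1), "non-negative")
})

test_that("expected cycle outcome reproduces the closed form", {
  expect_equal(expected_cycle_outcome(1, 10), 1024)
  expect_equal(expected_cycle_outcome(0.5, 2), 2.25)
  expect_equal(expected_cycle_outcome(0.37, 0), 1)
  for (n in 0:30) {
    expect_identical(expected_cycle_outcome(1, n), 2^n)
    expect_identical(expected_cycle_outcome(0.5, n), 1.5^n)
  }
  expect_error(expected_cycle_outcome(0.5, 2.5), "integer")
  expect_error(expected_cycle_outcome(0.5, -1), "integer")
  expect_error(expected_cycle_outcome(1.5, 2), "phi")
})

test_that("branching simulation is reproducible and respects its invariants", {
  tr <- simulate_branching(0.6, 12, n0 = 5, seed = 11)
  tr2 <- simulate_branching(0.6, 12, n0 = 5, seed = 11)
  expect_identical(tr$counts, tr2$counts)
  expect_length(tr$counts, 13)
  expect_identical(tr$counts[1], 5)
  expect_true(all(diff(tr$counts) >= 0))

  # degenerate ends of the phi range are deterministic
  expect_identical(simulate_branching(0, 7, n0 = 7, seed = 1)$counts,
                   rep(7, 8))
  expect_identical(simulate_branching(1, 5, n0 = 1, seed = 1)$counts,
                   2^(0:5))
})

test_that("branching means converge to (1 + phi)^n", {
  for (phi in c(0.25, 0.5, 0.75, 1)) {
    n <- 8L; n0 <- 20L; reps <- 1000L
    finals <- vapply(seq_len(reps), function(r) {
      tail(simulate_branching(phi, n, n0, seed = 1000 + r)$counts, 1)
    }, numeric(1))
    expected <- n0 * expected_cycle_outcome(phi, n)
    se <- sd(finals) / sqrt(reps)
    expect_lt(abs(mean(finals) - expected), max(3 * se, 1e-9))
  }
})

test_that("mass-action simulation respects conservation and degenerate inputs", {
  mech <- list(k_assoc_5p = 0.5, k_dissoc_5p = 0.5, k_anneal = 1,
               k_extend = 2, k_nick = 2)
  p <- rate_params(c_T0 = 1, c_X0 = 1e-6)
  out <- simulate_mass_action(p, mech, seq(0, 15, 0.1))
  total <- out$conc_T + out$conc_X5 + out$conc_X3 + out$conc_ds
  expect_true(all(abs(total - 1) <= 1e-9))
  expect_true(all(out$conc_X >= 0) && all(out$conc_T >= 0))

  # absorbing zero: no trigger, nothing happens
  p0 <- rate_params(c_T0 = 1, c_X0 = 0)
  out0 <- simulate_mass_action(p0, mech, seq(0, 10, 0.5))
  expect_true(all(out0$conc_X == 0) && all(out0$conc_ds == 0))

  # frozen system: all rates zero
  mech0 <- lapply(mech, function(x) 0)
  outf <- simulate_mass_action(p, mech0, seq(0, 10, 0.5))
  expect_true(all(outf$conc_X == 1e-6) && all(outf$conc_T == 1))
})

test_that("mass-action trigger growth is exponential early and anneal-limited", {
  mech <- list(k_assoc_5p = 0.5, k_dissoc_5p = 0.5, k_anneal = 1,
               k_extend = 2, k_nick = 2)
  p <- rate_params(c_T0 = 1, c_X0 = 1e-6)
  out <- simulate_mass_action(p, mech, seq(0, 20, 0.1))
  # early exponential phase: log-concentration is nearly linear in t
  early <- out[out$t >= 3 & out$t <= 8, ]
  fit <- lm(log(conc_X) ~ t, data = early)
  expect_gt(summary(fit)$r.squared, 0.999)

  # doubling the annealing rate shortens the time to reach 10 * c_X0
  t_reach <- function(m) {
    o <- simulate_mass_action(p, m, seq(0, 20, 0.05))
    o$t[which(o$conc_X >= 10 * p$c_X0)[1]]
  }
  mech_fast <- mech
  mech_fast$k_anneal <- 2
  expect_lt(t_reach(mech_fast), t_reach(mech))
})
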