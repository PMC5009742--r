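#' Kinetic parameters of the consecutive-reaction EXPAR model
#'
#' EXPAR on a symmetric template can be reduced to a consecutive reaction
#' scheme: the trigger X reversibly occupies the inextensible 5' copy of its
#' complement on the template (X/5'X'T), anneals productively to the 3' copy
#' (X/3'X'T), is extended into nickable double-stranded DNA, and nicking
#' releases a fresh copy of X. This constructor bundles the reduced-model
#' rate symbols and the initial concentrations.
#'
#' @param theta association/exchange rate of X with the 5'-terminal template
#'   copy (per molar per minute). Enters the reduced model only through the
#'   composite ratio `lam`; carried for completeness.
#' @param alpha annealing rate of X to the 3'-terminal template copy
#'   (per molar per minute).
#' @param epsilon conversion rate of the X/3'X'T duplex into double-stranded
#'   DNA (per minute).
#' @param gamma production rate of X from double-stranded DNA via nicking
#'   (per minute).
#' @param lam dimensionless composite ratio of the reduced model. Exposed as
#'   a free parameter with default 1.
#' @param phi fraction of annealed trigger that forms the extensible duplex
#'   at the template's 3' terminus; standard symmetric templates sit near
#'   0.5, the ideal asymmetric limit is 1.
#' @param c_T0 initial template concentration (molar).
#' @param c_X0 initial trigger concentration (molar).
#'
#' @return An object of class `rate_params`.
#' @seealso [beta_growth_rate()], [amplicon_concentration()]
#' @export
#' @examples
#' p <- rate_params(gamma = 2, epsilon = 1, lam = 2, alpha = 0.1,
#'                  phi = 0.8, c_T0 = 0.5)
#' beta_growth_rate(p)
rate_params <- function(theta = 1, alpha = 0, epsilon = 1, gamma = 1,
                        lam = 1, phi = 0.5, c_T0 = 1e-7, c_X0 = 1e-15) {
  for (nm in c("theta", "alpha", "epsilon", "gamma", "lam", "phi",
               "c_T0", "c_X0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_input("'%s' must be a single finite number", nm)
    }
  }
  if (theta < 0 || alpha < 0 || epsilon < 0 || gamma < 0) {
    stop_domain("rates theta, alpha, epsilon, gamma must be non-negative")
  }
  if (phi < 0 || phi > 1) stop_domain("phi must lie in [0, 1]")
  if (lam <= 0) stop_domain("lam must be positive")
  if (c_T0 <= 0) stop_domain("c_T0 must be positive")
  if (c_X0 < 0) stop_domain("c_X0 must be non-negative")
  structure(list(theta = theta, alpha = alpha, epsilon = epsilon,
                 gamma = gamma, lam = lam, phi = phi,
                 c_T0 = c_T0, c_X0 = c_X0),
            class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("EXPAR reduced-model rate parameters\n")
  cat(sprintf("  theta = %g  alpha = %g  epsilon = %g  gamma = %g\n",
              x$theta, x$alpha, x$epsilon, x$gamma))
  cat(sprintf("  lambda = %g  phi = %g\n", x$lam, x$phi))
  cat(sprintf("  c_T0 = %g M  c_X0 = %g M\n", x$c_T0, x$c_X0))
  invisible(x)
}

#' Closed-form exponential growth rate of the trigger
#'
#' In the reduced consecutive-reaction model the trigger concentration grows
#' as `c_X(t) = exp(beta * t) * c_X0`, with
#'
#' \deqn{\beta = \left(\frac{\gamma\lambda^2}{\epsilon(\lambda+1)}
#'   - \frac{1-\varphi}{\varphi(\lambda+1)} - \alpha\right) c_{T0}}
#'
#' The middle term is the efficiency penalty for trigger parked on the
#' inextensible 5' template copy; it vanishes at `phi = 1` and diverges as
#' `phi` approaches 0, so beta is strictly increasing in `phi`.
#'
#' @param params a [rate_params()] object.
#' @return The growth rate beta, per minute.
#' @export
beta_growth_rate <- function(params) {
  stopifnot(inherits(params, "rate_params"))
  if (params$phi <= 0) {
    stop_domain("phi must be strictly positive: 1/phi appears in beta")
  }
  if (params$epsilon <= 0) {
    stop_domain("epsilon must be strictly positive: it divides the gain term")
  }
  lam <- params$lam
  gain <- params$gamma * lam^2 / (params$epsilon * (lam + 1))
  penalty <- (1 - params$phi) / (params$phi * (lam + 1))
  (gain - penalty - params$alpha) * params$c_T0
}

#' Trigger concentration under exponential growth
#'
#' Evaluates `c_X(t) = exp(beta * t) * c_X0` with beta from
#' [beta_growth_rate()].
#'
#' @param params a [rate_params()] object.
#' @param t time, minutes; scalar or vector, all values non-negative.
#' @return Trigger concentration(s) in molar, same length as `t`.
#' @export
amplicon_concentration <- function(params, t) {
  stopifnot(inherits(params, "rate_params"))
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop_input("'t' must be finite numeric")
  }
  if (any(t < 0)) stop_domain("time t must be non-negative")
  params$c_X0 * exp(beta_growth_rate(params) * t)
}

#' Expected per-molecule outcome after n amplification cycles
#'
#' One starting trigger molecule yields on average `(1 + phi)^n` molecules
#' after `n` replication/nicking cycles: an ideal reaction (`phi = 1`)
#' doubles every cycle (`2^n`), a standard symmetric template with
#' `phi = 0.5` achieves only `1.5^n`.
#'
#' @param phi fraction of annealed trigger forming extensible duplexes,
#'   in `[0, 1]`.
#' @param n number of cycles; non-negative integer (vectorised).
#' @return Expected copies per starting molecule, `(1 + phi)^n`.
#' @export
#' @examples
#' expected_cycle_outcome(1, 10)    # 1024
#' expected_cycle_outcome(0.5, 2)   # 2.25
expected_cycle_outcome <- function(phi, n) {
  if (!is.numeric(phi) || length(phi) != 1L || phi < 0 || phi > 1) {
    stop_domain("phi must be a single value in [0, 1]")
  }
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 0) ||
      any(n != round(n))) {
    stop_domain("n must be non-negative integer cycle count(s)")
  }
  (1 + phi)^n
}

#' Stochastic branching simulation of EXPAR cycles
#'
#' Per cycle each current molecule independently spawns one new copy with
#' probability `phi` (the chance that its annealing event forms an
#' extensible duplex), so the increment is Binomial(N, phi) and the mean
#' trajectory follows `n0 * (1 + phi)^k`.
#'
#' @param phi per-molecule per-cycle success probability, in `[0, 1]`.
#' @param n number of cycles, non-negative integer.
#' @param n0 starting molecule count, integer `>= 1`.
#' @param seed RNG seed for reproducibility, or `NULL` to use the current
#'   RNG stream.
#' @return An object of class `branching_trajectory`: list with `phi`,
#'   `n_cycles`, `n0`, `seed` and `counts` (length `n + 1`, `counts[1] = n0`,
#'   non-decreasing).
#' @export
simulate_branching <- function(phi, n, n0 = 1L, seed = NULL) {
  if (!is.numeric(phi) || length(phi) != 1L || phi < 0 || phi > 1) {
    stop_domain("phi must be a single value in [0, 1]")
  }
  if (!is_count(n)) stop_domain("n must be a non-negative integer")
  if (!is_count(n0) || n0 < 1) stop_domain("n0 must be an integer >= 1")
  counts <- numeric(n + 1L)
  counts[1L] <- n0
  with_seed(seed, {
    for (k in seq_len(n)) {
      new <- rbinom(1L, size = counts[k], prob = phi)
      counts[k + 1L] <- counts[k] + new
    }
  })
  structure(list(phi = phi, n_cycles = as.integer(n), n0 = as.integer(n0),
                 counts = counts, seed = seed),
            class = "branching_trajectory")
}

#' Mass-action simulation of the EXPAR reaction scheme
#'
#' Integrates a mass-action ODE for the amplification cycle: reversible
#' occupancy of the 5'-terminal template copy, productive annealing to the
#' 3'-terminal copy, extension into double-stranded DNA, and catalytic
#' release of fresh trigger by nicking (`ds -> ds + X`). The free template
#' concentration is obtained from the conservation law
#' `T = c_T0 - X5 - X3 - ds`, which the integration therefore satisfies
#' exactly; the remaining species are integrated with tight tolerances.
#'
#' @param params a [rate_params()] object; supplies `c_T0` and `c_X0`.
#' @param mech named list of elementary rate constants:
#'   `k_assoc_5p`, `k_dissoc_5p` (X + T <-> X/5'X'T),
#'   `k_anneal` (X + T -> X/3'X'T), `k_extend` (X/3'X'T -> dsDNA),
#'   `k_nick` (dsDNA -> dsDNA + X). Bimolecular constants are per molar per
#'   minute, unimolecular per minute.
#' @param t_grid output times in minutes, strictly increasing from 0.
#' @param rtol,atol integrator tolerances.
#' @return A data frame with columns `t`, `conc_T`, `conc_X`, `conc_X5`,
#'   `conc_X3`, `conc_ds` (molar).
#' @export
simulate_mass_action <- function(params, mech, t_grid,
                                 rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(params, "rate_params"))
  needed <- c("k_assoc_5p", "k_dissoc_5p", "k_anneal", "k_extend", "k_nick")
  if (!is.list(mech) || !all(needed %in% names(mech))) {
    stop_input("mech must supply rates: %s", paste(needed, collapse = ", "))
  }
  if (any(unlist(mech[needed]) < 0)) stop_domain("mechanistic rates must be >= 0")
  if (!is.numeric(t_grid) || length(t_grid) < 2L || t_grid[1] != 0 ||
      any(diff(t_grid) <= 0)) {
    stop_input("t_grid must be strictly increasing and start at 0")
  }
  cT0 <- params$c_T0
  deriv <- function(t, y, p) {
    X <- y[1]; X5 <- y[2]; X3 <- y[3]; D <- y[4]
    Tfree <- cT0 - X5 - X3 - D
    dX5 <- p$k_assoc_5p * X * Tfree - p$k_dissoc_5p * X5
    dX3 <- p$k_anneal * X * Tfree - p$k_extend * X3
    dD  <- p$k_extend * X3
    dX  <- -p$k_assoc_5p * X * Tfree + p$k_dissoc_5p * X5 -
      p$k_anneal * X * Tfree + p$k_nick * D
    list(c(dX, dX5, dX3, dD))
  }
  y0 <- c(X = params$c_X0, X5 = 0, X3 = 0, D = 0)
  out <- deSolve::lsoda(y0, t_grid, deriv, mech, rtol = rtol, atol = atol)
  istate <- attr(out, "istate")[1]
  if (!is.null(istate) && istate < 0) {
    last <- out[nrow(out), ]
    stop_input("mass-action integration failed (istate %d); last state: t=%g X=%g",
               istate, last[1], last[2])
  }
  res <- data.frame(
    t = out[, "time"],
    conc_T = cT0 - out[, "X5"] - out[, "X3"] - out[, "D"],
    conc_X = out[, "X"],
    conc_X5 = out[, "X5"],
    conc_X3 = out[, "X3"],
    conc_ds = out[, "D"]
  )
  # integration noise can leave tiny negative excursions; clamp at -atol scale
  num <- c("conc_T", "conc_X", "conc_X5", "conc_X3", "conc_ds")
  for (nm in num) res[[nm]][res[[nm]] < 0 & res[[nm]] > -10 * atol] <- 0
  res
}
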