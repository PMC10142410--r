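# Newton solve of the coupled ventricular-arterial equations.
#
# Substituting the empirical slope-ratio relation k = 0.53 x^0.51 into the
# theoretical coupling equation x = Pad/Pes (1 + k ET/PEP) - 1 gives a single
# scalar root problem in x = Ees/Ea:
#
#   f(x) = Pad/Pes (1 + 0.53 x^0.51 ET/PEP) - 1 - x = 0,  x > 0.
#
# Writing A = Pad/Pes and B = A * 0.53 * ET/PEP, f(x) = (A - 1) + B x^0.51 - x
# is concave on x > 0 with a single interior maximum at
# x_peak = (0.51 B)^(1/0.49); since A <= 1 implies f(0+) <= 0 and f -> -inf,
# the function generically crosses zero twice. The physiological solution is
# the root on the decreasing branch (x > x_peak); Newton is started there and
# the fallback bisection brackets (x_peak, bracket_hi), where the sign change
# is guaranteed whenever a root exists.

#' Solver configuration for the coupling root problem
#'
#' @param x0 Initial guess for Ees/Ea. Default 1, mid-range physiological
#'   coupling (the slope-ratio calibration gives k = 0.53 there).
#' @param tol Absolute residual tolerance; the coupling equation is
#'   dimensionless, so the tolerance is scale-free.
#' @param max_iter Newton iteration cap.
#' @param bracket_lo,bracket_hi Fallback search bounds for Ees/Ea.
#' @param k_coef,k_exp Coefficient and exponent of the empirical slope-ratio
#'   relation `k = k_coef * (Ees/Ea)^k_exp`; fixed from experiment but
#'   overridable for sensitivity work.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(x0 = 1, tol = 1e-9, max_iter = 50L,
                          bracket_lo = 1e-6, bracket_hi = 100,
                          k_coef = K_COEF, k_exp = K_EXP) {
  stopifnot(tol > 0, max_iter >= 1, bracket_lo > 0, bracket_lo < bracket_hi,
            x0 > 0, k_coef > 0, k_exp > 0, k_exp < 1)
  structure(
    list(x0 = x0, tol = tol, max_iter = as.integer(max_iter),
         bracket_lo = bracket_lo, bracket_hi = bracket_hi,
         k_coef = k_coef, k_exp = k_exp),
    class = "solver_config"
  )
}

#' Residual of the ventricular-arterial coupling equation
#'
#' Evaluates \eqn{f(x) = (P_{ad}/P_{es})(1 + k_c x^{k_e}\, ET/PEP) - 1 - x},
#' the theoretical coupling equation with the empirical slope-ratio relation
#' substituted; its positive root is the coupling ratio Ees/Ea.
#'
#' @param x Candidate Ees/Ea (> 0; the fractional power is undefined at 0).
#' @param pad Diastolic arterial pressure (mmHg).
#' @param pes End-systolic pressure (mmHg).
#' @param et Ejection time (ms).
#' @param pep Pre-ejection period (ms).
#' @param k_coef,k_exp Slope-ratio relation constants.
#' @return The dimensionless residual; vectorized over `x`.
#' @export
coupling_residual <- function(x, pad, pes, et, pep,
                              k_coef = K_COEF, k_exp = K_EXP) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("domain error: `x` must be finite and > 0 (fractional power)", call. = FALSE)
  }
  check_positive(pad, "pad"); check_positive(pes, "pes")
  check_positive(et, "et"); check_positive(pep, "pep")
  (pad / pes) * (1 + k_coef * x^k_exp * (et / pep)) - 1 - x
}

# Analytic derivative f'(x) = (pad/pes) k_coef k_exp x^(k_exp-1) (et/pep) - 1.
coupling_residual_deriv <- function(x, pad, pes, et, pep,
                                    k_coef = K_COEF, k_exp = K_EXP) {
  (pad / pes) * k_coef * k_exp * x^(k_exp - 1) * (et / pep) - 1
}

#' Solve the coupling equations for Ees/Ea
#'
#' Solves the theoretical coupling equation together with the empirical
#' slope-ratio relation by Newton's method on the substituted one-dimensional
#' form, using the closed-form derivative. Newton steps are clamped to stay
#' strictly positive (`x_next >= x/10`); if the iteration leaves the admissible
#' interval or fails to converge, the solver falls back to bisection on the
#' decreasing branch of the residual and flags the fallback.
#'
#' @inheritParams coupling_residual
#' @param config A [solver_config()].
#' @return An object of class `coupling_solution`: `ees_over_ea`, `k`
#'   (slope ratio at the solution), `pes`, `pmax` (`pes * (1 + Ees/Ea)`),
#'   `iterations`, `converged`, `residual`, and `method` (`"newton"` or
#'   `"bisection"`).
#' @examples
#' solve_coupling(pad = 73, pes = estimate_pes(117, 73), et = 286, pep = 96)
#' @export
solve_coupling <- function(pad, pes, et, pep, config = solver_config()) {
  check_positive(pad, "pad"); check_positive(pes, "pes")
  check_positive(et, "et"); check_positive(pep, "pep")
  if (pad > pes) {
    stop_invalid("pad", "must not exceed pes (ejection pressure ordering)")
  }
  kc <- config$k_coef; ke <- config$k_exp
  f <- function(x) (pad / pes) * (1 + kc * x^ke * (et / pep)) - 1 - x
  fp <- function(x) (pad / pes) * kc * ke * x^(ke - 1) * (et / pep) - 1

  # Interior maximum of the concave residual; the physiological root lies to
  # its right.
  b <- (pad / pes) * kc * (et / pep)
  x_peak <- (ke * b)^(1 / (1 - ke))
  f_peak <- f(x_peak)
  if (f_peak < 0) {
    stop(sprintf(
      "no solution: coupling residual has no positive root (max f = %.3g at x = %.3g)",
      f_peak, x_peak
    ), call. = FALSE)
  }

  x <- max(config$x0, x_peak * (1 + 1e-6))
  converged <- FALSE
  method <- "newton"
  iterations <- 0L
  trace <- numeric(0)
  for (i in seq_len(config$max_iter)) {
    fx <- f(x)
    if (!is.finite(fx)) {
      stop(sprintf(
        "numerical error in Newton iteration at x = %.6g (trace: %s)",
        x, paste(signif(trace, 6), collapse = " -> ")
      ), call. = FALSE)
    }
    iterations <- i
    if (abs(fx) <= config$tol) {
      converged <- TRUE
      break
    }
    step <- fx / fp(x)
    x_new <- x - step
    x_new <- max(x_new, x / 10)  # keep the iterate strictly positive
    trace <- c(trace, x_new)
    if (x_new > config$bracket_hi || !is.finite(x_new)) break
    x <- x_new
  }

  if (!converged) {
    method <- "bisection"
    lo <- max(config$bracket_lo, x_peak)
    hi <- config$bracket_hi
    flo <- f(lo); fhi <- f(hi)
    if (flo < 0 || fhi > 0) {
      stop(sprintf(
        "no solution: no sign change on fallback bracket [%g, %g] (f = %.3g, %.3g)",
        lo, hi, flo, fhi
      ), call. = FALSE)
    }
    for (i in seq_len(200L)) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      iterations <- iterations + 1L
      if (abs(fm) <= config$tol || (hi - lo) / 2 < .Machine$double.eps * mid) {
        x <- mid
        converged <- abs(fm) <= config$tol
        break
      }
      if (fm > 0) lo <- mid else hi <- mid
      x <- mid
    }
  }

  structure(
    list(
      ees_over_ea = x,
      k = kc * x^ke,
      pes = pes,
      pmax = pes * (1 + x),
      iterations = iterations,
      converged = converged,
      residual = f(x),
      method = method
    ),
    class = "coupling_solution"
  )
}

#' @export
print.coupling_solution <- function(x, ...) {
  cat(sprintf(
    paste0("Coupling solution: Ees/Ea = %.6f (k = %.4f)\n",
           "  Pes = %.2f mmHg, Pmax = %.2f mmHg\n",
           "  %s, %d iteration(s), residual %.2e%s\n"),
    x$ees_over_ea, x$k, x$pes, x$pmax, x$method, x$iterations, x$residual,
    if (x$converged) "" else " [NOT CONVERGED]"
  ))
  invisible(x)
}
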