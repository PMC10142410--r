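# Method-agreement statistics: Bland-Altman bias and limits of agreement,
# percentage error with the 30% acceptability rule, and simple linear
# regression of the test method on the reference method.

PE_ACCEPTABLE_LIMIT <- 30  # percent; Critchley criterion

#' Limits of agreement from a bias / SD pair
#'
#' @param bias Mean of the paired differences (reference - test), ml.
#' @param sd_diff Standard deviation of the differences, ml.
#' @param loa_multiplier Half-width multiplier; default 2.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' agreement_limits(-11.2, 12.7)
#' @export
agreement_limits <- function(bias, sd_diff, loa_multiplier = 2) {
  if (!is.finite(bias) || !is.finite(sd_diff) || sd_diff < 0) {
    stop_invalid("sd_diff", "bias and sd_diff must be finite, sd_diff >= 0")
  }
  c(lower = bias - loa_multiplier * sd_diff,
    upper = bias + loa_multiplier * sd_diff)
}

#' Bland-Altman agreement analysis
#'
#' Computes the bias (mean of reference minus test differences), the sample SD
#' of the differences (n-1 denominator), the limits of agreement
#' `bias +/- loa_multiplier * SD`, and the percentage error
#' `100 * loa_multiplier * SD / mean(reference)`, judged clinically acceptable
#' at 30% or less. An ordinary least-squares regression of test on reference
#' is included when the reference series has positive variance and n >= 3
#' (otherwise those fields are `NA`).
#'
#' @param reference Reference-method measurements (ml).
#' @param test Test-method measurements (ml), paired with `reference`.
#' @param loa_multiplier Limits-of-agreement half-width multiplier. Default 2;
#'   set 1.96 for the normal-quantile convention.
#' @return An object of class `agreement_report`: `n`, `bias`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `percentage_error`, `r_squared`, `slope`,
#'   `intercept`, `acceptable`, `loa_multiplier`, `mean_reference`.
#' @examples
#' bland_altman(reference = c(90, 100, 110), test = c(101, 108, 124))
#' @export
bland_altman <- function(reference, test, loa_multiplier = 2) {
  if (length(reference) != length(test)) {
    stop("`reference` and `test` must have equal length", call. = FALSE)
  }
  n <- length(reference)
  if (n < 2) stop("need at least 2 paired measurements", call. = FALSE)
  if (any(!is.finite(reference)) || any(!is.finite(test))) {
    stop("all paired measurements must be finite", call. = FALSE)
  }
  d <- reference - test
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  mean_ref <- mean(reference)
  if (mean_ref == 0) {
    stop("mean of the reference method is zero: percentage error undefined",
         call. = FALSE)
  }
  loa <- agreement_limits(bias, sd_diff, loa_multiplier)
  pe <- 100 * loa_multiplier * sd_diff / mean_ref

  if (n >= 3 && stats::var(reference) > 0) {
    reg <- regression_summary(reference, test)
  } else {
    reg <- list(r_squared = NA_real_, slope = NA_real_, intercept = NA_real_)
  }

  structure(
    list(
      n = n, bias = bias, sd_diff = sd_diff,
      loa_lower = unname(loa["lower"]), loa_upper = unname(loa["upper"]),
      percentage_error = pe,
      r_squared = reg$r_squared, slope = reg$slope, intercept = reg$intercept,
      acceptable = is.finite(pe) && pe <= PE_ACCEPTABLE_LIMIT,
      loa_multiplier = loa_multiplier, mean_reference = mean_ref
    ),
    class = "agreement_report"
  )
}

#' Simple linear regression of test on reference
#'
#' Ordinary least squares with intercept; `r_squared` is the squared Pearson
#' correlation.
#'
#' @inheritParams bland_altman
#' @return List with `r_squared`, `slope`, `intercept`.
#' @export
regression_summary <- function(reference, test) {
  if (length(reference) != length(test)) {
    stop("`reference` and `test` must have equal length", call. = FALSE)
  }
  if (length(reference) < 3) stop("need at least 3 pairs for regression", call. = FALSE)
  if (stats::var(reference) == 0) {
    stop("reference series has zero variance: regression degenerate", call. = FALSE)
  }
  fit <- stats::lm(test ~ reference)
  cf <- stats::coef(fit)
  list(
    r_squared = stats::cor(reference, test)^2,
    slope = unname(cf["reference"]),
    intercept = unname(cf["(Intercept)"])
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(format_agreement(x), sep = "\n")
  invisible(x)
}

# Plain-text summary block shared by print() and the report writer.
format_agreement <- function(x) {
  c(
    sprintf("Method agreement (n = %d)", x$n),
    sprintf("  bias (reference - test): %.2f ml (SD %.2f ml)", x$bias, x$sd_diff),
    sprintf("  limits of agreement (x%.2f): %.2f to %.2f ml",
            x$loa_multiplier, x$loa_lower, x$loa_upper),
    sprintf("  percentage error: %.1f%% (%s; threshold %g%%)",
            x$percentage_error,
            if (x$acceptable) "clinically acceptable" else "not acceptable",
            PE_ACCEPTABLE_LIMIT),
    if (is.na(x$r_squared)) "  regression: not estimable" else
      sprintf("  regression: R^2 = %.3f, slope = %.3f, intercept = %.2f ml",
              x$r_squared, x$slope, x$intercept)
  )
}

#' Write an agreement report
#'
#' Writes the plain-text summary block and, alongside it, a two-column
#' delimited file (`<path>.csv`) of field/value pairs.
#'
#' @param report An `agreement_report`.
#' @param path Output path for the text summary.
#' @return `path`, invisibly.
#' @export
write_agreement <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  writeLines(format_agreement(report), path)
  fields <- c("n", "bias", "sd_diff", "loa_lower", "loa_upper",
              "percentage_error", "r_squared", "slope", "intercept",
              "acceptable", "loa_multiplier", "mean_reference")
  tab <- data.frame(field = fields,
                    value = vapply(report[fields], function(v)
                      format(v, digits = 10), character(1)))
  utils::write.csv(tab, paste0(path, ".csv"), row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bland-Altman plot
#'
#' Scatter of paired differences against paired means, with the bias and
#' limits of agreement drawn as horizontal lines.
#'
#' @inheritParams bland_altman
#' @param report Optionally, a precomputed `agreement_report` for the same
#'   series.
#' @param ... Passed to [graphics::plot()].
#' @return The `agreement_report`, invisibly.
#' @export
plot_bland_altman <- function(reference, test, report = NULL,
                              loa_multiplier = 2, ...) {
  if (is.null(report)) report <- bland_altman(reference, test, loa_multiplier)
  m <- (reference + test) / 2
  d <- reference - test
  graphics::plot(m, d, xlab = "Mean of methods (ml)",
                 ylab = "Reference - test (ml)", ...)
  graphics::abline(h = report$bias, lty = 1)
  graphics::abline(h = c(report$loa_lower, report$loa_upper), lty = 2)
  invisible(report)
}
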