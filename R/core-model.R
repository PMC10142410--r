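# Closed-form pieces of the estimation chain: end-systolic pressure from cuff
# pressures, peak isovolumic pressure from systolic time intervals, the
# coupling ratio from the two pressures, and EDV from SV and the coupling.

# Coefficients of the published linear form for end-systolic pressure.
PES_SBP_COEF <- 0.205
PES_DBP_COEF <- 0.898
PES_INTERCEPT <- 0.4214

# Empirical slope-ratio relation of the bilinear elastance approximation:
# k = K_COEF * (Ees/Ea)^K_EXP.
K_COEF <- 0.53
K_EXP <- 0.51

stop_invalid <- function(field, msg) {
  stop(sprintf("invalid input `%s`: %s", field, msg), call. = FALSE)
}

check_positive <- function(x, field) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop_invalid(field, "must be finite and > 0")
  }
  invisible(x)
}

#' Estimate end-systolic arterial pressure from cuff pressures
#'
#' Applies the published linear form
#' \eqn{P_{es} = 0.205\,SBP + 0.898\,DBP + 0.4214} relating brachial-cuff
#' systolic and diastolic pressure to end-systolic arterial pressure.
#'
#' @param sbp Systolic blood pressure (mmHg).
#' @param dbp Diastolic blood pressure (mmHg).
#' @param validate If `TRUE` (default), reject non-positive or inverted
#'   (`sbp <= dbp`) pressures. Disable only for contract exploration.
#' @return End-systolic pressure (mmHg). For physiological inputs the result
#'   lies strictly between `dbp` and `sbp`.
#' @examples
#' estimate_pes(117, 73)
#' @export
estimate_pes <- function(sbp, dbp, validate = TRUE) {
  if (validate) {
    check_positive(dbp, "dbp")
    check_positive(sbp, "sbp")
    if (any(sbp <= dbp)) stop_invalid("sbp", "must exceed dbp")
  }
  PES_SBP_COEF * sbp + PES_DBP_COEF * dbp + PES_INTERCEPT
}

#' Peak isovolumic pressure from systolic time intervals
#'
#' The hypothetical end-systolic pressure of a non-ejecting (aorta-clamped)
#' ventricle under the bilinear elastance approximation:
#' \eqn{P_{max} = P_{ad}\,[1 + (ET/PEP)\,k]}, where `k` is the slope ratio of
#' the ejection and isovolumic elastance segments.
#'
#' @param pad Diastolic arterial pressure (mmHg), the pressure at which
#'   ejection begins.
#' @param et Ejection time (ms).
#' @param pep Pre-ejection period (ms).
#' @param k Slope ratio of the bilinear elastance approximation
#'   (dimensionless).
#' @return Peak isovolumic pressure (mmHg); increasing in `pad`, `et` and `k`,
#'   decreasing in `pep`.
#' @examples
#' pmax_from_timings(70, et = 300, pep = 100, k = 0.53)
#' @export
pmax_from_timings <- function(pad, et, pep, k) {
  check_positive(pad, "pad")
  check_positive(et, "et")
  check_positive(pep, "pep")
  if (any(!is.finite(k)) || any(k < 0)) stop_invalid("k", "must be finite and >= 0")
  pad * (1 + (et / pep) * k)
}

#' Ventricular-arterial coupling ratio from pressures
#'
#' The coupling ratio follows from the pressure reserve of the non-ejecting
#' ventricle: \eqn{E_{es}/E_a = (P_{max} - P_{es}) / P_{es}}.
#'
#' @param pmax Peak isovolumic pressure (mmHg).
#' @param pes End-systolic pressure (mmHg).
#' @return The dimensionless ratio Ees/Ea; zero when `pmax == pes`.
#' @export
coupling_from_pressures <- function(pmax, pes) {
  check_positive(pes, "pes")
  if (any(!is.finite(pmax))) stop_invalid("pmax", "must be finite")
  (pmax - pes) / pes
}

#' Estimate end-diastolic volume from stroke volume and coupling
#'
#' Under the pressure-volume-loop geometry with end-systolic elastance
#' \eqn{E_{es} = P_{es}/(EDV - SV - V_0)} and arterial elastance
#' \eqn{E_a = P_{es}/SV}, the end-diastolic volume is
#' \eqn{EDV = SV\,(1 + E_a/E_{es}) + V_0}. `V0`, the ventricular volume at
#' zero end-systolic pressure, defaults to 0 ml (the method's key assumption
#' for hearts with normal function) but is exposed for sensitivity analysis.
#'
#' @param sv Stroke volume (ml).
#' @param ees_over_ea Coupling ratio Ees/Ea (dimensionless, > 0).
#' @param v0 Volume at zero end-systolic pressure (ml, >= 0).
#' @return An object of class `edv_estimate`: a list with `edv_calc` (ml),
#'   `esv_calc` (`edv_calc - sv`, ml), `ees_over_ea` and `v0`.
#' @examples
#' estimate_edv(sv = 61, ees_over_ea = 1.5)
#' @export
estimate_edv <- function(sv, ees_over_ea, v0 = 0) {
  check_positive(sv, "sv")
  check_positive(ees_over_ea, "ees_over_ea")
  if (any(!is.finite(v0)) || any(v0 < 0)) stop_invalid("v0", "must be finite and >= 0")
  edv <- sv * (1 + 1 / ees_over_ea) + v0
  structure(
    list(edv_calc = edv, esv_calc = edv - sv, ees_over_ea = ees_over_ea, v0 = v0),
    class = "edv_estimate"
  )
}

#' @export
print.edv_estimate <- function(x, ...) {
  cat(sprintf(
    "EDV estimate: %.2f ml (ESV %.2f ml; Ees/Ea = %.4f; V0 = %g ml)\n",
    x$edv_calc, x$esv_calc, x$ees_over_ea, x$v0
  ))
  invisible(x)
}

#' Construct a validated per-subject observation
#'
#' Bundles one subject's (or one beat's) noninvasive measurements: cuff
#' pressures, systolic time intervals, stroke volume, and an optional
#' reference EDV (e.g. from echocardiography).
#'
#' @param subject_id Text label.
#' @param sbp,dbp Cuff systolic and diastolic pressure (mmHg); `sbp > dbp > 0`.
#' @param pep Pre-ejection period (ms, > 0).
#' @param et Ejection time (ms, > 0).
#' @param sv Stroke volume (ml, > 0).
#' @param edv_ref Optional reference end-diastolic volume (ml); when given it
#'   must exceed `sv` so that the implied end-systolic volume is positive.
#' @param validate Set `FALSE` to skip invariant checks (contract tests only).
#' @return An object of class `beat_observation`.
#' @export
beat_observation <- function(subject_id, sbp, dbp, pep, et, sv,
                             edv_ref = NA_real_, validate = TRUE) {
  obs <- structure(
    list(
      subject_id = as.character(subject_id),
      sbp = as.numeric(sbp), dbp = as.numeric(dbp),
      pep = as.numeric(pep), et = as.numeric(et),
      sv = as.numeric(sv), edv_ref = as.numeric(edv_ref)
    ),
    class = "beat_observation"
  )
  if (validate) validate_observation(obs)
  obs
}

#' Check the invariants of a beat observation
#'
#' @param obs A `beat_observation`.
#' @return The observation, invisibly; errors name the offending field.
#' @export
validate_observation <- function(obs) {
  check_positive(obs$dbp, "dbp")
  check_positive(obs$sbp, "sbp")
  if (obs$sbp <= obs$dbp) stop_invalid("sbp", "must exceed dbp")
  check_positive(obs$pep, "pep")
  check_positive(obs$et, "et")
  check_positive(obs$sv, "sv")
  if (!is.na(obs$edv_ref) && obs$edv_ref <= obs$sv) {
    stop_invalid("edv_ref", "must exceed sv (end-systolic volume must be positive)")
  }
  invisible(obs)
}

#' @export
print.beat_observation <- function(x, ...) {
  cat(sprintf(
    "Subject %s: SBP/DBP %.1f/%.1f mmHg, PEP %.1f ms, ET %.1f ms, SV %.1f ml%s\n",
    x$subject_id, x$sbp, x$dbp, x$pep, x$et, x$sv,
    if (is.na(x$edv_ref)) "" else sprintf(", reference EDV %.1f ml", x$edv_ref)
  ))
  invisible(x)
}
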