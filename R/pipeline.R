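# Per-subject estimation chain and cohort-level exclusion filtering.

#' Run the full estimation chain on one observation
#'
#' Observation -> end-systolic pressure (linear cuff form) -> Ees/Ea (Newton
#' solve of the coupling equations, with diastolic pressure as the pressure at
#' which ejection begins) -> EDV (`SV (1 + Ea/Ees) + V0`). All intermediates
#' are retained for audit.
#'
#' @param obs A [beat_observation()].
#' @param config A [solver_config()].
#' @param v0 Volume at zero end-systolic pressure (ml); default 0.
#' @return An object of class `subject_result`: `observation`, `pes`,
#'   `coupling` (a `coupling_solution`), and `estimate` (an `edv_estimate`).
#' @examples
#' obs <- beat_observation("t1-means", sbp = 117, dbp = 73, pep = 96,
#'                         et = 286, sv = 61)
#' estimate_subject(obs)
#' @export
estimate_subject <- function(obs, config = solver_config(), v0 = 0) {
  stopifnot(inherits(obs, "beat_observation"))
  validate_observation(obs)
  withCallingHandlers(
    {
      pes <- estimate_pes(obs$sbp, obs$dbp)
      coupling <- solve_coupling(obs$dbp, pes, obs$et, obs$pep, config)
      estimate <- estimate_edv(obs$sv, coupling$ees_over_ea, v0)
      structure(
        list(observation = obs, pes = pes, coupling = coupling,
             estimate = estimate),
        class = "subject_result"
      )
    },
    error = function(e) {
      stop(sprintf("subject %s: %s", obs$subject_id, conditionMessage(e)),
           call. = FALSE)
    }
  )
}

#' @export
print.subject_result <- function(x, ...) {
  cat(sprintf(
    "Subject %s: Pes %.2f mmHg, Ees/Ea %.4f, Pmax %.2f mmHg, EDV calc %.1f ml\n",
    x$observation$subject_id, x$pes, x$coupling$ees_over_ea,
    x$coupling$pmax, x$estimate$edv_calc
  ))
  invisible(x)
}

# Canonical column order of a cohort results table.
RESULT_COLUMNS <- c(
  "subject_id", "sbp", "dbp", "pep_ms", "et_ms", "sv_ml", "edv_ref_ml",
  "pes", "ees_over_ea", "k", "pmax", "iterations", "converged",
  "edv_calc_ml", "esv_calc_ml", "excluded", "exclusion_reason"
)

#' Estimate every subject in a table
#'
#' Runs [estimate_subject()] row by row over a subject table (as returned by
#' [read_subjects()] or [generate_cohort()]). Rows with missing required
#' fields, or on which the solver fails, are retained with `excluded = TRUE`
#' and an `exclusion_reason`; nothing is silently dropped.
#'
#' @param subjects A data frame with columns `subject_id`, `sbp`, `dbp`,
#'   `pep_ms`, `et_ms`, `sv_ml` and optionally `edv_ref_ml`.
#' @inheritParams estimate_subject
#' @return A data frame (class `cohort_results`) with the inputs, all
#'   intermediates (Pes, Ees/Ea, k, Pmax, solver diagnostics) and the EDV
#'   estimate per subject.
#' @export
estimate_cohort <- function(subjects, config = solver_config(), v0 = 0) {
  subjects <- as.data.frame(subjects)
  if (!"edv_ref_ml" %in% names(subjects)) subjects$edv_ref_ml <- NA_real_
  required <- c("subject_id", "sbp", "dbp", "pep_ms", "et_ms", "sv_ml")
  missing_cols <- setdiff(required, names(subjects))
  if (length(missing_cols) > 0) {
    stop(sprintf("subject table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }

  n <- nrow(subjects)
  out <- data.frame(
    subject_id = as.character(subjects$subject_id),
    sbp = subjects$sbp, dbp = subjects$dbp,
    pep_ms = subjects$pep_ms, et_ms = subjects$et_ms,
    sv_ml = subjects$sv_ml, edv_ref_ml = subjects$edv_ref_ml,
    pes = NA_real_, ees_over_ea = NA_real_, k = NA_real_, pmax = NA_real_,
    iterations = NA_integer_, converged = NA,
    edv_calc_ml = NA_real_, esv_calc_ml = NA_real_,
    excluded = FALSE, exclusion_reason = "",
    stringsAsFactors = FALSE
  )

  numeric_inputs <- c("sbp", "dbp", "pep_ms", "et_ms", "sv_ml")
  for (i in seq_len(n)) {
    row <- out[i, ]
    if (anyNA(row[numeric_inputs])) {
      out$excluded[i] <- TRUE
      out$exclusion_reason[i] <- "missing data"
      next
    }
    res <- tryCatch(
      estimate_subject(
        beat_observation(row$subject_id, row$sbp, row$dbp,
                         row$pep_ms, row$et_ms, row$sv_ml,
                         edv_ref = row$edv_ref_ml),
        config = config, v0 = v0
      ),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      out$excluded[i] <- TRUE
      out$exclusion_reason[i] <- conditionMessage(res)
      next
    }
    out$pes[i] <- res$pes
    out$ees_over_ea[i] <- res$coupling$ees_over_ea
    out$k[i] <- res$coupling$k
    out$pmax[i] <- res$coupling$pmax
    out$iterations[i] <- res$coupling$iterations
    out$converged[i] <- res$coupling$converged
    out$edv_calc_ml[i] <- res$estimate$edv_calc
    out$esv_calc_ml[i] <- res$estimate$esv_calc
  }
  class(out) <- c("cohort_results", "data.frame")
  out[RESULT_COLUMNS]
}

#' Flag cohort exclusions
#'
#' Applies the study's exclusion rules to a results table: subjects with
#' missing required measurements, and subjects whose volume (reference EDV by
#' default) is at or above the cutoff, are flagged. All records are returned
#' with flags set; nothing is dropped, and the operation is idempotent and
#' order-preserving. The cutoff convention is inclusive: a volume exactly at
#' `edv_limit` is excluded.
#'
#' @param results A `cohort_results` data frame (or any data frame with the
#'   relevant volume column and `excluded`/`exclusion_reason` columns).
#' @param edv_limit Volume cutoff (ml); default 140.
#' @param field Which volume the cutoff applies to: the reference EDV
#'   (`"edv_ref"`, default, matching the normal-range motivation for the
#'   cutoff) or the stroke volume (`"sv"`).
#' @param quiet Suppress the message reporting the flagged count.
#' @return The results table with `excluded` and `exclusion_reason` updated.
#' @export
apply_exclusions <- function(results, edv_limit = 140,
                             field = c("edv_ref", "sv"), quiet = FALSE) {
  field <- match.arg(field)
  col <- switch(field, edv_ref = "edv_ref_ml", sv = "sv_ml")
  results <- as.data.frame(results)
  if (!"excluded" %in% names(results)) results$excluded <- FALSE
  if (!"exclusion_reason" %in% names(results)) results$exclusion_reason <- ""

  required <- intersect(c("sbp", "dbp", "pep_ms", "et_ms", "sv_ml"),
                        names(results))
  missing_any <- Reduce(`|`, lapply(results[required], is.na), rep(FALSE, nrow(results)))
  fresh_missing <- missing_any & !results$excluded
  results$excluded[fresh_missing] <- TRUE
  results$exclusion_reason[fresh_missing] <- "missing data"

  if (col %in% names(results)) {
    over <- !is.na(results[[col]]) & results[[col]] >= edv_limit & !results$excluded
    results$excluded[over] <- TRUE
    results$exclusion_reason[over] <- sprintf("volume >= %g", edv_limit)
  }
  if (!quiet) {
    message(sprintf("apply_exclusions: %d of %d record(s) flagged",
                    sum(results$excluded), nrow(results)))
  }
  class(results) <- unique(c("cohort_results", class(results)))
  results
}
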