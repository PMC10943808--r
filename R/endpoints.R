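#' Baseline-derived depletion/repopulation threshold
#'
#' The cohort threshold is the mean minus twice the sample standard
#' deviation (n-1 denominator) of the baseline percent-unmutated
#' distribution, clamped at 0. On the study-scale baseline summary (mean
#' 40.0, SD 17.8) this gives 4.4 percent.
#'
#' @param baseline_pcts baseline percent-unmutated values (>= 2).
#' @return a `threshold_spec`: list with `baseline_mean`, `baseline_sd`,
#'   `threshold`.
#' @export
baseline_threshold <- function(baseline_pcts) {
  baseline_pcts <- baseline_pcts[!is.na(baseline_pcts)]
  if (length(baseline_pcts) < 2L) {
    stop_bcd("at least 2 baseline values are required to derive a threshold",
             "bcelldyn_insufficient_data")
  }
  m <- mean(baseline_pcts)
  s <- sd(baseline_pcts)
  structure(list(baseline_mean = m, baseline_sd = s,
                 threshold = max(0, m - 2 * s)),
            class = "threshold_spec")
}

#' Fixed threshold override
#'
#' Wraps an externally supplied threshold (for example the planted
#' population value of a simulation) in a `threshold_spec`.
#'
#' @param threshold percent-unmutated cut, `>= 0`.
#' @export
threshold_override <- function(threshold) {
  assert_scalar_number(threshold, "threshold", lower = 0, upper = 100)
  structure(list(baseline_mean = NA_real_, baseline_sd = NA_real_,
                 threshold = threshold),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("BCR depletion/repopulation threshold: %.2f%% unmutated (baseline mean %.1f, SD %.1f)\n",
              x$threshold, x$baseline_mean, x$baseline_sd))
  invisible(x)
}

#' Impute failed samples as complete depletion
#'
#' Visits whose sample failed amplification receive an imputed
#' percent-unmutated of 0 (below any threshold), flagged `imputed = TRUE`.
#' The imputed value is used only by depletion calling — an imputed visit
#' can never trigger repopulation. Visits marked `not_collected` stay
#' missing and are skipped during the endpoint scan. Imputation is never
#' applied at baseline: a failed baseline invalidates the patient.
#'
#' @param timeline per-patient tibble with `visit_month`, `pct_unmutated`,
#'   `sample_status` (see [build_timeline()]).
#' @return the timeline with columns `pct_for_depletion` and `imputed`.
#' @export
impute_failed_samples <- function(timeline) {
  if (any(timeline$visit_month == 0L & timeline$sample_status == "failed_amplification")) {
    stop_bcd(sprintf("patient %s: baseline sample failed; patient must be excluded",
                     timeline$patient_id[1]),
             "bcelldyn_baseline_failure")
  }
  failed <- timeline$sample_status == "failed_amplification" & timeline$visit_month > 0L
  timeline$imputed <- failed
  timeline$pct_for_depletion <- ifelse(failed, 0, timeline$pct_unmutated)
  timeline
}

#' Call the post-BCR-depletion timepoint
#'
#' First post-baseline visit at which the (observed or imputed) percent of
#' unmutated clonotypes drops strictly below the threshold; `NA` if never
#' within follow-up. Missing (not collected / undefined) visits are skipped,
#' not interpolated. A baseline already below the threshold is an anomaly,
#' not a depletion at month 0.
#'
#' @param timeline imputed timeline from [impute_failed_samples()].
#' @param threshold a `threshold_spec`.
#' @return list with `depletion_month` (integer or `NA`) and `anomaly`.
#' @export
call_depletion <- function(timeline, threshold) {
  thr <- threshold$threshold
  base <- timeline$pct_unmutated[timeline$visit_month == 0L]
  if (length(base) != 1L || is.na(base)) {
    stop_bcd(sprintf("patient %s: baseline percent-unmutated unavailable",
                     timeline$patient_id[1]),
             "bcelldyn_insufficient_data")
  }
  if (base < thr) {
    return(list(depletion_month = NA_integer_, anomaly = "baseline below threshold"))
  }
  post <- timeline[timeline$visit_month > 0L, , drop = FALSE]
  post <- post[order(post$visit_month), , drop = FALSE]
  hit <- which(!is.na(post$pct_for_depletion) & post$pct_for_depletion < thr)
  list(depletion_month = if (length(hit)) post$visit_month[hit[1]] else NA_integer_,
       anomaly = NA_character_)
}

#' Call the post-BCR-repopulation timepoint
#'
#' First visit strictly after the depletion month at which the *observed*
#' (never imputed) percent unmutated is at or above the threshold; `NA` if
#' not reached within follow-up. Equality resolves to the repopulated side:
#' a value exactly at the threshold counts as repopulated, mirroring the
#' strict `<` used for depletion.
#'
#' @inheritParams call_depletion
#' @param depletion_month month returned by [call_depletion()]; must be set.
#' @return integer month or `NA`.
#' @export
call_repopulation <- function(timeline, threshold, depletion_month) {
  if (is.null(depletion_month) || is.na(depletion_month)) {
    stop_bcd("repopulation can only be called after a depletion month is defined",
             "bcelldyn_contract_error")
  }
  thr <- threshold$threshold
  post <- timeline[timeline$visit_month > depletion_month, , drop = FALSE]
  post <- post[order(post$visit_month), , drop = FALSE]
  observed <- !is.na(post$pct_unmutated) & !post$imputed & post$sample_status == "ok"
  hit <- which(observed & post$pct_unmutated >= thr)
  if (length(hit)) post$visit_month[hit[1]] else NA_integer_
}

#' Classify a patient's endpoint call
#'
#' Early BCR-depleters reached their depletion endpoint at month 1; early
#' BCR-repopulators reached their repopulation endpoint within 6 months.
#' `late` covers later endpoints and patients whose endpoint was never
#' reached within follow-up.
#'
#' @param call one-row endpoint call (list or data frame row) with
#'   `depletion_month` and `repopulation_month`.
#' @return the call with `depleter_class` and `repopulator_class` set.
#' @export
classify_patient <- function(call) {
  call$depleter_class <-
    if (!is.na(call$depletion_month) && call$depletion_month == 1L) "early" else "late"
  call$repopulator_class <-
    if (!is.na(call$repopulation_month) && call$repopulation_month <= 6L) "early" else "late"
  call
}

#' Build per-patient timelines from metrics and clinical visits
#'
#' @param metrics tibble from [cohort_metrics()] (needs `patient_id`,
#'   `visit_month`, `pct_unmutated`, `defined`).
#' @param clinical clinical visit tibble.
#' @return tibble of visits with percent unmutated joined on; samples whose
#'   metrics are undefined (nothing survived the UMI filter) are demoted to
#'   `failed_amplification` so the imputation rule covers them.
#' @export
build_timeline <- function(metrics, clinical) {
  tl <- dplyr::left_join(
    clinical,
    metrics[, c("patient_id", "visit_month", "pct_unmutated", "defined")],
    by = c("patient_id", "visit_month")
  )
  undefined <- !is.na(tl$defined) & !tl$defined
  tl$sample_status[undefined] <- "failed_amplification"
  tl$pct_unmutated[undefined] <- NA_real_
  tl$defined <- NULL
  dplyr::arrange(tl, .data$patient_id, .data$visit_month)
}

#' Call endpoints for a whole cohort
#'
#' Derives the threshold from the cohort's baseline percent-unmutated
#' distribution (unless `threshold` overrides it), applies
#' failure-as-depletion imputation, and calls and classifies both endpoints
#' for every patient.
#'
#' @param metrics tibble from [cohort_metrics()].
#' @param clinical clinical visit tibble.
#' @param threshold optional `threshold_spec` (or a bare number) overriding
#'   the data-derived threshold.
#' @return list with `threshold` and `calls` (one row per patient:
#'   `patient_id`, `depletion_month`, `repopulation_month`,
#'   `depleter_class`, `repopulator_class`, `used_imputation`,
#'   `months_imputed`, `anomaly`).
#' @export
call_endpoints <- function(metrics, clinical, threshold = NULL) {
  if (is.null(threshold)) {
    base <- metrics$pct_unmutated[metrics$visit_month == 0L & metrics$defined]
    threshold <- baseline_threshold(base)
  } else if (is.numeric(threshold)) {
    threshold <- threshold_override(threshold)
  }
  tl_all <- build_timeline(metrics, clinical)
  calls <- lapply(split(tl_all, tl_all$patient_id), function(tl) {
    dep <- tryCatch({
      tl <- impute_failed_samples(tl)
      call_depletion(tl, threshold)
    }, bcelldyn_baseline_failure = function(e) {
      list(depletion_month = NA_integer_, anomaly = "baseline sample failed")
    }, bcelldyn_insufficient_data = function(e) {
      list(depletion_month = NA_integer_, anomaly = "baseline unavailable")
    })
    if (is.null(tl$imputed)) tl$imputed <- FALSE
    rep_month <- if (!is.na(dep$depletion_month)) {
      call_repopulation(tl, threshold, dep$depletion_month)
    } else NA_integer_
    call <- list(patient_id = tl$patient_id[1],
                 depletion_month = dep$depletion_month,
                 repopulation_month = rep_month)
    call <- classify_patient(call)
    tibble::tibble(
      patient_id = call$patient_id,
      depletion_month = call$depletion_month,
      repopulation_month = call$repopulation_month,
      depleter_class = call$depleter_class,
      repopulator_class = call$repopulator_class,
      used_imputation = any(tl$imputed),
      months_imputed = paste(tl$visit_month[tl$imputed], collapse = ";"),
      anomaly = dep$anomaly
    )
  })
  list(threshold = threshold, calls = dplyr::bind_rows(calls))
}

#' Cumulative endpoint curve
#'
#' Fraction of patients having reached an endpoint by each scheduled visit,
#' as plotted in depletion/repopulation monitoring curves. Reported
#' percentages are rounded to the nearest integer; the unrounded values are
#' retained.
#'
#' @param endpoint_months integer endpoint month per patient (`NA` = never
#'   reached).
#' @param visit_months scheduled visit months.
#' @param n_total cohort denominator.
#' @return tibble with `month`, `n_cum`, `pct`, `pct_rounded`.
#' @export
cumulative_endpoint_curve <- function(endpoint_months, visit_months, n_total) {
  assert_scalar_number(n_total, "n_total", lower = 1)
  known <- endpoint_months[!is.na(endpoint_months)]
  if (any(!known %in% visit_months)) {
    stop_bcd("every endpoint month must be a scheduled visit month",
             "bcelldyn_validation_error")
  }
  visit_months <- sort(unique(visit_months))
  n_cum <- vapply(visit_months, function(t) sum(known <= t), integer(1))
  pct <- 100 * n_cum / n_total
  tibble::tibble(month = visit_months, n_cum = n_cum, pct = pct,
                 pct_rounded = round(pct))
}
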