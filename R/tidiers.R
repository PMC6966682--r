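# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Kaplan-Meier curve
#'
#' @param x A [km_fit()] object.
#' @param ... Unused.
#' @return Tibble with one row per observed time: `time`, `n_risk`,
#'   `n_event`, `survival`.
#' @export
tidy.km_curve <- function(x, ...) {
  x$curve
}

#' One-row summary of a Kaplan-Meier curve
#'
#' @param x A [km_fit()] object.
#' @param ... Unused.
#' @return Tibble: `n`, `n_events`, `median_survival`, `last_event_time`.
#' @export
glance.km_curve <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_events = sum(x$curve$n_event),
    median_survival = x$median_survival,
    last_event_time = x$last_event_time
  )
}

#' Tidy a log-rank test
#'
#' @param x A [logrank_test()] object.
#' @param ... Unused.
#' @return One-row tibble: `chi_square`, `df`, `p_value`, group sizes and
#'   event counts.
#' @export
tidy.logrank_test <- function(x, ...) {
  groups <- names(x$n_per_group)
  tibble::tibble(
    chi_square = x$chi_square, df = x$df, p_value = x$p_value,
    n_a = unname(x$n_per_group[1]), n_b = unname(x$n_per_group[2]),
    events_a = unname(x$events_per_group[groups[1]]),
    events_b = unname(x$events_per_group[groups[2]])
  )
}

#' @rdname tidy.logrank_test
#' @export
glance.logrank_test <- function(x, ...) tidy(x)

#' One-row overview of a pipeline run
#'
#' @param x A `neo_run_report` from [run_all()].
#' @param ... Unused.
#' @return Tibble with cohort size, tier totals, per-patient mean
#'   candidate count, and homology class counts (when that stage ran).
#' @export
glance.neo_run_report <- function(x, ...) {
  out <- tibble::tibble(
    n_patients = x$cohort_sizes$n_total,
    n_candidates = x$tier_totals$n_candidates,
    n_dai10 = x$tier_totals$n_dai10,
    n_dai10_highaff = x$tier_totals$n_dai10_highaff,
    mean_candidates = mean(x$patient_summaries$n_candidates)
  )
  if (!is.null(x$homology)) {
    cc <- x$homology$class_counts
    out$n_class_none <- cc$numerator[cc$label == "class_none"]
    out$n_class_self <- cc$numerator[cc$label == "class_self"]
    out$n_class_pathogen <- cc$numerator[cc$label == "class_pathogen"]
  }
  out
}
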