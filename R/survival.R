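# Survival analysis: Kaplan-Meier product-limit curves, two-group
# log-rank tests (Mantel-Cox), and the cohort dichotomization schemes used
# throughout the analysis (first-vs-third quartile; below-vs-above mean).
# Estimation is delegated to the survival package; this module fixes the
# interfaces, tie rules and boundary policies.

#' Fit a Kaplan-Meier curve
#'
#' Product-limit estimator over one group of patients.  Deaths at a tied
#' time are processed before censorings at the same time (the standard
#' convention); censored times reduce the risk set without a step.
#'
#' @param records Tibble with columns `time` (non-negative, days) and
#'   `event` (logical, `TRUE` = death).
#' @return Object of class `km_curve`: a list with `curve` (tibble `time`,
#'   `n_risk`, `n_event`, `survival` at each observed time),
#'   `median_survival` (NA when the curve never reaches 0.5),
#'   `last_event_time` (NA when no event), and `n`.
#' @export
km_fit <- function(records) {
  if (!nrow(records)) {
    rlang::abort("km_fit requires at least one record",
                 class = "neosurv_validation_error")
  }
  if (any(records$time < 0)) {
    rlang::abort("survival times must be non-negative",
                 class = "neosurv_validation_error")
  }
  fit <- survival::survfit(
    survival::Surv(records$time, records$event) ~ 1,
    conf.type = "none"
  )
  curve <- tibble::tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    survival = fit$surv
  )
  q <- stats::quantile(fit, probs = 0.5)
  med <- unname(if (is.list(q)) q$quantile else q)
  events <- records$time[records$event]
  structure(
    list(curve = curve,
         median_survival = if (is.na(med)) NA_real_ else med,
         last_event_time = if (length(events)) max(events) else NA_real_,
         n = nrow(records)),
    class = "km_curve"
  )
}

#' Evaluate a fitted Kaplan-Meier curve at given times
#'
#' @param km A [km_fit()] object.
#' @param times Times at which to evaluate the step function.
#' @return Numeric survival probabilities (1 before the first event).
#' @export
km_survival_at <- function(km, times) {
  steps <- km$curve[km$curve$n_event > 0, ]
  if (!nrow(steps)) return(rep(1, length(times)))
  idx <- findInterval(times, steps$time)
  c(1, steps$survival)[idx + 1L]
}

#' Two-group log-rank test (Mantel-Cox)
#'
#' @param records Tibble with `time`, `event`.
#' @param group Vector (length `nrow(records)`) with exactly two distinct
#'   values.
#' @return Object of class `logrank_test`: `chi_square`, `df` (1),
#'   `p_value`, `n_per_group` (named), `events_per_group`.  A group with
#'   zero observed events triggers a warning but still yields a defined
#'   result.
#' @export
logrank_test <- function(records, group) {
  group <- as.character(group)
  levels <- sort(unique(group))
  if (length(levels) != 2) {
    rlang::abort("logrank_test requires exactly two non-empty groups",
                 class = "neosurv_validation_error")
  }
  ev <- tapply(records$event, group, sum)
  if (any(ev == 0)) {
    rlang::warn(paste0("group(s) with zero observed events: ",
                       paste(names(ev)[ev == 0], collapse = ", ")))
  }
  chi <- if (sum(records$event) == 0) {
    0
  } else {
    g <- factor(group, levels = levels)
    unname(survival::survdiff(
      survival::Surv(records$time, records$event) ~ g, rho = 0
    )$chisq)
  }
  structure(
    list(chi_square = chi, df = 1L,
         p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
         n_per_group = table(factor(group, levels = levels)),
         events_per_group = ev),
    class = "logrank_test"
  )
}

# Mantel-Cox chi-square, computed directly so it can be evaluated many
# times cheaply (permutation oracles, power loops).  Cross-checked against
# survival::survdiff in the test suite.
logrank_chisq <- function(time, event, in_b) {
  dt <- sort(unique(time[event]))
  if (!length(dt)) return(0)
  o_b <- e_b <- v <- 0
  for (t in dt) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n_b <- sum(at_risk & in_b)
    d <- sum(event & time == t)
    d_b <- sum(event & time == t & in_b)
    o_b <- o_b + d_b
    e_b <- e_b + d * n_b / n
    if (n > 1) {
      v <- v + d * (n_b / n) * (1 - n_b / n) * (n - d) / (n - 1)
    }
  }
  if (v == 0) return(0)
  (o_b - e_b)^2 / v
}

#' Dichotomize a per-patient score
#'
#' Two schemes: `"quartile"` keeps only the tails — low = scores `<= Q1`,
#' high = scores `>= Q3` (linear-interpolation, type-7 quantiles;
#' interquartile patients stay unassigned) — and `"mean"` splits every
#' patient at the mean (scores exactly equal to the mean go to the high
#' group).
#'
#' @param scores Tibble with columns `patient` and `score`.
#' @param mode `"quartile"` or `"mean"`.
#' @return Tibble `patient`, `score`, `group` (factor low/high; `NA` for
#'   unassigned interquartile patients in quartile mode).
#' @export
dichotomize <- function(scores, mode = c("quartile", "mean")) {
  mode <- match.arg(mode)
  x <- scores$score
  if (length(unique(x)) < 2) {
    rlang::abort("scores are constant; no strata possible",
                 class = "neosurv_validation_error")
  }
  if (mode == "quartile") {
    if (length(x) < 4) {
      rlang::abort("quartile mode requires at least 4 patients",
                   class = "neosurv_validation_error")
    }
    q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    group <- dplyr::case_when(x <= q[1] ~ "low", x >= q[2] ~ "high",
                              .default = NA_character_)
  } else {
    group <- ifelse(x < mean(x), "low", "high")
  }
  tibble::tibble(patient = scores$patient, score = x,
                 group = factor(group, levels = c("low", "high")))
}

#' Survival curves and pairwise log-rank tests by class
#'
#' @param records Tibble with `patient`, `time`, `event`.
#' @param class_labels Tibble with `patient`, `label`; at least two
#'   classes must be present.
#' @return List with `curves` (named list of [km_fit()] objects per class)
#'   and `tests` (tibble of pairwise comparisons: `class_a`, `class_b`,
#'   `chi_square`, `p_value`, `n_a`, `n_b`, `low_n` flag when either class
#'   has fewer than 2 patients).
#' @export
survival_by_class <- function(records, class_labels) {
  merged <- dplyr::inner_join(records, class_labels, by = "patient")
  merged$label <- as.character(merged$label)
  classes <- sort(unique(merged$label))
  if (length(classes) < 2) {
    rlang::abort("survival_by_class requires at least two classes",
                 class = "neosurv_validation_error")
  }
  curves <- purrr::map(stats::setNames(classes, classes), function(cl) {
    km_fit(merged[merged$label == cl, ])
  })
  combos <- utils::combn(classes, 2, simplify = FALSE)
  tests <- purrr::map_dfr(combos, function(pair) {
    sub <- merged[merged$label %in% pair, ]
    n_a <- sum(sub$label == pair[1])
    n_b <- sum(sub$label == pair[2])
    low_n <- n_a < 2 || n_b < 2
    lr <- suppressWarnings(logrank_test(sub, sub$label))
    tibble::tibble(class_a = pair[1], class_b = pair[2],
                   chi_square = lr$chi_square, p_value = lr$p_value,
                   n_a = n_a, n_b = n_b, low_n = low_n)
  })
  list(curves = curves, tests = tests)
}

#' Seeded random training/validation split
#'
#' Reproduces the style of a random 30/85 training/validation division; the
#' original assignment is unrecoverable, so the seed is an explicit
#' argument.
#'
#' @param patients Character vector of patient identifiers.
#' @param n_training Number of training patients (default 30).
#' @param seed Integer seed.
#' @return Tibble `patient`, `set` (factor training/validation).
#' @export
split_cohort <- function(patients, n_training = 30L, seed = 1L) {
  if (n_training >= length(patients)) {
    rlang::abort("n_training must be smaller than the cohort",
                 class = "neosurv_validation_error")
  }
  train <- with_local_seed(component_seed(seed, "split"),
                           sample(patients, n_training))
  tibble::tibble(
    patient = patients,
    set = factor(ifelse(patients %in% train, "training", "validation"),
                 levels = c("training", "validation"))
  )
}
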