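# ggplot2 display methods.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Step plot of a Kaplan-Meier curve
#'
#' @param object A [km_fit()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.km_curve <- function(object, ...) {
  dat <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1),
    tidy(object)[, c("time", "survival")]
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves for several groups on one panel
#'
#' @param curves Named list of [km_fit()] objects (e.g. one per stratum).
#' @return A ggplot with one colored step per group.
#' @export
plot_km_groups <- function(curves) {
  dat <- purrr::imap_dfr(curves, function(km, nm) {
    dplyr::bind_rows(
      tibble::tibble(time = 0, survival = 1),
      tidy(km)[, c("time", "survival")]
    ) |> dplyr::mutate(group = nm)
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$survival,
                                    colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Funnel plot of the neoantigen filter cascade
#'
#' Bar chart of cohort totals at each tier of the cascade (all
#' candidates, DAI tier, high-affinity DAI tier).
#'
#' @param report A `neo_run_report` from [run_all()].
#' @return A ggplot.
#' @export
plot_tier_funnel <- function(report) {
  tt <- report$tier_totals
  dat <- tibble::tibble(
    stage = factor(c("candidates", "DAI > 10", "DAI > 10 & < 50 nM"),
                   levels = c("candidates", "DAI > 10",
                              "DAI > 10 & < 50 nM")),
    count = c(tt$n_candidates, tt$n_dai10, tt$n_dai10_highaff)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$stage, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Neoantigen records") +
    ggplot2::theme_minimal()
}

#' Bootstrap stability by infiltration cluster
#'
#' @param assignments Output of [cluster_gene_set()].
#' @return A ggplot of stability by cluster.
#' @export
plot_cluster_stability <- function(assignments) {
  ggplot2::ggplot(assignments,
                  ggplot2::aes(x = .data$cluster, y = .data$stability)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Infiltration cluster",
                  y = "Bootstrap stability") +
    ggplot2::theme_minimal()
}
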