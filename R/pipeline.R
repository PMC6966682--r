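# End-to-end orchestration: simulate (or accept) a cohort, call
# neoantigens, scan homology, profile the microenvironment, and run the
# survival stratifications, collecting every table and number the
# analysis emits into one reproducible report.

#' Configuration of a full pipeline run
#'
#' Collects every cascade threshold (with its analysis default), the
#' seeds, and the mode flags.  Thresholds: expression strictly `> 2`,
#' percent rank `<= 2`, mutant IC50 `< 500` nM, DAI `> 10`, high-affinity
#' IC50 `< 50` nM, homology `> 0.70`, TCR-contact identities `>= 2`,
#' bootstrap iterations `100`.
#'
#' @param sim A [simulation_config()] (used when no cohort is supplied to
#'   [run_all()]).
#' @param expr_min,rank_max,ic50_max,dai_min,highaff_max,sim_threshold,tcr_min,n_boot
#'   Cascade thresholds as above.
#' @param capture_mb Exome size for TMB.
#' @param dai_mode `"difference"` or `"ratio"`.
#' @param homology_mode `"similarity"` or `"identity"`.
#' @param priority Dual-class resolution, `"pathogen"` or `"self"`.
#' @param split_seed,boot_seed Seeds for the training/validation split and
#'   the clustering bootstrap.
#' @param n_training Training-set size for [split_cohort()].
#' @param paper_mode When `TRUE`, assert that every patient's event is
#'   observed (the replicated cohort contains only death-dated patients).
#' @param tme_genes Gene set for the infiltration clustering stage;
#'   `NULL` (default) uses the illustrative CD8 T-cell set, falling back
#'   to the marker genes when fewer than two of its members are present.
#' @param run_homology,run_tme Stage switches.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = simulation_config(),
                       expr_min = 2, rank_max = 2, ic50_max = 500,
                       dai_min = 10, highaff_max = 50,
                       sim_threshold = 0.70, tcr_min = 2, n_boot = 100L,
                       capture_mb = 38, dai_mode = "difference",
                       homology_mode = "similarity",
                       priority = "pathogen",
                       split_seed = 1L, boot_seed = 1L, n_training = 30L,
                       paper_mode = FALSE, tme_genes = NULL,
                       run_homology = TRUE, run_tme = TRUE) {
  structure(
    list(sim = sim, expr_min = expr_min, rank_max = rank_max,
         ic50_max = ic50_max, dai_min = dai_min, highaff_max = highaff_max,
         sim_threshold = sim_threshold, tcr_min = tcr_min,
         n_boot = as.integer(n_boot), capture_mb = capture_mb,
         dai_mode = dai_mode, homology_mode = homology_mode,
         priority = priority, split_seed = as.integer(split_seed),
         boot_seed = as.integer(boot_seed),
         n_training = as.integer(n_training),
         paper_mode = isTRUE(paper_mode), tme_genes = tme_genes,
         run_homology = isTRUE(run_homology), run_tme = isTRUE(run_tme)),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — cohort (simulated from
#' `config$sim` unless supplied), neoantigen calling, epitope homology,
#' microenvironment clustering and marker strata, survival
#' stratifications — and returns a `neo_run_report`.  All randomness flows
#' from the configured seeds, so identical configurations yield identical
#' reports.
#'
#' @param config A [run_config()] object.
#' @param cohort Optional pre-built [neo_cohort()]; when `NULL` the
#'   synthetic generator runs.
#' @return Object of class `neo_run_report`: a list with `cohort_sizes`,
#'   `records`, `patient_summaries`, `tier_totals`, `fractions`,
#'   `homology` (`matches`, `classes`, `class_counts`), `tme`
#'   (`assignments`, `gzma_split`, `infiltration_vs_counts`), `survival`
#'   (KM fits and log-rank tests per stratification) and `config`.
#' @export
run_all <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort)) cohort <- generate_cohort(config$sim)
  if (config$paper_mode && !all(cohort$clinical$event)) {
    rlang::abort("paper_mode requires every patient's death to be observed",
                 class = "neosurv_validation_error")
  }

  called <- call_neoantigens(
    cohort, expr_min = config$expr_min, rank_max = config$rank_max,
    ic50_max_nM = config$ic50_max, dai_mode = config$dai_mode,
    dai_min = config$dai_min, highaff_max = config$highaff_max,
    capture_mb = config$capture_mb
  )
  summary <- called$summary
  tier_totals <- tibble::tibble(
    n_candidates = sum(summary$n_candidates),
    n_dai10 = sum(summary$n_dai10),
    n_dai10_highaff = sum(summary$n_dai10_highaff)
  )
  fractions <- report_fractions(
    numerator = c(tier_totals$n_dai10, tier_totals$n_dai10_highaff),
    denominator = c(tier_totals$n_candidates, tier_totals$n_dai10),
    label = c("dai10_of_candidates", "highaff_of_dai10")
  )

  homology <- NULL
  if (config$run_homology) {
    matches <- scan_catalog(called$records, cohort$epitope_catalog,
                            sim_threshold = config$sim_threshold,
                            tcr_min = config$tcr_min,
                            mode = config$homology_mode)
    classes <- classify_samples(cohort$patients, matches,
                                priority = config$priority)
    class_counts <- dplyr::count(classes, .data$label, .drop = FALSE)
    class_counts <- report_fractions(
      numerator = class_counts$n,
      denominator = rep(length(cohort$patients), nrow(class_counts)),
      label = paste0("class_", class_counts$label)
    )
    homology <- list(matches = matches, classes = classes,
                     class_counts = class_counts)
  }

  tme <- NULL
  if (config$run_tme) {
    tme_genes <- config$tme_genes
    if (is.null(tme_genes)) {
      tme_genes <- intersect(default_gene_sets()$CD8_T,
                             rownames(cohort$expression))
      if (length(tme_genes) < 2) {
        tme_genes <- intersect(MARKER_GENES, rownames(cohort$expression))
      }
    }
    assignments <- cluster_gene_set(
      cohort$expression, tme_genes,
      n_boot = config$n_boot, seed = config$boot_seed
    )
    gzma_split <- gene_stratum(cohort$expression, "GZMA", mode = "mean")
    infiltration <- neoantigens_vs_infiltration(assignments, summary)
    tme <- list(assignments = assignments, gzma_split = gzma_split,
                infiltration_vs_counts = infiltration[c("p_value",
                                                        "statistic")])
  }

  clin <- cohort$clinical
  surv_tests <- list()
  km_curves <- list()
  strata_scores <- list(
    tmb = "tmb", neoantigens = "n_candidates", dai10 = "n_dai10",
    dai10_highaff = "n_dai10_highaff",
    hla_A = "n_hla_A", hla_B = "n_hla_B", hla_C = "n_hla_C"
  )
  for (nm in names(strata_scores)) {
    sc <- tibble::tibble(patient = summary$patient,
                         score = summary[[strata_scores[[nm]]]])
    for (mode in c("quartile", "mean")) {
      split <- tryCatch(dichotomize(sc, mode = mode),
                        neosurv_validation_error = function(e) NULL)
      if (is.null(split)) next
      merged <- dplyr::inner_join(clin, split[!is.na(split$group), ],
                                  by = "patient")
      if (length(unique(merged$group)) != 2 ||
          min(table(merged$group)) < 2) next
      lr <- suppressWarnings(logrank_test(merged, merged$group))
      key <- paste0(nm, "_", mode)
      km_curves[[key]] <- purrr::map(
        stats::setNames(c("low", "high"), c("low", "high")),
        function(g) km_fit(merged[merged$group == g, ])
      )
      surv_tests[[length(surv_tests) + 1L]] <- tibble::tibble(
        score = nm, mode = mode, chi_square = lr$chi_square,
        p_value = lr$p_value,
        n_low = sum(merged$group == "low"),
        n_high = sum(merged$group == "high"),
        median_low = km_curves[[key]]$low$median_survival,
        median_high = km_curves[[key]]$high$median_survival,
        last_event_low = km_curves[[key]]$low$last_event_time,
        last_event_high = km_curves[[key]]$high$last_event_time
      )
    }
  }
  if (config$run_tme) {
    merged <- dplyr::inner_join(clin, tme$gzma_split, by = "patient")
    lr <- suppressWarnings(logrank_test(merged, merged$group))
    surv_tests[[length(surv_tests) + 1L]] <- tibble::tibble(
      score = "GZMA_expression", mode = "mean", chi_square = lr$chi_square,
      p_value = lr$p_value,
      n_low = sum(merged$group == "low"),
      n_high = sum(merged$group == "high"),
      median_low = NA_real_, median_high = NA_real_,
      last_event_low = NA_real_, last_event_high = NA_real_
    )
  }
  if (config$run_homology &&
      sum(table(homology$classes$label) >= 2) >= 2) {
    present <- names(which(table(homology$classes$label) >= 2))
    cls <- homology$classes[homology$classes$label %in% present, ]
    by_class <- survival_by_class(clin, cls)
    km_curves[["homology_class"]] <- by_class$curves
    surv_tests[[length(surv_tests) + 1L]] <- dplyr::mutate(
      dplyr::rename(by_class$tests, n_low = "n_a", n_high = "n_b"),
      score = paste0("homology_", .data$class_a, "_vs_", .data$class_b),
      mode = "class", median_low = NA_real_, median_high = NA_real_,
      last_event_low = NA_real_, last_event_high = NA_real_,
      .keep = "unused"
    )[, c("score", "mode", "chi_square", "p_value", "n_low", "n_high",
          "median_low", "median_high", "last_event_low",
          "last_event_high")]
  }

  structure(
    list(
      cohort_sizes = tibble::tibble(
        n_total = length(cohort$patients),
        n_training = if (config$n_training < length(cohort$patients))
          config$n_training else NA_integer_,
        n_validation = if (config$n_training < length(cohort$patients))
          length(cohort$patients) - config$n_training else NA_integer_
      ),
      split = if (config$n_training < length(cohort$patients))
        split_cohort(cohort$patients, config$n_training,
                     seed = config$split_seed) else NULL,
      records = called$records,
      patient_summaries = summary,
      tier_totals = tier_totals,
      fractions = fractions,
      homology = homology,
      tme = tme,
      survival = list(tests = dplyr::bind_rows(surv_tests),
                      curves = km_curves),
      config = config
    ),
    class = "neo_run_report"
  )
}

#' Fractions table with recomputed percentages
#'
#' Percentages are always recomputed from the counts (never stored
#' independently), rounded half-even to `digits`; the raw ratio is
#' retained alongside.  A zero denominator yields `NA` percent with a
#' `defined = FALSE` flag.
#'
#' @param numerator,denominator Integer count vectors.
#' @param label Optional labels.
#' @param digits Decimal places for the rounded percent (default 2).
#' @return Tibble `label`, `numerator`, `denominator`, `ratio`, `percent`
#'   (rounded), `defined`.
#' @export
report_fractions <- function(numerator, denominator, label = NULL,
                             digits = 2) {
  if (is.null(label)) label <- as.character(seq_along(numerator))
  ratio <- ifelse(denominator > 0, numerator / denominator, NA_real_)
  tibble::tibble(
    label = label,
    numerator = numerator,
    denominator = denominator,
    ratio = ratio,
    percent = round(100 * ratio, digits),
    defined = denominator > 0
  )
}

#' Per-patient means from cohort totals
#'
#' @param totals Named numeric vector of cohort-level counts.
#' @param n_patients Number of patients.
#' @param digits Decimal places (default 1, matching per-sample averages
#'   as usually reported).
#' @return Tibble `label`, `total`, `n_patients`, `mean` (rounded) and
#'   `mean_raw`.
#' @export
cohort_means <- function(totals, n_patients, digits = 1) {
  tibble::tibble(
    label = names(totals),
    total = unname(totals),
    n_patients = n_patients,
    mean_raw = unname(totals) / n_patients,
    mean = round(unname(totals) / n_patients, digits)
  )
}

#' @export
print.neo_run_report <- function(x, ...) {
  cat("<neo_run_report>\n")
  cat("  patients:", x$cohort_sizes$n_total, "\n")
  cat("  neoantigen records:", x$tier_totals$n_candidates,
      "| DAI tier:", x$tier_totals$n_dai10,
      "| high-affinity:", x$tier_totals$n_dai10_highaff, "\n")
  if (!is.null(x$homology)) {
    cc <- x$homology$class_counts
    cat("  homology classes:",
        paste(cc$label, cc$numerator, collapse = ", "), "\n")
  }
  cat("  survival tests:", nrow(x$survival$tests), "\n")
  invisible(x)
}
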