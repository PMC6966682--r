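# The neoantigen prediction cascade: expressed missense variants ->
# mutant/wild-type 9-mer pairs -> binding filters (percent rank, IC50) ->
# DAI and quality tiers -> HLA-locus attribution -> per-patient summaries.
#
# Boundary semantics, read literally from the filter definitions:
# percent rank is kept at <= rank_max (inclusive); IC50 filters are strict
# (< 500 nM candidate, < 50 nM high affinity); the DAI tier bound is strict
# (> 10).

#' Filter variants to expressed genes
#'
#' Keeps variants whose mutated gene's expression in that patient is
#' strictly greater than `threshold` (unitless: the threshold applies to
#' whatever normalized unit the expression matrix carries).
#'
#' @param variants Tibble with a `gene_expression` column (see
#'   [attach_expression()]).
#' @param threshold Expression cutoff; default 2.
#' @return The filtered tibble, input order preserved.
#' @export
filter_expressed <- function(variants, threshold = 2) {
  if (!"gene_expression" %in% names(variants)) {
    rlang::abort("variants lack a gene_expression column; see attach_expression()",
                 class = "neosurv_validation_error")
  }
  if (anyNA(variants$gene_expression)) {
    bad <- variants[is.na(variants$gene_expression), ]
    rlang::abort(paste0("missing expression for mutated gene(s): ",
                        paste(bad$gene, bad$patient, sep = "@",
                              collapse = ", ")),
                 class = "neosurv_validation_error")
  }
  variants[variants$gene_expression > threshold, ]
}

#' Attach each patient's expression of the mutated gene
#'
#' @param variants Variant tibble (`patient`, `gene`, ...).
#' @param expression Gene-by-patient matrix.
#' @return `variants` with a `gene_expression` column added.
#' @export
attach_expression <- function(variants, expression) {
  missing_gene <- setdiff(unique(variants$gene), rownames(expression))
  if (length(missing_gene)) {
    rlang::abort(paste0("expression matrix lacks mutated gene(s): ",
                        paste(missing_gene, collapse = ", ")),
                 class = "neosurv_validation_error")
  }
  variants$gene_expression <- expression[cbind(variants$gene,
                                               variants$patient)]
  variants
}

#' Enumerate mutant/wild-type 9-mer pairs around missense variants
#'
#' For each variant, emits every 9-residue window of the protein that
#' contains the mutated position: window starts run from
#' `max(1, pos - 8)` to `min(pos, len - 8)` (1-based closed coordinates),
#' so an interior mutation yields exactly nine pairs.  The wild-type
#' peptide is the unmodified window; the mutant substitutes the alternate
#' residue at the mutated coordinate, so each pair differs at exactly one
#' position (`mut_offset`, 1-9 within the peptide).
#'
#' @param variants Variant tibble (`patient`, `gene`, `protein_pos`,
#'   `ref_aa`, `alt_aa`).
#' @param proteome Named character vector of protein sequences.
#' @return Tibble with one row per (variant, window): the variant columns
#'   plus `window_start`, `mut_offset`, `wildtype`, `mutant`.  Proteins
#'   shorter than 9 residues contribute no rows (with a warning).
#' @export
enumerate_pairs <- function(variants, proteome) {
  missing_gene <- setdiff(unique(variants$gene), names(proteome))
  if (length(missing_gene)) {
    rlang::abort(paste0("proteome lacks gene(s): ",
                        paste(missing_gene, collapse = ", ")),
                 class = "neosurv_validation_error")
  }
  len <- nchar(proteome)[variants$gene]
  ref_found <- substr(proteome[variants$gene], variants$protein_pos,
                      variants$protein_pos)
  mismatch <- ref_found != variants$ref_aa
  if (any(mismatch)) {
    bad <- variants[mismatch, ]
    rlang::abort(paste0("reference residue mismatch at ",
                        paste(bad$gene, bad$protein_pos, sep = ":",
                              collapse = ", ")),
                 class = "neosurv_validation_error")
  }
  short <- len < 9L
  if (any(short)) {
    rlang::warn(paste0(sum(short), " variant(s) fall in proteins shorter ",
                       "than 9 residues and yield no peptides"))
  }
  v <- variants[!short, , drop = FALSE]
  if (!nrow(v)) {
    return(dplyr::mutate(variants[0, ], window_start = integer(),
                         mut_offset = integer(), wildtype = character(),
                         mutant = character()))
  }
  len <- len[!short]
  first <- pmax(1L, v$protein_pos - 8L)
  last <- pmin(v$protein_pos, len - 8L)
  n_win <- last - first + 1L
  idx <- rep(seq_len(nrow(v)), n_win)
  window_start <- unlist(purrr::map2(first, last, seq.int), use.names = FALSE)
  out <- v[idx, , drop = FALSE]
  out$window_start <- as.integer(window_start)
  out$mut_offset <- out$protein_pos - out$window_start + 1L
  out$wildtype <- unname(substr(proteome[out$gene], out$window_start,
                                out$window_start + 8L))
  mutant <- out$wildtype
  substr(mutant, out$mut_offset, out$mut_offset) <- out$alt_aa
  out$mutant <- mutant
  tibble::as_tibble(out)
}

#' Differential agretopicity index (DAI)
#'
#' The default (`"difference"`) DAI is the wild-type minus the mutant
#' predicted IC50 in nM: positive values mean the mutation created a
#' stronger MHC binder.  `"ratio"` mode (wild-type / mutant IC50) is
#' provided for sensitivity analysis.
#'
#' @param mut_ic50_nM,wt_ic50_nM Positive predicted affinities in nM.
#' @param mode `"difference"` (default) or `"ratio"`.
#' @return Numeric DAI vector.
#' @export
compute_dai <- function(mut_ic50_nM, wt_ic50_nM,
                        mode = c("difference", "ratio")) {
  mode <- match.arg(mode)
  if (any(mut_ic50_nM <= 0) || any(wt_ic50_nM <= 0)) {
    rlang::abort("IC50 values must be positive",
                 class = "neosurv_validation_error")
  }
  switch(mode,
         difference = wt_ic50_nM - mut_ic50_nM,
         ratio = wt_ic50_nM / mut_ic50_nM)
}

#' Assign quality tiers to candidate neoantigens
#'
#' Tiers are nested: `DAI10_HIGHAFF` (DAI > `dai_min` and mutant IC50 <
#' `highaff_max`), `DAI10` (DAI > `dai_min` only), else `CANDIDATE`.
#' All bounds strict.
#'
#' @param dai DAI values.
#' @param mut_ic50_nM Mutant IC50 values (nM).
#' @param dai_min DAI bound, default 10.
#' @param highaff_max High-affinity IC50 bound in nM, default 50.
#' @return Factor with levels `CANDIDATE`, `DAI10`, `DAI10_HIGHAFF`.
#' @export
assign_tier <- function(dai, mut_ic50_nM, dai_min = 10, highaff_max = 50) {
  tier <- dplyr::case_when(
    dai > dai_min & mut_ic50_nM < highaff_max ~ "DAI10_HIGHAFF",
    dai > dai_min ~ "DAI10",
    .default = "CANDIDATE"
  )
  factor(tier, levels = c("CANDIDATE", "DAI10", "DAI10_HIGHAFF"))
}

#' Select candidate neoantigens from peptide pairs and binding predictions
#'
#' Joins each mutant peptide to its predictions on the patient's
#' (deduplicated) alleles, keeps records with percent rank `<= rank_max`
#' and mutant IC50 `< ic50_max_nM`, attaches the wild-type prediction on
#' the same allele (an error if absent: DAI would be undefined), and
#' derives DAI, tier and HLA locus.
#'
#' @param pairs Output of [enumerate_pairs()].
#' @param predictions Tibble of predictions (`peptide`, `allele`,
#'   `ic50_nM`, `percent_rank`) covering every mutant and wild-type
#'   peptide on the relevant alleles (e.g. [toy_predict()] or
#'   [read_predictor_output()]).
#' @param hla Tibble (`patient`, `allele`) of patient genotypes.
#' @param rank_max Percent-rank cutoff, inclusive; default 2.
#' @param ic50_max_nM Mutant IC50 cutoff, strict; default 500.
#' @param dai_mode Passed to [compute_dai()].
#' @param dai_min,highaff_max Passed to [assign_tier()].
#' @return Tibble of neoantigen records: `patient`, `gene`, pair columns,
#'   `allele`, `hla_locus`, `mut_ic50_nM`, `wt_ic50_nM`, `percent_rank`,
#'   `dai`, `tier`.
#' @export
select_candidates <- function(pairs, predictions, hla,
                              rank_max = 2, ic50_max_nM = 500,
                              dai_mode = "difference",
                              dai_min = 10, highaff_max = 50) {
  alleles <- dplyr::distinct(hla[, c("patient", "allele")])
  cand <- dplyr::inner_join(pairs, alleles, by = "patient",
                            relationship = "many-to-many")
  cand <- dplyr::left_join(
    cand,
    dplyr::rename(predictions, mut_ic50_nM = "ic50_nM"),
    by = c(mutant = "peptide", allele = "allele")
  )
  if (anyNA(cand$mut_ic50_nM)) {
    bad <- cand[is.na(cand$mut_ic50_nM), ]
    rlang::abort(paste0("missing prediction for mutant peptide(s): ",
                        paste(utils::head(unique(paste0(bad$mutant, "/",
                                                        bad$allele)), 5),
                              collapse = ", ")),
                 class = "neosurv_validation_error")
  }
  keep <- cand$percent_rank <= rank_max & cand$mut_ic50_nM < ic50_max_nM
  cand <- cand[keep, , drop = FALSE]
  cand <- dplyr::left_join(
    cand,
    dplyr::select(dplyr::rename(predictions, wt_ic50_nM = "ic50_nM"),
                  "peptide", "allele", "wt_ic50_nM"),
    by = c(wildtype = "peptide", allele = "allele")
  )
  if (anyNA(cand$wt_ic50_nM)) {
    bad <- cand[is.na(cand$wt_ic50_nM), ]
    rlang::abort(paste0("missing wild-type prediction for retained ",
                        "mutant(s); DAI undefined for: ",
                        paste(utils::head(unique(paste0(bad$wildtype, "/",
                                                        bad$allele)), 5),
                              collapse = ", ")),
                 class = "neosurv_validation_error")
  }
  cand$hla_locus <- hla_locus(cand$allele)
  cand$dai <- compute_dai(cand$mut_ic50_nM, cand$wt_ic50_nM, mode = dai_mode)
  cand$tier <- assign_tier(cand$dai, cand$mut_ic50_nM,
                           dai_min = dai_min, highaff_max = highaff_max)
  tibble::as_tibble(cand)
}

#' Tumor mutational burden
#'
#' @param n_mutations Somatic mutation count(s).
#' @param capture_mb Captured exome size in Mb (default 38, a standard
#'   exome; the denominator is configurable because capture designs vary).
#' @return Mutations per Mb.
#' @export
compute_tmb <- function(n_mutations, capture_mb = 38) {
  if (any(capture_mb <= 0)) {
    rlang::abort("capture_mb must be positive",
                 class = "neosurv_validation_error")
  }
  n_mutations / capture_mb
}

#' Summarize neoantigen records per patient
#'
#' Counts candidates and tier members per patient (tiers are nested:
#' `n_candidates >= n_dai10 >= n_dai10_highaff`), attributes counts to HLA
#' loci, and computes TMB.  In `count_mode = "record"` (default) a peptide
#' presented by k distinct alleles contributes k; `"peptide"` counts each
#' distinct mutant peptide once.  Exact duplicate (peptide, allele) rows
#' are always collapsed first.
#'
#' @param records Neoantigen record tibble from [select_candidates()].
#' @param variant_counts Tibble (`patient`, `n_mutations`) of somatic
#'   mutation counts per patient; patients listed here but absent from
#'   `records` receive zero counts.
#' @param capture_mb Exome size for TMB.
#' @param count_mode `"record"` or `"peptide"`.
#' @return Tibble with one row per patient: `tmb`, `n_candidates`,
#'   `n_dai10`, `n_dai10_highaff`, `n_hla_A`, `n_hla_B`, `n_hla_C`,
#'   `frac_highaff_of_dai10` (0 when no DAI-tier records).
#' @export
summarize_patients <- function(records, variant_counts, capture_mb = 38,
                               count_mode = c("record", "peptide")) {
  count_mode <- match.arg(count_mode)
  rec <- dplyr::distinct(records, .data$patient, .data$mutant, .data$allele,
                         .keep_all = TRUE)
  if (count_mode == "peptide") {
    # one row per distinct mutant peptide; keep its best (lowest IC50) allele
    rec <- dplyr::slice_min(dplyr::group_by(rec, .data$patient, .data$mutant),
                            .data$mut_ic50_nM, n = 1, with_ties = FALSE)
    rec <- dplyr::ungroup(rec)
  }
  per <- dplyr::summarise(
    dplyr::group_by(rec, .data$patient),
    n_candidates = dplyr::n(),
    n_dai10 = sum(.data$tier %in% c("DAI10", "DAI10_HIGHAFF")),
    n_dai10_highaff = sum(.data$tier == "DAI10_HIGHAFF"),
    n_hla_A = sum(.data$hla_locus == "A"),
    n_hla_B = sum(.data$hla_locus == "B"),
    n_hla_C = sum(.data$hla_locus == "C"),
    .groups = "drop"
  )
  out <- dplyr::left_join(tibble::as_tibble(variant_counts), per,
                          by = "patient")
  count_cols <- c("n_candidates", "n_dai10", "n_dai10_highaff",
                  "n_hla_A", "n_hla_B", "n_hla_C")
  out[count_cols] <- lapply(out[count_cols], function(x) {
    tidyr::replace_na(x, 0L)
  })
  out$tmb <- compute_tmb(out$n_mutations, capture_mb)
  out$frac_highaff_of_dai10 <- ifelse(out$n_dai10 > 0,
                                      out$n_dai10_highaff / out$n_dai10, 0)
  dplyr::relocate(out, "patient", "n_mutations", "tmb")
}

#' Run the full neoantigen-calling cascade on a cohort
#'
#' Convenience wrapper: attaches expression, applies the expression
#' filter, enumerates 9-mer pairs, predicts binding for every mutant and
#' wild-type peptide on each patient's alleles (with the bundle's toy
#' predictor unless `predictions` are supplied), and selects, tiers and
#' summarizes candidates.
#'
#' @param cohort A [neo_cohort()] bundle.
#' @param predictions Optional externally parsed predictions; default uses
#'   `cohort$predictor` via [toy_predict()].
#' @param expr_min Expression filter threshold (strictly greater than).
#' @param rank_max,ic50_max_nM,dai_mode,dai_min,highaff_max Cascade
#'   thresholds, see [select_candidates()].
#' @param capture_mb Exome size for TMB.
#' @return List with elements `records` (neoantigen records) and
#'   `summary` (per-patient summary including patients with zero
#'   candidates).
#' @export
call_neoantigens <- function(cohort, predictions = NULL,
                             expr_min = 2, rank_max = 2, ic50_max_nM = 500,
                             dai_mode = "difference", dai_min = 10,
                             highaff_max = 50, capture_mb = 38) {
  variants <- attach_expression(cohort$variants, cohort$expression)
  expressed <- filter_expressed(variants, threshold = expr_min)
  pairs <- enumerate_pairs(expressed, cohort$proteome)
  if (is.null(predictions)) {
    if (is.null(cohort$predictor)) {
      rlang::abort("no predictions supplied and cohort has no toy predictor",
                   class = "neosurv_validation_error")
    }
    alleles <- dplyr::distinct(cohort$hla[, c("patient", "allele")])
    need <- dplyr::inner_join(pairs, alleles, by = "patient",
                              relationship = "many-to-many")
    grid <- dplyr::distinct(tibble::tibble(
      peptide = c(need$mutant, need$wildtype),
      allele = rep(need$allele, 2L)
    ))
    predictions <- toy_predict(grid$peptide, grid$allele, cohort$predictor)
  }
  records <- select_candidates(pairs, predictions, cohort$hla,
                               rank_max = rank_max,
                               ic50_max_nM = ic50_max_nM,
                               dai_mode = dai_mode, dai_min = dai_min,
                               highaff_max = highaff_max)
  variant_counts <- dplyr::count(cohort$variants, .data$patient,
                                 name = "n_mutations")
  variant_counts <- dplyr::left_join(
    tibble::tibble(patient = cohort$patients), variant_counts, by = "patient"
  )
  variant_counts$n_mutations <- tidyr::replace_na(variant_counts$n_mutations,
                                                  0L)
  summary <- summarize_patients(records, variant_counts,
                                capture_mb = capture_mb)
  list(records = records, summary = summary)
}
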