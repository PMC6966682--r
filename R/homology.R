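# Homology of predicted neoepitopes to a catalog of validated epitopes.
#
# Comparison is ungapped, 9 against 9.  A position is "identical" when the
# residues are equal and "similar" when the substitution-matrix score
# (BLOSUM62 by default) is positive.  A pair passes when the similarity
# fraction exceeds the homology threshold AND at least `tcr_min` of the
# four TCR-contact positions (1, 4, 5, 8) are identical.  The homology
# metric defaults to similarity rather than strict identity because
# reported homologous pairs share as few as 5/9 identical residues;
# `mode = "identity"` restores the strict reading.

blosum62_env <- new.env(parent = emptyenv())

#' The BLOSUM62 substitution matrix over the 20 standard residues
#'
#' @return A 20 x 20 integer matrix (from the Biostrings data set).
#' @export
blosum62_matrix <- function() {
  if (is.null(blosum62_env$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum62_env$m <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  }
  blosum62_env$m
}

#' Score one neoepitope / catalog-epitope pair
#'
#' @param neoepitope,catalog_epitope 9-mer amino-acid strings.
#' @param matrix Substitution matrix; default BLOSUM62.
#' @param sim_threshold Homology threshold (fraction of the 9 positions);
#'   the pass rule is strict (`> sim_threshold`).  Default 0.70.
#' @param tcr_min Minimum identical TCR-contact positions of {1,4,5,8};
#'   default 2.
#' @param mode `"similarity"` (identical-or-positive-score positions count
#'   toward homology; default) or `"identity"` (identical positions only).
#' @return One-row tibble: `neoepitope`, `catalog_sequence`,
#'   `total_identical` (0-9), `tcr_identical` (0-4), `identity_fraction`,
#'   `similarity_fraction`, `passes`.
#' @export
score_epitope_pair <- function(neoepitope, catalog_epitope,
                               matrix = blosum62_matrix(),
                               sim_threshold = 0.70, tcr_min = 2,
                               mode = c("similarity", "identity")) {
  mode <- match.arg(mode)
  assert_peptide9(neoepitope, "neoepitope")
  assert_peptide9(catalog_epitope, "catalog epitope")
  a <- strsplit(neoepitope, "", fixed = TRUE)[[1]]
  b <- strsplit(catalog_epitope, "", fixed = TRUE)[[1]]
  identical_pos <- a == b
  similar_pos <- identical_pos | matrix[cbind(a, b)] > 0
  total_identical <- sum(identical_pos)
  tcr_identical <- sum(identical_pos[TCR_POSITIONS])
  identity_fraction <- total_identical / 9
  similarity_fraction <- sum(similar_pos) / 9
  homology <- if (mode == "similarity") similarity_fraction else
    identity_fraction
  tibble::tibble(
    neoepitope = neoepitope,
    catalog_sequence = catalog_epitope,
    total_identical = total_identical,
    tcr_identical = tcr_identical,
    identity_fraction = identity_fraction,
    similarity_fraction = similarity_fraction,
    passes = homology > sim_threshold & tcr_identical >= tcr_min
  )
}

# Vectorized position-wise comparison of equal-length peptide vectors.
compare_peptides <- function(a_mat, b_mat, matrix) {
  n <- nrow(a_mat)
  identical_count <- integer(n)
  similar_count <- integer(n)
  tcr_count <- integer(n)
  for (j in 1:9) {
    eq <- a_mat[, j] == b_mat[, j]
    sim <- eq | matrix[cbind(a_mat[, j], b_mat[, j])] > 0
    identical_count <- identical_count + eq
    similar_count <- similar_count + sim
    if (j %in% TCR_POSITIONS) tcr_count <- tcr_count + eq
  }
  list(identical = identical_count, similar = similar_count,
       tcr = tcr_count)
}

#' Scan predicted neoantigens against the epitope catalog
#'
#' Exhaustive all-vs-all ungapped comparison (no heuristic seeding) of
#' every distinct (patient, mutant peptide) against every catalog epitope,
#' returning passing matches only, ordered deterministically by patient,
#' neoepitope, descending similarity, then catalog row index.
#'
#' @param neoantigens Neoantigen record tibble (needs `patient`,
#'   `mutant`); typically `call_neoantigens()$records`.
#' @param catalog Epitope catalog tibble (`sequence`, `source_class`,
#'   `source_name`).
#' @param matrix,sim_threshold,tcr_min,mode See [score_epitope_pair()].
#' @return Tibble of passing matches: `patient`, `neoepitope`,
#'   `catalog_index`, `catalog_sequence`, `source_class`, `source_name`,
#'   `total_identical`, `tcr_identical`, `identity_fraction`,
#'   `similarity_fraction`.
#' @export
scan_catalog <- function(neoantigens, catalog,
                         matrix = blosum62_matrix(),
                         sim_threshold = 0.70, tcr_min = 2,
                         mode = c("similarity", "identity")) {
  mode <- match.arg(mode)
  if (!nrow(catalog)) {
    return(tibble::tibble(patient = character(), neoepitope = character(),
                          catalog_index = integer(),
                          catalog_sequence = character(),
                          source_class = character(),
                          source_name = character(),
                          total_identical = integer(),
                          tcr_identical = integer(),
                          identity_fraction = numeric(),
                          similarity_fraction = numeric()))
  }
  validate_catalog(catalog)
  neo <- dplyr::distinct(neoantigens[, c("patient", "mutant")])
  if (!nrow(neo)) return(scan_catalog(neoantigens, catalog[0, ]))
  n_neo <- nrow(neo)
  n_cat <- nrow(catalog)
  a_idx <- peptides_to_idx(neo$mutant)
  b_idx <- peptides_to_idx(catalog$sequence)
  # expand: every neoepitope against every catalog row
  ai <- rep(seq_len(n_neo), each = n_cat)
  bi <- rep(seq_len(n_cat), times = n_neo)
  a_mat <- matrix(AA_ALPHABET[a_idx[ai, ]], nrow = length(ai))
  b_mat <- matrix(AA_ALPHABET[b_idx[bi, ]], nrow = length(bi))
  cmp <- compare_peptides(a_mat, b_mat, matrix)
  homology <- if (mode == "similarity") cmp$similar / 9 else cmp$identical / 9
  passes <- homology > sim_threshold & cmp$tcr >= tcr_min
  out <- tibble::tibble(
    patient = neo$patient[ai][passes],
    neoepitope = neo$mutant[ai][passes],
    catalog_index = bi[passes],
    catalog_sequence = catalog$sequence[bi[passes]],
    source_class = catalog$source_class[bi[passes]],
    source_name = catalog$source_name[bi[passes]],
    total_identical = cmp$identical[passes],
    tcr_identical = cmp$tcr[passes],
    identity_fraction = cmp$identical[passes] / 9,
    similarity_fraction = cmp$similar[passes] / 9
  )
  dplyr::arrange(out, .data$patient, .data$neoepitope,
                 dplyr::desc(.data$similarity_fraction), .data$catalog_index)
}

#' Classify samples by the origin of their homologous neoantigens
#'
#' A patient with no passing match is `"none"`; with matches of one source
#' class, that class; with both classes, the configured `priority` class
#' (and `dual_flag = TRUE`).  The three labels always partition the
#' cohort.
#'
#' @param patients Character vector of all cohort patients (so that
#'   patients without matches are classified too).
#' @param matches Passing matches from [scan_catalog()].
#' @param priority `"pathogen"` (default) or `"self"`: the label assigned
#'   when a sample has homologs of both classes.
#' @return Tibble: `patient`, `label` (factor none/self/pathogen),
#'   `n_self`, `n_pathogen`, `dual_flag`.
#' @export
classify_samples <- function(patients, matches,
                             priority = c("pathogen", "self")) {
  priority <- match.arg(priority)
  counts <- dplyr::summarise(
    dplyr::group_by(matches, .data$patient),
    n_self = sum(.data$source_class == "self"),
    n_pathogen = sum(.data$source_class == "pathogen"),
    .groups = "drop"
  )
  out <- dplyr::left_join(tibble::tibble(patient = patients), counts,
                          by = "patient")
  out$n_self <- tidyr::replace_na(out$n_self, 0L)
  out$n_pathogen <- tidyr::replace_na(out$n_pathogen, 0L)
  out$dual_flag <- out$n_self > 0 & out$n_pathogen > 0
  out$label <- dplyr::case_when(
    out$dual_flag ~ priority,
    out$n_pathogen > 0 ~ "pathogen",
    out$n_self > 0 ~ "self",
    .default = "none"
  )
  out$label <- factor(out$label, levels = c("none", "self", "pathogen"))
  out[, c("patient", "label", "n_self", "n_pathogen", "dual_flag")]
}
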