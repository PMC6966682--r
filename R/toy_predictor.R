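# Deterministic position-weight binding predictor.
#
# Stands in for an external MHC-I binding predictor so the cascade can run
# and be tested offline.  The model is intentionally simple and auditable:
# a peptide's score for an allele is the sum of per-position,
# per-residue weights (anchor positions up-weighted), mapped monotonically
# to an IC50 in (0, 50000] nM; the percent rank is the peptide's score
# quantile within a fixed pseudo-random reference peptide set regenerated
# from (allele, seed).

#' Build a deterministic toy MHC-I binding predictor
#'
#' Creates per-allele position-specific scoring profiles and reference
#' score distributions.  The same `(peptide, allele)` pair always yields
#' the same IC50 and percent rank; profiles depend only on the allele name
#' and `seed`, so adding alleles never changes existing predictions.
#'
#' The score-to-IC50 map is calibrated per allele on the reference
#' distribution so that a score at its 98th percentile maps to 500 nM and
#' a score at its 99.9th percentile maps to 50 nM, mirroring the convention
#' that percent-rank and affinity cutoffs select comparable top fractions.
#'
#' @param alleles Character vector of HLA class-I allele names.
#' @param seed Integer master seed for profile and reference generation.
#' @param anchor_positions Peptide positions receiving `anchor_weight`
#'   (default positions 2 and 9, the canonical class-I anchors).
#' @param anchor_weight Multiplier for anchor-position weights.
#' @param rank_reference_size Number of reference 9-mers per allele used
#'   for the percent-rank quantile.
#' @return An object of class `toy_predictor` usable with [toy_predict()].
#' @export
toy_predictor_spec <- function(alleles, seed = 1L,
                               anchor_positions = c(2L, 9L),
                               anchor_weight = 3,
                               rank_reference_size = 2000L) {
  alleles <- unique(alleles)
  per_allele <- lapply(alleles, function(al) {
    profile <- with_local_seed(
      component_seed(seed, paste0("profile:", al)),
      matrix(stats::rnorm(20L * 9L), nrow = 20L, ncol = 9L,
             dimnames = list(AA_ALPHABET, NULL))
    )
    profile[, anchor_positions] <- profile[, anchor_positions] * anchor_weight
    ref_idx <- with_local_seed(
      component_seed(seed, paste0("reference:", al)),
      matrix(sample.int(20L, rank_reference_size * 9L, replace = TRUE),
             ncol = 9L)
    )
    ref_scores <- score_matrix(ref_idx, profile)
    q98 <- stats::quantile(ref_scores, 0.98, names = FALSE)
    q999 <- stats::quantile(ref_scores, 0.999, names = FALSE)
    w <- (q999 - q98) / (log(999) - log(99))
    if (w <= 0) w <- stats::sd(ref_scores) / 4  # degenerate reference guard
    s0 <- q98 - log(99) * w
    list(profile = profile, ref_sorted = sort(ref_scores), s0 = s0, w = w)
  })
  names(per_allele) <- alleles
  structure(
    list(alleles = per_allele, seed = seed,
         anchor_positions = anchor_positions,
         anchor_weight = anchor_weight,
         rank_reference_size = rank_reference_size),
    class = "toy_predictor"
  )
}

# residue-index matrix (n x 9) -> additive scores under a 20 x 9 profile
score_matrix <- function(idx, profile) {
  s <- numeric(nrow(idx))
  for (j in seq_len(ncol(idx))) {
    s <- s + profile[idx[, j], j]
  }
  s
}

peptides_to_idx <- function(peptides) {
  assert_peptide9(peptides)
  matrix(match(unlist(strsplit(peptides, "", fixed = TRUE)), AA_ALPHABET),
         ncol = 9L, byrow = TRUE)
}

#' Predict peptide-MHC binding with the toy predictor
#'
#' @param peptides Character vector of 9-mer peptides.
#' @param alleles Character vector (recycled against `peptides`) of allele
#'   names known to `spec`.
#' @param spec A [toy_predictor_spec()] object.
#' @return Tibble with columns `peptide`, `allele`, `ic50_nM` (in
#'   `(0, 50000]`) and `percent_rank` (in `(0, 100]`; lower = better
#'   binder).
#' @export
toy_predict <- function(peptides, alleles, spec) {
  stopifnot(inherits(spec, "toy_predictor"))
  n <- max(length(peptides), length(alleles))
  peptides <- rep_len(peptides, n)
  alleles <- rep_len(alleles, n)
  unknown <- setdiff(unique(alleles), names(spec$alleles))
  if (length(unknown)) {
    rlang::abort(paste0("unknown allele(s): ",
                        paste(unknown, collapse = ", "),
                        "; known alleles: ",
                        paste(names(spec$alleles), collapse = ", ")),
                 class = "neosurv_validation_error")
  }
  idx <- peptides_to_idx(peptides)
  ic50 <- numeric(n)
  prank <- numeric(n)
  N <- spec$rank_reference_size
  for (al in unique(alleles)) {
    sel <- alleles == al
    comp <- spec$alleles[[al]]
    s <- score_matrix(idx[sel, , drop = FALSE], comp$profile)
    ic50[sel] <- 50000 / (1 + exp((s - comp$s0) / comp$w))
    # rank in (0, 100]: fraction of reference scores >= s, add-one smoothed
    n_ge <- N - findInterval(s, comp$ref_sorted, left.open = TRUE)
    prank[sel] <- 100 * (n_ge + 1) / (N + 1)
  }
  tibble::tibble(peptide = peptides, allele = alleles,
                 ic50_nM = ic50, percent_rank = prank)
}
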