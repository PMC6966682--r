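# The cohort bundle: one object holding every input table the pipeline
# consumes, validated once at construction so downstream code never
# re-checks raw files.

MARKER_GENES <- c("GZMA", "FOXP3", "CD274")

#' Assemble and validate a cohort bundle
#'
#' Bundles the per-patient inputs of the pipeline — somatic missense
#' variants, reference proteome, expression matrix, HLA class-I genotypes,
#' clinical outcomes and the local epitope catalog — into a single validated
#' object.  Validation enforces: every mutated gene has a proteome sequence,
#' every variant position lies inside its protein and carries the stated
#' reference residue, the expression matrix covers every mutated gene plus
#' the microenvironment marker genes (GZMA, FOXP3, CD274), and all
#' expression values are non-negative.
#'
#' @param variants Tibble with columns `patient`, `gene`, `protein_pos`
#'   (1-based), `ref_aa`, `alt_aa` (see [read_mutation_table()]).
#' @param proteome Named character vector mapping gene symbol to amino-acid
#'   sequence (see [read_proteome()]).
#' @param expression Numeric gene-by-patient matrix with gene symbols as
#'   row names and patient identifiers as column names.  Units are whatever
#'   normalized measure the caller supplies; thresholds downstream apply to
#'   that unit.
#' @param hla Tibble with columns `patient`, `allele` (up to six class-I
#'   alleles per patient).
#' @param clinical Tibble with columns `patient`, `time` (days), `event`
#'   (logical, `TRUE` = death observed) and optional categorical covariates
#'   (`stage`, `etiology`, `treatment`).
#' @param epitope_catalog Tibble with columns `sequence` (9-mers),
#'   `source_class` (`"self"` or `"pathogen"`), `source_name`.
#' @return An object of class `neo_cohort` (a named list of the validated
#'   components, with `patients` the vector of patient identifiers).
#' @export
neo_cohort <- function(variants, proteome, expression, hla, clinical,
                       epitope_catalog) {
  variants <- tibble::as_tibble(variants)
  clinical <- tibble::as_tibble(clinical)
  hla <- tibble::as_tibble(hla)
  epitope_catalog <- tibble::as_tibble(epitope_catalog)

  missing_genes <- setdiff(unique(variants$gene), names(proteome))
  if (length(missing_genes)) {
    rlang::abort(paste0("mutated gene(s) absent from proteome: ",
                        paste(missing_genes, collapse = ", ")),
                 class = "neosurv_validation_error")
  }
  plen <- nchar(proteome)[variants$gene]
  out_of_range <- variants$protein_pos < 1L | variants$protein_pos > plen
  if (any(out_of_range)) {
    bad <- variants[out_of_range, ]
    rlang::abort(paste0("variant position outside protein for: ",
                        paste(bad$gene, bad$protein_pos, sep = ":",
                              collapse = ", ")),
                 class = "neosurv_validation_error")
  }
  ref_found <- substr(proteome[variants$gene],
                      variants$protein_pos, variants$protein_pos)
  mismatch <- ref_found != variants$ref_aa
  if (any(mismatch)) {
    bad <- variants[mismatch, ]
    rlang::abort(paste0("reference residue mismatch at ",
                        paste(bad$gene, bad$protein_pos, sep = ":",
                              collapse = ", ")),
                 class = "neosurv_validation_error")
  }
  need_expr <- union(unique(variants$gene), MARKER_GENES)
  missing_expr <- setdiff(need_expr, rownames(expression))
  if (length(missing_expr)) {
    rlang::abort(paste0("expression matrix lacks required gene(s): ",
                        paste(missing_expr, collapse = ", ")),
                 class = "neosurv_validation_error")
  }
  if (any(expression < 0)) {
    rlang::abort("expression values must be non-negative",
                 class = "neosurv_validation_error")
  }
  validate_catalog(epitope_catalog)

  if (!"locus" %in% names(hla)) {
    hla$locus <- hla_locus(hla$allele)
  }
  structure(
    list(
      patients = clinical$patient,
      variants = variants,
      proteome = proteome,
      expression = expression,
      hla = hla,
      clinical = clinical,
      epitope_catalog = epitope_catalog
    ),
    class = "neo_cohort"
  )
}

validate_catalog <- function(catalog) {
  if (nrow(catalog)) {
    assert_peptide9(catalog$sequence, "epitope catalog sequence")
    bad <- setdiff(unique(catalog$source_class), c("self", "pathogen"))
    if (length(bad)) {
      rlang::abort(paste0("epitope source_class must be 'self' or ",
                          "'pathogen'; got: ", paste(bad, collapse = ", ")),
                   class = "neosurv_validation_error")
    }
  }
  invisible(catalog)
}

#' @export
print.neo_cohort <- function(x, ...) {
  cat("<neo_cohort> ", length(x$patients), " patients, ",
      nrow(x$variants), " missense variants, ",
      length(x$proteome), " proteins, ",
      nrow(x$epitope_catalog), " catalog epitopes\n", sep = "")
  invisible(x)
}
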