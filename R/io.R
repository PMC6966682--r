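# Readers and writers for every tabular and sequence format the pipeline
# touches.  All readers validate on entry and return tibbles (or, for the
# proteome, a named character vector); malformed input raises a typed
# condition rather than silently dropping rows, except where a documented
# skip-with-message rule applies (synonymous variants, non-9-mer epitopes).

#' Read a somatic mutation table
#'
#' Reads a per-patient table of protein-level missense changes.  The
#' `simple` dialect expects columns `patient`, `gene`, `protein_pos`,
#' `ref_aa`, `alt_aa`; the `maf` dialect accepts the VEP-annotated MAF
#' column subset `Tumor_Sample_Barcode`, `Hugo_Symbol`, `Protein_position`,
#' `Amino_acids` (e.g. `"R/H"`).  A custom mapping from required field to
#' file column can be given via `col_map`.  Rows whose reference and
#' alternate residues are identical (synonymous) are rejected with a
#' message; positions are 1-based.
#'
#' @param path Path to a UTF-8 TSV file.
#' @param dialect `"simple"` (default) or `"maf"`.
#' @param col_map Optional named character vector mapping
#'   `patient`/`gene`/`protein_pos`/`ref_aa`/`alt_aa` to file columns.
#' @return Tibble with columns `patient`, `gene`, `protein_pos` (integer),
#'   `ref_aa`, `alt_aa`; the number of rejected synonymous rows is stored
#'   in attribute `n_rejected`.
#' @export
read_mutation_table <- function(path, dialect = c("simple", "maf"),
                                col_map = NULL) {
  dialect <- match.arg(dialect)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (is.null(col_map)) {
    col_map <- switch(dialect,
      simple = c(patient = "patient", gene = "gene",
                 protein_pos = "protein_pos", ref_aa = "ref_aa",
                 alt_aa = "alt_aa"),
      maf = c(patient = "Tumor_Sample_Barcode", gene = "Hugo_Symbol",
              protein_pos = "Protein_position", amino_acids = "Amino_acids")
    )
  }
  missing_cols <- setdiff(unname(col_map), names(raw))
  if (length(missing_cols)) {
    rlang::abort(paste0("mutation table is missing required column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "neosurv_format_error")
  }
  tab <- tibble::tibble(
    patient = raw[[col_map[["patient"]]]],
    gene = raw[[col_map[["gene"]]]]
  )
  if ("amino_acids" %in% names(col_map)) {
    aa <- stringr::str_split_fixed(raw[[col_map[["amino_acids"]]]], "/", 2)
    tab$ref_aa <- aa[, 1]
    tab$alt_aa <- ifelse(aa[, 2] == "", aa[, 1], aa[, 2])
  } else {
    tab$ref_aa <- raw[[col_map[["ref_aa"]]]]
    tab$alt_aa <- raw[[col_map[["alt_aa"]]]]
  }
  pos_chr <- raw[[col_map[["protein_pos"]]]]
  pos <- suppressWarnings(as.integer(pos_chr))
  pos_num <- suppressWarnings(as.numeric(pos_chr))
  bad_pos <- which(is.na(pos) | is.na(pos_num) | pos_num != pos)
  if (length(bad_pos)) {
    rlang::abort(paste0("non-integer protein position at data row(s): ",
                        paste(bad_pos, collapse = ", ")),
                 class = "neosurv_format_error")
  }
  tab$protein_pos <- pos
  tab <- tab[, c("patient", "gene", "protein_pos", "ref_aa", "alt_aa")]

  synonymous <- tab$ref_aa == tab$alt_aa
  if (any(synonymous)) {
    rlang::inform(paste0("rejected ", sum(synonymous),
                         " synonymous row(s) (ref == alt)"))
  }
  out <- tab[!synonymous, ]
  attr(out, "n_rejected") <- sum(synonymous)
  out
}

#' Read a protein FASTA file
#'
#' @param path Path to an amino-acid FASTA file; record names are taken as
#'   gene symbols (text before the first whitespace).
#' @return Named character vector of amino-acid sequences.
#' @export
read_proteome <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Read a gene-by-patient expression matrix
#'
#' @param path TSV with gene symbols in the first column (`gene`) and one
#'   numeric column per patient.
#' @return Numeric matrix, genes in rows, patients in columns.
#' @export
read_expression_matrix <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene
  if (any(is.na(m))) {
    rlang::abort("expression matrix contains non-numeric or missing values",
                 class = "neosurv_format_error")
  }
  m
}

#' Read per-patient HLA class-I genotypes
#'
#' Accepts either a long table (`patient`, `allele`) or a wide table with a
#' `patient` column plus up to six allele columns.
#'
#' @param path TSV path.
#' @return Tibble with columns `patient`, `allele`, `locus`.
#' @export
read_hla_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!"patient" %in% names(raw)) {
    rlang::abort("HLA table is missing required column: patient",
                 class = "neosurv_format_error")
  }
  if ("allele" %in% names(raw)) {
    long <- raw[, c("patient", "allele")]
  } else {
    long <- tidyr::pivot_longer(raw, -"patient", names_to = NULL,
                                values_to = "allele")
  }
  long <- dplyr::filter(long, !is.na(.data$allele), .data$allele != "")
  n_per <- dplyr::count(long, .data$patient)
  if (any(n_per$n > 6)) {
    rlang::abort("a patient carries more than 6 class-I alleles",
                 class = "neosurv_validation_error")
  }
  long$locus <- hla_locus(long$allele)
  tibble::as_tibble(long)
}

#' Read the clinical outcome table
#'
#' @param path TSV with columns `patient`, `time` (days), `event` (0/1 or
#'   TRUE/FALSE) and optional categorical covariates such as `stage`,
#'   `etiology`, `treatment`.
#' @return Tibble with `time` numeric and `event` logical.
#' @export
read_clinical_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    patient = "c", time = "d", event = "c", .default = "c"
  ), progress = FALSE)
  for (col in c("patient", "time", "event")) {
    if (!col %in% names(tab)) {
      rlang::abort(paste0("clinical table is missing required column: ", col),
                   class = "neosurv_format_error")
    }
  }
  tab$event <- tab$event %in% c("1", "TRUE", "true", "T")
  if (any(is.na(tab$time) | tab$time < 0)) {
    rlang::abort("clinical table has missing or negative survival times",
                 class = "neosurv_validation_error")
  }
  tab
}

#' Read a local epitope catalog
#'
#' Reads an IEDB-export-like table of validated epitopes.  Only 9-mers are
#' retained (others are skipped with a message); source classes are
#' restricted to `"self"` and `"pathogen"`.
#'
#' @param path TSV with columns `sequence`, `source_class`, `source_name`.
#' @return Tibble of 9-mer catalog epitopes; the number of skipped
#'   non-9-mer rows is stored in attribute `n_skipped`.
#' @export
read_epitope_catalog <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  for (col in c("sequence", "source_class", "source_name")) {
    if (!col %in% names(tab)) {
      rlang::abort(paste0("epitope catalog is missing required column: ", col),
                   class = "neosurv_format_error")
    }
  }
  not9 <- nchar(tab$sequence) != 9L
  if (any(not9)) {
    rlang::inform(paste0("skipped ", sum(not9),
                         " catalog row(s) that are not 9-mers"))
  }
  out <- tab[!not9, c("sequence", "source_class", "source_name")]
  validate_catalog(out)
  attr(out, "n_skipped") <- sum(not9)
  out
}

#' Read parsed output of an external MHC-I binding predictor
#'
#' Accepts whitespace- or tab-delimited text with header columns for the
#' peptide, allele, predicted affinity in nM (`ic50`, `ic50_nM`,
#' `affinity` or `aff`) and percent rank (`percent_rank`, `rank` or
#' `%rank`), in any order.  Exact duplicate (peptide, allele) rows are
#' collapsed to one; duplicates with conflicting values are an error.
#'
#' @param path Path to the predictor output file.
#' @return Tibble with columns `peptide`, `allele`, `ic50_nM`,
#'   `percent_rank`.
#' @export
read_predictor_output <- function(path) {
  tab <- readr::read_table(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  nm <- tolower(names(tab))
  pick <- function(cands, what) {
    hit <- which(nm %in% cands)
    if (!length(hit)) {
      rlang::abort(paste0("predictor output is missing a ", what,
                          " column (one of: ",
                          paste(cands, collapse = ", "), ")"),
                   class = "neosurv_format_error")
    }
    hit[1]
  }
  out <- tibble::tibble(
    peptide = tab[[pick("peptide", "peptide")]],
    allele = tab[[pick(c("allele", "hla"), "allele")]],
    ic50_chr = tab[[pick(c("ic50", "ic50_nm", "affinity", "aff"),
                         "affinity (nM)")]],
    rank_chr = tab[[pick(c("percent_rank", "rank", "%rank", "rank_el"),
                         "percent rank")]]
  )
  ic50 <- suppressWarnings(as.numeric(out$ic50_chr))
  rank <- suppressWarnings(as.numeric(out$rank_chr))
  bad <- which(is.na(ic50) | is.na(rank))
  if (length(bad)) {
    rlang::abort(paste0("unparseable affinity/rank at data row(s): ",
                        paste(bad, collapse = ", ")),
                 class = "neosurv_format_error")
  }
  out <- tibble::tibble(peptide = out$peptide, allele = out$allele,
                        ic50_nM = ic50, percent_rank = rank)
  assert_peptide9(out$peptide, "predictor output peptide")
  if (any(out$ic50_nM <= 0)) {
    rlang::abort("predictor output contains non-positive IC50 values",
                 class = "neosurv_validation_error")
  }
  dup <- dplyr::distinct(out)
  key_n <- dplyr::count(dup, .data$peptide, .data$allele)
  conflict <- key_n[key_n$n > 1, ]
  if (nrow(conflict)) {
    offending <- dplyr::semi_join(dup, conflict, by = c("peptide", "allele"))
    rlang::abort(
      paste0("conflicting duplicate predictions for (peptide, allele): ",
             paste(utils::capture.output(print(as.data.frame(offending))),
                   collapse = "\n")),
      class = "neosurv_format_error"
    )
  }
  dup
}

#' Write a cohort bundle to a directory of plain-text files
#'
#' Writes `mutations.tsv`, `proteome.fasta`, `expression.tsv`, `hla.tsv`,
#' `clinical.tsv` and `epitope_catalog.tsv`; [read_cohort()] reads the same
#' layout back.
#'
#' @param cohort A [neo_cohort()] object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(cohort$variants, file.path(dir, "mutations.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(cohort$proteome),
    file.path(dir, "proteome.fasta")
  )
  expr <- tibble::as_tibble(cohort$expression, rownames = "gene")
  readr::write_tsv(expr, file.path(dir, "expression.tsv"))
  readr::write_tsv(cohort$hla[, c("patient", "allele")],
                   file.path(dir, "hla.tsv"))
  clin <- cohort$clinical
  clin$event <- as.integer(clin$event)
  readr::write_tsv(clin, file.path(dir, "clinical.tsv"))
  readr::write_tsv(cohort$epitope_catalog,
                   file.path(dir, "epitope_catalog.tsv"))
  invisible(dir)
}

#' Read a cohort bundle written by [write_cohort()]
#'
#' @param dir Directory containing the bundle files.
#' @return A validated [neo_cohort()] object.
#' @export
read_cohort <- function(dir) {
  neo_cohort(
    variants = read_mutation_table(file.path(dir, "mutations.tsv")),
    proteome = read_proteome(file.path(dir, "proteome.fasta")),
    expression = read_expression_matrix(file.path(dir, "expression.tsv")),
    hla = read_hla_table(file.path(dir, "hla.tsv")),
    clinical = read_clinical_table(file.path(dir, "clinical.tsv")),
    epitope_catalog = read_epitope_catalog(file.path(dir,
                                                     "epitope_catalog.tsv"))
  )
}
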