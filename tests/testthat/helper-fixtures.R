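# Fixtures built in code: tiny cohorts, tables written to tempfiles, and
# brute-force oracles shared across test files.

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# A minimal hand-built cohort: 3 patients, 2 genes + markers, one protein
# long enough for interior windows.
tiny_cohort <- function() {
  proteome <- c(
    TP53 = paste0(rep("ACDEFGHIKL", 5), collapse = ""),  # 50 aa
    KRAS = "MTEYKLVVVGAGGVGKSALT",                       # 20 aa
    GZMA = paste0(rep("LMNPQRSTVW", 3), collapse = ""),
    FOXP3 = paste0(rep("ACDEFGHIKL", 3), collapse = ""),
    CD274 = paste0(rep("LMNPQRSTVW", 3), collapse = "")
  )
  variants <- tibble::tibble(
    patient = c("P1", "P1", "P2"),
    gene = c("TP53", "KRAS", "TP53"),
    protein_pos = c(25L, 10L, 1L),
    ref_aa = c("F", "G", "A"),
    alt_aa = c("Y", "D", "V")
  )
  expression <- matrix(
    5, nrow = length(proteome), ncol = 3,
    dimnames = list(names(proteome), c("P1", "P2", "P3"))
  )
  hla <- tibble::tibble(
    patient = rep(c("P1", "P2", "P3"), each = 2),
    allele = rep(c("HLA-A*02:01", "HLA-B*07:02"), 3)
  )
  clinical <- tibble::tibble(
    patient = c("P1", "P2", "P3"),
    time = c(100, 400, 900),
    event = c(TRUE, TRUE, TRUE),
    stage = c("I", "II", "III"),
    etiology = c("HBV", "HCV", "none"),
    treatment = c("RF", "CE", "N/A")
  )
  catalog <- tibble::tibble(
    sequence = c("ACDEFGHIK", "LMNPQRSTV"),
    source_class = c("self", "pathogen"),
    source_name = c("human_x", "virus_y")
  )
  neo_cohort(variants, proteome, expression, hla, clinical, catalog)
}

# A fast small simulation config for property tests (no planting).
fast_sim_config <- function(n_patients, seed, mut_rate_per_mb = 0.2,
                            n_genes = 25L,
                            planted_homologs = c(self = 0L, pathogen = 0L),
                            ...) {
  simulation_config(
    n_patients = n_patients, seed = seed,
    n_genes = n_genes, gene_length_aa = c(50L, 200L),
    mut_rate_per_mb = mut_rate_per_mb,
    planted_homologs = planted_homologs,
    n_background_epitopes = 6L, ...
  )
}

# Brute-force count of 9-mer windows of a length-L protein containing
# position p.
brute_force_window_count <- function(L, p) {
  if (L < 9) return(0L)
  sum(vapply(seq_len(L - 8L), function(s) p >= s && p <= s + 8L, logical(1)))
}

# Naive positional comparison of two 9-mers (independent of the package's
# vectorized path).
naive_pair_score <- function(a, b, mat) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  ident <- 0L; simil <- 0L; tcr <- 0L
  for (j in 1:9) {
    eq <- av[j] == bv[j]
    if (eq) ident <- ident + 1L
    if (eq || mat[av[j], bv[j]] > 0) simil <- simil + 1L
    if (eq && j %in% c(1, 4, 5, 8)) tcr <- tcr + 1L
  }
  list(identical = ident, similar = simil, tcr = tcr)
}

random_peptide_fixture <- function(n) {
  aa <- neosurv::AA_ALPHABET
  vapply(seq_len(n), function(i) {
    paste0(sample(aa, 9, replace = TRUE), collapse = "")
  }, character(1))
}

# Exponential survival data fixture.
exp_survival <- function(n, rate = 0.01, event = TRUE) {
  tibble::tibble(patient = sprintf("S%03d", seq_len(n)),
                 time = stats::rexp(n, rate),
                 event = rep_len(event, n))
}
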