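# Synthetic cohort generator.
#
# Emulates the structure of a liver-cancer cohort with exome-derived
# missense variants, a reference proteome, normalized expression, class-I
# HLA genotypes, time-to-death outcomes tied to covariates, and a local
# epitope catalog with planted homologs — everything the pipeline consumes,
# generated from one seed so runs are byte-identical.
#
# Each logical component (proteome, expression, mutations, HLA, survival,
# catalog) draws from its own seeded stream derived from the master seed,
# so adding or re-ordering components never perturbs the others' draws.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the replicated study conditions: 115 death-dated
#' patients, a mean somatic burden of 2.56 mutations/Mb over a 38 Mb exome
#' (about 97 missense variants per patient), all events observed
#' (no censoring), and a protective effect of above-mean GZMA expression of
#' -0.7 on the log hazard.
#'
#' @param n_patients Number of patients.
#' @param seed Master integer seed.
#' @param mut_rate_per_mb Target mean somatic mutation rate (mutations/Mb).
#' @param exome_mb Captured exome size in Mb.
#' @param n_genes Number of genes in the synthetic proteome/expression
#'   matrix (the marker genes GZMA, FOXP3, CD274 are always among them).
#' @param gene_length_aa Integer range (min, max) of protein lengths.
#' @param expression_logmean,expression_logsd Log-normal parameters of
#'   baseline expression for expressed ("on") genes, in arbitrary
#'   normalized units.
#' @param frac_low_expression Fraction of genes that are essentially
#'   silent (baseline drawn far below the expression filter's default
#'   threshold of 2).
#' @param hla_allele_frequencies Named list with elements `A`, `B`, `C`,
#'   each a named numeric vector of allele frequencies summing to 1.
#' @param planted_homologs Named integer vector `c(self = , pathogen = )`:
#'   how many catalog epitopes to plant so that they match a qualifying
#'   neoantigen of some patient under the default homology rules.
#' @param n_background_epitopes Number of random background catalog
#'   epitopes (half self, half pathogen).
#' @param survival_model List with `baseline_hazard` (per day) and
#'   `covariate_effects`, a named list of log hazard ratios.  Effect names
#'   of the form `"<GENE>_high"` refer to the indicator of that gene's
#'   expression lying at or above the cohort mean; other names must be
#'   `"<covariate>_<level>"` for a clinical covariate level (e.g.
#'   `"stage_III"`).
#' @param censoring_rate Probability that a patient's follow-up is censored
#'   before death.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_patients = 115L,
                              seed = 1L,
                              mut_rate_per_mb = 2.56,
                              exome_mb = 38,
                              n_genes = 400L,
                              gene_length_aa = c(100L, 1000L),
                              expression_logmean = 1.5,
                              expression_logsd = 1,
                              frac_low_expression = 0.7,
                              hla_allele_frequencies = default_hla_frequencies(),
                              planted_homologs = c(self = 3L, pathogen = 2L),
                              n_background_epitopes = 60L,
                              survival_model = list(
                                baseline_hazard = 0.001,
                                covariate_effects = list(GZMA_high = -0.7)
                              ),
                              censoring_rate = 0) {
  stopifnot(n_patients >= 1, mut_rate_per_mb > 0, exome_mb > 0,
            n_genes >= 3, length(gene_length_aa) == 2,
            gene_length_aa[1] >= 9,
            frac_low_expression >= 0, frac_low_expression <= 1,
            censoring_rate >= 0, censoring_rate <= 1,
            survival_model$baseline_hazard > 0)
  for (locus in c("A", "B", "C")) {
    fr <- hla_allele_frequencies[[locus]]
    if (is.null(fr) || abs(sum(fr) - 1) > 1e-8) {
      rlang::abort(paste0("HLA allele frequencies for locus ", locus,
                          " must sum to 1"),
                   class = "neosurv_validation_error")
    }
  }
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         mut_rate_per_mb = mut_rate_per_mb, exome_mb = exome_mb,
         n_genes = as.integer(n_genes),
         gene_length_aa = as.integer(gene_length_aa),
         expression_logmean = expression_logmean,
         expression_logsd = expression_logsd,
         frac_low_expression = frac_low_expression,
         hla_allele_frequencies = hla_allele_frequencies,
         planted_homologs = planted_homologs,
         n_background_epitopes = as.integer(n_background_epitopes),
         survival_model = survival_model,
         censoring_rate = censoring_rate),
    class = "sim_config"
  )
}

#' Illustrative class-I allele frequencies used by the generator
#'
#' Three common alleles per locus with round frequencies; no attempt at
#' population haplotype structure.
#' @return Named list with elements `A`, `B`, `C`.
#' @export
default_hla_frequencies <- function() {
  list(
    A = c("HLA-A*02:01" = 0.45, "HLA-A*01:01" = 0.30, "HLA-A*03:01" = 0.25),
    B = c("HLA-B*07:02" = 0.40, "HLA-B*08:01" = 0.35, "HLA-B*44:02" = 0.25),
    C = c("HLA-C*07:01" = 0.40, "HLA-C*07:02" = 0.35, "HLA-C*04:01" = 0.25)
  )
}

random_peptides <- function(n, len = 9L) {
  m <- matrix(sample(AA_ALPHABET, n * len, replace = TRUE), nrow = n)
  apply(m, 1, paste0, collapse = "")
}

#' Generate a complete synthetic cohort
#'
#' Draws every input of the analysis pipeline from the configuration:
#' proteome, per-patient missense variants (counts Poisson around
#' `mut_rate_per_mb * exome_mb`, positions uniform over proteins),
#' gene-by-patient expression (log-normal; the marker genes GZMA/FOXP3/
#' CD274 always expressed), two alleles per HLA locus, exponential survival
#' times with per-patient log hazard equal to the sum of configured
#' covariate effects, and an epitope catalog containing background 9-mers
#' plus planted homologs guaranteed to match a qualifying neoantigen of a
#' known patient under the default homology rules.
#'
#' The returned bundle also carries the [toy_predictor_spec()] used for
#' planting (element `predictor`), and the planted-homolog truth table as
#' attribute `"planted"` of `epitope_catalog` (columns `sequence`,
#' `source_class`, `patient`, `neoepitope`).
#'
#' @param config A [simulation_config()] object.
#' @return A validated [neo_cohort()] bundle.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed
  n <- config$n_patients
  patients <- sprintf("P%04d", seq_len(n))

  ## proteome ---------------------------------------------------------------
  # the immune panel (markers + illustrative gene sets) is always present
  # and expressed, so microenvironment profiling runs on any cohort
  panel <- unique(c(MARKER_GENES,
                    unlist(default_gene_sets(), use.names = FALSE)))
  if (config$n_genes <= length(panel)) {
    rlang::abort(paste0("n_genes must exceed the immune panel size (",
                        length(panel), ")"),
                 class = "neosurv_validation_error")
  }
  gene_names <- c(panel,
                  sprintf("GENE%04d",
                          seq_len(config$n_genes - length(panel))))
  proteome <- with_local_seed(component_seed(seed, "proteome"), {
    lens <- sample(config$gene_length_aa[1]:config$gene_length_aa[2],
                   config$n_genes, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste0(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
    }, character(1))
    stats::setNames(seqs, gene_names)
  })

  ## expression -------------------------------------------------------------
  expression <- with_local_seed(component_seed(seed, "expression"), {
    off <- stats::runif(config$n_genes) < config$frac_low_expression
    off[gene_names %in% panel] <- FALSE
    base_log <- ifelse(off, -2, config$expression_logmean)
    base_sd <- ifelse(off, 0.5, config$expression_logsd)
    gene_log <- stats::rnorm(config$n_genes, base_log, base_sd)
    noise <- matrix(stats::rnorm(config$n_genes * n, 0, 0.5),
                    nrow = config$n_genes)
    m <- exp(gene_log + noise)
    dimnames(m) <- list(gene_names, patients)
    m
  })

  ## mutations --------------------------------------------------------------
  variants <- with_local_seed(component_seed(seed, "mutations"), {
    counts <- stats::rpois(n, config$mut_rate_per_mb * config$exome_mb)
    lens <- nchar(proteome)
    gene_idx <- sample.int(config$n_genes, sum(counts), replace = TRUE,
                           prob = lens)
    gene <- gene_names[gene_idx]
    pos <- 1L + as.integer(floor(stats::runif(sum(counts)) * lens[gene_idx]))
    ref <- substr(proteome[gene], pos, pos)
    alt_shift <- sample.int(19L, sum(counts), replace = TRUE)
    alt <- AA_ALPHABET[(match(ref, AA_ALPHABET) - 1L + alt_shift) %% 20L + 1L]
    tibble::tibble(
      patient = rep(patients, counts),
      gene = gene, protein_pos = pos, ref_aa = ref, alt_aa = alt
    )
  })

  ## HLA genotypes ----------------------------------------------------------
  hla <- with_local_seed(component_seed(seed, "hla"), {
    draws <- purrr::map(c("A", "B", "C"), function(locus) {
      fr <- config$hla_allele_frequencies[[locus]]
      tibble::tibble(
        patient = rep(patients, each = 2L),
        allele = sample(names(fr), 2L * n, replace = TRUE, prob = fr)
      )
    })
    dplyr::arrange(dplyr::bind_rows(draws), .data$patient)
  })
  hla$locus <- hla_locus(hla$allele)

  ## clinical covariates + survival ------------------------------------------
  clinical <- with_local_seed(component_seed(seed, "survival"), {
    stage <- sample(c("I", "II", "III", "IV", "N/A"), n, replace = TRUE,
                    prob = c(0.33, 0.192, 0.346, 0.023, 0.108))
    etiology <- sample(c("HBV", "HCV", "none"), n, replace = TRUE,
                       prob = c(0.192, 0.361, 0.446))
    treatment <- sample(c("RF", "CE", "RE", "N/A"), n, replace = TRUE,
                        prob = c(0.046, 0.115, 0.038, 0.80))
    covars <- tibble::tibble(patient = patients, stage = stage,
                             etiology = etiology, treatment = treatment)
    lp <- numeric(n)
    effects <- config$survival_model$covariate_effects
    for (nm in names(effects)) {
      parts <- stringr::str_match(nm, "^(.*)_([^_]+)$")
      prefix <- parts[, 2]
      suffix <- parts[, 3]
      if (suffix == "high" && prefix %in% rownames(expression)) {
        ind <- expression[prefix, ] >= mean(expression[prefix, ])
      } else if (prefix %in% names(covars)) {
        ind <- covars[[prefix]] == suffix
      } else {
        rlang::abort(paste0("unrecognized covariate effect: ", nm),
                     class = "neosurv_validation_error")
      }
      lp <- lp + effects[[nm]] * as.numeric(ind)
    }
    hazard <- config$survival_model$baseline_hazard * exp(lp)
    time <- stats::rexp(n, rate = hazard)
    censored <- stats::runif(n) < config$censoring_rate
    time[censored] <- time[censored] * stats::runif(sum(censored))
    dplyr::mutate(covars, time = time, event = !censored,
                  .after = "patient")
  })

  ## epitope catalog with planted homologs -----------------------------------
  all_alleles <- sort(unique(hla$allele))
  predictor <- toy_predictor_spec(all_alleles,
                                  seed = component_seed(seed, "predictor"))
  catalog <- with_local_seed(component_seed(seed, "catalog"), {
    nb <- config$n_background_epitopes
    bg <- tibble::tibble(
      sequence = random_peptides(nb),
      source_class = rep_len(c("self", "pathogen"), nb),
      source_name = paste0("background_", seq_len(nb))
    )
    planted <- plant_homologs(config, patients, variants, expression, hla,
                              proteome, predictor)
    list(catalog = dplyr::bind_rows(
           bg, planted[, c("sequence", "source_class", "source_name")]),
         planted = planted)
  })

  epitope_catalog <- catalog$catalog
  attr(epitope_catalog, "planted") <-
    catalog$planted[, c("sequence", "source_class", "patient", "neoepitope")]

  bundle <- neo_cohort(variants = variants, proteome = proteome,
                       expression = expression, hla = hla,
                       clinical = clinical,
                       epitope_catalog = epitope_catalog)
  bundle$predictor <- predictor
  bundle
}

# Find qualifying neoantigens patient by patient and derive catalog epitopes
# that match them under the default homology rules: substitute up to two
# non-TCR-contact positions (3 and 7) with a BLOSUM62-positive partner so
# similarity stays 9/9, identity >= 7/9 and all four TCR contacts identical.
plant_homologs <- function(config, patients, variants, expression, hla,
                           proteome, predictor) {
  k_self <- config$planted_homologs[["self"]]
  k_path <- config$planted_homologs[["pathogen"]]
  k <- k_self + k_path
  empty <- tibble::tibble(sequence = character(), source_class = character(),
                          source_name = character(), patient = character(),
                          neoepitope = character())
  if (k == 0) return(empty)

  found <- list()
  for (p in patients) {
    if (length(found) >= k) break
    pv <- variants[variants$patient == p, ]
    if (!nrow(pv)) next
    pv$gene_expression <- expression[cbind(pv$gene, pv$patient)]
    pv <- filter_expressed(pv, threshold = 2)
    if (!nrow(pv)) next
    pairs <- enumerate_pairs(pv, proteome)
    if (!nrow(pairs)) next
    alleles <- unique(hla$allele[hla$patient == p])
    grid <- tidyr::expand_grid(mutant = unique(pairs$mutant),
                               allele = alleles)
    pred <- toy_predict(grid$mutant, grid$allele, predictor)
    hit <- pred[pred$percent_rank <= 2 & pred$ic50_nM < 500, ]
    hit <- hit[!hit$peptide %in%
                 vapply(found, function(f) f$neoepitope, character(1)), ]
    if (nrow(hit)) {
      found[[length(found) + 1L]] <-
        list(patient = p, neoepitope = hit$peptide[1])
    }
  }
  if (length(found) < k) {
    rlang::abort(paste0(
      "could not plant ", k, " homolog(s): only ", length(found),
      " patients carry a qualifying neoantigen under the default ",
      "thresholds; increase n_patients, mut_rate_per_mb or expression, ",
      "or reduce planted_homologs"
    ), class = "neosurv_simulation_error")
  }
  classes <- c(rep("self", k_self), rep("pathogen", k_path))
  purrr::imap_dfr(found[seq_len(k)], function(f, i) {
    tibble::tibble(
      sequence = homolog_of(f$neoepitope),
      source_class = classes[i],
      source_name = paste0("planted_", classes[i], "_", i),
      patient = f$patient,
      neoepitope = f$neoepitope
    )
  })
}

# Closest-positive BLOSUM62 partner of a residue (identity if none).
blosum_partner <- function(res) {
  m <- blosum62_matrix()
  vapply(res, function(r) {
    row <- m[r, setdiff(colnames(m), r)]
    pos <- row[row > 0]
    if (length(pos)) names(pos)[which.max(pos)] else r
  }, character(1), USE.NAMES = FALSE)
}

homolog_of <- function(peptide) {
  res <- strsplit(peptide, "", fixed = TRUE)[[1]]
  for (pos in c(3L, 7L)) {
    res[pos] <- blosum_partner(res[pos])
  }
  paste0(res, collapse = "")
}
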