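# Epitope homology scoring, catalog scanning, and sample classification.

test_that("pair scoring matches hand-derived examples", {
  m <- score_epitope_pair("ACDEFGHIK", "ACDEFGHIK")
  expect_equal(m$identity_fraction, 1)
  expect_equal(m$tcr_identical, 4L)
  expect_true(m$passes)

  # differ at every position with non-positive BLOSUM62 scores
  a <- "AAAAAAAAA"
  b <- "DDDDDDDDD"  # BLOSUM62[A, D] = -2
  m2 <- score_epitope_pair(a, b)
  expect_equal(m2$identity_fraction, 0)
  expect_equal(m2$similarity_fraction, 0)
  expect_false(m2$passes)

  # mismatches at exactly positions 2 and 9 (both non-TCR)
  a3 <- "ACDEFGHIK"
  b3 <- "AWDEFGHIW"
  m3 <- score_epitope_pair(a3, b3)
  expect_equal(m3$total_identical, 7L)
  expect_equal(m3$tcr_identical, 4L)
  expect_equal(m3$identity_fraction, 7 / 9, tolerance = 1e-12)
  expect_true(m3$passes)

  expect_error(score_epitope_pair("ACDEFGHIKL", "ACDEFGHIK"),
               class = "neosurv_length_error")
})

test_that("identity counts are symmetric and passes is threshold-monotone", {
  withr::with_seed(7, {
    for (i in 1:50) {
      a <- random_peptide_fixture(1)
      b <- random_peptide_fixture(1)
      ab <- score_epitope_pair(a, b)
      ba <- score_epitope_pair(b, a)
      expect_equal(ab$total_identical, ba$total_identical)
      expect_equal(ab$tcr_identical, ba$tcr_identical)
      expect_gte(ab$similarity_fraction, ab$identity_fraction)
      expect_lte(ab$tcr_identical, ab$total_identical)
      if (ab$passes) {
        # lowering either threshold can never turn a pass into a failure
        expect_true(score_epitope_pair(a, b, sim_threshold = 0.5)$passes)
        expect_true(score_epitope_pair(a, b, tcr_min = 0)$passes)
      }
      # identity mode is never more permissive than similarity mode
      if (score_epitope_pair(a, b, mode = "identity")$passes) {
        expect_true(ab$passes)
      }
    }
  })
})

test_that("catalog scan equals the naive double-loop oracle", {
  withr::with_seed(13, {
    neo <- tibble::tibble(patient = rep(sprintf("P%02d", 1:20), each = 10),
                          mutant = random_peptide_fixture(200))
    # plant some near-duplicates so that passes occur
    cat_seq <- c(random_peptide_fixture(180), {
      picks <- sample(neo$mutant, 20)
      vapply(picks, function(p) {
        r <- strsplit(p, "")[[1]]
        r[2] <- sample(AA_ALPHABET, 1)
        paste0(r, collapse = "")
      }, character(1))
    })
  })
  catalog <- tibble::tibble(
    sequence = cat_seq,
    source_class = rep_len(c("self", "pathogen"), length(cat_seq)),
    source_name = paste0("c", seq_along(cat_seq))
  )
  got <- scan_catalog(neo, catalog)

  mat <- blosum62_matrix()
  expected <- list()
  neo_d <- unique(neo[, c("patient", "mutant")])
  for (i in seq_len(nrow(neo_d))) {
    for (j in seq_len(nrow(catalog))) {
      sc <- naive_pair_score(neo_d$mutant[i], catalog$sequence[j], mat)
      if (sc$similar / 9 > 0.70 && sc$tcr >= 2) {
        expected[[length(expected) + 1L]] <- tibble::tibble(
          patient = neo_d$patient[i], neoepitope = neo_d$mutant[i],
          catalog_index = j, total_identical = sc$identical,
          tcr_identical = sc$tcr, similarity_fraction = sc$similar / 9
        )
      }
    }
  }
  expected <- dplyr::arrange(dplyr::bind_rows(expected),
                             patient, neoepitope,
                             dplyr::desc(similarity_fraction), catalog_index)
  expect_gt(nrow(expected), 0)
  expect_equal(nrow(got), nrow(expected))
  expect_equal(got$patient, expected$patient)
  expect_equal(got$neoepitope, expected$neoepitope)
  expect_equal(got$catalog_index, expected$catalog_index)
  expect_equal(got$total_identical, as.integer(expected$total_identical))
  expect_equal(got$tcr_identical, as.integer(expected$tcr_identical))
})

test_that("a wild-type 9-mer in the catalog is recovered as a self match", {
  # mutant differs from its wild type at one position: identity 8/9 > 0.70
  wt <- "ACDEFGHIK"
  mut <- "ACDEFGHIR"
  catalog <- tibble::tibble(sequence = wt, source_class = "self",
                            source_name = "wt_self")
  got <- scan_catalog(tibble::tibble(patient = "P1", mutant = mut), catalog)
  expect_equal(nrow(got), 1L)
  expect_equal(got$total_identical, 8L)

  empty <- scan_catalog(tibble::tibble(patient = "P1", mutant = mut),
                        catalog[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("planted homologs from the generator are recovered", {
  coh <- generate_cohort(simulation_config(
    n_patients = 15, seed = 23, n_genes = 60,
    planted_homologs = c(self = 2L, pathogen = 2L),
    n_background_epitopes = 20L
  ))
  planted <- attr(coh$epitope_catalog, "planted")
  res <- call_neoantigens(coh)
  matches <- scan_catalog(res$records, coh$epitope_catalog)
  for (i in seq_len(nrow(planted))) {
    hit <- matches[matches$catalog_sequence == planted$sequence[i] &
                     matches$patient == planted$patient[i] &
                     matches$neoepitope == planted$neoepitope[i], ]
    expect_gte(nrow(hit), 1L)
  }
})

test_that("classification partitions the cohort with priority resolution", {
  patients <- c("P1", "P2", "P3", "P4")
  matches <- tibble::tibble(
    patient = c("P1", "P2", "P2", "P3"),
    neoepitope = "ACDEFGHIK",
    source_class = c("self", "self", "pathogen", "pathogen")
  )
  cls <- classify_samples(patients, matches)
  expect_equal(as.character(cls$label), c("self", "pathogen", "pathogen",
                                          "none"))
  expect_equal(cls$dual_flag, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(sum(table(cls$label)), length(patients))

  cls_self <- classify_samples(patients, matches, priority = "self")
  expect_equal(as.character(cls_self$label[2]), "self")

  # invariant to match ordering
  cls_rev <- classify_samples(patients, matches[4:1, ])
  expect_equal(cls, cls_rev)

  # none labels have no supporting matches by construction
  expect_equal(cls$n_self[4] + cls$n_pathogen[4], 0L)
})
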