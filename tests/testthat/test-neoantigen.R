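# The prediction cascade: expression filter, window enumeration, binding
# filters, DAI, tiers, TMB, per-patient summaries.

test_that("expression filter is strictly greater-than", {
  v <- tibble::tibble(patient = "P1", gene = c("A1", "A2", "A3"),
                      gene_expression = c(2.0, 2.0000001, 50))
  kept <- filter_expressed(v, threshold = 2)
  expect_equal(kept$gene, c("A2", "A3"))
  expect_equal(nrow(filter_expressed(v[0, ], 2)), 0L)
  v$gene_expression[2] <- NA
  expect_error(filter_expressed(v), "A2",
               class = "neosurv_validation_error")
})

test_that("window enumeration matches the closed-form examples", {
  proteome <- c(G1 = paste0(rep("ACDEFGHIKL", 2), collapse = ""))  # 20 aa
  v <- tibble::tibble(patient = "P1", gene = "G1", protein_pos = 10L,
                      ref_aa = "L", alt_aa = "M")
  pairs <- enumerate_pairs(v, proteome)
  expect_equal(nrow(pairs), 9L)
  expect_equal(pairs$window_start, 2:10)
  expect_equal(pairs$mut_offset, 9:1)
  # each pair differs from wild type at exactly mut_offset
  diffs <- mapply(function(m, w, off) {
    d <- which(strsplit(m, "")[[1]] != strsplit(w, "")[[1]])
    identical(d, off)
  }, pairs$mutant, pairs$wildtype, as.integer(pairs$mut_offset))
  expect_true(all(diffs))

  v1 <- tibble::tibble(patient = "P1", gene = "G1", protein_pos = 1L,
                       ref_aa = "A", alt_aa = "V")
  p1 <- enumerate_pairs(v1, proteome)
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$mut_offset, 1L)

  prot9 <- c(G9 = "ACDEFGHIK")
  v9 <- tibble::tibble(patient = "P1", gene = "G9", protein_pos = 5L,
                       ref_aa = "F", alt_aa = "Y")
  p9 <- enumerate_pairs(v9, prot9)
  expect_equal(nrow(p9), 1L)
  expect_equal(p9$wildtype, "ACDEFGHIK")
  expect_equal(p9$mutant, "ACDEYGHIK")

  short <- c(GS = "ACDEFGH")
  vs <- tibble::tibble(patient = "P1", gene = "GS", protein_pos = 3L,
                       ref_aa = "D", alt_aa = "E")
  expect_warning(ps <- enumerate_pairs(vs, short), "shorter")
  expect_equal(nrow(ps), 0L)

  bad <- tibble::tibble(patient = "P1", gene = "G1", protein_pos = 10L,
                        ref_aa = "W", alt_aa = "M")
  expect_error(enumerate_pairs(bad, proteome), "mismatch",
               class = "neosurv_validation_error")
})

test_that("window counts equal brute force over random cases", {
  withr::with_seed(99, {
    for (i in 1:1000) {
      L <- sample(5:60, 1)
      p <- sample(seq_len(L), 1)
      prot <- paste0(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
      ref <- substr(prot, p, p)
      alt <- setdiff(AA_ALPHABET, ref)[1]
      v <- tibble::tibble(patient = "P", gene = "G", protein_pos = p,
                          ref_aa = ref, alt_aa = alt)
      n <- suppressWarnings(nrow(enumerate_pairs(v, c(G = prot))))
      expect_identical(n, as.integer(brute_force_window_count(L, p)))
    }
  })
})

test_that("candidate selection applies the boundary semantics literally", {
  pairs <- tibble::tibble(
    patient = "P1", gene = "G", protein_pos = 5L, ref_aa = "A",
    alt_aa = "V", window_start = 1L, mut_offset = 5L,
    wildtype = "AAAAAAAAA",
    mutant = c("AAAAVAAAA", "AAAAVAAAC", "AAAAVAAAD", "AAAAVAAAE")
  )
  predictions <- tibble::tibble(
    peptide = c(pairs$mutant, "AAAAAAAAA"),
    allele = "HLA-A*02:01",
    ic50_nM = c(499, 499, 500.0, 499, 5000),
    percent_rank = c(2.0, 2.01, 1.0, 1.0, 50)
  )
  hla <- tibble::tibble(patient = "P1", allele = "HLA-A*02:01")
  rec <- select_candidates(pairs, predictions, hla)
  # rank 2.0 kept (inclusive); rank 2.01 dropped; ic50 500.0 dropped (strict)
  expect_setequal(rec$mutant, c("AAAAVAAAA", "AAAAVAAAE"))
  expect_equal(unique(rec$hla_locus), "A")
  expect_equal(unique(rec$wt_ic50_nM), 5000)

  # missing wild-type prediction for a retained mutant is an error
  expect_error(
    select_candidates(pairs, predictions[predictions$peptide != "AAAAAAAAA", ],
                      hla),
    "wild-type", class = "neosurv_validation_error"
  )
})

test_that("DAI is a subtraction with the documented invariances", {
  expect_equal(compute_dai(40, 5000), 4960)
  expect_equal(compute_dai(123.4, 123.4), 0)
  expect_equal(compute_dai(460, 450), -10)
  # antisymmetry and shift invariance
  withr::with_seed(1, {
    m <- runif(50, 1, 1000); w <- runif(50, 1, 1000)
    expect_equal(compute_dai(m, w), -compute_dai(w, m))
    expect_equal(compute_dai(m + 7, w + 7), compute_dai(m, w))
  })
  expect_equal(compute_dai(10, 100, mode = "ratio"), 10)
  expect_error(compute_dai(-1, 10), class = "neosurv_validation_error")
})

test_that("tier assignment uses strict bounds and nests", {
  expect_equal(as.character(assign_tier(10.0, 20)), "CANDIDATE")
  expect_equal(as.character(assign_tier(11, 50.0)), "DAI10")
  expect_equal(as.character(assign_tier(11, 49.9)), "DAI10_HIGHAFF")
  expect_equal(as.character(assign_tier(10.0001, 500)), "DAI10")
})

test_that("TMB is mutations per megabase", {
  expect_equal(compute_tmb(97, 38), 97 / 38)
  expect_equal(compute_tmb(0, 38), 0)
  expect_error(compute_tmb(10, 0), class = "neosurv_validation_error")
  # simulation oracle: cohort mean TMB near the configured rate
  coh <- generate_cohort(simulation_config(
    n_patients = 150, seed = 12, mut_rate_per_mb = 2.56, n_genes = 40,
    planted_homologs = c(self = 0L, pathogen = 0L)
  ))
  n_mut <- table(factor(coh$variants$patient, levels = coh$patients))
  tmb <- compute_tmb(as.numeric(n_mut), 38)
  se <- sqrt(2.56 / 38 / 150)
  expect_lt(abs(mean(tmb) - 2.56), 3 * se)
})

test_that("per-patient summaries nest tiers, split loci and handle zeros", {
  coh <- generate_cohort(fast_sim_config(12, seed = 31,
                                         mut_rate_per_mb = 1.5))
  res <- call_neoantigens(coh)
  s <- res$summary
  expect_setequal(s$patient, coh$patients)
  expect_true(all(s$n_candidates >= s$n_dai10))
  expect_true(all(s$n_dai10 >= s$n_dai10_highaff))
  expect_equal(s$n_hla_A + s$n_hla_B + s$n_hla_C, s$n_candidates)
  zero <- s[s$n_candidates == 0, ]
  if (nrow(zero)) expect_true(all(zero$frac_highaff_of_dai10 == 0))
  # peptide counting never exceeds record counting
  s2 <- summarize_patients(res$records,
                           dplyr::count(coh$variants, patient,
                                        name = "n_mutations"),
                           count_mode = "peptide")
  merged <- dplyr::inner_join(s, s2, by = "patient")
  expect_true(all(merged$n_candidates.y <= merged$n_candidates.x))
})

test_that("permuting patient identities permutes summaries identically", {
  coh <- generate_cohort(fast_sim_config(8, seed = 17))
  res1 <- call_neoantigens(coh)

  perm <- rev(coh$patients)
  names(perm) <- coh$patients
  coh2 <- coh
  coh2$variants$patient <- unname(perm[coh2$variants$patient])
  colnames(coh2$expression) <- unname(perm[colnames(coh2$expression)])
  coh2$hla$patient <- unname(perm[coh2$hla$patient])
  coh2$clinical$patient <- unname(perm[coh2$clinical$patient])
  coh2$patients <- unname(perm[coh2$patients])
  res2 <- call_neoantigens(coh2)

  s1 <- res1$summary
  s2 <- res2$summary
  s2$patient <- names(perm)[match(s2$patient, perm)]
  expect_equal(dplyr::arrange(s1, patient), dplyr::arrange(s2, patient))
})
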