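# Kaplan-Meier estimation, log-rank testing, dichotomization.

test_that("product-limit estimates match hand calculation and edge cases", {
  rec <- tibble::tibble(time = c(1, 2, 3), event = TRUE)
  km <- km_fit(rec)
  expect_equal(km$curve$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$last_event_time, 3)
  expect_equal(km$median_survival, 2)

  flat <- km_fit(tibble::tibble(time = c(5, 6), event = FALSE))
  expect_true(all(flat$curve$survival == 1))
  expect_true(is.na(flat$last_event_time))

  expect_error(km_fit(tibble::tibble(time = numeric(), event = logical())),
               class = "neosurv_validation_error")
})

test_that("deaths are processed before censorings at tied times", {
  # death and censoring both at t=2: the death uses the full risk set
  rec <- tibble::tibble(time = c(1, 2, 2, 3), event = c(TRUE, TRUE, FALSE,
                                                        TRUE))
  km <- km_fit(rec)
  s <- km_survival_at(km, c(1, 2, 3))
  expect_equal(s, c(3 / 4, 3 / 4 * 2 / 3, 3 / 4 * 2 / 3 * 0))
})

test_that("uncensored curves equal one minus the empirical CDF", {
  withr::with_seed(5, {
    for (i in 1:500) {
      n <- sample(3:40, 1)
      rec <- tibble::tibble(time = round(rexp(n, 0.01), 2), event = TRUE)
      km <- km_fit(rec)
      at <- sort(unique(rec$time))
      expect_equal(km_survival_at(km, at),
                   vapply(at, function(t) mean(rec$time > t), numeric(1)))
    }
  })
})

test_that("km_fit is invariant to record order", {
  withr::with_seed(8, {
    rec <- exp_survival(30)
    rec$event[sample(30, 10)] <- FALSE
  })
  expect_equal(km_fit(rec)$curve, km_fit(rec[sample(30), ])$curve)
})

test_that("log-rank degenerates and symmetries behave", {
  a <- exp_survival(10, rate = 0.01)
  rec <- dplyr::bind_rows(a, a)
  grp <- rep(c("A", "B"), each = 10)
  lr <- logrank_test(rec, grp)
  expect_equal(lr$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)

  withr::with_seed(3, {
    b <- exp_survival(12, rate = 0.02)
  })
  rec2 <- dplyr::bind_rows(a, b)
  grp2 <- rep(c("A", "B"), c(10, 12))
  lr_ab <- logrank_test(rec2, grp2)
  lr_ba <- logrank_test(rec2, ifelse(grp2 == "A", "B", "A"))
  expect_equal(lr_ab$chi_square, lr_ba$chi_square)

  # scaling all times leaves the statistic unchanged
  rec3 <- rec2
  rec3$time <- rec3$time * 7.3
  expect_equal(logrank_test(rec3, grp2)$chi_square, lr_ab$chi_square)

  expect_warning(
    logrank_test(tibble::tibble(time = c(1, 2, 3, 4),
                                event = c(TRUE, TRUE, FALSE, FALSE)),
                 c("A", "A", "B", "B")),
    "zero observed events"
  )
  expect_error(logrank_test(a, rep("A", 10)),
               class = "neosurv_validation_error")
})

test_that("the internal Mantel-Cox statistic agrees with survdiff", {
  withr::with_seed(11, {
    for (i in 1:25) {
      n <- sample(6:30, 1)
      rec <- tibble::tibble(time = rexp(n, 0.01),
                            event = runif(n) < 0.8)
      grp <- sample(c("A", "B"), n, replace = TRUE)
      if (length(unique(grp)) < 2 || sum(rec$event) == 0) next
      ours <- neosurv:::logrank_chisq(rec$time, rec$event, grp == "B")
      ref <- survival::survdiff(survival::Surv(rec$time, rec$event) ~ grp)
      expect_equal(ours, unname(ref$chisq), tolerance = 1e-8)
    }
  })
})

test_that("log-rank p agrees with the exact permutation null on 6+6 data", {
  # fixed small two-group data set; all choose(12,6) = 924 assignments
  rec <- tibble::tibble(
    time = c(3, 5, 8, 10, 14, 20, 25, 30, 34, 41, 47, 60),
    event = TRUE
  )
  obs_in_b <- c(rep(FALSE, 6), rep(TRUE, 6))
  obs <- neosurv:::logrank_chisq(rec$time, rec$event, obs_in_b)
  lr <- logrank_test(rec, ifelse(obs_in_b, "B", "A"))
  expect_equal(lr$chi_square, obs, tolerance = 1e-8)

  combos <- utils::combn(12, 6)
  perm_stats <- apply(combos, 2, function(idx) {
    in_b <- seq_len(12) %in% idx
    neosurv:::logrank_chisq(rec$time, rec$event, in_b)
  })
  p_perm <- mean(perm_stats >= obs - 1e-12)
  expect_lt(abs(lr$p_value - p_perm), 0.035)
})

test_that("dichotomization implements both schemes with documented ties", {
  sc <- tibble::tibble(patient = paste0("P", 1:8), score = 1:8)
  q <- dichotomize(sc, mode = "quartile")
  expect_equal(sc$patient[which(q$group == "low")], paste0("P", 1:2))
  expect_equal(sc$patient[which(q$group == "high")], paste0("P", 7:8))
  expect_equal(sum(is.na(q$group)), 4L)

  sc2 <- tibble::tibble(patient = paste0("P", 1:4),
                        score = c(1, 2, 3, 100))
  m <- dichotomize(sc2, mode = "mean")
  expect_equal(as.character(m$group), c("low", "low", "low", "high"))
  expect_equal(sum(!is.na(m$group)), 4L)  # mean split covers everyone

  # a score exactly at the mean goes to the high group
  sc3 <- tibble::tibble(patient = paste0("P", 1:3), score = c(1, 2, 3))
  m3 <- dichotomize(sc3, mode = "mean")
  expect_equal(as.character(m3$group[2]), "high")

  expect_error(dichotomize(tibble::tibble(patient = "a", score = 1),
                           mode = "quartile"),
               class = "neosurv_validation_error")
  expect_error(dichotomize(tibble::tibble(patient = c("a", "b"),
                                          score = c(2, 2))),
               class = "neosurv_validation_error")
})

test_that("survival by class produces curves and pairwise tests", {
  withr::with_seed(6, {
    rec <- exp_survival(60)
    labels <- tibble::tibble(patient = rec$patient,
                             label = rep(c("none", "self", "pathogen"),
                                         each = 20))
  })
  out <- survival_by_class(rec, labels)
  expect_setequal(names(out$curves), c("none", "self", "pathogen"))
  expect_equal(nrow(out$tests), 3L)
  expect_false(any(out$tests$low_n))

  # a class with < 2 patients still yields a curve but is flagged
  labels2 <- labels
  labels2$label[labels2$label == "self"] <- "none"
  labels2$label[1] <- "self"
  out2 <- survival_by_class(rec, labels2)
  expect_true(any(out2$tests$low_n))

  expect_error(
    survival_by_class(rec, dplyr::mutate(labels, label = "none")),
    class = "neosurv_validation_error"
  )
})

test_that("the training/validation split is seeded and sized", {
  patients <- sprintf("P%03d", 1:115)
  s1 <- split_cohort(patients, 30, seed = 5)
  s2 <- split_cohort(patients, 30, seed = 5)
  expect_identical(s1, s2)
  expect_equal(sum(s1$set == "training"), 30L)
  expect_equal(sum(s1$set == "validation"), 85L)
  s3 <- split_cohort(patients, 30, seed = 6)
  expect_false(identical(s1$set, s3$set))
})

test_that("tidiers and autoplot methods return the expected shapes", {
  rec <- tibble::tibble(time = c(1, 2, 3, 4), event = c(TRUE, TRUE, FALSE,
                                                        TRUE))
  km <- km_fit(rec)
  td <- tidy(km)
  expect_true(all(c("time", "survival", "n_risk") %in% names(td)))
  gl <- glance(km)
  expect_equal(gl$n, 4L)
  expect_equal(gl$n_events, 3)
  expect_s3_class(autoplot(km), "ggplot")

  lr <- logrank_test(dplyr::bind_rows(rec, rec),
                     rep(c("A", "B"), each = 4))
  expect_equal(tidy(lr)$p_value, 1)
  expect_s3_class(plot_km_groups(list(a = km, b = km)), "ggplot")
})
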