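test_that("summary statistics match the textbook t-interval", {
  s <- summarise_values(c(1000, 1000, 1000))
  expect_equal(s$sd, 0)
  expect_equal(c(s$ci_low, s$ci_high), c(1000, 1000))
  s2 <- summarise_values(c(1000, 1100, 1200))
  expect_equal(s2$mean, 1100)
  expect_equal(s2$sd, 100)
  # frozen from qt(0.975, 2) * 100 / sqrt(3)
  expect_equal(s2$ci_low, 851.5862, tolerance = 1e-4)
  expect_equal(s2$ci_high, 1348.4138, tolerance = 1e-4)
  expect_error(summarise_values(1000), class = "t1stand_input_error")
})

test_that("cohort comparison routes on normality and requires both tests", {
  set.seed(12)
  a <- rnorm(50, 1100, 50); b <- rnorm(50, 1400, 50)
  cc <- compare_cohorts(list(healthy = a, AMY = b))
  expect_lt(cc$pairwise$p_value[1], 1e-10)
  expect_lt(cc$omnibus_p, 1e-10)
  expect_true(cc$pairwise$significant[1])

  same <- compare_cohorts(list(g1 = c(1, 2, 3, 4), g2 = c(1, 2, 3, 4)))
  expect_false(any(same$pairwise$significant))

  expect_warning(cc2 <- compare_cohorts(list(g1 = rep(5, 5), g2 = rnorm(5))),
                 "constant")
  expect_identical(cc2$route, "nonparametric")
  expect_error(compare_cohorts(list(a = 1:5)), class = "t1stand_input_error")
  expect_error(compare_cohorts(list(a = 1:2, b = 1:5)), class = "t1stand_input_error")
})

test_that("type-I error of the pairwise rule sits near the nominal level", {
  set.seed(99)
  hits <- 0L
  n_rep <- 300L
  for (i in seq_len(n_rep)) {
    g <- list(a = rnorm(20), b = rnorm(20))
    cc <- suppressWarnings(compare_cohorts(g))
    hits <- hits + any(cc$pairwise$significant)
  }
  rate <- hits / n_rep
  # 0.05 nominal; binomial 99.9% band for 300 replicates
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.10)
})

test_that("ROC analysis matches exhaustive pair counting and tie conventions", {
  perfect <- roc_analysis(c(1000, 1010), c(1300, 1310))
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_true(perfect$evidence)
  expect_equal(perfect$auc, 1)

  r <- roc_analysis(c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_equal(r$auc, 14 / 16)  # exhaustive pairs: 13 wins + 2 half-ties
  expect_equal(r$threshold, 2.5)  # J ties at 2.5/3.5/4.5 resolve to the lowest
  expect_equal(r$sensitivity + r$specificity - 100, 50)
  expect_error(roc_analysis(numeric(0), 1:3), class = "t1stand_input_error")
})

test_that("ROC is invariant under increasing transforms and label swap maps AUC", {
  set.seed(8)
  neg <- rnorm(40, 1100, 60); pos <- rnorm(30, 1250, 80)
  r <- roc_analysis(neg, pos)
  r2 <- roc_analysis(exp(neg / 400), exp(pos / 400))
  expect_equal(r2$auc, r$auc)
  expect_equal(r2$sensitivity, r$sensitivity)
  expect_equal(r2$specificity, r$specificity)
  swapped <- roc_analysis(pos, neg)
  expect_equal(swapped$auc, 1 - r$auc)
  # independent implementation agrees on the AUC
  pr <- suppressMessages(pROC::roc(response = c(rep(0, 40), rep(1, 30)),
                                   predictor = c(neg, pos), quiet = TRUE))
  expect_equal(r$auc, as.numeric(pROC::auc(pr)))
})

test_that("intra-subject progression computes per-subject COV pairs", {
  tab <- tibble::tibble(
    subject_id = c("s1", "s1", "s2", "s2", "s3"),
    map_id = paste0("m", 1:5),
    mean_before = c(1000, 1100, 1200, 1200, 1000),
    mean_after = c(1050, 1050, 1190, 1210, 990)
  )
  out <- intra_subject_progression(tab)
  expect_equal(nrow(out), 2)
  expect_equal(out$cov_before[out$subject_id == "s1"], sd(c(1000, 1100)) / 1050)
  expect_equal(out$cov_after[out$subject_id == "s1"], 0)
  expect_identical(attr(out, "excluded"), "s3")
})

test_that("repeat acquisitions concentrate after standardisation of clean data", {
  envs <- list(list(), list(scanner = "1.5T-ALT"))
  coh <- generate_cohort(6, design = "paired", environments = envs,
                         effects = additive_effects(), base_sd = 0, pixel_noise_sd = 0,
                         image_size = 16, r_outer = 4.5, r_inner = 2.5, seed = 61)
  m <- fit_pipeline(coh$records, pipeline_setting("linear", "absolute", "cascaded"))
  prog <- intra_subject_progression(standardise(m, coh$records))
  expect_true(all(prog$cov_before > 0))
  expect_true(all(prog$cov_after <= 1e-6))
})
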