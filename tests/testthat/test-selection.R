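small <- list(image_size = 16, r_outer = 4.5, r_inner = 2.5)

test_that("coefficient of variation matches sigma over mu", {
  expect_equal(coef_variation(c(1100, 1100, 1100)), 0)
  expect_equal(coef_variation(c(1000, 1100, 1200)), 100 / 1100)
  # scale invariance
  expect_equal(coef_variation(c(2000, 2200, 2400)), coef_variation(c(1000, 1100, 1200)))
  expect_error(coef_variation(numeric(0)), class = "t1stand_computation_error")
  expect_error(coef_variation(c(-1, 1)), class = "t1stand_computation_error")
})

test_that("pipeline evaluation is the COV of per-map standardised means", {
  recs <- list(uniform_map("a", 1000), uniform_map("b", 1100))
  m <- fit_pipeline(recs, pipeline_setting("linear", "absolute", "cascaded"),
                    t1stand:::validate_cp_set(list(cp_def("sex", "0010,0040", "categorical", "male"))))
  # zero-bias model: evaluation reduces to the COV of the raw means
  expect_equal(evaluate_pipeline(m, recs), stats::sd(c(1000, 1100)) / 1050)
  expect_error(evaluate_pipeline(m, list()), class = "t1stand_input_error")
})

test_that("the default grid enumerates 24 + 216 = 240 settings", {
  s1 <- grid_stage1_plan()
  expect_equal(nrow(s1), 24L)
  # enumeration order: regression type, then y type, then mode
  expect_equal(s1$regression_type[1:6], rep("linear", 6))
  expect_equal(s1$y_type[1:3], rep("absolute", 3))
  expect_equal(s1$mode[1:3], c("individual", "cascaded", "ensemble"))
  expect_true(all(s1$n_bins == 1L))
  s2 <- grid_stage2_plan(s1[1:3, ])
  expect_equal(nrow(s2), 216L)
  expect_equal(nrow(s1) + nrow(s2), 240L)
  expect_equal(sort(unique(s2$n_bins)), 2:10)
  expect_setequal(unique(s2$cluster_type), cluster_types())
})

test_that("a restricted grid search ranks by COV, beats baseline and reproduces", {
  train <- do.call(generate_cohort, c(list(15, design = "oat", seed = 31), small))
  test <- do.call(generate_cohort, c(list(10, design = "random", seed = 32), small))
  run <- function() grid_search(train$records, test$records, seed = 6,
                                regression_types = c("linear", "lsvr"),
                                modes = c("cascaded", "ensemble"),
                                bins = 2:3, clusters = c("equal_distant", "equal_size"),
                                top_n = 2)
  rep1 <- run()
  expect_equal(nrow(rep1$stage1), 2 * 2 * 2)
  expect_equal(nrow(rep1$stage2), 2 * 2 * 2)
  tab <- tidy(rep1)
  ok <- tab$cov[tab$status == "ok"]
  expect_equal(rep1$bpsp$cov, min(ok))
  expect_true(all(ok >= rep1$bpsp$cov))
  # injected CP biases are removed: the winner improves on the baseline
  expect_lt(rep1$bpsp$cov, rep1$baseline_cov)
  expect_identical(tab$worsened, !is.na(tab$cov) & tab$cov > rep1$baseline_cov)
  # deterministic under the same seed
  rep2 <- run()
  expect_identical(tidy(rep1), tidy(rep2))
  expect_identical(rep1$baseline_cov, rep2$baseline_cov)
})

test_that("grid reports serialise to CSV and a JSON summary naming the BPSP", {
  train <- do.call(generate_cohort, c(list(10, design = "oat", seed = 51), small))
  test <- do.call(generate_cohort, c(list(6, design = "random", seed = 52), small))
  rep <- grid_search(train$records, test$records, seed = 2,
                     regression_types = "linear", modes = "cascaded",
                     bins = 2, clusters = "equal_distant", top_n = 1)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_grid_report(rep, csv, js)
  tab <- utils::read.csv(csv)
  expect_equal(nrow(tab), nrow(tidy(rep)))
  summ <- jsonlite::read_json(js)
  expect_equal(summ$n_settings, nrow(tab))
  expect_equal(summ$bpsp$cov, rep$bpsp$cov, tolerance = 1e-12)
})
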