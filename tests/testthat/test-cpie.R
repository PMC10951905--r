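small <- list(image_size = 16, r_outer = 4.5, r_inner = 2.5)

test_that("per-bin targets are pooled means of reference-matching pixels", {
  recs <- list(uniform_map("a", 1100), uniform_map("b", 1200),
               uniform_map("c", 1400, scanner = "1.5T-ALT"))
  part <- fit_partition(unlist(lapply(recs, segmented_values)), 1, "equal_distant")
  expect_equal(compute_targets(recs, default_cps(), part), 1150)
  expect_equal(compute_targets(recs[1], default_cps(), part), 1100)
  only_alt <- list(uniform_map("d", 1000, scanner = "1.5T-ALT"))
  expect_error(compute_targets(only_alt, default_cps(), part),
               class = "t1stand_config_error")
})

test_that("noise-free additive biases are recovered exactly in every mode", {
  eff <- additive_effects()
  coh <- do.call(generate_cohort,
                 c(list(20, base_sd = 0, pixel_noise_sd = 0, design = "oat",
                        effects = eff, seed = 42), small))
  inj <- c(female = 25, `1.5T-ALT` = -150, SASHA = 35)
  cpn <- c(female = "sex", `1.5T-ALT` = "scanner", SASHA = "sequence")
  for (mode in c("individual", "cascaded", "ensemble")) {
    m <- fit_pipeline(coh$records, pipeline_setting("linear", "absolute", mode, seed = 1))
    res <- standardise(m, coh$records)
    # all maps collapse onto the reference environment value
    ma <- vapply(res, `[[`, numeric(1), "mean_after")
    expect_lt(diff(range(ma)), 1e-6)
    # estimated offsets equal injected ones and the brute-force group-mean oracle
    for (cat in names(inj)) {
      rec_idx <- which(vapply(coh$records, function(r)
        identical(as.character(r$cp_values[[cpn[[cat]]]]), cat), logical(1)))[1]
      r <- res[[rec_idx]]
      est <- sum(vapply(r$bias_components, mean, numeric(1)))
      expect_equal(est, unname(inj[cat]), tolerance = 1e-6)
      expect_equal(est, oracle_offset(coh$records, cpn[[cat]], cat), tolerance = 1e-6)
    }
  }
})

test_that("relative pipelines invert multiplicative biases on clean data", {
  eff <- effect_spec(tibble::tibble(cp = "scanner", category = "1.5T-ALT",
                                    kind = "multiplicative", amount = 1.10))
  coh <- do.call(generate_cohort,
                 c(list(12, base_sd = 0, pixel_noise_sd = 0, design = "oat",
                        effects = eff, seed = 7), small))
  for (mode in c("individual", "cascaded", "ensemble")) {
    m <- fit_pipeline(coh$records, pipeline_setting("lsvr", "relative", mode, seed = 1))
    ma <- vapply(standardise(m, coh$records), `[[`, numeric(1), "mean_after")
    expect_lt(max(abs(ma - 1150)), 1)
  }
})

test_that("maps already in the reference environment receive zero bias", {
  eff <- additive_effects()
  coh <- do.call(generate_cohort,
                 c(list(10, base_sd = 0, pixel_noise_sd = 0, design = "oat",
                        effects = eff, seed = 3), small))
  m <- fit_pipeline(coh$records, pipeline_setting("linear", "absolute", "individual", seed = 1))
  ref_rec <- coh$records[[which(coh$truth$bias_total == 0 & coh$truth$cp_age == "18")[1]]]
  r <- standardise_map(m, ref_rec)
  for (comp in r$bias_components) expect_lt(max(abs(comp)), 1e-6)
  expect_equal(r$values_standardised, r$values_original, tolerance = 1e-9)
})

test_that("uncovered categories act like no bias; ensemble refuses them", {
  coh <- do.call(generate_cohort,
                 c(list(10, base_sd = 0, pixel_noise_sd = 0, design = "oat", seed = 3), small))
  unk <- coh$records[[1]]
  unk$cp_values$sequence <- "SASHA-GRE"
  mc <- fit_pipeline(coh$records, pipeline_setting("linear", "absolute", "cascaded", seed = 1))
  r <- standardise_map(mc, unk)
  expect_identical(unname(r$bias_components$sequence), rep(0, length(r$values_original)))
  expect_match(r$notes, "not covered", all = FALSE)
  me <- fit_pipeline(coh$records, pipeline_setting("linear", "absolute", "ensemble", seed = 1))
  expect_error(standardise_map(me, unk), class = "t1stand_application_error")
})

test_that("with a single CP, cascaded and individual fits are identical", {
  cps <- t1stand:::validate_cp_set(list(cp_def("scanner", "0008,1090", "categorical", "3.0T-REF")))
  recs <- c(
    lapply(1:4, function(i) uniform_map(paste0("r", i), 1100 + i)),
    lapply(1:4, function(i) uniform_map(paste0("s", i), 1240 + i, scanner = "1.5T-ALT"))
  )
  for (r in seq_along(recs)) recs[[r]]$cp_values <- list(scanner = recs[[r]]$cp_values$scanner)
  mi <- fit_pipeline(recs, pipeline_setting("linear", "absolute", "individual", seed = 5), cps)
  mc <- fit_pipeline(recs, pipeline_setting("linear", "absolute", "cascaded", seed = 5), cps)
  expect_identical(mi$submodels, mc$submodels)
  expect_identical(mi$per_bin_targets, mc$per_bin_targets)
  expect_identical(standardise(mi, recs), standardise(mc, recs))
})

test_that("absolute one-bin pipelines shift all pixels of a map equally; relative scales", {
  coh <- do.call(generate_cohort,
                 c(list(10, design = "oat", pixel_noise_sd = 25, seed = 17), small))
  ma <- fit_pipeline(coh$records, pipeline_setting("linear", "absolute", "cascaded", seed = 1))
  for (r in standardise(ma, coh$records)) {
    shift <- r$values_original - r$values_standardised
    expect_lt(diff(range(shift)), 1e-9)
  }
  mr <- fit_pipeline(coh$records, pipeline_setting("linear", "relative", "ensemble", seed = 1))
  for (r in standardise(mr, coh$records)) {
    frac <- (r$values_original - r$values_standardised) / r$values_original
    bins <- assign_bin(mr$partition, r$values_original)
    for (b in unique(bins)) expect_lt(diff(range(frac[bins == b])), 1e-9)
  }
})

test_that("tree-ensemble pipelines are deterministic under a fixed seed", {
  coh <- do.call(generate_cohort,
                 c(list(8, design = "oat", pixel_noise_sd = 30, seed = 23), small))
  s <- pipeline_setting("etr", "absolute", "ensemble", n_bins = 2,
                        cluster_type = "k_means", seed = 77)
  r1 <- standardise(fit_pipeline(coh$records, s), coh$records)
  r2 <- standardise(fit_pipeline(coh$records, s), coh$records)
  expect_identical(r1, r2)
})

test_that("cp_order must be a permutation and empty masks are rejected", {
  coh <- do.call(generate_cohort, c(list(6, design = "oat", seed = 4), small))
  s <- pipeline_setting("linear", "absolute", "cascaded", cp_order = c("age", "sex"))
  expect_error(fit_pipeline(coh$records, s), class = "t1stand_config_error")
  m <- fit_pipeline(coh$records, pipeline_setting("linear", "absolute", "cascaded"))
  bad <- coh$records[[1]]; bad$mask <- NULL
  expect_error(standardise_map(m, bad), class = "t1stand_input_error")
})
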