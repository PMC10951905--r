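test_that("ring phantom mask matches brute-force lattice enumeration", {
  ring <- render_ring_phantom(128, 40, 25, 1100)
  # independent oracle: explicit double loop over lattice points
  ctr <- (128 + 1) / 2
  count <- 0L
  for (i in 1:128) for (j in 1:128) {
    d2 <- (i - ctr)^2 + (j - ctr)^2
    if (d2 > 25^2 && d2 <= 40^2) count <- count + 1L
  }
  expect_equal(sum(ring$mask), count)
  expect_true(all(ring$pixels[ring$mask == 1] == 1100))
  expect_true(all(ring$pixels[ring$mask == 0] == 0))
  expect_error(render_ring_phantom(128, 30, 30, 1100), class = "t1stand_input_error")
  expect_error(render_ring_phantom(32, 20, 5, 1100), class = "t1stand_input_error")
})

test_that("zero effects and zero noise give maps equal to the subject base", {
  eff <- effect_spec(tibble::tibble(cp = "age", category = NA_character_,
                                    kind = "slope", amount = 0))
  coh <- generate_cohort(5, effects = eff, base_sd = 30, pixel_noise_sd = 0,
                         design = "random", seed = 19,
                         image_size = 16, r_outer = 4.5, r_inner = 2.5)
  for (i in seq_along(coh$records)) {
    v <- segmented_values(coh$records[[i]])
    expect_equal(unname(diff(range(v))), 0)
    expect_equal(mean(v), coh$truth$base_t1[i])
    expect_equal(coh$truth$bias_total[i], 0)
  }
})

test_that("cohort generation is reproducible and truth accounts for all bias", {
  coh1 <- generate_cohort(8, design = "random", seed = 37, cohort = "AMY",
                          image_size = 16, r_outer = 4.5, r_inner = 2.5)
  coh2 <- generate_cohort(8, design = "random", seed = 37, cohort = "AMY",
                          image_size = 16, r_outer = 4.5, r_inner = 2.5)
  expect_identical(coh1, coh2)
  tr <- coh1$truth
  expect_equal(tr$clean_value, tr$base_t1 + tr$bias_total + tr$disease_offset)
  expect_true(all(tr$disease_offset == 200))
  # generated records satisfy the record invariants
  for (r in coh1$records) {
    expect_gt(sum(r$mask), 0)
    v <- segmented_values(r)
    expect_true(all(is.finite(v) & v > 0))
  }
})

test_that("paired subjects isolate an injected scanner offset exactly", {
  eff <- additive_effects(sex = 0, scanner = 100, sequence = 0, age_slope = 0)
  coh <- generate_cohort(6, design = "paired",
                         environments = list(list(), list(scanner = "1.5T-ALT")),
                         effects = eff, pixel_noise_sd = 0, seed = 5,
                         image_size = 16, r_outer = 4.5, r_inner = 2.5)
  means <- vapply(coh$records, function(r) mean(segmented_values(r)), numeric(1))
  sc <- vapply(coh$records, function(r) as.character(r$cp_values$scanner), character(1))
  per_subject <- split(data.frame(means, sc),
                       vapply(coh$records, `[[`, character(1), "subject_id"))
  for (d in per_subject) {
    expect_equal(d$means[d$sc == "1.5T-ALT"] - d$means[d$sc == "3.0T-REF"], 100)
  }
})

test_that("disease offsets shift cohort means by the configured amount", {
  base <- list(pixel_noise_sd = 0, base_sd = 0, design = "oat", seed = 71,
               image_size = 16, r_outer = 4.5, r_inner = 2.5,
               effects = additive_effects(sex = 0, scanner = 0, sequence = 0))
  healthy <- do.call(generate_cohort, c(list(6, cohort = "healthy"), base))
  amy <- do.call(generate_cohort, c(list(6, cohort = "AMY"), base))
  mh <- mean(vapply(healthy$records, function(r) mean(segmented_values(r)), numeric(1)))
  ma <- mean(vapply(amy$records, function(r) mean(segmented_values(r)), numeric(1)))
  expect_equal(ma - mh, 200)
})

test_that("misconfigured effect specs are rejected", {
  expect_error(effect_spec(tibble::tibble(cp = "x", category = "y",
                                          kind = "multiplicative", amount = -1)),
               class = "t1stand_config_error")
  bad <- effect_spec(tibble::tibble(cp = "voltage", category = "b",
                                    kind = "additive", amount = 5))
  expect_error(generate_cohort(3, effects = bad, seed = 1),
               class = "t1stand_config_error")
  expect_error(generate_cohort(3, cohort = "unknown", seed = 1),
               class = "t1stand_config_error")
})
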