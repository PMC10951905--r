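# fixtures built in code: tiny cohorts and hand-made records

# a uniform-valued ring map with an explicit CP environment
uniform_map <- function(map_id, value, subject_id = map_id, cohort = "healthy",
                        age = 18, sex = "male", scanner = "3.0T-REF",
                        sequence = "MOLLI533b", image_size = 16,
                        r_outer = 4.5, r_inner = 2.5) {
  ring <- render_ring_phantom(image_size, r_outer, r_inner, value)
  t1_map(map_id, subject_id, cohort, ring$pixels, ring$mask,
         cp_values = list(age = age, sex = sex, scanner = scanner, sequence = sequence))
}

# additive-only effect spec used by the oracle tests: every injected bias is
# an exact per-category constant
additive_effects <- function(sex = 25, scanner = -150, sequence = 35, age_slope = 0) {
  rows <- tibble::tibble(
    cp = c("age", "sex", "scanner", "sequence"),
    category = c(NA, "female", "1.5T-ALT", "SASHA"),
    kind = c("slope", "additive", "additive", "additive"),
    amount = c(age_slope, sex, scanner, sequence)
  )
  effect_spec(rows[rows$amount != 0 | rows$cp == "age", ])
}

# brute-force category-offset oracle: group mean minus reference-group mean
# over segmented pixels, computed directly from the records
oracle_offset <- function(records, cp_name, category) {
  vals <- lapply(records, segmented_values)
  labs <- vapply(records, function(r) as.character(r$cp_values[[cp_name]]), character(1))
  at_ref <- vapply(records, function(r) {
    all(vapply(names(r$cp_values), function(nm) {
      if (nm == cp_name) TRUE else identical(as.character(r$cp_values[[nm]]),
                                             as.character(default_cps()[[nm]]$reference_value))
    }, logical(1)))
  }, logical(1))
  ref_lab <- as.character(default_cps()[[cp_name]]$reference_value)
  mean(unlist(vals[at_ref & labs == category])) - mean(unlist(vals[at_ref & labs == ref_lab]))
}
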