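#' Specify injected confounder effects for synthetic cohorts
#'
#' Each effect row injects a known bias: `kind = "slope"` adds
#' `amount * (value - reference)` ms for a numerical CP (ms/year for age),
#' `"additive"` adds `amount` ms for one category, `"multiplicative"`
#' multiplies by `amount` (a positive factor) for one category. Reference
#' categories carry zero effect by construction. `disease_offsets` adds a
#' per-cohort ms shift that is not tied to any CP (so it must survive
#' standardisation).
#'
#' @param effects Tibble/data frame with columns `cp`, `category` (NA for
#'   slope effects), `kind`, `amount`.
#' @param disease_offsets Named numeric vector, cohort label -> ms.
#' @return An `effect_spec`.
#' @export
effect_spec <- function(effects, disease_offsets = c(healthy = 0, HCM = 50, AMY = 200)) {
  effects <- tibble::as_tibble(effects)
  need <- c("cp", "category", "kind", "amount")
  if (!all(need %in% names(effects))) {
    abort_config("effects needs columns cp, category, kind, amount")
  }
  if (!all(effects$kind %in% c("slope", "additive", "multiplicative"))) {
    abort_config("effect kind must be slope, additive or multiplicative")
  }
  if (any(effects$kind == "multiplicative" & effects$amount <= 0)) {
    abort_config("multiplicative effect factors must be > 0")
  }
  structure(list(effects = effects, disease_offsets = disease_offsets),
            class = "effect_spec")
}

#' Default injected effects
#'
#' Magnitudes chosen to mimic the bias structure reported for clinical T1
#' mapping: a mild age slope, a moderate sex offset, a strong field-strength
#' (scanner) effect expressed multiplicatively, a sequence-scheme offset,
#' and disease offsets of roughly +50 ms (HCM) and +200 ms (AMY) over
#' healthy myocardium.
#'
#' @return An [effect_spec()].
#' @export
default_effects <- function() {
  effect_spec(tibble::tibble(
    cp = c("age", "sex", "scanner", "sequence"),
    category = c(NA, "female", "1.5T-ALT", "SASHA"),
    kind = c("slope", "additive", "multiplicative", "additive"),
    amount = c(0.5, 25, 0.87, 35)
  ))
}

#' Render a ring phantom (annular myocardium stand-in)
#'
#' The mid-ventricular myocardium on a short-axis slice is an annulus; the
#' synthetic cohorts use a rendered ring as the segmented region. A pixel at
#' grid position (i, j) belongs to the mask when its centre distance d from
#' the image centre satisfies `r_inner < d <= r_outer`.
#'
#' @param image_size Side length in pixels (square image).
#' @param r_outer,r_inner Outer/inner radii in pixels,
#'   `0 < r_inner < r_outer < image_size / 2`.
#' @param value T1 value (ms) assigned inside the annulus; background is 0.
#' @return List with `pixels` and binary `mask` matrices.
#' @export
render_ring_phantom <- function(image_size, r_outer, r_inner, value) {
  if (!(r_inner > 0 && r_inner < r_outer && r_outer < image_size / 2)) {
    abort_input("radii must satisfy 0 < r_inner < r_outer < image_size/2")
  }
  ctr <- (image_size + 1) / 2
  d2 <- outer((seq_len(image_size) - ctr)^2, (seq_len(image_size) - ctr)^2, `+`)
  mask <- (d2 > r_inner^2 & d2 <= r_outer^2) * 1L
  list(pixels = mask * value, mask = mask)
}

cp_categories <- function(cp, effects) {
  cats <- effects$effects$category[effects$effects$cp == cp$name &
                                     effects$effects$kind != "slope"]
  unique(c(as.character(cp$reference_value), cats[!is.na(cats)]))
}

# compose the clean (noise-free) map value and per-CP bias attribution:
# slope effects first, then multiplicative, then additive (in CP order),
# then the disease offset
compose_value <- function(base, cp_values, cps, effects, disease) {
  ef <- effects$effects
  bias <- stats::setNames(numeric(length(cps)), names(cps))
  v <- base
  for (nm in names(cps)) {
    row <- ef[ef$cp == nm & ef$kind == "slope", ]
    if (nrow(row)) {
      inc <- row$amount[1] * (as.numeric(cp_values[[nm]]) - as.numeric(cps[[nm]]$reference_value))
      v <- v + inc; bias[nm] <- bias[nm] + inc
    }
  }
  for (nm in names(cps)) {
    row <- ef[ef$cp == nm & ef$kind == "multiplicative" &
                !is.na(ef$category) & ef$category == as.character(cp_values[[nm]]), ]
    if (nrow(row)) {
      inc <- v * (row$amount[1] - 1)
      v <- v + inc; bias[nm] <- bias[nm] + inc
    }
  }
  for (nm in names(cps)) {
    row <- ef[ef$cp == nm & ef$kind == "additive" &
                !is.na(ef$category) & ef$category == as.character(cp_values[[nm]]), ]
    if (nrow(row)) {
      v <- v + row$amount[1]; bias[nm] <- bias[nm] + row$amount[1]
    }
  }
  list(value = v + disease, bias = bias)
}

#' Generate a synthetic T1-map cohort with known injected biases
#'
#' Emulates a study cohort without any clinical data: per subject a base T1
#' is drawn, a CP environment is assigned, the configured CP effects and the
#' cohort's disease offset are applied, and per-pixel Gaussian noise is
#' added inside a rendered ring mask. The exact injected bias per map and CP
#' is returned alongside, so estimated biases can be checked against ground
#' truth.
#'
#' Designs: `"random"` draws every CP uniformly (age uniform over
#' `age_range`); `"oat"` (one-at-a-time) cycles subjects through "all CPs at
#' reference" and "exactly one CP varied", guaranteeing the reference
#' environment and every single-CP stratum are populated (what the
#' individual fitting mode needs); `"paired"` gives every subject one map in
#' each environment of `environments` (named lists of CP values; omitted
#' CPs sit at reference), so scanner/sequence comparisons are within
#' subject.
#'
#' @param n_subjects Number of subjects.
#' @param cohort Cohort label; must appear in the effect spec's
#'   `disease_offsets`.
#' @param cps CP definitions.
#' @param effects An [effect_spec()].
#' @param base_mean,base_sd Subject base T1 distribution (ms); defaults 1150
#'   and 40.
#' @param pixel_noise_sd Per-pixel Gaussian noise (ms); default 30.
#' @param maps_per_subject Repeat acquisitions per subject (same
#'   environment, fresh noise); ignored for the paired design.
#' @param design `"random"`, `"oat"` or `"paired"`.
#' @param environments List of named lists for the paired design.
#' @param age_range Two-element numeric range for drawn ages (years).
#' @param image_size,r_outer,r_inner Ring-phantom geometry.
#' @param seed Integer seed; identical seeds reproduce the cohort exactly.
#' @return List with `records` (list of [t1_map]) and `truth` (tibble with
#'   per-map CP values, base T1, per-CP injected bias, total bias and the
#'   clean map value).
#' @export
generate_cohort <- function(n_subjects, cohort = "healthy", cps = default_cps(),
                            effects = default_effects(), base_mean = 1150, base_sd = 40,
                            pixel_noise_sd = 30, maps_per_subject = 1L,
                            design = c("random", "oat", "paired"), environments = NULL,
                            age_range = c(18, 80), image_size = 32L, r_outer = 10,
                            r_inner = 6, seed = 1L) {
  design <- match.arg(design)
  cps <- validate_cp_set(cps)
  stopifnot(inherits(effects, "effect_spec"))
  bad <- setdiff(unique(effects$effects$cp), names(cps))
  if (length(bad)) abort_config(paste0("effects reference unknown CPs: ", paste(bad, collapse = ", ")))
  if (!cohort %in% names(effects$disease_offsets)) {
    abort_config(paste0("cohort '", cohort, "' has no disease offset in the effect spec"))
  }
  if (design == "paired" && (is.null(environments) || length(environments) == 0)) {
    abort_config("paired design needs a nonempty list of environments")
  }
  disease <- effects$disease_offsets[[cohort]]

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  draw_env <- function(slot) {
    env <- lapply(cps, function(cp) {
      if (cp$representation == "numerical") as.numeric(cp$reference_value)
      else as.character(cp$reference_value)
    })
    if (identical(slot, "random")) {
      for (nm in names(cps)) {
        cp <- cps[[nm]]
        if (cp$representation == "numerical") {
          env[[nm]] <- sample(seq(age_range[1], age_range[2]), 1)
        } else {
          env[[nm]] <- sample(cp_categories(cp, effects), 1)
        }
      }
    } else if (!identical(slot, "ref")) {
      cp <- cps[[slot]]
      if (cp$representation == "numerical") {
        lo <- age_range[1]; hi <- age_range[2]
        cand <- setdiff(seq(lo, hi), as.numeric(cp$reference_value))
        env[[slot]] <- sample(cand, 1)
      } else {
        nonref <- setdiff(cp_categories(cp, effects), as.character(cp$reference_value))
        if (length(nonref) == 0) abort_config(paste0("CP '", slot, "' has no non-reference category"))
        env[[slot]] <- if (length(nonref) == 1) nonref else sample(nonref, 1)
      }
    }
    env
  }

  # one-at-a-time slots: only CPs that can actually vary get a slot
  variable_cp <- names(cps)[vapply(names(cps), function(nm) {
    cp <- cps[[nm]]
    cp$representation == "numerical" || length(cp_categories(cp, effects)) > 1L
  }, logical(1))]
  oat_slots <- c("ref", variable_cp)
  records <- list()
  truth_rows <- list()
  for (si in seq_len(n_subjects)) {
    subject_id <- sprintf("S%03d", si)
    base <- stats::rnorm(1, base_mean, base_sd)
    envs <- if (design == "paired") {
      lapply(environments, function(e) {
        env <- draw_env("ref")
        for (nm in names(e)) {
          if (!nm %in% names(cps)) abort_config(paste0("environment references unknown CP '", nm, "'"))
          env[[nm]] <- e[[nm]]
        }
        env
      })
    } else {
      slot <- if (design == "random") "random" else oat_slots[(si - 1L) %% length(oat_slots) + 1L]
      rep(list(draw_env(slot)), maps_per_subject)
    }
    for (mi in seq_along(envs)) {
      env <- envs[[mi]]
      comp <- compose_value(base, env, cps, effects, disease)
      map_id <- sprintf("%s_M%02d", subject_id, mi)
      ring <- render_ring_phantom(image_size, r_outer, r_inner, comp$value)
      pix <- ring$pixels
      if (pixel_noise_sd > 0) {
        idx <- ring$mask != 0
        pix[idx] <- pix[idx] + stats::rnorm(sum(idx), 0, pixel_noise_sd)
      }
      source_meta <- list()
      for (nm in names(cps)) {
        cp <- cps[[nm]]
        source_meta[[cp$source]] <- if (nm == "age") {
          sprintf("%03dY", as.integer(round(as.numeric(env[[nm]]))))
        } else {
          as.character(env[[nm]])
        }
      }
      records[[map_id]] <- t1_map(map_id, subject_id, cohort, pix, ring$mask,
                                  cp_values = env, source_meta = source_meta)
      row <- tibble::tibble(map_id = map_id, subject_id = subject_id, cohort = cohort,
                            base_t1 = base, disease_offset = disease,
                            clean_value = comp$value, bias_total = sum(comp$bias))
      for (nm in names(cps)) {
        row[[paste0("cp_", nm)]] <- as.character(env[[nm]])
        row[[paste0("bias_", nm)]] <- comp$bias[[nm]]
      }
      truth_rows[[map_id]] <- row
    }
  }
  list(records = records, truth = dplyr::bind_rows(truth_rows))
}

#' Write a synthetic cohort to disk as DICOM + PNG fixtures
#'
#' Emits `<map_id>.dcm`, `<map_id>_mask.png`, a `labels.csv`
#' (map/subject/cohort) and, when ground truth is supplied, a `truth.csv`,
#' so the full DICOM input path can be exercised end to end.
#'
#' @param records List of [t1_map] records (e.g. from [generate_cohort()]).
#' @param dir Output directory (created if needed).
#' @param truth Optional ground-truth tibble to write as `truth.csv`.
#' @param slope Rescale slope used when storing pixel values.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(records, dir, truth = NULL, slope = 0.1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- purrr::map_dfr(records, function(r) {
    tibble::tibble(map_id = r$map_id, subject_id = r$subject_id, cohort = r$cohort)
  })
  for (r in records) {
    sex_raw <- toupper(substr(as.character(r$cp_values$sex %||% "M"), 1, 1))
    age_raw <- sprintf("%03dY", as.integer(round(as.numeric(r$cp_values$age %||% 18))))
    pix <- pmax(r$pixels, 0)
    write_t1_dicom(file.path(dir, paste0(r$map_id, ".dcm")), pix,
                   patient_id = r$subject_id, patient_age = age_raw, patient_sex = sex_raw,
                   scanner = as.character(r$cp_values$scanner %||% "unknown"),
                   series_description = paste0("T1 Map ", as.character(r$cp_values$sequence %||% "unknown")),
                   slope = slope)
    png::writePNG(r$mask * 1.0, file.path(dir, paste0(r$map_id, "_mask.png")))
  }
  utils::write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  if (!is.null(truth)) utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
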