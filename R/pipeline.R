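## Experiment drivers replicating the simulation studies: the good-vs-bad
## decoding effect for block and event-related designs, the no-signal null
## control, and the image-statistics variance comparison.

simulate_condition_runs <- function(design, config, condition, n_runs = 6L) {
  lapply(seq_len(n_runs), function(r) {
    if (inherits(design, "block_design")) {
      simulate_block_run(design, config, condition = condition,
                        run_id = sprintf("%s_run%d", condition, r))
    } else {
      simulate_event_run(design, config, condition = condition,
                        run_id = sprintf("%s_run%d", condition, r))
    }
  })
}

decode_condition <- function(runs, design, C = 0.02, shift_seconds = 4,
                             categories = scene_categories()) {
  if (inherits(design, "block_design")) {
    loro_cross_validate(runs, C = C, shift_seconds = shift_seconds,
                        categories = categories)
  } else {
    betas <- lapply(runs, event_glm_betas)
    loro_cross_validate_patterns(betas, C = C, categories = categories)
  }
}

#' Simulated good-vs-bad decoding experiment
#'
#' For each synthetic subject, generates a fresh category prototype set,
#' then for each repetition simulates six runs per condition — good
#' exemplars drawn with SD `sigma_good`, bad with `sigma_bad`
#' (`sigma_bad^2 = 2 sigma_good^2` by default) — decodes each condition
#' with leave-one-run-out cross-validation (per-volume SVM + majority
#' voting for the block design; per-run GLM beta patterns for the
#' event-related design), averages accuracy over repetitions per subject,
#' and finally compares conditions with a two-tailed paired t-test across
#' subjects.
#'
#' @param config A [simulation_config()]; `n_subjects` and `n_repetitions`
#'   set the experiment scale.
#' @param design `"block"` or `"event"` (or a design object).
#' @param seed Master seed; every random stream is derived from it.
#' @param C SVM cost.
#' @return An object of class `experiment_report`: `per_subject`
#'   (data.frame subject / good / bad), `test` (from
#'   [compare_conditions()]), `design`, `config`, `seed`, and the raw
#'   per-repetition `accuracies` array (subject x repetition x condition).
#' @export
run_goodbad_experiment <- function(config = simulation_config(),
                                   design = c("block", "event"),
                                   seed = 1, C = 0.02) {
  if (is.character(design)) {
    design <- switch(match.arg(design), block = block_design(),
                     event = event_design())
  }
  n_sub <- config$n_subjects
  n_rep <- config$n_repetitions
  subject_seeds <- derive_seeds(seed, n_sub)
  rep_seeds <- matrix(derive_seeds(seed + 1L, n_sub * n_rep), n_sub, n_rep)
  acc <- array(NA_real_, dim = c(n_sub, n_rep, 2L),
               dimnames = list(NULL, NULL, c("good", "bad")))
  for (s in seq_len(n_sub)) {
    cfg <- config
    cfg$prototypes <- generate_prototypes(config$n_voxels, config$separation,
                                          seed = subject_seeds[s])
    for (r in seq_len(n_rep)) {
      set.seed(rep_seeds[s, r])
      for (cond in c("good", "bad")) {
        runs <- simulate_condition_runs(design, cfg, cond)
        res <- decode_condition(runs, design, C = C)
        acc[s, r, cond] <- res$accuracy
      }
    }
  }
  per_subject <- data.frame(
    subject = seq_len(n_sub),
    good = apply(acc[, , "good", drop = FALSE], 1, mean),
    bad = apply(acc[, , "bad", drop = FALSE], 1, mean)
  )
  test <- compare_conditions(per_subject$good, per_subject$bad)
  structure(
    list(design = if (inherits(design, "block_design")) "block" else "event",
         per_subject = per_subject, test = test, accuracies = acc,
         config = config, seed = seed),
    class = "experiment_report"
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Good/bad decoding experiment (%s design, %d subjects x %d reps)\n",
              x$design, nrow(x$per_subject), dim(x$accuracies)[2]))
  cat(sprintf("  mean accuracy good %.3f, bad %.3f; paired t(%d) = %.2f, p = %.3g\n",
              mean(x$per_subject$good), mean(x$per_subject$bad),
              x$test$df, x$test$t, x$test$p))
  invisible(x)
}

#' Null (no category signal) decoding control
#'
#' Runs the block-design simulation and LORO decoder with all six category
#' prototypes identical (separation 0), so block labels carry no signal and
#' decoding can only perform at chance (1/6). Reports the mean accuracy
#' over all subjects and repetitions with a Monte-Carlo 95% confidence
#' interval over repetition-level accuracies.
#'
#' @param config A [simulation_config()]; its `separation` is forced to 0.
#' @param n_reps Repetitions per subject.
#' @param seed Master seed.
#' @return List with `mean_accuracy`, `ci` (95% normal-approximation CI),
#'   `accuracies` (subject x repetition matrix) and `chance`.
#' @export
run_null_experiment <- function(config = simulation_config(), n_reps = 50,
                                seed = 1) {
  config$separation <- 0
  config$n_repetitions <- as.integer(n_reps)
  design <- block_design()
  n_sub <- config$n_subjects
  subject_seeds <- derive_seeds(seed, n_sub)
  rep_seeds <- matrix(derive_seeds(seed + 1L, n_sub * n_reps), n_sub, n_reps)
  acc <- matrix(NA_real_, n_sub, n_reps)
  for (s in seq_len(n_sub)) {
    cfg <- config
    cfg$prototypes <- generate_prototypes(config$n_voxels, 0,
                                          seed = subject_seeds[s])
    for (r in seq_len(n_reps)) {
      set.seed(rep_seeds[s, r])
      runs <- simulate_condition_runs(design, cfg, "good")
      acc[s, r] <- loro_cross_validate(runs)$accuracy
    }
  }
  m <- mean(acc)
  se <- sd(as.vector(acc)) / sqrt(length(acc))
  list(mean_accuracy = m, ci = c(m - 1.96 * se, m + 1.96 * se),
       accuracies = acc, chance = 1 / 6)
}

#' Image-statistics variance comparison for good vs bad image sets
#'
#' For each of the six synthetic scene categories, generates a low-jitter
#' ("good") and a high-jitter ("bad") exemplar set, computes form (Gabor)
#' and color (hue-saturation histogram) feature matrices, and the total
#' variance of each set in each space.
#'
#' @param good_jitter,bad_jitter Jitter scales of the two sets
#'   (`bad_jitter` must exceed `good_jitter`).
#' @param n_images Images per set (>= 2; the study used 60 per set).
#' @param seed Master seed.
#' @param image_size Image size passed to the generators.
#' @param spaces Feature spaces to evaluate.
#' @return data.frame with columns `category`, `space`, `good_variance`,
#'   `bad_variance`, `good_less_than_bad`.
#' @export
run_imagestat_experiment <- function(good_jitter = 0.3, bad_jitter = 1.0,
                                     n_images = 60, seed = 1,
                                     image_size = c(450L, 600L),
                                     spaces = c("form", "color")) {
  if (bad_jitter <= good_jitter) {
    stop("`bad_jitter` must exceed `good_jitter`", call. = FALSE)
  }
  cats <- scene_categories()
  seeds <- matrix(derive_seeds(seed, length(cats) * 2L), length(cats), 2L)
  out <- list()
  for (i in seq_along(cats)) {
    good_spec <- default_scene_specs(jitter_scale = good_jitter,
                                     image_size = image_size)[[i]]
    bad_spec <- default_scene_specs(jitter_scale = bad_jitter,
                                    image_size = image_size)[[i]]
    good_imgs <- generate_scene_image_set(good_spec, n_images,
                                          seed = seeds[i, 1])
    bad_imgs <- generate_scene_image_set(bad_spec, n_images,
                                         seed = seeds[i, 2])
    for (sp in spaces) {
      gv <- feature_variance(feature_matrix(good_imgs, sp))
      bv <- feature_variance(feature_matrix(bad_imgs, sp))
      out[[length(out) + 1L]] <- data.frame(
        category = cats[i], space = sp, good_variance = gv,
        bad_variance = bv, good_less_than_bad = gv < bv,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
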