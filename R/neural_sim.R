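## BOLD time-course simulation for block and event-related designs:
## isotropic Gaussian exemplar patterns, gamma HRF convolution, white
## measurement noise, sampled at the TR.

#' Gamma hemodynamic response parameters
#'
#' @param p Shape exponent (dimensionless), default 8.6.
#' @param q Time constant in seconds, default 0.547.
#' @return An object of class `hrf_params`.
#' @export
hrf_params <- function(p = 8.6, q = 0.547) {
  if (p <= 0 || q <= 0) stop("`p` and `q` must be positive", call. = FALSE)
  structure(list(p = p, q = q), class = "hrf_params")
}

#' Sampled gamma-variate hemodynamic response kernel
#'
#' Samples h(t) = (t / (p q))^p * exp(p - t / q) on a regular grid. The
#' continuous form peaks at exactly 1 at t = p q (about 4.7 s for the
#' defaults); the sampled kernel is rescaled to unit peak so the maximum is
#' exactly 1 on any grid. h(0) = 0.
#'
#' @param params An [hrf_params()] object.
#' @param dt Grid step in seconds (> 0).
#' @param duration Kernel support in seconds (>= 30 recommended; the tail
#'   mass beyond 32 s is negligible for the default parameters).
#' @return Numeric vector of kernel samples at times `(0, dt, 2 dt, ...)`,
#'   with the grid step in attribute `"dt"`.
#' @export
#' @examples
#' h <- hrf_kernel(hrf_params(), dt = 0.1)
#' (which.max(h) - 1) * 0.1  # close to 8.6 * 0.547 = 4.7042 s
hrf_kernel <- function(params = hrf_params(), dt = 0.1, duration = 32) {
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  t <- seq(0, duration, by = dt)
  p <- params$p; q <- params$q
  h <- (t / (p * q))^p * exp(p - t / q)
  h[1] <- 0
  h <- h / max(h)
  attr(h, "dt") <- dt
  h
}

#' Block fMRI design
#'
#' Timing of one blocked run: initial fixation, then for each of the six
#' categories (in a per-run random order) a 16-second block of ten 1.6-second
#' image presentations followed by interblock fixation. The default includes
#' an extra 12 s of final fixation, giving a 192 s run (96 volumes at
#' TR = 2 s); set `extra_final_fixation = 0` for the literal 180 s
#' composition.
#'
#' @param initial_fixation,block_duration,interblock_fixation,extra_final_fixation
#'   Durations in seconds.
#' @param images_per_block,blocks_per_run Counts.
#' @param image_duration Seconds per image.
#' @return An object of class `block_design` with computed `duration` and
#'   block `onsets`.
#' @export
block_design <- function(initial_fixation = 12, block_duration = 16,
                         images_per_block = 10, image_duration = 1.6,
                         interblock_fixation = 12, blocks_per_run = 6,
                         extra_final_fixation = 12) {
  if (abs(block_duration - images_per_block * image_duration) > 1e-9) {
    stop("block_duration must equal images_per_block * image_duration",
         call. = FALSE)
  }
  onsets <- initial_fixation +
    (seq_len(blocks_per_run) - 1) * (block_duration + interblock_fixation)
  duration <- initial_fixation +
    blocks_per_run * (block_duration + interblock_fixation) +
    extra_final_fixation
  structure(
    list(initial_fixation = initial_fixation, block_duration = block_duration,
         images_per_block = images_per_block, image_duration = image_duration,
         interblock_fixation = interblock_fixation,
         blocks_per_run = blocks_per_run,
         extra_final_fixation = extra_final_fixation,
         onsets = onsets, duration = duration),
    class = "block_design"
  )
}

#' Event-related fMRI design
#'
#' Timing of one fast event-related run: initial fixation, then 60 trials
#' (10 per category, randomly interleaved) of 1.6 s stimulus + 2.4 s
#' fixation, then final fixation — 264 s in total (132 volumes at TR = 2 s).
#'
#' @param initial_fixation,trial_stimulus,trial_fixation,final_fixation
#'   Durations in seconds.
#' @param trials_per_run Number of trials (must be divisible by 6).
#' @return An object of class `event_design` with computed `duration` and
#'   trial `onsets`.
#' @export
event_design <- function(initial_fixation = 12, trial_stimulus = 1.6,
                         trial_fixation = 2.4, trials_per_run = 60,
                         final_fixation = 12) {
  if (trials_per_run %% 6 != 0) {
    stop("`trials_per_run` must be divisible by the 6 categories", call. = FALSE)
  }
  onsets <- initial_fixation +
    (seq_len(trials_per_run) - 1) * (trial_stimulus + trial_fixation)
  duration <- initial_fixation +
    trials_per_run * (trial_stimulus + trial_fixation) + final_fixation
  structure(
    list(initial_fixation = initial_fixation, trial_stimulus = trial_stimulus,
         trial_fixation = trial_fixation, trials_per_run = trials_per_run,
         final_fixation = final_fixation, onsets = onsets,
         duration = duration),
    class = "event_design"
  )
}

#' Simulation configuration
#'
#' Bundles the generative parameters of the neural simulator: the category
#' prototype geometry, the good/bad exemplar variance specification, the
#' measurement-noise SD, the experiment scale and the numerical grid.
#' Activation units are arbitrary BOLD-like units shared by `separation`,
#' the exemplar SDs and `sigma_noise`.
#'
#' @param n_voxels Voxels per simulated region of interest.
#' @param separation Between-category prototype separation scale.
#' @param variance_spec An [exemplar_variance_spec()].
#' @param sigma_noise Measurement-noise SD added to each TR sample.
#' @param n_subjects Number of synthetic subjects.
#' @param n_repetitions Simulated experiment repetitions per subject.
#' @param fine_dt Neural-activity grid step in seconds; must divide both the
#'   image duration (1.6 s) and the TR (2 s).
#' @param TR Repetition time in seconds.
#' @param hrf An [hrf_params()].
#' @param prototypes Optional fixed [generate_prototypes()] output; when
#'   `NULL`, pipeline drivers generate per-subject prototypes.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_voxels = 60, separation = 1,
                              variance_spec = exemplar_variance_spec(),
                              sigma_noise = 14, n_subjects = 8,
                              n_repetitions = 100, fine_dt = 0.1, TR = 2,
                              hrf = hrf_params(), prototypes = NULL) {
  if (sigma_noise < 0) stop("`sigma_noise` must be >= 0", call. = FALSE)
  for (tt in c(1.6, TR)) {
    ratio <- tt / fine_dt
    if (abs(ratio - round(ratio)) > 1e-9) {
      stop("`fine_dt` must divide both the image duration and the TR",
           call. = FALSE)
    }
  }
  structure(
    list(n_voxels = as.integer(n_voxels), separation = separation,
         variance_spec = variance_spec, sigma_noise = sigma_noise,
         n_subjects = as.integer(n_subjects),
         n_repetitions = as.integer(n_repetitions),
         fine_dt = fine_dt, TR = TR, hrf = hrf, prototypes = prototypes),
    class = "simulation_config"
  )
}

#' Draw one exemplar activity pattern
#'
#' A random draw from the isotropic multivariate Gaussian of a category:
#' the category prototype plus independent Gaussian noise of SD `sigma` per
#' voxel. Uses the current RNG state.
#'
#' @param prototypes A `prototype_set`.
#' @param category Category label or index.
#' @param sigma Exemplar SD (>= 0).
#' @return Numeric vector of length `n_voxels`.
#' @export
sample_exemplar_pattern <- function(prototypes, category, sigma) {
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (is.character(category)) {
    if (!category %in% prototypes$category_names) {
      stop(sprintf("unknown category '%s'", category), call. = FALSE)
    }
    category <- match(category, prototypes$category_names)
  }
  mu <- prototypes$prototypes[category, ]
  mu + rnorm(length(mu), sd = sigma)
}

## Convolved unit-boxcar response: dt * (boxcar of `duration` s) * HRF,
## on the fine grid. Multiplying by dt makes the amplitude grid-invariant.
stimulus_response <- function(duration, hrf, fine_dt, kernel_duration = 32) {
  h <- hrf_kernel(hrf, dt = fine_dt, duration = kernel_duration)
  box <- rep(1, round(duration / fine_dt))
  ## FIR convolution; length = length(box) + length(h) - 1
  r <- convolve(c(box, rep(0, length(h) - 1)),
                rev(c(h, rep(0, length(box) - 1))), type = "open")
  r <- r[seq_len(length(box) + length(h) - 1)]
  r * fine_dt
}

## Slot regressor matrix sampled at the TR: entry [k, s] is the convolved
## response of slot s at acquisition time (k - 1) * TR. Slot onsets must lie
## on the fine grid.
slot_regressors <- function(onsets, slot_duration, n_volumes, TR, hrf,
                            fine_dt) {
  r <- stimulus_response(slot_duration, hrf, fine_dt)
  sample_times <- (seq_len(n_volumes) - 1) * TR
  s <- matrix(0, n_volumes, length(onsets))
  for (j in seq_along(onsets)) {
    rel <- sample_times - onsets[j]
    idx <- round(rel / fine_dt) + 1L
    ok <- idx >= 1L & idx <= length(r)
    s[ok, j] <- r[idx[ok]]
  }
  s
}

make_scan_run <- function(data, TR, onsets, durations, labels, condition,
                          run_id, design_type, neural = NULL) {
  structure(
    list(data = data, TR = TR, onsets = onsets, durations = durations,
         labels = labels, condition = condition, run_id = run_id,
         design_type = design_type, neural = neural),
    class = "scan_run"
  )
}

#' @export
print.scan_run <- function(x, ...) {
  cat(sprintf("ScanRun '%s' (%s design, %s): %d volumes x %d voxels, TR %g s\n",
              x$run_id, x$design_type, x$condition, nrow(x$data),
              ncol(x$data), x$TR))
  invisible(x)
}

#' Simulate one blocked fMRI run
#'
#' Assembles fine-grid neural activity — zero during fixation, a fresh
#' exemplar draw (prototype + isotropic Gaussian noise) for every 1.6 s image
#' slot — convolves it with the gamma HRF, samples at the TR and adds i.i.d.
#' Gaussian measurement noise of SD `config$sigma_noise`.
#'
#' @param design A [block_design()].
#' @param config A [simulation_config()] with non-`NULL` `prototypes`.
#' @param category_order Permutation of the six category labels (one block
#'   each); drawn at random when `NULL`.
#' @param condition `"good"` or `"bad"`; selects the exemplar SD.
#' @param seed Optional integer seed.
#' @param run_id Identifier stored in the result.
#' @param keep_neural If `TRUE`, the fine-grid neural activity matrix is
#'   attached to the result (for diagnostics).
#' @return A `scan_run`: `data` is a T x V matrix with
#'   `T = design$duration / config$TR`.
#' @export
simulate_block_run <- function(design, config, category_order = NULL,
                               condition = c("good", "bad"), seed = NULL,
                               run_id = "run", keep_neural = FALSE) {
  condition <- match.arg(condition)
  stopifnot(inherits(design, "block_design"))
  proto <- config$prototypes
  if (is.null(proto)) stop("config must carry a prototype set", call. = FALSE)
  maybe_set_seed(seed)
  cats <- proto$category_names
  if (is.null(category_order)) category_order <- sample(cats)
  if (!setequal(category_order, cats) || length(category_order) != 6L) {
    stop("`category_order` must be a permutation of the six categories",
         call. = FALSE)
  }
  sigma_ex <- if (condition == "good") config$variance_spec$sigma_good
              else config$variance_spec$sigma_bad
  n_volumes <- design$duration / config$TR
  if (abs(n_volumes - round(n_volumes)) > 1e-9) {
    stop("run duration is not a whole number of TRs", call. = FALSE)
  }
  n_volumes <- as.integer(round(n_volumes))

  ## every image slot is a fresh exemplar draw
  slot_onsets <- as.vector(vapply(design$onsets, function(o) {
    o + (seq_len(design$images_per_block) - 1) * design$image_duration
  }, numeric(design$images_per_block)))
  slot_cats <- rep(category_order, each = design$images_per_block)
  patterns <- t(vapply(slot_cats, function(cc) {
    sample_exemplar_pattern(proto, cc, sigma_ex)
  }, numeric(proto$n_voxels)))

  s <- slot_regressors(slot_onsets, design$image_duration, n_volumes,
                       config$TR, config$hrf, config$fine_dt)
  bold <- s %*% patterns
  if (config$sigma_noise > 0) {
    bold <- bold + matrix(rnorm(length(bold), sd = config$sigma_noise),
                          nrow = n_volumes)
  }
  neural <- NULL
  if (keep_neural) {
    n_fine <- round(design$duration / config$fine_dt)
    fine_ind <- matrix(0, n_fine, length(slot_onsets))
    for (j in seq_along(slot_onsets)) {
      from <- round(slot_onsets[j] / config$fine_dt) + 1L
      len <- round(design$image_duration / config$fine_dt)
      fine_ind[from:(from + len - 1L), j] <- 1
    }
    neural <- fine_ind %*% patterns
  }
  make_scan_run(bold, config$TR, design$onsets,
                rep(design$block_duration, length(design$onsets)),
                category_order, condition, run_id, "block", neural)
}

#' Simulate one event-related fMRI run
#'
#' As [simulate_block_run()], but each 1.6 s trial is a single exemplar draw
#' followed by 2.4 s fixation; 60 trials (10 per category) are randomly
#' interleaved within the run.
#'
#' @inheritParams simulate_block_run
#' @param design An [event_design()].
#' @param trial_order Vector of 60 category labels containing each category
#'   exactly 10 times; drawn at random when `NULL`.
#' @return A `scan_run` with one onset per trial.
#' @export
simulate_event_run <- function(design, config, trial_order = NULL,
                               condition = c("good", "bad"), seed = NULL,
                               run_id = "run", keep_neural = FALSE) {
  condition <- match.arg(condition)
  stopifnot(inherits(design, "event_design"))
  proto <- config$prototypes
  if (is.null(proto)) stop("config must carry a prototype set", call. = FALSE)
  maybe_set_seed(seed)
  cats <- proto$category_names
  per_cat <- design$trials_per_run / 6L
  if (is.null(trial_order)) trial_order <- sample(rep(cats, per_cat))
  tab <- table(factor(trial_order, levels = cats))
  if (length(trial_order) != design$trials_per_run || any(tab != per_cat)) {
    stop(sprintf("`trial_order` must contain each category exactly %d times",
                 per_cat), call. = FALSE)
  }
  sigma_ex <- if (condition == "good") config$variance_spec$sigma_good
              else config$variance_spec$sigma_bad
  n_volumes <- as.integer(round(design$duration / config$TR))
  patterns <- t(vapply(trial_order, function(cc) {
    sample_exemplar_pattern(proto, cc, sigma_ex)
  }, numeric(proto$n_voxels)))
  s <- slot_regressors(design$onsets, design$trial_stimulus, n_volumes,
                       config$TR, config$hrf, config$fine_dt)
  bold <- s %*% patterns
  if (config$sigma_noise > 0) {
    bold <- bold + matrix(rnorm(length(bold), sd = config$sigma_noise),
                          nrow = n_volumes)
  }
  neural <- NULL
  if (keep_neural) {
    n_fine <- round(design$duration / config$fine_dt)
    fine_ind <- matrix(0, n_fine, length(design$onsets))
    for (j in seq_along(design$onsets)) {
      from <- round(design$onsets[j] / config$fine_dt) + 1L
      len <- round(design$trial_stimulus / config$fine_dt)
      fine_ind[from:(from + len - 1L), j] <- 1
    }
    neural <- fine_ind %*% patterns
  }
  make_scan_run(bold, config$TR, design$onsets,
                rep(design$trial_stimulus, length(design$onsets)),
                trial_order, condition, run_id, "event", neural)
}

#' Per-category beta patterns from an event-related run
#'
#' Fits, by ordinary least squares, the TR-sampled series of every voxel on
#' six HRF-convolved category regressors plus an intercept, and returns the
#' 6 x V matrix of category beta patterns. These betas are the inputs to
#' leave-one-run-out decoding for the event-related design.
#'
#' @param run An event-design `scan_run`.
#' @param hrf [hrf_params()] used to build the regressors.
#' @param fine_dt Convolution grid step.
#' @return 6 x V numeric matrix, rows named by category.
#' @export
event_glm_betas <- function(run, hrf = hrf_params(), fine_dt = 0.1) {
  stopifnot(inherits(run, "scan_run"))
  if (run$design_type != "event") {
    stop("`run` must come from an event-related design", call. = FALSE)
  }
  x <- build_design_matrix(run$onsets, run$durations, run$labels,
                           n_volumes = nrow(run$data), TR = run$TR,
                           hrf = hrf, fine_dt = fine_dt)
  fit <- fit_glm(run, x)
  fit$betas[setdiff(rownames(fit$betas), "intercept"), , drop = FALSE]
}
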