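## Synthetic inputs for the pipeline: voxel prototypes, scene-like images,
## and crowdsourced rating tables with check trials.

#' Generate per-category voxel prototypes
#'
#' Synthesizes one mean multi-voxel activation pattern per scene category.
#' Each prototype is an independent Gaussian draw per voxel, scaled by
#' `separation`, so the expected pairwise Euclidean distance between category
#' means grows linearly with `separation`; `separation = 0` collapses all six
#' prototypes onto the origin (no category signal). These prototypes play the
#' role of the category means of the multivariate Gaussian activity model in
#' the neural simulator.
#'
#' @param n_voxels Number of voxels V (>= 2).
#' @param separation Non-negative scale of between-category separation, in
#'   the same arbitrary BOLD-like activation units as the exemplar and
#'   measurement noise standard deviations.
#' @param seed Optional integer seed for reproducibility.
#' @param categories Character vector of 6 category labels.
#' @return An object of class `prototype_set`: a list with `category_names`,
#'   `prototypes` (6 x V matrix) and `n_voxels`.
#' @export
#' @examples
#' ps <- generate_prototypes(20, separation = 1, seed = 1)
#' dim(ps$prototypes)
generate_prototypes <- function(n_voxels, separation = 1, seed = NULL,
                                categories = scene_categories()) {
  stop_if_not_count(n_voxels, "n_voxels", min = 2L)
  if (!is.numeric(separation) || length(separation) != 1L || separation < 0) {
    stop("`separation` must be a single non-negative number", call. = FALSE)
  }
  if (length(categories) != 6L || anyDuplicated(categories)) {
    stop("`categories` must be 6 distinct labels", call. = FALSE)
  }
  maybe_set_seed(seed)
  proto <- matrix(rnorm(6L * n_voxels), nrow = 6L) * separation
  rownames(proto) <- categories
  structure(
    list(category_names = categories, prototypes = proto,
         n_voxels = as.integer(n_voxels), separation = separation),
    class = "prototype_set"
  )
}

#' @export
print.prototype_set <- function(x, ...) {
  cat("Category prototype set:", x$n_voxels, "voxels,",
      length(x$category_names), "categories (separation",
      format(x$separation), ")\n")
  invisible(x)
}

#' Exemplar-variance specification for good and bad image sets
#'
#' Holds the standard deviations of the isotropic Gaussian exemplar
#' distributions. By default the bad-exemplar variance is double the
#' good-exemplar variance (`sigma_bad = sqrt(2) * sigma_good`), the ratio
#' motivated by the image-statistics result that bad exemplar sets are about
#' twice as variable as good sets in form space.
#'
#' @param sigma_good Exemplar SD for the good condition (activation units).
#' @param sigma_bad Exemplar SD for the bad condition; defaults to
#'   `sqrt(2) * sigma_good`.
#' @return An object of class `exemplar_variance_spec`.
#' @export
exemplar_variance_spec <- function(sigma_good = 6, sigma_bad = sqrt(2) * sigma_good) {
  if (sigma_good <= 0 || sigma_bad <= 0) {
    stop("exemplar standard deviations must be positive", call. = FALSE)
  }
  structure(list(sigma_good = sigma_good, sigma_bad = sigma_bad),
            class = "exemplar_variance_spec")
}

#' Specification of a synthetic scene-image category template
#'
#' Describes the oriented-texture + palette composition used as a stand-in
#' for photographs of one scene category: a band-limited luminance grating
#' with a dominant orientation and spatial frequency, colored by a fixed
#' hue-saturation anchor. `jitter_scale` controls per-image perturbation of
#' orientation, frequency, phase, palette and pixel noise; 0 means every
#' image in the set is identical to the template.
#'
#' @param category_id Category label.
#' @param dominant_orientation Orientation of the template grating (radians).
#' @param dominant_frequency Spatial frequency (cycles/pixel).
#' @param palette Numeric `c(hue, saturation)`, both in \[0, 1\].
#' @param jitter_scale Non-negative within-category variability scale.
#' @param image_size `c(rows, cols)` in pixels; default 450 x 600, the
#'   resolution at which image statistics are computed.
#' @return An object of class `scene_image_spec`.
#' @export
scene_image_spec <- function(category_id, dominant_orientation = 0,
                             dominant_frequency = 0.02,
                             palette = c(0.3, 0.6), jitter_scale = 0.3,
                             image_size = c(450L, 600L)) {
  if (jitter_scale < 0) stop("`jitter_scale` must be >= 0", call. = FALSE)
  if (any(image_size < 1)) stop("image dimensions must be positive", call. = FALSE)
  if (dominant_frequency <= 0) stop("`dominant_frequency` must be > 0", call. = FALSE)
  structure(
    list(category_id = category_id,
         dominant_orientation = dominant_orientation,
         dominant_frequency = dominant_frequency,
         palette = palette, jitter_scale = jitter_scale,
         image_size = as.integer(image_size)),
    class = "scene_image_spec"
  )
}

#' Default synthetic templates for the six scene categories
#'
#' One `scene_image_spec` per category, with distinct dominant orientations,
#' spatial frequencies and palettes (e.g. horizontal low-frequency structure
#' with a blue palette for beaches, vertical structure with a gray palette
#' for city streets).
#'
#' @param jitter_scale Jitter applied to every spec.
#' @param image_size Image size passed to every spec.
#' @return Named list of 6 `scene_image_spec` objects.
#' @export
default_scene_specs <- function(jitter_scale = 0.3, image_size = c(450L, 600L)) {
  cats <- scene_categories()
  orientations <- c(0, pi / 2, pi / 2, 0, pi / 4, 3 * pi / 4)
  frequencies <- c(0.010, 0.040, 0.060, 0.015, 0.020, 0.050)
  palettes <- list(c(0.55, 0.55), c(0.08, 0.15), c(0.30, 0.65),
                   c(0.12, 0.35), c(0.60, 0.30), c(0.10, 0.45))
  specs <- lapply(seq_along(cats), function(i) {
    scene_image_spec(cats[i], orientations[i], frequencies[i], palettes[[i]],
                     jitter_scale = jitter_scale, image_size = image_size)
  })
  names(specs) <- cats
  specs
}

## Vectorized HSV -> RGB (standard hexcone transform); h, s, v in [0, 1],
## recycled to a common length.
hsv_to_rgb <- function(h, s, v) {
  n <- max(length(h), length(s), length(v))
  h <- rep_len(h, n); s <- rep_len(s, n); v <- rep_len(v, n)
  h <- (h %% 1) * 6
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

render_scene_image <- function(spec, theta, freq, phase, hue, sat,
                               pixel_noise_sd = 0) {
  h <- spec$image_size[1]
  w <- spec$image_size[2]
  rows <- seq_len(h) - (h + 1) / 2
  cols <- seq_len(w) - (w + 1) / 2
  ## grating argument: 2*pi*f*(x cos(theta) + y sin(theta)) + phase
  arg <- outer(rows * sin(theta), cols * cos(theta), "+")
  lum <- 0.5 + 0.35 * sin(2 * pi * freq * arg + phase)
  if (pixel_noise_sd > 0) {
    lum <- lum + matrix(rnorm(h * w, sd = pixel_noise_sd), h, w)
  }
  lum <- pmin(pmax(lum, 0), 1)
  rgb <- hsv_to_rgb(hue, sat, as.vector(lum))
  img <- array(0, dim = c(h, w, 3L))
  img[, , 1] <- rgb$r
  img[, , 2] <- rgb$g
  img[, , 3] <- rgb$b
  img
}

#' Noise-free template image of a scene-image spec
#'
#' @param spec A [scene_image_spec()].
#' @return An H x W x 3 RGB array in \[0, 1\].
#' @export
scene_image_template <- function(spec) {
  render_scene_image(spec, spec$dominant_orientation, spec$dominant_frequency,
                     phase = 0, hue = spec$palette[1], sat = spec$palette[2])
}

#' Generate a synthetic scene-image exemplar set
#'
#' Draws `n_images` RGB images around the category template described by
#' `spec`. Each image perturbs the template's orientation, spatial frequency,
#' phase, hue and saturation by Gaussian jitter proportional to
#' `spec$jitter_scale`, and adds pixel luminance noise on the same scale, so
#' larger jitter produces exemplar sets with larger within-set variance in
#' the Gabor form space (the good-vs-bad image-statistics structure).
#'
#' @param spec A [scene_image_spec()].
#' @param n_images Number of images (>= 2; variance is undefined below that).
#' @param seed Optional integer seed.
#' @return List of `n_images` H x W x 3 arrays in \[0, 1\].
#' @export
generate_scene_image_set <- function(spec, n_images, seed = NULL) {
  if (!inherits(spec, "scene_image_spec")) {
    stop("`spec` must be a scene_image_spec", call. = FALSE)
  }
  stop_if_not_count(n_images, "n_images", min = 2L)
  maybe_set_seed(seed)
  j <- spec$jitter_scale
  lapply(seq_len(n_images), function(i) {
    theta <- spec$dominant_orientation + 0.25 * j * rnorm(1)
    freq  <- spec$dominant_frequency * exp(0.15 * j * rnorm(1))
    phase <- 2.0 * j * rnorm(1)
    hue   <- (spec$palette[1] + 0.08 * j * rnorm(1)) %% 1
    sat   <- pmin(pmax(spec$palette[2] + 0.15 * j * rnorm(1), 0.02), 1)
    render_scene_image(spec, theta, freq, phase, hue, sat,
                       pixel_noise_sd = 0.08 * j)
  })
}

#' Generate a synthetic crowdsourced rating table with check trials
#'
#' Emulates a category-representativeness rating task: each rater rates a
#' stream of images (response = a category label, rating 1-5), and after
#' every 10 ordinary trials a check trial repeats one image randomly chosen
#' from the preceding 10 trials (so check trials sit at positions 11, 22,
#' 33, ...). Consistent raters repeat their previous response and rating
#' exactly on check trials (discount 0); planted inconsistent raters flip the
#' category label on every check trial, so with at least three check trials
#' their discount score (5 per flip) exceeds the exclusion threshold of 10.
#'
#' @param n_raters Number of raters.
#' @param n_trials_per_rater Total trials per rater including check trials
#'   (>= 11 so that at least one check trial occurs).
#' @param planted_bad_raters Number of raters made inconsistent (<= n_raters).
#' @param seed Optional integer seed.
#' @param n_images_pool Size of the image pool shared by all raters.
#' @param categories Category labels.
#' @return A data.frame with columns `rater_id`, `trial`, `image_id`,
#'   `response`, `rating`, `is_check`, `refers_to`; the ids of planted bad
#'   raters are attached as attribute `"planted"`.
#' @export
generate_rating_table <- function(n_raters, n_trials_per_rater,
                                  planted_bad_raters = 0, seed = NULL,
                                  n_images_pool = 120,
                                  categories = scene_categories()) {
  stop_if_not_count(n_raters, "n_raters", min = 1L)
  stop_if_not_count(n_trials_per_rater, "n_trials_per_rater", min = 11L)
  if (planted_bad_raters > n_raters) {
    stop("`planted_bad_raters` cannot exceed `n_raters`", call. = FALSE)
  }
  maybe_set_seed(seed)
  image_ids <- sprintf("img_%03d", seq_len(n_images_pool))
  image_cat <- rep_len(categories, n_images_pool)
  names(image_cat) <- image_ids
  bad_ids <- sprintf("rater_%02d", seq_len(n_raters))[seq_len(planted_bad_raters)]

  rows <- vector("list", n_raters)
  for (r in seq_len(n_raters)) {
    rid <- sprintf("rater_%02d", r)
    is_bad <- rid %in% bad_ids
    trial <- integer(0); img <- character(0); resp <- character(0)
    rating <- integer(0); is_check <- logical(0); refers <- integer(0)
    for (pos in seq_len(n_trials_per_rater)) {
      if (pos %% 11L == 0L) {
        ref <- sample((pos - 10L):(pos - 1L), 1L)
        ref_img <- img[ref]
        if (is_bad) {
          new_resp <- sample(setdiff(categories, resp[ref]), 1L)
          new_rating <- sample.int(5L, 1L)
        } else {
          new_resp <- resp[ref]
          new_rating <- rating[ref]
        }
        trial <- c(trial, pos); img <- c(img, ref_img)
        resp <- c(resp, new_resp); rating <- c(rating, new_rating)
        is_check <- c(is_check, TRUE); refers <- c(refers, ref)
      } else {
        this_img <- sample(image_ids, 1L)
        trial <- c(trial, pos); img <- c(img, this_img)
        resp <- c(resp, unname(image_cat[this_img]))
        rating <- c(rating, sample.int(5L, 1L))
        is_check <- c(is_check, FALSE); refers <- c(refers, NA_integer_)
      }
    }
    rows[[r]] <- data.frame(
      rater_id = rid, trial = trial, image_id = img, response = resp,
      rating = rating, is_check = is_check, refers_to = refers,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "planted") <- bad_ids
  out
}
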