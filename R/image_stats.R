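## Form (Gabor) and color (hue-saturation) feature spaces for exemplar sets,
## plus the covariance-eigenvalue variance summary and pixel-wise averages.

ANALYSIS_ROWS <- 450L
ANALYSIS_COLS <- 600L

## Luminance weights fixed for bit-reproducibility.
rgb_to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L && dim(img)[3] >= 3L) {
    return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  }
  stop("input is not an RGB image array or grayscale matrix", call. = FALSE)
}

## Bilinear resize of a matrix to (rows, cols).
resize_bilinear <- function(m, rows, cols) {
  h <- nrow(m); w <- ncol(m)
  if (h == rows && w == cols) return(m)
  ry <- (seq_len(rows) - 0.5) * h / rows + 0.5
  rx <- (seq_len(cols) - 0.5) * w / cols + 0.5
  y0 <- pmin(pmax(floor(ry), 1L), h); y1 <- pmin(y0 + 1L, h)
  x0 <- pmin(pmax(floor(rx), 1L), w); x1 <- pmin(x0 + 1L, w)
  fy <- pmin(pmax(ry - y0, 0), 1); fx <- pmin(pmax(rx - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx)
  b <- m[y1, x0, drop = FALSE] * outer(fy, 1 - fx)
  cc <- m[y0, x1, drop = FALSE] * outer(1 - fy, fx)
  d <- m[y1, x1, drop = FALSE] * outer(fy, fx)
  a + b + cc + d
}

#' Gabor filter bank used for the form feature space
#'
#' 64 even-symmetric (cosine-phase) Gabor kernels of size 8 x 8 pixels:
#' 8 orientations at k*pi/8 (k = 0..7) crossed with 8 spatial frequencies
#' whose wavelengths are geometrically spaced between 2 and 8 pixels. Each
#' kernel is mean-subtracted (DC-free, so constant images give exactly zero
#' response) and L2-normalized. Feature ordering is orientation-major:
#' entry (o - 1) * 8 + f corresponds to orientation index o and frequency
#' index f.
#'
#' @param kernel_size Side length of the square kernels in pixels.
#' @return A list with `kernels` (kernel_size^2 x 64 matrix, one column per
#'   filter, taps in column-major kernel order), `orientation` and
#'   `wavelength` (length-64 vectors describing each column).
#' @export
gabor_bank <- function(kernel_size = 8L) {
  orientations <- (0:7) * pi / 8
  wavelengths <- 2 * (8 / 2)^((0:7) / 7)
  n <- kernel_size
  ctr <- (n + 1) / 2
  xs <- seq_len(n) - ctr
  kernels <- matrix(0, n * n, 64L)
  ori_out <- numeric(64L); wl_out <- numeric(64L)
  idx <- 0L
  for (o in seq_along(orientations)) {
    th <- orientations[o]
    for (f in seq_along(wavelengths)) {
      wl <- wavelengths[f]
      sigma <- 0.56 * wl
      ## kernel[y, x]: rotated coordinate along the modulation axis
      xr <- outer(xs * sin(th), xs * cos(th), "+")
      rr <- outer(xs^2, xs^2, "+")
      k <- exp(-rr / (2 * sigma^2)) * cos(2 * pi * xr / wl)
      k <- k - mean(k)
      k <- k / sqrt(sum(k^2))
      idx <- idx + 1L
      kernels[, idx] <- as.vector(k)
      ori_out[idx] <- th; wl_out[idx] <- wl
    }
  }
  list(kernels = kernels, orientation = ori_out, wavelength = wl_out,
       kernel_size = n)
}

## Patch matrix for valid correlation with k x k kernels: one row per valid
## pixel location, one column per kernel tap (column-major tap order).
image_patches <- function(g, k) {
  oh <- nrow(g) - k + 1L
  ow <- ncol(g) - k + 1L
  p <- matrix(0, oh * ow, k * k)
  idx <- 0L
  for (dx in 0:(k - 1L)) {
    for (dy in 0:(k - 1L)) {
      idx <- idx + 1L
      p[, idx] <- as.vector(g[dy + seq_len(oh), dx + seq_len(ow)])
    }
  }
  p
}

#' Gabor form features of an image
#'
#' Converts an RGB image to grayscale, resamples it to the 450 x 600
#' analysis resolution if needed, correlates it with the 64-filter Gabor
#' bank, and averages the absolute filter responses over all valid pixel
#' locations, yielding one 64-element "form" feature vector per image.
#' The kernels are DC-free, so a uniform image maps to the zero vector.
#'
#' @param img RGB array (H x W x 3) or grayscale matrix, values in \[0, 1\].
#' @param bank A [gabor_bank()]; the default bank is used when `NULL`.
#' @return Numeric vector of length 64 (orientation-major ordering).
#' @export
gabor_form_features <- function(img, bank = NULL) {
  g <- rgb_to_gray(img)
  g <- resize_bilinear(g, ANALYSIS_ROWS, ANALYSIS_COLS)
  if (is.null(bank)) bank <- gabor_bank()
  p <- image_patches(g, bank$kernel_size)
  resp <- abs(p %*% bank$kernels)
  as.vector(colMeans(resp))
}

#' Hue-saturation color histogram features of an image
#'
#' Converts RGB pixels to hue and saturation, discretizes both uniformly
#' into 8 bins, and returns the flattened 8 x 8 joint histogram normalized
#' to proportions (entries sum to 1). Achromatic pixels (saturation 0) have
#' hue 0 and fall in the first hue bin. Entry (h - 1) * 8 + s corresponds to
#' hue bin h and saturation bin s.
#'
#' @param img RGB array (H x W x 3), values in \[0, 1\].
#' @return Numeric vector of length 64 summing to 1.
#' @export
color_histogram <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3] < 3L) {
    stop("input is not an RGB image array", call. = FALSE)
  }
  hsv <- rgb2hsv(as.vector(img[, , 1]), as.vector(img[, , 2]),
                 as.vector(img[, , 3]), maxColorValue = 1)
  hbin <- pmin(floor(hsv[1, ] * 8), 7) + 1L
  sbin <- pmin(floor(hsv[2, ] * 8), 7) + 1L
  counts <- tabulate((hbin - 1L) * 8L + sbin, nbins = 64L)
  counts / sum(counts)
}

#' Feature matrix of an image set
#'
#' @param images List of RGB images.
#' @param space `"form"` (Gabor) or `"color"` (hue-saturation histogram).
#' @param set_tag Optional label stored as attribute.
#' @return n_images x 64 matrix with the space recorded in attribute
#'   `"space"`.
#' @export
feature_matrix <- function(images, space = c("form", "color"),
                           set_tag = NULL) {
  space <- match.arg(space)
  bank <- if (space == "form") gabor_bank() else NULL
  rows <- lapply(images, function(img) {
    if (space == "form") gabor_form_features(img, bank)
    else color_histogram(img)
  })
  m <- do.call(rbind, rows)
  attr(m, "space") <- space
  attr(m, "set_tag") <- set_tag
  m
}

#' Total variance of a feature-vector set
#'
#' Forms the covariance matrix of the rows under the population (1/n)
#' convention, decomposes it by singular value decomposition, and returns
#' the sum of its eigenvalues. This equals the mean squared Euclidean
#' distance of the feature vectors from their mean — the overall variance of
#' the exemplar set in the feature space.
#'
#' @param features n x d numeric matrix (n >= 2), one feature vector per row.
#' @return Single non-negative number.
#' @export
feature_variance <- function(features) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 2L) stop("variance requires at least 2 feature vectors", call. = FALSE)
  centered <- sweep(features, 2L, colMeans(features))
  covm <- crossprod(centered) / n
  sum(svd(covm, nu = 0, nv = 0)$d)
}

#' Pixel-wise average image of a set
#'
#' Arithmetic mean of the RGB values at every pixel, the "prototype image"
#' of an exemplar set.
#'
#' @param images List of RGB arrays with identical dimensions.
#' @return RGB array of the common dimensions.
#' @export
average_image <- function(images) {
  if (length(images) < 1L) stop("empty image set", call. = FALSE)
  dims <- lapply(images, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("all images must share the same dimensions", call. = FALSE)
  }
  Reduce(`+`, images) / length(images)
}
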