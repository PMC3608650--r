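## Univariate regression analyses: HRF-convolved condition regressors,
## percent signal change, residual-based noise-SD estimation, and the
## block-halves repetition-suppression variant.

#' Build an HRF-convolved design matrix
#'
#' One boxcar regressor per condition (or per condition x block-half when
#' `halves = TRUE`, splitting each event into equal first/second
#' sub-events), convolved with the gamma HRF on a fine grid, sampled at the
#' TR, and scaled to unit peak so that betas are in the units of the data.
#' An intercept column is appended.
#'
#' @param onsets Event onsets in seconds.
#' @param durations Event durations in seconds (recycled).
#' @param labels Condition label per event.
#' @param n_volumes Number of TR samples in the run.
#' @param TR Repetition time (s).
#' @param hrf [hrf_params()].
#' @param halves If `TRUE`, each event contributes to a `<condition>_first`
#'   and `<condition>_second` regressor instead of one per condition.
#' @param fine_dt Convolution grid step (s).
#' @param conditions Optional declared condition set; an error is raised if
#'   any declared condition has no events.
#' @return An object of class `design_matrix`: `X` (n_volumes x k), the
#'   task `columns`, `TR` and `hrf`.
#' @export
build_design_matrix <- function(onsets, durations, labels, n_volumes, TR = 2,
                                hrf = hrf_params(), halves = FALSE,
                                fine_dt = 0.1, conditions = NULL) {
  durations <- rep_len(durations, length(onsets))
  labels <- as.character(labels)
  if (length(labels) != length(onsets)) {
    stop("`labels` must match `onsets` in length", call. = FALSE)
  }
  if (!is.null(conditions)) {
    missing_cond <- setdiff(conditions, labels)
    if (length(missing_cond)) {
      stop(sprintf("condition(s) with no events: %s",
                   paste(missing_cond, collapse = ", ")), call. = FALSE)
    }
  }
  if (halves) {
    onsets <- c(onsets, onsets + durations / 2)
    durations <- rep(durations / 2, 2L)
    labels <- c(paste0(labels, "_first"), paste0(labels, "_second"))
  }
  cols <- unique(labels)
  run_duration <- n_volumes * TR
  n_fine <- round(run_duration / fine_dt)
  sample_idx <- round(((seq_len(n_volumes) - 1) * TR) / fine_dt) + 1L
  ## convolved response of a single event, cached per distinct duration;
  ## a condition regressor is the sum of shifted copies over its events
  resp_cache <- list()
  event_response <- function(dur) {
    key <- format(dur, digits = 12)
    if (is.null(resp_cache[[key]])) {
      resp_cache[[key]] <<- stimulus_response(dur, hrf, fine_dt)
    }
    resp_cache[[key]]
  }
  x <- matrix(0, n_volumes, length(cols), dimnames = list(NULL, cols))
  for (cond in cols) {
    sel <- which(labels == cond)
    ind <- numeric(n_fine)
    max_len <- max(vapply(sel, function(j) length(event_response(durations[j])),
                          integer(1)))
    col_fine <- numeric(n_fine + max_len)
    for (j in sel) {
      from <- round(onsets[j] / fine_dt) + 1L
      to <- min(round((onsets[j] + durations[j]) / fine_dt), n_fine)
      if (from > n_fine) next
      if (any(ind[from:to] > 0)) {
        stop(sprintf("overlapping events within condition '%s'", cond),
             call. = FALSE)
      }
      ind[from:to] <- 1
      r <- event_response(durations[j])
      span <- from:(from + length(r) - 1L)
      col_fine[span] <- col_fine[span] + r
    }
    col <- col_fine[sample_idx]
    peak <- max(abs(col))
    if (peak == 0) {
      stop(sprintf("regressor '%s' is all zero within the run", cond),
           call. = FALSE)
    }
    x[, cond] <- col / peak
  }
  x <- cbind(x, intercept = 1)
  structure(list(X = x, columns = cols, TR = TR, hrf = hrf),
            class = "design_matrix")
}

#' Fit the univariate GLM to a run
#'
#' Ordinary least squares of every voxel's time series on the design
#' matrix. Percent signal change for each task regressor is computed as
#' 100 * beta / intercept per voxel (regressors are unit-peak), averaged
#' over voxels; the pooled residual standard deviation (degrees-of-freedom
#' corrected) estimates the measurement-noise SD, the quantity that
#' calibrates the simulator.
#'
#' @param run A `scan_run` or a T x V numeric matrix.
#' @param design A [build_design_matrix()] result (or bare matrix with an
#'   `intercept` column).
#' @return An object of class `glm_fit`: `betas` (k x V), `residuals`
#'   (T x V), `residual_sd`, `psc` (named per task column, `NA` when the
#'   mean intercept is numerically zero), `fitted`.
#' @export
fit_glm <- function(run, design) {
  y <- if (inherits(run, "scan_run")) run$data else as.matrix(run)
  x <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  if (nrow(y) != nrow(x)) {
    stop("design and data disagree on the number of volumes", call. = FALSE)
  }
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) stop("design matrix is rank deficient", call. = FALSE)
  betas <- qr.coef(qrx, y)
  fitted <- x %*% betas
  res <- y - fitted
  dof <- (nrow(y) - ncol(x)) * ncol(y)
  residual_sd <- sqrt(sum(res^2) / dof)
  task_cols <- setdiff(colnames(x), "intercept")
  b0 <- betas["intercept", ]
  psc <- vapply(task_cols, function(cond) {
    if (abs(mean(b0)) < 1e-12) return(NA_real_)
    mean(100 * betas[cond, ] / b0)
  }, numeric(1))
  structure(
    list(betas = betas, residuals = res, fitted = fitted,
         residual_sd = residual_sd, psc = psc),
    class = "glm_fit"
  )
}

#' Two-way repeated-measures ANOVA on block-halves percent signal change
#'
#' Takes per-subject percent-signal-change values for the 2 x 2 design
#' (good/bad exemplars x first/second block half) and runs the classical
#' two-within-factor repeated-measures ANOVA with subject as the blocking
#' factor, reporting both main effects and the interaction. A reliable
#' first-half > second-half main effect is the signature of repetition
#' suppression over the course of a block.
#'
#' @param psc_table data.frame with columns `subject`, `exemplar`
#'   (good/bad), `half` (first/second) and `psc`; one row per cell per
#'   subject (>= 2 subjects).
#' @return List with `cell_means` (2 x 2 matrix) and `anova` (data.frame
#'   with effect, df1, df2, F, p).
#' @export
halves_contrast <- function(psc_table) {
  req <- c("subject", "exemplar", "half", "psc")
  if (!all(req %in% names(psc_table))) {
    stop("`psc_table` must have columns subject, exemplar, half, psc",
         call. = FALSE)
  }
  psc_table$subject <- factor(psc_table$subject)
  psc_table$exemplar <- factor(psc_table$exemplar)
  psc_table$half <- factor(psc_table$half)
  if (nlevels(psc_table$subject) < 2L) {
    stop("need at least 2 subjects", call. = FALSE)
  }
  if (nlevels(psc_table$exemplar) != 2L || nlevels(psc_table$half) != 2L) {
    stop("`exemplar` and `half` must each have exactly 2 levels", call. = FALSE)
  }
  counts <- table(psc_table$subject, psc_table$exemplar, psc_table$half)
  if (any(counts != 1L)) {
    stop("each subject must contribute exactly one value per 2 x 2 cell",
         call. = FALSE)
  }
  fit <- aov(psc ~ exemplar * half + Error(subject / (exemplar * half)),
             data = psc_table)
  sm <- summary(fit)
  ## round-off floor: effect sums of squares below this are null effects
  ss_floor <- 1e-20 * (sum(psc_table$psc^2) + 1)
  pick <- function(stratum, effect) {
    tab <- sm[[stratum]][[1]]
    row <- trimws(rownames(tab)) == effect
    fv <- tab[row, "F value"]
    pv <- tab[row, "Pr(>F)"]
    if (!is.finite(fv) || tab[row, "Sum Sq"] < ss_floor) {
      fv <- 0; pv <- 1
    }
    data.frame(effect = effect, df1 = tab[row, "Df"],
               df2 = tab[trimws(rownames(tab)) == "Residuals", "Df"],
               F = fv, p = pv, stringsAsFactors = FALSE)
  }
  anova_tab <- rbind(
    pick("Error: subject:exemplar", "exemplar"),
    pick("Error: subject:half", "half"),
    pick("Error: subject:exemplar:half", "exemplar:half")
  )
  rownames(anova_tab) <- NULL
  cell_means <- tapply(psc_table$psc, list(psc_table$exemplar, psc_table$half),
                       mean)
  list(cell_means = cell_means, anova = anova_tab)
}
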