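## Multi-voxel pattern analysis: run normalization, block-volume extraction
## with hemodynamic shift, per-volume linear SVM, majority voting with
## decision-value tie-breaking, and leave-one-run-out cross-validation.

#' Normalize a run to its temporal mean
#'
#' Divides every voxel's time series by its within-run temporal mean, the
#' standard percent-of-baseline scaling applied before pattern analysis.
#' Voxels whose temporal mean is (numerically) zero cannot be scaled; they
#' are set to a constant 1 and reported in a warning.
#'
#' @param run A `scan_run`.
#' @param tol Absolute tolerance below which a temporal mean counts as zero.
#' @return The run with normalized `data` (every voxel's temporal mean 1).
#' @export
normalize_run <- function(run, tol = 1e-12) {
  stopifnot(inherits(run, "scan_run"))
  mu <- colMeans(run$data)
  bad <- abs(mu) < tol
  if (any(bad)) {
    warning(sprintf("%d voxel(s) with zero temporal mean set to constant 1",
                    sum(bad)), call. = FALSE)
    run$data[, bad] <- 1
    mu[bad] <- 1
  }
  run$data <- sweep(run$data, 2L, mu, "/")
  run
}

#' Extract per-block volume samples with a hemodynamic shift
#'
#' For each block, returns the 8 consecutive volumes (16 s block at TR 2 s)
#' starting `shift_seconds` after the block onset, the shift approximating
#' the delay of the BOLD response. The shift must be a whole number of TRs
#' (no temporal interpolation is performed).
#'
#' @param run A block-design `scan_run`.
#' @param shift_seconds Hemodynamic shift in seconds (default 4 = 2 TRs).
#' @return List of `block_sample` objects: `volumes` (8 x V matrix),
#'   `label`, `run_id`, `condition`, `block_index`.
#' @export
extract_block_samples <- function(run, shift_seconds = 4) {
  stopifnot(inherits(run, "scan_run"))
  tr <- run$TR
  if (abs(shift_seconds / tr - round(shift_seconds / tr)) > 1e-9) {
    stop("`shift_seconds` must be an integer multiple of the TR", call. = FALSE)
  }
  n_vol_block <- as.integer(round(run$durations[1] / tr))
  n_total <- nrow(run$data)
  lapply(seq_along(run$onsets), function(b) {
    start <- round((run$onsets[b] + shift_seconds) / tr)  # 0-based volume
    idx <- start + seq_len(n_vol_block)                   # 1-based rows
    if (idx[length(idx)] > n_total || idx[1] < 1L) {
      stop(sprintf("shifted window of block %d (volumes %d..%d) exceeds the run (%d volumes)",
                   b, idx[1], idx[length(idx)], n_total), call. = FALSE)
    }
    structure(
      list(volumes = run$data[idx, , drop = FALSE], label = run$labels[b],
           run_id = run$run_id, condition = run$condition, block_index = b),
      class = "block_sample"
    )
  })
}

#' Train a six-way linear support-vector classifier
#'
#' Fits a linear-kernel soft-margin SVM with cost `C` (default 0.02) in a
#' one-vs-rest arrangement: one binary margin per category, giving a
#' well-defined per-category decision value for any input volume. Predicted
#' label = category with the largest decision value.
#'
#' @param x n x V matrix of training volumes.
#' @param y Vector/factor of category labels (>= 2 classes present).
#' @param C Soft-margin cost parameter.
#' @param tolerance Termination tolerance of the underlying libsvm
#'   optimizer.
#' @return An object of class `category_svm`.
#' @export
train_category_classifier <- function(x, y, C = 0.02, tolerance = 0.01) {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) {
    stop("training data must contain at least 2 classes", call. = FALSE)
  }
  models <- lapply(classes, function(cl) {
    yy <- factor(ifelse(y == cl, "pos", "neg"), levels = c("pos", "neg"))
    m <- e1071::svm(x, yy, kernel = "linear", cost = C, scale = FALSE,
                    fitted = FALSE, tolerance = tolerance)
    ## libsvm orients the decision value towards the first class it saw in
    ## the data; recover the orientation from the decision-value column name.
    dv <- attr(stats::predict(m, x[1, , drop = FALSE], decision.values = TRUE),
               "decision.values")
    sign_flip <- if (colnames(dv)[1] == "pos/neg") 1 else -1
    list(model = m, sign = sign_flip)
  })
  names(models) <- classes
  structure(list(models = models, classes = classes, C = C),
            class = "category_svm")
}

#' Per-category decision values of a trained classifier
#'
#' @param object A `category_svm`.
#' @param newdata m x V matrix of volumes.
#' @return m x n_classes matrix of signed decision values (positive favors
#'   the column's category).
#' @export
decision_values <- function(object, newdata) {
  stopifnot(inherits(object, "category_svm"))
  newdata <- as.matrix(newdata)
  dv <- vapply(object$models, function(m) {
    v <- attr(stats::predict(m$model, newdata, decision.values = TRUE),
              "decision.values")
    as.vector(v) * m$sign
  }, numeric(nrow(newdata)))
  dv <- matrix(dv, nrow = nrow(newdata),
               dimnames = list(NULL, object$classes))
  dv
}

#' @export
predict.category_svm <- function(object, newdata, ...) {
  dv <- decision_values(object, newdata)
  object$classes[max.col(dv, ties.method = "first")]
}

#' Aggregate per-volume votes into one block label
#'
#' Majority vote over the per-volume predicted labels. Ties among the most
#' frequently predicted categories are resolved by the largest per-category
#' decision value summed over the block's volumes; an (measure-zero) exact
#' tie after that falls back to the first tied category in `classes` order.
#' Decision values are consulted only when the vote is tied.
#'
#' @param labels Character vector of per-volume predicted labels.
#' @param dv Matrix of per-volume decision values (rows = volumes, columns
#'   named by category), or a function returning it; only evaluated on ties.
#' @param classes Category ordering used for the final deterministic
#'   fallback.
#' @return Single predicted category label.
#' @export
majority_vote <- function(labels, dv, classes) {
  counts <- table(factor(labels, levels = classes))
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) return(top)
  if (is.function(dv)) dv <- dv()
  sums <- colSums(dv[, top, drop = FALSE])
  top[which.max(sums)]
}

#' Predict the category of one block
#'
#' Classifies each of the block's 8 volumes independently with the linear
#' SVM, then aggregates with [majority_vote()].
#'
#' @param classifier A `category_svm`.
#' @param block A `block_sample`.
#' @return Predicted category label.
#' @export
predict_block <- function(classifier, block) {
  stopifnot(inherits(block, "block_sample"))
  dv <- decision_values(classifier, block$volumes)
  labels <- classifier$classes[max.col(dv, ties.method = "first")]
  majority_vote(labels, dv, classifier$classes)
}

#' Leave-one-run-out cross-validated block decoding
#'
#' For each of the runs in turn: train the linear SVM (cost `C`) on every
#' volume of every block of the remaining runs (each volume labeled with its
#' block's category), then predict each held-out block with per-volume
#' classification + majority voting. Accuracy is the fraction of blocks with
#' correct category predictions, aggregated over all folds, together with a
#' category x category confusion matrix (rows = truth, columns = predicted).
#'
#' @param runs List of >= 2 block-design `scan_run`s with a common voxel
#'   count.
#' @param C SVM cost.
#' @param shift_seconds Hemodynamic shift passed to
#'   [extract_block_samples()].
#' @param categories Category ordering for the confusion matrix.
#' @return An object of class `decoding_result`: `accuracy`, `confusion`,
#'   and `predictions` (data.frame run_id / block / truth / predicted).
#' @export
loro_cross_validate <- function(runs, C = 0.02, shift_seconds = 4,
                                categories = scene_categories()) {
  if (length(runs) < 2L) stop("need at least 2 runs", call. = FALSE)
  nv <- vapply(runs, function(r) ncol(r$data), integer(1))
  if (length(unique(nv)) != 1L) {
    stop("all runs must have the same number of voxels", call. = FALSE)
  }
  samples <- lapply(runs, extract_block_samples, shift_seconds = shift_seconds)
  block_sets <- lapply(samples, function(s) {
    list(x = do.call(rbind, lapply(s, `[[`, "volumes")),
         y = rep(vapply(s, `[[`, character(1), "label"),
                 each = nrow(s[[1]]$volumes)))
  })
  preds <- vector("list", length(runs))
  for (fold in seq_along(runs)) {
    train <- block_sets[-fold]
    clf <- train_category_classifier(
      do.call(rbind, lapply(train, `[[`, "x")),
      unlist(lapply(train, `[[`, "y")), C = C)
    ## one batched decision-value pass over the held-out run, sliced per
    ## block (identical to predict_block on each block, just faster)
    test <- samples[[fold]]
    n_per_block <- nrow(test[[1]]$volumes)
    dv_all <- decision_values(clf, do.call(rbind,
                                           lapply(test, `[[`, "volumes")))
    predicted <- vapply(seq_along(test), function(b) {
      rows <- (b - 1L) * n_per_block + seq_len(n_per_block)
      dv <- dv_all[rows, , drop = FALSE]
      labels <- clf$classes[max.col(dv, ties.method = "first")]
      majority_vote(labels, dv, clf$classes)
    }, character(1))
    preds[[fold]] <- data.frame(
      run_id = runs[[fold]]$run_id,
      block = vapply(test, `[[`, integer(1), "block_index"),
      truth = vapply(test, `[[`, character(1), "label"),
      predicted = predicted,
      stringsAsFactors = FALSE
    )
  }
  preds <- do.call(rbind, preds)
  finalize_decoding_result(preds, categories)
}

#' Leave-one-run-out decoding of per-run pattern sets
#'
#' The event-related analogue of [loro_cross_validate()]: each run
#' contributes a labeled matrix of patterns (e.g. the per-category GLM beta
#' patterns from [event_glm_betas()]); each fold trains on the patterns of
#' the other runs and classifies each held-out pattern directly.
#'
#' @param pattern_runs List of matrices with rownames = category labels
#'   (one labeled pattern per row).
#' @param C SVM cost.
#' @param categories Category ordering for the confusion matrix.
#' @return A `decoding_result`.
#' @export
loro_cross_validate_patterns <- function(pattern_runs, C = 0.02,
                                         categories = scene_categories()) {
  if (length(pattern_runs) < 2L) stop("need at least 2 runs", call. = FALSE)
  preds <- vector("list", length(pattern_runs))
  for (fold in seq_along(pattern_runs)) {
    train <- do.call(rbind, pattern_runs[-fold])
    clf <- train_category_classifier(train, rownames(train), C = C)
    test <- pattern_runs[[fold]]
    preds[[fold]] <- data.frame(
      run_id = sprintf("run%d", fold),
      block = seq_len(nrow(test)),
      truth = rownames(test),
      predicted = predict(clf, test),
      stringsAsFactors = FALSE
    )
  }
  preds <- do.call(rbind, preds)
  finalize_decoding_result(preds, categories)
}

finalize_decoding_result <- function(preds, categories) {
  confusion <- table(
    truth = factor(preds$truth, levels = categories),
    predicted = factor(preds$predicted, levels = categories)
  )
  confusion <- unclass(confusion)
  structure(
    list(accuracy = mean(preds$truth == preds$predicted),
         confusion = confusion, predictions = preds),
    class = "decoding_result"
  )
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("Decoding result: accuracy %.3f over %d blocks\n",
              x$accuracy, nrow(x$predictions)))
  invisible(x)
}

#' Compare decoding accuracy between conditions across subjects
#'
#' Two-tailed paired t-test of the per-subject good vs bad accuracies, plus
#' one-tailed one-sample t-tests of each condition against chance (1/6).
#' Degenerate inputs (zero-variance differences) are flagged: identical
#' samples give t = 0, p = 1; a constant nonzero difference gives
#' t = +/- Inf, p = 0.
#'
#' @param acc_good,acc_bad Equal-length numeric vectors of per-subject
#'   accuracies (n >= 2).
#' @param chance Chance level (default 1/6).
#' @return List with `mean_diff`, `t`, `df`, `p`, `degenerate`, and
#'   per-condition one-tailed tests `vs_chance_good` / `vs_chance_bad`
#'   (each `t`, `df`, `p`, `mean`).
#' @export
compare_conditions <- function(acc_good, acc_bad, chance = 1 / 6) {
  n <- length(acc_good)
  if (n < 2L || length(acc_bad) != n) {
    stop("need two paired samples of equal length >= 2", call. = FALSE)
  }
  d <- acc_good - acc_bad
  ## numerically constant differences would make the t statistic blow up
  degenerate <- sd(d) <= 1e-12 * max(abs(d), 1)
  if (degenerate) {
    zero_mean <- abs(mean(d)) <= 1e-12
    tval <- if (zero_mean) 0 else sign(mean(d)) * Inf
    pval <- if (zero_mean) 1 else 0
  } else {
    tt <- t.test(acc_good, acc_bad, paired = TRUE)
    tval <- unname(tt$statistic)
    pval <- tt$p.value
  }
  one_sided <- function(x) {
    if (sd(x) <= 1e-12 * max(abs(x - chance), 1)) {
      dm <- mean(x) - chance
      tv <- if (abs(dm) <= 1e-12) 0 else sign(dm) * Inf
      pv <- if (abs(dm) <= 1e-12) 0.5 else if (dm > 0) 0 else 1
    } else {
      tt <- t.test(x, mu = chance, alternative = "greater")
      tv <- unname(tt$statistic); pv <- tt$p.value
    }
    list(t = tv, df = n - 1L, p = pv, mean = mean(x))
  }
  list(mean_diff = mean(d), t = tval, df = n - 1L, p = pval,
       degenerate = degenerate,
       vs_chance_good = one_sided(acc_good),
       vs_chance_bad = one_sided(acc_bad))
}
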