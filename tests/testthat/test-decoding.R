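test_that("run normalization rescales every voxel to unit temporal mean", {
  cfg <- tiny_config(n_voxels = 5)
  run <- simulate_block_run(block_design(), cfg, seed = 1)
  run$data <- abs(run$data) + 50  # give it a baseline
  norm <- normalize_run(run)
  expect_equal(unname(colMeans(norm$data)), rep(1, 5))

  # constant series of 5 -> constant series of 1
  run$data[, 2] <- 5
  expect_equal(unique(normalize_run(run)$data[, 2]), 1)

  # idempotence
  norm2 <- normalize_run(normalize_run(run))
  expect_equal(norm2$data, normalize_run(run)$data, tolerance = 1e-12)

  # zero-mean voxel flagged and set constant
  run$data[, 3] <- run$data[, 3] - mean(run$data[, 3])
  expect_warning(nz <- normalize_run(run), "zero temporal mean")
  expect_equal(unique(nz$data[, 3]), 1)
})

test_that("block extraction returns the 8 shifted volumes of each block", {
  cfg <- tiny_config(n_voxels = 4)
  run <- simulate_block_run(block_design(), cfg, seed = 2)
  blocks <- extract_block_samples(run, shift_seconds = 4)
  expect_length(blocks, 6L)
  for (b in blocks) expect_equal(nrow(b$volumes), 8L)
  # onset 12 s, shift 4 s, TR 2 s -> volumes at 0-based indices 8..15
  expect_equal(blocks[[1]]$volumes, run$data[9:16, ])
  expect_equal(blocks[[2]]$volumes, run$data[23:30, ])  # onset 40 s

  # shift 0 with a block starting at t = 0 -> volumes 0..7
  run0 <- run; run0$onsets[1] <- 0
  b0 <- extract_block_samples(run0, shift_seconds = 0)
  expect_equal(b0[[1]]$volumes, run0$data[1:8, ])

  expect_error(extract_block_samples(run, shift_seconds = 3), "multiple")
  run_bad <- run; run_bad$onsets[6] <- 180
  expect_error(extract_block_samples(run_bad, shift_seconds = 4),
               "block 6")
})

test_that("the linear SVM separates well-separated clouds and exposes decision values", {
  set.seed(10)
  x <- rbind(matrix(rnorm(40 * 5, mean = 0, sd = 0.1), 40, 5),
             matrix(rnorm(40 * 5, mean = 10, sd = 0.1), 40, 5))
  y <- rep(c("a", "b"), each = 40)
  clf <- train_category_classifier(x, y, C = 0.02)
  expect_equal(mean(predict(clf, x) == y), 1.0)
  dv <- decision_values(clf, x[1:3, ])
  expect_equal(dim(dv), c(3L, 2L))
  expect_true(all(dv[, "a"] > dv[, "b"]))

  # duplicating the training set leaves the predictions unchanged
  clf2 <- train_category_classifier(rbind(x, x), c(y, y), C = 0.02)
  expect_identical(predict(clf2, x), predict(clf, x))

  # a sample deep inside one class's region gets that class
  expect_identical(predict(clf, matrix(10, 1, 5)), "b")

  expect_error(train_category_classifier(x, rep("a", 80)), "2 classes")
})

test_that("block prediction uses majority voting, consulting decision values only on ties", {
  classes <- c("A", "B", "C")
  # strict majority: decision values must never be touched
  poison <- function() stop("decision values consulted on a strict majority")
  expect_identical(
    majority_vote(c("A", "A", "A", "A", "A", "B", "B", "C"), poison, classes),
    "A")
  expect_identical(majority_vote(rep("C", 8), poison, classes), "C")

  # 3-3-2 tie: largest summed decision value among the tied categories wins
  dv <- matrix(0, 8, 3, dimnames = list(NULL, classes))
  dv[, "A"] <- 0.15; dv[, "B"] <- 0.25; dv[, "C"] <- 10
  expect_identical(
    majority_vote(c("A", "A", "A", "B", "B", "B", "C", "C"), dv, classes),
    "B")

  # exact decision-value tie falls back to the fixed category order
  dv0 <- matrix(1, 8, 3, dimnames = list(NULL, classes))
  expect_identical(
    majority_vote(c("A", "A", "B", "B", "C", "C", "A", "B"), dv0, classes),
    "A")
})

test_that("LORO decoding is perfect for separable data and chance for identical prototypes", {
  # huge separation, near-zero noise: separable by construction
  cfg <- tiny_config(n_voxels = 15, separation = 50, sigma_good = 0.01,
                     sigma_bad = 0.01, sigma_noise = 0.01)
  runs <- lapply(1:3, function(i) {
    simulate_block_run(block_design(), cfg, seed = 100 + i,
                       run_id = sprintf("r%d", i))
  })
  res <- loro_cross_validate(runs)
  expect_equal(res$accuracy, 1.0)
  expect_equal(unname(rowSums(res$confusion)), rep(3, 6))
  expect_equal(sum(res$confusion), nrow(res$predictions))
  expect_equal(res$accuracy,
               sum(diag(res$confusion)) / sum(res$confusion))

  # consistent voxel reordering leaves the predictions unchanged
  perm <- sample(15)
  runs_perm <- lapply(runs, function(r) { r$data <- r$data[, perm]; r })
  expect_identical(loro_cross_validate(runs_perm)$predictions$predicted,
                   res$predictions$predicted)

  expect_error(loro_cross_validate(runs[1]), "at least 2")
  runs_bad <- runs; runs_bad[[2]]$data <- runs_bad[[2]]$data[, 1:10]
  expect_error(loro_cross_validate(runs_bad), "same number of voxels")
})

test_that("label permutation drives LORO accuracy to chance", {
  cfg <- tiny_config(n_voxels = 12, separation = 1, sigma_good = 2,
                     sigma_noise = 4)
  runs <- lapply(1:3, function(i) {
    simulate_block_run(block_design(), cfg, seed = 200 + i,
                       run_id = sprintf("r%d", i))
  })
  set.seed(314)
  accs <- replicate(200, {
    shuffled <- lapply(runs, function(r) { r$labels <- sample(r$labels); r })
    loro_cross_validate(shuffled)$accuracy
  })
  expect_lt(abs(mean(accs) - 1 / 6), 0.03)
})

test_that("decoding accuracy decreases with exemplar variance", {
  bd <- block_design()
  mean_acc <- function(sigma) {
    accs <- vapply(1:50, function(r) {
      cfg <- tiny_config(n_voxels = 20, sigma_good = sigma,
                         sigma_bad = sigma, sigma_noise = 5,
                         proto_seed = 17)
      set.seed(4000 + r)
      runs <- lapply(1:4, function(i) {
        simulate_block_run(bd, cfg, run_id = sprintf("r%d", i))
      })
      loro_cross_validate(runs)$accuracy
    }, numeric(1))
    mean(accs)
  }
  accs <- vapply(c(1, 4, 12), mean_acc, numeric(1))
  expect_true(all(diff(accs) <= 0))
})

test_that("condition comparison handles regular and degenerate inputs", {
  # identical samples: t = 0, p = 1
  same <- c(0.3, 0.4, 0.5)
  res <- compare_conditions(same, same)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_true(res$degenerate)

  # constant nonzero difference: flagged, t = +Inf
  res2 <- compare_conditions(c(0.4, 0.5, 0.6, 0.7), c(0.3, 0.4, 0.5, 0.6))
  expect_true(res2$degenerate)
  expect_equal(res2$t, Inf)
  expect_equal(res2$p, 0)

  # hand-computed t for differences (0.1, 0.2, 0.3):
  # mean 0.2, sd 0.1, t = 0.2 / (0.1 / sqrt(3)) = 3.4641
  res3 <- compare_conditions(c(0.3, 0.4, 0.5), c(0.2, 0.2, 0.2))
  expect_equal(res3$t, 3.4641016, tolerance = 1e-6)
  expect_equal(res3$df, 2L)
  expect_false(res3$degenerate)
  # one-sample tests against chance come along
  expect_lt(res3$vs_chance_good$p, 0.05)       # mean 0.4 vs 1/6, sd 0.1
  expect_equal(res3$vs_chance_bad$p, 0)        # constant 0.2 above chance

  expect_error(compare_conditions(0.5, 0.5), "equal length")
})
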