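test_that("the gamma HRF starts at zero and peaks at p*q with unit amplitude", {
  h <- hrf_kernel(hrf_params(), dt = 0.001, duration = 32)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  # analytic peak latency: d/dt log h = p/t - 1/q = 0 at t = p*q = 4.7042 s
  expect_equal((which.max(h) - 1) * 0.001, 8.6 * 0.547, tolerance = 1e-3)
  expect_error(hrf_kernel(hrf_params(), dt = 0), "dt")
  expect_error(hrf_params(p = -1), "positive")
})

test_that("exemplar draws are prototype plus isotropic Gaussian noise", {
  ps <- generate_prototypes(5, separation = 2, seed = 3)
  set.seed(1)
  expect_equal(sample_exemplar_pattern(ps, "beach", 0), ps$prototypes[1, ])
  expect_error(sample_exemplar_pattern(ps, "lagoon", 1), "unknown category")

  set.seed(2)
  draws <- t(replicate(10000, sample_exemplar_pattern(ps, 2, sigma = 1.5)))
  sds <- apply(draws, 2, sd)
  expect_true(all(abs(sds - 1.5) / 1.5 < 0.03))
  mus <- colMeans(draws)
  expect_true(all(abs(mus - ps$prototypes[2, ]) < 4 * 1.5 / sqrt(10000)))
})

test_that("design bookkeeping matches the experiment timings", {
  bd <- block_design()
  expect_equal(bd$duration, 192)
  expect_equal(bd$onsets, c(12, 40, 68, 96, 124, 152))
  expect_equal(block_design(extra_final_fixation = 0)$duration, 180)
  expect_error(block_design(block_duration = 15), "images_per_block")

  ed <- event_design()
  expect_equal(ed$duration, 264)
  expect_equal(length(ed$onsets), 60L)
  expect_equal(diff(ed$onsets)[1], 4)
})

test_that("simulated runs have exact TR bookkeeping and zero activity in fixation", {
  cfg <- tiny_config(n_voxels = 12)
  run <- simulate_block_run(block_design(), cfg, seed = 21, keep_neural = TRUE)
  expect_equal(nrow(run$data), 96L)   # 192 s / 2 s
  expect_equal(ncol(run$data), 12L)

  fine_t <- (seq_len(nrow(run$neural)) - 1) * cfg$fine_dt
  in_block <- Reduce(`|`, lapply(block_design()$onsets, function(o) {
    fine_t >= o & fine_t < o + 16
  }))
  expect_equal(max(abs(run$neural[!in_block, ])), 0)

  erun <- simulate_event_run(event_design(), cfg, seed = 22)
  expect_equal(nrow(erun$data), 132L)  # 264 s / 2 s
  expect_equal(length(erun$labels), 60L)
  expect_true(all(table(erun$labels) == 10L))

  bad_order <- rep(scene_categories()[1], 60)
  expect_error(simulate_event_run(event_design(), cfg, trial_order = bad_order),
               "exactly 10 times")
  expect_error(
    simulate_block_run(block_design(), cfg,
                       category_order = rep("beach", 6)),
    "permutation")
})

test_that("the simulator is deterministic and linear in the prototypes", {
  cfg <- noiseless_config(n_voxels = 8)
  order6 <- scene_categories()
  r1 <- simulate_block_run(block_design(), cfg, category_order = order6,
                           seed = 1)
  r2 <- simulate_block_run(block_design(), cfg, category_order = order6,
                           seed = 99)
  # zero exemplar + measurement noise: identical regardless of seed
  expect_equal(r1$data, r2$data, tolerance = 1e-9)

  # BOLD of summed prototypes = sum of BOLDs (pre-noise linearity)
  cfg_a <- cfg; cfg_b <- cfg; cfg_ab <- cfg
  cfg_b$prototypes$prototypes <- matrix(rnorm(48, sd = 2), 6, 8)
  cfg_ab$prototypes$prototypes <-
    cfg_a$prototypes$prototypes + cfg_b$prototypes$prototypes
  ra <- simulate_block_run(block_design(), cfg_a, category_order = order6)
  rb <- simulate_block_run(block_design(), cfg_b, category_order = order6)
  rab <- simulate_block_run(block_design(), cfg_ab, category_order = order6)
  expect_equal(rab$data, ra$data + rb$data, tolerance = 1e-8)
})

test_that("event GLM betas recover the generating patterns", {
  cfg <- noiseless_config(n_voxels = 10)
  run <- simulate_event_run(event_design(), cfg, seed = 5)
  betas <- event_glm_betas(run)
  expect_equal(dim(betas), c(6L, 10L))
  # noiseless run: per-category betas proportional to the prototypes
  for (cc in rownames(betas)) {
    expect_gt(cor(betas[cc, ], cfg$prototypes$prototypes[cc, ]), 0.999)
  }

  # only one category active -> all other betas vanish
  cfg1 <- cfg
  cfg1$prototypes$prototypes[2:6, ] <- 0
  run1 <- simulate_event_run(event_design(), cfg1, seed = 6)
  b1 <- event_glm_betas(run1)
  inactive <- setdiff(rownames(b1), "beach")
  expect_lt(max(abs(b1[inactive, ])), 1e-6)
  expect_gt(max(abs(b1["beach", ])), 1)

  # a constant offset is absorbed by the intercept
  run_shift <- run
  run_shift$data <- run$data + 7
  expect_equal(event_glm_betas(run_shift), betas, tolerance = 1e-8)

  expect_error(event_glm_betas(simulate_block_run(block_design(), cfg)),
               "event")
})
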