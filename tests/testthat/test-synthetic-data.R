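test_that("prototype generation honors the separation parameter", {
  # zero separation collapses all categories onto one mean
  ps0 <- generate_prototypes(10, separation = 0, seed = 1)
  expect_equal(max(abs(ps0$prototypes)), 0)
  expect_equal(nrow(ps0$prototypes), 6L)

  # seeded determinism: bit-identical output
  a <- generate_prototypes(25, separation = 1.5, seed = 42)
  b <- generate_prototypes(25, separation = 1.5, seed = 42)
  expect_identical(a$prototypes, b$prototypes)

  # mean pairwise distance grows with separation (same seed)
  pairdist <- function(ps) {
    d <- as.matrix(dist(ps$prototypes))
    mean(d[upper.tri(d)])
  }
  wide <- generate_prototypes(25, separation = 2.0, seed = 7)
  narrow <- generate_prototypes(25, separation = 0.5, seed = 7)
  expect_gt(pairdist(wide), pairdist(narrow))
  expect_true(all(is.finite(wide$prototypes)))
  expect_gt(min(dist(wide$prototypes)), 0)

  expect_error(generate_prototypes(1), "n_voxels")
  expect_error(generate_prototypes(10, separation = -1), "separation")
})

test_that("scene-image sets collapse to the template at zero jitter and vary with it", {
  spec0 <- scene_image_spec("forest", dominant_orientation = pi / 2,
                            dominant_frequency = 0.05, jitter_scale = 0,
                            image_size = c(45L, 60L))
  imgs <- generate_scene_image_set(spec0, 3, seed = 1)
  expect_identical(imgs[[1]], imgs[[2]])
  expect_identical(imgs[[2]], imgs[[3]])
  expect_equal(imgs[[1]], scene_image_template(spec0))
  expect_equal(dim(imgs[[1]]), c(45L, 60L, 3L))
  expect_true(all(imgs[[1]] >= 0 & imgs[[1]] <= 1))

  # determinism under a fixed seed
  specj <- scene_image_spec("forest", dominant_frequency = 0.05,
                            jitter_scale = 0.5, image_size = c(45L, 60L))
  s1 <- generate_scene_image_set(specj, 4, seed = 3)
  s2 <- generate_scene_image_set(specj, 4, seed = 3)
  expect_identical(s1, s2)
  expect_false(identical(s1[[1]], s1[[2]]))

  expect_error(generate_scene_image_set(specj, 1), "n_images")
})

test_that("pixel-wise averages of low-jitter sets stay closer to the template", {
  base <- default_scene_specs(image_size = c(90L, 120L))[["mountain"]]
  lo <- scene_image_spec(base$category_id, base$dominant_orientation,
                         base$dominant_frequency, base$palette,
                         jitter_scale = 0.3, image_size = c(90L, 120L))
  hi <- scene_image_spec(base$category_id, base$dominant_orientation,
                         base$dominant_frequency, base$palette,
                         jitter_scale = 1.0, image_size = c(90L, 120L))
  tpl <- scene_image_template(lo)
  mse <- function(a, b) mean((a - b)^2)
  lo_imgs <- generate_scene_image_set(lo, 8, seed = 11)
  hi_imgs <- generate_scene_image_set(hi, 8, seed = 11)
  expect_lt(mse(average_image(lo_imgs), tpl), mse(average_image(hi_imgs), tpl))
})

test_that("rating tables place one check trial per 10 trials, referencing recent trials", {
  tab <- generate_rating_table(4, 44, planted_bad_raters = 0, seed = 5)
  one <- tab[tab$rater_id == "rater_01", ]
  expect_identical(one$trial[one$is_check], c(11L, 22L, 33L, 44L))
  # every check references an earlier trial within the preceding 10
  checks <- tab[tab$is_check, ]
  expect_true(all(checks$refers_to >= checks$trial - 10 &
                  checks$refers_to < checks$trial))
  # the check repeats the image of the referenced trial
  for (i in seq_len(nrow(checks))) {
    ref <- tab[tab$rater_id == checks$rater_id[i] &
               tab$trial == checks$refers_to[i], ]
    expect_identical(checks$image_id[i], ref$image_id)
  }
  expect_true(all(tab$rating %in% 1:5))

  expect_error(generate_rating_table(2, 33, planted_bad_raters = 3),
               "planted_bad_raters")
  expect_error(generate_rating_table(2, 10), "n_trials_per_rater")
})

test_that("consistent raters score zero discount; planted raters exceed the threshold", {
  tab <- generate_rating_table(5, 44, planted_bad_raters = 0, seed = 8)
  ledger <- discount_score(tab)
  expect_true(all(ledger$totals$discount == 0))

  # a planted rater flips category on every check: 4 checks x 5 = 20 > 10
  tab2 <- generate_rating_table(6, 44, planted_bad_raters = 2, seed = 9)
  ledger2 <- discount_score(tab2)
  planted <- attr(tab2, "planted")
  planted_scores <- ledger2$totals$discount[ledger2$totals$rater_id %in% planted]
  expect_true(all(planted_scores >= 15))
  expect_setequal(setdiff(ledger2$totals$rater_id, filter_raters(ledger2)),
                  planted)
})
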