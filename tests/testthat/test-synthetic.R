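test_that("scene generation is deterministic and class-complete", {
  spec <- scene_spec(height = 96, width = 96, bands = 12, seed = 21)
  a <- generate_scene(spec)
  b <- generate_scene(spec)
  expect_identical(a$scene$values, b$scene$values)
  expect_identical(a$labels, b$labels)
  expect_setequal(unique(as.vector(a$labels)), 1:7)
  expect_equal(dim(a$scene$values), c(12, 96, 96))
  expect_true(all(is.finite(a$scene$values)))
})

test_that("separation zero collapses all class spectra to the grand mean", {
  spec <- scene_spec(height = 24, width = 24, bands = 4, n_classes = 3,
                     separation = 0, noise_sd = 0, mixed_pixel_fraction = 0,
                     seed = 22)
  sim <- generate_scene(spec)
  for (b in 1:4) {
    expect_lt(diff(range(sim$scene$values[b, , ])), 1e-12)
  }
})

test_that("vegetation classes carry the near-infrared elevation", {
  # NIR-like band (4th of 4: B/G/R/NIR) exceeds the red band for the
  # vegetation classes and not for water
  spec <- scene_spec(height = 64, width = 64, bands = 4, noise_sd = 0,
                     mixed_pixel_fraction = 0, seed = 23)
  sim <- generate_scene(spec)
  lab <- as.vector(sim$labels)
  nir <- as.vector(sim$scene$values[4, , ])
  red <- as.vector(sim$scene$values[3, , ])
  for (veg in which(spec$class_names %in% c("Sugarcane", "Tree"))) {
    sel <- lab == veg
    expect_true(all(nir[sel] > red[sel]))
  }
  water <- which(spec$class_names == "River")
  expect_true(all(nir[lab == water] < red[lab == water]))
})

test_that("ROI sampling is balanced, label-consistent and deterministic", {
  spec <- scene_spec(height = 96, width = 96, seed = 24)
  sim <- generate_scene(spec)
  roi <- generate_roi(sim$labels, n_per_class = 100, seed = 25)
  expect_equal(nrow(roi), 700)
  expect_equal(unname(table(roi$class_id)), rep(100L, 7), ignore_attr = TRUE)
  got <- sim$labels[cbind(roi$row + 1L, roi$col + 1L)]
  expect_equal(got, roi$class_id)
  roi2 <- generate_roi(sim$labels, n_per_class = 100, seed = 25)
  expect_identical(roi, roi2)
  expect_error(generate_roi(sim$labels, n_per_class = 1e6, seed = 1),
               "cannot draw")
})

test_that("empirical class means converge to the specified spectra", {
  spec <- scene_spec(height = 128, width = 128, bands = 6, noise_sd = 0.02,
                     mixed_pixel_fraction = 0, separation = 1, seed = 26)
  sim <- generate_scene(spec)
  base <- dynspec:::class_signatures(7, 6)
  roi <- generate_roi(sim$labels, n_per_class = 300, seed = 27)
  s <- extract_samples(sim$scene, roi)
  bn <- attr(s, "band_names")
  for (cl in 1:7) {
    emp <- colMeans(as.matrix(s[s$class == cl, bn]))
    # standard error ~ noise_sd / sqrt(300) ~ 0.0012 per band
    expect_lt(max(abs(emp - base[cl, ])), 0.006)
  }
})

test_that("generated data feed every downstream stage without adapters", {
  spec <- scene_spec(height = 48, width = 48, bands = 4, n_classes = 3,
                     seed = 28)
  sim <- generate_scene(spec)
  roi <- generate_roi(sim$labels, 30, seed = 29, class_names = spec$class_names)
  s <- split_samples(extract_samples(sim$scene, roi), 0.6, seed = 30)
  fit <- fit_network(s, small_config(bands = 4, n_classes = 3),
                     train_config(max_epochs = 3, seed = 31))
  rep <- evaluate_network(fit, s)
  expect_s3_class(rep, "metrics_report")
  areas <- class_areas(sim$labels, sim$scene$pixel_size, spec$class_names)
  expect_equal(sum(areas$pixels), 48 * 48)
})

test_that("difficulty sweeps report one row per separation, improving with it", {
  spec <- scene_spec(height = 64, width = 64, bands = 4, n_classes = 3,
                     seed = 32)
  sw <- difficulty_sweep(spec, c(0, 0.5, 1.5), n_per_class = 40,
                         tc = train_config(max_epochs = 8, seed = 33))
  expect_equal(nrow(sw), 3)
  expect_equal(sw$separation, c(0, 0.5, 1.5))
  # rank correlation between separation and accuracy is positive
  expect_gt(cor(sw$separation, sw$oa, method = "spearman"), 0)
  # chance level at zero separation (3 classes, 99% binomial interval)
  n <- sw$n_test[1]
  half <- stats::qnorm(0.995) * sqrt((1 / 3) * (2 / 3) / n) * 100
  expect_lt(abs(sw$oa[1] - 100 / 3), half + 1e-9)
})
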