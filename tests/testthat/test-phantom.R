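# Smaller-than-default phantoms keep the rendering loops fast while
# preserving the class geometry; the default study-scale phantom is
# exercised in the end-to-end recovery tests.
small_counts <- c(epithelial = 4L, leukocyte = 10L, bacteria = 40L,
                  debris = 6L)

test_that("phantom rendering is deterministic and honours the spec", {
  spec <- phantom_spec(seed = 7, image_shape_px = c(320L, 320L),
                       n_per_class = small_counts)
  a <- render_phantom(spec)
  b <- render_phantom(spec)
  expect_identical(a$low$pixels, b$low$pixels)
  expect_identical(a$high$pixels, b$high$pixels)
  expect_identical(a$truth, b$truth)
  expect_identical(as.vector(table(a$truth$true_class)[names(small_counts)]),
                   as.vector(small_counts))
  expect_identical(a$low$exposure_class, "low")
  expect_identical(a$high$exposure_class, "high")
  # truth areas respect the class taxonomy
  tr <- a$truth
  expect_true(all(tr$true_area_um2[tr$true_class == "epithelial"] > 500))
  expect_true(all(tr$true_area_um2[tr$true_class == "bacteria"] < 30))
  lk <- tr$true_area_um2[tr$true_class == "leukocyte"]
  expect_true(all(lk >= 30 & lk <= 500))
})

test_that("an empty spec renders a background-only image with empty truth", {
  spec <- phantom_spec(seed = 1, image_shape_px = c(64L, 64L),
                       n_per_class = c(epithelial = 0L, leukocyte = 0L,
                                       bacteria = 0L, debris = 0L),
                       noise_sd = 0)
  ph <- render_phantom(spec)
  expect_identical(nrow(ph$truth), 0L)
  expect_identical(length(unique(as.vector(ph$low$pixels[, , 2]))), 1L)
  expect_identical(which(binarize(ph$low)), integer(0))
})

test_that("phantom spec validation lists every offending field", {
  expect_error(phantom_spec(area_dist = list(
    epithelial = c(median_um2 = 400, sdlog = 0.2),   # below 500: invalid
    leukocyte = c(median_um2 = 90, sdlog = 0.2),
    bacteria = c(median_um2 = 40, sdlog = 0.2),      # above 30: invalid
    debris = c(median_um2 = 12, sdlog = 0.2))),
    "epithelial median.*bacteria median")
  expect_error(phantom_spec(edge_fraction = 1.5), "edge_fraction")
  expect_error(phantom_spec(leukocyte_red_shift = 0.5), "red_shift")
})

test_that("placement failure is reported with the number of objects placed", {
  spec <- phantom_spec(seed = 3, image_shape_px = c(128L, 128L),
                       n_per_class = c(epithelial = 60L, leukocyte = 0L,
                                       bacteria = 0L, debris = 0L))
  expect_error(render_phantom(spec), "placed \\d+ of 60",
               class = "aosediment_placement_error")
})

test_that("measured areas track truth areas within rasterisation tolerance", {
  spec <- phantom_spec(seed = 9, image_shape_px = c(420L, 420L),
                       n_per_class = c(epithelial = 6L, leukocyte = 14L,
                                       bacteria = 20L, debris = 0L),
                       noise_sd = 0)
  ph <- render_phantom(spec)
  cfg <- calibration_config(pixel_size_um = spec$pixel_size_um)
  tab <- analyze_fov(ph$low, cfg)
  m <- match_objects_to_truth(tab, ph$truth)
  big <- m[m$true_area_px >= 50 & !is.na(m$measured_area_um2), ]
  expect_gt(nrow(big), 0)
  rel_err <- abs(big$measured_area_um2 - big$true_area_um2) /
    big$true_area_um2
  expect_true(all(rel_err <= 0.05))
})

test_that("class recovery degrades monotonically on average as noise grows", {
  noise_levels <- c(2, 25, 60)
  seeds <- 1:10
  recovery <- sapply(noise_levels, function(ns) {
    mean(sapply(seeds, function(s) {
      spec <- phantom_spec(seed = s, image_shape_px = c(320L, 320L),
                           n_per_class = small_counts, noise_sd = ns)
      ph <- render_phantom(spec)
      cfg <- calibration_config(pixel_size_um = spec$pixel_size_um)
      tab <- analyze_fov(ph$low, cfg)
      m <- match_objects_to_truth(tab, ph$truth)
      mean(!is.na(m$measured_label) & m$measured_label == m$true_class)
    }))
  })
  expect_true(all(diff(recovery) <= 1e-9))
  expect_gt(recovery[1], 0.95)
})

test_that("saturated-core phantoms are excluded at exactly the truth rate", {
  spec <- phantom_spec(seed = 13, image_shape_px = c(420L, 420L),
                       n_per_class = c(epithelial = 8L, leukocyte = 16L,
                                       bacteria = 30L, debris = 4L),
                       saturation_fraction = 0.25)
  ph <- render_phantom(spec)
  cfg <- calibration_config(pixel_size_um = spec$pixel_size_um)
  tab <- analyze_fov(ph$low, cfg)
  rep <- enumerate_specimen(tab, "sat", n_fovs = 1)
  expect_gt(sum(ph$truth$is_saturated), 0)
  expect_identical(rep$excluded$saturation,
                   sum(ph$truth$is_saturated & !ph$truth$touches_edge))
})

test_that("rating fixtures are seeded and unanimous at zero disagreement", {
  spec <- phantom_spec(seed = 11, n_per_class = small_counts)
  rt0 <- render_rating_fixture(spec, n_raters = 3, disagreement_rate = 0)
  expect_identical(nrow(rt0), 3L * sum(small_counts))
  for (cl in unique(rt0$label)) {
    expect_equal(as.numeric(percent_agreement(rt0, cl)), 100)
  }
  r1 <- render_rating_fixture(spec, n_raters = 3, disagreement_rate = 0.2)
  r2 <- render_rating_fixture(spec, n_raters = 3, disagreement_rate = 0.2)
  expect_identical(r1, r2)
  expect_error(render_rating_fixture(spec, n_raters = 1,
                                     disagreement_rate = 0), "2 raters")
})
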