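cfg_default <- calibration_config(pixel_size_um = 0.5)

test_that("the area rule partitions [0, Inf) with closed leukocyte boundaries", {
  expect_identical(classify_by_area(600, cfg_default), "epithelial")
  expect_identical(classify_by_area(25, cfg_default), "bacteria")
  expect_identical(classify_by_area(100, cfg_default), "leukocyte")
  # boundary convention: the thresholds are strict, so 30 and 500 um^2
  # both fall to the leukocyte interval
  expect_identical(classify_by_area(c(30, 500), cfg_default),
                   rep("leukocyte", 2))

  set.seed(41)
  areas <- c(0, runif(200, 0, 1500), 10^runif(50, -2, 4))
  cls <- classify_by_area(areas, cfg_default)
  expect_true(all(cls %in% c("epithelial", "leukocyte", "bacteria")))
  # monotone: every bacteria area < every leukocyte area < every epithelial
  expect_true(max(c(-Inf, areas[cls == "bacteria"])) <
                min(c(Inf, areas[cls == "leukocyte"])))
  expect_true(max(c(-Inf, areas[cls == "leukocyte"])) <=
                min(c(Inf, areas[cls == "epithelial"])))
  expect_error(classify_by_area(-1, cfg_default), "non-negative")
})

test_that("object classification follows the stated precedence", {
  row <- function(area, focus = 0.6, rg = 0.3, edge = FALSE, sat = FALSE) {
    data.frame(area_um2 = area, rg_ratio = rg, focus_score = focus,
               touches_edge = edge, has_saturation = sat)
  }
  expect_identical(classify_object(row(25), cfg_default), "bacteria")
  expect_identical(classify_object(row(20, focus = 0.1), cfg_default),
                   "debris")
  expect_identical(classify_object(row(600, edge = TRUE), cfg_default),
                   "excluded")
  expect_identical(classify_object(row(100, sat = TRUE), cfg_default),
                   "excluded")
  # exclusion outranks the debris rule
  expect_identical(classify_object(row(20, focus = 0.1, edge = TRUE),
                                   cfg_default), "excluded")
  # undefined RG ratio forces debris
  expect_identical(classify_object(row(100, rg = NA), cfg_default), "debris")
  # large in-focus epithelial cells are never debris, whatever the score
  expect_identical(classify_object(row(800, focus = 0.0), cfg_default),
                   "epithelial")
  expect_identical(classify_object(row(100), cfg_default), "leukocyte")
})

test_that("classification requires exclusion flags to be set", {
  ft <- data.frame(area_um2 = 10, rg_ratio = 0.2, focus_score = 0.5,
                   touches_edge = NA, has_saturation = NA)
  expect_error(classify_objects(ft, cfg_default), "flag_exclusions")
})

test_that("range categories tile the integers as in clinical reporting", {
  expected <- c(rep("Trace (0–2)", 3),      # 0, 1, 2
                rep("Few (3–10)", 8),       # 3..10
                rep("Moderate (11–25)", 15),# 11..25
                "Many (>25)")                    # 26
  got <- to_range_category(0:26)
  expect_identical(got, expected)
  # each count maps to exactly one category
  expect_identical(length(got), 27L)
  expect_identical(to_range_category(4), "Few (3–10)")
  expect_identical(to_range_category(22), "Moderate (11–25)")
  expect_identical(to_range_category(1000), "Many (>25)")
  expect_error(to_range_category(-1), "non-negative")
})

test_that("percent agreement matches hand-counted and oracle values", {
  # three raters, unanimous: 100% for every assigned class
  un <- make_unanimous_ratings(rep(c("bacteria", "leukocyte"), 5))
  for (cl in c("bacteria", "leukocyte")) {
    expect_equal(as.numeric(percent_agreement(un, cl)), 100)
  }
  expect_true(is.na(percent_agreement(un, "epithelial")))

  # two raters, four objects, one bacteria->debris flip: 3 of 4
  # bacteria-involving pairs agree
  a <- data.frame(object_id = sprintf("o%d", 1:4), rater_id = "A",
                  label = "bacteria", stringsAsFactors = FALSE)
  b <- a; b$rater_id <- "B"; b$label[4] <- "debris"
  flip <- rbind(a, b)
  expect_equal(as.numeric(percent_agreement(flip, "bacteria")), 75)
  expect_equal(attr(percent_agreement(flip, "bacteria"), "n_pairs"), 4L)

  expect_error(percent_agreement(a, "bacteria"), "two raters")

  # seeded noisy fixture against the exhaustive pair-count oracle
  spec <- phantom_spec(seed = 5, n_per_class = c(epithelial = 10,
                                                 leukocyte = 30,
                                                 bacteria = 100,
                                                 debris = 20))
  rt <- render_rating_fixture(spec, n_raters = 3, disagreement_rate = 0.15)
  for (cl in c("epithelial", "leukocyte", "bacteria", "debris")) {
    expect_equal(as.numeric(percent_agreement(rt, cl)),
                 oracle_agreement(rt, cl))
  }
})

test_that("agreement_table reports one row per class", {
  un <- make_unanimous_ratings(rep("bacteria", 6))
  at <- agreement_table(un)
  expect_identical(at$class, c("epithelial", "leukocyte", "bacteria",
                               "debris"))
  expect_equal(at$percent[at$class == "bacteria"], 100)
  expect_true(all(is.na(at$percent[at$class != "bacteria"])))
})

test_that("specimen enumeration aggregates counts, means, categories and exclusions", {
  mk <- function(fov, label, reason = NA_character_, n = 1) {
    data.frame(fov_id = fov, label = label, excluded_reason = reason,
               stringsAsFactors = FALSE)[rep(1, n), ]
  }
  one <- mk("f1", "bacteria", n = 4)
  rep1 <- enumerate_specimen(one, "s1", n_fovs = 1)
  expect_identical(unlist(rep1$counts),
                   c(epithelial = 0L, leukocyte = 0L, bacteria = 4L))
  expect_identical(rep1$categories$bacteria, "Few (3–10)")

  two <- rbind(mk("f1", "bacteria", n = 3), mk("f2", "bacteria", n = 5))
  rep2 <- enumerate_specimen(two, "s2")
  expect_identical(rep2$counts$bacteria, 8L)
  expect_equal(rep2$per_fov_mean$bacteria, 4.0)
  expect_identical(rep2$n_fovs, 2L)

  mixed <- rbind(mk("f1", "leukocyte", n = 7),
                 mk("f1", "debris", n = 2),
                 mk("f1", "excluded", reason = "edge", n = 3),
                 mk("f1", "excluded", reason = "saturation", n = 1))
  rep3 <- enumerate_specimen(mixed, "s3", n_fovs = 1, n_subfloor = 5)
  expect_identical(unlist(rep3$excluded),
                   c(edge = 3L, saturation = 1L, subfloor = 5L, debris = 2L))
  expect_identical(rep3$total_detections, nrow(mixed) + 5L)
  # conservation: counts + exclusions = detections
  expect_identical(sum(unlist(rep3$counts)) + sum(unlist(rep3$excluded)),
                   rep3$total_detections)

  expect_error(enumerate_specimen(one, "s", n_fovs = 0), "at least one")
})
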