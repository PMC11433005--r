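test_that("ROI statistics are exact on constructed images", {
  img <- uniform_image(100)
  st <- roi_stats(img, roi_spec(c(100, 100), 0.1))
  expect_equal(st$mean, 100); expect_equal(st$sd, 0)
  expect_gte(st$n_pixels, 30)
  # half 100 / half 200 split through the ROI center: mean 150, sd 50
  px <- matrix(100, 200, 200); px[, 101:200] <- 200
  img2 <- bmode_image(px, 0.02)
  st2 <- roi_stats(img2, roi_spec(c(100, 100.5), 0.1))
  expect_equal(st2$mean, 150); expect_equal(st2$sd, 50)
})

test_that("ROI geometry violations raise classed errors", {
  img <- uniform_image(100)
  expect_error(roi_stats(img, roi_spec(c(3, 100), 0.1)), class = "geometry_error")
  # spacing so coarse the ROI covers < 30 px
  coarse <- bmode_image(matrix(100, 50, 50), 0.5)
  expect_error(roi_stats(coarse, roi_spec(c(25, 25), 0.1)),
               class = "resolution_error")
})

test_that("hepatic-renal ratio enforces area and depth-match tolerances", {
  img <- uniform_image(100)
  expect_equal(hepatic_renal_ratio(img, roi_spec(c(100, 60), 0.1),
                                   roi_spec(c(100, 140), 0.1)), 1.0)
  expect_error(hepatic_renal_ratio(img, roi_spec(c(100, 60), 0.2),
                                   roi_spec(c(100, 140), 0.1)),
               class = "roi_area_error")
  # depths 1.0 mm vs 2.0 mm differ by far more than 10%
  expect_error(hepatic_renal_ratio(img, roi_spec(c(50, 60), 0.1),
                                   roi_spec(c(100, 140), 0.1)),
               class = "depth_error")
})

test_that("hepatic-portal ratio divides liver by portal lumen mean, guarding zero", {
  px <- matrix(90, 200, 200); px[, 101:200] <- 30
  img <- bmode_image(px, 0.02)
  expect_equal(hepatic_portal_ratio(img, roi_spec(c(100, 50), 0.1),
                                    roi_spec(c(100, 150), 0.1)), 3.0)
  expect_equal(hepatic_portal_ratio(uniform_image(80), roi_spec(c(100, 50), 0.1),
                                    roi_spec(c(100, 150), 0.1)), 1.0)
  dark <- bmode_image(matrix(0, 200, 200), 0.02)
  expect_error(hepatic_portal_ratio(dark, roi_spec(c(100, 50), 0.1),
                                    roi_spec(c(100, 150), 0.1)),
               class = "division_guard_error")
})

test_that("phantom hepatic-renal ratio is gain-invariant pre-quantization", {
  sp <- liver_kidney_phantom_spec(94.8, 120, seed = 6)
  img <- generate_phantom(sp, quantize = FALSE)
  l <- roi_spec(c(300, 170), 0.1); c <- roi_spec(c(300, 480), 0.1)
  hr1 <- roi_stats(img, l)$mean / roi_stats(img, c)$mean
  img$pixels <- img$pixels * 1.7        # global linear gain
  hr2 <- roi_stats(img, l)$mean / roi_stats(img, c)$mean
  expect_equal(hr2, hr1, tolerance = 1e-12)
})

test_that("GLH analysis reports plane means, heterogeneity and anisotropy", {
  planes <- c("left_lobe_long", "caudate_long", "right_median_axial")
  imgs <- setNames(lapply(c(90, 100, 110), uniform_image), planes)
  roi <- roi_spec(c(100, 100), 1)
  g <- glh_analysis(imgs, roi)
  expect_equal(unname(g$glh_means), c(90, 100, 110))
  expect_equal(g$heterogeneity, 0)
  expect_equal(g$anisotropy, sqrt(200 / 3), tolerance = 1e-12)  # population SD
  # all-equal planes: both dispersion measures are zero
  g0 <- glh_analysis(setNames(lapply(rep(100, 3), uniform_image), planes), roi)
  expect_equal(g0$heterogeneity, 0); expect_equal(g0$anisotropy, 0)
  # a missing plane is an incomplete set
  expect_error(glh_analysis(imgs[1:2], roi), class = "incomplete_set_error")
  # GLH ROIs are the 1 mm^2 protocol, not the 0.1 mm^2 one
  expect_error(glh_analysis(imgs, roi_spec(c(100, 100), 0.1)),
               class = "roi_area_error")
})

test_that("portal vein diameter converts pixel distance to mm isotropically", {
  img <- uniform_image(100, spacing = 0.02)
  expect_equal(pv_diameter(img, rbind(c(50, 50), c(50, 100))), 1.0)
  d_axis <- pv_diameter(img, rbind(c(20, 20), c(20, 70)))
  d_diag <- pv_diameter(img, rbind(c(20, 20), c(20 + 50 / sqrt(2), 20 + 50 / sqrt(2))))
  expect_equal(d_axis, d_diag, tolerance = 1e-9)
  expect_error(pv_diameter(img, rbind(c(50, 50), c(50, 50))),
               class = "degenerate_measurement_error")
  expect_error(pv_diameter(img, rbind(c(50, 50), c(50, 500))),
               class = "geometry_error")
})

test_that("visual grade frequency table reproduces count arithmetic", {
  # 24-week WD females: 5/8 at echostructure pattern 2, 3/8 at pattern 3
  grades <- tibble::tibble(
    group = "WD_F_24w",
    echostructure = c(2, 2, 2, 2, 2, 3, 3, 3),
    echogenicity_vs_cortex = c(0, 0, 1, 1, 1, 1, 1, 1),
    ascites = 0)
  tab <- grade_frequency_table(grades)
  es <- tab[tab$category == "echostructure", ]
  expect_equal(es$pct[es$level == 2], 62.5)
  expect_equal(es$pct[es$level == 3], 37.5)
  # percentages sum to 100 per category
  sums <- tapply(tab$pct, tab$category, sum)
  expect_true(all(abs(sums - 100) < 0.01))
  # out-of-vocabulary scores are rejected
  bad <- grades; bad$echostructure[1] <- 5
  expect_error(grade_frequency_table(bad), class = "validation_error")
  # empty factor level: zero counts, undefined percentages
  grades$group <- factor(grades$group, levels = c("WD_F_24w", "SD_F_24w"))
  tab2 <- grade_frequency_table(grades)
  empty <- tab2[tab2$group == "SD_F_24w", ]
  expect_true(all(empty$n == 0))
  expect_true(all(is.nan(empty$pct)))
})
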