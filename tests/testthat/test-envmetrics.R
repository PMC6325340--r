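test_that("nodule size filter keeps the closed 0.5-60 cm2 interval", {
  expect_equal(filter_nodules(c(0.4, 0.5, 5, 60, 61)), c(0.5, 5, 60))
  expect_equal(filter_nodules(numeric(0)), numeric(0))
  expect_error(filter_nodules(c(1, -2)), "negative")
  set.seed(1)
  x <- runif(1000, 0, 100)
  expect_equal(length(filter_nodules(x)), sum(x >= 0.5 & x <= 60))
})

test_that("per-image and per-unit nodule cover arithmetic is exact", {
  images <- data.frame(image_id = c("a", "b", "c"), unit = "u1",
                       footprint = 1.71, stringsAsFactors = FALSE)
  nodules <- data.frame(image_id = c("a", "a", "b"),
                        area_cm2 = c(1000, 710, 1710))
  nc <- nodule_cover(nodules, images = images, size_range = c(0, Inf))
  expect_equal(nc$images$cover, c(10, 10, 0))
  expect_equal(nc$units$cover, 20 / 3)          # unweighted mean of 10,10,0
  expect_equal(nc$units$total_m2, 3420 / 1e4)
  # unit cover lies within the per-image range
  expect_gte(nc$units$cover, min(nc$images$cover))
  expect_lte(nc$units$cover, max(nc$images$cover))
  expect_error(nodule_cover(nodules,
                            images = transform(images, footprint = 0)),
               "zero")
  # the default size filter drops out-of-range detections before cover
  nf <- nodule_cover(nodules, images = images)
  expect_true(all(nf$images$cover == 0))   # all toy areas exceed 60 cm2
})

test_that("a ~10% cover unit over ~1320 m2 carries ~134 m2 of nodules", {
  # consistency of the two cover currencies: percent and absolute area
  images <- data.frame(image_id = as.character(1:774), unit = "u1",
                       footprint = 1324 / 774, stringsAsFactors = FALSE)
  per_img <- 0.101 * (1324 / 774) * 1e4
  nodules <- data.frame(image_id = as.character(1:774), area_cm2 = per_img)
  nc <- nodule_cover(nodules, images = images, size_range = c(0, Inf))
  expect_equal(nc$units$cover, 10.1, tolerance = 1e-9)
  expect_equal(nc$units$total_m2, 133.7, tolerance = 0.01)
})

test_that("grain statistics follow the geometric method of moments", {
  expect_equal(grain_stats(cbind(4, 16), 1)$gm_size_um, 8)
  expect_equal(grain_stats(cbind(4, 16), 1)$mud_pct, 100)
  gs <- grain_stats(rbind(c(2, 8), c(8, 32)), c(0.5, 0.5))
  expect_equal(gs$gm_size_um, sqrt(4 * 16))     # symmetry in ln space
  # three-class worked example against direct ln-space summation
  b <- rbind(c(1, 4), c(4, 16), c(16, 63))
  f <- c(0.2, 0.5, 0.3)
  mids <- sqrt(b[, 1] * b[, 2])
  expect_equal(grain_stats(b, f)$gm_size_um, exp(sum(f * log(mids))))
  # scale equivariance
  expect_equal(grain_stats(b * 3, f)$gm_size_um,
               3 * grain_stats(b, f)$gm_size_um)
  # straddling class prorated linearly in ln size
  gs2 <- grain_stats(rbind(c(8, 63), c(63, 252)), c(0.5, 0.5))
  expect_equal(gs2$mud_pct, 50)
  gs3 <- grain_stats(cbind(31.5, 126), 1)
  expect_equal(gs3$mud_pct, 100 * log(63 / 31.5) / log(126 / 31.5))
  expect_error(grain_stats(cbind(4, 16), 0), "all-zero")
})

test_that("carbonate and molar C:N arithmetic matches direct computation", {
  expect_equal(carbonate_cn(0.42, 0.42, 0.1)$caco3_pct, 0)
  expect_equal(carbonate_cn(0.46, 0.42, 0.1)$caco3_pct,
               0.04 * 100.09 / 12.01)
  expect_equal(carbonate_cn(0.46, 0.42)$caco3_pct, 0.333, tolerance = 0.002)
  expect_equal(carbonate_cn(0.46, 0.42, 0.1225)$cn_molar,
               (0.42 / 12.01) / (0.1225 / 14.007))
  expect_equal(carbonate_cn(0.46, 0.42, 0.1225)$cn_molar, 4.0,
               tolerance = 0.001)
  expect_error(carbonate_cn(0.40, 0.42, 0.1), "TC < TOC")
  expect_warning(out <- carbonate_cn(0.46, 0.42, 0), "undefined")
  expect_true(is.na(out$cn_molar))
  # non-negativity whenever preconditions hold
  set.seed(2)
  toc <- runif(50, 0, 1); tc <- toc + runif(50, 0, 1); tn <- runif(50, 0.01, 1)
  out <- carbonate_cn(tc, toc, tn)
  expect_true(all(out$caco3_pct >= 0) && all(out$cn_molar >= 0))
})

test_that("synthetic sediment samples reproduce the target chemistry", {
  sed <- generate_sediment(seed = 9)
  expect_equal(nrow(sed), 15)
  bounds <- attr(sed, "bounds_um")
  fcols <- grep("^f_", names(sed))
  g <- grain_stats(bounds, as.numeric(sed[1, fcols]))
  expect_gt(g$mud_pct, 80)
  expect_true(g$gm_size_um > 4 && g$gm_size_um < 20)
  chem <- carbonate_cn(sed$tc, sed$toc, sed$tn)
  expect_equal(mean(chem$cn_molar[sed$area == "Flat"]), 4.0, tolerance = 0.3)
  expect_lt(abs(mean(sed$toc[sed$area == "Flat"]) - 0.42), 0.06)
})
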