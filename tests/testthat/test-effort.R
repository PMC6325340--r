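test_that("a constant parameter has zero CV at every size", {
  std <- small_survey()
  pool <- effort_pool(std, "Flat")
  cv <- resample_parameter(pool, function(cnt, a, b) 7,
                           sizes = c(10, 50, 100), reps = 50, seed = 1)
  expect_true(all(cv$cv == 0))
  expect_true(all(cv$centre == 7))
})

test_that("full-pool draws without replacement reproduce the pooled value exactly", {
  std <- small_survey()
  pool <- effort_pool(std, "Ridge")
  res <- resample_parameter(pool, "density", sizes = pool$n_images,
                            reps = 20, replace = FALSE, seed = 2)
  expect_equal(res$cv, 0)
  expect_equal(res$centre,
               sum(pool$counts) / sum(pool$footprint), tolerance = 1e-12)
  expect_equal(res$mean_individuals, sum(pool$counts))
  expect_equal(res$mean_area_m2, sum(pool$footprint), tolerance = 1e-9)
})

test_that("mean individuals per size equals the counts of the drawn images", {
  std <- small_survey()
  pool <- effort_pool(std, "Flat")
  res <- resample_parameter(pool, "density", sizes = c(20, 80), reps = 100,
                            seed = 3)
  # at any size, E[individuals] = size x mean per-image count
  per_img <- sum(pool$counts) / pool$n_images
  expect_equal(res$mean_individuals, res$size * per_img, tolerance = 0.1)
  expect_true(all(diff(res$mean_area_m2) > 0))
})

test_that("autosimilarity is 100% for identical single-species images", {
  counts <- matrix(3L, nrow = 40, ncol = 1,
                   dimnames = list(paste0("i", 1:40), "sp1"))
  pool <- structure(list(counts = counts, footprint = rep(1.71, 40),
                         biovolume = rep(0.5, 40), area = "X",
                         n_images = 40L), class = "effort_pool")
  res <- autosimilarity(pool, sizes = c(5, 10, 20), reps = 30, seed = 4)
  expect_true(all(res$centre == 100))
})

test_that("autosimilarity is bounded and rises with size on homogeneous pools", {
  std <- small_survey()
  pool <- effort_pool(std, "Flat")
  sizes <- c(20, 60, 180, floor(pool$n_images / 2))
  res <- autosimilarity(pool, sizes = sizes, reps = 200, seed = 5)
  expect_true(all(res$centre >= 0 & res$centre <= 100))
  expect_true(all(diff(res$centre) > 0))
  # infeasible sizes are skipped with a warning
  expect_warning(autosimilarity(pool, sizes = c(10, pool$n_images),
                                reps = 5, seed = 6), "skipped")
})

test_that("stabilization detection follows its definition on shaped curves", {
  mk <- function(centres, sizes = seq_along(centres)) {
    structure(data.frame(size = sizes, mean_area_m2 = sizes * 1.71,
                         mean_individuals = sizes * 0.8, centre = centres,
                         cv = 0, lo = centres, hi = centres, reps = 10,
                         replace = TRUE),
              class = c("effort_curve", "data.frame"), parameter = "toy")
  }
  flat <- detect_stabilization(mk(rep(5, 8)))
  expect_true(flat$reached)
  expect_equal(flat$size_images, 1)
  # step curve: jumps at the 5th grid point, flat afterwards
  step <- detect_stabilization(mk(c(1, 1, 1, 1, 10, 10, 10, 10)))
  expect_true(step$reached)
  expect_equal(step$size_images, 5)
  # never stabilizes inside the tolerance band
  wild <- detect_stabilization(mk(c(1, 9, 2, 8, 3, 9, 1, 20)), window = 3)
  expect_false(wild$reached)
})

test_that("density CV shrinks as size^(-1/2) on a homogeneous Poisson community", {
  # direct Poisson image pool: the sampling-theory oracle predicts a
  # log-log slope of -1/2 for the CV of a bootstrap mean
  set.seed(7)
  n <- 600
  counts <- matrix(rpois(n, 1.2), ncol = 1,
                   dimnames = list(paste0("i", 1:n), "sp1"))
  pool <- structure(list(counts = counts, footprint = rep(1.71, n),
                         biovolume = rep(0, n), area = "X", n_images = n),
                    class = "effort_pool")
  sizes <- c(10, 20, 40, 80, 160, 320)
  res <- resample_parameter(pool, "density", sizes = sizes, reps = 200,
                            seed = 8)
  slope <- coef(lm(log(res$cv) ~ log(res$size)))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.1)
  # accuracy is immediate: the centre is flat across sizes
  expect_lt(max(abs(res$centre - mean(res$centre))) / mean(res$centre), 0.05)
})

test_that("richness stabilizes later than density on a long-tailed community", {
  std <- small_survey()
  pool <- effort_pool(std, "Flat")
  sizes <- effort_sizes(pool, n_points = 10)
  dens <- resample_parameter(pool, "density", sizes, reps = 150, seed = 9)
  rich <- resample_parameter(pool, "richness", sizes, reps = 150,
                             replace = FALSE, seed = 10)
  sd_ <- detect_stabilization(dens)
  sr <- detect_stabilization(rich)
  expect_true(sd_$reached)
  expect_true(!sr$reached || sr$size_images > sd_$size_images)
})
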