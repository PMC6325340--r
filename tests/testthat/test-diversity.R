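test_that("biovolume is the ellipsoid of revolution with correct scaling", {
  d <- 10
  expect_equal(biovolume(d, d), pi * d^3 / 6 / 1000)      # sphere
  expect_equal(biovolume(100, 10), 5.236, tolerance = 1e-4)
  expect_equal(biovolume(100, 10) * 1000, pi / 6 * 100 * 100,
               tolerance = 1e-9)
  expect_equal(biovolume(50, 20), 4 * biovolume(50, 10))  # W doubling
  expect_error(biovolume(0, 1), "positive")
  expect_error(biovolume(5, 10), "exceed")
})

test_that("Hill numbers match direct summation and their ordering", {
  expect_equal(unname(hill_numbers(rep(7, 4))), c(4, 4, 4))
  expect_equal(unname(hill_numbers(c(0, 5, 0))), c(1, 1, 1))
  h <- hill_numbers(c(1, 2, 3))
  expect_equal(h[["S"]], 3)
  expect_equal(h[["expH"]], 2.7496, tolerance = 1e-4)
  expect_equal(h[["invD"]], 2.5714, tolerance = 1e-4)
  expect_error(hill_numbers(c(0, 0)), "empty")
  # ordering S >= expH >= invD >= 1 on random count vectors
  set.seed(3)
  for (i in 1:200) {
    cnt <- rpois(sample(2:30, 1), lambda = rexp(1, 0.2))
    if (sum(cnt) == 0) next
    h <- hill_numbers(cnt)
    expect_true(h[["S"]] >= h[["expH"]] - 1e-12 &&
                  h[["expH"]] >= h[["invD"]] - 1e-12 &&
                  h[["invD"]] >= 1 - 1e-12)
  }
})

test_that("unit densities are count over area, overall and by guild", {
  std <- small_survey()
  ab <- abundance_table(std)
  m <- unit_metrics(ab)
  expect_equal(m$density, m$n / m$area_m2)
  # density x area = count, exactly
  expect_equal(m$density * m$area_m2, rowSums(ab$counts)[m$unit],
               ignore_attr = TRUE)
  # guild densities sum to the total (metazoans all carry a guild)
  expect_equal(m$density_SF + m$density_DF + m$density_PS, m$density,
               tolerance = 1e-12)
})

test_that("worked density examples divide exactly", {
  expect_equal(647 / 1320, 0.4902, tolerance = 1e-4)
  counts <- c(SF = 390, DF = 80, PS = 20)
  expect_equal(unname(counts / 1000), c(0.39, 0.08, 0.02))
})

test_that("K-dominance curves are monotone, end at 100%, and handle ties", {
  k1 <- k_dominance(matrix(c(5, 0, 0), 1))
  expect_true(all(k1$mean == 100))
  k2 <- k_dominance(matrix(c(3, 1), 1))
  expect_equal(k2$mean, c(75, 100))
  # identical replicate units give a zero-width interval
  k3 <- k_dominance(rbind(c(4, 3, 2, 1), c(4, 3, 2, 1)))
  expect_equal(k3$lo, k3$hi)
  # monotone non-decreasing to 100 on random tables
  set.seed(4)
  for (i in 1:50) {
    cnt <- matrix(rpois(12, 3), 3, 4)
    if (any(rowSums(cnt) == 0)) next
    kd <- k_dominance(cnt)
    expect_true(all(diff(kd$mean) >= -1e-12))
    expect_equal(kd$mean[nrow(kd)], 100)
  }
})
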