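test_that("BPI and TRI vanish on a constant grid and BPI is forced at a peak", {
  g <- bathy_grid(matrix(4100, 25, 25), cell_size = 100)
  expect_true(all(abs(compute_bpi(g, 150, 600)) < 1e-9))
  expect_true(all(compute_tri(g, 300) == 0))

  d <- matrix(4100, 25, 25)
  d[13, 13] <- 4090  # single-cell peak, 10 m shallower
  gp <- bathy_grid(d, cell_size = 100)
  bpi <- compute_bpi(gp, 150, 600)
  expect_equal(bpi[13, 13], 10, tolerance = 1e-9)
})

test_that("BPI matches the brute-force annulus oracle on random grids", {
  for (s in 1:3) {
    set.seed(s)
    d <- matrix(4100 + rnorm(30 * 30, sd = 20), 30, 30)
    g <- bathy_grid(d, cell_size = 100)
    expect_equal(compute_bpi(g, 150, 700), brute_bpi(d, 100, 150, 700),
                 tolerance = 1e-8)
  }
})

test_that("sinusoidal ridges get positive crest and negative trough BPI", {
  x <- (1:80) * 100
  d <- matrix(rep(4100 - 50 * sin(2 * pi * x / 5000), each = 40), 40, 80)
  g <- bathy_grid(d, cell_size = 100)
  bpi <- compute_bpi(g, 500, 4000)
  crest <- which.min(d[1, ]); trough <- which.max(d[1, ])
  expect_gt(bpi[20, crest], 0)
  expect_lt(bpi[20, trough], 0)
})

test_that("TRI matches the brute-force neighbourhood oracle and its slope form", {
  for (s in 1:3) {
    set.seed(s + 10)
    d <- matrix(4100 + rnorm(30 * 30, sd = 20), 30, 30)
    g <- bathy_grid(d, cell_size = 100)
    expect_equal(compute_tri(g, 250), brute_tri(d, 100, 250),
                 tolerance = 1e-9)
  }
  # uniform east-west slope, 1-cell radius: interior neighbourhood is the
  # 4-cell rook move set, two neighbours differ by s, two by 0
  d <- matrix(rep(4000 + 2 * (1:20), each = 20), 20, 20) # 2 m per cell
  g <- bathy_grid(d, cell_size = 100, depth_range = NULL)
  tri <- compute_tri(g, 100)
  expect_equal(tri[10, 10], (2 + 2 + 0 + 0) / 4, tolerance = 1e-12)
})

test_that("terrain derivatives are invariant to a constant depth shift", {
  set.seed(99)
  d <- matrix(4100 + rnorm(25 * 25, sd = 15), 25, 25)
  g1 <- bathy_grid(d, cell_size = 100)
  g2 <- bathy_grid(d + 40, cell_size = 100)
  expect_equal(compute_bpi(g2, 150, 600), compute_bpi(g1, 150, 600),
               tolerance = 1e-9)
  expect_equal(compute_tri(g2, 300), compute_tri(g1, 300), tolerance = 1e-9)
  expect_true(all(compute_tri(g1, 300) >= 0))
})

test_that("landscape classification applies the threshold boxes with flat precedence", {
  bpi <- matrix(c(0, 75, 200, -75, 50, -50), 2, 3)
  tri <- matrix(c(0, 100, 10, 100, 40, 40), 2, 3)
  cls <- classify_landscape(bpi, tri)
  expect_equal(as.vector(cls),
               c("flat", "ridge", "unclassified", "trough", "flat", "flat"))
  expect_error(classify_landscape(bpi, tri[, 1:2]), "shape")
})

test_that("generator ridges and troughs are recovered by classification", {
  g <- generate_bathymetry(nrow = 50, ncol = 300, cell_size = 100,
                           ridge_spacing = 6000, amplitude = 70,
                           noise_sd = 2, crenulation = 0.2, seed = 21)
  tm <- terrain_maps(g, inner_radius = 500, outer_radius = 6000,
                     tri_radius = 500)
  # locate crests/troughs from the noiseless structure of column means
  cm <- colMeans(g$depths)
  crest_cols <- which(cm < quantile(cm, 0.1))
  trough_cols <- which(cm > quantile(cm, 0.9))
  crest_cells <- tm$classes[, crest_cols]
  trough_cells <- tm$classes[, trough_cols]
  expect_gt(mean(crest_cells == "ridge", na.rm = TRUE), 0.5)
  expect_gt(mean(trough_cells == "trough", na.rm = TRUE), 0.5)
})
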