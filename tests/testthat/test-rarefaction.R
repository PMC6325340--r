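test_that("interpolation hits the endpoint and the n = 1 identities", {
  set.seed(5)
  counts <- matrix(rpois(4 * 12, 1.5), 4, 12)
  counts[, 1] <- counts[, 1] + 1   # guarantee non-empty
  rc <- rarefy_richness(counts, effort = 1:4, mode = "sample")
  S_obs <- sum(colSums(counts) > 0)
  expect_equal(rc$S[4], S_obs, tolerance = 1e-12)
  pooled <- colSums(counts)
  ri <- rarefy_richness(pooled, effort = c(1, sum(pooled)),
                        mode = "individual")
  expect_equal(ri$S[1], 1, tolerance = 1e-12)   # one individual, one species
  expect_equal(ri$S[2], S_obs, tolerance = 1e-12)
})

test_that("sample-based interpolation equals exhaustive subset enumeration", {
  set.seed(6)
  for (rep in 1:5) {
    Tn <- sample(4:8, 1)
    counts <- matrix(rpois(Tn * 10, 0.8), Tn, 10)
    counts[1, 1] <- counts[1, 1] + 1
    rc <- rarefy_richness(counts, effort = seq_len(Tn), mode = "sample")
    for (t in seq_len(Tn)) {
      expect_equal(rc$S[t], brute_rarefy(counts > 0, t), tolerance = 1e-9)
    }
  }
})

test_that("richness curves are monotone and match vegan's expectation", {
  set.seed(7)
  counts <- matrix(rpois(6 * 25, 1), 6, 25)
  counts[, 1] <- counts[, 1] + 1
  rc <- rarefy_richness(counts, effort = 1:6, mode = "sample")
  expect_true(all(diff(rc$S) >= -1e-12))
  sv <- suppressWarnings(vegan::specaccum(counts, method = "exact"))
  expect_equal(rc$S, unname(sv$richness), tolerance = 1e-8)
  # individual-based curve against vegan::rarefy
  pooled <- colSums(counts)
  eff <- c(5, 20, 60)
  ri <- rarefy_richness(pooled, effort = eff, mode = "individual")
  expect_equal(ri$S,
               suppressWarnings(as.numeric(vegan::rarefy(pooled, eff))),
               tolerance = 1e-8)
})

test_that("extrapolation continues smoothly and approaches the Chao asymptote", {
  set.seed(8)
  counts <- matrix(rpois(4 * 40, 0.7), 4, 40)
  counts[, 1] <- counts[, 1] + 1
  expect_warning(
    rc <- rarefy_richness(counts, effort = c(2, 4, 5, 8, 40),
                          mode = "sample", boot = 50, seed = 1),
    "beyond 3x")
  S_obs <- sum(colSums(counts) > 0)
  S_chao <- attr(rc, "S_chao")
  expect_true(all(diff(rc$S) >= -1e-9))
  expect_gt(rc$S[3], S_obs)                 # extrapolated beyond observed
  expect_lt(rc$S[5], S_chao + 1e-9)         # bounded by the asymptote
  expect_equal(rc$S[5], S_chao, tolerance = 0.05)
  # area mode maps units to square metres via the mean unit area
  ra <- rarefy_richness(counts, effort = c(1320, 2640), mode = "area",
                        unit_area_m2 = 1320)
  rs <- rarefy_richness(counts, effort = c(1, 2), mode = "sample")
  expect_equal(ra$S, rs$S, tolerance = 1e-12)
})

test_that("bootstrap diversity rarefaction converges to the pooled index", {
  counts <- matrix(c(30, 20, 10, 28, 22, 9), 2, 3, byrow = TRUE)
  pooled <- hill_numbers(colSums(counts))
  rd <- rarefy_diversity(counts, effort = 2, mode = "sample", reps = 3000,
                         seed = 2)
  # at full effort with replacement, means concentrate near pooled values
  expect_equal(rd$mean[rd$index == "expH"], pooled[["expH"]],
               tolerance = 0.05)
  expect_equal(rd$mean[rd$index == "invD"], pooled[["invD"]],
               tolerance = 0.05)
  expect_error(rarefy_diversity(counts, effort = 0), "positive")
})

test_that("bootstrap mean matches exhaustive multinomial expectation at tiny n", {
  cnt <- c(5, 3, 2)
  p <- cnt / sum(cnt)
  m <- 4
  # enumerate all ordered draws via compositions of m
  comps <- expand.grid(a = 0:m, b = 0:m, c = 0:m)
  comps <- comps[rowSums(comps) == m, ]
  probs <- apply(comps, 1, function(k) stats::dmultinom(k, m, p))
  exp_expH <- sum(probs * apply(comps, 1, function(k) {
    hill_numbers(as.numeric(k))[["expH"]]
  }))
  rd <- rarefy_diversity(cnt, effort = m, mode = "individual", reps = 20000,
                         seed = 3)
  expect_equal(rd$mean[rd$index == "expH"], exp_expH, tolerance = 0.01)
})
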