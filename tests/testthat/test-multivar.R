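test_that("Bray-Curtis on sqrt densities has the dissimilarity properties", {
  toy <- toy_abundance()
  d <- bray_curtis(toy$counts, areas_m2 = toy$areas)
  expect_true(all(diag(d) == 0))
  expect_equal(unclass(d), t(unclass(d)), ignore_attr = TRUE)
  expect_true(all(d >= 0 & d <= 1))
  # identical rows and disjoint rows
  m <- rbind(a = c(4, 1, 0), b = c(4, 1, 0), c = c(0, 0, 9))
  dm <- bray_curtis(m, transform = "none")
  expect_equal(dm["a", "b"], 0)
  expect_equal(dm["a", "c"], 1)
  # worked example: y rows (2,2) vs (1,3) -> 0.25
  y <- rbind(c(4, 4), c(1, 9))    # sqrt densities (2,2) and (1,3)
  expect_equal(bray_curtis(y, transform = "sqrt")[1, 2], 0.25)
  # matches vegan on sqrt-transformed densities
  dens <- sqrt(sweep(toy$counts, 1, toy$areas, `/`))
  dv <- as.matrix(vegan::vegdist(dens, method = "bray"))
  expect_equal(unclass(d), dv, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("empty unit pairs are flagged as undefined", {
  m <- rbind(c(0, 0), c(0, 0), c(1, 2))
  expect_warning(d <- bray_curtis(m, transform = "none"), "empty")
  expect_true(is.na(d[1, 2]))
  expect_false(is.na(d[1, 3]))
})

test_that("PERMANOVA statistics agree with vegan::adonis2", {
  toy <- toy_abundance()
  d <- bray_curtis(toy$counts, areas_m2 = toy$areas)
  res <- permanova(d, toy$groups, n_perm = 199, seed = 1)
  ad <- vegan::adonis2(stats::as.dist(d) ~ g,
                       data = data.frame(g = toy$groups),
                       permutations = 199)
  expect_equal(res$F, ad$F[1], tolerance = 1e-10)
  expect_equal(res$R2, ad$R2[1], tolerance = 1e-10)
  expect_true(res$R2 >= 0 && res$R2 <= 1)
  expect_true(res$p > 0 && res$p <= 1)
  expect_equal(nrow(res$pairwise), 3)
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p))
})

test_that("permutation p equals exhaustive label enumeration for small N", {
  set.seed(11)
  m <- matrix(rpois(6 * 8, 2), 6, 8) + 1
  d <- bray_curtis(m, transform = "none")
  g <- rep(c("A", "B"), each = 3)
  res <- permanova(d, g, n_perm = 1000, seed = 2)   # 20 arrangements
  expect_true(res$exact)
  # independent enumeration over all C(6,3) label splits
  d2 <- unclass(d)^2
  fstat <- function(gg) {
    N <- 6; a <- 2
    sst <- sum(d2[upper.tri(d2)]) / N
    ssw <- sum(vapply(split(1:6, gg), function(ii) {
      sum(d2[ii, ii][upper.tri(d2[ii, ii])]) / length(ii)
    }, numeric(1)))
    ((sst - ssw) / (a - 1)) / (ssw / (N - a))
  }
  Fobs <- fstat(g)
  Fs <- apply(utils::combn(6, 3), 2, function(ii) {
    gg <- rep("B", 6); gg[ii] <- "A"; fstat(gg)
  })
  expect_equal(res$p, mean(Fs >= Fobs - 1e-12), tolerance = 1e-12)
})

test_that("duplicating units of separated groups pushes R2 towards 1", {
  m <- rbind(c(10, 0, 0), c(9, 1, 0), c(0, 0, 10), c(0, 1, 9))
  g <- c("A", "A", "B", "B")
  r1 <- permanova(bray_curtis(m, transform = "none"), g, n_perm = 99,
                  seed = 3)
  m2 <- m[rep(1:4, 3), ]
  r2 <- permanova(bray_curtis(m2, transform = "none"), rep(g, 3),
                  n_perm = 99, seed = 3)
  expect_gt(r2$R2, r1$R2)
})

test_that("SIMPER decomposes the mean between-group dissimilarity exactly", {
  toy <- toy_abundance()
  sel <- toy$groups %in% c("A", "B")
  sp <- simper(toy$counts[sel, ], toy$groups[sel])
  d <- bray_curtis(toy$counts[sel, ])
  cross <- unclass(d)[1:2, 3:4]
  expect_equal(attr(sp, "overall"), mean(cross), tolerance = 1e-9)
  expect_equal(sum(sp$contribution), mean(cross), tolerance = 1e-9)
  expect_equal(sp$cum_percent[nrow(sp)], 100, tolerance = 1e-9)
  # a single differing species carries 100% of the dissimilarity
  m <- rbind(c(5, 3), c(5, 1), c(5, 9), c(5, 7))
  s1 <- simper(m, c("A", "A", "B", "B"), transform = "none")
  expect_equal(s1$percent[1], 100)
  expect_equal(s1$species[1], "2")   # the only differing species leads
  expect_error(simper(toy$counts, toy$groups), "two groups")
})

test_that("SIMPER contributions equal hand-computed pairwise averages", {
  m <- rbind(u1 = c(2, 0), u2 = c(1, 1), u3 = c(0, 2), u4 = c(1, 0))
  g <- c("A", "A", "B", "B")
  sp <- simper(m, g, transform = "none")
  # cross pairs: (u1,u3) (u1,u4) (u2,u3) (u2,u4)
  c1 <- mean(c(2 / 4, 1 / 3, 1 / 4, 0 / 3))     # species 1
  c2 <- mean(c(2 / 4, 0 / 3, 1 / 4, 1 / 3))     # species 2
  expect_equal(sp$contribution[sp$species == "1"], c1, tolerance = 1e-12)
  expect_equal(sp$contribution[sp$species == "2"], c2, tolerance = 1e-12)
  expect_equal(sum(sp$contribution), c1 + c2, tolerance = 1e-12)
})

test_that("Spearman correlation handles perfect, inverse and tied data", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  y <- c(2.2, 1.1, 4.0, 3.3, 6.6, 5.0)
  res <- spearman_cor(x, y)
  expect_equal(res$rho, cor(rank(x), rank(y)))
  expect_equal(res$rho,
               suppressWarnings(cor.test(x, y, method = "spearman")$estimate),
               ignore_attr = TRUE)
  # exact permutation p at n = 6 matches cor.test's exact p
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  expect_warning(out <- spearman_cor(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out$rho))
})
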