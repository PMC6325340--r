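# Shared fixtures, built in code. Sizes are deliberately small: the suite's
# heavier statistical checks live in test-acceptance.R.

# A compact standardized survey over the three landscape-type areas.
small_survey <- local({
  sim <- NULL
  function() {
    if (is.null(sim)) {
      cm <- generate_community(seed = 11)
      raw <- simulate_survey(
        survey = survey_spec(units_per_area = 5, replicates_per_area = 2),
        community = cm,
        nodule_fields = nodule_field_spec(mean_cover = 6.4),
        seed = 12)
      sim <<- standardize_units(raw, seed = 13)
    }
    sim
  }
})

# Tiny deterministic abundance fixture: 6 units, 3 areas, 5 species.
toy_abundance <- function() {
  counts <- matrix(
    c(10, 4, 1, 0, 0,
      12, 3, 0, 1, 0,
      2, 9, 3, 0, 1,
      1, 11, 2, 0, 0,
      0, 1, 8, 6, 2,
      1, 0, 7, 8, 1),
    nrow = 6, byrow = TRUE,
    dimnames = list(paste0("u", 1:6), paste0("sp", 1:5)))
  list(counts = counts,
       groups = rep(c("A", "B", "C"), each = 2),
       areas = rep(1, 6))
}

# Brute-force annulus/neighbourhood means for the terrain oracles.
brute_bpi <- function(depths, cell, inner, outer) {
  z <- -depths
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0; n <- 0
    for (a in seq_len(nr)) for (b in seq_len(nc)) {
      d <- sqrt((a - i)^2 + (b - j)^2) * cell
      if (d > inner && d <= outer && is.finite(z[a, b])) {
        acc <- acc + z[a, b]; n <- n + 1
      }
    }
    out[i, j] <- if (n > 0) z[i, j] - acc / n else NA_real_
  }
  out
}

brute_tri <- function(depths, cell, radius) {
  z <- -depths
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0; n <- 0
    for (a in seq_len(nr)) for (b in seq_len(nc)) {
      d <- sqrt((a - i)^2 + (b - j)^2) * cell
      if (d <= radius && !(a == i && b == j)) {
        acc <- acc + abs(z[i, j] - z[a, b]); n <- n + 1
      }
    }
    out[i, j] <- if (n > 0) acc / n else NA_real_
  }
  out
}

# Exhaustive sample-based rarefaction: mean richness over all size-t subsets.
brute_rarefy <- function(counts, t) {
  Tn <- nrow(counts)
  subs <- utils::combn(Tn, t, simplify = FALSE)
  mean(vapply(subs, function(ii) {
    sum(colSums(counts[ii, , drop = FALSE]) > 0)
  }, numeric(1)))
}
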