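# Sampling-unit-size adequacy evaluation: accuracy (stabilization of the
# centre statistic), precision (CV), confidence intervals and
# autosimilarity as functions of the number of images (hence seabed area
# and individuals) per simulated sampling unit.

#' Pool the images of one study area for effort evaluation
#'
#' Collapses a populated survey to per-image summaries for one area: an
#' images x morphospecies count matrix, image footprints, and per-image
#' summed biovolumes. These pools are what the resampling evaluators draw
#' from.
#'
#' @param sim A populated `survey_sim` (standardized or not).
#' @param area Area name.
#' @param taxon Taxon subset as in [abundance_table()].
#' @return List of class `effort_pool`: `counts`, `footprint`, `biovolume`,
#'   `area`, `n_images`.
#' @export
effort_pool <- function(sim, area, taxon = "metazoan") {
  stopifnot(inherits(sim, "survey_sim"))
  img <- sim$images[sim$images$area == area, , drop = FALSE]
  if (!nrow(img)) stop("no images in area ", area, call. = FALSE)
  sp <- sim$specimens
  sp <- sp[sp$image_id %in% img$image_id, , drop = FALSE]
  if (taxon != "both") sp <- sp[sp$taxon == taxon, , drop = FALSE]
  counts <- table(factor(sp$image_id, levels = img$image_id), sp$msp)
  counts <- matrix(as.integer(counts), nrow = nrow(img),
                   dimnames = list(img$image_id, colnames(counts)))
  bv <- tapply(biovolume(sp$length_mm, sp$width_mm),
               factor(sp$image_id, levels = img$image_id),
               sum, default = 0)
  structure(list(counts = counts, footprint = img$footprint,
                 biovolume = as.numeric(bv), area = area,
                 n_images = nrow(img)),
            class = "effort_pool")
}

.parameter_fns <- list(
  density  = function(cnt, area, biovol) sum(cnt) / area,
  biomass  = function(cnt, area, biovol) biovol / area,
  richness = function(cnt, area, biovol) sum(cnt > 0),
  expH     = function(cnt, area, biovol) hill_numbers(cnt)[["expH"]],
  invD     = function(cnt, area, biovol) hill_numbers(cnt)[["invD"]])

#' Default image-count grid for effort curves
#'
#' Geometric spacing from `from` images up to the pool size.
#'
#' @param pool An `effort_pool` or an integer pool size.
#' @param n_points Number of grid points (default 16).
#' @param from Smallest size (default 10 images).
#' @return Integer vector of image counts.
#' @export
effort_sizes <- function(pool, n_points = 16, from = 10) {
  n <- if (inherits(pool, "effort_pool")) pool$n_images else pool
  unique(round(exp(seq(log(min(from, n)), log(n), length.out = n_points))))
}

#' Bootstrap a community parameter over increasing sampling-unit sizes
#'
#' At each candidate unit size (number of images), draws `reps` random
#' image subsets from the pooled images of a study area (with replacement
#' for bootstrap parameters, without replacement for rarefaction-style
#' ones), evaluates the parameter on each aggregated subset, and records
#' the centre statistic (mean, or median as used for biomass), the
#' precision (CV = sd/mean over replicate values), percentile confidence
#' limits, and the mean seabed area and individuals represented at that
#' size. At the full pool without replacement every draw is the pool
#' itself, so the centre equals the pooled value and the CV is 0.
#'
#' @param pool An [effort_pool()].
#' @param parameter One of `"density"`, `"biomass"`, `"richness"`,
#'   `"expH"`, `"invD"`, or a function `f(counts, area_m2, biovolume_ml)`.
#' @param sizes Image-count grid (default [effort_sizes()]).
#' @param reps Replicate draws per size (default 1000).
#' @param replace Draw with replacement (default `TRUE`; use `FALSE` for
#'   richness rarefaction). Sizes above the pool are dropped when drawing
#'   without replacement.
#' @param centre `"mean"` or `"median"`; default median for biomass, mean
#'   otherwise.
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return Data frame of class `effort_curve`: `size` (images),
#'   `mean_area_m2`, `mean_individuals`, `centre`, `cv`, `lo`, `hi`,
#'   `reps`, `replace`; attribute `parameter`.
#' @export
resample_parameter <- function(pool, parameter = "density",
                               sizes = effort_sizes(pool), reps = 1000,
                               replace = TRUE, centre = NULL, conf = 0.95,
                               seed = NULL) {
  stopifnot(inherits(pool, "effort_pool"))
  pname <- if (is.character(parameter)) parameter else "custom"
  fn <- if (is.function(parameter)) parameter else
    .parameter_fns[[match.arg(parameter, names(.parameter_fns))]]
  centre <- centre %||% if (pname == "biomass") "median" else "mean"
  n <- pool$n_images
  if (!replace) sizes <- sizes[sizes <= n]
  if (!length(sizes)) stop("no valid sizes for this pool", call. = FALSE)
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  with_seed(seed, {
    rows <- lapply(sizes, function(s) {
      vals <- areas <- inds <- numeric(reps)
      redraws <- 0L
      for (r in seq_len(reps)) {
        val <- NA_real_
        for (try in 1:100) {   # empty draws redone up to a retry cap
          ii <- sample.int(n, s, replace = replace)
          cnt <- colSums(pool$counts[ii, , drop = FALSE])
          a <- sum(pool$footprint[ii])
          val <- tryCatch(fn(cnt, a, sum(pool$biovolume[ii])),
                          error = function(e) NA_real_)
          if (!is.na(val)) break
          redraws <- redraws + 1L
        }
        vals[r] <- val
        areas[r] <- a
        inds[r] <- sum(cnt)
      }
      if (anyNA(vals)) {
        warning(sprintf(
          "parameter undefined on %d draw(s) at size %d after retries",
          sum(is.na(vals)), s), call. = FALSE)
      }
      ctr <- if (centre == "median") stats::median(vals, na.rm = TRUE)
        else mean(vals, na.rm = TRUE)
      q <- stats::quantile(vals, probs, na.rm = TRUE)
      data.frame(size = s, mean_area_m2 = mean(areas),
                 mean_individuals = mean(inds), centre = ctr,
                 cv = stats::sd(vals, na.rm = TRUE) / mean(vals, na.rm = TRUE),
                 lo = q[[1]], hi = q[[2]], reps = reps, replace = replace)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    structure(out, class = c("effort_curve", "data.frame"),
              parameter = pname, centre = centre)
  })
}

#' Autosimilarity over increasing sampling-unit sizes
#'
#' Precision of assemblage description: at each size, two disjoint image
#' groups of that size are drawn without replacement from the pool, counts
#' are aggregated per group and converted to square-root densities, and the
#' percentage Bray-Curtis similarity `100 * (1 - d)` between the two groups
#' is recorded; the mean and percentile confidence limits over `reps`
#' draws form the curve. Sizes for which two disjoint groups do not fit in
#' the pool are skipped with a warning.
#'
#' @inheritParams resample_parameter
#' @return An `effort_curve` data frame (parameter `"autosimilarity"`,
#'   centre in percent similarity).
#' @export
autosimilarity <- function(pool, sizes = NULL, reps = 1000, conf = 0.95,
                           seed = NULL) {
  stopifnot(inherits(pool, "effort_pool"))
  n <- pool$n_images
  sizes <- sizes %||% effort_sizes(floor(n / 2))
  ok <- 2 * sizes <= n
  if (any(!ok)) {
    warning("size(s) skipped: pool too small for two disjoint groups",
            call. = FALSE)
    sizes <- sizes[ok]
  }
  if (!length(sizes)) stop("no feasible sizes", call. = FALSE)
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  with_seed(seed, {
    rows <- lapply(sizes, function(s) {
      vals <- areas <- inds <- numeric(reps)
      for (r in seq_len(reps)) {
        ii <- sample.int(n, 2 * s, replace = FALSE)
        g1 <- ii[seq_len(s)]
        g2 <- ii[s + seq_len(s)]
        y1 <- sqrt(colSums(pool$counts[g1, , drop = FALSE]) /
                     sum(pool$footprint[g1]))
        y2 <- sqrt(colSums(pool$counts[g2, , drop = FALSE]) /
                     sum(pool$footprint[g2]))
        tot <- sum(y1 + y2)
        vals[r] <- if (tot == 0) NA_real_ else
          100 * (1 - sum(abs(y1 - y2)) / tot)
        areas[r] <- sum(pool$footprint[g1])
        inds[r] <- sum(pool$counts[g1, ])
      }
      q <- stats::quantile(vals, probs, na.rm = TRUE)
      data.frame(size = s, mean_area_m2 = mean(areas),
                 mean_individuals = mean(inds),
                 centre = mean(vals, na.rm = TRUE),
                 cv = stats::sd(vals, na.rm = TRUE) / mean(vals, na.rm = TRUE),
                 lo = q[[1]], hi = q[[2]], reps = reps, replace = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    structure(out, class = c("effort_curve", "data.frame"),
              parameter = "autosimilarity", centre = "mean")
  })
}

#' Detect stabilization of an effort curve
#'
#' Accuracy criterion: the minimum unit size from which the centre
#' statistic stays within a tolerance band around the terminal
#' (largest-size) centre. The reported size `s*` is the smallest grid size
#' such that all sizes from `s*` up (at least `window` grid points) lie
#' within `+/- tol_fraction * |terminal centre|`. If no such run exists the
#' report states that stabilization was not reached.
#'
#' @param curve An `effort_curve` from [resample_parameter()] or
#'   [autosimilarity()].
#' @param tol_fraction Half-width of the tolerance band as a fraction of
#'   the terminal centre (default 0.05).
#' @param window Minimum number of consecutive terminal grid points in the
#'   band (default 3).
#' @return List of class `stabilization_report`: `parameter`, `reached`,
#'   `size_images`, `size_individuals`, `size_m2`, `terminal`,
#'   `tol_fraction`, `window`.
#' @export
detect_stabilization <- function(curve, tol_fraction = 0.05, window = 3) {
  stopifnot(inherits(curve, "effort_curve"))
  curve <- curve[order(curve$size), , drop = FALSE]
  term <- curve$centre[nrow(curve)]
  inband <- abs(curve$centre - term) <= tol_fraction * abs(term)
  # longest all-in-band suffix
  run <- rev(cumprod(rev(inband)))
  idx <- which(run == 1)
  reached <- length(idx) >= window
  i0 <- if (reached) idx[1] else NA_integer_
  structure(list(
    parameter = attr(curve, "parameter"),
    reached = reached,
    size_images = if (reached) curve$size[i0] else NA_real_,
    size_individuals = if (reached) curve$mean_individuals[i0] else NA_real_,
    size_m2 = if (reached) curve$mean_area_m2[i0] else NA_real_,
    terminal = term, tol_fraction = tol_fraction, window = window),
    class = "stabilization_report")
}

#' @export
print.stabilization_report <- function(x, ...) {
  if (x$reached) {
    cat(sprintf(
      "%s stabilizes from %d images (~%.0f individuals, ~%.0f m^2); terminal %.4g\n",
      x$parameter, x$size_images, x$size_individuals, x$size_m2, x$terminal))
  } else {
    cat(sprintf("%s: stabilization not reached (terminal %.4g)\n",
                x$parameter, x$terminal))
  }
  invisible(x)
}
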