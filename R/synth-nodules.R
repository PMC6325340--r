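#' Specification of a polymetallic-nodule cover field
#'
#' Parameters of the stochastic nodule field for one study area: the mean
#' seabed percentage cover, the spatial correlation length of the cover
#' patches, and the lognormal size distribution of individual nodules.
#'
#' Default sizes (`meanlog = 0.616`, `sdlog = 0.775` on cm^2) give a mean
#' nodule area of about 2.5 cm^2 with 90% of nodules below 5 cm^2, matching
#' the ellipsoidal-projection areas reported by automated nodule delineation
#' in the landscape this package emulates. The default correlation length of
#' 50 m reproduces cover patchiness at tens of metres.
#'
#' @param mean_cover Mean seabed cover, percent (0--100).
#' @param corr_length Patch correlation length, metres (> 0).
#' @param size_meanlog,size_sdlog Lognormal parameters of nodule area (cm^2).
#' @param cover_logit_sd Standard deviation of the underlying Gaussian field
#'   on the logit scale; controls patch contrast.
#' @return An object of class `nodule_field_spec`.
#' @export
nodule_field_spec <- function(mean_cover = 10.1, corr_length = 50,
                              size_meanlog = 0.616, size_sdlog = 0.775,
                              cover_logit_sd = 1.0) {
  if (!is.numeric(mean_cover) || mean_cover < 0 || mean_cover > 100) {
    stop("'mean_cover' must lie in [0, 100]", call. = FALSE)
  }
  stop_if_not_scalar_pos(corr_length, "corr_length")
  if (cover_logit_sd < 0) stop("'cover_logit_sd' must be >= 0", call. = FALSE)
  structure(list(mean_cover = mean_cover, corr_length = corr_length,
                 size_meanlog = size_meanlog, size_sdlog = size_sdlog,
                 cover_logit_sd = cover_logit_sd),
            class = "nodule_field_spec")
}

#' Generate a spatially correlated nodule cover field
#'
#' Realises a stationary random cover field over a rectangular area: Gaussian
#' noise smoothed to the requested correlation length, squashed through a
#' logit link, and shifted so the realised mean cover equals the requested
#' mean exactly (solved on the realised field). The returned object exposes
#' `cover_at(x, y)` (percent cover at coordinates, nearest-cell lookup) and
#' `sample_nodules(footprint_m2, x, y)` which draws per-nodule areas (cm^2)
#' for one image: a Poisson number of nodules with expectation
#' `local cover x footprint / mean nodule area`, sizes i.i.d. lognormal.
#'
#' @param spec A [nodule_field_spec()].
#' @param area Numeric vector `c(xmin, xmax, ymin, ymax)` in metres.
#' @param cell Field resolution in metres (default 10, finer than the
#'   correlation length).
#' @param seed Integer seed.
#' @return An object of class `nodule_field` with elements `cover` (matrix,
#'   percent), `cell`, `area`, `spec`, and functions `cover_at`,
#'   `sample_nodules`.
#' @export
generate_nodule_field <- function(spec, area = c(0, 2000, 0, 2000),
                                  cell = 10, seed = NULL) {
  stopifnot(inherits(spec, "nodule_field_spec"))
  if (length(area) != 4 || area[2] <= area[1] || area[4] <= area[3]) {
    stop("'area' must be c(xmin, xmax, ymin, ymax) with positive extent",
         call. = FALSE)
  }
  nr <- max(2L, ceiling((area[4] - area[3]) / cell))
  nc <- max(2L, ceiling((area[2] - area[1]) / cell))
  p_target <- spec$mean_cover / 100
  cover <- with_seed(seed, {
    if (p_target == 0 || spec$cover_logit_sd == 0) {
      matrix(spec$mean_cover, nr, nc)
    } else {
      z <- gauss_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                        spec$corr_length / cell / 2)
      z <- (z - mean(z)) / stats::sd(as.vector(z)) * spec$cover_logit_sd
      # shift so the realised mean of plogis(z + delta) hits the target
      delta <- stats::uniroot(
        function(d) mean(stats::plogis(z + d)) - p_target,
        lower = -40, upper = 40, tol = 1e-10)$root
      100 * stats::plogis(z + delta)
    }
  })
  mean_size <- exp(spec$size_meanlog + spec$size_sdlog^2 / 2)
  cover_at <- function(x, y) {
    ci <- pmin(nc, pmax(1L, ceiling((x - area[1]) / cell)))
    ri <- pmin(nr, pmax(1L, ceiling((area[4] - y) / cell)))
    cover[cbind(ri, ci)]
  }
  sample_nodules <- function(footprint_m2, x = NULL, y = NULL) {
    cov <- if (is.null(x)) spec$mean_cover else cover_at(x, y)
    target_cm2 <- cov / 100 * footprint_m2 * 1e4
    n <- stats::rpois(1L, target_cm2 / mean_size)
    if (n == 0L) return(numeric(0))
    stats::rlnorm(n, spec$size_meanlog, spec$size_sdlog)
  }
  structure(list(cover = cover, cell = cell, area = area, spec = spec,
                 cover_at = cover_at, sample_nodules = sample_nodules),
            class = "nodule_field")
}

#' @export
print.nodule_field <- function(x, ...) {
  cat(sprintf(
    "nodule_field: %.1f%% mean cover (realised %.2f%%), corr length %g m\n",
    x$spec$mean_cover, mean(x$cover), x$spec$corr_length))
  invisible(x)
}
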