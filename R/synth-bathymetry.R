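#' Generate horst-and-graben style synthetic bathymetry
#'
#' Builds a depth raster emulating an abyssal-hill landscape: quasi-periodic
#' north--south oriented ridges and troughs (a sinusoid across easting with a
#' slowly drifting phase that crenulates the crest lines) over a flat base
#' depth, plus smooth correlated noise. Depths are reported in metres,
#' positive down, and are kept inside `depth_range`.
#'
#' @param nrow,ncol Grid dimensions (cells).
#' @param cell_size Cell size in metres (default 100, a typical shipboard
#'   multibeam DEM resolution at abyssal depth).
#' @param base_depth Mean depth in metres (default 4100).
#' @param ridge_spacing Ridge-to-ridge wavelength in metres; must lie in
#'   1--10 km, the characteristic spacing of abyssal horst-and-graben
#'   terrain, and exceed two cells (Nyquist).
#' @param amplitude Half peak-to-trough relief of the ridge sinusoid (m).
#'   `0` gives a flat seafloor.
#' @param noise_sd Standard deviation (m) of the smooth depth noise.
#' @param noise_corr Correlation length of the noise, in metres.
#' @param crenulation Phase-drift amplitude (radians) across the grid's
#'   north--south extent; wiggles the crest lines without changing the
#'   east--west period.
#' @param depth_range Permitted depth interval (m); output is clamped to it.
#' @param seed Integer seed; fixed seed gives identical grids.
#' @return A [bathy_grid()].
#' @examples
#' g <- generate_bathymetry(nrow = 60, ncol = 80, seed = 1)
#' range(g$depths)
#' @export
generate_bathymetry <- function(nrow = 200, ncol = 200, cell_size = 100,
                                base_depth = 4100, ridge_spacing = 5000,
                                amplitude = 75, noise_sd = 5,
                                noise_corr = 500,
                                crenulation = 0.6,
                                depth_range = c(3950, 4250),
                                seed = NULL) {
  stop_if_not_scalar_pos(cell_size, "cell_size")
  if (ridge_spacing < 1000 || ridge_spacing > 10000) {
    stop("'ridge_spacing' must lie within 1000-10000 m", call. = FALSE)
  }
  if (ridge_spacing < 2 * cell_size) {
    stop("'ridge_spacing' below two cells: the ridge pattern would alias",
         call. = FALSE)
  }
  if (amplitude < 0 || noise_sd < 0) {
    stop("'amplitude' and 'noise_sd' must be non-negative", call. = FALSE)
  }
  with_seed(seed, {
    x <- (seq_len(ncol) - 0.5) * cell_size       # easting of cell centres
    yfrac <- (seq_len(nrow) - 0.5) / nrow        # 0..1 north to south
    phase0 <- stats::runif(1, 0, 2 * pi)
    # slow sinusoidal phase drift with latitude -> crenulated crests
    phase <- phase0 + crenulation * sin(2 * pi * yfrac +
                                          stats::runif(1, 0, 2 * pi))
    ridge <- -amplitude *
      sin(outer(phase, 2 * pi * x / ridge_spacing, "+"))  # negative = shallower
    noise <- 0
    if (noise_sd > 0) {
      raw <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
      sm <- gauss_smooth(raw, noise_corr / cell_size / 2)
      noise <- sm / stats::sd(as.vector(sm)) * noise_sd
    }
    depths <- base_depth + ridge + noise
    depths <- pmin(pmax(depths, depth_range[1]), depth_range[2])
    bathy_grid(depths, cell_size = cell_size, depth_range = depth_range)
  })
}
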