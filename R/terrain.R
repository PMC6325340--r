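#' Bathymetric position index (BPI)
#'
#' BPI compares each cell's elevation with the mean elevation of an annulus
#' around it: `bpi = elevation(cell) - mean(elevation, inner < r <= outer)`,
#' with elevation = -depth, so positive BPI marks local highs (ridges) and
#' negative BPI local lows (troughs). Radii are in metres; annulus membership
#' is decided by cell-centre distance. Cells near the grid edge use the part
#' of the annulus that falls inside the grid; nodata cells are ignored.
#'
#' The broad-scale configuration used for landscape mapping is an inner
#' radius of 500 m and an outer radius of 10,000 m.
#'
#' @param grid A [bathy_grid()].
#' @param inner_radius,outer_radius Annulus radii (m); `inner < outer` and
#'   `outer >=` one cell.
#' @param standardize If `TRUE`, return integer z-scores
#'   (`round(100 * (bpi - mean) / sd)`, the common GIS convention) instead of
#'   raw metres. Default `FALSE`: thresholds are legible in metres.
#' @return Numeric matrix of BPI values, same shape as the grid.
#' @export
compute_bpi <- function(grid, inner_radius = 500, outer_radius = 10000,
                        standardize = FALSE) {
  stopifnot(inherits(grid, "bathy_grid"))
  cs <- grid$cell_size
  if (!(inner_radius < outer_radius)) {
    stop("'inner_radius' must be smaller than 'outer_radius'", call. = FALSE)
  }
  if (outer_radius < cs) {
    stop("'outer_radius' must be at least one cell", call. = FALSE)
  }
  k <- disc_kernel(outer_radius / cs, inner_cells = inner_radius / cs)
  if (sum(k) == 0) {
    stop("annulus contains no cells at this resolution", call. = FALSE)
  }
  elev <- -grid$depths
  bpi <- elev - neighbourhood_mean(elev, k)
  if (standardize) {
    mu <- mean(bpi, na.rm = TRUE)
    sd <- stats::sd(as.vector(bpi), na.rm = TRUE)
    bpi <- round(100 * (bpi - mu) / sd)
  }
  bpi
}

#' Terrain ruggedness index (TRI)
#'
#' Mean absolute elevation difference between each cell and all cells whose
#' centres fall within a circular neighbourhood of the given radius
#' (excluding the cell itself). Always non-negative and invariant to adding
#' a constant to all depths. The landscape-mapping configuration uses a
#' 500 m radius.
#'
#' @param grid A [bathy_grid()].
#' @param radius Neighbourhood radius in metres; at least one cell.
#' @param variant `"mean_abs"` (default) for the mean |difference|, or
#'   `"rms"` for the root-mean-square difference.
#' @return Numeric matrix of TRI values (m).
#' @export
compute_tri <- function(grid, radius = 500,
                        variant = c("mean_abs", "rms")) {
  stopifnot(inherits(grid, "bathy_grid"))
  variant <- match.arg(variant)
  cs <- grid$cell_size
  if (radius < cs) {
    stop("'radius' must be at least one cell", call. = FALSE)
  }
  z <- -grid$depths
  r <- radius / cs
  rc <- ceiling(r)
  offs <- expand.grid(dr = -rc:rc, dc = -rc:rc)
  offs <- offs[sqrt(offs$dr^2 + offs$dc^2) <= r &
                 !(offs$dr == 0 & offs$dc == 0), , drop = FALSE]
  if (nrow(offs) == 0) {
    stop("neighbourhood contains no cells at this resolution", call. = FALSE)
  }
  nr <- nrow(z); nc <- ncol(z)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (i in seq_len(nrow(offs))) {
    dr <- offs$dr[i]; dc <- offs$dc[i]
    sh <- matrix(NA_real_, nr, nc)
    rs <- max(1, 1 - dr):min(nr, nr - dr)   # destination rows
    cs2 <- max(1, 1 - dc):min(nc, nc - dc)  # destination cols
    sh[rs, cs2] <- z[rs + dr, cs2 + dc]
    d <- z - sh
    ok <- is.finite(d)
    d[!ok] <- 0
    acc <- acc + if (variant == "mean_abs") abs(d) else d^2
    cnt <- cnt + ok
  }
  out <- acc / cnt
  if (variant == "rms") out <- sqrt(out)
  out[cnt == 0 | !is.finite(z)] <- NA_real_
  out
}

#' Classify landscape types from BPI and TRI
#'
#' Assigns each cell to `"flat"`, `"ridge"`, `"trough"` or `"unclassified"`
#' by closed-interval membership in threshold boxes: ridge (BPI 50--100,
#' TRI 0--150), trough (BPI -100 to -50, TRI 0--150), flat (BPI -50 to 50,
#' TRI 0--50). Values outside all boxes are unclassified. At the shared
#' boundaries |BPI| = 50 the flat box takes precedence, so classification is
#' deterministic.
#'
#' @param bpi,tri Congruent numeric matrices, in metres.
#' @param thresholds Named list with `ridge`, `trough`, `flat` elements, each
#'   `list(bpi = c(lo, hi), tri = c(lo, hi))`.
#' @return Character matrix over
#'   `{"flat","ridge","trough","unclassified"}`; `NA` where inputs are `NA`.
#' @export
classify_landscape <- function(bpi, tri,
                               thresholds = landscape_thresholds()) {
  if (!identical(dim(bpi), dim(tri))) {
    stop("'bpi' and 'tri' must have identical shape", call. = FALSE)
  }
  inbox <- function(b, lo, hi) is.finite(b) & b >= lo & b <= hi
  cls <- matrix("unclassified", nrow(bpi), ncol(bpi))
  for (type in c("ridge", "trough", "flat")) {  # flat last: wins ties
    th <- thresholds[[type]]
    sel <- inbox(bpi, th$bpi[1], th$bpi[2]) &
      inbox(tri, th$tri[1], th$tri[2])
    cls[sel] <- type
  }
  cls[!is.finite(bpi) | !is.finite(tri)] <- NA_character_
  cls
}

#' Default landscape classification thresholds
#'
#' The threshold boxes used to map ridge, trough and flat terrain from broad
#' BPI and TRI rasters (metres).
#'
#' @return Named list of boxes.
#' @export
landscape_thresholds <- function() {
  list(
    ridge  = list(bpi = c(50, 100),   tri = c(0, 150)),
    trough = list(bpi = c(-100, -50), tri = c(0, 150)),
    flat   = list(bpi = c(-50, 50),   tri = c(0, 50)))
}

#' Compute the full terrain-map set for a grid
#'
#' Convenience wrapper returning BPI, TRI and the landscape class raster.
#'
#' @inheritParams compute_bpi
#' @param tri_radius TRI neighbourhood radius (m).
#' @param thresholds Passed to [classify_landscape()].
#' @return List with elements `bpi`, `tri`, `classes`.
#' @export
terrain_maps <- function(grid, inner_radius = 500, outer_radius = 10000,
                         tri_radius = 500,
                         thresholds = landscape_thresholds()) {
  bpi <- compute_bpi(grid, inner_radius, outer_radius)
  tri <- compute_tri(grid, tri_radius)
  list(bpi = bpi, tri = tri,
       classes = classify_landscape(bpi, tri, thresholds))
}
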