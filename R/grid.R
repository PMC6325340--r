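#' Bathymetric depth grid
#'
#' A `bathy_grid` is a regular raster of water depths in metres (positive
#' down), stored as a numeric matrix with rows running north to south and
#' columns west to east, plus the cell size and the coordinates of the
#' lower-left corner. It is the substrate for the terrain derivatives
#' ([compute_bpi()], [compute_tri()]) and for survey simulation.
#'
#' @param depths Numeric matrix of depths (m, positive down). `NA` marks
#'   nodata cells.
#' @param cell_size Cell edge length in metres.
#' @param origin_x,origin_y Coordinates (m) of the lower-left grid corner.
#' @param depth_range Permitted closed depth interval; generated or read
#'   grids are validated against it. Default 3950--4250 m, the abyssal-hill
#'   setting the package simulates.
#' @return An object of class `bathy_grid`.
#' @export
bathy_grid <- function(depths, cell_size, origin_x = 0, origin_y = 0,
                       depth_range = c(3950, 4250)) {
  if (!is.matrix(depths) || !is.numeric(depths)) {
    stop("'depths' must be a numeric matrix", call. = FALSE)
  }
  stop_if_not_scalar_pos(cell_size, "cell_size")
  finite <- depths[is.finite(depths)]
  if (length(finite) && !is.null(depth_range)) {
    if (min(finite) < depth_range[1] || max(finite) > depth_range[2]) {
      stop(sprintf(
        "depths outside permitted range [%g, %g] m", depth_range[1],
        depth_range[2]), call. = FALSE)
    }
  }
  structure(
    list(depths = depths, cell_size = cell_size,
         origin_x = origin_x, origin_y = origin_y,
         depth_range = depth_range),
    class = "bathy_grid")
}

#' @export
print.bathy_grid <- function(x, ...) {
  d <- x$depths
  cat(sprintf("bathy_grid: %d x %d cells, %g m resolution\n",
              nrow(d), ncol(d), x$cell_size))
  cat(sprintf("  extent: %g x %g m, origin (%g, %g)\n",
              ncol(d) * x$cell_size, nrow(d) * x$cell_size,
              x$origin_x, x$origin_y))
  f <- d[is.finite(d)]
  if (length(f)) {
    cat(sprintf("  depth: %.1f - %.1f m (mean %.1f)\n",
                min(f), max(f), mean(f)))
  }
  invisible(x)
}

#' @export
dim.bathy_grid <- function(x) dim(x$depths)

#' Read an ESRI ASCII grid
#'
#' Parses the plain-text Arc/Info ASCII raster format (6-line header of
#' `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` followed by
#' whitespace-separated rows, north row first).
#'
#' @param path File path.
#' @param as_bathy Return a [bathy_grid()] (`TRUE`, default) or a bare list
#'   with the matrix and header fields.
#' @param depth_range Passed to [bathy_grid()]; use `NULL` to skip range
#'   validation.
#' @return A `bathy_grid` or list.
#' @export
read_ascii_grid <- function(path, as_bathy = TRUE, depth_range = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("not an ESRI ASCII grid: incomplete header", call. = FALSE)
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop(sprintf("expected %d values, found %d", nr * nc, length(vals)),
         call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  if (!as_bathy) return(c(hdr, list(values = m)))
  bathy_grid(m, cell_size = hdr$cellsize, origin_x = hdr$xllcorner,
             origin_y = hdr$yllcorner, depth_range = depth_range)
}

#' Write a matrix or bathy_grid as an ESRI ASCII grid
#'
#' @param x A `bathy_grid` or numeric matrix (north row first).
#' @param path Output path.
#' @param cell_size,origin_x,origin_y Header fields when `x` is a bare
#'   matrix; ignored for a `bathy_grid`.
#' @param nodata Value written for `NA` cells.
#' @param digits Significant digits written.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(x, path, cell_size = 1, origin_x = 0,
                             origin_y = 0, nodata = -9999, digits = 6) {
  if (inherits(x, "bathy_grid")) {
    m <- x$depths; cell_size <- x$cell_size
    origin_x <- x$origin_x; origin_y <- x$origin_y
  } else {
    m <- x
  }
  stopifnot(is.matrix(m))
  m[!is.finite(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", origin_x),
    sprintf("yllcorner %.10g", origin_y),
    sprintf("cellsize %.10g", cell_size),
    sprintf("NODATA_value %g", nodata)), con)
  writeLines(apply(m, 1L, function(r) {
    paste(formatC(r, digits = digits, format = "g"), collapse = " ")
  }), con)
  invisible(path)
}
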