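#' Specimen biovolume from two body measurements
#'
#' Generalised volumetric proxy for fresh wet-weight biomass: the specimen
#' is treated as an ellipsoid of revolution about its long axis,
#' `V = (pi/6) L W^2` in mm^3, converted to millilitres (1 ml = 1000 mm^3;
#' approximately 1 g fresh wet weight). A per-morphospecies shape factor can
#' scale the ellipsoid for non-ellipsoidal bodies.
#'
#' @param length_mm,width_mm Body length and width (mm); `length >= width
#'   > 0`.
#' @param shape Multiplicative shape factor (default 1).
#' @return Biovolume in ml, vectorised.
#' @examples
#' biovolume(100, 10)  # 5.236 ml
#' @export
biovolume <- function(length_mm, width_mm, shape = 1) {
  if (any(length_mm <= 0) || any(width_mm <= 0)) {
    stop("body dimensions must be positive", call. = FALSE)
  }
  if (any(width_mm > length_mm)) {
    stop("'width_mm' cannot exceed 'length_mm'", call. = FALSE)
  }
  shape * pi / 6 * length_mm * width_mm^2 / 1000
}

#' Hill diversity numbers of order 0, 1 and 2
#'
#' Morphospecies richness `S`, the exponential Shannon index
#' `exp H = exp(-sum p_i log p_i)` and the inverse Simpson index
#' `1/D = 1 / sum p_i^2`, computed from a count vector. For any non-empty
#' sample `S >= exp H >= 1/D >= 1`.
#'
#' @param counts Non-negative count vector.
#' @return Named numeric vector `c(S, expH, invD)`.
#' @examples
#' hill_numbers(c(1, 2, 3))
#' @export
hill_numbers <- function(counts) {
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  n <- sum(counts)
  if (n == 0) stop("empty sample: Hill numbers undefined", call. = FALSE)
  p <- counts[counts > 0] / n
  c(S = length(p),
    expH = exp(-sum(p * log(p))),
    invD = 1 / sum(p^2))
}

#' Per-unit standing-stock and diversity metrics
#'
#' Computes, for every sampling unit of an [abundance_table()]: numerical
#' density (ind m^-2) overall and split by guild, life habit and taxon
#' group; biovolume biomass density (ml m^-2, a fresh-wet-weight proxy) when
#' specimen measurements are available; and the Hill numbers S, exp H and
#' 1/D.
#'
#' @param x An `abundance_table`.
#' @return Data frame with one row per unit.
#' @export
unit_metrics <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  units <- x$units
  sp <- x$specimens
  out <- lapply(seq_len(nrow(units)), function(i) {
    u <- units$unit[i]
    area <- x$areas_m2[[u]]
    if (area <= 0) stop("zero unit area", call. = FALSE)
    cnt <- x$counts[u, ]
    su <- sp[!is.na(sp$unit) & sp$unit == u, , drop = FALSE]
    hill <- if (sum(cnt) > 0) hill_numbers(cnt) else
      c(S = 0, expH = NA_real_, invD = NA_real_)
    biom <- if (nrow(su)) {
      sum(biovolume(su$length_mm, su$width_mm)) / area
    } else 0
    guild_d <- vapply(c("SF", "DF", "PS"), function(g) {
      sum(su$guild == g, na.rm = TRUE) / area
    }, numeric(1))
    data.frame(unit = u, area = units$area[i], area_m2 = area,
               n = sum(cnt), density = sum(cnt) / area,
               biomass = biom,
               density_SF = guild_d[["SF"]], density_DF = guild_d[["DF"]],
               density_PS = guild_d[["PS"]],
               density_NA = sum(su$habit == "NA", na.rm = TRUE) / area,
               S = hill[["S"]], expH = hill[["expH"]],
               invD = hill[["invD"]],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' K-dominance curves across replicate units
#'
#' For each unit, morphospecies are ranked by decreasing abundance and the
#' cumulative relative abundance (%) is computed against rank; the curve for
#' a pooled assemblage of `S` species therefore starts at the Berger-Parker
#' dominance and reaches 100% at rank `S`. The mean curve across replicate
#' units is returned with a t-based 95% confidence band; units with fewer
#' ranks than the longest curve are held at 100% beyond their own richness.
#'
#' @param counts Units x species count matrix (or an `abundance_table`).
#' @param conf Confidence level (default 0.95).
#' @return Data frame: `rank`, `mean`, `lo`, `hi`, plus one `cum_<unit>`
#'   column per unit.
#' @export
k_dominance <- function(counts, conf = 0.95) {
  if (inherits(counts, "abundance_table")) counts <- counts$counts
  counts <- as.matrix(counts)
  if (nrow(counts) == 0) stop("no units supplied", call. = FALSE)
  per_unit <- apply(counts, 1L, function(r) {
    r <- sort(r[r > 0], decreasing = TRUE)
    if (!length(r)) stop("empty unit in K-dominance input", call. = FALSE)
    cumsum(r) / sum(r) * 100
  }, simplify = FALSE)
  rmax <- max(lengths(per_unit))
  mat <- matrix(vapply(per_unit, function(v) c(v, rep(100, rmax - length(v))),
                       numeric(rmax)), nrow = rmax)
  m <- rowMeans(mat)
  n <- ncol(mat)
  se <- apply(mat, 1L, stats::sd) / sqrt(n)
  tq <- if (n > 1) stats::qt(1 - (1 - conf) / 2, n - 1) else 0
  out <- data.frame(rank = seq_len(rmax), mean = m,
                    lo = pmax(0, m - tq * se), hi = pmin(100, m + tq * se))
  cum <- as.data.frame(mat)
  names(cum) <- paste0("cum_", rownames(counts) %||% seq_len(n))
  cbind(out, cum)
}
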