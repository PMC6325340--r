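#' Filter nodule areas to the analysable size range
#'
#' Keeps per-nodule areas within the closed interval 0.5--60 cm^2
#' (maximum diameters of roughly 1--10 cm); smaller detections are noise,
#' larger ones are non-nodule formations.
#'
#' @param areas_cm2 Non-negative nodule areas (cm^2).
#' @param range Closed retention interval (cm^2).
#' @return The retained areas.
#' @examples
#' filter_nodules(c(0.4, 0.5, 5, 60, 61))  # 0.5 5 60
#' @export
filter_nodules <- function(areas_cm2, range = c(0.5, 60)) {
  if (any(areas_cm2 < 0)) stop("negative nodule area", call. = FALSE)
  areas_cm2[areas_cm2 >= range[1] & areas_cm2 <= range[2]]
}

#' Nodule cover metrics per image and per sampling unit
#'
#' Per-image percent cover is `100 * sum(areas_cm2) / (footprint_m2 * 1e4)`.
#' Per unit, the cover is the unweighted mean of the per-image covers (an
#' area-weighted mean is available behind a flag) and the total nodule area
#' is the sum over images in square metres (`sum(areas_cm2) / 1e4`). The
#' pooled mean nodule surface size (cm^2 per nodule) and the hard-substrata
#' density (items per hectare) are reported alongside.
#'
#' @param sim A populated `survey_sim` (nodule areas are size-filtered with
#'   [filter_nodules()] first), or a data frame with columns `image_id`,
#'   `area_cm2` plus an `images` data frame.
#' @param images Data frame with `image_id`, `unit`, `footprint` (m^2), and
#'   optionally `hard_substrata` counts; taken from `sim` when omitted.
#' @param size_range Passed to [filter_nodules()].
#' @param weighted Use footprint-weighted unit means (default `FALSE`:
#'   unweighted across selected images).
#' @return List with `images` (per-image cover) and `units` (per-unit mean
#'   cover %, total nodule area m^2, mean nodule size cm^2, nodule count,
#'   hard-substrata items per ha).
#' @export
nodule_cover <- function(sim, images = NULL, size_range = c(0.5, 60),
                         weighted = FALSE) {
  if (inherits(sim, "survey_sim")) {
    nodules <- sim$nodules
    images <- images %||% sim$images
  } else {
    nodules <- sim
    if (is.null(images)) stop("'images' required", call. = FALSE)
  }
  if (any(images$footprint <= 0)) stop("zero image footprint", call. = FALSE)
  nodules <- nodules[nodules$area_cm2 >= size_range[1] &
                       nodules$area_cm2 <= size_range[2], , drop = FALSE]
  if (any(nodules$area_cm2 < 0)) stop("negative nodule area", call. = FALSE)
  per_img_area <- tapply(nodules$area_cm2,
                         factor(nodules$image_id, levels = images$image_id),
                         sum, default = 0)
  n_img <- tapply(rep(1, nrow(nodules)),
                  factor(nodules$image_id, levels = images$image_id),
                  sum, default = 0)
  img <- data.frame(image_id = images$image_id, unit = images$unit,
                    footprint = images$footprint,
                    nodule_cm2 = as.numeric(per_img_area),
                    n_nodules = as.numeric(n_img),
                    cover = 100 * as.numeric(per_img_area) /
                      (images$footprint * 1e4),
                    stringsAsFactors = FALSE)
  hs <- images$hard_substrata %||% rep(0, nrow(images))
  units <- do.call(rbind, lapply(split(seq_len(nrow(img)), img$unit),
                                 function(ii) {
    w <- if (weighted) img$footprint[ii] else rep(1, length(ii))
    data.frame(
      unit = img$unit[ii][1],
      cover = sum(w * img$cover[ii]) / sum(w),
      total_m2 = sum(img$nodule_cm2[ii]) / 1e4,
      mean_size_cm2 = if (sum(img$n_nodules[ii]) > 0)
        sum(img$nodule_cm2[ii]) / sum(img$n_nodules[ii]) else NA_real_,
      n_nodules = sum(img$n_nodules[ii]),
      area_m2 = sum(img$footprint[ii]),
      hard_substrata_ha = sum(hs[ii]) / sum(img$footprint[ii]) * 1e4,
      stringsAsFactors = FALSE)
  }))
  rownames(units) <- NULL
  list(images = img, units = units)
}

#' Sediment grain-size statistics
#'
#' Geometric method of moments on a particle-size distribution given as
#' class volume fractions between size bounds: the geometric mean is
#' `exp(sum f_i log m_i)` with `m_i` the geometric midpoint
#' `sqrt(lo_i * hi_i)` of each class, and the mud content is the percentage
#' of particles finer than 63 um, prorating any class straddling 63 um
#' linearly in log-size.
#'
#' @param bounds_um Two-column matrix (or data frame) of class lower/upper
#'   bounds in micrometres, finest class first.
#' @param fractions Volume fractions per class (will be renormalised; must
#'   not be all zero).
#' @return List with `gm_size_um` and `mud_pct`.
#' @export
grain_stats <- function(bounds_um, fractions) {
  bounds_um <- as.matrix(bounds_um)
  if (nrow(bounds_um) != length(fractions)) {
    stop("one fraction per size class required", call. = FALSE)
  }
  if (any(fractions < 0)) stop("negative fraction", call. = FALSE)
  if (sum(fractions) == 0) stop("all-zero distribution", call. = FALSE)
  if (any(bounds_um <= 0) || any(bounds_um[, 2] <= bounds_um[, 1])) {
    stop("class bounds must be positive and increasing", call. = FALSE)
  }
  f <- fractions / sum(fractions)
  mid <- sqrt(bounds_um[, 1] * bounds_um[, 2])
  gm <- exp(sum(f * log(mid)))
  below <- ifelse(bounds_um[, 2] <= 63, 1,
                  ifelse(bounds_um[, 1] >= 63, 0,
                         (log(63) - log(bounds_um[, 1])) /
                           (log(bounds_um[, 2]) - log(bounds_um[, 1]))))
  list(gm_size_um = gm, mud_pct = 100 * sum(f * below))
}

#' Carbonate content and molar C:N ratio
#'
#' Carbonate (% dry weight) from the difference between total and organic
#' carbon, assuming all carbonate is CaCO3:
#' `CaCO3 = (TC - TOC) * 100.09 / 12.01`. The C:N ratio is molar:
#' `(TOC / 12.01) / (TN / 14.007)`.
#'
#' @param tc,toc,tn Total carbon, total organic carbon, total nitrogen, all
#'   in % dry weight. `tc >= toc` required; `tn = 0` yields an `NA` C:N
#'   with a warning.
#' @return Data frame with `caco3_pct` and `cn_molar`, vectorised.
#' @export
carbonate_cn <- function(tc, toc, tn = NA_real_) {
  if (any(tc < toc)) stop("TC < TOC: inorganic carbon negative",
                          call. = FALSE)
  if (any(toc < 0)) stop("negative TOC", call. = FALSE)
  caco3 <- (tc - toc) * 100.09 / 12.01
  cn <- rep(NA_real_, length(toc))
  ok <- !is.na(tn) & tn > 0
  cn[ok] <- (toc[ok] / 12.01) / (tn[ok] / 14.007)
  if (any(!is.na(tn) & tn == 0)) {
    warning("TN = 0: molar C:N undefined", call. = FALSE)
  }
  data.frame(caco3_pct = caco3, cn_molar = cn)
}
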