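#' Generate synthetic sediment samples
#'
#' Emulates replicate megacorer samples of radiolarian-bearing pelagic
#' clay/silt: a particle-size distribution concentrated below 63 um (mud
#' around 91--93%, geometric mean size around 8--10 um), TOC near 0.42 %dw,
#' a molar C:N near 4 and CaCO3 near 0.3--0.5 %dw. Per-sample variability is
#' lognormal around the area means.
#'
#' @param areas Area names.
#' @param n_per_area Replicate samples per area (default 5).
#' @param mean_gm_um Target geometric mean size per area (um).
#' @param toc,caco3,cn Area means for TOC (%dw), CaCO3 (%dw) and molar C:N.
#' @param cv Relative sample-to-sample variability.
#' @param seed Integer seed.
#' @return Data frame: one row per sample with class fractions in columns
#'   `f_<lo>_<hi>` (um bounds), plus `tc`, `toc`, `tn` (%dw).
#' @export
generate_sediment <- function(areas = c("Flat", "Ridge", "Trough"),
                              n_per_area = 5,
                              mean_gm_um = c(8.1, 9.5, 9.2),
                              toc = c(0.42, 0.41, 0.44),
                              caco3 = c(0.33, 0.48, 0.36),
                              cn = c(4.0, 3.8, 4.1),
                              cv = 0.08, seed = NULL) {
  bounds <- cbind(lo = c(0.5, 2, 7.8, 20, 63, 125),
                  hi = c(2, 7.8, 20, 63, 125, 500))
  mid <- log(sqrt(bounds[, 1] * bounds[, 2]))
  with_seed(seed, {
    rows <- lapply(seq_along(areas), function(i) {
      do.call(rbind, lapply(seq_len(n_per_area), function(s) {
        gm <- mean_gm_um[i] * stats::rlnorm(1, 0, cv)
        # lognormal particle-size density across classes around gm
        f <- stats::dnorm(mid, log(gm), 1.1)
        f <- f / sum(f)
        toc_s <- toc[i] * stats::rlnorm(1, 0, cv)
        caco3_s <- caco3[i] * stats::rlnorm(1, 0, 2 * cv)
        cn_s <- cn[i] * stats::rlnorm(1, 0, cv)
        out <- data.frame(area = areas[i], sample = s,
                          stringsAsFactors = FALSE)
        for (k in seq_len(nrow(bounds))) {
          out[[sprintf("f_%g_%g", bounds[k, 1], bounds[k, 2])]] <- f[k]
        }
        out$toc <- toc_s
        out$tc <- toc_s + caco3_s * 12.01 / 100.09
        out$tn <- (toc_s / 12.01) / cn_s * 14.007
        out
      }))
    })
    res <- do.call(rbind, rows)
    attr(res, "bounds_um") <- bounds
    res
  })
}
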