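# Sample-based and individual-based rarefaction with Chao-type
# extrapolation. Interpolation uses the exact hypergeometric expectation;
# expressing the binomial-coefficient ratios through lgamma() keeps them
# stable at large effort and admits non-integer effort on the area axis.

# alpha_i(t) = C(T - Y_i, t) / C(T, t), vectorised over Y; 0 when the
# reduced pool cannot hold t samples.
.alpha_ratio <- function(Y, T, t) {
  num <- lgamma(T - Y + 1) - lgamma(T - Y - t + 1)
  den <- lgamma(T + 1) - lgamma(T - t + 1)
  out <- exp(num - den)
  out[T - Y - t < 0] <- 0
  out
}

.chao_f0 <- function(f1, f2, T) {
  if (f2 > 0) ((T - 1) / T) * f1^2 / (2 * f2)
  else ((T - 1) / T) * f1 * (f1 - 1) / 2
}

#' Rarefied and extrapolated morphospecies richness
#'
#' Expected richness as a function of sampling effort. Within the observed
#' effort the curve is the exact expectation under random subsampling
#' without replacement, `E[S(t)] = S_obs - sum_i C(T - Y_i, t) / C(T, t)`
#' (sample-based, with incidence frequencies `Y_i` over `T` units) or the
#' analogous abundance form (individual-based). Beyond the observed effort
#' the curve follows the Chao-type asymptotic estimator of undetected
#' richness (Chao2 for samples, Chao1 for individuals) with the standard
#' exponential approach to the asymptote. The area mode is the sample-based
#' curve with effort expressed in square metres through the mean
#' standardized unit area.
#'
#' Confidence intervals: interpolated points use the analytic unconditional
#' variance `sigma^2(t) = sum_i (1 - alpha_it)^2 - S(t)^2 / S_chao`;
#' extrapolated points use a percentile bootstrap over resampled units (or
#' individuals).
#'
#' @param x An [abundance_table()], a units x species count/incidence
#'   matrix (sample and area modes), or a species count vector (individual
#'   mode).
#' @param effort Effort grid: number of units (sample), individuals
#'   (individual) or square metres (area). Default: every observed level
#'   plus, if `extrapolate_to` is given, an even grid up to it.
#' @param mode `"sample"`, `"individual"` or `"area"`.
#' @param extrapolate_to Optional maximum effort for extrapolation (e.g.
#'   3000 individuals or 15000 m^2); efforts beyond 3x the observed effort
#'   are flagged with a warning.
#' @param conf Confidence level.
#' @param boot Bootstrap replicates for extrapolated-point intervals.
#' @param unit_area_m2 Area represented by one unit in area mode; default
#'   the mean analysed unit area (1320 m^2 for a standardized survey).
#' @param seed Integer seed (bootstrap only).
#' @return A data frame of class `rarefaction_curve`: `effort`, `S`, `lo`,
#'   `hi`, `interpolated`.
#' @export
rarefy_richness <- function(x, effort = NULL,
                            mode = c("sample", "individual", "area"),
                            extrapolate_to = NULL, conf = 0.95, boot = 200,
                            unit_area_m2 = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (inherits(x, "abundance_table")) {
    if (is.null(unit_area_m2)) unit_area_m2 <- mean(x$areas_m2)
    x <- if (mode == "individual") colSums(x$counts) else x$counts
  }
  unit_area_m2 <- unit_area_m2 %||% 1320
  z <- stats::qnorm(1 - (1 - conf) / 2)

  if (mode == "individual") {
    X <- x[x > 0]
    n <- sum(X)
    S_obs <- length(X)
    f0 <- .chao_f0(sum(X == 1), sum(X == 2), n)
    f1 <- sum(X == 1)
    S_chao <- S_obs + f0
    eff_obs <- n
    est <- function(t) {
      a <- .alpha_ratio(X, n, t)
      c(S = S_obs - sum(a), var = sum((1 - a)^2) - (S_obs - sum(a))^2 / S_chao)
    }
    ext <- function(t, Xb = X) {
      nb <- sum(Xb); Sb <- length(Xb[Xb > 0])
      f1b <- sum(Xb == 1); f0b <- .chao_f0(f1b, sum(Xb == 2), nb)
      if (f0b == 0) return(Sb)
      Sb + f0b * (1 - (1 - f1b / (nb * f0b + f1b))^(t - nb))
    }
    resample <- function() {
      tab <- tabulate(sample.int(S_obs, n, replace = TRUE, prob = X / n),
                      nbins = S_obs)
      tab[tab > 0]
    }
  } else {
    counts <- as.matrix(x)
    inc <- counts > 0
    Tn <- nrow(inc)
    Y <- colSums(inc)
    Y <- Y[Y > 0]
    S_obs <- length(Y)
    Q1 <- sum(Y == 1)
    f0 <- .chao_f0(Q1, sum(Y == 2), Tn)
    S_chao <- S_obs + f0
    eff_obs <- Tn
    est <- function(t) {
      a <- .alpha_ratio(Y, Tn, t)
      c(S = S_obs - sum(a), var = sum((1 - a)^2) - (S_obs - sum(a))^2 / S_chao)
    }
    ext <- function(t, Yb = Y) {
      Sb <- length(Yb); Q1b <- sum(Yb == 1)
      f0b <- .chao_f0(Q1b, sum(Yb == 2), Tn)
      if (f0b == 0) return(Sb)
      Sb + f0b * (1 - (1 - Q1b / (Tn * f0b + Q1b))^(t - Tn))
    }
    resample <- function() {
      yb <- colSums(inc[sample.int(Tn, Tn, replace = TRUE), , drop = FALSE])
      yb[yb > 0]
    }
  }

  scale <- if (mode == "area") unit_area_m2 else 1
  if (is.null(effort)) {
    effort <- seq_len(eff_obs) * scale
    if (!is.null(extrapolate_to) && extrapolate_to > eff_obs * scale) {
      effort <- c(effort, seq(eff_obs * scale, extrapolate_to,
                              length.out = 21)[-1])
    }
  }
  t_units <- effort / scale
  if (any(t_units > 3 * eff_obs)) {
    warning("extrapolating beyond 3x the observed effort", call. = FALSE)
  }
  interp <- t_units <= eff_obs

  S <- lo <- hi <- numeric(length(effort))
  for (i in seq_along(effort)) {
    t <- t_units[i]
    if (t < 0) stop("negative effort", call. = FALSE)
    if (interp[i]) {
      e <- est(t)
      se <- sqrt(max(0, e[["var"]]))
      S[i] <- e[["S"]]; lo[i] <- max(0, S[i] - z * se); hi[i] <- S[i] + z * se
    } else {
      S[i] <- ext(t)
    }
  }
  if (any(!interp)) {
    bs <- with_seed(seed, {
      vapply(seq_len(boot), function(b) {
        rb <- resample()
        vapply(t_units[!interp], function(t) ext(t, rb), numeric(1))
      }, numeric(sum(!interp)))
    })
    bs <- matrix(bs, nrow = sum(!interp))
    qs <- apply(bs, 1L, stats::quantile,
                probs = c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
    # recentre the bootstrap band on the point estimate
    lo[!interp] <- S[!interp] + qs[1, ] - rowMeans(bs)
    hi[!interp] <- S[!interp] + qs[2, ] - rowMeans(bs)
  }
  structure(data.frame(effort = effort, S = S, lo = lo, hi = hi,
                       interpolated = interp),
            class = c("rarefaction_curve", "data.frame"),
            mode = mode, S_obs = S_obs, S_chao = S_chao)
}

#' Bootstrap rarefaction of exp H and 1/D
#'
#' Diversity of orders 1 and 2 as a function of effort, estimated by
#' resampling with replacement: at each effort level, `reps` bootstrap
#' samples are drawn (units with replacement in sample mode; individuals by
#' multinomial draw in individual mode), the pooled Hill numbers computed,
#' and the mean with percentile confidence limits reported.
#'
#' @param x An [abundance_table()], counts matrix, or count vector
#'   (individual mode).
#' @param effort Effort grid (units or individuals). Default `1:T` units or
#'   an even grid of individuals.
#' @param mode `"sample"` or `"individual"`.
#' @param reps Bootstrap replicates (default 1000).
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return Data frame: `effort`, `index` (`expH`/`invD`), `mean`, `lo`,
#'   `hi`.
#' @export
rarefy_diversity <- function(x, effort = NULL,
                             mode = c("sample", "individual"),
                             reps = 1000, conf = 0.95, seed = NULL) {
  mode <- match.arg(mode)
  if (inherits(x, "abundance_table")) {
    x <- if (mode == "individual") colSums(x$counts) else x$counts
  }
  if (mode == "sample") {
    counts <- as.matrix(x)
    Tn <- nrow(counts)
    if (is.null(effort)) effort <- seq_len(Tn)
    draw <- function(t) {
      colSums(counts[sample.int(Tn, t, replace = TRUE), , drop = FALSE])
    }
  } else {
    X <- x[x > 0]
    n <- sum(X)
    if (is.null(effort)) effort <- unique(round(seq(1, n, length.out = 15)))
    draw <- function(t) {
      stats::rmultinom(1, t, X / n)[, 1]
    }
  }
  if (any(effort <= 0)) stop("effort must be positive", call. = FALSE)
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  with_seed(seed, {
    rows <- lapply(effort, function(t) {
      h <- vapply(seq_len(reps), function(r) {
        cnt <- draw(t)
        if (sum(cnt) == 0) c(expH = NA_real_, invD = NA_real_)
        else hill_numbers(cnt)[c("expH", "invD")]
      }, numeric(2))
      do.call(rbind, lapply(c("expH", "invD"), function(ix) {
        v <- h[ix, ]
        q <- stats::quantile(v, probs, na.rm = TRUE)
        data.frame(effort = t, index = ix, mean = mean(v, na.rm = TRUE),
                   lo = q[[1]], hi = q[[2]], stringsAsFactors = FALSE)
      }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
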