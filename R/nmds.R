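#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Ordinates a dissimilarity matrix in `k` dimensions by minimising
#' Kruskal's stress-1, `sqrt(sum (d_config - dhat)^2 / sum d_config^2)`,
#' where `dhat` is the isotonic (monotone) regression of configuration
#' distances on the ranked input dissimilarities (primary/"weak" treatment
#' of ties: tied dissimilarities are free to take any order). Each start is
#' refined by alternating isotonic fits with Guttman-transform updates,
#' using step halving so the recorded stress never increases within a run;
#' the best of `restarts` starts (the first is a classical-scaling start,
#' the rest random) is returned. Deterministic under a fixed seed.
#'
#' @param d Symmetric dissimilarity matrix (e.g. [bray_curtis()]), `n >= 4`.
#' @param k Target dimensionality (default 2).
#' @param restarts Number of starts (default 20).
#' @param maxit,tol Iteration cap and relative stress-improvement tolerance
#'   per start.
#' @param seed Integer seed.
#' @return Object of class `nmds_fit`: `points` (n x k, centred and rotated
#'   to principal axes), `stress`, `trace` (stress path of the winning
#'   start), `converged`, `restarts`.
#' @export
nmds <- function(d, k = 2, restarts = 20, maxit = 200, tol = 1e-7,
                 seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 4) stop("nMDS needs at least 4 points", call. = FALSE)
  if (anyNA(d)) stop("dissimilarity matrix contains NA", call. = FALSE)
  lt <- lower.tri(d)
  dv <- d[lt]
  if (stats::sd(dv) == 0) {
    warning("degenerate input: all dissimilarities equal", call. = FALSE)
  }
  run_start <- function(X) {
    stress_of <- function(X) {
      dd <- as.matrix(stats::dist(X))[lt]
      # primary ("weak") tie treatment: tied dissimilarities are ordered by
      # the current configuration distances, so ties carry no penalty
      ord <- order(dv, dd)
      fit <- stats::isoreg(dd[ord])
      dhat <- numeric(length(dd))
      dhat[ord] <- fit$yf
      list(stress = sqrt(sum((dd - dhat)^2) / sum(dd^2)), dhat = dhat,
           dd = dd)
    }
    cur <- stress_of(X)
    trace <- cur$stress
    converged <- FALSE
    for (it in seq_len(maxit)) {
      # Guttman transform towards the fitted dhat
      dm <- matrix(0, n, n)
      dm[lt] <- ifelse(cur$dd > 0, cur$dhat / cur$dd, 0)
      dm <- dm + t(dm)
      B <- -dm
      diag(B) <- rowSums(dm)
      Xg <- B %*% X / n
      alpha <- 1
      improved <- FALSE
      for (h in 1:12) {
        Xt <- X + alpha * (Xg - X)
        cand <- stress_of(Xt)
        if (cand$stress <= cur$stress + 1e-15) {
          improved <- cand$stress < cur$stress * (1 - tol)
          X <- Xt; cur <- cand
          break
        }
        alpha <- alpha / 2
      }
      trace <- c(trace, cur$stress)
      if (!improved) { converged <- TRUE; break }
    }
    list(points = X, stress = cur$stress, trace = trace,
         converged = converged)
  }

  with_seed(seed, {
    starts <- vector("list", restarts)
    cmd <- try(stats::cmdscale(d, k = k), silent = TRUE)
    starts[[1]] <- if (!inherits(cmd, "try-error") && ncol(cmd) == k) cmd
      else matrix(stats::rnorm(n * k), n, k)
    for (r in seq_len(restarts)[-1]) {
      starts[[r]] <- matrix(stats::runif(n * k, -1, 1), n, k)
    }
    fits <- lapply(starts, run_start)
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "stress"))]]
    X <- scale(best$points, scale = FALSE)
    X <- X %*% svd(X)$v       # principal-axis rotation
    dimnames(X) <- list(rownames(d), paste0("MDS", seq_len(k)))
    structure(list(points = X, stress = best$stress, trace = best$trace,
                   converged = best$converged, restarts = restarts, k = k),
              class = "nmds_fit")
  })
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat(sprintf("nMDS (k = %d): stress-1 = %.4f after %d restarts%s\n",
              x$k, x$stress, x$restarts,
              if (x$converged) "" else " (iteration cap reached)"))
  invisible(x)
}
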