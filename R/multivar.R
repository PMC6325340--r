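#' Bray-Curtis dissimilarity on square-root transformed densities
#'
#' Converts counts to densities (`count / analysed area`), applies a
#' square-root transform, and computes the Bray-Curtis dissimilarity
#' `d_ij = sum_k |y_ik - y_jk| / sum_k (y_ik + y_jk)` for every unit pair.
#' Values lie in [0, 1]: 0 for identical rows, 1 for disjoint species sets.
#' A pair of two all-zero units has an undefined dissimilarity and is
#' returned as `NA` with a warning.
#'
#' @param x An [abundance_table()] or a numeric units x species matrix.
#' @param areas_m2 Unit areas (m^2) when `x` is a bare matrix; default 1
#'   (i.e. the matrix is already density or is to be used as is).
#' @param transform `"sqrt"` (default), `"none"`, or a function.
#' @return Symmetric matrix of class `dissimilarity` with zero diagonal.
#' @export
bray_curtis <- function(x, areas_m2 = NULL, transform = c("sqrt", "none")) {
  if (inherits(x, "abundance_table")) {
    areas_m2 <- areas_m2 %||% x$areas_m2
    x <- x$counts
  }
  if (!is.function(transform)) transform <- switch(match.arg(transform),
                                                   sqrt = sqrt,
                                                   none = identity)
  x <- as.matrix(x)
  areas_m2 <- areas_m2 %||% rep(1, nrow(x))
  if (any(areas_m2 <= 0)) stop("unit areas must be positive", call. = FALSE)
  y <- transform(sweep(x, 1L, areas_m2, `/`))
  n <- nrow(y)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      tot <- sum(y[i, ] + y[j, ])
      d[i, j] <- d[j, i] <- if (tot == 0) NA_real_ else
        sum(abs(y[i, ] - y[j, ])) / tot
    }
  }
  if (anyNA(d)) warning("pair(s) of empty units: dissimilarity undefined",
                        call. = FALSE)
  structure(d, class = c("dissimilarity", "matrix"), transform = "sqrt-density")
}

ss_within <- function(d2, groups) {
  sum(vapply(split(seq_along(groups), groups), function(ii) {
    if (length(ii) < 2) return(0)
    sum(d2[ii, ii][upper.tri(d2[ii, ii])]) / length(ii)
  }, numeric(1)))
}

permanova_stats <- function(d2, groups) {
  N <- length(groups)
  a <- length(unique(groups))
  SS_T <- sum(d2[upper.tri(d2)]) / N
  SS_W <- ss_within(d2, groups)
  SS_A <- SS_T - SS_W
  Fstat <- (SS_A / (a - 1)) / (SS_W / (N - a))
  c(F = Fstat, R2 = SS_A / SS_T)
}

#' One-way permutational multivariate ANOVA (PERMANOVA)
#'
#' Partitions the total sum of squared dissimilarities into among- and
#' within-group components (`SS_T = sum d^2 / N`, `SS_W` summed per group,
#' `SS_A = SS_T - SS_W`), forms the pseudo-F statistic
#' `(SS_A/(a-1)) / (SS_W/(N-a))` and `R^2 = SS_A / SS_T`, and obtains the
#' p-value by free permutation of unit labels:
#' `p = (1 + #permuted F >= observed F) / (1 + n_perm)`. Pairwise follow-up
#' tests rerun the analysis on each group pair; Holm-adjusted p-values are
#' reported alongside raw ones.
#'
#' @param d A `dissimilarity` matrix (see [bray_curtis()]).
#' @param groups Group label per unit; at least two groups of two.
#' @param n_perm Number of label permutations (default 999). When the
#'   number of distinct group relabellings is small (<= `n_perm`), the
#'   complete enumeration is used instead and the p-value is exact.
#' @param pairwise Run pairwise follow-ups (default `TRUE` for 3+ groups).
#' @param seed Integer seed.
#' @return List of class `permanova` with `F`, `R2`, `p`, `n_perm`,
#'   `exact`, and a `pairwise` data frame.
#' @export
permanova <- function(d, groups, n_perm = 999, pairwise = NULL,
                      seed = NULL) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  N <- length(groups)
  stopifnot(nrow(d) == N)
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least two groups", call. = FALSE)
  if (any(tab < 2)) stop("every group needs n >= 2 units", call. = FALSE)
  d2 <- d^2
  obs <- permanova_stats(d2, groups)

  n_arrangements <- exp(lgamma(N + 1) - sum(lgamma(tab + 1)))
  exact <- is.finite(n_arrangements) && n_arrangements <= n_perm
  perm_F <- if (exact) {
    perms <- label_arrangements(groups)
    vapply(perms, function(g) permanova_stats(d2, g)[["F"]], numeric(1))
  } else {
    with_seed(seed, vapply(seq_len(n_perm), function(i) {
      permanova_stats(d2, sample(groups))[["F"]]
    }, numeric(1)))
  }
  tol <- 1e-12
  if (exact) {
    # complete enumeration includes the observed arrangement once
    p <- sum(perm_F >= obs[["F"]] - tol) / length(perm_F)
  } else {
    p <- (1 + sum(perm_F >= obs[["F"]] - tol)) / (1 + length(perm_F))
  }

  pairwise <- pairwise %||% (length(tab) > 2)
  pw <- NULL
  if (isTRUE(pairwise)) {
    prs <- utils::combn(names(tab), 2, simplify = FALSE)
    pw <- do.call(rbind, lapply(seq_along(prs), function(k) {
      sel <- groups %in% prs[[k]]
      sub <- permanova(d[sel, sel, drop = FALSE], groups[sel],
                       n_perm = n_perm, pairwise = FALSE,
                       seed = child_seed(seed, k))
      data.frame(group1 = prs[[k]][1], group2 = prs[[k]][2],
                 F = sub$F, R2 = sub$R2, p = sub$p,
                 stringsAsFactors = FALSE)
    }))
    pw$p_adj <- stats::p.adjust(pw$p, method = "holm")
  }
  structure(list(F = obs[["F"]], R2 = obs[["R2"]], p = p,
                 n_perm = if (exact) length(perm_F) else n_perm,
                 exact = exact, pairwise = pw, groups = tab),
            class = "permanova")
}

# All distinct arrangements of a label multiset (used for exact tests).
label_arrangements <- function(groups) {
  N <- length(groups)
  lv <- unique(groups)
  rec <- function(remaining, slots) {
    if (length(lv[remaining > 0]) == 1L) {
      g <- character(length(slots))
      g[] <- lv[remaining > 0]
      return(list(stats::setNames(g, NULL)))
    }
    l1 <- which(remaining > 0)[1]
    out <- list()
    for (pick in utils::combn(seq_along(slots), remaining[l1],
                              simplify = FALSE)) {
      rem2 <- remaining
      rem2[l1] <- 0
      for (tail in rec(rem2, slots[-pick])) {
        g <- character(length(slots))
        g[pick] <- lv[l1]
        g[-pick] <- tail
        out[[length(out) + 1L]] <- g
      }
    }
    out
  }
  counts <- vapply(lv, function(l) sum(groups == l), integer(1))
  lapply(rec(counts, seq_len(N)), function(g) g)
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.3f, p = %.4g (%s, %d perms)\n",
              x$F, x$R2, x$p,
              if (x$exact) "exact enumeration" else "free permutation",
              x$n_perm))
  if (!is.null(x$pairwise)) {
    cat("pairwise:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' SIMPER: species contributions to between-group dissimilarity
#'
#' For every cross-group pair of units, each species' contribution to the
#' pair's Bray-Curtis dissimilarity is
#' `delta_k = |y_ik - y_jk| / sum_s (y_is + y_js)`; contributions are
#' averaged over all cross-group pairs and expressed as a percentage of the
#' mean between-group dissimilarity. By construction the per-species mean
#' contributions sum exactly to the mean dissimilarity.
#'
#' @param x An [abundance_table()] or units x species matrix.
#' @param groups Two-level group label per unit.
#' @param areas_m2,transform As in [bray_curtis()].
#' @return Data frame of class `simper`, sorted by decreasing contribution:
#'   `species`, `contribution` (dissimilarity units), `percent`,
#'   `cum_percent`, `mean_y_<group>` columns; the mean between-group
#'   dissimilarity is attached as attribute `overall`.
#' @export
simper <- function(x, groups, areas_m2 = NULL, transform = "sqrt") {
  if (inherits(x, "abundance_table")) {
    areas_m2 <- areas_m2 %||% x$areas_m2
    x <- x$counts
  }
  x <- as.matrix(x)
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) stop("SIMPER requires exactly two groups",
                            call. = FALSE)
  if (min(table(groups)) < 1) stop("empty group", call. = FALSE)
  areas_m2 <- areas_m2 %||% rep(1, nrow(x))
  f <- if (is.function(transform)) transform else
    switch(transform, sqrt = sqrt, none = identity)
  y <- f(sweep(x, 1L, areas_m2, `/`))
  i1 <- which(groups == lv[1])
  i2 <- which(groups == lv[2])
  contrib <- matrix(0, length(i1) * length(i2), ncol(y))
  k <- 0L
  for (i in i1) for (j in i2) {
    k <- k + 1L
    tot <- sum(y[i, ] + y[j, ])
    contrib[k, ] <- if (tot == 0) NA_real_ else abs(y[i, ] - y[j, ]) / tot
  }
  mc <- colMeans(contrib)
  overall <- sum(mc)
  ord <- order(mc, decreasing = TRUE)
  out <- data.frame(
    species = colnames(y)[ord] %||% as.character(ord),
    contribution = mc[ord],
    percent = 100 * mc[ord] / overall,
    stringsAsFactors = FALSE)
  out$cum_percent <- cumsum(out$percent)
  out[[paste0("mean_y_", lv[1])]] <- colMeans(y[i1, , drop = FALSE])[ord]
  out[[paste0("mean_y_", lv[2])]] <- colMeans(y[i2, , drop = FALSE])[ord]
  structure(out, class = c("simper", "data.frame"), overall = overall)
}

#' Spearman rank correlation with a permutation p-value
#'
#' Spearman's rho computed on mid-ranks (ties allowed), with significance
#' assessed by permutation of one variable (appropriate at the small sample
#' sizes of replicate-unit metrics) or by the asymptotic t approximation.
#'
#' @param x,y Numeric vectors, `n >= 4`.
#' @param n_perm Permutations (default 9999). For `n <= 7` all `n!`
#'   orderings are enumerated and the p-value is exact.
#' @param method `"permutation"` (default) or `"asymptotic"`.
#' @param seed Integer seed.
#' @return List with `rho`, `p`, `n`, `method`.
#' @export
spearman_cor <- function(x, y, n_perm = 9999,
                         method = c("permutation", "asymptotic"),
                         seed = NULL) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) stop("need n >= 4", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: rho undefined", call. = FALSE)
    return(list(rho = NA_real_, p = NA_real_, n = n, method = method))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (method == "asymptotic") {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  } else if (n <= 7) {
    perms <- perm_all(n)
    rhos <- vapply(perms, function(pm) stats::cor(rx, ry[pm]), numeric(1))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    p <- with_seed(seed, {
      rhos <- vapply(seq_len(n_perm), function(i) {
        stats::cor(rx, sample(ry))
      }, numeric(1))
      (1 + sum(abs(rhos) >= abs(rho) - 1e-12)) / (1 + n_perm)
    })
  }
  list(rho = rho, p = p, n = n, method = method)
}

perm_all <- function(n) {
  if (n == 1) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(perm_all(n - 1L), function(p) c(i, (seq_len(n)[-i])[p]))
  }))
}
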