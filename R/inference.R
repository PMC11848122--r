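## Permutational MANOVA on a distance matrix (sequential pond + year +
## pond:year partition of the Gower-centered inner-product matrix), SIMPER
## decompositions restricted to the year-to-centroid and consecutive-year
## comparisons, and least-squares vector fitting of external variables onto
## ordination scores.

# orthogonal projector onto the column space of X
.proj <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

#' Permutational multivariate ANOVA (PERMANOVA)
#'
#' Partitions the Gower-centered inner-product matrix `G = -1/2 J D^2 J` by
#' the sequential model `pond + year + pond:year`.  With `year_type =
#' "numeric"` (default) year enters as a single-df covariate, giving the
#' `pond (m-1 df) + year (1 df) + interaction (m-1 df)` pattern.  Pseudo-F
#' per term is `(SS_t / df_t) / (SS_res / df_res)`; significance is by free
#' permutation of the rows of the data (equivalently of `G`), with
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`.
#'
#' @param D dissimilarity matrix (rows aligned with `pond`/`year`).
#' @param pond categorical factor per row (default: matrix metadata).
#' @param year numeric covariate per row (default: matrix metadata).
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed for the permutations.
#' @param year_type `"numeric"` (1 df) or `"categorical"`.
#' @return data.frame with one row per term plus residual and total, and
#'   columns `df`, `SS`, `F`, `p`; attributes `n_perm` and `seed`; class
#'   `permanova`.
#' @export
permanova <- function(D, pond = NULL, year = NULL, n_perm = 999, seed = 1,
                      year_type = c("numeric", "categorical")) {
  year_type <- match.arg(year_type)
  g <- .resolve_groups(D, pond, year)
  pond <- factor(g$groups); year <- g$years
  if (is.null(pond) || is.null(year))
    stop("pond and year must be supplied or present as matrix metadata")
  if (n_perm < 99) stop("n_perm must be >= 99")
  Dm <- as.matrix(unclass(D))
  n <- nrow(Dm)
  yr <- if (year_type == "numeric") as.numeric(year) else factor(year)

  X0 <- matrix(1, n, 1)
  X1 <- stats::model.matrix(~pond)
  X2 <- stats::model.matrix(~ pond + yr)
  X3 <- stats::model.matrix(~ pond * yr)
  ranks <- vapply(list(X0, X1, X2, X3), function(X) qr(X)$rank, 0L)
  dfs <- diff(ranks)
  names(dfs) <- c("pond", "year", "pond:year")
  expected <- c(nlevels(pond) - 1,
                if (year_type == "numeric") 1 else nlevels(yr) - 1,
                NA)
  expected[3] <- expected[1] * expected[2]
  if (any(dfs[1:2] < expected[1:2]) || dfs[3] < 1) {
    aliased <- names(dfs)[c(dfs[1:2] < expected[1:2], dfs[3] < 1)]
    stop("rank-deficient design; aliased terms: ", paste(aliased, collapse = ", "))
  }
  df_res <- n - ranks[4]
  if (df_res < 1) stop("no residual degrees of freedom")

  P0 <- .proj(X0); P1 <- .proj(X1); P2 <- .proj(X2); P3 <- .proj(X3)
  H <- list(pond = P1 - P0, year = P2 - P1, `pond:year` = P3 - P2)
  R <- diag(n) - P3
  G <- gower_center(Dm)

  ss_of <- function(Gm) c(vapply(H, function(h) sum(h * Gm), 0), res = sum(R * Gm))
  obs <- ss_of(G)
  ss <- obs[1:3]; ss_res <- obs[4]
  Fobs <- (ss / dfs) / (ss_res / df_res)

  exceed <- rep(0L, 3)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      pm <- sample.int(n)
      sp <- ss_of(G[pm, pm])
      Fp <- (sp[1:3] / dfs) / (sp[4] / df_res)
      exceed <- exceed + (Fp >= Fobs)
    }
  })
  pvals <- (1 + exceed) / (1 + n_perm)

  out <- data.frame(
    term = c(names(dfs), "Residuals", "Total"),
    df = c(dfs, df_res, n - 1),
    SS = c(ss, ss_res, sum(diag(G))),
    F = c(Fobs, NA, NA),
    p = c(pvals, NA, NA)
  )
  rownames(out) <- NULL
  structure(out, class = c("permanova", "data.frame"),
            n_perm = n_perm, seed = seed, year_type = year_type)
}

#' Per-variable contributions to one Bray-Curtis comparison
#'
#' `contribution_i = |x_i - y_i| / sum_s (x_s + y_s)`; the contributions sum
#' exactly to the Bray-Curtis dissimilarity of the pair.
#'
#' @param x,y non-negative composition rows (equal length).
#' @return named numeric vector of contributions.
#' @export
simper_pair <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(x < 0) || any(y < 0)) stop("negative entries")
  tot <- sum(x + y)
  if (tot == 0) {
    warning("all-zero row pair: contributions set to 0")
    return(stats::setNames(rep(0, length(x)), names(x)))
  }
  abs(x - y) / tot
}

#' SIMPER restricted to year-to-centroid comparisons
#'
#' Per pond, the time-mean composition row is appended and each year is
#' compared to it; contributions are averaged over years and expressed as a
#' percent of their total.
#'
#' @param M non-negative community matrix.
#' @param groups,years row index (default: matrix metadata).
#' @return data.frame with columns `pond`, `variable`, `contribution`
#'   (average), `percent`; class `simper_result`.
#' @export
simper_year_to_centroid <- function(M, groups = NULL, years = NULL) {
  g <- .resolve_groups(M, groups, years)
  groups <- as.character(g$groups)
  V <- as.matrix(unclass(M))
  if (is.null(colnames(V))) colnames(V) <- paste0("c", seq_len(ncol(V)))
  out <- do.call(rbind, lapply(unique(groups), function(p) {
    i <- which(groups == p)
    if (length(i) < 2) stop("pond '", p, "' needs >= 2 years")
    ctr <- colMeans(V[i, , drop = FALSE])
    contrib <- rowMeans(vapply(i, function(r) simper_pair(V[r, ], ctr),
                               numeric(ncol(V))))
    tot <- sum(contrib)
    pct <- if (tot == 0) rep(0, length(contrib)) else 100 * contrib / tot
    data.frame(pond = p, variable = colnames(V), contribution = unname(contrib),
               percent = unname(pct), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("simper_result", "data.frame")
  out
}

#' SIMPER restricted to consecutive-year comparisons
#'
#' Per pond and consecutive year pair, the per-variable contributions and
#' percents; optionally a pond-level summary averaging group-summed percents
#' over transitions (the pie-chart numbers: feeding modes for species,
#' functional roles for traits).
#'
#' @inheritParams simper_year_to_centroid
#' @param column_groups optional named vector mapping columns to groups.
#' @return list of class `simper_result` with `per_transition` (data.frame:
#'   `pond`, `from_year`, `to_year`, `variable`, `contribution`, `percent`)
#'   and `pond_summary` (data.frame: `pond`, `group`, `percent`, or `NULL`).
#' @export
simper_year_to_year <- function(M, groups = NULL, years = NULL,
                                column_groups = NULL) {
  g <- .resolve_groups(M, groups, years)
  groups <- as.character(g$groups); years <- g$years
  V <- as.matrix(unclass(M))
  if (is.null(colnames(V))) colnames(V) <- paste0("c", seq_len(ncol(V)))
  rows <- list()
  for (p in unique(groups)) {
    i <- which(groups == p)
    i <- i[order(years[i])]
    yr <- years[i]
    ok <- which(diff(yr) == 1)
    for (t in ok) {
      contrib <- simper_pair(V[i[t], ], V[i[t + 1], ])
      tot <- sum(contrib)
      pct <- if (tot == 0) rep(0, length(contrib)) else 100 * contrib / tot
      rows[[length(rows) + 1]] <- data.frame(
        pond = p, from_year = yr[t], to_year = yr[t + 1],
        variable = colnames(V), contribution = unname(contrib),
        percent = unname(pct), stringsAsFactors = FALSE
      )
    }
  }
  per_transition <- do.call(rbind, rows)
  rownames(per_transition) <- NULL
  pond_summary <- NULL
  if (!is.null(column_groups)) {
    per_transition$group <- unname(column_groups[per_transition$variable])
    if (anyNA(per_transition$group)) stop("column_groups does not cover all columns")
    key <- paste(per_transition$pond, per_transition$from_year, sep = "\r")
    gsum <- stats::aggregate(percent ~ pond + from_year + group,
                             data = per_transition, FUN = sum)
    pond_summary <- stats::aggregate(percent ~ pond + group, data = gsum, FUN = mean)
    pond_summary <- pond_summary[order(pond_summary$pond, pond_summary$group), ]
    rownames(pond_summary) <- NULL
    per_transition$group <- NULL
  }
  structure(list(per_transition = per_transition, pond_summary = pond_summary),
            class = "simper_result")
}

#' Fit external variables onto an ordination (vector fitting)
#'
#' For each variable: least-squares regression of the centered variable on
#' the centered ordination scores; `R^2 = 1 - SSE/SST`; the arrow direction
#' is the coefficient vector normalized to unit length; significance by
#' permuting the variable's rows, `p = (1 + #\{R^2_perm >= R^2_obs\}) /
#' (1 + n_perm)`.
#'
#' @param ord an `ordination` (or a plain score matrix).
#' @param V matrix of variables, rows aligned with the scores.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @return data.frame with direction cosines (`nMDS1`, ..., unit norm),
#'   `r2` and `p` per variable; class `envfit_result`.
#' @export
envfit <- function(ord, V, n_perm = 999, seed = 1) {
  S <- if (inherits(ord, "ordination")) ord$scores else as.matrix(ord)
  V <- as.matrix(unclass(V))
  if (nrow(V) != nrow(S)) stop("rows of V must align with ordination scores")
  k <- ncol(S)
  if (k < 2) stop("need at least 2 ordination axes")
  Sc <- scale(S, center = TRUE, scale = FALSE)
  XtXi <- solve(crossprod(Sc))
  Hfit <- Sc %*% XtXi %*% t(Sc)

  res <- with_seed(seed, {
    lapply(seq_len(ncol(V)), function(j) {
      v <- V[, j] - mean(V[, j])
      sst <- sum(v^2)
      if (sst == 0) {
        warning("constant variable '", colnames(V)[j] %||% j,
                "': R^2 = 0, p = 1")
        return(c(rep(0, k), 0, 1))
      }
      beta <- XtXi %*% crossprod(Sc, v)
      r2 <- sum((Hfit %*% v)^2) / sst
      dir <- as.numeric(beta) / sqrt(sum(beta^2))
      exceed <- 0L
      for (b in seq_len(n_perm)) {
        vp <- v[sample.int(length(v))]
        if (sum((Hfit %*% vp)^2) / sst >= r2 - 1e-15) exceed <- exceed + 1L
      }
      c(dir, r2, (1 + exceed) / (1 + n_perm))
    })
  })
  out <- as.data.frame(do.call(rbind, res))
  names(out) <- c(colnames(S) %||% paste0("nMDS", seq_len(k)), "r2", "p")
  out <- cbind(variable = colnames(V) %||% paste0("v", seq_len(ncol(V))), out)
  rownames(out) <- NULL
  structure(out, class = c("envfit_result", "data.frame"),
            n_perm = n_perm, seed = seed)
}
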