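## From-scratch multivariate engines: Bray-Curtis dissimilarity, principal
## coordinates analysis (Gower double centering, negative eigenvalues kept),
## and non-metric multidimensional scaling (Kruskal stress-1, isotonic
## regression by pool-adjacent-violators, Guttman update with backtracking).

#' Bray-Curtis dissimilarity matrix
#'
#' `d(j, k) = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik)` over rows of a
#' non-negative matrix.  A pair of all-zero rows has no defined
#' dissimilarity; it is set to 0 with a warning.
#'
#' @param M non-negative matrix (rows = communities).
#' @return symmetric n x n matrix of class `dist_matrix`, zero diagonal,
#'   entries in \[0, 1\]; rownames of `M` carried over, and the (pond, year)
#'   index of a [community_matrix()] preserved in attribute `meta`.
#' @export
bray_curtis <- function(M) {
  meta <- if (inherits(M, "community_matrix")) cm_meta(M) else attr(M, "meta")
  V <- as.matrix(unclass(M))
  neg <- which(V < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative entry at row '%s', column '%s'",
                 rownames(V)[neg[1, 1]] %||% neg[1, 1],
                 colnames(V)[neg[1, 2]] %||% neg[1, 2]))
  n <- nrow(V)
  D <- matrix(0, n, n, dimnames = list(rownames(V), rownames(V)))
  rs <- rowSums(V)
  warned <- FALSE
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      tot <- rs[i] + rs[j]
      if (tot == 0) {
        if (!warned) { warning("all-zero row pair: dissimilarity set to 0"); warned <- TRUE }
        d <- 0
      } else d <- sum(abs(V[i, ] - V[j, ])) / tot
      D[i, j] <- D[j, i] <- d
    }
  }
  structure(D, class = c("dist_matrix", "matrix"), meta = meta)
}

#' Principal coordinates analysis
#'
#' Eigendecomposition of the Gower-centered matrix `-1/2 J D^2 J`.
#' Non-Euclidean dissimilarities (e.g. Bray-Curtis) yield negative
#' eigenvalues; coordinates are kept separately for positive- and
#' negative-eigenvalue axes so that squared distances reconstruct as
#' (positive part) - (negative part).
#'
#' @param D symmetric dissimilarity matrix.
#' @return object of class `pcoa`: list with `pos` (n x k+ coordinates),
#'   `neg` (n x k- coordinates), `eigenvalues` (descending, zeros dropped),
#'   `labels`, `meta`.
#' @export
pcoa <- function(D) {
  D <- as.matrix(unclass(D))
  n <- nrow(D)
  G <- gower_center(D)
  e <- eigen(G, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9 + 1e-12
  pos <- which(e$values > tol)
  neg <- which(e$values < -tol)
  P <- if (length(pos)) e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), length(pos))
       else matrix(0, n, 0)
  N <- if (length(neg)) e$vectors[, neg, drop = FALSE] %*% diag(sqrt(-e$values[neg]), length(neg))
       else matrix(0, n, 0)
  rownames(P) <- rownames(N) <- rownames(D)
  structure(list(pos = P, neg = N,
                 eigenvalues = e$values[c(pos, neg)],
                 labels = rownames(D), meta = attr(D, "meta")),
            class = "pcoa")
}

# -1/2 J D^2 J with J = I - 11'/n
gower_center <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  rm_ <- rowMeans(A); gm <- mean(A)
  G <- A - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm
  (G + t(G)) / 2
}

# squared distances (signed geometry) from points to a reference point
pcoa_sqdist_to <- function(pc, ref_pos, ref_neg) {
  dp <- sweep(pc$pos, 2, ref_pos)
  dn <- sweep(pc$neg, 2, ref_neg)
  rowSums(dp^2) - rowSums(dn^2)
}

#' @export
print.pcoa <- function(x, ...) {
  cat(sprintf("pcoa: %d points, %d positive / %d negative eigenvalue axes\n",
              length(x$labels), ncol(x$pos), ncol(x$neg)))
  invisible(x)
}

# weighted pool-adjacent-violators: nondecreasing fit to y
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n == 0) return(numeric(0))
  val <- y; wt <- w; len <- rep(1L, n)
  k <- 1L
  for (i in seq_len(n)) {
    val[k] <- y[i]; wt[k] <- w[i]; len[k] <- 1L
    while (k > 1 && val[k - 1] > val[k]) {
      tw <- wt[k - 1] + wt[k]
      val[k - 1] <- (wt[k - 1] * val[k - 1] + wt[k] * val[k]) / tw
      wt[k - 1] <- tw
      len[k - 1] <- len[k - 1] + len[k]
      k <- k - 1L
    }
    k <- k + 1L
  }
  rep.int(val[seq_len(k - 1L)], len[seq_len(k - 1L)])
}

# lower-triangle (i > j) index pairs for an n x n matrix
lt_pairs <- function(n) {
  stopifnot(n >= 2)
  cbind(i = unlist(lapply(2:n, function(r) rep(r, r - 1))),
        j = unlist(lapply(2:n, function(r) seq_len(r - 1))))
}

# Kruskal stress-1 of configuration X against dissimilarities d (vector,
# lower triangle), with primary (weak) tie handling
.stress1 <- function(d, cd, ord = NULL) {
  ord <- ord %||% order(d, cd)
  dhat <- numeric(length(d))
  dhat[ord] <- pava(cd[ord])
  sqrt(sum((cd - dhat)^2) / sum(cd^2))
}

#' Stress of a configuration against a dissimilarity matrix
#'
#' Kruskal stress-1 with disparities from isotonic (pool-adjacent-violators)
#' regression of configuration distances on the rank-ordered dissimilarities
#' (primary tie treatment).  Useful for checking rotation invariance and
#' external configurations.
#'
#' @param D dissimilarity matrix.
#' @param X n x k configuration.
#' @return stress-1 value in \[0, 1\].
#' @export
nmds_stress <- function(D, X) {
  D <- as.matrix(unclass(D))
  p <- lt_pairs(nrow(D))
  cdm <- as.matrix(stats::dist(X))
  .stress1(D[p], cdm[p])
}

#' Non-metric multidimensional scaling
#'
#' Minimizes Kruskal stress-1 by alternating isotonic regression (primary
#' ties) with a Guttman configuration update, backtracking the step so that
#' stress never increases within a start.  Runs `n_starts` random starts
#' plus one principal-coordinates start and returns the best.
#'
#' @param D dissimilarity matrix.
#' @param k number of ordination axes.
#' @param n_starts random starts in addition to the PCoA start.
#' @param max_iter iteration cap per start.
#' @param tol stop when the stress improvement falls below `tol`.
#' @param seed integer seed (random starts).
#' @return object of class `ordination`: list with `scores` (n x k,
#'   centered), `stress`, `converged`, `n_starts`, `stress_trace` (best
#'   start), `meta`.
#' @export
nmds <- function(D, k = 2, n_starts = 20, max_iter = 200, tol = 1e-7, seed = 1) {
  Dm <- as.matrix(unclass(D))
  n <- nrow(Dm)
  if (k < 1) stop("k must be >= 1")
  if (n < k + 1) stop("need n >= k + 1 points")
  p <- lt_pairs(n)
  d <- Dm[p]

  run_start <- function(X) {
    trace <- numeric(0)
    conv <- FALSE
    cdm <- as.matrix(stats::dist(X))
    s <- .stress1(d, cdm[p])
    trace <- s
    for (it in seq_len(max_iter)) {
      cd <- cdm[p]
      ord <- order(d, cd)
      dhat <- numeric(length(d)); dhat[ord] <- pava(cd[ord])
      # Guttman transform with disparities dhat
      B <- matrix(0, n, n)
      ratio <- ifelse(cd > 1e-12, dhat / cd, 0)
      B[p] <- -ratio; B[p[, c(2, 1)]] <- -ratio
      diag(B) <- -rowSums(B)
      Xg <- B %*% X / n
      alpha <- 1
      repeat {
        Xn <- X + alpha * (Xg - X)
        cdm_n <- as.matrix(stats::dist(Xn))
        sn <- .stress1(d, cdm_n[p])
        if (sn <= s + 1e-15 || alpha < 1e-4) break
        alpha <- alpha / 2
      }
      if (sn > s + 1e-15) { conv <- TRUE; break }   # no improving step
      improved <- s - sn
      X <- Xn; cdm <- cdm_n; s <- sn
      trace <- c(trace, s)
      if (improved < tol) { conv <- TRUE; break }
    }
    list(X = X, stress = s, converged = conv, trace = trace)
  }

  with_seed(seed, {
    starts <- list()
    pc <- pcoa(Dm)
    X0 <- cbind(pc$pos, matrix(stats::rnorm(n * k, 0, 1e-4), n, k))[, seq_len(k), drop = FALSE]
    starts[[1]] <- X0
    for (s in seq_len(n_starts))
      starts[[s + 1]] <- matrix(stats::rnorm(n * k), n, k)
    best <- NULL
    for (X in starts) {
      r <- run_start(X)
      if (is.null(best) || r$stress < best$stress) best <- r
    }
    scores <- scale(best$X, center = TRUE, scale = FALSE)
    attr(scores, "scaled:center") <- NULL
    dimnames(scores) <- list(rownames(Dm), paste0("nMDS", seq_len(k)))
    structure(list(scores = scores, stress = best$stress,
                   converged = best$converged, n_starts = n_starts,
                   stress_trace = best$trace,
                   meta = attr(D, "meta")),
              class = "ordination")
  })
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("nMDS ordination: %d points x %d axes, stress-1 = %.5f (%s)\n",
              nrow(x$scores), ncol(x$scores), x$stress,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Serialize a distance matrix or ordination
#'
#' @param D,ord objects to write.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_dist_csv <- function(D, path) {
  utils::write.csv(as.data.frame(as.matrix(unclass(D))), path, quote = FALSE)
  invisible(path)
}

#' @rdname write_dist_csv
#' @export
write_ordination_csv <- function(ord, path) {
  df <- data.frame(label = rownames(ord$scores), ord$scores, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  writeLines(sprintf("stress-1 = %.6f (converged: %s; %d random starts)",
                     ord$stress, ord$converged, ord$n_starts),
             paste0(path, ".stress.txt"))
  invisible(path)
}
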