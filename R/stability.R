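## Stability metrics: betadisper-style year-to-centroid distances (in PCoA
## space, with the negative-eigenvalue correction) or raw Bray-Curtis to the
## time-mean composition; year-to-year distances between consecutive years;
## max-normalized relative stability; and the crossed two-way ANOVA
## comparing ponds and composition types.

.resolve_dist <- function(x) {
  if (inherits(x, "dist_matrix")) x
  else if (inherits(x, "community_matrix") || is.matrix(x)) bray_curtis(x)
  else stop("x must be a dist_matrix or a community matrix")
}

.resolve_groups <- function(x, groups, years) {
  meta <- if (!is.null(attr(x, "meta"))) attr(x, "meta")
          else if (inherits(x, "community_matrix")) cm_meta(x) else NULL
  list(groups = groups %||% meta$pond, years = years %||% meta$year)
}

#' Year-to-centroid distances per pond
#'
#' For each pond, the distance of each yearly community from the pond's
#' multi-year average.  The default mode (`"pcoa_centroid"`) works in
#' principal-coordinates space as the dispersion analysis of vegan's
#' `betadisper`: squared distance = (positive-axis part) - (negative-axis
#' part), floored at zero before the square root.  Mode `"raw_to_mean"`
#' instead takes the Bray-Curtis dissimilarity between each year's raw
#' composition row and the pond's time-averaged composition row (requires a
#' community matrix, not just a distance matrix).
#'
#' @param x a `dist_matrix`, or a community matrix (required for
#'   `"raw_to_mean"`; Bray-Curtis is computed internally for
#'   `"pcoa_centroid"`).
#' @param groups pond label per row (default: from the matrix metadata).
#' @param years year per row (default: from the matrix metadata).
#' @param mode `"pcoa_centroid"` or `"raw_to_mean"`.
#' @param centroid_type `"centroid"` (group mean, the default) or
#'   `"median"` (spatial median found numerically, as in `betadisper`'s
#'   default).
#' @return data.frame with columns `pond`, `year`, `distance`; attribute
#'   `n_floored` counts negative squared distances floored at 0.
#' @export
year_to_centroid <- function(x, groups = NULL, years = NULL,
                             mode = c("pcoa_centroid", "raw_to_mean"),
                             centroid_type = c("centroid", "median")) {
  mode <- match.arg(mode)
  centroid_type <- match.arg(centroid_type)
  g <- .resolve_groups(x, groups, years)
  groups <- as.character(g$groups); years <- g$years
  if (is.null(groups) || is.null(years))
    stop("groups and years must be supplied or present as matrix metadata")

  keep_ponds <- names(which(table(groups) >= 2))
  dropped <- setdiff(unique(groups), keep_ponds)
  if (length(dropped))
    warning("ponds with a single year dropped: ", paste(dropped, collapse = ", "))

  n_floored <- 0L
  if (mode == "raw_to_mean") {
    if (!is.matrix(x) || inherits(x, "dist_matrix"))
      stop("raw_to_mean mode needs the composition matrix, not a distance matrix")
    V <- as.matrix(unclass(x))
    out <- do.call(rbind, lapply(keep_ponds, function(p) {
      i <- which(groups == p)
      ctr <- colMeans(V[i, , drop = FALSE])
      d <- vapply(i, function(r) {
        tot <- sum(V[r, ] + ctr)
        if (tot == 0) 0 else sum(abs(V[r, ] - ctr)) / tot
      }, 0)
      data.frame(pond = p, year = years[i], distance = d)
    }))
  } else {
    D <- .resolve_dist(x)
    pc <- pcoa(D)
    out <- do.call(rbind, lapply(keep_ponds, function(p) {
      i <- which(groups == p)
      if (centroid_type == "centroid") {
        cp <- colMeans(pc$pos[i, , drop = FALSE])
        cn <- colMeans(pc$neg[i, , drop = FALSE])
      } else {
        ctr <- .spatial_median(pc$pos[i, , drop = FALSE], pc$neg[i, , drop = FALSE])
        cp <- ctr$pos; cn <- ctr$neg
      }
      d2 <- pcoa_sqdist_to(pc, cp, cn)[i]
      n_floored <<- n_floored + sum(d2 < 0)
      data.frame(pond = p, year = years[i], distance = sqrt(pmax(d2, 0)))
    }))
  }
  rownames(out) <- NULL
  attr(out, "n_floored") <- n_floored
  attr(out, "mode") <- mode
  out
}

# numerical spatial (L1) median in the signed PCoA geometry
.spatial_median <- function(pos, neg) {
  kp <- ncol(pos); kn <- ncol(neg)
  obj <- function(par) {
    cp <- par[seq_len(kp)]
    cn <- if (kn) par[kp + seq_len(kn)] else numeric(0)
    d2 <- rowSums(sweep(pos, 2, cp)^2)
    if (kn) d2 <- d2 - rowSums(sweep(neg, 2, cn)^2)
    sum(sqrt(pmax(d2, 0)))
  }
  start <- c(colMeans(pos), if (kn) colMeans(neg))
  if (length(start) == 0) return(list(pos = numeric(0), neg = numeric(0)))
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  list(pos = fit$par[seq_len(kp)],
       neg = if (kn) fit$par[kp + seq_len(kn)] else numeric(0))
}

#' Year-to-year distances per pond
#'
#' For each pond, the dissimilarity between consecutive observed years.
#' A gap in the year sequence is logged and not bridged (no distance is
#' reported across missing years).
#'
#' @inheritParams year_to_centroid
#' @return data.frame with columns `pond`, `from_year`, `to_year`,
#'   `distance`.
#' @export
year_to_year <- function(x, groups = NULL, years = NULL) {
  D <- .resolve_dist(x)
  g <- .resolve_groups(D, groups, years)
  groups <- as.character(g$groups); years <- g$years
  if (is.null(groups) || is.null(years))
    stop("groups and years must be supplied or present as matrix metadata")
  Dm <- as.matrix(unclass(D))
  out <- list()
  for (p in unique(groups)) {
    i <- which(groups == p)
    if (length(i) < 2) {
      warning("pond '", p, "' has < 2 years: no transitions")
      next
    }
    i <- i[order(years[i])]
    yr <- years[i]
    dy <- diff(yr)
    gaps <- which(dy > 1)
    if (length(gaps))
      message(sprintf("year_to_year: pond '%s' has %d gap(s) in the year sequence (not bridged)",
                      p, length(gaps)))
    ok <- which(dy == 1)
    if (length(ok))
      out[[p]] <- data.frame(
        pond = p, from_year = yr[ok], to_year = yr[ok + 1],
        distance = Dm[cbind(i[ok], i[ok + 1])]
      )
  }
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(pond = character(0), from_year = numeric(0),
               to_year = numeric(0), distance = numeric(0))
  rownames(out) <- NULL
  out
}

#' Max-normalized relative stability
#'
#' Divides every distance by the maximum distance observed across all ponds
#' and units within the composition type, so the least stable pond-unit has
#' relative distance 1.
#'
#' @param distances data.frame from [year_to_centroid()] or
#'   [year_to_year()] (must have a `distance` column).
#' @param composition_type label, e.g. `"species"` or `"trait"`.
#' @return the input with `composition_type` and `relative_distance`
#'   columns appended; class `stability_table`.
#' @export
relative_stability <- function(distances, composition_type) {
  stopifnot("distance" %in% names(distances))
  mx <- max(distances$distance)
  if (mx == 0) {
    warning("all distances are zero; relative distances set to 0")
    rel <- rep(0, nrow(distances))
  } else rel <- distances$distance / mx
  out <- cbind(distances,
               composition_type = rep(composition_type, nrow(distances)),
               relative_distance = rel)
  class(out) <- c("stability_table", "data.frame")
  out
}

#' Two-way ANOVA of relative stability
#'
#' Fixed-effects crossed ANOVA `relative_distance ~ pond * composition_type`
#' with years (or year transitions) as replicates.  Balanced designs use
#' sequential (Type I) sums of squares, which coincide with all other types
#' when balanced; an unbalanced design triggers a warning and Type II sums
#' of squares.
#'
#' @param table a `stability_table` (rows for both composition types), or
#'   any data.frame with `pond`, `composition_type`, `relative_distance`.
#' @param response response column name.
#' @return data.frame with one row per term (`pond`, `composition_type`,
#'   `pond:composition_type`, `Residuals`) and columns `df`, `sumsq`,
#'   `meansq`, `F`, `p`; class `anova_table`.
#' @export
stability_anova <- function(table, response = "relative_distance") {
  d <- data.frame(pond = factor(table$pond),
                  composition_type = factor(table$composition_type),
                  y = table[[response]])
  cells <- table(d$pond, d$composition_type)
  if (any(cells == 0)) stop("empty pond x composition_type cells: design must be complete")
  balanced <- length(unique(as.vector(cells))) == 1

  if (stats::var(d$y) < 1e-24) {
    # degenerate: identical response everywhere, every F is 0 by convention
    dfs <- c(nlevels(d$pond) - 1, nlevels(d$composition_type) - 1,
             (nlevels(d$pond) - 1) * (nlevels(d$composition_type) - 1))
    out <- data.frame(
      term = c("pond", "composition_type", "pond:composition_type", "Residuals"),
      df = c(dfs, nrow(d) - 1 - sum(dfs)),
      sumsq = 0, meansq = 0, F = c(0, 0, 0, NA), p = c(1, 1, 1, NA))
    class(out) <- c("anova_table", "data.frame")
    return(out)
  }

  if (nlevels(d$pond) == 1 || nlevels(d$composition_type) == 1) {
    # degenerate crossing: one-way ANOVA on the remaining factor
    fac <- if (nlevels(d$pond) > 1) "pond" else "composition_type"
    fit <- stats::lm(stats::reformulate(fac, "y"), data = d)
    a <- stats::anova(fit)
    out <- data.frame(term = rownames(a), df = a$Df, sumsq = a$`Sum Sq`,
                      meansq = a$`Mean Sq`, F = a$`F value`, p = a$`Pr(>F)`)
    rownames(out) <- NULL
    class(out) <- c("anova_table", "data.frame")
    return(out)
  }

  if (balanced) {
    fit <- stats::lm(y ~ pond * composition_type, data = d)
    a <- stats::anova(fit)
    out <- data.frame(term = rownames(a), df = a$Df, sumsq = a$`Sum Sq`,
                      meansq = a$`Mean Sq`, F = a$`F value`, p = a$`Pr(>F)`)
  } else {
    warning("unbalanced design: using Type II sums of squares")
    full <- stats::lm(y ~ pond * composition_type, data = d)
    mains <- stats::lm(y ~ pond + composition_type, data = d)
    no_pond <- stats::lm(y ~ composition_type, data = d)
    no_type <- stats::lm(y ~ pond, data = d)
    rss <- function(m) sum(stats::residuals(m)^2)
    df_res <- stats::df.residual(full)
    ms_res <- rss(full) / df_res
    ss <- c(pond = rss(no_pond) - rss(mains),
            composition_type = rss(no_type) - rss(mains),
            `pond:composition_type` = rss(mains) - rss(full))
    dfs <- c(nlevels(d$pond) - 1, nlevels(d$composition_type) - 1,
             (nlevels(d$pond) - 1) * (nlevels(d$composition_type) - 1))
    Fv <- (ss / dfs) / ms_res
    out <- data.frame(term = c(names(ss), "Residuals"),
                      df = c(dfs, df_res),
                      sumsq = c(ss, rss(full)),
                      meansq = c(ss / dfs, ms_res),
                      F = c(Fv, NA),
                      p = c(stats::pf(Fv, dfs, df_res, lower.tail = FALSE), NA))
  }
  rownames(out) <- NULL
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Compact text summary of a stability table
#'
#' Mean relative distance per pond and per composition type, the numeric
#' content of the usual box-plot summaries.
#'
#' @param table a `stability_table`.
#' @param path optional file to write; `NULL` prints to the console.
#' @return the summary lines, invisibly.
#' @export
stability_report <- function(table, path = NULL) {
  by_pond <- tapply(table$relative_distance,
                    list(table$pond, table$composition_type), mean)
  by_type <- tapply(table$relative_distance, table$composition_type, mean)
  lines <- c("mean relative distance (lower = more stable)",
             "", "by pond x composition type:",
             utils::capture.output(print(round(by_pond, 4))),
             "", "by composition type:",
             utils::capture.output(print(round(by_type, 4))))
  if (is.null(path)) writeLines(lines) else writeLines(lines, path)
  invisible(lines)
}
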