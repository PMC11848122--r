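## Community matrices: one row per pond x year, columns either species
## (mean counts, two-stage averaged over stations then months) or the 13
## community-weighted traits.

#' Construct a community matrix
#'
#' A numeric matrix with a (pond, year) row index carried as an attribute;
#' rownames are `"pond:year"`.
#'
#' @param values numeric matrix.
#' @param pond,year row index vectors, one entry per row of `values`.
#' @return object of class `community_matrix`.
#' @export
community_matrix <- function(values, pond, year) {
  values <- as.matrix(values)
  stopifnot(length(pond) == nrow(values), length(year) == nrow(values))
  rn <- paste(pond, year, sep = ":")
  if (anyDuplicated(rn)) stop("duplicate (pond, year) row labels")
  rownames(values) <- rn
  structure(values, class = c("community_matrix", "matrix"),
            meta = data.frame(pond = as.character(pond), year = as.numeric(year),
                              stringsAsFactors = FALSE))
}

#' @rdname community_matrix
#' @param x a `community_matrix` (or any matrix with `"pond:year"` rownames).
#' @return `cm_meta()`: data.frame with columns `pond` and `year`.
#' @export
cm_meta <- function(x) {
  m <- attr(x, "meta")
  if (!is.null(m)) return(m)
  parts <- strsplit(rownames(x), ":", fixed = TRUE)
  data.frame(pond = vapply(parts, `[`, "", 1),
             year = as.numeric(vapply(parts, `[`, "", 2)),
             stringsAsFactors = FALSE)
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix: %d pond-year rows x %d columns\n", nrow(x), ncol(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Build the species abundance matrix from survey records
#'
#' Counts are first averaged across stations within each month (accounting
#' for dependence within a pond), then averaged across months (seasonal
#' presence); species absent from a sampled station-month count as zero.
#' Denominators are the stations/months actually sampled in each pond-year,
#' taken from the records themselves.  `average = "grand"` instead takes one
#' grand mean over all sampled station-months.
#'
#' @param records survey data.frame (count rows are used).
#' @param average `"two_stage"` (default) or `"grand"`.
#' @return a [community_matrix()] of mean counts, species columns in
#'   alphabetical order.
#' @export
build_abundance_matrix <- function(records, average = c("two_stage", "grand")) {
  average <- match.arg(average)
  cnt <- records[!is.na(records$count), , drop = FALSE]
  if (nrow(cnt) == 0) stop("no count records")
  if (any(cnt$count < 0)) stop("negative counts")

  key <- paste(cnt$pond, cnt$year, cnt$month, cnt$station, cnt$species, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate (pond,year,month,station,species) rows summed")
    agg <- stats::aggregate(count ~ pond + year + month + station + species,
                            data = cnt, FUN = sum)
    cnt <- agg
  }
  species <- sort(unique(cnt$species))
  # sampling events actually present
  ev <- unique(cnt[, c("pond", "year", "month", "station")])
  pym <- unique(ev[, c("pond", "year", "month")])
  n_st <- stats::aggregate(station ~ pond + year + month, data = ev, FUN = length)
  names(n_st)[4] <- "n_stations"
  n_mo <- stats::aggregate(month ~ pond + year, data = pym, FUN = length)
  names(n_mo)[3] <- "n_months"

  # sum over stations, divide by stations sampled that month, sum over
  # months, divide by months sampled that year
  s1 <- stats::aggregate(count ~ pond + year + month + species, data = cnt, FUN = sum)
  s1 <- merge(s1, n_st, by = c("pond", "year", "month"))
  if (average == "two_stage") {
    s1$mcount <- s1$count / s1$n_stations
    s2 <- stats::aggregate(mcount ~ pond + year + species, data = s1, FUN = sum)
    s2 <- merge(s2, n_mo, by = c("pond", "year"))
    s2$cell <- s2$mcount / s2$n_months
  } else {
    n_ev <- stats::aggregate(station ~ pond + year, data = ev, FUN = length)
    names(n_ev)[3] <- "n_events"
    s2 <- stats::aggregate(count ~ pond + year + species, data = cnt, FUN = sum)
    s2 <- merge(s2, n_ev, by = c("pond", "year"))
    s2$cell <- s2$count / s2$n_events
  }

  py <- unique(s2[, c("pond", "year")])
  py <- py[order(py$pond, py$year), ]
  M <- matrix(0, nrow(py), length(species),
              dimnames = list(NULL, species))
  ri <- match(paste(s2$pond, s2$year), paste(py$pond, py$year))
  ci <- match(s2$species, species)
  M[cbind(ri, ci)] <- s2$cell
  zero <- rowSums(M) == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero pond-year rows dropped")
    M <- M[!zero, , drop = FALSE]; py <- py[!zero, , drop = FALSE]
  }
  community_matrix(M, py$pond, py$year)
}

#' Build the community-weighted trait matrix
#'
#' Cell (pond-year, trait) is the weighted mean of the predicted individual
#' trait values in that pond-year (weights = individuals represented), i.e.
#' the community-weighted mean trait.  Negative cells (possible for the
#' excretion difference traits) are clamped to zero by default, since the
#' downstream Bray-Curtis dissimilarity assumes non-negative data.
#'
#' @param predictions output of [impute_survey_traits()] (columns `pond`,
#'   `year`, `trait`, `value`, optional `weight`).
#' @param clamp_negative clamp negative community-weighted cells to 0.
#' @return a [community_matrix()], trait columns in [trait_names()] order.
#' @export
build_trait_matrix <- function(predictions, clamp_negative = TRUE) {
  stopifnot(all(c("pond", "year", "trait", "value") %in% names(predictions)))
  w <- predictions$weight %||% rep(1, nrow(predictions))
  keep <- w > 0
  predictions <- predictions[keep, , drop = FALSE]; w <- w[keep]
  if (nrow(predictions) == 0) stop("no predictions with positive weight")
  traits <- intersect(trait_names(), unique(predictions$trait))
  py <- unique(predictions[, c("pond", "year")])
  py <- py[order(py$pond, py$year), ]
  rkey <- paste(py$pond, py$year)
  ri <- match(paste(predictions$pond, predictions$year), rkey)
  ci <- match(predictions$trait, traits)
  num <- matrix(0, nrow(py), length(traits), dimnames = list(NULL, traits))
  den <- num
  lin <- ri + (ci - 1L) * nrow(py)
  ns <- rowsum(cbind(w * predictions$value, w), lin)
  at <- as.integer(rownames(ns))
  num[at] <- ns[, 1]
  den[at] <- ns[, 2]
  if (any(den == 0)) stop("pond-year x trait cells with zero total weight")
  M <- num / den
  if (clamp_negative) {
    n_neg <- sum(M < 0)
    if (n_neg > 0) {
      message(sprintf("build_trait_matrix: %d negative community-weighted cells clamped to 0", n_neg))
      M[M < 0] <- 0
    }
  }
  community_matrix(M, py$pond, py$year)
}

#' Aggregate a species abundance matrix into feeding modes
#'
#' Each mode column is the sum of its member-species columns; row totals are
#' conserved exactly.
#'
#' @param A species [community_matrix()].
#' @param lookup data.frame with columns `species` and `feeding_mode`, or a
#'   named character vector `species -> mode`.
#' @return a [community_matrix()] with one column per feeding mode present.
#' @export
aggregate_by_feeding_mode <- function(A, lookup) {
  if (is.data.frame(lookup))
    lookup <- stats::setNames(as.character(lookup$feeding_mode), lookup$species)
  unmapped <- setdiff(colnames(A), names(lookup))
  if (length(unmapped))
    stop("species without a feeding mode: ", paste(unmapped, collapse = ", "))
  modes <- lookup[colnames(A)]
  mode_order <- intersect(feeding_modes(), unique(modes))
  if (!length(mode_order)) mode_order <- sort(unique(modes))
  M <- sapply(mode_order, function(m) rowSums(A[, modes == m, drop = FALSE]))
  if (is.null(dim(M))) M <- matrix(M, nrow = 1, dimnames = list(NULL, mode_order))
  meta <- cm_meta(A)
  community_matrix(M, meta$pond, meta$year)
}

#' Min-max rescale columns to \[0, 1\]
#'
#' Optional pre-processing before Bray-Curtis when trait columns live on
#' very different natural scales.  Constant columns map to 0 with a warning.
#'
#' @param M a matrix or [community_matrix()].
#' @return the rescaled matrix (class preserved).
#' @export
rescale_minmax <- function(M) {
  meta <- attr(M, "meta")
  V <- unclass(M)
  rng <- apply(V, 2, range)
  span <- rng[2, ] - rng[1, ]
  const <- span == 0
  if (any(const)) {
    warning("constant columns rescaled to 0: ",
            paste(colnames(V)[const], collapse = ", "))
    span[const] <- 1
  }
  V <- sweep(sweep(V, 2, rng[1, ]), 2, span, "/")
  V[, const] <- 0
  if (!is.null(meta)) community_matrix(V, meta$pond, meta$year) else V
}

#' Round-trip community matrices as CSV
#'
#' Written with leading `pond,year` index columns, then the value columns
#' in their fixed order.
#'
#' @param M a [community_matrix()].
#' @param path file path.
#' @return the matrix (reader) or `path` invisibly (writer).
#' @export
write_community_csv <- function(M, path) {
  meta <- cm_meta(M)
  utils::write.csv(cbind(meta, as.data.frame(unclass(M), check.names = FALSE)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_community_csv
#' @export
read_community_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("pond", "year") %in% names(x)))
    stop("community CSV must have pond and year columns")
  vals <- as.matrix(x[, setdiff(names(x), c("pond", "year")), drop = FALSE])
  community_matrix(vals, x$pond, x$year)
}
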