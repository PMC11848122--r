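## Trait imputation: per-trait additive models fitted to measured
## individuals (taxon intercepts + penalized thin-plate smooth of fork
## length, penalty chosen by REML), then evaluated for every surveyed
## individual.  Morphometric traits are modeled at species level; nutrient
## recycling traits at family level, matching how the measurements are
## collected.

#' Fit a penalized additive model for one trait
#'
#' Model: `value ~ taxon + s(fork_length, bs = "tp", k = k)` with the
#' smoothing penalty selected by REML.  With `smooth = "by_taxon"` each
#' taxon gets its own smooth.  Fitting is delegated to [mgcv::gam()], the
#' standard engine for thin-plate penalized regression splines.
#'
#' Taxa represented by a single record cannot inform the length effect;
#' they are flagged and imputed as their taxon mean with a warning.
#'
#' @param records data.frame of individual measurements with columns
#'   `species`, `family`, `fork_length_mm`, `trait`, `value`.
#' @param trait which trait to fit (one of [trait_names()]).
#' @param taxon_level `"species"` or `"family"`.
#' @param k basis dimension of the thin-plate smooth.
#' @param smooth `"shared"` (one smooth of length) or `"by_taxon"`.
#' @param sp optional fixed smoothing parameter; `NULL` selects by REML.
#' @return an object of class `trait_model` with elements `gam` (the mgcv
#'   fit), `trait`, `taxon_level`, `taxa`, `penalty` (selected lambda),
#'   `reml` (REML score), `edf`, `residual_sd`, `length_range`, and
#'   `flagged` (taxon-mean fallbacks for single-record taxa).
#' @export
fit_trait_model <- function(records, trait, taxon_level = c("species", "family"),
                            k = 10, smooth = c("shared", "by_taxon"), sp = NULL) {
  taxon_level <- match.arg(taxon_level)
  smooth <- match.arg(smooth)
  d <- records[records$trait == trait, , drop = FALSE]
  if (nrow(d) == 0) stop("no records for trait '", trait, "'")
  d <- data.frame(taxon = factor(d[[taxon_level]]),
                  fork_length = as.numeric(d$fork_length_mm),
                  value = as.numeric(d$value))
  if (any(!is.finite(d$fork_length)) || any(d$fork_length <= 0))
    stop("fork lengths must be positive and finite")
  if (length(unique(d$fork_length)) < 2)
    stop("need >= 2 distinct fork lengths to fit a length smooth")

  tab <- table(d$taxon)
  flagged <- names(tab)[tab < 2]
  flagged_means <- NULL
  if (length(flagged)) {
    warning("taxa with a single record imputed as taxon mean: ",
            paste(flagged, collapse = ", "))
    flagged_means <- vapply(flagged, function(tx) mean(d$value[d$taxon == tx]), 0)
  }

  k <- min(k, max(3, length(unique(d$fork_length)) - 1))
  form <- if (nlevels(d$taxon) > 1) {
    if (smooth == "shared") value ~ taxon + s(fork_length, bs = "tp", k = k)
    else value ~ taxon + s(fork_length, bs = "tp", k = k, by = taxon)
  } else {
    value ~ s(fork_length, bs = "tp", k = k)
  }
  g <- mgcv::gam(form, data = d, method = "REML", sp = sp)

  structure(
    list(gam = g, trait = trait, taxon_level = taxon_level,
         taxa = levels(d$taxon), smooth = smooth, k = k,
         penalty = unname(g$sp), reml = as.numeric(g$gcv.ubre),
         edf = sum(g$edf), residual_sd = sqrt(g$sig2),
         length_range = range(d$fork_length),
         flagged = flagged_means),
    class = "trait_model"
  )
}

#' Predict trait values for taxa at given fork lengths
#'
#' Lengths outside the training range are clamped to the range boundary
#' (splines extrapolate wildly); the number of clamped lengths is attached
#' as attribute `n_clamped`.  Unknown taxa are an error.
#'
#' @param object a `trait_model`.
#' @param taxa character vector of taxon labels.
#' @param lengths numeric vector of fork lengths (recycled against taxa).
#' @param clamp clamp out-of-range lengths (default TRUE).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.trait_model <- function(object, taxa, lengths, clamp = TRUE, ...) {
  n <- max(length(taxa), length(lengths))
  taxa <- rep_len(as.character(taxa), n)
  lengths <- rep_len(as.numeric(lengths), n)
  unknown <- setdiff(unique(taxa), object$taxa)
  if (length(unknown))
    stop("taxa not in model '", object$trait, "': ", paste(unknown, collapse = ", "))
  n_clamped <- 0L
  if (clamp) {
    lo <- object$length_range[1]; hi <- object$length_range[2]
    n_clamped <- sum(lengths < lo | lengths > hi)
    lengths <- pmin(pmax(lengths, lo), hi)
  }
  nd <- data.frame(taxon = factor(taxa, levels = object$taxa), fork_length = lengths)
  p <- as.numeric(mgcv::predict.gam(object$gam, newdata = nd))
  if (length(object$flagged)) {
    hit <- taxa %in% names(object$flagged)
    p[hit] <- object$flagged[taxa[hit]]
  }
  attr(p, "n_clamped") <- n_clamped
  p
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf("trait_model '%s' (%s level, %s smooth): lambda = %s, EDF = %.2f, residual SD = %.4g\n",
              x$trait, x$taxon_level, x$smooth,
              paste(signif(x$penalty, 4), collapse = "/"), x$edf, x$residual_sd))
  invisible(x)
}

#' Fit the standard 13-trait model set
#'
#' Morphometric traits at species level, nutrient recycling traits
#' (`NH4`, `PO4`, `N_P`) at family level.
#'
#' @param measurements trait-measurement data.frame.
#' @param traits traits to fit (default: those present in `measurements`).
#' @inheritParams fit_trait_model
#' @return named list of `trait_model` objects.
#' @export
fit_trait_models <- function(measurements, traits = NULL, k = 10,
                             smooth = c("shared", "by_taxon")) {
  smooth <- match.arg(smooth)
  traits <- traits %||% intersect(trait_names(), unique(measurements$trait))
  models <- lapply(traits, function(tr) {
    lvl <- if (tr %in% nutrient_traits()) "family" else "species"
    fit_trait_model(measurements, tr, taxon_level = lvl, k = k, smooth = smooth)
  })
  stats::setNames(models, traits)
}

#' Impute traits for every surveyed individual
#'
#' Each measured individual (survey row with a fork length) receives one
#' prediction per trait.  Counted-but-unmeasured individuals (cell count
#' minus measured rows) are represented by one pseudo-individual at the
#' species' survey-wide mean length, weighted by how many fish it stands
#' for; the number of such fallbacks is reported.  Family-level models are
#' reached through the `species -> family` map.
#'
#' @param models named list of `trait_model`s (one per trait).
#' @param records survey data.frame (see [simulate_survey()]).
#' @param species_map data.frame with columns `species` and `family`.
#' @return data.frame with columns `pond`, `year`, `species`, `trait`,
#'   `value`, `weight` (individuals represented), with attributes
#'   `n_clamped` and `n_length_fallback`.
#' @export
impute_survey_traits <- function(models, records, species_map) {
  stopifnot(is.list(models), length(models) > 0)
  ind <- records[!is.na(records$fork_length_mm), , drop = FALSE]
  cnt <- records[is.na(records$fork_length_mm) & !is.na(records$count), , drop = FALSE]

  species <- sort(unique(records$species))
  fam_of <- stats::setNames(as.character(species_map$family), species_map$species)
  if (any(!(species %in% names(fam_of))))
    stop("species missing from species_map: ",
         paste(setdiff(species, names(fam_of)), collapse = ", "))
  for (m in models) {
    need <- if (m$taxon_level == "species") species else unique(fam_of[species])
    unmapped <- setdiff(need, m$taxa)
    if (length(unmapped))
      stop("surveyed taxa not covered by model '", m$trait, "': ",
           paste(unmapped, collapse = ", "))
  }

  # survey-wide mean length per species for the unmeasured fallback
  mean_len <- tapply(ind$fork_length_mm, ind$species, mean)
  global_mean <- mean(ind$fork_length_mm)

  # unmeasured individuals per pond x year x species
  n_fallback_rows <- 0L
  fb <- NULL
  if (nrow(cnt)) {
    key <- function(d) paste(d$pond, d$year, d$species, sep = "\r")
    tot <- tapply(cnt$count, key(cnt), sum)
    nm <- if (nrow(ind)) table(key(ind)) else table(character(0))
    unmeas <- tot - as.numeric(nm[names(tot)] %0% 0)
    unmeas[is.na(unmeas)] <- tot[is.na(unmeas)]
    unmeas <- pmax(unmeas, 0)
    keep <- unmeas > 0
    if (any(keep)) {
      parts <- do.call(rbind, strsplit(names(unmeas)[keep], "\r", fixed = TRUE))
      fb <- data.frame(pond = parts[, 1], year = as.numeric(parts[, 2]),
                       species = parts[, 3], weight = as.numeric(unmeas[keep]),
                       stringsAsFactors = FALSE)
      fb$fork_length_mm <- as.numeric(mean_len[fb$species])
      miss <- is.na(fb$fork_length_mm)
      if (any(miss)) fb$fork_length_mm[miss] <- global_mean
      n_fallback_rows <- nrow(fb)
      message(sprintf("impute_survey_traits: %d pseudo-individuals (%s fish) at species mean length",
                      n_fallback_rows, format(sum(fb$weight))))
    }
  }

  base <- rbind(
    if (nrow(ind)) data.frame(pond = ind$pond, year = ind$year, species = ind$species,
                              fork_length_mm = ind$fork_length_mm, weight = 1,
                              stringsAsFactors = FALSE),
    if (!is.null(fb)) fb[, c("pond", "year", "species", "fork_length_mm", "weight")]
  )
  if (is.null(base) || nrow(base) == 0) stop("no surveyed individuals to impute")

  n_clamped <- 0L
  out <- lapply(models, function(m) {
    taxa <- if (m$taxon_level == "species") base$species else unname(fam_of[base$species])
    v <- predict(m, taxa, base$fork_length_mm)
    n_clamped <<- n_clamped + attr(v, "n_clamped")
    data.frame(pond = base$pond, year = base$year, species = base$species,
               trait = m$trait, value = as.numeric(v), weight = base$weight,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (n_clamped > 0)
    message(sprintf("impute_survey_traits: %d predictions at clamped lengths", n_clamped))
  attr(out, "n_clamped") <- n_clamped
  attr(out, "n_length_fallback") <- n_fallback_rows
  out
}

`%0%` <- function(a, b) { a[is.na(a)] <- b; a }

#' Write a per-trait model summary report
#'
#' One line per trait: selected penalty, effective degrees of freedom and
#' residual SD of the length smooth model.
#'
#' @param models named list of `trait_model`s.
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
write_model_report <- function(models, path) {
  lines <- vapply(models, function(m) {
    sprintf("%-4s level=%-7s lambda=%-12s EDF=%-6.2f residual_sd=%.5g",
            m$trait, m$taxon_level, paste(signif(m$penalty, 4), collapse = "/"),
            m$edf, m$residual_sd)
  }, "")
  writeLines(c("trait imputation model summary", lines), path)
  invisible(path)
}
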