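## Synthetic multitrophic survey generator.
##
## Emulates a repeated seine survey of coastal pond fish: several ponds
## sampled monthly over several years at fixed stations, ~27 species spread
## over four trophic feeding modes, per-individual fork lengths, and
## species-and-length-dependent trait values.  The knobs that matter for the
## species-vs-trait stability question are functional redundancy (trait
## overlap within a feeding mode), persistent pond-level filters, interannual
## turnover, and compensatory dynamics within feeding modes.

# baseline scale of each trait; morphometric ratios are O(0.1-1), excretion
# rates a few umol/ind/30min, N:P of order 10
.trait_base_scale <- function() {
  stats::setNames(
    c(0.35, 0.8, 0.5, 0.15, 0.25,
      0.5, 0.3, 1.2, 0.45, 0.3,
      2.0, 0.5, 10),
    trait_names()
  )
}

#' Specification of one synthetic species
#'
#' @param name species identifier.
#' @param feeding_mode one of [feeding_modes()].
#' @param trait_means strictly positive 13-vector named by [trait_names()].
#' @param trait_length_slopes 13-vector of per-mm trait slopes.
#' @param length_mean,length_sd fork-length distribution (mm), both positive.
#' @param base_abundance positive expected count per station visit.
#' @param family family identifier (nutrient traits are measured per family).
#' @return an object of class `species_spec`.
#' @export
species_spec <- function(name, feeding_mode, trait_means, trait_length_slopes,
                         length_mean, length_sd, base_abundance,
                         family = paste0("fam_", name)) {
  feeding_mode <- match.arg(feeding_mode, feeding_modes())
  trait_means <- unlist(trait_means)
  trait_length_slopes <- unlist(trait_length_slopes)
  if (is.null(names(trait_means))) names(trait_means) <- trait_names()[seq_along(trait_means)]
  if (is.null(names(trait_length_slopes)))
    names(trait_length_slopes) <- names(trait_means)
  if (any(trait_means <= 0)) stop("trait_means must be strictly positive")
  if (length_sd <= 0 || length_mean <= 0) stop("length_mean and length_sd must be positive")
  if (base_abundance <= 0) stop("base_abundance must be positive")
  structure(
    list(name = as.character(name), feeding_mode = feeding_mode,
         trait_means = trait_means, trait_length_slopes = trait_length_slopes,
         length_mean = length_mean, length_sd = length_sd,
         base_abundance = base_abundance, family = as.character(family)),
    class = "species_spec"
  )
}

# feeding-mode head-count for n species; 27 species reproduce the 3/6/9/9
# detritivore/planktivore/meiofauna/macrofauna split of the study system
.mode_counts <- function(n_species) {
  w <- c(3, 6, 9, 9) / 27
  counts <- pmax(1L, round(n_species * w))
  while (sum(counts) != n_species) {
    i <- if (sum(counts) > n_species) which.max(counts) else which.min(counts)
    counts[i] <- counts[i] + sign(n_species - sum(counts))
  }
  stats::setNames(counts, feeding_modes())
}

#' Generate a synthetic species pool with tunable functional redundancy
#'
#' Each feeding mode has a trait archetype; every member species mixes that
#' archetype with an independent lognormal draw using convex weight
#' `redundancy`.  `redundancy = 1` gives identical trait means within a mode
#' (perfect redundancy); `redundancy = 0` gives fully independent species.
#' The random draws do not depend on `redundancy`, so pools generated at the
#' same seed but different redundancy are exact convex mixtures of each
#' other.
#'
#' @param n_species number of species, at least 4 (one per feeding mode).
#' @param redundancy convex mixture weight in \[0, 1\].
#' @param seed integer seed.
#' @return an object of class `species_pool`: a list of [species_spec()].
#' @export
generate_species_pool <- function(n_species, redundancy = 0.5, seed = 1) {
  if (n_species < 4) stop("n_species must be >= 4 (one species per feeding mode)")
  if (redundancy < 0 || redundancy > 1) stop("redundancy must be in [0, 1]")
  base <- .trait_base_scale()
  with_seed(seed, {
    counts <- .mode_counts(n_species)
    archetypes <- lapply(feeding_modes(), function(m) base * exp(stats::rnorm(13, 0, 0.35)))
    names(archetypes) <- feeding_modes()
    pool <- list()
    idx <- 0L
    for (m in feeding_modes()) {
      fam_new <- c(TRUE, stats::runif(max(counts[m] - 1L, 0L)) > 0.25)
      fam_id <- cumsum(fam_new)
      for (j in seq_len(counts[m])) {
        idx <- idx + 1L
        indep <- base * exp(stats::rnorm(13, 0, 0.35))
        tm <- redundancy * archetypes[[m]] + (1 - redundancy) * indep
        length_mean <- stats::runif(1, 60, 200)
        length_sd <- 0.18 * length_mean
        slopes <- tm * stats::rnorm(13, 0, 0.25) / (4 * length_sd)
        pool[[idx]] <- species_spec(
          name = sprintf("sp%02d", idx), feeding_mode = m,
          trait_means = tm, trait_length_slopes = slopes,
          length_mean = length_mean, length_sd = length_sd,
          base_abundance = stats::rlnorm(1, log(5), 0.8),
          family = sprintf("fam_%s_%02d", substr(m, 1, 4), fam_id[j])
        )
      }
    }
    structure(pool, class = "species_pool", redundancy = redundancy, seed = seed)
  })
}

#' Species lookup table for a pool
#'
#' @param pool a `species_pool`.
#' @return data.frame with columns `species`, `family`, `feeding_mode`.
#' @export
species_lookup <- function(pool) {
  data.frame(
    species = vapply(pool, `[[`, "", "name"),
    family = vapply(pool, `[[`, "", "family"),
    feeding_mode = vapply(pool, `[[`, "", "feeding_mode"),
    stringsAsFactors = FALSE
  )
}

#' Configuration of a synthetic survey
#'
#' Defaults mirror the study design: 6 ponds sampled at 2 stations monthly
#' (6 months, May-October) over 6 years, with a 27-species pool.
#'
#' @param n_ponds,n_years,n_months,n_stations survey dimensions.
#' @param species_pool a `species_pool`; generated from `n_species` and
#'   `redundancy` when missing.
#' @param n_species,redundancy pool parameters used when `species_pool` is
#'   missing.
#' @param spatial_filter_strength SD of the persistent per-species pond
#'   offset on log abundance (>= 0).
#' @param temporal_cv interannual lognormal coefficient of variation (>= 0).
#' @param compensation within-feeding-mode negative covariance of yearly
#'   fluctuations, in \[0, 1\]; 1 forces mode-level shocks to sum to zero.
#' @param measured_fraction fraction of counted individuals that also get an
#'   individual fork-length row.
#' @param seed integer seed.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_ponds = 6, n_years = 6, n_months = 6, n_stations = 2,
                         species_pool = NULL, n_species = 27, redundancy = 0.5,
                         spatial_filter_strength = 0.5, temporal_cv = 0.5,
                         compensation = 0, measured_fraction = 1, seed = 1) {
  if (is.null(species_pool))
    species_pool <- generate_species_pool(n_species, redundancy, seed = derive_seed(seed, 11))
  if (n_ponds < 2) stop("n_ponds must be >= 2")
  if (n_years < 3) stop("n_years must be >= 3")
  if (n_months < 1 || n_stations < 1) stop("n_months and n_stations must be >= 1")
  if (length(species_pool) == 0) stop("species_pool must be nonempty")
  if (spatial_filter_strength < 0) stop("spatial_filter_strength must be >= 0")
  if (temporal_cv < 0) stop("temporal_cv must be >= 0")
  if (compensation < 0 || compensation > 1) stop("compensation must be in [0, 1]")
  if (measured_fraction < 0 || measured_fraction > 1) stop("measured_fraction must be in [0, 1]")
  structure(
    list(n_ponds = as.integer(n_ponds), n_years = as.integer(n_years),
         n_months = as.integer(n_months), n_stations = as.integer(n_stations),
         species_pool = species_pool,
         redundancy = attr(species_pool, "redundancy") %||% NA_real_,
         spatial_filter_strength = spatial_filter_strength,
         temporal_cv = temporal_cv, compensation = compensation,
         measured_fraction = measured_fraction, seed = as.integer(seed)),
    class = "synth_config"
  )
}

# positive truncated normal fork lengths
.rlength <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Simulate a long-format seine survey
#'
#' Counts are Poisson with a lognormal mean:
#' `log E(count) = log(base_abundance) + pond offset + year shock`, where
#' pond offsets are fixed per species-pond across years (persistent spatial
#' filtering) and year shocks are drawn per species-year with SD
#' `sqrt(log(1 + temporal_cv^2))`; within each feeding mode the shocks have
#' their mode mean removed in proportion to `compensation`, so at
#' `compensation = 1` the mode-level log-fluctuations sum to zero
#' (compensatory dynamics).  Each counted individual can carry a fork length
#' drawn from the species' truncated-normal length distribution.
#'
#' @param config a [synth_config()].
#' @return data.frame of survey records with columns `pond`, `year`,
#'   `month`, `station`, `species`, `count`, `fork_length_mm`.  Count rows
#'   (`fork_length_mm` NA) give the cell total; individual rows (`count` NA)
#'   enumerate the measured subset of that total.
#' @export
simulate_survey <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  pool <- config$species_pool
  sp_names <- vapply(pool, `[[`, "", "name")
  modes <- vapply(pool, `[[`, "", "feeding_mode")
  base_ab <- vapply(pool, `[[`, 0, "base_abundance")
  ns <- length(pool)
  ponds <- sprintf("pond%02d", seq_len(config$n_ponds))
  years <- 2010L + seq_len(config$n_years) - 1L
  sigma <- sqrt(log(1 + config$temporal_cv^2))

  with_seed(config$seed, {
    # persistent spatial filter: species x pond
    pond_off <- matrix(stats::rnorm(ns * config$n_ponds, 0, config$spatial_filter_strength),
                       nrow = ns)
    # interannual shocks: species x year, compensated within feeding modes
    shock <- matrix(stats::rnorm(ns * config$n_years, 0, sigma), nrow = ns)
    for (m in unique(modes)) {
      i <- which(modes == m)
      if (length(i) > 1 || config$compensation > 0) {
        mode_mean <- colMeans(shock[i, , drop = FALSE])
        shock[i, ] <- shock[i, ] - config$compensation *
          matrix(mode_mean, nrow = length(i), ncol = config$n_years, byrow = TRUE)
      }
    }
    grid <- expand.grid(
      species_i = seq_len(ns), station = seq_len(config$n_stations),
      month = seq_len(config$n_months), year_i = seq_len(config$n_years),
      pond_i = seq_len(config$n_ponds), KEEP.OUT.ATTRS = FALSE
    )
    lambda <- base_ab[grid$species_i] *
      exp(pond_off[cbind(grid$species_i, grid$pond_i)] +
            shock[cbind(grid$species_i, grid$year_i)])
    grid$count <- stats::rpois(nrow(grid), lambda)
    grid <- grid[grid$count > 0, , drop = FALSE]

    count_rows <- data.frame(
      pond = ponds[grid$pond_i], year = years[grid$year_i],
      month = grid$month, station = grid$station,
      species = sp_names[grid$species_i], count = grid$count,
      fork_length_mm = NA_real_, stringsAsFactors = FALSE
    )
    n_meas <- floor(grid$count * config$measured_fraction)
    ind_idx <- rep.int(seq_len(nrow(grid)), n_meas)
    ind_rows <- if (length(ind_idx)) {
      si <- grid$species_i[ind_idx]
      lm_ <- vapply(pool, `[[`, 0, "length_mean")
      ls_ <- vapply(pool, `[[`, 0, "length_sd")
      data.frame(
        pond = ponds[grid$pond_i[ind_idx]], year = years[grid$year_i[ind_idx]],
        month = grid$month[ind_idx], station = grid$station[ind_idx],
        species = sp_names[si], count = NA_real_,
        fork_length_mm = .rlength(length(ind_idx), lm_[si], ls_[si]),
        stringsAsFactors = FALSE
      )
    } else count_rows[0, ]
    out <- rbind(count_rows, ind_rows)
    out <- out[order(out$pond, out$year, out$month, out$station, out$species,
                     is.na(out$fork_length_mm), out$fork_length_mm), ]
    rownames(out) <- NULL
    attr(out, "synth_config") <- config
    out
  })
}

#' Simulate per-individual trait measurements
#'
#' Emulates the field collections that feed the trait-imputation models:
#' for each species, `n_per_species` individuals with fork lengths spanning
#' the species' size range evenly, each measured for the requested traits
#' with value `trait_mean + slope * (length - length_mean) + N(0, noise_sd)`.
#'
#' @param config a [synth_config()] (its pool and seed are used).
#' @param n_per_species individuals per species, at least 2.
#' @param noise_sd measurement noise SD (absolute, recycled over traits).
#' @param traits subset of [trait_names()] to measure.
#' @return data.frame with columns `species`, `family`, `fork_length_mm`,
#'   `trait`, `value`.
#' @export
simulate_trait_measurements <- function(config, n_per_species = 20, noise_sd = 0.05,
                                        traits = trait_names()) {
  stopifnot(inherits(config, "synth_config"))
  if (n_per_species < 2) stop("n_per_species must be >= 2 (length effect unidentifiable)")
  traits <- match.arg(traits, trait_names(), several.ok = TRUE)
  pool <- config$species_pool
  with_seed(derive_seed(config$seed, 101), {
    out <- lapply(pool, function(sp) {
      L <- seq(max(1, sp$length_mean - 2 * sp$length_sd),
               sp$length_mean + 2 * sp$length_sd, length.out = n_per_species)
      do.call(rbind, lapply(traits, function(tr) {
        data.frame(
          species = sp$name, family = sp$family, fork_length_mm = L, trait = tr,
          value = sp$trait_means[[tr]] + sp$trait_length_slopes[[tr]] * (L - sp$length_mean) +
            stats::rnorm(n_per_species, 0, noise_sd),
          stringsAsFactors = FALSE
        )
      }))
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Read and write the survey and trait CSV dialects
#'
#' The survey CSV has columns
#' `pond,year,month,station,species,count,fork_length_mm` (count-only rows
#' plus one row per measured individual); the trait-measurement CSV has
#' columns `species,family,fork_length_mm,trait,value`.
#'
#' @param records,measurements data.frames in the respective schemas.
#' @param path file path.
#' @return readers return the data.frame; writers return `path` invisibly.
#' @export
write_survey_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pond", "year", "month", "station", "species", "count", "fork_length_mm")
  if (!all(need %in% names(x)))
    stop("survey CSV must have columns: ", paste(need, collapse = ","))
  x
}

#' @rdname write_survey_csv
#' @export
write_trait_csv <- function(measurements, path) {
  utils::write.csv(measurements, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_trait_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "family", "fork_length_mm", "trait", "value")
  if (!all(need %in% names(x)))
    stop("trait CSV must have columns: ", paste(need, collapse = ","))
  x
}
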