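# Shared fixture builders. Everything is generated in code at test time.

tiny_config <- function(seed = 3, ...) {
  args <- utils::modifyList(
    list(n_ponds = 3, n_years = 4, n_months = 2, n_stations = 2,
         n_species = 6, redundancy = 0.5, seed = seed),
    list(...)
  )
  do.call(synth_config, args)
}

# hand-built survey records: one count row (+ optional individual rows)
survey_row <- function(pond, year, month, station, species, count = NA,
                       fork = NA) {
  data.frame(pond = pond, year = year, month = month, station = station,
             species = species, count = count, fork_length_mm = fork,
             stringsAsFactors = FALSE)
}

# a small pond-year community matrix with explicit values
cm_fixture <- function(values, ponds, years, cols = NULL) {
  M <- matrix(values, nrow = length(ponds), byrow = TRUE)
  colnames(M) <- cols %||% paste0("c", seq_len(ncol(M)))
  community_matrix(M, ponds, years)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Euclidean distance matrix of a point configuration, with pond:year labels
euclid_dist <- function(X, ponds = NULL, years = NULL) {
  D <- as.matrix(stats::dist(X))
  structure(D, class = c("dist_matrix", "matrix"),
            meta = if (!is.null(ponds)) data.frame(pond = ponds, year = years))
}

# measurement records with an exact generating law (no randomness)
linear_measurements <- function(species, intercepts, slopes, lengths,
                                trait = "Osf", family = NULL) {
  family <- family %||% paste0("fam_", species)
  do.call(rbind, lapply(seq_along(species), function(i) {
    data.frame(species = species[i], family = family[i],
               fork_length_mm = lengths,
               trait = trait,
               value = intercepts[i] + slopes[i] * lengths,
               stringsAsFactors = FALSE)
  }))
}
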