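## End-to-end orchestration: impute -> matrices -> distances -> stability
## -> inference -> mock simulation, with CSV outputs and a run manifest
## that records every design-decision flag and seed.

#' Pipeline configuration
#'
#' @param survey path to the long-format survey CSV.
#' @param traits path to the trait-measurement CSV.
#' @param lookup path to the species lookup CSV (`species`, `family`,
#'   `feeding_mode`).
#' @param out_dir output directory (created if missing).
#' @param seed integer seed for every stochastic stage.
#' @param centroid_type `"centroid"` or `"median"` (see
#'   [year_to_centroid()]).
#' @param y2c_mode `"pcoa_centroid"` or `"raw_to_mean"`.
#' @param trait_scaling `"none"` or `"minmax"` rescaling of trait columns
#'   before dissimilarity.
#' @param nmds_starts,n_perm,mock_reps,mock_dims tuning knobs.
#' @param gam_k,gam_smooth trait-model options (see [fit_trait_model()]).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(survey, traits, lookup, out_dir, seed = 1,
                            centroid_type = c("centroid", "median"),
                            y2c_mode = c("pcoa_centroid", "raw_to_mean"),
                            trait_scaling = c("none", "minmax"),
                            nmds_starts = 20, n_perm = 999,
                            mock_reps = 100, mock_dims = NULL,
                            gam_k = 10, gam_smooth = "shared") {
  for (f in c(survey, traits, lookup))
    if (!file.exists(f)) stop("input file does not exist: ", f)
  structure(list(
    survey = survey, traits = traits, lookup = lookup, out_dir = out_dir,
    seed = as.integer(seed),
    centroid_type = match.arg(centroid_type),
    y2c_mode = match.arg(y2c_mode),
    trait_scaling = match.arg(trait_scaling),
    nmds_starts = as.integer(nmds_starts), n_perm = as.integer(n_perm),
    mock_reps = as.integer(mock_reps), mock_dims = mock_dims,
    gam_k = as.integer(gam_k), gam_smooth = gam_smooth
  ), class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full species-vs-trait stability analysis
#'
#' Sequences: trait model fitting and imputation; abundance, feeding-mode
#' and community-weighted trait matrices; Bray-Curtis distances; nMDS
#' ordinations; year-to-centroid and year-to-year stability with
#' max-normalized relative stability and the two-way ANOVA; PERMANOVA for
#' both composition types; the two bespoke SIMPER decompositions; vector
#' fitting of species and feeding-mode abundances onto the trait
#' ordination; and the mock-community dimensional-reduction control.
#' All tables are written as CSV under `cfg$out_dir` together with
#' `manifest.json`.
#'
#' @param cfg a [pipeline_config()].
#' @return the result bundle (named list of all tables), invisibly.
#' @export
run_full_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_ <- function(fmt, ...) message(sprintf(paste0("[pipeline] ", fmt), ...))

  records <- .stage("read_survey", read_survey_csv(cfg$survey))
  measurements <- .stage("read_traits", read_trait_csv(cfg$traits))
  lookup <- .stage("read_lookup", utils::read.csv(cfg$lookup, stringsAsFactors = FALSE))
  log_("inputs: %d survey rows, %d trait measurements, %d species in lookup",
       nrow(records), nrow(measurements), nrow(lookup))

  models <- .stage("fit_trait_models",
                   fit_trait_models(measurements, k = cfg$gam_k, smooth = cfg$gam_smooth))
  write_model_report(models, file.path(cfg$out_dir, "trait_models.txt"))

  predictions <- .stage("impute",
                        impute_survey_traits(models, records, lookup))
  log_("imputed %d individual-level predictions", nrow(predictions))

  A <- .stage("abundance_matrix", build_abundance_matrix(records))
  T_ <- .stage("trait_matrix", build_trait_matrix(predictions))
  modeA <- .stage("feeding_mode_matrix", aggregate_by_feeding_mode(A, lookup))
  T_use <- if (cfg$trait_scaling == "minmax") rescale_minmax(T_) else T_
  write_community_csv(A, file.path(cfg$out_dir, "abundance_matrix.csv"))
  write_community_csv(T_, file.path(cfg$out_dir, "trait_matrix.csv"))
  write_community_csv(modeA, file.path(cfg$out_dir, "feeding_mode_matrix.csv"))
  log_("matrices: %d pond-years x %d species / %d traits", nrow(A), ncol(A), ncol(T_))

  Dsp <- .stage("bray_species", bray_curtis(A))
  Dtr <- .stage("bray_traits", bray_curtis(T_use))
  write_dist_csv(Dsp, file.path(cfg$out_dir, "dist_species.csv"))
  write_dist_csv(Dtr, file.path(cfg$out_dir, "dist_traits.csv"))

  ord_sp <- .stage("nmds_species",
                   nmds(Dsp, k = 2, n_starts = cfg$nmds_starts, seed = derive_seed(cfg$seed, 1)))
  ord_tr <- .stage("nmds_traits",
                   nmds(Dtr, k = 2, n_starts = cfg$nmds_starts, seed = derive_seed(cfg$seed, 2)))
  write_ordination_csv(ord_sp, file.path(cfg$out_dir, "nmds_species.csv"))
  write_ordination_csv(ord_tr, file.path(cfg$out_dir, "nmds_traits.csv"))
  log_("nMDS stress: species %.4f, traits %.4f", ord_sp$stress, ord_tr$stress)

  y2c <- rbind(
    relative_stability(.stage("y2c_species",
      year_to_centroid(if (cfg$y2c_mode == "raw_to_mean") A else Dsp,
                       mode = cfg$y2c_mode, centroid_type = cfg$centroid_type)),
      "species"),
    relative_stability(.stage("y2c_traits",
      year_to_centroid(if (cfg$y2c_mode == "raw_to_mean") T_use else Dtr,
                       mode = cfg$y2c_mode, centroid_type = cfg$centroid_type)),
      "trait")
  )
  y2y <- rbind(
    relative_stability(.stage("y2y_species", year_to_year(Dsp)), "species"),
    relative_stability(.stage("y2y_traits", year_to_year(Dtr)), "trait")
  )
  utils::write.csv(y2c, file.path(cfg$out_dir, "stability_year_to_centroid.csv"), row.names = FALSE)
  utils::write.csv(y2y, file.path(cfg$out_dir, "stability_year_to_year.csv"), row.names = FALSE)

  anova_y2c <- .stage("anova_y2c", stability_anova(y2c))
  anova_y2y <- .stage("anova_y2y", stability_anova(y2y))
  utils::write.csv(anova_y2c, file.path(cfg$out_dir, "anova_year_to_centroid.csv"), row.names = FALSE)
  utils::write.csv(anova_y2y, file.path(cfg$out_dir, "anova_year_to_year.csv"), row.names = FALSE)
  stability_report(y2c, file.path(cfg$out_dir, "stability_report.txt"))

  perm_sp <- .stage("permanova_species",
                    permanova(Dsp, n_perm = cfg$n_perm, seed = derive_seed(cfg$seed, 3)))
  perm_tr <- .stage("permanova_traits",
                    permanova(Dtr, n_perm = cfg$n_perm, seed = derive_seed(cfg$seed, 4)))
  utils::write.csv(perm_sp, file.path(cfg$out_dir, "permanova_species.csv"), row.names = FALSE)
  utils::write.csv(perm_tr, file.path(cfg$out_dir, "permanova_traits.csv"), row.names = FALSE)

  mode_of <- stats::setNames(lookup$feeding_mode, lookup$species)
  simper_out <- .stage("simper", list(
    y2c_species = simper_year_to_centroid(A),
    y2c_traits = simper_year_to_centroid(T_use),
    y2y_species = simper_year_to_year(A, column_groups = mode_of),
    y2y_traits = simper_year_to_year(T_use, column_groups = trait_groups())
  ))
  utils::write.csv(simper_out$y2c_species, file.path(cfg$out_dir, "simper_y2c_species.csv"), row.names = FALSE)
  utils::write.csv(simper_out$y2c_traits, file.path(cfg$out_dir, "simper_y2c_traits.csv"), row.names = FALSE)
  utils::write.csv(simper_out$y2y_species$per_transition, file.path(cfg$out_dir, "simper_y2y_species.csv"), row.names = FALSE)
  utils::write.csv(simper_out$y2y_species$pond_summary, file.path(cfg$out_dir, "simper_y2y_species_modes.csv"), row.names = FALSE)
  utils::write.csv(simper_out$y2y_traits$per_transition, file.path(cfg$out_dir, "simper_y2y_traits.csv"), row.names = FALSE)
  utils::write.csv(simper_out$y2y_traits$pond_summary, file.path(cfg$out_dir, "simper_y2y_traits_groups.csv"), row.names = FALSE)

  fit_sp <- .stage("envfit_species",
                   envfit(ord_tr, A, n_perm = cfg$n_perm, seed = derive_seed(cfg$seed, 5)))
  fit_mode <- .stage("envfit_modes",
                     envfit(ord_tr, modeA, n_perm = cfg$n_perm, seed = derive_seed(cfg$seed, 6)))
  utils::write.csv(fit_sp, file.path(cfg$out_dir, "envfit_species.csv"), row.names = FALSE)
  utils::write.csv(fit_mode, file.path(cfg$out_dir, "envfit_feeding_modes.csv"), row.names = FALSE)

  mock_dims <- cfg$mock_dims %||% min(ncol(T_), ncol(A))
  mock <- .stage("mocksim", run_mock_experiment(
    A, T_use, mock_config(mock_dims, n_reps = cfg$mock_reps,
                          seed = derive_seed(cfg$seed, 7))))
  utils::write.csv(mock$per_rep, file.path(cfg$out_dir, "mock_experiment.csv"), row.names = FALSE)
  writeLines(utils::capture.output(print(mock)), file.path(cfg$out_dir, "mock_summary.txt"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("traitstab")),
    inputs = list(survey = cfg$survey, traits = cfg$traits, lookup = cfg$lookup),
    seed = cfg$seed,
    options = cfg[c("centroid_type", "y2c_mode", "trait_scaling", "nmds_starts",
                    "n_perm", "mock_reps", "gam_k", "gam_smooth")],
    mock_dims = mock_dims,
    counts = list(survey_rows = nrow(records), predictions = nrow(predictions),
                  pond_years = nrow(A), species = ncol(A), traits = ncol(T_),
                  clamped_lengths = attr(predictions, "n_clamped"),
                  length_fallbacks = attr(predictions, "n_length_fallback"))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  invisible(list(models = models, predictions = predictions,
                 abundance = A, traits = T_, feeding_modes = modeA,
                 dist_species = Dsp, dist_traits = Dtr,
                 nmds_species = ord_sp, nmds_traits = ord_tr,
                 stability_y2c = y2c, stability_y2y = y2y,
                 anova_y2c = anova_y2c, anova_y2y = anova_y2y,
                 permanova_species = perm_sp, permanova_traits = perm_tr,
                 simper = simper_out, envfit_species = fit_sp,
                 envfit_modes = fit_mode, mock = mock, manifest = manifest))
}

#' Generate a self-contained synthetic fixture directory
#'
#' `"tiny"`: 3 ponds x 4 years x 6 species with 4 traits measured;
#' `"paper_shape"`: 6 ponds x 6 years x 27 species (feeding modes split
#' 3/6/9/9) with all 13 traits.  Writes `survey.csv`, `traits.csv` and
#' `lookup.csv`.
#'
#' @param preset `"tiny"` or `"paper_shape"`.
#' @param seed integer seed.
#' @param dir output directory.
#' @return `dir`, invisibly; attribute `config` holds the [synth_config()].
#' @export
make_fixture <- function(preset = c("tiny", "paper_shape"), seed = 1,
                         dir = tempfile("fixture")) {
  preset <- match.arg(preset)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (preset == "tiny") {
    cfg <- synth_config(n_ponds = 3, n_years = 4, n_months = 3, n_stations = 2,
                        n_species = 6, redundancy = 0.5, seed = seed)
    traits <- c("Osf", "Bsf", "NH4", "N_P")
    n_per <- 12
  } else {
    cfg <- synth_config(n_ponds = 6, n_years = 6, n_months = 6, n_stations = 2,
                        n_species = 27, redundancy = 0.5, seed = seed)
    traits <- trait_names()
    n_per <- 20
  }
  write_survey_csv(simulate_survey(cfg), file.path(dir, "survey.csv"))
  write_trait_csv(simulate_trait_measurements(cfg, n_per_species = n_per,
                                              noise_sd = 0.05, traits = traits),
                  file.path(dir, "traits.csv"))
  utils::write.csv(species_lookup(cfg$species_pool), file.path(dir, "lookup.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(structure(dir, config = cfg))
}
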