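test_that("constant-within-taxon data give taxon-mean predictions with a flat smooth", {
  m <- linear_measurements(c("a", "b", "c"), intercepts = c(2, 5, 9),
                           slopes = c(0, 0, 0), lengths = seq(50, 150, by = 10))
  fit <- suppressWarnings(fit_trait_model(m, "Osf", "species"))
  p <- predict(fit, rep(c("a", "b", "c"), each = 3), rep(c(60, 100, 140), 3))
  expect_equal(as.numeric(p), rep(c(2, 5, 9), each = 3), tolerance = 1e-6)
  # smooth contributes essentially nothing beyond the intercepts
  expect_lt(fit$edf, 3 + 1.1)   # 3 parametric coefficients + ~1 for the flat smooth
})

test_that("a linear length effect is recovered exactly at any length", {
  lengths <- seq(40, 160, length.out = 15)
  m <- linear_measurements(c("a", "b"), intercepts = c(1, 4),
                           slopes = c(0.02, 0.02), lengths = lengths)
  fit <- suppressWarnings(fit_trait_model(m, "Osf", "species"))
  L <- c(45, 80, 133)
  expect_equal(as.numeric(predict(fit, rep("a", 3), L)), 1 + 0.02 * L,
               tolerance = 1e-3)
  expect_equal(as.numeric(predict(fit, rep("b", 3), L)), 4 + 0.02 * L,
               tolerance = 1e-3)
})

test_that("a quadratic length effect is recovered within 3x the noise SD", {
  set.seed(99)
  lengths <- runif(300, 40, 160)
  f <- function(L) 2 + 0.015 * L - 8e-5 * (L - 100)^2
  m <- data.frame(species = "a", family = "fam_a", fork_length_mm = lengths,
                  trait = "Osf", value = f(lengths) + rnorm(300, 0, 0.01))
  fit <- fit_trait_model(m, "Osf", "species")
  hold <- seq(45, 155, length.out = 40)
  pred <- as.numeric(predict(fit, rep("a", 40), hold))
  rmse <- sqrt(mean((pred - f(hold))^2))
  expect_lte(rmse, 3 * 0.01)
})

test_that("REML-selected penalty is locally optimal on the lambda grid", {
  set.seed(7)
  lengths <- runif(120, 40, 160)
  m <- data.frame(species = rep(c("a", "b"), each = 60), family = "f",
                  fork_length_mm = lengths,
                  trait = "Osf",
                  value = rep(c(1, 2), each = 60) + sin(lengths / 25) +
                    rnorm(120, 0, 0.1))
  fit <- fit_trait_model(m, "Osf", "species")
  lam <- fit$penalty
  for (f in c(0.1, 10)) {
    alt <- fit_trait_model(m, "Osf", "species", sp = lam * f)
    expect_lte(fit$reml, alt$reml + 1e-6)
  }
})

test_that("as lambda -> Inf the fit degenerates to least squares with a linear length term", {
  set.seed(13)
  lengths <- runif(80, 40, 160)
  d <- data.frame(species = rep(c("a", "b"), each = 40), family = "f",
                  fork_length_mm = lengths, trait = "Osf",
                  value = rep(c(1, 3), each = 40) + 0.01 * lengths +
                    sin(lengths / 20) * 0.3 + rnorm(80, 0, 0.05))
  fit_inf <- fit_trait_model(d, "Osf", "species", sp = 1e9)
  ls <- stats::lm(value ~ species + fork_length_mm, data = d)
  pred_gam <- as.numeric(predict(fit_inf, d$species, d$fork_length_mm))
  pred_ls <- as.numeric(stats::predict(ls))
  expect_equal(pred_gam, pred_ls, tolerance = 1e-4)
})

test_that("predictions are invariant to input record order", {
  set.seed(3)
  lengths <- runif(60, 40, 160)
  m <- data.frame(species = rep(c("a", "b", "c"), 20), family = "f",
                  fork_length_mm = lengths, trait = "Osf",
                  value = rnorm(60, 2, 0.3))
  f1 <- fit_trait_model(m, "Osf", "species")
  f2 <- fit_trait_model(m[sample.int(60), ], "Osf", "species")
  L <- seq(50, 150, length.out = 11)
  expect_lt(max(abs(predict(f1, rep("a", 11), L) - predict(f2, rep("a", 11), L))),
            1e-10)
})

test_that("degenerate taxa and empty input are handled as specified", {
  expect_error(fit_trait_model(data.frame(species = character(0), family = character(0),
                                          fork_length_mm = numeric(0),
                                          trait = character(0), value = numeric(0)),
                               "Osf"), "no records")
  m <- rbind(
    linear_measurements("a", 2, 0.01, seq(50, 150, by = 25)),
    data.frame(species = "lonely", family = "fam_lonely", fork_length_mm = 90,
               trait = "Osf", value = 7)
  )
  w <- testthat::capture_warnings(fit <- fit_trait_model(m, "Osf", "species"))
  expect_true(any(grepl("single record", w)))
  expect_equal(as.numeric(predict(fit, c("lonely", "lonely"), c(60, 140))),
               c(7, 7))
})

test_that("impute_survey_traits predicts per individual with clamping and fallbacks", {
  m <- linear_measurements(c("a", "b"), intercepts = c(1, 4), slopes = c(0.02, 0.02),
                           lengths = seq(50, 150, by = 10))
  models <- list(Osf = suppressWarnings(fit_trait_model(m, "Osf", "species")))
  map <- data.frame(species = c("a", "b"), family = c("fam_a", "fam_b"))

  # 10 measured individuals -> 10 predictions per trait model
  sv <- rbind(
    survey_row("p1", 2010, 1, 1, "a", count = 10),
    do.call(rbind, lapply(seq(55, 145, by = 10),
                          function(L) survey_row("p1", 2010, 1, 1, "a", fork = L)))
  )
  pred <- impute_survey_traits(models, sv, map)
  expect_equal(nrow(pred), 10)
  expect_equal(sum(pred$weight), 10)
  expect_equal(pred$value, 1 + 0.02 * seq(55, 145, by = 10), tolerance = 1e-3)

  # lengths beyond the training range are clamped to the boundary
  sv_out <- rbind(survey_row("p1", 2010, 1, 1, "a", count = 1),
                  survey_row("p1", 2010, 1, 1, "a", fork = 500))
  pred_out <- impute_survey_traits(models, sv_out, map)
  expect_equal(attr(pred_out, "n_clamped"), 1L)
  expect_equal(pred_out$value, 1 + 0.02 * 150, tolerance = 1e-3)

  # unmeasured individuals get the species survey-wide mean length
  sv_fb <- rbind(survey_row("p1", 2010, 1, 1, "a", count = 3),
                 survey_row("p1", 2010, 1, 1, "a", fork = 80),
                 survey_row("p1", 2010, 1, 1, "a", fork = 120))
  expect_message(pred_fb <- impute_survey_traits(models, sv_fb, map),
                 "pseudo-individuals")
  expect_equal(nrow(pred_fb), 3)
  expect_equal(sum(pred_fb$weight), 3)
  expect_equal(attr(pred_fb, "n_length_fallback"), 1L)
  # pseudo-individual sits at the mean of the two measured lengths (100 mm)
  expect_equal(sort(pred_fb$value), 1 + 0.02 * c(80, 100, 120), tolerance = 1e-3)

  # unmapped species is a hard error naming the species
  sv_bad <- survey_row("p1", 2010, 1, 1, "zzz", fork = 100)
  expect_error(impute_survey_traits(models, sv_bad, map), "zzz")
})

test_that("a flat model gives every individual of a species the same value", {
  m <- linear_measurements(c("a", "b"), intercepts = c(2, 6), slopes = c(0, 0),
                           lengths = seq(50, 150, by = 20))
  models <- list(Osf = suppressWarnings(fit_trait_model(m, "Osf", "species", sp = 1e9)))
  sv <- do.call(rbind, lapply(c(55, 90, 149), function(L)
    survey_row("p1", 2010, 1, 1, "a", fork = L)))
  pred <- impute_survey_traits(models, sv,
                               data.frame(species = c("a", "b"),
                                          family = c("fa", "fb")))
  expect_equal(max(pred$value) - min(pred$value), 0, tolerance = 1e-6)
})
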