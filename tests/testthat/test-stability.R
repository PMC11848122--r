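test_that("year_to_centroid matches direct geometry in simple cases", {
  # identical year-communities -> both distances 0
  M <- community_matrix(rbind(c(1, 2), c(1, 2), c(3, 1), c(3, 1)),
                        rep(c("p1", "p2"), each = 2), c(2010, 2011, 2010, 2011))
  colnames(M) <- c("a", "b")
  y <- year_to_centroid(bray_curtis(M))
  expect_equal(y$distance, rep(0, 4), tolerance = 1e-10)

  # pond with 2 years, Euclidean-embeddable D: both distances d(1,2)/2
  X <- rbind(c(0, 0), c(2, 0), c(5, 5), c(6, 6))
  D <- euclid_dist(X, ponds = c("p1", "p1", "p2", "p2"),
                   years = c(2010, 2011, 2010, 2011))
  y2 <- year_to_centroid(D)
  expect_equal(y2$distance[y2$pond == "p1"], c(1, 1), tolerance = 1e-8)

  # raw_to_mean: rows (2,0) and (0,2) -> mean (1,1); both BC = 0.5
  Mr <- community_matrix(rbind(c(2, 0), c(0, 2)), c("p1", "p1"), c(2010, 2011))
  y3 <- year_to_centroid(Mr, mode = "raw_to_mean")
  expect_equal(y3$distance, c(0.5, 0.5))

  # a pond with a single year is dropped with a warning
  D1 <- euclid_dist(rbind(c(0, 0), c(1, 0), c(9, 9)),
                    ponds = c("p1", "p1", "p2"), years = c(2010, 2011, 2010))
  expect_warning(y4 <- year_to_centroid(D1), "single year")
  expect_setequal(y4$pond, "p1")
})

test_that("pcoa_centroid distances equal Euclidean point-to-centroid distances", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(6:10, 1)
    X <- matrix(rnorm(n * 2), n, 2)
    g <- sample(rep(c("p1", "p2"), length.out = n))
    D <- euclid_dist(X, ponds = g, years = seq_len(n))
    y <- year_to_centroid(D)
    direct <- unlist(lapply(c("p1", "p2"), function(p) {
      i <- which(g == p)
      ctr <- colMeans(X[i, , drop = FALSE])
      sqrt(rowSums(sweep(X[i, , drop = FALSE], 2, ctr)^2))
    }))
    expect_equal(y$distance, unname(direct), tolerance = 1e-8)
  }
})

test_that("year_to_centroid centroid mode matches vegan betadisper", {
  skip_if_not_installed("vegan")
  set.seed(23)
  M <- matrix(runif(12 * 6), 12, 6)
  g <- factor(rep(c("p1", "p2", "p3"), each = 4))
  D <- bray_curtis(M)
  y <- year_to_centroid(D, groups = g, years = rep(1:4, 3))
  bd <- vegan::betadisper(stats::as.dist(unclass(D)), g, type = "centroid")
  expect_equal(y$distance, unname(as.numeric(bd$distances)), tolerance = 1e-10)
})

test_that("year_to_year walks consecutive observed years only", {
  X <- rbind(c(0, 0), c(0, 0.2), c(0, 0.6), c(5, 0), c(5, 1))
  D <- euclid_dist(X, ponds = c("p1", "p1", "p1", "p2", "p2"),
                   years = c(2010, 2011, 2012, 2010, 2011))
  y <- year_to_year(D)
  expect_equal(nrow(y), 3)
  expect_equal(y$distance[y$pond == "p1"], c(0.2, 0.4), tolerance = 1e-12)
  expect_equal(mean(y$distance[y$pond == "p1"]), 0.3, tolerance = 1e-12)

  # 6 years -> 5 transitions; constant community -> all transitions 0
  M <- community_matrix(matrix(rep(c(1, 2), each = 6), 6, 2), rep("p1", 6),
                        2010:2015)
  # need a second pond for BC matrix validity of attr handling
  y6 <- year_to_year(bray_curtis(M))
  expect_equal(nrow(y6), 5)
  expect_equal(y6$distance, rep(0, 5))

  # a gap in the year sequence is logged, not bridged
  Dg <- euclid_dist(rbind(c(0, 0), c(1, 0), c(2, 0)),
                    ponds = rep("p1", 3), years = c(2010, 2011, 2013))
  expect_message(yg <- year_to_year(Dg), "gap")
  expect_equal(nrow(yg), 1)
  expect_equal(yg$to_year, 2011)
})

test_that("relative stability divides by the within-type maximum", {
  d <- data.frame(pond = "p1", year = 1:3, distance = c(0.2, 0.4, 0.5))
  r <- relative_stability(d, "species")
  expect_equal(r$relative_distance, c(0.4, 0.8, 1.0))
  expect_equal(max(r$relative_distance), 1)

  # single distance -> 1; scale invariance
  expect_equal(relative_stability(data.frame(distance = 0.3), "t")$relative_distance, 1)
  d7 <- d; d7$distance <- d$distance * 7
  expect_equal(relative_stability(d7, "s")$relative_distance, r$relative_distance)

  expect_warning(r0 <- relative_stability(data.frame(distance = c(0, 0)), "s"),
                 "zero")
  expect_equal(r0$relative_distance, c(0, 0))
})

test_that("stability_anova reproduces the crossed design dfs and textbook sums of squares", {
  # balanced 6 ponds x 2 types x 6 years -> dfs 5, 1, 5, 60
  set.seed(31)
  d <- expand.grid(pond = paste0("p", 1:6), composition_type = c("species", "trait"),
                   year = 1:6)
  d$relative_distance <- runif(nrow(d))
  a <- stability_anova(d)
  expect_equal(a$df, c(5, 1, 5, 60))

  # 5 transitions -> residual df 48
  d5 <- d[d$year <= 5, ]
  expect_equal(stability_anova(d5)$df, c(5, 1, 5, 48))

  # identical response everywhere -> all F = 0
  dc <- d; dc$relative_distance <- 0.5
  expect_equal(stability_anova(dc)$F[1:3], rep(0, 3))

  # zero-noise known cell means: SS match hand-computed sums of squares
  mu_pond <- c(p1 = 0.1, p2 = 0.3); mu_type <- c(species = 0, trait = 0.2)
  dh <- expand.grid(pond = c("p1", "p2"), composition_type = c("species", "trait"),
                    rep = 1:4)
  dh$relative_distance <- mu_pond[dh$pond] + mu_type[as.character(dh$composition_type)]
  # zero-noise fit: suppress the "essentially perfect fit" warning
  ah <- suppressWarnings(stability_anova(dh))
  n_per <- 8  # observations per factor level
  expect_equal(ah$sumsq[1], n_per * sum((c(0.1, 0.3) - 0.2)^2))  # pond SS
  expect_equal(ah$sumsq[2], n_per * sum((c(0, 0.2) - 0.1)^2))    # type SS
  expect_lt(ah$sumsq[3], 1e-16)
  expect_lt(ah$sumsq[4], 1e-16)

  # collapsing ponds to one: F for composition_type equals the squared
  # two-sample t statistic
  set.seed(8)
  d1 <- data.frame(pond = "p1",
                   composition_type = rep(c("species", "trait"), each = 10),
                   relative_distance = c(rnorm(10, 1), rnorm(10, 1.4)))
  a1 <- stability_anova(d1)
  tt <- stats::t.test(relative_distance ~ composition_type, data = d1,
                      var.equal = TRUE)
  expect_equal(a1$F[a1$term == "composition_type"], unname(tt$statistic)^2,
               tolerance = 1e-10)

  # empty cells are an error; unbalanced designs fall back to Type II
  dbad <- d[!(d$pond == "p1" & d$composition_type == "trait"), ]
  expect_error(stability_anova(dbad), "empty")
  dunb <- d[-1, ]
  expect_warning(au <- stability_anova(dunb), "unbalanced")
  expect_equal(au$df[4], 59)
})
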