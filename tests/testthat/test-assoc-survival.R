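# Contingency tests, Kaplan-Meier/log-rank and Cox proportional hazards.

test_that("uncorrected chi-square reproduces the published dual-IF comparisons", {
  # claudin-low 11/20 vs other subtypes 17/66 dual positive
  t1 <- chiSquare2x2(matrix(c(11, 17, 9, 49), 2))
  expect_equal(t1$chi2, 86 * (11 * 49 - 9 * 17)^2 / (20 * 66 * 28 * 58),
               tolerance = 1e-12)
  expect_equal(round(t1$p.value, 3), 0.014)
  # claudin-low 11/20 vs basal-like 14/18
  t2 <- chiSquare2x2(matrix(c(11, 14, 9, 4), 2))
  expect_equal(round(t2$p.value, 2), 0.14)
  # continuity correction is available but changes the first p materially
  expect_gt(chiSquare2x2(matrix(c(11, 17, 9, 49), 2),
                         correct = TRUE)$p.value, 0.02)
  # proportional table: no association
  t3 <- chiSquare2x2(matrix(c(10, 20, 10, 20), 2))
  expect_equal(t3$chi2, 0)
  expect_equal(t3$p.value, 1)
  # invariant to transposition; zero margin errors
  tab <- matrix(c(3, 9, 5, 2), 2)
  expect_equal(chiSquare2x2(tab)$chi2, chiSquare2x2(t(tab))$chi2)
  expect_error(chiSquare2x2(matrix(c(0, 0, 5, 2), 2)), "margin")
})

test_that("Fisher's exact test follows the probability-mass rule", {
  expect_equal(fisherExact2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  # [[3,0],[0,3]]: 2 of the 20 equally likely tables are as extreme
  expect_equal(fisherExact2x2(matrix(c(3, 0, 0, 3), 2)), 0.1,
               tolerance = 1e-12)
  expect_equal(fisherExact2x2(matrix(c(4, 3, 0, 0), 2)), 1)
  p <- fisherExact2x2(matrix(c(12, 2, 3, 11), 2))
  expect_true(p >= 0 && p <= 1)
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  # events at t = 1, 2; censored at 3, 4: S = 3/4 then 3/4 * 2/3 = 1/2
  km <- kmLogrank(time = c(1, 2, 3, 4), event = c(1, 1, 0, 0),
                  group = rep("all", 4))
  curve <- km$curves[["all"]]
  expect_equal(curve$surv[curve$time == 1], 0.75)
  expect_equal(curve$surv[curve$time == 2], 0.50)
  # no censoring: KM equals the empirical survival function
  tt <- c(5, 1, 3, 2, 4)
  km2 <- kmLogrank(tt, rep(1, 5), rep("all", 5))
  c2 <- km2$curves[["all"]]
  expect_equal(c2$surv, 1 - ecdf(tt)(sort(tt)), tolerance = 1e-12)
  # no events anywhere: flat curves, p = 1 with a warning
  expect_warning(km3 <- kmLogrank(1:6, rep(0, 6), rep(c("a", "b"), 3)),
                 "no events")
  expect_true(all(unlist(lapply(km3$curves, function(cv) cv$surv)) == 1))
  expect_equal(km3$p.value, 1)
})

test_that("log-rank is zero for identical groups and detects separated hazards", {
  tt <- c(2, 4, 6, 8, 10)
  ev <- c(1, 1, 0, 1, 0)
  km <- kmLogrank(rep(tt, 2), rep(ev, 2), rep(c("a", "b"), each = 5))
  expect_equal(km$chi2, 0, tolerance = 1e-10)
  expect_equal(km$p.value, 1, tolerance = 1e-10)
  set.seed(30)
  t1 <- rexp(60, 0.02); t2 <- rexp(60, 0.1)
  km2 <- kmLogrank(c(t1, t2), rep(1, 120), rep(c("slow", "fast"), each = 60))
  expect_lt(km2$p.value, 0.001)
  expect_equal(km2$df, 1L)
})

test_that("Cox fit matches a brute-force Breslow partial-likelihood grid", {
  time <- c(3, 5, 6, 8, 10, 12)
  event <- c(1, 1, 1, 0, 1, 0)
  x <- c(1, 0, 1, 0, 1, 0)
  fit <- coxPH(time, event, data.frame(x = x))
  grid <- seq(-3, 3, by = 5e-4)
  ll <- vapply(grid, breslowLoglik, numeric(1), time = time,
               event = event, x = x)
  expect_equal(fit$coef, grid[which.max(ll)], tolerance = 1e-3)
  expect_equal(fit$hr, exp(fit$coef), tolerance = 1e-12)
})

test_that("Cox degeneracies error rather than report silent numbers", {
  time <- c(3, 5, 6, 8, 10, 12)
  event <- c(1, 1, 1, 0, 1, 0)
  x <- c(1, 0, 1, 0, 1, 0)
  # duplicated covariate pair is non-identifiable
  expect_error(coxPH(time, event, data.frame(x = x, x2 = x)),
               "degenerate|identifiable")
  # identical event patterns in both arms: HR = 1
  fit <- coxPH(rep(time, 2), rep(event, 2),
               data.frame(arm = rep(c(0, 1), each = 6)))
  expect_equal(fit$hr, 1, tolerance = 1e-8)
  expect_error(coxPH(time, rep(0, 6), data.frame(x = x)), "event")
})

test_that("the Cox CI covers a true log-hazard ratio of 0.7 at n = 400", {
  set.seed(11)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, rate = 0.05 * exp(0.7 * x))
  cens <- runif(n, 5, 60)
  time <- pmin(tt, cens)
  event <- as.integer(tt <= cens)
  fit <- coxPH(time, event, data.frame(x = x))
  expect_lt(fit$lower95, exp(0.7))
  expect_gt(fit$upper95, exp(0.7))
  expect_equal(fit$coef, 0.7, tolerance = 0.25)
})

test_that("claudin-low tumors show the built-in excess hazard vs luminal A", {
  cfg <- syntheticConfig(seed = 77)
  cfg$nPerSubtype[] <- 80L
  se <- generateTumorCohort(cfg)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  sel <- cd$true_subtype %in% c("ClaudinLow", "LumA")
  fit <- coxPH(cd$rfs_time[sel], cd$rfs_event[sel],
               data.frame(cl = as.integer(cd$true_subtype[sel] ==
                                            "ClaudinLow")))
  expect_gt(fit$hr, 1)
})

test_that("stratified Cox accepts a cohort stratum", {
  set.seed(12)
  n <- 120
  x <- rbinom(n, 1, 0.5)
  strat <- rep(c("c1", "c2"), each = n / 2)
  base <- ifelse(strat == "c1", 0.03, 0.08)
  tt <- rexp(n, base * exp(0.6 * x))
  cens <- runif(n, 10, 80)
  fit <- coxPH(pmin(tt, cens), as.integer(tt <= cens),
               data.frame(x = x), strata = strat)
  expect_equal(fit$coef, 0.6, tolerance = 0.5)
})
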