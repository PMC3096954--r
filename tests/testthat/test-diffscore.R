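# Differentiation scores along the MaSC -> pL -> mL axis and score
# dichotomization.

fitDefaultModel <- function(seed = 3) {
  pops <- generateSortedPopulations(syntheticConfig(seed = seed))
  pl <- SummarizedExperiment::colData(pops)$population
  x <- exprsMatrix(pops)
  fitDifferentiationModel(x[, pl == "MaSC", drop = FALSE],
                          x[, pl == "pL", drop = FALSE],
                          x[, pl == "mL", drop = FALSE])
}

test_that("a pL-centroid sample in a symmetric test set scores exactly zero", {
  # noiseless symmetric populations: MaSC = -u, pL = 0, mL = +u, so the
  # training medians coincide with the pL centroid and the stored origin
  # is exactly zero
  set.seed(1)
  genes <- paste0("g", 1:30)
  u <- rnorm(30)
  mk <- function(v, pfx) matrix(v, 30, 2, dimnames = list(genes,
                                                          paste0(pfx, 1:2)))
  dm <- fitDifferentiationModel(mk(-u, "m"), mk(0, "p"), mk(u, "l"))
  expect_equal(dm@plCentroid, setNames(rep(0, 30), NULL),
               ignore_attr = TRUE)
  # any test set symmetric about a common center: the center sample is the
  # zero vector after centering, hence projects to score 0
  v <- rnorm(30)
  q <- rnorm(30)
  test <- cbind(q + v, q, q - v)
  dimnames(test) <- list(genes, c("plus", "origin", "minus"))
  sc <- computeDifferentiationScores(dm, test)
  expect_equal(sc$score[sc$sample_id == "origin"], 0)
  expect_equal(sc$proj_masc[sc$sample_id == "origin"], 0)
  # mL-like sample scores positive, MaSC-like negative
  mtest <- cbind(u, -u, rnorm(30, sd = 1e-3))
  dimnames(mtest) <- list(genes, c("mlike", "masclike", "mid"))
  sc2 <- computeDifferentiationScores(dm, mtest)
  expect_gt(sc2$score[1], 0)
  expect_lt(sc2$score[2], 0)
})

test_that("scores order held-out populations MaSC < pL < mL with correct signs", {
  dm <- fitDefaultModel(seed = 3)
  ho <- generateSortedPopulations(syntheticConfig(seed = 33),
                                  nPerPopulation = 20)
  lab <- SummarizedExperiment::colData(ho)$population
  sc <- computeDifferentiationScores(dm, exprsMatrix(ho))
  means <- tapply(sc$score, lab, mean)
  expect_lt(means["MaSC"], means["pL"])
  expect_lt(means["pL"], means["mL"])
  expect_lt(means["MaSC"], 0)
  expect_gt(means["mL"], 0)
})

test_that("synthetic tumor subtypes follow the differentiation hierarchy", {
  dm <- fitDefaultModel(seed = 3)
  se <- generateTumorCohort(syntheticConfig(seed = 44))
  lab <- SummarizedExperiment::colData(se)$true_subtype
  sc <- computeDifferentiationScores(dm, normalizeExpression(se))
  means <- tapply(sc$score, lab, mean)
  expect_lt(means["ClaudinLow"], means["Basal"])
  expect_lt(means["Basal"], means["HER2E"])
  expect_lt(means["HER2E"], min(means["LumA"], means["LumB"]))
})

test_that("scores are invariant to gene permutation and all-missing extra genes", {
  dm <- fitDefaultModel()
  test <- randomMatrix(length(dm@genes), 8, seed = 17)
  rownames(test) <- dm@genes
  base <- computeDifferentiationScores(dm, test)
  perm <- computeDifferentiationScores(dm, test[sample(nrow(test)), ])
  expect_equal(base$score, perm$score, tolerance = 1e-12)
  extra <- rbind(test, matrix(NA_real_, 5, 8,
                              dimnames = list(paste0("x", 1:5),
                                              colnames(test))))
  expect_equal(computeDifferentiationScores(dm, extra)$score, base$score,
               tolerance = 1e-12)
  expect_error(computeDifferentiationScores(dm, test[1:10, ]),
               "model genes")
})

test_that("differentiation models roundtrip through JSON", {
  dm <- fitDefaultModel()
  f <- withr::local_tempfile(fileext = ".json")
  writeDifferentiationModel(dm, f)
  back <- readDifferentiationModel(f)
  test <- randomMatrix(length(dm@genes), 5, seed = 18)
  rownames(test) <- dm@genes
  expect_equal(computeDifferentiationScores(back, test),
               computeDifferentiationScores(dm, test), tolerance = 1e-10)
})

test_that("dichotomization splits equally with the odd sample going low", {
  s6 <- c(5, 1, 3, 6, 2, 4)
  g6 <- dichotomizeScores(s6)
  expect_equal(sum(g6 == "low"), 3)
  expect_equal(as.character(g6[s6 <= 3]), rep("low", 3))
  g7 <- dichotomizeScores(c(s6, 7))
  expect_equal(sum(g7 == "low"), 4)
  # all-equal scores split by stable input order
  gE <- dichotomizeScores(rep(1, 5))
  expect_equal(as.character(gE), c("low", "low", "low", "high", "high"))
  expect_error(dichotomizeScores(1), ">= 2")
})

test_that("low differentiation scores track higher event rates in synthetic survival", {
  dm <- fitDefaultModel(seed = 3)
  cfg <- syntheticConfig(seed = 55)
  cfg$nPerSubtype[] <- 60L
  se <- generateTumorCohort(cfg)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  sc <- computeDifferentiationScores(dm, normalizeExpression(se))
  grp <- dichotomizeScores(sc$score)
  evRate <- tapply(cd$rfs_event, grp, mean)
  expect_gt(evRate["low"], evRate["high"])
})
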