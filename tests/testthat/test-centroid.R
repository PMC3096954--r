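# Centroid model construction, nearest-centroid classification, the
# claudin-low override and binary predictor evaluation.

test_that("centroids equal brute-force per-class gene means", {
  x <- randomMatrix(30, 12, seed = 7)
  labs <- rep(c("claudin-low", "others"), each = 6)
  mod <- buildCentroidModel(x, labs)
  for (cl in c("claudin-low", "others")) {
    expect_equal(centroidMatrix(mod)[, cl],
                 rowMeans(x[, labs == cl]), tolerance = 1e-12)
  }
  # single-sample class centroid is that sample's profile
  mod1 <- buildCentroidModel(x[, 1:3], c("a", "b", "b"))
  expect_equal(centroidMatrix(mod1)[, "a"], x[, 1], ignore_attr = TRUE)
})

test_that("euclidean distances match a brute-force recomputation", {
  x <- randomMatrix(20, 10, seed = 8)
  labs <- rep(c("claudin-low", "others"), each = 5)
  mod <- buildCentroidModel(x, labs)
  test <- randomMatrix(20, 6, seed = 9)
  calls <- classifyNearestCentroid(mod, test)
  for (j in 1:6) {
    for (cl in c("claudin-low", "others")) {
      expect_equal(calls[[paste0("dist.", cl)]][j],
                   sqrt(sum((test[, j] - centroidMatrix(mod)[, cl])^2)),
                   tolerance = 1e-12)
    }
    expect_equal(calls$call[j],
                 c("claudin-low", "others")[
                   which.min(c(calls$`dist.claudin-low`[j],
                               calls$dist.others[j]))])
  }
})

test_that("a sample equal to a centroid is called with distance 0 and ties go to others", {
  x <- randomMatrix(15, 8, seed = 10)
  labs <- rep(c("claudin-low", "others"), each = 4)
  mod <- buildCentroidModel(x, labs)
  cent <- centroidMatrix(mod)
  # exact claudin-low centroid
  t1 <- matrix(cent[, "claudin-low"], ncol = 1,
               dimnames = list(rownames(x), "t1"))
  c1 <- classifyNearestCentroid(mod, t1)
  expect_equal(c1$call, "claudin-low")
  expect_equal(c1$`dist.claudin-low`, 0)
  # exactly equidistant sample: the midpoint
  t2 <- matrix((cent[, 1] + cent[, 2]) / 2, ncol = 1,
               dimnames = list(rownames(x), "t2"))
  c2 <- classifyNearestCentroid(mod, t2)
  expect_equal(c2$call, "others")
})

test_that("calls are invariant to gene-row permutation and missing genes rescale distance", {
  x <- randomMatrix(25, 10, seed = 11)
  labs <- rep(c("claudin-low", "others"), each = 5)
  mod <- buildCentroidModel(x, labs)
  test <- randomMatrix(25, 5, seed = 12)
  base <- classifyNearestCentroid(mod, test)
  perm <- classifyNearestCentroid(mod, test[sample(25), ])
  expect_equal(base$call, perm$call)
  expect_equal(base$`dist.claudin-low`, perm$`dist.claudin-low`)
  # one missing value: distance over n-1 genes rescaled by sqrt(n/(n-1))
  t2 <- test[, 1, drop = FALSE]
  t2[3, 1] <- NA
  d <- classifyNearestCentroid(mod, t2)$`dist.claudin-low`
  manual <- sqrt(sum((t2[-3, 1] - centroidMatrix(mod)[-3, 1])^2) * 25 / 24)
  expect_equal(d, manual, tolerance = 1e-12)
  # too little overlap errors
  expect_error(classifyNearestCentroid(mod, test[1:5, ]), "model genes")
})

test_that("spearman calls are invariant under strictly monotone transforms", {
  x <- randomMatrix(40, 12, seed = 13)
  labs <- rep(c("a", "b", "c"), each = 4)
  mod <- buildCentroidModel(x, labs, metric = "spearman")
  test <- randomMatrix(40, 6, seed = 14)
  base <- classifyNearestCentroid(mod, test)
  warped <- classifyNearestCentroid(mod, exp(test) + test^3)
  expect_equal(base$call, warped$call)
  expect_equal(base$cor.a, warped$cor.a)
})

test_that("the claudin-low override replaces the primary call only when positive", {
  primary <- data.frame(sample_id = c("s1", "s2", "s3"),
                        call = c("basal-like", "LumA", "HER2E"))
  cl <- data.frame(sample_id = c("s1", "s2", "s3"),
                   call = c("claudin-low", "others", "others"))
  out <- combineSubtypeCalls(primary, cl)
  expect_equal(unname(out), c("claudin-low", "LumA", "HER2E"))
  # all-negative claudin-low predictor leaves the primary map untouched
  clNeg <- transform(cl, call = "others")
  expect_equal(unname(combineSubtypeCalls(primary, clNeg)), primary$call)
  expect_error(combineSubtypeCalls(primary, cl[1:2, ]), "different samples")
})

test_that("binary predictor metrics reproduce the published worked example", {
  predicted <- rep(c(TRUE, TRUE, FALSE, FALSE), c(28, 9, 4, 296))
  gold <- rep(c(TRUE, FALSE, TRUE, FALSE), c(28, 9, 4, 296))
  ev <- evaluateBinaryPredictor(predicted, gold)
  expect_equal(ev$sensitivity, 87.5)
  expect_equal(ev$specificity, 97.0)
  expect_equal(ev$ppv, 75.7)
  expect_equal(ev$npv, 98.7)
  expect_equal(unlist(ev[c("tp", "fp", "fn", "tn")]),
               c(tp = 28, fp = 9, fn = 4, tn = 296))

  perfect <- evaluateBinaryPredictor(gold, gold)
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 100, specificity = 100, ppv = 100, npv = 100))

  allNeg <- evaluateBinaryPredictor(rep(FALSE, 10),
                                    rep(c(TRUE, FALSE), c(3, 7)))
  expect_equal(allNeg$sensitivity, 0)
  expect_true(is.na(allNeg$ppv))  # zero denominator reported as absent
})

test_that("centroid models roundtrip through JSON", {
  x <- randomMatrix(12, 8, seed = 15)
  mod <- buildCentroidModel(x, rep(c("claudin-low", "others"), each = 4),
                            metric = "euclidean", provenance = "test")
  f <- withr::local_tempfile(fileext = ".json")
  writeCentroidModel(mod, f)
  back <- readCentroidModel(f)
  expect_equal(centroidMatrix(back), centroidMatrix(mod), tolerance = 1e-12)
  expect_equal(modelGenes(back), modelGenes(mod))
  expect_equal(modelMetric(back), "euclidean")
  test <- randomMatrix(12, 4, seed = 16)
  expect_equal(classifyNearestCentroid(back, test),
               classifyNearestCentroid(mod, test), tolerance = 1e-10)
})

test_that("a trained claudin-low predictor classifies an independent draw accurately", {
  train <- generateTumorCohort(syntheticConfig(seed = 11))
  test <- generateTumorCohort(syntheticConfig(seed = 22))
  xtr <- normalizeExpression(train)
  xte <- normalizeExpression(test)
  ltr <- SummarizedExperiment::colData(train)$true_subtype
  lte <- SummarizedExperiment::colData(test)$true_subtype
  cl <- ifelse(ltr == "ClaudinLow", "claudin-low", "others")
  sam <- samSelect(xtr, cl, fdrTarget = 0.05, seed = 1)
  mod <- buildCentroidModel(xtr, cl, genes = selectedGenes(sam))
  calls <- classifyNearestCentroid(mod, xte)
  acc <- mean((calls$call == "claudin-low") == (lte == "ClaudinLow"))
  expect_gte(acc, 0.95)

  # with no signal the same pipeline falls to chance
  flat <- generateTumorCohort(syntheticConfig(seed = 11, effectSize = 0))
  xf <- normalizeExpression(flat)
  modF <- buildCentroidModel(xf, cl, genes = selectedGenes(sam))
  flatTest <- generateTumorCohort(syntheticConfig(seed = 22, effectSize = 0))
  callsF <- classifyNearestCentroid(modF, normalizeExpression(flatTest))
  accF <- mean((callsF$call == "claudin-low") == (lte == "ClaudinLow"))
  expect_lt(accF, 0.75)
})
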