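# End-to-end orchestration: simulate -> preprocess -> train predictors ->
# classify -> signature scores -> differentiation scores -> clinical
# statistics -> machine-readable report. Every stage seed derives
# deterministically from the global seed so two runs with the same
# configuration are byte-identical.

#' Pipeline configuration
#'
#' @param synthetic a [syntheticConfig()] describing the simulated training
#'   cohort; the held-out test cohort and the sorted populations use seeds
#'   derived from `seed`.
#' @param fdrTarget SAM FDR target for the claudin-low predictor genes.
#' @param normalFdrTarget SAM FDR target for the normal-breast predictor.
#' @param nPermutations SAM permutation count.
#' @param dwd a [dwdConfig()].
#' @param seed global seed; all stage seeds derive from it.
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(synthetic = syntheticConfig(),
                           fdrTarget = 0.05, normalFdrTarget = 0,
                           nPermutations = 200L,
                           dwd = dwdConfig(), seed = 1L) {
  structure(list(synthetic = synthetic, fdrTarget = fdrTarget,
                 normalFdrTarget = normalFdrTarget,
                 nPermutations = as.integer(nPermutations),
                 dwd = dwd, seed = as.integer(seed)),
            class = "PipelineConfig")
}

.stageSeed <- function(seed, k)
  as.integer((as.numeric(seed) * 131 + k * 7919) %% 2147483647)

#' Run the full claudin-low characterization pipeline
#'
#' Stages, in order: simulate a training and an independent test tumor
#' cohort plus sorted mammary populations; normalize; select claudin-low
#' predictor genes by two-class unpaired SAM (FDR target 5%) and
#' normal-breast genes at 0% FDR; build Euclidean centroid predictors and a
#' multi-class Spearman centroid subtype model; classify the test cohort
#' and apply the claudin-low override; evaluate the claudin-low predictor
#' against the generating labels; score module signatures with across-
#' subtype ANOVA; fit the DWD differentiation model, score and dichotomize
#' the test tumors and compare survival (KM/log-rank, Cox claudin-low vs
#' luminal A); run the pCR and triple-negative contingency tests; write
#' every table and a JSON summary to `outDir`.
#'
#' @param cfg a [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @return the summary list, invisibly; files are written to `outDir`.
#' @export
runPipeline <- function(cfg = pipelineConfig(), outDir) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## -- simulate ----------------------------------------------------------
  summary <- list(seed = cfg$seed)
  synTrain <- cfg$synthetic
  synTrain$seed <- .stageSeed(cfg$seed, 1L)
  synTest <- cfg$synthetic
  synTest$seed <- .stageSeed(cfg$seed, 2L)
  synPops <- cfg$synthetic
  synPops$seed <- .stageSeed(cfg$seed, 3L)

  train <- stage("simulate", generateTumorCohort(synTrain, cohort = "TRAIN"))
  test <- stage("simulate", generateTumorCohort(synTest, cohort = "TEST"))
  pops <- stage("simulate", generateSortedPopulations(synPops))
  writeExpressionMatrix(train, file.path(outDir, "expression_train.tsv"))
  writeExpressionMatrix(test, file.path(outDir, "expression_test.tsv"))
  clinTrain <- as.data.frame(SummarizedExperiment::colData(train))
  clinTest <- as.data.frame(SummarizedExperiment::colData(test))
  write.table(clinTrain, file.path(outDir, "clinical_train.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(clinTest, file.path(outDir, "clinical_test.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## -- preprocess --------------------------------------------------------
  xTrain <- stage("preprocess", normalizeExpression(train))
  xTest <- stage("preprocess", normalizeExpression(test))
  labTrain <- clinTrain$true_subtype
  labTest <- clinTest$true_subtype

  ## -- train claudin-low + normal predictors -----------------------------
  clLabels <- ifelse(labTrain == "ClaudinLow", "claudin-low", "others")
  samCl <- stage("train-claudinlow",
                 samSelect(xTrain, clLabels, fdrTarget = cfg$fdrTarget,
                           nPermutations = cfg$nPermutations,
                           seed = .stageSeed(cfg$seed, 4L)))
  clGenes <- selectedGenes(samCl)
  if (!length(clGenes)) stop("pipeline stage 'train-claudinlow' failed: ",
                             "SAM selected no genes")
  clModel <- stage("train-claudinlow",
                   buildCentroidModel(xTrain, clLabels, genes = clGenes,
                                      metric = "euclidean",
                                      provenance = "synthetic training cohort"))
  writeCentroidModel(clModel, file.path(outDir, "claudinlow_model.json"))
  writeSamResult(samCl, file.path(outDir, "claudinlow_sam.json"))

  nbLabels <- ifelse(labTrain == "NormalLike", "normal", "others")
  samNb <- stage("train-normal",
                 samSelect(xTrain, nbLabels,
                           fdrTarget = cfg$normalFdrTarget,
                           nPermutations = cfg$nPermutations,
                           seed = .stageSeed(cfg$seed, 5L)))
  nbGenes <- selectedGenes(samNb)
  nbModel <- if (length(nbGenes))
    buildCentroidModel(xTrain, nbLabels, genes = nbGenes,
                       metric = "euclidean",
                       provenance = "synthetic training cohort") else NULL
  if (!is.null(nbModel))
    writeCentroidModel(nbModel, file.path(outDir, "normal_model.json"))

  # PAM50-style multi-class Spearman model on the most variable genes
  vr <- apply(xTrain, 1, var)
  hv <- names(sort(vr, decreasing = TRUE))[seq_len(min(200, nrow(xTrain)))]
  primModel <- stage("train-primary",
                     buildCentroidModel(xTrain, labTrain, genes = hv,
                                        metric = "spearman",
                                        provenance = "synthetic training cohort"))

  ## -- classify ----------------------------------------------------------
  clCalls <- stage("classify", classifyNearestCentroid(clModel, xTest))
  primCalls <- stage("classify", classifyNearestCentroid(primModel, xTest))
  finalCalls <- combineSubtypeCalls(primCalls, clCalls)
  callTab <- data.frame(sample_id = primCalls$sample_id,
                        primary_call = primCalls$call,
                        claudinlow_call = clCalls$call,
                        final_call = unname(finalCalls),
                        true_subtype = labTest,
                        stringsAsFactors = FALSE)
  write.table(callTab, file.path(outDir, "subtype_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  evalCl <- evaluateBinaryPredictor(clCalls$call == "claudin-low",
                                    labTest == "ClaudinLow")
  summary$predictor_evaluation <- evalCl
  summary$final_call_accuracy <- mean(
    ifelse(callTab$final_call == "claudin-low", "ClaudinLow",
           callTab$final_call) == labTest)

  ## -- signature scores --------------------------------------------------
  sigs <- moduleGeneSets(test)
  scores <- stage("signatures", scoreSignatures(xTest, sigs))
  write.table(data.frame(sample_id = rownames(scores), scores),
              file.path(outDir, "signature_scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary$signature_anova <- lapply(colnames(scores), function(sg)
    compareSubtypeMeans(scores[, sg], labTest, test = "anova"))
  names(summary$signature_anova) <- colnames(scores)
  summary$signature_subtype_means <- lapply(colnames(scores), function(sg)
    tapply(scores[, sg], labTest, mean))
  names(summary$signature_subtype_means) <- colnames(scores)

  ## -- differentiation score ---------------------------------------------
  popLab <- SummarizedExperiment::colData(pops)$population
  xPops <- exprsMatrix(pops)
  dm <- stage("diffscore", fitDifferentiationModel(
    xPops[, popLab == "MaSC", drop = FALSE],
    xPops[, popLab == "pL", drop = FALSE],
    xPops[, popLab == "mL", drop = FALSE], cfg$dwd))
  writeDifferentiationModel(dm, file.path(outDir, "differentiation_model.json"))
  ds <- stage("diffscore", computeDifferentiationScores(dm, xTest))
  ds$group <- dichotomizeScores(ds$score)
  write.table(ds, file.path(outDir, "differentiation_scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary$diff_score_subtype_means <- tapply(ds$score, labTest, mean)

  km <- stage("survival", kmLogrank(clinTest$rfs_time, clinTest$rfs_event,
                                    ds$group))
  summary$diffscore_logrank <- list(chi2 = km$chi2, p.value = km$p.value)
  sel <- labTest %in% c("ClaudinLow", "LumA")
  cox <- stage("survival", coxPH(
    clinTest$rfs_time[sel], clinTest$rfs_event[sel],
    data.frame(claudinlow = as.integer(labTest[sel] == "ClaudinLow"))))
  summary$cox_claudinlow_vs_luma <- as.list(cox[1, ])

  ## -- contingency -------------------------------------------------------
  pcrCl <- clinTest$pcr[labTest == "ClaudinLow"]
  pcrBl <- clinTest$pcr[labTest == "Basal"]
  pcrTab <- matrix(c(sum(pcrCl), sum(1 - pcrCl),
                     sum(pcrBl), sum(1 - pcrBl)), 2, byrow = TRUE)
  summary$pcr <- list(
    claudinlow_rate = mean(pcrCl), basal_rate = mean(pcrBl),
    fisher_p = fisherExact2x2(pcrTab))
  tn <- with(clinTest, er == 0 & pr == 0 & her2 == 0)
  tnTab <- matrix(c(sum(tn[labTest == "ClaudinLow"]),
                    sum(!tn[labTest == "ClaudinLow"]),
                    sum(tn[labTest != "ClaudinLow"]),
                    sum(!tn[labTest != "ClaudinLow"])), 2, byrow = TRUE)
  chi <- chiSquare2x2(tnTab)
  summary$triple_negative <- list(
    claudinlow_rate = mean(tn[labTest == "ClaudinLow"]),
    other_rate = mean(tn[labTest != "ClaudinLow"]),
    chi2 = chi$chi2, p.value = chi$p.value)

  ## -- report ------------------------------------------------------------
  summary$files <- list.files(outDir)
  jsonlite::write_json(summary, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(summary)
}
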