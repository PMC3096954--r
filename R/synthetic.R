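# Synthetic cohort generator.
#
# Emulates the statistical structure the downstream analyses assume: six
# intrinsic subtypes with subtype-specific shifts of eight biological gene
# modules (plus a dedicated ERBB2 marker and a large null-gene background),
# immune/stromal contamination of bulk tumors, a contamination-free
# cell-line panel, sorted mammary epithelial populations with an ordered
# luminal differentiation axis, and clinical outcomes (receptors, pCR,
# exponential survival with subtype-dependent hazards).

SUBTYPES <- c("LumA", "LumB", "HER2E", "Basal", "ClaudinLow", "NormalLike")
MODULES <- c("luminal", "proliferation", "basal_keratin", "claudin_adhesion",
             "emt", "immune", "stromal", "stem")

# Per-subtype module mean shifts in units of effect_size. Claudin-low:
# adhesion and luminal markers low (lowest of all subtypes: "low to
# absent" luminal differentiation), EMT/immune/stromal/stem high,
# proliferation moderately low (slower cycling than basal-like);
# basal-like keeps a milder luminal loss.
.moduleShiftTable <- function() {
  sh <- matrix(0, length(MODULES), length(SUBTYPES),
               dimnames = list(MODULES, SUBTYPES))
  sh["luminal", ]          <- c(1, 1, 0, -0.75, -1, 0)
  sh["proliferation", ]    <- c(-0.5, 1, 0.5, 1, -0.5, -1)
  sh["basal_keratin", ]    <- c(0, 0, 0, 1, 0, 0)
  sh["claudin_adhesion", ] <- c(0, 0, 0, 0, -1, 0)
  sh["emt", ]              <- c(0, 0, 0, 0, 1, 0)
  sh["immune", ]           <- c(0, 0, 0, 0, 1, 0.5)
  sh["stromal", ]          <- c(0, 0, 0, 0, 1, 0.5)
  sh["stem", ]             <- c(0, 0, 0, 0, 1, 0)
  sh
}

# Seed genes of each module get recognizable marker aliases so marker-level
# checks (CD44/CD24 ratio, claudin/E-cadherin levels, Ki67) are possible.
.moduleAliases <- list(
  luminal = c("CD24", "KRT18", "KRT19", "ESR1", "GATA3", "MUC1", "EPCAM"),
  proliferation = c("MKI67", "CCNB1", "AURKA"),
  basal_keratin = c("KRT5", "KRT14", "KRT17"),
  claudin_adhesion = c("CLDN3", "CLDN4", "CLDN7", "CDH1", "OCLN"),
  emt = c("VIM", "SNAI1", "SNAI2", "TWIST1", "TWIST2", "ZEB1", "ZEB2"),
  immune = c("CD79B", "CD14", "VAV1"),
  stromal = c("FGF7", "MMP9"),
  stem = c("CD44", "CD49F", "ALDH1A1")
)

#' Configuration for the synthetic cohort generator
#'
#' All defaults are fixed study conditions: 30 tumors per subtype, eight
#' 10-gene modules plus a dedicated ERBB2 marker gene and 900 null genes,
#' a 2.0 log2-unit module effect size with Gaussian noise sd 0.5, 10%
#' immune/stromal contamination of bulk tumors, pathological complete
#' response probabilities of 0.389 (claudin-low) and 0.733 (basal-like)
#' with luminal tumors far lower, and exponential relapse hazards scaled
#' 2.83-fold in claudin-low relative to luminal A with uniform censoring
#' on 12-120 months.
#'
#' @param nPerSubtype named integer vector over the six subtypes.
#' @param moduleSizes named integer vector over the eight gene modules.
#' @param nNullGenes number of unshifted background genes.
#' @param effectSize log2 magnitude of module shifts.
#' @param noiseSd Gaussian noise standard deviation (log2 units).
#' @param contaminationFraction convex admixture weight of a normal
#'   immune/stromal profile added to bulk tumors (0 for cell lines).
#' @param pcrProb named per-subtype probability of pathological complete
#'   response.
#' @param hazardScale named per-subtype multiplier of `baseHazard`.
#' @param baseHazard exponential event rate per month for luminal A.
#' @param censorRange censoring times drawn uniformly from this interval
#'   (months).
#' @param seed integer; every random draw flows from it.
#' @return a `SyntheticConfig` list.
#' @export
syntheticConfig <- function(
    nPerSubtype = c(LumA = 30L, LumB = 30L, HER2E = 30L, Basal = 30L,
                    ClaudinLow = 30L, NormalLike = 30L),
    moduleSizes = setNames(rep(10L, length(MODULES)), MODULES),
    nNullGenes = 900L,
    effectSize = 2.0,
    noiseSd = 0.5,
    contaminationFraction = 0.10,
    pcrProb = c(LumA = 0.05, LumB = 0.15, HER2E = 0.35, Basal = 0.733,
                ClaudinLow = 0.389, NormalLike = 0.05),
    hazardScale = c(LumA = 1, LumB = 2.5, HER2E = 2.5, Basal = 2.5,
                    ClaudinLow = 2.83, NormalLike = 1.2),
    baseHazard = 0.004,
    censorRange = c(12, 120),
    seed = 1L) {
  stopifnot(all(SUBTYPES %in% names(nPerSubtype)),
            all(MODULES %in% names(moduleSizes)),
            all(moduleSizes >= 1), nNullGenes >= 0,
            effectSize >= 0, noiseSd > 0,
            contaminationFraction >= 0, contaminationFraction <= 1,
            all(pcrProb >= 0 & pcrProb <= 1),
            all(hazardScale > 0), baseHazard > 0,
            length(censorRange) == 2, censorRange[1] > 0,
            censorRange[2] > censorRange[1])
  cfg <- list(nPerSubtype = nPerSubtype[SUBTYPES],
              moduleSizes = moduleSizes[MODULES],
              nNullGenes = as.integer(nNullGenes),
              effectSize = effectSize, noiseSd = noiseSd,
              contaminationFraction = contaminationFraction,
              pcrProb = pcrProb[SUBTYPES],
              hazardScale = hazardScale[SUBTYPES],
              baseHazard = baseHazard, censorRange = censorRange,
              seed = as.integer(seed))
  class(cfg) <- "SyntheticConfig"
  cfg
}

# Gene universe: module genes (with marker aliases), ERBB2, null genes.
.geneUniverse <- function(cfg) {
  moduleGenes <- lapply(MODULES, function(m) {
    k <- cfg$moduleSizes[[m]]
    al <- .moduleAliases[[m]]
    ids <- c(al[seq_len(min(k, length(al)))],
             if (k > length(al))
               sprintf("%s_%03d", toupper(m), seq_len(k - length(al))))
    ids[seq_len(k)]
  })
  names(moduleGenes) <- MODULES
  nulls <- if (cfg$nNullGenes)
    sprintf("NULL_%04d", seq_len(cfg$nNullGenes)) else character()
  list(modules = moduleGenes, erbb2 = "ERBB2", nulls = nulls,
       all = c(unlist(moduleGenes, use.names = FALSE), "ERBB2", nulls))
}

# Per-gene mean vector for one subtype (log2 units).
.subtypeMeanVector <- function(cfg, uni, subtype) {
  sh <- .moduleShiftTable()
  mu <- setNames(numeric(length(uni$all)), uni$all)
  for (m in MODULES)
    mu[uni$modules[[m]]] <- sh[m, subtype] * cfg$effectSize
  if (subtype == "HER2E") mu["ERBB2"] <- cfg$effectSize
  mu
}

# Normal immune/stromal contamination profile (log2 units).
.contaminationProfile <- function(cfg, uni) {
  p <- setNames(numeric(length(uni$all)), uni$all)
  p[uni$modules$immune] <- cfg$effectSize
  p[uni$modules$stromal] <- cfg$effectSize
  p
}

.drawExpression <- function(cfg, uni, subtypes, prefix,
                            contamination = 0) {
  n <- length(subtypes)
  mu <- vapply(subtypes, function(s) .subtypeMeanVector(cfg, uni, s),
               numeric(length(uni$all)))
  x <- mu + matrix(rnorm(length(uni$all) * n, sd = cfg$noiseSd),
                   length(uni$all), n)
  if (contamination > 0) {
    prof <- .contaminationProfile(cfg, uni)
    x <- (1 - contamination) * x + contamination * prof
  }
  rownames(x) <- uni$all
  colnames(x) <- sprintf("%s_%03d", prefix, seq_len(n))
  x
}

.drawClinical <- function(cfg, subtypes, sampleIds, cohort) {
  n <- length(subtypes)
  # receptor positivity probabilities by subtype
  pER <- c(LumA = 0.95, LumB = 0.90, HER2E = 0.30, Basal = 0.10,
           ClaudinLow = 0.20, NormalLike = 0.60)[subtypes]
  pPR <- c(LumA = 0.85, LumB = 0.70, HER2E = 0.25, Basal = 0.10,
           ClaudinLow = 0.15, NormalLike = 0.50)[subtypes]
  pH2 <- c(LumA = 0.10, LumB = 0.20, HER2E = 0.95, Basal = 0.05,
           ClaudinLow = 0.10, NormalLike = 0.10)[subtypes]
  er <- rbinom(n, 1, pER)
  pr <- rbinom(n, 1, pPR)
  her2 <- rbinom(n, 1, pH2)
  pcr <- rbinom(n, 1, cfg$pcrProb[subtypes])
  rate <- cfg$baseHazard * cfg$hazardScale[subtypes]
  rfsT <- rexp(n, rate)
  osT <- rexp(n, rate * 0.6)
  cens <- runif(n, cfg$censorRange[1], cfg$censorRange[2])
  censOS <- runif(n, cfg$censorRange[1], cfg$censorRange[2])
  data.frame(
    sample_id = sampleIds,
    true_subtype = subtypes,
    er = er, pr = pr, her2 = her2, pcr = pcr,
    rfs_time = pmin(rfsT, cens), rfs_event = as.integer(rfsT <= cens),
    os_time = pmin(osT, censOS), os_event = as.integer(osT <= censOS),
    cohort = cohort,
    stringsAsFactors = FALSE)
}

.asSE <- function(x, clinical, cfg, uni) {
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = x),
    colData = S4Vectors::DataFrame(clinical, row.names = clinical$sample_id),
    metadata = list(config = cfg, moduleGenes = uni$modules))
}

#' Generate a synthetic bulk tumor cohort
#'
#' Draws a gene-by-sample log2 expression matrix with subtype-specific
#' module shifts, immune/stromal contamination, and a clinical table
#' (receptors, pCR, relapse-free and overall survival).
#'
#' @param cfg a [syntheticConfig()].
#' @param cohort cohort label written into the clinical table.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `exprs`, clinical `colData` (including `true_subtype`), and
#'   `metadata(x)$moduleGenes` naming the genes of each module.
#' @examples
#' se <- generateTumorCohort(syntheticConfig(seed = 7))
#' table(SummarizedExperiment::colData(se)$true_subtype)
#' @export
generateTumorCohort <- function(cfg = syntheticConfig(), cohort = "SYN") {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  if (any(cfg$nPerSubtype < 1))
    stop("every requested subtype needs >= 1 sample")
  set.seed(cfg$seed)
  uni <- .geneUniverse(cfg)
  subtypes <- rep(SUBTYPES, cfg$nPerSubtype)
  x <- .drawExpression(cfg, uni, subtypes, paste0(cohort, "_T"),
                       contamination = cfg$contaminationFraction)
  clinical <- .drawClinical(cfg, subtypes, colnames(x), cohort)
  .asSE(x, clinical, cfg, uni)
}

#' Generate a synthetic breast cancer cell-line panel
#'
#' Same module structure as tumors but with contamination forced to zero
#' (cultures contain no normal epithelial or stromal admixture) and no
#' normal breast-like class. The default panel holds 52 lines including
#' nine claudin-low lines.
#'
#' @param cfg a [syntheticConfig()]; its `nPerSubtype` is ignored in favor
#'   of `nPerLine` unless the latter is NULL.
#' @param nPerLine named integer vector over the five cell-line subtypes.
#' @return SummarizedExperiment with assay `exprs` and `colData` column
#'   `true_subtype`.
#' @export
generateCellLinePanel <- function(cfg = syntheticConfig(),
                                  nPerLine = c(LumA = 10L, LumB = 10L,
                                               HER2E = 10L, Basal = 13L,
                                               ClaudinLow = 9L)) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  if (any(nPerLine < 1)) stop("every requested subtype needs >= 1 line")
  if ("NormalLike" %in% names(nPerLine))
    stop("cell-line panels contain no normal breast-like class")
  set.seed(cfg$seed)
  uni <- .geneUniverse(cfg)
  subtypes <- rep(names(nPerLine), nPerLine)
  x <- .drawExpression(cfg, uni, subtypes, "CELL", contamination = 0)
  cd <- data.frame(sample_id = colnames(x), true_subtype = subtypes,
                   stringsAsFactors = FALSE)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = x),
    colData = S4Vectors::DataFrame(cd, row.names = cd$sample_id),
    metadata = list(config = cfg, moduleGenes = uni$modules))
}

#' Generate sorted mammary epithelial populations
#'
#' Mammary stem cell (MaSC), luminal progenitor (pL) and mature luminal
#' (mL) populations with luminal-module means ordered MaSC < pL < mL and
#' stem/EMT modules ordered MaSC > pL > mL; an optional stromal population
#' can be added.
#'
#' @param cfg a [syntheticConfig()].
#' @param nPerPopulation samples per population (>= 3).
#' @param includeStromal add a stromal population.
#' @return SummarizedExperiment with `colData` column `population`.
#' @export
generateSortedPopulations <- function(cfg = syntheticConfig(),
                                      nPerPopulation = 20L,
                                      includeStromal = FALSE) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  if (nPerPopulation < 3) stop("need >= 3 samples per population")
  set.seed(cfg$seed)
  uni <- .geneUniverse(cfg)
  e <- cfg$effectSize
  shift <- list(
    MaSC = c(luminal = -e, stem = e, emt = e),
    pL = c(luminal = 0, stem = 0, emt = 0),
    mL = c(luminal = e, stem = -e, emt = -e))
  if (includeStromal)
    shift$stromal <- c(luminal = -e, stem = 0.5 * e, emt = 0.5 * e,
                       stromal = e, immune = 0.5 * e)
  pops <- rep(names(shift), each = nPerPopulation)
  mu <- matrix(0, length(uni$all), length(pops),
               dimnames = list(uni$all, NULL))
  for (i in seq_along(pops)) {
    sh <- shift[[pops[i]]]
    for (m in names(sh)) mu[uni$modules[[m]], i] <- sh[[m]]
  }
  x <- mu + matrix(rnorm(length(mu), sd = cfg$noiseSd), nrow(mu), ncol(mu))
  colnames(x) <- sprintf("POP_%s_%02d", pops,
                         sequence(rep(nPerPopulation, length(shift))))
  cd <- data.frame(sample_id = colnames(x), population = pops,
                   stringsAsFactors = FALSE)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = x),
    colData = S4Vectors::DataFrame(cd, row.names = cd$sample_id),
    metadata = list(config = cfg, moduleGenes = uni$modules))
}

#' Module gene sets of a synthetic object
#'
#' @param se a SummarizedExperiment produced by one of the generators.
#' @return named list of gene-id vectors, one per module.
#' @export
moduleGeneSets <- function(se) {
  mg <- S4Vectors::metadata(se)$moduleGenes
  if (is.null(mg)) stop("object carries no moduleGenes metadata")
  mg
}
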