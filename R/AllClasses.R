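#' @import methods
#' @importFrom stats median mad quantile sd var cor optim rexp runif rnorm
#'   rbinom setNames aov t.test chisq.test fisher.test pchisq anova
#'   p.adjust
#' @importFrom utils read.delim write.table count.fields
NULL

#' Nearest-centroid predictor model
#'
#' Holds the gene list, class names, per-class centroid vectors and the
#' distance/correlation metric of a centroid predictor, e.g. the
#' claudin-low vs. others Euclidean predictor or a multi-class
#' Spearman-correlation subtype predictor.
#'
#' @slot genes character vector of gene identifiers (rows of `centroids`).
#' @slot classNames character vector of class labels (columns of `centroids`).
#' @slot centroids numeric matrix, genes x classes.
#' @slot metric `"euclidean"` or `"spearman"`.
#' @slot provenance free-text note on how the model was trained.
#'
#' @examples
#' m <- matrix(rnorm(40), 10, 4,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' mod <- buildCentroidModel(m, labels = c("a", "a", "b", "b"))
#' mod
#' @export
setClass("CentroidModel",
  representation(
    genes = "character",
    classNames = "character",
    centroids = "matrix",
    metric = "character",
    provenance = "character"
  )
)

setValidity("CentroidModel", function(object) {
  msg <- character()
  if (nrow(object@centroids) != length(object@genes))
    msg <- c(msg, "centroid rows must match gene list length")
  if (ncol(object@centroids) != length(object@classNames))
    msg <- c(msg, "centroid columns must match class name list length")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "duplicate gene identifiers")
  if (anyDuplicated(object@classNames))
    msg <- c(msg, "duplicate class names")
  if (!object@metric %in% c("euclidean", "spearman"))
    msg <- c(msg, "metric must be 'euclidean' or 'spearman'")
  if (length(msg)) msg else TRUE
})

#' Two-class SAM result
#'
#' Per-gene modified t statistics, the fudge factor s0, the chosen
#' threshold delta, the permutation FDR table and the selected up/down
#' gene lists.
#'
#' @slot d numeric per-gene modified t statistic.
#' @slot s numeric per-gene standard error.
#' @slot s0 numeric fudge factor added to the denominator.
#' @slot delta numeric selection threshold actually used (NA when no
#'   threshold met the FDR target).
#' @slot fdrTable data.frame with columns `delta`, `n_selected`,
#'   `median_false`, `fdr` (monotone non-increasing in `delta`).
#' @slot upGenes,downGenes character vectors of selected genes by sign of d.
#' @slot nPermutations integer number of label permutations used.
#' @slot seed integer seed the permutations were drawn from.
#' @export
setClass("SamResult",
  representation(
    d = "numeric",
    s = "numeric",
    s0 = "numeric",
    delta = "numeric",
    fdrTable = "data.frame",
    upGenes = "character",
    downGenes = "character",
    nPermutations = "integer",
    seed = "integer"
  )
)

setValidity("SamResult", function(object) {
  msg <- character()
  if (length(object@d) != length(object@s))
    msg <- c(msg, "d and s must have equal length")
  if (length(object@s0) != 1L || object@s0 < 0)
    msg <- c(msg, "s0 must be a single non-negative number")
  if (length(intersect(object@upGenes, object@downGenes)))
    msg <- c(msg, "up and down gene lists must be disjoint")
  if (nrow(object@fdrTable) &&
      (any(object@fdrTable$fdr < 0) || any(object@fdrTable$fdr > 1)))
    msg <- c(msg, "FDR values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Mammary differentiation model
#'
#' DWD-derived axis model for the MaSC -> pL -> mL differentiation
#' hierarchy: the luminal-progenitor (pL) centroid used as origin and the
#' unit-norm MaSC-ward and mature-luminal-ward direction vectors.
#'
#' @slot genes character gene identifiers.
#' @slot plCentroid numeric per-gene mean of the pL training population
#'   (the origin of the axis).
#' @slot mascVector,mlVector numeric unit vectors (sum of squares 1)
#'   pointing from pL toward MaSC and toward mL respectively.
#' @slot trainingMedians numeric per-gene medians of the pooled training
#'   populations, kept for cross-platform alignment.
#' @export
setClass("DifferentiationModel",
  representation(
    genes = "character",
    plCentroid = "numeric",
    mascVector = "numeric",
    mlVector = "numeric",
    trainingMedians = "numeric"
  )
)

setValidity("DifferentiationModel", function(object) {
  msg <- character()
  p <- length(object@genes)
  if (length(object@plCentroid) != p || length(object@mascVector) != p ||
      length(object@mlVector) != p || length(object@trainingMedians) != p)
    msg <- c(msg, "all vectors must match the gene list length")
  if (p) {
    if (abs(sum(object@mascVector^2) - 1) > 1e-6)
      msg <- c(msg, "mascVector must have sum of squares 1")
    if (abs(sum(object@mlVector^2) - 1) > 1e-6)
      msg <- c(msg, "mlVector must have sum of squares 1")
  }
  if (length(msg)) msg else TRUE
})

#' Average-linkage dendrogram with node correlations
#'
#' Wraps an agglomerative average-linkage merge tree built on
#' 1 - Pearson correlation distances. Each internal node carries a
#' node correlation (1 - merge height), the value used to hand-pick
#' gene clusters (e.g. node correlation > 0.75).
#'
#' @slot merge integer matrix as in [stats::hclust()]: negative entries
#'   are leaves, positive entries earlier merges.
#' @slot height numeric merge heights (1 - correlation scale).
#' @slot labels character leaf identifiers.
#' @export
setClass("GeneDendrogram",
  representation(
    merge = "matrix",
    height = "numeric",
    labels = "character"
  )
)

setValidity("GeneDendrogram", function(object) {
  n <- length(object@labels)
  msg <- character()
  if (nrow(object@merge) != n - 1L)
    msg <- c(msg, "n leaves require exactly n-1 internal nodes")
  if (length(object@height) != nrow(object@merge))
    msg <- c(msg, "one height per internal node required")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CentroidModel", function(object) {
  cat("CentroidModel:", length(object@genes), "genes,",
      length(object@classNames), "classes (",
      paste(object@classNames, collapse = ", "), ")\n")
  cat("  metric:", object@metric, "\n")
  if (length(object@provenance) && nzchar(object@provenance[1]))
    cat("  provenance:", object@provenance[1], "\n")
})

setMethod("show", "SamResult", function(object) {
  cat("SamResult:", length(object@d), "genes, s0 =",
      format(object@s0, digits = 4), "\n")
  cat("  delta =", format(object@delta, digits = 4), ";",
      length(object@upGenes), "up,", length(object@downGenes),
      "down genes selected\n")
  cat("  permutations:", object@nPermutations, "(seed", object@seed, ")\n")
})

setMethod("show", "DifferentiationModel", function(object) {
  cat("DifferentiationModel:", length(object@genes),
      "genes; pL origin with unit MaSC and mL axis vectors\n")
})

setMethod("show", "GeneDendrogram", function(object) {
  cat("GeneDendrogram:", length(object@labels), "leaves,",
      nrow(object@merge), "internal nodes; node correlation range [",
      format(min(nodeCorrelations(object)), digits = 3), ",",
      format(max(nodeCorrelations(object)), digits = 3), "]\n")
})

#' Accessors for model objects
#'
#' @param object a \linkS4class{CentroidModel},
#'   \linkS4class{DifferentiationModel}, \linkS4class{SamResult} or
#'   \linkS4class{GeneDendrogram}.
#' @return `modelGenes`: character vector of gene ids; `classNames`:
#'   character class labels; `centroidMatrix`: genes x classes numeric
#'   matrix; `modelMetric`: the metric string; `selectedGenes`: character
#'   vector (up then down); `nodeCorrelations`: numeric per internal node.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("modelGenes", function(object) standardGeneric("modelGenes"))
#' @rdname accessors
#' @export
setGeneric("classNames", function(object) standardGeneric("classNames"))
#' @rdname accessors
#' @export
setGeneric("centroidMatrix", function(object) standardGeneric("centroidMatrix"))
#' @rdname accessors
#' @export
setGeneric("modelMetric", function(object) standardGeneric("modelMetric"))
#' @rdname accessors
#' @export
setGeneric("selectedGenes", function(object) standardGeneric("selectedGenes"))
#' @rdname accessors
#' @export
setGeneric("nodeCorrelations", function(object) standardGeneric("nodeCorrelations"))

#' @rdname accessors
setMethod("modelGenes", "CentroidModel", function(object) object@genes)
#' @rdname accessors
setMethod("modelGenes", "DifferentiationModel", function(object) object@genes)
#' @rdname accessors
setMethod("classNames", "CentroidModel", function(object) object@classNames)
#' @rdname accessors
setMethod("centroidMatrix", "CentroidModel", function(object) object@centroids)
#' @rdname accessors
setMethod("modelMetric", "CentroidModel", function(object) object@metric)
#' @rdname accessors
setMethod("selectedGenes", "SamResult",
          function(object) c(object@upGenes, object@downGenes))
#' @rdname accessors
setMethod("nodeCorrelations", "GeneDendrogram",
          function(object) 1 - object@height)
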