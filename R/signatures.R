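# Gene-signature mean scoring, average-linkage dendrograms with node
# correlations, node-correlation cluster extraction and subtype-wise mean
# comparisons.

#' Score gene signatures by mean expression
#'
#' The score of an unsigned signature is the arithmetic mean of its genes'
#' values per sample (non-missing); a signed signature (list with `up` and
#' `down` components) scores mean(up) - mean(down).
#'
#' @param m expression matrix or SummarizedExperiment.
#' @param signatures named list; each element either a character vector of
#'   gene ids (unsigned) or a list with character elements `up` and `down`.
#' @return numeric matrix, samples x signatures.
#' @export
scoreSignatures <- function(m, signatures) {
  x <- exprsMatrix(m)
  if (is.null(names(signatures)) || any(!nzchar(names(signatures))))
    stop("signatures must be a named list")
  meanOf <- function(ids, sig) {
    ids <- unique(ids)
    hit <- intersect(ids, rownames(x))
    if (!length(hit))
      stop("signature '", sig, "' has no genes in the matrix")
    colMeans(x[hit, , drop = FALSE], na.rm = TRUE)
  }
  out <- vapply(names(signatures), function(sig) {
    s <- signatures[[sig]]
    if (is.list(s)) meanOf(s$up, sig) - meanOf(s$down, sig)
    else meanOf(s, sig)
  }, numeric(ncol(x)))
  matrix(out, nrow = ncol(x),
         dimnames = list(colnames(x), names(signatures)))
}

#' Average-linkage dendrogram on centered Pearson correlation
#'
#' Agglomerative average-linkage (UPGMA) merges on the distance
#' 1 - Pearson correlation; each internal node's "node correlation" is
#' 1 - merge height, the value used for hand-picking clusters.
#'
#' @param m expression matrix or SummarizedExperiment.
#' @param over cluster `"genes"` (rows) or `"samples"` (columns).
#' @return a \linkS4class{GeneDendrogram}.
#' @export
averageLinkageDendrogram <- function(m, over = c("genes", "samples")) {
  x <- exprsMatrix(m)
  over <- match.arg(over)
  if (over == "samples") x <- t(x)
  if (nrow(x) < 2) stop("need >= 2 items to cluster")
  s <- apply(x, 1, sd, na.rm = TRUE)
  if (any(!is.finite(s) | s == 0))
    stop("constant rows have undefined correlation: ",
         paste(utils::head(rownames(x)[!is.finite(s) | s == 0], 10),
               collapse = ", "))
  r <- cor(t(x), use = "pairwise.complete.obs")
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  new("GeneDendrogram", merge = hc$merge, height = hc$height,
      labels = rownames(x))
}

# leaf labels under internal node k (1-based merge row index)
.nodeLeaves <- function(merge, labels, k) {
  stack <- k
  leaves <- integer()
  while (length(stack)) {
    node <- stack[[1]]; stack <- stack[-1]
    for (child in merge[node, ]) {
      if (child < 0) leaves <- c(leaves, -child)
      else stack <- c(stack, child)
    }
  }
  labels[leaves]
}

#' Extract the gene cluster around an anchor by node correlation
#'
#' Returns the leaf set of the largest subtree containing `anchor` whose
#' root node correlation exceeds `minCorr`; when no node qualifies, the
#' singleton `{anchor}` is returned.
#'
#' @param dend a \linkS4class{GeneDendrogram}.
#' @param anchor leaf gene id.
#' @param minCorr node-correlation threshold (strict).
#' @return character vector of gene ids.
#' @export
extractClusterByNodeCorrelation <- function(dend, anchor, minCorr = 0.75) {
  stopifnot(is(dend, "GeneDendrogram"))
  if (!anchor %in% dend@labels) stop("anchor '", anchor, "' not a leaf")
  corr <- 1 - dend@height
  best <- character()
  for (k in seq_len(nrow(dend@merge))) {
    if (corr[k] <= minCorr) next
    leaves <- .nodeLeaves(dend@merge, dend@labels, k)
    if (anchor %in% leaves && length(leaves) > length(best)) best <- leaves
  }
  if (!length(best)) anchor else best
}

#' Compare signature or gene means across subtype groups
#'
#' Two groups: two-sided t test (unequal-variance Welch by default, pooled
#' with `varEqual = TRUE`). More groups: one-way ANOVA F test.
#'
#' @param scores numeric value per sample.
#' @param groups group label per sample.
#' @param test `"auto"` picks t for two groups, ANOVA otherwise.
#' @param varEqual pooled-variance t test instead of Welch.
#' @return list with `statistic`, `p.value`, `test`.
#' @export
compareSubtypeMeans <- function(scores, groups,
                                test = c("auto", "t", "anova"),
                                varEqual = FALSE) {
  test <- match.arg(test)
  groups <- factor(groups)
  if (length(scores) != length(groups)) stop("scores/groups length mismatch")
  k <- nlevels(droplevels(groups))
  if (k < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 samples")
  if (test == "auto") test <- if (k == 2) "t" else "anova"
  if (test == "t") {
    if (k != 2) stop("t test requires exactly 2 groups")
    tt <- t.test(scores ~ groups, var.equal = varEqual)
    list(statistic = unname(tt$statistic), p.value = tt$p.value,
         test = if (varEqual) "t(pooled)" else "t(Welch)")
  } else {
    a <- anova(aov(scores ~ groups))
    list(statistic = a[["F value"]][1], p.value = a[["Pr(>F)"]][1],
         test = "anova")
  }
}

#' Placeholder signature sets with published sizes
#'
#' Synthetic stand-in gene signatures with the gene-set sizes used in the
#' claudin-low characterization literature (e.g. mammosphere n = 58,
#' CD44+/CD24- up/down n = 357/353, stem-like up/down n = 119/279), drawn
#' from a supplied gene universe. These are placeholders for testing the
#' scoring machinery; real GMT files can be supplied instead.
#'
#' @param genes character vector, the gene universe to draw from.
#' @param seed integer seed.
#' @return named list of signatures as accepted by [scoreSignatures()].
#' @export
placeholderSignatures <- function(genes, seed = 1L) {
  sizes <- list(mammosphere = 58L,
                cd44_cd24 = c(up = 357L, down = 353L),
                stem_like = c(up = 119L, down = 279L))
  set.seed(seed)
  out <- list()
  for (nm in names(sizes)) {
    sz <- sizes[[nm]]
    if (length(sz) == 1) {
      out[[nm]] <- sample(genes, min(sz, length(genes)))
    } else {
      up <- sample(genes, min(sz["up"], length(genes)))
      down <- sample(setdiff(genes, up),
                     min(sz["down"], length(genes) - length(up)))
      out[[nm]] <- list(up = up, down = down)
    }
  }
  out
}
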