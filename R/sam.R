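# Two-class significance analysis of microarrays (SAM), unpaired and
# paired, with permutation-estimated false discovery rates.
#
# d_i = (mean_1 - mean_2) / (s_i + s0), where s_i is the pooled-variance
# standard error of the mean difference (unpaired) or the standard error of
# the within-pair differences (paired), and s0 is the exchangeability
# "fudge factor" chosen to decouple d from gene-wise variance.

.samLabels <- function(labels, n) {
  labels <- as.character(labels)
  if (length(labels) != n) stop("one label per sample required")
  lv <- unique(labels)
  if (length(lv) != 2) stop("exactly two classes required")
  labels
}

# fixed class order (sorted) so that d = mean(class1) - mean(class2) is a
# property of the labeling, not of sample order
.samClassOrder <- function(labels) sort(unique(labels))

# Numerator r and gene-wise standard error s for one labeling.
.samRS <- function(x, labels, design, pairs = NULL) {
  lv <- .samClassOrder(labels)
  if (design == "unpaired") {
    i1 <- labels == lv[1]; i2 <- labels == lv[2]
    n1 <- sum(i1); n2 <- sum(i2)
    if (n1 < 2 || n2 < 2) stop("unpaired SAM needs >= 2 samples per class")
    m1 <- rowMeans(x[, i1, drop = FALSE], na.rm = TRUE)
    m2 <- rowMeans(x[, i2, drop = FALSE], na.rm = TRUE)
    ss1 <- rowSums((x[, i1, drop = FALSE] - m1)^2, na.rm = TRUE)
    ss2 <- rowSums((x[, i2, drop = FALSE] - m2)^2, na.rm = TRUE)
    s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
    list(r = m1 - m2, s = s)
  } else {
    if (is.null(pairs)) stop("paired SAM requires a pairs vector")
    p1 <- split(which(labels == lv[1]), pairs[labels == lv[1]])
    p2 <- split(which(labels == lv[2]), pairs[labels == lv[2]])
    common <- intersect(names(p1), names(p2))
    if (!length(common)) stop("paired SAM: zero matched pairs")
    if (any(lengths(p1[common]) != 1) || any(lengths(p2[common]) != 1))
      stop("each pair id must occur once per class")
    d <- x[, unlist(p1[common]), drop = FALSE] -
      x[, unlist(p2[common]), drop = FALSE]
    k <- ncol(d)
    r <- rowMeans(d, na.rm = TRUE)
    s <- apply(d, 1, sd, na.rm = TRUE) / sqrt(k)
    s[!is.finite(s)] <- 0
    list(r = r, s = s)
  }
}

# Tusher-style automatic fudge factor: among percentiles of s, pick the s0
# minimizing the coefficient of variation of the spread of d across bins
# of s. Falls back to median(s) when degenerate.
.chooseS0 <- function(r, s) {
  cand <- unique(quantile(s, probs = seq(0, 1, by = 0.05), na.rm = TRUE))
  nbin <- min(100L, max(2L, floor(length(s) / 20)))
  bins <- cut(rank(s, ties.method = "first"), nbin, labels = FALSE)
  cvs <- vapply(cand, function(s0) {
    d <- r / (s + s0)
    v <- tapply(d, bins, mad)
    v <- v[is.finite(v)]
    if (length(v) < 2 || mean(v) == 0) return(NA_real_)
    sd(v) / mean(v)
  }, numeric(1))
  if (all(is.na(cvs))) return(median(s))
  as.numeric(cand[which.min(cvs)])
}

#' SAM modified t statistics
#'
#' @param m expression matrix or SummarizedExperiment (genes x samples).
#' @param labels two-class label per sample.
#' @param design `"unpaired"` (pooled-variance SE) or `"paired"`
#'   (within-pair differences; requires `pairs`).
#' @param s0 non-negative fudge factor, or `"auto"` to choose the
#'   percentile of the gene-wise standard errors minimizing the coefficient
#'   of variation of the spread of d across standard-error bins.
#' @param pairs pair identifier per sample (paired design only).
#' @return list with per-gene `d` and `s`, and the scalar `s0` used.
#'   Class 1 in the numerator is the alphabetically first label, so d is a
#'   property of the labeling, not of sample order. All-constant genes get
#'   d = 0 by convention.
#' @examples
#' x <- rbind(g1 = c(1, 2, 3, 4, 5, 6))
#' colnames(x) <- paste0("s", 1:6)
#' samStatistics(x, rep(c("a", "b"), each = 3), s0 = 0)$d  # -3.674
#' @export
samStatistics <- function(m, labels, design = c("unpaired", "paired"),
                          s0 = "auto", pairs = NULL) {
  x <- exprsMatrix(m)
  design <- match.arg(design)
  labels <- .samLabels(labels, ncol(x))
  rs <- .samRS(x, labels, design, pairs)
  s0v <- if (identical(s0, "auto")) .chooseS0(rs$r, rs$s) else {
    stopifnot(is.numeric(s0), s0 >= 0)
    s0
  }
  den <- rs$s + s0v
  d <- ifelse(den == 0, 0, rs$r / den)
  d[rs$r == 0] <- 0
  names(d) <- names(rs$s) <- rownames(x)
  list(d = d, s = rs$s, s0 = s0v)
}

# One balanced permutation of a two-class labeling: the permuted first
# class draws about half its members from each original class.
.balancedPermutation <- function(labels) {
  lv <- .samClassOrder(labels)
  i1 <- which(labels == lv[1]); i2 <- which(labels == lv[2])
  n1 <- length(i1); n2 <- length(i2)
  h <- round(n1 / 2)
  h <- max(h, n1 - n2)  # permuted class 1 cannot take more than n2 from class 2
  h <- min(h, n1)
  new1 <- c(sample(i1, h), sample(i2, n1 - h))
  out <- rep(lv[2], length(labels))
  out[new1] <- lv[1]
  out
}

#' SAM gene selection at a target permutation FDR
#'
#' Permutes class labels (balanced, seeded), evaluates a symmetric
#' threshold delta over a grid spanning the observed |d| range, estimates
#' FDR(delta) as the median permutation false count divided by the observed
#' count (capped at 1, monotonized to be non-increasing in delta), and
#' returns the largest gene set whose estimated FDR is at or below
#' `fdrTarget`, split by sign of d.
#'
#' @inheritParams samStatistics
#' @param fdrTarget target false discovery rate in [0, 1].
#' @param nPermutations number of balanced label permutations.
#' @param seed integer seed for the permutations.
#' @param nDelta grid resolution over the |d| range.
#' @return a \linkS4class{SamResult}. When no threshold achieves the
#'   target, the gene lists are empty and a warning is raised.
#' @export
samSelect <- function(m, labels, design = c("unpaired", "paired"),
                      fdrTarget = 0.05, nPermutations = 200L,
                      seed = 1L, s0 = "auto", pairs = NULL,
                      nDelta = 200L) {
  x <- exprsMatrix(m)
  design <- match.arg(design)
  stopifnot(fdrTarget >= 0, fdrTarget <= 1, nPermutations >= 1)
  labels <- .samLabels(labels, ncol(x))
  obs <- samStatistics(x, labels, design, s0 = s0, pairs = pairs)
  absd <- abs(obs$d)
  deltas <- seq(0, max(absd), length.out = nDelta)

  set.seed(seed)
  falseCounts <- matrix(0L, nPermutations, length(deltas))
  for (b in seq_len(nPermutations)) {
    pl <- if (design == "paired") {
      # paired design: randomly flip the sign of each pair
      flip <- unique(pairs)[as.logical(rbinom(length(unique(pairs)), 1, 0.5))]
      lab <- labels
      sw <- pairs %in% flip
      lab[sw] <- rev(unique(labels))[match(labels[sw], unique(labels))]
      lab
    } else .balancedPermutation(labels)
    rs <- .samRS(x, pl, design, pairs)
    den <- rs$s + obs$s0
    dp <- abs(ifelse(den == 0, 0, rs$r / den))
    falseCounts[b, ] <- vapply(deltas, function(dl) sum(dp >= dl), integer(1))
  }
  nSel <- vapply(deltas, function(dl) sum(absd >= dl), integer(1))
  medFalse <- apply(falseCounts, 2, median)
  fdr <- ifelse(nSel == 0, 0, pmin(1, medFalse / nSel))
  # enforce monotone non-increasing FDR in delta, conservatively: a smaller
  # delta (larger gene set) cannot claim a lower FDR than any larger delta
  fdr <- rev(cummax(rev(fdr)))
  tab <- data.frame(delta = deltas, n_selected = nSel,
                    median_false = medFalse, fdr = fdr)

  ok <- which(fdr <= fdrTarget & nSel > 0)
  if (!length(ok)) {
    warning("no delta achieves FDR target ", fdrTarget,
            "; returning empty gene lists")
    delta <- NA_real_
    up <- down <- character()
  } else {
    delta <- deltas[ok[1]]
    sel <- absd >= delta
    up <- rownames(x)[sel & obs$d > 0]
    down <- rownames(x)[sel & obs$d < 0]
  }
  new("SamResult", d = obs$d, s = obs$s, s0 = obs$s0, delta = delta,
      fdrTable = tab, upGenes = up, downGenes = down,
      nPermutations = as.integer(nPermutations), seed = as.integer(seed))
}

#' Serialize a SamResult to JSON
#'
#' @param object a \linkS4class{SamResult}.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSamResult <- function(object, path) {
  stopifnot(is(object, "SamResult"))
  jsonlite::write_json(list(
    d = as.list(object@d), s0 = object@s0, delta = object@delta,
    fdr_table = object@fdrTable,
    up_genes = object@upGenes, down_genes = object@downGenes,
    n_permutations = object@nPermutations, seed = object@seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
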