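# Expression-matrix data model, I/O and preprocessing.
#
# Matrices are plain numeric matrices, genes x samples, log2 scale, with NA
# as the explicit missing-value mask; rownames are gene identifiers and
# colnames sample identifiers. SummarizedExperiment objects carrying an
# "exprs" assay are accepted everywhere via exprsMatrix().

#' Extract a gene-by-sample expression matrix
#'
#' Accepts either a plain numeric matrix (genes in rows, samples in
#' columns) or a [SummarizedExperiment::SummarizedExperiment] whose first
#' assay holds the expression values.
#'
#' @param x matrix or SummarizedExperiment.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
exprsMatrix <- function(x) {
  if (is(x, "SummarizedExperiment"))
    x <- SummarizedExperiment::assay(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression input must be a numeric matrix or SummarizedExperiment")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(x))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(x))) stop("duplicate sample identifiers")
  x
}

#' Filter probes on intensity and collapse to gene level
#'
#' Probes are kept only when their lowest normalized intensity across all
#' arrays is above `intensityThreshold` in both the sample (Cy5) and
#' control (Cy3) channels. Surviving probes mapping to the same gene
#' identifier are averaged per sample (unweighted mean over non-missing
#' values). Probes without a gene mapping are dropped with a message.
#'
#' @param log2Ratios numeric matrix, probes x samples, log2(sample/control)
#'   ratios; rownames are probe ids.
#' @param sampleIntensity,controlIntensity numeric matrices of the same
#'   shape with the per-channel normalized intensities.
#' @param probeGeneMap data.frame with columns `probe_id`, `gene_id`; each
#'   probe maps to at most one gene. Probes absent from the map (or with
#'   NA/empty gene) are dropped.
#' @param intensityThreshold positive scalar; probes whose minimum
#'   intensity in either channel is <= this value are removed.
#' @return numeric matrix, genes x samples.
#' @examples
#' r <- matrix(c(1, 3), 2, 1, dimnames = list(c("p1", "p2"), "s1"))
#' si <- matrix(50, 2, 1, dimnames = dimnames(r))
#' map <- data.frame(probe_id = c("p1", "p2"), gene_id = c("g1", "g1"))
#' preprocessProbeTable(r, si, si, map, 10)  # g1 = mean(1, 3) = 2
#' @export
preprocessProbeTable <- function(log2Ratios, sampleIntensity,
                                 controlIntensity, probeGeneMap,
                                 intensityThreshold = 10) {
  stopifnot(is.matrix(log2Ratios),
            identical(dim(log2Ratios), dim(sampleIntensity)),
            identical(dim(log2Ratios), dim(controlIntensity)))
  if (!is.numeric(intensityThreshold) || intensityThreshold <= 0)
    stop("intensityThreshold must be > 0")
  if (any(sampleIntensity < 0, na.rm = TRUE) ||
      any(controlIntensity < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  probes <- rownames(log2Ratios)
  if (is.null(probes)) stop("log2Ratios must have probe rownames")
  if (anyDuplicated(probeGeneMap$probe_id))
    stop("a probe maps to more than one gene")

  gene <- probeGeneMap$gene_id[match(probes, probeGeneMap$probe_id)]
  gene[!is.na(gene) & !nzchar(gene)] <- NA
  nUnmapped <- sum(is.na(gene))
  if (nUnmapped)
    message(nUnmapped, " probe(s) without gene mapping dropped")

  minS <- apply(sampleIntensity, 1, min, na.rm = TRUE)
  minC <- apply(controlIntensity, 1, min, na.rm = TRUE)
  keep <- !is.na(gene) & minS > intensityThreshold & minC > intensityThreshold
  if (!any(keep))
    stop("no probes survive the intensity filter at threshold ",
         intensityThreshold)

  r <- log2Ratios[keep, , drop = FALSE]
  g <- gene[keep]
  out <- rowsum(ifelse(is.na(r), 0, r), g, na.rm = FALSE)
  cnt <- rowsum((!is.na(r)) * 1, g)
  out <- out / ifelse(cnt == 0, NA, cnt)
  out <- as.matrix(out)
  colnames(out) <- colnames(log2Ratios)
  allMissing <- rowSums(!is.na(out)) == 0
  out[!allMissing, , drop = FALSE]
}

#' Median-center genes and standardize samples
#'
#' The standard two-step normalization applied to every data set before
#' analysis: each gene row is median-centered (median over non-missing
#' values) and each sample column is then standardized to zero mean and
#' unit variance. Gene rows that are entirely missing are dropped.
#'
#' @param m expression matrix or SummarizedExperiment.
#' @param centerGenes logical, median-center gene rows.
#' @param standardizeSamples logical, scale columns to mean 0, variance 1.
#' @return normalized numeric matrix.
#' @export
normalizeExpression <- function(m, centerGenes = TRUE,
                                standardizeSamples = TRUE) {
  x <- exprsMatrix(m)
  allMissing <- rowSums(!is.na(x)) == 0
  if (any(allMissing)) {
    message(sum(allMissing), " all-missing gene row(s) dropped")
    x <- x[!allMissing, , drop = FALSE]
  }
  if (centerGenes) {
    med <- apply(x, 1, median, na.rm = TRUE)
    x <- x - med
  }
  if (standardizeSamples) {
    if (ncol(x) < 2)
      stop("standardization requires at least 2 samples")
    mu <- colMeans(x, na.rm = TRUE)
    x <- sweep(x, 2, mu)
    s <- apply(x, 2, sd, na.rm = TRUE)
    bad <- !is.finite(s) | s == 0
    if (any(bad))
      stop("zero-variance sample column(s): ",
           paste(colnames(x)[bad], collapse = ", "))
    x <- sweep(x, 2, s, "/")
  }
  x
}

#' Read and write expression matrices as TSV
#'
#' Tab-delimited UTF-8 text with a `gene_id` first column and sample ids in
#' the header; empty cells are missing values. A write -> read roundtrip is
#' value-identical including the missing mask.
#'
#' @param path file path.
#' @param m matrix (or SummarizedExperiment) to write.
#' @return `readExpressionMatrix` returns the numeric matrix;
#'   `writeExpressionMatrix` returns `path` invisibly.
#' @export
readExpressionMatrix <- function(path) {
  nf <- count.fields(path, sep = "\t", quote = "", blank.lines.skip = FALSE)
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop("ragged TSV: line ", bad, " has ", nf[bad],
         " fields, expected ", nf[1])
  }
  df <- read.delim(path, check.names = FALSE, na.strings = "",
                   colClasses = NA, quote = "")
  if (ncol(df) < 2) stop("expression TSV needs gene_id plus >=1 sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate gene rows: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  x <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- ids
  x
}

#' @rdname readExpressionMatrix
#' @export
writeExpressionMatrix <- function(m, path) {
  x <- exprsMatrix(m)
  df <- data.frame(gene_id = rownames(x),
                   format(x, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[-1][is.na(x)] <- ""
  colnames(df) <- c("gene_id", colnames(x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write GMT gene-set files
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>...`.
#' Duplicate gene ids within a set are removed with a warning.
#'
#' @param path file path.
#' @param sets named list of character gene-id vectors.
#' @param descriptions optional character vector parallel to `sets`.
#' @return `readGMT` returns a named list of unique gene-id vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line with fewer than 3 fields: ", f[1])
    ids <- f[-(1:2)]
    ids <- ids[nzchar(ids)]
    if (anyDuplicated(ids)) {
      warning("duplicate gene ids in set '", f[1], "' deduplicated")
      ids <- unique(ids)
    }
    out[[f[1]]] <- ids
  }
  out
}

#' @rdname readGMT
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], unique(sets[[i]])),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
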