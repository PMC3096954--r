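# Centroid predictors: Euclidean claudin-low / normal-breast two-class
# predictors, Spearman correlation-to-centroid multi-class machinery, the
# combined subtype-call override rule, and binary predictor evaluation.

#' Build a nearest-centroid model
#'
#' Each class centroid is the per-gene arithmetic mean (over non-missing
#' values) of its training samples, restricted to `genes`.
#'
#' @param m expression matrix or SummarizedExperiment.
#' @param labels class label per sample (>= 1 sample per class).
#' @param genes gene ids to use; defaults to all rows of `m`.
#' @param metric `"euclidean"` (nearest distance wins) or `"spearman"`
#'   (highest rank correlation wins).
#' @param provenance free-text training note.
#' @return a \linkS4class{CentroidModel}.
#' @export
buildCentroidModel <- function(m, labels, genes = NULL,
                               metric = c("euclidean", "spearman"),
                               provenance = "") {
  x <- exprsMatrix(m)
  metric <- match.arg(metric)
  labels <- as.character(labels)
  if (length(labels) != ncol(x)) stop("one label per sample required")
  if (is.null(genes)) genes <- rownames(x)
  missing <- setdiff(genes, rownames(x))
  if (length(missing))
    stop("genes absent from the matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  cls <- unique(labels)
  if (any(table(labels) < 1) || length(cls) < 2)
    stop("every class needs >= 1 training sample and >= 2 classes")
  xg <- x[genes, , drop = FALSE]
  cent <- vapply(cls, function(cl)
    rowMeans(xg[, labels == cl, drop = FALSE], na.rm = TRUE),
    numeric(length(genes)))
  cent <- matrix(cent, nrow = length(genes),
                 dimnames = list(genes, cls))
  new("CentroidModel", genes = genes, classNames = cls, centroids = cent,
      metric = metric, provenance = provenance)
}

# class receiving ties: "others" when present, else the last class
# (conservative: the positive finding should not be inflated by ties).
.tieClass <- function(model) {
  if ("others" %in% model@classNames) "others"
  else model@classNames[length(model@classNames)]
}

#' Classify samples by nearest centroid
#'
#' Euclidean metric: distance to each centroid over the genes shared by
#' model and matrix; per-sample missing entries are skipped and the
#' distance rescaled by sqrt(n_model_genes / n_used) to stay comparable
#' across missingness patterns. Spearman metric: rank correlation to each
#' centroid, highest wins. Exact ties go to the "others" (or last) class.
#'
#' @param model a \linkS4class{CentroidModel}.
#' @param m expression matrix or SummarizedExperiment.
#' @param minGeneFraction minimum fraction of model genes that must be
#'   present in the matrix.
#' @return data.frame with `sample_id`, `call`, one statistic column per
#'   class (`dist.<class>` or `cor.<class>`), and `margin` (runner-up gap,
#'   positive).
#' @export
classifyNearestCentroid <- function(model, m, minGeneFraction = 0.5) {
  stopifnot(is(model, "CentroidModel"))
  x <- exprsMatrix(m)
  shared <- intersect(model@genes, rownames(x))
  if (length(shared) < minGeneFraction * length(model@genes))
    stop("only ", length(shared), "/", length(model@genes),
         " model genes present; missing: ",
         paste(utils::head(setdiff(model@genes, rownames(x)), 10),
               collapse = ", "))
  cent <- model@centroids[shared, , drop = FALSE]
  xs <- x[shared, , drop = FALSE]
  nModel <- length(model@genes)
  tieCl <- .tieClass(model)
  k <- ncol(cent)

  stat <- matrix(NA_real_, ncol(xs), k,
                 dimnames = list(colnames(xs), colnames(cent)))
  for (j in seq_len(ncol(xs))) {
    v <- xs[, j]
    for (c in seq_len(k)) {
      use <- !is.na(v) & !is.na(cent[, c])
      if (!any(use)) next
      if (model@metric == "euclidean") {
        stat[j, c] <- sqrt(sum((v[use] - cent[use, c])^2) *
                             nModel / sum(use))
      } else {
        stat[j, c] <- suppressWarnings(
          cor(v[use], cent[use, c], method = "spearman"))
      }
    }
  }
  better <- if (model@metric == "euclidean") function(a, b) a < b
            else function(a, b) a > b
  call <- character(nrow(stat))
  margin <- numeric(nrow(stat))
  for (j in seq_len(nrow(stat))) {
    s <- stat[j, ]
    best <- if (model@metric == "euclidean") min(s, na.rm = TRUE)
            else max(s, na.rm = TRUE)
    winners <- colnames(stat)[which(s == best)]
    call[j] <- if (length(winners) > 1 && tieCl %in% winners) tieCl
               else winners[1]
    margin[j] <- abs(diff(sort(if (model@metric == "euclidean") s else -s,
                               na.last = NA)[1:2]))
    if (!is.finite(margin[j])) margin[j] <- 0
  }
  out <- data.frame(sample_id = colnames(xs), call = call,
                    stat, margin = margin,
                    check.names = FALSE, stringsAsFactors = FALSE)
  pfx <- if (model@metric == "euclidean") "dist." else "cor."
  colnames(out)[2 + seq_len(k)] <- paste0(pfx, colnames(cent))
  rownames(out) <- NULL
  out
}

#' Combine primary subtype calls with the claudin-low predictor
#'
#' Samples positive for the claudin-low predictor are called claudin-low
#' regardless of the primary (PAM50-style) call; all other samples keep
#' their primary call.
#'
#' @param primaryCalls data.frame from [classifyNearestCentroid()] (or any
#'   data.frame with `sample_id` and `call`).
#' @param claudinLowCalls same, from the two-class claudin-low predictor.
#' @param positiveClass label counting as a positive claudin-low call.
#' @return named character vector of final labels per sample.
#' @export
combineSubtypeCalls <- function(primaryCalls, claudinLowCalls,
                                positiveClass = "claudin-low") {
  if (!setequal(primaryCalls$sample_id, claudinLowCalls$sample_id))
    stop("primary and claudin-low calls cover different samples")
  cl <- claudinLowCalls$call[match(primaryCalls$sample_id,
                                   claudinLowCalls$sample_id)]
  out <- ifelse(cl == positiveClass, positiveClass, primaryCalls$call)
  names(out) <- primaryCalls$sample_id
  out
}

#' Evaluate a binary predictor against a gold standard
#'
#' @param predicted logical (or 0/1) predicted positivity per sample.
#' @param gold logical gold-standard positivity, same samples.
#' @return list with confusion counts (`tp`, `fp`, `fn`, `tn`) and
#'   `sensitivity`, `specificity`, `ppv`, `npv` as percentages rounded to
#'   one decimal; a metric with zero denominator is `NA`.
#' @examples
#' # 337 samples, 32 gold positives, 37 predicted, 28 overlapping:
#' p <- rep(c(TRUE, TRUE, FALSE, FALSE), c(28, 9, 4, 296))
#' g <- rep(c(TRUE, FALSE, TRUE, FALSE), c(28, 9, 4, 296))
#' unlist(evaluateBinaryPredictor(p, g)[c("sensitivity", "specificity",
#'                                        "ppv", "npv")])
#' @export
evaluateBinaryPredictor <- function(predicted, gold) {
  predicted <- as.logical(predicted)
  gold <- as.logical(gold)
  if (length(predicted) != length(gold))
    stop("predicted and gold must cover the same samples")
  if (anyNA(predicted) || anyNA(gold)) stop("labels must be binary, no NA")
  tp <- sum(predicted & gold); fp <- sum(predicted & !gold)
  fn <- sum(!predicted & gold); tn <- sum(!predicted & !gold)
  pct <- function(num, den) if (den == 0) NA_real_
                            else round(100 * num / den, 1)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       sensitivity = pct(tp, tp + fn),
       specificity = pct(tn, tn + fp),
       ppv = pct(tp, tp + fp),
       npv = pct(tn, tn + fn))
}

#' Read and write centroid models as JSON
#'
#' @param model a \linkS4class{CentroidModel}.
#' @param path file path.
#' @return `readCentroidModel` returns the model; the writer returns
#'   `path` invisibly.
#' @export
writeCentroidModel <- function(model, path) {
  stopifnot(is(model, "CentroidModel"))
  jsonlite::write_json(list(
    genes = model@genes, class_names = model@classNames,
    centroids = model@centroids, metric = model@metric,
    provenance = model@provenance), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCentroidModel
#' @export
readCentroidModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cent <- j$centroids
  if (!is.matrix(cent))
    cent <- matrix(as.numeric(unlist(cent)), nrow = length(j$genes),
                   byrow = TRUE)
  dimnames(cent) <- list(j$genes, j$class_names)
  new("CentroidModel", genes = j$genes, classNames = j$class_names,
      centroids = cent, metric = j$metric,
      provenance = if (is.null(j$provenance)) "" else j$provenance)
}
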