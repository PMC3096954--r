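# Distance-weighted discrimination (DWD).
#
# DWD finds the separating hyperplane minimizing the sum of inverse
# distances of samples to the plane, which keeps all samples in play in
# high-dimension low-sample-size settings where SVM margins degenerate
# (data piling). We solve the equivalent smooth convex loss formulation
# (generalized DWD with exponent q = 1):
#
#   min_{w, b}  (1/n) sum_i V(y_i (w'x_i + b)) + (lambda/2) ||w||^2
#   V(u) = 1 - u            for u <= 1/2
#        = 1 / (4u)         for u  > 1/2
#
# V is convex and continuously differentiable, so the problem is solved
# with L-BFGS-B using the analytic gradient. The direction is w / ||w||.

.dwdLoss <- function(u) ifelse(u <= 0.5, 1 - u, 1 / (4 * u))
.dwdGrad <- function(u) ifelse(u <= 0.5, -1, -1 / (4 * u^2))

#' DWD solver configuration
#'
#' @param penalty DWD penalty C; default `NULL` computes
#'   100 / median(pairwise distance)^2 from the training data. The ridge
#'   weight of the smooth formulation is lambda = 1 / (n * C).
#' @param tol solver convergence tolerance (factr-style relative).
#' @param maxit maximum L-BFGS-B iterations.
#' @param meanDifference use the per-gene mean-difference direction instead
#'   of solving DWD (diagnostic fallback; not the default path).
#' @return a `DwdConfig` list.
#' @export
dwdConfig <- function(penalty = NULL, tol = 1e-10, maxit = 2000L,
                      meanDifference = FALSE) {
  if (!is.null(penalty) && penalty <= 0) stop("penalty must be > 0")
  structure(list(penalty = penalty, tol = tol, maxit = as.integer(maxit),
                 meanDifference = meanDifference), class = "DwdConfig")
}

#' DWD separating direction between two classes
#'
#' Returns the unit-norm normal vector of the DWD hyperplane, oriented from
#' `classA` toward `classB` (samples of `classB` project positively).
#'
#' @param classA,classB expression matrices (genes x samples) or
#'   SummarizedExperiments on a common gene space.
#' @param cfg a [dwdConfig()].
#' @return unit-norm numeric vector named by gene.
#' @examples
#' a <- matrix(c(0, 0), 2, 1, dimnames = list(c("g1", "g2"), "a1"))
#' b <- matrix(c(4, 0), 2, 1, dimnames = list(c("g1", "g2"), "b1"))
#' dwdDirection(a, b)  # (1, 0)
#' @export
dwdDirection <- function(classA, classB, cfg = dwdConfig()) {
  xa <- exprsMatrix(classA); xb <- exprsMatrix(classB)
  common <- intersect(rownames(xa), rownames(xb))
  if (!length(common)) stop("classes share no genes")
  xa <- xa[common, , drop = FALSE]; xb <- xb[common, , drop = FALSE]
  if (anyNA(xa) || anyNA(xb))
    stop("DWD requires complete (non-missing) training matrices")
  X <- t(cbind(xa, xb))                     # n x p
  y <- c(rep(-1, ncol(xa)), rep(1, ncol(xb)))
  n <- nrow(X); p <- ncol(X)

  md <- colMeans(X[y > 0, , drop = FALSE]) -
    colMeans(X[y < 0, , drop = FALSE])
  if (sqrt(sum(md^2)) == 0)
    stop("class means coincide; no direction defined")
  if (isTRUE(cfg$meanDifference)) {
    w <- md / sqrt(sum(md^2))
    names(w) <- common
    return(w)
  }

  C <- cfg$penalty
  if (is.null(C)) {
    dd <- as.matrix(stats::dist(X))
    medd <- median(dd[upper.tri(dd)])
    if (!is.finite(medd) || medd == 0) medd <- 1
    C <- 100 / medd^2
  }
  lambda <- 1 / (n * C)

  obj <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1]
    u <- y * (X %*% w + b)
    mean(.dwdLoss(u)) + lambda / 2 * sum(w^2)
  }
  grd <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1]
    u <- as.numeric(y * (X %*% w + b))
    g <- .dwdGrad(u) * y / n
    c(as.numeric(crossprod(X, g)) + lambda * w, sum(g))
  }
  w0 <- 2 * md / sum(md^2)
  b0 <- -sum(w0 * (colMeans(X[y > 0, , drop = FALSE]) +
                     colMeans(X[y < 0, , drop = FALSE])) / 2)
  fit <- optim(c(w0, b0), obj, grd, method = "L-BFGS-B",
               control = list(maxit = cfg$maxit,
                              factr = cfg$tol / .Machine$double.eps))
  if (fit$convergence != 0)
    stop("DWD solver failed to converge (code ", fit$convergence, "): ",
         fit$message, "; objective ", format(fit$value, digits = 6))
  w <- fit$par[seq_len(p)]
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop("DWD returned a zero direction")
  w <- w / nw
  if (sum(w * md) < 0) w <- -w  # orient from classA toward classB
  names(w) <- common
  w
}

#' Fit the mammary differentiation model
#'
#' Computes the pL (luminal progenitor) centroid as origin and the DWD
#' directions MaSC-vs-pL and pL-vs-mL, each unit-normalized (sum of
#' squares 1) and oriented from pL toward MaSC and toward mL respectively.
#'
#' @param masc,pl,ml expression matrices (or SummarizedExperiments) of the
#'   mammary stem cell, luminal progenitor and mature luminal populations
#'   on a common gene space.
#' @param cfg a [dwdConfig()].
#' @return a \linkS4class{DifferentiationModel}.
#' @export
fitDifferentiationModel <- function(masc, pl, ml, cfg = dwdConfig()) {
  xm <- exprsMatrix(masc); xp <- exprsMatrix(pl); xl <- exprsMatrix(ml)
  if (!ncol(xm) || !ncol(xp) || !ncol(xl))
    stop("every population needs >= 1 sample")
  common <- Reduce(intersect, list(rownames(xm), rownames(xp), rownames(xl)))
  if (!length(common)) stop("populations share no genes")
  xm <- xm[common, , drop = FALSE]
  xp <- xp[common, , drop = FALSE]
  xl <- xl[common, , drop = FALSE]

  # gene medians over the pooled training populations; the pL origin is
  # stored in this median-centered space so that it aligns with
  # median-centered test sets (the platform-bias correction)
  med <- apply(cbind(xm, xp, xl), 1, median, na.rm = TRUE)
  xm <- xm - med; xp <- xp - med; xl <- xl - med
  plCent <- rowMeans(xp, na.rm = TRUE)
  vMasc <- dwdDirection(xp, xm, cfg)   # pL -> MaSC
  vMl <- dwdDirection(xp, xl, cfg)     # pL -> mL
  new("DifferentiationModel", genes = common, plCentroid = plCent,
      mascVector = as.numeric(vMasc), mlVector = as.numeric(vMl),
      trainingMedians = med)
}

#' Differentiation scores along the MaSC -> pL -> mL axis
#'
#' Per sample: (1) median-center each gene across the test set (the test
#' set is assumed to cover the range of differentiation, which makes the
#' per-gene median a platform-bias correction); (2) subtract the pL
#' centroid; (3) scale the sample vector to unit length (an exactly zero
#' vector is left at zero); (4) project onto the MaSC and mL unit vectors
#' by inner product; (5) score = proj_ml - proj_masc, so higher scores
#' mean greater (mature-luminal-ward) differentiation.
#'
#' @param model a \linkS4class{DifferentiationModel}.
#' @param m test expression matrix or SummarizedExperiment.
#' @param minGeneFraction minimum overlap with the model gene space.
#' @return data.frame with `sample_id`, `proj_masc`, `proj_ml`, `score`.
#' @export
computeDifferentiationScores <- function(model, m, minGeneFraction = 0.5) {
  stopifnot(is(model, "DifferentiationModel"))
  x <- exprsMatrix(m)
  shared <- intersect(model@genes, rownames(x))
  if (length(shared) < minGeneFraction * length(model@genes))
    stop("only ", length(shared), "/", length(model@genes),
         " model genes present in the test set")
  idx <- match(shared, model@genes)
  xs <- x[shared, , drop = FALSE]
  xs <- xs - apply(xs, 1, median, na.rm = TRUE)   # platform-bias correction
  xs <- xs - model@plCentroid[idx]                # pL at the origin
  vm <- model@mascVector[idx]; vl <- model@mlVector[idx]

  projM <- projL <- numeric(ncol(xs))
  for (j in seq_len(ncol(xs))) {
    v <- xs[, j]
    use <- !is.na(v)
    len <- sqrt(sum(v[use]^2))
    vv <- if (len > 0) v[use] / len else v[use]
    projM[j] <- sum(vv * vm[use])
    projL[j] <- sum(vv * vl[use])
  }
  data.frame(sample_id = colnames(xs), proj_masc = projM, proj_ml = projL,
             score = projL - projM, stringsAsFactors = FALSE)
}

#' Split samples into low/high differentiation halves
#'
#' Samples are rank-ordered by score and divided into two equal groups;
#' with an odd count the extra sample goes to the low group. Ties keep the
#' stable input order.
#'
#' @param scores numeric score per sample.
#' @return factor with levels `low`, `high`, in input order.
#' @export
dichotomizeScores <- function(scores) {
  n <- length(scores)
  if (n < 2) stop("need >= 2 samples to dichotomize")
  ord <- order(scores)  # stable for ties
  grp <- rep("high", n)
  grp[ord[seq_len(ceiling(n / 2))]] <- "low"
  factor(grp, levels = c("low", "high"))
}

#' Read and write differentiation models as JSON
#'
#' @param model a \linkS4class{DifferentiationModel}.
#' @param path file path.
#' @export
writeDifferentiationModel <- function(model, path) {
  stopifnot(is(model, "DifferentiationModel"))
  jsonlite::write_json(list(
    genes = model@genes, pl_centroid = model@plCentroid,
    masc_vector = model@mascVector, ml_vector = model@mlVector,
    training_medians = model@trainingMedians),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDifferentiationModel
#' @export
readDifferentiationModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("DifferentiationModel", genes = j$genes,
      plCentroid = as.numeric(j$pl_centroid),
      mascVector = as.numeric(j$masc_vector),
      mlVector = as.numeric(j$ml_vector),
      trainingMedians = as.numeric(j$training_medians))
}
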