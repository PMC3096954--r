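# Association and survival statistics for clinical characterization:
# 2x2 chi-square and Fisher tests, Kaplan-Meier curves with log-rank
# comparison, and Cox proportional-hazards fits (Breslow ties).

.check2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L))) stop("a 2x2 table is required")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be
 non-negative integers")
  if (sum(tab) == 0) stop("table total must be > 0")
  tab
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected by default (`correct = FALSE`): the convention that
#' reproduces the published dual-immunofluorescence comparisons; Yates
#' continuity correction available via the flag.
#'
#' @param tab 2x2 matrix of counts (rows = group, columns = outcome).
#' @param correct apply the Yates continuity correction.
#' @return list with `chi2`, `p.value`, `df`.
#' @examples
#' chiSquare2x2(matrix(c(11, 17, 9, 49), 2))  # p = 0.0145
#' @export
chiSquare2x2 <- function(tab, correct = FALSE) {
  tab <- .check2x2(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin")
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  list(chi2 = unname(ct$statistic), p.value = ct$p.value, df = 1L)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p by the probability-mass rule: the sum of hypergeometric
#' probabilities of all tables no more likely than the observed one.
#' Degenerate margins give p = 1.
#'
#' @param tab 2x2 matrix of counts.
#' @return two-sided p value.
#' @export
fisherExact2x2 <- function(tab) {
  tab <- .check2x2(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  fisher.test(tab)$p.value
}

#' Kaplan-Meier curves and log-rank comparison
#'
#' Product-limit estimator with Greenwood standard errors per group and the
#' k-group log-rank test (df = k - 1). With no events anywhere, the curves
#' are returned flat at 1 and p = 1 with a warning.
#'
#' @param time positive follow-up time per subject.
#' @param event 0/1 event indicator per subject.
#' @param group group label per subject.
#' @return list with `curves` (per-group data.frame of `time`, `n.risk`,
#'   `n.event`, `surv`, `std.err`), `chi2`, `df`, `p.value`.
#' @export
kmLogrank <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (any(time <= 0)) stop("times must be > 0")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  group <- factor(group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group,
                           conf.type = "log")
  strataOf <- if (is.null(fit$strata)) rep(levels(group), length(fit$time))
              else rep(sub("^group=", "", names(fit$strata)), fit$strata)
  curves <- split(data.frame(time = fit$time, n.risk = fit$n.risk,
                             n.event = fit$n.event, surv = fit$surv,
                             std.err = fit$std.err * fit$surv),
                  strataOf)
  if (sum(event) == 0) {
    warning("no events observed; log-rank p set to 1")
    return(list(curves = curves, chi2 = 0, df = nlevels(group) - 1L,
                p.value = 1))
  }
  if (nlevels(droplevels(group)) < 2)
    return(list(curves = curves, chi2 = NA_real_, df = 0L,
                p.value = NA_real_))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(curves = curves, chi2 = unname(sd$chisq), df = df,
       p.value = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Breslow tie handling (Efron via the flag)
#' and optional stratification. Non-identifiable covariates (e.g. a
#' duplicated pair) and monotone-likelihood degeneracies are errors, not
#' silent numbers.
#'
#' @param time,event survival outcome per subject.
#' @param covariates data.frame of covariates (numeric or factor).
#' @param strata optional stratum label per subject.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return data.frame with one row per coefficient: `term`, `coef`, `hr`,
#'   `lower95`, `upper95`, `p.value`.
#' @export
coxPH <- function(time, event, covariates, strata = NULL,
                  ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  stopifnot(is.data.frame(covariates), nrow(covariates) == length(time))
  if (sum(event) < 1) stop("at least one event is required")
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  rhs <- paste(colnames(covariates), collapse = " + ")
  if (!is.null(strata)) {
    dat$.stratum <- strata
    rhs <- paste(rhs, "+ strata(.stratum)")
  }
  form <- stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs))
  fit <- withCallingHandlers(
    survival::coxph(form, data = dat, ties = ties),
    warning = function(w) {
      if (grepl("converge|infinite|singular|beta may be",
                conditionMessage(w)))
        stop("Cox fit degenerate: ", conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  if (anyNA(fit$coefficients))
    stop("non-identifiable covariate(s): ",
         paste(names(fit$coefficients)[is.na(fit$coefficients)],
               collapse = ", "))
  ci <- summary(fit)$conf.int
  data.frame(term = rownames(co), coef = co[, "coef"],
             hr = ci[, "exp(coef)"], lower95 = ci[, "lower .95"],
             upper95 = ci[, "upper .95"],
             p.value = co[, "Pr(>|z|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}
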