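#' Per-grade feature summaries of a bifurcation table
#'
#' Mean and SD of every geometry feature per retinopathy grade, computed
#' over bifurcation-level rows (the unit of analysis is the bifurcation,
#' pooled within patients). Missing junction exponents are excluded from
#' the chi summary with their count reported; unusable rows are dropped.
#'
#' @param features bifurcation-level data.frame (see [featureColumns()]).
#' @param patientTable data.frame with `patient_id` and `grade`.
#' @param stratum `"all"`, `"arteriole"` or `"venule"`.
#' @param featureNames features to summarise.
#' @return data.frame with columns `feature`, `grade`, `n`, `mean`,
#'   `sd`, `n_missing`. Grades absent from the data are reported absent
#'   (no row), never as zeros.
#' @export
summarizeGroups <- function(features, patientTable,
                            stratum = c("all", "arteriole", "venule"),
                            featureNames = c(
                              "d0", "d1", "d2", "theta",
                              "theta1", "theta2", "chi"
                            )) {
  stratum <- match.arg(stratum)
  df <- .mergeGrade(features, patientTable)
  if (stratum != "all") df <- df[df$vessel_type == stratum, , drop = FALSE]
  if ("usable" %in% names(df)) df <- df[df$usable, , drop = FALSE]
  out <- list()
  for (f in featureNames) {
    v <- df[[f]]
    for (g in unique(df$grade)) {
      vg <- v[df$grade == g]
      miss <- sum(is.na(vg))
      vg <- vg[!is.na(vg)]
      if (!length(vg)) next
      out[[length(out) + 1L]] <- data.frame(
        feature = f, grade = g, n = length(vg),
        mean = mean(vg), sd = if (length(vg) > 1) stats::sd(vg) else 0,
        n_missing = miss, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

.mergeGrade <- function(features, patientTable) {
  stopifnot("patient_id" %in% names(features))
  cols <- intersect(
    c(
      "patient_id", "grade", "age", "sex", "diabetes_type", "duration",
      "hypertension", "high_cholesterol", "progressor"
    ),
    names(patientTable)
  )
  # drop patient columns already present in the feature table so a
  # pre-merged table can be passed through again without name clashes
  dup <- intersect(setdiff(cols, "patient_id"), names(features))
  if (length(dup)) features <- features[, setdiff(names(features), dup), drop = FALSE]
  unknown <- setdiff(features$patient_id, patientTable$patient_id)
  if (length(unknown)) {
    stop(
      "feature rows reference unknown patients: ",
      paste(utils::head(unknown, 5), collapse = ", ")
    )
  }
  merge(features, patientTable[, cols, drop = FALSE], by = "patient_id")
}

#' One-way analysis of variance
#'
#' Classical between/within sum-of-squares decomposition across groups,
#' fitted with [stats::aov()]. Used both for grade comparisons and for
#' the repeatability analysis.
#'
#' @param values numeric response vector.
#' @param groups grouping vector (coerced to factor), same length.
#' @return A list of class `"rvgAnova"`: `F`, `dfBetween`, `dfWithin`,
#'   `p`, `ssBetween`, `ssWithin`, `ssTotal`, `mse`, `groupMeans`,
#'   `groupSds`, `groupNs`, `grandMean`.
#' @examples
#' oneWayAnova(c(1, 2, 3, 2, 3, 4, 3, 4, 5), rep(c("a", "b", "c"), each = 3))
#' @export
oneWayAnova <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  if (nlevels(groups) < 2) stop("one-way ANOVA needs at least 2 groups")
  if (any(table(groups) < 1)) stop("every group needs at least one observation")
  if (length(values) - nlevels(groups) < 1) {
    stop("one-way ANOVA needs at least 1 residual degree of freedom")
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  res <- list(
    F = tab[1, "F value"], dfBetween = tab[1, "Df"], dfWithin = tab[2, "Df"],
    p = tab[1, "Pr(>F)"],
    ssBetween = tab[1, "Sum Sq"], ssWithin = tab[2, "Sum Sq"],
    ssTotal = tab[1, "Sum Sq"] + tab[2, "Sum Sq"],
    mse = tab[2, "Mean Sq"],
    groupMeans = tapply(values, groups, mean),
    groupSds = tapply(values, groups, stats::sd),
    groupNs = as.vector(table(groups)),
    grandMean = mean(values)
  )
  if (res$ssTotal <= 1e-12 * max(1, mean(values)^2) * length(values)) {
    # all observations equal (up to float dust): no variance to explain
    res$F <- 0
    res$p <- 1
  }
  names(res$groupNs) <- levels(groups)
  class(res) <- "rvgAnova"
  res
}

#' @export
print.rvgAnova <- function(x, ...) {
  cat(sprintf(
    "One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
    x$dfBetween, x$dfWithin, x$F, x$p
  ))
  invisible(x)
}

#' Fisher-protected least significant difference post-hoc test
#'
#' Pairwise two-sided t-tests between group means using the pooled
#' within-group mean square error and its degrees of freedom from the
#' omnibus one-way ANOVA. The "protection" is the gate: pairwise
#' comparisons are declared significant only when the omnibus ANOVA p
#' is itself at or below `alpha`; otherwise every pair is marked
#' non-significant regardless of its pairwise p-value. Homogeneous
#' subset letters are derived from the significance matrix: groups
#' sharing a letter are not significantly different.
#'
#' @param values numeric response vector.
#' @param groups grouping vector.
#' @param anova result of [oneWayAnova()] on the same data (recomputed
#'   when NULL; a mismatch in group counts is an error).
#' @param alpha protection and significance level.
#' @return A list of class `"rvgPosthoc"`: `pairwise` (data.frame with
#'   group pair, difference, t, p, significant), `letters` (named
#'   character vector per group), `protected` (logical: whether the
#'   omnibus gate passed), `alpha`.
#' @export
flsdPosthoc <- function(values, groups, anova = NULL, alpha = 0.05) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  if (is.null(anova)) anova <- oneWayAnova(values, groups)
  if (!inherits(anova, "rvgAnova")) stop("anova must be an rvgAnova result")
  if (length(anova$groupNs) != nlevels(groups) ||
    !all(anova$groupNs == as.vector(table(groups)))) {
    stop("anova result does not match the supplied data")
  }
  lev <- levels(groups)
  means <- tapply(values, groups, mean)
  ns <- table(groups)
  protected <- anova$p <= alpha
  pairs <- utils::combn(lev, 2)
  pw <- apply(pairs, 2, function(pr) {
    i <- pr[1]
    j <- pr[2]
    se <- sqrt(anova$mse * (1 / ns[[i]] + 1 / ns[[j]]))
    tstat <- (means[[i]] - means[[j]]) / se
    p <- 2 * stats::pt(-abs(tstat), df = anova$dfWithin)
    c(t = tstat, p = p)
  })
  pairwise <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    difference = means[pairs[1, ]] - means[pairs[2, ]],
    t = pw["t", ], p = pw["p", ],
    significant = protected & pw["p", ] <= alpha,
    stringsAsFactors = FALSE
  )
  rownames(pairwise) <- NULL
  res <- list(
    pairwise = pairwise,
    letters = .homogeneousLetters(means, pairwise),
    protected = protected, alpha = alpha
  )
  class(res) <- "rvgPosthoc"
  res
}

# Compact letter display: maximal runs of mean-ordered groups with no
# significant pair inside share a letter.
.homogeneousLetters <- function(means, pairwise) {
  ord <- names(sort(means))
  k <- length(ord)
  sig <- function(a, b) {
    hit <- (pairwise$group1 == a & pairwise$group2 == b) |
      (pairwise$group1 == b & pairwise$group2 == a)
    any(pairwise$significant[hit])
  }
  subsets <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(vapply(i:j, function(m) sig(ord[m], ord[j + 1]), logical(1)))) {
      j <- j + 1
    }
    subsets[[length(subsets) + 1L]] <- ord[i:j]
  }
  # drop subsets contained in another
  keep <- vapply(seq_along(subsets), function(i) {
    !any(vapply(seq_along(subsets), function(j) {
      i != j && all(subsets[[i]] %in% subsets[[j]])
    }, logical(1)))
  }, logical(1))
  subsets <- unique(subsets[keep])
  letters_out <- stats::setNames(rep("", k), ord)
  for (s in seq_along(subsets)) {
    lab <- letters[s]
    for (g in subsets[[s]]) letters_out[g] <- paste0(letters_out[g], lab)
  }
  letters_out
}

#' @export
print.rvgPosthoc <- function(x, ...) {
  cat(sprintf(
    "Fisher-protected LSD (alpha = %.2f, omnibus %s)\n", x$alpha,
    if (x$protected) "significant" else "not significant - all pairs ns"
  ))
  print(x$pairwise, digits = 4)
  cat("letters:", paste(names(x$letters), x$letters, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

# Fixed covariate coding, printed in every regression result.
.covariateCoding <- paste(
  "coding: sex female=1, male=0; diabetes type 2=1, type 1=0;",
  "hypertension yes=1; high cholesterol yes=1"
)

#' Nested linear models of geometry on demographic risk factors
#'
#' Ordinary least squares regression of a bifurcation-level geometry
#' feature on demographic and clinical covariates, in three nested
#' models: model 1 age and sex; model 2 additionally diabetes type and
#' history of hypertension; model 3 additionally diabetes duration and
#' history of hypercholesterolemia. Categorical covariates are coded
#' 0/1 (female = 1, type 2 = 1, condition present = 1) and the coding
#' is recorded in the result.
#'
#' @param features bifurcation-level data.frame.
#' @param patientTable patient covariate data.frame.
#' @param feature name of the outcome feature column.
#' @param modelId 1, 2 or 3.
#' @param stratum `"all"`, `"arteriole"` or `"venule"`.
#' @param imageMean when TRUE, fit on per-image feature means instead of
#'   bifurcation-level rows.
#' @return A list of class `"rvgRegression"`: `modelId`, `feature`,
#'   `coefficients` (data.frame with estimate, se, t, p), `n`, `coding`,
#'   `stratum`.
#' @export
fitRiskFactorModels <- function(features, patientTable, feature,
                                modelId = 3,
                                stratum = c("all", "arteriole", "venule"),
                                imageMean = FALSE) {
  stratum <- match.arg(stratum)
  stopifnot(modelId %in% 1:3, feature %in% names(features))
  df <- .mergeGrade(features, patientTable)
  if (stratum != "all") df <- df[df$vessel_type == stratum, , drop = FALSE]
  if ("usable" %in% names(df)) df <- df[df$usable, , drop = FALSE]
  df <- df[!is.na(df[[feature]]), , drop = FALSE]
  df$sexF <- as.numeric(df$sex == "female")
  df$type2 <- as.numeric(df$diabetes_type == 2)
  df$htn <- as.numeric(df$hypertension)
  df$chol <- as.numeric(df$high_cholesterol)
  if (imageMean) {
    agg <- stats::aggregate(
      df[, c(feature, "age", "sexF", "type2", "htn", "chol", "duration")],
      by = list(image_id = df$image_id), FUN = mean
    )
    df <- agg
  }
  covs <- switch(as.character(modelId),
    "1" = c("age", "sexF"),
    "2" = c("age", "sexF", "type2", "htn"),
    "3" = c("age", "sexF", "type2", "htn", "duration", "chol")
  )
  X <- as.matrix(df[, covs, drop = FALSE])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    bad <- covs[qrX$pivot[seq.int(qrX$rank + 1, ncol(X) + 1)] - 1]
    stop(
      "rank-deficient design; collinear columns: ",
      paste(bad, collapse = ", ")
    )
  }
  fml <- stats::as.formula(paste(feature, "~", paste(covs, collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  sm <- summary(fit)$coefficients
  res <- list(
    modelId = modelId, feature = feature, stratum = stratum,
    coefficients = data.frame(
      term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
      t = sm[, 3], p = sm[, 4], row.names = NULL,
      stringsAsFactors = FALSE
    ),
    n = nrow(df), coding = .covariateCoding
  )
  class(res) <- "rvgRegression"
  res
}

#' @export
print.rvgRegression <- function(x, ...) {
  cat(sprintf(
    "Linear model %d for %s (%s stratum, n = %d)\n%s\n",
    x$modelId, x$feature, x$stratum, x$n, x$coding
  ))
  print(x$coefficients, digits = 4)
  invisible(x)
}

# Logistic fit with a tiny ridge fallback under complete separation.
# Returns list(coef, se, penalized).
.logisticFit <- function(X, y, ridge = 1e-6) {
  Xd <- cbind(`(Intercept)` = 1, X)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(Xd, y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  coef <- fit$coefficients
  if (separated || any(abs(coef[-1]) > 25, na.rm = TRUE) || anyNA(coef)) {
    coef <- .ridgeLogistic(Xd, y, lambda = ridge)
    separated <- TRUE
  }
  eta <- drop(Xd %*% coef)
  p <- stats::plogis(eta)
  W <- p * (1 - p)
  info <- crossprod(Xd, Xd * W)
  if (separated) info <- info + diag(c(0, rep(1e-6, ncol(Xd) - 1)), ncol(Xd))
  se <- sqrt(diag(solve(info)))
  list(coef = coef, se = stats::setNames(se, names(coef)), penalized = separated)
}

# Newton-Raphson logistic regression with an L2 penalty on slopes.
.ridgeLogistic <- function(Xd, y, lambda = 1e-6, maxit = 100L) {
  beta <- rep(0, ncol(Xd))
  pen <- diag(c(0, rep(lambda, ncol(Xd) - 1)), ncol(Xd))
  for (i in seq_len(maxit)) {
    p <- stats::plogis(drop(Xd %*% beta))
    W <- pmax(p * (1 - p), 1e-10)
    grad <- crossprod(Xd, y - p) - pen %*% beta
    hess <- crossprod(Xd, Xd * W) + pen
    step <- solve(hess, grad)
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-10) break
  }
  stats::setNames(beta, colnames(Xd))
}

#' Odds ratio for retinopathy progression from one baseline feature
#'
#' Maximum-likelihood logistic regression of the progressor flag on a
#' single bifurcation-level geometry feature measured at the baseline
#' visit, reporting the per-unit odds ratio with a Wald 95% confidence
#' interval. Complete separation is flagged and the fit retried with a
#' small ridge penalty (1e-6) on the slope.
#'
#' @param features bifurcation-level data.frame; rows with
#'   `visit == "baseline"` are used when a visit column is present.
#' @param patientTable data.frame with `patient_id` and logical
#'   `progressor`.
#' @param feature outcome feature column name.
#' @param stratum `"all"`, `"arteriole"` or `"venule"`.
#' @return A list of class `"rvgLogistic"`: `feature`, `coefficient`,
#'   `se`, `oddsRatio`, `ci95` (length 2), `p`, `n`, `penalized`,
#'   `stratum`.
#' @export
fitProgressionLogistic <- function(features, patientTable, feature,
                                   stratum = c("all", "arteriole", "venule")) {
  stratum <- match.arg(stratum)
  stopifnot(feature %in% names(features))
  df <- features
  if ("visit" %in% names(df)) df <- df[df$visit == "baseline", , drop = FALSE]
  if (stratum != "all") df <- df[df$vessel_type == stratum, , drop = FALSE]
  if ("usable" %in% names(df)) df <- df[df$usable, , drop = FALSE]
  df <- merge(df, patientTable[, c("patient_id", "progressor")], by = "patient_id")
  df <- df[!is.na(df[[feature]]) & !is.na(df$progressor), , drop = FALSE]
  if (length(unique(df$progressor)) < 2) {
    stop("progression logistic needs both progressors and non-progressors")
  }
  y <- as.numeric(df$progressor)
  X <- matrix(df[[feature]], ncol = 1, dimnames = list(NULL, feature))
  fit <- .logisticFit(X, y)
  b <- fit$coef[[feature]]
  se <- fit$se[[feature]]
  res <- list(
    feature = feature, stratum = stratum,
    coefficient = b, se = se,
    oddsRatio = exp(b),
    ci95 = exp(b + c(-1, 1) * stats::qnorm(0.975) * se),
    p = 2 * stats::pnorm(-abs(b / se)),
    n = nrow(df), penalized = fit$penalized
  )
  class(res) <- "rvgLogistic"
  res
}

#' @export
print.rvgLogistic <- function(x, ...) {
  cat(sprintf(
    "Progression logistic for %s (%s, n = %d)%s\n",
    x$feature, x$stratum, x$n, if (x$penalized) " [ridge-penalized]" else ""
  ))
  cat(sprintf(
    "  coeff = %.3f, OR = %.2f (95%% CI %.2f - %.2f), p = %.3g\n",
    x$coefficient, x$oddsRatio, x$ci95[1], x$ci95[2], x$p
  ))
  invisible(x)
}

#' Repeatability coefficient of variation
#'
#' Intra-observer repeatability across measurement sessions: a one-way
#' ANOVA with bifurcation as the grouping factor gives the
#' within-bifurcation mean square; its square root is the
#' between-session SD, and the coefficient of variation is
#' `100 * within-SD / grand mean`. Bifurcations measured in a single
#' session are excluded with a warning.
#'
#' @param measurements data.frame with columns `bifurcation`, `session`
#'   and `value` (e.g. from [generateRepeatMeasurements()]).
#' @return A list of class `"rvgRepeatability"`: `cov` (percent),
#'   `withinSd`, `grandMean`, `nBifurcations`, `nExcluded`.
#' @export
repeatabilityCoV <- function(measurements) {
  stopifnot(all(c("bifurcation", "session", "value") %in% names(measurements)))
  counts <- table(measurements$bifurcation)
  singles <- names(counts)[counts < 2]
  if (length(singles)) {
    warning(
      length(singles),
      " bifurcation(s) with a single session excluded from repeatability"
    )
    measurements <- measurements[
      !measurements$bifurcation %in% singles, ,
      drop = FALSE
    ]
  }
  if (!nrow(measurements)) stop("no bifurcation has 2 or more sessions")
  # within-bifurcation mean square, computed directly so a single
  # remaining bifurcation is still analysable
  groups <- factor(measurements$bifurcation)
  groupMeans <- tapply(measurements$value, groups, mean)
  ssWithin <- sum((measurements$value - groupMeans[groups])^2)
  dfWithin <- nrow(measurements) - nlevels(groups)
  if (dfWithin < 1) stop("no residual degrees of freedom for repeatability")
  withinSd <- sqrt(ssWithin / dfWithin)
  grandMean <- mean(measurements$value)
  res <- list(
    cov = 100 * withinSd / grandMean,
    withinSd = withinSd, grandMean = grandMean,
    nBifurcations = length(unique(measurements$bifurcation)),
    nExcluded = length(singles)
  )
  class(res) <- "rvgRepeatability"
  res
}

#' @export
print.rvgRepeatability <- function(x, ...) {
  cat(sprintf(
    "Repeatability: CoV = %.2f%% (within-SD %.3f, grand mean %.3f, %d bifurcations)\n",
    x$cov, x$withinSd, x$grandMean, x$nBifurcations
  ))
  invisible(x)
}
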