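#' Match patients on optic nerve head distance ratio
#'
#' Controls patient-level feature comparisons for distance from the
#' optic nerve head. The reference is the patient with the lowest mean
#' distance ratio (ties broken by patient id order), kept untrimmed.
#' For every other patient the bifurcation with the highest distance
#' ratio is discarded repeatedly until the patient's mean falls strictly
#' below the reference mean — "just lower": restoring the last
#' discarded bifurcation would bring the mean back to or above the
#' reference. Ties among removal candidates are broken by removing the
#' later row. A patient reduced to a single bifurcation whose mean is
#' still at or above the reference is kept with one row and flagged
#' unmatchable.
#'
#' @param features bifurcation-level data.frame with `patient_id` and
#'   finite `distance_ratio` for every row.
#' @return A list of class `"rvgMatching"`: `kept` (trimmed
#'   data.frame), `discarded` (removed rows), `referencePatient`,
#'   `referenceMean`, `unmatchable` (patient ids), `summary`
#'   (per-patient n kept/discarded and trimmed mean).
#' @examples
#' df <- data.frame(
#'   patient_id = rep(c("A", "B"), c(3, 3)),
#'   distance_ratio = c(1, 2, 3, 1.5, 2, 4)
#' )
#' m <- matchDistanceRatio(df)
#' m$summary
#' @export
matchDistanceRatio <- function(features) {
  if (!nrow(features)) stop("empty feature table")
  stopifnot(all(is.finite(features$distance_ratio)))
  if ("usable" %in% names(features)) {
    features <- features[features$usable, , drop = FALSE]
    if (!nrow(features)) stop("no usable bifurcations to match")
  }
  means <- tapply(features$distance_ratio, features$patient_id, mean)
  ids <- sort(names(means)) # patient_id order breaks reference ties
  refId <- ids[which.min(means[ids])]
  refMean <- means[[refId]]
  keptList <- list()
  discardedList <- list()
  unmatchable <- character()
  for (pid in ids) {
    rows <- features[features$patient_id == pid, , drop = FALSE]
    if (pid == refId) {
      keptList[[pid]] <- rows
      next
    }
    dropped <- rows[0, , drop = FALSE]
    while (mean(rows$distance_ratio) >= refMean && nrow(rows) > 1) {
      # most distant bifurcation; ties broken by the later row
      worst <- max(which(rows$distance_ratio == max(rows$distance_ratio)))
      dropped <- rbind(dropped, rows[worst, , drop = FALSE])
      rows <- rows[-worst, , drop = FALSE]
    }
    if (mean(rows$distance_ratio) >= refMean) unmatchable <- c(unmatchable, pid)
    keptList[[pid]] <- rows
    discardedList[[pid]] <- dropped
  }
  kept <- do.call(rbind, keptList)
  rownames(kept) <- NULL
  discarded <- do.call(rbind, discardedList)
  if (!is.null(discarded)) rownames(discarded) <- NULL
  summaryDf <- data.frame(
    patient_id = ids,
    n_kept = as.vector(table(factor(kept$patient_id, levels = ids))),
    n_discarded = if (is.null(discarded)) {
      0L
    } else {
      as.vector(table(factor(discarded$patient_id, levels = ids)))
    },
    trimmed_mean = vapply(
      ids,
      function(p) mean(kept$distance_ratio[kept$patient_id == p]), numeric(1)
    ),
    unmatchable = ids %in% unmatchable,
    stringsAsFactors = FALSE
  )
  res <- list(
    kept = kept, discarded = discarded,
    referencePatient = refId, referenceMean = refMean,
    unmatchable = unmatchable, summary = summaryDf
  )
  class(res) <- "rvgMatching"
  res
}

#' @export
print.rvgMatching <- function(x, ...) {
  cat(sprintf(
    "Distance-ratio matching: reference %s (mean %.3f), %d kept / %d discarded rows%s\n",
    x$referencePatient, x$referenceMean, nrow(x$kept),
    if (is.null(x$discarded)) 0L else nrow(x$discarded),
    if (length(x$unmatchable)) {
      paste0("; unmatchable: ", paste(x$unmatchable, collapse = ", "))
    } else {
      ""
    }
  ))
  invisible(x)
}

#' Patient-level feature profiles from matched bifurcation sets
#'
#' Characterises each patient (one image per patient) by the means of
#' the grade-model predictors over the kept bifurcations, arterioles
#' and venules pooled: mean parent diameter and mean deflection angle
#' of the smaller child, plus the mean distance ratio and the discard
#' count from matching.
#'
#' @param matching an `"rvgMatching"` result, or a plain data.frame of
#'   kept rows.
#' @return data.frame with columns `patient_id`, `mean_d0`,
#'   `mean_theta2`, `mean_distance_ratio`, `n_kept`, `n_discarded`,
#'   `unmatchable`.
#' @export
buildPatientProfiles <- function(matching) {
  if (inherits(matching, "rvgMatching")) {
    kept <- matching$kept
    summaryDf <- matching$summary
  } else {
    kept <- matching
    summaryDf <- NULL
  }
  ids <- sort(unique(kept$patient_id))
  prof <- data.frame(
    patient_id = ids,
    mean_d0 = vapply(ids, function(p) mean(kept$d0[kept$patient_id == p]), numeric(1)),
    mean_theta2 = vapply(ids, function(p) mean(kept$theta2[kept$patient_id == p]), numeric(1)),
    mean_distance_ratio = vapply(
      ids,
      function(p) mean(kept$distance_ratio[kept$patient_id == p]), numeric(1)
    ),
    n_kept = as.vector(table(factor(kept$patient_id, levels = ids))),
    stringsAsFactors = FALSE
  )
  if (!is.null(summaryDf)) {
    prof$n_discarded <- summaryDf$n_discarded[match(ids, summaryDf$patient_id)]
    prof$unmatchable <- summaryDf$unmatchable[match(ids, summaryDf$patient_id)]
  } else {
    prof$n_discarded <- 0L
    prof$unmatchable <- FALSE
  }
  rownames(prof) <- NULL
  prof
}

#' Leave-one-out cross-validated grade classification
#'
#' Patient-level logistic grade models evaluated by leave-one-out
#' cross-validation: for each patient a logistic model is fitted on all
#' other patients and the held-out patient's probability computed, with
#' the class decided at the probability threshold.
#'
#' Model `"one"` separates patients without retinopathy from those with
#' any retinopathy (minimal, severe and proliferative merged; positive
#' class = retinopathy) using mean parent diameter and mean
#' smaller-child deflection angle. Model `"two"` separates proliferative
#' from non-proliferative retinopathy among retinopathy cases (positive
#' class = proliferative) using mean parent diameter alone; with
#' `scoreNoDR = TRUE` the no-retinopathy patients are additionally
#' scored by a model fitted on all retinopathy cases and folded into an
#' overall specificity.
#'
#' @param profiles patient profile data.frame from
#'   [buildPatientProfiles()].
#' @param patientTable data.frame with `patient_id` and `grade`.
#' @param model `"one"` or `"two"`.
#' @param threshold decision probability threshold.
#' @param predictors override of predictor column names (defaults:
#'   model one `c("mean_d0", "mean_theta2")`; model two `"mean_d0"`).
#' @param scoreNoDR model two only: also score no-retinopathy patients
#'   (reported as `overallSpecificity`).
#' @return A list of class `"rvgClassification"`: `model`,
#'   `sensitivity` and `specificity` (percent), `predictions`
#'   (per-patient data.frame with truth, probability, prediction and the
#'   fold's coefficients), `excluded` (patients whose fold lost a
#'   class), `threshold`, and for model two optionally
#'   `overallSpecificity`.
#' @export
looClassify <- function(profiles, patientTable, model = c("one", "two"),
                        threshold = 0.5, predictors = NULL,
                        scoreNoDR = FALSE) {
  model <- match.arg(model)
  stopifnot(all(c("patient_id", "grade") %in% names(patientTable)))
  df <- merge(profiles, patientTable[, c("patient_id", "grade")],
    by = "patient_id"
  )
  df <- df[order(df$patient_id), , drop = FALSE]
  if (model == "one") {
    predictors <- predictors %||% c("mean_d0", "mean_theta2")
    df$y <- as.numeric(df$grade != "NoDR") # positive: any retinopathy
    extra <- NULL
  } else {
    predictors <- predictors %||% "mean_d0"
    extra <- df[df$grade == "NoDR", , drop = FALSE]
    df <- df[df$grade != "NoDR", , drop = FALSE]
    df$y <- as.numeric(df$grade == "PDR") # positive: proliferative
  }
  if (length(unique(df$y)) < 2 || min(table(df$y)) < 2) {
    stop("each class needs at least 2 patients")
  }
  n <- nrow(df)
  X <- as.matrix(df[, predictors, drop = FALSE])
  preds <- vector("list", n)
  excluded <- character()
  for (i in seq_len(n)) {
    yTrain <- df$y[-i]
    if (length(unique(yTrain)) < 2) {
      excluded <- c(excluded, df$patient_id[i])
      warning(
        "fold for patient ", df$patient_id[i],
        " has a single class; patient excluded"
      )
      next
    }
    fit <- .logisticFit(X[-i, , drop = FALSE], yTrain)
    prob <- stats::plogis(drop(c(1, X[i, ]) %*% fit$coef))
    preds[[i]] <- data.frame(
      patient_id = df$patient_id[i], true = df$y[i],
      probability = prob, predicted = as.numeric(prob > threshold),
      penalized = fit$penalized,
      t(fit$coef),
      stringsAsFactors = FALSE, check.names = FALSE
    )
  }
  predictions <- do.call(rbind, preds)
  pos <- predictions$true == 1
  sens <- 100 * mean(predictions$predicted[pos] == 1)
  spec <- 100 * mean(predictions$predicted[!pos] == 0)
  res <- list(
    model = model, sensitivity = sens, specificity = spec,
    predictions = predictions, excluded = excluded,
    threshold = threshold, predictors = predictors
  )
  if (model == "two" && scoreNoDR && !is.null(extra) && nrow(extra)) {
    fitAll <- .logisticFit(X, df$y)
    probs <- stats::plogis(
      drop(cbind(1, as.matrix(extra[, predictors, drop = FALSE])) %*% fitAll$coef)
    )
    correctNoDR <- sum(probs <= threshold) # non-proliferative is correct
    nNeg <- sum(!pos)
    res$noDRCorrect <- correctNoDR
    res$noDRTotal <- nrow(extra)
    res$overallSpecificity <- 100 *
      (sum(predictions$predicted[!pos] == 0) + correctNoDR) /
      (nNeg + nrow(extra))
  }
  class(res) <- "rvgClassification"
  res
}

#' @export
print.rvgClassification <- function(x, ...) {
  cat(sprintf(
    "LOO grade model %s (threshold %.2f, predictors %s)\n",
    x$model, x$threshold, paste(x$predictors, collapse = " + ")
  ))
  cat(sprintf(
    "  sensitivity %.1f%%, specificity %.1f%% (%d patients%s)\n",
    x$sensitivity, x$specificity, nrow(x$predictions),
    if (length(x$excluded)) paste0(", ", length(x$excluded), " excluded") else ""
  ))
  if (!is.null(x$overallSpecificity)) {
    cat(sprintf(
      "  overall specificity incl. no-retinopathy patients: %.1f%%\n",
      x$overallSpecificity
    ))
  }
  invisible(x)
}

#' End-to-end grade assessment from a feature table
#'
#' Convenience wrapper chaining [matchDistanceRatio()],
#' [buildPatientProfiles()] and [looClassify()].
#'
#' @param features bifurcation-level data.frame.
#' @param patientTable data.frame with `patient_id` and `grade`.
#' @param model `"one"` or `"two"`.
#' @param threshold decision threshold.
#' @param ... passed to [looClassify()].
#' @return An `"rvgClassification"` result with the matching attached
#'   as `matching`.
#' @export
classifyGrades <- function(features, patientTable, model = "one",
                           threshold = 0.5, ...) {
  matching <- matchDistanceRatio(features)
  profiles <- buildPatientProfiles(matching)
  res <- looClassify(profiles, patientTable,
    model = model,
    threshold = threshold, ...
  )
  res$matching <- matching
  res
}
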