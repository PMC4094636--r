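#' Comparative grade analysis report
#'
#' Orchestrates the cross-sectional comparison: per-grade mean/SD
#' summaries of every geometry feature with the omnibus one-way ANOVA p
#' value and Fisher-protected LSD homogeneous-subset letters, for the
#' overall data and the arteriolar and venular strata. Empty strata are
#' omitted with a warning recorded in the report; every stage's row
#' counts (rows in, unusable, missing chi) are reconciled in `counts`.
#'
#' @param features bifurcation-level data.frame.
#' @param patientTable patient data.frame with `grade`.
#' @param alpha significance level for the ANOVA gate and post-hoc.
#' @param featureNames features to compare.
#' @return A list of class `"rvgReport"`: `kind`, `config`, `counts`,
#'   `warnings`, `tables` (one per stratum: data.frame of grade
#'   summaries with `anova_p` and FLSD letters appended).
#' @export
runComparative <- function(features, patientTable, alpha = 0.05,
                           featureNames = c(
                             "d0", "d1", "d2", "theta",
                             "theta1", "theta2", "chi"
                           )) {
  if (!"grade" %in% names(patientTable) || anyNA(patientTable$grade)) {
    bad <- patientTable$patient_id[is.na(patientTable$grade %||% NA)]
    stop(
      "missing grade labels for patients: ",
      paste(utils::head(bad, 10), collapse = ", ")
    )
  }
  df <- .mergeGrade(features, patientTable)
  warningsOut <- character()
  nIn <- nrow(df)
  usable <- if ("usable" %in% names(df)) df$usable else rep(TRUE, nIn)
  counts <- list(
    rows_in = nIn, rows_usable = sum(usable),
    rows_flagged = sum(!usable),
    chi_missing = sum(is.na(df$chi[usable]))
  )
  tables <- list()
  for (stratum in c("all", "arteriole", "venule")) {
    sub <- if (stratum == "all") df else df[df$vessel_type == stratum, , drop = FALSE]
    sub <- sub[if ("usable" %in% names(sub)) sub$usable else TRUE, , drop = FALSE]
    if (!nrow(sub)) {
      warningsOut <- c(warningsOut, paste0("stratum '", stratum, "' is empty; table omitted"))
      next
    }
    summ <- summarizeGroups(sub, patientTable,
      stratum = "all",
      featureNames = featureNames
    )
    rows <- list()
    for (f in featureNames) {
      v <- sub[[f]]
      ok <- !is.na(v)
      if (length(unique(sub$grade[ok])) < 2) next
      an <- oneWayAnova(v[ok], sub$grade[ok])
      ph <- flsdPosthoc(v[ok], sub$grade[ok], anova = an, alpha = alpha)
      fs <- summ[summ$feature == f, , drop = FALSE]
      fs$anova_p <- an$p
      fs$anova_F <- an$F
      fs$letters <- ph$letters[fs$grade]
      fs$significant <- an$p <= alpha
      rows[[f]] <- fs
    }
    tables[[stratum]] <- do.call(rbind, rows)
    rownames(tables[[stratum]]) <- NULL
  }
  res <- list(
    kind = "comparative",
    config = list(alpha = alpha, features = featureNames),
    counts = counts, warnings = warningsOut, tables = tables
  )
  class(res) <- "rvgReport"
  res
}

#' Predictive (progression) analysis report
#'
#' Orchestrates the longitudinal analysis of a progression cohort:
#' cross-visit one-way ANOVA comparisons of the resolution-independent
#' features (branching angles and junction exponent only — absolute
#' widths are excluded from cross-visit comparison, since pixel widths
#' are not comparable across acquisitions) per arm and stratum, plus
#' the baseline odds-ratio table: a binary logistic regression of
#' progression on each baseline feature for the overall, arteriolar and
#' venular data.
#'
#' @param features bifurcation-level data.frame with a `visit` column.
#' @param patientTable patient data.frame with logical `progressor`.
#' @param alpha significance level.
#' @return A list of class `"rvgReport"` with `visitTables` (per arm:
#'   mean/SD per visit with ANOVA p; angles and chi only) and `orTable`
#'   (coefficient, OR, 95% CI, p per feature and stratum).
#' @export
runPredictive <- function(features, patientTable, alpha = 0.05) {
  stopifnot("visit" %in% names(features))
  if (!"progressor" %in% names(patientTable)) {
    stop("patient table lacks a progressor column")
  }
  arms <- list(
    progressors = patientTable$patient_id[patientTable$progressor %in% TRUE],
    non_progressors = patientTable$patient_id[patientTable$progressor %in% FALSE]
  )
  if (any(vapply(arms, length, integer(1)) < 2)) {
    stop("each arm needs at least 2 patients")
  }
  warningsOut <- character()
  crossVisit <- c("theta1", "theta2", "chi") # widths excluded by design
  visitTables <- list()
  for (arm in names(arms)) {
    sub <- features[features$patient_id %in% arms[[arm]], , drop = FALSE]
    if ("usable" %in% names(sub)) sub <- sub[sub$usable, , drop = FALSE]
    rows <- list()
    for (f in crossVisit) {
      v <- sub[[f]]
      ok <- !is.na(v)
      an <- oneWayAnova(v[ok], sub$visit[ok])
      means <- tapply(v[ok], sub$visit[ok], mean)
      sds <- tapply(v[ok], sub$visit[ok], stats::sd)
      rows[[f]] <- data.frame(
        feature = f, visit = names(means),
        mean = as.vector(means), sd = as.vector(sds),
        anova_p = an$p, stringsAsFactors = FALSE
      )
    }
    visitTables[[arm]] <- do.call(rbind, rows)
    rownames(visitTables[[arm]]) <- NULL
  }
  orFeatures <- c("d0", "d1", "d2", "theta1", "theta2", "chi")
  orRows <- list()
  for (stratum in c("all", "arteriole", "venule")) {
    for (f in orFeatures) {
      fit <- tryCatch(
        fitProgressionLogistic(features, patientTable, f, stratum = stratum),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        warningsOut <- c(warningsOut, paste0(
          "logistic fit unavailable for ", f, " (", stratum, ")"
        ))
        next
      }
      if (fit$penalized) {
        warningsOut <- c(warningsOut, paste0(
          "separation: ridge-penalized fit for ", f, " (", stratum, ")"
        ))
      }
      orRows[[paste(stratum, f)]] <- data.frame(
        stratum = stratum, feature = f,
        coefficient = fit$coefficient, odds_ratio = fit$oddsRatio,
        ci_low = fit$ci95[1], ci_high = fit$ci95[2], p = fit$p,
        n = fit$n, penalized = fit$penalized, stringsAsFactors = FALSE
      )
    }
  }
  orTable <- do.call(rbind, orRows)
  rownames(orTable) <- NULL
  res <- list(
    kind = "predictive",
    config = list(alpha = alpha),
    counts = list(rows_in = nrow(features)),
    warnings = warningsOut,
    visitTables = visitTables, orTable = orTable
  )
  class(res) <- "rvgReport"
  res
}

#' @export
print.rvgReport <- function(x, ...) {
  cat(sprintf("RVG %s report\n", x$kind))
  cat("counts:", paste(names(x$counts), unlist(x$counts), sep = "=", collapse = ", "), "\n")
  if (length(x$warnings)) {
    cat("warnings:\n")
    for (w in x$warnings) cat("  -", w, "\n")
  }
  for (nm in names(x$tables %||% list())) {
    cat("\n==", nm, "stratum ==\n")
    print(x$tables[[nm]], digits = 3)
  }
  for (nm in names(x$visitTables %||% list())) {
    cat("\n==", nm, "==\n")
    print(x$visitTables[[nm]], digits = 3)
  }
  if (!is.null(x$orTable)) {
    cat("\n== baseline progression odds ratios ==\n")
    print(x$orTable, digits = 3)
  }
  invisible(x)
}

#' Serialise a report to JSON
#'
#' @param report an `"rvgReport"` or `"rvgClassification"` result.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(
    report, path,
    auto_unbox = TRUE, digits = NA, force = TRUE, pretty = TRUE
  )
  invisible(path)
}
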