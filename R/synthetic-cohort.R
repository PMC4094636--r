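#' Default generative parameters for synthetic cohorts
#'
#' Parameter bundle describing the statistical structure the cohort
#' simulator draws from: per-grade, per-vessel-type means and SDs of the
#' bifurcation features (widths in pixels, branching angles in degrees),
#' group sizes, the arteriole:venule mix, patient-level random-effect
#' SDs, demographic covariate distributions and signed covariate effects
#' on the features, and the progression-arm settings.
#'
#' Grade means and SDs default to the observed distribution of
#' bifurcation geometry across retinopathy grades in a clinical fundus
#' cohort (widths increasing with grade severity, the smaller-child
#' branching angle widening); group sizes default to 10/10/12/19
#' patients with on average 15 bifurcations per image. The bifurcation
#' angle is never drawn directly: theta1 and theta2 are generated (with
#' a negative correlation chosen so the SD of their sum matches the
#' configured theta SD) and summed, and the junction exponent is always
#' computed from the generated widths.
#'
#' @return A named list of parameters; pass (possibly modified) to
#'   [generateCohort()] or [generateProgressionCohort()].
#' @seealso [nullGenerativeParams()]
#' @export
defaultGenerativeParams <- function() {
  grades <- c("NoDR", "MinimalNPDR", "SevereNPDR", "PDR")
  feat <- c("d0", "d1", "d2", "theta1", "theta2")
  mk <- function(x) matrix(x, nrow = 4, ncol = 5, byrow = FALSE,
                           dimnames = list(grades, feat))
  list(
    grades = grades,
    nPatients = c(NoDR = 10L, MinimalNPDR = 10L, SevereNPDR = 12L, PDR = 19L),
    bifurcationsPerImage = 15,
    arterioleFraction = c(
      NoDR = 117 / 242, MinimalNPDR = 136 / 310,
      SevereNPDR = 139 / 372, PDR = 231 / 594
    ),
    means = list(
      arteriole = mk(c(
        6.47, 7.54, 7.58, 8.06,
        5.78, 6.65, 6.73, 7.23,
        4.60, 5.42, 5.43, 5.62,
        25.77, 27.32, 28.33, 27.44,
        50.36, 51.99, 50.45, 56.88
      )),
      venule = mk(c(
        7.42, 9.04, 9.13, 9.55,
        6.51, 8.04, 8.05, 8.50,
        4.72, 5.51, 5.55, 5.82,
        24.81, 23.43, 24.34, 23.53,
        53.00, 57.34, 57.43, 59.65
      ))
    ),
    sds = list(
      arteriole = mk(c(
        1.08, 1.68, 1.65, 1.84,
        1.10, 1.62, 1.66, 1.80,
        0.99, 1.37, 1.33, 1.43,
        15.2, 16.6, 15.4, 16.4,
        20.3, 21.3, 20.3, 22.9
      )),
      venule = mk(c(
        1.87, 2.62, 2.56, 2.88,
        1.83, 2.55, 2.54, 2.79,
        1.08, 1.64, 1.47, 1.85,
        12.9, 14.9, 15.0, 16.8,
        17.9, 20.9, 22.1, 23.7
      ))
    ),
    # SD of theta = theta1 + theta2, used to infer corr(theta1, theta2)
    thetaSds = list(
      arteriole = c(NoDR = 15.8, MinimalNPDR = 17.9, SevereNPDR = 18.4, PDR = 18.6),
      venule = c(NoDR = 15.1, MinimalNPDR = 16.9, SevereNPDR = 17.4, PDR = 19.1)
    ),
    # patient random-effect SD per feature family (shared across grades;
    # must stay below the smallest configured total SD)
    patientSd = c(d2 = 0.28, theta1 = 3.5, theta2 = 4.5),
    # signed covariate effects (centred within grade, see vignette):
    # widthsAll shifts all three widths; widthsLarge shifts d0 and d1
    # only (via the d1 - d2 gap); theta2 shifts the smaller-child angle
    covariateEffects = list(
      age = list(widthsAll = -0.02), # px per year, both vessel types
      female = list(widthsLarge.venule = -0.35), # px, venular d0/d1 only
      type2 = list(widthsAll.arteriole = 0.40), # px, arteriolar widths
      duration = list(widthsAll = 0.004), # px per month
      hypertension = list(widthsLarge.venule = 0.30), # px, venular d0/d1
      cholesterol = list(theta2.arteriole = 3.0) # degrees
    ),
    covariates = list(
      age = list(
        mean = c(55.5, 56.6, 53, 50), sd = c(8.9, 9.5, 9.0, 12.5),
        min = c(43, 37, 41, 26), max = c(65, 65, 65, 65)
      ),
      femalePct = c(0.60, 0.50, 0.42, 0.58),
      type2Pct = c(0.70, 0.80, 0.83, 0.73),
      duration = list(
        mean = c(118, 148, 128, 211), sd = c(65, 74, 93, 124),
        min = c(24, 37, 12, 2), max = c(144, 240, 300, 456)
      ),
      hypertensionPct = c(0.50, 0.70, 0.67, 0.48),
      cholesterolPct = c(0.40, 0.70, 0.34, 0.57)
    ),
    # ONH distance ratios: bifurcations are nominated across the whole
    # image (wide within-patient spread); the per-patient mean varies
    # only mildly with image clarity, so distance matching trims a
    # minority of rows rather than degenerating patients to singletons
    distanceRatio = list(patientMeanRange = c(2.45, 2.75), sd = 0.9),
    # repeatability: between-session measurement noise as a percentage
    # of the grand mean (width features; angle features)
    sessionCov = c(width = 4.2, angle = 3.8),
    progression = list(
      nPerArm = 5L,
      # baseline shift of the smaller-child width for future progressors,
      # in pixels; the default implies a bifurcation-level log-odds slope
      # of -0.318 per pixel given the no-retinopathy width SD
      baselineD2Shift = -0.318 * 1.04^2,
      ageRange = c(47, 65)
    )
  )
}

#' Null generative parameters
#'
#' A copy of [defaultGenerativeParams()] with every grade's feature
#' means set to the no-retinopathy row, all covariate effects zeroed,
#' the progression shift zeroed and patient random effects removed —
#' under these parameters every bifurcation is exchangeable, so
#' downstream tests should reject at their nominal rate.
#'
#' @return A parameter list.
#' @export
nullGenerativeParams <- function() {
  p <- defaultGenerativeParams()
  for (v in c("arteriole", "venule")) {
    p$means[[v]][] <- rep(p$means[[v]]["NoDR", ], each = 4)
    p$sds[[v]][] <- rep(p$sds[[v]]["NoDR", ], each = 4)
    p$thetaSds[[v]][] <- p$thetaSds[[v]][["NoDR"]]
  }
  p$covariateEffects <- lapply(p$covariateEffects, function(e) list())
  p$patientSd[] <- 0
  p$progression$baselineD2Shift <- 0
  # equal vessel-type mix across grades: with per-type means retained,
  # a grade-varying mix would itself be a (real) grade signal
  p$arterioleFraction[] <- 623 / 1518
  p
}

# Gamma draw parameterised by mean and SD (exact first two moments,
# positive support); degenerate at the mean when sd ~ 0.
rgammaMS <- function(n, mean, sd) {
  mean <- pmax(rep_len(mean, n), 0.05)
  sd <- rep_len(sd, n)
  out <- mean
  live <- sd > 1e-9
  if (any(live)) {
    shape <- (mean[live] / sd[live])^2
    out[live] <- stats::rgamma(sum(live), shape = shape,
                               rate = shape / mean[live])
  }
  out
}

# Gamma quantile transform of standard-normal draws (Gaussian copula
# marginal), same mean/SD parameterisation as rgammaMS.
qgammaMS <- function(z, mean, sd) {
  n <- length(z)
  mean <- pmax(rep_len(mean, n), 0.05)
  sd <- rep_len(sd, n)
  out <- mean
  live <- sd > 1e-9
  if (any(live)) {
    shape <- (mean[live] / sd[live])^2
    out[live] <- stats::qgamma(stats::pnorm(z[live]), shape = shape,
                               rate = shape / mean[live])
  }
  out
}

# Truncated-normal draw by rejection (used for bounded covariates).
rtruncated <- function(n, mean, sd, lower, upper) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
  }
  out
}

# Draw the patient covariate table for a vector of grades (indices 1-4).
.drawPatients <- function(gradeIdx, params, idPrefix = "P") {
  cv <- params$covariates
  n <- length(gradeIdx)
  data.frame(
    patient_id = sprintf("%s%03d", idPrefix, seq_len(n)),
    age = round(rtruncated(
      n, cv$age$mean[gradeIdx], cv$age$sd[gradeIdx],
      cv$age$min[gradeIdx], cv$age$max[gradeIdx]
    )),
    sex = ifelse(stats::runif(n) < cv$femalePct[gradeIdx], "female", "male"),
    diabetes_type = ifelse(stats::runif(n) < cv$type2Pct[gradeIdx], 2L, 1L),
    duration = round(rtruncated(
      n, cv$duration$mean[gradeIdx], cv$duration$sd[gradeIdx],
      cv$duration$min[gradeIdx], cv$duration$max[gradeIdx]
    )),
    hypertension = stats::runif(n) < cv$hypertensionPct[gradeIdx],
    high_cholesterol = stats::runif(n) < cv$cholesterolPct[gradeIdx],
    grade = params$grades[gradeIdx],
    stringsAsFactors = FALSE
  )
}

# Per-row covariate effect terms, centred within grade so configured
# grade means are the grade-conditional feature means.
.covariateTerms <- function(pat, gradeIdx, params) {
  eff <- params$covariateEffects
  cv <- params$covariates
  pick <- function(e, name, vtype) {
    (e[[name]] %||% 0) + (e[[paste0(name, ".", vtype)]] %||% 0)
  }
  terms <- list()
  for (vtype in c("arteriole", "venule")) {
    zero <- rep(0, nrow(pat))
    t0 <- list(widthsAll = zero, widthsLarge = zero, theta2 = zero)
    centred <- list(
      age = pat$age - cv$age$mean[gradeIdx],
      female = (pat$sex == "female") - cv$femalePct[gradeIdx],
      type2 = (pat$diabetes_type == 2L) - cv$type2Pct[gradeIdx],
      duration = pat$duration - cv$duration$mean[gradeIdx],
      hypertension = pat$hypertension - cv$hypertensionPct[gradeIdx],
      cholesterol = pat$high_cholesterol - cv$cholesterolPct[gradeIdx]
    )
    for (covName in names(eff)) {
      e <- eff[[covName]]
      if (!length(e)) next
      for (target in c("widthsAll", "widthsLarge", "theta2")) {
        b <- pick(e, target, vtype)
        if (b != 0) t0[[target]] <- t0[[target]] + b * centred[[covName]]
      }
    }
    terms[[vtype]] <- t0
  }
  terms
}

# Core feature simulator: given per-bifurcation grade index, vessel
# type, patient index and per-patient structures, draw one feature row
# each. meanShiftD2 is an optional per-bifurcation extra shift on the
# smaller-child width (used for progression arms).
.drawFeatureRows <- function(gradeIdx, vtype, patIdx, patientZ, covTerms,
                             params, meanShiftD2 = 0) {
  n <- length(gradeIdx)
  getMean <- function(f) {
    ifelse(vtype == "arteriole",
      params$means$arteriole[cbind(gradeIdx, match(f, colnames(params$means$arteriole)))],
      params$means$venule[cbind(gradeIdx, match(f, colnames(params$means$venule)))]
    )
  }
  getSd <- function(f) {
    ifelse(vtype == "arteriole",
      params$sds$arteriole[cbind(gradeIdx, match(f, colnames(params$sds$arteriole)))],
      params$sds$venule[cbind(gradeIdx, match(f, colnames(params$sds$venule)))]
    )
  }
  term <- function(which) {
    art <- covTerms$arteriole[[which]]
    ven <- covTerms$venule[[which]]
    ifelse(vtype == "arteriole", art[patIdx], ven[patIdx])
  }
  psd <- params$patientSd
  residSd <- function(f, base) {
    total <- getSd(f)
    sqrt(pmax(total^2 - psd[[base]]^2, 0))
  }

  # widths: smaller child + positive child and parent gaps, so the
  # ordering d0 >= d1 >= d2 holds by construction and the shared
  # components induce realistic width correlations
  m2 <- getMean("d2") + term("widthsAll") +
    patientZ$d2[patIdx] * psd[["d2"]] + meanShiftD2
  d2 <- pmax(rgammaMS(n, m2, residSd("d2", "d2")), 0.5)
  gap21 <- rgammaMS(
    n, getMean("d1") - getMean("d2") + term("widthsLarge"),
    sqrt(pmax(getSd("d1")^2 - getSd("d2")^2, 0))
  )
  gap10 <- rgammaMS(
    n, getMean("d0") - getMean("d1"),
    sqrt(pmax(getSd("d0")^2 - getSd("d1")^2, 0))
  )
  d1 <- d2 + gap21
  d0 <- d1 + gap10

  # angles: gamma marginals coupled through a Gaussian copula with the
  # negative correlation implied by the configured SD of theta
  s1 <- getSd("theta1")
  s2 <- getSd("theta2")
  sTheta <- ifelse(vtype == "arteriole",
    params$thetaSds$arteriole[gradeIdx], params$thetaSds$venule[gradeIdx]
  )
  rho <- pmin(pmax((sTheta^2 - s1^2 - s2^2) / (2 * s1 * s2), -0.9), 0)
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  theta1 <- qgammaMS(
    z1, getMean("theta1") + patientZ$theta1[patIdx] * psd[["theta1"]],
    residSd("theta1", "theta1")
  )
  theta2 <- qgammaMS(
    z2, getMean("theta2") + term("theta2") +
      patientZ$theta2[patIdx] * psd[["theta2"]],
    residSd("theta2", "theta2")
  )
  theta1 <- pmin(theta1, 180 - 1e-9)
  theta2 <- pmin(theta2, 180 - 1e-9)

  chi <- solveJunctionExponent(d0, d1, d2)
  ratios <- computeDerivedRatios(d0, d1, d2)
  data.frame(
    vessel_type = vtype,
    d0 = d0, d1 = d1, d2 = d2,
    theta1 = theta1, theta2 = theta2, theta = theta1 + theta2,
    chi = chi, jer = ratios$jer,
    asymmetry_ratio = ratios$asymmetryRatio,
    area_ratio = ratios$areaRatio,
    stringsAsFactors = FALSE
  )
}

#' Simulate a cross-sectional patient cohort
#'
#' Draws a hierarchical cohort: patients with demographic covariates per
#' retinopathy grade, then bifurcation-level geometry with grade means,
#' within-grade covariate effects, a shared patient random effect and a
#' residual scaled so the total bifurcation-level SD matches the
#' configured SD. Widths are generated as a smaller-child width plus
#' positive gaps so `d0 >= d1 >= d2` always holds; `theta` is the sum
#' of the generated branching angles; the junction exponent is computed
#' from the generated widths.
#'
#' @param params parameter list, see [defaultGenerativeParams()].
#' @param nPatients named or positional integer vector of patients per
#'   grade (defaults to `params$nPatients`).
#' @param seed integer seed; the same seed reproduces the cohort
#'   exactly.
#' @return An [RvgCohort-class].
#' @examples
#' cohort <- generateCohort(seed = 1)
#' cohort
#' @export
generateCohort <- function(params = defaultGenerativeParams(),
                           nPatients = NULL, seed = 1L) {
  nPatients <- nPatients %||% params$nPatients
  stopifnot(length(nPatients) == 4L, all(nPatients >= 1))
  if (any(params$patientSd^2 >
    vapply(c("d2", "theta1", "theta2"), function(f) {
      min(params$sds$arteriole[, f]^2, params$sds$venule[, f]^2)
    }, numeric(1)))) {
    stop("infeasible SD decomposition: patientSd exceeds a total feature SD")
  }
  withSeed(seed, {
    gradeIdx <- rep(seq_len(4L), times = nPatients)
    pat <- .drawPatients(gradeIdx, params)
    nPat <- nrow(pat)
    patientZ <- list(
      d2 = stats::rnorm(nPat), theta1 = stats::rnorm(nPat),
      theta2 = stats::rnorm(nPat)
    )
    covTerms <- .covariateTerms(pat, gradeIdx, params)
    nBif <- pmax(stats::rpois(nPat, params$bifurcationsPerImage), 1L)
    patIdx <- rep(seq_len(nPat), times = nBif)
    rowGrade <- gradeIdx[patIdx]
    vtype <- ifelse(
      stats::runif(length(patIdx)) < params$arterioleFraction[rowGrade],
      "arteriole", "venule"
    )
    rows <- .drawFeatureRows(rowGrade, vtype, patIdx, patientZ, covTerms, params)
    drMean <- stats::runif(
      nPat, params$distanceRatio$patientMeanRange[1],
      params$distanceRatio$patientMeanRange[2]
    )
    features <- cbind(
      data.frame(
        patient_id = pat$patient_id[patIdx],
        image_id = paste0("img_", pat$patient_id[patIdx]),
        bifurcation = unlist(lapply(nBif, seq_len)),
        stringsAsFactors = FALSE
      ),
      rows,
      data.frame(
        distance_ratio = rgammaMS(
          length(patIdx), drMean[patIdx], params$distanceRatio$sd
        ),
        usable = TRUE
      )
    )
    features <- features[, featureColumns()]
    pat$progressor <- NA
    pat$visit <- NA_character_
    new("RvgCohort",
      features = features, patients = pat,
      params = params, seed = as.integer(seed)
    )
  })
}

#' Simulate a longitudinal progression cohort
#'
#' Two arms of initially retinopathy-free diabetic patients followed
#' over three screening visits (baseline, penultimate, final).
#' Progressors have their baseline smaller-child width shifted downward
#' by `params$progression$baselineD2Shift` (narrower d2 at baseline
#' predicting progression) and present proliferative-grade geometry at
#' the final visit; non-progressors keep no-retinopathy geometry
#' throughout. Patient random effects persist across visits, inducing
#' within-patient correlation.
#'
#' @param params parameter list, see [defaultGenerativeParams()].
#' @param nPerArm patients per arm (progressors, non-progressors);
#'   defaults to `params$progression$nPerArm`.
#' @param bifurcationsPerImage mean bifurcations per visit image
#'   (defaults to `params$bifurcationsPerImage`).
#' @param seed integer seed.
#' @return An [RvgCohort-class]; features carry a `visit` column and
#'   patients a logical `progressor` column.
#' @export
generateProgressionCohort <- function(params = defaultGenerativeParams(),
                                      nPerArm = NULL,
                                      bifurcationsPerImage = NULL,
                                      seed = 1L) {
  nPerArm <- as.integer(nPerArm %||% params$progression$nPerArm)
  stopifnot(nPerArm >= 2)
  bpi <- bifurcationsPerImage %||% params$bifurcationsPerImage
  withSeed(seed, {
    nPat <- 2L * nPerArm
    progressor <- rep(c(TRUE, FALSE), each = nPerArm)
    gradeIdx <- rep(1L, nPat) # all grade-matched at baseline: NoDR
    pat <- .drawPatients(gradeIdx, params, idPrefix = "L")
    pat$age <- round(rtruncated(
      nPat, mean(params$progression$ageRange), 5,
      params$progression$ageRange[1], params$progression$ageRange[2]
    ))
    pat$progressor <- progressor
    pat$grade <- "NoDR"
    patientZ <- list(
      d2 = stats::rnorm(nPat), theta1 = stats::rnorm(nPat),
      theta2 = stats::rnorm(nPat)
    )
    covTerms <- .covariateTerms(pat, gradeIdx, params)
    visits <- c("baseline", "penultimate", "final")
    shift <- params$progression$baselineD2Shift
    pieces <- lapply(visits, function(v) {
      nBif <- pmax(stats::rpois(nPat, bpi), 1L)
      patIdx <- rep(seq_len(nPat), times = nBif)
      # final-visit progressors show proliferative-grade geometry
      rowGrade <- ifelse(v == "final" & progressor[patIdx], 4L, 1L)
      vtype <- ifelse(
        stats::runif(length(patIdx)) < params$arterioleFraction[rowGrade],
        "arteriole", "venule"
      )
      d2Shift <- ifelse(v == "baseline" & progressor[patIdx], shift, 0)
      rows <- .drawFeatureRows(
        rowGrade, vtype, patIdx, patientZ, covTerms, params,
        meanShiftD2 = d2Shift
      )
      drMean <- stats::runif(
        nPat, params$distanceRatio$patientMeanRange[1],
        params$distanceRatio$patientMeanRange[2]
      )
      cbind(
        data.frame(
          patient_id = pat$patient_id[patIdx],
          image_id = paste0("img_", pat$patient_id[patIdx], "_", v),
          bifurcation = unlist(lapply(nBif, seq_len)),
          stringsAsFactors = FALSE
        ),
        rows,
        data.frame(
          distance_ratio = rgammaMS(
            length(patIdx), drMean[patIdx], params$distanceRatio$sd
          ),
          usable = TRUE, visit = v
        )
      )
    })
    features <- do.call(rbind, pieces)
    features <- features[, c(featureColumns(), "visit")]
    pat$visit <- NA_character_
    pat$final_grade <- ifelse(progressor, "PDR", "NoDR")
    new("RvgCohort",
      features = features, patients = pat,
      params = params, seed = as.integer(seed)
    )
  })
}

#' Simulate repeated measurement sessions of one feature
#'
#' Re-measures a vector of true per-bifurcation values over several
#' sessions with additive Gaussian measurement noise whose SD is a
#' percentage (`cov`) of the grand mean — the generative counterpart of
#' the repeatability coefficient of variation computed by
#' [repeatabilityCoV()].
#'
#' @param values numeric vector of true per-bifurcation values.
#' @param nSessions number of measurement sessions (>= 2).
#' @param cov between-session coefficient of variation, percent.
#' @param seed integer seed.
#' @return data.frame with columns `bifurcation`, `session`, `value`.
#' @export
generateRepeatMeasurements <- function(values, nSessions = 3L, cov = 4.2,
                                       seed = 1L) {
  stopifnot(nSessions >= 2, all(is.finite(values)))
  withSeed(seed, {
    n <- length(values)
    sdNoise <- cov / 100 * mean(values)
    data.frame(
      bifurcation = rep(seq_len(n), times = nSessions),
      session = rep(seq_len(nSessions), each = n),
      value = rep(values, times = nSessions) +
        stats::rnorm(n * nSessions, 0, sdNoise)
    )
  })
}
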