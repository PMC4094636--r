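test_that("cohort generation is seed-deterministic", {
  a <- generateCohort(seed = 123)
  b <- generateCohort(seed = 123)
  expect_identical(features(a), features(b))
  expect_identical(patients(a), patients(b))
  c <- generateCohort(seed = 124)
  expect_false(identical(features(a), features(c)))
})

test_that("generated tables always satisfy the geometry invariants", {
  for (s in c(1, 9, 31)) {
    f <- features(generateCohort(nPatients = c(6, 6, 6, 6), seed = s))
    expect_true(all(f$d0 >= f$d1))
    expect_true(all(f$d1 >= f$d2))
    expect_true(all(f$d2 > 0))
    expect_equal(f$theta, f$theta1 + f$theta2, tolerance = 1e-12)
    expect_true(all(f$theta1 >= 0 & f$theta1 <= 180))
    expect_true(all(f$theta2 >= 0 & f$theta2 <= 180))
    expect_true(all(is.na(f$chi) | f$chi > 0))
    expect_true(all(f$distance_ratio >= 0))
    # chi is computed from widths, not drawn: solver agreement
    i <- which(!is.na(f$chi))[1:20]
    expect_equal(
      f$chi[i], solveJunctionExponent(f$d0[i], f$d1[i], f$d2[i]),
      tolerance = 1e-9
    )
  }
})

test_that("zero-SD parameters collapse every draw to its group mean structure", {
  p <- defaultGenerativeParams()
  p$sds$arteriole[] <- 0
  p$sds$venule[] <- 0
  p$thetaSds$arteriole[] <- 0
  p$thetaSds$venule[] <- 0
  p$patientSd[] <- 0
  p$covariateEffects <- lapply(p$covariateEffects, function(e) list())
  co <- generateCohort(p, nPatients = c(3, 3, 3, 3), seed = 1)
  f <- features(co)
  pats <- patients(co)
  g <- pats$grade[match(f$patient_id, pats$patient_id)]
  art <- f$vessel_type == "arteriole" & g == "NoDR"
  if (any(art)) {
    expect_true(all(abs(f$d2[art] - 4.60) < 1e-9))
    expect_true(all(abs(f$d0[art] - 6.47) < 1e-9))
    expect_true(all(abs(f$theta2[art] - 50.36) < 1e-9))
  }
  ven <- f$vessel_type == "venule" & g == "PDR"
  if (any(ven)) {
    expect_true(all(abs(f$d0[ven] - 9.55) < 1e-9))
  }
})

test_that("large cohorts recover the configured grade means within 2 SE", {
  p <- defaultGenerativeParams()
  co <- generateCohort(p, nPatients = c(70, 70, 70, 70), seed = 8)
  f <- features(co)
  pats <- patients(co)
  g <- pats$grade[match(f$patient_id, pats$patient_id)]
  # pooled (both vessel types) expectations from the per-type means and
  # the configured arteriole fraction
  for (gi in seq_along(p$grades)) {
    gr <- p$grades[gi]
    frac <- p$arterioleFraction[[gi]]
    rows <- g == gr
    n <- sum(rows)
    for (feat in c("d0", "d1", "d2", "theta1", "theta2")) {
      target <- frac * p$means$arteriole[gr, feat] +
        (1 - frac) * p$means$venule[gr, feat]
      sdPool <- max(p$sds$arteriole[gr, feat], p$sds$venule[gr, feat])
      got <- mean(f[[feat]][rows])
      expect_lt(
        abs(got - target), 2 * sdPool / sqrt(n) + 0.02 * target,
        label = sprintf("%s mean for %s (got %.3f, target %.3f)", feat, gr, got, target)
      )
    }
  }
})

test_that("an infeasible SD decomposition errors", {
  p <- defaultGenerativeParams()
  p$patientSd["d2"] <- 5
  expect_error(generateCohort(p, seed = 1), "infeasible SD decomposition")
})

test_that("progression cohorts have three visits, arms, and a baseline d2 deficit", {
  co <- generateProgressionCohort(nPerArm = 40, seed = 3)
  f <- features(co)
  p <- patients(co)
  expect_setequal(unique(f$visit), c("baseline", "penultimate", "final"))
  expect_equal(sum(p$progressor), 40)
  base <- f[f$visit == "baseline", ]
  prog <- p$progressor[match(base$patient_id, p$patient_id)]
  shift <- defaultGenerativeParams()$progression$baselineD2Shift
  expect_lt(
    mean(base$d2[prog]) - mean(base$d2[!prog]),
    shift / 2 # clearly negative, at least half the configured deficit
  )
  expect_identical(
    features(generateProgressionCohort(nPerArm = 40, seed = 3)), f
  )
  # final-visit progressors are labeled proliferative
  expect_true(all(p$final_grade[p$progressor] == "PDR"))
})

test_that("a null progression shift gives an odds ratio near 1", {
  p <- nullGenerativeParams()
  co <- generateProgressionCohort(p, nPerArm = 150, bifurcationsPerImage = 1, seed = 21)
  fit <- fitProgressionLogistic(features(co), patients(co), "d2")
  # null slope: a 3-SE band holds with ~99.7% probability
  expect_lt(abs(fit$coefficient), 3 * fit$se)
  expect_true(fit$ci95[1] <= exp(fit$se) && exp(-fit$se) <= fit$ci95[2])
})

test_that("the progression shift maps to the intended logistic coefficient", {
  # designed recovery run: no patient effects, one bifurcation per
  # patient, shift chosen for a log-odds slope of -0.3 per pixel
  p <- nullGenerativeParams()
  sigma2 <- 0.483 * 0.99^2 + 0.517 * 1.08^2 +
    0.483 * 0.517 * (4.72 - 4.60)^2 # mixture variance of d2 at baseline
  p$progression$baselineD2Shift <- -0.3 * sigma2
  co <- generateProgressionCohort(p, nPerArm = 250, bifurcationsPerImage = 1, seed = 77)
  fit <- fitProgressionLogistic(features(co), patients(co), "d2")
  expect_lt(abs(fit$coefficient - (-0.3)), 2 * fit$se)
  expect_equal(fit$oddsRatio, exp(fit$coefficient))
})

test_that("repeat-measurement simulation round-trips the configured CoV", {
  withr::local_seed(5)
  truth <- stats::runif(117, 5, 10)
  m <- generateRepeatMeasurements(truth, nSessions = 3, cov = 4.2, seed = 9)
  r <- repeatabilityCoV(m)
  expect_equal(r$cov, 4.2, tolerance = 0.6)
  expect_identical(
    generateRepeatMeasurements(truth, nSessions = 3, cov = 4.2, seed = 9), m
  )
})

test_that("width-by-grade ANOVA has high power at scaled group sizes and nominal size under the null", {
  sig <- vapply(1:30, function(s) {
    co <- generateCohort(nPatients = c(40, 40, 48, 76), seed = 1000 + s)
    f <- features(co)
    p <- patients(co)
    g <- p$grade[match(f$patient_id, p$patient_id)]
    oneWayAnova(f$d0, g)$p <= 0.05
  }, logical(1))
  expect_gt(mean(sig), 0.9)

  nullP <- nullGenerativeParams()
  rej <- vapply(1:60, function(s) {
    co <- generateCohort(nullP, seed = 2000 + s)
    f <- features(co)
    p <- patients(co)
    g <- p$grade[match(f$patient_id, p$patient_id)]
    oneWayAnova(f$d0, g)$p <= 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.18) # coarse gate; the calibrated rate is in acceptance
})
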