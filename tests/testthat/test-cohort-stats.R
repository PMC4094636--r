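test_that("one-way ANOVA matches hand-computed sums of squares", {
  # groups {1,2,3}, {2,3,4}, {3,4,5}: SSB = 6, SSW = 6, F = 3
  v <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  g <- rep(c("a", "b", "c"), each = 3)
  an <- oneWayAnova(v, g)
  expect_equal(an$ssBetween, 6)
  expect_equal(an$ssWithin, 6)
  expect_equal(an$F, 3)
  expect_equal(an$dfBetween, 2)
  expect_equal(an$dfWithin, 6)
  expect_equal(an$p, stats::pf(3, 2, 6, lower.tail = FALSE))
  expect_equal(an$ssTotal, an$ssBetween + an$ssWithin, tolerance = 1e-9)
})

test_that("two-group ANOVA F equals the squared pooled-variance t statistic", {
  withr::local_seed(3)
  x <- stats::rnorm(12, 5)
  y <- stats::rnorm(9, 6)
  an <- oneWayAnova(c(x, y), rep(c("x", "y"), c(12, 9)))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(an$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(an$p, tt$p.value, tolerance = 1e-9)
})

test_that("constant data gives F = 0 and p = 1; tiny groups error", {
  an <- oneWayAnova(rep(4, 8), rep(c("a", "b"), 4))
  expect_equal(an$F, 0)
  expect_equal(an$p, 1)
  expect_error(oneWayAnova(1:5, rep("a", 5)), "at least 2 groups")
  expect_error(oneWayAnova(c(1, 2), c("a", "b")), "residual degree")
})

test_that("SS decomposition holds on random data to 1e-9 relative", {
  withr::local_seed(21)
  for (i in 1:10) {
    v <- stats::rnorm(60, sd = stats::runif(1, 0.5, 10))
    g <- sample(letters[1:4], 60, replace = TRUE)
    an <- oneWayAnova(v, g)
    total <- sum((v - mean(v))^2)
    expect_equal(an$ssBetween + an$ssWithin, total, tolerance = 1e-9)
  }
})

test_that("FLSD with two groups reproduces the pooled t-test exactly", {
  withr::local_seed(9)
  v <- c(stats::rnorm(10, 5), stats::rnorm(14, 6.2))
  g <- rep(c("a", "b"), c(10, 14))
  an <- oneWayAnova(v, g)
  ph <- flsdPosthoc(v, g, anova = an)
  tt <- stats::t.test(v[g == "a"], v[g == "b"], var.equal = TRUE)
  expect_equal(ph$pairwise$p, tt$p.value, tolerance = 1e-12)
  expect_equal(ph$pairwise$p, an$p, tolerance = 1e-12)
})

test_that("the protection gate marks all pairs non-significant when the omnibus fails", {
  withr::local_seed(13)
  # three groups, one pair would be 'significant' unprotected but the
  # omnibus p stays above alpha
  repeat {
    v <- stats::rnorm(30)
    g <- rep(c("a", "b", "c"), each = 10)
    an <- oneWayAnova(v, g)
    ph <- flsdPosthoc(v, g, anova = an)
    if (an$p > 0.05 && any(ph$pairwise$p <= 0.05)) break
  }
  expect_false(ph$protected)
  expect_false(any(ph$pairwise$significant))
})

test_that("FLSD pairwise p-values match pairwise.t.test with pooled SD", {
  withr::local_seed(31)
  v <- c(stats::rnorm(12, 5), stats::rnorm(15, 5.5), stats::rnorm(11, 7))
  g <- rep(c("a", "b", "c"), c(12, 15, 11))
  ph <- flsdPosthoc(v, g)
  ref <- stats::pairwise.t.test(v, g, p.adjust.method = "none", pool.sd = TRUE)
  expect_equal(
    ph$pairwise$p[ph$pairwise$group1 == "a" & ph$pairwise$group2 == "b"],
    ref$p.value["b", "a"],
    tolerance = 1e-12
  )
  expect_equal(
    ph$pairwise$p[ph$pairwise$group1 == "b" & ph$pairwise$group2 == "c"],
    ref$p.value["c", "b"],
    tolerance = 1e-12
  )
  # an outlying group mean earns its own homogeneous-subset letter
  expect_false(ph$letters[["c"]] %in% c(ph$letters[["a"]], ph$letters[["b"]]))
  expect_true(nchar(ph$letters[["c"]]) >= 1)
})

test_that("risk-factor models recover a planted age effect within 2 SE", {
  co <- generateCohort(plantedAgeParams(), nPatients = c(20, 20, 20, 20), seed = 5)
  fit <- fitRiskFactorModels(features(co), patients(co), "d0", modelId = 1)
  row <- fit$coefficients[fit$coefficients$term == "age", ]
  expect_lt(abs(row$estimate - (-0.05)), 2 * row$se)
  expect_match(fit$coding, "female=1")
})

test_that("nested model covariates grow from model 1 to model 3", {
  co <- generateCohort(nPatients = c(5, 5, 5, 5), seed = 2)
  terms <- lapply(1:3, function(m) {
    fitRiskFactorModels(features(co), patients(co), "d0", modelId = m)$coefficients$term
  })
  expect_true(all(terms[[1]] %in% terms[[2]]))
  expect_true(all(terms[[2]] %in% terms[[3]]))
  expect_setequal(
    terms[[3]],
    c("(Intercept)", "age", "sexF", "type2", "htn", "duration", "chol")
  )
})

test_that("a constant covariate triggers a rank-deficiency error naming it", {
  co <- generateCohort(nPatients = c(5, 5, 5, 5), seed = 4)
  p <- patients(co)
  p$duration <- 120
  expect_error(
    fitRiskFactorModels(features(co), p, "d0", modelId = 3),
    "rank-deficient.*duration"
  )
})

test_that("logistic odds ratio on a 2x2 table equals the ad/bc closed form", {
  # counts: exposed (x=1): 10 progressors, 5 non; unexposed: 5 / 10
  feat <- data.frame(
    patient_id = sprintf("Q%02d", 1:30),
    d2 = rep(c(1, 1, 0, 0), c(10, 5, 5, 10)),
    vessel_type = "arteriole", usable = TRUE
  )
  pats <- data.frame(
    patient_id = sprintf("Q%02d", 1:30),
    progressor = rep(c(TRUE, FALSE, TRUE, FALSE), c(10, 5, 5, 10))
  )
  fit <- fitProgressionLogistic(feat, pats, "d2")
  expect_equal(fit$oddsRatio, (10 * 10) / (5 * 5), tolerance = 1e-6)
  expect_equal(fit$oddsRatio, exp(fit$coefficient))
  expect_true(fit$ci95[1] <= fit$oddsRatio && fit$oddsRatio <= fit$ci95[2])
})

test_that("complete separation falls back to a flagged ridge fit", {
  feat <- data.frame(
    patient_id = sprintf("R%02d", 1:20),
    d2 = c(seq(1, 2, length.out = 10), seq(5, 6, length.out = 10)),
    vessel_type = "arteriole", usable = TRUE
  )
  pats <- data.frame(
    patient_id = sprintf("R%02d", 1:20),
    progressor = rep(c(FALSE, TRUE), each = 10)
  )
  fit <- fitProgressionLogistic(feat, pats, "d2")
  expect_true(fit$penalized)
  expect_true(is.finite(fit$coefficient))
  expect_gt(fit$oddsRatio, 1)
})

test_that("OLS and logistic fits agree with brute-force grid optimisation", {
  withr::local_seed(55)
  x <- stats::runif(80, -2, 2)
  yOls <- 1.2 + 0.7 * x + stats::rnorm(80, sd = 0.4)
  fitOls <- stats::lm(yOls ~ x)
  gOls <- gridFit2(x, yOls, "ols", aRange = c(0.8, 1.6), bRange = c(0.3, 1.1))
  expect_lt(abs(unname(stats::coef(fitOls)[2]) - gOls[["b"]]), 0.011)
  expect_lt(abs(unname(stats::coef(fitOls)[1]) - gOls[["a"]]), 0.011)

  yLog <- stats::rbinom(80, 1, stats::plogis(-0.4 + 1.1 * x))
  feat <- data.frame(
    patient_id = sprintf("G%03d", 1:80), d2 = x,
    vessel_type = "arteriole", usable = TRUE
  )
  pats <- data.frame(patient_id = sprintf("G%03d", 1:80), progressor = yLog == 1)
  fitLog <- fitProgressionLogistic(feat, pats, "d2")
  gLog <- gridFit2(x, yLog, "logistic",
    aRange = c(fitLog$coefficient * 0 - 1.5, 1),
    bRange = c(0, 2.5)
  )
  expect_lt(abs(fitLog$coefficient - gLog[["b"]]), 0.011)
})

test_that("repeatability CoV matches hand arithmetic and is scale invariant", {
  m <- data.frame(
    bifurcation = rep(1:3, each = 3),
    session = rep(1:3, times = 3),
    value = c(10, 11, 12, 20, 19, 21, 30, 31, 29)
  )
  r <- repeatabilityCoV(m)
  # within-group SS = 2 + 2 + 2 = 6 over df 6: MSE = 1, within-SD = 1;
  # grand mean 61/3
  expect_equal(r$withinSd, 1, tolerance = 1e-12)
  expect_equal(r$cov, 100 / (61 / 3), tolerance = 1e-12)
  m2 <- m
  m2$value <- m$value * 7
  expect_equal(repeatabilityCoV(m2)$cov, r$cov, tolerance = 1e-12)
  # identical sessions: zero CoV
  m3 <- m
  m3$value <- rep(c(10, 20, 30), each = 3)
  expect_equal(repeatabilityCoV(m3)$cov, 0)
})

test_that("single-session bifurcations are excluded with a warning", {
  m <- data.frame(
    bifurcation = c(1, 1, 2),
    session = c(1, 2, 1),
    value = c(5, 6, 9)
  )
  expect_warning(r <- repeatabilityCoV(m), "single session")
  expect_equal(r$nBifurcations, 1)
  expect_equal(r$nExcluded, 1)
})

test_that("group summaries use bifurcation rows and partition by stratum", {
  co <- generateCohort(nPatients = c(4, 4, 4, 4), seed = 6)
  f <- features(co)
  p <- patients(co)
  sAll <- summarizeGroups(f, p, featureNames = "d0")
  sArt <- summarizeGroups(f, p, stratum = "arteriole", featureNames = "d0")
  sVen <- summarizeGroups(f, p, stratum = "venule", featureNames = "d0")
  for (g in unique(sAll$grade)) {
    nA <- sAll$n[sAll$grade == g]
    expect_equal(
      nA,
      sum(sArt$n[sArt$grade == g], sVen$n[sVen$grade == g])
    )
  }
  # single-row group: mean equals the value, SD 0
  one <- summarizeGroups(
    data.frame(
      patient_id = "Z1", image_id = "z", vessel_type = "arteriole",
      d0 = 7.5, usable = TRUE
    ),
    data.frame(patient_id = "Z1", grade = "NoDR"),
    featureNames = "d0"
  )
  expect_equal(one$mean, 7.5)
  expect_equal(one$sd, 0)
})
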