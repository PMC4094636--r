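test_that("distance-ratio matching follows the stated hand trace", {
  df <- data.frame(
    patient_id = rep(c("ref", "oth"), c(3, 3)),
    distance_ratio = c(1, 2, 3, 1.5, 2, 4)
  )
  m <- matchDistanceRatio(df)
  expect_equal(m$referencePatient, "ref") # mean 2 < 2.5
  expect_equal(m$referenceMean, 2)
  kept <- m$kept[m$kept$patient_id == "oth", ]
  expect_equal(sort(kept$distance_ratio), c(1.5, 2))
  expect_equal(mean(kept$distance_ratio), 1.75)
  expect_equal(nrow(m$discarded), 1)
  expect_equal(m$discarded$distance_ratio, 4)
})

test_that("patients already below the reference keep everything", {
  df <- data.frame(
    patient_id = rep(c("a", "b"), c(3, 3)),
    distance_ratio = c(2, 2.5, 3, 1, 1.2, 1.4)
  )
  m <- matchDistanceRatio(df)
  expect_equal(m$referencePatient, "b")
  expect_equal(m$summary$n_discarded[m$summary$patient_id == "b"], 0)
  expect_gt(m$summary$n_discarded[m$summary$patient_id == "a"], 0)
})

test_that("matching post-conditions hold on random patient sets", {
  for (s in 1:40) {
    df <- randomPatientSets(s)
    m <- matchDistanceRatio(df)
    ref <- m$referenceMean
    for (pid in unique(df$patient_id)) {
      keptV <- m$kept$distance_ratio[m$kept$patient_id == pid]
      if (pid == m$referencePatient) {
        expect_equal(mean(keptV), ref)
        next
      }
      if (pid %in% m$unmatchable) {
        expect_equal(length(keptV), 1L)
        expect_gte(mean(keptV), ref)
      } else {
        expect_lt(mean(keptV), ref)
        dropped <- m$discarded$distance_ratio[m$discarded$patient_id == pid]
        if (length(dropped)) {
          # restoring the last discarded row brings the mean back >= ref
          expect_gte(mean(c(keptV, dropped[length(dropped)])), ref)
        }
      }
      # row conservation per patient
      nDropped <- if (is.null(m$discarded)) 0L else sum(m$discarded$patient_id == pid)
      expect_equal(length(keptV) + nDropped, sum(df$patient_id == pid))
    }
  }
})

test_that("ties among removal candidates drop the later-indexed row", {
  df <- data.frame(
    patient_id = c("a", "a", "b", "b", "b"),
    distance_ratio = c(1, 1.2, 3, 3, 1),
    mark = c("", "", "first", "second", "")
  )
  m <- matchDistanceRatio(df)
  expect_equal(m$discarded$mark[1], "second")
})

test_that("empty input errors", {
  expect_error(matchDistanceRatio(data.frame()), "empty")
})

test_that("profiles average the kept rows, pooling vessel types", {
  kept <- data.frame(
    patient_id = c("a", "a", "a"),
    d0 = c(6, 8, 10), theta2 = c(40, 50, 60),
    distance_ratio = c(1, 2, 3),
    vessel_type = c("arteriole", "venule", "arteriole")
  )
  pr <- buildPatientProfiles(kept)
  expect_equal(pr$mean_d0, 8)
  expect_equal(pr$mean_theta2, 50)
  expect_equal(pr$n_kept, 3L)
  one <- buildPatientProfiles(kept[1, ])
  expect_equal(one$mean_d0, 6)
  # weighted-mean identity across images
  expect_equal(
    pr$mean_d0,
    stats::weighted.mean(c(mean(c(6, 8)), 10), c(2, 1))
  )
})

test_that("perfect separation yields 100/100 and constant predictors fall to the majority class", {
  pr <- separatedProfiles()
  pats <- separatedPatients()
  res <- looClassify(pr, pats, model = "one")
  expect_equal(res$sensitivity, 100)
  expect_equal(res$specificity, 100)
  # constant predictor: every prediction is the training-fold majority
  prC <- pr
  prC$mean_d0 <- 7
  prC$mean_theta2 <- 50
  resC <- looClassify(prC, pats, model = "one")
  expect_true(all(resC$predictions$predicted == 1)) # majority is positive
  expect_equal(resC$sensitivity, 100)
  expect_equal(resC$specificity, 0)
})

test_that("leave-one-out folds are strict: perturbing the held-out patient leaves fold coefficients identical", {
  withr::local_seed(77)
  pr <- separatedProfiles()
  pr$mean_d0 <- pr$mean_d0 + stats::rnorm(nrow(pr), sd = 1.5) # overlap
  pats <- separatedPatients()
  r1 <- looClassify(pr, pats, model = "one")
  i <- 4
  pr2 <- pr
  pr2$mean_d0[i] <- pr2$mean_d0[i] + 50
  pr2$mean_theta2[i] <- pr2$mean_theta2[i] - 30
  r2 <- looClassify(pr2, pats, model = "one")
  cols <- c("(Intercept)", "mean_d0", "mean_theta2")
  expect_identical(
    r1$predictions[i, cols],
    r2$predictions[i, cols]
  )
  # the held-out probability is recomputed from the unchanged fold
  # coefficients applied to the perturbed feature vector
  coefI <- unlist(r2$predictions[i, cols])
  expect_equal(
    r2$predictions$probability[i],
    stats::plogis(sum(coefI * c(1, pr2$mean_d0[i], pr2$mean_theta2[i]))),
    tolerance = 1e-12
  )
  # other folds do change (they train on patient i)
  expect_false(identical(r1$predictions[-i, cols], r2$predictions[-i, cols]))
})

test_that("model two uses the parent diameter only and can score no-retinopathy patients", {
  withr::local_seed(12)
  n <- 24
  pr <- data.frame(
    patient_id = sprintf("T%02d", 1:n),
    mean_d0 = c(seq(6, 7, length.out = 8), seq(8, 9, length.out = 8), seq(10, 11, length.out = 8)),
    mean_theta2 = stats::runif(n, 45, 60),
    mean_distance_ratio = 2.5, n_kept = 10, n_discarded = 0, unmatchable = FALSE
  )
  pats <- data.frame(
    patient_id = pr$patient_id,
    grade = rep(c("NoDR", "SevereNPDR", "PDR"), each = 8)
  )
  res <- looClassify(pr, pats, model = "two", scoreNoDR = TRUE)
  expect_equal(res$predictors, "mean_d0")
  expect_equal(nrow(res$predictions), 16) # retinopathy cases only
  expect_equal(res$noDRTotal, 8)
  expect_equal(res$sensitivity, 100)
  expect_equal(res$specificity, 100)
  expect_equal(res$overallSpecificity, 100)
})

test_that("permuted labels give chance-level performance", {
  co <- generateCohort(seed = 303)
  f <- features(co)
  p <- patients(co)
  matching <- matchDistanceRatio(f)
  pr <- buildPatientProfiles(matching)
  withr::local_seed(404)
  bal <- vapply(1:40, function(i) {
    p2 <- p
    p2$grade <- sample(p2$grade)
    r <- tryCatch(looClassify(pr, p2, model = "one"),
      warning = function(w) suppressWarnings(looClassify(pr, p2, model = "one"))
    )
    (r$sensitivity + r$specificity) / 2
  }, numeric(1))
  expect_lt(abs(mean(bal) - 50), 8)
})

test_that("classifyGrades wires matching into classification", {
  co <- generateCohort(seed = 17)
  res <- classifyGrades(features(co), patients(co), model = "one")
  expect_s3_class(res$matching$summary, "data.frame")
  expect_true(res$sensitivity > 50) # grade effects present
  expect_equal(nrow(res$predictions), nrow(patients(co)))
})
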