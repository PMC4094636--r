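test_that("rendered noiseless scenes round-trip through measurement", {
  for (s in c(3, 17, 42)) {
    sc <- renderBifurcationImage(randomSceneSpec(s))
    m <- measureBifurcation(sc$image, sc$annotation, sc$onh)
    expect_true(m@usable)
    expect_lt(max(abs(c(
      m@d0 - sc$truth@d0, m@d1 - sc$truth@d1, m@d2 - sc$truth@d2
    ))), 0.5)
    expect_lt(max(abs(c(
      m@theta1 - sc$truth@theta1, m@theta2 - sc$truth@theta2
    ))), 1)
    expect_equal(m@theta, m@theta1 + m@theta2)
    expect_equal(m@distanceRatio, sc$truth@distanceRatio)
  }
})

test_that("rendering is deterministic in the seed, including noise", {
  sp <- sceneSpec(noiseSd = 0.05, seed = 99L)
  a <- renderBifurcationImage(sp)
  b <- renderBifurcationImage(sp)
  expect_identical(a$image, b$image)
  sp2 <- sceneSpec(noiseSd = 0.05, seed = 100L)
  expect_false(identical(renderBifurcationImage(sp2)$image, a$image))
})

test_that("moderate noise leaves width estimates unbiased", {
  # noise SD at 10% of the vessel-background contrast
  errs <- vapply(1:100, function(s) {
    sp <- sceneSpec(noiseSd = 0.06, seed = as.integer(s))
    sc <- renderBifurcationImage(sp)
    m <- measureBifurcation(sc$image, sc$annotation, sc$onh)
    m@d0 - sc$truth@d0
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.5)
})

test_that("scene rotation leaves measured widths unchanged", {
  base <- sceneSpec(directions = c(170, 30, -45), trueWidths = c(9, 7, 5.5))
  m0 <- measureBifurcation(
    renderBifurcationImage(base)$image,
    renderBifurcationImage(base)$annotation, base@onh
  )
  for (rot in c(38, 115)) {
    sp <- sceneSpec(
      directions = c(170, 30, -45) + rot,
      trueWidths = c(9, 7, 5.5)
    )
    sc <- renderBifurcationImage(sp)
    m <- measureBifurcation(sc$image, sc$annotation, sc$onh)
    expect_lt(abs(m@d0 - m0@d0), 0.5)
    expect_lt(abs(m@d1 - m0@d1), 0.5)
    expect_lt(abs(m@d2 - m0@d2), 0.5)
    # angles are rotation invariant by construction
    expect_equal(m@theta, m0@theta, tolerance = 1e-6)
  }
})

test_that("perturbing annotation endpoints by under a pixel barely moves widths", {
  sp <- randomSceneSpec(8)
  sc <- renderBifurcationImage(sp)
  m0 <- measureBifurcation(sc$image, sc$annotation, sc$onh)
  withr::local_seed(5)
  ann <- sc$annotation
  jitter <- function(p) p + stats::runif(2, -0.5, 0.5)
  ann2 <- bifurcationAnnotation(
    apex = jitter(ann@apex), parentEnd = jitter(ann@parentEnd),
    childAEnd = jitter(ann@childAEnd), childBEnd = jitter(ann@childBEnd),
    seeds = ann@seeds, vesselType = ann@vesselType, imageId = ann@imageId
  )
  m1 <- measureBifurcation(sc$image, ann2, sc$onh)
  expect_lt(abs(m1@d0 - m0@d0), 0.5)
  expect_lt(abs(m1@d1 - m0@d1), 0.5)
  expect_lt(abs(m1@d2 - m0@d2), 0.5)
})

test_that("a failed segment flags the record unusable instead of aborting", {
  sc <- renderBifurcationImage(sceneSpec())
  ann <- sc$annotation
  # point the parent seed at empty background: flat profile
  badSeeds <- ann@seeds
  badSeeds[[1]] <- rectangleSeed(c(15, 110), axisAngle = 0, length = 10, initialWidth = 6)
  annBad <- bifurcationAnnotation(
    apex = ann@apex, parentEnd = ann@parentEnd,
    childAEnd = ann@childAEnd, childBEnd = ann@childBEnd,
    seeds = badSeeds, vesselType = ann@vesselType, imageId = ann@imageId
  )
  m <- measureBifurcation(sc$image, annBad, sc$onh)
  expect_false(m@usable)
  expect_match(paste(m@flags, collapse = ";"), "segment_parent")
  # unusable rows are excluded from summaries
  row <- geometryAsRow(m, "P1", "img1")
  good <- geometryAsRow(measureBifurcation(sc$image, ann, sc$onh), "P1", "img1", 2L)
  tab <- rbind(row, good)
  pats <- data.frame(patient_id = "P1", grade = "NoDR")
  s <- summarizeGroups(tab, pats, featureNames = "d0")
  expect_equal(s$n, 1)
})

test_that("measureImage returns one row per annotation with identifiers", {
  sc <- renderBifurcationImage(sceneSpec())
  tab <- measureImage(sc$image, list(sc$annotation, sc$annotation), sc$onh,
    patientId = "P9", imageId = "imgA"
  )
  expect_equal(nrow(tab), 2)
  expect_equal(tab$bifurcation, 1:2)
  expect_setequal(setdiff(featureColumns(), names(tab)), character())
})

test_that("scenes exceeding the image bounds are rejected", {
  expect_error(
    renderBifurcationImage(sceneSpec(lengths = c(200, 45, 45))),
    "exceeds image bounds"
  )
})
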