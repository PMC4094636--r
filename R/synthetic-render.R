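#' Render a synthetic bifurcation image with exact ground truth
#'
#' Draws three straight vessel segments radiating from an apex onto a
#' uniform background, each with the requested cross-sectional profile
#' evaluated from the exact distance of every pixel to the segment
#' centreline (one-pixel linear anti-aliasing ramp for the box profile;
#' the gaussian profile's `trueWidth` is its full width at half
#' maximum). Additive Gaussian noise is seeded from the spec, so equal
#' specs render byte-identical images. Alongside the image the function
#' emits a [BifurcationAnnotation-class] whose rectangle seeds sit on
#' the true centrelines (clear of the junction core) and the
#' ground-truth [BifurcationGeometry-class] computed analytically from
#' the spec.
#'
#' @param spec a [SceneSpec-class].
#' @param vesselType vessel type recorded in the annotation.
#' @param imageId identifier recorded in the annotation.
#' @return A list with `image` (numeric matrix), `annotation`, `truth`
#'   (a `BifurcationGeometry`), and `onh`.
#' @examples
#' sc <- renderBifurcationImage(sceneSpec(trueWidths = c(8, 6, 5)))
#' m <- measureBifurcation(sc$image, sc$annotation, sc$onh)
#' abs(m@d0 - sc$truth@d0) < 0.5
#' @export
renderBifurcationImage <- function(spec, vesselType = "arteriole",
                                   imageId = "synthetic") {
  stopifnot(is(spec, "SceneSpec"))
  w <- spec@imageSize[1]
  h <- spec@imageSize[2]
  apex <- spec@apex
  dirs <- lapply(spec@directions, unitVector)
  ends <- lapply(1:3, function(i) apex + spec@lengths[i] * dirs[[i]])

  margin <- max(spec@trueWidths) + 2
  for (e in ends) {
    if (e[1] < margin || e[1] > w - 1 - margin ||
      e[2] < margin || e[2] > h - 1 - margin) {
      stop("scene geometry exceeds image bounds")
    }
  }

  xs <- rep(0:(w - 1), each = h)
  ys <- rep(0:(h - 1), times = w)
  coverage <- numeric(w * h)
  for (i in 1:3) {
    d <- .pointSegmentDistance(xs, ys, apex, ends[[i]])
    ci <- if (spec@profile == "box") {
      pmin(pmax(spec@trueWidths[i] / 2 + 0.5 - d, 0), 1)
    } else {
      sigma <- spec@trueWidths[i] / (2 * sqrt(2 * log(2)))
      exp(-d^2 / (2 * sigma^2))
    }
    coverage <- pmax(coverage, ci)
  }
  img <- spec@background - (spec@background - spec@vesselLevel) * coverage
  if (spec@noiseSd > 0) {
    img <- img + withSeed(spec@seed, stats::rnorm(w * h, 0, spec@noiseSd))
  }
  image <- matrix(img, nrow = h, ncol = w) # filled column-major: [y+1, x+1]

  # Seeds centred at 65% of each segment, spanning 40% of its length,
  # keeping the profile stations clear of the junction core.
  seeds <- lapply(1:3, function(i) {
    rectangleSeed(
      center = apex + 0.65 * spec@lengths[i] * dirs[[i]],
      axisAngle = spec@directions[i],
      length = 0.4 * spec@lengths[i],
      initialWidth = spec@trueWidths[i]
    )
  })
  annotation <- bifurcationAnnotation(
    apex = apex, parentEnd = ends[[1]],
    childAEnd = ends[[2]], childBEnd = ends[[3]],
    seeds = seeds, vesselType = vesselType, imageId = imageId
  )

  angles <- computeBranchAngles(apex, ends[[1]], ends[[2]], ends[[3]])
  roles <- assignChildRoles(
    spec@trueWidths[2], angles$angleA,
    spec@trueWidths[3], angles$angleB
  )
  d0 <- spec@trueWidths[1]
  chi <- if (d0 > roles$d1) solveJunctionExponent(d0, roles$d1, roles$d2) else NA_real_
  ratios <- computeDerivedRatios(d0, roles$d1, roles$d2)
  truth <- new("BifurcationGeometry",
    d0 = d0, d1 = roles$d1, d2 = roles$d2,
    theta1 = roles$theta1, theta2 = roles$theta2,
    theta = roles$theta1 + roles$theta2,
    chi = as.numeric(chi), jer = ratios$jer,
    asymmetryRatio = ratios$asymmetryRatio, areaRatio = ratios$areaRatio,
    distanceRatio = onhDistanceRatio(apex, spec@onh),
    vesselType = vesselType, usable = TRUE,
    flags = if (is.na(chi)) "chi_undefined" else character()
  )
  list(image = image, annotation = annotation, truth = truth, onh = spec@onh)
}

# Distance from points (x, y) to the segment a--b (vectorised).
.pointSegmentDistance <- function(x, y, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- ((x - a[1]) * ab[1] + (y - a[2]) * ab[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  px <- a[1] + t * ab[1]
  py <- a[2] + t * ab[2]
  sqrt((x - px)^2 + (y - py)^2)
}

#' Draw a random valid bifurcation scene
#'
#' Convenience sampler used by round-trip validation: widths are drawn
#' uniformly with `d0 > d1 >= d2`, child directions are separated from
#' the extrapolated parent direction by the requested angle range, and
#' segment lengths are chosen to fit the image.
#'
#' @param seed RNG seed.
#' @param widthRange range of segment widths in pixels.
#' @param angleRange range of child deflection angles in degrees.
#' @param imageSize image side length in pixels.
#' @param noiseSd additive noise SD.
#' @param profile cross-section profile.
#' @return A [SceneSpec-class].
#' @export
randomSceneSpec <- function(seed, widthRange = c(3, 15),
                            angleRange = c(20, 120),
                            imageSize = 160L, noiseSd = 0,
                            profile = "box") {
  withSeed(seed, {
    # keep the children's widths separated by > 0.4 px so the
    # larger/smaller role assignment stays identifiable under sub-pixel
    # measurement error
    d0 <- stats::runif(1, widthRange[1] + 2, widthRange[2])
    d1 <- stats::runif(1, widthRange[1] + 0.5, d0 - 0.5)
    d2 <- stats::runif(1, widthRange[1], d1 - 0.4)
    parentDir <- stats::runif(1, 0, 360)
    flow <- parentDir + 180 # extrapolated parent direction
    # keep the two children at least 55 degrees apart so their
    # measurement rectangles never overlap the sibling vessel
    repeat {
      aA <- stats::runif(1, angleRange[1], angleRange[2])
      aB <- stats::runif(1, angleRange[1], angleRange[2])
      if (aA + aB >= 55) break
    }
    imageSize <- as.integer(imageSize)
    len <- imageSize * 0.28
    sceneSpec(
      imageSize = c(imageSize, imageSize),
      directions = c(parentDir, flow + aA, flow - aB),
      lengths = rep(len, 3),
      trueWidths = c(d0, d1, d2),
      noiseSd = noiseSd, profile = profile,
      seed = as.integer(seed %% .Machine$integer.max)
    )
  })
}
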