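#' Measure the full geometry of one annotated bifurcation
#'
#' Composes the measurement pipeline for a single junction: perpendicular
#' profile extraction and width estimation for each of the three
#' segments, branching angles from the four annotated centreline points,
#' larger/smaller child role assignment, junction exponent, derived
#' ratios and the ONH distance ratio. A failure in any sub-step (flat
#' profile, out-of-bounds rectangle, no finite junction exponent root,
#' ...) flags the record unusable rather than aborting, so one bad
#' junction never loses an image.
#'
#' @param image numeric intensity matrix (`[row, col]`).
#' @param annotation a [BifurcationAnnotation-class].
#' @param onh an [OnhReference-class].
#' @param nStations stations per segment rectangle.
#' @param method width estimator, `"rectangle_halfheight"` or `"fwhm"`.
#' @param darkVessel logical, vessel polarity (dark on bright default).
#' @return A [BifurcationGeometry-class]; `usable` is FALSE and `flags`
#'   explains when a sub-step failed. An undefined junction exponent
#'   leaves the record usable with `chi = NA` and a
#'   `"chi_undefined"` flag.
#' @seealso [renderBifurcationImage()] for generating test scenes with
#'   known ground truth.
#' @export
measureBifurcation <- function(image, annotation, onh,
                               nStations = 5L,
                               method = "rectangle_halfheight",
                               darkVessel = TRUE) {
  stopifnot(is(annotation, "BifurcationAnnotation"), is(onh, "OnhReference"))
  flags <- character()
  widths <- rep(NA_real_, 3L)
  for (i in 1:3) {
    widths[i] <- tryCatch(
      {
        profs <- extractPerpendicularProfiles(image, annotation@seeds[[i]],
          nStations = nStations
        )
        estimateSegmentWidth(profs, method = method, darkVessel = darkVessel)
      },
      error = function(e) {
        flags <<- c(flags, sprintf(
          "segment_%s: %s", c("parent", "child_a", "child_b")[i],
          conditionMessage(e)
        ))
        NA_real_
      }
    )
  }
  angles <- tryCatch(
    computeBranchAngles(
      annotation@apex, annotation@parentEnd,
      annotation@childAEnd, annotation@childBEnd
    ),
    error = function(e) {
      flags <<- c(flags, paste("angles:", conditionMessage(e)))
      NULL
    }
  )
  distRatio <- onhDistanceRatio(annotation@apex, onh)

  unusable <- function(flags) {
    new("BifurcationGeometry",
      d0 = NA_real_, d1 = NA_real_, d2 = NA_real_,
      theta1 = NA_real_, theta2 = NA_real_, theta = NA_real_,
      chi = NA_real_, jer = NA_real_,
      asymmetryRatio = NA_real_, areaRatio = NA_real_,
      distanceRatio = distRatio, vesselType = annotation@vesselType,
      usable = FALSE, flags = flags
    )
  }
  if (anyNA(widths) || is.null(angles)) {
    return(unusable(flags))
  }
  roles <- assignChildRoles(widths[2], angles$angleA, widths[3], angles$angleB)
  d0 <- widths[1]
  if (d0 < roles$d1) {
    # measured parent narrower than a child: structurally inconsistent
    flags <- c(flags, "parent_narrower_than_child")
    return(unusable(flags))
  }
  if (angles$sameSide) flags <- c(flags, "children_same_side")
  chi <- solveJunctionExponent(d0, roles$d1, roles$d2)
  if (is.na(chi)) flags <- c(flags, "chi_undefined")
  ratios <- computeDerivedRatios(d0, roles$d1, roles$d2)
  new("BifurcationGeometry",
    d0 = d0, d1 = roles$d1, d2 = roles$d2,
    theta1 = roles$theta1, theta2 = roles$theta2,
    theta = roles$theta1 + roles$theta2,
    chi = as.numeric(chi), jer = ratios$jer,
    asymmetryRatio = ratios$asymmetryRatio, areaRatio = ratios$areaRatio,
    distanceRatio = distRatio, vesselType = annotation@vesselType,
    usable = TRUE, flags = flags
  )
}

#' Measure every annotated bifurcation of an image
#'
#' @param image numeric intensity matrix.
#' @param annotations list of [BifurcationAnnotation-class] objects.
#' @param onh an [OnhReference-class].
#' @param patientId,imageId identifiers copied into the output rows.
#' @param ... passed to [measureBifurcation()].
#' @return A data.frame in the [featureColumns()] layout, one row per
#'   annotation; unusable junctions are retained with `usable = FALSE`
#'   so downstream aggregates can exclude and count them.
#' @export
measureImage <- function(image, annotations, onh,
                         patientId = NA_character_, imageId = NA_character_,
                         ...) {
  rows <- lapply(seq_along(annotations), function(i) {
    geom <- measureBifurcation(image, annotations[[i]], onh, ...)
    geometryAsRow(geom,
      patientId = patientId, imageId = imageId,
      bifurcation = i
    )
  })
  do.call(rbind, rows)
}
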