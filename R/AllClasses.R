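#' @import methods
NULL

.isPoint <- function(p) {
  is.numeric(p) && length(p) == 2L && all(is.finite(p))
}

#' Rectangle seed for a vascular segment
#'
#' A rectangle aligned with a vessel segment centreline, used to
#' initialise width measurement: intensity profiles are sampled
#' perpendicular to the rectangle axis at stations spread along its
#' length.
#'
#' @slot center numeric(2), (x, y) centre of the rectangle in pixel
#'   coordinates (0-based, x = column, y = row).
#' @slot axisAngle numeric(1), direction of the centreline in degrees
#'   (image convention: y increases downwards).
#' @slot length numeric(1), rectangle length along the axis in pixels.
#' @slot initialWidth numeric(1), initial width guess in pixels; the
#'   perpendicular profile half-length is twice this value.
#'
#' @seealso [rectangleSeed()], [extractPerpendicularProfiles()]
#' @exportClass RectangleSeed
setClass("RectangleSeed",
  representation(
    center = "numeric",
    axisAngle = "numeric",
    length = "numeric",
    initialWidth = "numeric"
  )
)

setValidity("RectangleSeed", function(object) {
  msg <- character()
  if (!.isPoint(object@center)) msg <- c(msg, "center must be a finite (x, y) pair")
  if (!is.finite(object@axisAngle)) msg <- c(msg, "axisAngle must be finite")
  if (!isTRUE(object@length > 0)) msg <- c(msg, "length must be > 0")
  if (!isTRUE(object@initialWidth > 0)) msg <- c(msg, "initialWidth must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a RectangleSeed
#'
#' @param center numeric(2), (x, y) rectangle centre in pixels.
#' @param axisAngle centreline direction in degrees.
#' @param length rectangle length in pixels (> 0).
#' @param initialWidth initial width guess in pixels (> 0).
#' @return A [RectangleSeed-class] object.
#' @examples
#' rectangleSeed(c(40, 25), axisAngle = 90, length = 20, initialWidth = 6)
#' @export
rectangleSeed <- function(center, axisAngle, length, initialWidth) {
  new("RectangleSeed",
    center = as.numeric(center), axisAngle = as.numeric(axisAngle),
    length = as.numeric(length), initialWidth = as.numeric(initialWidth)
  )
}

#' Optic nerve head reference
#'
#' Location and diameter of the optic nerve head (ONH), used to
#' normalise bifurcation distances: the distance ratio of a bifurcation
#' is its Euclidean distance to the ONH centre divided by the ONH
#' diameter.
#'
#' @slot center numeric(2), (x, y) ONH centre in pixels.
#' @slot diameter numeric(1), ONH diameter in pixels (> 0).
#' @seealso [onhReference()], [onhDistanceRatio()]
#' @exportClass OnhReference
setClass("OnhReference",
  representation(center = "numeric", diameter = "numeric")
)

setValidity("OnhReference", function(object) {
  msg <- character()
  if (!.isPoint(object@center)) msg <- c(msg, "center must be a finite (x, y) pair")
  if (!isTRUE(object@diameter > 0)) msg <- c(msg, "diameter must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct an OnhReference
#'
#' @param center numeric(2), (x, y) ONH centre in pixels.
#' @param diameter ONH diameter in pixels (> 0).
#' @return An [OnhReference-class] object.
#' @export
onhReference <- function(center, diameter) {
  new("OnhReference", center = as.numeric(center), diameter = as.numeric(diameter))
}

#' Manual annotation of one vascular bifurcation
#'
#' The four centreline points marked for a junction (the apex where the
#' three centrelines intersect, plus the outer end point of the parent
#' and of each child segment) together with one rectangle seed per
#' segment. Segment order throughout is parent, child A, child B.
#'
#' @slot apex numeric(2), junction point (x, y) in pixels.
#' @slot parentEnd numeric(2), outer end of the parent centreline.
#' @slot childAEnd numeric(2), outer end of the first child centreline.
#' @slot childBEnd numeric(2), outer end of the second child centreline.
#' @slot seeds list of three [RectangleSeed-class] objects (parent,
#'   child A, child B).
#' @slot vesselType "arteriole" or "venule".
#' @slot imageId character(1) identifier of the source image.
#' @seealso [bifurcationAnnotation()], [measureBifurcation()]
#' @exportClass BifurcationAnnotation
setClass("BifurcationAnnotation",
  representation(
    apex = "numeric", parentEnd = "numeric",
    childAEnd = "numeric", childBEnd = "numeric",
    seeds = "list", vesselType = "character", imageId = "character"
  )
)

setValidity("BifurcationAnnotation", function(object) {
  msg <- character()
  pts <- list(object@apex, object@parentEnd, object@childAEnd, object@childBEnd)
  if (!all(vapply(pts, .isPoint, logical(1)))) {
    msg <- c(msg, "apex and the three end points must be finite (x, y) pairs")
  } else {
    ends <- pts[-1]
    for (i in seq_along(ends)) {
      if (all(ends[[i]] == object@apex)) {
        msg <- c(msg, "end points must be distinct from the apex")
        break
      }
    }
    if (anyDuplicated(vapply(ends, paste, character(1), collapse = ","))) {
      msg <- c(msg, "the three end points must be pairwise distinct")
    }
  }
  if (length(object@seeds) != 3L ||
    !all(vapply(object@seeds, is, logical(1), "RectangleSeed"))) {
    msg <- c(msg, "seeds must be a list of exactly 3 RectangleSeed objects")
  }
  if (length(object@vesselType) != 1L ||
    !object@vesselType %in% c("arteriole", "venule")) {
    msg <- c(msg, "vesselType must be 'arteriole' or 'venule'")
  }
  if (length(object@imageId) != 1L) msg <- c(msg, "imageId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a BifurcationAnnotation
#'
#' @param apex,parentEnd,childAEnd,childBEnd numeric(2) points (x, y).
#' @param seeds list of three [RectangleSeed-class] objects in segment
#'   order parent, child A, child B.
#' @param vesselType "arteriole" or "venule".
#' @param imageId image identifier.
#' @return A [BifurcationAnnotation-class] object.
#' @export
bifurcationAnnotation <- function(apex, parentEnd, childAEnd, childBEnd,
                                  seeds, vesselType = "arteriole",
                                  imageId = "image") {
  new("BifurcationAnnotation",
    apex = as.numeric(apex), parentEnd = as.numeric(parentEnd),
    childAEnd = as.numeric(childAEnd), childBEnd = as.numeric(childBEnd),
    seeds = seeds, vesselType = vesselType, imageId = as.character(imageId)
  )
}

#' Geometry of one measured bifurcation
#'
#' All structural and geometric quantities derived for a junction:
#' widths of the parent, larger child and smaller child (d0 >= d1 >= d2),
#' branching angles of the larger and smaller child (theta1, theta2) and
#' their sum theta, the junction exponent chi solving
#' d1^chi + d2^chi = d0^chi (NA when no finite root exists), derived
#' optimality ratios, and the distance ratio from the optic nerve head.
#'
#' @slot d0,d1,d2 numeric(1) widths in pixels.
#' @slot theta1,theta2,theta numeric(1) angles in degrees.
#' @slot chi numeric(1) junction exponent, NA when undefined.
#' @slot jer numeric(1) junction exponent ratio, NA when undefined.
#' @slot asymmetryRatio,areaRatio numeric(1) dimensionless ratios.
#' @slot distanceRatio numeric(1) ONH distance over ONH diameter.
#' @slot vesselType "arteriole" or "venule".
#' @slot usable logical(1), FALSE when any measurement sub-step failed.
#' @slot flags character vector of failure/qualifier flags.
#' @seealso [measureBifurcation()], [geometryAsRow()]
#' @exportClass BifurcationGeometry
setClass("BifurcationGeometry",
  representation(
    d0 = "numeric", d1 = "numeric", d2 = "numeric",
    theta1 = "numeric", theta2 = "numeric", theta = "numeric",
    chi = "numeric", jer = "numeric",
    asymmetryRatio = "numeric", areaRatio = "numeric",
    distanceRatio = "numeric", vesselType = "character",
    usable = "logical", flags = "character"
  )
)

setValidity("BifurcationGeometry", function(object) {
  msg <- character()
  if (isTRUE(object@usable)) {
    if (!(object@d0 >= object@d1 && object@d1 >= object@d2 && object@d2 > 0)) {
      msg <- c(msg, "usable geometry requires d0 >= d1 >= d2 > 0")
    }
    if (!(object@theta1 >= 0 && object@theta1 <= 180 &&
      object@theta2 >= 0 && object@theta2 <= 180)) {
      msg <- c(msg, "branching angles must lie in [0, 180] degrees")
    }
    if (abs(object@theta - (object@theta1 + object@theta2)) > 1e-9) {
      msg <- c(msg, "theta must equal theta1 + theta2")
    }
    if (!is.na(object@chi) && !(object@chi > 0)) {
      msg <- c(msg, "chi must be > 0 when defined")
    }
    if (!is.na(object@distanceRatio) && object@distanceRatio < 0) {
      msg <- c(msg, "distanceRatio must be >= 0")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Scene specification for a rendered synthetic bifurcation
#'
#' Ground-truth description of a synthetic bifurcation image: three
#' straight vessel segments radiating from an apex, each with its own
#' direction, length, true width and cross-sectional profile, drawn dark
#' on a brighter background with optional additive Gaussian noise.
#'
#' @slot imageSize integer(2), image (width, height) in pixels.
#' @slot background numeric(1) background intensity in [0, 1].
#' @slot vesselLevel numeric(1) vessel core intensity (< background).
#' @slot noiseSd numeric(1) additive Gaussian noise SD (intensity units).
#' @slot directions numeric(3) segment directions in degrees
#'   (parent, child A, child B); the parent is drawn from the apex
#'   outwards along its direction.
#' @slot lengths numeric(3) segment lengths in pixels.
#' @slot trueWidths numeric(3) true segment widths in pixels (for the
#'   gaussian profile this is the full width at half maximum).
#' @slot profile "box" or "gaussian" cross-section.
#' @slot apex numeric(2) junction location (x, y).
#' @slot onh [OnhReference-class].
#' @slot seed integer(1) RNG seed for the noise field.
#' @seealso [sceneSpec()], [renderBifurcationImage()]
#' @exportClass SceneSpec
setClass("SceneSpec",
  representation(
    imageSize = "integer", background = "numeric", vesselLevel = "numeric",
    noiseSd = "numeric", directions = "numeric", lengths = "numeric",
    trueWidths = "numeric", profile = "character", apex = "numeric",
    onh = "OnhReference", seed = "integer"
  )
)

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (length(object@imageSize) != 2L || any(object@imageSize < 8L)) {
    msg <- c(msg, "imageSize must be two integers >= 8")
  }
  if (!isTRUE(object@vesselLevel < object@background)) {
    msg <- c(msg, "vessels must be darker than the background")
  }
  if (!isTRUE(object@noiseSd >= 0)) msg <- c(msg, "noiseSd must be >= 0")
  if (length(object@directions) != 3L || length(object@lengths) != 3L ||
    length(object@trueWidths) != 3L) {
    msg <- c(msg, "directions, lengths and trueWidths must each have length 3")
  }
  if (!all(object@trueWidths > 0)) msg <- c(msg, "trueWidths must be > 0")
  if (!all(object@lengths > 0)) msg <- c(msg, "lengths must be > 0")
  if (!object@profile %in% c("box", "gaussian")) {
    msg <- c(msg, "profile must be 'box' or 'gaussian'")
  }
  if (!.isPoint(object@apex)) msg <- c(msg, "apex must be a finite (x, y) pair")
  if (length(msg)) msg else TRUE
})

#' Construct a SceneSpec
#'
#' @param imageSize image (width, height) in pixels; a single value is
#'   used for both.
#' @param directions numeric(3) directions in degrees for parent,
#'   child A, child B segments.
#' @param lengths numeric(3) segment lengths in pixels.
#' @param trueWidths numeric(3) true widths in pixels.
#' @param apex junction (x, y); defaults to the image centre.
#' @param background,vesselLevel intensities in [0, 1], vessel darker.
#' @param noiseSd additive Gaussian noise SD.
#' @param profile "box" or "gaussian".
#' @param onh [OnhReference-class]; defaults to a disc near the image
#'   corner with diameter a quarter of the image width.
#' @param seed RNG seed for the noise field.
#' @return A [SceneSpec-class] object.
#' @export
sceneSpec <- function(imageSize = c(128L, 128L),
                      directions = c(180, 40, -40),
                      lengths = c(45, 45, 45),
                      trueWidths = c(8, 6.5, 5),
                      apex = NULL,
                      background = 0.85, vesselLevel = 0.25,
                      noiseSd = 0, profile = "box",
                      onh = NULL, seed = 1L) {
  imageSize <- as.integer(rep_len(imageSize, 2L))
  if (is.null(apex)) apex <- (imageSize - 1) / 2
  if (is.null(onh)) {
    onh <- onhReference(c(imageSize[1] * 0.1, imageSize[2] * 0.1),
      diameter = imageSize[1] / 4
    )
  }
  new("SceneSpec",
    imageSize = imageSize, background = as.numeric(background),
    vesselLevel = as.numeric(vesselLevel), noiseSd = as.numeric(noiseSd),
    directions = as.numeric(directions), lengths = as.numeric(lengths),
    trueWidths = as.numeric(trueWidths), profile = profile,
    apex = as.numeric(apex), onh = onh, seed = as.integer(seed)
  )
}

#' A synthetic patient cohort with its generating parameters
#'
#' Container pairing a bifurcation-level feature table with the patient
#' table and the generative parameters that produced them. Regenerating
#' with the same parameters and seed reproduces the cohort exactly.
#'
#' @slot features data.frame, one row per bifurcation (see
#'   [featureColumns()] for the column contract).
#' @slot patients data.frame, one row per patient (per visit for
#'   longitudinal cohorts).
#' @slot params list of generative parameters (see
#'   [defaultGenerativeParams()]).
#' @slot seed integer(1) seed used for generation.
#' @seealso [generateCohort()], [generateProgressionCohort()]
#' @exportClass RvgCohort
setClass("RvgCohort",
  representation(
    features = "data.frame", patients = "data.frame",
    params = "list", seed = "integer"
  )
)

setValidity("RvgCohort", function(object) {
  msg <- character()
  need <- c("patient_id", "image_id", "vessel_type", "d0", "d1", "d2")
  missing <- setdiff(need, names(object@features))
  if (length(missing)) {
    msg <- c(msg, paste("features lacks columns:", paste(missing, collapse = ", ")))
  }
  if (!"patient_id" %in% names(object@patients)) {
    msg <- c(msg, "patients lacks a patient_id column")
  } else if (nrow(object@features) &&
    !all(object@features$patient_id %in% object@patients$patient_id)) {
    msg <- c(msg, "every feature row must reference a known patient")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn RvgCohort-class feature table accessor
#' @param object an `RvgCohort`.
#' @export
setGeneric("features", function(object) standardGeneric("features"))
setMethod("features", "RvgCohort", function(object) object@features)

#' @describeIn RvgCohort-class patient table accessor
#' @export
setGeneric("patients", function(object) standardGeneric("patients"))
setMethod("patients", "RvgCohort", function(object) object@patients)

#' @describeIn RvgCohort-class generative parameter accessor
#' @export
setGeneric("generativeParams", function(object) standardGeneric("generativeParams"))
setMethod("generativeParams", "RvgCohort", function(object) object@params)

setMethod("show", "RvgCohort", function(object) {
  cat(
    "RvgCohort:", nrow(object@patients), "patient rows,",
    nrow(object@features), "bifurcations",
    sprintf("(seed %d)\n", object@seed)
  )
  if ("grade" %in% names(object@patients)) {
    print(table(grade = object@patients$grade))
  }
  invisible(object)
})

setMethod("show", "BifurcationGeometry", function(object) {
  cat(sprintf(
    "BifurcationGeometry [%s]%s\n", object@vesselType,
    if (object@usable) "" else " (UNUSABLE)"
  ))
  cat(sprintf(
    "  widths  d0=%.2f d1=%.2f d2=%.2f px\n",
    object@d0, object@d1, object@d2
  ))
  cat(sprintf(
    "  angles  theta1=%.1f theta2=%.1f theta=%.1f deg\n",
    object@theta1, object@theta2, object@theta
  ))
  cat(sprintf(
    "  chi=%s  jer=%.3g  asymmetry=%.3f  area=%.3f  distRatio=%.3f\n",
    ifelse(is.na(object@chi), "NA", sprintf("%.3f", object@chi)),
    object@jer, object@asymmetryRatio, object@areaRatio, object@distanceRatio
  ))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "RectangleSeed", function(object) {
  cat(sprintf(
    "RectangleSeed centre=(%.1f, %.1f) angle=%.1f deg length=%.1f width0=%.1f\n",
    object@center[1], object@center[2], object@axisAngle,
    object@length, object@initialWidth
  ))
  invisible(object)
})

setMethod("show", "BifurcationAnnotation", function(object) {
  cat(sprintf(
    "BifurcationAnnotation [%s, image %s] apex=(%.1f, %.1f)\n",
    object@vesselType, object@imageId, object@apex[1], object@apex[2]
  ))
  invisible(object)
})

#' Canonical feature-table columns
#'
#' The column contract for bifurcation-level feature tables used across
#' the statistics and classification functions.
#'
#' @return Character vector of column names.
#' @export
featureColumns <- function() {
  c(
    "patient_id", "image_id", "bifurcation", "vessel_type",
    "d0", "d1", "d2", "theta1", "theta2", "theta",
    "chi", "jer", "asymmetry_ratio", "area_ratio", "distance_ratio",
    "usable"
  )
}

#' Convert a BifurcationGeometry to a one-row data.frame
#'
#' @param geometry a [BifurcationGeometry-class] object.
#' @param patientId,imageId,bifurcation identifiers for the row.
#' @return A one-row data.frame with the [featureColumns()] layout.
#' @export
geometryAsRow <- function(geometry, patientId = NA_character_,
                          imageId = NA_character_, bifurcation = 1L) {
  data.frame(
    patient_id = patientId, image_id = imageId,
    bifurcation = as.integer(bifurcation),
    vessel_type = geometry@vesselType,
    d0 = geometry@d0, d1 = geometry@d1, d2 = geometry@d2,
    theta1 = geometry@theta1, theta2 = geometry@theta2, theta = geometry@theta,
    chi = geometry@chi, jer = geometry@jer,
    asymmetry_ratio = geometry@asymmetryRatio,
    area_ratio = geometry@areaRatio,
    distance_ratio = geometry@distanceRatio,
    usable = geometry@usable,
    stringsAsFactors = FALSE
  )
}
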