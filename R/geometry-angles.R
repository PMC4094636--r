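#' Branching angles at a bifurcation from four centreline points
#'
#' The parent flow direction is the apex minus the parent end point,
#' extrapolated through the apex. Each child's branching (deflection)
#' angle is the unsigned angle between the child centreline vector
#' (end minus apex) and the extrapolated parent direction, in
#' `[0, 180]` degrees. The bifurcation angle is their sum. When both
#' children lie on the same side of the parent axis the sum is no
#' longer the inter-child angle; `sameSide` reports this.
#'
#' @param apex numeric(2), junction point (x, y).
#' @param parentEnd numeric(2), outer end of the parent centreline.
#' @param childAEnd,childBEnd numeric(2), outer ends of the child
#'   centrelines.
#' @return A list with elements `angleA`, `angleB`, `total` (degrees)
#'   and `sameSide` (logical).
#' @examples
#' computeBranchAngles(c(0, 0), c(-10, 0), c(10, 10), c(10, -10))
#' @export
computeBranchAngles <- function(apex, parentEnd, childAEnd, childBEnd) {
  parentFlow <- apex - parentEnd # extrapolated through the apex
  va <- childAEnd - apex
  vb <- childBEnd - apex
  if (vectorNorm(parentFlow) == 0 || vectorNorm(va) == 0 || vectorNorm(vb) == 0) {
    stop("degenerate annotation: zero-length centreline vector")
  }
  angleTo <- function(v) {
    cosang <- sum(v * parentFlow) / (vectorNorm(v) * vectorNorm(parentFlow))
    acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  }
  cross <- function(v) parentFlow[1] * v[2] - parentFlow[2] * v[1]
  sa <- cross(va)
  sb <- cross(vb)
  list(
    angleA = angleTo(va), angleB = angleTo(vb),
    total = angleTo(va) + angleTo(vb),
    sameSide = (sa * sb) > 0
  )
}

#' Assign larger/smaller child roles
#'
#' The child with the strictly greater width becomes the larger child
#' (d1, theta1); the other becomes the smaller child (d2, theta2). A
#' width tie is broken deterministically by giving the larger-child role
#' to the child with the smaller deflection angle.
#'
#' @param widthA,widthB child widths in pixels (> 0).
#' @param angleA,angleB child deflection angles in degrees.
#' @return A list with `d1`, `theta1`, `d2`, `theta2`.
#' @examples
#' assignChildRoles(6, 30, 4, 60)
#' @export
assignChildRoles <- function(widthA, angleA, widthB, angleB) {
  stopifnot(widthA > 0, widthB > 0)
  aIsLarger <- if (widthA != widthB) widthA > widthB else angleA <= angleB
  if (aIsLarger) {
    list(d1 = widthA, theta1 = angleA, d2 = widthB, theta2 = angleB)
  } else {
    list(d1 = widthB, theta1 = angleB, d2 = widthA, theta2 = angleA)
  }
}

#' Distance ratio of a bifurcation from the optic nerve head
#'
#' Euclidean distance from the bifurcation apex to the ONH centre,
#' divided by the ONH diameter. Being a ratio of lengths it is invariant
#' under uniform rescaling of the image.
#'
#' @param apex numeric(2), bifurcation apex (x, y) in pixels.
#' @param onh an [OnhReference-class].
#' @return Non-negative dimensionless ratio.
#' @examples
#' onhDistanceRatio(c(400, 300), onhReference(c(100, 300), 150))
#' @export
onhDistanceRatio <- function(apex, onh) {
  stopifnot(is(onh, "OnhReference"))
  vectorNorm(as.numeric(apex) - onh@center) / onh@diameter
}
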