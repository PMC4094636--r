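#' Sample intensity profiles perpendicular to a segment centreline
#'
#' Realises the rectangle width-measurement technique deterministically:
#' a rectangle is aligned with the vessel centreline and intensity
#' profiles are sampled perpendicular to its axis at evenly spaced
#' stations along its length, with bilinear interpolation at sub-pixel
#' positions.
#'
#' @param image numeric matrix of intensities, indexed `[row, col]`;
#'   coordinates in seeds are 0-based with x = column, y = row.
#' @param seed a [RectangleSeed-class] describing the rectangle.
#' @param nStations number of stations along the rectangle length
#'   (>= 1); with one station the profile passes through the centre.
#' @param sampleStep spacing between profile samples in pixels.
#' @param halfLengthFactor profile half-length as a multiple of the
#'   seed's `initialWidth` (>= 2 to bracket the vessel comfortably).
#'
#' @return A list of numeric vectors, one intensity profile per station.
#'   Attribute `positions` holds the signed sample positions in pixels
#'   (0 at the centreline).
#' @examples
#' img <- matrix(1, 40, 40)
#' img[, 18:22] <- 0 # vertical dark strip, width 5 px
#' s <- rectangleSeed(c(19.5, 19.5), axisAngle = 90, length = 10, initialWidth = 5)
#' profs <- extractPerpendicularProfiles(img, s, nStations = 3)
#' length(profs)
#' @export
extractPerpendicularProfiles <- function(image, seed, nStations = 5L,
                                         sampleStep = 0.25,
                                         halfLengthFactor = 2) {
  stopifnot(is.matrix(image), is(seed, "RectangleSeed"), nStations >= 1)
  halfLengthFactor <- max(halfLengthFactor, 2)
  axis <- unitVector(seed@axisAngle)
  perp <- unitVector(seed@axisAngle + 90)
  half <- halfLengthFactor * seed@initialWidth
  offsets <- if (nStations == 1L) 0 else seq(-seed@length / 2, seed@length / 2,
    length.out = nStations
  )
  positions <- seq(-half, half, by = sampleStep)
  nc <- ncol(image)
  nr <- nrow(image)
  profiles <- vector("list", length(offsets))
  for (i in seq_along(offsets)) {
    base <- seed@center + offsets[i] * axis
    xs <- base[1] + positions * perp[1]
    ys <- base[2] + positions * perp[2]
    if (any(xs < 0 | xs > nc - 1 | ys < 0 | ys > nr - 1)) {
      stop(sprintf(
        "profile rectangle exits image bounds (seed centre (%.1f, %.1f), angle %.1f deg)",
        seed@center[1], seed@center[2], seed@axisAngle
      ))
    }
    profiles[[i]] <- bilinearSample(image, xs, ys)
  }
  attr(profiles, "positions") <- positions
  profiles
}

#' Estimate a vessel segment width from perpendicular profiles
#'
#' For each profile the background level is the median of the outer 25%
#' of samples and the vessel core level the minimum of the central 50%.
#' Edges are located where the intensity crosses the half-height level
#' `(background + core) / 2`, with sub-pixel positions by linear
#' interpolation; the segment width is the mean edge-to-edge distance
#' over stations. The `"fwhm"` method instead works on the
#' background-minus-intensity depth curve and takes the full width at
#' half of its peak depth — identical for symmetric profiles but defined
#' through the depth maximum rather than the central minimum.
#'
#' Vessels are assumed darker than the background (fundus green-channel
#' polarity); pass `darkVessel = FALSE` for bright-vessel images, which
#' flips the profile in place.
#'
#' @param profiles list of numeric profiles as returned by
#'   [extractPerpendicularProfiles()] (the `positions` attribute is used
#'   when present; otherwise `sampleStep` spacing centred on the middle
#'   sample is assumed).
#' @param method `"rectangle_halfheight"` (default) or `"fwhm"`.
#' @param sampleStep sample spacing in pixels, used when `profiles`
#'   carries no `positions` attribute.
#' @param darkVessel logical; set FALSE for bright vessels.
#' @param manualEdges optional numeric(2) of manually marked edge
#'   positions (pixels, signed, same frame as `positions`); overrides
#'   profile-based detection and returns their distance.
#' @return Width in pixels (mean over stations).
#' @examples
#' pos <- seq(-10, 10, by = 0.25)
#' prof <- ifelse(abs(pos) <= 2.5, 0, 1) # box of width 5
#' p <- list(prof)
#' attr(p, "positions") <- pos
#' estimateSegmentWidth(p)
#' @export
estimateSegmentWidth <- function(profiles, method = c("rectangle_halfheight", "fwhm"),
                                 sampleStep = 0.25, darkVessel = TRUE,
                                 manualEdges = NULL) {
  method <- match.arg(method)
  if (!is.null(manualEdges)) {
    stopifnot(length(manualEdges) == 2L)
    return(abs(diff(sort(as.numeric(manualEdges)))))
  }
  stopifnot(length(profiles) >= 1)
  positions <- attr(profiles, "positions")
  widths <- vapply(profiles, function(p) {
    pos <- positions %||% ((seq_along(p) - (length(p) + 1) / 2) * sampleStep)
    if (!darkVessel) p <- max(p) + min(p) - p
    .profileWidth(p, pos, method)
  }, numeric(1))
  mean(widths)
}

# Width of a single dip profile; pos are signed pixel positions.
.profileWidth <- function(p, pos, method) {
  n <- length(p)
  if (n < 8) stop("profile too short for width estimation")
  outer <- max(1L, floor(n * 0.125))
  background <- stats::median(c(p[seq_len(outer)], p[seq.int(n - outer + 1L, n)]))
  centralIdx <- seq.int(floor(n * 0.25) + 1L, ceiling(n * 0.75))
  core <- min(p[centralIdx])
  span <- max(p) - min(p)
  contrast <- background - core
  if (span <= .Machine$double.eps || contrast <= 1e-8 * max(1, abs(background))) {
    # distinguish a bright vessel from a flat profile
    if ((max(p[centralIdx]) - background) > abs(contrast) &&
      (max(p[centralIdx]) - background) > 1e-6) {
      stop("contrast polarity error: vessel appears brighter than background")
    }
    stop("width measurement failure: profile has no vessel dip")
  }
  if ((max(p[centralIdx]) - background) > contrast) {
    stop("contrast polarity error: vessel appears brighter than background")
  }
  if (method == "fwhm") {
    depth <- background - p
    peakIdx <- centralIdx[which.max(depth[centralIdx])]
    level <- background - max(depth[centralIdx]) / 2
  } else {
    peakIdx <- centralIdx[which.min(p[centralIdx])]
    level <- (background + core) / 2
  }
  left <- .crossingOutward(p, pos, peakIdx, level, direction = -1L)
  right <- .crossingOutward(p, pos, peakIdx, level, direction = 1L)
  if (is.na(left) || is.na(right)) {
    stop("width measurement failure: no half-height crossing found")
  }
  right - left
}

# Walk outward from the dip minimum until the profile rises through
# `level`; linear interpolation between the bracketing samples.
.crossingOutward <- function(p, pos, from, level, direction) {
  i <- from
  n <- length(p)
  while (i + direction >= 1L && i + direction <= n) {
    j <- i + direction
    if (p[i] <= level && p[j] >= level) {
      if (p[j] == p[i]) {
        return(pos[j])
      }
      f <- (level - p[i]) / (p[j] - p[i])
      return(pos[i] + f * (pos[j] - pos[i]))
    }
    i <- j
  }
  NA_real_
}
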