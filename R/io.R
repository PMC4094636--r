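#' Read a grayscale image
#'
#' Reads a single-channel PNG (or TIFF when the tiff package is
#' available) into a numeric intensity matrix indexed `[row, col]`.
#' Multi-channel images are reduced to their second (green) channel,
#' the conventional channel for fundus vessel analysis.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return Numeric matrix of intensities in `[0, 1]`.
#' @export
readGrayImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the tiff package")
    }
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format: ", ext)
  }
  if (length(dim(img)) == 3L) img <- img[, , min(2L, dim(img)[3])]
  img
}

#' Write a grayscale image
#'
#' @param image numeric matrix; values are clipped to `[0, 1]`.
#' @param path output path (`.png`, `.tif`, `.tiff`).
#' @return The path, invisibly.
#' @export
writeGrayImage <- function(image, path) {
  image <- pmin(pmax(image, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(image, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("writing TIFF requires the tiff package")
    }
    tiff::writeTIFF(image, path)
  } else {
    stop("unsupported image format: ", ext)
  }
  invisible(path)
}

#' Read per-image bifurcation annotations from JSON
#'
#' One JSON document per image:
#' `{"image_id": ..., "onh": {"cx", "cy", "diameter"},`
#' `"bifurcations": [{"apex": {"x", "y"}, "parent_end": ...,`
#' `"child_a_end": ..., "child_b_end": ..., "seeds": [...],`
#' `"vessel_type": ...}]}` where each seed has `cx`, `cy`, `angle`,
#' `length`, `width`.
#'
#' @param path JSON file path.
#' @return A list with `imageId`, `onh` ([OnhReference-class]) and
#'   `annotations` (list of [BifurcationAnnotation-class]).
#' @export
readAnnotations <- function(path) {
  doc <- jsonlite::read_json(path)
  onh <- onhReference(
    c(doc$onh$cx, doc$onh$cy),
    diameter = doc$onh$diameter
  )
  pt <- function(p) c(p$x, p$y)
  anns <- lapply(doc$bifurcations, function(b) {
    seeds <- lapply(b$seeds, function(s) {
      rectangleSeed(c(s$cx, s$cy),
        axisAngle = s$angle,
        length = s$length, initialWidth = s$width
      )
    })
    bifurcationAnnotation(
      apex = pt(b$apex), parentEnd = pt(b$parent_end),
      childAEnd = pt(b$child_a_end), childBEnd = pt(b$child_b_end),
      seeds = seeds, vesselType = b$vessel_type,
      imageId = doc$image_id
    )
  })
  list(imageId = doc$image_id, onh = onh, annotations = anns)
}

#' Write per-image bifurcation annotations to JSON
#'
#' Inverse of [readAnnotations()].
#'
#' @param annotations list of [BifurcationAnnotation-class].
#' @param onh an [OnhReference-class].
#' @param imageId image identifier.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
writeAnnotations <- function(annotations, onh, imageId, path) {
  pt <- function(p) list(x = p[1], y = p[2])
  doc <- list(
    image_id = imageId,
    onh = list(cx = onh@center[1], cy = onh@center[2], diameter = onh@diameter),
    bifurcations = lapply(annotations, function(a) {
      list(
        apex = pt(a@apex), parent_end = pt(a@parentEnd),
        child_a_end = pt(a@childAEnd), child_b_end = pt(a@childBEnd),
        seeds = lapply(a@seeds, function(s) {
          list(
            cx = s@center[1], cy = s@center[2], angle = s@axisAngle,
            length = s@length, width = s@initialWidth
          )
        }),
        vessel_type = a@vesselType
      )
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read or write bifurcation feature tables as CSV
#'
#' @param path CSV path.
#' @return `readFeatureTable` returns a data.frame in the
#'   [featureColumns()] layout (extra columns such as `visit` are
#'   preserved).
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(featureColumns(), names(df))
  if (length(missing)) {
    stop("feature CSV lacks columns: ", paste(missing, collapse = ", "))
  }
  df
}

#' @rdname readFeatureTable
#' @param features data.frame to write.
#' @export
writeFeatureTable <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Read or write patient covariate tables as CSV
#'
#' @param path CSV path.
#' @return `readPatientTable` returns a data.frame with at least
#'   `patient_id` and `grade`.
#' @export
readPatientTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(df)) stop("patient CSV lacks patient_id")
  for (col in c("hypertension", "high_cholesterol", "progressor")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  df
}

#' @rdname readPatientTable
#' @param patientTable data.frame to write.
#' @export
writePatientTable <- function(patientTable, path) {
  utils::write.csv(patientTable, path, row.names = FALSE)
  invisible(path)
}
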