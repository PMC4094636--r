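# Internal helpers shared across modules.

# Run code with a temporarily seeded RNG, restoring the caller's RNG
# state afterwards so package functions never clobber the session RNG.
withSeed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stage label, keeping the
# result a valid 32-bit integer.
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Bilinear interpolation of image intensities at fractional pixel
# coordinates. Images are numeric matrices indexed [row, col] with
# 0-based (x = col, y = row) coordinates in function interfaces.
bilinearSample <- function(image, x, y) {
  nr <- nrow(image)
  nc <- ncol(image)
  x0 <- floor(x)
  y0 <- floor(y)
  fx <- x - x0
  fy <- y - y0
  x0 <- pmin(pmax(x0, 0), nc - 1)
  y0 <- pmin(pmax(y0, 0), nr - 1)
  x1 <- pmin(x0 + 1, nc - 1)
  y1 <- pmin(y0 + 1, nr - 1)
  i00 <- image[cbind(y0 + 1, x0 + 1)]
  i10 <- image[cbind(y0 + 1, x1 + 1)]
  i01 <- image[cbind(y1 + 1, x0 + 1)]
  i11 <- image[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i10) + fy * ((1 - fx) * i01 + fx * i11)
}

degToRad <- function(deg) deg * pi / 180

unitVector <- function(angleDeg) {
  a <- degToRad(angleDeg)
  c(cos(a), sin(a))
}

vectorNorm <- function(v) sqrt(sum(v^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
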