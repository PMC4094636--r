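# Independent oracles and fixture builders shared across the suite.

# Multi-stage sign-change grid oracle for the junction exponent:
# locates the sign change of g(chi) = (d1/d0)^chi + (d2/d0)^chi - 1 on
# successively refined grids (0.01 -> 1e-4 -> 1e-6), independent of the
# package's bisection solver.
chiGridOracle <- function(d0, d1, d2) {
  g <- function(chi) (d1 / d0)^chi + (d2 / d0)^chi - 1
  lo <- 1e-3
  hi <- 50
  for (step in c(1e-2, 1e-4, 1e-6)) {
    grid <- seq(lo, hi + step, by = step)
    vals <- g(grid)
    i <- which(vals[-length(vals)] > 0 & vals[-1] <= 0)[1]
    if (is.na(i)) {
      return(NA_real_)
    }
    lo <- grid[i]
    hi <- grid[i + 1]
  }
  (lo + hi) / 2
}

# Brute-force 2-parameter grid search: OLS (minimise SSE) or logistic
# (minimise negative log-likelihood) for y ~ a + b * x.
gridFit2 <- function(x, y, kind = c("ols", "logistic"),
                     aRange, bRange, step = 0.01) {
  kind <- match.arg(kind)
  aGrid <- seq(aRange[1], aRange[2], by = step)
  bGrid <- seq(bRange[1], bRange[2], by = step)
  best <- c(a = NA, b = NA)
  bestVal <- Inf
  for (a in aGrid) {
    eta <- a + outer(x, bGrid)
    val <- if (kind == "ols") {
      colSums((y - eta)^2)
    } else {
      -colSums(y * stats::plogis(eta, log.p = TRUE) +
        (1 - y) * stats::plogis(-eta, log.p = TRUE))
    }
    j <- which.min(val)
    if (val[j] < bestVal) {
      bestVal <- val[j]
      best <- c(a = a, b = bGrid[j])
    }
  }
  best
}

# Vertical dark strip image of the given full width centred at x = cx
# (0-based coordinates), with a 1-pixel anti-aliasing ramp.
stripImage <- function(size = 48L, cx = 23.5, width = 5,
                       background = 1, vessel = 0) {
  xs <- 0:(size - 1)
  cov <- pmin(pmax(width / 2 + 0.5 - abs(xs - cx), 0), 1)
  row <- background - (background - vessel) * cov
  matrix(rep(row, each = size), nrow = size, ncol = size)
}

# Random per-patient distance-ratio sets for matching property checks.
randomPatientSets <- function(seed, nPatients = 8, maxBif = 12) {
  withr::local_seed(seed)
  n <- sample(2:maxBif, nPatients, replace = TRUE)
  data.frame(
    patient_id = rep(sprintf("P%02d", seq_len(nPatients)), times = n),
    d0 = stats::runif(sum(n), 5, 10),
    theta2 = stats::runif(sum(n), 30, 80),
    distance_ratio = stats::rgamma(sum(n), shape = 6, rate = 2.4)
  )
}

# Null cohort parameters with a planted age effect on widths and an
# age distribution common to all grades, so the age+sex linear model is
# correctly specified (no omitted-grade confounding).
plantedAgeParams <- function(beta = -0.05) {
  p <- nullGenerativeParams()
  p$covariateEffects$age <- list(widthsAll = beta)
  p$covariates$age <- list(
    mean = rep(53, 4), sd = rep(10, 4),
    min = rep(26, 4), max = rep(65, 4)
  )
  p
}

# Small patient-profile fixture with perfectly separated classes.
separatedProfiles <- function(nNeg = 6, nPos = 10) {
  data.frame(
    patient_id = sprintf("S%02d", seq_len(nNeg + nPos)),
    mean_d0 = c(seq(5, 6, length.out = nNeg), seq(8, 10, length.out = nPos)),
    mean_theta2 = c(
      seq(45, 50, length.out = nNeg),
      seq(58, 66, length.out = nPos)
    ),
    mean_distance_ratio = 2.5, n_kept = 10, n_discarded = 0,
    unmatchable = FALSE, stringsAsFactors = FALSE
  )
}

separatedPatients <- function(nNeg = 6, nPos = 10) {
  data.frame(
    patient_id = sprintf("S%02d", seq_len(nNeg + nPos)),
    grade = c(rep("NoDR", nNeg), rep("PDR", nPos)),
    stringsAsFactors = FALSE
  )
}
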