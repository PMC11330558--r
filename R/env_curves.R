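#' Fit a natural smoothing spline to an environmental series
#'
#' Environmental series (sea-surface temperature in deg C, dissolved O2 in
#' uM) arrive as values averaged over 1 Myr intervals. A natural cubic
#' smoothing spline (second derivative zero at the boundaries) turns them
#' into a curve that can be evaluated at arbitrary ages; `smoothing = 0`
#' interpolates the samples exactly, `smoothing = NULL` (default) selects the
#' penalty by generalized cross-validation.
#'
#' @param age_ma Ages of the samples (Ma), unique.
#' @param value Sample values.
#' @param smoothing Non-negative penalty (`lambda` of
#'   [stats::smooth.spline()]); 0 = pure interpolation; `NULL` = GCV.
#' @return An object of class `env_curve`.
#' @export
fit_smoothing_spline <- function(age_ma, value, smoothing = NULL) {
  if (length(age_ma) != length(value)) stop("age and value lengths differ")
  if (length(age_ma) < 4) stop("need at least 4 samples")
  if (anyDuplicated(age_ma)) stop("duplicate ages in environmental samples")
  ord <- order(age_ma)
  age_ma <- age_ma[ord]; value <- value[ord]
  fitted <- NULL
  if (is.null(smoothing)) {
    fit <- stats::smooth.spline(age_ma, value, all.knots = TRUE, cv = FALSE,
                                keep.data = FALSE)
  } else {
    if (smoothing < 0) stop("smoothing must be non-negative")
    # fixed penalty: solve the normal equations (I + lambda K) f = y of the
    # natural smoothing spline directly (Green-Silverman form, knots scaled
    # to [0, 1] as smooth.spline does); the smoothing spline is then the
    # natural cubic interpolant of its own fitted values
    fitted <- if (smoothing == 0) value else {
      K <- natural_spline_penalty((age_ma - age_ma[1]) / diff(range(age_ma)))
      drop(solve(diag(length(value)) + smoothing * K, value))
    }
    fit <- stats::splinefun(age_ma, fitted, method = "natural")
  }
  structure(
    list(fit = fit, range = range(age_ma), knots = age_ma,
         knot_values = value, fitted = fitted, smoothing = smoothing,
         step = 0.25),
    class = "env_curve"
  )
}

#' Natural-spline roughness penalty matrix
#'
#' The Green-Silverman penalty `K = Q R^{-1} Q^T` such that
#' `f^T K f = int f''(u)^2 du` for the natural cubic spline with values `f`
#' at knots `u`.
#'
#' @param u Strictly increasing knot locations.
#' @return The n x n penalty matrix.
#' @export
natural_spline_penalty <- function(u) {
  n <- length(u)
  if (n < 3) stop("need at least 3 knots")
  h <- diff(u)
  Qm <- matrix(0, n, n - 2)
  Rm <- matrix(0, n - 2, n - 2)
  for (i in 2:(n - 1)) {
    j <- i - 1
    Qm[i - 1, j] <- 1 / h[i - 1]
    Qm[i, j] <- -1 / h[i - 1] - 1 / h[i]
    Qm[i + 1, j] <- 1 / h[i]
    Rm[j, j] <- (h[i - 1] + h[i]) / 3
    if (j > 1) {
      Rm[j - 1, j] <- h[i - 1] / 6
      Rm[j, j - 1] <- h[i - 1] / 6
    }
  }
  Qm %*% solve(Rm, t(Qm))
}

#' @export
print.env_curve <- function(x, ...) {
  cat("<env_curve> ", length(x$knots), " knots on [",
      x$range[1], ", ", x$range[2], "] Ma\n", sep = "")
  invisible(x)
}

#' Evaluate an environmental curve at given ages
#'
#' Strictly refuses extrapolation: every age must lie inside the fitted
#' range. Clip the tree or extend the curve explicitly if the root predates
#' the series.
#'
#' @param curve An `env_curve`.
#' @param age_ma Ages (Ma) to evaluate at.
#' @return Numeric vector of curve values.
#' @export
env_value_at <- function(curve, age_ma) {
  stopifnot(inherits(curve, "env_curve"))
  out <- age_ma < curve$range[1] - 1e-9 | age_ma > curve$range[2] + 1e-9
  if (any(out)) {
    stop("age(s) outside fitted curve range [", curve$range[1], ", ",
         curve$range[2], "] Ma: ", paste(utils::head(age_ma[out], 5), collapse = ", "),
         "; clip the tree or extend the curve explicitly - no extrapolation")
  }
  age_ma <- pmin(pmax(age_ma, curve$range[1]), curve$range[2])
  if (inherits(curve$fit, "smooth.spline")) {
    stats::predict(curve$fit, age_ma)$y
  } else {
    curve$fit(age_ma)
  }
}

#' Resample a fitted curve on a regular age grid
#'
#' @param curve An `env_curve`.
#' @param step Grid spacing in Myr (default 0.25, the interpolation
#'   granularity used throughout the trait-model machinery).
#' @return A data.frame with columns `age_ma` and `value`.
#' @export
resample_curve <- function(curve, step = 0.25) {
  stopifnot(inherits(curve, "env_curve"))
  if (step <= 0) stop("step must be positive")
  if (step > diff(curve$range)) stop("step larger than the fitted range")
  grid <- seq(curve$range[1], curve$range[2], by = step)
  data.frame(age_ma = grid, value = env_value_at(curve, grid))
}

#' Read an environmental curve from CSV
#'
#' Expects columns `age_ma` and `value`; fits [fit_smoothing_spline()].
#'
#' @param path CSV path.
#' @param smoothing Passed to [fit_smoothing_spline()].
#' @return An `env_curve`.
#' @export
read_env_curve <- function(path, smoothing = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age_ma", "value") %in% names(tab))) {
    stop("curve CSV needs columns age_ma, value")
  }
  fit_smoothing_spline(tab$age_ma, tab$value, smoothing = smoothing)
}
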