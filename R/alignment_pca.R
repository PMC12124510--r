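#' Derive the master PC1 loading from a reference spectrum set
#'
#' Mean-centers the preprocessed reference spectra (columns of the set),
#' computes principal components over wavenumbers, and returns the first
#' loading with the sign convention that the coefficient at the grid point
#' nearest 1665 cm-1 (amide I) is non-negative, plus the variance-explained
#' fractions of all components.  The returned object defines a *fixed*
#' affine map: test spectra are centered by the reference mean, never their
#' own, so scores are comparable across samples and runs.
#'
#' @param reference a preprocessed [RamanSpectra-class] with >= 2 spectra on
#'   a common grid.
#' @return A [LoadingFunction-class].
#' @export
deriveLoading <- function(reference) {
  if (ncol(reference) < 2)
    stop("need at least 2 reference spectra")
  X <- t(intensities(reference))      # spectra in rows
  if (max(abs(sweep(X, 2, colMeans(X)))) == 0)
    stop("degenerate reference set: all spectra identical")
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  coefs <- p$rotation[, 1]
  grid <- wavenumbers(reference)
  i0 <- which.min(abs(grid - 1665))
  if (coefs[i0] < 0) coefs <- -coefs
  new("LoadingFunction", grid = grid, coefficients = unname(coefs),
      referenceMean = unname(p$center), varianceExplained = unname(ve))
}

setMethod("show", "LoadingFunction", function(object) {
  cat(sprintf(
    "LoadingFunction on %d wavenumbers [%.1f, %.1f] cm-1; PC1 %.1f%% var\n",
    length(object@grid), min(object@grid), max(object@grid),
    100 * object@varianceExplained[1]))
})

#' Variance explained by each principal component of a spectrum set
#'
#' @param x a preprocessed [RamanSpectra-class] with >= 2 spectra.
#' @return Numeric fractions, non-increasing, summing to 1.
#' @export
varianceExplained <- function(x) {
  if (ncol(x) < 2) stop("need at least 2 spectra")
  X <- t(intensities(x))
  if (max(abs(sweep(X, 2, colMeans(X)))) == 0)
    stop("degenerate set: all spectra identical")
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  p$sdev^2 / sum(p$sdev^2)
}

#' Project spectra onto the master loading
#'
#' The PC1 score of a spectrum `s` is
#' `dot(s - referenceMean, coefficients)` -- a linear functional of the
#' spectrum.  Grids must match exactly; no silent interpolation (see
#' [resampleSpectra()]).
#'
#' @param x a preprocessed [RamanSpectra-class].
#' @param loading a [LoadingFunction-class].
#' @return A data.frame: the acquisition metadata plus a `score` column.
#' @export
projectPC1 <- function(x, loading) {
  w <- wavenumbers(x)
  if (length(w) != length(loading@grid) || any(w != loading@grid))
    stop("wavenumber grid does not match the loading grid; ",
         "resample explicitly with resampleSpectra()")
  sc <- drop(crossprod(intensities(x) - loading@referenceMean,
                       loading@coefficients))
  out <- acquisitionMeta(x)
  out$score <- as.numeric(sc)
  out
}

#' Fit the PC1-vs-polarization-angle sinusoid
#'
#' Least-squares fit of `PC1 = PC1_0 + A * sin(pi * (phi - phi_c) / 90)`
#' over all (angle, score) pairs.  The model is linear in the
#' reparameterization `(PC1_0, a, b)` with
#' `a = A cos(pi phi_c / 90)`, `b = -A sin(pi phi_c / 90)`, so the global
#' least-squares optimum is obtained in closed form from the period-180
#' Fourier component; `A >= 0` and `phi_c` wrapped to `[0, 180)` resolve the
#' `(A, phi_c) ~ (-A, phi_c + 90)` branch ambiguity.  Fits with
#' `A < 2 * rmse` are flagged `aligned = FALSE` (phase unreliable).
#'
#' @param scores either a data.frame with columns `pol_angle_deg` and
#'   `score` (e.g. from [projectPC1()]) or a named list mapping angles to
#'   score vectors.
#' @return A [SineFit-class].
#' @export
fitSine <- function(scores) {
  if (is.data.frame(scores)) {
    phi <- scores$pol_angle_deg
    y <- scores$score
  } else {
    phi <- rep(as.numeric(names(scores)), lengths(scores))
    y <- unlist(scores, use.names = FALSE)
  }
  if (length(unique(phi)) < 3)
    stop("need scores at >= 3 distinct polarization angles")
  k <- pi / 90
  X <- cbind(1, sin(k * phi), cos(k * phi))
  cf <- qr.coef(qr(X), y)
  a <- cf[2]; b <- cf[3]
  A <- sqrt(a^2 + b^2)
  phic <- if (A > 0) (atan2(-b, a) / k) %% 180 else 0
  resid <- y - drop(X %*% cf)
  rmse <- sqrt(mean(resid^2))
  aligned <- A >= 2 * rmse && A > 0
  new("SineFit", pc1Offset = unname(cf[1]), amplitude = unname(A),
      phaseDeg = unname(phic), betaPrsDeg = unname((phic + 45) %% 180),
      rmse = rmse, nAngles = length(unique(phi)), aligned = aligned)
}

setMethod("show", "SineFit", function(object) {
  cat(sprintf(
    "SineFit: PC1_0 = %.4g, A = %.4g, phi_c = %.2f deg, beta_PRS = %.2f deg",
    object@pc1Offset, object@amplitude, object@phaseDeg, object@betaPrsDeg),
    if (!object@aligned) " [below noise floor]" else "", "\n", sep = "")
})

#' PRS alignment angle from a sine fit
#'
#' The polarization angle of maximum PC1 score,
#' `beta_PRS = (phi_c + 45) mod 180` degrees.  Errors on fits flagged
#' unaligned, whose phase is unidentifiable.
#'
#' @param fit a [SineFit-class].
#' @return Angle in degrees, in `[0, 180)`.
#' @export
alignmentAngle <- function(fit) {
  if (!fit@aligned)
    stop("fit amplitude is below the noise floor; alignment angle undefined")
  (fit@phaseDeg + 45) %% 180
}

#' Student-t confidence interval for a mean
#'
#' `mean +/- t_{1-alpha/2, n-1} * SD / sqrt(n)` with the sample (n-1)
#' standard deviation.  Either pass raw `values`, or summary statistics via
#' `mean`, `sd` and `n`.
#'
#' @param values numeric vector (n >= 2), or `NULL` if summary statistics
#'   are given.
#' @param alpha significance level (default 0.05 for a 95% interval).
#' @param mean,sd,n optional summary statistics used when `values` is NULL.
#' @return Named numeric `c(lo, hi)`.
#' @export
confidenceInterval <- function(values = NULL, alpha = 0.05,
                               mean = NULL, sd = NULL, n = NULL) {
  if (!is.null(values)) {
    if (length(values) < 2) stop("need n >= 2 values")
    n <- length(values)
    m <- base::mean(values)
    s <- stats::sd(values)
  } else {
    if (is.null(mean) || is.null(sd) || is.null(n) || n < 2)
      stop("provide values, or mean, sd and n >= 2")
    m <- mean; s <- sd
  }
  tcrit <- qt(1 - alpha / 2, df = n - 1)
  half <- tcrit * s / sqrt(n)
  c(lo = m - half, hi = m + half)
}

#' Alignment aspect ratio gamma = A / A_max
#'
#' Normalizes per-location amplitudes by the maximum amplitude measured in
#' the sample, giving a dimensionless alignment aspect ratio comparable
#' across modalities.
#'
#' @param amplitudes named numeric of positive per-location amplitudes.
#' @return Named numeric of `gamma` values in `(0, 1]`; at least one equals 1.
#' @export
aspectRatio <- function(amplitudes) {
  if (any(amplitudes <= 0)) stop("amplitudes must be positive")
  amplitudes / max(amplitudes)
}

#' Per-location summary of PRS alignment
#'
#' Fits one sinusoid per measurement point (grouping scores by location,
#' ROI and point), then summarizes the fitted amplitudes per location with
#' mean, SD and a Student-t confidence interval, the circular-mean phase
#' and the derived alignment angle `beta_PRS`.
#'
#' @param scores data.frame from [projectPC1()] (columns `location`, `roi`,
#'   `point`, `pol_angle_deg`, `score`).
#' @param alpha significance level for the confidence interval.
#' @param pooled if TRUE, fit one sinusoid per location over all points
#'   jointly instead of per point.
#' @return data.frame with one row per location: `location`, `n_points`,
#'   `A_mean`, `A_sd`, `ci_lo`, `ci_hi`, `phase_deg`, `beta_prs_deg`,
#'   `gamma`.
#' @export
summarizeAlignment <- function(scores, alpha = 0.05, pooled = FALSE) {
  locs <- unique(scores$location)
  rows <- lapply(locs, function(loc) {
    sl <- scores[scores$location == loc, ]
    if (pooled) {
      fit <- fitSine(sl)
      amps <- fit@amplitude
      phase <- fit@phaseDeg
    } else {
      grp <- interaction(sl$roi, sl$point, drop = TRUE)
      fits <- lapply(split(sl, grp), fitSine)
      amps <- vapply(fits, slot, numeric(1), "amplitude")
      phases <- vapply(fits, slot, numeric(1), "phaseDeg")
      ok <- vapply(fits, slot, logical(1), "aligned")
      phase <- if (any(ok)) .axial_mean_deg(phases[ok]) else NA_real_
    }
    ci <- if (length(amps) >= 2) confidenceInterval(amps, alpha)
          else c(lo = NA_real_, hi = NA_real_)
    data.frame(location = loc, n_points = length(amps),
               A_mean = mean(amps),
               A_sd = if (length(amps) >= 2) sd(amps) else NA_real_,
               ci_lo = ci[["lo"]], ci_hi = ci[["hi"]],
               phase_deg = phase,
               beta_prs_deg = (phase + 45) %% 180)
  })
  out <- do.call(rbind, rows)
  out$gamma <- out$A_mean / max(out$A_mean)
  rownames(out) <- NULL
  out
}

# mean of axial (period-180) angles via the doubled-angle embedding
.axial_mean_deg <- function(deg) {
  z <- exp(2i * deg * pi / 180)
  (Arg(mean(z)) * 180 / pi / 2) %% 180
}
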