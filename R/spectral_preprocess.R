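#' Preprocessing configuration for polarized Raman spectra
#'
#' Bundles the parameters of the fixed preprocessing chain
#' baseline -> Savitzky-Golay -> SNV -> crop (in that order; requesting any
#' other order is refused).  Defaults follow common practice for
#' PBS-submerged tissue spectra: an eleventh-order polynomial baseline, a
#' third-order/11-point smoothing window, and a 1400-1800 cm-1 analysis
#' window that avoids the glass-substrate background below 1300 cm-1.
#'
#' @param baselineOrder integer >= 1, polynomial order of the iterative
#'   baseline fit (default 11).
#' @param sgPolyorder,sgWindow Savitzky-Golay polynomial order (default 3)
#'   and odd frame length (default 11), `sgWindow > sgPolyorder`.
#' @param cropLo,cropHi analysis window in cm-1 (default 1400-1800).
#' @param averageReplicates logical, average replicate acquisitions per
#'   (sample, location, ROI, point, polarization angle) after SNV
#'   (default TRUE).
#' @param steps character, the processing order; only the canonical
#'   `c("baseline", "smooth", "snv", "crop")` is accepted.
#' @return A list of class `PreprocessConfig`.
#' @export
preprocessConfig <- function(baselineOrder = 11L, sgPolyorder = 3L,
                             sgWindow = 11L, cropLo = 1400, cropHi = 1800,
                             averageReplicates = TRUE,
                             steps = c("baseline", "smooth", "snv", "crop")) {
  if (!identical(as.character(steps),
                 c("baseline", "smooth", "snv", "crop")))
    stop("the preprocessing order is fixed: baseline -> smooth -> snv -> crop")
  if (baselineOrder < 1) stop("baselineOrder must be >= 1")
  if (sgWindow %% 2 != 1 || sgWindow <= sgPolyorder)
    stop("sgWindow must be odd and greater than sgPolyorder")
  if (cropLo >= cropHi) stop("cropLo must be < cropHi")
  structure(list(baselineOrder = as.integer(baselineOrder),
                 sgPolyorder = as.integer(sgPolyorder),
                 sgWindow = as.integer(sgWindow),
                 cropLo = cropLo, cropHi = cropHi,
                 averageReplicates = isTRUE(averageReplicates)),
            class = "PreprocessConfig")
}

.modpoly_baseline <- function(w, y, order, maxIter = 300, tol = 1e-6) {
  # iterative modified polynomial fit with a residual-deviation guard
  # (I-ModPoly): points rising more than one residual SD above the current
  # baseline are clipped before each refit, so bands are progressively
  # excluded while the smooth background is kept
  rng <- diff(range(y))
  if (rng == 0) return(y)
  ws <- (w - mean(w)) / (diff(range(w)) / 2)  # scale for conditioning
  X <- outer(ws, 0:order, `^`)
  qrX <- qr(X)
  yw <- y
  b <- drop(X %*% qr.coef(qrX, yw))
  for (it in seq_len(maxIter)) {
    dev <- sd(yw - b)
    yw <- pmin(yw, b + dev)
    bn <- drop(X %*% qr.coef(qrX, yw))
    delta <- max(abs(bn - b))
    b <- bn
    if (delta < tol * rng) return(b)
  }
  warning("baseline iteration did not converge within ", maxIter,
          " iterations (last change ", signif(delta, 3), ")")
  b
}

#' Subtract a smooth polynomial background
#'
#' Removes the broad fluorescence/buffer background with an iterative
#' modified polynomial fit of the given order: the polynomial is refit to
#' the elementwise minimum of the spectrum and the current baseline until
#' the baseline changes by less than `tol` of the intensity range, so Raman
#' bands are excluded from the background estimate while smooth structure is
#' removed.  Exact on inputs that are polynomials up to `order`.
#'
#' @param x a [RamanSpectra-class] object.
#' @param order polynomial order (default 11).
#' @param maxIter,tol iteration cap and relative convergence tolerance.
#' @return `x` with the fitted baseline removed from every spectrum.
#' @export
subtractBaseline <- function(x, order = 11L, maxIter = 300, tol = 1e-6) {
  w <- wavenumbers(x)
  if (length(w) <= order + 1)
    stop("need more than order + 1 = ", order + 1, " points, got ", length(w))
  ints <- intensities(x)
  for (j in seq_len(ncol(ints)))
    ints[, j] <- ints[, j] - .modpoly_baseline(w, ints[, j], order,
                                               maxIter, tol)
  RamanSpectra(ints, w, acquisitionMeta(x),
               procLog = c(x@procLog, sprintf("baseline(order=%d)", order)),
               checkAngles = FALSE)
}

#' Savitzky-Golay smoothing
#'
#' Standard Savitzky-Golay FIR smoothing via [signal::sgolayfilt()];
#' polynomials up to `polyorder` pass through unchanged (including at the
#' endpoints, which use the one-sided projection rows).
#'
#' @param x a [RamanSpectra-class] object.
#' @param polyorder polynomial order (default 3).
#' @param window odd frame length (default 11), `window > polyorder` and at
#'   most the spectrum length.
#' @return Smoothed `x`, same length.
#' @export
smoothSG <- function(x, polyorder = 3L, window = 11L) {
  if (window %% 2 != 1) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (nrow(x) < window) stop("spectrum shorter than the smoothing window")
  ints <- intensities(x)
  for (j in seq_len(ncol(ints)))
    ints[, j] <- signal::sgolayfilt(ints[, j], p = polyorder, n = window)
  RamanSpectra(ints, wavenumbers(x), acquisitionMeta(x),
               procLog = c(x@procLog,
                           sprintf("sg(p=%d,n=%d)", polyorder, window)),
               checkAngles = FALSE)
}

#' Standard normal variate normalization
#'
#' Centers and scales each spectrum to mean 0 and sample standard deviation
#' 1 (n-1 denominator), removing multiplicative intensity drift between
#' acquisitions.  Idempotent; invariant to positive affine transforms of the
#' input.
#'
#' @param x a [RamanSpectra-class] object.
#' @return Normalized `x`.
#' @export
snv <- function(x) {
  ints <- intensities(x)
  s <- apply(ints, 2, sd)
  if (any(s == 0))
    stop("zero-variance spectrum (column ", which(s == 0)[1],
         "): SNV undefined")
  ints <- sweep(ints, 2, colMeans(ints))
  ints <- sweep(ints, 2, s, "/")
  RamanSpectra(ints, wavenumbers(x), acquisitionMeta(x),
               procLog = c(x@procLog, "snv"), checkAngles = FALSE)
}

#' Crop spectra to a wavenumber window
#'
#' Retains samples with `lo <= w <= hi` (closed interval).
#'
#' @param x a [RamanSpectra-class] object.
#' @param lo,hi window bounds in cm-1.
#' @return Cropped `x`.
#' @export
cropSpectra <- function(x, lo = 1400, hi = 1800) {
  w <- wavenumbers(x)
  keep <- which(w >= lo & w <= hi)
  if (!length(keep))
    stop("crop window [", lo, ", ", hi, "] contains no samples")
  out <- x[keep, ]
  out@procLog <- c(x@procLog, sprintf("crop(%g,%g)", lo, hi))
  out
}

#' Average replicate acquisitions
#'
#' Averages spectra over the `replicate` index within each
#' (sample, location, ROI, point, polarization angle) group; the averaged
#' columns carry `replicate = 0`.
#'
#' @param x a [RamanSpectra-class] object.
#' @return A [RamanSpectra-class] with one column per group.
#' @export
averageReplicates <- function(x) {
  md <- acquisitionMeta(x)
  keys <- c("sample_id", "location", "roi", "point", "pol_angle_deg")
  kc <- interaction(md[keys], drop = TRUE, sep = "|", lex.order = TRUE)
  idx <- split(seq_len(ncol(x)), kc)
  ints <- intensities(x)
  avg <- vapply(idx, function(i) rowMeans(ints[, i, drop = FALSE]),
                numeric(nrow(x)))
  meta <- md[vapply(idx, `[`, 1L, 1L), .meta_cols]
  meta$replicate <- 0L
  RamanSpectra(matrix(avg, nrow = nrow(x)), wavenumbers(x), meta,
               procLog = c(x@procLog, "average_replicates"), checkAngles = FALSE)
}

#' Run the full preprocessing chain
#'
#' Applies, in this fixed order: polynomial baseline subtraction,
#' Savitzky-Golay smoothing, SNV normalization, spectral cropping, and
#' (optionally) replicate averaging.  Cropping comes last so smoothing edge
#' effects fall outside the analysis window; averaging acts on normalized
#' spectra so per-shot intensity drift does not weight the mean.
#'
#' @param x a [RamanSpectra-class] object.
#' @param config a [preprocessConfig()] list.
#' @return Preprocessed [RamanSpectra-class].
#' @export
preprocessSpectra <- function(x, config = preprocessConfig()) {
  stopifnot(inherits(config, "PreprocessConfig"))
  x <- subtractBaseline(x, config$baselineOrder)
  x <- smoothSG(x, config$sgPolyorder, config$sgWindow)
  x <- snv(x)
  x <- cropSpectra(x, config$cropLo, config$cropHi)
  if (config$averageReplicates) x <- averageReplicates(x)
  x
}
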