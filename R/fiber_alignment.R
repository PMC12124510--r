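#' Construct a FiberSet
#'
#' @param anglesDeg numeric fiber angles in degrees; wrapped modulo 180.
#' @param lengthsUm,widthsUm,straightness optional parallel vectors.
#' @param roiSizeUm square ROI edge length in micrometers (default 100).
#' @return A [FiberSet-class].
#' @export
FiberSet <- function(anglesDeg, lengthsUm = numeric(0),
                     widthsUm = numeric(0), straightness = numeric(0),
                     roiSizeUm = 100) {
  new("FiberSet", anglesDeg = as.numeric(anglesDeg) %% 180,
      lengthsUm = as.numeric(lengthsUm), widthsUm = as.numeric(widthsUm),
      straightness = as.numeric(straightness), roiSizeUm = roiSizeUm)
}

#' @describeIn FiberSet Number of fibers.
#' @param x a `FiberSet`.
#' @export
nFibers <- function(x) length(x@anglesDeg)

#' @describeIn FiberSet Fiber angles in degrees, `[0, 180)`.
#' @export
fiberAngles <- function(x) x@anglesDeg

setMethod("show", "FiberSet", function(object) {
  cat("FiberSet:", nFibers(object), "fibers in a",
      object@roiSizeUm, "um ROI\n")
  if (nFibers(object) >= 2) {
    r <- alignmentIndex(object)
    cat(sprintf("  S = %.3f, mean axis = %.1f deg (axial SD %.1f deg)\n",
                r$S, r$mean_axis_deg, r$theta_sd_deg))
  }
})

#' Read a CT-FIRE-style fiber table
#'
#' Expects a CSV with at least an angle column (`angle_deg`, or an alias
#' given in `aliases`); optional `length_um`, `width_um`, `straightness`
#' columns are carried along and extra columns ignored.  Angles are wrapped
#' to `[0, 180)`.
#'
#' @param path CSV path.
#' @param aliases named character vector mapping canonical column names
#'   (`angle_deg`, `length_um`, `width_um`, `straightness`) to the column
#'   names used in the file.
#' @param roiSizeUm ROI edge length recorded on the result.
#' @return A [FiberSet-class].
#' @export
readFiberTable <- function(path, aliases = character(0), roiSizeUm = 100) {
  if (!file.exists(path)) stop("fiber table not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(tab)) stop("fiber table is empty: ", path)
  pick <- function(canon) {
    nm <- if (canon %in% names(aliases)) aliases[[canon]] else canon
    if (nm %in% colnames(tab)) tab[[nm]] else NULL
  }
  ang <- pick("angle_deg")
  if (is.null(ang))
    stop("fiber table has no angle column (expected 'angle_deg' or alias)")
  angn <- suppressWarnings(as.numeric(ang))
  if (anyNA(angn))
    stop("non-numeric angle in fiber table row ", which(is.na(angn))[1])
  opt <- function(canon) {
    v <- pick(canon)
    if (is.null(v)) numeric(0) else as.numeric(v)
  }
  FiberSet(angn, lengthsUm = opt("length_um"), widthsUm = opt("width_um"),
           straightness = opt("straightness"), roiSizeUm = roiSizeUm)
}

# resultant of doubled angles: length R in [0,1] and mean doubled angle
.axial_resultant <- function(deg, weights = NULL) {
  t2 <- 2 * deg * pi / 180
  if (is.null(weights)) weights <- rep(1, length(deg))
  w <- weights / sum(weights)
  c2 <- sum(w * cos(t2)); s2 <- sum(w * sin(t2))
  list(R = sqrt(c2^2 + s2^2), mean2 = atan2(s2, c2))
}

#' Mean fiber axis from the orientation tensor
#'
#' The principal axis of the second-order orientation tensor `<u u^T>` over
#' unit vectors `u(theta)` -- the major axis of the ellipse fitted to all
#' fibers -- equivalently the axis maximizing `<cos 2 theta>`.  For a
#' perfectly isotropic set the tensor is degenerate and the axis is
#' undefined.
#'
#' @param f a [FiberSet-class] with >= 2 fibers.
#' @param weights optional fiber weights (e.g. lengths).
#' @return List with `axis_deg` in `[0, 180)` (NA when undefined) and
#'   `defined` logical.
#' @export
meanFiberAxis <- function(f, weights = NULL) {
  if (nFibers(f) < 2) stop("need at least 2 fibers")
  r <- .axial_resultant(f@anglesDeg, weights)
  if (r$R < 1e-12)
    return(list(axis_deg = NA_real_, defined = FALSE))
  list(axis_deg = (r$mean2 * 90 / pi) %% 180, defined = TRUE)
}

#' Alignment index S and axial angle statistics
#'
#' Computes the order parameter `S = 2<cos^2 theta> - 1 = <cos 2 theta>`
#' where `theta` is each fiber's angle from the mean fiber axis and the
#' average is an unweighted count average over fibers (a length-weighted
#' mode is available).  With the mean axis chosen to maximize
#' `<cos 2 theta>`, `S` equals the resultant length of the doubled angles
#' and lies in `[0, 1]`: 0 for an isotropic set, 1 for perfect alignment.
#' The angular SD uses axial circular statistics (double the angles, take
#' the circular SD, halve), which is stable across the 0/180 wrap.
#'
#' @param f a [FiberSet-class] with >= 2 fibers.
#' @param lengthWeighted if TRUE, weight fibers by `lengthsUm` (default
#'   FALSE: fibers are counted).
#' @return List: `S`, `mean_axis_deg`, `theta_sd_deg` (axial circular SD,
#'   degrees), `theta_sd_arith_deg` (arithmetic SD of angles about the axis,
#'   for comparison), `n_fibers`, `axis_defined`.
#' @export
alignmentIndex <- function(f, lengthWeighted = FALSE) {
  n <- nFibers(f)
  if (n < 2) stop("need at least 2 fibers")
  weights <- NULL
  if (lengthWeighted) {
    if (!length(f@lengthsUm)) stop("no fiber lengths available to weight by")
    weights <- f@lengthsUm
  }
  r <- .axial_resultant(f@anglesDeg, weights)
  axis_defined <- r$R >= 1e-12
  axis <- if (axis_defined) (r$mean2 * 90 / pi) %% 180 else NA_real_
  S <- min(r$R, 1)   # <cos 2(theta - axis)> maximized over axes
  # sqrt(-2 log R) is the circular SD of the doubled angles (radians);
  # halve it and convert to degrees (R clamped against rounding above 1):
  Rcl <- min(r$R, 1)
  sd_ax <- if (Rcl > 0) (sqrt(-2 * log(Rcl)) / 2) * 180 / pi else Inf
  dev <- ((f@anglesDeg - axis + 90) %% 180) - 90
  list(S = S,
       mean_axis_deg = axis,
       theta_sd_deg = sd_ax,
       theta_sd_arith_deg = if (axis_defined) sqrt(mean(dev^2) * n / (n - 1))
                            else NA_real_,
       n_fibers = n,
       axis_defined = axis_defined)
}

#' Polar histogram of fiber angles
#'
#' Half-open bins `[lo, hi)` of width `binDeg` covering `[0, 180)`;
#' `binDeg` must divide 180.  Counts always sum to the number of fibers.
#'
#' @param f a [FiberSet-class].
#' @param binDeg bin width in degrees (default 10).
#' @return List with `edges` (length nbins + 1) and `counts`.
#' @export
polarHistogram <- function(f, binDeg = 10) {
  if (180 %% binDeg != 0) stop("binDeg must divide 180")
  edges <- seq(0, 180, by = binDeg)
  idx <- floor(f@anglesDeg / binDeg) + 1L
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  list(edges = edges, counts = counts)
}

#' Plot a polar histogram of fiber angles
#'
#' Base-graphics rose plot on the axial circle (each bin mirrored at
#' +180 degrees, as fiber orientations are head-tail symmetric).
#'
#' @param f a [FiberSet-class].
#' @param binDeg bin width in degrees.
#' @param main plot title.
#' @return Invisibly, the histogram from [polarHistogram()].
#' @export
plotPolarHistogram <- function(f, binDeg = 10, main = "Fiber orientations") {
  h <- polarHistogram(f, binDeg)
  r <- max(h$counts)
  graphics::plot(NA, xlim = c(-r, r), ylim = c(-r, r), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  for (i in seq_along(h$counts)) {
    if (h$counts[i] == 0) next
    for (off in c(0, 180)) {
      th <- seq(h$edges[i] + off, h$edges[i + 1] + off,
                length.out = 16) * pi / 180
      graphics::polygon(c(0, h$counts[i] * cos(th)),
                        c(0, h$counts[i] * sin(th)),
                        col = "steelblue", border = "white")
    }
  }
  graphics::symbols(0, 0, circles = r, inches = FALSE, add = TRUE,
                    fg = "grey60")
  invisible(h)
}
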