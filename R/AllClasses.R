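#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame
#' @importFrom stats approx coef lm optimize qt quantile rnorm runif sd var
#' @importFrom utils read.csv write.csv head tail
NULL

#' Polarization-resolved Raman spectra with acquisition metadata
#'
#' `RamanSpectra` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single `intensity` assay (wavenumber x acquisition), a numeric
#' `wavenumber` column in `rowData`, and the acquisition metadata in
#' `colData`: `sample_id`, `location` (typically one of `CE`, `ME`, `MC`),
#' `roi`, `point`, `replicate` and `pol_angle_deg`.
#'
#' Polarization angles are stored modulo 180 degrees: protein fiber
#' orientation distributions have period 180, so a polarizer at 190 degrees
#' probes the same axis as one at 10 degrees.
#'
#' @slot procLog character vector recording the preprocessing steps applied,
#'   in order.
#' @export
setClass("RamanSpectra",
  contains = "SummarizedExperiment",
  representation(procLog = "character"),
  prototype(procLog = character(0))
)

.meta_cols <- c("sample_id", "location", "roi", "point", "replicate",
                "pol_angle_deg")
.std_angles <- c(0, 30, 60, 90, 120, 150)

setValidity("RamanSpectra", function(object) {
  msg <- character(0)
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!"wavenumber" %in% colnames(rd)) {
    msg <- c(msg, "rowData column 'wavenumber' is required")
  } else {
    w <- rd$wavenumber
    if (anyNA(w) || any(!is.finite(w)))
      msg <- c(msg, "wavenumbers must be finite")
    else if (length(w) > 1 && any(diff(w) <= 0))
      msg <- c(msg, "wavenumbers must be strictly increasing")
  }
  cd <- SummarizedExperiment::colData(object)
  miss <- setdiff(.meta_cols, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("missing colData columns:",
                        paste(miss, collapse = ", ")))
  if ("pol_angle_deg" %in% colnames(cd) && ncol(object) > 0) {
    a <- cd$pol_angle_deg
    if (anyNA(a) || any(a < 0 | a >= 180))
      msg <- c(msg, "pol_angle_deg must lie in [0, 180)")
  }
  if (ncol(object) > 0 && length(msg) == 0) {
    x <- SummarizedExperiment::assay(object, "intensity")
    if (any(!is.finite(x)))
      msg <- c(msg, "intensities must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' Master PC1 loading derived from a reference spectrum set
#'
#' Holds the first principal-component loading ("master loading function")
#' computed from preprocessed spectra of a highly aligned reference tissue,
#' together with the reference-set mean spectrum used for centering and the
#' variance-explained fractions of all components.  The loading is unit
#' Euclidean norm and its sign is fixed so the coefficient at the grid point
#' nearest 1665 cm-1 (amide I, C=O stretch) is non-negative, making scores
#' reproducible across runs.
#'
#' @slot grid numeric, wavenumber grid (cm-1), strictly increasing.
#' @slot coefficients numeric, unit-norm loading values on `grid`.
#' @slot referenceMean numeric, mean preprocessed reference spectrum.
#' @slot varianceExplained numeric, non-increasing fractions summing to 1.
#' @export
setClass("LoadingFunction",
  representation(grid = "numeric", coefficients = "numeric",
                 referenceMean = "numeric", varianceExplained = "numeric"))

setValidity("LoadingFunction", function(object) {
  msg <- character(0)
  n <- length(object@grid)
  if (length(object@coefficients) != n || length(object@referenceMean) != n)
    msg <- c(msg, "grid, coefficients and referenceMean lengths differ")
  if (n > 1 && any(diff(object@grid) <= 0))
    msg <- c(msg, "grid must be strictly increasing")
  if (n > 0 && abs(sqrt(sum(object@coefficients^2)) - 1) > 1e-8)
    msg <- c(msg, "coefficients must have unit Euclidean norm")
  if (n > 0) {
    i0 <- which.min(abs(object@grid - 1665))
    if (object@coefficients[i0] < 0)
      msg <- c(msg, "sign convention: coefficient nearest 1665 cm-1 must be >= 0")
  }
  ve <- object@varianceExplained
  if (length(ve)) {
    if (abs(sum(ve) - 1) > 1e-8)
      msg <- c(msg, "varianceExplained must sum to 1")
    if (any(diff(ve) > 1e-12))
      msg <- c(msg, "varianceExplained must be non-increasing")
  }
  if (length(msg)) msg else TRUE
})

#' Sinusoidal fit of PC1 score against polarization angle
#'
#' Parameters of the model `PC1 = PC1_0 + A * sin(pi * (phi - phi_c) / 90)`
#' fitted over polarization angles `phi` (degrees).  The amplitude `A >= 0`
#' is the extent-of-alignment metric; the phase `phi_c` in `[0, 180)` gives
#' the PRS alignment angle `beta_PRS = (phi_c + 45) mod 180`, the
#' polarization angle of maximum PC1 score.  Fits whose amplitude does not
#' rise above the noise floor (`A < 2 * rmse`) carry `aligned = FALSE`: the
#' phase of a vanishing sinusoid is unidentifiable.
#'
#' @slot pc1Offset,amplitude,phaseDeg,betaPrsDeg,rmse numeric scalars.
#' @slot nAngles integer, number of distinct polarization angles used.
#' @slot aligned logical, whether the amplitude is resolvable above noise.
#' @export
setClass("SineFit",
  representation(pc1Offset = "numeric", amplitude = "numeric",
                 phaseDeg = "numeric", betaPrsDeg = "numeric",
                 rmse = "numeric", nAngles = "integer", aligned = "logical"))

setValidity("SineFit", function(object) {
  msg <- character(0)
  if (object@amplitude < 0) msg <- c(msg, "amplitude must be >= 0")
  if (object@phaseDeg < 0 || object@phaseDeg >= 180)
    msg <- c(msg, "phaseDeg must lie in [0, 180)")
  b <- (object@phaseDeg + 45) %% 180
  if (abs(((object@betaPrsDeg - b + 90) %% 180) - 90) > 1e-8)
    msg <- c(msg, "betaPrsDeg must equal (phaseDeg + 45) mod 180")
  if (length(msg)) msg else TRUE
})

#' A set of discrete fiber orientations
#'
#' Fiber angles from curvelet-based fiber extraction output (or a synthetic
#' generator), wrapped to the axial half-circle `[0, 180)`, with optional
#' per-fiber geometry.  Angles are measured counterclockwise from the image
#' horizontal axis; in the construct coordinate frame used throughout the
#' package the inter-anchor (contraction) axis lies at 90 degrees.
#'
#' @slot anglesDeg numeric, fiber angles in `[0, 180)`.
#' @slot lengthsUm,widthsUm,straightness numeric, optional parallel vectors
#'   (length 0 or equal to `anglesDeg`).
#' @slot roiSizeUm numeric scalar, edge length of the square ROI (default 100).
#' @export
setClass("FiberSet",
  representation(anglesDeg = "numeric", lengthsUm = "numeric",
                 widthsUm = "numeric", straightness = "numeric",
                 roiSizeUm = "numeric"),
  prototype(lengthsUm = numeric(0), widthsUm = numeric(0),
            straightness = numeric(0), roiSizeUm = 100))

setValidity("FiberSet", function(object) {
  msg <- character(0)
  a <- object@anglesDeg
  if (anyNA(a) || any(!is.finite(a)))
    msg <- c(msg, "angles must be finite")
  else if (any(a < 0 | a >= 180))
    msg <- c(msg, "angles must be wrapped to [0, 180)")
  for (s in c("lengthsUm", "widthsUm", "straightness")) {
    v <- slot(object, s)
    if (length(v) && length(v) != length(a))
      msg <- c(msg, paste(s, "must have length 0 or match anglesDeg"))
  }
  if (length(object@roiSizeUm) != 1 || object@roiSizeUm <= 0)
    msg <- c(msg, "roiSizeUm must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Structured quadrilateral mesh of the construct's central region
#'
#' Reference (undeformed) discretization of the cell-laden central region of
#' the dog-bone construct: a regular grid of square 4-node elements, the two
#' edges adjoining the adhesion wings (y = 0 and y = H) fully fixed, the
#' lateral edges free.
#'
#' @slot nodes numeric matrix (n x 2), reference coordinates in mm.
#' @slot elements integer matrix (ne x 4), counter-clockwise connectivity.
#' @slot cellLaden logical, per-element flag (shrinkage applied where TRUE).
#' @slot fixedNodes integer, indices of fully constrained nodes.
#' @slot nx,ny integer, element counts along x and y.
#' @slot elementSize numeric, element edge length in mm.
#' @slot thickness numeric, out-of-plane thickness in mm.
#' @export
setClass("TissueMesh",
  representation(nodes = "matrix", elements = "matrix",
                 cellLaden = "logical", fixedNodes = "integer",
                 nx = "integer", ny = "integer",
                 elementSize = "numeric", thickness = "numeric"))

#' Converged nodal displacement field of the contraction model
#'
#' @slot u numeric matrix (n x 2), nodal displacements in mm.
#' @slot converged logical.
#' @slot residualNorm numeric, final relative residual.
#' @slot epsS numeric, shrinkage strain magnitude that produced the field.
#' @export
setClass("DisplacementField",
  representation(u = "matrix", converged = "logical",
                 residualNorm = "numeric", epsS = "numeric"))
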