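#' Parametric model of a polarization-modulated Raman spectrum
#'
#' Describes synthetic protein spectra as a sum of Gaussian bands on a
#' smooth polynomial baseline with additive Gaussian noise.  Band centers
#' default to the features seen in collagen-rich soft tissue between 1400
#' and 1800 cm-1: CH2 bending (1445), CH2/CH3 deformation (1465), C=C
#' stretching / aromatic amino acids (1605), and the amide I envelope
#' (1656, 1675).  The amide I bands carry a polarization modulation
#' `height(phi) = base * (1 + m * sin(pi * (phi - phaseDeg) / 90))` with
#' period 180 degrees, mirroring how C=O bond intensity varies with the
#' angle between polarizer and fiber axis; the other bands are unmodulated
#' by default.
#'
#' @param bands data.frame with columns `center` (cm-1), `width` (Gaussian
#'   sigma, cm-1), `height` (base intensity) and `m` (modulation depth in
#'   `[0, 1]`).
#' @param phaseDeg modulation phase `phi_c` in degrees.
#' @param baseline numeric polynomial coefficients (ascending powers of the
#'   scaled wavenumber) of the smooth background.
#' @param noiseSd additive Gaussian noise SD (intensity units).
#' @param gridLo,gridHi,gridStep wavenumber grid (default 1350-1850 cm-1,
#'   step 1), wide enough that smoothing edge effects fall outside the
#'   1400-1800 analysis window.
#' @return A list of class `SpectrumModel`.
#' @export
spectrumModel <- function(bands = data.frame(
                            center = c(1445, 1465, 1605, 1656, 1675),
                            width = c(12, 10, 9, 12, 10),
                            height = c(60, 35, 25, 80, 50),
                            m = c(0, 0, 0, 0.5, 0.5)),
                          phaseDeg = 75,
                          baseline = c(200, -40, 25),
                          noiseSd = 1,
                          gridLo = 1350, gridHi = 1850, gridStep = 1) {
  stopifnot(all(bands$m >= 0), all(bands$m <= 1), noiseSd >= 0,
            all(bands$center >= gridLo & bands$center <= gridHi))
  structure(list(bands = bands, phaseDeg = phaseDeg %% 180,
                 baseline = baseline, noiseSd = noiseSd,
                 grid = seq(gridLo, gridHi, by = gridStep)),
            class = "SpectrumModel")
}

.model_spectrum <- function(model, phi) {
  w <- model$grid
  ws <- (w - mean(w)) / (diff(range(w)) / 2)
  y <- drop(outer(ws, seq_along(model$baseline) - 1, `^`) %*% model$baseline)
  for (b in seq_len(nrow(model$bands))) {
    bb <- model$bands[b, ]
    hgt <- bb$height * (1 + bb$m * sin(pi * (phi - model$phaseDeg) / 90))
    if (hgt < 0)
      stop("modulation depth drives band ", bb$center,
           " cm-1 to negative height at phi = ", phi)
    y <- y + hgt * exp(-(w - bb$center)^2 / (2 * bb$width^2))
  }
  y
}

#' Generate polarization-resolved synthetic spectra
#'
#' One spectrum per (angle, replicate): deterministic band structure from
#' the model plus seeded i.i.d. Gaussian noise.  Replicate indices are
#' assigned so that each polarization angle receives
#' `replicates` acquisitions, mirroring an acquisition scheme where the
#' replicate cycle spans the angle set.
#'
#' @param model a [spectrumModel()] list.
#' @param angles polarization angles in degrees (default 0-150 by 30).
#' @param replicates acquisitions per angle (default 2).
#' @param meta list of metadata defaults (`sample_id`, `location`, `roi`,
#'   `point`).
#' @param seed integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @return A [RamanSpectra-class] object.
#' @export
genPolarizedSpectra <- function(model, angles = seq(0, 150, by = 30),
                                replicates = 2,
                                meta = list(sample_id = "synthetic",
                                            location = "MC", roi = 1L,
                                            point = 1L),
                                seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  grid <- model$grid
  cols <- list(); md <- list()
  k <- 0
  for (r in seq_len(replicates)) {
    for (a in angles) {
      k <- k + 1
      y <- .model_spectrum(model, a)
      if (model$noiseSd > 0) y <- y + rnorm(length(grid), 0, model$noiseSd)
      cols[[k]] <- y
      md[[k]] <- data.frame(sample_id = meta$sample_id,
                            location = meta$location, roi = meta$roi,
                            point = meta$point,
                            replicate = as.integer(r),
                            pol_angle_deg = a %% 180)
    }
  }
  RamanSpectra(do.call(cbind, cols), grid, do.call(rbind, md))
}

#' Generate a full multi-point PRS acquisition set
#'
#' Emulates the acquisition layout of a PRS session at one location: `nroi`
#' ROIs x `npoints` points per ROI x `nreplicates` replicate acquisitions
#' per point, with the replicate cycle spread over the polarization angles
#' (replicate `r` is acquired at angle `angles[((r - 1) mod
#' length(angles)) + 1]`), so 11 points x 12 replicates x 2 ROIs with six
#' angles yields 264 spectra at 22 distinct points, 2 acquisitions per
#' point and angle.  Per-point phase jitter and modulation-depth variation
#' emulate spatial heterogeneity.
#'
#' @param model a [spectrumModel()] list.
#' @param location location label (e.g. `"CE"`).
#' @param nroi,npoints,nreplicates layout (defaults 2, 11, 12).
#' @param angles polarization angle cycle (default 0-150 by 30).
#' @param phaseJitterSd per-point SD of the modulation phase, degrees.
#' @param seed integer seed.
#' @return A [RamanSpectra-class] object.
#' @export
genAcquisitionSet <- function(model, location = "MC", nroi = 2,
                              npoints = 11, nreplicates = 12,
                              angles = seq(0, 150, by = 30),
                              phaseJitterSd = 0, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cols <- list(); md <- list()
  k <- 0
  for (roi in seq_len(nroi)) {
    for (pt in seq_len(npoints)) {
      mpt <- model
      if (phaseJitterSd > 0)
        mpt$phaseDeg <- (model$phaseDeg +
                           rnorm(1, 0, phaseJitterSd)) %% 180
      for (r in seq_len(nreplicates)) {
        a <- angles[((r - 1) %% length(angles)) + 1]
        k <- k + 1
        y <- .model_spectrum(mpt, a)
        if (model$noiseSd > 0)
          y <- y + rnorm(length(model$grid), 0, model$noiseSd)
        cols[[k]] <- y
        md[[k]] <- data.frame(sample_id = "synthetic",
                              location = location, roi = as.integer(roi),
                              point = as.integer(pt),
                              replicate = as.integer(r),
                              pol_angle_deg = a %% 180)
      }
    }
  }
  RamanSpectra(do.call(cbind, cols), model$grid, do.call(rbind, md))
}

#' Generate a reference spectrum set for loading derivation
#'
#' Emulates a highly aligned reference tissue (e.g. muscle) scanned over
#' polarization angles: `n` spectra whose dominant variance direction is
#' the amide-I polarization modulation, so the derived PC1 loading is
#' supported on the amide I envelope.
#'
#' @param model a [spectrumModel()] list with nonzero amide modulation.
#' @param n number of spectra (default 110).
#' @param seed integer seed.
#' @return A [RamanSpectra-class] object, `location = "REF"`.
#' @export
genReferenceSet <- function(model, n = 110, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  angles <- seq(0, 180, length.out = n + 1)[seq_len(n)] %% 180
  cols <- lapply(angles, function(a) {
    y <- .model_spectrum(model, a)
    if (model$noiseSd > 0) y <- y + rnorm(length(model$grid), 0,
                                          model$noiseSd)
    y
  })
  md <- data.frame(sample_id = "reference", location = "REF", roi = 1L,
                   point = seq_len(n), replicate = 1L,
                   pol_angle_deg = angles)
  RamanSpectra(do.call(cbind, cols), model$grid, md, checkAngles = FALSE)
}

#' Draw fiber angles from an axial wrapped-normal distribution
#'
#' Samples `n` angles as `mean + N(0, sd)` wrapped modulo 180 -- the
#' wrapped normal on the axial circle.  Its closed form
#' `E[cos 2(theta - mean)] = exp(-2 sigma^2)` (sigma in radians) makes it
#' an analytic oracle for the alignment index: `S -> exp(-2 sigma^2)` as
#' `n` grows.  Defaults emulate a moderately aligned corner-edge fiber
#' population (mean 129.1 degrees, SD 25 degrees).
#'
#' @param n number of fibers.
#' @param meanDeg axial mean direction, degrees.
#' @param sdDeg angular SD, degrees (> 0; `0` gives a point mass).
#' @param seed integer seed.
#' @return A [FiberSet-class].
#' @export
genFiberAngles <- function(n = 150, meanDeg = 129.1, sdDeg = 25, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ang <- if (sdDeg > 0) rnorm(n, meanDeg, sdDeg) else rep(meanDeg, n)
  FiberSet(ang %% 180)
}
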