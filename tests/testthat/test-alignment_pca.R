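grid <- seq(1400, 1800, by = 1)

mk_set <- function(mat, angles = rep(0, ncol(mat))) {
  meta <- do.call(rbind, lapply(seq_len(ncol(mat)), function(i)
    meta_row(point = i, angle = angles[i])))
  RamanSpectra(mat, grid, meta, checkAngles = FALSE)
}

test_that("the master loading isolates the varying amide band, sign-fixed", {
  base <- exp(-(grid - 1500)^2 / (2 * 20^2))
  amide <- exp(-(grid - 1665)^2 / (2 * 10^2))
  heights <- seq(0.5, 1.5, length.out = 20)
  mat <- sapply(heights, function(hh) base + hh * amide)
  ld <- deriveLoading(mk_set(mat))
  co <- ld@coefficients
  in_band <- grid >= 1630 & grid <= 1700
  expect_gte(sum(co[in_band]^2) / sum(co^2), 0.95)
  expect_gte(co[which.min(abs(grid - 1665))], 0)
  expect_equal(sum(co^2), 1)
  # single direction of variance dominates
  expect_gt(ld@varianceExplained[1], 0.999)
})

test_that("two spectra differing in one grid point give an indicator loading", {
  mat <- cbind(rep(1, length(grid)), rep(1, length(grid)))
  i <- which.min(abs(grid - 1665))
  mat[i, 2] <- 2
  ld <- deriveLoading(mk_set(mat))
  expect_equal(abs(ld@coefficients[i]), 1, tolerance = 1e-10)
  expect_lt(max(abs(ld@coefficients[-i])), 1e-10)
})

test_that("degenerate reference sets are rejected", {
  mat <- matrix(rep(sin(grid / 40), 110), ncol = 110)
  expect_error(deriveLoading(mk_set(mat)), "identical")
  expect_error(deriveLoading(mk_set(mat[, 1, drop = FALSE])), "at least 2")
})

test_that("projection is the fixed affine map onto the loading", {
  set.seed(7)
  mat <- sapply(1:12, function(i) sin(grid / 40) + rnorm(length(grid), 0, .1))
  ld <- deriveLoading(mk_set(mat))
  # reference mean projects to zero
  s0 <- projectPC1(mk_set(matrix(ld@referenceMean, ncol = 1)), ld)$score
  expect_equal(s0, 0, tolerance = 1e-10)
  # mean + c * coefficients projects to c
  c1 <- 2.71
  s1 <- projectPC1(mk_set(matrix(ld@referenceMean + c1 * ld@coefficients,
                                 ncol = 1)), ld)$score
  expect_equal(s1, c1, tolerance = 1e-10)
  # linearity of the functional
  a <- mat[, 1]; b <- mat[, 2]
  sab <- projectPC1(mk_set(matrix(a + b - ld@referenceMean, ncol = 1)),
                    ld)$score
  sa <- projectPC1(mk_set(matrix(a, ncol = 1)), ld)$score
  sb <- projectPC1(mk_set(matrix(b, ncol = 1)), ld)$score
  expect_equal(sab, sa + sb, tolerance = 1e-8)
  # grid mismatch refuses to project
  short <- RamanSpectra(matrix(rnorm(100), ncol = 1), grid[1:100],
                        meta_row(), checkAngles = FALSE)
  expect_error(projectPC1(short, ld), "grid")
})

test_that("variance-explained fractions are a valid spectrum decomposition", {
  # variance confined to one direction
  mat <- outer(sin(grid / 30), c(1, 2, 3, 4))
  ve <- varianceExplained(mk_set(mat))
  expect_equal(ve[1], 1, tolerance = 1e-10)
  # isotropic noise: n >> d gives near-equal fractions
  set.seed(11)
  d <- 5
  iso <- matrix(rnorm(5 * 4000), nrow = d)   # d "wavenumbers", many spectra
  x <- RamanSpectra(iso, seq(1400, 1440, by = 10),
                    do.call(rbind, lapply(seq_len(ncol(iso)), function(i)
                      meta_row(point = i))), checkAngles = FALSE)
  vi <- varianceExplained(x)
  expect_true(all(abs(vi - 1 / d) < 0.2 / d))
  expect_equal(sum(vi), 1)
  expect_true(all(diff(vi) <= 1e-12))
})

test_that("the sinusoid fit recovers noiseless parameters exactly", {
  ang <- seq(0, 150, by = 30)
  y <- 0.2 + 0.5 * sin(pi * (ang - 30) / 90)
  fit <- fitSine(data.frame(pol_angle_deg = ang, score = y))
  expect_equal(fit@pc1Offset, 0.2, tolerance = 1e-6)
  expect_equal(fit@amplitude, 0.5, tolerance = 1e-6)
  expect_equal(fit@phaseDeg, 30, tolerance = 1e-6)
  expect_true(fit@aligned)
  expect_equal(fit@betaPrsDeg, 75)

  # phase 75 gives the corner-edge alignment angle 120
  y2 <- 0.1 + 0.4 * sin(pi * (ang - 75) / 90)
  fit2 <- fitSine(data.frame(pol_angle_deg = ang, score = y2))
  expect_equal(fit2@phaseDeg, 75, tolerance = 1e-6)
  expect_equal(alignmentAngle(fit2), 120, tolerance = 1e-6)

  # constant scores: amplitude 0, flagged unaligned
  fit3 <- fitSine(data.frame(pol_angle_deg = ang, score = rep(1, 6)))
  expect_equal(fit3@amplitude, 0)
  expect_false(fit3@aligned)
  expect_error(alignmentAngle(fit3), "noise floor")

  expect_error(fitSine(data.frame(pol_angle_deg = c(0, 30),
                                  score = c(1, 2))), "3 distinct")
})

test_that("alignment angles wrap on the axial circle", {
  mk <- function(phi) {
    ang <- seq(0, 150, by = 30)
    fitSine(data.frame(pol_angle_deg = ang,
                       score = sin(pi * (ang - phi) / 90)))
  }
  expect_equal(alignmentAngle(mk(75)), 120, tolerance = 1e-6)
  expect_equal(alignmentAngle(mk(45)), 90, tolerance = 1e-6)
  expect_equal(alignmentAngle(mk(150)), 15, tolerance = 1e-6)
})

test_that("confidence intervals reproduce the t-formula", {
  # critical t for 21 df is 2.080 (two-tailed, alpha = 0.05)
  expect_equal(round(qt(0.975, 21), 3), 2.080)
  ci1 <- confidenceInterval(mean = 0.83, sd = 0.05, n = 22)
  expect_equal(round(unname(ci1), 2), c(0.81, 0.85))
  ci2 <- confidenceInterval(mean = 0.37, sd = 0.06, n = 22)
  expect_equal(round(unname(ci2), 2), c(0.34, 0.40))
  # degenerate: zero SD collapses the interval onto the mean
  ci3 <- confidenceInterval(c(2, 2, 2))
  expect_equal(unname(ci3), c(2, 2))
  expect_error(confidenceInterval(1), "n >= 2")
  # values route agrees with the closed form
  set.seed(3)
  v <- rnorm(22, 0.4, 0.07)
  expect_equal(unname(confidenceInterval(v)),
               unname(confidenceInterval(mean = mean(v), sd = sd(v),
                                         n = 22)))
})

test_that("aspect ratio normalizes by the in-sample maximum", {
  g <- aspectRatio(c(CE = 0.83, ME = 0.37, MC = 0.40))
  expect_equal(round(unname(g), 2), c(1.00, 0.45, 0.48))
  expect_equal(sum(g == 1), 1)
  expect_equal(unname(aspectRatio(c(A = 0.5))), 1)
  expect_equal(unname(aspectRatio(c(a = 2, b = 2))), c(1, 1))
  expect_error(aspectRatio(c(a = 0, b = 1)), "positive")
})

test_that("full pipeline recovers the generator phase and ranks modulation depth", {
  cfg <- preprocessConfig()
  ref <- genReferenceSet(spectrumModel(noiseSd = 0.5, phaseDeg = 90),
                         n = 60, seed = 21)
  ld <- deriveLoading(preprocessSpectra(ref, cfg))

  amps <- c()
  for (m in c(0.1, 0.3, 0.5, 0.8)) {
    mod <- spectrumModel(noiseSd = 0.5, phaseDeg = 40)
    mod$bands$m[4:5] <- m
    set <- genPolarizedSpectra(mod, replicates = 4, seed = 31 + 100 * m)
    fit <- fitSine(projectPC1(preprocessSpectra(set, cfg), ld))
    expect_equal(fit@phaseDeg, 40, tolerance = 5)
    amps <- c(amps, fit@amplitude)
  }
  expect_true(all(diff(amps) > 0))
})

test_that("per-point summaries aggregate amplitudes and phases by location", {
  cfg <- preprocessConfig()
  ref <- genReferenceSet(spectrumModel(noiseSd = 0.3, phaseDeg = 90),
                         n = 40, seed = 2)
  ld <- deriveLoading(preprocessSpectra(ref, cfg))
  set <- genAcquisitionSet(spectrumModel(noiseSd = 0.3, phaseDeg = 75),
                           location = "CE", nroi = 1, npoints = 4,
                           nreplicates = 12, seed = 8)
  sc <- projectPC1(preprocessSpectra(set, cfg), ld)
  sm <- summarizeAlignment(sc)
  expect_equal(nrow(sm), 1)
  expect_equal(sm$n_points, 4)
  expect_equal(sm$beta_prs_deg, 120, tolerance = 2)
  expect_true(sm$ci_lo <= sm$A_mean && sm$A_mean <= sm$ci_hi)
  expect_equal(sm$gamma, 1)
})
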