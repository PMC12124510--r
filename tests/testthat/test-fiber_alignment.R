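test_that("fiber tables read with wrapping, aliases, and row preservation", {
  d <- withr::local_tempdir()
  p <- file.path(d, "fibers.csv")
  set.seed(1)
  tab <- data.frame(fiber_id = 1:150,
                    angle_deg = runif(150, 0, 180),
                    length_um = runif(150, 5, 40),
                    width_um = runif(150, 0.5, 2),
                    straightness = runif(150, 0.8, 1))
  write.csv(tab, p, row.names = FALSE)
  f <- readFiberTable(p)
  expect_equal(nFibers(f), 150)
  expect_equal(length(f@lengthsUm), 150)

  # angles beyond 180 wrap
  write.csv(data.frame(angle_deg = 185), p, row.names = FALSE)
  expect_equal(fiberAngles(readFiberTable(p)), 5)

  # CT-FIRE style column aliases
  write.csv(data.frame(orientation = c(10, 20)), p, row.names = FALSE)
  f2 <- readFiberTable(p, aliases = c(angle_deg = "orientation"))
  expect_equal(fiberAngles(f2), c(10, 20))

  write.csv(data.frame(length_um = 1:3), p, row.names = FALSE)
  expect_error(readFiberTable(p), "angle column")
  write.csv(tab[0, ], p, row.names = FALSE)
  expect_error(readFiberTable(p), "empty")
})

test_that("mean fiber axis is axial, not arithmetic", {
  expect_equal(meanFiberAxis(FiberSet(c(80, 100)))$axis_deg, 90)
  # wrap-around pair: arithmetic mean 90 would be wrong
  expect_equal(meanFiberAxis(FiberSet(c(170, 10)))$axis_deg, 0)
  # isotropic pair has no defined axis
  ax <- meanFiberAxis(FiberSet(c(0, 90)))
  expect_false(ax$defined)
  expect_error(meanFiberAxis(FiberSet(10)), "at least 2")
})

test_that("alignment index spans its limits and matches the wrapped-normal closed form", {
  # perfect alignment
  r1 <- alignmentIndex(FiberSet(rep(129, 150)))
  expect_equal(r1$S, 1)
  expect_equal(r1$mean_axis_deg, 129)
  expect_equal(r1$theta_sd_deg, 0)

  # equal counts at +/- 45 degrees about any axis: S = 0
  r0 <- alignmentIndex(FiberSet(c(45, 135, 45, 135)))
  expect_equal(r0$S, 0, tolerance = 1e-12)

  # wrapped normal sigma = 25 deg: E[cos 2 theta] = exp(-2 sigma^2)
  f <- genFiberAngles(n = 1e5, meanDeg = 129.1, sdDeg = 25, seed = 99)
  r <- alignmentIndex(f)
  sigma <- 25 * pi / 180
  expect_equal(r$S, exp(-2 * sigma^2), tolerance = 0.01)
  expect_equal(r$mean_axis_deg, 129.1, tolerance = 0.5)
  expect_equal(r$theta_sd_deg, 25, tolerance = 0.5)
  expect_error(alignmentIndex(FiberSet(1)), "at least 2")
})

test_that("S is invariant to global rotation and head-tail relabeling", {
  f <- genFiberAngles(n = 400, meanDeg = 40, sdDeg = 30, seed = 4)
  S0 <- alignmentIndex(f)$S
  for (rot in c(17.3, 90, 139)) {
    fr <- FiberSet((fiberAngles(f) + rot) %% 180)
    expect_equal(alignmentIndex(fr)$S, S0, tolerance = 1e-10)
  }
  # theta vs theta + 180 is the same fiber
  f180 <- FiberSet((fiberAngles(f) + 180) %% 180)
  expect_equal(alignmentIndex(f180)$S, S0)
})

test_that("mean axis agrees with brute-force maximization of <cos 2 theta>", {
  for (seed in 1:5) {
    f <- genFiberAngles(n = 60, meanDeg = runif(1, 0, 180), sdDeg = 35,
                        seed = 200 + seed)
    ax <- meanFiberAxis(f)$axis_deg
    cand <- seq(0, 179.9, by = 0.1)
    obj <- vapply(cand, function(a)
      mean(cos(2 * (fiberAngles(f) - a) * pi / 180)), numeric(1))
    brute <- cand[which.max(obj)]
    expect_lt(axialDiff(ax, brute), 0.1 + 1e-9)
  }
})

test_that("polar histograms conserve counts in half-open bins", {
  f <- FiberSet(rep(42, 150))
  h <- polarHistogram(f, 10)
  expect_equal(sum(h$counts), 150)
  expect_equal(h$counts[5], 150)   # [40, 50)

  u <- FiberSet(0:179)
  hu <- polarHistogram(u, 10)
  expect_equal(hu$counts, rep(10, 18))
  expect_error(polarHistogram(u, 7), "divide")

  set.seed(12)
  fr <- FiberSet(runif(333, 0, 180))
  expect_equal(sum(polarHistogram(fr, 15)$counts), 333)
})

test_that("length weighting is available but off by default", {
  f <- FiberSet(c(0, 0, 90), lengthsUm = c(1, 1, 100))
  unw <- alignmentIndex(f)
  lw <- alignmentIndex(f, lengthWeighted = TRUE)
  expect_equal(unw$mean_axis_deg, 0)
  expect_equal(lw$mean_axis_deg, 90, tolerance = 1e-8)
  expect_error(alignmentIndex(FiberSet(c(0, 10)), lengthWeighted = TRUE),
               "lengths")
})
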