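test_that("deformation gradients are exact for affine fields", {
  mesh <- buildMesh(tissueGeometry(elementSize = 0.5))
  pts <- rbind(c(0.3, 0.3), c(2, 5), c(3.9, 9.7))

  A <- diag(c(0.5, 0.9))
  Fs <- deformationGradientAt(mesh, affine_field(mesh, A), pts)
  for (Fm in Fs) expect_equal(Fm, A, tolerance = 1e-12)

  F0 <- deformationGradientAt(mesh, affine_field(mesh, diag(2)), pts)
  for (Fm in F0) expect_equal(Fm, diag(2))

  set.seed(31)
  for (rep in 1:4) {
    Ar <- diag(2) + matrix(rnorm(4, 0, 0.3), 2, 2)
    if (det(Ar) <= 0.05) Ar <- diag(c(1.2, 0.7))
    Fr <- deformationGradientAt(mesh, affine_field(mesh, Ar), pts)
    for (Fm in Fr) expect_equal(Fm, Ar, tolerance = 1e-12)
  }
  expect_error(deformationGradientAt(mesh, affine_field(mesh, A),
                                     c(-1, 5)), "outside")
})

test_that("polar decomposition matches an SVD oracle", {
  expect_equal(polarDecompose(diag(2))$U, diag(2))
  expect_equal(polarDecompose(diag(2))$R, diag(2))

  R30 <- rot2(30)
  pd <- polarDecompose(R30)
  expect_equal(pd$U, diag(2), tolerance = 1e-12)
  expect_equal(pd$R, R30, tolerance = 1e-12)

  set.seed(17)
  for (rep in 1:20) {
    Fm <- matrix(rnorm(4), 2, 2)
    if (det(Fm) <= 0) Fm[, 1] <- -Fm[, 1]
    pd <- polarDecompose(Fm)
    # independent oracle: F = W D V^T  =>  R = W V^T, U = V D V^T
    sv <- svd(Fm)
    s <- sign(det(sv$u %*% t(sv$v)))   # keep R proper
    W <- sv$u; W[, 2] <- s * W[, 2]
    d <- sv$d; d[2] <- s * d[2]
    R_or <- W %*% t(sv$v)
    U_or <- sv$v %*% diag(d) %*% t(sv$v)
    expect_equal(pd$R, R_or, tolerance = 1e-10)
    expect_equal(pd$U, U_or, tolerance = 1e-10)
    # invariants
    expect_equal(crossprod(pd$R), diag(2), tolerance = 1e-10)
    expect_equal(det(pd$R), 1, tolerance = 1e-10)
    expect_equal(pd$U, t(pd$U), tolerance = 1e-12)
    expect_lt(norm(Fm - pd$R %*% pd$U, "F"), 1e-10 * norm(Fm, "F"))
  }
  expect_error(polarDecompose(diag(c(1, -1))), "positive")
})

test_that("deformed ellipses give alpha and the spatial major-axis angle", {
  e1 <- ellipseFromF(diag(c(2, 0.5)))
  expect_equal(e1$alpha, 4)
  expect_equal(e1$beta_model_deg, 0)
  expect_equal(e1$b, 0.05 * 2)
  expect_equal(e1$a, 0.05 * 0.5)

  e2 <- ellipseFromF(rot2(30) %*% diag(c(2, 1)))
  expect_equal(e2$alpha, 2, tolerance = 1e-12)
  expect_equal(e2$beta_model_deg, 30, tolerance = 1e-10)

  e3 <- ellipseFromF(3 * diag(2))
  expect_equal(e3$alpha, 1)
  expect_false(e3$beta_defined)

  # alpha agrees with the stretch ratio from the polar decomposition
  set.seed(23)
  for (rep in 1:10) {
    Fm <- matrix(rnorm(4), 2, 2); if (det(Fm) <= 0) Fm[, 1] <- -Fm[, 1]
    lam <- polarDecompose(Fm)$lambda
    expect_equal(ellipseFromF(Fm)$alpha, lam[1] / lam[2],
                 tolerance = 1e-10)
  }
})

test_that("beta is invariant to seed radius and scale, equivariant to rotation", {
  Fm <- rot2(20) %*% diag(c(3, 1.2))
  b1 <- ellipseFromF(Fm, r = 0.05)$beta_model_deg
  expect_equal(ellipseFromF(Fm, r = 7)$beta_model_deg, b1)
  expect_equal(ellipseFromF(5 * Fm)$beta_model_deg, b1)
  expect_equal(ellipseFromF(5 * Fm)$alpha, ellipseFromF(Fm)$alpha)

  for (q in c(15, 60, 125)) {
    eq <- ellipseFromF(rot2(q) %*% Fm)
    expect_equal(eq$beta_model_deg, (b1 + q) %% 180, tolerance = 1e-8)
    expect_equal(eq$alpha, ellipseFromF(Fm)$alpha, tolerance = 1e-12)
    SQ <- alignmentIndex(embedFibers(rot2(q) %*% Fm, 150))$S
    expect_equal(SQ, alignmentIndex(embedFibers(Fm, 150))$S,
                 tolerance = 1e-10)
  }
})

test_that("embedded fibers transform as material tangents", {
  # single 45-degree fiber under diag(2, 1) rotates to atan(1/2)
  f <- embedFibers(diag(c(2, 1)), 4)   # angles 0, 45, 90, 135
  expect_equal(fiberAngles(f)[2], atan2(1, 2) * 180 / pi,
               tolerance = 1e-10)
  expect_equal(fiberAngles(embedFibers(diag(2), 8)),
               (0:7) * 180 / 8)
})

test_that("equivalent S converges to the pure-stretch closed form (alpha-1)/(alpha+1)", {
  for (alpha in c(2, 3.5, 7.8)) {
    closed <- (alpha - 1) / (alpha + 1)
    # large-n Monte-Carlo-style oracle with uniform fibers
    S_big <- alignmentIndex(embedFibers(diag(c(alpha, 1)), 1e5))$S
    expect_equal(S_big, closed, tolerance = 1e-3)
    # at the working fiber count the deviation stays below 0.02
    S150 <- alignmentIndex(embedFibers(diag(c(alpha, 1)), 150))$S
    expect_lt(abs(S150 - closed), 0.02)
  }
})

test_that("alignment maps are uniform for affine fields and sample regions", {
  mesh <- buildMesh(tissueGeometry(elementSize = 0.5))
  fld <- affine_field(mesh, diag(c(1, 2)))   # stretch along anchors
  map <- alignmentMap(mesh, fld)
  expect_true(all(abs(map$elements$alpha - 2) < 1e-10))
  expect_true(all(abs(map$elements$gamma_model - 1) < 1e-10))
  expect_true(all(abs(map$elements$beta_model_deg - 90) < 1e-8))
  expect_equal(sort(map$regions$location), sort(c("CE", "ME", "MC")))
  expect_equal(map$regions$S_equiv, rep((2 - 1) / (2 + 1), 3),
               tolerance = 0.02)
  bad <- new("DisplacementField", u = fld@u, converged = FALSE,
             residualNorm = 1, epsS = 0)
  expect_error(alignmentMap(mesh, bad), "not converged")
})

test_that("map export writes the element table", {
  mesh <- buildMesh(tissueGeometry(elementSize = 1))
  map <- alignmentMap(mesh, affine_field(mesh, diag(c(0.8, 1))))
  d <- withr::local_tempdir()
  p <- writeAlignmentMap(map, file.path(d, "map.csv"))
  tab <- read.csv(p)
  expect_equal(nrow(tab), nrow(mesh@elements))
  expect_true(all(c("x", "y", "alpha", "beta_model_deg", "gamma_model")
                  %in% colnames(tab)))
  v <- writeVTK(mesh, affine_field(mesh, diag(c(0.8, 1))),
                file.path(d, "u.vtk"))
  expect_true(file.exists(v))
  expect_match(readLines(v, n = 4)[4], "UNSTRUCTURED_GRID")
})
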