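mat <- tissueMaterial()

test_that("mesh construction matches the construct geometry", {
  mesh <- buildMesh(tissueGeometry())
  expect_equal(nrow(mesh@elements), 4000)       # 40 x 100 at 100 um
  expect_equal(nrow(mesh@nodes), 41 * 101)
  # fixed edges are the two 4-mm anchor interfaces
  expect_equal(length(mesh@fixedNodes), 2 * 41)
  expect_true(all(mesh@nodes[mesh@fixedNodes, 2] %in% c(0, 10)))

  coarse <- buildMesh(tissueGeometry(elementSize = 1))
  expect_equal(nrow(coarse@elements), 40)
  expect_error(buildMesh(tissueGeometry(elementSize = 0.3)), "divide")
})

test_that("a free cell-laden patch shrinks stress-free to (1 - eps) scale", {
  mesh <- buildMesh(tissueGeometry(centerW = 0.2, centerH = 0.2,
                                   elementSize = 0.1))
  n <- nrow(mesh@nodes)
  # constrain rigid modes only: pin the center node, stop rotation at one
  # neighbor's y dof (both compatible with a homogeneous stretch about it)
  ctr <- which(mesh@nodes[, 1] == 0.1 & mesh@nodes[, 2] == 0.1)
  nbr <- which(mesh@nodes[, 1] == 0.2 & mesh@nodes[, 2] == 0.1)
  f <- solveContraction(mesh, mat, 0.3, rampSteps = 5,
                        fixedDofs = c(ctr, ctr + n, nbr + n))
  xy <- mesh@nodes + f@u
  rel <- sweep(xy, 2, xy[ctr, ])
  ref <- sweep(mesh@nodes, 2, mesh@nodes[ctr, ])
  expect_equal(rel, 0.7 * ref, tolerance = 1e-6)
  # the exact affine shrinkage state carries no internal force at all
  u_exact <- 0.7 * ref - ref + matrix(f@u[ctr, ], nrow(ref), 2,
                                      byrow = TRUE)
  expect_lt(max(abs(internalForces(mesh, u_exact, mat, 0.3))), 1e-10)
})

test_that("zero shrinkage gives zero displacement", {
  mesh <- buildMesh(tissueGeometry(elementSize = 0.5))
  f <- solveContraction(mesh, mat, 0)
  expect_equal(max(abs(f@u)), 0)
  expect_true(f@converged)
})

test_that("the residual is the gradient of the strain energy", {
  mesh <- buildMesh(tissueGeometry(centerW = 0.4, centerH = 0.6,
                                   elementSize = 0.2))
  set.seed(5)
  u <- matrix(rnorm(2 * nrow(mesh@nodes), 0, 0.01), ncol = 2)
  g <- internalForces(mesh, u, mat, 0.25)
  h <- 1e-6
  idx <- cbind(sample(nrow(u), 12, replace = TRUE),
               sample(2, 12, replace = TRUE))
  for (k in seq_len(nrow(idx))) {
    up <- u; up[idx[k, 1], idx[k, 2]] <- up[idx[k, 1], idx[k, 2]] + h
    um <- u; um[idx[k, 1], idx[k, 2]] <- um[idx[k, 1], idx[k, 2]] - h
    num <- (strainEnergy(mesh, up, mat, 0.25) -
              strainEnergy(mesh, um, mat, 0.25)) / (2 * h)
    expect_equal(g[idx[k, 1], idx[k, 2]], num,
                 tolerance = 1e-5 * max(1, abs(num)))
  }
})

test_that("the discrete energy is frame-indifferent", {
  mesh <- buildMesh(tissueGeometry(centerW = 0.6, centerH = 0.4,
                                   elementSize = 0.2))
  set.seed(9)
  for (rep in 1:3) {
    A <- diag(2) + matrix(rnorm(4, 0, 0.2), 2, 2)
    if (det(A) <= 0.1) A <- diag(c(0.8, 1.1))
    Q <- rot2(runif(1, 0, 360))
    uA <- mesh@nodes %*% t(A) - mesh@nodes
    uQA <- mesh@nodes %*% t(Q %*% A) - mesh@nodes
    eA <- strainEnergy(mesh, uA, mat, 0.2)
    eQA <- strainEnergy(mesh, uQA, mat, 0.2)
    expect_equal(eA, eQA, tolerance = 1e-8)
  }
})

test_that("the construct solution is symmetric about both midlines", {
  run <- coarse_run(0.6, 0.2)
  mesh <- run$mesh; u <- run$field@u
  W <- 4; H <- 10
  key <- function(x, y) paste(round(x, 9), round(y, 9))
  lookup <- setNames(seq_len(nrow(mesh@nodes)),
                     key(mesh@nodes[, 1], mesh@nodes[, 2]))
  mx <- lookup[key(W - mesh@nodes[, 1], mesh@nodes[, 2])]
  my <- lookup[key(mesh@nodes[, 1], H - mesh@nodes[, 2])]
  # x-mirror: u_x flips sign, u_y preserved
  expect_lt(max(abs(u[, 1] + u[mx, 1])), 1e-6)
  expect_lt(max(abs(u[, 2] - u[mx, 2])), 1e-6)
  # y-mirror: u_y flips sign, u_x preserved
  expect_lt(max(abs(u[, 2] + u[my, 2])), 1e-6)
  expect_lt(max(abs(u[, 1] - u[my, 1])), 1e-6)
  # alignment angle at the exact center is the inter-anchor axis
  Fm <- deformationGradientAt(mesh, run$field, c(W / 2, H / 2))[[1]]
  expect_equal(ellipseFromF(Fm)$beta_model_deg, 90, tolerance = 1e-6)
})

test_that("area shrinkage measures the deformed boundary polygon", {
  mesh <- buildMesh(tissueGeometry(elementSize = 0.5))
  zero <- affine_field(mesh, diag(2))
  expect_equal(areaShrinkage(mesh, zero), 0)
  half <- affine_field(mesh, diag(c(0.5, 0.5)))
  expect_equal(areaShrinkage(mesh, half), 0.75, tolerance = 1e-12)
  bad <- new("DisplacementField", u = zero@u, converged = FALSE,
             residualNorm = 1, epsS = 0)
  expect_error(areaShrinkage(mesh, bad), "not converged")
})

test_that("shrinkage-strain fitting selects the area-matching grid point", {
  mesh <- buildMesh(tissueGeometry(elementSize = 0.5))
  fit <- fitShrinkageStrain(0, mesh, mat, grid = seq(0, 0.3, by = 0.1))
  expect_equal(fit$epsS, 0)
  fit2 <- fitShrinkageStrain(0.35, mesh, mat, grid = seq(0, 0.6, by = 0.1))
  # predicted shrinkage is monotone in eps_s over the sweep
  expect_true(all(diff(fit2$sweep$area_shrinkage) > 0))
  expect_equal(fit2$epsS,
               fit2$sweep$eps_s[which.min(abs(fit2$sweep$area_shrinkage -
                                                0.35))])
})
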