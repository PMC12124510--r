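# small in-code fixtures shared across test files

meta_row <- function(location = "CE", roi = 1L, point = 1L,
                     replicate = 1L, angle = 0) {
  data.frame(sample_id = "s1", location = location, roi = roi,
             point = point, replicate = replicate, pol_angle_deg = angle)
}

# a handful of spectra on a simple grid with distinct metadata
tiny_spectra <- function(n = 3, grid = seq(1400, 1800, by = 10)) {
  meta <- do.call(rbind, lapply(seq_len(n), function(i)
    meta_row(point = i, angle = 30 * ((i - 1) %% 6))))
  ints <- sapply(seq_len(n), function(i) sin(grid / 50 + i) + i)
  RamanSpectra(ints, grid, meta)
}

rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

# displacement field object from an explicit affine map x -> A x
affine_field <- function(mesh, A, epsS = 0) {
  u <- mesh@nodes %*% t(A) - mesh@nodes
  new("DisplacementField", u = u, converged = TRUE, residualNorm = 0,
      epsS = epsS)
}

# shared cache for the expensive best-fit FE run used by several
# acceptance checks (computed once per test session)
.fe_cache <- new.env(parent = emptyenv())

best_fit_run <- function() {
  if (is.null(.fe_cache$fit)) {
    mesh <- buildMesh(tissueGeometry())      # 100 um elements
    mat <- tissueMaterial()
    fit <- fitShrinkageStrain(0.60, mesh, mat,
                              grid = seq(0, 0.7, by = 0.05))
    .fe_cache$fit <- list(mesh = mesh, mat = mat, fit = fit,
                          map = alignmentMap(mesh, fit$field))
  }
  .fe_cache$fit
}

coarse_run <- function(epsS = 0.6, h = 0.2) {
  key <- sprintf("coarse_%g_%g", epsS, h)
  if (is.null(.fe_cache[[key]])) {
    mesh <- buildMesh(tissueGeometry(elementSize = h))
    f <- solveContraction(mesh, tissueMaterial(), epsS, rampSteps = 12)
    .fe_cache[[key]] <- list(mesh = mesh, field = f)
  }
  .fe_cache[[key]]
}
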