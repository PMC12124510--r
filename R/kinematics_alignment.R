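#' Deformation gradient at reference points
#'
#' Evaluates `F = I + du/dX` from the bilinear shape-function gradients of
#' the element containing each query point, at that point's local
#' coordinates.  Exact for affine displacement fields.
#'
#' @param mesh a [TissueMesh-class].
#' @param field a [DisplacementField-class] (or n x 2 displacement matrix).
#' @param points numeric (m x 2) reference coordinates, mm, inside the
#'   domain.
#' @return A list of m 2x2 matrices.
#' @export
deformationGradientAt <- function(mesh, field, points) {
  u <- if (is(field, "DisplacementField")) field@u else as.matrix(field)
  points <- matrix(as.numeric(points), ncol = 2)
  h <- mesh@elementSize
  W <- mesh@nx * h; H <- mesh@ny * h
  out <- vector("list", nrow(points))
  for (p in seq_len(nrow(points))) {
    x <- points[p, 1]; y <- points[p, 2]
    if (x < 0 || x > W || y < 0 || y > H)
      stop("point (", x, ", ", y, ") lies outside the reference domain")
    i <- min(mesh@nx, max(1L, 1L + floor(x / h)))
    j <- min(mesh@ny, max(1L, 1L + floor(y / h)))
    e <- (j - 1L) * mesh@nx + i
    conn <- mesh@elements[e, ]
    xi <- 2 * (x - (i - 0.5) * h) / h    # local coords in [-1, 1]
    eta <- 2 * (y - (j - 0.5) * h) / h
    dNdxi <- c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / 4
    dNdeta <- c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4
    dN <- rbind(dNdxi, dNdeta) * (2 / h)
    ue <- u[conn, , drop = FALSE]           # 4 x 2
    Fm <- diag(2) + t(ue) %*% t(dN)         # 2 x 2: I + du/dX
    out[[p]] <- unname(Fm)
  }
  out
}

#' Polar decomposition F = R U
#'
#' Right polar decomposition via the eigendecomposition of `C = F^T F`:
#' `U = sqrt(C)` (symmetric positive definite) and `R = F U^{-1}` (proper
#' rotation).  Requires `det F > 0`.
#'
#' @param F a 2x2 matrix with positive determinant.
#' @return List with `U`, `R`, and the principal stretches
#'   `lambda = c(max, min)` with corresponding `directions` (columns,
#'   reference frame).
#' @export
polarDecompose <- function(F) {
  F <- matrix(as.numeric(F), 2, 2)
  if (det(F) <= 0) stop("det F must be positive")
  C <- crossprod(F)
  e <- eigen(C, symmetric = TRUE)     # values decreasing
  lam <- sqrt(pmax(e$values, 0))
  U <- e$vectors %*% diag(lam) %*% t(e$vectors)
  Uinv <- e$vectors %*% diag(1 / lam) %*% t(e$vectors)
  R <- F %*% Uinv
  list(U = U, R = R, lambda = lam, directions = e$vectors)
}

#' Ellipse deformed from an embedded material circle
#'
#' A circle of radius `r` at a material point deforms under `F` into an
#' ellipse with semi-axes `r * lambda_max` (major, `b`) and
#' `r * lambda_min` (minor, `a`), where lambda are the principal stretches
#' of `U`.  The local alignment factor is `alpha = b / a >= 1` and the
#' model alignment angle `beta_model` is the orientation of the *spatial*
#' major axis -- the principal direction of `F F^T` with largest
#' eigenvalue (equivalently `R` applied to the major eigenvector of `U`) --
#' in degrees on `[0, 180)`.  For isotropic `F` (equal stretches) the angle
#' is undefined.
#'
#' @param F a 2x2 matrix, `det F > 0`.
#' @param r seed circle radius (default 0.05 mm); scales `a` and `b` only.
#' @return List: `a`, `b`, `alpha`, `beta_model_deg` (NA if undefined),
#'   `beta_defined`.
#' @export
ellipseFromF <- function(F, r = 0.05) {
  F <- matrix(as.numeric(F), 2, 2)
  if (det(F) <= 0) stop("det F must be positive")
  B <- tcrossprod(F)                  # F F^T, spatial
  e <- eigen(B, symmetric = TRUE)
  lam <- sqrt(pmax(e$values, 0))      # principal stretches, decreasing
  iso <- (lam[1] - lam[2]) <= 1e-12 * lam[1]
  beta <- if (iso) NA_real_ else
    (atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi) %% 180
  list(a = r * lam[2], b = r * lam[1],
       alpha = lam[1] / lam[2],
       beta_model_deg = beta, beta_defined = !iso)
}

#' Embed uniformly distributed fibers and deform them
#'
#' Seeds `n` fibers at reference angles `theta_i = i * 180 / n`
#' (`i = 0 .. n-1`), maps each unit tangent through `F`, and returns the
#' deformed angles wrapped to `[0, 180)`.  Feeding the result to
#' [alignmentIndex()] gives the equivalent discrete-fiber alignment index
#' of the continuum deformation; for pure stretch with axis ratio `alpha`
#' and `n -> Inf` this converges to `S = (alpha - 1) / (alpha + 1)`.
#'
#' @param F a 2x2 matrix, `det F > 0`.
#' @param n number of fibers (default 150, matching typical fiber counts in
#'   a 100 um x 100 um immunofluorescence ROI).
#' @return A [FiberSet-class] of deformed fiber angles.
#' @export
embedFibers <- function(F, n = 150) {
  F <- matrix(as.numeric(F), 2, 2)
  if (det(F) <= 0) stop("det F must be positive")
  th <- (seq_len(n) - 1) * pi / n
  tx <- cos(th); ty <- sin(th)
  dx <- F[1, 1] * tx + F[1, 2] * ty
  dy <- F[2, 1] * tx + F[2, 2] * ty
  FiberSet((atan2(dy, dx) * 180 / pi) %% 180)
}

# F components at the 4 gauss points of every element; list of 4 lists
.element_gauss_F <- function(mesh, u) {
  pre <- .fem_precompute(mesh)
  ue <- .gather_ue(mesh, u)
  lapply(pre$dNs, function(dN) .def_grad(ue, dN))
}

.alpha_beta_from_F <- function(F11, F12, F21, F22) {
  # eigen-structure of B = F F^T for 2x2, vectorized
  B11 <- F11^2 + F12^2
  B22 <- F21^2 + F22^2
  B12 <- F11 * F21 + F12 * F22
  tr <- B11 + B22
  disc <- sqrt(pmax((B11 - B22)^2 / 4 + B12^2, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  alpha <- sqrt(l1 / pmax(l2, .Machine$double.xmin))
  beta <- (0.5 * atan2(2 * B12, B11 - B22) * 180 / pi) %% 180
  list(alpha = alpha, beta = beta, iso = disc <= 1e-12 * tr)
}

#' Element-wise alignment map and region samples
#'
#' Converts a converged displacement field into a per-element map of the
#' local alignment factor `alpha`, the model alignment angle `beta_model`,
#' and the normalized `gamma_model = alpha / max(alpha)`, each averaged
#' over the element's 2x2 quadrature points (angles averaged axially).
#' Regions of interest are sampled at reference coordinates: by default the
#' corner-edge (CE) element lies on the free lateral edge one element away
#' from the fixed anchor corner, the middle-edge (ME) element on the same
#' free edge at mid-span, and the middle-center (MC) element at the domain
#' center.  For each region the equivalent
#' alignment index `S` is computed with [embedFibers()] (`nFibers` fibers
#' at each quadrature point, averaged).
#'
#' @param mesh a [TissueMesh-class].
#' @param field a converged [DisplacementField-class].
#' @param samplePoints named list of reference (x, y) coordinates for the
#'   sampled regions; `NULL` for the CE/ME/MC defaults.
#' @param nFibers fibers per quadrature point for the equivalent `S`.
#' @return List of class `AlignmentMap`: `elements` (data.frame with
#'   centroid `x`, `y`, `alpha`, `beta_model_deg`, `gamma_model`) and
#'   `regions` (data.frame with `location`, `x`, `y`, `alpha`,
#'   `beta_model_deg`, `S_equiv`, `gamma_model`).
#' @export
alignmentMap <- function(mesh, field, samplePoints = NULL, nFibers = 150) {
  if (!field@converged) stop("displacement field is not converged")
  h <- mesh@elementSize
  W <- mesh@nx * h; H <- mesh@ny * h
  if (is.null(samplePoints))
    samplePoints <- list(CE = c(W - h / 2, 1.5 * h),
                         ME = c(W - h / 2, H / 2),
                         MC = c(W / 2, H / 2))
  Fg <- .element_gauss_F(mesh, field@u)
  ab <- lapply(Fg, function(g) .alpha_beta_from_F(g$F11, g$F12, g$F21,
                                                  g$F22))
  alpha_el <- Reduce(`+`, lapply(ab, `[[`, "alpha")) / 4
  # axial average of the four gauss-point angles
  z <- Reduce(`+`, lapply(ab, function(a) exp(2i * a$beta * pi / 180))) / 4
  beta_el <- (Arg(z) * 90 / pi) %% 180
  cent <- elementCentroids(mesh)
  elements <- data.frame(x = cent[, 1], y = cent[, 2], alpha = alpha_el,
                         beta_model_deg = beta_el,
                         gamma_model = alpha_el / max(alpha_el))
  elem_of <- function(pt) {
    i <- min(mesh@nx, max(1L, 1L + floor(pt[1] / h)))
    j <- min(mesh@ny, max(1L, 1L + floor(pt[2] / h)))
    (j - 1L) * mesh@nx + i
  }
  rows <- lapply(names(samplePoints), function(loc) {
    e <- elem_of(samplePoints[[loc]])
    Smean <- mean(vapply(seq_len(4), function(g) {
      Fm <- matrix(c(Fg[[g]]$F11[e], Fg[[g]]$F21[e],
                     Fg[[g]]$F12[e], Fg[[g]]$F22[e]), 2, 2)
      alignmentIndex(embedFibers(Fm, nFibers))$S
    }, numeric(1)))
    data.frame(location = loc, x = cent[e, 1], y = cent[e, 2],
               alpha = alpha_el[e], beta_model_deg = beta_el[e],
               S_equiv = Smean, gamma_model = NA_real_)
  })
  regions <- do.call(rbind, rows)
  regions$gamma_model <- regions$alpha / max(regions$alpha)
  structure(list(elements = elements, regions = regions,
                 elementSize = h), class = "AlignmentMap")
}

#' Average alignment factor over a physical window
#'
#' Mean of quadrature-point `alpha` values whose reference gauss-point
#' location falls inside the rectangle `[x0, x1] x [y0, y1]`.  Useful for
#' comparing meshes of different resolution over the same physical region.
#'
#' @param mesh a [TissueMesh-class].
#' @param field a [DisplacementField-class].
#' @param window numeric `c(x0, x1, y0, y1)` in mm.
#' @return Scalar mean alpha.
#' @export
alphaInWindow <- function(mesh, field, window) {
  h <- mesh@elementSize
  gp <- c(-1, 1) / sqrt(3)
  pts <- expand.grid(xi = gp, eta = gp)
  cent <- elementCentroids(mesh)
  Fg <- .element_gauss_F(mesh, field@u)
  vals <- c(); keep <- c()
  for (g in seq_len(4)) {
    gx <- cent[, 1] + pts$xi[g] * h / 2
    gy <- cent[, 2] + pts$eta[g] * h / 2
    a <- .alpha_beta_from_F(Fg[[g]]$F11, Fg[[g]]$F12, Fg[[g]]$F21,
                            Fg[[g]]$F22)$alpha
    inw <- gx >= window[1] & gx <= window[2] &
      gy >= window[3] & gy <= window[4]
    vals <- c(vals, a[inw])
  }
  if (!length(vals)) stop("no quadrature points in window")
  mean(vals)
}

#' Export an alignment map as CSV
#'
#' @param map an `AlignmentMap` from [alignmentMap()].
#' @param path output CSV path (element centroid x, y, alpha, beta, gamma).
#' @return `path`, invisibly.
#' @export
writeAlignmentMap <- function(map, path) {
  write.csv(map$elements, path, row.names = FALSE)
  invisible(path)
}

#' Export a mesh and displacement field as legacy VTK
#'
#' ASCII legacy VTK unstructured grid with point displacement data, for
#' visualization in ParaView.
#'
#' @param mesh a [TissueMesh-class].
#' @param field a [DisplacementField-class].
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
writeVTK <- function(mesh, field, path) {
  n <- nrow(mesh@nodes); ne <- nrow(mesh@elements)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "tissue contraction displacement field",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9g %.9g 0", mesh@nodes[, 1], mesh@nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", ne, 5 * ne), con)
  writeLines(sprintf("4 %d %d %d %d", mesh@elements[, 1] - 1L,
                     mesh@elements[, 2] - 1L, mesh@elements[, 3] - 1L,
                     mesh@elements[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("9", ne), con)   # VTK_QUAD
  writeLines(c(sprintf("POINT_DATA %d", n),
               "VECTORS displacement double"), con)
  writeLines(sprintf("%.9g %.9g 0", field@u[, 1], field@u[, 2]), con)
  invisible(path)
}
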