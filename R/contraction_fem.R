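#' Geometry of the dog-bone construct's central region
#'
#' Defaults follow the engineered construct: a 4 mm x 10 mm cell-laden
#' central region spanning the 10 mm gap between the two anchorage wings,
#' 1 mm thick, discretized into 100 um square elements.  Only the central
#' region is meshed; the short (4 mm) edges where the tissue meets the
#' functionalized wings act as fixed boundaries, and the long lateral
#' edges are free, so the strip necks as the gel contracts.  In this frame
#' the inter-anchor (contraction) axis is the y axis, i.e. at 90 degrees.
#'
#' @param centerW width of the strip (x, free edges), mm (default 4).
#' @param centerH span between the anchors (y), mm (default 10).
#' @param thickness out-of-plane thickness, mm (default 1).
#' @param elementSize element edge length, mm (default 0.1 = 100 um); must
#'   divide both `centerW` and `centerH`.
#' @return A list of class `TissueGeometry`.
#' @export
tissueGeometry <- function(centerW = 4, centerH = 10, thickness = 1,
                           elementSize = 0.1) {
  stopifnot(centerW > 0, centerH > 0, thickness > 0, elementSize > 0)
  structure(list(centerW = centerW, centerH = centerH,
                 thickness = thickness, elementSize = elementSize),
            class = "TissueGeometry")
}

#' Material parameters of the collagen gel
#'
#' Compressible neo-Hookean constants for the cell-laden collagen
#' construct: elastic modulus `E` = 700 Pa and Poisson's ratio `nu` = 0.4
#' by default.
#'
#' @param E elastic modulus, Pa (> 0).
#' @param nu Poisson's ratio in `[0, 0.5)`.
#' @return A list of class `TissueMaterial` (also carrying the shear
#'   modulus `mu = E / (2 (1 + nu))` and bulk modulus
#'   `kappa = E / (3 (1 - 2 nu))`).
#' @export
tissueMaterial <- function(E = 700, nu = 0.4) {
  stopifnot(E > 0, nu >= 0, nu < 0.5)
  structure(list(E = E, nu = nu,
                 mu = E / (2 * (1 + nu)),
                 kappa = E / (3 * (1 - 2 * nu))),
            class = "TissueMaterial")
}

#' Build the structured quadrilateral mesh
#'
#' Regular grid of square 4-node elements over the central region, nodes at
#' `(i * h, j * h)`.  The two edges adjoining the adhesion wings (y = 0 and
#' y = centerH) are fully fixed; the lateral edges (x = 0, x = centerW) are
#' free.  All elements are cell-laden.
#'
#' @param geometry a [tissueGeometry()] list.
#' @return A [TissueMesh-class].
#' @export
buildMesh <- function(geometry) {
  h <- geometry$elementSize
  nx <- geometry$centerW / h
  ny <- geometry$centerH / h
  if (abs(nx - round(nx)) > 1e-9 || abs(ny - round(ny)) > 1e-9)
    stop("elementSize must divide both region dimensions")
  nx <- as.integer(round(nx)); ny <- as.integer(round(ny))
  xs <- seq(0, geometry$centerW, length.out = nx + 1)
  ys <- seq(0, geometry$centerH, length.out = ny + 1)
  nodes <- cbind(rep(xs, times = ny + 1), rep(ys, each = nx + 1))
  nid <- function(i, j) (j - 1L) * (nx + 1L) + i   # i in 1..nx+1, j in 1..ny+1
  ii <- rep(seq_len(nx), times = ny)
  jj <- rep(seq_len(ny), each = nx)
  elements <- cbind(nid(ii, jj), nid(ii + 1L, jj),
                    nid(ii + 1L, jj + 1L), nid(ii, jj + 1L))  # CCW
  fixed <- which(nodes[, 2] == 0 | nodes[, 2] == geometry$centerH)
  new("TissueMesh", nodes = nodes, elements = elements,
      cellLaden = rep(TRUE, nrow(elements)), fixedNodes = as.integer(fixed),
      nx = nx, ny = ny, elementSize = h, thickness = geometry$thickness)
}

setMethod("show", "TissueMesh", function(object) {
  cat(sprintf(
    "TissueMesh: %d x %d elements (%g mm), %d nodes, %d fixed\n",
    object@nx, object@ny, object@elementSize, nrow(object@nodes),
    length(object@fixedNodes)))
})

#' Element centroids of a mesh
#' @param mesh a [TissueMesh-class].
#' @return Numeric matrix (ne x 2) of reference centroids, mm.
#' @export
elementCentroids <- function(mesh) {
  x <- matrix(mesh@nodes[mesh@elements, 1], ncol = 4)
  y <- matrix(mesh@nodes[mesh@elements, 2], ncol = 4)
  cbind(rowMeans(x), rowMeans(y))
}

# --- plane-stress compressible neo-Hookean point evaluation ---------------
# psi(F_e, l3) = mu/2 (J^(-2/3) I1 - 3) + kappa/2 (J - 1)^2
# with J = det(F2d) * l3, I1 = tr(F2d^T F2d) + l3^2; the out-of-plane
# elastic stretch l3 solves d psi / d l3 = 0 (plane stress) pointwise.

# vectorized over points; F components as vectors
.plane_stress_l3 <- function(j2, i2, mu, kappa, l3 = NULL, tol = 1e-10,
                             maxit = 60) {
  if (is.null(l3)) l3 <- rep(1, length(j2))
  for (it in seq_len(maxit)) {
    J <- j2 * l3
    Jm23 <- J^(-2 / 3)
    I1 <- i2 + l3^2
    g <- mu * (Jm23 * l3 - (1 / 3) * Jm23 / J * j2 * I1) +
      kappa * (J - 1) * j2
    gp <- mu * ((-2 / 3) * Jm23 / J * j2 * l3 + Jm23 -
                  (1 / 3) * ((-5 / 3) * Jm23 / J^2 * j2^2 * I1 +
                               Jm23 / J * j2 * 2 * l3)) +
      kappa * j2^2
    step <- g / gp
    l3n <- l3 - step
    l3n <- pmax(l3n, 0.2 * l3)   # safeguard positivity
    conv <- max(abs(l3n - l3)) < tol
    l3 <- l3n
    if (conv) break
  }
  l3
}

# first Piola stress (elastic, 2D in-plane block) given elastic F2d and l3
# returns list of P11,P12,P21,P22 vectors
.piola_2d <- function(F11, F12, F21, F22, l3, mu, kappa) {
  j2 <- F11 * F22 - F12 * F21
  J <- j2 * l3
  I1 <- F11^2 + F12^2 + F21^2 + F22^2 + l3^2
  Jm23 <- J^(-2 / 3)
  # F2d^{-T} = 1/j2 * [F22, -F21; -F12, F11]
  iT11 <- F22 / j2; iT12 <- -F21 / j2
  iT21 <- -F12 / j2; iT22 <- F11 / j2
  cvol <- kappa * (J - 1) * J
  list(P11 = mu * Jm23 * (F11 - I1 / 3 * iT11) + cvol * iT11,
       P12 = mu * Jm23 * (F12 - I1 / 3 * iT12) + cvol * iT12,
       P21 = mu * Jm23 * (F21 - I1 / 3 * iT21) + cvol * iT21,
       P22 = mu * Jm23 * (F22 - I1 / 3 * iT22) + cvol * iT22)
}

# shape-function gradients of the bilinear quad on a square of edge h,
# at the 2x2 Gauss points; returns list over gauss points of 2x4 matrices
.quad_dN <- function(h) {
  gp <- c(-1, 1) / sqrt(3)
  pts <- expand.grid(xi = gp, eta = gp)
  lapply(seq_len(4), function(g) {
    xi <- pts$xi[g]; eta <- pts$eta[g]
    dNdxi <- c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / 4
    dNdeta <- c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4
    rbind(dNdxi, dNdeta) * (2 / h)   # d/dX = d/dxi * dxi/dX, dxi/dX = 2/h
  })
}

# deformation gradient components at one gauss point for all elements
# ue: ne x 8 matrix (ux1..ux4, uy1..uy4); dN: 2x4
.def_grad <- function(ue, dN) {
  ux <- ue[, 1:4, drop = FALSE]; uy <- ue[, 5:8, drop = FALSE]
  list(F11 = 1 + drop(ux %*% dN[1, ]), F12 = drop(ux %*% dN[2, ]),
       F21 = drop(uy %*% dN[1, ]), F22 = 1 + drop(uy %*% dN[2, ]))
}

# internal force (ne x 8 element contributions) and total energy
# s: per-element stress-free stretch (1 - eps_s where cell-laden, else 1)
.internal_force <- function(ue, dNs, s, mu, kappa, wdet, l3_cache = NULL,
                            want_energy = FALSE) {
  ne <- nrow(ue)
  fel <- matrix(0, ne, 8)
  energy <- 0
  l3_out <- vector("list", 4)
  ok <- TRUE
  for (g in seq_len(4)) {
    dN <- dNs[[g]]
    Fg <- .def_grad(ue, dN)
    # elastic part: F_e = F / s
    F11 <- Fg$F11 / s; F12 <- Fg$F12 / s
    F21 <- Fg$F21 / s; F22 <- Fg$F22 / s
    j2 <- F11 * F22 - F12 * F21
    if (any(j2 <= 0)) { ok <- FALSE; break }
    i2 <- F11^2 + F12^2 + F21^2 + F22^2
    l3 <- .plane_stress_l3(j2, i2, mu, kappa,
                           l3 = if (is.null(l3_cache)) NULL else
                             l3_cache[[g]])
    l3_out[[g]] <- l3
    P <- .piola_2d(F11, F12, F21, F22, l3, mu, kappa)
    # total referential stress: Js * P_e * F_s^{-T} = s^3 * P_e / s = s^2 P_e
    cs <- s^2 * wdet
    fel[, 1:4] <- fel[, 1:4] +
      outer(cs * P$P11, dN[1, ]) + outer(cs * P$P12, dN[2, ])
    fel[, 5:8] <- fel[, 5:8] +
      outer(cs * P$P21, dN[1, ]) + outer(cs * P$P22, dN[2, ])
    if (want_energy) {
      J <- j2 * l3
      I1 <- i2 + l3^2
      psi <- mu / 2 * (J^(-2 / 3) * I1 - 3) + kappa / 2 * (J - 1)^2
      energy <- energy + sum(s^3 * wdet * psi)
    }
  }
  list(fel = fel, energy = energy, l3 = l3_out, ok = ok)
}

#' Total strain energy of a displacement state
#'
#' Strain energy of the compressible neo-Hookean model (isochoric shear
#' term plus volumetric penalty on the elastic volume ratio), integrated
#' over the reference configuration with the shrinkage split
#' `F = F_e F_s`, `F_s = (1 - epsS) I` in cell-laden elements.  Used by the
#' gradient-consistency checks.
#'
#' @param mesh a [TissueMesh-class].
#' @param u numeric (n x 2) nodal displacement matrix.
#' @param material a [tissueMaterial()] list.
#' @param epsS shrinkage strain magnitude.
#' @return Scalar energy (Pa mm^3 = uJ x 10^-3 scale).
#' @export
strainEnergy <- function(mesh, u, material, epsS) {
  pre <- .fem_precompute(mesh)
  ue <- .gather_ue(mesh, u)
  s <- ifelse(mesh@cellLaden, 1 - epsS, 1)
  r <- .internal_force(ue, pre$dNs, s, material$mu, material$kappa,
                       pre$wdet, want_energy = TRUE)
  if (!r$ok) stop("inverted element (det F_e <= 0) in energy evaluation")
  r$energy
}

#' Internal nodal force vector (residual of the equilibrium equations)
#'
#' The assembled gradient of [strainEnergy()] with respect to the free
#' nodal displacements.
#'
#' @inheritParams strainEnergy
#' @return Numeric matrix (n x 2) of nodal forces (fixed nodes included).
#' @export
internalForces <- function(mesh, u, material, epsS) {
  pre <- .fem_precompute(mesh)
  ue <- .gather_ue(mesh, u)
  s <- ifelse(mesh@cellLaden, 1 - epsS, 1)
  r <- .internal_force(ue, pre$dNs, s, material$mu, material$kappa,
                       pre$wdet)
  if (!r$ok) stop("inverted element (det F_e <= 0)")
  .scatter_forces(mesh, r$fel)
}

.fem_precompute <- function(mesh) {
  h <- mesh@elementSize
  # gauss weight x jacobian x thickness, same for every (square) element
  wdet <- (h / 2)^2 * mesh@thickness
  list(dNs = .quad_dN(h), wdet = wdet)
}

.gather_ue <- function(mesh, u) {
  el <- mesh@elements
  cbind(matrix(u[el, 1], ncol = 4), matrix(u[el, 2], ncol = 4))
}

.scatter_forces <- function(mesh, fel) {
  n <- nrow(mesh@nodes)
  el <- mesh@elements
  fx <- rowsum(as.vector(fel[, 1:4]), as.vector(el), reorder = FALSE)
  fy <- rowsum(as.vector(fel[, 5:8]), as.vector(el), reorder = FALSE)
  f <- matrix(0, n, 2)
  f[as.integer(rownames(fx)), 1] <- fx
  f[as.integer(rownames(fy)), 2] <- fy
  f
}

# assemble sparse tangent by central differences on element displacements
.tangent <- function(mesh, ue, s, mu, kappa, pre, l3_cache, du = 1e-7) {
  ne <- nrow(ue)
  el <- mesh@elements
  n <- nrow(mesh@nodes)
  gdof <- cbind(el, el + n)   # ne x 8 global dof ids (x dofs then y dofs)
  blocks <- vector("list", 8)
  for (k in seq_len(8)) {
    up <- ue; up[, k] <- up[, k] + du
    um <- ue; um[, k] <- um[, k] - du
    rp <- .internal_force(up, pre$dNs, s, mu, kappa, pre$wdet, l3_cache)
    rm <- .internal_force(um, pre$dNs, s, mu, kappa, pre$wdet, l3_cache)
    if (!rp$ok || !rm$ok) return(NULL)
    blocks[[k]] <- (rp$fel - rm$fel) / (2 * du)   # ne x 8: d f_j / d u_k
  }
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  ii <- rep(as.vector(gdof), times = 8)                 # row: force dof j
  jj <- as.vector(gdof[, rep(seq_len(8), each = 8)])    # col: displaced dof k
  xx <- unlist(lapply(seq_len(8), function(k) as.vector(blocks[[k]])),
               use.names = FALSE)
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(2 * n, 2 * n))
}

#' Solve the cell-contraction problem
#'
#' Total-Lagrangian Newton solution of the plane-stress compressible
#' neo-Hookean model under a multiplicative shrinkage split
#' `F = F_e F_s` with `F_s = (1 - epsS) I` in cell-laden elements: the
#' stress-free state of contracted material is an isotropically shrunken
#' copy of itself, and elastic stress arises only from the deviation
#' `F_e = F F_s^{-1}`.  The out-of-plane elastic stretch is solved
#' pointwise for zero transverse stress (plane stress).  The load is ramped
#' in `rampSteps` increments with full Newton iteration per step and
#' automatic step halving (up to 5 times) on divergence or element
#' inversion.
#'
#' @param mesh a [TissueMesh-class].
#' @param material a [tissueMaterial()] list.
#' @param epsS shrinkage strain magnitude in `[0, 1)`.
#' @param rampSteps number of load increments (default 20).
#' @param tol relative residual tolerance (default 1e-8).
#' @param maxNewton Newton iteration cap per increment.
#' @param init optional [DisplacementField-class] (or n x 2 matrix) used as
#'   the starting state, e.g. the converged solution at a smaller `epsS`
#'   (continuation); the ramp then runs from that field's `epsS` to `epsS`.
#' @param fixedDofs optional integer vector of constrained global degrees
#'   of freedom (x dof of node `i` is `i`, y dof is `i + n`), overriding
#'   the mesh's fixed-node set; used e.g. to constrain only rigid-body
#'   modes in patch tests.
#' @param quiet suppress progress messages.
#' @return A [DisplacementField-class].
#' @export
solveContraction <- function(mesh, material, epsS, rampSteps = 20,
                             tol = 1e-8, maxNewton = 30, init = NULL,
                             fixedDofs = NULL, quiet = TRUE) {
  stopifnot(epsS >= 0, epsS < 1)
  n <- nrow(mesh@nodes)
  u <- matrix(0, n, 2)
  eps0 <- 0
  if (!is.null(init)) {
    if (is(init, "DisplacementField")) {
      u <- init@u; eps0 <- init@epsS
    } else u <- as.matrix(init)
  }
  if (epsS == eps0)
    return(new("DisplacementField", u = u, converged = TRUE,
               residualNorm = 0, epsS = epsS))
  pre <- .fem_precompute(mesh)
  if (is.null(fixedDofs))
    fixedDofs <- c(mesh@fixedNodes, mesh@fixedNodes + n)
  free <- setdiff(seq_len(2 * n), fixedDofs)
  mu <- material$mu; kappa <- material$kappa
  targets <- eps0 + (epsS - eps0) * seq_len(rampSteps) / rampSteps
  i <- 1; halvings <- 0
  eps_cur <- eps0
  res_norm <- NA_real_
  # force scale for the relative residual: reaction magnitude of a fully
  # clamped uniform shrinkage state
  fscale <- material$E * mesh@thickness * mesh@elementSize
  while (i <= length(targets)) {
    eps_try <- targets[i]
    s <- ifelse(mesh@cellLaden, 1 - eps_try, 1)
    u_try <- u
    ok <- FALSE
    for (it in seq_len(maxNewton)) {
      ue <- .gather_ue(mesh, u_try)
      r <- .internal_force(ue, pre$dNs, s, mu, kappa, pre$wdet)
      if (!r$ok) break
      fvec <- .scatter_forces(mesh, r$fel)
      res <- c(fvec[, 1], fvec[, 2])[free]
      res_norm <- sqrt(sum(res^2)) / fscale
      if (res_norm < tol) { ok <- TRUE; break }
      K <- .tangent(mesh, ue, s, mu, kappa, pre, r$l3)
      if (is.null(K)) break
      Kff <- K[free, free]
      duf <- tryCatch(as.numeric(Matrix::solve(Kff, res)),
                      error = function(e) NULL)
      if (is.null(duf) || any(!is.finite(duf))) break
      full <- numeric(2 * n); full[free] <- duf
      u_try <- u_try - cbind(full[seq_len(n)], full[n + seq_len(n)])
    }
    if (ok) {
      u <- u_try; eps_cur <- eps_try; i <- i + 1; halvings <- 0
      if (!quiet) message(sprintf("eps = %.4f converged (res %.2e)",
                                  eps_cur, res_norm))
    } else {
      halvings <- halvings + 1
      if (halvings > 5)
        stop("Newton diverged after 5 step halvings at eps = ",
             signif(eps_try, 4), " (last relative residual ",
             signif(res_norm, 3), ")")
      # insert a midpoint target between current state and failed target
      targets <- c(targets[seq_len(i - 1)], (eps_cur + eps_try) / 2,
                   targets[i:length(targets)])
    }
  }
  new("DisplacementField", u = u, converged = TRUE,
      residualNorm = res_norm, epsS = epsS)
}

setMethod("show", "DisplacementField", function(object) {
  cat(sprintf(
    "DisplacementField: eps_s = %.3f, %s, relative residual %.2e\n",
    object@epsS, if (object@converged) "converged" else "NOT converged",
    object@residualNorm))
})

#' Fractional area shrinkage of the cell-laden region
#'
#' `1 - deformed area / reference area`, with the deformed area computed by
#' the shoelace formula on the deformed boundary polygon of the cell-laden
#' region.
#'
#' @param mesh a [TissueMesh-class].
#' @param field a converged [DisplacementField-class].
#' @return Fraction in `[0, 1)` (0 for zero displacement).
#' @export
areaShrinkage <- function(mesh, field) {
  if (!field@converged) stop("displacement field is not converged")
  xy <- mesh@nodes + field@u
  nx <- mesh@nx; ny <- mesh@ny
  nid <- function(i, j) (j - 1L) * (nx + 1L) + i
  ring <- c(nid(seq_len(nx + 1L), 1L),
            nid(nx + 1L, 2:(ny + 1L)),
            nid(rev(seq_len(nx)), ny + 1L),
            nid(1L, rev(seq_len(ny))))
  px <- xy[ring, 1]; py <- xy[ring, 2]
  area <- abs(sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py)) / 2
  ref <- mesh@nx * mesh@ny * mesh@elementSize^2
  1 - area / ref
}

#' Fit the shrinkage strain to a measured area change
#'
#' Sweeps the shrinkage strain over a grid (warm-starting each solve from
#' the previous grid point, so the sweep is one continuation run) and
#' returns the grid value minimizing the absolute difference between the
#' simulated and target area shrinkage; ties resolve to the smaller strain.
#' Grid points that fail to converge are skipped with a warning.
#'
#' @param target target fractional area shrinkage in `(0, 1)`.
#' @param mesh a [TissueMesh-class].
#' @param material a [tissueMaterial()] list.
#' @param grid shrinkage-strain grid (default `seq(0, 0.7, by = 0.05)`).
#' @param rampStepsPerPoint ramp increments between consecutive grid points.
#' @return List: `epsS` (best fit), `sweep` (data.frame of `eps_s`,
#'   `area_shrinkage`), `field` (the displacement field at the best fit).
#' @export
fitShrinkageStrain <- function(target, mesh, material,
                               grid = seq(0, 0.7, by = 0.05),
                               rampStepsPerPoint = 2) {
  stopifnot(target >= 0, target < 1, all(grid >= 0), all(grid < 1))
  grid <- sort(unique(grid))
  shr <- rep(NA_real_, length(grid))
  fields <- vector("list", length(grid))
  prev <- NULL
  for (i in seq_along(grid)) {
    f <- tryCatch(
      solveContraction(mesh, material, grid[i],
                       rampSteps = rampStepsPerPoint, init = prev),
      error = function(e) {
        warning("eps_s = ", grid[i], " skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(f)) {
      shr[i] <- areaShrinkage(mesh, f)
      fields[[i]] <- f
      prev <- f
    }
  }
  ok <- which(!is.na(shr))
  if (!length(ok)) stop("no grid point converged")
  best <- ok[which.min(abs(shr[ok] - target))]
  list(epsS = grid[best],
       sweep = data.frame(eps_s = grid, area_shrinkage = shr),
       field = fields[[best]])
}
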