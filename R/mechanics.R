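# Growing finite-element mechanics.
#
# Each cell is refined into 2D three-node membrane triangles that never
# cross cell boundaries.  A linear St. Venant (Kirchhoff) isotropic
# material is used under plane stress with unit thickness: with Green
# strain Eg = (F'F - I)/2 of the map F from the element rest shape to its
# current shape, the stored energy density is
#     W = lambda/2 * tr(Eg)^2 + mu * tr(Eg^2),
# lambda = E*nu/(1-nu^2), mu = E/(2(1+nu)).  Growth multiplies the rest
# configuration by G = R diag(exp(k_par*dt), exp(k_per*dt)) R' with R
# rotating the cell polarity onto the first axis; equilibrium is then
# re-solved and residual stresses released (rest := current).

plane_stress_lame <- function(E, nu) {
  list(lambda = E * nu / (1 - nu^2), mu = E / (2 * (1 + nu)))
}

# Assemble the element structure from the current cell polygons; rest
# configuration = current configuration (stress-free), as after a
# residual-stress release.
#
# fem fields:
#   nodes  m x 2 current node positions (rows 1..n_v are tissue vertices,
#          then one centroid node per fanned cell)
#   n_vert number of tissue-vertex rows
#   idx    e x 3 node indices per element
#   cell   owning cell *index* (into the tissue's current cell arrays)
#   Bm     e x 4 inverse rest-shape matrices (b11, b21, b12, b22)
#   A0     e rest areas
#   E, nu, lambda, mu material constants

#' Build finite elements for every cell
#'
#' Triangulates each cell (centroid fan for star-shaped cells, ear clipping
#' otherwise) and stores a stress-free rest configuration equal to the
#' current geometry.  Called at the start of every growth step and after
#' divisions, which is valid because residual stresses are released at the
#' end of every step.
#'
#' @param tissue a tissue.
#' @param E Young's modulus (MPa), default 100.
#' @param nu Poisson ratio, default 0.3.
#' @return the tissue with \code{$fem} populated.
#' @export
fem_build <- function(tissue, E = 100, nu = 0.3) {
  n_v <- nrow(tissue$pos)
  extra <- list()
  idx <- vector("list", n_cells(tissue))
  cellv <- vector("list", n_cells(tissue))
  next_node <- n_v
  for (i in seq_along(tissue$ring)) {
    r <- tissue$ring[[i]]
    p <- tissue$pos[r, , drop = FALSE]
    tr <- tryCatch(triangulate_polygon(p), error = function(e)
      stop("triangulation failed for cell ", tissue$cell_id[i], ": ",
           conditionMessage(e)))
    if (!is.na(tr$centroid_node)) {
      next_node <- next_node + 1L
      extra[[length(extra) + 1L]] <- tr$nodes[tr$centroid_node, ]
      glob <- c(r, next_node)
    } else {
      glob <- r
    }
    idx[[i]] <- matrix(glob[tr$tri], ncol = 3)
    cellv[[i]] <- rep(i, nrow(tr$tri))
  }
  nodes <- rbind(tissue$pos,
                 if (length(extra)) do.call(rbind, extra) else NULL)
  idx <- do.call(rbind, idx)
  lame <- plane_stress_lame(E, nu)
  fem <- list(nodes = nodes, n_vert = n_v, idx = idx,
              cell = unlist(cellv, use.names = FALSE),
              E = E, nu = nu, lambda = lame$lambda, mu = lame$mu)
  fem <- fem_set_rest(fem)
  fem <- fem_make_S(fem)
  tissue$fem <- fem
  tissue
}

# rest := current (used at build time and by release_residual_stress)
fem_set_rest <- function(fem) {
  n <- fem$nodes
  i1 <- fem$idx[, 1]; i2 <- fem$idx[, 2]; i3 <- fem$idx[, 3]
  d11 <- n[i2, 1] - n[i1, 1]; d21 <- n[i2, 2] - n[i1, 2]
  d12 <- n[i3, 1] - n[i1, 1]; d22 <- n[i3, 2] - n[i1, 2]
  det <- d11 * d22 - d12 * d21
  if (any(det <= 0)) stop("degenerate or inverted rest triangle")
  fem$Bm <- cbind(d22 / det, -d21 / det, -d12 / det, d11 / det)
  fem$A0 <- det / 2
  fem
}

# Energy and gradient of the St. Venant membrane assembly at node
# positions `nodes` (m x 2).  Returns list(energy, grad (m x 2)).
# An inverted-element guard adds a convex quadratic penalty below
# det F = det_floor so that minimization is pushed back to det F > 0;
# with the step sizes used by the simulator it never engages.
fem_energy_grad <- function(fem, nodes, want_grad = TRUE, det_floor = 0.05) {
  i1 <- fem$idx[, 1]; i2 <- fem$idx[, 2]; i3 <- fem$idx[, 3]
  b11 <- fem$Bm[, 1]; b21 <- fem$Bm[, 2]; b12 <- fem$Bm[, 3]; b22 <- fem$Bm[, 4]
  d11 <- nodes[i2, 1] - nodes[i1, 1]; d21 <- nodes[i2, 2] - nodes[i1, 2]
  d12 <- nodes[i3, 1] - nodes[i1, 1]; d22 <- nodes[i3, 2] - nodes[i1, 2]
  f11 <- d11 * b11 + d12 * b21; f12 <- d11 * b12 + d12 * b22
  f21 <- d21 * b11 + d22 * b21; f22 <- d21 * b12 + d22 * b22
  c11 <- f11 * f11 + f21 * f21
  c12 <- f11 * f12 + f21 * f22
  c22 <- f12 * f12 + f22 * f22
  e11 <- (c11 - 1) / 2; e12 <- c12 / 2; e22 <- (c22 - 1) / 2
  trE <- e11 + e22
  trE2 <- e11 * e11 + 2 * e12 * e12 + e22 * e22
  la <- fem$lambda; mu <- fem$mu
  w <- la / 2 * trE * trE + mu * trE2
  detF <- f11 * f22 - f12 * f21
  inv <- detF < det_floor
  kpen <- fem$E
  energy <- sum(fem$A0 * w)
  if (any(inv)) {
    energy <- energy + sum(fem$A0[inv] * kpen * (det_floor - detF[inv])^2)
  }
  out <- list(energy = energy, n_inverted = sum(detF <= 0))
  if (!want_grad) return(out)
  s11 <- la * trE + 2 * mu * e11
  s12 <- 2 * mu * e12
  s22 <- la * trE + 2 * mu * e22
  p11 <- f11 * s11 + f12 * s12; p12 <- f11 * s12 + f12 * s22
  p21 <- f21 * s11 + f22 * s12; p22 <- f21 * s12 + f22 * s22
  if (any(inv)) {
    # d/dF of kpen*(floor - detF)^2 = -2*kpen*(floor - detF) * cof(F)
    cf <- -2 * kpen * (det_floor - detF[inv])
    p11[inv] <- p11[inv] + cf * f22[inv]
    p12[inv] <- p12[inv] - cf * f21[inv]
    p21[inv] <- p21[inv] - cf * f12[inv]
    p22[inv] <- p22[inv] + cf * f11[inv]
  }
  # H = A0 * P %*% t(Bm); columns of H are dW/dx2, dW/dx3
  h11 <- fem$A0 * (p11 * b11 + p12 * b12)
  h12 <- fem$A0 * (p11 * b21 + p12 * b22)
  h21 <- fem$A0 * (p21 * b11 + p22 * b12)
  h22 <- fem$A0 * (p21 * b21 + p22 * b22)
  gx <- c(-(h11 + h12), h11, h12)
  gy <- c(-(h21 + h22), h21, h22)
  if (!is.null(fem$S)) {
    grad <- cbind(as.vector(fem$S %*% gx), as.vector(fem$S %*% gy))
  } else {
    m <- nrow(nodes)
    ii <- c(i1, i2, i3)
    grad <- cbind(
      unname(rowsum(c(gx, double(m)), c(ii, seq_len(m)))[, 1]),
      unname(rowsum(c(gy, double(m)), c(ii, seq_len(m)))[, 1]))
  }
  out$grad <- grad
  out
}

# Precompute the node-assembly scatter matrix (m x 3e) used to accumulate
# per-element gradient contributions.
fem_make_S <- function(fem) {
  e <- nrow(fem$idx)
  fem$S <- Matrix::sparseMatrix(
    i = c(fem$idx[, 1], fem$idx[, 2], fem$idx[, 3]),
    j = seq_len(3L * e), x = 1,
    dims = c(nrow(fem$nodes), 3L * e))
  fem
}

#' Total elastic energy of the tissue
#'
#' @param tissue a tissue with \code{$fem} built.
#' @return scalar energy (MPa times area units, unit thickness).
#' @export
elastic_energy <- function(tissue) {
  stopifnot(!is.null(tissue$fem))
  fem_energy_grad(tissue$fem, tissue$fem$nodes, want_grad = FALSE)$energy
}

#' Per-node elastic forces
#'
#' Forces are minus the gradient of the elastic energy with respect to
#' node positions (tissue vertices first, then cell centroid nodes).
#'
#' @param tissue a tissue with \code{$fem} built.
#' @return matrix (n_nodes x 2) of forces.
#' @export
elastic_forces <- function(tissue) {
  stopifnot(!is.null(tissue$fem))
  -fem_energy_grad(tissue$fem, tissue$fem$nodes)$grad
}

#' Apply specified growth to element rest configurations
#'
#' Each element belonging to cell i has its rest shape mapped by
#' G = R diag(exp(k_par*dt), exp(k_per*dt)) R', where R rotates the cell's
#' polarity direction onto the first axis.  Rest areas multiply by
#' exp((k_par + k_per) * dt).  Exponential-in-dt growth makes the specified
#' rates step-size independent.
#'
#' @param tissue a tissue with \code{$fem} built and per-cell
#'   \code{k_par}, \code{k_per}, \code{polarity} assigned.
#' @param dt time step (days), > 0.
#' @return the tissue with grown rest configurations.
#' @export
apply_growth <- function(tissue, dt) {
  stopifnot(!is.null(tissue$fem), dt >= 0)
  if (dt == 0) return(tissue)
  fem <- tissue$fem
  ci <- fem$cell
  px <- tissue$polarity[ci, 1]; py <- tissue$polarity[ci, 2]
  pn <- px * px + py * py
  if (any(!is.finite(pn) | abs(pn - 1) > 1e-6))
    stop("unset or non-unit polarity on a growing cell")
  a <- exp(-tissue$k_par[ci] * dt)   # inverse stretches (applied to Bm)
  b <- exp(-tissue$k_per[ci] * dt)
  gi11 <- a * px * px + b * py * py
  gi12 <- (a - b) * px * py
  gi22 <- a * py * py + b * px * px
  b11 <- fem$Bm[, 1]; b21 <- fem$Bm[, 2]; b12 <- fem$Bm[, 3]; b22 <- fem$Bm[, 4]
  # Bm' = Bm %*% Ginv  (Ginv symmetric)
  fem$Bm <- cbind(b11 * gi11 + b12 * gi12,
                  b21 * gi11 + b22 * gi12,
                  b11 * gi12 + b12 * gi22,
                  b21 * gi12 + b22 * gi22)
  fem$A0 <- fem$A0 * exp((tissue$k_par[ci] + tissue$k_per[ci]) * dt)
  tissue$fem <- fem
  tissue
}

# Minimize the assembly energy over unconstrained node coordinates.
# free_mask: logical (m x 2) marking free DOFs.  Deterministic.
solve_fem <- function(fem, free_mask, tol, max_iter = 5000L) {
  if (is.null(fem$S)) fem <- fem_make_S(fem)
  nodes <- fem$nodes
  free <- which(free_mask)
  cache <- new.env(parent = emptyenv())
  eval_at <- function(par) {
    if (!is.null(cache$par) && identical(cache$par, par)) return(cache$eg)
    nd <- nodes; nd[free] <- par
    eg <- fem_energy_grad(fem, nd)
    cache$par <- par; cache$eg <- eg
    eg
  }
  fn <- function(par) eval_at(par)$energy
  gr <- function(par) eval_at(par)$grad[free]
  par <- nodes[free]
  for (attempt in 1:6) {
    res <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = max_iter, factr = 10,
                                       pgtol = tol / 4))
    par <- res$par
    g <- gr(par)
    if (max(abs(g)) < tol) {
      nodes[free] <- par
      return(list(nodes = nodes, residual = max(abs(g)),
                  energy = res$value))
    }
  }
  stop(sprintf(
    "equilibrium failed to converge: residual force %.3e > tol %.3e",
    max(abs(g)), tol))
}

#' Solve mechanical equilibrium
#'
#' Quasi-Newton (L-BFGS-B) minimization of the elastic energy with the
#' analytic gradient, subject to Dirichlet constraints: base vertices are
#' fixed in the longitudinal (y) direction, the anchor vertex is fully
#' fixed, all other coordinates are free.  Converges when the largest
#' residual force component on the free coordinates is below \code{tol}.
#'
#' @param tissue a tissue with \code{$fem} built.
#' @param tol residual force tolerance; default
#'   \code{1e-8 * E * mean(rest areas)}.
#' @param max_iter maximum L-BFGS-B iterations per attempt.
#' @return the tissue with updated vertex (and centroid-node) positions.
#' @export
solve_equilibrium <- function(tissue, tol = NULL, max_iter = 5000L) {
  fem <- tissue$fem
  stopifnot(!is.null(fem))
  if (is.null(tol)) tol <- 1e-8 * fem$E * mean(fem$A0)
  m <- nrow(fem$nodes)
  free_mask <- matrix(TRUE, m, 2)
  nv <- fem$n_vert
  free_mask[seq_len(nv), 1] <- tissue$constraint != CONSTRAINT_FIXED
  free_mask[seq_len(nv), 2] <- tissue$constraint == CONSTRAINT_NONE
  sol <- solve_fem(fem, free_mask, tol, max_iter)
  tissue$fem$nodes <- sol$nodes
  tissue$pos <- sol$nodes[seq_len(nv), , drop = FALSE]
  attr(tissue, "equilibrium_residual") <- sol$residual
  tissue
}

#' Release residual stresses
#'
#' Replaces every element's rest configuration by its current shape, so the
#' elastic energy is exactly zero afterwards and retriangulation after cell
#' division changes no force distribution (all forces are zero before and
#' after).  Idempotent.
#'
#' @param tissue a tissue with \code{$fem} built.
#' @return the tissue, stress-free.
#' @export
release_residual_stress <- function(tissue) {
  stopifnot(!is.null(tissue$fem))
  tissue$fem <- fem_set_rest(tissue$fem)
  tissue
}

#' Single-element uniaxial plane-stress material test
#'
#' Builds a unit square of two membrane triangles with the default
#' material, imposes a small axial (x) strain with free lateral
#' contraction, solves equilibrium and reports the effective stiffness
#' (axial engineering stress over axial strain) and the magnitude of the
#' lateral-to-axial strain ratio.  For the St. Venant plane-stress model
#' these recover Young's modulus and the Poisson ratio up to O(strain).
#'
#' @param E Young's modulus (MPa).
#' @param nu Poisson ratio.
#' @param strain imposed axial strain (default 1e-4).
#' @return list with \code{E_eff} (MPa) and \code{nu_eff}.
#' @export
material_test <- function(E = 100, nu = 0.3, strain = 1e-4) {
  nodes <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  fem <- list(nodes = nodes, n_vert = 4L,
              idx = rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)),
              cell = c(1L, 1L), E = E, nu = nu)
  lame <- plane_stress_lame(E, nu)
  fem$lambda <- lame$lambda; fem$mu <- lame$mu
  fem <- fem_set_rest(fem)
  # impose: left edge x = 0, right edge x = 1 + strain, pin y of node 1
  fem$nodes[c(2, 3), 1] <- 1 + strain
  free <- matrix(TRUE, 4, 2)
  free[, 1] <- FALSE                 # all x prescribed
  free[1, 2] <- FALSE                # remove rigid y translation
  tol <- 1e-8 * E * mean(fem$A0)
  sol <- solve_fem(fem, free, tol)
  nd <- sol$nodes
  h <- (nd[3, 2] + nd[4, 2]) / 2 - (nd[1, 2] + nd[2, 2]) / 2
  lateral_strain <- h - 1
  g <- fem_energy_grad(fem, nd)$grad
  reaction <- g[2, 1] + g[3, 1]      # force transmitted through the clamp
  sigma <- reaction / 1              # engineering stress, unit rest section
  list(E_eff = sigma / strain, nu_eff = -lateral_strain / strain)
}
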