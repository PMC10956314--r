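## One-timestep movement: deterministic bulk-field diffusion (forward Euler
## on Fick's second law, 6-neighbor stencil) and stochastic Brownian
## displacement of point particles with specular reflection and
## compartment restriction.

#' One forward-Euler diffusion step of a bulk concentration field
#'
#' Updates per-voxel amounts by the explicit 6-neighbor finite-difference
#' stencil: `N_i' = N_i + (D dt / h^2) * sum_j (N_j - N_i)` over the face
#' neighbors `j` accessible to the species; flux across interfaces to
#' restricted compartments is zero. Pair fluxes are applied
#' antisymmetrically, so total amount is conserved exactly up to
#' floating point. The stability bound `D dt / h^2 <= 1/6` is enforced.
#'
#' @param field numeric 3-D array of molecule amounts per voxel.
#' @param D diffusion coefficient (um^2/s).
#' @param dt timestep (s).
#' @param lattice a [VoxelLattice-class].
#' @param species the bulk [Species-class] (accessibility and error naming).
#' @return the updated 3-D array.
#' @export
bulkDiffusionStep <- function(field, D, dt, lattice, species) {
  alpha <- D * dt / lattice@h^2
  if (alpha > 1 / 6 + 1e-12)
    stop(sprintf("stability violation for species '%s': D*dt/h^2 = %.4g > 1/6",
                 species@name, alpha))
  if (alpha == 0) return(field)
  acc <- accessibilityMask(species, lattice)
  d <- lattice@dims
  out <- field
  if (d[1L] > 1L) {
    a <- seq_len(d[1L] - 1L); b <- a + 1L
    flux <- alpha * (field[b, , , drop = FALSE] - field[a, , , drop = FALSE]) *
      (acc[a, , , drop = FALSE] & acc[b, , , drop = FALSE])
    out[a, , ] <- out[a, , , drop = FALSE] + flux
    out[b, , ] <- out[b, , , drop = FALSE] - flux
  }
  if (d[2L] > 1L) {
    a <- seq_len(d[2L] - 1L); b <- a + 1L
    flux <- alpha * (field[, b, , drop = FALSE] - field[, a, , drop = FALSE]) *
      (acc[, a, , drop = FALSE] & acc[, b, , drop = FALSE])
    out[, a, ] <- out[, a, , drop = FALSE] + flux
    out[, b, ] <- out[, b, , drop = FALSE] - flux
  }
  if (d[3L] > 1L) {
    a <- seq_len(d[3L] - 1L); b <- a + 1L
    flux <- alpha * (field[, , b, drop = FALSE] - field[, , a, drop = FALSE]) *
      (acc[, , a, drop = FALSE] & acc[, , b, drop = FALSE])
    out[, , a] <- out[, , a, drop = FALSE] + flux
    out[, , b] <- out[, , b, drop = FALSE] - flux
  }
  out
}

#' One Brownian step of point particles
#'
#' Displaces each free axis by an independent Gaussian draw with standard
#' deviation `sqrt(2 D dt)`. Membrane-bound species currently in a 2-D
#' membrane compartment keep their frozen-axis (outward normal) coordinate. The
#' proposed positions are passed through [reflectPosition()] so that every
#' particle ends in bounds and in a voxel accessible to its species.
#'
#' @param pos numeric n x 3 matrix of positions (um); a bare length-3
#'   vector is treated as one particle.
#' @param species the particle [Species-class].
#' @param D diffusion coefficient (um^2/s).
#' @param dt timestep (s).
#' @param lattice a [VoxelLattice-class].
#' @return matrix (or vector, matching the input shape) of new positions.
#' @export
particleStep <- function(pos, species, D, dt, lattice) {
  single <- is.null(dim(pos))
  if (single) pos <- matrix(pos, ncol = 3L)
  n <- nrow(pos)
  if (n == 0L) return(pos)
  disp <- matrix(stats::rnorm(3L * n, sd = sqrt(2 * D * dt)), n, 3L)
  if (species@membraneBound) {
    lin <- .linIndex(voxelOf(pos, lattice), lattice@dims)
    inMem <- lattice@membrane2d[lattice@compartmentOf[lin]]
    if (any(inMem)) {
      fr <- lattice@frozenAxis[lin]
      rows <- which(inMem & fr > 0L)
      disp[cbind(rows, fr[rows])] <- 0
    }
  }
  out <- reflectPosition(pos, pos + disp, species, lattice)
  if (species@membraneBound) {
    lin <- .linOfPos(pos, lattice)
    res <- .enforceMembraneFrame(pos, lin, out, .linOfPos(out, lattice), lattice)
    out <- res$pos
  }
  if (single) out[1L, ] else out
}

## Membrane-edge deflection for 2-D (membrane-bound) particles: a step that
## would carry a particle past a cube edge onto a face with a different
## outward normal is reflected at the edge instead of transported around
## it, so each particle keeps its diffusion plane. Returns corrected
## positions and linear indices.
.enforceMembraneFrame <- function(old, oldLin, newPos, newLin, lattice) {
  frOld <- lattice@frozenAxis[oldLin]
  frNew <- lattice@frozenAxis[newLin]
  mem <- lattice@membrane2d[lattice@compartmentOf[newLin]]
  bad <- which(frOld > 0L & mem & frNew != frOld)
  if (!length(bad)) return(list(pos = newPos, lin = newLin))
  h <- lattice@h
  for (r in bad) {
    po <- old[r, ]; pp <- newPos[r, ]
    vo <- floor(po / h); vp <- floor(pp / h)
    for (a in which(vo != vp)) {
      plane <- h * max(vo[a], vp[a])
      pp[a] <- 2 * plane - pp[a]
    }
    lin2 <- .linOfPos(matrix(pp, 1L, 3L), lattice)
    ok <- all(pp >= 0) && all(pp < lattice@dims * h) &&
      lattice@frozenAxis[lin2] == frOld[r] &&
      lattice@compartmentOf[lin2] == lattice@compartmentOf[oldLin[r]]
    if (ok) {
      newPos[r, ] <- pp
      newLin[r] <- lin2
    } else {
      newPos[r, ] <- po
      newLin[r] <- oldLin[r]
    }
  }
  list(pos = newPos, lin = newLin)
}

#' Reflect a proposed particle position into legal space
#'
#' If the proposed position lies in bounds and in a voxel accessible to the
#' species it is returned unchanged. Otherwise the position is specularly
#' reflected at the crossed boundary plane (the simulation-space face for
#' out-of-bounds moves, the shared voxel face for moves into a restricted
#' compartment) and re-checked; after 10 failed reflections the particle
#' stays at its old position.
#'
#' @param posOld,posProposed numeric n x 3 matrices (or length-3 vectors)
#'   of old and proposed positions; `posOld` must be legal.
#' @param species the particle [Species-class].
#' @param lattice a [VoxelLattice-class].
#' @return matrix (or vector) of legal positions.
#' @export
reflectPosition <- function(posOld, posProposed, species, lattice) {
  single <- is.null(dim(posOld))
  if (single) {
    posOld <- matrix(posOld, ncol = 3L)
    posProposed <- matrix(posProposed, ncol = 3L)
  }
  ext <- lattice@dims * lattice@h
  out <- posProposed
  oob <- which(out[, 1L] < 0 | out[, 1L] >= ext[1L] |
               out[, 2L] < 0 | out[, 2L] >= ext[2L] |
               out[, 3L] < 0 | out[, 3L] >= ext[3L])
  if (length(oob)) {
    ## specular fold at the simulation-space faces (only the violators)
    sub <- out[oob, , drop = FALSE]
    extM <- matrix(rep(ext, each = length(oob)), ncol = 3L)
    for (rep in 1:10) {
      low <- sub < 0
      if (any(low)) sub[low] <- -sub[low]
      high <- sub >= extM
      if (any(high)) sub[high] <- 2 * extM[high] - sub[high]
      if (!any(sub < 0 | sub >= extM)) break
    }
    stillOut <- rowSums(sub < 0 | sub >= extM) > 0L
    sub[stillOut, ] <- posOld[oob[stillOut], , drop = FALSE]
    out[oob, ] <- sub
  }

  okComp <- lattice@compartmentNames %in% species@allowed
  bad <- if (all(okComp)) integer() else
    which(!okComp[lattice@compartmentOf[.linOfPos(out, lattice)]])
  if (length(bad)) {
    h <- lattice@h
    for (r in bad) {
      po <- posOld[r, ]; pp <- out[r, ]
      vo <- floor(po / h)
      done <- FALSE
      for (iter in 1:10) {
        vp <- floor(pp / h)
        if (all(pp >= 0) && all(pp < ext) &&
            okComp[lattice@compartmentOf[.linIndex(vp, lattice@dims)]]) {
          done <- TRUE; break
        }
        moved <- which(vp != vo)
        if (!length(moved)) break
        for (a in moved) {
          plane <- h * max(vo[a], vp[a])
          pp[a] <- 2 * plane - pp[a]
        }
      }
      out[r, ] <- if (done) pp else po
    }
  }
  if (single) out[1L, ] else out
}
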