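## Lattice geometry: voxel grid resolution, compartment/microdomain
## membership, neighbor topology, accessibility and membrane frames.
## Voxel indices are 0-based triples (i,j,k); positions are continuous
## coordinates in [0, n*h) per axis (half-open).

## 0-based (i,j,k) matrix -> 1-based linear index into a 3-D array
.linIndex <- function(ijk, dims) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, ncol = 3L)
  1L + ijk[, 1L] + dims[1L] * (ijk[, 2L] + dims[2L] * ijk[, 3L])
}

.inBoundsVoxel <- function(ijk, dims) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, ncol = 3L)
  ijk[, 1L] >= 0L & ijk[, 1L] < dims[1L] &
  ijk[, 2L] >= 0L & ijk[, 2L] < dims[2L] &
  ijk[, 3L] >= 0L & ijk[, 3L] < dims[3L]
}

## voxel set of a Compartment as 1-based linear indices
.compartmentLin <- function(comp, dims) {
  lin <- integer()
  if (nrow(comp@boxes)) {
    for (b in seq_len(nrow(comp@boxes))) {
      bx <- comp@boxes[b, ]
      is <- seq.int(bx[1L], bx[2L] - 1L)
      js <- seq.int(bx[3L], bx[4L] - 1L)
      ks <- seq.int(bx[5L], bx[6L] - 1L)
      g <- as.matrix(expand.grid(i = is, j = js, k = ks))
      lin <- c(lin, .linIndex(g, dims))
    }
  }
  if (nrow(comp@voxels)) lin <- c(lin, .linIndex(comp@voxels, dims))
  unique(lin)
}

#' Build the realized voxel lattice of a model
#'
#' Resolves compartment boxes and voxel lists into per-voxel innermost
#' compartment membership (later compartments in the model list override
#' earlier ones), microdomain membership, and the frozen axis of each
#' membrane voxel (outward normal; edge/corner membrane voxels take one
#' axis by priority x, then y, then z).
#'
#' @param model a validated [SimModel-class].
#' @return a [VoxelLattice-class].
#' @export
buildLattice <- function(model) {
  e <- model@environment
  dims <- c(e@nx, e@ny, e@nz)
  cnames <- compartmentNames(model)
  comp <- array(0L, dim = dims)
  for (ci in seq_along(model@compartments))
    comp[.compartmentLin(model@compartments[[ci]], dims)] <- ci
  if (any(comp == 0L))
    stop("lattice has voxels not covered by any compartment")

  mnames <- vapply(model@microdomains, slot, character(1), name = "name")
  micro <- array(0L, dim = dims)
  for (mi in seq_along(model@microdomains))
    micro[.linIndex(model@microdomains[[mi]]@voxels, dims)] <- mi

  mem2d <- vapply(model@compartments, slot, logical(1), name = "membrane2d")
  frozen <- array(0L, dim = dims)
  if (any(mem2d)) {
    memVox <- which(array(mem2d[comp], dim = dims), arr.ind = TRUE) - 1L
    if (nrow(memVox)) {
      ax <- integer(nrow(memVox))
      onX <- memVox[, 1L] == 0L | memVox[, 1L] == dims[1L] - 1L
      onY <- memVox[, 2L] == 0L | memVox[, 2L] == dims[2L] - 1L
      onZ <- memVox[, 3L] == 0L | memVox[, 3L] == dims[3L] - 1L
      ax[onZ] <- 3L; ax[onY] <- 2L; ax[onX] <- 1L  # priority x > y > z
      frozen[.linIndex(memVox, dims)] <- ax
    }
  }
  new("VoxelLattice", dims = dims, h = e@voxelLen, compartmentNames = cnames,
      microdomainNames = mnames, compartmentOf = comp, microdomainOf = micro,
      membrane2d = mem2d, frozenAxis = frozen)
}

## fast, check-free position -> 1-based linear voxel index (positions
## assumed legal; upper edge clamped)
.linOfPos <- function(pos, lattice) {
  h <- lattice@h; d <- lattice@dims
  i <- pmin(floor(pos[, 1L] / h), d[1L] - 1L)
  j <- pmin(floor(pos[, 2L] / h), d[2L] - 1L)
  k <- pmin(floor(pos[, 3L] / h), d[3L] - 1L)
  as.integer(1 + i + d[1L] * (j + d[2L] * k))
}

#' Map continuous positions to voxel indices
#'
#' @param pos numeric length-3 vector or n x 3 matrix of coordinates (um).
#' @param lattice a [VoxelLattice-class].
#' @return integer voxel index triple (0-based), or an n x 3 matrix.
#' @export
voxelOf <- function(pos, lattice) {
  single <- is.null(dim(pos))
  if (single) pos <- matrix(pos, ncol = 3L)
  ext <- lattice@dims * lattice@h
  if (any(pos < 0 | pos >= rep(ext, each = nrow(pos))))
    stop("position out of bounds")
  v <- matrix(as.integer(floor(pos / lattice@h)), ncol = 3L)
  ## guard against floor(x/h) == n at the upper edge from rounding
  v <- pmin(v, matrix(rep(lattice@dims - 1L, each = nrow(v)), ncol = 3L))
  colnames(v) <- c("i", "j", "k")
  if (single) v[1L, ] else v
}

#' Face-adjacent neighbors of a voxel
#'
#' @param voxel integer (i,j,k) triple, 0-based.
#' @param lattice a [VoxelLattice-class].
#' @return integer matrix of the at-most-6 in-bounds face neighbors.
#' @export
voxelNeighbors <- function(voxel, lattice) {
  if (!all(.inBoundsVoxel(voxel, lattice@dims))) stop("voxel out of bounds")
  off <- rbind(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
               c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))
  nb <- sweep(off, 2L, as.integer(voxel), "+")
  nb <- nb[.inBoundsVoxel(nb, lattice@dims), , drop = FALSE]
  colnames(nb) <- c("i", "j", "k")
  nb
}

#' Per-voxel accessibility mask of a species
#'
#' @param species a [Species-class].
#' @param lattice a [VoxelLattice-class].
#' @return logical 3-D array, TRUE where the species may be.
#' @export
accessibilityMask <- function(species, lattice) {
  okComp <- lattice@compartmentNames %in% species@allowed
  array(okComp[lattice@compartmentOf], dim = lattice@dims)
}

#' Test whether a voxel is accessible to a species
#'
#' A voxel is accessible iff its innermost compartment is among the
#' species' allowed compartments.
#'
#' @param species a [Species-class].
#' @param voxel integer (i,j,k) triple or n x 3 matrix, 0-based.
#' @param lattice a [VoxelLattice-class].
#' @return logical.
#' @export
isAccessible <- function(species, voxel, lattice) {
  lin <- .linIndex(voxel, lattice@dims)
  lattice@compartmentNames[lattice@compartmentOf[lin]] %in% species@allowed
}

#' Frozen-axis descriptor of a membrane voxel
#'
#' For a voxel of a 2-D membrane compartment, returns the outward-normal
#' axis whose coordinate is frozen during diffusion.
#'
#' @param voxel integer (i,j,k) triple, 0-based.
#' @param lattice a [VoxelLattice-class].
#' @return one of "x", "y", "z".
#' @export
surfaceFrame <- function(voxel, lattice) {
  lin <- .linIndex(voxel, lattice@dims)
  ci <- lattice@compartmentOf[lin]
  if (!lattice@membrane2d[ci])
    stop(sprintf("voxel (%d,%d,%d) is not in a membrane compartment",
                 voxel[1L], voxel[2L], voxel[3L]))
  ax <- lattice@frozenAxis[lin]
  if (ax == 0L)
    stop(sprintf("membrane voxel (%d,%d,%d) is not in the outer layer",
                 voxel[1L], voxel[2L], voxel[3L]))
  c("x", "y", "z")[ax]
}

#' Total lattice extent per axis
#'
#' @param lattice a [VoxelLattice-class].
#' @return numeric length-3 vector of extents (um).
#' @export
latticeExtent <- function(lattice) lattice@dims * lattice@h

#' Voxel volume in litres
#'
#' One cubic voxel of edge `h` micrometres has volume h^3 um^3 =
#' h^3 x 1e-15 L.
#'
#' @param h voxel edge length (um).
#' @return volume in litres.
#' @export
voxelVolumeL <- function(h) h^3 * 1e-15

## Avogadro's number; fixed unit conventions: lengths um, time s,
## concentrations mol/L, bimolecular k in M^-1 s^-1.
.NA_AVOGADRO <- 6.02214076e23

## 1 M^-1 s^-1 expressed in um^3/s
.kBimolToUm3 <- function(k) k * 1e15 / .NA_AVOGADRO
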