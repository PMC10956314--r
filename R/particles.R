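## Internal particle container: a plain list of parallel columns, sized for
## vectorized per-step updates. Site-occupancy and state-flag matrices are
## padded to the widest species; column meaning is per-species (site/state
## declaration order).

.newParticleTable <- function(maxSites, maxStates) {
  structure(list(id = integer(), species = integer(),
                 pos = matrix(numeric(), 0L, 3L), lin = integer(),
                 occ = matrix(logical(), 0L, maxSites),
                 flags = matrix(logical(), 0L, maxStates),
                 immobilized = logical(), nextId = 1L),
            class = "particleTable")
}

.nParticles <- function(pt) length(pt$id)

.addParticles <- function(pt, species, pos, occ = NULL, flags = NULL,
                          immobilized = NULL, ids = NULL, lin = NULL) {
  n <- nrow(pos)
  if (n == 0L) return(pt)
  if (is.null(occ)) occ <- matrix(FALSE, n, ncol(pt$occ))
  if (is.null(flags)) flags <- matrix(FALSE, n, ncol(pt$flags))
  if (is.null(immobilized)) immobilized <- rep(FALSE, n)
  if (is.null(lin)) lin <- rep(NA_integer_, n)
  if (is.null(ids)) {
    ids <- seq.int(pt$nextId, length.out = n)
    pt$nextId <- pt$nextId + n
  }
  pt$id <- c(pt$id, ids)
  pt$species <- c(pt$species, rep_len(as.integer(species), n))
  pt$pos <- rbind(pt$pos, pos)
  pt$lin <- c(pt$lin, lin)
  pt$occ <- rbind(pt$occ, occ)
  pt$flags <- rbind(pt$flags, flags)
  pt$immobilized <- c(pt$immobilized, immobilized)
  pt
}

.removeParticles <- function(pt, idx) {
  if (!length(idx)) return(pt)
  keep <- setdiff(seq_along(pt$id), idx)
  pt$id <- pt$id[keep]
  pt$species <- pt$species[keep]
  pt$pos <- pt$pos[keep, , drop = FALSE]
  pt$lin <- pt$lin[keep]
  pt$occ <- pt$occ[keep, , drop = FALSE]
  pt$flags <- pt$flags[keep, , drop = FALSE]
  pt$immobilized <- pt$immobilized[keep]
  pt
}

## Compile an rxPattern against the model's species list for fast matching.
.compilePattern <- function(pat, species) {
  sn <- vapply(species, slot, character(1), name = "name")
  si <- match(pat$species, sn)
  if (is.na(si)) stop(sprintf("unknown species '%s' in pattern", pat$species))
  sp <- species[[si]]
  siteCols <- match(names(pat$sites), sp@sites)
  stateCols <- match(names(pat$states), sp@states)
  if (anyNA(siteCols)) stop(sprintf("undeclared site for species '%s'", pat$species))
  if (anyNA(stateCols)) stop(sprintf("undeclared state for species '%s'", pat$species))
  list(speciesIdx = si, kind = sp@kind,
       siteCols = siteCols, siteVals = unname(pat$sites),
       stateCols = stateCols, stateVals = unname(pat$states))
}

## Logical mask of particles matching a compiled pattern.
.matchMask <- function(pt, cp) {
  m <- pt$species == cp$speciesIdx
  for (q in seq_along(cp$siteCols))
    m <- m & (pt$occ[, cp$siteCols[q]] == cp$siteVals[q])
  for (q in seq_along(cp$stateCols))
    m <- m & (pt$flags[, cp$stateCols[q]] == cp$stateVals[q])
  m
}

## Row indices of particles matching a compiled pattern (faster than
## which(.matchMask()) when the species is a minority of the table).
.matchRows <- function(pt, cp) {
  idx <- which(pt$species == cp$speciesIdx)
  for (q in seq_along(cp$siteCols)) {
    if (!length(idx)) return(idx)
    idx <- idx[pt$occ[idx, cp$siteCols[q]] == cp$siteVals[q]]
  }
  for (q in seq_along(cp$stateCols)) {
    if (!length(idx)) return(idx)
    idx <- idx[pt$flags[idx, cp$stateCols[q]] == cp$stateVals[q]]
  }
  idx
}

## Apply a compiled product pattern in place to rows of the table (state
## change on the same particle; species must match).
.assignPattern <- function(pt, rows, cp) {
  for (q in seq_along(cp$siteCols))
    pt$occ[rows, cp$siteCols[q]] <- cp$siteVals[q]
  for (q in seq_along(cp$stateCols))
    pt$flags[rows, cp$stateCols[q]] <- cp$stateVals[q]
  pt
}

## Fresh occ/flags rows for particles created from a product pattern.
.patternRows <- function(cp, n, maxSites, maxStates) {
  occ <- matrix(FALSE, n, maxSites)
  flags <- matrix(FALSE, n, maxStates)
  occ[, cp$siteCols] <- rep(cp$siteVals, each = n)
  flags[, cp$stateCols] <- rep(cp$stateVals, each = n)
  list(occ = occ, flags = flags)
}

## Uniform random positions inside the given voxels (1-based linear ids).
## Consumes one voxel draw + 3 uniforms per particle.
.randomPositionsIn <- function(linSet, n, lattice, weights = NULL) {
  if (!length(linSet)) stop("no accessible voxels available for placement")
  pick <- linSet[sample.int(length(linSet), n, replace = TRUE, prob = weights)]
  d <- lattice@dims
  i0 <- (pick - 1L) %% d[1L]
  j0 <- ((pick - 1L) %/% d[1L]) %% d[2L]
  k0 <- (pick - 1L) %/% (d[1L] * d[2L])
  u <- matrix(stats::runif(3L * n), n, 3L)
  pos <- cbind(x = (i0 + u[, 1L]) * lattice@h,
               y = (j0 + u[, 2L]) * lattice@h,
               z = (k0 + u[, 3L]) * lattice@h)
  attr(pos, "lin") <- as.integer(pick)
  pos
}
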