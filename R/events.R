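## Non-reaction events per timestep: sources/sinks, probabilistic
## inter-compartment transport, microdomain partition biasing, and
## reversible immobilization.

#' Apply concentration sources and sinks
#'
#' Applied after diffusion within each step: `clamp` voxels are set to the
#' target concentration (a Dirichlet boundary), `influx` voxels gain a
#' fixed amount per step, `absorb` voxels are emptied.
#'
#' @param state a simulation state from [initSimState()].
#' @param specs list of [SourceSink-class] specifications.
#' @param dt timestep (s) (present for interface symmetry; the modes are
#'   defined per step).
#' @return the updated state.
#' @export
applySourcesSinks <- function(state, specs, dt = NULL) {
  for (ss in specs) {
    f <- state$fields[[ss@species]]
    if (is.null(f)) stop(sprintf("no bulk field for species '%s'", ss@species))
    lin <- .linIndex(ss@voxels, state$lattice@dims)
    f[lin] <- switch(ss@mode,
      clamp = ss@value * voxelVolumeL(state$lattice@h) * .NA_AVOGADRO,
      influx = f[lin] + ss@value,
      absorb = 0)
    state$fields[[ss@species]] <- f
  }
  state
}

## compiled transport: indices resolved once. Destination voxels are
## weighted by the species' microdomain entry bias so that relocation
## respects partition exclusion (a species with entry bias 0 is never
## delivered into the domain).
.compileTransport <- function(tr, species, lattice, domains = list()) {
  sn <- vapply(species, slot, character(1), name = "name")
  si <- match(tr@species, sn)
  sp <- species[[si]]
  pat <- .compilePattern(rxPattern(tr@species, tr@sites, tr@states), species)
  fromId <- match(tr@from, lattice@compartmentNames)
  toId <- match(tr@to, lattice@compartmentNames)
  blockCol <- if (!is.na(tr@blockedBy)) match(tr@blockedBy, sp@states) else NA_integer_
  okComp <- lattice@compartmentNames %in% sp@allowed
  destLin <- which(as.vector(lattice@compartmentOf == toId & okComp[lattice@compartmentOf]))
  destW <- NULL
  if (length(domains)) {
    dom <- lattice@microdomainOf[destLin]
    if (any(dom > 0L)) {
      w <- rep(1, length(destLin))
      for (di in unique(dom[dom > 0L])) {
        part <- domains[[di]]@partition
        i <- match(tr@species, part$species)
        if (!is.na(i)) w[dom == di] <- part$entry[i]
      }
      if (any(w != 1)) destW <- w
    }
  }
  list(id = tr@id, pat = pat, fromId = fromId, toId = toId, prob = tr@prob,
       blockCol = blockCol, destLin = destLin, destW = destW)
}

#' One probabilistic transport step
#'
#' Each particle matching the rule's pattern and located in the source
#' compartment relocates, with the rule's per-step probability, to a
#' uniformly random position in an accessible voxel of the destination
#' compartment. Particles carrying the blocking state, and immobilized
#' particles, never relocate. Particle identity is preserved.
#'
#' @param state a simulation state from [initSimState()].
#' @param rule a [Transport-class].
#' @return the updated state.
#' @export
transportStep <- function(state, rule) {
  ct <- if (is(rule, "Transport"))
    .compileTransport(rule, state$species, state$lattice,
                      domains = state$model@microdomains) else rule
  pt <- state$particles
  cand <- .matchRows(pt, ct$pat)
  cand <- cand[!pt$immobilized[cand]]
  if (length(cand) && !is.na(ct$blockCol))
    cand <- cand[!pt$flags[cand, ct$blockCol]]
  if (!length(cand)) return(state)
  lin <- .particleLin(state, cand)
  cand <- cand[state$lattice@compartmentOf[lin] == ct$fromId]
  if (!length(cand) || ct$prob == 0) return(state)
  move <- cand[stats::runif(length(cand)) < ct$prob]
  if (!length(move)) return(state)
  if (!length(ct$destLin))
    stop(sprintf("transport '%s': destination has no accessible voxel", ct$id))
  newPos <- .randomPositionsIn(ct$destLin, length(move), state$lattice,
                               weights = ct$destW)
  state$particles$pos[move, ] <- newPos
  state$particles$lin[move] <- attr(newPos, "lin")
  .logEvents(state, ct$id, length(move))
}

## per-crossing acceptance probability between microdomain regions
## (0 = outside any domain); product of exit and entry biases
.partitionProb <- function(speciesName, fromDom, toDom, domains) {
  bias <- function(md, col) {
    i <- match(speciesName, md@partition$species)
    if (is.na(i)) 1 else md@partition[[col]][i]
  }
  p <- 1
  if (fromDom > 0L) p <- p * bias(domains[[fromDom]], "exit")
  if (toDom > 0L) p <- p * bias(domains[[toDom]], "entry")
  p
}

#' Decide a microdomain boundary crossing
#'
#' Crossing into a microdomain is allowed with that domain's per-species
#' entry bias, crossing out of it with the exit bias (a direct move
#' between two domains uses the product). A denial means the particle's
#' step is deflected at the domain boundary. Biases of 1 never consume
#' randomness, so enabling microdomains with all biases 1 leaves
#' trajectories unchanged under the same seed.
#'
#' @param speciesName the particle's species name.
#' @param fromRegion,toRegion microdomain names (or `NA`/`""` for the
#'   non-domain membrane region).
#' @param domains list of [Microdomain-class] definitions.
#' @return TRUE (allow) or FALSE (deny).
#' @export
partitionCrossing <- function(speciesName, fromRegion, toRegion, domains) {
  nm <- vapply(domains, slot, character(1), name = "name")
  asIdx <- function(rg) {
    if (is.null(rg) || is.na(rg) || !nzchar(rg)) return(0L)
    i <- match(rg, nm)
    if (is.na(i)) stop(sprintf("unknown microdomain '%s'", rg))
    i
  }
  p <- .partitionProb(speciesName, asIdx(fromRegion), asIdx(toRegion), domains)
  if (p >= 1) TRUE else stats::runif(1L) < p
}

## compiled immobilization
.compileImmobilization <- function(im, species, lattice, dt) {
  pat <- .compilePattern(rxPattern(im@species, im@sites, im@states), species)
  scopeLin <- NULL
  if (length(im@compartments)) {
    inComp <- lattice@compartmentNames[lattice@compartmentOf] %in% im@compartments
    inDom <- lattice@microdomainOf > 0L &
      lattice@microdomainNames[pmax(lattice@microdomainOf, 1L)] %in% im@compartments
    scopeLin <- as.vector(inComp | inDom)
  }
  list(id = im@id, pat = pat, pOn = 1 - exp(-im@kOn * dt),
       pOff = 1 - exp(-im@kOff * dt), scopeLin = scopeLin)
}

#' One reversible immobilization step
#'
#' Mobile particles matching the rule become immobilized with probability
#' `1 - exp(-kOn dt)`; immobilized matches are released with
#' `1 - exp(-kOff dt)`. Immobilized particles skip diffusion and
#' transport; the immobilized count is the "clustered" readout of
#' receptor trans-binding models.
#'
#' @param state a simulation state from [initSimState()].
#' @param rule an [Immobilization-class].
#' @param dt timestep (s).
#' @return the updated state.
#' @export
immobilizeStep <- function(state, rule, dt) {
  ci <- if (is(rule, "Immobilization")) .compileImmobilization(rule, state$species, state$lattice, dt) else rule
  pt <- state$particles
  cand <- .matchRows(pt, ci$pat)
  if (!length(cand)) return(state)
  if (!is.null(ci$scopeLin)) cand <- cand[ci$scopeLin[.particleLin(state, cand)]]
  if (!length(cand)) return(state)
  imm <- pt$immobilized[cand]
  on <- cand[!imm]
  if (length(on) && ci$pOn > 0) {
    hit <- on[stats::runif(length(on)) < ci$pOn]
    state$particles$immobilized[hit] <- TRUE
    state <- .logEvents(state, ci$id, length(hit))
  }
  off <- cand[imm]
  if (length(off) && ci$pOff > 0) {
    rel <- off[stats::runif(length(off)) < ci$pOff]
    state$particles$immobilized[rel] <- FALSE
  }
  state
}
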