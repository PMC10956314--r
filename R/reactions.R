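## One-timestep reaction events. All step functions operate on a
## simulation state list (see initSimState()): $particles (internal
## particle table), $fields (named list of 3-D amount arrays), $lattice,
## $species, $eventLog. They are deterministic given the global RNG state.

## Compile a Reaction against the model for fast per-step evaluation.
## Determines the rule type from reactant kinds, maps each reactant to its
## product action (catalyst/state-change, consume), and splits remaining
## products into created particles and bulk increments.
.compileReaction <- function(rx, species, dt, lattice = NULL) {
  pats <- lapply(rx@reactants, .compilePattern, species = species)
  prods <- lapply(rx@products, .compilePattern, species = species)
  kinds <- vapply(pats, `[[`, character(1), "kind")
  type <- if (length(pats) == 1L) {
    if (kinds == "particle") "uni-particle" else "uni-bulk"
  } else if (all(kinds == "particle")) "particle-particle"
  else if (all(kinds == "bulk")) "bulk-bulk"
  else "bulk-particle"

  used <- rep(FALSE, length(prods))
  map <- vector("list", length(pats))
  for (i in seq_along(pats)) {
    j <- which(!used & vapply(prods, function(p) p$speciesIdx == pats[[i]]$speciesIdx,
                              logical(1)))
    if (length(j) && pats[[i]]$kind == "particle") {
      map[[i]] <- list(action = "keep", prod = prods[[j[1L]]])
      used[j[1L]] <- TRUE
    } else {
      map[[i]] <- list(action = "consume")
    }
  }
  rest <- prods[!used]
  restKind <- vapply(rest, `[[`, character(1), "kind")
  created <- rest[restKind == "particle"]
  bulkAdd <- vapply(rest[restKind == "bulk"], `[[`, integer(1), "speciesIdx")

  scopeLin <- NULL
  if (length(rx@compartments) && !is.null(lattice)) {
    inComp <- lattice@compartmentNames[lattice@compartmentOf] %in% rx@compartments
    inDom <- lattice@microdomainOf > 0L &
      lattice@microdomainNames[pmax(lattice@microdomainOf, 1L)] %in% rx@compartments
    scopeLin <- as.vector(inComp | inDom)
  }
  list(id = rx@id, type = type, k = rx@k, p = 1 - exp(-rx@k * dt),
       pats = pats, map = map, created = created, bulkAdd = bulkAdd,
       scopeLin = scopeLin, sep = 0)
}

.logEvents <- function(state, id, n) {
  state$eventLog[id] <- (if (is.na(state$eventLog[id])) 0 else state$eventLog[id]) + n
  state
}

.particleLin <- function(state, rows = NULL) {
  pt <- state$particles
  lin <- if (is.null(rows)) pt$lin else pt$lin[rows]
  if (length(lin) && !anyNA(lin)) return(lin)
  pos <- if (is.null(rows)) pt$pos else pt$pos[rows, , drop = FALSE]
  .linOfPos(pos, state$lattice)
}

.inScope <- function(cr, lin) if (is.null(cr$scopeLin)) rep(TRUE, length(lin)) else cr$scopeLin[lin]

## Place n created product particles for a firing at `pos` (n x 3 of event
## centers); two-particle creations are separated by `sep` along a uniform
## random direction. Returns updated particle table.
.createProducts <- function(state, cr, centers) {
  n <- nrow(centers)
  if (n == 0L || !length(cr$created)) return(state)
  pt <- state$particles
  nc <- length(cr$created)
  offsets <- vector("list", nc)
  if (nc == 2L && cr$sep > 0) {
    u <- matrix(stats::rnorm(3L * n), n, 3L)
    u <- u / sqrt(rowSums(u^2))
    offsets[[1L]] <- (cr$sep / 2) * u
    offsets[[2L]] <- -(cr$sep / 2) * u
  } else {
    for (q in seq_len(nc)) offsets[[q]] <- matrix(0, n, 3L)
  }
  for (q in seq_len(nc)) {
    cp <- cr$created[[q]]
    sp <- state$species[[cp$speciesIdx]]
    pos <- reflectPosition(centers, centers + offsets[[q]], sp, state$lattice)
    ## defensive: if the center itself is not accessible to the product
    ## species the reflection returns it unchanged; such placements are
    ## prevented by model validation in practice
    rows <- .patternRows(cp, n, ncol(pt$occ), ncol(pt$flags))
    pt <- .addParticles(pt, cp$speciesIdx, pos, rows$occ, rows$flags,
                        lin = .linOfPos(pos, state$lattice))
  }
  state$particles <- pt
  state
}

## Apply per-reactant actions for firings. rowsList: list over reactants of
## the particle row indices fired (parallel vectors). Returns state and the
## row indices to drop.
.applyReactantActions <- function(state, cr, rowsList) {
  drop <- integer()
  for (i in seq_along(cr$map)) {
    act <- cr$map[[i]]
    if (cr$pats[[i]]$kind != "particle") next
    rows <- rowsList[[i]]
    if (!length(rows)) next
    if (act$action == "keep") {
      state$particles <- .assignPattern(state$particles, rows, act$prod)
    } else {
      drop <- c(drop, rows)
    }
  }
  list(state = state, drop = drop)
}

#' One unimolecular reaction step
#'
#' Particle reactants matching the rule convert with probability
#' `1 - exp(-k dt)` (exact for any dt); bulk reactants convert
#' deterministically by the same fraction per voxel. Products inherit the
#' reactant's position/voxel; a pair of created particle products is
#' placed at the rule's unbinding separation.
#'
#' @param state a simulation state from [initSimState()].
#' @param rule a one-reactant [Reaction-class].
#' @param dt timestep (s).
#' @return the updated state; firings are added to `state$eventLog`.
#' @export
unimolecularStep <- function(state, rule, dt) {
  cr <- if (is(rule, "Reaction")) .compileReaction(rule, state$species, dt, state$lattice) else rule
  if (cr$type == "uni-bulk") return(.uniBulkStep(state, cr))
  .uniParticleStep(state, cr)
}

.uniParticleStep <- function(state, cr) {
  pt <- state$particles
  cand <- .matchRows(pt, cr$pats[[1L]])
  if (!length(cand)) return(state)
  if (!is.null(cr$scopeLin)) cand <- cand[cr$scopeLin[.particleLin(state, cand)]]
  if (!length(cand) || cr$p == 0) return(state)
  fired <- cand[stats::runif(length(cand)) < cr$p]
  if (!length(fired)) return(state)
  centers <- pt$pos[fired, , drop = FALSE]
  if (length(cr$bulkAdd)) {
    lin <- .particleLin(state, fired)
    for (bi in cr$bulkAdd) {
      nm <- state$species[[bi]]@name
      tab <- tabulate(lin, nbins = length(state$fields[[nm]]))
      state$fields[[nm]] <- state$fields[[nm]] + array(tab, dim = dim(state$fields[[nm]]))
    }
  }
  res <- .applyReactantActions(state, cr, list(fired))
  state <- res$state
  state <- .createProducts(state, cr, centers)
  state$particles <- .removeParticles(state$particles, res$drop)
  .logEvents(state, cr$id, length(fired))
}

.uniBulkStep <- function(state, cr) {
  nm <- state$species[[cr$pats[[1L]]$speciesIdx]]@name
  f <- state$fields[[nm]]
  conv <- cr$p * f
  if (!is.null(cr$scopeLin)) conv <- conv * array(cr$scopeLin, dim = dim(f))
  state$fields[[nm]] <- f - conv
  for (bi in cr$bulkAdd) {
    pn <- state$species[[bi]]@name
    state$fields[[pn]] <- state$fields[[pn]] + conv
  }
  .logEvents(state, cr$id, sum(conv))
}

## All candidate pairs (i from p1, j from p2) at distance <= sigma, with
## the (minimum-image) separation vector delta = p1[i,] - p2[j,]. A dense
## distance matrix is used for small sets; large sets use a sorted
## x-axis window prefilter (with periodic images when `period` is given),
## which gives identical pair sets.
.pairCandidates <- function(p1, p2, sigma, period = NULL) {
  n1 <- nrow(p1); n2 <- nrow(p2)
  empty <- list(i = integer(), j = integer(), d2 = numeric(),
                delta = matrix(numeric(), 0L, 3L))
  if (n1 == 0L || n2 == 0L) return(empty)
  if (n1 * n2 <= 10000L) {
    dvec <- function(a) {
      d <- outer(p1[, a], p2[, a], "-")
      if (!is.null(period)) d <- d - round(d / period[a]) * period[a]
      d
    }
    dx <- dvec(1L); dy <- dvec(2L); dz <- dvec(3L)
    d2 <- dx^2 + dy^2 + dz^2
    hits <- which(d2 <= sigma^2, arr.ind = TRUE)
    if (!nrow(hits)) return(empty)
    return(list(i = hits[, 1L], j = hits[, 2L], d2 = d2[hits],
                delta = cbind(dx[hits], dy[hits], dz[hits])))
  }
  bx <- p2[, 1L]
  idx2 <- seq_len(n2)
  if (!is.null(period)) {
    lowI <- which(bx < sigma)
    highI <- which(bx > period[1L] - sigma)
    bx <- c(bx, bx[lowI] + period[1L], bx[highI] - period[1L])
    idx2 <- c(idx2, lowI, highI)
  }
  o <- order(bx)
  bx <- bx[o]; idx2 <- idx2[o]
  lo <- findInterval(p1[, 1L] - sigma, bx) + 1L
  hi <- findInterval(p1[, 1L] + sigma, bx)
  cnt <- pmax(hi - lo + 1L, 0L)
  if (sum(cnt) == 0L) return(empty)
  i <- rep.int(seq_len(n1), cnt)
  j <- idx2[sequence(cnt, from = lo)]
  delta <- p1[i, , drop = FALSE] - p2[j, , drop = FALSE]
  if (!is.null(period))
    for (a in 1:3) delta[, a] <- delta[, a] - round(delta[, a] / period[a]) * period[a]
  d2 <- delta[, 1L]^2 + delta[, 2L]^2 + delta[, 3L]^2
  keep <- d2 <= sigma^2
  list(i = i[keep], j = j[keep], d2 = d2[keep],
       delta = delta[keep, , drop = FALSE])
}

#' One particle-particle bimolecular reaction step
#'
#' All unordered reactant pairs at distance at most the rule's binding
#' radius react, matched greedily nearest-first with each particle
#' reacting at most once per step. The reaction probability within the
#' radius is 1; all rate control is via the Andrews-Bray-adjusted radius
#' (see [bindingRadius()]). A single product is placed at the reactants'
#' midpoint. Immobilized particles do not take part.
#'
#' @param state a simulation state from [initSimState()].
#' @param rule a two-particle-reactant [Reaction-class].
#' @param sigma binding radius (um), e.g. from [bindingRadius()]; if
#'   missing it is computed from the rule's k, the reactants' D sum and `dt`.
#' @param dt timestep (s); needed only when `sigma` is missing.
#' @param period optional periodic box extents (um) for benchmark use;
#'   distances then use the minimum image convention.
#' @return the updated state.
#' @export
bimolecularParticleStep <- function(state, rule, sigma = NULL, dt = NULL, period = NULL) {
  cr <- if (is(rule, "Reaction")) {
    stopifnot(!is.null(dt))
    c0 <- .compileReaction(rule, state$species, dt, state$lattice)
    if (is.null(sigma) && rule@k > 0) {
      Dsum <- state$species[[c0$pats[[1L]]$speciesIdx]]@D +
              state$species[[c0$pats[[2L]]$speciesIdx]]@D
      sigma <- bindingRadius(rule@k, Dsum, dt)
    }
    c0$sigma <- sigma
    c0
  } else rule
  if (is.null(cr$sigma) || cr$sigma <= 0 || cr$k == 0) return(state)
  pt <- state$particles
  i1 <- .matchRows(pt, cr$pats[[1L]])
  i1 <- i1[!pt$immobilized[i1]]
  i2 <- .matchRows(pt, cr$pats[[2L]])
  i2 <- i2[!pt$immobilized[i2]]
  samePat <- identical(cr$pats[[1L]], cr$pats[[2L]])
  if (!length(i1) || !length(i2)) return(state)
  if (!is.null(cr$scopeLin)) {
    i1 <- i1[cr$scopeLin[.particleLin(state, i1)]]
    i2 <- i2[cr$scopeLin[.particleLin(state, i2)]]
    if (!length(i1) || !length(i2)) return(state)
  }
  p1 <- pt$pos[i1, , drop = FALSE]
  p2 <- pt$pos[i2, , drop = FALSE]
  cand <- .pairCandidates(p1, p2, cr$sigma, period)
  if (!length(cand$i)) return(state)
  keep <- if (samePat) i1[cand$i] < i2[cand$j] else rep(TRUE, length(cand$i))
  if (!any(keep)) return(state)
  ## greedy nearest-first matching; each particle reacts at most once
  ord <- order(cand$d2[keep])
  ci <- cand$i[keep][ord]; cj <- cand$j[keep][ord]
  cd <- cand$delta[keep, , drop = FALSE][ord, , drop = FALSE]
  usedRow <- logical(length(pt$id))
  sel <- integer()
  for (hh in seq_along(ci)) {
    a <- i1[ci[hh]]; b <- i2[cj[hh]]
    if (!usedRow[a] && !usedRow[b]) {
      usedRow[a] <- usedRow[b] <- TRUE
      sel <- c(sel, hh)
    }
  }
  if (!length(sel)) return(state)
  ra <- i1[ci[sel]]; rb <- i2[cj[sel]]
  ## midpoint via the (minimum-image) separation from reactant 1
  centers <- pt$pos[ra, , drop = FALSE] - cd[sel, , drop = FALSE] / 2
  if (!is.null(period))
    centers <- centers %% matrix(rep(period, each = nrow(centers)), ncol = 3L)
  if (length(cr$bulkAdd)) {
    lin <- .linIndex(voxelOf(centers, state$lattice), state$lattice@dims)
    for (bi in cr$bulkAdd) {
      nm <- state$species[[bi]]@name
      tab <- tabulate(lin, nbins = length(state$fields[[nm]]))
      state$fields[[nm]] <- state$fields[[nm]] + array(tab, dim = dim(state$fields[[nm]]))
    }
  }
  res <- .applyReactantActions(state, cr, list(ra, rb))
  state <- res$state
  state <- .createProducts(state, cr, centers)
  state$particles <- .removeParticles(state$particles, res$drop)
  .logEvents(state, cr$id, length(ra))
}

#' One bulk-particle bimolecular reaction step
#'
#' Each matching particle reacts with probability `1 - exp(-k C_local dt)`
#' where `C_local` is the bulk reactant's concentration (mol/L) in the
#' particle's voxel. On firing, one molecule-equivalent is subtracted from
#' that voxel's bulk amount (floored at 0) and the particle-side product
#' pattern is applied.
#'
#' @param state a simulation state from [initSimState()].
#' @param rule a [Reaction-class] with one bulk and one particle reactant.
#' @param dt timestep (s).
#' @return the updated state.
#' @export
bulkParticleStep <- function(state, rule, dt) {
  cr <- if (is(rule, "Reaction")) .compileReaction(rule, state$species, dt, state$lattice) else rule
  bulkI <- which(vapply(cr$pats, `[[`, character(1), "kind") == "bulk")
  partI <- 3L - bulkI
  nmB <- state$species[[cr$pats[[bulkI]]$speciesIdx]]@name
  f <- state$fields[[nmB]]
  pt <- state$particles
  cand <- .matchRows(pt, cr$pats[[partI]])
  if (!length(cand) || cr$k == 0) return(state)
  lin <- .particleLin(state, cand)
  if (!is.null(cr$scopeLin)) {
    keep <- cr$scopeLin[lin]
    cand <- cand[keep]; lin <- lin[keep]
  }
  if (!length(cand)) return(state)
  vol <- voxelVolumeL(state$lattice@h)
  Cloc <- f[lin] / (vol * .NA_AVOGADRO)
  p <- 1 - exp(-cr$k * Cloc * dt)
  fire <- stats::runif(length(cand)) < p
  fired <- cand[fire]
  if (!length(fired)) return(state)
  linF <- lin[fire]
  ## consume one molecule-equivalent per firing, floored at zero
  consumed <- (!is.null(cr$map[[bulkI]]) && cr$map[[bulkI]]$action == "consume")
  if (consumed) {
    tab <- tabulate(linF, nbins = length(f))
    f <- pmax(f - array(tab, dim = dim(f)), 0)
    state$fields[[nmB]] <- f
  }
  centers <- pt$pos[fired, , drop = FALSE]
  if (length(cr$bulkAdd)) {
    for (bi in cr$bulkAdd) {
      nm <- state$species[[bi]]@name
      tab <- tabulate(linF, nbins = length(state$fields[[nm]]))
      state$fields[[nm]] <- state$fields[[nm]] + array(tab, dim = dim(state$fields[[nm]]))
    }
  }
  rowsList <- list(integer(), integer())
  rowsList[[partI]] <- fired
  res <- .applyReactantActions(state, cr, rowsList)
  state <- res$state
  state <- .createProducts(state, cr, centers)
  state$particles <- .removeParticles(state$particles, res$drop)
  .logEvents(state, cr$id, length(fired))
}

#' One bulk-bulk mass-action reaction step
#'
#' Deterministic per-voxel mass-action decrement
#' `dN = k C_a C_b V N_A dt`, capped at `min(N_a, N_b)` so no amount goes
#' negative; products are incremented by the same amount.
#'
#' @param state a simulation state from [initSimState()].
#' @param rule a two-bulk-reactant [Reaction-class].
#' @param dt timestep (s).
#' @return the updated state.
#' @export
bulkBulkStep <- function(state, rule, dt) {
  cr <- if (is(rule, "Reaction")) .compileReaction(rule, state$species, dt, state$lattice) else rule
  nmA <- state$species[[cr$pats[[1L]]$speciesIdx]]@name
  nmB <- state$species[[cr$pats[[2L]]$speciesIdx]]@name
  fa <- state$fields[[nmA]]; fb <- state$fields[[nmB]]
  vol <- voxelVolumeL(state$lattice@h)
  dN <- cr$k * dt * fa * fb / (vol * .NA_AVOGADRO)
  dN <- if (identical(nmA, nmB)) pmin(dN, fa / 2) else pmin(dN, fa, fb)
  if (!is.null(cr$scopeLin)) dN <- dN * array(cr$scopeLin, dim = dim(dN))
  if (identical(nmA, nmB)) {
    state$fields[[nmA]] <- fa - 2 * dN
  } else {
    state$fields[[nmA]] <- fa - dN
    state$fields[[nmB]] <- fb - dN
  }
  for (bi in cr$bulkAdd) {
    nm <- state$species[[bi]]@name
    state$fields[[nm]] <- state$fields[[nm]] + dN
  }
  .logEvents(state, cr$id, sum(dN))
}

#' Apply a pure state-change rule to particles
#'
#' For rules whose product pattern differs from the reactant only in
#' site occupancy / state flags (e.g. phosphorylation): flags are updated
#' in place, position and particle id are preserved.
#'
#' @param state a simulation state from [initSimState()].
#' @param rows particle row indices to modify.
#' @param rule the [Reaction-class] whose (single, particle) product
#'   pattern is applied.
#' @return the updated state.
#' @export
applyStateChange <- function(state, rows, rule) {
  cr <- .compileReaction(rule, state$species, dt = 1, state$lattice)
  keepMaps <- Filter(function(m) m$action == "keep", cr$map)
  if (!length(keepMaps))
    stop(sprintf("rule '%s' is not a state-change rule", rule@id))
  for (m in keepMaps)
    state$particles <- .assignPattern(state$particles, rows, m$prod)
  state
}
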