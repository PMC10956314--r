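## Timestep loop orchestration, RNG management and output logging.
## Phase order within each step (fixed for reproducibility):
##   1 bulk diffusion, 2 particle diffusion (with reflection and
##   microdomain partition biasing), 3 reactions (unimolecular ->
##   bulk-particle -> particle-particle -> bulk-bulk), 4 transport,
##   5 immobilization, 6 sources/sinks, 7 logging.
## A single RNG stream (Mersenne-Twister, inversion normals) is consumed
## in this fixed order, so identical (model, seed) gives identical output.

#' Initialize a simulation state from a model
#'
#' Builds the lattice, creates the bulk concentration fields and places
#' the initial particles (uniformly at random in the accessible voxels of
#' their placement compartment). Placement consumes the current RNG
#' stream; [runSimulation()] seeds it first.
#'
#' @param model a valid [SimModel-class].
#' @return a simulation state: a list with elements `model`, `lattice`,
#'   `species` (list of [Species-class]), `fields` (named list of 3-D
#'   amount arrays, one per bulk species), `particles` (internal particle
#'   table), `eventLog` (named cumulative firing counts) and `step`.
#' @export
initSimState <- function(model) {
  .assertValid(model)
  lattice <- buildLattice(model)
  species <- model@species
  sn <- speciesNames(model)
  dims <- lattice@dims
  vol <- voxelVolumeL(lattice@h)

  fields <- list()
  for (sp in species)
    if (sp@kind == "bulk") fields[[sp@name]] <- array(0, dim = dims)

  maxSites <- max(c(0L, vapply(species, function(s) length(s@sites), integer(1))))
  maxStates <- max(c(0L, vapply(species, function(s) length(s@states), integer(1))))
  pt <- .newParticleTable(maxSites, maxStates)

  compIds <- structure(seq_along(lattice@compartmentNames),
                       names = lattice@compartmentNames)
  for (r in seq_len(nrow(model@initials))) {
    ini <- model@initials[r, ]
    si <- match(ini$species, sn)
    sp <- species[[si]]
    okComp <- lattice@compartmentNames %in% sp@allowed
    linSet <- which(as.vector(lattice@compartmentOf == compIds[[ini$compartment]] &
                              okComp[lattice@compartmentOf]))
    if (!length(linSet))
      stop(sprintf("initial condition for '%s': no accessible voxel in compartment '%s'",
                   ini$species, ini$compartment))
    if (sp@kind == "bulk") {
      total <- if (ini$amount == "count") ini$value
               else ini$value * length(linSet) * vol * .NA_AVOGADRO
      fields[[sp@name]][linSet] <- fields[[sp@name]][linSet] + total / length(linSet)
    } else {
      n <- if (ini$amount == "count") as.integer(round(ini$value))
           else as.integer(round(ini$value * length(linSet) * vol * .NA_AVOGADRO))
      if (n > 0L) {
        pos <- .randomPositionsIn(linSet, n, lattice)
        pt <- .addParticles(pt, si, pos, lin = attr(pos, "lin"))
      }
    }
  }
  list(model = model, lattice = lattice, species = species, speciesNames = sn,
       fields = fields, particles = pt, eventLog = numeric(), step = 0L)
}

## expand reversible reactions into forward + reverse rules and compile;
## assigns binding radii (sigma) to particle-particle rules and placement
## separations (sep) to rules creating particle pairs
.compileRuleSet <- function(model, lattice, dt) {
  rules <- list()
  for (rx in model@reactions) {
    rules[[length(rules) + 1L]] <- rx
    if (rx@reversible) {
      rev <- newReaction(id = paste0(rx@id, ".rev"), reactants = rx@products,
                         products = rx@reactants, k = rx@kRev,
                         compartments = rx@compartments, sigmaUMult = rx@sigmaUMult)
      attr(rev, "revOf") <- rx@id
      rules[[length(rules) + 1L]] <- rev
    }
  }
  crs <- lapply(rules, function(rx) {
    cr <- .compileReaction(rx, model@species, dt, lattice)
    if (cr$type == "particle-particle" && rx@k > 0) {
      Dsum <- model@species[[cr$pats[[1L]]$speciesIdx]]@D +
              model@species[[cr$pats[[2L]]$speciesIdx]]@D
      cr$sigma <- bindingRadius(rx@k, Dsum, dt)
    }
    cr$sigmaUMult <- rx@sigmaUMult
    cr$revOf <- attr(rx, "revOf")
    cr
  })
  ## pair-product placement separation: the unbinding radius of the rule
  ## that would re-bind the created pair (sigmaUMult * its binding radius)
  ppBySpecies <- list()
  for (cr in crs)
    if (cr$type == "particle-particle" && !is.null(cr$sigma)) {
      key <- paste(sort(c(cr$pats[[1L]]$speciesIdx, cr$pats[[2L]]$speciesIdx)),
                   collapse = "-")
      if (is.null(ppBySpecies[[key]]))
        ppBySpecies[[key]] <- cr$sigma * cr$sigmaUMult
    }
  crs <- lapply(crs, function(cr) {
    if (length(cr$created) == 2L) {
      key <- paste(sort(vapply(cr$created, `[[`, integer(1), "speciesIdx")),
                   collapse = "-")
      if (!is.null(ppBySpecies[[key]])) cr$sep <- ppBySpecies[[key]]
    }
    cr
  })
  phase <- vapply(crs, function(cr)
    switch(cr$type, "uni-particle" = 1L, "uni-bulk" = 1L, "bulk-particle" = 2L,
           "particle-particle" = 3L, "bulk-bulk" = 4L), integer(1))
  crs[order(phase, seq_along(crs))]
}

## species-state count column definitions (declaration order)
.countColumns <- function(model) {
  immobSpecies <- unique(vapply(model@immobilizations, slot, character(1),
                                name = "species"))
  cols <- list()
  for (si in seq_along(model@species)) {
    sp <- model@species[[si]]
    if (sp@kind == "bulk") {
      cols[[length(cols) + 1L]] <- list(name = sp@name, si = si, type = "bulk")
      next
    }
    cols[[length(cols) + 1L]] <- list(name = sp@name, si = si, type = "total")
    if (length(sp@sites))
      for (kk in 0:length(sp@sites))
        cols[[length(cols) + 1L]] <- list(name = sprintf("%s_%d", sp@name, kk),
                                          si = si, type = "nbound", k = kk)
    for (st in seq_along(sp@states))
      cols[[length(cols) + 1L]] <- list(name = sprintf("%s:%s", sp@name, sp@states[st]),
                                        si = si, type = "state", col = st)
    if (sp@name %in% immobSpecies)
      cols[[length(cols) + 1L]] <- list(name = sprintf("%s:immobilized", sp@name),
                                        si = si, type = "immob")
  }
  cols
}

.countRow <- function(state, cols, rows = NULL) {
  pt <- state$particles
  vapply(cols, function(cl) {
    if (cl$type == "bulk") {
      f <- state$fields[[cl$name]]
      return(if (is.null(rows)) sum(f) else sum(f[rows$lin]))
    }
    m <- pt$species == cl$si
    if (!is.null(rows)) m <- m & rows$pmask
    switch(cl$type,
      total = sum(m),
      nbound = {
        ns <- length(state$species[[cl$si]]@sites)
        sum(m & rowSums(pt$occ[, seq_len(ns), drop = FALSE]) == cl$k)
      },
      state = sum(m & pt$flags[, cl$col]),
      immob = sum(m & pt$immobilized))
  }, numeric(1))
}

#' Run a simulation
#'
#' Executes the model's timestep loop: bulk diffusion, particle diffusion
#' (with reflection and microdomain partition biasing), reactions in the
#' fixed sub-order unimolecular, bulk-particle, particle-particle,
#' bulk-bulk, then transport, immobilization and sources/sinks, logging
#' counts at the configured interval. Fully reproducible given
#' (model, seed).
#'
#' @param model a valid [SimModel-class].
#' @param nSteps,seed,logInterval,particleLog,perCompartment optional
#'   overrides of the model's environment/output settings.
#' @param hooks optional list with a `phase` function called as
#'   `phase(name, step)` at the start of each phase (instrumentation).
#' @return a [SimResult-class].
#' @export
runSimulation <- function(model, nSteps = NULL, seed = NULL, logInterval = NULL,
                          particleLog = NULL, perCompartment = NULL, hooks = NULL) {
  .assertValid(model)
  e <- model@environment
  nSteps <- if (is.null(nSteps)) e@nSteps else as.integer(nSteps)
  seed <- if (is.null(seed)) e@seed else as.integer(seed)
  logInterval <- if (is.null(logInterval)) model@output$logInterval else as.integer(logInterval)
  particleLog <- if (is.null(particleLog)) model@output$particleLog else isTRUE(particleLog)
  perCompartment <- if (is.null(perCompartment)) isTRUE(model@output$perCompartment) else isTRUE(perCompartment)
  dt <- e@timestep
  phaseHook <- if (!is.null(hooks$phase)) hooks$phase else function(name, step) NULL

  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  state <- initSimState(model)
  lattice <- state$lattice
  dims <- lattice@dims

  bulkSpecies <- which(vapply(state$species, slot, character(1), name = "kind") == "bulk")
  crs <- .compileRuleSet(model, lattice, dt)
  cts <- lapply(model@transports, .compileTransport, species = state$species,
                lattice = lattice, domains = model@microdomains)
  cims <- lapply(model@immobilizations, .compileImmobilization,
                 species = state$species, lattice = lattice, dt = dt)
  nD <- length(model@microdomains)
  nS <- length(state$species)
  entryBias <- matrix(1, nS, max(nD, 1L))
  exitBias <- matrix(1, nS, max(nD, 1L))
  for (di in seq_len(nD)) {
    part <- model@microdomains[[di]]@partition
    for (q in seq_len(nrow(part))) {
      si <- match(part$species[q], state$speciesNames)
      entryBias[si, di] <- part$entry[q]
      exitBias[si, di] <- part$exit[q]
    }
  }

  cols <- .countColumns(model)
  colNames <- vapply(cols, `[[`, character(1), "name")
  nLog <- nSteps %/% logInterval + 1L
  counts <- matrix(NA_real_, nLog, length(cols))
  logSteps <- integer(nLog)
  compCounts <- NULL
  compLinSets <- NULL
  if (perCompartment) {
    compCounts <- array(NA_real_, dim = c(nLog, length(lattice@compartmentNames),
                                          length(cols)),
                        dimnames = list(NULL, lattice@compartmentNames, colNames))
    compLinSets <- lapply(seq_along(lattice@compartmentNames), function(ci)
      which(as.vector(lattice@compartmentOf == ci)))
  }
  plogRows <- if (particleLog) vector("list", nLog) else NULL

  stateLabel <- function(pt) {
    lab <- character(length(pt$id))
    for (si in unique(pt$species)) {
      sp <- state$species[[si]]
      rows <- which(pt$species == si)
      parts <- character(length(rows))
      if (length(sp@sites)) {
        nb <- rowSums(pt$occ[rows, seq_along(sp@sites), drop = FALSE])
        parts <- sprintf("%d", nb)
      }
      if (length(sp@states)) {
        fl <- pt$flags[rows, seq_along(sp@states), drop = FALSE]
        stLab <- apply(fl, 1L, function(v) paste(sp@states[v], collapse = "+"))
        parts <- ifelse(nzchar(parts) & nzchar(stLab), paste(parts, stLab, sep = "|"),
                        paste0(parts, stLab))
      }
      lab[rows] <- parts
    }
    lab
  }

  doLog <- function(li, stepNo) {
    counts[li, ] <<- .countRow(state, cols)
    logSteps[li] <<- stepNo
    if (perCompartment) {
      pt <- state$particles
    plin <- if (length(pt$id)) .particleLin(state) else integer()
      for (ci in seq_along(compLinSets)) {
        rows <- list(lin = compLinSets[[ci]],
                     pmask = if (length(pt$id))
                       state$lattice@compartmentOf[plin] == ci else logical())
        compCounts[li, ci, ] <<- .countRow(state, cols, rows)
      }
    }
    if (particleLog) {
      pt <- state$particles
      if (length(pt$id)) {
        lin <- .particleLin(state)
        plogRows[[li]] <<- data.frame(
          step = stepNo, particle_id = pt$id,
          species = state$speciesNames[pt$species],
          state = stateLabel(pt),
          x_um = pt$pos[, 1L], y_um = pt$pos[, 2L], z_um = pt$pos[, 3L],
          compartment = lattice@compartmentNames[lattice@compartmentOf[lin]],
          immobilized = pt$immobilized)
      }
    }
    for (f in state$fields)
      if (!all(is.finite(f)))
        stop(sprintf("non-finite bulk amount at step %d", stepNo))
  }

  li <- 1L
  doLog(li, 0L)
  okCompBySpecies <- lapply(state$species, function(sp)
    lattice@compartmentNames %in% sp@allowed)

  for (stepNo in seq_len(nSteps)) {
    ## 1. bulk diffusion
    phaseHook("diffusion", stepNo)
    for (si in bulkSpecies) {
      sp <- state$species[[si]]
      if (sp@D > 0)
        state$fields[[sp@name]] <- bulkDiffusionStep(state$fields[[sp@name]],
                                                     sp@D, dt, lattice, sp)
    }
    ## 2. particle diffusion with partition biasing
    pt <- state$particles
    if (length(pt$id)) {
      for (si in sort(unique(pt$species))) {
        sp <- state$species[[si]]
        rows <- which(pt$species == si & !pt$immobilized)
        if (!length(rows) || sp@D == 0) next
        old <- pt$pos[rows, , drop = FALSE]
        oldLin <- pt$lin[rows]
        disp <- matrix(stats::rnorm(3L * length(rows), sd = sqrt(2 * sp@D * dt)),
                       ncol = 3L)
        if (sp@membraneBound) {
          inMem <- lattice@membrane2d[lattice@compartmentOf[oldLin]]
          if (any(inMem)) {
            fr <- lattice@frozenAxis[oldLin]
            mrw <- which(inMem & fr > 0L)
            disp[cbind(mrw, fr[mrw])] <- 0
          }
        }
        newPos <- reflectPosition(old, old + disp, sp, lattice)
        newLin <- .linOfPos(newPos, lattice)
        if (sp@membraneBound) {
          res <- .enforceMembraneFrame(old, oldLin, newPos, newLin, lattice)
          newPos <- res$pos
          newLin <- res$lin
        }
        if (nD > 0L) {
          dOld <- lattice@microdomainOf[oldLin]
          dNew <- lattice@microdomainOf[newLin]
          cross <- which(dOld != dNew)
          for (q in cross) {
            pAcc <- (if (dOld[q] > 0L) exitBias[si, dOld[q]] else 1) *
                    (if (dNew[q] > 0L) entryBias[si, dNew[q]] else 1)
            if (pAcc >= 1) next
            if (stats::runif(1L) < pAcc) next
            ## denied: deflect at the domain boundary (shared voxel faces);
            ## fall back to staying put
            po <- old[q, ]; pp <- newPos[q, ]
            vo <- floor(po / lattice@h); vp <- floor(pp / lattice@h)
            for (a in which(vo != vp)) {
              plane <- lattice@h * max(vo[a], vp[a])
              pp[a] <- 2 * plane - pp[a]
            }
            ok <- all(pp >= 0) && all(pp < dims * lattice@h)
            if (ok) {
              lin2 <- .linIndex(floor(pp / lattice@h), dims)
              ok <- okCompBySpecies[[si]][lattice@compartmentOf[lin2]] &&
                    lattice@microdomainOf[lin2] == dOld[q]
            }
            if (ok) {
              newPos[q, ] <- pp
              newLin[q] <- lin2
            } else {
              newPos[q, ] <- po
              newLin[q] <- oldLin[q]
            }
          }
        }
        pt$pos[rows, ] <- newPos
        pt$lin[rows] <- newLin
      }
      state$particles <- pt
    }
    ## 3. reactions
    phaseHook("reactions", stepNo)
    for (cr in crs) {
      state <- switch(cr$type,
        "uni-particle" = .uniParticleStep(state, cr),
        "uni-bulk" = .uniBulkStep(state, cr),
        "bulk-particle" = bulkParticleStep(state, cr, dt),
        "particle-particle" = bimolecularParticleStep(state, cr),
        "bulk-bulk" = bulkBulkStep(state, cr, dt))
    }
    ## 4. transport
    phaseHook("transport", stepNo)
    for (ct in cts) state <- transportStep(state, ct)
    ## 5. immobilization
    for (ci in cims) state <- immobilizeStep(state, ci, dt)
    ## 6. sources/sinks
    if (length(model@sources)) state <- applySourcesSinks(state, model@sources, dt)
    ## 7. logging
    if (stepNo %% logInterval == 0L) {
      li <- li + 1L
      doLog(li, stepNo)
    }
  }

  countsDf <- data.frame(step = logSteps, time_s = logSteps * dt)
  for (ci in seq_along(cols)) countsDf[[colNames[ci]]] <- counts[, ci]
  plog <- if (particleLog) do.call(rbind, plogRows[!vapply(plogRows, is.null, logical(1))])
          else NULL
  if (length(state$eventLog))
    state$eventLog <- state$eventLog[order(names(state$eventLog))]
  new("SimResult", counts = countsDf, compartmentCounts = compCounts,
      particleLogDf = plog,
      finalState = list(fields = state$fields, particles = state$particles,
                        eventLog = state$eventLog, step = nSteps),
      seed = seed, modelHash = .modelHash(model), model = model)
}

#' Write the counts table as a tab-delimited file
#'
#' Header `step`, `time_s`, then one column per species-state combination
#' in declaration order; bulk amounts are written as full-precision reals,
#' particle counts as integers. Re-parsing reproduces the in-memory table
#' exactly.
#'
#' @param result a [SimResult-class].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeCountsTsv <- function(result, file) {
  df <- result@counts
  cells <- vapply(names(df), function(nm) {
    v <- df[[nm]]
    if (nm == "step") sprintf("%d", as.integer(v)) else .fmtNum(v)
  }, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L,
                                      dimnames = list(NULL, names(df)))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(apply(cells, 1L, paste, collapse = "\t"), con)
  invisible(file)
}

#' Write the particle log as a tab-delimited file
#'
#' Columns: step, particle_id, species, state, x_um, y_um, z_um,
#' compartment, immobilized.
#'
#' @param result a [SimResult-class] run with particle logging enabled.
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeParticleLog <- function(result, file) {
  pl <- result@particleLogDf
  if (is.null(pl)) stop("particle logging was not enabled for this result")
  utils::write.table(pl, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read back a counts TSV
#'
#' @param file path written by [writeCountsTsv()].
#' @return data.frame with the original column types.
#' @export
readCountsTsv <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE)
  df$step <- as.integer(df$step)
  for (nm in setdiff(names(df), "step")) df[[nm]] <- as.numeric(df[[nm]])
  df
}
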