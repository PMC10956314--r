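# Small programmatic fixtures shared across test files.

# one open cubic compartment, one particle + one bulk species, no rules
tinyModel <- function(n = 3L, h = 0.2, dt = 1e-6, nSteps = 10L, D = 5) {
  env <- newEnvironment(n, n, n, voxelLen = h, timestep = dt, nSteps = nSteps)
  comp <- list(newCompartment("main", boxes = c(0, n, 0, n, 0, n)))
  species <- list(
    newSpecies("B", "bulk", D = D, allowed = "main"),
    newSpecies("P", "particle", D = D, allowed = "main"))
  newSimModel(env, comp, species,
              initials = data.frame(species = c("B", "P"), amount = "count",
                                    value = c(100, 10), compartment = "main"))
}

# two-compartment model: inner box restricted for species "P"
restrictedModel <- function(n = 5L, h = 0.2, dt = 1e-6) {
  env <- newEnvironment(n, n, n, voxelLen = h, timestep = dt, nSteps = 10L)
  comp <- list(
    newCompartment("outer", boxes = c(0, n, 0, n, 0, n)),
    newCompartment("inner", boxes = c(2, 3, 2, 3, 2, 3), parent = "outer"))
  species <- list(
    newSpecies("B", "bulk", D = 5, allowed = c("outer", "inner")),
    newSpecies("P", "particle", D = 5, allowed = "outer"))
  newSimModel(env, comp, species,
              initials = data.frame(species = "P", amount = "count",
                                    value = 20, compartment = "outer"))
}

# membrane-only particle model (outer layer 2-D membrane) with an optional
# raft microdomain; used by partition/immobilization tests
membraneModel <- function(n = 6L, h = 0.2, dt = 5e-5, nParticles = 200L,
                          raft = FALSE, entry = 1, exit = 1,
                          kOn = 0, kOff = 0) {
  env <- newEnvironment(n, n, n, voxelLen = h, timestep = dt, nSteps = 10L)
  comp <- list(
    newCompartment("membrane", boxes = c(0, n, 0, n, 0, n), membrane2d = TRUE),
    newCompartment("core", boxes = c(1, n - 1, 1, n - 1, 1, n - 1),
                   parent = "membrane"))
  species <- list(newSpecies("M", "particle", D = 0.5, allowed = "membrane",
                             membraneBound = TRUE))
  domains <- if (raft) {
    mid <- c(2L, 3L)
    vox <- rbind(as.matrix(expand.grid(i = 0L, j = mid, k = mid)),
                 as.matrix(expand.grid(i = n - 1L, j = mid, k = mid)),
                 as.matrix(expand.grid(i = mid, j = 0L, k = mid)),
                 as.matrix(expand.grid(i = mid, j = n - 1L, k = mid)),
                 as.matrix(expand.grid(i = mid, j = mid, k = 0L)),
                 as.matrix(expand.grid(i = mid, j = mid, k = n - 1L)))
    colnames(vox) <- c("i", "j", "k")
    list(newMicrodomain("raft", vox,
                        partition = data.frame(species = "M", entry = entry,
                                               exit = exit)))
  } else list()
  immob <- if (kOn > 0 || kOff > 0)
    list(newImmobilization("pin", "M", kOn = kOn, kOff = kOff,
                           compartments = "membrane")) else list()
  newSimModel(env, comp, species, microdomains = domains,
              immobilizations = immob,
              initials = data.frame(species = "M", amount = "count",
                                    value = nParticles, compartment = "membrane"))
}

# random small valid model for serialization round-trip properties
randomModel <- function(seed) {
  set.seed(seed)
  n <- sample(2:5, 1)
  h <- round(runif(1, 0.05, 0.5), 3)
  env <- newEnvironment(n, n, n, voxelLen = h, timestep = 10^runif(1, -7, -5),
                        nSteps = sample(0:50, 1), seed = sample(0:100, 1))
  comps <- list(newCompartment("main", boxes = c(0, n, 0, n, 0, n)))
  if (runif(1) < 0.5 && n >= 4)
    comps <- c(comps, list(newCompartment("inner",
      boxes = c(1, n - 1, 1, n - 1, 1, n - 1), parent = "main")))
  cn <- vapply(comps, slot, character(1), name = "name")
  nSpecies <- sample(1:3, 1)
  species <- lapply(seq_len(nSpecies), function(i) {
    kind <- if (i == 1) "bulk" else sample(c("bulk", "particle"), 1)
    # keep bulk D inside the stability bound for this (h, dt) pair
    maxD <- h^2 / (6 * env@timestep)
    newSpecies(sprintf("S%d", i), kind,
               D = round(runif(1, 0, min(maxD * 0.9, 50)), 4),
               sites = if (kind == "particle" && runif(1) < 0.5) c("a", "b") else character(),
               states = if (kind == "particle" && runif(1) < 0.5) "mod" else character(),
               allowed = cn)
  })
  reactions <- list()
  partIdx <- which(vapply(species, slot, character(1), name = "kind") == "particle")
  if (length(partIdx)) {
    sp <- species[[partIdx[1]]]
    if (length(sp@states))
      reactions <- list(newReaction("flip",
        rxPattern(sp@name, states = c(mod = FALSE)),
        rxPattern(sp@name, states = c(mod = TRUE)),
        k = round(runif(1, 0, 100), 3)))
  }
  initials <- data.frame(
    species = vapply(species, slot, character(1), name = "name"),
    amount = "count", value = sample(0:50, nSpecies, replace = TRUE),
    compartment = "main")
  newSimModel(env, comps, species, reactions = reactions, initials = initials,
              logInterval = sample(1:5, 1),
              particleLog = runif(1) < 0.3)
}
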