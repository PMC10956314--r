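#' Construct a simulation environment
#'
#' @param nx,ny,nz voxel counts per axis.
#' @param voxelLen voxel edge length (um).
#' @param timestep timestep (s).
#' @param nSteps number of steps.
#' @param seed RNG seed.
#' @return a [SimEnvironment-class].
#' @export
newEnvironment <- function(nx, ny, nz, voxelLen, timestep, nSteps, seed = 0L) {
  new("SimEnvironment", nx = as.integer(nx), ny = as.integer(ny),
      nz = as.integer(nz), voxelLen = as.numeric(voxelLen),
      timestep = as.numeric(timestep), nSteps = as.integer(nSteps),
      seed = as.integer(seed))
}

#' Construct a compartment
#'
#' @param name compartment name.
#' @param boxes numeric matrix/vector of half-open index ranges
#'   (x0,x1,y0,y1,z0,z1); a length-6 vector is taken as one box.
#' @param voxels integer matrix of explicit (i,j,k) voxel indices (0-based).
#' @param parent optional enclosing compartment name.
#' @param membrane2d restrict resident particles to 2-D diffusion.
#' @return a [Compartment-class].
#' @export
newCompartment <- function(name, boxes = NULL, voxels = NULL, parent = NA_character_,
                           membrane2d = FALSE) {
  if (is.null(boxes)) {
    boxes <- matrix(numeric(), 0L, 6L)
  } else if (is.null(dim(boxes))) {
    boxes <- matrix(as.numeric(boxes), ncol = 6L, byrow = TRUE)
  }
  colnames(boxes) <- c("x0", "x1", "y0", "y1", "z0", "z1")
  if (is.null(voxels)) {
    voxels <- matrix(integer(), 0L, 3L)
  } else if (is.null(dim(voxels))) {
    voxels <- matrix(as.integer(voxels), ncol = 3L, byrow = TRUE)
  }
  storage.mode(voxels) <- "integer"
  colnames(voxels) <- c("i", "j", "k")
  new("Compartment", name = name, boxes = boxes, voxels = voxels,
      parent = as.character(parent), membrane2d = membrane2d)
}

#' Construct a species definition
#'
#' @param name species name.
#' @param kind `"bulk"` or `"particle"`.
#' @param D diffusion coefficient (um^2/s).
#' @param sites binding site names (particles only); site order is the
#'   sequential filling order used by state-dependent binding rules.
#' @param states boolean modification flag names.
#' @param allowed compartments the species may occupy.
#' @param membraneBound logical, see [Species-class].
#' @return a [Species-class].
#' @export
newSpecies <- function(name, kind = c("particle", "bulk"), D, sites = character(),
                       states = character(), allowed, membraneBound = FALSE) {
  kind <- match.arg(kind)
  new("Species", name = name, kind = kind, D = as.numeric(D),
      sites = as.character(sites), states = as.character(states),
      allowed = as.character(allowed), membraneBound = membraneBound)
}

#' Species-with-state pattern
#'
#' Builds the pattern lists used on both sides of [newReaction()] and by
#' transport/immobilization rules. On the reactant side, named entries of
#' `sites`/`states` are constraints (`TRUE` = bound/set, `FALSE` =
#' empty/unset); unnamed sites are unconstrained. On the product side they
#' are assignments applied to the matched particle; unassigned sites/states
#' are carried through.
#'
#' @param species species name.
#' @param sites named logical vector of site constraints/assignments.
#' @param states named logical vector of state constraints/assignments.
#' @return a pattern list with class `"rxPattern"`.
#' @export
rxPattern <- function(species, sites = logical(), states = logical()) {
  stopifnot(is.character(species), length(species) == 1L)
  if (length(sites) && is.null(names(sites))) stop("sites must be named")
  if (length(states) && is.null(names(states))) stop("states must be named")
  structure(list(species = species, sites = sites, states = states),
            class = c("rxPattern", "list"))
}

#' Construct a reaction rule
#'
#' @param id rule identifier.
#' @param reactants,products lists of [rxPattern()] patterns (a single
#'   pattern may be given bare).
#' @param k forward rate constant (s^-1 unimolecular, M^-1 s^-1 bimolecular).
#' @param reversible logical.
#' @param kRev reverse rate constant.
#' @param compartments scope (compartment or microdomain names; empty =
#'   everywhere).
#' @param sigmaUMult unbinding-radius multiplier (>= 1).
#' @return a [Reaction-class].
#' @export
newReaction <- function(id, reactants, products, k, reversible = FALSE, kRev = 0,
                        compartments = character(), sigmaUMult = 1) {
  aslist <- function(x) if (inherits(x, "rxPattern")) list(x) else x
  new("Reaction", id = id, reactants = aslist(reactants), products = aslist(products),
      k = as.numeric(k), reversible = reversible, kRev = as.numeric(kRev),
      compartments = as.character(compartments), sigmaUMult = as.numeric(sigmaUMult))
}

#' Construct a transport rule
#'
#' @param id rule identifier.
#' @param species species name to relocate.
#' @param from,to source and destination compartment names.
#' @param prob per-step relocation probability.
#' @param blockedBy state name blocking transport (`NA` for none).
#' @param sites,states optional pattern constraints.
#' @return a [Transport-class].
#' @export
newTransport <- function(id, species, from, to, prob, blockedBy = NA_character_,
                         sites = logical(), states = logical()) {
  new("Transport", id = id, species = species, sites = sites, states = states,
      from = from, to = to, prob = as.numeric(prob),
      blockedBy = as.character(blockedBy))
}

#' Construct a source/sink specification
#'
#' @param species bulk species name.
#' @param voxels integer matrix/vector of (i,j,k) voxel indices (0-based).
#' @param mode `"clamp"`, `"influx"` or `"absorb"`.
#' @param value target concentration (mol/L, clamp) or amount per step (influx).
#' @return a [SourceSink-class].
#' @export
newSourceSink <- function(species, voxels, mode = c("clamp", "influx", "absorb"),
                          value = 0) {
  mode <- match.arg(mode)
  if (is.null(dim(voxels))) voxels <- matrix(as.integer(voxels), ncol = 3L, byrow = TRUE)
  storage.mode(voxels) <- "integer"
  colnames(voxels) <- c("i", "j", "k")
  new("SourceSink", species = species, voxels = voxels, mode = mode,
      value = as.numeric(value))
}

#' Construct a membrane microdomain
#'
#' @param name microdomain name.
#' @param voxels integer matrix/vector of (i,j,k) membrane voxel indices.
#' @param partition data.frame with columns species, entry, exit.
#' @return a [Microdomain-class].
#' @export
newMicrodomain <- function(name, voxels, partition = NULL) {
  if (is.null(dim(voxels))) voxels <- matrix(as.integer(voxels), ncol = 3L, byrow = TRUE)
  storage.mode(voxels) <- "integer"
  colnames(voxels) <- c("i", "j", "k")
  if (is.null(partition))
    partition <- data.frame(species = character(), entry = numeric(), exit = numeric())
  new("Microdomain", name = name, voxels = voxels, partition = partition)
}

#' Construct an immobilization rule
#'
#' @param id rule identifier.
#' @param species species name to match.
#' @param kOn,kOff immobilization/release rates (s^-1).
#' @param compartments compartment scope (empty = everywhere).
#' @param sites,states optional pattern constraints.
#' @return an [Immobilization-class].
#' @export
newImmobilization <- function(id, species, kOn, kOff, compartments = character(),
                              sites = logical(), states = logical()) {
  new("Immobilization", id = id, species = species, sites = sites, states = states,
      kOn = as.numeric(kOn), kOff = as.numeric(kOff),
      compartments = as.character(compartments))
}

#' Construct a complete simulation model
#'
#' @param environment a [SimEnvironment-class].
#' @param compartments,species,reactions,transports,sources,microdomains,immobilizations
#'   lists of the corresponding rule/definition objects.
#' @param initials data.frame with columns species, amount ("count" or
#'   "concentration"), value, compartment.
#' @param logInterval logging interval in steps.
#' @param particleLog enable the per-particle position/state log.
#' @param perCompartment log counts broken out by compartment.
#' @return a [SimModel-class].
#' @export
newSimModel <- function(environment, compartments, species, reactions = list(),
                        transports = list(), sources = list(), microdomains = list(),
                        immobilizations = list(), initials = NULL, logInterval = 1L,
                        particleLog = FALSE, perCompartment = FALSE) {
  if (is.null(initials))
    initials <- data.frame(species = character(), amount = character(),
                           value = numeric(), compartment = character())
  initials$species <- as.character(initials$species)
  initials$amount <- as.character(initials$amount)
  initials$compartment <- as.character(initials$compartment)
  new("SimModel", environment = environment, compartments = compartments,
      species = species, reactions = reactions, transports = transports,
      sources = sources, microdomains = microdomains,
      immobilizations = immobilizations, initials = initials,
      output = list(logInterval = as.integer(logInterval),
                    particleLog = isTRUE(particleLog),
                    perCompartment = isTRUE(perCompartment)))
}

## ---- accessors ----

#' Accessors for model and result components
#'
#' @param object a [SimModel-class] or [SimResult-class].
#' @return `speciesDefs`, `compartmentDefs`, `reactionRules`: the
#'   corresponding list from the model. `simEnvironment`: the
#'   [SimEnvironment-class]. `simCounts`: the counts data.frame of a result.
#'   `particleLog`: the particle-log data.frame or NULL.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("speciesDefs", function(object) standardGeneric("speciesDefs"))
#' @rdname accessors
#' @export
setMethod("speciesDefs", "SimModel", function(object) object@species)

#' @rdname accessors
#' @export
setGeneric("compartmentDefs", function(object) standardGeneric("compartmentDefs"))
#' @rdname accessors
#' @export
setMethod("compartmentDefs", "SimModel", function(object) object@compartments)

#' @rdname accessors
#' @export
setGeneric("reactionRules", function(object) standardGeneric("reactionRules"))
#' @rdname accessors
#' @export
setMethod("reactionRules", "SimModel", function(object) object@reactions)

#' @rdname accessors
#' @export
setGeneric("simEnvironment", function(object) standardGeneric("simEnvironment"))
#' @rdname accessors
#' @export
setMethod("simEnvironment", "SimModel", function(object) object@environment)

#' @rdname accessors
#' @export
setGeneric("simCounts", function(object) standardGeneric("simCounts"))
#' @rdname accessors
#' @export
setMethod("simCounts", "SimResult", function(object) object@counts)

#' @rdname accessors
#' @export
setGeneric("particleLog", function(object) standardGeneric("particleLog"))
#' @rdname accessors
#' @export
setMethod("particleLog", "SimResult", function(object) object@particleLogDf)

#' Species, compartment and rule names of a model
#'
#' @param model a [SimModel-class].
#' @return character vector of names.
#' @export
speciesNames <- function(model) vapply(model@species, slot, character(1), name = "name")

#' @rdname speciesNames
#' @export
compartmentNames <- function(model) vapply(model@compartments, slot, character(1), name = "name")

## ---- show methods ----

setMethod("show", "SimModel", function(object) {
  e <- object@environment
  cat(sprintf("SimModel: %dx%dx%d voxels, h = %g um, dt = %g s, %d steps\n",
              e@nx, e@ny, e@nz, e@voxelLen, e@timestep, e@nSteps))
  cat(sprintf("  compartments: %s\n", paste(compartmentNames(object), collapse = ", ")))
  kinds <- vapply(object@species, slot, character(1), name = "kind")
  cat(sprintf("  species: %d (%d bulk, %d particle)\n", length(kinds),
              sum(kinds == "bulk"), sum(kinds == "particle")))
  cat(sprintf("  rules: %d reactions, %d transports, %d immobilizations, %d sources, %d microdomains\n",
              length(object@reactions), length(object@transports),
              length(object@immobilizations), length(object@sources),
              length(object@microdomains)))
  invisible(NULL)
})

setMethod("show", "SimResult", function(object) {
  n <- nrow(object@counts)
  cat(sprintf("SimResult: %d logged steps (final t = %g s), seed %d\n",
              n, if (n) object@counts$time_s[n] else 0, object@seed))
  cat(sprintf("  count columns: %s\n",
              paste(setdiff(names(object@counts), c("step", "time_s")), collapse = ", ")))
  if (!is.null(object@particleLogDf))
    cat(sprintf("  particle log: %d rows\n", nrow(object@particleLogDf)))
  invisible(NULL)
})

setMethod("show", "VoxelLattice", function(object) {
  cat(sprintf("VoxelLattice: %dx%dx%d voxels, h = %g um, compartments: %s\n",
              object@dims[1], object@dims[2], object@dims[3], object@h,
              paste(object@compartmentNames, collapse = ", ")))
  invisible(NULL)
})
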