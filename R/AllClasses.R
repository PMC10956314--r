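#' @import methods
NULL

## Central S4 containers. All user-facing construction goes through the
## new*() constructors in constructors.R; validity here enforces the
## structural invariants that do not need cross-references (those are
## checked model-wide by validateModel()).

#' Simulation environment geometry and time discretization
#'
#' Describes the cubic c-voxel lattice (counts per axis, voxel edge length)
#' and the time discretization of a simulation. Voxel edges are intended for
#' the 0.01--1 micrometre range typical of meso-scale cellular models;
#' values outside that range are legal but flagged as warnings by
#' [validateModel()].
#'
#' @slot nx,ny,nz integer voxel counts per axis (>= 1).
#' @slot voxelLen voxel edge length in micrometres (> 0).
#' @slot timestep timestep in seconds (> 0).
#' @slot nSteps number of timesteps to simulate.
#' @slot seed RNG seed used by [runSimulation()] unless overridden.
#' @exportClass SimEnvironment
setClass("SimEnvironment",
  slots = c(nx = "integer", ny = "integer", nz = "integer",
            voxelLen = "numeric", timestep = "numeric",
            nSteps = "integer", seed = "integer"),
  prototype = list(nx = 1L, ny = 1L, nz = 1L, voxelLen = 0.2,
                   timestep = 1e-6, nSteps = 0L, seed = 0L))

setValidity("SimEnvironment", function(object) {
  msg <- character()
  if (length(object@nx) != 1L || object@nx < 1L) msg <- c(msg, "nx must be a single integer >= 1")
  if (length(object@ny) != 1L || object@ny < 1L) msg <- c(msg, "ny must be a single integer >= 1")
  if (length(object@nz) != 1L || object@nz < 1L) msg <- c(msg, "nz must be a single integer >= 1")
  if (length(object@voxelLen) != 1L || !is.finite(object@voxelLen) || object@voxelLen <= 0)
    msg <- c(msg, "voxelLen must be a single positive number")
  if (length(object@timestep) != 1L || !is.finite(object@timestep) || object@timestep <= 0)
    msg <- c(msg, "timestep must be a single positive number")
  if (length(object@nSteps) != 1L || object@nSteps < 0L) msg <- c(msg, "nSteps must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Compartment definition
#'
#' A compartment is a named set of voxels, given as zero or more axis-aligned
#' boxes (0-based, half-open index ranges) plus zero or more explicit voxel
#' index triples. Later compartments in a model's compartment list override
#' earlier ones voxel-by-voxel, so a child compartment carved out of a parent
#' is simply listed after it; every voxel belongs to exactly one innermost
#' compartment. Membrane compartments (`membrane2d = TRUE`) must lie in the
#' outer voxel layer and restrict their particles to in-plane diffusion.
#'
#' @slot name compartment name.
#' @slot boxes numeric matrix with columns x0,x1,y0,y1,z0,z1 (half-open).
#' @slot voxels integer matrix with columns i,j,k (0-based).
#' @slot parent optional name of the enclosing compartment (`NA` if none).
#' @slot membrane2d logical flag for 2-D membrane compartments.
#' @exportClass Compartment
setClass("Compartment",
  slots = c(name = "character", boxes = "matrix", voxels = "matrix",
            parent = "character", membrane2d = "logical"),
  prototype = list(name = "main",
                   boxes = matrix(numeric(), 0L, 6L,
                                  dimnames = list(NULL, c("x0","x1","y0","y1","z0","z1"))),
                   voxels = matrix(integer(), 0L, 3L, dimnames = list(NULL, c("i","j","k"))),
                   parent = NA_character_, membrane2d = FALSE))

setValidity("Compartment", function(object) {
  msg <- character()
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msg <- c(msg, "name must be a non-empty string")
  if (ncol(object@boxes) != 6L) msg <- c(msg, "boxes must have 6 columns (x0,x1,y0,y1,z0,z1)")
  if (ncol(object@voxels) != 3L) msg <- c(msg, "voxels must have 3 columns (i,j,k)")
  if (nrow(object@boxes) == 0L && nrow(object@voxels) == 0L)
    msg <- c(msg, sprintf("compartment '%s' has an empty voxel set", object@name))
  if (length(msg)) msg else TRUE
})

#' Molecular species definition
#'
#' Species are either `bulk` (small, abundant molecules represented as a
#' real-valued amount per voxel, diffusing deterministically) or `particle`
#' (individually tracked point molecules with continuous off-lattice
#' coordinates, named binding sites and boolean modification states).
#'
#' @slot name species name.
#' @slot kind `"bulk"` or `"particle"`.
#' @slot D diffusion coefficient in um^2/s (>= 0).
#' @slot sites names of sequential binding sites (particles only).
#' @slot states names of boolean modification flags, e.g. phosphorylation.
#' @slot allowed names of compartments the species may occupy.
#' @slot membraneBound logical; membrane-resident species diffuse in 2-D
#'   while inside a membrane compartment.
#' @exportClass Species
setClass("Species",
  slots = c(name = "character", kind = "character", D = "numeric",
            sites = "character", states = "character",
            allowed = "character", membraneBound = "logical"),
  prototype = list(name = "X", kind = "particle", D = 1,
                   sites = character(), states = character(),
                   allowed = character(), membraneBound = FALSE))

setValidity("Species", function(object) {
  msg <- character()
  if (!object@kind %in% c("bulk", "particle"))
    msg <- c(msg, sprintf("species '%s': kind must be 'bulk' or 'particle'", object@name))
  if (length(object@D) != 1L || !is.finite(object@D) || object@D < 0)
    msg <- c(msg, sprintf("species '%s': D must be a single number >= 0", object@name))
  if (object@kind == "bulk" && (length(object@sites) || length(object@states)))
    msg <- c(msg, sprintf("species '%s': bulk species cannot have sites or states", object@name))
  if (anyDuplicated(object@sites)) msg <- c(msg, sprintf("species '%s': duplicate site names", object@name))
  if (anyDuplicated(object@states)) msg <- c(msg, sprintf("species '%s': duplicate state names", object@name))
  if (length(msg)) msg else TRUE
})

#' Reaction rule
#'
#' A typed unimolecular (one reactant) or bimolecular (two reactants)
#' interaction rule. Reactants and products are species-with-state patterns
#' built by [rxPattern()]: named site/state entries constrain matching
#' (reactant side) or are assigned (product side); unnamed sites/states are
#' wildcards and carried through unchanged. A species appearing on both
#' sides with an unchanged pattern is a catalyst and is never consumed.
#'
#' Rate constant units: s^-1 for unimolecular rules, M^-1 s^-1 for
#' bimolecular rules. Reversible rules carry `kRev` for the reverse
#' direction; for reversible particle-particle binding the two reverse
#' products are placed at the unbinding radius `sigmaUMult * sigma_b`.
#'
#' @slot id rule identifier.
#' @slot reactants,products lists of patterns from [rxPattern()].
#' @slot k forward rate constant.
#' @slot reversible logical.
#' @slot kRev reverse rate constant (used when `reversible`).
#' @slot compartments compartment/microdomain scope (empty = everywhere).
#' @slot sigmaUMult unbinding-radius multiplier (>= 1, default 1: products
#'   of the reverse reaction are placed at contact).
#' @exportClass Reaction
setClass("Reaction",
  slots = c(id = "character", reactants = "list", products = "list",
            k = "numeric", reversible = "logical", kRev = "numeric",
            compartments = "character", sigmaUMult = "numeric"),
  prototype = list(id = "r", reactants = list(), products = list(),
                   k = 0, reversible = FALSE, kRev = 0,
                   compartments = character(), sigmaUMult = 1))

setValidity("Reaction", function(object) {
  msg <- character()
  nr <- length(object@reactants)
  if (nr < 1L || nr > 2L)
    msg <- c(msg, sprintf("reaction '%s': must have 1 or 2 reactants", object@id))
  if (length(object@k) != 1L || !is.finite(object@k) || object@k < 0)
    msg <- c(msg, sprintf("reaction '%s': k must be >= 0", object@id))
  if (object@reversible && (length(object@kRev) != 1L || !is.finite(object@kRev) || object@kRev < 0))
    msg <- c(msg, sprintf("reaction '%s': kRev must be >= 0", object@id))
  if (object@sigmaUMult < 1)
    msg <- c(msg, sprintf("reaction '%s': sigmaUMult must be >= 1", object@id))
  bad <- !vapply(c(object@reactants, object@products), is.list, logical(1))
  if (any(bad)) msg <- c(msg, sprintf("reaction '%s': patterns must be rxPattern() lists", object@id))
  if (length(msg)) msg else TRUE
})

#' Probabilistic transport rule
#'
#' Relocates matching particles from one compartment to a uniformly random
#' position in an accessible voxel of another compartment with a fixed
#' per-step probability; an abstraction of vesicle-mediated trafficking
#' (e.g. clathrin-mediated internalization). Particles carrying the
#' `blockedBy` state never relocate.
#'
#' @slot id rule identifier.
#' @slot species species name to match.
#' @slot sites,states pattern constraints as in [rxPattern()].
#' @slot from,to compartment names (must differ).
#' @slot prob per-step relocation probability in [0, 1].
#' @slot blockedBy state name that blocks transport (`NA` for none).
#' @exportClass Transport
setClass("Transport",
  slots = c(id = "character", species = "character", sites = "logical",
            states = "logical", from = "character", to = "character",
            prob = "numeric", blockedBy = "character"),
  prototype = list(id = "t", species = "X", sites = logical(), states = logical(),
                   from = "a", to = "b", prob = 0, blockedBy = NA_character_))

setValidity("Transport", function(object) {
  msg <- character()
  if (length(object@prob) != 1L || !is.finite(object@prob) ||
      object@prob < 0 || object@prob > 1)
    msg <- c(msg, sprintf("transport '%s': prob must be in [0,1]", object@id))
  if (identical(object@from, object@to))
    msg <- c(msg, sprintf("transport '%s': from and to must differ", object@id))
  if (length(msg)) msg else TRUE
})

#' Concentration source/sink specification
#'
#' Fixed per-voxel interventions applied at the end of each timestep:
#' `clamp` holds the voxel at a target concentration (mol/L), `influx` adds
#' a fixed molecule amount per step, `absorb` empties the voxel.
#'
#' @slot species bulk species name.
#' @slot voxels integer matrix (i,j,k), 0-based.
#' @slot mode `"clamp"`, `"influx"` or `"absorb"`.
#' @slot value concentration (mol/L) for clamp, amount per step for influx.
#' @exportClass SourceSink
setClass("SourceSink",
  slots = c(species = "character", voxels = "matrix", mode = "character",
            value = "numeric"),
  prototype = list(species = "X",
                   voxels = matrix(integer(), 0L, 3L, dimnames = list(NULL, c("i","j","k"))),
                   mode = "clamp", value = 0))

setValidity("SourceSink", function(object) {
  msg <- character()
  if (!object@mode %in% c("clamp", "influx", "absorb"))
    msg <- c(msg, "mode must be clamp, influx or absorb")
  if (object@mode != "absorb" &&
      (length(object@value) != 1L || !is.finite(object@value) || object@value < 0))
    msg <- c(msg, "clamp/influx value must be >= 0")
  if (ncol(object@voxels) != 3L) msg <- c(msg, "voxels must have 3 columns")
  if (length(msg)) msg else TRUE
})

#' Membrane microdomain (lipid raft) specification
#'
#' A subset of a membrane compartment's voxels with species-specific
#' partitioning: a particle's step that would cross the domain boundary is
#' accepted with probability `entry` (into the domain) or `exit` (out of
#' it), and otherwise deflected. Biases of 1 leave trajectories untouched.
#'
#' @slot name microdomain name.
#' @slot voxels integer matrix (i,j,k), 0-based; subset of a membrane
#'   compartment's voxel set.
#' @slot partition data.frame with columns species, entry, exit (each bias
#'   in [0,1]); species absent from the table use entry = exit = 1.
#' @exportClass Microdomain
setClass("Microdomain",
  slots = c(name = "character", voxels = "matrix", partition = "data.frame"),
  prototype = list(name = "raft",
                   voxels = matrix(integer(), 0L, 3L, dimnames = list(NULL, c("i","j","k"))),
                   partition = data.frame(species = character(),
                                          entry = numeric(), exit = numeric())))

setValidity("Microdomain", function(object) {
  msg <- character()
  p <- object@partition
  if (!all(c("species", "entry", "exit") %in% names(p)))
    msg <- c(msg, "partition must have columns species, entry, exit")
  else if (nrow(p) && (any(p$entry < 0 | p$entry > 1) || any(p$exit < 0 | p$exit > 1)))
    msg <- c(msg, sprintf("microdomain '%s': biases must be in [0,1]", object@name))
  if (ncol(object@voxels) != 3L) msg <- c(msg, "voxels must have 3 columns")
  if (length(msg)) msg else TRUE
})

#' Reversible immobilization rule (trans-binding surrogate)
#'
#' First-order reversible immobilization of matching membrane particles:
#' mobile matches become immobilized with per-step probability
#' 1 - exp(-kOn dt) and are released with 1 - exp(-kOff dt). Immobilized
#' particles skip diffusion and transport. Used to mimic trans-binding of
#' surface receptors to an apposed cell.
#'
#' @slot id rule identifier.
#' @slot species species name to match.
#' @slot sites,states pattern constraints as in [rxPattern()].
#' @slot kOn,kOff forward/reverse rates (s^-1, >= 0).
#' @slot compartments compartment scope (empty = everywhere).
#' @exportClass Immobilization
setClass("Immobilization",
  slots = c(id = "character", species = "character", sites = "logical",
            states = "logical", kOn = "numeric", kOff = "numeric",
            compartments = "character"),
  prototype = list(id = "im", species = "X", sites = logical(), states = logical(),
                   kOn = 0, kOff = 0, compartments = character()))

setValidity("Immobilization", function(object) {
  msg <- character()
  if (object@kOn < 0 || object@kOff < 0) msg <- c(msg, "kOn and kOff must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Complete simulation model
#'
#' The in-memory model description: environment geometry, compartments,
#' species, reaction/transport/immobilization rules, sources and sinks,
#' microdomains, initial conditions and output configuration. Build with
#' [newSimModel()] or one of the model generators, read/write XML with
#' [parseModel()]/[writeModel()], and check cross-references and numeric
#' ranges with [validateModel()].
#'
#' @slot environment a [SimEnvironment-class].
#' @slot compartments list of [Compartment-class].
#' @slot species list of [Species-class].
#' @slot reactions list of [Reaction-class].
#' @slot transports list of [Transport-class].
#' @slot sources list of [SourceSink-class].
#' @slot microdomains list of [Microdomain-class].
#' @slot immobilizations list of [Immobilization-class].
#' @slot initials data.frame with columns species, amount ("count" or
#'   "concentration"), value, compartment.
#' @slot output list(logInterval, particleLog, perCompartment).
#' @exportClass SimModel
setClass("SimModel",
  slots = c(environment = "SimEnvironment", compartments = "list",
            species = "list", reactions = "list", transports = "list",
            sources = "list", microdomains = "list",
            immobilizations = "list", initials = "data.frame",
            output = "list"),
  prototype = list(environment = new("SimEnvironment"),
                   compartments = list(), species = list(), reactions = list(),
                   transports = list(), sources = list(), microdomains = list(),
                   immobilizations = list(),
                   initials = data.frame(species = character(), amount = character(),
                                         value = numeric(), compartment = character()),
                   output = list(logInterval = 1L, particleLog = FALSE,
                                 perCompartment = FALSE)))

setValidity("SimModel", function(object) {
  msg <- character()
  chk <- function(lst, cls, what) {
    ok <- vapply(lst, is, logical(1), class2 = cls)
    if (!all(ok)) sprintf("%s must all be %s objects", what, cls) else character()
  }
  msg <- c(msg,
           chk(object@compartments, "Compartment", "compartments"),
           chk(object@species, "Species", "species"),
           chk(object@reactions, "Reaction", "reactions"),
           chk(object@transports, "Transport", "transports"),
           chk(object@sources, "SourceSink", "sources"),
           chk(object@microdomains, "Microdomain", "microdomains"),
           chk(object@immobilizations, "Immobilization", "immobilizations"))
  need <- c("species", "amount", "value", "compartment")
  if (!all(need %in% names(object@initials)))
    msg <- c(msg, "initials must have columns species, amount, value, compartment")
  if (!all(c("logInterval", "particleLog") %in% names(object@output)))
    msg <- c(msg, "output must contain logInterval and particleLog")
  if (length(msg)) msg else TRUE
})

#' Realized c-voxel lattice
#'
#' The resolved voxel grid of a model: per-voxel innermost compartment,
#' per-voxel microdomain membership, and the frozen (outward-normal) axis of
#' membrane voxels. Built from a validated model by [buildLattice()].
#'
#' @slot dims integer voxel counts (nx, ny, nz).
#' @slot h voxel edge length (um).
#' @slot compartmentNames,microdomainNames name lookups for the id arrays.
#' @slot compartmentOf integer 3-D array of compartment ids (1-based).
#' @slot microdomainOf integer 3-D array of microdomain ids (0 = none).
#' @slot membrane2d logical per compartment.
#' @slot frozenAxis integer 3-D array: 0 none, 1 x, 2 y, 3 z.
#' @exportClass VoxelLattice
setClass("VoxelLattice",
  slots = c(dims = "integer", h = "numeric", compartmentNames = "character",
            microdomainNames = "character", compartmentOf = "array",
            microdomainOf = "array", membrane2d = "logical",
            frozenAxis = "array"))

#' Simulation result
#'
#' Holds the per-step molecule-count table (bulk amounts as real sums over
#' voxels, particle counts as integers, broken out by species-state label),
#' the optional per-compartment count array and particle log, the final
#' state, and the provenance needed for reproduction (seed, model hash, the
#' model itself). See [simCounts()], [particleLog()], [summarizeResult()],
#' [writeCountsTsv()].
#'
#' @slot counts data.frame: step, time_s, then one column per species-state.
#' @slot compartmentCounts 3-D array [logged step, compartment, column] or NULL.
#' @slot particleLogDf data.frame particle log or NULL.
#' @slot finalState list with fields, particle table, step.
#' @slot seed integer seed used.
#' @slot modelHash hash of the model's canonical XML serialization.
#' @slot model the [SimModel-class] that was run.
#' @exportClass SimResult
setClass("SimResult",
  slots = c(counts = "data.frame", compartmentCounts = "ANY",
            particleLogDf = "ANY", finalState = "list", seed = "integer",
            modelHash = "character", model = "SimModel"))
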