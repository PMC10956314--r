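## Built-in model generators: cooperative calcium-calmodulin activation
## (well-mixed box and quintile microdomain variants) and CEACAM1
## membrane-clustering (raft / no-raft variants). Parameterized exactly
## where the modeled systems prescribe numbers; other knobs are exposed
## with defaults documented in the methods vignette.

## the eight state-dependent binding/unbinding rules implementing
## sequential cooperative binding per lobe (site 2 binds only after site 1)
.camBindingRules <- function(rates) {
  list(
    newReaction("bind_N1", list(rxPattern("Ca"), rxPattern("CaM", sites = c(N1 = FALSE))),
                rxPattern("CaM", sites = c(N1 = TRUE)), k = rates$N_lobe$k_on1),
    newReaction("bind_N2", list(rxPattern("Ca"), rxPattern("CaM", sites = c(N1 = TRUE, N2 = FALSE))),
                rxPattern("CaM", sites = c(N2 = TRUE)), k = rates$N_lobe$k_on2),
    newReaction("unbind_N1", rxPattern("CaM", sites = c(N1 = TRUE, N2 = FALSE)),
                list(rxPattern("CaM", sites = c(N1 = FALSE)), rxPattern("Ca")),
                k = rates$N_lobe$k_off1),
    newReaction("unbind_N2", rxPattern("CaM", sites = c(N2 = TRUE)),
                list(rxPattern("CaM", sites = c(N2 = FALSE)), rxPattern("Ca")),
                k = rates$N_lobe$k_off2),
    newReaction("bind_C1", list(rxPattern("Ca"), rxPattern("CaM", sites = c(C1 = FALSE))),
                rxPattern("CaM", sites = c(C1 = TRUE)), k = rates$C_lobe$k_on1),
    newReaction("bind_C2", list(rxPattern("Ca"), rxPattern("CaM", sites = c(C1 = TRUE, C2 = FALSE))),
                rxPattern("CaM", sites = c(C2 = TRUE)), k = rates$C_lobe$k_on2),
    newReaction("unbind_C1", rxPattern("CaM", sites = c(C1 = TRUE, C2 = FALSE)),
                list(rxPattern("CaM", sites = c(C1 = FALSE)), rxPattern("Ca")),
                k = rates$C_lobe$k_off1),
    newReaction("unbind_C2", rxPattern("CaM", sites = c(C2 = TRUE)),
                list(rxPattern("CaM", sites = c(C2 = FALSE)), rxPattern("Ca")),
                k = rates$C_lobe$k_off2))
}

#' Well-mixed cooperative calmodulin activation model
#'
#' A single-compartment cube of 4 x 4 x 4 c-voxels of 0.2 um edge
#' (0.8 um side, 5.12e-16 L). Calcium is a bulk species; calmodulin
#' molecules are point particles with four sequential binding sites
#' (N1, N2, C1, C2; one lobe's second site binds only once its first is
#' occupied, with higher affinity). Both species start uniformly
#' distributed at the given total concentrations.
#'
#' @param caTotal total calcium concentration (mol/L).
#' @param camTotal total calmodulin concentration (mol/L; default 2 uM).
#' @param rates cooperative rate constants, see [calmodulinRates()].
#' @param dCa,dCam diffusion coefficients (um^2/s).
#' @param dt timestep (s).
#' @param nSteps number of steps.
#' @param logInterval logging interval (steps).
#' @param seed RNG seed.
#' @return a validated [SimModel-class].
#' @export
buildCalmodulinModel <- function(caTotal, camTotal = 2e-6, rates = calmodulinRates(),
                                 dCa = 220, dCam = 30, dt = 5e-7, nSteps = 60000L,
                                 logInterval = 2000L, seed = 0L) {
  env <- newEnvironment(4, 4, 4, voxelLen = 0.2, timestep = dt, nSteps = nSteps,
                        seed = seed)
  comp <- list(newCompartment("cell", boxes = c(0, 4, 0, 4, 0, 4)))
  species <- list(
    newSpecies("Ca", "bulk", D = dCa, allowed = "cell"),
    newSpecies("CaM", "particle", D = dCam, sites = c("N1", "N2", "C1", "C2"),
               allowed = "cell"))
  initials <- data.frame(
    species = c("Ca", "CaM"), amount = "concentration",
    value = c(caTotal, camTotal), compartment = "cell")
  newSimModel(env, comp, species, reactions = .camBindingRules(rates),
              initials = initials, logInterval = logInterval)
}

.qLayouts <- list(
  center = cbind(j = c(4L, 4L, 5L, 5L), k = c(4L, 5L, 4L, 5L)),
  original = cbind(j = c(5L, 5L, 6L, 6L), k = c(5L, 6L, 5L, 6L)),
  split = cbind(j = c(2L, 2L, 7L, 7L), k = c(2L, 7L, 2L, 7L)))

#' Calcium microdomain (quintile) calmodulin model
#'
#' A 10 x 10 x 10 lattice of 0.08 um c-voxels subdivided into five
#' 2 x 10 x 10 slab compartments (quintiles Q1--Q5) along x. Four voxels
#' on the Q1 outer face are clamped to the source calcium concentration
#' each step (Dirichlet boundary); the Q5 outer face absorbs calcium.
#' All other boundaries are hard (reflecting). Calmodulin particles
#' diffuse freely through all quintiles. Per-compartment logging is
#' enabled so quintile concentration and saturation profiles can be read
#' with [summarizeResult()].
#'
#' @param layout source-voxel arrangement on the Q1 face: `"center"`
#'   (2 x 2 block at the face center), `"original"` (2 x 2 block offset
#'   one voxel diagonally) or `"split"` (4 voxels at the quarter points).
#' @param sourceConc clamp concentration (mol/L; default 1 mM).
#' @param camConc calmodulin concentration (mol/L; default 2 uM).
#' @param rates,dCa,dCam,dt,nSteps,logInterval,seed as in
#'   [buildCalmodulinModel()].
#' @return a validated [SimModel-class].
#' @export
buildMicrodomainModel <- function(layout = c("center", "original", "split"),
                                  sourceConc = 1e-3, camConc = 2e-6,
                                  rates = calmodulinRates(), dCa = 220, dCam = 30,
                                  dt = 1e-6, nSteps = 12000L, logInterval = 100L,
                                  seed = 0L) {
  layout <- match.arg(layout)
  env <- newEnvironment(10, 10, 10, voxelLen = 0.08, timestep = dt,
                        nSteps = nSteps, seed = seed)
  comp <- lapply(1:5, function(q)
    newCompartment(sprintf("Q%d", q), boxes = c(2 * (q - 1), 2 * q, 0, 10, 0, 10)))
  qn <- sprintf("Q%d", 1:5)
  species <- list(
    newSpecies("Ca", "bulk", D = dCa, allowed = qn),
    newSpecies("CaM", "particle", D = dCam, sites = c("N1", "N2", "C1", "C2"),
               allowed = qn))
  jk <- .qLayouts[[layout]]
  srcVox <- cbind(i = 0L, jk)
  sinkVox <- as.matrix(expand.grid(i = 9L, j = 0:9, k = 0:9))
  sources <- list(
    newSourceSink("Ca", srcVox, mode = "clamp", value = sourceConc),
    newSourceSink("Ca", sinkVox, mode = "absorb"))
  initials <- data.frame(
    species = "CaM", amount = "concentration", value = camConc,
    compartment = qn, stringsAsFactors = FALSE)
  newSimModel(env, comp, species, reactions = .camBindingRules(rates),
              sources = sources, initials = initials, logInterval = logInterval,
              perCompartment = TRUE)
}

## raft voxel patches: one 2 x 2 patch centered on each of the six faces
.raftVoxels <- function(n = 6L) {
  mid <- c(2L, 3L)
  lo <- 0L; hi <- n - 1L
  vox <- rbind(
    as.matrix(expand.grid(i = lo, j = mid, k = mid)),
    as.matrix(expand.grid(i = hi, j = mid, k = mid)),
    as.matrix(expand.grid(i = mid, j = lo, k = mid)),
    as.matrix(expand.grid(i = mid, j = hi, k = mid)),
    as.matrix(expand.grid(i = mid, j = mid, k = lo)),
    as.matrix(expand.grid(i = mid, j = mid, k = hi)))
  colnames(vox) <- c("i", "j", "k")
  vox
}

#' CEACAM1 lipid-raft clustering model
#'
#' A 6 x 6 x 6 lattice of 0.2 um c-voxels with four compartments: the
#' outer voxel layer is a 2-D membrane, the next layer a cytosolic
#' interface, and the 2 x 2 x 2 core is split between cytosol and an
#' inert organelle. CEACAM1 cis-dimers and monomers are membrane-bound
#' particles shuttling between cytosol and membrane through probabilistic
#' transport (clathrin-mediated internalization is blocked for
#' ITIM-phosphorylated monomers); activated calmodulin dissociates dimers
#' into monomers; Lck phosphorylates monomers; monomers are reversibly
#' immobilized on the membrane (trans-binding surrogate; the immobilized
#' count is the "clustered" readout). The raft variant adds membrane
#' microdomains that enrich monomers (and confine Lck) and exclude
#' dimers, and restricts phosphorylation to rafts.
#'
#' @param raft include lipid-raft microdomains (TRUE) or the no-raft
#'   control (FALSE).
#' @param nLck,nCam initial molecule counts of Lck and activated
#'   calmodulin (the modeled sweep uses 0/10/20 and 0/2/5/10/20).
#' @param nDimers initial CEACAM1 dimer count in the cytosol.
#' @param kDis dimer + CaM dissociation rate constant (M^-1 s^-1).
#' @param kDim monomer dimerization rate constant (M^-1 s^-1).
#' @param kPhos Lck phosphorylation rate constant (M^-1 s^-1).
#' @param kOnTrans,kOffTrans trans-binding (immobilization) on/off rates (s^-1).
#' @param exportProb,internalizeProb per-step transport probabilities.
#' @param camCatalytic if TRUE (default) activated calmodulin survives the
#'   dissociation reaction (catalytic); if FALSE it is consumed.
#' @param monomerEntry,monomerExit,dimerEntry,dimerExit raft partition
#'   biases.
#' @param dt timestep (s; the modeled system uses 50 us).
#' @param nSteps number of steps (the full system runs 200000 = 10 s;
#'   scaled-down runs use fewer).
#' @param logInterval logging interval (steps).
#' @param seed RNG seed.
#' @return a validated [SimModel-class].
#' @export
buildCeacamModel <- function(raft = TRUE, nLck = 20L, nCam = 20L, nDimers = 50L,
                             kDis = 1e7, kDim = 1e6, kPhos = 1e6,
                             kOnTrans = 5, kOffTrans = 0.2,
                             exportProb = 1e-3, internalizeProb = 1e-3,
                             camCatalytic = TRUE,
                             monomerEntry = 1, monomerExit = 0.2,
                             dimerEntry = 0.2, dimerExit = 1,
                             dt = 5e-5, nSteps = 20000L, logInterval = 100L,
                             seed = 0L) {
  env <- newEnvironment(6, 6, 6, voxelLen = 0.2, timestep = dt, nSteps = nSteps,
                        seed = seed)
  comp <- list(
    newCompartment("membrane", boxes = c(0, 6, 0, 6, 0, 6), membrane2d = TRUE),
    newCompartment("cytosolic_interface", boxes = c(1, 5, 1, 5, 1, 5),
                   parent = "membrane"),
    newCompartment("cytosol", boxes = c(2, 4, 2, 4, 3, 4),
                   parent = "cytosolic_interface"),
    newCompartment("organelle", boxes = c(2, 4, 2, 4, 2, 3),
                   parent = "cytosolic_interface"))
  species <- list(
    newSpecies("CEACAM1_dimer", "particle", D = 0.1,
               allowed = c("membrane", "cytosol"), membraneBound = TRUE),
    newSpecies("CEACAM1_monomer", "particle", D = 0.2, states = "phos",
               allowed = c("membrane", "cytosol"), membraneBound = TRUE),
    newSpecies("Lck", "particle", D = 0.2, allowed = "membrane",
               membraneBound = TRUE),
    newSpecies("CaM_active", "particle", D = 10,
               allowed = c("cytosolic_interface", "membrane")))
  dimPat <- rxPattern("CEACAM1_dimer")
  monoFree <- rxPattern("CEACAM1_monomer", states = c(phos = FALSE))
  reactions <- list(
    newReaction("dissociation",
                list(dimPat, rxPattern("CaM_active")),
                c(list(rxPattern("CEACAM1_monomer"), rxPattern("CEACAM1_monomer")),
                  if (camCatalytic) list(rxPattern("CaM_active"))),
                k = kDis),
    newReaction("dimerization", list(monoFree, monoFree), dimPat, k = kDim,
                sigmaUMult = 2),
    newReaction("phosphorylation",
                list(rxPattern("Lck"), monoFree),
                list(rxPattern("Lck"),
                     rxPattern("CEACAM1_monomer", states = c(phos = TRUE))),
                k = kPhos,
                compartments = if (raft) "raft" else character()))
  transports <- list(
    newTransport("export_dimer", "CEACAM1_dimer", "cytosol", "membrane", exportProb),
    newTransport("export_monomer", "CEACAM1_monomer", "cytosol", "membrane", exportProb),
    newTransport("internalize_dimer", "CEACAM1_dimer", "membrane", "cytosol",
                 internalizeProb),
    newTransport("internalize_monomer", "CEACAM1_monomer", "membrane", "cytosol",
                 internalizeProb, blockedBy = "phos"))
  immob <- list(newImmobilization("trans_binding", "CEACAM1_monomer",
                                  kOn = kOnTrans, kOff = kOffTrans,
                                  compartments = "membrane"))
  domains <- if (raft) list(newMicrodomain("raft", .raftVoxels(6L),
    partition = data.frame(
      species = c("CEACAM1_monomer", "CEACAM1_dimer", "Lck"),
      entry = c(monomerEntry, dimerEntry, 1),
      exit = c(monomerExit, dimerExit, 0)))) else list()
  initials <- data.frame(
    species = c("CEACAM1_dimer", "Lck", "CaM_active"),
    amount = "count",
    value = c(nDimers, nLck, nCam),
    compartment = c("cytosol", "membrane", "cytosolic_interface"))
  initials <- initials[initials$value > 0, , drop = FALSE]
  newSimModel(env, comp, species, reactions = reactions, transports = transports,
              microdomains = domains, immobilizations = immob,
              initials = initials, logInterval = logInterval,
              perCompartment = TRUE)
}

#' Summary statistics of a simulation result
#'
#' Computes per-compartment time series (requires a run with
#' `perCompartment = TRUE`): bulk concentrations in mol/L, occupancy-class
#' fractions for particle species with binding sites, and raw counts for
#' the other columns; plus their time averages over a post-burn-in window.
#'
#' @param result a [SimResult-class].
#' @param from,to time window (s) for the averages; defaults to the second
#'   half of the run.
#' @return list with `series` (long data.frame: step, time_s, compartment,
#'   column, value, and `concentration` for bulk columns / `fraction` for
#'   occupancy columns) and `averages` (the same, averaged over the window).
#' @export
summarizeResult <- function(result, from = NULL, to = NULL) {
  cc <- result@compartmentCounts
  if (is.null(cc)) stop("result was not run with perCompartment = TRUE")
  model <- result@model
  lattice <- buildLattice(model)
  counts <- result@counts
  tEnd <- counts$time_s[nrow(counts)]
  if (is.null(from)) from <- tEnd / 2
  if (is.null(to)) to <- tEnd
  if (to <= from && nrow(counts) > 1L) stop("empty averaging window")
  vox <- voxelVolumeL(lattice@h)
  nVox <- vapply(seq_along(lattice@compartmentNames), function(ci)
    sum(lattice@compartmentOf == ci), numeric(1))
  sn <- speciesNames(model)
  kinds <- vapply(model@species, slot, character(1), name = "kind")
  siteSpecies <- sn[vapply(model@species, function(s) length(s@sites) > 0, logical(1))]
  colNames <- dimnames(cc)[[3L]]
  rows <- list()
  for (ci in seq_along(lattice@compartmentNames)) {
    for (cj in seq_along(colNames)) {
      nm <- colNames[cj]
      val <- cc[, ci, cj]
      conc <- if (nm %in% sn[kinds == "bulk"]) val / (nVox[ci] * vox * .NA_AVOGADRO)
              else NA_real_
      frac <- NA_real_
      base <- sub("_[0-9]+$", "", nm)
      if (grepl("_[0-9]+$", nm) && base %in% siteSpecies) {
        tot <- cc[, ci, base]
        frac <- ifelse(tot > 0, val / tot, NA_real_)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        step = counts$step, time_s = counts$time_s,
        compartment = lattice@compartmentNames[ci], column = nm,
        value = val, concentration = conc, fraction = frac)
    }
  }
  series <- do.call(rbind, rows)
  win <- series$time_s >= from & series$time_s <= to
  avg <- stats::aggregate(series[win, c("value", "concentration", "fraction")],
                          by = list(compartment = series$compartment[win],
                                    column = series$column[win]),
                          FUN = function(v) mean(v, na.rm = TRUE))
  list(series = series, averages = avg, window = c(from = from, to = to))
}
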