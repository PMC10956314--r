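#' Validate a simulation model
#'
#' Checks every structural and cross-reference invariant of a model:
#' environment ranges, compartment coverage and bounds, membrane layering,
#' species definitions, rule references (species, sites, states,
#' compartments), source/sink and microdomain placement, initial
#' conditions, and the forward-Euler stability bound D*dt/h^2 <= 1/6 for
#' every bulk species. Violations are returned as data, not thrown.
#'
#' @param model a [SimModel-class].
#' @return data.frame with columns `element` (the offending model element),
#'   `severity` (`"error"` or `"warning"`) and `message`. A model is valid
#'   iff it produces no `"error"` rows (warnings, e.g. a voxel edge outside
#'   the 0.01--1 um working range, do not invalidate it).
#' @export
validateModel <- function(model) {
  out <- list()
  add <- function(element, message, severity = "error")
    out[[length(out) + 1L]] <<- data.frame(element = element, severity = severity,
                                           message = message)
  e <- model@environment
  dims <- c(e@nx, e@ny, e@nz)
  if (any(dims < 1L)) add("environment", "voxel counts nx, ny, nz must be >= 1")
  if (!is.finite(e@voxelLen) || e@voxelLen <= 0)
    add("environment", "voxel_len must be > 0")
  else if (e@voxelLen < 0.01 || e@voxelLen > 1)
    add("environment", sprintf("voxel_len %g um is outside the typical 0.01-1 um working range",
                               e@voxelLen), "warning")
  if (!is.finite(e@timestep) || e@timestep <= 0) add("environment", "timestep must be > 0")
  envOK <- !any(dims < 1L) && e@voxelLen > 0

  cnames <- compartmentNames(model)
  if (anyDuplicated(cnames))
    add("compartments", sprintf("duplicate compartment names: %s",
                                paste(unique(cnames[duplicated(cnames)]), collapse = ", ")))
  snames <- if (length(model@species)) speciesNames(model) else character()
  if (anyDuplicated(snames))
    add("species", sprintf("duplicate species names: %s",
                           paste(unique(snames[duplicated(snames)]), collapse = ", ")))
  mnames <- vapply(model@microdomains, slot, character(1), name = "name")
  scopeNames <- c(cnames, mnames)

  boxInBounds <- function(bx) all(bx[c(1, 3, 5)] >= 0) && bx[2] <= dims[1] &&
    bx[4] <= dims[2] && bx[6] <= dims[3] && all(bx[c(2, 4, 6)] > bx[c(1, 3, 5)])
  for (cp in model@compartments) {
    el <- sprintf("compartment '%s'", cp@name)
    if (nrow(cp@boxes) && !all(apply(cp@boxes, 1L, boxInBounds)))
      add(el, "box range outside lattice bounds or empty")
    if (nrow(cp@voxels) && !all(.inBoundsVoxel(cp@voxels, dims)))
      add(el, "voxel index outside lattice bounds")
    if (!is.na(cp@parent) && !cp@parent %in% cnames)
      add(el, sprintf("unknown parent compartment '%s'", cp@parent))
  }

  coverageOK <- FALSE
  if (envOK && length(model@compartments)) {
    comp <- array(0L, dim = dims)
    ok <- TRUE
    for (ci in seq_along(model@compartments)) {
      lin <- tryCatch(.compartmentLin(model@compartments[[ci]], dims), error = function(e) NULL)
      if (is.null(lin) || any(lin < 1L) || any(lin > prod(dims))) { ok <- FALSE; break }
      comp[lin] <- ci
    }
    if (ok && any(comp == 0L))
      add("compartments", sprintf("%d voxels not covered by any compartment", sum(comp == 0L)))
    else if (ok) coverageOK <- TRUE
    if (coverageOK) {
      for (ci in seq_along(model@compartments)) {
        cp <- model@compartments[[ci]]
        if (!cp@membrane2d) next
        vox <- which(comp == ci, arr.ind = TRUE) - 1L
        outer <- vox[, 1L] == 0L | vox[, 1L] == dims[1L] - 1L |
                 vox[, 2L] == 0L | vox[, 2L] == dims[2L] - 1L |
                 vox[, 3L] == 0L | vox[, 3L] == dims[3L] - 1L
        if (nrow(vox) && !all(outer))
          add(sprintf("compartment '%s'", cp@name),
              "membrane_2d compartment has voxels outside the outer voxel layer")
      }
    }
  } else if (envOK && !length(model@compartments)) {
    add("compartments", "model defines no compartments")
  }

  for (sp in model@species) {
    el <- sprintf("species '%s'", sp@name)
    if (!length(sp@allowed)) add(el, "allowed_compartments must be non-empty")
    miss <- setdiff(sp@allowed, cnames)
    if (length(miss)) add(el, sprintf("unknown allowed compartment '%s'", miss[1L]))
    if (sp@D < 0) add(el, "diffusion coefficient D must be >= 0")
    if (sp@kind == "bulk" && envOK && e@timestep > 0) {
      ratio <- sp@D * e@timestep / e@voxelLen^2
      if (ratio > 1 / 6 + 1e-12)
        add(el, sprintf("forward-Euler stability violated: D*dt/h^2 = %.4g > 1/6", ratio))
    }
  }

  spKind <- structure(vapply(model@species, slot, character(1), name = "kind"), names = snames)
  spSites <- structure(lapply(model@species, slot, name = "sites"), names = snames)
  spStates <- structure(lapply(model@species, slot, name = "states"), names = snames)

  chkPattern <- function(pat, el, side) {
    if (!pat$species %in% snames) {
      add(el, sprintf("unknown species '%s' in %s pattern", pat$species, side))
      return(invisible(NULL))
    }
    if (spKind[[pat$species]] == "bulk" && (length(pat$sites) || length(pat$states))) {
      add(el, sprintf("bulk species '%s' cannot carry site/state constraints", pat$species))
      return(invisible(NULL))
    }
    badS <- setdiff(names(pat$sites), spSites[[pat$species]])
    if (length(badS)) add(el, sprintf("undeclared site '%s' for species '%s'", badS[1L], pat$species))
    badT <- setdiff(names(pat$states), spStates[[pat$species]])
    if (length(badT)) add(el, sprintf("undeclared state '%s' for species '%s'", badT[1L], pat$species))
  }

  rids <- vapply(model@reactions, slot, character(1), name = "id")
  if (anyDuplicated(rids)) add("reactions", "duplicate reaction ids")
  for (rx in model@reactions) {
    el <- sprintf("reaction '%s'", rx@id)
    for (p in rx@reactants) chkPattern(p, el, "reactant")
    for (p in rx@products) chkPattern(p, el, "product")
    miss <- setdiff(rx@compartments, scopeNames)
    if (length(miss)) add(el, sprintf("unknown compartment/microdomain scope '%s'", miss[1L]))
    rs <- vapply(rx@reactants, function(p) p$species, character(1))
    known <- rs %in% snames
    if (all(known) && length(rs) && all(spKind[rs] == "bulk")) {
      ps <- vapply(rx@products, function(p) p$species, character(1))
      ps <- ps[ps %in% snames]
      if (any(spKind[ps] == "particle"))
        add(el, "bulk-only reactants cannot produce particle species")
    }
  }

  for (tr in model@transports) {
    el <- sprintf("transport '%s'", tr@id)
    if (!tr@species %in% snames) add(el, sprintf("unknown species '%s'", tr@species))
    miss <- setdiff(c(tr@from, tr@to), cnames)
    if (length(miss)) add(el, sprintf("unknown compartment '%s'", miss[1L]))
    if (!is.na(tr@blockedBy) && tr@species %in% snames &&
        !tr@blockedBy %in% spStates[[tr@species]])
      add(el, sprintf("blocked_by references undeclared state '%s'", tr@blockedBy))
    if (tr@species %in% snames && tr@to %in% cnames) {
      sp <- model@species[[match(tr@species, snames)]]
      if (!tr@to %in% sp@allowed)
        add(el, sprintf("destination compartment '%s' is not accessible to species '%s'",
                        tr@to, tr@species))
    }
  }

  for (ss in model@sources) {
    el <- sprintf("source/sink for '%s'", ss@species)
    if (!ss@species %in% snames) add(el, sprintf("unknown species '%s'", ss@species))
    else if (spKind[[ss@species]] != "bulk") add(el, "sources/sinks apply to bulk species only")
    if (nrow(ss@voxels) && envOK && !all(.inBoundsVoxel(ss@voxels, dims)))
      add(el, "voxel index outside lattice bounds")
  }

  if (length(model@microdomains) && coverageOK) {
    memIds <- which(vapply(model@compartments, slot, logical(1), name = "membrane2d"))
    for (md in model@microdomains) {
      el <- sprintf("microdomain '%s'", md@name)
      if (!all(.inBoundsVoxel(md@voxels, dims))) { add(el, "voxel index outside lattice bounds"); next }
      inMem <- comp[.linIndex(md@voxels, dims)] %in% memIds
      if (!all(inMem)) add(el, "voxel set not contained in a membrane_2d compartment")
      miss <- setdiff(md@partition$species, snames)
      if (length(miss)) add(el, sprintf("unknown species '%s' in partition table", miss[1L]))
    }
  }

  for (im in model@immobilizations) {
    el <- sprintf("immobilization '%s'", im@id)
    if (!im@species %in% snames) add(el, sprintf("unknown species '%s'", im@species))
    miss <- setdiff(im@compartments, scopeNames)
    if (length(miss)) add(el, sprintf("unknown compartment scope '%s'", miss[1L]))
  }

  if (nrow(model@initials)) {
    for (r in seq_len(nrow(model@initials))) {
      ini <- model@initials[r, ]
      el <- sprintf("initial condition for '%s'", ini$species)
      if (!ini$species %in% snames) add(el, sprintf("unknown species '%s'", ini$species))
      if (!ini$compartment %in% cnames)
        add(el, sprintf("unknown compartment '%s'", ini$compartment))
      if (!ini$amount %in% c("count", "concentration"))
        add(el, "amount must be 'count' or 'concentration'")
      if (!is.finite(ini$value) || ini$value < 0) add(el, "initial value must be >= 0")
    }
  }

  if (!length(out))
    return(data.frame(element = character(), severity = character(), message = character()))
  do.call(rbind, out)
}

#' Is a model valid?
#'
#' @param model a [SimModel-class].
#' @return TRUE iff [validateModel()] reports no errors (warnings allowed).
#' @export
isValidModel <- function(model) {
  v <- validateModel(model)
  !any(v$severity == "error")
}

.assertValid <- function(model) {
  v <- validateModel(model)
  bad <- v[v$severity == "error", , drop = FALSE]
  if (nrow(bad))
    stop("invalid model:\n", paste(sprintf("  %s: %s", bad$element, bad$message),
                                   collapse = "\n"), call. = FALSE)
  invisible(model)
}
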