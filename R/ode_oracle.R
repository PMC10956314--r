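## Well-mixed mass-action reference kinetics: a forward-Euler integrator
## over an arbitrary mass-action network, plus the algebraic equilibrium of
## the cooperative calmodulin network. These serve as the deterministic
## reference that the spatial simulations are compared against.

#' Forward-Euler integration of a well-mixed mass-action network
#'
#' Integrates `dC/dt` for a list of mass-action reactions under the
#' well-mixed assumption using the explicit forward Euler method. Each
#' reaction is a list with elements `reactants` (character vector, repeat
#' a species for stoichiometry 2), `products` (character vector) and `k`
#' (rate constant in s^-1 / M^-1 s^-1 according to order).
#'
#' @param reactions list of reaction lists as described.
#' @param init named numeric vector of initial concentrations (mol/L).
#' @param dt integration step (s); must resolve the fastest rate.
#' @param tEnd end time (s).
#' @param recordEvery record the state every this many steps (default:
#'   about 200 output rows).
#' @return data.frame with column `time` and one column per species.
#' @export
massActionEuler <- function(reactions, init, dt, tEnd,
                            recordEvery = max(1L, floor(tEnd / dt / 200))) {
  species <- names(init)
  nS <- length(species)
  C <- as.numeric(init)
  ## index vectors for first/second reactant (nS + 1 is a constant 1) and
  ## a stoichiometry matrix, so each step is a few vectorized operations
  i1 <- integer(); i2 <- integer(); kk <- numeric()
  S <- matrix(0, nS, length(reactions))
  for (j in seq_along(reactions)) {
    r <- reactions[[j]]
    ri <- match(r$reactants, species); pi <- match(r$products, species)
    if (anyNA(c(ri, pi))) stop("reaction references a species missing from init")
    if (length(ri) > 2L) stop("mass-action networks of order > 2 are not supported")
    i1[j] <- ri[1L]
    i2[j] <- if (length(ri) == 2L) ri[2L] else nS + 1L
    kk[j] <- r$k
    for (q in ri) S[q, j] <- S[q, j] - 1
    for (q in pi) S[q, j] <- S[q, j] + 1
  }
  nSteps <- as.integer(round(tEnd / dt))
  out <- list()
  rec <- function(tm) out[[length(out) + 1L]] <<- c(tm, C)
  rec(0)
  Caug <- c(C, 1)
  for (s in seq_len(nSteps)) {
    rates <- kk * Caug[i1] * Caug[i2]
    C <- C + dt * as.vector(S %*% rates)
    if (any(!is.finite(C)))
      stop(sprintf("non-finite concentration at step %d; reduce dt", s))
    C[C < 0] <- 0
    Caug[seq_len(nS)] <- C
    if (s %% recordEvery == 0L || s == nSteps) rec(s * dt)
  }
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("time", species)
  df
}

#' Calmodulin cooperative binding rate constants
#'
#' Loads the versioned parameter file shipped with the package (sequential
#' two-site binding per lobe; see the file's provenance comments).
#'
#' @param file optional path to an alternative YAML parameter file.
#' @return nested list with `N_lobe` and `C_lobe`, each holding
#'   `k_on1`, `k_off1`, `k_on2`, `k_off2`.
#' @export
calmodulinRates <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "calmodulin_rates.yaml", package = "vox4d")
  yaml::read_yaml(file)
}

## lobe state of one calmodulin molecule: 0, 1 or 2 ions bound per lobe;
## joint species labels CaM_<nN><nC>
.camSpeciesNames <- function() {
  g <- expand.grid(nN = 0:2, nC = 0:2)
  sprintf("CaM_%d%d", g$nN, g$nC)
}

#' Mass-action network of cooperative calmodulin activation
#'
#' Builds the 9-state (two lobes, 0--2 ions each) x free-calcium
#' mass-action network for [massActionEuler()], using the sequential
#' per-lobe scheme of [calmodulinRates()].
#'
#' @param rates rate-constant list as returned by [calmodulinRates()].
#' @return list of reactions for [massActionEuler()]; species are `Ca`
#'   and `CaM_<nN><nC>`.
#' @export
calmodulinNetwork <- function(rates = calmodulinRates()) {
  rxs <- list()
  addRx <- function(from, to, k, withCa) {
    rxs[[length(rxs) + 1L]] <<- if (withCa)
      list(reactants = c("Ca", from), products = to, k = k)
    else list(reactants = from, products = c("Ca", to), k = k)
  }
  for (nN in 0:2) for (nC in 0:2) {
    from <- sprintf("CaM_%d%d", nN, nC)
    if (nN < 2) addRx(from, sprintf("CaM_%d%d", nN + 1L, nC),
                      if (nN == 0) rates$N_lobe$k_on1 else rates$N_lobe$k_on2, TRUE)
    if (nN > 0) addRx(from, sprintf("CaM_%d%d", nN - 1L, nC),
                      if (nN == 1) rates$N_lobe$k_off1 else rates$N_lobe$k_off2, FALSE)
    if (nC < 2) addRx(from, sprintf("CaM_%d%d", nN, nC + 1L),
                      if (nC == 0) rates$C_lobe$k_on1 else rates$C_lobe$k_on2, TRUE)
    if (nC > 0) addRx(from, sprintf("CaM_%d%d", nN, nC - 1L),
                      if (nC == 1) rates$C_lobe$k_off1 else rates$C_lobe$k_off2, FALSE)
  }
  rxs
}

#' Occupancy-class fractions from a calmodulin network state
#'
#' Collapses the 9 two-lobe states to the CaM_0..CaM_4 classes (number of
#' occupied sites).
#'
#' @param conc named numeric vector or one-row data.frame holding the
#'   `CaM_<nN><nC>` concentrations.
#' @return numeric vector of fractions named CaM_0..CaM_4 (summing to 1).
#' @export
camClassFractions <- function(conc) {
  conc <- unlist(conc)
  nm <- .camSpeciesNames()
  v <- conc[nm]
  tot <- sum(v)
  nb <- as.integer(substr(nm, 5L, 5L)) + as.integer(substr(nm, 6L, 6L))
  out <- vapply(0:4, function(k) sum(v[nb == k]) / tot, numeric(1))
  names(out) <- sprintf("CaM_%d", 0:4)
  out
}

#' Algebraic equilibrium of cooperative calmodulin activation
#'
#' Solves the detailed-balance equilibrium of the two-lobe sequential
#' binding scheme under calcium conservation: the free-calcium
#' concentration is found by monotone root finding, and the lobe-state
#' distribution follows from the per-lobe partition functions.
#'
#' @param caTotal total calcium concentration (mol/L).
#' @param camTotal total calmodulin concentration (mol/L).
#' @param rates rate-constant list as returned by [calmodulinRates()].
#' @return list with `caFree` (mol/L), `fractions` (CaM_0..CaM_4) and
#'   `boundPerCaM` (mean ions bound per molecule).
#' @export
camEquilibrium <- function(caTotal, camTotal, rates = calmodulinRates()) {
  K1N <- rates$N_lobe$k_on1 / rates$N_lobe$k_off1
  K2N <- rates$N_lobe$k_on2 / rates$N_lobe$k_off2
  K1C <- rates$C_lobe$k_on1 / rates$C_lobe$k_off1
  K2C <- rates$C_lobe$k_on2 / rates$C_lobe$k_off2
  lobe <- function(c, K1, K2) {
    w <- c(1, K1 * c, K1 * K2 * c^2)
    list(f = w / sum(w), mean = sum(c(0, 1, 2) * w) / sum(w))
  }
  bound <- function(c) lobe(c, K1N, K2N)$mean + lobe(c, K1C, K2C)$mean
  if (caTotal <= 0) {
    fr <- c(1, 0, 0, 0, 0); names(fr) <- sprintf("CaM_%d", 0:4)
    return(list(caFree = 0, fractions = fr, boundPerCaM = 0))
  }
  g <- function(c) c + camTotal * bound(c) - caTotal
  cFree <- stats::uniroot(g, c(0, caTotal), tol = caTotal * 1e-12)$root
  fN <- lobe(cFree, K1N, K2N)$f
  fC <- lobe(cFree, K1C, K2C)$f
  joint <- outer(fN, fC)
  nb <- outer(0:2, 0:2, "+")
  fr <- vapply(0:4, function(k) sum(joint[nb == k]), numeric(1))
  names(fr) <- sprintf("CaM_%d", 0:4)
  list(caFree = cFree, fractions = fr, boundPerCaM = bound(cFree))
}
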