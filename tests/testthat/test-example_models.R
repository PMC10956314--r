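test_that("initial particle counts follow N = C V N_A", {
  m <- buildCalmodulinModel(caTotal = 8e-6, camTotal = 2e-6)
  # 4x4x4 voxels of 0.2 um: V = 5.12e-16 L
  V <- 64 * voxelVolumeL(0.2)
  expect_equal(V, 5.12e-16)
  st <- initSimState(m)
  expect_equal(sum(st$particles$species == 2L),
               round(2e-6 * V * 6.02214076e23))
  expect_equal(sum(st$fields$Ca), 8e-6 * V * 6.02214076e23, tolerance = 1e-12)
})

test_that("without calcium all calmodulin stays unbound", {
  m <- buildCalmodulinModel(caTotal = 0, nSteps = 400L, logInterval = 100L)
  r <- runSimulation(m, seed = 1L)
  expect_true(all(r@counts$CaM_0 == r@counts$CaM[1]))
  expect_true(all(r@counts$CaM_4 == 0))
})

test_that("the forward-Euler oracle matches closed-form kinetics", {
  # first order decay
  out <- massActionEuler(list(list(reactants = "A", products = "B", k = 5)),
                         c(A = 1e-6, B = 0), dt = 1e-5, tEnd = 0.5)
  expect_equal(tail(out$A, 1), 1e-6 * exp(-5 * 0.5), tolerance = 1e-3)
  # second order with unequal initial amounts
  k <- 1e8; a0 <- 2e-6; b0 <- 1e-6
  out2 <- massActionEuler(list(list(reactants = c("A", "B"), products = "C", k = k)),
                          c(A = a0, B = b0, C = 0), dt = 1e-5, tEnd = 50)
  d <- a0 - b0
  aInf <- d / (1 - (b0 / a0) * exp(-k * d * 50))
  expect_equal(tail(out2$A, 1), aInf, tolerance = 5e-3)
  expect_error(massActionEuler(list(list(reactants = "X", products = "Y", k = 1)),
                               c(A = 1), dt = 1e-3, tEnd = 1), "missing")
})

test_that("oracle integration agrees with an independent stiff solver", {
  rates <- calmodulinRates()
  net <- calmodulinNetwork(rates)
  init <- c(Ca = 8e-6, structure(numeric(9), names = vox4d:::.camSpeciesNames()))
  init["CaM_00"] <- 2e-6
  mine <- massActionEuler(net, init, dt = 2e-7, tEnd = 0.02)

  species <- names(init)
  deriv <- function(t, y, parms) {
    dy <- numeric(length(y))
    names(dy) <- species
    for (r in net) {
      rate <- r$k * prod(y[r$reactants])
      dy[r$reactants] <- dy[r$reactants] - rate
      dy[r$products] <- dy[r$products] + rate
    }
    list(dy)
  }
  ode <- deSolve::lsoda(init, c(0, 0.02), deriv, parms = NULL,
                        rtol = 1e-8, atol = 1e-14)
  final <- ode[2, species]
  for (s in species)
    expect_equal(unname(tail(mine[[s]], 1)), unname(final[[s]]),
                 tolerance = 1e-3, label = s)
})

test_that("oracle equilibrium matches the detailed-balance solution", {
  rates <- calmodulinRates()
  eq <- camEquilibrium(8e-6, 2e-6, rates)
  net <- calmodulinNetwork(rates)
  init <- c(Ca = 8e-6, structure(numeric(9), names = vox4d:::.camSpeciesNames()))
  init["CaM_00"] <- 2e-6
  out <- massActionEuler(net, init, dt = 2e-6, tEnd = 0.4)
  fr <- camClassFractions(out[nrow(out), ])
  for (k in 0:4)
    expect_equal(unname(fr[[sprintf("CaM_%d", k)]]),
                 unname(eq$fractions[[sprintf("CaM_%d", k)]]),
                 tolerance = 5e-3, label = sprintf("CaM_%d", k))
  # conservation and monotonicity of the algebraic solution
  scan <- seq(0, 1.6e-5, length.out = 9)
  cam4 <- vapply(scan, function(ca) camEquilibrium(ca, 2e-6, rates)$fractions[["CaM_4"]],
                 numeric(1))
  expect_true(all(diff(cam4) >= 0))
})

test_that("calmodulin site bookkeeping conserves total calcium", {
  m <- buildCalmodulinModel(caTotal = 8e-6, nSteps = 400L, logInterval = 50L)
  r <- runSimulation(m, seed = 11L)
  cn <- r@counts
  bound <- as.vector(as.matrix(cn[, sprintf("CaM_%d", 0:4)]) %*% (0:4))
  total <- bound + cn$Ca
  expect_lt(max(abs(total - total[1])) / total[1], 1e-9)
  # class fractions always sum to the molecule count
  expect_true(all(rowSums(cn[, sprintf("CaM_%d", 0:4)]) == cn$CaM))
})

test_that("the quintile model builds correctly for every layout", {
  for (ly in c("center", "original", "split")) {
    m <- buildMicrodomainModel(ly)
    expect_true(isValidModel(m))
    expect_equal(compartmentNames(m), sprintf("Q%d", 1:5))
    src <- m@sources[[1]]
    expect_equal(nrow(src@voxels), 4L)
    expect_true(all(src@voxels[, "i"] == 0L))
    expect_equal(src@mode, "clamp")
    expect_equal(src@value, 1e-3)
    lat <- buildLattice(m)
    expect_equal(sum(lat@compartmentOf == 1L), 200L)
  }
  # zero source: no calcium, no binding
  m0 <- buildMicrodomainModel("center", sourceConc = 0, nSteps = 200L,
                              logInterval = 100L)
  r0 <- runSimulation(m0, seed = 1L)
  expect_true(all(r0@counts$Ca == 0))
  expect_true(all(r0@counts$CaM_0 == r0@counts$CaM[1]))
})

test_that("the resting-cell receptor model produces no monomers", {
  m <- buildCeacamModel(raft = TRUE, nCam = 0L, nLck = 0L)
  r <- runSimulation(m, nSteps = 2000L, seed = 17L, logInterval = 400L)
  expect_true(all(r@counts$CEACAM1_monomer == 0))
  expect_true(all(r@counts[["CEACAM1_monomer:immobilized"]] == 0))
  expect_true(all(r@counts$CEACAM1_dimer == 50))
})

test_that("receptor stoichiometry 2*dimer + monomer is invariant", {
  m <- buildCeacamModel(raft = FALSE)
  r <- runSimulation(m, nSteps = 3000L, seed = 19L, logInterval = 300L)
  tot <- 2 * r@counts$CEACAM1_dimer + r@counts$CEACAM1_monomer
  expect_true(all(tot == 100))
})

test_that("summaries report concentrations, fractions and the clustered count", {
  m <- buildCeacamModel(raft = TRUE, nSteps = 1200L, logInterval = 200L)
  r <- runSimulation(m, seed = 23L, particleLog = TRUE)
  s <- summarizeResult(r)
  expect_true(all(c("series", "averages", "window") %in% names(s)))
  # clustered count equals immobilized monomers in the particle log
  pl <- particleLog(r)
  lastStep <- max(pl$step)
  fromLog <- sum(pl$immobilized[pl$step == lastStep &
                                pl$species == "CEACAM1_monomer"])
  fromCounts <- tail(r@counts[["CEACAM1_monomer:immobilized"]], 1)
  expect_identical(as.integer(fromCounts), as.integer(fromLog))

  mq <- buildMicrodomainModel("center", nSteps = 300L, logInterval = 100L)
  rq <- runSimulation(mq, seed = 2L)
  sq <- summarizeResult(rq, from = 0, to = 1)
  ca <- sq$averages[sq$averages$column == "Ca", ]
  expect_equal(nrow(ca), 5L)
  expect_true(all(is.finite(ca$concentration)))
  # uniform field: per-compartment concentration equals the global one
  mu <- buildMicrodomainModel("center", sourceConc = 0, nSteps = 10L)
  stU <- initSimState(mu)
  ru <- runSimulation(mu, nSteps = 0L, seed = 1L)
  cc <- ru@compartmentCounts
  vol <- 200 * voxelVolumeL(0.08) * 6.02214076e23
  concs <- cc[1, , "Ca"] / vol
  expect_true(all(abs(concs - concs[1]) < 1e-15))
  expect_error(summarizeResult(runSimulation(tinyModel(), seed = 1L)),
               "perCompartment")
})
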