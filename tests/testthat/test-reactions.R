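test_that("binding radius recovers both analytic limits", {
  kconv <- 1e15 / 6.02214076e23           # M^-1 s^-1 -> um^3/s
  # dt -> 0: Smoluchowski, sigma = k / (4 pi D)
  k <- 1e9; D <- 1; dt <- 1e-9
  sig <- bindingRadius(k, D, dt)
  expect_lt(abs(sig / (k * kconv / (4 * pi * D)) - 1), 0.02)
  # large dt: well-mixed volume, sigma = (3 k dt / 4 pi)^(1/3)
  k <- 1e9; D <- 100; dt <- 1
  sig <- bindingRadius(k, D, dt)
  expect_lt(abs(sig / ((3 * k * kconv * dt / (4 * pi))^(1 / 3)) - 1), 0.02)
})

test_that("binding radius is monotone in k and errors when not collision-limited", {
  sig <- vapply(c(1e7, 1e8, 1e9), bindingRadius, numeric(1), Dsum = 10, dt = 1e-6)
  expect_true(all(diff(sig) > 0))
  expect_error(bindingRadius(1e9, 0, 1e-6), "activation-limited")
  expect_error(bindingRadius(1e9, 10, 1e-6, maxRadius = 1e-4), "activation-limited")
})

test_that("binding radius reproduces the requested rate in the intermediate regime", {
  # independent brute-force oracle: many independent A-B pairs in a periodic
  # box; relative coordinate diffuses; absorb at sigma and reinsert uniformly
  k <- 1e9; D1 <- 10; D2 <- 10; dt <- 1e-6
  sig <- bindingRadius(k, D1 + D2, dt)
  s <- sqrt(2 * (D1 + D2) * dt)
  expect_gt(s / sig, 0.1); expect_lt(s / sig, 2)  # genuinely intermediate

  L <- 0.2
  M <- 20000L
  set.seed(101)
  rel <- matrix(runif(3 * M, -L / 2, L / 2), M, 3)
  hits <- 0L; steps <- 0L
  for (it in 1:3500) {
    rel <- rel + matrix(rnorm(3 * M, sd = s), M, 3)
    rel <- (rel + L / 2) %% L - L / 2
    d2 <- rowSums(rel^2)
    ab <- d2 <= sig^2
    if (it > 500) { hits <- hits + sum(ab); steps <- steps + 1L }
    if (any(ab)) rel[ab, ] <- matrix(runif(3 * sum(ab), -L / 2, L / 2), sum(ab), 3)
  }
  kBox <- (hits / steps / M) * L^3 / dt          # um^3/s, one sink per cell
  # periodic-image correction for a simple-cubic array of sinks at mean
  # density normalization (Hasimoto lattice constant 2.837297)
  kEff <- kBox / (1 + 2.837297 * kBox / (4 * pi * (D1 + D2) * L))
  kEffM <- kEff * 6.02214076e23 / 1e15           # back to M^-1 s^-1
  expect_lt(abs(kEffM / k - 1), 0.05)
})

test_that("unimolecular conversion follows the exponential decay law", {
  # k = 0: nothing happens
  m <- tinyModel(n = 3L, dt = 1e-3)
  m@reactions <- list(newReaction("conv", rxPattern("P"), rxPattern("B"), k = 0))
  m@initials <- data.frame(species = "P", amount = "count", value = 100,
                           compartment = "main")
  r <- runSimulation(m, nSteps = 20L, seed = 1L)
  expect_true(all(r@counts$P == 100))

  # exponential survival within 3 binomial s.e. at every logged time
  kdt <- 0.01; dt <- 1e-3; k <- kdt / dt
  env <- newEnvironment(3, 3, 3, voxelLen = 0.2, timestep = dt, nSteps = 500L)
  comp <- list(newCompartment("main", boxes = c(0, 3, 0, 3, 0, 3)))
  species <- list(newSpecies("A", "particle", D = 0, allowed = "main"),
                  newSpecies("Prod", "particle", D = 0, allowed = "main"))
  mD <- newSimModel(env, comp, species,
    reactions = list(newReaction("decay", rxPattern("A"), rxPattern("Prod"), k = k)),
    initials = data.frame(species = "A", amount = "count", value = 1e4,
                          compartment = "main"),
    logInterval = 50L)
  r <- runSimulation(mD, seed = 5L)
  n0 <- 1e4
  for (i in seq_len(nrow(r@counts))) {
    tm <- r@counts$time_s[i]
    pSurv <- exp(-k * tm)
    se <- sqrt(n0 * pSurv * (1 - pSurv))
    expect_lt(abs(r@counts$A[i] - n0 * pSurv), 3 * se + 1e-9,
              label = sprintf("t=%g", tm))
  }
  # total count conserved
  expect_true(all(r@counts$A + r@counts$Prod == 1e4))
})

test_that("bulk unimolecular conversion is the exact deterministic fraction", {
  dt <- 1e-3
  k <- -log(0.9) / dt                      # 1 - exp(-k dt) = 0.1 exactly
  env <- newEnvironment(2, 2, 2, voxelLen = 0.2, timestep = dt, nSteps = 1L)
  comp <- list(newCompartment("main", boxes = c(0, 2, 0, 2, 0, 2)))
  species <- list(newSpecies("A", "bulk", D = 0, allowed = "main"),
                  newSpecies("Bp", "bulk", D = 0, allowed = "main"))
  m <- newSimModel(env, comp, species,
    reactions = list(newReaction("conv", rxPattern("A"), rxPattern("Bp"), k = k)),
    initials = data.frame(species = "A", amount = "count", value = 100,
                          compartment = "main"))
  r <- runSimulation(m, seed = 1L)
  expect_equal(tail(r@counts$A, 1), 90)
  expect_equal(tail(r@counts$Bp, 1), 10)
  expect_equal(tail(r@counts$A + r@counts$Bp, 1), 100)
})

test_that("bimolecular particle pairs react within the binding radius", {
  env <- newEnvironment(5, 5, 5, voxelLen = 0.2, timestep = 1e-6, nSteps = 1L)
  comp <- list(newCompartment("main", boxes = c(0, 5, 0, 5, 0, 5)))
  species <- list(newSpecies("A", "particle", D = 1, allowed = "main"),
                  newSpecies("Bb", "particle", D = 1, allowed = "main"),
                  newSpecies("C", "particle", D = 1, allowed = "main"))
  rule <- newReaction("bind", list(rxPattern("A"), rxPattern("Bb")),
                      rxPattern("C"), k = 1e9)
  m <- newSimModel(env, comp, species,
                   initials = data.frame(species = character(), amount = character(),
                                         value = numeric(), compartment = character()))
  m@reactions <- list(rule)
  st <- initSimState(m)
  sig <- 0.01
  addAt <- function(st, spIdx, p) {
    st$particles <- vox4d:::.addParticles(st$particles, spIdx, matrix(p, 1, 3),
                                          lin = vox4d:::.linOfPos(matrix(p, 1, 3), st$lattice))
    st
  }
  # no pair within sigma: nothing happens
  st1 <- addAt(addAt(st, 1L, c(0.1, 0.1, 0.1)), 2L, c(0.9, 0.9, 0.9))
  out1 <- bimolecularParticleStep(st1, rule, sigma = sig, dt = 1e-6)
  expect_identical(out1$particles$species, st1$particles$species)

  # A at origin-ish, B at 0.9 sigma along z: exactly one C at the midpoint
  a <- c(0.5, 0.5, 0.5); b <- a + c(0, 0, 0.9 * sig)
  st2 <- addAt(addAt(st, 1L, a), 2L, b)
  out2 <- bimolecularParticleStep(st2, rule, sigma = sig, dt = 1e-6)
  expect_equal(sum(out2$particles$species == 3L), 1L)
  expect_equal(sum(out2$particles$species %in% 1:2), 0L)
  expect_equal(out2$particles$pos[1, ], (a + b) / 2, ignore_attr = TRUE)

  # each particle reacts at most once per step: one A among two close Bs
  st3 <- addAt(addAt(addAt(st, 1L, a), 2L, a + c(0, 0, 0.5 * sig)),
               2L, a - c(0, 0, 0.6 * sig))
  out3 <- bimolecularParticleStep(st3, rule, sigma = sig, dt = 1e-6)
  expect_equal(sum(out3$particles$species == 3L), 1L)
  expect_equal(sum(out3$particles$species == 2L), 1L)
  # greedy nearest-first: the closer B (at 0.5 sigma) was consumed
  expect_equal(out3$particles$pos[out3$particles$species == 3L, 3],
               0.5 + 0.25 * sig)
})

test_that("bulk-particle firing follows the local-concentration Bernoulli law", {
  dt <- 1e-4
  env <- newEnvironment(3, 3, 3, voxelLen = 0.2, timestep = dt, nSteps = 1L)
  comp <- list(newCompartment("main", boxes = c(0, 3, 0, 3, 0, 3)))
  species <- list(newSpecies("S", "bulk", D = 0, allowed = "main"),
                  newSpecies("E", "particle", D = 0, allowed = "main",
                             states = "hit"))
  rule <- newReaction("fire", list(rxPattern("S"), rxPattern("E", states = c(hit = FALSE))),
                      rxPattern("E", states = c(hit = TRUE)), k = 1e8)
  conc <- 5e-5
  m <- newSimModel(env, comp, species, reactions = list(rule),
    initials = data.frame(species = c("S", "E"), amount = c("concentration", "count"),
                          value = c(conc, 1e4), compartment = "main"))
  r <- runSimulation(m, seed = 9L)
  p <- 1 - exp(-1e8 * conc * dt)
  fired <- tail(r@counts[["E:hit"]], 1)
  se <- sqrt(1e4 * p * (1 - p))
  expect_lt(abs(fired - 1e4 * p), 3 * se)
  # zero concentration: no firing
  m0 <- m
  m0@initials$value[1] <- 0
  r0 <- runSimulation(m0, seed = 9L)
  expect_equal(tail(r0@counts[["E:hit"]], 1), 0)
})

test_that("bulk-particle accuracy improves with bulk diffusion", {
  # enzyme particles deplete substrate locally; faster substrate diffusion
  # erases the depletion error against the well-mixed ODE
  errFor <- function(D) {
    dt <- 5e-6; nSteps <- 400L
    env <- newEnvironment(5, 5, 5, voxelLen = 0.1, timestep = dt, nSteps = nSteps)
    comp <- list(newCompartment("main", boxes = c(0, 5, 0, 5, 0, 5)))
    species <- list(newSpecies("S", "bulk", D = D, allowed = "main"),
                    newSpecies("E", "particle", D = 0.05, allowed = "main"))
    rule <- newReaction("consume", list(rxPattern("S"), rxPattern("E")),
                        rxPattern("E"), k = 6e7)
    m <- newSimModel(env, comp, species, reactions = list(rule),
      initials = data.frame(species = c("S", "E"), amount = "count",
                            value = c(5000, 200), compartment = "main"),
      logInterval = nSteps)
    r <- runSimulation(m, seed = 33L)
    V <- 125 * voxelVolumeL(0.1)
    cE <- 200 / (V * 6.02214076e23)
    expected <- 5000 * exp(-6e7 * cE * dt * nSteps)
    abs(tail(r@counts$S, 1) - expected) / expected
  }
  eLow <- errFor(2); eHigh <- errFor(200)
  expect_lt(eHigh, eLow)
})

test_that("bulk-bulk mass action matches the well-mixed ODE and never goes negative", {
  dt <- 1e-5; nSteps <- 1000L
  env <- newEnvironment(3, 3, 3, voxelLen = 0.2, timestep = dt, nSteps = nSteps)
  comp <- list(newCompartment("main", boxes = c(0, 3, 0, 3, 0, 3)))
  species <- list(newSpecies("A", "bulk", D = 0, allowed = "main"),
                  newSpecies("Bk", "bulk", D = 0, allowed = "main"),
                  newSpecies("C", "bulk", D = 0, allowed = "main"))
  k <- 1e8
  rule <- newReaction("r", list(rxPattern("A"), rxPattern("Bk")), rxPattern("C"), k = k)
  cA <- 2e-6; cB <- 1e-6
  m <- newSimModel(env, comp, species, reactions = list(rule),
    initials = data.frame(species = c("A", "Bk"), amount = "concentration",
                          value = c(cA, cB), compartment = "main"),
    logInterval = nSteps)
  r <- runSimulation(m, seed = 1L)
  # second-order closed form with unequal initial amounts
  tEnd <- dt * nSteps
  d <- cA - cB
  cAend <- d / (1 - (cB / cA) * exp(-k * d * tEnd))
  V <- 27 * voxelVolumeL(0.2) * 6.02214076e23
  expect_lt(abs(tail(r@counts$A, 1) / V - cAend) / cAend, 0.01)
  # zero field: no change
  m0 <- m; m0@initials <- m0@initials[1, , drop = FALSE]
  r0 <- runSimulation(m0, nSteps = 10L, seed = 1L)
  expect_equal(tail(r0@counts$A, 1), r0@counts$A[1])
  # cap: amounts never negative even at absurd k
  mBig <- m; mBig@reactions[[1]]@k <- 1e15
  rBig <- runSimulation(mBig, nSteps = 5L, seed = 1L)
  expect_true(all(rBig@counts$A >= 0 & rBig@counts$Bk >= 0))
})

test_that("state-change rules preserve identity, position and catalysts", {
  m <- buildCeacamModel(raft = FALSE, nCam = 5L, nLck = 5L, nSteps = 10L)
  st <- initSimState(m)
  rule <- m@reactions[[which(vapply(m@reactions, slot, character(1), name = "id")
                             == "phosphorylation")]]
  mono <- vox4d:::.compilePattern(rxPattern("CEACAM1_monomer"), st$species)
  # inject a monomer and remember an Lck
  pos <- matrix(c(0.1, 0.5, 0.5), 1, 3)
  st$particles <- vox4d:::.addParticles(st$particles, mono$speciesIdx, pos,
                                        lin = vox4d:::.linOfPos(pos, st$lattice))
  row <- length(st$particles$id)
  id0 <- st$particles$id[row]
  nLck <- sum(st$particles$species == 3L)
  st2 <- applyStateChange(st, row, rule)
  expect_true(st2$particles$flags[row, 1])
  expect_identical(st2$particles$id[row], id0)
  expect_identical(st2$particles$pos[row, ], st$particles$pos[row, ])
  expect_identical(sum(st2$particles$species == 3L), nLck)

  # identity rule: nothing changes
  idRule <- newReaction("noop", rxPattern("CEACAM1_monomer"),
                        rxPattern("CEACAM1_monomer"), k = 1)
  st3 <- applyStateChange(st, row, idRule)
  expect_identical(st3$particles$flags, st$particles$flags)
  expect_error(applyStateChange(st, row,
    newReaction("bad", rxPattern("CEACAM1_monomer"),
                rxPattern("CEACAM1_monomer", states = c(ghost = TRUE)), k = 1)))
})

test_that("calcium binding flips exactly one declared site per firing", {
  m <- buildCalmodulinModel(caTotal = 8e-6, nSteps = 50L, logInterval = 1L)
  r <- runSimulation(m, seed = 2L)
  cn <- r@counts
  # per logged step, total site flips equal net binding events; occupancy
  # classes only move by single-site transitions, so bound-count totals
  # change by the event balance exactly
  bound <- as.vector(as.matrix(cn[, sprintf("CaM_%d", 0:4)]) %*% (0:4))
  free <- cn$Ca
  expect_equal(bound + free, rep(bound[1] + free[1], nrow(cn)), tolerance = 1e-9)
})

test_that("catalysts are never consumed by bimolecular firings", {
  m <- buildCeacamModel(raft = TRUE, nCam = 10L)
  r <- runSimulation(m, nSteps = 3000L, seed = 4L, logInterval = 500L)
  expect_true(all(r@counts$CaM_active == 10L))
  expect_true(all(r@counts$Lck == 20L))
})

test_that("reaction stoichiometry is conserved per rule", {
  m <- buildCeacamModel(raft = TRUE)
  r <- runSimulation(m, nSteps = 4000L, seed = 6L, logInterval = 500L)
  # 2 * dimers + monomers (all states, incl. immobilized) is invariant
  tot <- 2 * r@counts$CEACAM1_dimer + r@counts$CEACAM1_monomer
  expect_true(all(tot == tot[1]))
})
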