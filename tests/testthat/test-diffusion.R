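test_that("bulk diffusion leaves uniform and immobile fields unchanged", {
  m <- tinyModel(n = 4L)
  lat <- buildLattice(m)
  sp <- m@species[[1]]
  f <- array(7.5, dim = c(4, 4, 4))
  expect_equal(bulkDiffusionStep(f, D = 5, dt = 1e-6, lat, sp), f)
  f2 <- array(runif(64), dim = c(4, 4, 4))
  expect_equal(bulkDiffusionStep(f2, D = 0, dt = 1e-6, lat, sp), f2)
  expect_error(bulkDiffusionStep(f2, D = 1e5, dt = 1e-3, lat, sp), "'B'")
})

test_that("flux goes only to accessible neighbors and conserves mass", {
  # 3x3x3; only the center voxel and its +x, +y, +z neighbors are open
  env <- newEnvironment(3, 3, 3, voxelLen = 0.2, timestep = 1e-6, nSteps = 1L)
  open <- rbind(c(1, 1, 1), c(2, 1, 1), c(1, 2, 1), c(1, 1, 2))
  comp <- list(newCompartment("blocked", boxes = c(0, 3, 0, 3, 0, 3)),
               newCompartment("open", voxels = open, parent = "blocked"))
  sp <- newSpecies("B", "bulk", D = 5, allowed = "open")
  m <- newSimModel(env, comp, list(sp),
                   initials = data.frame(species = character(), amount = character(),
                                         value = numeric(), compartment = character()))
  lat <- buildLattice(m)
  f <- array(0, dim = c(3, 3, 3))
  f[2, 2, 2] <- 100
  f[3, 2, 2] <- 5; f[2, 3, 2] <- 5; f[2, 2, 3] <- 5
  f2 <- bulkDiffusionStep(f, D = 5, dt = 1e-6, lat, sp)
  expect_lt(f2[2, 2, 2], 100)
  expect_gt(f2[3, 2, 2], 5)
  expect_gt(f2[2, 3, 2], 5)
  expect_gt(f2[2, 2, 3], 5)
  expect_equal(sum(f2), 115)
  # blocked voxels receive nothing
  expect_equal(f2[1, 2, 2], 0)
  expect_equal(sum(f2 != 0), 4L)
})

test_that("bulk diffusion matches an independent finite-difference oracle", {
  n <- 11L
  m <- tinyModel(n = n, h = 0.1, dt = 1e-6, D = 100)
  lat <- buildLattice(m)
  sp <- m@species[[1]]
  f <- array(0, dim = c(n, n, n)); f[6, 6, 6] <- 1000
  alpha <- 100 * 1e-6 / 0.1^2

  # plain-loop forward-Euler oracle, written independently of the package path
  oracle <- f
  for (s in 1:50) {
    nxt <- oracle
    for (i in 1:n) for (j in 1:n) for (k in 1:n) {
      acc <- 0
      for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
        ii <- i + d[1]; jj <- j + d[2]; kk <- k + d[3]
        if (ii >= 1 && ii <= n && jj >= 1 && jj <= n && kk >= 1 && kk <= n)
          acc <- acc + (oracle[ii, jj, kk] - oracle[i, j, k])
      }
      nxt[i, j, k] <- oracle[i, j, k] + alpha * acc
    }
    oracle <- nxt
  }
  sim <- f
  for (s in 1:50) sim <- bulkDiffusionStep(sim, 100, 1e-6, lat, sp)
  expect_lt(max(abs(sim - oracle)) / max(oracle), 1e-10)
  expect_lt(abs(sum(sim) - 1000) / 1000, 1e-12)
  expect_true(all(sim >= 0))
})

test_that("bulk point spread matches the continuous Gaussian solution", {
  n <- 15L; h <- 0.1; D <- 50; dt <- 2e-5   # alpha = 0.1; final sigma = 2.5 h
  m <- tinyModel(n = n, h = h, dt = dt, D = D)
  lat <- buildLattice(m)
  sp <- m@species[[1]]
  f <- array(0, dim = c(n, n, n)); f[8, 8, 8] <- 1
  nSteps <- 31L
  for (s in seq_len(nSteps)) f <- bulkDiffusionStep(f, D, dt, lat, sp)
  sg <- sqrt(2 * D * dt * nSteps)
  edges <- (0:n) * h - 7.5 * h   # voxel edges centered on the source voxel
  p1 <- diff(pnorm(edges, 0, sg))
  gauss <- outer(outer(p1, p1), p1)
  rmsd <- sqrt(sum((f - gauss)^2) / sum(gauss^2))
  expect_lt(rmsd, 0.03)
})

test_that("particle MSD matches 6 D dt and the mean displacement is zero", {
  m <- tinyModel(n = 5L, h = 10, dt = 1e-3, D = 1)  # huge voxels: no reflection
  lat <- buildLattice(m)
  sp <- m@species[[2]]
  n <- 1e5
  set.seed(7)
  pos <- matrix(25, n, 3)
  new <- particleStep(pos, sp, D = 1, dt = 1e-3, lat)
  d <- new - pos
  msd <- mean(rowSums(d^2))
  expect_lt(abs(msd / (6 * 1 * 1e-3) - 1), 0.02)
  se <- sqrt(2 * 1 * 1e-3 / n)
  expect_lt(max(abs(colMeans(d))), 3 * se)

  expect_equal(particleStep(pos[1:5, ], sp, D = 0, dt = 1e-3, lat), pos[1:5, ])
})

test_that("membrane-bound particles keep the frozen axis over many steps", {
  m <- membraneModel(n = 6L)
  lat <- buildLattice(m)
  sp <- m@species[[1]]
  p <- matrix(c(0.65, 0.65, 1.15), 1, 3)  # voxel (3,3,5): frozen axis z
  z0 <- p[1, 3]
  set.seed(11)
  for (s in 1:1000) p <- matrix(particleStep(p[1, ], sp, D = 0.01, dt = 5e-5, lat), 1, 3)
  expect_identical(p[1, 3], z0)
  expect_true(p[1, 1] != 0.65 || p[1, 2] != 0.65)  # it did move laterally
})

test_that("reflection is specular and keeps particles in legal voxels", {
  m <- tinyModel(n = 5L, h = 0.2)
  lat <- buildLattice(m)
  sp <- m@species[[2]]
  inside <- c(0.5, 0.5, 0.5)
  expect_equal(reflectPosition(inside, c(0.55, 0.52, 0.48), sp, lat),
               c(0.55, 0.52, 0.48))
  expect_equal(reflectPosition(c(0.01, 0.5, 0.5), c(-0.03, 0.5, 0.5), sp, lat),
               c(0.03, 0.5, 0.5))
  expect_equal(reflectPosition(c(0.99, 0.5, 0.5), c(1.02, 0.5, 0.5), sp, lat),
               c(0.98, 0.5, 0.5))

  # restricted compartment: particle never ends in a disallowed voxel
  mr <- restrictedModel()
  latR <- buildLattice(mr)
  spP <- mr@species[[2]]
  set.seed(3)
  old <- matrix(rep(c(0.39, 0.5, 0.5), 500), ncol = 3, byrow = TRUE)  # next to inner
  prop <- old + matrix(rnorm(1500, sd = 0.15), ncol = 3)
  out <- reflectPosition(old, prop, spP, latR)
  expect_true(all(isAccessible(spP, voxelOf(out, latR), latR)))
})

test_that("long-run positions in a closed box are uniform per octant", {
  m <- tinyModel(n = 5L, h = 0.2, dt = 1e-3, D = 5)
  lat <- buildLattice(m)
  sp <- m@species[[2]]
  set.seed(19)
  n <- 5e4
  pos <- matrix(runif(3 * n), n, 3)
  samples <- matrix(numeric(), 0, 3)
  # rms step 0.1 um (half a voxel): 25 steps walk ~0.5 um, decorrelating
  # positions between blocks on the 1 um box
  for (block in 1:6) {
    for (s in 1:25) pos <- particleStep(pos, sp, D = 5, dt = 1e-3, lat)
    samples <- rbind(samples, pos)
  }
  oct <- 1 + (samples[, 1] >= 0.5) + 2 * (samples[, 2] >= 0.5) +
         4 * (samples[, 3] >= 0.5)
  frac <- tabulate(oct, 8) / nrow(samples)
  expect_true(all(abs(frac - 1 / 8) / (1 / 8) < 0.02))
  chi <- sum((tabulate(oct, 8) - nrow(samples) / 8)^2 / (nrow(samples) / 8))
  expect_gt(pchisq(chi, df = 7, lower.tail = FALSE), 1e-4)
})

test_that("bulk and particle representations spread consistently", {
  # matched point sources, compared on slab (quintile) occupancy
  n <- 10L; h <- 0.1; D <- 5; dt <- 1e-4
  m <- tinyModel(n = n, h = h, dt = dt, D = D)
  lat <- buildLattice(m)
  spB <- m@species[[1]]; spP <- m@species[[2]]
  f <- array(0, dim = c(n, n, n)); f[5, 5, 5] <- 1
  nSteps <- 8L
  for (s in seq_len(nSteps)) f <- bulkDiffusionStep(f, D, dt, lat, spB)
  set.seed(23)
  np <- 1e4
  pos <- matrix(rep(c(0.45, 0.45, 0.45), np), ncol = 3, byrow = TRUE)
  for (s in seq_len(nSteps)) pos <- particleStep(pos, spP, D, dt, lat)
  slabB <- sapply(1:5, function(q) sum(f[(2 * q - 1):(2 * q), , ]))
  ix <- findInterval(pos[, 1], (0:5) * 0.2, rightmost.closed = TRUE)
  slabP <- tabulate(ix, 5) / np
  expect_true(all(abs(slabB - slabP) < 0.05))
  # also in relative terms on the well-populated slabs
  big <- slabB > 0.05
  expect_true(all(abs(slabB[big] - slabP[big]) / slabB[big] < 0.25))
})

test_that("random bulk steps conserve mass exactly under restriction", {
  m <- restrictedModel()
  lat <- buildLattice(m)
  sp <- m@species[[1]]
  set.seed(5)
  for (rep in 1:20) {
    f <- array(runif(125, 0, 100), dim = c(5, 5, 5))
    f2 <- bulkDiffusionStep(f, D = 5, dt = 1e-6, lat, sp)
    expect_lt(abs(sum(f2) - sum(f)) / sum(f), 1e-12)
    expect_true(all(f2 >= 0))
  }
})
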