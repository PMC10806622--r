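# Partial RDF estimator, coordination numbers, ion pairing, orientation
# profiles and system molality.

test_that("histogram RDF equals the naive O(N^2) double loop exactly", {
  spec <- fixtureSpec("ideal_gas", n = 100, box = 14, seed = 21)
  traj <- generateFixture(spec, nFrames = 2)
  # split one class into two halves so alpha != beta paths are exercised
  lab <- atomLabels(traj)
  lab[1:50] <- "A"; lab[51:100] <- "B"
  traj2 <- trajectory(list(frameCoords(traj, 1), frameCoords(traj, 2)),
                      lab, moleculeIndex(traj), boxLengths(traj))
  fast <- computePartialRDF(traj2, "A", "B", rMax = 6, nBins = 60)
  expect_equal(gValues(fast), naiveRDF(traj2, "A", "B", 6, 60),
               tolerance = 1e-12)
  fastSame <- computePartialRDF(traj2, "A", "A", rMax = 6, nBins = 60)
  expect_equal(gValues(fastSame), naiveRDF(traj2, "A", "A", 6, 60),
               tolerance = 1e-12)
})

test_that("ideal-gas fixture is flat at g = 1 within 3 sigma counting noise", {
  spec <- fixtureSpec("ideal_gas", n = 800, box = 24, seed = 22)
  traj <- generateFixture(spec, nFrames = 8)
  nBins <- 48
  rdf <- computePartialRDF(traj, "X", "X", rMax = 9.6, nBins = nBins)
  breaks <- seq(0, 9.6, length.out = nBins + 1)
  shell <- 4 / 3 * pi * diff(breaks^3)
  # flatness band: exact Poisson on the unordered pair counts (the normal
  # "3 sigma" approximation is invalid in the few-count inner bins), with a
  # Bonferroni correction so the whole profile is tested at the 3-sigma
  # family level; the same-class estimator has mean (N-1)/N
  norm <- shell * partnerDensity(rdf) * 800 * 8
  m <- gValues(rdf) * norm / 2
  expect_equal(m, round(m), tolerance = 1e-6)
  lam <- norm * (799 / 800) / 2
  alpha <- 0.0027 / nBins
  expect_true(all(m >= qpois(alpha / 2, lam) & m <= qpois(1 - alpha / 2, lam)))
})

test_that("two atoms at a known separation fill a single bin", {
  traj <- trajectory(rbind(c(10, 10, 10), c(13.7, 10, 10)), c("A", "B"),
                     molecule = c(1L, 2L), box = 40)
  rdf <- computePartialRDF(traj, "A", "B", rMax = 8, nBins = 80)
  hit <- which(gValues(rdf) > 0)
  expect_length(hit, 1L)
  expect_lt(abs(rGrid(rdf)[hit] - 3.7), 0.1 / 2 + 1e-9)
  # same-molecule pairs are excluded from interspecies RDFs
  intra <- trajectory(rbind(c(10, 10, 10), c(13.7, 10, 10)), c("A", "B"),
                      molecule = c(1L, 1L), box = 40)
  expect_true(all(gValues(computePartialRDF(intra, "A", "B", 8, 80)) == 0))
})

test_that("Gaussian-shell fixture peaks at the planted radius", {
  spec <- fixtureSpec("gaussian_shell", nCenters = 40, nShell = 12, r0 = 6,
                      sigma = 0.3, box = 40, seed = 23)
  traj <- generateFixture(spec, nFrames = 10)
  rdf <- computePartialRDF(traj, "CEN", "SHL", rMax = 10, nBins = 100)
  expect_lt(abs(rGrid(rdf)[which.max(gValues(rdf))] - 6), 0.1 + 1e-9)
})

test_that("empirical shell RDF matches the analytic model within 3 sigma", {
  spec <- fixtureSpec("gaussian_shell", nCenters = 40, nShell = 12, r0 = 6,
                      sigma = 0.3, box = 40, seed = 24)
  traj <- generateFixture(spec, nFrames = 30)
  nBins <- 50
  rdf <- computePartialRDF(traj, "CEN", "SHL", rMax = 10, nBins = nBins)
  model <- analyticRdf(k = 12, r0 = 6, sigma = 0.3, rho = partnerDensity(rdf),
                       r = rGrid(rdf))
  breaks <- seq(0, 10, length.out = nBins + 1)
  E <- pmax(4 / 3 * pi * diff(breaks^3) * partnerDensity(rdf) * 40 * 30 *
              gValues(model), 1e-12)
  z <- (gValues(rdf) - gValues(model)) * sqrt(E) / gValues(model)
  expect_lt(max(abs(z[rGrid(rdf) > 1])), 3)
})

test_that("all statistics are invariant under lattice translations", {
  spec <- fixtureSpec("gaussian_shell", nCenters = 10, nShell = 6, box = 30,
                      seed = 25)
  traj <- generateFixture(spec, nFrames = 2)
  shift <- boxLengths(traj) * c(1, -2, 3)
  moved <- trajectory(lapply(1:2, function(f)
    sweep(frameCoords(traj, f), 2, shift, `+`)),
    atomLabels(traj), moleculeIndex(traj), boxLengths(traj))
  g0 <- gValues(computePartialRDF(traj, "CEN", "SHL", 10, 100))
  g1 <- gValues(computePartialRDF(moved, "CEN", "SHL", 10, 100))
  expect_equal(g0, g1, tolerance = 1e-12)
  expect_equal(ionPairCensus(traj, "CEN", "SHL", 4, 7),
               ionPairCensus(moved, "CEN", "SHL", 4, 7), tolerance = 1e-12)
})

test_that("rMax beyond the minimum-image bound and empty classes error", {
  traj <- generateFixture(fixtureSpec("ideal_gas", n = 50, box = 10, seed = 1))
  expect_error(computePartialRDF(traj, "X", "X", rMax = 6), "minimum-image")
  expect_error(computePartialRDF(traj, "X", "Y", rMax = 4), "no atoms")
})

test_that("coordination number integrates g to quadrature accuracy", {
  # closed form: g == 1 -> (4/3) pi R^3 rho
  flat <- analyticRdf(k = 0, rho = 0.02, r = seq(0.01, 10, by = 0.01))
  expect_equal(coordinationNumber(flat, 8), 4 / 3 * pi * 8^3 * 0.02,
               tolerance = 1e-3)
  # Gaussian shell with k neighbors: integrating past the shell recovers k
  shell <- analyticRdf(k = 7, r0 = 6, sigma = 0.3, rho = 0.02,
                       r = seq(0.01, 10, by = 0.01))
  expect_equal(coordinationNumber(shell, 9) - coordinationNumber(flat, 9), 7,
               tolerance = 0.01)
  # below the first shell the excess is zero
  expect_equal(coordinationNumber(shell, 3), coordinationNumber(flat, 3),
               tolerance = 1e-6)
  expect_error(coordinationNumber(shell, 12.5), "r-grid")
})

test_that("ion-pair census separates contact from solvent-shared shells", {
  # one anion planted at 4 A of each cation center
  centers <- rbind(c(10, 10, 10), c(30, 30, 30))
  anions4 <- centers + matrix(rep(c(4, 0, 0), 2), 2, byrow = TRUE)
  traj4 <- trajectory(rbind(centers, anions4), c("N", "N", "Cl", "Cl"),
                      molecule = 1:4, box = 40)
  expect_equal(ionPairCensus(traj4, "N", "Cl", 5.5, 8),
               c(contact = 1, solventShared = 0))
  anions7 <- centers + matrix(rep(c(0, 7, 0), 2), 2, byrow = TRUE)
  traj7 <- trajectory(rbind(centers, anions7), c("N", "N", "Cl", "Cl"),
                      molecule = 1:4, box = 40)
  expect_equal(ionPairCensus(traj7, "N", "Cl", 5.5, 8),
               c(contact = 0, solventShared = 1))
  expect_error(ionPairCensus(traj7, "N", "Cl", 8, 5.5), "contactCut")
  expect_error(ionPairCensus(traj7, "N", "Cl", 5.5, 30), "half")
})

test_that("random anion placement matches the sphere-volume expectation", {
  set.seed(26)
  nA <- 4000
  box <- 40
  X <- rbind(c(20, 20, 20), matrix(runif(3 * nA) * box, ncol = 3))
  traj <- trajectory(X, c("N", rep("Cl", nA)), molecule = seq_len(nA + 1),
                     box = box)
  cens <- ionPairCensus(traj, "N", "Cl", 5.5, 8)
  rho <- nA / box^3
  expContact <- 4 / 3 * pi * 5.5^3 * rho
  expShared <- 4 / 3 * pi * (8^3 - 5.5^3) * rho
  expect_lt(abs(cens[["contact"]] - expContact), 3 * sqrt(expContact))
  expect_lt(abs(cens[["solventShared"]] - expShared), 3 * sqrt(expShared))
})

test_that("orientation profile resolves dipole and OH conventions", {
  box <- 60
  center <- c(30, 30, 30)
  set.seed(27)
  # 200 waters at random radii 3..8, dipoles pointing exactly at the center
  nW <- 200
  u <- matrix(rnorm(3 * nW), ncol = 3)
  u <- u / sqrt(rowSums(u * u))
  O <- sweep(u * runif(nW, 3, 8), 2, center, `+`)
  blocks <- lapply(seq_len(nW), function(i)
    waterAt(O[i, ], dipoleDir = center - O[i, ]))
  X <- rbind(center, do.call(rbind, blocks))
  traj <- trajectory(X, c("N", rep(c("O_W", "H_W", "H_W"), nW)),
                     molecule = c(1L, rep(2:(nW + 1L), each = 3)), box = box)
  prof <- orientationProfile(traj, "N", rBreaks = seq(2, 9, 1))
  expect_equal(prof$cosDipole[prof$n > 0], rep(-1, sum(prof$n > 0)),
               tolerance = 1e-9)
  # OH bonds then sit at half the water angle from the inward direction
  expect_equal(prof$cosOH[prof$n > 0],
               rep(-cos(104.52 / 2 * pi / 180), sum(prof$n > 0)),
               tolerance = 1e-9)
})

test_that("isotropically oriented waters average to zero orientation", {
  box <- 60
  center <- c(30, 30, 30)
  set.seed(28)
  nW <- 600
  u <- matrix(rnorm(3 * nW), ncol = 3)
  u <- u / sqrt(rowSums(u * u))
  O <- sweep(u * runif(nW, 3, 8), 2, center, `+`)
  blocks <- lapply(seq_len(nW), function(i)
    waterAt(O[i, ], dipoleDir = rnorm(3)))
  X <- rbind(center, do.call(rbind, blocks))
  traj <- trajectory(X, c("N", rep(c("O_W", "H_W", "H_W"), nW)),
                     molecule = c(1L, rep(2:(nW + 1L), each = 3)), box = box)
  prof <- orientationProfile(traj, "N", rBreaks = c(2, 9))
  # sd of cos(theta) for an isotropic vector is 1/sqrt(3)
  expect_lt(abs(prof$cosDipole[1]), 3 / sqrt(3 * prof$n[1]))
  expect_error(orientationProfile(
    trajectory(X[1:3, ], c("N", "O_W", "H_W"), c(1L, 2L, 2L), box), "N"),
    "2 hydrogens")
})

test_that("system molality follows the solute/water mole ratio", {
  expect_equal(molalityOfSystem(50, 1388), 2.0, tolerance = 0.005)
  expect_equal(molalityOfSystem(0, 500), 0)
  expect_equal(molalityOfSystem(100, 1388), 2 * molalityOfSystem(50, 1388),
               tolerance = 1e-12)
  expect_error(molalityOfSystem(50, 0), "nWater")
  expect_error(molalityOfSystem(-1, 100), "nSolute")
})

test_that("RDF TSV round trip preserves grid, values and metadata", {
  rdf <- analyticRdf(k = 5, rho = 0.01, r = seq(0.05, 10, by = 0.05))
  path <- tempfile(fileext = ".tsv")
  writeRDFTSV(rdf, path)
  back <- readRDFTSV(path)
  expect_equal(gValues(back), gValues(rdf), tolerance = 1e-10)
  expect_equal(partnerDensity(back), partnerDensity(rdf))
  expect_identical(pairLabels(back), pairLabels(rdf))
})
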