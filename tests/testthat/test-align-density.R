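# Permutation-based label-free alignment and bulk-normalized density maps.

test_that("permutation generators enumerate S4 and its even subgroup", {
  p <- allPermutations(4)
  expect_equal(nrow(p), 24)
  expect_equal(nrow(unique(p)), 24)
  proper <- symmetryPermutations(4, "proper")
  expect_equal(nrow(proper), 12)
  # closed under composition (a group)
  keys <- apply(proper, 1, paste, collapse = ",")
  for (i in seq_len(12)) for (j in seq_len(12))
    expect_true(paste(proper[i, ][proper[j, ]], collapse = ",") %in% keys)
})

test_that("rotated and label-permuted neighborhoods realign exactly", {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  ref <- alignmentReference(1.49 * v)
  set.seed(41)
  for (rep in 1:5) {
    R <- randomRotationMatrix()
    perm <- sample(4)
    traj <- soluteFrame(rotation = R)
    # scramble the carbon order in the stored topology
    X <- frameCoords(traj, 1)
    X[2:5, ] <- X[1 + perm, ]
    scrambled <- trajectory(X, atomLabels(traj), moleculeIndex(traj),
                            boxLengths(traj))
    al <- alignNeighborhood(scrambled, 1, 1, ref, "N", "C_TMA")
    expect_lt(al$rmsd, 1e-10)
    expect_false(al$reflected)
    # the applied transform undoes the planted rotation up to tetrahedral
    # symmetry: aligned carbons occupy the reference sites as a set
    carbons <- al$coords[atomLabels(scrambled)[al$atoms] == "C_TMA", ]
    dists <- as.matrix(dist(rbind(carbons, 1.49 * v)))[1:4, 5:8]
    expect_lt(max(apply(dists, 1, min)), 1e-9)
  }
})

test_that("permutation search equals brute force over all labelings", {
  set.seed(42)
  for (rep in 1:5) {
    A <- matrix(rnorm(12), 4, 3)
    A <- sweep(A, 2, colMeans(A))
    B <- matrix(rnorm(12), 4, 3)
    B <- sweep(B, 2, colMeans(B))
    ref <- alignmentReference(A)
    traj <- trajectory(rbind(c(0, 0, 0), B) + 25, c("N", rep("C_TMA", 4)),
                       rep(1L, 5), 50)
    al <- alignNeighborhood(traj, 1, 1, ref, "N", "C_TMA")
    expect_equal(al$rmsd, bruteForceAlignRMSD(B, A), tolerance = 1e-6)
  }
})

test_that("searching permutations can only improve on a fixed labeling", {
  set.seed(43)
  for (rep in 1:5) {
    A <- matrix(rnorm(12, sd = 2), 4, 3)
    B <- A[sample(4), ] + matrix(rnorm(12, sd = 0.3), 4, 3)
    refFull <- alignmentReference(A)
    refLabeled <- alignmentReference(A, symmetry = matrix(1:4, 1))
    traj <- trajectory(rbind(c(0, 0, 0), B) + 25, c("N", rep("C_TMA", 4)),
                       rep(1L, 5), 50)
    full <- alignNeighborhood(traj, 1, 1, refFull, "N", "C_TMA")
    labeled <- alignNeighborhood(traj, 1, 1, refLabeled, "N", "C_TMA")
    expect_lte(full$rmsd, labeled$rmsd + 1e-12)
  }
})

test_that("the representative conformation avoids outliers", {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  regular <- 1.49 * v
  distorted <- regular * matrix(c(2.5, 1, 1, 1), 4, 3)
  set.seed(44)
  frames <- lapply(1:8, function(f) {
    R <- randomRotationMatrix()
    geom <- if (f == 3) distorted else regular
    rbind(c(0, 0, 0), geom %*% t(R)) + 25
  })
  traj <- trajectory(frames, c("N", rep("C_TMA", 4)), rep(1L, 5), 50)
  ref <- pickReference(traj, "N", "C_TMA", subsample = 8, seed = 0)
  # chosen reference superposes onto the regular geometry, not the outlier
  refTraj <- trajectory(rbind(c(0, 0, 0), regular) + 25,
                        c("N", rep("C_TMA", 4)), rep(1L, 5), 50)
  al <- alignNeighborhood(refTraj, 1, 1, ref, "N", "C_TMA")
  expect_lt(al$rmsd, 1e-9)
  # single conformation: it is its own reference
  one <- trajectory(frames[[1]], c("N", rep("C_TMA", 4)), rep(1L, 5), 50)
  ref1 <- pickReference(one, "N", "C_TMA", seed = 0)
  expect_lt(alignNeighborhood(one, 1, 1, ref1, "N", "C_TMA")$rmsd, 1e-10)
  expect_error(pickReference(one, "Zz", "C_TMA"), "no atoms")
})

test_that("density accumulation is equivariant under a global rotation", {
  # the alignment geometry is slightly distorted so the optimal permutation
  # is unique; a perfectly symmetric solute leaves the 12 proper
  # correspondences degenerate and tie-breaking is arbitrary
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  set.seed(45)
  geom <- 1.49 * v + matrix(rnorm(12, sd = 0.05), 4, 3)
  frames <- lapply(1:20, function(f) {
    R <- randomRotationMatrix()
    extra <- matrix(runif(3 * 80) * 60, ncol = 3)  # structureless species
    rbind(sweep(rbind(c(0, 0, 0), geom) %*% t(R), 2, c(30, 30, 30), `+`),
          extra)
  })
  labels <- c("N", rep("C_TMA", 4), rep("W", 80))
  mol <- c(rep(1L, 5), 1L + seq_len(80))
  traj <- trajectory(frames, labels, mol, 60)
  ref <- pickReference(traj, "N", "C_TMA", seed = 0)
  grid0 <- accumulateDensity(traj, "W", ref, "N", "C_TMA")
  G <- randomRotationMatrix()
  c0 <- boxLengths(traj) / 2
  rotated <- trajectory(lapply(seq_len(nFrames(traj)), function(f)
    sweep(sweep(frameCoords(traj, f), 2, c0) %*% t(G), 2, c0, `+`)),
    atomLabels(traj), moleculeIndex(traj), boxLengths(traj))
  grid1 <- accumulateDensity(rotated, "W", ref, "N", "C_TMA")
  expect_lt(mean(abs(gridValues(grid1) - gridValues(grid0))), 1e-8)
})

test_that("a homogeneous species normalizes to bulk density 1", {
  spec <- fixtureSpec("anisotropic", nSolutes = 5, box = 50, pattern = "faces",
                      background = 1200, minSep = 12, seed = 47)
  traj <- generateFixture(spec, nFrames = 100)  # 500 neighborhoods
  ref <- pickReference(traj, "N", "C_TMA", seed = 0)
  grid <- accumulateDensity(traj, "W", ref, "N", "C_TMA")
  expect_equal(grid@nNeighborhoods, 500)
  expect_lt(abs(bulkShellMean(grid) - 1), 0.05)
  # doubling the frames leaves the (unbiased) estimate in the same band
  traj2 <- generateFixture(spec, nFrames = 200)
  grid2 <- accumulateDensity(traj2, "W", ref, "N", "C_TMA")
  expect_lt(abs(bulkShellMean(grid2) - 1), 0.05)
})

test_that("planted face and corner patterns are recovered as site occupancy", {
  refv <- NULL
  for (pattern in c("faces", "corners")) {
    spec <- fixtureSpec("anisotropic", nSolutes = 10, box = 50,
                        pattern = pattern, radius = 4.5, seed = 48)
    traj <- generateFixture(spec, nFrames = 60)  # 600 neighborhoods
    ref <- pickReference(traj, "N", "C_TMA", seed = 0)
    grid <- accumulateDensity(traj, "P", ref, "N", "C_TMA")
    occ <- siteOccupancy(grid, ref, radius = 4.5)
    if (pattern == "faces") {
      expect_gt(mean(occ@faces), 2)
      expect_lt(mean(occ@corners), 0.2)
      expect_gt(mean(occ@faces), mean(occ@edges))
      expect_gt(mean(occ@edges) + 1e-9, mean(occ@corners))
    } else {
      expect_gt(mean(occ@corners), 2)
      expect_lt(mean(occ@faces), 0.2)
    }
  }
})

test_that("uniform grids read 1 at every tetrahedral site", {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  ref <- alignmentReference(1.49 * v)
  grid <- densityGrid(array(1, dim = c(41, 41, 41)), voxel = 0.5)
  occ <- siteOccupancy(grid, ref, radius = 4.5)
  expect_equal(c(occ@faces, occ@edges, occ@corners), rep(1, 14),
               tolerance = 1e-12)
  expect_error(siteOccupancy(grid, ref, radius = 30), "outside")
})

test_that("trilinear interpolation is exact for a linear field", {
  vals <- array(0, dim = c(11, 11, 11))
  ax <- (0:10 - 5) * 0.5
  for (i in 1:11) for (j in 1:11) for (k in 1:11)
    vals[i, j, k] <- 5 + 0.3 * ax[i] - 0.7 * ax[j] + 0.1 * ax[k]
  grid <- densityGrid(vals, voxel = 0.5)
  pts <- matrix(c(0.13, -0.52, 0.77, -1.2, 0.4, 1.9), 2, 3, byrow = TRUE)
  expected <- 5 + 0.3 * pts[, 1] - 0.7 * pts[, 2] + 0.1 * pts[, 3]
  expect_equal(interpolateDensity(grid, pts), expected, tolerance = 1e-12)
})

test_that("OpenDX export round trips and thresholds the planted sites", {
  spec <- fixtureSpec("anisotropic", nSolutes = 6, box = 50, pattern = "faces",
                      radius = 4.5, seed = 49)
  traj <- generateFixture(spec, nFrames = 30)
  ref <- pickReference(traj, "N", "C_TMA", seed = 0)
  grid <- accumulateDensity(traj, "P", ref, "N", "C_TMA")
  path <- tempfile(fileext = ".dx")
  exportDensityDX(grid, path, isoLevels = c(2, 3, 6))
  back <- readDensityDX(path)
  expect_lt(max(abs(gridValues(back) - gridValues(grid))), 1e-6 * max(1, max(gridValues(grid))))
  expect_true(file.exists(paste0(path, ".meta.json")))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_equal(unlist(meta$iso_levels), c(2, 3, 6))
  # inside the foreign-solute exclusion zone, voxels above 3x bulk cluster
  # at the face sites only (farther out, planted atoms of neighboring
  # solutes enter the 10 A neighborhood at arbitrary orientations)
  d <- dim(gridValues(back))
  idx <- which(gridValues(back) > 3, arr.ind = TRUE)
  centers <- sweep((idx - 1) * back@voxel, 2, back@origin, `+`)
  near <- sqrt(rowSums(centers^2)) < 6
  sites <- tetrahedralSites(ref)$faces * 4.5
  minDist <- apply(centers[near, , drop = FALSE], 1, function(p)
    min(sqrt(colSums((t(sites) - p)^2))))
  expect_gt(length(minDist), 0)
  expect_true(all(minDist < 1.5))
  # a grid of ones exports with value range [1, 1]
  ones <- densityGrid(array(1, dim = c(5, 5, 5)), voxel = 0.5)
  p1 <- tempfile(fileext = ".dx")
  exportDensityDX(ones, p1)
  expect_equal(range(gridValues(readDensityDX(p1))), c(1, 1))
})

test_that("Gaussian cube export writes a well-formed header", {
  grid <- densityGrid(array(1:8 / 8, dim = c(2, 2, 2)), voxel = 0.5)
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  ref <- alignmentReference(1.49 * v)
  path <- tempfile(fileext = ".cube")
  exportDensityCube(grid, path, ref = ref)
  lines <- readLines(path)
  expect_equal(as.integer(strsplit(trimws(lines[3]), "\\s+")[[1]][1]), 4)
  nums <- as.numeric(unlist(strsplit(trimws(lines[11:length(lines)]), "\\s+")))
  expect_equal(sort(nums), sort(as.numeric(gridValues(grid))),
               tolerance = 1e-5)
})
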