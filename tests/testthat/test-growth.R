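cfg <- growthConfig()

test_that("splitting plane is the parent x sibling cross product through CM", {
  p <- splittingPlane(c(1, 0, 0), c(0, 1, 0), c(0, 0, 0))
  expect_equal(p@normal, c(0, 0, 1))
  expect_equal(p@point, c(0, 0, 0))
  # hand cross product: (0,0,-1) x (0,1,-1) = (1, 0, 0), plane x = 5
  p2 <- splittingPlane(c(0, 0, -1), c(0, 1, -1), c(5, 5, 5))
  expect_equal(p2@normal, c(1, 0, 0))
  expect_equal(p2@point, c(5, 5, 5))
  expect_error(splittingPlane(c(1, 0, 0), c(2, 0, 0), c(0, 0, 0)), "degenerate")
})

test_that("plane partition is exhaustive with ties to the positive side", {
  plane <- new("SplitPlane", point = c(0, 0, 0), normal = c(0, 0, 1))
  s <- seedSet(rbind(c(0, 0, 1), c(0, 0, -1)), 1)
  parts <- partitionSeeds(plane, s)
  expect_equal(nSeeds(parts[[1L]]), 1L)
  expect_equal(nSeeds(parts[[2L]]), 1L)
  # a seed exactly on the plane goes to the positive side
  onPlane <- partitionSeeds(plane, seedSet(rbind(c(1, 2, 0)), 1))
  expect_equal(nSeeds(onPlane[[1L]]), 1L)
  expect_equal(nSeeds(onPlane[[2L]]), 0L)
  set.seed(5)
  s500 <- seedSet(matrix(stats::rnorm(1500), ncol = 3L), 1)
  parts <- partitionSeeds(plane, s500)
  expect_equal(nSeeds(parts[[1L]]) + nSeeds(parts[[2L]]), 500L)
})

test_that("centre of volume is the seed centroid", {
  expect_equal(centreOfVolume(seedSet(rbind(c(0, 0, 0), c(2, 0, 0)), 1)),
               c(x = 1, y = 0, z = 0))
  expect_equal(unname(centreOfVolume(seedSet(rbind(c(3, -1, 2)), 1))),
               c(3, -1, 2))
  set.seed(11)
  cube <- seedSet(matrix(stats::runif(3000), ncol = 3L), 1)
  expect_true(all(abs(centreOfVolume(cube) - 0.5) < 0.05))
  expect_error(centreOfVolume(seedSet(matrix(0, 0, 3), 1)), "empty")
})

test_that("children extend 40% of the way to the sub-space centroid", {
  ch <- proposeChild(c(0, 0, 0), c(10, 0, 0), cfg)
  expect_equal(ch$end, c(4, 0, 0))
  expect_equal(ch$length, 4)
  ch2 <- proposeChild(c(1, 1, 1), c(1, 1, 11), cfg)
  expect_equal(ch2$end, c(1, 1, 5))
  expect_equal(ch2$length, 4)
  expect_error(proposeChild(c(1, 1, 1), c(1, 1, 1), cfg), "coincides")
})

test_that("child length is clamped to 1.5x the parent length", {
  expect_equal(clampChildLength(4, 2, cfg), 3)
  expect_equal(clampChildLength(2, 2, cfg), 2)
  expect_equal(clampChildLength(3.0, 2.0, cfg), 3.0) # boundary is allowed
})

test_that("diameters follow D = L/3 clamped to 0.95 of the parent", {
  expect_equal(assignDiameter(3, 10, cfg), 1.0)
  expect_equal(assignDiameter(60, 10, cfg), 9.5)
  expect_equal(assignDiameter(3, 0.3, cfg), 0.285)
})

test_that("branching angle is the arccos of the direction dot product", {
  expect_equal(branchingAngle(c(0, 0, -1), c(0, 0, -1)), 0)
  expect_equal(branchingAngle(c(0, 0, -1), c(0, 1, 0)), 90)
  expect_equal(branchingAngle(c(1, 0, 0), c(1, 1, 0)), 45)
})

test_that("over-cap angles rotate to exactly 75 degrees, length preserved", {
  mkChild <- function(theta) {
    d <- c(sin(theta * pi / 180), 0, cos(theta * pi / 180))
    list(start = c(0, 0, 0), end = 3 * d, length = 3)
  }
  out <- enforceAngleLimit(c(0, 0, 1), mkChild(80), cfg)
  expect_true(out$rotated)
  expect_equal(out$angle, 75)
  expect_equal(branchingAngle(c(0, 0, 1), out$end - out$start), 75)
  expect_equal(sqrt(sum((out$end - out$start)^2)), 3)
  out60 <- enforceAngleLimit(c(0, 0, 1), mkChild(60), cfg)
  expect_false(out60$rotated)
  expect_equal(out60$angle, 60)
  out75 <- enforceAngleLimit(c(0, 0, 1), mkChild(75), cfg)
  expect_false(out75$rotated) # boundary: no rotation
  # parallel child: angle 0, nothing to rotate
  out0 <- enforceAngleLimit(c(0, 0, 1), mkChild(0), cfg)
  expect_false(out0$rotated)
})

test_that("terminal test combines length and volume rules (or/and)", {
  expect_true(isTerminal(1.2, 500, cfg))   # short branch
  expect_true(isTerminal(5, 200, cfg))     # small sub-space
  expect_false(isTerminal(5, 500, cfg))
  andCfg <- growthConfig(terminalRule = "and")
  expect_false(isTerminal(1.2, 500, andCfg))
  expect_true(isTerminal(1.2, 200, andCfg))
})

test_that("seed re-assignment matches a step-by-step oracle", {
  set.seed(21)
  P <- matrix(stats::runif(600, -10, 10), ncol = 3L)
  s <- seedSet(P, 1)
  chA <- list(start = c(0, 0, 0), end = c(3, 0, 1), length = sqrt(10))
  chB <- list(start = c(0, 0, 0), end = c(-3, 1, 0), length = sqrt(10))
  plane <- P[, 1L] >= 0
  # i = 0 keeps the plane partition untouched
  r0 <- reassignSeeds(chA, chB, s, 0L, cfg, partition = plane)
  expect_identical(r0$inA, plane)
  expect_identical(r0$childA, chA)
  # oracle: three manual assign / recompute / re-propose cycles
  segd <- function(P, a, b) {
    ab <- b - a
    t <- pmin(1, pmax(0, ((P[, 1] - a[1]) * ab[1] + (P[, 2] - a[2]) * ab[2] +
                            (P[, 3] - a[3]) * ab[3]) / sum(ab^2)))
    proj <- cbind(a[1] + t * ab[1], a[2] + t * ab[2], a[3] + t * ab[3])
    rowSums((P - proj)^2)
  }
  oA <- chA; oB <- chB
  for (it in 1:3) {
    inA <- segd(P, oA$start, oA$end) <= segd(P, oB$start, oB$end)
    cmA <- colMeans(P[inA, , drop = FALSE])
    cmB <- colMeans(P[!inA, , drop = FALSE])
    oA <- list(start = oA$start, end = oA$start + 0.4 * (cmA - oA$start),
               length = 0.4 * sqrt(sum((cmA - oA$start)^2)))
    oB <- list(start = oB$start, end = oB$start + 0.4 * (cmB - oB$start),
               length = 0.4 * sqrt(sum((cmB - oB$start)^2)))
  }
  r3 <- reassignSeeds(chA, chB, s, 3L, cfg, partition = plane)
  expect_equal(r3$childA$end, oA$end)
  expect_equal(r3$childB$end, oB$end)
  expect_equal(r3$inA, inA)
  expect_equal(sum(r3$inA) + sum(!r3$inA), 200L)
})

test_that("symmetric seeds stay balanced across re-assignment", {
  P <- as.matrix(expand.grid(x = seq(-5, 5, 1), y = seq(-5, 5, 1), z = 1))
  P <- P[P[, 1L] != 0, ] # no on-axis ties
  chA <- list(start = c(0, 0, 0), end = c(2, 0, 1), length = sqrt(5))
  chB <- list(start = c(0, 0, 0), end = c(-2, 0, 1), length = sqrt(5))
  r <- reassignSeeds(chA, chB, seedSet(P, 1), 4L, cfg, partition = P[, 1L] > 0)
  expect_equal(sum(r$inA), sum(!r$inA))
})

test_that("a starting leaf below the volume threshold stops immediately", {
  st <- stubTree(c(0, 0, 0), c(0, 0, -1), 8)
  leaf <- leafIds(st, unflaggedOnly = TRUE)
  s <- seedSet(rbind(c(0, 0, -3), c(1, 0, -4), c(0, 1, -5)), 64) # 192 mm^3
  sets <- stats::setNames(list(s), as.character(leaf))
  tr <- growTree(st, sets, cfg)
  expect_equal(nBranches(tr), 3L) # zero new branches
  b <- branches(tr)
  expect_true(b$terminal[b$id == leaf])
  expect_equal(b$subspace_volume[b$id == leaf], 192)
})

test_that("growth is deterministic and satisfies every hard constraint", {
  lobe <- smallGrownLobe()
  tr <- lobe$tree
  tr2 <- growTree(lobe$fix$tree, lobe$sets)
  expect_identical(branches(tr), branches(tr2))
  b <- branches(tr)
  gen <- b$provenance == "generated"
  pRow <- match(b$parent, b$id)
  # length rule: L_child <= 1.5 L_parent
  expect_true(all(b$length[gen] <= 1.5 * b$length[pRow[gen]] * (1 + 1e-9)))
  # diameter rule: D_child <= 0.95 D_parent, hence monotone along paths
  expect_true(all(b$diameter[gen] <= 0.95 * b$diameter[pRow[gen]] * (1 + 1e-9)))
  # angle cap, recomputed from raw geometry
  ang <- branchingAngles(tr, "generated")$angles
  expect_true(all(ang <= 75 + 1e-6))
  expect_equal(b$angle[gen], ang, tolerance = 1e-6)
  # generation increments
  expect_equal(b$generation[gen], b$generation[pRow[gen]] + 1L)
  # every leaf ends up flagged terminal and satisfies the stopping rule
  leafs <- !(b$id %in% b$parent)
  expect_true(all(b$terminal[leafs]))
  tbGen <- leafs & gen & b$subspace_volume > 0
  expect_true(all(b$length[tbGen] < 1.4 | b$subspace_volume[tbGen] < 233.75))
})

test_that("seed volume is conserved exactly into the terminal sub-spaces", {
  lobe <- smallGrownLobe()
  b <- branches(lobe$tree)
  vTerm <- sum(b$subspace_volume[b$terminal], na.rm = TRUE)
  vIn <- sum(vapply(lobe$sets, seedVolume, 1))
  expect_equal(vTerm, vIn, tolerance = 1e-12)
  expect_equal(vIn, seedVolume(lobe$seeds), tolerance = 1e-12)
})

test_that("a centred stub splits a sphere into near-equal halves", {
  mask <- ellipsoidMask(c(36.3, 36.3, 36.3), c(1, 1, 1)) # ~2e5 mm^3
  st <- stubTree(c(0, 0, 36), c(0, 0, -1), 6)
  s <- seedsFromMask(mask, 1L, 64L)
  sets <- assignSeedsToSubtrees(st, s)
  tr <- growTree(st, sets)
  b <- branches(tr)
  leaf <- leafIds(st, unflaggedOnly = TRUE)
  first <- b[!is.na(b$parent) & b$parent == leaf & b$provenance == "generated", ]
  expect_equal(nrow(first), 2L)
  expect_lt(abs(diff(first$subspace_volume)) / mean(first$subspace_volume), 0.05)
})

test_that("terminal count lands near volume / mean acinar volume", {
  lobe <- smallGrownLobe()
  nTB <- sum(branches(lobe$tree)$terminal)
  expect_lt(abs(nTB - 1e5 / 171.6) / (1e5 / 171.6), 0.25)
})

test_that("the depth guard aborts pathological configurations", {
  st <- stubTree(c(0, 0, 0), c(0, 0, -1), 8)
  leaf <- leafIds(st, unflaggedOnly = TRUE)
  set.seed(2)
  s <- seedSet(matrix(stats::runif(3000, -30, 0), ncol = 3L), 64)
  sets <- stats::setNames(list(s), as.character(leaf))
  shallow <- growthConfig(maxDepth = 3L)
  expect_error(growTree(st, sets, shallow), "depth")
})
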