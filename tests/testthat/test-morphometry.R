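test_that("homothety ratios match hand arithmetic on a toy tree", {
  # three bifurcations with hand-set diameters
  rows <- rbind(
    branchRow(1L, NA_integer_, c(0, 0, 0), c(0, 0, 1), diameter = 10),
    branchRow(2L, 1L, c(0, 0, 1), c(1, 0, 2), diameter = 7.94),
    branchRow(3L, 1L, c(0, 0, 1), c(-1, 0, 2), diameter = 5),
    branchRow(4L, 2L, c(1, 0, 2), c(2, 0, 3), diameter = 6),
    branchRow(5L, 2L, c(1, 0, 2), c(0, 0, 3), diameter = 4),
    branchRow(6L, 3L, c(-1, 0, 2), c(-2, 0, 3), diameter = 4),
    branchRow(7L, 3L, c(-1, 0, 2), c(0, 0, 3), diameter = 2))
  hr <- homothetyRatios(airwayTree(rows))
  ratios <- c(7.94 / 10, 5 / 10, 6 / 7.94, 4 / 7.94, 4 / 5, 2 / 5)
  expect_equal(sort(hr$ratios), sort(ratios))
  expect_equal(hr$hr[["mean"]], mean(ratios))
  expect_equal(hr$hr[["sd"]], sd(ratios))
  expect_equal(hr$hrMajor[["mean"]], mean(c(0.794, 6 / 7.94, 0.8)))
  expect_equal(hr$hrMinor[["mean"]], mean(c(0.5, 4 / 7.94, 0.4)))
})

test_that("a tree with uniform diameter ratio r has HR = r with sd 0", {
  tr <- completeBinaryTree(3) # diameters halve every level
  hr <- homothetyRatios(tr)
  expect_equal(hr$hr[["mean"]], 0.5)
  expect_equal(hr$hr[["sd"]], 0)
})

test_that("rotation angles recover constructed plane rotations", {
  mkTree <- function(phiDeg) {
    # grandparent bifurcation in the xz-plane; child bifurcation plane
    # rotated by phi about the parent axis (z)
    a <- phiDeg * pi / 180
    rows <- rbind(
      branchRow(1L, NA_integer_, c(0, 0, -1), c(0, 0, 0)),
      branchRow(2L, 1L, c(0, 0, 0), c(1, 0, 1)),
      branchRow(3L, 1L, c(0, 0, 0), c(-1, 0, 1)),
      branchRow(4L, 2L, c(1, 0, 1), c(1 + cos(a), sin(a), 2)),
      branchRow(5L, 2L, c(1, 0, 1), c(1 - cos(a), -sin(a), 2)))
    airwayTree(rows)
  }
  expect_equal(rotationAngles(mkTree(0), "all")$angles, 0)
  expect_equal(rotationAngles(mkTree(90), "all")$angles, 90)
  expect_equal(rotationAngles(mkTree(30), "all")$angles, 30, tolerance = 1e-9)
})

test_that("ratio fits are exact on geometric sequences", {
  rb <- ratioFit(data.frame(order = 1:3, value = c(4, 2, 1)))
  expect_equal(rb$ratio, 2.0)
  expect_equal(rb$r2, 1.0)
  rd <- ratioFit(data.frame(order = 1:4, value = c(1, 2, 4, 8)))
  expect_equal(rd$ratio, 2.0) # increasing sequence: slope magnitude
  expect_error(ratioFit(data.frame(order = 1:2, value = c(4, 2))), "3 orders")
})

test_that("noisy fits match a closed-form OLS oracle", {
  set.seed(31)
  ord <- 1:8
  y <- log10(1000 * 0.45^ord) + stats::rnorm(8, 0, 0.05)
  fit <- ratioFit(data.frame(order = ord, value = 10^y))
  # closed-form simple regression
  slope <- sum((ord - mean(ord)) * (y - mean(y))) / sum((ord - mean(ord))^2)
  r2 <- slope^2 * sum((ord - mean(ord))^2) / sum((y - mean(y))^2)
  expect_equal(fit$ratio, 10^abs(slope), tolerance = 1e-9)
  expect_equal(fit$r2, r2, tolerance = 1e-9)
})

test_that("the single root-order outlier is excluded deterministically", {
  tab <- data.frame(order = 1:6, value = c(1024, 512, 256, 128, 64, 1))
  noDrop <- ratioFit(tab)
  drop <- ratioFit(tab, dropRootOutlier = TRUE)
  expect_equal(drop$nOrders, 5L)
  expect_equal(drop$ratio, 2.0)
  expect_lt(noDrop$r2, drop$r2)
  # a clean sequence is never trimmed
  clean <- ratioFit(data.frame(order = 1:6, value = 2^(10:5)),
                    dropRootOutlier = TRUE)
  expect_equal(clean$nOrders, 6L)
})

test_that("AGR statistics equal direct path-length computation", {
  cb <- completeBinaryTree(4)
  a <- agrStats(cb)
  expect_equal(a$mean[a$lobe == "all"], 4)
  expect_equal(a$sd[a$lobe == "all"], 0)
  expect_equal(a$min[a$lobe == "all"], 4)
  expect_equal(a$max[a$lobe == "all"], 4)
  single <- rbind(
    branchRow(1L, NA_integer_, c(0, 0, 0), c(0, 0, 1)),
    branchRow(2L, 1L, c(0, 0, 1), c(0, 0, 2), generation = 1L),
    branchRow(3L, 2L, c(0, 0, 2), c(0, 0, 3), generation = 2L),
    branchRow(4L, 3L, c(0, 0, 3), c(0, 0, 4), generation = 3L,
              terminal = TRUE))
  a1 <- agrStats(airwayTree(single))
  expect_equal(unlist(a1[a1$lobe == "all", c("mean", "sd", "min", "max")],
                      use.names = FALSE), c(3, 0, 3, 3))
  rt <- randomTree(30, 8)
  g <- generations(rt, preserveSegmented = FALSE)
  b <- branches(rt)
  expect_equal(agrStats(rt)$mean[1L], mean(g[b$terminal]))
})

test_that("order normalization interpolates log-linearly, endpoints preserved", {
  tab <- data.frame(order = 1:3, count = c(4, 2, 1))
  same <- normalizeOrders(tab, 3)
  expect_equal(same$count, c(4, 2, 1))
  onto5 <- normalizeOrders(tab, 5)
  expect_equal(nrow(onto5), 5L)
  expect_equal(onto5$count[1L], 4)
  expect_equal(onto5$count[5L], 1)
  # hand interpolation: target order 2 sits at source order 1.5
  expect_equal(onto5$count[2L], 10^((log10(4) + log10(2)) / 2))
  onto12 <- normalizeOrders(data.frame(order = 1:4, count = c(8, 4, 2, 1)), 12)
  expect_equal(onto12$order, 1:12)
})

test_that("tree summaries populate every statistic consistently", {
  lobe <- smallGrownLobe()
  s <- summarizeTree(lobe$tree)
  b <- branches(lobe$tree)
  expect_equal(s$nAcini, sum(b$terminal))
  expect_equal(sum(s$perHorsfield$n), nBranches(lobe$tree))
  # terminals below the acinar threshold unless stopped by the length rule
  expect_lt(s$vAc[["mean"]], 233.75)
  # the diameter rule can only lower D below L/3, so mean L/D >= 3
  expect_gte(s$ld[["mean"]], 3.0)
  expect_true(all(s$ldDist$fraction >= 0 & s$ldDist$fraction <= 1))
  expect_gte(s$ratios$strahler$RB$r2, 0)
  expect_lte(s$ratios$strahler$RB$r2, 1)
  expect_true(s$terminalsByLengthRule >= 0)
  # degenerate single-branch tree: one-row tables, zero sds
  single <- airwayTree(branchRow(1L, NA_integer_, c(0, 0, 0), c(0, 0, 3),
                                 diameter = 1, terminal = TRUE,
                                 subspace_volume = 100))
  s1 <- summarizeTree(single, provenance = "all")
  expect_equal(nrow(s1$perGeneration), 1L)
  expect_equal(s1$dTB[["sd"]], 0)
  expect_equal(s1$nAcini, 1L)
})
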