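# Helpers shared across the suite: hand-built trees, random-tree generation
# and independent (brute-force recursive) ordering oracles.

# a branch row with sensible defaults; geometry is only as real as tests need
branchRow <- function(id, parent, start, end, diameter = 1, generation = 0L,
                      terminal = FALSE, provenance = "generated",
                      angle = NA_real_, subspace_volume = NA_real_) {
  data.frame(id = id, parent = parent,
             sx = start[1], sy = start[2], sz = start[3],
             ex = end[1], ey = end[2], ez = end[3],
             length = sqrt(sum((end - start)^2)), diameter = diameter,
             angle = angle, generation = generation, terminal = terminal,
             provenance = provenance, subspace_volume = subspace_volume,
             lobe = NA_real_)
}

# chain of n branches stacked along +z
chainTree <- function(n) {
  rows <- lapply(seq_len(n), function(i)
    branchRow(i, if (i == 1L) NA_integer_ else i - 1L,
              c(0, 0, i - 1), c(0, 0, i), generation = i - 1L,
              terminal = i == n))
  airwayTree(do.call(rbind, rows))
}

# complete binary tree of given depth (root = depth 0); leafs flagged terminal
completeBinaryTree <- function(depth) {
  rows <- list(branchRow(1L, NA_integer_, c(0, 0, 0), c(0, 0, 1),
                         diameter = 2^depth))
  nextId <- 2L
  frontier <- list(list(id = 1L, end = c(0, 0, 1), gen = 0L))
  for (d in seq_len(depth)) {
    newFrontier <- list()
    for (node in frontier) {
      for (s in c(-1, 1)) {
        endPt <- node$end + c(s * 2^(depth - d), 0, 1)
        rows[[length(rows) + 1L]] <- branchRow(
          nextId, node$id, node$end, endPt, diameter = 2^(depth - d),
          generation = node$gen + 1L, terminal = d == depth)
        newFrontier[[length(newFrontier) + 1L]] <-
          list(id = nextId, end = endPt, gen = node$gen + 1L)
        nextId <- nextId + 1L
      }
    }
    frontier <- newFrontier
  }
  airwayTree(do.call(rbind, rows))
}

# random binary tree grown by splitting a uniformly chosen leaf
randomTree <- function(nSplits, seed) {
  set.seed(seed)
  rows <- list(branchRow(1L, NA_integer_, c(0, 0, 0), c(0, 0, 1)))
  leafs <- 1L
  ends <- list(`1` = c(0, 0, 1))
  gens <- c(`1` = 0L)
  nextId <- 2L
  for (k in seq_len(nSplits)) {
    pick <- leafs[sample.int(length(leafs), 1L)]
    e <- ends[[as.character(pick)]]
    for (s in c(-1, 1)) {
      d <- c(stats::runif(1, -1, 1), stats::runif(1, -1, 1), stats::runif(1, 0.2, 1))
      rows[[length(rows) + 1L]] <- branchRow(
        nextId, pick, e, e + d, generation = gens[[as.character(pick)]] + 1L)
      ends[[as.character(nextId)]] <- e + d
      gens[[as.character(nextId)]] <- gens[[as.character(pick)]] + 1L
      leafs <- c(leafs, nextId)
      nextId <- nextId + 1L
    }
    leafs <- setdiff(leafs, pick)
  }
  b <- do.call(rbind, rows)
  b$terminal <- !(b$id %in% b$parent)
  airwayTree(b)
}

# independent recursive ordering oracles (memo-free, plain recursion)
oracleOrders <- function(tree, strahler) {
  b <- branches(tree)
  kids <- split(b$id, factor(b$parent, levels = b$id))
  rec <- function(id) {
    ki <- kids[[as.character(id)]]
    if (length(ki) == 0L) return(1L)
    sub <- vapply(ki, rec, integer(1))
    m <- max(sub)
    if (strahler && sum(sub == m) < 2L) m else m + 1L
  }
  vapply(b$id, rec, integer(1))
}

oracleMaxRootLeafDepth <- function(tree) {
  b <- branches(tree)
  kids <- split(b$id, factor(b$parent, levels = b$id))
  rec <- function(id, d) {
    ki <- kids[[as.character(id)]]
    if (length(ki) == 0L) return(d)
    max(vapply(ki, rec, numeric(1), d = d + 1L))
  }
  root <- b$id[is.na(b$parent)]
  max(vapply(root, rec, numeric(1), d = 0L))
}

# a small grown lobe reused by several files (cached per session)
smallGrownLobe <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    fix <- syntheticLung(1e5, 1, c(1, 1, 1), seed = 7)
    s <- seedsFromMask(fix$mask, 1L, 64L)
    sets <- suppressWarnings(assignSeedsToSubtrees(fix$tree, s))
    cache <<- list(fix = fix, seeds = s, sets = sets,
                   tree = growTree(fix$tree, sets))
    cache
  }
})
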