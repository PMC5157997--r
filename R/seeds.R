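#' Sub-sample a lobe mask into a seed grid
#'
#' The foreground voxels of one lobe are decimated on a regular lattice:
#' voxels are enumerated in a fixed scan order (z outermost, then y, then x
#' innermost) and every \code{voxelsPerSeed}-th voxel centre becomes a seed,
#' with a minimum of one seed per non-empty lobe. The represented volume per
#' seed is set so that the seed set represents the lobe's voxel volume
#' exactly: \code{volumePerSeed = nVoxels * voxelVolume / nSeeds}. A
#' sub-sampling of 32-64 voxels per seed keeps several seeds per acinus while
#' staying tractable.
#'
#' @param mask a \linkS4class{LobeMask}.
#' @param lobeLabel which lobe to sample.
#' @param voxelsPerSeed decimation factor (>= 1).
#' @return a \linkS4class{SeedSet}.
#' @examples
#' m <- ellipsoidMask(c(10, 10, 10), c(1, 1, 1))
#' s <- seedsFromMask(m, 1L, 64L)
#' seedVolume(s) == lobeVolume(m, 1L)
#' @export
seedsFromMask <- function(mask, lobeLabel, voxelsPerSeed = 64L) {
  stopifnot(is(mask, "LobeMask"), voxelsPerSeed >= 1L)
  idx <- which(mask@labels == lobeLabel)
  if (length(idx) == 0L)
    stop("lobe label ", lobeLabel, " absent from mask")
  n <- length(idx)
  nPts <- max(1L, n %/% as.integer(voxelsPerSeed))
  # R arrays are column-major: linear index order is x fastest, z slowest,
  # i.e. the documented z-outer / y / x-inner scan order
  take <- idx[1L + (seq_len(nPts) - 1L) * as.integer(voxelsPerSeed)]
  ijk <- arrayInd(take, dim(mask@labels)) - 1L # 0-based voxel indices
  pts <- sweep(sweep(ijk, 2L, mask@spacing, "*"), 2L, mask@origin, "+")
  seedSet(pts, volumePerSeed = n * prod(mask@spacing) / nPts,
          lobeLabel = lobeLabel, sourceVoxelCount = n)
}

# squared distance from each row of P to segment [a, b]; clamped projection
.segDist2 <- function(P, a, b) {
  ab <- b - a
  len2 <- sum(ab * ab)
  dx <- P[, 1L] - a[1L]; dy <- P[, 2L] - a[2L]; dz <- P[, 3L] - a[3L]
  if (len2 == 0) return(dx * dx + dy * dy + dz * dz)
  t <- (dx * ab[1L] + dy * ab[2L] + dz * ab[3L]) / len2
  t[t < 0] <- 0; t[t > 1] <- 1
  ex <- dx - t * ab[1L]; ey <- dy - t * ab[2L]; ez <- dz - t * ab[3L]
  ex * ex + ey * ey + ez * ez
}

# minimum squared distance from each seed to any segment of a set of branches
.skeletonDist2 <- function(P, b) {
  d <- rep(Inf, nrow(P))
  for (i in seq_len(nrow(b))) {
    di <- .segDist2(P, c(b$sx[i], b$sy[i], b$sz[i]), c(b$ex[i], b$ey[i], b$ez[i]))
    d <- pmin(d, di)
  }
  d
}

#' Assign seeds to the sub-trees of a segmented airway tree
#'
#' Iterative top-down partition of the seed grid: starting at the first
#' branch point distal to the lobar entry, each seed is assigned to the child
#' sub-tree whose branch skeleton (closest line segment over all branches of
#' the sub-tree) is nearest, and the recursion continues until the unflagged
#' leafs of the segmented structure are reached. Sub-trees containing no
#' unflagged leaf (e.g. flagged stub siblings) take no seeds. The partition
#' is exhaustive and disjoint: every seed lands in exactly one leaf's set.
#' Distance ties go to the child sub-tree containing the lower branch id.
#'
#' @param tree an \linkS4class{AirwayTree} with at least one unflagged leaf.
#' @param seeds a \linkS4class{SeedSet} for one lobe.
#' @return named list mapping unflagged-leaf id (as character) to its
#'   \linkS4class{SeedSet}; leafs that receive zero seeds are kept with an
#'   empty set and a warning is raised.
#' @export
assignSeedsToSubtrees <- function(tree, seeds) {
  b <- branches(tree)
  # restrict to branches of this lobe where lobe labels are recorded
  if (any(!is.na(b$lobe)) && any(b$lobe == seeds@lobeLabel, na.rm = TRUE)) {
    keep <- is.na(b$lobe) | b$lobe == seeds@lobeLabel
    b <- b[keep, , drop = FALSE]
  }
  leafs <- b$id[!(b$id %in% b$parent) & !b$terminal]
  if (length(leafs) == 0L) stop("tree has no unflagged leaf for this lobe")
  childrenOf <- split(b$id, factor(b$parent, levels = b$id))
  subtreeIds <- function(id) {
    out <- id
    frontier <- id
    while (length(frontier)) {
      kids <- unlist(childrenOf[as.character(frontier)], use.names = FALSE)
      out <- c(out, kids)
      frontier <- kids
    }
    out
  }
  hasLeaf <- function(ids) any(ids %in% leafs)
  out <- list()
  recurse <- function(id, ptIdx) {
    kids <- sort(childrenOf[[as.character(id)]])
    if (length(kids) == 0L) {
      out[[as.character(id)]] <<- ptIdx
      return(invisible())
    }
    subs <- lapply(kids, subtreeIds)
    eligible <- vapply(subs, hasLeaf, logical(1L))
    kids <- kids[eligible]; subs <- subs[eligible]
    if (length(kids) == 0L) return(invisible()) # dead end: no growing leaf below
    if (length(kids) == 1L || length(ptIdx) == 0L) {
      for (k in seq_along(kids))
        recurse(kids[k], if (k == 1L) ptIdx else integer(0))
      return(invisible())
    }
    P <- seeds@points[ptIdx, , drop = FALSE]
    D <- vapply(subs, function(ids)
      .skeletonDist2(P, b[match(ids, b$id), , drop = FALSE]), numeric(nrow(P)))
    if (nrow(P) == 1L) D <- matrix(D, nrow = 1L)
    side <- max.col(-D, ties.method = "first") # ties -> earlier (lower-id) child
    for (k in seq_along(kids)) recurse(kids[k], ptIdx[side == k])
    invisible()
  }
  roots <- sort(b$id[is.na(b$parent) | !(b$parent %in% b$id)])
  allIdx <- seq_len(nrow(seeds@points))
  if (length(roots) == 1L) {
    recurse(roots, allIdx)
  } else {
    # several entries into the lobe: split at the top level first
    subs <- lapply(roots, subtreeIds)
    eligible <- vapply(subs, hasLeaf, logical(1L))
    roots <- roots[eligible]; subs <- subs[eligible]
    P <- seeds@points
    D <- vapply(subs, function(ids)
      .skeletonDist2(P, b[match(ids, b$id), , drop = FALSE]), numeric(nrow(P)))
    if (nrow(P) == 1L) D <- matrix(D, nrow = 1L)
    side <- max.col(-D, ties.method = "first")
    for (k in seq_along(roots)) recurse(roots[k], allIdx[side == k])
  }
  empty <- setdiff(as.character(sort(leafs)), names(out)[vapply(out, length, 1L) > 0])
  for (id in as.character(sort(leafs)))
    if (is.null(out[[id]])) out[[id]] <- integer(0)
  if (length(empty))
    warning("leaf(s) ", paste(empty, collapse = ", "),
            " received zero seeds and will not be grown")
  res <- lapply(out, function(ix)
    seedSet(seeds@points[ix, , drop = FALSE], seeds@volumePerSeed,
            seeds@lobeLabel,
            sourceVoxelCount = seeds@sourceVoxelCount * length(ix) /
              max(1L, nrow(seeds@points))))
  res[order(as.integer(names(res)))]
}

#' Export a SeedSet as CSV
#'
#' Columns: x, y, z (mm), lobe, volume_per_seed (mm^3).
#'
#' @param seeds a \linkS4class{SeedSet}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeSeedsCSV <- function(seeds, path) {
  df <- data.frame(x = seeds@points[, 1L], y = seeds@points[, 2L],
                   z = seeds@points[, 3L], lobe = seeds@lobeLabel,
                   volume_per_seed = seeds@volumePerSeed)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
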