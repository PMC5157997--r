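#' Splitting plane for a bifurcation
#'
#' The sub-space dividing plane passes through the centre of volume \code{cm}
#' and is perpendicular to the plane of the parent and parent-sibling
#' branches: its normal is the (normalized) cross product of the parent
#' vector with the parent-sibling vector.
#'
#' @param parentVec direction vector of the branch being expanded.
#' @param parentSiblingVec direction vector of its sibling.
#' @param cm centre of volume of the confining sub-space (mm).
#' @return a \linkS4class{SplitPlane}.
#' @examples
#' splittingPlane(c(1, 0, 0), c(0, 1, 0), c(0, 0, 0)) # normal (0, 0, 1)
#' @export
splittingPlane <- function(parentVec, parentSiblingVec, cm) {
  n <- .crossp(as.numeric(parentVec), as.numeric(parentSiblingVec))
  nn <- .vnorm(n)
  if (nn <= 1e-12 * .vnorm(parentVec) * .vnorm(parentSiblingVec) || nn == 0)
    stop("degenerate splitting plane: parent and sibling are collinear")
  new("SplitPlane", point = as.numeric(cm), normal = n / nn)
}

# deterministic fallbacks when the parent and its sibling are collinear:
# first try the plane perpendicular to the parent-grandparent plane, then any
# plane containing the parent direction (via the least-aligned axis)
.splittingPlaneSafe <- function(parentVec, parentSiblingVec, grandVec, cm) {
  p <- tryCatch(splittingPlane(parentVec, parentSiblingVec, cm),
                error = function(e) NULL)
  if (!is.null(p)) return(p)
  if (!is.null(grandVec)) {
    p <- tryCatch(splittingPlane(parentVec, grandVec, cm),
                  error = function(e) NULL)
    if (!is.null(p)) return(p)
  }
  u <- .unitv(as.numeric(parentVec))
  e <- diag(3)[, which.min(abs(u))]
  new("SplitPlane", point = as.numeric(cm), normal = .unitv(.crossp(u, e)))
}

#' Partition a seed set by a splitting plane
#'
#' Seeds on the non-negative side of the plane (including those exactly on
#' it, a fixed tie-break) go to the first output, the rest to the second.
#'
#' @param plane a \linkS4class{SplitPlane}.
#' @param seeds a \linkS4class{SeedSet}.
#' @return list of two \linkS4class{SeedSet}s; counts always sum to the
#'   input count. An empty side signals that the plane failed to divide the
#'   sub-space (the caller treats the branch as a terminal candidate).
#' @export
partitionSeeds <- function(plane, seeds) {
  stopifnot(nrow(seeds@points) >= 1L)
  s <- .planeSide(plane@normal, plane@point, seeds@points)
  list(.subsetSeeds(seeds, which(s)), .subsetSeeds(seeds, which(!s)))
}

.planeSide <- function(normal, point, P) {
  (P[, 1L] - point[1L]) * normal[1L] + (P[, 2L] - point[2L]) * normal[2L] +
    (P[, 3L] - point[3L]) * normal[3L] >= 0
}

.subsetSeeds <- function(seeds, idx) {
  frac <- length(idx) / max(1L, nrow(seeds@points))
  seedSet(seeds@points[idx, , drop = FALSE], seeds@volumePerSeed,
          seeds@lobeLabel, sourceVoxelCount = seeds@sourceVoxelCount * frac)
}

#' Centre of volume of a seed set
#'
#' With uniform represented volume per seed the mass centroid is the
#' arithmetic mean of the seed coordinates.
#'
#' @param seeds a \linkS4class{SeedSet} (non-empty).
#' @return numeric(3) mm.
#' @export
centreOfVolume <- function(seeds) {
  if (nrow(seeds@points) == 0L) stop("centre of volume of an empty seed set")
  colMeans(seeds@points)
}

#' Propose a child branch skeleton toward a sub-space centroid
#'
#' The child starts at the parent end-point and extends 40% (the configured
#' \code{lengthFraction}) of the way toward the sub-space centre of volume.
#'
#' @param parentEnd parent end-point (mm).
#' @param cmSub sub-space centre of volume (mm).
#' @param config a \linkS4class{GrowthConfig}.
#' @return list with \code{start}, \code{end}, \code{length}.
#' @examples
#' proposeChild(c(0, 0, 0), c(10, 0, 0), growthConfig()) # ends at (4, 0, 0)
#' @export
proposeChild <- function(parentEnd, cmSub, config = growthConfig()) {
  parentEnd <- as.numeric(parentEnd); cmSub <- as.numeric(cmSub)
  d <- cmSub - parentEnd
  if (.vnorm(d) == 0) stop("sub-space centroid coincides with the parent end-point")
  end <- parentEnd + config@lengthFraction * d
  list(start = parentEnd, end = end, length = config@lengthFraction * .vnorm(d))
}

#' Clamp a child length against its parent
#'
#' Enforces L_child <= lRatioMax * L_parent (default 1.5); when clamped the
#' caller pulls the end-point toward the start along the child direction.
#'
#' @param lChild,lParent lengths in mm, both > 0.
#' @param config a \linkS4class{GrowthConfig}.
#' @return clamped child length (mm).
#' @export
clampChildLength <- function(lChild, lParent, config = growthConfig()) {
  stopifnot(lChild > 0, lParent > 0)
  min(lChild, config@lRatioMax * lParent)
}

#' Assign a child diameter from its length
#'
#' Diameters are set from the length-to-diameter rule D = L/3 (rather than a
#' fixed parent-child homothety) and clamped so that
#' D_child <= dRatioMax * D_parent (default 0.95). No lower diameter limit is
#' imposed: tree expansion does not depend on the diameter.
#'
#' @param lChild child length (mm).
#' @param dParent parent diameter (mm).
#' @param config a \linkS4class{GrowthConfig}.
#' @return child diameter (mm).
#' @export
assignDiameter <- function(lChild, dParent, config = growthConfig()) {
  stopifnot(lChild > 0, dParent > 0)
  min(lChild / config@ldRatio, config@dRatioMax * dParent)
}

#' Branching angle between parent and child directions
#'
#' @param parentDir,childDir nonzero direction vectors.
#' @return angle in degrees, in [0, 180].
#' @export
branchingAngle <- function(parentDir, childDir) {
  u <- .unitv(as.numeric(parentDir)); v <- .unitv(as.numeric(childDir))
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Enforce the branching-angle cap on a proposed child
#'
#' If the parent-child angle exceeds \code{thetaMax} (default 75 degrees) the
#' child is rotated within the plane spanned by the parent and child
#' directions, toward the parent, until the angle equals the cap; the length
#' is preserved. After a rotation the caller must re-run the seed assignment
#' for this bifurcation (single pass). A child parallel to its parent needs
#' no rotation (the angle is 0).
#'
#' @param parentDir parent direction vector.
#' @param child list(start, end, length) as from \code{\link{proposeChild}}.
#' @param config a \linkS4class{GrowthConfig}.
#' @return list(start, end, length, angle, rotated).
#' @export
enforceAngleLimit <- function(parentDir, child, config = growthConfig()) {
  u <- .unitv(as.numeric(parentDir))
  v <- .unitv(child$end - child$start)
  theta <- acos(max(-1, min(1, sum(u * v)))) * 180 / pi
  if (theta <= config@thetaMax + 1e-6)
    return(c(child, list(angle = theta, rotated = FALSE)))
  # in-plane unit vector orthogonal to the parent, on the child's side
  w <- v - sum(u * v) * u
  if (.vnorm(w) < 1e-12) return(c(child, list(angle = theta, rotated = FALSE)))
  w <- .unitv(w)
  a <- config@thetaMax * pi / 180
  vNew <- .unitv(cos(a) * u + sin(a) * w)
  list(start = child$start, end = child$start + child$length * vNew,
       length = child$length, angle = config@thetaMax, rotated = TRUE)
}

#' Terminal-bronchiole test
#'
#' A branch is a terminal bronchiole when its length falls below the TB
#' length threshold (1.4 mm) or the sub-space volume it supplies falls below
#' the acinar-volume threshold (233.75 mm^3). The two criteria combine by
#' "or" (default) or "and" depending on the configuration.
#'
#' @param length branch length (mm).
#' @param subspaceVolume supplied sub-space volume (mm^3).
#' @param config a \linkS4class{GrowthConfig}.
#' @return logical flag.
#' @export
isTerminal <- function(length, subspaceVolume, config = growthConfig()) {
  lenHit <- length < config@lTB
  volHit <- subspaceVolume < config@vAcThreshold
  if (config@terminalRule == "or") lenHit | volHit else lenHit & volHit
}

#' Iterative seed re-assignment between two proposed children
#'
#' For each iteration every seed is re-assigned to the nearest child skeleton
#' segment (ties to the first child), both centroids are recomputed and both
#' child skeletons re-proposed toward the updated centroids. With
#' \code{iterations = 0} the initial plane partition is returned unchanged.
#' A child that loses all its seeds is returned empty (terminal candidate).
#'
#' @param childA,childB child skeletons, list(start, end, length).
#' @param seeds the parent's \linkS4class{SeedSet}.
#' @param iterations number of assign/recompute cycles (>= 0).
#' @param config a \linkS4class{GrowthConfig}.
#' @param partition initial assignment: logical vector, TRUE = child A
#'   (from the plane partition).
#' @return list(childA, childB, inA) where \code{inA} is the final logical
#'   assignment vector.
#' @export
reassignSeeds <- function(childA, childB, seeds, iterations = 1L,
                          config = growthConfig(),
                          partition = NULL) {
  P <- seeds@points
  inA <- if (is.null(partition)) {
    .segDist2(P, childA$start, childA$end) <= .segDist2(P, childB$start, childB$end)
  } else partition
  if (iterations < 1L) return(list(childA = childA, childB = childB, inA = inA))
  for (it in seq_len(iterations)) {
    dA <- .segDist2(P, childA$start, childA$end)
    dB <- .segDist2(P, childB$start, childB$end)
    newInA <- dA <= dB # tie -> first (lower-id) child
    if (!any(newInA) || all(newInA)) { inA <- newInA; break }
    inA <- newInA
    cmA <- colMeans(P[inA, , drop = FALSE])
    cmB <- colMeans(P[!inA, , drop = FALSE])
    childA <- proposeChild(childA$start, cmA, config)
    childB <- proposeChild(childB$start, cmB, config)
  }
  list(childA = childA, childB = childB, inA = inA)
}

#' Grow the conducting airway tree by recursive space subdivision
#'
#' Expands every unflagged leaf of the starting tree into the sub-space its
#' seed set discretizes, bifurcation by bifurcation, until every generated
#' leaf satisfies the terminal-bronchiole criteria. Per bifurcation the order
#' of operations is: splitting plane through the sub-space centre of volume
#' (normal = parent x parent-sibling); plane partition of the seeds;
#' sub-space centroids; child skeletons at 40% of the centroid distance;
#' optional seed re-assignment iterations; length clamp; diameter
#' assignment; branching-angle check with in-plane rotation to the cap and a
#' single post-rotation seed re-partition. The procedure is fully
#' deterministic: no randomness is used anywhere in the expansion.
#'
#' @param tree starting \linkS4class{AirwayTree}; every unflagged leaf must
#'   have a parent and a parent-sibling (so the first splitting plane is
#'   defined).
#' @param seedSets named list (leaf id as name) of \linkS4class{SeedSet}s, as
#'   produced by \code{\link{assignSeedsToSubtrees}}.
#' @param config a \linkS4class{GrowthConfig}.
#' @param verbose log each bifurcation decision.
#' @return the grown \linkS4class{AirwayTree}: generated branches carry
#'   provenance "generated", their measured branching angle, generation =
#'   parent generation + 1 and the supplied sub-space volume
#'   (nSeeds x volumePerSeed); all leafs end up flagged terminal.
#' @examples
#' fix <- syntheticLung(5e4, 1, c(2, 2, 2), seed = 1)
#' s <- seedsFromMask(fix$mask, 1L, 8L)
#' sets <- assignSeedsToSubtrees(fix$tree, s)
#' tr <- growTree(fix$tree, sets)
#' tr
#' @export
growTree <- function(tree, seedSets, config = growthConfig(), verbose = FALSE) {
  b <- branches(tree)
  n <- nrow(b)
  cap <- max(64L, 4L * n)
  col <- function(x, fill) c(x, rep(fill, cap - length(x)))
  id <- col(b$id, NA_integer_); parent <- col(b$parent, NA_integer_)
  sx <- col(b$sx, NA_real_); sy <- col(b$sy, NA_real_); sz <- col(b$sz, NA_real_)
  ex <- col(b$ex, NA_real_); ey <- col(b$ey, NA_real_); ez <- col(b$ez, NA_real_)
  len <- col(b$length, NA_real_); dia <- col(b$diameter, NA_real_)
  ang <- col(b$angle, NA_real_); gen <- col(b$generation, NA_integer_)
  term <- col(b$terminal, NA); prov <- col(b$provenance, NA_character_)
  ssv <- col(b$subspace_volume, NA_real_); lob <- col(b$lobe, NA_real_)
  ensure <- function(k) {
    if (n + k <= cap) return(invisible())
    cap2 <- max(cap * 2L, n + k)
    grow <- function(x, fill) c(x, rep(fill, cap2 - length(x)))
    id <<- grow(id, NA_integer_); parent <<- grow(parent, NA_integer_)
    sx <<- grow(sx, NA_real_); sy <<- grow(sy, NA_real_); sz <<- grow(sz, NA_real_)
    ex <<- grow(ex, NA_real_); ey <<- grow(ey, NA_real_); ez <<- grow(ez, NA_real_)
    len <<- grow(len, NA_real_); dia <<- grow(dia, NA_real_)
    ang <<- grow(ang, NA_real_); gen <<- grow(gen, NA_integer_)
    term <<- grow(term, NA); prov <<- grow(prov, NA_character_)
    ssv <<- grow(ssv, NA_real_); lob <<- grow(lob, NA_real_)
    cap <<- cap2
  }
  nextId <- max(b$id) + 1L
  vps <- if (length(seedSets)) seedSets[[1L]]@volumePerSeed else NA_real_
  seedsBy <- new.env(parent = emptyenv())
  depthBy <- new.env(parent = emptyenv())
  queue <- integer(0)
  for (nm in names(seedSets)) {
    i <- match(as.integer(nm), id)
    if (is.na(i)) stop("seed set supplied for unknown branch id ", nm)
    if (term[i]) next
    assign(nm, seedSets[[nm]]@points, envir = seedsBy)
    assign(nm, 0L, envir = depthBy)
    queue <- c(queue, as.integer(nm))
  }
  if (length(queue) == 0L) stop("no unflagged leaf with a seed set to grow")
  # any unflagged leaf without seeds is flagged empty and skipped
  allLeafs <- b$id[!(b$id %in% b$parent) & !b$terminal]
  for (i0 in setdiff(allLeafs, queue)) {
    j <- match(i0, id); term[j] <- TRUE; ssv[j] <- 0
  }
  qHead <- 1L
  while (qHead <= length(queue)) {
    cur <- queue[qHead]; qHead <- qHead + 1L
    i <- match(cur, id)
    key <- as.character(cur)
    P <- get(key, envir = seedsBy)
    rm(list = key, envir = seedsBy)
    depth <- get(key, envir = depthBy)
    if (depth > config@maxDepth)
      stop("maximum generated depth ", config@maxDepth,
           " exceeded; pathological configuration?")
    V <- nrow(P) * vps
    ssv[i] <- V
    if (isTerminal(len[i], V, config)) {
      term[i] <- TRUE
      if (verbose) message("branch ", cur, ": terminal (L=", signif(len[i], 3),
                           " mm, V=", signif(V, 4), " mm^3)")
      next
    }
    pEnd <- c(ex[i], ey[i], ez[i])
    pVec <- pEnd - c(sx[i], sy[i], sz[i])
    # sibling: the other child of this branch's parent
    pid <- parent[i]
    sib <- id[!is.na(parent) & parent == pid & id != cur]
    if (length(sib) == 0L)
      stop("branch ", cur, " has no sibling: the first splitting plane is undefined")
    js <- match(sib[1L], id)
    sVec <- c(ex[js] - sx[js], ey[js] - sy[js], ez[js] - sz[js])
    gVec <- if (!is.na(pid) && !is.na(match(pid, id))) {
      jg <- match(pid, id)
      c(ex[jg] - sx[jg], ey[jg] - sy[jg], ez[jg] - sz[jg])
    } else NULL
    cm <- colMeans(P)
    plane <- .splittingPlaneSafe(pVec, sVec, gVec, cm)
    inA <- .planeSide(plane@normal, plane@point, P)
    if (!any(inA) || all(inA)) {
      # the plane failed to divide the sub-space: terminal candidate
      term[i] <- TRUE
      if (verbose) message("branch ", cur, ": empty sub-space side, flagged terminal")
      next
    }
    cmA <- colMeans(P[inA, , drop = FALSE])
    cmB <- colMeans(P[!inA, , drop = FALSE])
    if (isTRUE(all.equal(cmA, pEnd, tolerance = 1e-12)) ||
        isTRUE(all.equal(cmB, pEnd, tolerance = 1e-12))) {
      term[i] <- TRUE
      next
    }
    chA <- proposeChild(pEnd, cmA, config)
    chB <- proposeChild(pEnd, cmB, config)
    re <- reassignSeeds(chA, chB, seedSet(P, vps), config@reassignIterations,
                        config, partition = inA)
    chA <- re$childA; chB <- re$childB; inA <- re$inA
    mk <- function(ch) {
      L <- clampChildLength(ch$length, len[i], config)
      if (L < ch$length) {
        d <- .unitv(ch$end - ch$start)
        ch$end <- ch$start + L * d
        ch$length <- L
      }
      ch <- enforceAngleLimit(pVec, ch, config)
      ch$diameter <- assignDiameter(ch$length, dia[i], config)
      ch
    }
    chA <- mk(chA); chB <- mk(chB)
    if (chA$rotated || chB$rotated) {
      # recalculation of the assigned confining space: one nearest-skeleton pass
      dA <- .segDist2(P, chA$start, chA$end)
      dB <- .segDist2(P, chB$start, chB$end)
      inA <- dA <= dB
    }
    ensure(2L)
    for (side in 1:2) {
      ch <- if (side == 1L) chA else chB
      cnt <- if (side == 1L) sum(inA) else sum(!inA)
      n <- n + 1L
      id[n] <- nextId; parent[n] <- cur
      sx[n] <- ch$start[1L]; sy[n] <- ch$start[2L]; sz[n] <- ch$start[3L]
      ex[n] <- ch$end[1L]; ey[n] <- ch$end[2L]; ez[n] <- ch$end[3L]
      len[n] <- ch$length; dia[n] <- ch$diameter; ang[n] <- ch$angle
      gen[n] <- gen[i] + 1L; prov[n] <- "generated"; lob[n] <- lob[i]
      ssv[n] <- cnt * vps
      if (cnt == 0L) {
        term[n] <- TRUE # lost every seed: terminal candidate, zero volume
      } else {
        term[n] <- FALSE
        key2 <- as.character(nextId)
        assign(key2, P[if (side == 1L) inA else !inA, , drop = FALSE],
               envir = seedsBy)
        assign(key2, depth + 1L, envir = depthBy)
        queue <- c(queue, nextId)
      }
      nextId <- nextId + 1L
    }
    if (verbose)
      message("branch ", cur, ": split ", sum(inA), "/", sum(!inA), " seeds")
  }
  keep <- seq_len(n)
  airwayTree(data.frame(
    id = id[keep], parent = parent[keep], sx = sx[keep], sy = sy[keep],
    sz = sz[keep], ex = ex[keep], ey = ey[keep], ez = ez[keep],
    length = len[keep], diameter = dia[keep], angle = ang[keep],
    generation = gen[keep], terminal = term[keep], provenance = prov[keep],
    subspace_volume = ssv[keep], lobe = lob[keep]))
}
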