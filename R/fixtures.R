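#' Voxelize an axis-aligned ellipsoid into a LobeMask
#'
#' A synthetic stand-in for a segmented lobar volume: all voxel centres with
#' (x/a)^2 + (y/b)^2 + (z/c)^2 <= 1 around \code{centre} are labelled. The
#' voxel volume converges to (4/3) pi a b c as spacing shrinks.
#'
#' @param radii numeric(3) semi-axes (a, b, c) in mm.
#' @param spacing numeric(3) voxel edge lengths in mm.
#' @param label lobe label (> 0) to write.
#' @param centre ellipsoid centre in mm.
#' @return a \linkS4class{LobeMask}.
#' @examples
#' m <- ellipsoidMask(c(10, 10, 10), c(1, 1, 1))
#' lobeVolume(m, 1L) # close to 4188.79 mm^3
#' @export
ellipsoidMask <- function(radii, spacing, label = 1L, centre = c(0, 0, 0)) {
  stopifnot(length(radii) == 3L, length(spacing) == 3L)
  if (any(radii <= 0) || any(spacing <= 0))
    stop("radii and spacing must be strictly positive")
  if (any(radii < 2 * spacing))
    stop("degenerate mask: radii must be at least 2x the voxel spacing")
  # grid with one voxel margin, centred on the ellipsoid
  half <- ceiling(radii / spacing) + 1L
  dims <- 2L * half + 1L
  origin <- centre - half * spacing
  ax <- ((seq_len(dims[1L]) - 1L) * spacing[1L] + origin[1L] - centre[1L]) / radii[1L]
  ay <- ((seq_len(dims[2L]) - 1L) * spacing[2L] + origin[2L] - centre[2L]) / radii[2L]
  az <- ((seq_len(dims[3L]) - 1L) * spacing[3L] + origin[3L] - centre[3L]) / radii[3L]
  inside <- outer(outer(ax^2, ay^2, "+"), az^2, "+") <= 1
  labels <- array(0L, dim = dims)
  labels[inside] <- as.integer(label)
  new("LobeMask", labels = labels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

# rotate `v` by `angleDeg` within the plane spanned by (v, axisMate); used to
# place non-collinear stub siblings deterministically
.rotateInPlane <- function(v, angleDeg) {
  u <- .unitv(v)
  # pick the coordinate axis least aligned with v to define the plane
  e <- diag(3)[, which.min(abs(u))]
  w <- .unitv(.crossp(.crossp(u, e), u)) # in-plane direction orthogonal to u
  a <- angleDeg * pi / 180
  cos(a) * u + sin(a) * w
}

#' Minimal stub of segmented central airways for one lobe entry
#'
#' Builds the smallest segmented tree the growth algorithm can start from:
#' a root (lobar bronchus), an unflagged leaf ending at \code{entryPoint}
#' (the starting point of model expansion) and a flagged sibling sharing the
#' leaf's origin, so the first splitting-plane normal (leaf direction x
#' sibling direction) is defined at step one.
#'
#' @param entryPoint mm triple where the leaf ends (inside the lobe surface).
#' @param entryDirection direction the leaf points in (into the lobe);
#'   normalized internally, must be nonzero.
#' @param diameter leaf diameter in mm.
#' @param lobeLabel lobe label carried by the leaf.
#' @param leafLength leaf length in mm (default 2.5 x diameter).
#' @param siblingAngle angle (degrees) between leaf and its stub sibling.
#' @param idOffset first id to use (stubs for several lobes need disjoint ids).
#' @return an \linkS4class{AirwayTree} with 3 branches; the unflagged leaf is
#'   the one ending at \code{entryPoint}.
#' @export
stubTree <- function(entryPoint, entryDirection, diameter, lobeLabel = 1L,
                     leafLength = 2.5 * diameter, siblingAngle = 45,
                     idOffset = 1L) {
  if (.vnorm(entryDirection) == 0) stop("entryDirection must be nonzero")
  stopifnot(diameter > 0, leafLength > 0)
  d <- .unitv(as.numeric(entryDirection))
  entryPoint <- as.numeric(entryPoint)
  leafStart <- entryPoint - leafLength * d
  rootDir <- .rotateInPlane(d, -20)
  rootLen <- 1.25 * leafLength
  rootStart <- leafStart - rootLen * rootDir
  sibDir <- .rotateInPlane(d, siblingAngle)
  sibLen <- 0.8 * leafLength
  ids <- idOffset + 0:2
  airwayTree(data.frame(
    id = ids, parent = c(NA_integer_, ids[1L], ids[1L]),
    sx = c(rootStart[1], leafStart[1], leafStart[1]),
    sy = c(rootStart[2], leafStart[2], leafStart[2]),
    sz = c(rootStart[3], leafStart[3], leafStart[3]),
    ex = c(leafStart[1], entryPoint[1], leafStart[1] + sibLen * sibDir[1]),
    ey = c(leafStart[2], entryPoint[2], leafStart[2] + sibLen * sibDir[2]),
    ez = c(leafStart[3], entryPoint[3], leafStart[3] + sibLen * sibDir[3]),
    length = c(rootLen, leafLength, sibLen),
    diameter = c(diameter / 0.794, diameter, 0.8 * diameter),
    angle = c(NA, 20, siblingAngle),
    generation = c(0L, 1L, 1L),
    terminal = c(FALSE, FALSE, TRUE),
    provenance = "segmented",
    lobe = as.numeric(lobeLabel)))
}

# canonical human lobe volume fractions (RU, RM, RL, LU, LL)
.LOBE_FRACTIONS <- c(0.20, 0.10, 0.25, 0.20, 0.25)

#' Synthetic lung: ellipsoidal lobes plus stub central airways
#'
#' Generates 1-5 non-overlapping ellipsoidal lobes whose summed voxel volume
#' matches \code{totalVolume} (within voxelization error), with one unflagged
#' stub leaf per lobe entering at the lobe's superior-medial surface and
#' pointing into the lobe. Lobe volume fractions follow typical human lobar
#' shares (RU/RM/RL/LU/LL = 20/10/25/20/25%, renormalized when fewer lobes
#' are requested). The seed only jitters lobe shape and entry orientation;
#' the same seed always reproduces the same fixture bit-for-bit.
#'
#' @param totalVolume target summed lobe volume in mm^3.
#' @param nLobes number of lobes (1-5).
#' @param spacing numeric(3) voxel spacing in mm.
#' @param seed integer seed for the shape/orientation jitter.
#' @return list with elements \code{mask} (\linkS4class{LobeMask}) and
#'   \code{tree} (\linkS4class{AirwayTree} holding all lobe stubs).
#' @examples
#' fix <- syntheticLung(1e5, 1, c(2, 2, 2), seed = 1)
#' fix$mask
#' @export
syntheticLung <- function(totalVolume, nLobes = 1L, spacing = c(1, 1, 1),
                          seed = 1L) {
  stopifnot(totalVolume > 0, nLobes >= 1L, nLobes <= 5L, length(spacing) == 3L)
  rng <- .lcgSequence(seed, 6L * nLobes)
  frac <- .LOBE_FRACTIONS[seq_len(nLobes)]
  frac <- frac / sum(frac)
  shapes <- vector("list", nLobes)
  for (k in seq_len(nLobes)) {
    u <- rng[(6L * (k - 1L) + 1L):(6L * k)]
    ratios <- c(0.85, 0.95, 1.25) * (0.95 + 0.10 * u[1:3]) # mild prolate jitter
    s <- (3 * frac[k] * totalVolume / (4 * pi * prod(ratios)))^(1 / 3)
    radii <- s * ratios
    if (any(radii < 2 * spacing))
      stop("volume not realizable at given spacing: lobe ", k,
           " radii fall below 2x the voxel size")
    shapes[[k]] <- list(radii = radii, jitter = u[4:6])
  }
  # place lobes along x with a 4-voxel gap so labels never overlap
  maxA <- vapply(shapes, function(s) s$radii[1L], 0)
  gap <- 4 * spacing[1L]
  cx <- cumsum(c(0, head(maxA, -1) + maxA[-1] + gap))
  masks <- vector("list", nLobes)
  trees <- vector("list", nLobes)
  for (k in seq_len(nLobes)) {
    sh <- shapes[[k]]
    centre <- c(cx[k], 0, 0)
    masks[[k]] <- ellipsoidMask(sh$radii, spacing, label = k, centre = centre)
    # entry on the superior-medial surface, pointing into the lobe with a
    # seed-controlled tilt so the first split is not artificially symmetric
    v <- .unitv(c(-0.35, 0.15, 0.92) + 0.1 * (sh$jitter - 0.5))
    entry <- centre + sh$radii * v
    aim <- centre + sh$radii * 0.15 * (sh$jitter - 0.5)
    dir <- .unitv(aim - entry)
    dEntry <- 2 * (frac[k] * totalVolume / 1e6)^(1 / 3) * 4 # ~8 mm for a 1 L lobe
    trees[[k]] <- stubTree(entry, dir, diameter = dEntry, lobeLabel = k,
                           idOffset = 1L + 3L * (k - 1L))
  }
  mask <- .mergeMasks(masks)
  got <- lobeVolume(mask)
  if (abs(got - totalVolume) / totalVolume > 0.05)
    stop(sprintf("volume not realizable at given spacing: got %.4g of %.4g mm^3",
                 got, totalVolume))
  tree <- airwayTree(do.call(rbind, lapply(trees, branches)))
  list(mask = mask, tree = tree)
}

# deterministic uniform(0,1) stream independent of R's global RNG state
.lcgSequence <- function(seed, n) {
  x <- (as.numeric(seed) %% 2147483647) + 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- (16807 * x) %% 2147483647
    out[i] <- x / 2147483647
  }
  out
}

# combine per-lobe masks (disjoint by construction) into one common grid
.mergeMasks <- function(masks) {
  sp <- masks[[1L]]@spacing
  lo <- do.call(rbind, lapply(masks, function(m) m@origin))
  hi <- do.call(rbind, lapply(masks, function(m) m@origin + (dim(m@labels) - 1L) * sp))
  origin <- apply(lo, 2L, min)
  top <- apply(hi, 2L, max)
  dims <- as.integer(round((top - origin) / sp)) + 1L
  labels <- array(0L, dim = dims)
  for (m in masks) {
    off <- as.integer(round((m@origin - origin) / sp))
    d <- dim(m@labels)
    sub <- labels[off[1L] + seq_len(d[1L]), off[2L] + seq_len(d[2L]),
                  off[3L] + seq_len(d[3L]), drop = FALSE]
    keep <- m@labels > 0L
    if (any(sub[keep] > 0L)) stop("lobe masks overlap")
    sub[keep] <- m@labels[keep]
    labels[off[1L] + seq_len(d[1L]), off[2L] + seq_len(d[2L]),
           off[3L] + seq_len(d[3L])] <- sub
  }
  new("LobeMask", labels = labels, spacing = sp, origin = as.numeric(origin))
}
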