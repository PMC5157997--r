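#' @import methods
NULL

.vnorm <- function(v) sqrt(sum(v * v))

.unitv <- function(v) {
  n <- .vnorm(v)
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

.crossp <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' LobeMask: a labelled voxel volume of lobar confining spaces
#'
#' A 3D integer label array (0 = background, k > 0 = lobe k) together with the
#' physical voxel spacing and the physical position of voxel (0,0,0). Voxel
#' indices are 0-based in the physical convention: the centre of voxel
#' \code{(i,j,k)} lies at \code{origin + c(i,j,k) * spacing} (mm).
#'
#' @slot labels 3D integer array of lobe labels.
#' @slot spacing numeric(3), voxel edge lengths in mm, all > 0.
#' @slot origin numeric(3), physical position (mm) of the centre of voxel (0,0,0).
#' @export
setClass("LobeMask",
  representation(labels = "array", spacing = "numeric", origin = "numeric"))

setValidity("LobeMask", function(object) {
  msg <- NULL
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive finite values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be three finite values")
  if (any(object@labels < 0, na.rm = TRUE))
    msg <- c(msg, "labels must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' SeedSet: a uniform point discretization of a confining space
#'
#' Each seed stands for an equal share of the lobe volume, so the set as a
#' whole represents the source voxel volume exactly:
#' \code{nSeeds * volumePerSeed == sourceVoxelCount * voxelVolume}.
#'
#' @slot points numeric matrix (n x 3) of seed coordinates in mm.
#' @slot volumePerSeed mm^3 represented by each seed.
#' @slot lobeLabel integer lobe label the seeds were drawn from.
#' @slot sourceVoxelCount number of foreground voxels the set represents
#'   (fractional for subsets produced by partitioning).
#' @export
setClass("SeedSet",
  representation(points = "matrix", volumePerSeed = "numeric",
                 lobeLabel = "integer", sourceVoxelCount = "numeric"))

setValidity("SeedSet", function(object) {
  msg <- NULL
  if (ncol(object@points) != 3L) msg <- c(msg, "points must have 3 columns")
  if (length(object@volumePerSeed) != 1L || object@volumePerSeed <= 0)
    msg <- c(msg, "volumePerSeed must be a single positive value")
  if (object@sourceVoxelCount < 0)
    msg <- c(msg, "sourceVoxelCount must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' SplitPlane: a point + unit-normal division of a sub-space
#'
#' The plane through \code{point} with unit normal \code{normal}; a seed at
#' position s lies on the non-negative side iff \code{sum(normal * (s - point)) >= 0}.
#'
#' @slot point numeric(3), a point on the plane (the centre of volume), mm.
#' @slot normal numeric(3), unit normal vector.
#' @export
setClass("SplitPlane",
  representation(point = "numeric", normal = "numeric"))

setValidity("SplitPlane", function(object) {
  msg <- NULL
  if (length(object@point) != 3L) msg <- c(msg, "point must be length 3")
  if (length(object@normal) != 3L) msg <- c(msg, "normal must be length 3")
  else if (abs(.vnorm(object@normal) - 1) > 1e-9)
    msg <- c(msg, "normal must be a unit vector")
  if (is.null(msg)) TRUE else msg
})

.BRANCH_COLS <- c("id", "parent", "sx", "sy", "sz", "ex", "ey", "ez",
                  "length", "diameter", "angle", "generation", "terminal",
                  "provenance", "subspace_volume", "lobe")

#' AirwayTree: a rooted branching collection of airway segments
#'
#' Branches are straight tubes stored one per row of a data.frame with
#' columns: \code{id}, \code{parent} (NA for a root), start/end coordinates
#' \code{sx..ez} (mm), \code{length} (mm), \code{diameter} (mm),
#' \code{angle} (branching angle vs the parent, degrees; NA for roots),
#' \code{generation} (trachea/root = 0), \code{terminal} (flagged leaf:
#' terminal bronchiole or non-growing segmented end), \code{provenance}
#' ("segmented" or "generated"), \code{subspace_volume} (mm^3 of confining
#' space supplied; NA when never assigned) and \code{lobe} (label, NA if
#' unknown).
#'
#' @slot branches data.frame as described above.
#' @export
setClass("AirwayTree", representation(branches = "data.frame"))

setValidity("AirwayTree", function(object) {
  b <- object@branches
  msg <- NULL
  if (!all(.BRANCH_COLS %in% names(b)))
    return(paste("branches must have columns:",
                 paste(setdiff(.BRANCH_COLS, names(b)), collapse = ", ")))
  if (nrow(b) == 0L) return(TRUE)
  if (anyDuplicated(b$id)) msg <- c(msg, "branch ids must be unique")
  known <- b$parent %in% b$id | is.na(b$parent)
  if (!all(known)) msg <- c(msg, "every parent id must exist in the tree")
  if (!any(is.na(b$parent))) msg <- c(msg, "tree must contain at least one root")
  if (any(b$id == b$parent, na.rm = TRUE)) msg <- c(msg, "self-parenting branch")
  if (any(b$length <= 0, na.rm = TRUE)) msg <- c(msg, "branch lengths must be > 0")
  if (any(b$diameter <= 0, na.rm = TRUE))
    msg <- c(msg, "assigned diameters must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' GrowthConfig: every expansion rule threshold as an explicit parameter
#'
#' Defaults reproduce the published growth conditions: child length set at 40%
#' of the distance from the parent end-point to the sub-space centre of
#' volume, length clamp L_child <= 1.5 L_parent, diameter D = L/3 clamped to
#' D_child <= 0.95 D_parent, branching-angle cap 75 degrees, terminal
#' bronchiole length threshold 1.4 mm and acinar-volume threshold 233.75 mm^3.
#'
#' @slot lengthFraction fraction of the parent-end-to-centroid distance used
#'   as the proposed child length (default 0.4).
#' @slot lRatioMax maximum child/parent length ratio (default 1.5).
#' @slot ldRatio length-to-diameter ratio used to set diameters, D = L/ldRatio
#'   (default 3).
#' @slot dRatioMax maximum child/parent diameter ratio (default 0.95).
#' @slot thetaMax branching-angle cap in degrees (default 75).
#' @slot lTB terminal-bronchiole length threshold in mm (default 1.4).
#' @slot vAcThreshold acinar (sub-space) volume threshold in mm^3
#'   (default 233.75).
#' @slot reassignIterations number of seed re-assignment iterations per
#'   bifurcation (default 1).
#' @slot maxDepth safety cap on generated depth below a starting leaf.
#' @slot terminalRule "or" (either criterion terminates, default) or "and"
#'   (both required).
#' @export
setClass("GrowthConfig",
  representation(lengthFraction = "numeric", lRatioMax = "numeric",
                 ldRatio = "numeric", dRatioMax = "numeric",
                 thetaMax = "numeric", lTB = "numeric",
                 vAcThreshold = "numeric", reassignIterations = "integer",
                 maxDepth = "integer", terminalRule = "character"))

setValidity("GrowthConfig", function(object) {
  msg <- NULL
  num <- c(object@lengthFraction, object@lRatioMax, object@ldRatio,
           object@dRatioMax, object@thetaMax, object@lTB, object@vAcThreshold)
  if (any(!is.finite(num)) || any(num <= 0))
    msg <- c(msg, "all numeric thresholds must be positive and finite")
  if (object@thetaMax > 90) msg <- c(msg, "thetaMax must be <= 90 degrees")
  if (object@reassignIterations < 0L) msg <- c(msg, "reassignIterations must be >= 0")
  if (object@maxDepth < 1L) msg <- c(msg, "maxDepth must be >= 1")
  if (!object@terminalRule %in% c("or", "and"))
    msg <- c(msg, 'terminalRule must be "or" or "and"')
  if (is.null(msg)) TRUE else msg
})

#' Create a growth configuration
#'
#' @param lengthFraction,lRatioMax,ldRatio,dRatioMax,thetaMax,lTB,vAcThreshold
#'   see \linkS4class{GrowthConfig}.
#' @param reassignIterations number of per-bifurcation seed re-assignment
#'   iterations (0 keeps the raw plane partition).
#' @param maxDepth safety cap on generated depth.
#' @param terminalRule "or" or "and" combination of the length and volume
#'   stopping criteria.
#' @return a \linkS4class{GrowthConfig}.
#' @examples
#' cfg <- growthConfig()
#' cfg@lTB
#' @export
growthConfig <- function(lengthFraction = 0.4, lRatioMax = 1.5, ldRatio = 3,
                         dRatioMax = 0.95, thetaMax = 75, lTB = 1.4,
                         vAcThreshold = 233.75, reassignIterations = 1L,
                         maxDepth = 60L, terminalRule = c("or", "and")) {
  new("GrowthConfig", lengthFraction = lengthFraction, lRatioMax = lRatioMax,
      ldRatio = ldRatio, dRatioMax = dRatioMax, thetaMax = thetaMax,
      lTB = lTB, vAcThreshold = vAcThreshold,
      reassignIterations = as.integer(reassignIterations),
      maxDepth = as.integer(maxDepth),
      terminalRule = match.arg(terminalRule))
}

#' Construct a SeedSet
#'
#' @param points n x 3 matrix of mm coordinates.
#' @param volumePerSeed mm^3 represented by each seed.
#' @param lobeLabel lobe label of origin.
#' @param sourceVoxelCount voxel count the set represents.
#' @return a \linkS4class{SeedSet}.
#' @export
seedSet <- function(points, volumePerSeed, lobeLabel = 1L,
                    sourceVoxelCount = nrow(points)) {
  points <- matrix(as.numeric(points), ncol = 3L,
                   dimnames = list(NULL, c("x", "y", "z")))
  new("SeedSet", points = points, volumePerSeed = volumePerSeed,
      lobeLabel = as.integer(lobeLabel),
      sourceVoxelCount = as.numeric(sourceVoxelCount))
}

#' Construct an AirwayTree from a branch table
#'
#' Missing optional columns (\code{angle}, \code{subspace_volume},
#' \code{lobe}) are filled with NA.
#'
#' @param branches branch data.frame, see \linkS4class{AirwayTree}.
#' @return an \linkS4class{AirwayTree}.
#' @export
airwayTree <- function(branches) {
  for (col in c("angle", "subspace_volume", "lobe"))
    if (is.null(branches[[col]])) branches[[col]] <- NA_real_
  branches$id <- as.integer(branches$id)
  branches$parent <- as.integer(branches$parent)
  branches$generation <- as.integer(branches$generation)
  branches$terminal <- as.logical(branches$terminal)
  branches$provenance <- as.character(branches$provenance)
  branches <- branches[, .BRANCH_COLS]
  rownames(branches) <- NULL
  new("AirwayTree", branches = branches)
}
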