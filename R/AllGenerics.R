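#' Branch table of an AirwayTree
#' @param x an \linkS4class{AirwayTree}.
#' @return data.frame of branches, one row per airway segment.
#' @export
setGeneric("branches", function(x) standardGeneric("branches"))

#' @rdname branches
#' @export
setMethod("branches", "AirwayTree", function(x) x@branches)

#' Number of branches
#' @param x an \linkS4class{AirwayTree}.
#' @return integer branch count.
#' @export
setGeneric("nBranches", function(x) standardGeneric("nBranches"))

#' @rdname nBranches
#' @export
setMethod("nBranches", "AirwayTree", function(x) nrow(x@branches))

#' Ids of leaf branches (no children)
#'
#' @param x an \linkS4class{AirwayTree}.
#' @param unflaggedOnly if TRUE (default FALSE) return only leafs not flagged
#'   terminal, i.e. those still eligible for expansion.
#' @return integer vector of branch ids.
#' @export
setGeneric("leafIds", function(x, unflaggedOnly = FALSE) standardGeneric("leafIds"))

#' @rdname leafIds
#' @export
setMethod("leafIds", "AirwayTree", function(x, unflaggedOnly = FALSE) {
  b <- x@branches
  out <- b$id[!(b$id %in% b$parent)]
  if (unflaggedOnly) out <- out[!b$terminal[match(out, b$id)]]
  sort(out)
})

#' Ids of terminal (flagged) branches
#' @param x an \linkS4class{AirwayTree}.
#' @return integer vector of branch ids flagged terminal.
#' @export
setGeneric("terminalIds", function(x) standardGeneric("terminalIds"))

#' @rdname terminalIds
#' @export
setMethod("terminalIds", "AirwayTree", function(x) sort(x@branches$id[x@branches$terminal]))

#' Voxel spacing in mm
#' @param x a \linkS4class{LobeMask}.
#' @return numeric(3) spacing.
#' @export
setGeneric("maskSpacing", function(x) standardGeneric("maskSpacing"))

#' @rdname maskSpacing
#' @export
setMethod("maskSpacing", "LobeMask", function(x) x@spacing)

#' Physical origin (centre of voxel (0,0,0)) in mm
#' @param x a \linkS4class{LobeMask}.
#' @return numeric(3) origin.
#' @export
setGeneric("maskOrigin", function(x) standardGeneric("maskOrigin"))

#' @rdname maskOrigin
#' @export
setMethod("maskOrigin", "LobeMask", function(x) x@origin)

#' Label array of a LobeMask
#' @param x a \linkS4class{LobeMask}.
#' @return 3D integer array.
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))

#' @rdname maskLabels
#' @export
setMethod("maskLabels", "LobeMask", function(x) x@labels)

#' Physical volume of one voxel in mm^3
#' @param x a \linkS4class{LobeMask}.
#' @return scalar mm^3.
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @rdname voxelVolume
#' @export
setMethod("voxelVolume", "LobeMask", function(x) prod(x@spacing))

#' Voxel volume of a lobe (or of all foreground)
#' @param x a \linkS4class{LobeMask}.
#' @param label lobe label; if NULL, all non-zero voxels.
#' @return volume in mm^3.
#' @export
setGeneric("lobeVolume", function(x, label = NULL) standardGeneric("lobeVolume"))

#' @rdname lobeVolume
#' @export
setMethod("lobeVolume", "LobeMask", function(x, label = NULL) {
  n <- if (is.null(label)) sum(x@labels > 0L) else sum(x@labels == label)
  n * prod(x@spacing)
})

#' Seed coordinates
#' @param x a \linkS4class{SeedSet}.
#' @return n x 3 matrix of mm coordinates.
#' @export
setGeneric("seedPoints", function(x) standardGeneric("seedPoints"))

#' @rdname seedPoints
#' @export
setMethod("seedPoints", "SeedSet", function(x) x@points)

#' Number of seeds
#' @param x a \linkS4class{SeedSet}.
#' @return integer count.
#' @export
setGeneric("nSeeds", function(x) standardGeneric("nSeeds"))

#' @rdname nSeeds
#' @export
setMethod("nSeeds", "SeedSet", function(x) nrow(x@points))

#' Volume represented by each seed (mm^3)
#' @param x a \linkS4class{SeedSet}.
#' @return scalar mm^3.
#' @export
setGeneric("volumePerSeed", function(x) standardGeneric("volumePerSeed"))

#' @rdname volumePerSeed
#' @export
setMethod("volumePerSeed", "SeedSet", function(x) x@volumePerSeed)

#' Total represented volume of a seed set (mm^3)
#' @param x a \linkS4class{SeedSet}.
#' @return scalar mm^3.
#' @export
setGeneric("seedVolume", function(x) standardGeneric("seedVolume"))

#' @rdname seedVolume
#' @export
setMethod("seedVolume", "SeedSet", function(x) nrow(x@points) * x@volumePerSeed)

setMethod("show", "AirwayTree", function(object) {
  b <- object@branches
  cat("AirwayTree with", nrow(b), "branches\n")
  if (nrow(b)) {
    cat("  generations:", min(b$generation), "-", max(b$generation), "\n")
    cat("  terminals:", sum(b$terminal),
        "| generated:", sum(b$provenance == "generated"),
        "| segmented:", sum(b$provenance == "segmented"), "\n")
    sv <- b$subspace_volume[b$terminal]
    if (any(!is.na(sv)))
      cat(sprintf("  terminal sub-space volume: mean %.1f mm^3\n",
                  mean(sv, na.rm = TRUE)))
  }
})

setMethod("show", "LobeMask", function(object) {
  d <- dim(object@labels)
  labs <- sort(unique(object@labels[object@labels > 0L]))
  cat("LobeMask", paste(d, collapse = " x "),
      sprintf("voxels @ (%.3g, %.3g, %.3g) mm\n",
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat("  lobes:", paste(labs, collapse = ", "),
      sprintf("| foreground volume %.4g mm^3\n", lobeVolume(object)))
})

setMethod("show", "SeedSet", function(object) {
  cat(sprintf("SeedSet: %d seeds x %.4g mm^3 (lobe %d, total %.4g mm^3)\n",
              nrow(object@points), object@volumePerSeed, object@lobeLabel,
              seedVolume(object)))
})

setMethod("show", "GrowthConfig", function(object) {
  cat("GrowthConfig:\n")
  cat(sprintf("  length fraction %.2f | L_child <= %.2f L_parent | D = L/%.2f, D_child <= %.2f D_parent\n",
              object@lengthFraction, object@lRatioMax, object@ldRatio,
              object@dRatioMax))
  cat(sprintf("  theta cap %.1f deg | L_TB %.2f mm | V_ac %.2f mm^3 (%s rule) | reassign i = %d\n",
              object@thetaMax, object@lTB, object@vAcThreshold,
              object@terminalRule, object@reassignIterations))
})

setMethod("show", "SplitPlane", function(object) {
  cat(sprintf("SplitPlane through (%.3g, %.3g, %.3g), normal (%.3g, %.3g, %.3g)\n",
              object@point[1], object@point[2], object@point[3],
              object@normal[1], object@normal[2], object@normal[3]))
})
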