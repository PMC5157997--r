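.MORPH_FIELDS <- c("Airway_ID", "Vida_Name", "CenterLineLength", "Diameter",
                   "Branching_Angle", "VidaGeneration", "xs", "ys", "zs",
                   "xe", "ye", "ze", "Adept_Names", "Generation", "RootFlag",
                   "SpaceVolume")

#' Write an airway tree as morphology + connectivity files
#'
#' The morphology file is tab-separated with a header row and one row per
#' airway: Airway_ID, Vida_Name (\"0\" for generated branches),
#' CenterLineLength (mm), Diameter (mm), Branching_Angle (degrees),
#' VidaGeneration, xs ys zs xe ye ze (start/end coordinates in voxels),
#' Adept_Names, Generation, RootFlag (1 for flagged leafs), SpaceVolume
#' (supplied sub-space volume in mm^3, written for terminals, -1 where
#' unknown). The
#' connectivity (dico) file lists one \"child_id parent_id\" pair per line.
#' Coordinates are converted from mm to voxels with the supplied spacing and
#' origin. Floating-point fields are printed with 6 decimals; a re-read is
#' identical at that precision.
#'
#' @param tree an \linkS4class{AirwayTree}.
#' @param morphologyPath,dicoPath output paths.
#' @param spacing,origin voxel geometry used for the mm-to-voxel conversion.
#' @return invisibly, c(morphologyPath, dicoPath).
#' @export
writeMorphology <- function(tree, morphologyPath, dicoPath,
                            spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  b <- branches(tree)
  vox <- function(x, k) (x - origin[k]) / spacing[k]
  fmt <- function(x) sprintf("%.6f", x)
  df <- data.frame(
    Airway_ID = b$id,
    Vida_Name = ifelse(b$provenance == "segmented", paste0("seg_", b$id), "0"),
    CenterLineLength = fmt(b$length),
    Diameter = fmt(b$diameter),
    Branching_Angle = fmt(ifelse(is.na(b$angle), -1, b$angle)),
    VidaGeneration = b$generation,
    xs = fmt(vox(b$sx, 1L)), ys = fmt(vox(b$sy, 2L)), zs = fmt(vox(b$sz, 3L)),
    xe = fmt(vox(b$ex, 1L)), ye = fmt(vox(b$ey, 2L)), ze = fmt(vox(b$ez, 3L)),
    Adept_Names = ifelse(b$provenance == "segmented",
                         paste0("seg_", b$id), paste0("gen_", b$id)),
    Generation = b$generation,
    RootFlag = as.integer(b$terminal),
    SpaceVolume = fmt(ifelse(b$terminal & !is.na(b$subspace_volume),
                             b$subspace_volume, -1)))
  utils::write.table(df, morphologyPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pairs <- b[!is.na(b$parent), c("id", "parent")]
  writeLines(paste(pairs$id, pairs$parent), dicoPath)
  invisible(c(morphologyPath, dicoPath))
}

#' Read an airway tree from morphology + connectivity files
#'
#' Inverse of \code{\link{writeMorphology}}: geometry comes from the
#' morphology rows (voxel coordinates converted to mm via spacing and
#' origin), connectivity from the dico file's explicit child-parent pairs,
#' leaf flags from RootFlag. Orphan branches, cyclic connectivity and
#' missing fields raise format errors naming the offending row.
#'
#' @param morphologyPath,dicoPath input paths.
#' @param spacing,origin voxel geometry for the voxel-to-mm conversion.
#' @return an \linkS4class{AirwayTree}.
#' @export
readMorphology <- function(morphologyPath, dicoPath,
                           spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  df <- utils::read.table(morphologyPath, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  missing <- setdiff(.MORPH_FIELDS, names(df))
  if (length(missing))
    stop("morphology file lacks field(s): ", paste(missing, collapse = ", "))
  for (fld in c("CenterLineLength", "Diameter", "xs", "ys", "zs",
                "xe", "ye", "ze", "SpaceVolume", "Branching_Angle"))
    if (!is.numeric(df[[fld]]))
      stop("non-numeric value in field ", fld, " (row ",
           which(is.na(suppressWarnings(as.numeric(df[[fld]]))))[1L], ")")
  dico <- utils::read.table(dicoPath, col.names = c("child", "parent"))
  bad <- !(dico$child %in% df$Airway_ID)
  if (any(bad))
    stop("dico row ", which(bad)[1L], ": child id ", dico$child[which(bad)[1L]],
         " absent from morphology")
  badP <- !(dico$parent %in% df$Airway_ID)
  if (any(badP))
    stop("dico row ", which(badP)[1L], ": parent id ",
         dico$parent[which(badP)[1L]], " absent from morphology")
  if (anyDuplicated(dico$child))
    stop("dico assigns multiple parents to child ",
         dico$child[anyDuplicated(dico$child)])
  parent <- dico$parent[match(df$Airway_ID, dico$child)]
  mm <- function(x, k) x * spacing[k] + origin[k]
  ang <- df$Branching_Angle
  ang[ang < 0] <- NA_real_
  b <- data.frame(
    id = df$Airway_ID, parent = parent,
    sx = mm(df$xs, 1L), sy = mm(df$ys, 2L), sz = mm(df$zs, 3L),
    ex = mm(df$xe, 1L), ey = mm(df$ye, 2L), ez = mm(df$ze, 3L),
    length = df$CenterLineLength, diameter = df$Diameter, angle = ang,
    generation = df$Generation, terminal = df$RootFlag == 1L,
    provenance = ifelse(df$Vida_Name == "0", "generated", "segmented"),
    subspace_volume = ifelse(df$SpaceVolume >= 0, df$SpaceVolume, NA_real_),
    lobe = NA_real_)
  tree <- airwayTree(b)
  .topoOrder(branches(tree)) # raises on cycles/orphans
  tree
}

#' Write a LobeMask as a NIfTI volume
#'
#' @param mask a \linkS4class{LobeMask}.
#' @param path output path (.nii or .nii.gz).
#' @return invisibly, the path.
#' @export
writeLobeMask <- function(mask, path) {
  img <- RNifti::asNifti(mask@labels)
  RNifti::pixdim(img) <- mask@spacing
  img <- RNifti::updateNifti(img, list(
    qform_code = 2L,
    qoffset_x = mask@origin[1L], qoffset_y = mask@origin[2L],
    qoffset_z = mask@origin[3L]))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a LobeMask from a NIfTI volume
#'
#' @param path input path.
#' @return a \linkS4class{LobeMask}.
#' @export
readLobeMask <- function(path) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  labels <- array(as.integer(round(as.array(img))), dim = dim(img))
  new("LobeMask", labels = labels,
      spacing = as.numeric(hdr$pixdim[2:4]),
      origin = as.numeric(c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)))
}

#' Parse a flat key = value configuration file into a GrowthConfig
#'
#' Recognized keys mirror the \linkS4class{GrowthConfig} slot names
#' (lengthFraction, lRatioMax, ldRatio, dRatioMax, thetaMax, lTB,
#' vAcThreshold, reassignIterations, maxDepth, terminalRule). Blank lines
#' and lines starting with # are ignored.
#'
#' @param path configuration file path.
#' @return a \linkS4class{GrowthConfig}.
#' @export
readGrowthConfig <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1L]])
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  known <- c("lengthFraction", "lRatioMax", "ldRatio", "dRatioMax", "thetaMax",
             "lTB", "vAcThreshold", "reassignIterations", "maxDepth",
             "terminalRule")
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- as.list(vals)
  names(args) <- keys
  for (k in setdiff(keys, "terminalRule")) args[[k]] <- as.numeric(args[[k]])
  do.call(growthConfig, args)
}
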