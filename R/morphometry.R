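.meanSd <- function(x) {
  x <- x[!is.na(x)]
  c(mean = if (length(x)) mean(x) else NA_real_,
    sd = if (length(x) > 1L) stats::sd(x) else 0,
    n = length(x))
}

# per-branch direction matrix (end - start)
.dirs <- function(b) cbind(b$ex - b$sx, b$ey - b$sy, b$ez - b$sz)

#' Homothety (parent-child diameter) ratios
#'
#' The homothety ratio HR is the child-to-parent diameter ratio at a
#' bifurcation. The theoretical value 2^(-1/3) = 0.794 corresponds to
#' volume-preserving symmetric branching. The major child of a bifurcation
#' is the larger-diameter sibling (falling back to length on an exact
#' diameter tie; a tie in both excludes the pair from the major/minor split).
#'
#' @param tree an \linkS4class{AirwayTree}.
#' @param provenance evaluate ratios for children of this provenance
#'   ("generated", "segmented" or "all").
#' @return list with \code{ratios} (per-child vector), and mean/sd/n
#'   summaries \code{hr}, \code{hrMajor}, \code{hrMinor}.
#' @export
homothetyRatios <- function(tree, provenance = c("generated", "all", "segmented")) {
  provenance <- match.arg(provenance)
  b <- branches(tree)
  pRow <- match(b$parent, b$id)
  sel <- !is.na(pRow) & !is.na(b$diameter) & !is.na(b$diameter[pRow])
  if (provenance != "all") sel <- sel & b$provenance == provenance
  ratio <- b$diameter[sel] / b$diameter[pRow[sel]]
  # major/minor over bifurcations with exactly two selected children
  rows <- which(sel)
  byParent <- split(rows, b$parent[rows])
  maj <- min <- numeric(0)
  for (kids in byParent) {
    if (length(kids) != 2L) next
    d <- b$diameter[kids]; l <- b$length[kids]
    if (d[1L] == d[2L] && l[1L] == l[2L]) next # exact tie: excluded
    major <- if (d[1L] != d[2L]) which.max(d) else which.max(l)
    pd <- b$diameter[match(b$parent[kids[1L]], b$id)]
    maj <- c(maj, d[major] / pd)
    min <- c(min, d[-major] / pd)
  }
  list(ratios = ratio, hr = .meanSd(ratio), hrMajor = .meanSd(maj),
       hrMinor = .meanSd(min))
}

#' Branching angles of a tree
#'
#' Recomputes the parent-child centreline angle for every non-root branch
#' from the stored geometry.
#'
#' @param tree an \linkS4class{AirwayTree}.
#' @param provenance restrict to children of this provenance.
#' @return list(angles, stats = mean/sd/n).
#' @export
branchingAngles <- function(tree, provenance = c("generated", "all", "segmented")) {
  provenance <- match.arg(provenance)
  b <- branches(tree)
  pRow <- match(b$parent, b$id)
  sel <- !is.na(pRow)
  if (provenance != "all") sel <- sel & b$provenance == provenance
  d <- .dirs(b)
  ang <- rep(NA_real_, nrow(b))
  for (i in which(sel))
    ang[i] <- branchingAngle(d[pRow[i], ], d[i, ])
  list(angles = ang[sel], stats = .meanSd(ang[sel]))
}

#' Planar rotation angles between successive bifurcation planes
#'
#' Each bifurcation (a branch with exactly two children) defines a plane
#' through its two daughter directions. The rotation angle phi of a
#' bifurcation is the angle between its plane normal and the normal of its
#' parent's bifurcation plane, folded into [0, 180] degrees; daughters are
#' taken in id order so the normals are deterministic.
#'
#' @param tree an \linkS4class{AirwayTree}.
#' @param provenance restrict to bifurcations whose daughters have this
#'   provenance.
#' @return list(angles, stats = mean/sd/n).
#' @export
rotationAngles <- function(tree, provenance = c("generated", "all")) {
  provenance <- match.arg(provenance)
  b <- branches(tree)
  d <- .dirs(b)
  kids <- .childrenList(b)
  normals <- vector("list", nrow(b))
  for (i in seq_len(nrow(b))) {
    ki <- kids[[as.character(b$id[i])]]
    if (length(ki) != 2L) next
    ki <- ki[order(b$id[ki])]
    nrm <- .crossp(d[ki[1L], ], d[ki[2L], ])
    if (.vnorm(nrm) > 1e-12) normals[[i]] <- .unitv(nrm)
  }
  pRow <- match(b$parent, b$id)
  phi <- numeric(0)
  for (i in seq_len(nrow(b))) {
    if (is.null(normals[[i]]) || is.na(pRow[i]) || is.null(normals[[pRow[i]]]))
      next
    if (provenance == "generated") {
      ki <- kids[[as.character(b$id[i])]]
      if (!all(b$provenance[ki] == "generated")) next
    }
    a <- acos(max(-1, min(1, sum(normals[[i]] * normals[[pRow[i]]])))) * 180 / pi
    phi <- c(phi, a)
  }
  list(angles = phi, stats = .meanSd(phi))
}

#' Branching/diameter/length ratio from a log-linear fit over orders
#'
#' The classical RB/RD/RL measure: ordinary least squares of log10(value)
#' against order; the ratio is the antilog of the slope magnitude, reported
#' with the R^2 of the fit. When the single highest-order point has count 1
#' and is an outlier (|externally studentized residual| > 2) it is excluded
#' (deterministically) before fitting.
#'
#' @param tab data.frame with columns \code{order} and \code{value} (counts
#'   for RB, mean diameters for RD, mean lengths for RL); at least 3 orders
#'   with positive values.
#' @param dropRootOutlier apply the single-root-point exclusion rule (only
#'   meaningful for count data).
#' @return list(ratio, r2, slope, nOrders).
#' @examples
#' ratioFit(data.frame(order = 1:3, value = c(4, 2, 1)))$ratio # exactly 2
#' @export
ratioFit <- function(tab, dropRootOutlier = FALSE) {
  names(tab)[1:2] <- c("order", "value")
  tab <- tab[is.finite(tab$value) & tab$value > 0, , drop = FALSE]
  if (nrow(tab) < 3L) stop("ratio fit needs at least 3 orders with positive values")
  fit <- stats::lm(log10(value) ~ order, data = tab)
  if (dropRootOutlier && nrow(tab) > 3L) {
    top <- which.max(tab$order)
    if (tab$value[top] == 1) {
      rs <- stats::rstudent(fit)[top]
      if (is.finite(rs) && abs(rs) > 2) {
        tab <- tab[-top, , drop = FALSE]
        fit <- stats::lm(log10(value) ~ order, data = tab)
      }
    }
  }
  slope <- unname(stats::coef(fit)[2L])
  y <- log10(tab$value)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  list(ratio = 10^abs(slope), r2 = r2, slope = slope, nOrders = nrow(tab))
}

#' Acinus generation distance (AGR) statistics
#'
#' The AGR of a terminal bronchiole is the number of bifurcations between the
#' trachea and the terminal, i.e. its generation index. Statistics are given
#' overall and per lobe where lobe labels are available.
#'
#' @param tree an \linkS4class{AirwayTree} with terminals flagged.
#' @return data.frame with rows per lobe plus an "all" row; columns lobe,
#'   n, mean, sd, min, max.
#' @export
agrStats <- function(tree) {
  b <- branches(tree)
  g <- generations(tree)
  sel <- b$terminal
  agr <- g[sel]
  lobe <- b$lobe[sel]
  one <- function(x, name) {
    s <- .meanSd(x)
    data.frame(lobe = name, n = s[["n"]], mean = s[["mean"]], sd = s[["sd"]],
               min = if (length(x)) min(x) else NA, max = if (length(x)) max(x) else NA)
  }
  out <- one(agr, "all")
  if (any(!is.na(lobe)))
    for (lb in sort(unique(lobe[!is.na(lobe)])))
      out <- rbind(out, one(agr[!is.na(lobe) & lobe == lb], as.character(lb)))
  rownames(out) <- NULL
  out
}

#' Normalize an order-count table onto a common order range
#'
#' Trees of different depth are compared by rescaling orders linearly onto
#' [1, targetMax] and interpolating log10(count) at the integer target
#' orders; endpoint counts are preserved.
#'
#' @param tab data.frame(order, count) over at least 2 orders.
#' @param targetMax maximum order of the normalized range.
#' @return data.frame(order = 1..targetMax, count).
#' @export
normalizeOrders <- function(tab, targetMax) {
  names(tab)[1:2] <- c("order", "count")
  stopifnot(nrow(tab) >= 2L, targetMax >= 2)
  o <- tab$order
  x <- 1 + (o - min(o)) / (max(o) - min(o)) * (targetMax - 1)
  y <- stats::approx(x, log10(tab$count), xout = seq_len(targetMax))$y
  data.frame(order = seq_len(targetMax), count = 10^y)
}

#' Full morphometric summary of a grown tree
#'
#' Computes every validation statistic in one pass: per-generation and
#' per-order tables of diameter, length and branching angle; homothety
#' ratios (overall, major, minor); mean L/D with its frequency distribution
#' (bins 2.5-3.5, 3.5-4.5, 4.5-5.5); branching-angle distribution in 15
#' degree bins; planar rotation angles; terminal-bronchiole diameter,
#' length and acinar-volume statistics with a V_ac histogram; RB/RD/RL
#' log-linear fits under Horsfield and Strahler ordering; AGR statistics;
#' and the number of acini (= terminal branches).
#'
#' @param tree a grown \linkS4class{AirwayTree}.
#' @param provenance branch set used for the angle/L/D/HR statistics
#'   ("generated" default, or "all").
#' @param vacBinWidth acinar-volume histogram bin width in mm^3.
#' @return a named list (see Details in the vignette).
#' @export
summarizeTree <- function(tree, provenance = c("generated", "all"),
                          vacBinWidth = 33.2) {
  provenance <- match.arg(provenance)
  b <- branches(tree)
  g <- generations(tree)
  uh <- horsfieldOrders(tree)
  us <- strahlerOrders(tree)
  angs <- branchingAngles(tree, provenance)
  selAng <- if (provenance == "all") !is.na(match(b$parent, b$id)) else
    b$provenance == provenance & !is.na(match(b$parent, b$id))
  angAll <- rep(NA_real_, nrow(b)); angAll[selAng] <- angs$angles
  sel <- if (provenance == "all") rep(TRUE, nrow(b)) else b$provenance == provenance
  perTable <- function(key, keySel) {
    out <- do.call(rbind, lapply(sort(unique(key[keySel])), function(k) {
      r <- keySel & key == k
      dm <- .meanSd(b$diameter[r]); lm <- .meanSd(b$length[r])
      am <- .meanSd(angAll[r & selAng])
      data.frame(order = k, n = sum(r), d_mean = dm[["mean"]], d_sd = dm[["sd"]],
                 l_mean = lm[["mean"]], l_sd = lm[["sd"]],
                 theta_mean = am[["mean"]], theta_sd = am[["sd"]])
    }))
    rownames(out) <- NULL
    out
  }
  perGeneration <- perTable(g, sel)
  perHorsfield <- perTable(uh, rep(TRUE, nrow(b)))
  perStrahler <- perTable(us, rep(TRUE, nrow(b)))
  hr <- homothetyRatios(tree, if (provenance == "all") "all" else "generated")
  ld <- b$length[sel] / b$diameter[sel]
  ld <- ld[is.finite(ld)]
  ldBins <- c(sum(ld >= 2.5 & ld < 3.5), sum(ld >= 3.5 & ld < 4.5),
              sum(ld >= 4.5 & ld < 5.5))
  ldDist <- data.frame(bin = c("2.5-3.5", "3.5-4.5", "4.5-5.5"),
                       fraction = ldBins / max(1L, length(ld)))
  thetaBreaks <- seq(0, 180, by = 15)
  thetaHist <- table(cut(angs$angles, thetaBreaks, right = FALSE))
  phi <- rotationAngles(tree, if (provenance == "all") "all" else "generated")
  tb <- b$terminal
  vac <- b$subspace_volume[tb]
  vac <- vac[!is.na(vac) & vac > 0]
  vacBreaks <- seq(0, max(vacBinWidth * 20, max(vac, 0) + vacBinWidth),
                   by = vacBinWidth)
  vacHist <- table(cut(vac, vacBreaks, right = FALSE))
  # terminals stopped by the length rule despite an over-threshold volume
  cfg <- growthConfig()
  lenRule <- sum(b$length[tb] < cfg@lTB & !is.na(b$subspace_volume[tb]) &
                   b$subspace_volume[tb] >= cfg@vAcThreshold)
  fits <- list()
  for (sc in c("horsfield", "strahler")) {
    u <- if (sc == "horsfield") uh else us
    cnt <- countByOrder(tree, sc)
    per <- if (sc == "horsfield") perHorsfield else perStrahler
    fits[[sc]] <- list(
      RB = tryCatch(ratioFit(cnt, dropRootOutlier = TRUE), error = function(e) NULL),
      RD = tryCatch(ratioFit(data.frame(order = per$order, value = per$d_mean)),
                    error = function(e) NULL),
      RL = tryCatch(ratioFit(data.frame(order = per$order, value = per$l_mean)),
                    error = function(e) NULL))
  }
  list(
    nBranches = nrow(b), nAcini = sum(tb),
    perGeneration = perGeneration, perHorsfield = perHorsfield,
    perStrahler = perStrahler,
    hr = hr$hr, hrMajor = hr$hrMajor, hrMinor = hr$hrMinor,
    theta = angs$stats, thetaHist = thetaHist,
    phi = phi$stats,
    ld = .meanSd(ld), ldDist = ldDist,
    dTB = .meanSd(b$diameter[tb]), lTB = .meanSd(b$length[tb]),
    vAc = .meanSd(vac), vAcHist = vacHist,
    terminalsByLengthRule = lenRule,
    agr = agrStats(tree),
    ratios = fits)
}

#' Plot branch counts against order on a log scale
#'
#' @param tree an \linkS4class{AirwayTree}.
#' @param scheme ordering scheme.
#' @param ... passed to \code{plot}.
#' @return invisibly, the count table.
#' @export
plotCountsByOrder <- function(tree, scheme = c("strahler", "horsfield"), ...) {
  scheme <- match.arg(scheme)
  tab <- countByOrder(tree, scheme)
  graphics::plot(tab$order, tab$count, log = "y", type = "b", pch = 19,
                 xlab = paste(scheme, "order"), ylab = "number of branches", ...)
  invisible(tab)
}
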