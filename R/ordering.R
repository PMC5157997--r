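#' Generation numbers (trachea = 0)
#'
#' Generations count bifurcation depth from the stem: the root is generation
#' 0 and every child is one generation higher than its parent. Segmented
#' branches that carry an externally supplied (e.g. Boyden-based) generation
#' keep it when \code{preserveSegmented} is TRUE.
#'
#' @param tree an \linkS4class{AirwayTree}.
#' @param preserveSegmented keep stored generations on segmented branches.
#' @return integer vector of generations, in branch-table row order.
#' @export
generations <- function(tree, preserveSegmented = TRUE) {
  b <- branches(tree)
  g <- rep(NA_integer_, nrow(b))
  ord <- .topoOrder(b)
  pRow <- match(b$parent, b$id)
  for (i in ord) {
    if (preserveSegmented && b$provenance[i] == "segmented" &&
        !is.na(b$generation[i])) {
      g[i] <- b$generation[i]
    } else if (is.na(b$parent[i]) || is.na(pRow[i])) {
      g[i] <- 0L
    } else {
      g[i] <- g[pRow[i]] + 1L
    }
  }
  g
}

# rows in root-to-leaf (topological) order; errors on cycles
.topoOrder <- function(b) {
  n <- nrow(b)
  pRow <- match(b$parent, b$id)
  depth <- rep(NA_integer_, n)
  frontier <- which(is.na(pRow))
  depth[frontier] <- 0L
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    frontier <- which(pRow %in% frontier & is.na(depth))
    depth[frontier] <- d
    if (d > n) stop("cyclic connectivity in airway tree")
  }
  if (anyNA(depth)) stop("orphan branches disconnected from any root")
  order(depth)
}

.childrenList <- function(b) split(seq_len(nrow(b)), factor(b$parent, levels = b$id))

#' Horsfield orders
#'
#' Leafs take order 1; every parent takes one plus the maximum order among
#' its children. Trifurcations (possible in segmented input) use the same
#' max-over-children rule.
#'
#' @param tree an \linkS4class{AirwayTree}.
#' @return integer vector of Horsfield orders, in branch-table row order.
#' @export
horsfieldOrders <- function(tree) {
  .leafUpOrders(branches(tree), strahler = FALSE)
}

#' Strahler orders
#'
#' Leafs take order 1; a parent is one higher than its two children of the
#' same (maximal) order, or else takes the order of the highest-order child.
#' With more than two children the order increments iff at least two children
#' attain the maximum.
#'
#' @param tree an \linkS4class{AirwayTree}.
#' @return integer vector of Strahler orders, in branch-table row order.
#' @export
strahlerOrders <- function(tree) {
  .leafUpOrders(branches(tree), strahler = TRUE)
}

.leafUpOrders <- function(b, strahler) {
  ord <- rev(.topoOrder(b)) # leafs first
  kids <- .childrenList(b)
  u <- rep(NA_integer_, nrow(b))
  for (i in ord) {
    ki <- kids[[as.character(b$id[i])]]
    if (length(ki) == 0L) {
      u[i] <- 1L
    } else {
      m <- max(u[ki])
      u[i] <- if (strahler && sum(u[ki] == m) < 2L) m else m + 1L
    }
  }
  u
}

#' Count branches per order
#'
#' @param tree an \linkS4class{AirwayTree}.
#' @param scheme "horsfield", "strahler" or "generation".
#' @return data.frame(order, count); counts sum to the branch count.
#' @export
countByOrder <- function(tree, scheme = c("horsfield", "strahler", "generation")) {
  scheme <- match.arg(scheme)
  u <- switch(scheme,
              horsfield = horsfieldOrders(tree),
              strahler = strahlerOrders(tree),
              generation = generations(tree))
  tab <- table(u)
  data.frame(order = as.integer(names(tab)), count = as.integer(tab))
}
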