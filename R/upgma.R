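#' UPGMA ultrametric tree from a distance matrix
#'
#' Average-linkage agglomeration: at each step the pair of clusters at
#' minimal distance is merged at height distance/2, and the new cluster's
#' distance to every other cluster is the size-weighted average of its
#' members' distances. Ties are broken by the lexicographic order of the
#' competing pairs' smallest member labels (then the other member's label),
#' so the output is deterministic. Every leaf sits at height 0 and all
#' root-to-leaf path lengths are equal.
#'
#' @param d square symmetric numeric matrix with zero diagonal and
#'   non-negative entries (e.g. a divergence-time matrix in generations).
#' @param labels taxon labels; default the matrix dimnames.
#' @return nested-list tree of class \code{upgma_tree}; each internal node
#'   has \code{height}, \code{children} and \code{label} (its smallest leaf
#'   label), each leaf has \code{height = 0} and its \code{label}.
#' @export
upgma <- function(d, labels = rownames(d)) {
  d <- as.matrix(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  stopifnot(nrow(d) == ncol(d), length(labels) == nrow(d))
  if (any(is.na(d)) || any(d < 0))
    stop("distance matrix must be non-negative and complete")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero")
  n <- nrow(d)
  if (n == 1)
    return(structure(list(height = 0, label = labels[1]),
                     class = "upgma_tree"))
  nodes <- lapply(labels, function(l) list(height = 0, label = l))
  sizes <- rep(1L, n)
  active <- seq_len(n)
  dd <- d
  dimnames(dd) <- NULL
  while (length(active) > 1) {
    k <- length(active)
    best <- NULL
    for (ai in seq_len(k - 1)) for (aj in (ai + 1):k) {
      i <- active[ai]; j <- active[aj]
      cand <- list(dist = dd[i, j], i = i, j = j)
      lab <- sort(c(nodes[[i]]$label, nodes[[j]]$label))
      cand$key <- paste(lab, collapse = "\r")
      if (is.null(best) || cand$dist < best$dist - 1e-15 ||
          (abs(cand$dist - best$dist) <= 1e-15 && cand$key < best$key))
        best <- cand
    }
    i <- best$i; j <- best$j
    new_node <- list(height = best$dist / 2,
                     children = list(nodes[[i]], nodes[[j]]),
                     label = min(nodes[[i]]$label, nodes[[j]]$label))
    # size-weighted average distance to remaining clusters
    for (m in setdiff(active, c(i, j))) {
      dm <- (sizes[i] * dd[i, m] + sizes[j] * dd[j, m]) /
        (sizes[i] + sizes[j])
      dd[i, m] <- dd[m, i] <- dm
    }
    nodes[[i]] <- new_node
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  structure(nodes[[active]], class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("upgma_tree, root height", x$height, "\n")
  cat(write_newick(x), "\n")
  invisible(x)
}

#' Leaf labels of an UPGMA tree
#' @param tree an \code{upgma_tree}.
#' @return character vector of leaf labels.
#' @export
tree_leaves <- function(tree) {
  if (is.null(tree$children)) return(tree$label)
  unlist(lapply(tree$children, tree_leaves))
}

#' Serialize an UPGMA tree as Newick text
#'
#' Branch lengths are height differences; children are ordered by their
#' subtree label (smallest leaf label first), so the string is canonical:
#' permuting the input matrix leaves it unchanged.
#'
#' @param tree an \code{upgma_tree}.
#' @param units \code{"generations"} (as stored) or \code{"years"}
#'   (multiplies every branch length by \code{generation_years}).
#' @param generation_years years per generation for the unit conversion.
#' @param digits significant digits for branch lengths.
#' @return Newick string terminated by \code{";"}.
#' @export
write_newick <- function(tree, units = c("generations", "years"),
                         generation_years = 25, digits = 10) {
  units <- match.arg(units)
  mult <- if (units == "years") generation_years else 1
  fmt <- function(x) format(x * mult, digits = digits, trim = TRUE,
                            scientific = FALSE)
  rec <- function(node, parent_height) {
    bl <- fmt(parent_height - node$height)
    if (is.null(node$children)) return(paste0(node$label, ":", bl))
    kids <- node$children[order(vapply(node$children, `[[`, "", "label"))]
    inner <- paste(vapply(kids, rec, "", parent_height = node$height),
                   collapse = ",")
    paste0("(", inner, "):", bl)
  }
  if (is.null(tree$children))
    return(paste0(tree$label, ";"))
  kids <- tree$children[order(vapply(tree$children, `[[`, "", "label"))]
  inner <- paste(vapply(kids, rec, "", parent_height = tree$height),
                 collapse = ",")
  paste0("(", inner, ");")
}

#' Node heights of all leaves measured from the root
#'
#' Utility for ultrametricity checks: the root-to-leaf path length for every
#' leaf.
#'
#' @param tree an \code{upgma_tree}.
#' @return named numeric vector, one entry per leaf.
#' @export
leaf_depths <- function(tree) {
  rec <- function(node, acc) {
    if (is.null(node$children))
      return(stats::setNames(acc, node$label))
    unlist(lapply(node$children,
                  function(ch) rec(ch, acc + node$height - ch$height)))
  }
  rec(tree, 0)
}
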