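#' Rooted local genealogy at one genomic position
#'
#' A `local_tree` is the marginal coalescent tree applying to one
#' non-recombined segment of the genome: a rooted tree whose node times are
#' ages in generations (leaves are typically at time 0) and whose leaves are
#' labelled by haplotype identifiers.
#'
#' @param parent integer vector; `parent[v]` is the parent node of `v`,
#'   `NA` for the root. Node ids are `1..length(parent)`.
#' @param time numeric vector of node ages in generations, same length as
#'   `parent`; every parent must be at least as old as its children.
#' @param labels character vector of leaf labels. Either of length equal to
#'   the number of nodes (with `NA` at internal nodes) or of length equal to
#'   the number of leaves, assigned to leaves in node-id order.
#' @param position optional focal genomic position (0-based, bp).
#' @param interval optional length-2 numeric, the left-closed right-open
#'   genomic interval over which this genealogy applies.
#'
#' @return an object of class `local_tree`.
#' @export
local_tree <- function(parent, time, labels, position = NULL,
                       interval = NULL) {
  parent <- as.integer(parent)
  nn <- length(parent)
  stopifnot(length(time) == nn)
  leaf <- !(seq_len(nn) %in% parent)
  full_labels <- rep(NA_character_, nn)
  if (length(labels) == nn) {
    full_labels <- as.character(labels)
  } else if (length(labels) == sum(leaf)) {
    full_labels[leaf] <- as.character(labels)
  } else {
    stop("labels must cover either all nodes or exactly the leaves")
  }
  x <- structure(
    list(parent = parent, time = as.numeric(time), labels = full_labels,
         position = position, interval = interval),
    class = "local_tree")
  validate_local_tree(x)
  x
}

#' Validate a local genealogy
#'
#' Checks the `local_tree` invariants: a single root, no cycles, parent
#' times no younger than child times, non-negative times, and unique
#' non-missing leaf labels.
#'
#' @param x a `local_tree`.
#' @return `x`, invisibly; errors otherwise.
#' @export
validate_local_tree <- function(x) {
  parent <- x$parent
  nn <- length(parent)
  root <- which(is.na(parent))
  if (length(root) != 1L)
    stop("tree must have exactly one root, found ", length(root))
  if (any(parent[!is.na(parent)] < 1L | parent[!is.na(parent)] > nn))
    stop("parent id out of range")
  # cycle check: every node must reach the root
  depth <- rep(NA_integer_, nn)
  depth[root] <- 0L
  for (v in seq_len(nn)) {
    w <- v
    seen <- integer(0)
    while (is.na(depth[w])) {
      seen <- c(seen, w)
      w <- parent[w]
      if (length(seen) > nn) stop("tree contains a cycle")
    }
    if (length(seen)) depth[seen] <- depth[w] + rev(seq_along(seen))
  }
  if (any(x$time < 0)) stop("node times must be non-negative")
  kids <- !is.na(parent)
  if (any(x$time[parent[kids]] < x$time[kids]))
    stop("a parent node is younger than its child")
  leaf <- is_leaf(x)
  labs <- x$labels[leaf]
  if (anyNA(labs)) stop("every leaf must be labelled")
  if (anyDuplicated(labs)) stop("leaf labels must be unique")
  invisible(x)
}

is_leaf <- function(x) !(seq_along(x$parent) %in% x$parent)

root_node <- function(x) which(is.na(x$parent))

#' @export
print.local_tree <- function(x, ...) {
  leaf <- is_leaf(x)
  cat("<local_tree> ", sum(leaf), " leaves, ", length(x$parent), " nodes, ",
      "root age ", format(x$time[root_node(x)]), " generations\n", sep = "")
  if (!is.null(x$position)) cat("  position: ", x$position, "\n", sep = "")
  invisible(x)
}

#' Number of leaves of a local genealogy
#' @param x a `local_tree`.
#' @return integer.
#' @export
n_leaves <- function(x) sum(is_leaf(x))

#' Leaf labels of a local genealogy, in node-id order
#' @param x a `local_tree`.
#' @return character vector.
#' @export
leaf_labels <- function(x) x$labels[is_leaf(x)]

#' Convert an ape "phylo" tree to a local genealogy
#'
#' Branch lengths are interpreted as time differences in generations; the
#' age of a node is the longest path from the node down to any descendant
#' leaf, so ultrametric trees get their exact coalescent times and leaves
#' sit at time 0.
#'
#' @param phy an [ape::read.tree()] style `phylo` object with edge lengths.
#' @param position optional focal position (bp).
#' @return a `local_tree`. Tips keep ape's ordering (nodes `1..n`).
#' @export
as_local_tree <- function(phy, position = NULL) {
  if (!inherits(phy, "phylo")) stop("expected a 'phylo' object")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  nn <- ape::Ntip(phy) + phy$Nnode
  parent <- rep(NA_integer_, nn)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  blen <- rep(0, nn)
  blen[phy$edge[, 2]] <- phy$edge.length
  # node age = max path length to a descendant leaf (post-order over edges)
  time <- rep(0, nn)
  ord <- order(node_depths(parent), decreasing = TRUE)
  for (v in ord) {
    p <- parent[v]
    if (!is.na(p)) time[p] <- max(time[p], time[v] + blen[v])
  }
  labels <- rep(NA_character_, nn)
  labels[seq_len(ape::Ntip(phy))] <- phy$tip.label
  local_tree(parent, time, labels, position = position)
}

node_depths <- function(parent) {
  nn <- length(parent)
  depth <- rep(NA_integer_, nn)
  depth[is.na(parent)] <- 0L
  repeat {
    todo <- which(is.na(depth))
    if (!length(todo)) break
    ready <- todo[!is.na(depth[parent[todo]])]
    if (!length(ready)) stop("disconnected tree")
    depth[ready] <- depth[parent[ready]] + 1L
  }
  depth
}

#' Convert a local genealogy to an ape "phylo" tree
#' @param x a `local_tree`.
#' @return a `phylo` object with branch lengths in generations.
#' @export
as_phylo <- function(x) {
  leaf <- is_leaf(x)
  nn <- length(x$parent)
  ntip <- sum(leaf)
  # ape wants tips 1..ntip, root ntip+1, then internals
  internal <- which(!leaf)
  root <- root_node(x)
  internal <- c(root, setdiff(internal, root))
  remap <- integer(nn)
  remap[which(leaf)] <- seq_len(ntip)
  remap[internal] <- ntip + seq_along(internal)
  kids <- which(!is.na(x$parent))
  edge <- cbind(remap[x$parent[kids]], remap[kids])
  structure(list(
    edge = edge,
    edge.length = x$time[x$parent[kids]] - x$time[kids],
    tip.label = x$labels[leaf],
    Nnode = length(internal)), class = "phylo", order = NULL)
}

#' Read one-newick-per-line local genealogies
#'
#' Each line holds one rooted newick tree; branch lengths are time
#' differences in generations. Trees are keyed by SNP position, either taken
#' from `positions` or parsed from a leading `"<position> "` prefix on each
#' line; there is no interpolation between positions.
#'
#' @param path file with one newick string per line.
#' @param positions optional integer vector of focal positions (0-based bp),
#'   one per line.
#' @return a `tree_list` (see [local_tree_at()]).
#' @export
read_newick_trees <- function(path, positions = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (is.null(positions)) {
    m <- regmatches(lines, regexpr("^[0-9]+[[:space:]]+", lines))
    if (all(lengths(regmatches(lines, gregexpr("^[0-9]+[[:space:]]+", lines))) == 1L)) {
      positions <- as.numeric(trimws(m))
      lines <- sub("^[0-9]+[[:space:]]+", "", lines)
    } else {
      stop("positions not given and lines carry no '<position> ' prefix")
    }
  }
  stopifnot(length(positions) == length(lines))
  trees <- lapply(seq_along(lines), function(i) {
    phy <- ape::read.tree(text = lines[[i]])
    if (is.null(phy)) stop("cannot parse newick on line ", i)
    as_local_tree(phy, position = positions[[i]])
  })
  tree_list(trees, positions)
}

#' Apply node-time sanitation rules to a local genealogy
#'
#' Two cleaning rules for trees coming from numerical TMRCA estimates:
#' internal node times below `floor` are raised to `floor`, and an internal
#' child whose age is within `collapse_eps` of its parent's age is deleted,
#' its children reattached to the parent (creating polytomies). The
#' operation is idempotent and preserves the leaf set.
#'
#' @param x a `local_tree`.
#' @param floor minimal allowed internal node time (generations).
#' @param collapse_eps maximal parent-child age difference below which the
#'   child node is collapsed into the parent.
#' @return a sanitised `local_tree`.
#' @export
sanitize_times <- function(x, floor = 1e-12, collapse_eps = 1e-14) {
  parent <- x$parent
  time <- x$time
  labels <- x$labels
  leaf <- !(seq_along(parent) %in% parent)
  time[!leaf & time < floor] <- floor
  repeat {
    leaf <- !(seq_along(parent) %in% parent)
    drop <- which(!leaf & !is.na(parent) &
                  (time[parent] - time) <= collapse_eps)
    if (!length(drop)) break
    v <- drop[[1L]]
    parent[parent == v] <- parent[v]
    keep <- setdiff(seq_along(parent), v)
    remap <- integer(length(parent))
    remap[keep] <- seq_along(keep)
    parent <- remap[parent[keep]]
    parent[parent == 0L] <- NA_integer_
    # remap() of NA root stays NA through indexing
    time <- time[keep]
    labels <- labels[keep]
  }
  out <- structure(
    list(parent = parent, time = time, labels = labels,
         position = x$position, interval = x$interval),
    class = "local_tree")
  validate_local_tree(out)
  out
}

# Reorder node ids so that leaves come first, in the order of `labels`.
# Internal nodes follow in increasing original id. The C++ batch driver
# assumes this canonical layout.
canonical_leaf_order <- function(x, labels) {
  leaf <- is_leaf(x)
  idx <- match(labels, x$labels)
  if (anyNA(idx))
    stop("haplotypes absent from tree: ",
         paste(labels[is.na(idx)], collapse = ", "))
  if (length(idx) != sum(leaf))
    stop("tree has leaves not present among the haplotypes: ",
         paste(setdiff(x$labels[leaf], labels), collapse = ", "))
  internal <- which(!leaf)
  old <- c(idx, internal)
  remap <- integer(length(x$parent))
  remap[old] <- seq_along(old)
  parent <- remap[x$parent[old]]
  parent[is.na(x$parent[old])] <- NA_integer_
  structure(list(parent = parent, time = x$time[old],
                 labels = x$labels[old], position = x$position,
                 interval = x$interval),
            class = "local_tree")
}
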