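#' Succinct sequence of local genealogies along a chromosome
#'
#' Container for the marginal trees of an ancestral recombination graph:
#' each genomic interval (left-closed, right-open, 0-based) carries one
#' rooted tree with node times. All trees share the same node count and the
#' same leaf set (leaves are nodes `1..n`).
#'
#' @param parent integer matrix, nodes x trees; `NA` marks each tree's root.
#' @param time numeric matrix, nodes x trees, ages in generations.
#' @param left,right numeric vectors of interval bounds (bp).
#' @param labels character vector of leaf labels (leaves are nodes
#'   `1..length(labels)`).
#' @param sequence_length total sequence span (bp).
#' @return an object of class `tree_sequence`.
#' @export
tree_sequence <- function(parent, time, left, right, labels,
                          sequence_length) {
  stopifnot(is.matrix(parent), is.matrix(time),
            nrow(parent) == nrow(time), ncol(parent) == ncol(time),
            length(left) == ncol(parent), length(right) == ncol(parent))
  if (any(right <= left)) stop("empty interval in tree sequence")
  structure(list(parent = parent, time = time, left = left, right = right,
                 labels = labels, sequence_length = sequence_length),
            class = "tree_sequence")
}

#' @export
print.tree_sequence <- function(x, ...) {
  cat("<tree_sequence> ", length(x$labels), " haplotypes, ",
      ncol(x$parent), " stored trees, span ",
      format(x$sequence_length), " bp\n", sep = "")
  invisible(x)
}

#' A set of local genealogies keyed by SNP position
#'
#' Used when only per-SNP trees are available (e.g. one newick per SNP):
#' each tree answers exactly for its own position, with no interpolation.
#'
#' @param trees list of `local_tree`.
#' @param positions numeric vector of 0-based positions, one per tree.
#' @return an object of class `tree_list`.
#' @export
tree_list <- function(trees, positions) {
  stopifnot(length(trees) == length(positions))
  structure(list(trees = trees, positions = as.numeric(positions)),
            class = "tree_list")
}

#' Extract the local genealogy containing a genomic position
#'
#' Returns the marginal tree whose left-closed right-open interval contains
#' `position`, with node times copied from the source.
#'
#' @param x a tree source: `tree_sequence`, `tree_list`, or the result of
#'   [simulate_scenario()].
#' @param position 0-based genomic position (bp).
#' @return a `local_tree`.
#' @export
extract_local_tree <- function(x, position) local_tree_at(x, position)

#' @rdname extract_local_tree
#' @export
local_tree_at <- function(x, position) UseMethod("local_tree_at")

#' @export
local_tree_at.tree_sequence <- function(x, position) {
  if (position < 0 || position >= x$sequence_length)
    stop("position ", position, " outside the sequence span [0, ",
         x$sequence_length, ")")
  i <- which(x$left <= position & position < x$right)
  if (!length(i))
    stop("no stored tree covers position ", position,
         " (tree sequence holds mutated intervals only)")
  i <- i[[1L]]
  parent <- x$parent[, i]
  time <- x$time[, i]
  labels <- x$labels
  nleaf <- length(labels)
  if (isTRUE(x$prune)) {
    # table-built sequences carry every node of the full graph; keep the
    # nodes on paths from the sampled leaves to their root
    keep <- logical(length(parent))
    for (v in seq_len(nleaf)) {
      w <- v
      while (!is.na(w) && !keep[w]) {
        keep[w] <- TRUE
        w <- parent[w]
      }
    }
    idx <- which(keep)
    remap <- integer(length(parent))
    remap[idx] <- seq_along(idx)
    parent <- remap[parent[idx]]
    parent[parent == 0L] <- NA_integer_
    time <- time[idx]
  }
  nroots <- sum(is.na(parent))
  if (nroots != 1L)
    stop("marginal tree at position ", position, " has ", nroots,
         " roots; expected a single rooted genealogy")
  local_tree(parent, time, labels,
             position = position, interval = c(x$left[i], x$right[i]))
}

#' @export
local_tree_at.tree_list <- function(x, position) {
  i <- which(x$positions == position)
  if (!length(i)) stop("no tree keyed at position ", position)
  x$trees[[i[[1L]]]]
}

#' @export
local_tree_at.function <- function(x, position) x(position)

#' Build a tree sequence from plain-text node and edge tables
#'
#' Reads the text dump of a succinct tree sequence: a node table with
#' columns `id`, `is_sample`, `time` and an edge table with columns `left`,
#' `right`, `parent`, `child` (ids 0-based, as written by tskit-style
#' tools). Sample nodes become the leaves.
#'
#' @param nodes_path,edges_path tab- or whitespace-delimited files with a
#'   header row.
#' @param labels optional leaf labels; defaults to `n0, n1, ...` by node id.
#' @param sequence_length total span; defaults to the maximal edge `right`.
#' @return a `tree_sequence`.
#' @export
read_tree_tables <- function(nodes_path, edges_path, labels = NULL,
                             sequence_length = NULL) {
  nodes <- read.table(nodes_path, header = TRUE)
  edges <- read.table(edges_path, header = TRUE)
  need_n <- c("id", "is_sample", "time")
  need_e <- c("left", "right", "parent", "child")
  if (!all(need_n %in% names(nodes)))
    stop("node table must have columns: ", paste(need_n, collapse = ", "))
  if (!all(need_e %in% names(edges)))
    stop("edge table must have columns: ", paste(need_e, collapse = ", "))
  nodes <- nodes[order(nodes$id), ]
  samples <- nodes$id[nodes$is_sample != 0]
  others <- nodes$id[nodes$is_sample == 0]
  # canonical layout: leaves first
  order_ids <- c(samples, others)
  remap <- integer(nrow(nodes))
  remap[order_ids + 1L] <- seq_along(order_ids)
  time <- nodes$time[match(order_ids, nodes$id)]
  if (is.null(sequence_length)) sequence_length <- max(edges$right)
  breaks <- sort(unique(c(0, edges$left, edges$right, sequence_length)))
  breaks <- breaks[breaks < sequence_length]
  nn <- nrow(nodes)
  ntrees <- length(breaks)
  P <- matrix(NA_integer_, nn, ntrees)
  Tm <- matrix(rep(time, ntrees), nn, ntrees)
  for (j in seq_len(ntrees)) {
    pos <- breaks[j]
    act <- edges$left <= pos & pos < edges$right
    P[remap[edges$child[act] + 1L], j] <- remap[edges$parent[act] + 1L]
  }
  if (is.null(labels)) labels <- paste0("n", samples)
  rights <- c(breaks[-1L], sequence_length)
  ts <- tree_sequence(P, Tm, breaks, rights, labels, sequence_length)
  # the full node table contains nodes absent from individual marginal
  # trees; extraction prunes to the subtree spanned by the samples
  ts$prune <- TRUE
  ts
}
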