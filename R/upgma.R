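#' Symmetric pairwise-TMRCA matrix at one site
#'
#' Times to the most recent common ancestor for every pair of haplotypes at
#' one genomic position, as produced by sequentially-Markovian-coalescent
#' methods. Local genealogies are rebuilt from these matrices by UPGMA.
#'
#' @param values symmetric numeric matrix (generations), zero diagonal,
#'   positive off-diagonal.
#' @param ids haplotype identifiers; defaults to the matrix dimnames.
#' @param position focal 0-based position (bp).
#' @return an object of class `tmrca_matrix`.
#' @export
tmrca_matrix <- function(values, ids = rownames(values), position = NULL) {
  values <- as.matrix(values)
  if (is.null(ids)) stop("haplotype ids are required")
  if (nrow(values) != ncol(values)) stop("matrix must be square")
  if (nrow(values) != length(ids)) stop("ids must match the matrix size")
  if (!isTRUE(all.equal(values, t(values), tolerance = 0)))
    stop("TMRCA matrix must be symmetric")
  if (any(diag(values) != 0)) stop("diagonal must be zero")
  off <- values[upper.tri(values)]
  if (any(off <= 0)) stop("off-diagonal TMRCA values must be positive")
  dimnames(values) <- list(ids, ids)
  structure(list(ids = as.character(ids), values = values,
                 position = position),
            class = "tmrca_matrix")
}

#' Build a rooted ultrametric genealogy by UPGMA from pairwise TMRCAs
#'
#' Average-linkage hierarchical clustering on the distance `d(i,j) =
#' scale * TMRCA(i,j)`. With the default `scale = 2` the height of the node
#' joining two clusters is half the linkage distance, so pair-join heights
#' equal TMRCA values and node times are ages in generations. Ties are
#' broken deterministically by joining the pair of clusters whose smallest
#' member ids are lexicographically smallest.
#'
#' @param m a [tmrca_matrix()].
#' @param scale multiplier turning TMRCA into distance (the topology is
#'   unaffected; node times scale by `scale / 2`).
#' @return an ultrametric `local_tree` with leaves `1..n` in the order of
#'   `m$ids`.
#' @export
upgma_tree <- function(m, scale = 2) {
  if (!inherits(m, "tmrca_matrix")) m <- tmrca_matrix(m)
  n <- length(m$ids)
  if (n < 2) stop("need at least 2 haplotypes")
  D <- scale * m$values
  nn <- 2L * n - 1L
  parent <- rep(NA_integer_, nn)
  time <- rep(0, nn)
  labels <- c(m$ids, rep(NA_character_, n - 1L))
  active <- seq_len(n)          # node id of each live cluster
  sizes <- rep(1L, n)
  minlab <- m$ids               # smallest member label per live cluster
  Dm <- D                       # linkage distances among live clusters
  nxt <- n + 1L
  while (length(active) > 1L) {
    k <- length(active)
    dv <- Dm
    diag(dv) <- Inf
    best <- min(dv)
    cand <- which(dv == best, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break on the clusters' smallest member labels
    key1 <- pmin(minlab[cand[, 1]], minlab[cand[, 2]])
    key2 <- pmax(minlab[cand[, 1]], minlab[cand[, 2]])
    pick <- order(key1, key2)[1L]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    if (j < i) { tmp <- i; i <- j; j <- tmp }
    node <- nxt; nxt <- nxt + 1L
    parent[active[i]] <- node
    parent[active[j]] <- node
    time[node] <- best / 2
    # average-linkage update; equal inputs kept exact for ultrametric input
    newd <- ifelse(Dm[, i] == Dm[, j], Dm[, i],
                   (sizes[i] * Dm[, i] + sizes[j] * Dm[, j]) /
                     (sizes[i] + sizes[j]))
    Dm[, i] <- newd
    Dm[i, ] <- newd
    Dm[i, i] <- 0
    keep <- setdiff(seq_len(k), j)
    Dm <- Dm[keep, keep, drop = FALSE]
    active[i] <- node
    sizes[i] <- sizes[i] + sizes[j]
    minlab[i] <- min(minlab[i], minlab[j])
    active <- active[keep]
    sizes <- sizes[keep]
    minlab <- minlab[keep]
  }
  out <- local_tree(parent[seq_len(nxt - 1L)], time[seq_len(nxt - 1L)],
                    labels[seq_len(nxt - 1L)], position = m$position)
  validate_local_tree(out)
  out
}

#' Read stacked per-site TMRCA matrices
#'
#' Whitespace-delimited text: a header row `pos <id1> <id2> ...` followed by
#' one square block per site, each row starting with the site's position.
#'
#' @param path file path.
#' @return a list of [tmrca_matrix()] objects, one per site.
#' @export
read_tmrca_matrices <- function(path) {
  tab <- read.table(path, header = TRUE, check.names = FALSE)
  ids <- colnames(tab)[-1L]
  n <- length(ids)
  if (nrow(tab) %% n != 0)
    stop("row count is not a multiple of the number of haplotypes")
  pos <- tab[[1L]]
  out <- list()
  for (b in seq_len(nrow(tab) %/% n)) {
    rows <- ((b - 1L) * n + 1L):(b * n)
    if (length(unique(pos[rows])) != 1L)
      stop("block ", b, " mixes several positions")
    vals <- as.matrix(tab[rows, -1L])
    rownames(vals) <- ids
    out[[b]] <- tmrca_matrix(vals, ids, position = pos[rows[1L]])
  }
  out
}
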