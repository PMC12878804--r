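# Independent brute-force oracles and small fixture builders used across the
# test files. The oracles enumerate joint assignments directly and never
# share code with the package's dynamic programs.

NUC <- c("A", "C", "G", "T")
nuc_int <- function(x) match(x, NUC)

# random coalescent genealogy (ape::rcoal) as a local_tree, times scaled
random_tree <- function(n, scale = 1) {
  phy <- ape::rcoal(n)
  phy$edge.length <- phy$edge.length * scale
  as_local_tree(phy)
}

random_leaf_states <- function(tree, min_distinct = 1) {
  labs <- leaf_labels(tree)
  repeat {
    st <- setNames(sample(NUC, length(labs), replace = TRUE), labs)
    if (length(unique(st)) >= min_distinct) return(st)
  }
}

# best joint log score per root state by exhaustive enumeration over all
# 4^(#internal) assignments (includes the root prior)
brute_joint_scores <- function(tree, leaf_states, model) {
  nn <- length(tree$parent)
  leaf <- !(seq_len(nn) %in% tree$parent)
  internal <- which(!leaf)
  root <- which(is.na(tree$parent))
  st <- rep(NA_integer_, nn)
  st[leaf] <- nuc_int(unname(leaf_states[tree$labels[leaf]]))
  logP <- vector("list", nn)
  for (v in seq_len(nn)) {
    if (!is.na(tree$parent[v]))
      logP[[v]] <- log(transition_matrix(
        model, tree$time[tree$parent[v]] - tree$time[v]))
  }
  best <- rep(-Inf, 4)
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
  for (g in seq_len(nrow(grid))) {
    st[internal] <- grid[g, ]
    lp <- log(unname(model$pi[st[root]]))
    for (v in seq_len(nn)) {
      p <- tree$parent[v]
      if (!is.na(p)) lp <- lp + logP[[v]][st[p], st[v]]
    }
    r <- st[root]
    if (lp > best[r]) best[r] <- lp
  }
  setNames(best, NUC)
}

# minimal number of state changes with the root fixed, by enumeration
brute_min_mutations <- function(tree, leaf_states, root_state) {
  nn <- length(tree$parent)
  leaf <- !(seq_len(nn) %in% tree$parent)
  internal <- which(!leaf)
  root <- which(is.na(tree$parent))
  st <- rep(NA_integer_, nn)
  st[leaf] <- nuc_int(unname(leaf_states[tree$labels[leaf]]))
  rs <- nuc_int(root_state)
  free <- setdiff(internal, root)
  best <- Inf
  grid <- as.matrix(expand.grid(rep(list(1:4), length(free))))
  for (g in seq_len(max(1L, nrow(grid)))) {
    st[root] <- rs
    if (length(free)) st[free] <- grid[g, ]
    changes <- 0L
    for (v in seq_len(nn)) {
      p <- tree$parent[v]
      if (!is.na(p) && st[v] != st[p]) changes <- changes + 1L
    }
    if (changes < best) best <- changes
  }
  best
}

# hand-built tree helpers ---------------------------------------------------

# 2-leaf tree: leaves a, b at time 0, root at `height`; unequal root branches
# via leaf times would break ultrametry, so use leaf times t_a, t_b >= 0
two_leaf_tree <- function(height = 1, t_a = 0, t_b = 0) {
  local_tree(parent = c(3L, 3L, NA), time = c(t_a, t_b, height),
             labels = c("a", "b", NA))
}

# balanced quartet ((a,b),(c,d)) with cherry heights h_ab, h_cd, root h_root
quartet_tree <- function(h_ab = 1, h_cd = 1, h_root = 2) {
  local_tree(parent = c(5L, 5L, 6L, 6L, 7L, 7L, NA),
             time = c(0, 0, 0, 0, h_ab, h_cd, h_root),
             labels = c("a", "b", "c", "d", NA, NA, NA))
}

default_model <- function(mu = 0.1) substitution_model("jc69", mu = mu)
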