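test_that("local_tree enforces its invariants", {
  expect_error(local_tree(c(NA, NA), c(1, 1), c("a", "b")),
               "exactly one root")
  expect_error(local_tree(c(3L, 3L, NA), c(5, 0, 1), c("a", "b", NA)),
               "younger than its child")
  expect_error(local_tree(c(3L, 3L, NA), c(0, 0, -1), c("a", "b", NA)),
               "non-negative")
  expect_error(local_tree(c(3L, 3L, NA), c(0, 0, 1), c("a", "a", NA)),
               "unique")
  t <- two_leaf_tree(height = 5)
  expect_equal(n_leaves(t), 2L)
  expect_equal(leaf_labels(t), c("a", "b"))
})

test_that("extract_local_tree returns the marginal tree containing a position", {
  # hand-built 2-tree sequence across a breakpoint at 50:
  # tree 1 = ((a,b),c) heights 1,2 ; tree 2 = (a,(b,c)) heights 0.5,2
  P <- cbind(c(4L, 4L, 5L, 5L, NA), c(5L, 4L, 4L, 5L, NA))
  Tm <- cbind(c(0, 0, 0, 1, 2), c(0, 0, 0, 0.5, 2))
  ts <- tree_sequence(P, Tm, left = c(0, 50), right = c(50, 100),
                      labels = c("a", "b", "c"), sequence_length = 100)
  t1 <- extract_local_tree(ts, 10)
  t2 <- extract_local_tree(ts, 75)
  expect_false(identical(t1$parent, t2$parent))
  # left edge of an interval belongs to that interval (half-open convention)
  tb <- extract_local_tree(ts, 50)
  expect_identical(tb$parent, t2$parent)
  expect_identical(extract_local_tree(ts, 0)$parent, t1$parent)
  expect_error(extract_local_tree(ts, 100), "outside the sequence span")
  expect_error(extract_local_tree(ts, -1), "outside the sequence span")
})

test_that("a 2-haplotype simulation yields 3-node marginal trees", {
  cfg <- scenario_config(1, sequence_length = 5e4)
  sim <- simulate_scenario(cfg, seed = 4)
  t <- extract_local_tree(sim$ts, sim$sites$pos[1] - 1L)
  expect_equal(length(t$parent), 3L)
  expect_equal(n_leaves(t), 2L)
})

test_that("sanitize_times applies the floor and collapses near-zero branches", {
  # internal node at time 0 is raised to the floor
  t <- local_tree(c(4L, 4L, 5L, 5L, NA), c(0, 0, 0, 0, 3),
                  c("a", "b", "c", NA, NA))
  s <- sanitize_times(t)
  expect_equal(s$time[[4]], 1e-12)
  # internal child within 1e-14 of its parent is deleted, making a polytomy
  t2 <- local_tree(c(5L, 5L, 6L, 6L, 7L, 7L, NA),
                   c(0, 0, 0, 0, 1, 2 - 1e-15, 2),
                   c("a", "b", "c", "d", NA, NA, NA))
  s2 <- sanitize_times(t2)
  expect_equal(length(s2$parent), 6L)
  root <- which(is.na(s2$parent))
  expect_equal(sum(s2$parent == root, na.rm = TRUE), 3L)  # polytomy
  expect_setequal(leaf_labels(s2), leaf_labels(t2))
  # idempotence
  expect_equal(sanitize_times(s2), s2)
  t3 <- random_tree(6)
  expect_equal(sanitize_times(sanitize_times(t3)), sanitize_times(t3))
})

test_that("newick round trip preserves topology and node times", {
  t <- random_tree(8, scale = 1000)
  f <- tempfile(fileext = ".nwk")
  write_newick_trees(list(t), f, positions = 123)
  tl <- read_newick_trees(f)
  t2 <- local_tree_at(tl, 123)
  expect_equal(sort(leaf_labels(t2)), sort(leaf_labels(t)))
  # compare pairwise TMRCAs (topology + times), label-matched
  d1 <- ape::cophenetic.phylo(as_phylo(t))
  d2 <- ape::cophenetic.phylo(as_phylo(t2))
  expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-8)
  expect_error(local_tree_at(tl, 999), "no tree keyed")
})

test_that("tree sequences load from plain-text node/edge tables", {
  nodes <- data.frame(id = 0:4, is_sample = c(1, 1, 1, 0, 0),
                      time = c(0, 0, 0, 1, 2))
  # interval [0,50): ((n0,n1)@1, n2)@2 ; interval [50,100): ((n1,n2)@1, n0)@2
  edges <- data.frame(left = c(0, 50, 0, 0, 0, 50),
                      right = c(50, 100, 100, 100, 50, 100),
                      parent = c(3, 3, 3, 4, 4, 4),
                      child = c(0, 2, 1, 3, 2, 0))
  nf <- tempfile(); ef <- tempfile()
  write.table(nodes, nf, row.names = FALSE, quote = FALSE)
  write.table(edges, ef, row.names = FALSE, quote = FALSE)
  ts <- read_tree_tables(nf, ef)
  t1 <- extract_local_tree(ts, 10)
  t2 <- extract_local_tree(ts, 75)
  expect_equal(n_leaves(t1), 3L)
  expect_equal(max(t1$time), 2)
  d1 <- ape::cophenetic.phylo(as_phylo(t1))
  d2 <- ape::cophenetic.phylo(as_phylo(t2))
  expect_equal(d1["n0", "n1"], 2)   # cherry in tree 1
  expect_equal(d2["n1", "n2"], 2)   # cherry in tree 2
  expect_equal(d2["n0", "n1"], 4)
})
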