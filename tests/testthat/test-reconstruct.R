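test_that("two-leaf posteriors respect JC symmetry and branch-length signal", {
  m <- default_model()
  # equal root branches: A and T exchangeable, C = G below both
  t <- two_leaf_tree(height = 1)
  p <- joint_reconstruct(t, c(a = "A", b = "T"), m)
  expect_equal(p$posterior[["A"]], p$posterior[["T"]], tolerance = 1e-14)
  expect_equal(p$posterior[["C"]], p$posterior[["G"]], tolerance = 1e-14)
  expect_lt(p$posterior[["C"]], p$posterior[["A"]])
  expect_true(p$tied)
  # much shorter branch to the A leaf: A favoured as ancestral
  t2 <- two_leaf_tree(height = 2, t_a = 1.95, t_b = 0)
  p2 <- joint_reconstruct(t2, c(a = "A", b = "T"), m)
  expect_gt(p2$posterior[["A"]], p2$posterior[["T"]])
})

test_that("monomorphic leaves give the shared state as root argmax", {
  m <- default_model()
  for (rep in 1:5) {
    t <- random_tree(sample(3:8, 1))
    st <- setNames(rep("G", n_leaves(t)), leaf_labels(t))
    p <- joint_reconstruct(t, st, m)
    expect_equal(names(which.max(p$posterior)), "G")
    expect_equal(unname(p$assignment["G", ]),
                 rep("G", ncol(p$assignment)))
  }
})

test_that("joint reconstruction equals exhaustive enumeration on small trees", {
  set.seed(31)
  models <- list(default_model(0.2),
                 substitution_model("k80", mu = 0.2, kappa = 5),
                 substitution_model("jc69", mu = 0.2,
                                    pi = c(0.1, 0.2, 0.3, 0.4)))
  for (rep in 1:15) {
    n <- sample(3:7, 1)
    t <- random_tree(n)
    st <- random_leaf_states(t, min_distinct = 2)
    m <- models[[1 + rep %% length(models)]]
    oracle <- brute_joint_scores(t, st, m)
    got <- joint_reconstruct(t, st, m)
    expect_equal(unname(got$score), unname(oracle), tolerance = 1e-9)
    po <- exp(oracle - max(oracle))
    expect_equal(unname(got$posterior), unname(po / sum(po)),
                 tolerance = 1e-9)
  }
})

test_that("posterior sums to 1 and backtrace assignments are consistent", {
  set.seed(5)
  m <- default_model()
  for (rep in 1:5) {
    t <- random_tree(6)
    st <- random_leaf_states(t, 2)
    p <- joint_reconstruct(t, st, m)
    expect_equal(sum(p$posterior), 1, tolerance = 1e-12)
    leaf <- match(leaf_labels(t), names(st))
    for (r in NUC)
      expect_equal(unname(p$assignment[r, seq_along(leaf)]),
                   unname(st[leaf]))
  }
})

test_that("within-clade topology does not move the restricted posterior", {
  m <- default_model(0.05)
  # clade {a,b,c} all A, clade root at height 2; clade {d,e} all T, clade
  # root at 1.5; tree root at 4. Shape 1: ((a,b),c); shape 2: (a,(b,c)).
  shape1 <- local_tree(
    parent = c(6L, 6L, 7L, 8L, 8L, 7L, 9L, 9L, NA),
    time = c(0, 0, 0, 0, 0, 0.3, 2, 1.5, 4),
    labels = c("a", "b", "c", "d", "e", NA, NA, NA, NA))
  shape2 <- local_tree(
    parent = c(7L, 6L, 6L, 8L, 8L, 7L, 9L, 9L, NA),
    time = c(0, 0, 0, 0, 0, 1.2, 2, 1.5, 4),
    labels = c("a", "b", "c", "d", "e", NA, NA, NA, NA))
  st <- c(a = "A", b = "A", c = "A", d = "T", e = "T")
  r1 <- ancestral_call(joint_reconstruct(shape1, st, m), c("A", "T"))
  r2 <- ancestral_call(joint_reconstruct(shape2, st, m), c("A", "T"))
  expect_equal(r1$restricted, r2$restricted, tolerance = 1e-12)
  # and the longer root branch carries the mutation more probably: the
  # A-clade root branch (4-2=2) is shorter than the T side (4-1.5=2.5),
  # so A is the likelier ancestral state
  expect_gt(r1$restricted[["A"]], 0.5)
})

test_that("symmetric models swap posteriors under allele/branch exchange", {
  for (m in list(default_model(0.1),
                 substitution_model("k80", mu = 0.1, kappa = 5))) {
    t1 <- two_leaf_tree(height = 3, t_a = 1, t_b = 0)
    t2 <- two_leaf_tree(height = 3, t_a = 0, t_b = 1)
    p1 <- joint_reconstruct(t1, c(a = "C", b = "T"), m)$posterior
    p2 <- joint_reconstruct(t2, c(a = "T", b = "C"), m)$posterior
    expect_equal(p1[["C"]], p2[["C"]], tolerance = 1e-14)
    expect_equal(p1[["T"]], p2[["T"]], tolerance = 1e-14)
  }
})

test_that("no underflow on 400-leaf trees with times up to 1e6 generations", {
  set.seed(8)
  t <- random_tree(400, scale = 1e6 / 3)
  st <- random_leaf_states(t)
  m <- substitution_model("jc69", mu = 1.25e-8)
  p <- joint_reconstruct(t, st, m)
  expect_true(all(is.finite(p$posterior)))
  expect_equal(sum(p$posterior), 1, tolerance = 1e-12)
})

test_that("ancestral_call restricts, renormalises and flags ties", {
  p <- list(posterior = c(A = 0.7, C = 0.05, G = 0.05, T = 0.2))
  r <- ancestral_call(p, c("A", "T"))
  expect_equal(r$allele, "A")
  expect_equal(r$probability, 0.7 / 0.9, tolerance = 1e-12)
  expect_false(r$ambiguous)
  r2 <- ancestral_call(list(posterior = c(A = 0.3, C = 0.3, G = 0.2,
                                          T = 0.2)), c("A", "C"))
  expect_true(r2$ambiguous)
  expect_equal(r2$allele, "A")   # lexicographic pick
  r3 <- ancestral_call(p, "G")
  expect_equal(r3$probability, 1)
})

test_that("reconstruction errors are informative", {
  m <- default_model()
  t <- two_leaf_tree()
  expect_error(joint_reconstruct(t, c(a = "A"), m), "missing state.*b")
  expect_error(joint_reconstruct(t, c(a = "A", b = "N"), m),
               "invalid nucleotide")
})
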