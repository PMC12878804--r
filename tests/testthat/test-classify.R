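test_that("map_mutations reproduces hand-traced counts and placements", {
  t <- quartet_tree()
  st <- c(a = "A", b = "T", c = "T", d = "T")
  r_t <- map_mutations(t, st, "T")
  expect_equal(r_t$count, 1L)
  expect_equal(r_t$placements$node, 1L)        # edge above leaf a
  expect_equal(r_t$placements$to, "A")
  r_a <- map_mutations(t, st, "A")
  expect_equal(r_a$count, 2L)
  # 2-leaf tree: one change whichever root state
  t2 <- two_leaf_tree()
  expect_equal(map_mutations(t2, c(a = "A", b = "T"), "A")$count, 1L)
  expect_equal(map_mutations(t2, c(a = "A", b = "T"), "T")$count, 1L)
  # monomorphic leaves, matching root: no changes
  expect_equal(map_mutations(t, setNames(rep("C", 4), letters[1:4]),
                             "C")$count, 0L)
  expect_error(map_mutations(t, st, "N"), "invalid")
})

test_that("map_mutations equals brute-force Sankoff on random small trees", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(3:7, 1)
    t <- random_tree(n)
    st <- random_leaf_states(t)
    for (root in NUC) {
      expect_equal(map_mutations(t, st, root)$count,
                   brute_min_mutations(t, st, root),
                   info = paste("rep", rep, "root", root))
    }
  }
})

test_that("polytomies are handled and flagged by placement position", {
  # root with 3 children: a, b, (c,d); mutation on a leaf under the root
  t <- local_tree(parent = c(6L, 6L, 5L, 5L, 6L, NA),
                  time = c(0, 0, 0, 0, 1, 2),
                  labels = c("a", "b", "c", "d", NA, NA))
  st <- c(a = "G", b = "A", c = "A", d = "A")
  r <- map_mutations(t, st, "A")
  expect_equal(r$count, 1L)
  expect_true(r$polytomy)
  cls <- classify_site(t, st)
  expect_true(cls$polytomy_mutation)
})

test_that("classify_site flags follow the parsimony tie structure", {
  # 2-leaf segregating site: both candidates need one mutation
  cls <- classify_site(two_leaf_tree(), c(a = "A", b = "T"))
  expect_true(cls$non_informative)
  expect_false(cls$multiple_mutations)
  # quartet with a derived singleton inside a cherry: informative, anc = T
  t <- quartet_tree()
  cls2 <- classify_site(t, c(a = "A", b = "T", c = "T", d = "T"))
  expect_false(cls2$non_informative)
  expect_equal(cls2$min_candidates, "T")
  expect_equal(cls2$min_count, 1L)
  # alternating pattern: two mutations for both candidates
  cls3 <- classify_site(t, c(a = "A", b = "T", c = "A", d = "T"))
  expect_true(cls3$non_informative)
  expect_true(cls3$multiple_mutations)
  expect_true(cls3$homoplasy)
  expect_equal(cls3$min_count, 2L)
  expect_error(classify_site(t, setNames(rep("A", 4), letters[1:4])),
               "monomorphic")
})

test_that("observed-allele candidates match the all-four default on
          single-mutation sites", {
  set.seed(3)
  for (rep in 1:10) {
    t <- random_tree(6)
    st <- random_leaf_states(t, 2)
    c_obs <- classify_site(t, st)
    c_all <- classify_site(t, st, candidate_states = NUC)
    expect_equal(c_obs$min_count, c_all$min_count)
    if (c_obs$min_count == 1L)
      expect_equal(c_obs$non_informative, c_all$non_informative)
  }
})

test_that("singleton-ancestral quartets are always non-informative", {
  # with 4 haplotypes, an ancestral singleton forces the derived triple to
  # be a clade only when the singleton hangs off the root, so parsimony
  # always ties; check every labelled quartet topology
  topos <- list(
    quartet_tree(),                                       # ((a,b),(c,d))
    local_tree(c(6L, 6L, 5L, 5L, 6L, NA), c(0, 0, 0, 0, 1, 2),
               c("a", "b", "c", "d", NA, NA)),            # root polytomy
    local_tree(c(5L, 5L, 6L, 7L, 6L, 7L, NA), c(0, 0, 0, 0, 1, 2, 3),
               c("a", "b", "c", "d", NA, NA, NA)))        # caterpillar
  for (t in topos) {
    labs <- leaf_labels(t)
    for (single in labs) {
      st <- setNames(ifelse(labs == single, "A", "G"), labs)
      # ancestral allele is the singleton A: derived triple G is ancestral-
      # tied or better, so the site cannot be informative for A
      cls <- classify_site(t, st)
      expect_true(cls$non_informative || cls$min_candidates == "G")
    }
  }
})

test_that("filter policies implement the documented rules", {
  t <- quartet_tree()
  informative <- classify_site(t, c(a = "A", b = "T", c = "T", d = "T"))
  noninf <- classify_site(two_leaf_tree(), c(a = "A", b = "T"))
  homopl <- classify_site(t, c(a = "A", b = "T", c = "A", d = "T"))
  expect_true(apply_filters(informative, "strict"))
  expect_false(apply_filters(noninf, "strict"))
  expect_false(apply_filters(homopl, "strict"))
  # spectrum policy keeps anything needing at most two mutations
  expect_true(apply_filters(homopl, "usfs"))
  expect_true(apply_filters(informative, "usfs"))
  # real-data: drop non-informative, allow count <= observed alleles
  expect_false(apply_filters(noninf, "real-data"))
  expect_false(apply_filters(homopl, "real-data"))  # non-informative too
  expect_true(apply_filters(informative, "real-data"))
  expect_error(apply_filters(informative, "bogus"))
})
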