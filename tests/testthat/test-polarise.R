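test_that("site_records validates genotypes and haplotype ids", {
  g <- matrix(c("A", "T", "A", "A"), 1, 4,
              dimnames = list(NULL, paste0("h", 1:4)))
  sr <- site_records(10L, g)
  expect_equal(sr$position, 10L)
  expect_error(site_records(10L, matrix("A", 1, 2)), "column names")
  g2 <- g; g2[1] <- "N"
  expect_error(site_records(10L, g2), "invalid genotype")
})

test_that("polarisation from true trees is perfect after strict filtering", {
  set.seed(12)
  m <- substitution_model("jc69", mu = 1.25e-8)
  sim <- simulate_scenario(scenario_default(5, sequence_length = 2e5))
  sr <- sim_site_records(sim, "single_mutation")
  pol <- suppressMessages(polarise_sites(sr, sim, m, policy = "strict"))
  acc <- accuracy_report(pol, sim$truth)
  kept <- acc$overall[acc$overall$subset == "kept", ]
  expect_gt(kept$n_sites, 100)
  expect_equal(kept$accuracy, 1.0)
  # kept implies informative single-mutation classification
  expect_true(all(!pol$non_informative[pol$kept]))
  expect_true(all(pol$min_mutations[pol$kept] == 1))
})

test_that("polarisation output is invariant to input site order", {
  set.seed(13)
  m <- substitution_model("jc69", mu = 1.25e-8)
  sim <- simulate_scenario(scenario_default(3, sequence_length = 1e5))
  sr <- sim_site_records(sim)
  pol1 <- suppressMessages(polarise_sites(sr, sim, m))
  perm <- sample(length(sr$position))
  sr2 <- site_records(sr$position[perm], sr$genotypes[perm, , drop = FALSE])
  pol2 <- suppressMessages(polarise_sites(sr2, sim, m))
  pol2 <- pol2[order(pol2$pos), ]
  rownames(pol2) <- NULL
  expect_equal(pol2, pol1, ignore_attr = TRUE)
})

test_that("a 2-leaf A/T genealogy is dropped under the strict policy", {
  g <- matrix(c("A", "T"), 1, 2, dimnames = list(NULL, c("a", "b")))
  sr <- site_records(5L, g)
  src <- function(p) two_leaf_tree(height = 1000)
  pol <- polarise_sites(sr, src, default_model(1e-3), policy = "strict")
  expect_false(pol$kept)
  expect_true(pol$non_informative)
})

test_that("multi-allelic sites are processed with multi-candidate counts", {
  g <- matrix(c("A", "T", "G", "T"), 1, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  sr <- site_records(0L, g)
  src <- function(p) quartet_tree()
  pol <- polarise_sites(sr, src, default_model(0.01), policy = "usfs")
  expect_equal(pol$n_alleles, 3)
  expect_gte(pol$min_mutations, 2)
  expect_true(is.na(pol$derived_count))
})

test_that("haplotype mismatches and monomorphic sites are handled", {
  g <- matrix(c("A", "T"), 1, 2, dimnames = list(NULL, c("a", "zzz")))
  sr <- site_records(5L, g)
  expect_error(
    polarise_sites(sr, function(p) two_leaf_tree(), default_model()),
    "zzz")
  g2 <- matrix(c("A", "A"), 1, 2, dimnames = list(NULL, c("a", "b")))
  sr2 <- site_records(5L, g2)
  expect_message(
    pol <- polarise_sites(sr2, function(p) two_leaf_tree(), default_model()),
    "non-segregating")
  expect_equal(nrow(pol), 0L)
})

test_that("frequency baselines follow their definitions", {
  expect_equal(max_frequency_polariser(c(A = 8, T = 2))$allele, "A")
  tie <- max_frequency_polariser(c(A = 5, T = 5))
  expect_true(tie$ambiguous)
  expect_true(is.na(tie$allele))
  expect_equal(max_frequency_polariser(c(A = 3, C = 3, G = 4))$allele, "G")
  expect_equal(random_frequency_polariser(c(A = 10))$allele, "A")
  set.seed(2); draws <- replicate(4000,
    random_frequency_polariser(c(A = 5, T = 5))$allele)
  expect_equal(mean(draws == "A"), 0.5, tolerance = 0.05)
  set.seed(9); a <- replicate(20, random_frequency_polariser(c(A = 1, T = 3))$allele)
  set.seed(9); b <- replicate(20, random_frequency_polariser(c(A = 1, T = 3))$allele)
  expect_identical(a, b)
})

test_that("accuracy_report stratifies by the true ancestral allele class", {
  pol <- data.frame(pos = 1:4,
                    cnt_A = c(6, 5, 2, 5), cnt_C = 0, cnt_G = 0,
                    cnt_T = c(4, 5, 8, 5),
                    ancestral_call = c("A", "A", "T", "T"),
                    kept = c(TRUE, TRUE, FALSE, TRUE))
  truth <- data.frame(pos = 1:4,
                      ancestral_state = c("A", "A", "A", "A"))
  r <- accuracy_report(pol, truth)
  expect_equal(r$overall$accuracy[r$overall$subset == "all"], 0.5)
  bs <- r$by_stratum[r$by_stratum$subset == "all", ]
  expect_equal(bs$accuracy[bs$stratum == "major"], 1)      # site 1
  expect_equal(bs$accuracy[bs$stratum == "equal"], 0.5)    # sites 2, 4
  expect_equal(bs$accuracy[bs$stratum == "minor"], 0)      # site 3
  expect_equal(r$kept_prop, 0.75)
  expect_error(accuracy_report(pol, truth[1:2, ]), "absent from truth")
})
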