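# minimal polarised-frame builder for arithmetic checks
fake_pol <- function(n, c1, p1, kept = TRUE, pos = seq_along(c1)) {
  # biallelic A/T sites: c1 copies of A, p1 = restricted P(A ancestral)
  k <- length(c1)
  data.frame(pos = pos, n = n, n_alleles = 2,
             cnt_A = c1, cnt_C = 0, cnt_G = 0, cnt_T = n - c1,
             pr_A = p1, pr_C = 0, pr_G = 0, pr_T = 1 - p1,
             ancestral_call = ifelse(p1 >= 0.5, "A", "T"),
             derived_count = ifelse(p1 >= 0.5, n - c1, c1),
             kept = kept)
}

test_that("posterior-average mass splits across complementary categories", {
  # one site, n = 10, counts 2/8, P(8-copy allele ancestral) = 0.9
  pol <- fake_pol(10, c1 = 2, p1 = 0.1)       # A is the 2-copy allele
  u <- usfs_posterior_average(pol)
  expect_equal(u$E[2], 0.9)
  expect_equal(u$E[8], 0.1)
  expect_equal(sum(u$E), 1, tolerance = 1e-12)
})

test_that("the filter correction rescales kept-site averages by Lx", {
  # folded class {2, 8} of n = 10: Lx = 4 sites, 2 kept with P(Dx) 0.8, 0.6
  pol <- fake_pol(10, c1 = c(2, 2, 2, 2), p1 = c(0.2, 0.4, 0.9, 0.8),
                  kept = c(TRUE, TRUE, FALSE, FALSE))
  # kept sites contribute P(D2) = P(T ancestral) = 1 - p1 = 0.8, 0.6
  u <- usfs_posterior_average(pol, use_filter_correction = TRUE)
  expect_equal(u$E[2], 4 * (0.8 + 0.6) / 2)
  expect_equal(u$E[8], 4 * (0.2 + 0.4) / 2)
  expect_equal(u$Lx[2], 4)
  expect_equal(u$Lx_prime[2], 2)
  # a folded class with no kept sites warns and contributes zero
  pol2 <- rbind(pol, fake_pol(10, c1 = 5, p1 = 0.7, kept = FALSE, pos = 9))
  expect_warning(u2 <- usfs_posterior_average(pol2, TRUE), "no kept site")
  expect_equal(u2$E[5], 0)
})

test_that("max-posterior counting adds unit mass at the called category", {
  pol <- fake_pol(10, c1 = c(2, 3), p1 = c(0.1, 0.95))
  # site 1: T (8 copies) called ancestral -> derived count 2
  # site 2: A (3 copies) called ancestral -> derived count 7
  u <- usfs_max_pp(pol)
  expect_equal(u$E[2], 1)
  expect_equal(u$E[7], 1)
  expect_equal(sum(u$E), 2)
  uf <- usfs_max_pp(fake_pol(10, c1 = c(2, 3), p1 = c(0.1, 0.95),
                             kept = c(FALSE, TRUE)), filtered = TRUE)
  expect_equal(sum(uf$E), 1)
  expect_equal(uf$E[7], 1)
  # degenerate limit: all posteriors 1 -> posterior average equals MAX PP
  pol3 <- fake_pol(10, c1 = c(2, 6), p1 = c(1, 0))
  expect_equal(usfs_posterior_average(pol3)$E, usfs_max_pp(pol3)$E)
})

test_that("posterior-average mass is conserved on simulated data", {
  set.seed(21)
  m <- substitution_model("jc69", mu = 1.25e-8)
  sim <- simulate_scenario(scenario_default(5, sequence_length = 2e5))
  sr <- sim_site_records(sim)
  pol <- suppressMessages(polarise_sites(sr, sim, m, policy = "usfs"))
  nbi <- sum(pol$n_alleles == 2)
  u <- usfs_posterior_average(pol)
  expect_equal(sum(u$E), nbi, tolerance = 1e-9)
  # folded tallies are symmetric
  expect_equal(u$Lx, rev(u$Lx))
})

test_that("qq_compare and relative_error follow their definitions", {
  a <- usfs(c(5, 3, 2), 4)
  expect_equal(qq_compare(a, a)$est_cum, qq_compare(a, a)$ref_cum)
  b <- usfs(c(2, 3, 5), 4)
  qq <- qq_compare(b, a)
  expect_equal(qq$ref_cum, c(0.5, 0.8, 1))
  expect_equal(qq$est_cum, c(0.2, 0.5, 1))
  expect_error(qq_compare(a, usfs(rep(1, 9), 10)), "different n")
  expect_error(qq_compare(usfs(c(0, 0, 0), 4), a), "zero-total")
  re <- relative_error(a, a)
  expect_equal(re$rel_error, c(0, 0, 0))
  est <- usfs(c(0.084, 0.916, 0), 4)
  tru <- usfs(c(0.1, 0.9, 0), 4)
  re2 <- relative_error(est, tru)
  expect_equal(re2$rel_error[1], -0.16, tolerance = 1e-12)
  expect_true(is.na(re2$rel_error[3]))
})

test_that("empty input gives an all-zero spectrum", {
  empty <- fake_pol(10, c1 = 2, p1 = 0.5)[0, ]
  u <- usfs_max_pp(empty, n_haplotypes = 10)
  expect_equal(sum(u$E), 0)
  expect_length(u$E, 9)
  u2 <- usfs_posterior_average(empty, n_haplotypes = 10)
  expect_equal(sum(u2$E), 0)
})
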