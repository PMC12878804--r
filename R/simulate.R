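#' Coalescent simulation scenario
#'
#' Configuration for the built-in coalescent-with-recombination simulator
#' (SMC' approximation, discrete finite sites). Defaults reproduce the
#' neutral constant-size study conditions: Ne = 30,000 diploids,
#' mu = 1.25e-8 per bp per generation under JC69, uniform recombination
#' 1e-8 per bp per generation, 1 Mb, 10 replicates.
#'
#' @param n_diploids number of diploid individuals sampled (2 haplotypes
#'   each).
#' @param sequence_length chromosome span in bp.
#' @param Ne effective population size (diploids) of the most recent epoch.
#' @param mu mutation rate per site per generation.
#' @param recomb recombination rate per bp per generation.
#' @param model mutation model, `"jc69"` or `"k80"`.
#' @param kappa transition/transversion rate ratio (K80).
#' @param root_pi root nucleotide distribution (A, C, G, T).
#' @param demography `"constant"`, or a logarithmic size change over
#'   `change_duration` generations: `"growth"` (forward-time increase from
#'   `size_old` to `Ne`) or `"decline"` (forward-time decrease from
#'   `size_old` to `Ne`); the log-linear size trajectory is discretised
#'   into `n_epochs` piecewise-constant epochs. Alternatively a data.frame
#'   with columns `start` (generations ago, first row 0) and `size`.
#' @param size_old population size at the start of the change (forward
#'   time), i.e. the ancestral size.
#' @param change_duration duration of the size change, generations.
#' @param n_epochs number of piecewise-constant epochs used to discretise
#'   the log-linear trajectory.
#' @param replicates default replicate count for experiment drivers.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(n_diploids, sequence_length = 1e6, Ne = 30000,
                            mu = 1.25e-8, recomb = 1e-8,
                            model = c("jc69", "k80"), kappa = 5,
                            root_pi = rep(0.25, 4),
                            demography = "constant", size_old = NULL,
                            change_duration = 150000, n_epochs = 64,
                            replicates = 10) {
  model <- match.arg(model)
  stopifnot(n_diploids >= 1, sequence_length > 0, Ne > 0, mu > 0,
            recomb > 0, kappa > 0, length(root_pi) == 4,
            abs(sum(root_pi) - 1) < 1e-9)
  structure(list(n_diploids = as.integer(n_diploids),
                 sequence_length = sequence_length, Ne = Ne, mu = mu,
                 recomb = recomb, model = model, kappa = kappa,
                 root_pi = setNames(as.numeric(root_pi), NUCS),
                 demography = demography, size_old = size_old,
                 change_duration = change_duration, n_epochs = n_epochs,
                 replicates = replicates),
            class = "scenario_config")
}

#' @rdname scenario_config
#' @param ... overrides passed to [scenario_config()].
#' @export
scenario_default <- function(n_diploids, ...)
  scenario_config(n_diploids, ...)

#' @rdname scenario_config
#' @export
scenario_high_rate <- function(n_diploids, ...)
  scenario_config(n_diploids, mu = 1e-7, ...)

#' @rdname scenario_config
#' @export
scenario_k80 <- function(n_diploids, ...)
  scenario_config(n_diploids, model = "k80", kappa = 5, ...)

#' @rdname scenario_config
#' @export
scenario_gc_bias <- function(n_diploids, ...)
  scenario_config(n_diploids, root_pi = c(A = 0.2, C = 0.3, G = 0.3,
                                          T = 0.2), ...)

#' @rdname scenario_config
#' @export
scenario_growth <- function(n_diploids, Ne = 46000, size_old = 960, ...)
  scenario_config(n_diploids, Ne = Ne, size_old = size_old,
                  demography = "growth", ...)

#' @rdname scenario_config
#' @export
scenario_decline <- function(n_diploids, Ne = 960, size_old = 46000, ...)
  scenario_config(n_diploids, Ne = Ne, size_old = size_old,
                  demography = "decline", ...)

# piecewise-constant epochs (start time backwards in generations, diploid
# size); log-linear interpolation between the present size and size_old
build_epochs <- function(cfg) {
  if (is.data.frame(cfg$demography)) {
    stopifnot(all(c("start", "size") %in% names(cfg$demography)),
              cfg$demography$start[1] == 0)
    return(list(start = cfg$demography$start, size = cfg$demography$size))
  }
  if (identical(cfg$demography, "constant"))
    return(list(start = 0, size = cfg$Ne))
  if (!cfg$demography %in% c("growth", "decline"))
    stop("unknown demography: ", cfg$demography)
  if (is.null(cfg$size_old)) stop("size_old required for a size change")
  K <- cfg$n_epochs
  Tm <- cfg$change_duration
  starts <- (seq_len(K) - 1) * Tm / K
  mids <- starts + Tm / (2 * K)
  sizes <- exp(log(cfg$Ne) + (log(cfg$size_old) - log(cfg$Ne)) * mids / Tm)
  list(start = c(starts, Tm), size = c(sizes, cfg$size_old))
}

hap_labels <- function(n_hap)
  paste0("S", (seq_len(n_hap) - 1L) %/% 2L, "_", (seq_len(n_hap) - 1L) %% 2L)

#' Simulate one replicate of a scenario with ground truth
#'
#' Runs the coalescent-with-recombination simulator and lays down discrete
#' finite-site mutations under the configured model, recording for every
#' mutated site the true (root) ancestral allele and the number of
#' mutations. Reproducible: the same `seed` gives byte-identical output.
#'
#' @param cfg a [scenario_config()].
#' @param seed optional integer seed (applied with [set.seed()]).
#' @param store_all_trees keep every marginal tree, not only those carrying
#'   mutations (memory-heavy for long sequences).
#' @return an object of class `polar_sim`: list with `ts` (a
#'   [tree_sequence()] over the mutated intervals), `sites` (data.frame:
#'   `pos` 1-based, `n_mutations`, `n_alleles`, `segregating`), `genotypes`
#'   (character matrix sites x haplotypes), `truth` (data.frame: `pos`,
#'   `ancestral_state`, `n_mutations`), `config`, `seed`.
#' @export
simulate_scenario <- function(cfg, seed = NULL, store_all_trees = FALSE) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  ep <- build_epochs(cfg)
  n_hap <- 2L * cfg$n_diploids
  raw <- sim_replicate_cpp(n_hap, cfg$sequence_length, cfg$recomb, cfg$mu,
                           if (cfg$model == "jc69") 0L else 1L, cfg$kappa,
                           unname(cfg$root_pi), ep$start, ep$size,
                           store_all_trees)
  labels <- hap_labels(n_hap)
  parent <- raw$tree_parent + 1L
  parent[parent == 0L] <- NA_integer_
  ts <- tree_sequence(parent, raw$tree_time, raw$tree_left, raw$tree_right,
                      labels, cfg$sequence_length)
  geno <- matrix(int_to_nuc(raw$leaf_states + 1L),
                 nrow = length(raw$site_pos),
                 dimnames = list(NULL, labels))
  sites <- data.frame(pos = raw$site_pos + 1L,
                      tree = raw$site_tree + 1L,
                      n_mutations = raw$site_nmut,
                      n_alleles = raw$site_nalleles,
                      segregating = raw$site_nalleles >= 2L)
  truth <- data.frame(pos = raw$site_pos + 1L,
                      ancestral_state = int_to_nuc(raw$site_anc + 1L),
                      n_mutations = raw$site_nmut)
  structure(list(ts = ts, sites = sites, genotypes = geno, truth = truth,
                 config = cfg, seed = seed,
                 n_recomb = raw$n_recomb, n_intervals = raw$n_intervals),
            class = "polar_sim")
}

#' @export
print.polar_sim <- function(x, ...) {
  cat("<polar_sim> ", ncol(x$genotypes), " haplotypes, ",
      sum(x$sites$segregating), " segregating sites, ",
      x$n_intervals, " marginal-tree intervals\n", sep = "")
  invisible(x)
}

#' @export
local_tree_at.polar_sim <- function(x, position) local_tree_at(x$ts, position)

#' Site records from a simulation
#'
#' @param sim a `polar_sim`.
#' @param which `"segregating"` (default), `"single_mutation"` (biallelic
#'   sites carrying exactly one mutation), `"multiallelic"` (more than two
#'   observed alleles), or `"all"` mutated sites.
#' @return a [site_records()] object.
#' @export
sim_site_records <- function(sim, which = c("segregating", "single_mutation",
                                            "multiallelic", "all")) {
  which <- match.arg(which)
  keep <- switch(which,
    segregating = sim$sites$segregating,
    single_mutation = sim$sites$segregating & sim$sites$n_mutations == 1L &
                      sim$sites$n_alleles == 2L,
    multiallelic = sim$sites$n_alleles > 2L,
    all = rep(TRUE, nrow(sim$sites)))
  site_records(sim$sites$pos[keep] - 1L,
               sim$genotypes[keep, , drop = FALSE])
}

#' Watterson's estimator of the scaled mutation rate
#'
#' @param S number of segregating sites.
#' @param n_hap number of haplotypes.
#' @param L sequence length (bp).
#' @return theta per bp (`4 Ne mu` under neutrality).
#' @export
watterson_theta <- function(S, n_hap, L)
  S / (L * sum(1 / seq_len(n_hap - 1L)))

#' Polarisation accuracy experiment across sample sizes
#'
#' For each sample size and replicate: simulate, polarise from the true
#' marginal trees with the genealogy-based method and the two frequency
#' baselines, and score the calls against the simulated ancestral alleles,
#' overall and stratified by whether the true ancestral allele is the
#' major, equal-frequency, or minor allele.
#'
#' @param cfg a [scenario_config()]; its `n_diploids` is overridden by
#'   `sample_sizes`.
#' @param sample_sizes diploid sample sizes to sweep.
#' @param policy filter policy for the genealogy-based method.
#' @param sites which sites to analyse, see [sim_site_records()].
#' @param replicates replicates per sample size.
#' @param seed integer seed for the whole experiment.
#' @param model reconstruction model; defaults to JC69 at the scenario's
#'   mutation rate (the reconstruction model need not match the simulation
#'   model).
#' @return data.frame with one row per (sample size, replicate, method,
#'   subset, stratum): accuracy, site counts, kept and non-informative
#'   proportions.
#' @export
run_accuracy_experiment <- function(cfg, sample_sizes,
                                    policy = "strict",
                                    sites = "single_mutation",
                                    replicates = cfg$replicates,
                                    seed = 1,
                                    model = substitution_model("jc69",
                                                               mu = cfg$mu)) {
  set.seed(seed)
  rows <- list()
  for (nd in sample_sizes) {
    cfg_n <- cfg
    cfg_n$n_diploids <- as.integer(nd)
    for (rep in seq_len(replicates)) {
      sim <- simulate_scenario(cfg_n)
      sr <- sim_site_records(sim, which = sites)
      if (!length(sr$position)) next
      pol <- suppressMessages(
        polarise_sites(sr, sim, model, policy = policy))
      acc <- accuracy_report(pol, sim$truth)
      add <- function(method, subset, stratum, nsit, accu) {
        rows[[length(rows) + 1L]] <<- data.frame(
          sample_size = nd, replicate = rep, method = method,
          subset = subset, stratum = stratum, n_sites = nsit,
          accuracy = accu, kept_prop = acc$kept_prop,
          noninf_prop = mean(pol$non_informative))
      }
      for (s in c("all", "kept")) {
        o <- acc$overall[acc$overall$subset == s, ]
        add("arg", s, "overall", o$n_sites, o$accuracy)
        bs <- acc$by_stratum[acc$by_stratum$subset == s, ]
        for (k in seq_len(nrow(bs)))
          add("arg", s, bs$stratum[k], bs$n_sites[k], bs$accuracy[k])
      }
      # frequency baselines (scored on all sites)
      truth_anc <- sim$truth$ancestral_state[match(pol$pos, sim$truth$pos)]
      for (m in c("max_frequency", "random_frequency")) {
        calls <- baseline_calls(sr, m)
        correct <- calls$ancestral_call == truth_anc
        add(m, "all", "overall", length(correct),
            mean(correct, na.rm = TRUE))
        for (s in c("major", "equal", "minor")) {
          j <- acc$stratum == s
          add(m, "all", s, sum(j),
              if (any(j)) mean(correct[j], na.rm = TRUE) else NA_real_)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' uSFS estimation experiment
#'
#' Simulates replicates, polarises all biallelic segregating sites under the
#' spectrum filter policy (sites needing more than two mutations dropped),
#' and compares the uSFS estimators against the true spectrum pooled over
#' replicates.
#'
#' @param cfg a [scenario_config()].
#' @param sample_size diploid sample size.
#' @param estimators subset of `"max_pp"`, `"max_pp_filtered"`,
#'   `"posterior_average"`, `"posterior_average_corrected"`.
#' @param replicates,seed,model as in [run_accuracy_experiment()].
#' @return list with `usfs` (named list of pooled [usfs()] objects incl.
#'   `truth`), `qq` and `rel_error` tables per estimator.
#' @export
run_usfs_experiment <- function(cfg, sample_size,
                                estimators = c("max_pp", "max_pp_filtered",
                                               "posterior_average",
                                               "posterior_average_corrected"),
                                replicates = cfg$replicates, seed = 1,
                                model = substitution_model("jc69",
                                                           mu = cfg$mu)) {
  set.seed(seed)
  cfg_n <- cfg
  cfg_n$n_diploids <- as.integer(sample_size)
  n_hap <- 2L * cfg_n$n_diploids
  pooled <- list(truth = numeric(n_hap - 1L))
  for (e in estimators) pooled[[e]] <- numeric(n_hap - 1L)
  Lx <- numeric(n_hap - 1L); Lxp <- numeric(n_hap - 1L)
  for (rep in seq_len(replicates)) {
    sim <- simulate_scenario(cfg_n)
    sr <- sim_site_records(sim, which = "segregating")
    pol <- suppressMessages(
      polarise_sites(sr, sim, model, policy = "usfs"))
    pooled$truth <- pooled$truth + usfs_truth(pol, sim$truth)$E
    for (e in estimators) {
      u <- switch(e,
        max_pp = usfs_max_pp(pol, filtered = FALSE),
        max_pp_filtered = usfs_max_pp(pol, filtered = TRUE),
        posterior_average = usfs_posterior_average(pol, FALSE),
        posterior_average_corrected = usfs_posterior_average(pol, TRUE))
      pooled[[e]] <- pooled[[e]] + u$E
      if (e == estimators[[1L]]) {
        Lx <- Lx + u$Lx
        Lxp <- Lxp + u$Lx_prime
      }
    }
  }
  out_usfs <- list(truth = usfs(pooled$truth, n_hap, "truth"))
  qq <- list(); rel <- list()
  for (e in estimators) {
    out_usfs[[e]] <- usfs(pooled[[e]], n_hap, e, Lx = Lx, Lx_prime = Lxp)
    qq[[e]] <- qq_compare(out_usfs[[e]], out_usfs$truth)
    rel[[e]] <- relative_error(out_usfs[[e]], out_usfs$truth)
  }
  list(usfs = out_usfs, qq = qq, rel_error = rel)
}
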