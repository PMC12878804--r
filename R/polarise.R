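#' Per-site haplotype records
#'
#' Bundles the phased states of every haplotype at a set of sites with their
#' genomic coordinates. Positions are 0-based internally; 1-based VCF
#' coordinates are converted at the I/O boundary only.
#'
#' @param positions integer vector of 0-based positions (bp).
#' @param genotypes character matrix, sites x haplotypes, entries in
#'   A, C, G, T; column names are haplotype identifiers matching the tree
#'   leaf labels.
#' @param chrom chromosome name(s), recycled.
#' @return an object of class `site_records`.
#' @export
site_records <- function(positions, genotypes, chrom = "1") {
  genotypes <- as.matrix(genotypes)
  if (is.null(colnames(genotypes)))
    stop("genotype matrix needs haplotype ids as column names")
  if (length(positions) != nrow(genotypes))
    stop("one position per genotype row required")
  bad <- !(genotypes %in% NUCS)
  if (any(bad))
    stop("invalid genotype states: ",
         paste(unique(genotypes[bad]), collapse = ", "))
  structure(list(chrom = rep_len(as.character(chrom), length(positions)),
                 position = as.integer(positions), genotypes = genotypes),
            class = "site_records")
}

#' @export
print.site_records <- function(x, ...) {
  cat("<site_records> ", length(x$position), " sites, ",
      ncol(x$genotypes), " haplotypes\n", sep = "")
  invisible(x)
}

#' Polarise segregating sites from their local genealogies
#'
#' The per-site pipeline: resolve each site's local genealogy from
#' `tree_source`, run the joint ancestral reconstruction
#' ([joint_reconstruct()]), restrict the root posterior to the observed
#' alleles, call the maximum-posterior allele as ancestral, classify the
#' genealogy by parsimony ([classify_site()]) and apply the filter
#' `policy`. Monomorphic sites are skipped with a logged count.
#'
#' @param sites a [site_records()] object.
#' @param tree_source a `tree_sequence`, `tree_list`, simulation result, or
#'   a function `position -> local_tree`.
#' @param model a [substitution_model()].
#' @param policy filter policy, see [apply_filters()].
#' @param candidates_all4 consider all four nucleotides as candidate
#'   ancestral states in the parsimony classification instead of only the
#'   observed alleles.
#' @return data.frame with one row per segregating site: coordinates,
#'   alleles and counts, the ancestral call and its restricted posterior
#'   probability, the unrestricted (`p_*`) and restricted (`pr_*`) root
#'   posteriors, classification flags, `kept` under the policy, the derived
#'   allele count (`NA` for multi-allelic sites) and the method tag.
#'   Attribute `n_skipped` counts non-segregating input sites.
#' @export
polarise_sites <- function(sites, tree_source, model,
                           policy = c("strict", "usfs", "real-data", "none"),
                           candidates_all4 = FALSE) {
  policy <- match.arg(policy)
  stopifnot(inherits(sites, "site_records"))
  haps <- colnames(sites$genotypes)
  n <- length(haps)
  nsite <- length(sites$position)
  if (nsite == 0L) return(empty_polarised())

  # resolve one canonical tree per site (deduplicated for interval sources)
  if (inherits(tree_source, "polar_sim")) tree_source <- tree_source$ts
  if (inherits(tree_source, "tree_sequence") && !isTRUE(tree_source$prune)) {
    ts <- tree_source
    idx <- findInterval(sites$position, ts$left)
    bad <- idx < 1L | sites$position >= ts$right[pmax(idx, 1L)] |
      sites$position < ts$left[pmax(idx, 1L)]
    if (any(bad))
      stop("no stored tree covers position(s) ",
           paste(utils::head(sites$position[bad]), collapse = ", "))
    uniq <- sort(unique(idx))
    canonical <- identical(ts$labels, haps)
    trees <- lapply(uniq, function(i) {
      lt <- structure(list(parent = ts$parent[, i], time = ts$time[, i],
                           labels = c(ts$labels,
                                      rep(NA_character_,
                                          nrow(ts$parent) -
                                            length(ts$labels)))),
                      class = "local_tree")
      if (canonical) lt else canonical_leaf_order(lt, haps)
    })
    site_tree <- match(idx, uniq)
  } else {
    trees <- lapply(sites$position, function(p)
      canonical_leaf_order(local_tree_at(tree_source, p), haps))
    site_tree <- seq_len(nsite)
  }

  states <- matrix(nuc_to_int(sites$genotypes), nrow = nsite)
  res <- polarise_batch_cpp(lapply(trees, tree_parent0),
                            lapply(trees, `[[`, "time"),
                            site_tree - 1L, states - 1L,
                            model_code(model), model$mu, model$kappa,
                            unname(model$pi), candidates_all4)
  seg <- !is.na(res[, 9])
  n_skipped <- sum(!seg)
  if (n_skipped > 0)
    message(n_skipped, " non-segregating site(s) skipped")

  cnt <- sapply(1:4, function(s) rowSums(states == s))
  if (nsite == 1L) cnt <- matrix(cnt, nrow = 1L)
  # observed-allele pattern code (1..15), vectorised string assembly
  pattern <- (cnt[, 1] > 0) + 2L * (cnt[, 2] > 0) + 4L * (cnt[, 3] > 0) +
    8L * (cnt[, 4] > 0)
  alleles <- character(nsite)
  counts_str <- character(nsite)
  for (p in unique(pattern)) {
    obs <- which(bitwAnd(p, c(1L, 2L, 4L, 8L)) > 0L)
    rows <- pattern == p
    alleles[rows] <- paste(NUCS[obs], collapse = "/")
    counts_str[rows] <- do.call(paste, c(lapply(obs, function(s)
      cnt[rows, s]), sep = "/"))
  }
  call <- int_to_nuc(res[, 9] + 1L)
  call_cnt <- cnt[cbind(seq_len(nsite), res[, 9] + 1L)]
  derived_count <- ifelse(res[, 16] == 2, n - call_cnt, NA_real_)
  p_anc <- res[cbind(seq_len(nsite), 5L + res[, 9])]

  out <- data.frame(
    chrom = sites$chrom,
    pos = sites$position + 1L,
    alleles = alleles,
    counts = counts_str,
    n = n,
    n_alleles = res[, 16],
    cnt_A = cnt[, 1], cnt_C = cnt[, 2], cnt_G = cnt[, 3], cnt_T = cnt[, 4],
    ancestral_call = call,
    p_ancestral = p_anc,
    p_A = res[, 1], p_C = res[, 2], p_G = res[, 3], p_T = res[, 4],
    pr_A = res[, 5], pr_C = res[, 6], pr_G = res[, 7], pr_T = res[, 8],
    tie = res[, 10] == 1,
    min_mutations = res[, 11],
    non_informative = res[, 12] == 1,
    multiple_mutations = res[, 13] == 1,
    homoplasy = res[, 14] == 1,
    polytomy_mutation = res[, 15] == 1,
    derived_count = derived_count,
    method = "arg",
    stringsAsFactors = FALSE)
  out$kept <- switch(policy,
    "strict" = !out$non_informative & !out$multiple_mutations &
               !out$polytomy_mutation,
    "usfs" = out$min_mutations <= 2,
    "real-data" = !out$non_informative & out$min_mutations <= out$n_alleles,
    "none" = rep(TRUE, nsite))
  out <- out[seg, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  attr(out, "policy") <- policy
  out
}

empty_polarised <- function() {
  out <- data.frame(chrom = character(0), pos = integer(0),
                    alleles = character(0), counts = character(0),
                    n = integer(0), n_alleles = numeric(0))
  attr(out, "n_skipped") <- 0L
  out
}

#' Maximum-frequency baseline polariser
#'
#' Treats the most frequent (major) allele as ancestral. An exact tie for
#' the maximum is reported as ambiguous / missing.
#'
#' @param counts named numeric vector of allele counts at one site.
#' @return list with `allele` (`NA` when ambiguous) and `ambiguous`.
#' @export
max_frequency_polariser <- function(counts) {
  counts <- counts[counts > 0]
  best <- max(counts)
  winners <- sort(names(counts)[counts == best])
  if (length(winners) > 1L) list(allele = NA_character_, ambiguous = TRUE)
  else list(allele = winners, ambiguous = FALSE)
}

#' Random-frequency baseline polariser
#'
#' Samples the ancestral allele with probability equal to its sample
#' frequency. Reproducible under `set.seed()` (or the optional `seed`).
#'
#' @param counts named numeric vector of allele counts at one site.
#' @param seed optional integer seed applied before drawing.
#' @return list with `allele`.
#' @export
random_frequency_polariser <- function(counts, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- counts[counts > 0]
  if (length(counts) == 1L) return(list(allele = names(counts)))
  list(allele = sample(names(counts), 1L, prob = counts / sum(counts)))
}

# vectorised baseline calls over a site_records object
baseline_calls <- function(sites, method = c("max_frequency",
                                             "random_frequency"),
                           seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  states <- matrix(nuc_to_int(sites$genotypes),
                   nrow = length(sites$position))
  calls <- vapply(seq_len(nrow(states)), function(i) {
    cnt <- tabulate(states[i, ], nbins = 4)
    names(cnt) <- NUCS
    r <- if (method == "max_frequency") max_frequency_polariser(cnt)
         else random_frequency_polariser(cnt)
    if (is.na(r$allele)) NA_character_ else r$allele
  }, character(1))
  data.frame(pos = sites$position + 1L, ancestral_call = calls,
             method = method, stringsAsFactors = FALSE)
}

#' Accuracy of polarisation calls against the simulated truth
#'
#' Joins calls to the true ancestral alleles and reports overall accuracy,
#' accuracy stratified by the frequency class of the true ancestral allele
#' (major / equal / minor), the proportion of kept sites, and counts of the
#' classification flags.
#'
#' @param polarised output of [polarise_sites()] (or a data.frame with at
#'   least `pos`, `ancestral_call` and the `cnt_*` columns).
#' @param truth data.frame with columns `pos` (1-based) and
#'   `ancestral_state`.
#' @return list with elements `overall` (accuracy on all calls and on kept
#'   calls), `by_stratum`, `kept_prop`, and `flags`.
#' @export
accuracy_report <- function(polarised, truth) {
  i <- match(polarised$pos, truth$pos)
  if (anyNA(i))
    stop("sites absent from truth: ",
         paste(utils::head(polarised$pos[is.na(i)]), collapse = ", "))
  anc <- truth$ancestral_state[i]
  cntm <- as.matrix(polarised[, c("cnt_A", "cnt_C", "cnt_G", "cnt_T")])
  anc_cnt <- cntm[cbind(seq_len(nrow(cntm)), nuc_to_int(anc))]
  other_max <- vapply(seq_len(nrow(cntm)), function(k) {
    v <- cntm[k, ]
    v[nuc_to_int(anc[k])] <- -1L
    max(v)
  }, numeric(1))
  stratum <- ifelse(anc_cnt > other_max, "major",
                    ifelse(anc_cnt == other_max, "equal", "minor"))
  correct <- polarised$ancestral_call == anc
  kept <- if ("kept" %in% names(polarised)) polarised$kept
          else rep(TRUE, nrow(polarised))
  strat_tab <- function(sel) {
    do.call(rbind, lapply(c("major", "equal", "minor"), function(s) {
      j <- sel & stratum == s
      data.frame(stratum = s, n_sites = sum(j),
                 accuracy = if (any(j)) mean(correct[j]) else NA_real_)
    }))
  }
  all_sel <- rep(TRUE, nrow(polarised))
  overall <- data.frame(
    subset = c("all", "kept"),
    n_sites = c(sum(all_sel), sum(kept)),
    accuracy = c(mean(correct), if (any(kept)) mean(correct[kept]) else NA_real_))
  by_stratum <- rbind(cbind(subset = "all", strat_tab(all_sel)),
                      cbind(subset = "kept", strat_tab(kept)))
  flags <- c(
    non_informative = sum(polarised$non_informative %||% FALSE),
    multiple_mutations = sum(polarised$multiple_mutations %||% FALSE),
    homoplasy = sum(polarised$homoplasy %||% FALSE),
    polytomy_mutation = sum(polarised$polytomy_mutation %||% FALSE))
  list(overall = overall, by_stratum = by_stratum,
       kept_prop = mean(kept), flags = flags,
       stratum = stratum, correct = correct)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write per-site polarisation results as TSV
#' @param polarised output of [polarise_sites()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_polarised_tsv <- function(polarised, path) {
  write.table(polarised, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
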