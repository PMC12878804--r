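#' Joint ancestral-state reconstruction on a local genealogy
#'
#' Maximum-probability (joint, max-product) assignment of nucleotide states
#' to all internal nodes, computed by dynamic programming entirely in log
#' space: the score of a subtree given its top state is the sum over
#' children of the best log transition + child score, so no conditional
#' likelihoods are averaged at inner nodes and trees with hundreds of leaves
#' do not underflow. The empirical-Bayes posterior of each root state is
#' obtained by log-sum-exp over the per-root-state joint scores combined
#' with the root prior `model$pi`.
#'
#' The returned posterior is a "joint-path" posterior (built from maximum
#' joint scores, not sum-product marginals).
#'
#' @param tree a `local_tree`; polytomies are handled natively.
#' @param leaf_states named character vector of nucleotides, names matching
#'   the tree's leaf labels (or unnamed, in leaf node order).
#' @param model a [substitution_model()]; its `pi` is the root prior.
#' @return an object of class `root_posterior`: list with `posterior`
#'   (named, sums to 1), `score` (log prior + joint log-likelihood per root
#'   state), `loglik` (joint log-likelihood per root state), `assignment`
#'   (4 x nodes character matrix, the best joint assignment for each
#'   candidate root state), `tied` (TRUE if the posterior argmax is not
#'   unique), `tree`.
#' @export
joint_reconstruct <- function(tree, leaf_states, model) {
  validate_local_tree(tree)
  st <- match_leaf_states(tree, leaf_states)
  res <- reconstruct_cpp(tree_parent0(tree), tree$time, st - 1L,
                         model_code(model), model$mu, model$kappa,
                         unname(model$pi))
  posterior <- setNames(res$posterior, NUCS)
  best <- max(posterior)
  tied <- sum(posterior >= best - 1e-12 * max(1, best)) > 1L
  assignment <- matrix(int_to_nuc(res$assignment + 1L), nrow = 4,
                       dimnames = list(NUCS, NULL))
  structure(list(posterior = posterior,
                 score = setNames(res$score, NUCS),
                 loglik = setNames(res$loglik, NUCS),
                 assignment = assignment, tied = tied, tree = tree),
            class = "root_posterior")
}

#' @export
print.root_posterior <- function(x, ...) {
  cat("<root_posterior>\n")
  print(round(x$posterior, 6))
  if (x$tied) cat("  (argmax tied)\n")
  invisible(x)
}

# leaf states as integer codes 1..4 aligned to node ids (NA for internals)
match_leaf_states <- function(tree, leaf_states) {
  leaf <- is_leaf(tree)
  nn <- length(tree$parent)
  st <- rep(NA_integer_, nn)
  if (is.null(names(leaf_states))) {
    if (length(leaf_states) != sum(leaf))
      stop("unnamed leaf_states must have one state per leaf")
    st[leaf] <- nuc_to_int(toupper(leaf_states))
  } else {
    idx <- match(tree$labels[leaf], names(leaf_states))
    if (anyNA(idx))
      stop("missing state for leaf: ",
           paste(tree$labels[leaf][is.na(idx)], collapse = ", "))
    st[leaf] <- nuc_to_int(toupper(leaf_states[idx]))
  }
  if (anyNA(st[leaf]))
    stop("missing state for leaf: ",
         paste(tree$labels[leaf][is.na(st[leaf])], collapse = ", "))
  st[!leaf] <- 0L   # ignored by the recursion
  st
}

tree_parent0 <- function(tree) {
  p <- tree$parent
  p[is.na(p)] <- 0L
  p - 1L
}

#' Call the ancestral allele from a root posterior
#'
#' Restricts the root posterior to the alleles observed at the site,
#' renormalises, and returns the highest-posterior observed allele. Exact
#' ties are flagged ambiguous and resolved lexicographically (A < C < G <
#' T). With a single observed allele the call has probability 1.
#'
#' @param p a `root_posterior` (or any list with a named `posterior`).
#' @param observed_alleles character vector of alleles seen at the site.
#' @return list with `allele`, `probability` (restricted posterior of the
#'   call), `ambiguous` flag, and the full `restricted` posterior.
#' @export
ancestral_call <- function(p, observed_alleles) {
  obs <- sort(unique(toupper(observed_alleles)))
  nuc_to_int(obs)  # validates
  r <- p$posterior[obs]
  tot <- sum(r)
  r <- if (tot > 0) r / tot else setNames(rep(1 / length(obs), length(obs)), obs)
  best <- max(r)
  winners <- names(r)[r >= best - 1e-12 * max(1, best)]
  list(allele = winners[[1L]], probability = unname(r[winners[[1L]]]),
       ambiguous = length(winners) > 1L, restricted = r)
}
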