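#' Minimal mutation count on a genealogy for a fixed root state
#'
#' Fixed-root small parsimony (Hartigan/Sankoff with unit costs): the
#' minimum number of state changes on edges needed to explain the leaf
#' states when the root is constrained to `fixed_root_state`, together with
#' one optimal placement. Ties in the down pass prefer the parent's state,
#' so each change is recorded on the edge above the highest node whose
#' assigned state differs from its parent's (topmost-change convention).
#'
#' @param tree a `local_tree` (polytomies allowed).
#' @param leaf_states named character vector of leaf nucleotides.
#' @param fixed_root_state nucleotide constrained at the root.
#' @return list with `count`, `placements` (data.frame: `node`, `from`,
#'   `to`, one row per mutated edge, `node` being the child end) and
#'   `polytomy` (TRUE if a mutation sits on a node whose parent has more
#'   than two children).
#' @export
map_mutations <- function(tree, leaf_states, fixed_root_state) {
  validate_local_tree(tree)
  st <- match_leaf_states(tree, leaf_states)
  rs <- nuc_to_int(toupper(fixed_root_state))
  if (length(rs) != 1L || is.na(rs)) stop("invalid root state")
  res <- sankoff_cpp(tree_parent0(tree), st - 1L, rs - 1L)
  list(count = res$count,
       placements = data.frame(node = res$mut_node,
                               from = int_to_nuc(res$mut_from + 1L),
                               to = int_to_nuc(res$mut_to + 1L)),
       polytomy = res$polytomy)
}

#' Classify a segregating site by parsimony on its genealogy
#'
#' Runs [map_mutations()] for every candidate ancestral state and derives
#' the classification flags:
#' * `non_informative` - two or more candidates attain the minimal mutation
#'   count, so parsimony cannot distinguish the ancestral state;
#' * `multiple_mutations` - the overall minimum exceeds one;
#' * `homoplasy` - multiple mutations with exactly two observed alleles
#'   (the same allele arose more than once);
#' * `polytomy_mutation` - under some minimising candidate a mutation is
#'   placed on a node whose parent has more than two children.
#'
#' @param tree a `local_tree`.
#' @param leaf_states named character vector of leaf nucleotides; must be
#'   segregating (at least two distinct states).
#' @param candidate_states candidate ancestral states; defaults to the
#'   observed alleles (an unobserved state can never beat an observed one
#'   when the observed minimum is a single mutation); set to
#'   `c("A","C","G","T")` to consider all four.
#' @return an object of class `site_classification`.
#' @export
classify_site <- function(tree, leaf_states, candidate_states = NULL) {
  validate_local_tree(tree)
  st <- match_leaf_states(tree, leaf_states)
  leaf <- is_leaf(tree)
  obs <- sort(unique(st[leaf]))
  if (length(obs) < 2L) stop("site is monomorphic; classification needs a segregating site")
  cand <- if (is.null(candidate_states)) obs
          else sort(unique(nuc_to_int(toupper(candidate_states))))
  res <- classify_cpp(tree_parent0(tree), st - 1L, cand - 1L)
  counts <- setNames(res$counts, int_to_nuc(cand))
  min_count <- res$min_count
  min_cands <- names(counts)[counts == min_count]
  first_min <- map_mutations(tree, leaf_states, min_cands[[1L]])
  structure(list(
    counts = counts,
    min_count = min_count,
    min_candidates = min_cands,
    n_observed_alleles = length(obs),
    non_informative = res$n_min >= 2L,
    multiple_mutations = min_count > 1L,
    homoplasy = min_count > 1L && length(obs) == 2L,
    polytomy_mutation = isTRUE(res$polytomy),
    placements = first_min$placements),
    class = "site_classification")
}

#' @export
print.site_classification <- function(x, ...) {
  cat("<site_classification> min mutations ", x$min_count, " (candidates: ",
      paste(x$min_candidates, collapse = ","), ")\n", sep = "")
  flags <- c(non_informative = x$non_informative,
             multiple_mutations = x$multiple_mutations,
             homoplasy = x$homoplasy,
             polytomy_mutation = x$polytomy_mutation)
  cat("  flags:", paste(names(flags)[flags], collapse = ", "), "\n")
  invisible(x)
}

#' Site filter policies
#'
#' Decides whether a classified site is kept for downstream analysis:
#' * `"strict"` (polarisation): drop non-informative sites, sites needing
#'   more than one mutation, and mutations under polytomies;
#' * `"usfs"` (spectrum estimation): drop only sites needing more than two
#'   mutations;
#' * `"real-data"`: drop non-informative sites and sites whose inferred
#'   mutation count exceeds the number of observed alleles;
#' * `"none"`: keep everything.
#'
#' @param classification a `site_classification`.
#' @param policy policy name.
#' @return logical: keep the site?
#' @export
apply_filters <- function(classification,
                          policy = c("strict", "usfs", "real-data", "none")) {
  policy <- match.arg(policy)
  c <- classification
  switch(policy,
    "strict" = !c$non_informative && !c$multiple_mutations &&
               !c$polytomy_mutation,
    "usfs" = c$min_count <= 2L,
    "real-data" = !c$non_informative &&
                  c$min_count <= c$n_observed_alleles,
    "none" = TRUE)
}
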