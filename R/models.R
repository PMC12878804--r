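#' Nucleotide substitution model
#'
#' Time-reversible models used for ancestral reconstruction and simulation:
#' JC69 (equal rates) and K80 (distinct transition and transversion rates,
#' ratio `kappa`). Both are parameterised so the total substitution rate per
#' site is `mu` per generation; branch lengths are times in generations, so
#' the expected number of substitutions over a branch of length `t` is
#' `mu * t`. Trees measured in substitutions/site can be used with `mu = 1`.
#'
#' @param model `"jc69"` or `"k80"`.
#' @param mu substitution rate per site per generation (> 0).
#' @param kappa transition/transversion rate ratio (K80 only; `kappa = 1`
#'   reduces K80 to JC69).
#' @param pi root state distribution over A, C, G, T. The reconstruction
#'   default is uniform; simulations may use a biased root distribution.
#' @return an object of class `substitution_model`.
#' @export
substitution_model <- function(model = c("jc69", "k80"), mu,
                               kappa = 1, pi = rep(0.25, 4)) {
  model <- match.arg(model)
  if (!is.numeric(mu) || mu <= 0) stop("mu must be positive")
  if (!is.numeric(kappa) || kappa <= 0) stop("kappa must be positive")
  pi <- as.numeric(pi)
  if (length(pi) != 4 || any(pi < 0) || abs(sum(pi) - 1) > 1e-9)
    stop("pi must be 4 non-negative frequencies summing to 1")
  structure(list(model = model, mu = mu, kappa = kappa,
                 pi = setNames(pi, NUCS)),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("<substitution_model> ", toupper(x$model), ", mu = ", format(x$mu),
      if (x$model == "k80") paste0(", kappa = ", format(x$kappa)) else "",
      "\n", sep = "")
  invisible(x)
}

model_code <- function(m) if (m$model == "jc69") 0L else 1L

#' Transition probability matrix over a branch
#'
#' Closed-form `P(t)` for the model: under JC69 with `d = mu * t`,
#' `P(i -> i) = 1/4 + 3/4 exp(-4d/3)` and
#' `P(i -> j) = 1/4 - 1/4 exp(-4d/3)`; under K80 the standard two-parameter
#' form with rate `beta = mu / (kappa + 2)` so the total rate is `mu`.
#'
#' @param model a [substitution_model()].
#' @param branch_time branch length in generations (>= 0).
#' @return 4 x 4 row-stochastic matrix with A, C, G, T dimnames.
#' @export
transition_matrix <- function(model, branch_time) {
  if (branch_time < 0) stop("branch_time must be non-negative")
  P <- transition_matrix_cpp(model_code(model), model$mu, model$kappa,
                             branch_time)
  dimnames(P) <- list(NUCS, NUCS)
  P
}

#' Single transition probability over a branch
#'
#' @inheritParams transition_matrix
#' @param from_state,to_state nucleotides in `A`, `C`, `G`, `T`.
#' @return probability of observing `to_state` at the bottom of a branch of
#'   length `branch_time` whose top carries `from_state`.
#' @export
transition_prob <- function(model, from_state, to_state, branch_time) {
  P <- transition_matrix(model, branch_time)
  P[nuc_to_int(from_state), nuc_to_int(to_state)]
}
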