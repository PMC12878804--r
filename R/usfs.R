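#' Unfolded site-frequency spectrum container
#'
#' Expected number of biallelic sites per derived-allele-count category
#' `x = 1..n-1`, together with the folded-class site tallies used by the
#' filter-bias correction: `Lx` is the number of biallelic sites whose
#' allele counts are `{x, n-x}` (in whichever order) and `Lx_prime` the
#' number of those kept after filtering. Folded classes are unordered, so
#' `Lx = L(n-x)`.
#'
#' @param E numeric vector of expected counts, length `n - 1`.
#' @param n number of haplotypes.
#' @param estimator tag describing how `E` was computed.
#' @param Lx,Lx_prime per-category folded-class tallies (optional).
#' @return an object of class `usfs`.
#' @export
usfs <- function(E, n, estimator = "counts", Lx = NULL, Lx_prime = NULL) {
  stopifnot(length(E) == n - 1, all(E >= 0 | is.na(E)))
  structure(list(E = as.numeric(E), n = as.integer(n),
                 estimator = estimator, Lx = Lx, Lx_prime = Lx_prime),
            class = "usfs")
}

#' @export
print.usfs <- function(x, ...) {
  cat("<usfs> n = ", x$n, ", estimator = ", x$estimator,
      ", total mass ", format(sum(x$E, na.rm = TRUE)), "\n", sep = "")
  invisible(x)
}

#' Tabulate a uSFS
#' @param u a [usfs()] object.
#' @return data.frame with `x`, `E_Dx`, `Lx`, `Lx_prime`, `freq`.
#' @export
usfs_table <- function(u) {
  tot <- sum(u$E, na.rm = TRUE)
  data.frame(x = seq_len(u$n - 1L), E_Dx = u$E,
             Lx = u$Lx %||% NA, Lx_prime = u$Lx_prime %||% NA,
             freq = if (tot > 0) u$E / tot else NA_real_)
}

# biallelic rows with per-site category bookkeeping:
# x_call = derived count under the called ancestral allele;
# x1/p1 = category and restricted posterior mass if allele1 is ancestral
# (then the derived allele is allele2 with count c2 -> category c2), etc.
biallelic_frame <- function(polarised) {
  b <- polarised[polarised$n_alleles == 2 & !is.na(polarised$ancestral_call), ,
                 drop = FALSE]
  if (!nrow(b)) return(b)
  cntm <- as.matrix(b[, c("cnt_A", "cnt_C", "cnt_G", "cnt_T")])
  prm <- as.matrix(b[, c("pr_A", "pr_C", "pr_G", "pr_T")])
  a1 <- integer(nrow(b)); a2 <- integer(nrow(b))
  for (k in seq_len(nrow(b))) {
    obs <- which(cntm[k, ] > 0)
    a1[k] <- obs[1L]; a2[k] <- obs[2L]
  }
  b$c1 <- cntm[cbind(seq_len(nrow(b)), a1)]
  b$c2 <- cntm[cbind(seq_len(nrow(b)), a2)]
  b$p1 <- prm[cbind(seq_len(nrow(b)), a1)]   # P(allele1 ancestral)
  b$p2 <- prm[cbind(seq_len(nrow(b)), a2)]
  b
}

#' uSFS by maximum-posterior counting
#'
#' Each biallelic site adds one full count to the category of its called
#' derived-allele count ("MAX PP"); with `filtered = TRUE` only sites kept
#' by the filter policy contribute ("MAX PP + filtering"). Because the
#' probability that a genealogy is non-informative depends on the derived
#' allele frequency, the filtered variant is biased relative to the truth.
#'
#' @param polarised output of [polarise_sites()].
#' @param filtered restrict to kept sites.
#' @param n_haplotypes sample size; needed only when `polarised` is empty.
#' @return a [usfs()] object.
#' @export
usfs_max_pp <- function(polarised, filtered = FALSE, n_haplotypes = NULL) {
  b <- biallelic_frame(polarised)
  n <- usfs_n(b, polarised, n_haplotypes)
  tal <- fold_tallies(b, n)
  if (filtered) b <- b[b$kept, , drop = FALSE]
  E <- tabulate(b$derived_count, nbins = n - 1L)
  usfs(E, n, if (filtered) "max_pp_filtered" else "max_pp",
       Lx = tal$Lx, Lx_prime = tal$Lxp)
}

usfs_n <- function(b, polarised, n_haplotypes) {
  if (nrow(b)) return(b$n[[1L]])
  if (nrow(polarised)) return(polarised$n[[1L]])
  if (is.null(n_haplotypes))
    stop("empty input: supply n_haplotypes to size the spectrum")
  as.integer(n_haplotypes)
}

fold_tallies <- function(b, n) {
  Lx <- numeric(n - 1L); Lxp <- numeric(n - 1L)
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      xs <- unique(c(b$c1[k], b$c2[k]))
      Lx[xs] <- Lx[xs] + 1
      if (isTRUE(b$kept[k])) Lxp[xs] <- Lxp[xs] + 1
    }
  }
  list(Lx = Lx, Lxp = Lxp)
}

#' uSFS by posterior averaging
#'
#' Splits each biallelic site's mass across its two complementary
#' categories according to the restricted root posterior: a site with
#' allele counts `x` and `n - x` contributes `P_i(Dx)` (the posterior that
#' the allele with `n - x` copies is ancestral) to `E[Dx]` and the
#' complement to `E[D(n-x)]`, so `E[Dx] = sum_i P_i(Dx)` and the total mass
#' equals the number of contributing sites.
#'
#' With `use_filter_correction = TRUE` the average is taken over kept sites
#' only and rescaled by the full folded-class tally:
#' `E[Dx] = Lx * mean over kept sites in class {x, n-x} of P_i(Dx)`,
#' which corrects the frequency-dependent bias of filtering. A folded class
#' with sites but no kept site (`Lx' = 0`) triggers a warning and
#' contributes zero mass.
#'
#' @param polarised output of [polarise_sites()].
#' @param use_filter_correction apply the `Lx / Lx'` reweighting.
#' @param n_haplotypes sample size; needed only when `polarised` is empty.
#' @return a [usfs()] object.
#' @export
usfs_posterior_average <- function(polarised, use_filter_correction = FALSE,
                                   n_haplotypes = NULL) {
  b <- biallelic_frame(polarised)
  n <- usfs_n(b, polarised, n_haplotypes)
  tal <- fold_tallies(b, n)
  E <- numeric(n - 1L)
  if (!use_filter_correction) {
    if (nrow(b)) {
      for (k in seq_len(nrow(b))) {
        # allele1 ancestral -> derived is allele2, category c2
        E[b$c2[k]] <- E[b$c2[k]] + b$p1[k]
        E[b$c1[k]] <- E[b$c1[k]] + b$p2[k]
      }
    }
    return(usfs(E, n, "posterior_average", Lx = tal$Lx, Lx_prime = tal$Lxp))
  }
  kept <- b[b$kept, , drop = FALSE]
  mass <- numeric(n - 1L)   # sum over kept sites of P_i(Dx)
  if (nrow(kept)) {
    for (k in seq_len(nrow(kept))) {
      mass[kept$c2[k]] <- mass[kept$c2[k]] + kept$p1[k]
      mass[kept$c1[k]] <- mass[kept$c1[k]] + kept$p2[k]
    }
  }
  starved <- FALSE
  for (x in seq_len(n - 1L)) {
    if (tal$Lx[x] == 0) next
    if (tal$Lxp[x] == 0) { starved <- TRUE; next }
    E[x] <- tal$Lx[x] * mass[x] / tal$Lxp[x]
  }
  if (starved)
    warning("folded class with sites but no kept site; ",
            "its corrected mass is set to 0")
  usfs(E, n, "posterior_average_corrected", Lx = tal$Lx, Lx_prime = tal$Lxp)
}

#' True uSFS from a simulation truth table
#'
#' Counts biallelic sites per true derived-allele-count category using the
#' simulated ancestral states.
#'
#' @param polarised output of [polarise_sites()] (for allele counts).
#' @param truth data.frame with `pos` and `ancestral_state`.
#' @return a [usfs()] object.
#' @export
usfs_truth <- function(polarised, truth) {
  b <- biallelic_frame(polarised)
  n <- if (nrow(b)) b$n[[1L]] else polarised$n[[1L]]
  i <- match(b$pos, truth$pos)
  if (anyNA(i)) stop("sites absent from truth table")
  anc <- truth$ancestral_state[i]
  cntm <- as.matrix(b[, c("cnt_A", "cnt_C", "cnt_G", "cnt_T")])
  anc_cnt <- cntm[cbind(seq_len(nrow(b)), nuc_to_int(anc))]
  x <- b$n - anc_cnt
  ok <- x >= 1 & x <= n - 1
  usfs(tabulate(x[ok], nbins = n - 1L), n, "truth")
}

#' Quantile-quantile comparison of two spectra
#'
#' For each category boundary, the cumulative proportion of the reference
#' spectrum and of the estimate; identical spectra fall on the diagonal.
#'
#' @param est,ref [usfs()] objects with the same `n`.
#' @return data.frame with `x`, `ref_cum`, `est_cum`.
#' @export
qq_compare <- function(est, ref) {
  if (est$n != ref$n) stop("spectra have different n")
  te <- sum(est$E, na.rm = TRUE); tr <- sum(ref$E, na.rm = TRUE)
  if (te <= 0 || tr <= 0) stop("cannot compare a zero-total spectrum")
  data.frame(x = seq_len(est$n - 1L),
             ref_cum = cumsum(ifelse(is.na(ref$E), 0, ref$E)) / tr,
             est_cum = cumsum(ifelse(is.na(est$E), 0, est$E)) / te)
}

#' Per-category relative error of an estimated spectrum
#'
#' `(est_freq - true_freq) / true_freq` per category, frequencies being
#' `E[Dx]` normalised by the total mass. Categories empty in the truth are
#' reported as `NA`.
#'
#' @param est,truth [usfs()] objects with the same `n`.
#' @return data.frame with `x`, `est_freq`, `true_freq`, `rel_error`.
#' @export
relative_error <- function(est, truth) {
  if (est$n != truth$n) stop("spectra have different n")
  fe <- est$E / sum(est$E, na.rm = TRUE)
  ft <- truth$E / sum(truth$E, na.rm = TRUE)
  re <- ifelse(ft > 0, (fe - ft) / ft, NA_real_)
  data.frame(x = seq_len(est$n - 1L), est_freq = fe, true_freq = ft,
             rel_error = re)
}

#' Write a uSFS as TSV and/or JSON
#' @param u a [usfs()] object.
#' @param tsv,json output paths (either may be `NULL`).
#' @return invisibly, the table written.
#' @export
write_usfs <- function(u, tsv = NULL, json = NULL) {
  tab <- usfs_table(u)
  if (!is.null(tsv))
    write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(n = u$n, estimator = u$estimator,
                              E_Dx = u$E, Lx = u$Lx, Lx_prime = u$Lx_prime),
                         json, auto_unbox = TRUE, digits = NA)
  invisible(tab)
}
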