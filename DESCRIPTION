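Package: argpolar
Title: Outgroup-Free SNP Polarisation from Local Genealogies of the
    Ancestral Recombination Graph
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers the ancestral allele at segregating sites without an
    outgroup, using the local genealogy of the ancestral recombination
    graph (ARG) at each SNP. For every site the marginal rooted tree is
    extracted from a tree sequence (or built by UPGMA from pairwise
    TMRCA matrices), the joint maximum-probability assignment of
    ancestral states is computed in log space under a nucleotide
    substitution model (JC69 or K80), and an empirical-Bayes posterior
    over root states is obtained. Fixed-root parsimony classifies
    genealogies as informative or non-informative and detects multiple
    mutations, homoplasy and mutations under polytomies; configurable
    filter policies combine these flags. The unfolded site-frequency
    spectrum is estimated by maximum-posterior counting or by posterior
    averaging with a reweighting that corrects the bias introduced by
    filtering. A coalescent simulator with recombination (SMC'
    approximation), piecewise demography and JC69/K80 mutation models
    generates ground-truth data for validation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
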