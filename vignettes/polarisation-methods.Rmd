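---
title: "Polarising SNPs from ARG local genealogies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polarising SNPs from ARG local genealogies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(argpolar)
```

## The problem

Many population-genetic analyses need to know, for every segregating site,
which allele is ancestral and which is derived ("polarisation"): the
unfolded site-frequency spectrum (uSFS), selection scans, allele-age
estimation and several ARG inference tools all consume this information.
The standard approach compares the focal population to one or more outgroup
genomes, which fails exactly where it is most needed — species without
close outgroups, or genomic regions that cannot be aligned across species.

`argpolar` polarises without any outgroup. The genealogical history of the
sample itself carries the signal: at every position the sample is related
by a rooted local coalescent tree (a marginal tree of the ancestral
recombination graph, ARG), and the allele carried by the root of that tree
is the ancestral one. Given local genealogies with branch lengths — from a
simulation, from per-SNP newick trees, or rebuilt from pairwise TMRCA
matrices produced by sequentially-Markovian-coalescent methods — the
package reconstructs the root state probabilistically and propagates the
reconstruction uncertainty into the uSFS.

## Joint ancestral reconstruction

For one site with local tree $T$ (node times in generations) and observed
leaf nucleotides, the package computes, for every candidate root state $r$,
the probability of the *best joint assignment* of states to all internal
nodes:

$$ S(r) \;=\; \max_{a:\,a(\mathrm{root})=r} \; \pi(r)
   \prod_{(u \to v) \in T} P_{a(u) a(v)}\!\big(t_u - t_v\big), $$

where $P(t)$ is the transition matrix of the substitution model and $\pi$
the root prior. The maximisation is a max-product dynamic program over the
tree; because no conditional likelihoods are averaged at inner nodes, the
whole recursion runs on log probabilities and never underflows, even for
hundreds of leaves and times of $10^6$ generations (this is why the joint,
rather than marginal, reconstruction was chosen). An empirical-Bayes
posterior over root states follows by normalising with log-sum-exp:
$\Pr(r \mid \text{data}) = e^{S(r)} / \sum_s e^{S(s)}$. The posterior is
therefore a "joint-path" posterior; the per-root-state backtraces are
also returned.

For calling, the posterior is restricted to the alleles actually observed
at the site and renormalised (the unrestricted four-state posterior is kept
in the output). The call is the maximum-posterior observed allele; exact
ties are flagged and broken lexicographically (A < C < G < T).

### Substitution models

Two time-reversible models are provided in closed form, both parameterised
so the total substitution rate is $\mu$ per site per generation and branch
"length" is time in generations ($d = \mu t$; trees measured in
substitutions/site can be used with $\mu = 1$):

* **JC69**: $P_{ii} = \tfrac14 + \tfrac34 e^{-4d/3}$,
  $P_{ij} = \tfrac14 - \tfrac14 e^{-4d/3}$.
* **K80** with transition/transversion rate ratio $\kappa$ (rate
  $\beta = \mu/(\kappa+2)$): the standard two-parameter closed form;
  $\kappa = 1$ reduces exactly to JC69.

The reconstruction root prior defaults to uniform, independent of any
simulation root distribution: the reconstruction is deliberately generic
(it is run with JC69 even on data simulated under K80; for any model that
is symmetric in the two observed alleles the restricted posterior depends
only on the two root branch lengths, so model misspecification of this kind
does not bias the calls). `pi` is configurable for experiments.

### Numerical choices

* $-\infty$ is a saturating sentinel at $-10^{100}$; impossible
  configurations never turn into NaN.
* Posterior ties are detected at relative tolerance $10^{-12}$ and
  resolved lexicographically, with an explicit `tied`/`ambiguous` flag.
* Polytomies are handled natively (the recursion takes a product over all
  children).

## Informative and non-informative genealogies

A genealogy is *non-informative* for polarisation when parsimony cannot
separate the candidate ancestral states: the canonical case is a single
mutation on one of the two root-adjacent branches, where both "left
ancestral" and "right ancestral" need exactly one mutation. The package
classifies every site by fixed-root small parsimony (Hartigan/Sankoff with
unit costs), run once per candidate ancestral state:

* `non_informative` — two or more candidates attain the minimal mutation
  count;
* `multiple_mutations` — the minimum exceeds one;
* `homoplasy` — multiple mutations with exactly two observed alleles;
* `polytomy_mutation` — a mutation placed on a node whose parent has more
  than two children (polytomies arise in sanitised, inferred trees and
  signal unresolved topology).

Candidates default to the observed alleles: when the observed-allele
minimum is one mutation, an unobserved state would need at least two, so it
can never join the minimal set; the candidate set can be switched to all
four nucleotides for experiments. In the parsimony down pass, ties prefer
the parent's state, so each change is recorded on the edge above the
highest node whose state differs from its parent's (topmost-change
convention).

Three named filter policies combine the flags: `strict` for polarisation
(drop non-informative, multiple-mutation, and polytomy-mutation sites),
`usfs` for spectrum estimation (drop only sites needing more than two
mutations), and `real-data` (drop non-informative sites and sites whose
mutation count exceeds the number of observed alleles).

On true simulated genealogies, the strict policy removes *all* errors:
every kept single-mutation biallelic site is polarised correctly, at every
sample size (the test suite asserts accuracy exactly 1.0). Without
filtering, errors concentrate where the genealogy is non-informative —
for two diploids roughly two thirds of single-mutation sites (the expected
fraction of tree length on root-adjacent branches at $n=4$ is 66.7%),
falling to about a fifth at 200 diploids.

## Estimating the unfolded SFS

With $n$ haplotypes, a biallelic site with allele counts $x$ and $n-x$
belongs to derived-allele-frequency category $D_x$ if the allele with
$n-x$ copies is ancestral. Three estimators are provided:

* **MAX PP** — each site adds a unit count at its called category;
* **MAX PP + filtering** — the same on kept sites only. Because the
  probability of being non-informative depends on the derived allele
  frequency, this estimator is *biased* — more than the unfiltered one —
  and is included deliberately as the cautionary comparator;
* **Posterior average** — each site contributes its restricted posterior
  mass $P_i(D_x)$ to category $x$ and $1 - P_i(D_x)$ to $n-x$:
  $E[D_x] = \sum_i P_i(D_x)$. Total mass equals the number of contributing
  biallelic sites exactly. With the filter correction, writing $L_x$ for
  the number of biallelic sites in the unordered class $\{x, n-x\}$ and
  $L'_x$ for those kept,
  $$ E[D_x] \;=\; L_x \cdot \frac{1}{L'_x} \sum_{i \in \text{kept}}
     P_i(D_x), $$
  which undoes the frequency-dependent loss from filtering. A folded class
  with $L_x > 0$ but $L'_x = 0$ has no usable posterior; it emits a warning
  and contributes zero mass (the reweighting is undefined there).

Folded classes are unordered pairs $\{x, n-x\}$; for even $n$ the class
$x = n/2$ is its own complement and is tallied once. The restricted
(two-allele) posterior is the default so that each site carries unit mass;
an unrestricted mode exists behind a flag but forfeits mass conservation.
Note that the truth spectrum of a simulation can hold slightly *fewer*
sites than the estimators: a site hit by two mutations can lose its
ancestral allele entirely, leaving it with no valid truth category while
still carrying posterior mass.

Comparison utilities mirror standard practice: `qq_compare()` tabulates
cumulative proportions against a reference spectrum, and
`relative_error()` reports $(\hat f_x - f_x)/f_x$ per category, with `NA`
where the truth category is empty.

## Local trees from TMRCA matrices

SMC-based inference tools output pairwise TMRCAs at SNP positions rather
than trees. `upgma_tree()` rebuilds a rooted ultrametric genealogy by
average-linkage clustering on $d(i,j) = 2\,\mathrm{TMRCA}(i,j)$, so the
height of the node joining two clusters is directly a TMRCA in
generations. The factor 2 is a package choice — a monotone transform leaves
the topology unchanged — exposed as the `scale` argument for users who
prefer raw TMRCA distances. Ties join the pair of clusters whose smallest
member labels sort first, so reruns are bitwise identical, and
average-linkage updates preserve exactly equal distances so that
ultrametric inputs are recovered without rounding drift.

Trees from numerical pipelines then pass through `sanitize_times()`:
internal node times below `1e-12` generations are raised to that floor,
and an internal child within `1e-14` of its parent's age is deleted, its
children reattached (creating polytomies that the classification stage
treats as unresolved). The operation is idempotent and preserves the leaf
set.

Binary succinct tree-sequence files are not read directly; the package
ingests tskit-style *text* node/edge tables (`read_tree_tables()`),
one-newick-per-line files keyed by SNP position (`read_newick_trees()`,
no interpolation between positions), and stacked per-site TMRCA matrices
(`read_tmrca_matrices()`). Genomic intervals are left-closed, right-open
and 0-based internally; 1-based VCF coordinates are converted only at the
I/O boundary, and a phased diploid sample `S` contributes haplotypes
`S_0` and `S_1`, matched to tree leaf labels by exactly this rule
(mismatches are hard errors, never guesses).

## The built-in simulator

Validation runs on data the package simulates itself: a coalescent with
recombination along the chromosome under the SMC' approximation. The first
marginal tree is drawn from the (piecewise-constant) coalescent;
breakpoints arrive at rate $r \times$ (total branch length) per bp; at
each breakpoint a detached lineage re-coalesces with the full standing
tree, back-coalescence onto its own branch leaving the tree unchanged.
SMC' is the standard approximation in this setting; its marginal trees
match the coalescent closely, and all quantities measured here are
per-site statistics of marginal trees. Mutations fall on discrete integer
sites (so several hits at one position yield multi-allelic or homoplasic
sites) under JC69 or K80 with a configurable root distribution, and the
truth table records each site's root (ancestral) allele and mutation
count.

Scenario defaults are the study conditions and are not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `Ne` | 30,000 diploids | constant effective size |
| `mu` | 1.25e-8 /bp/gen | JC69 mutation rate (`1e-7` in the high-rate scenario) |
| `recomb` | 1e-8 /bp/gen | uniform recombination rate |
| `sequence_length` | 1 Mb | per replicate |
| `replicates` | 10 | per condition |
| `kappa` | 5 | K80 scenario |
| `root_pi` | uniform | `(0.2, 0.3, 0.3, 0.2)` in the GC-biased scenario (GC:AT = 3:2) |

The demographic-change scenarios interpolate the population size
log-linearly between 46,000 and 960 diploids over the most recent 150,000
generations (64 piecewise-constant epochs; the trajectory resolution is a
package choice since only "logarithmic change" is specified), constant at
the older value beyond. A uniform recombination rate replaces
recombination-map input at these desk scales; a custom piecewise
demography can be supplied as a data frame.

What the simulator does *not* emulate: selection (no forward component),
sequencing or phasing error, gene conversion, and non-uniform
recombination maps. Passing tests therefore demonstrate correctness of the
polarisation and spectrum machinery given correct genealogies — they do
not certify accuracy when the ARG itself must be inferred from data, which
the package deliberately leaves to external tools whose output it
consumes.

## Problem sizes used by the checks

The experiment drivers default to the study conditions above. The test
suite exercises the same pipeline at reduced scale so the default run
stays fast: 0.1–1.2 Mb sequences, 1–4 replicates per condition, sample
sizes 2–200 diploids; brute-force oracles (exhaustive enumeration over all
$4^{\#\text{internal}}$ joint assignments, and over all fixed-root
parsimony assignments) cover trees of up to 7 leaves, and an independent
average-linkage implementation (`stats::hclust`) cross-checks UPGMA. The
acceptance script `scripts/acceptance.R` re-runs the full sweep (1 Mb, 10
replicates, sizes 2–200; high-rate sizes 20–100) in a few minutes on one
CPU.

## Known limitations

* The posterior is a joint-path posterior (max-product); marginal
  (sum-product) posteriors are not an output mode.
* Uncertainty in the ARG itself is not integrated over: the package
  conditions on one tree per site.
* Sites with any missing or unphased genotype are skipped with a count,
  not imputed.
* Multi-allelic sites are polarised but excluded from the biallelic uSFS,
  keeping $D_x$ well defined.
* The strict policy's perfect accuracy is a property of *true*
  genealogies; with inferred trees the same filters trade sites for
  accuracy and the filter correction of the posterior-average estimator
  becomes important.
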