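---
title: "Models and methods behind phylosect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phylosect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

phylosect is a desk-scale re-implementation of the analytical workflow used
in transcriptome-based phylogenomic studies of deep animal relationships:
assemble hundreds to thousands of per-gene amino-acid alignments into one
partitioned supermatrix, quantify its completeness, infer trees under both
site-homogeneous maximum likelihood and a site-heterogeneous (CAT-style)
Bayesian mixture, measure support by fixed-size amino-acid jackknife and by
posterior bipartition frequencies, diagnose long-branch attraction (LBA) by
splitting genes into evolutionary-rate quartiles, and map marker-gene
losses on the tree by Dollo parsimony. Everything runs on synthetic data
produced by the package's own generator, so the full workflow is testable
without any external dataset.

## The substitution model

The likelihood core is a standard time-reversible amino-acid model. The
generator is `Q_ij = r_ij * pi_j` for `i != j`, with symmetric positive
exchangeabilities `r_ij` (Poisson, i.e. all equal, by default; the LG
empirical matrix is available via the installed phangorn) and stationary
frequencies `pi`. `Q` is normalized so `-sum_i pi_i Q_ii = 1`, putting
branch lengths in expected substitutions per site. Transition matrices come
from the symmetric eigendecomposition of the reversible generator, which is
numerically stable and lets `P(t)` be rebuilt cheaply for any `t`.

Among-site rate variation uses the discrete gamma approximation with equal
category weights. Category rates are the conditional means of the
`Gamma(alpha, alpha)` distribution over its quantile bins ("mean" rather
than "median" discretization), computed in closed form from the incomplete
gamma function, so the mean rate is exactly 1. One consequence worth
stating: in the large-`alpha` limit the outermost of four bin means sits
about `1.27 / sqrt(alpha)` away from 1 — the categories approach 1 at rate
`1/sqrt(alpha)`, not faster.

Site heterogeneity in equilibrium frequencies is modeled by a finite set of
K frequency profiles. Each alignment column belongs to one profile; the
likelihood of a column under a profile uses that profile's `pi` both in `Q`
and at the root. With K = 1 the machinery reduces bitwise to the plain
model. This finite mixture is a deliberate, tractable stand-in for the
Dirichlet-process CAT model: it retains the mechanism that matters for LBA
(different columns prefer different amino-acid subsets, so convergent
states arise much more often than a homogeneous model expects) while
keeping Gibbs reallocation exact and cheap.

## Likelihood computation

`log_likelihood()` implements Felsenstein pruning over site patterns
(identical columns are collapsed and weighted) with per-node rescaling:
after a node's partial likelihoods are complete, they are divided by their
per-pattern maximum and the log factor is accumulated, so matrices of 1e5+
columns cannot underflow. Missing states contribute all-ones partials; a
column missing in every taxon contributes exactly zero log-likelihood.
The inner loops are C++ (RcppArmadillo), vectorized over patterns.

Branch lengths are optimized one branch at a time by Brent search
(tolerance 1e-6 on length), sweeping until the log-likelihood gain drops
below tolerance; flat profiles resolve toward the smaller length, and all
lengths are floored at 1e-8 to keep the eigendecomposition-based `P(t)`
well conditioned. Tree search is greedy NNI hill-climbing from a
neighbour-joining start, where NJ distances are two-taxon maximum-likelihood
branch lengths restricted to the columns both taxa share. These choices
trade thoroughness for predictable desk-scale runtimes; they are not meant
to compete with dedicated ML programs on large trees.

## The synthetic-data generator

The generator draws, per simulation: a topology (balanced, caterpillar, or
explicit Newick) with iid exponential branch lengths (mean 0.1 by default);
per-gene lengths (negative binomial, floored at 10 columns); per-gene rate
multipliers from `Gamma(shape, shape)` — mean fixed at 1, shape 2 by
default since the generative law of real gene rates is unknown; per-column
profile assignments and gamma rate categories; and root states from each
column's profile. States evolve along each branch by uniformization of the
normalized generator (exact, and vectorized over columns), with effective
length `branch x gene_rate x category_rate`.

Missing data are imposed at the (taxon, gene) block level — whole genes
vanish from a taxon, the way incomplete transcriptomes lose whole
transcripts — with a per-taxon keep probability centred on the target
completeness (default 0.72, the completeness scale typical of
transcriptome supermatrices) and a small beta-distributed spread across
taxa. Every taxon keeps at least one gene.

Three presets set the study conditions:

* `preset_flatworm()`: 24 taxa, 400 genes of mean length 270 (~108,000
  columns), 72% completeness, four long-branch taxa at 5x, K = 10 spiky
  profiles (Dirichlet concentration 0.3). This echoes the shape of a
  flatworm-scale transcriptomic supermatrix at desk scale.
* `preset_desk()`: 8 taxa, 40 genes of mean length 100 — the default
  pipeline preset, sized so the full six-stage pipeline (including two
  MCMC chains and a jackknife) completes in about two minutes.
* `preset_lba_demo()`: a four-taxon Felsenstein-zone quartet. Two
  non-sister terminals of base length 0.04 are scaled 12.5-fold to 0.5
  substitutions/site; the other terminals are 0.05 and each internal stem
  0.02; 100 genes of mean length 100 with rate shape 2; K = 8 profiles at
  concentration 0.2 (strongly heterogeneous). The geometry was chosen, by
  simulation during design, to place the zone boundary *between* the
  slowest and fastest gene-rate quartiles: at quartile-1 rates
  (roughly 0.4x) homogeneous ML recovers the true tree, while at
  quartile-4 rates (roughly 2x) the convergent states generated by the
  spiky profiles overwhelm the short internal signal and homogeneous ML
  unites the two long branches.

What the generator deliberately does not emulate: alignment error, indels,
codon structure, compositional drift across lineages, orthology mistakes,
and correlated (clade-structured) missingness. Passing tests therefore
certify the machinery and its statistical contracts on data with known
truth — not the behaviour of any inference method on real transcriptomes.

## Signal dissection

`estimate_gene_rates()` re-optimizes branch lengths per gene on the fixed
reference topology (pruned to the taxa with data for that gene; genes with
fewer than four such taxa are excluded with a warning) and defines the
gene's rate as its optimized tree length; relative rates are normalized to
mean 1. `partition_quartiles()` sorts genes by rate (ties by id, so a
permuted input yields identical quartiles) and fills Q1..Q4 greedily
against cumulative column thresholds, making the four datasets equal in
amino-acid columns up to one gene length. "Equal in columns" (not in gene
count) was chosen because support measures in this workflow are
column-denominated; a gene-count mode is available. The per-quartile rate
is the column-weighted mean of member-gene relative rates — with mean-1
normalization over genes, the four quartile rates straddle 1, so this
statistic is comparable across runs but is not claimed to reproduce any
particular published normalization.

## Jackknife and split statistics

Jackknife replicates sample a fixed number of columns (default 20,000;
default 100 replicates) uniformly without replacement, independently per
replicate; a gene-level mode accumulates whole genes to the target and
truncates the last one, since column- versus gene-denominated resampling is
a genuine protocol ambiguity. Bipartitions are canonicalized as the split
side not containing the alphabetically first taxon; trivial splits are
dropped. The majority-rule consensus keeps splits with frequency strictly
above 1/2 (such splits are mutually compatible, so the laminar family
nests into a tree) and labels nodes with exact frequencies.
`chain_compare()` implements the MaxDiff/MeanDiff convergence statistic
over the union of observed splits, with no frequency floor — versions of
the original diagnostic differ on this point, and the no-floor convention
is the conservative one.

## The Bayesian mixture sampler

`mcmc_run()` is Metropolis-within-Gibbs on (topology, branch lengths,
alpha, K profile frequency vectors, per-site allocations): exact Gibbs
reallocation of sites to profiles (via per-pattern likelihood under each
profile and the Gumbel-max trick); Dirichlet random-walk proposals on each
profile with the correct Hastings ratio; log-scale multiplier proposals on
branch lengths and alpha (window tuned during burn-in only, then frozen,
so retained samples obey detailed balance); and uniform NNI topology
proposals (the phangorn NNI neighbourhood preserves the branch-length
multiset and is an involution, hence symmetric). Priors: iid exponential
(mean 0.1) branch lengths, exponential (mean 1) alpha, flat Dirichlet
profiles, uniform topology; mixture weights are fixed at 1/K.
Exchangeabilities are fixed at the configured matrix rather than sampled —
sampling 190 exchangeabilities is the main (documented) simplification
relative to a full CAT+GTR sampler.

The primary correctness property is prior recovery: with an all-missing
matrix the sampler must reproduce its priors (uniform quartet topologies,
exponential branch lengths and alpha), which the test suite checks with
batch-means Monte-Carlo error bands and a KS test on a thinned chain.

## Marker detection and Dollo mapping

Marker presence is called by Smith-Waterman local alignment (BLOSUM62, gap
open 11 / extend 1 — conventional protein-search defaults) of each
reference against each sequence of a taxon. The default threshold is the
score a 35%-identity alignment over 60 residues (or the reference length,
if shorter) would achieve under the reference's residue composition; on
unrelated random sequences this sits far above the null score
distribution. Cells are "present" or "undetected" — never "absent" —
because failure to find a gene in a partial transcriptome is weak evidence
of genomic loss; empty sequence sets warn and stay undetected.

`dollo_map()` places a single gain at the MRCA of the present taxa and
finds the minimal loss set as the stems of the maximal all-undetected
subtrees inside that clade. Minimality is provable (each such subtree
needs at least one loss on its root path, and one loss at each stem
suffices) and is verified against exhaustive subset enumeration in the
tests. Undetected taxa outside the gain clade need no loss — under a
single-gain model they simply never had the marker.

## Pipeline and reproducibility

`run_pipeline()` chains simulate, gene-rate estimation, quartile
dissection (homogeneous ML per quartile), jackknife (NJ per replicate by
default, NNI-ML optionally), a two-chain MCMC on a column subsample with
its MaxDiff/MeanDiff report, and marker detection plus Dollo mapping,
writing every artifact as deterministic text (TSV with a `#` header line,
floats at six significant digits, Newick, relaxed PHYLIP) plus an md5
manifest. Every stochastic operation draws from a stream derived from the
master seed by a stable label, so adding a stage never perturbs the
others, and identical configuration plus seed reproduce identical digests.

Problem sizes throughout the defaults (8-taxon desk pipeline, 10-taxon
jackknife matrix, 20-replicate LBA experiment, a few hundred MCMC
iterations in-pipeline) are the package's chosen desk scale: large enough
for every statistical contract to be tested, small enough that the whole
suite runs on one CPU in minutes. Known limitations worth restating: NNI
(no SPR/TBR) search can stall on large trees; the sampler fixes
exchangeabilities and mixture weights; detection has no translated-frame
or profile-HMM search; and none of the synthetic presets are estimates of
any real dataset's parameters.
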