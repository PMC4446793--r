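# phylosect

Tools for dissecting phylogenetic signal in amino-acid phylogenomic
supermatrices — built for the kind of question that arises in deep
metazoan phylogenomics (flatworm-scale transcriptome studies being the
motivating case): *is a contested grouping genuine signal, or an artifact
of fast-evolving genes and long branches?*

The package implements the full analytical loop around that question:

* **Synthetic supermatrices** with known truth: partitioned taxa × columns
  amino-acid matrices simulated under a site-heterogeneous profile mixture
  (CAT-style: each column has its own equilibrium-frequency profile), with
  per-gene rate multipliers, discrete-gamma among-site rates, designated
  long-branch taxa, and transcriptome-style gene-block missing data.
* **Supermatrix assembly and accounting**: concatenation of per-gene
  alignments with a 0-based half-open partition map, completeness
  statistics (percent of positions with data, per taxon / per gene /
  overall), column slicing, FASTA / relaxed PHYLIP / partition-TSV IO.
* **A likelihood engine**: Felsenstein pruning over site patterns with
  per-node rescaling (C++ core), reversible models `Q_ij = r_ij pi_j`
  normalized to one expected substitution per site, mean-of-bin discrete
  gamma, per-branch Brent optimization, NNI hill-climbing, and NJ starting
  trees from pairwise ML distances.
* **Signal dissection**: per-gene rate estimation on a reference topology,
  genes split into four rate quartiles equal in columns, independent
  inference per quartile — the instrument for diagnosing long-branch
  attraction (LBA): slow quartiles keep the true signal, fast quartiles
  carry the artifact.
* **Jackknife support**: fixed-size column (or gene) resampling without
  replacement, bipartition frequencies, strict majority-rule consensus
  with exact support labels, and the between-run MaxDiff/MeanDiff split
  diagnostic.
* **A desk-scale Bayesian sampler**: Metropolis-within-Gibbs over
  topology, branch lengths, gamma shape, K frequency profiles and per-site
  allocations — a working miniature of CAT-style site-heterogeneous MCMC,
  validated by prior recovery.
* **Marker loss mapping**: Smith–Waterman/BLOSUM62 presence calls
  ("present" vs "undetected", never "absent") and Dollo parsimony
  (single gain, minimal losses) on a rooted tree.

## A worked example

```r
library(phylosect)

spec  <- preset_desk(seed = 1)              # 8 taxa, 40 genes, 72% target completeness
model <- substitution_model("poisson", alpha = 1)
sim   <- simulate_supermatrix(spec, model)

completeness_stats(sim$matrix)
#> completeness: overall 70.67% (taxa 59.76-83.91%, 40 genes)

rates <- estimate_gene_rates(sim$matrix, ape::unroot(sim$truth$true_tree), model)
quart <- partition_quartiles(sim$matrix, rates)
quart$summary
#>   quartile n_genes n_columns relative_rate pct_missing
#> 1       Q1       9       970     0.3157845    29.67784
#> 2       Q2      10       897     0.7814770    25.09755
#> 3       Q3      10       892     1.1817211    32.00673
#> 4       Q4       8       862     1.8879262    16.87935

reps  <- jackknife_replicates(sim$matrix, jackknife_config(1000, 20, seed = 1))
trees <- lapply(reps, nj_tree, model = model)
ape::write.tree(majority_consensus(trees))
#> (((t03,t04)1,(((t05,t06)0.95,t08)0.75,t07)1)1,t01,t02);

cc <- chain_compare(split_frequencies(trees[1:10]), split_frequencies(trees[11:20]))
sprintf("MaxDiff = %.4g ; MeanDiff = %.4g", cc$max_diff, cc$mean_diff)
#> "MaxDiff = 0.3 ; MeanDiff = 0.1143"
```

Reading the output: realized completeness lands within sampling error of
the 72% target; the four quartile datasets are equal in columns to within
one gene length, with relative rates rising Q1→Q4 (here 0.32 to 1.89,
mean 1 across genes by construction); consensus node labels are exact
jackknife split frequencies; MaxDiff/MeanDiff compare split frequencies
between two independent replicate sets (0 = identical, 1 = disjoint).

The whole loop — including the LBA demonstration on a Felsenstein-zone
quartet (`preset_lba_demo()`), the Bayesian stage, and marker-loss mapping
— runs as a single seeded pipeline:

```r
run_pipeline(pipeline_config(outdir = "out", seed = 1))
```

which writes per-stage artifacts (PHYLIP matrices, partition tables,
Newick trees, support and rate tables, a convergence report, a
presence/absence matrix with Dollo losses) and a digest manifest; the same
config and seed reproduce the manifest digest-for-digest. A thin CLI
wrapper lives at `inst/scripts/run_pipeline.R`.

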