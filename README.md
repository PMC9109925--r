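# sgnb — isoform-level differential expression without isoform structures

`sgnb` implements splicing-graph negative binomial (SGNB) differential
expression analysis for two-condition RNA-seq studies.  It is aimed at
analysts who want isoform-level sensitivity — in particular, detection of
**isoform switches**, where a gene's isoform composition changes while its
total output stays the same — but work with organisms whose isoform
structures are unknown or unreliable.  Only exon coordinates (a GTF file)
are needed.

## The method in brief

Each gene's exons are flattened into non-overlapping exons numbered
`1..E`, and every aligned read is summarised into a *read type*: the
ordered chain of flat-exon IDs it covers (`"1"`, `"2-4"`, ...).  Counts
X_ghj of type *h* of gene *g* in sample *j* are modelled as

    X_ghj ~ NB(N*_j * theta_gh, phi_gh)

with TMM-normalized effective library sizes N\*_j, relative expression
theta_gh and common-across-conditions dispersion phi_gh.  The read-type
means are linked to the (unknown) isoform copy numbers by
theta_g = P_g k_g; when P_g has full column rank, testing
H0: theta⁰_gh = theta¹_gh for every read type is equivalent to testing
that no isoform changed.  Read types that are always generated by the same
isoform set have proportional rows in P_g and are merged via a splicing
graph before testing (model simplification), which reduces the number of
hypotheses without changing the null.  Per merged group, the dispersion is
estimated by quantile-adjusted conditional maximum likelihood, theta by an
EM on the Gamma–Poisson representation, and the two conditions are
compared with an exact test on the conditional law of the per-condition
pseudo-count sums.  Gene-level p-values use within-gene Bonferroni over
the m tested groups; Bonferroni and BH corrections across genes are both
reported.

The package also ships a mechanistic single-end read simulator with exact
ground truth (start-position counts l_gih, the matrix P_g, true
always-showing-together classes), used throughout the test suite and the
benchmark loop.

## Worked example

Simulate the 10-gene isoform-switch experiment (one gene with two
equal-length isoforms at expected copies 10/50 in condition 0 and 50/10 in
condition 1, nine null genes, 20 samples per condition) and analyse it
both ways:

```r
library(sgnb)

cfg <- sim_config(n_genes = 10, samples_per_condition = 20,
                  dispersion_const = 5)
sim <- simulate_experiment(cfg, seed = 42, switch_gene = TRUE)

run <- run_sgnb(sim$design, table = sim$table, merge = TRUE)
run
#> sgnb_run: 10 genes; 83 read types; 23 tested groups (merged)
subset(run$result$genes, gene_id == "gene_switch")
#>       gene_id m         min_p        gene_p    bonferroni            bh
#> 1 gene_switch 4 2.225074e-308 8.900295e-308 8.900295e-307 8.900295e-307

gt <- gene_total_test(sim$table, sim$design)
subset(gt$genes, gene_id == "gene_switch")
#>       gene_id m     min_p    gene_p bonferroni        bh
#> 1 gene_switch 1 0.5560961 0.5560961          1 0.9876609
```

The switch gene's read-type groups separate the two isoforms, so SGNB
calls it differentially expressed at any representable level (the exact
test bottoms out at the smallest positive double), while the gene-level
total-count test — which only sees the unchanged total — returns
p ≈ 0.56.  `run_benchmark()`
repeats this over replicates and scores FDR/TPR for SGNB with and without
model simplification against the gene-level baseline.

A thin command-line wrapper with `flatten`, `count`, `test`, `simulate`
and `benchmark` subcommands is installed under
`system.file("scripts", "sgnb_cli.R", package = "sgnb")`.

## Vignette

`vignettes/sgnb-methods.Rmd` documents the model and its assumptions, the
estimation and testing machinery, every tunable parameter with its
default, the simulator's scope, and known limitations.
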