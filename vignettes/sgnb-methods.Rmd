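---
title: "Splicing-graph negative binomial testing: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splicing-graph negative binomial testing: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgnb)
```

## The problem

Gene-level differential expression tests compare the *total size* of a
gene's transcripts, $\sum_i k_{gi} l_{gi\cdot}$ (copy number times length,
summed over isoforms $i$).  When a gene's isoform composition switches but
its total output stays put — the classic isoform switch — such tests see
nothing.  Isoform-level tools exist, but require known isoform structures,
which many species lack.  `sgnb` tests at an intermediate resolution that
needs only exon coordinates: the **read type**.

## Read types

A gene's exons (possibly overlapping in the annotation) are first flattened
into non-overlapping exons numbered $1..E$ left to right along the genome.
A read's type is the ordered chain of flat-exon IDs its aligned segments
cover, e.g. `"2"` or `"1-3"`.  Because the flat exons partition the exon
union, every exonic base has exactly one ID and typing is unambiguous.
Reads that stray outside the gene's exons, or into the exons of more than
one gene, are discarded with a tallied reason: the model assumes each read
comes from one gene, and there is no partial-type notion.

## The model

Let $X_{ghj}$ be the count of type-$h$ reads of gene $g$ in sample $j$,
$N_j$ the sample's total mapped reads.  Conditional on a latent
per-sample rate the count is Poisson; letting the isoform copy numbers
vary across biological replicates with a Gamma law gives the marginal

$$X_{ghj} \sim \mathrm{NB}(N^*_j\,\theta_{gh},\ \phi_{gh}),$$

with effective library size $N^*_j$ (TMM-normalized), relative expression
$\theta_{gh}$, and dispersion $\phi_{gh}$ assumed common across the two
conditions.  The read-type means relate to the isoform copies through
$\vec\theta_g = P_g \vec k_g$, where $P_g$ has entries
$p_{gih} = l_{gih}/l_{gi\cdot}$ and $l_{gih}$ counts the read-start
positions on isoform $i$ that produce type $h$.  When $P_g$ has full
column rank, "no isoform changed" is equivalent to "no read-type mean
changed", so testing every read type tests the isoform-level null without
knowing the isoforms.

## Model simplification: the splicing graph

Two read types generated by exactly the same set of isoforms ("always
showing together") have proportional rows in $P_g$; summing them changes
neither the rank of $P_g$ nor the null hypothesis, and saves one test.
Such pairs are found from a directed graph over the observed types: an
edge $u \to v$ is drawn when $v$ is the immediate continuation of $u$
(one exon ID appended after $u$'s last, or $u$'s first ID removed), plus a
pseudo START to the lexicographically smallest node and the largest node
to a pseudo END.  An edge $u \to v$ with out-degree$(u)$ =
in-degree$(v)$ = 1 forces $u$ and $v$ to co-occur, and chains of such
edges are merged into one group.  Pseudo-node edges count toward the
degrees; this is the conservative reading (it blocks merging at gene ends
slightly more often than ignoring them would).  The graph is built from
observed types only — types with zero total count carry no information and
unobservable theoretical types cannot be enumerated without isoform
structures.  The construction may in principle merge types whose rows are
not proportional; the property that matters, and the one the test suite
checks on simulated genes, is that the merged $P_g$ keeps full column rank
whenever the original had it, so wrongly merged types cannot change the
hypothesis being tested.

## Estimation

Per read-type group:

* **Normalization.**  TMM scaling factors (30% trim on log-ratios, 5% on
  abundance, precision weights, reference chosen by upper-quartile
  fraction) are computed on the read-type count matrix with
  `edgeR::calcNormFactors`; effective sizes are $N^*_j = N_j f_j$ and the
  common pseudo-size $N^*$ is their geometric mean, which distorts both
  conditions least among single-target choices.
* **Dispersion** is estimated by quantile-adjusted conditional maximum
  likelihood: counts are mapped to the common size $N^*$ through their NB
  mid-quantile (numeric inversion, linear interpolation between integer
  support points; a zero count maps to zero), and $\hat\phi$ maximizes the
  summed per-condition conditional log-likelihoods
  $\sum_j \log\Gamma(x_j + \phi^{-1}) + \log\Gamma(J\phi^{-1})
  - \log\Gamma(z + J\phi^{-1}) - J\log\Gamma(\phi^{-1})$
  on $[10^{-6}, 10]$ by bounded scalar maximization (tolerance $10^{-6}$).
  The outer loop alternates $\theta$-estimation, quantile adjustment and
  $\phi$-maximization until the relative change in $\hat\phi$ falls below
  $10^{-4}$ (at most 20 iterations); hits of the search bounds are
  flagged.
* **Means.**  For fixed $\phi$, $\theta$ is estimated by EM on the
  Gamma–Poisson representation: E-step
  $E[\Theta_j \mid x_j] = (x_j + 1/\phi)/(N^*_j + 1/(\phi\theta))$,
  M-step $\theta \leftarrow$ mean of posterior means, to relative
  tolerance $10^{-8}$ (at most 200 iterations).  With equal offsets the
  fixed point is $\bar x / N^*$ exactly; with unequal offsets the tests
  pin the estimate to the marginal NB likelihood maximizer found by grid
  search, so the scheme's validity does not rest on its derivation.
  During the dispersion loop the pooled-condition $\theta$ is used for
  quantile adjustment (the conditional likelihood eliminates the means,
  and a common target keeps the two conditions comparable); per-condition
  estimates are recomputed at the final $\phi$ for reporting.

Pseudo counts stay real-valued through estimation and are rounded (half
up) only when the per-condition sums $Z^0, Z^1$ are formed, because the
exact test needs integer support.

## Testing

Under the null, $Z^e \sim \mathrm{NB}(J_e N^* \theta, \phi/J_e)$
independently.  The p-value comes from the conditional law of
$Z^0$ given $Z^0 + Z^1 = z$: with $q(a) \propto P(Z^0\!=\!a)\,
P(Z^1\!=\!z-a)$, all outcomes with $q(a) \le q(z^0)(1+10^{-10})$ are
summed — the standard two-sided exact-test convention (minimum-likelihood
region; a doubled-smaller-tail rule would be an alternative; the
$\phi \to 0$ limit, the conditional Binomial$(z, J_0/(J_0+J_1))$, anchors
the chosen convention numerically).  $z = 0$ gives $p = 1$.  A gene's
p-value is $\min(1, m \cdot \min_h p_h)$ over its $m$ tested groups
(within-gene Bonferroni); zero-count groups are excluded from testing and
from $m$.  Across genes both Bonferroni and Benjamini–Hochberg adjusted
values are emitted and the caller picks.

A gene-level baseline (`gene_total_test`) collapses each gene to one total
count per sample and runs the identical NB machinery with $m = 1$ — the
internal stand-in for classic gene-level exact tests in benchmarks.

## The simulator

`simulate_experiment` emulates a fragment-and-sequence protocol at the
study's reference conditions: base isoform copies
$k \sim \mathrm{NB}(\mu = 10, \sigma^2 = 210)$; 1000 expected reads per
gene per sample, split among isoforms in proportion to $k_i L_i$ and
anchored to the condition-0 total so fold changes move a gene's output;
per-sample realized reads per isoform $\sim \mathrm{NB}(\text{mean},
\text{size} = \text{mean}/c)$ with dispersion constant $c$ (5 = small,
30 = large), the per-transcript convention of read-count simulators;
~30% DE genes with per-isoform log2 fold changes $\mathrm{N}(0,1)$;
read length 100 bp; fragment lengths $\mathrm{N}(250, 25)$ truncated
below at the read length.  Gene models are drawn with 3–10 exons of
80–500 bp and 1–4 isoforms that always contain the terminal exons — a
stand-in for a real annotation chosen to produce both mergeable chains
and branch points.  One deliberate modelling choice: the *read start* is
uniform over the usable length $L - 100 + 1$.  Since the read is the
leftmost 100 bases of its fragment, the fragment length never changes
which bases are read, and placing fragment (rather than read) starts
uniformly would deplete read starts near the 3' end and contradict the
uniform-sampling law the $l_{gih}$ bookkeeping assumes — a discrepancy a
per-base oracle check catches immediately.

The simulator records its own per-read truth, so the returned count table
is exact; an optional pre-aligned SAM emission exercises the alignment
code path without a mapper.  What the simulator does *not* emulate:
sequencing errors and quality, GC/positional bias, paired-end inserts,
multi-mapping, and overlap between genes.  Passing tests therefore
demonstrate correctness of the statistics under the model's own sampling
assumptions, not robustness to those artefacts.

The isoform-switch preset is a 10-gene transcriptome: nine null genes and
one gene with two equal-length isoforms at expected copies (10, 50) in
condition 0 and (50, 10) in condition 1, so the gene total is unchanged.
The background genes are strictly null in this preset — with only ten
genes, a 30% DE background would both contradict the one-DE-gene design
and destabilize TMM on so small a transcriptome.  The sample size is 20
per condition (the reference design spans 5–20; the largest is used since
the method is explicitly aimed at large-sample studies, and detection is
already saturated there).

## Problem sizes used in validation

The test suite validates at desk scale: 100 switch replicates (10 genes,
40 samples each), one 300-gene all-null run at 15 samples/condition for
type-I error, 200 random gene models for merging soundness, 200
model-simulated groups at $J = 50$ per condition for estimator recovery
($\theta = 5\times10^{-4}$, $\phi \in \{0.05, 0.2\}$), and 10 mixed-DE
benchmark replicates at 100 genes, 15 samples/condition.  Full-scale
analyses (thousands of genes, real annotations) are a matter of runtime,
not of code paths.

## Numerical choices and degenerate inputs

* NB parameterisation is (mean, dispersion) with variance
  $\mu + \phi\mu^2$; $\phi < 10^{-12}$ switches to exact Poisson limits.
* All-zero groups are skipped with a reason; genes with no typed reads do
  not appear in results.
* Ties in the exact-test rejection region use a $1+10^{-10}$ relative
  tolerance; rounding of pseudo sums is half-up.
* `theta = 0` with a positive count is rejected as a model inconsistency
  rather than silently clamped.
* Chain order everywhere is elementwise integer comparison with shorter
  prefixes first (`"1" < "1-2" < "1-3" < "2"`), implemented via
  fixed-width keys; group labels join members with `"+"`.
* Strand is recorded but never used for exon numbering: IDs increase with
  genomic coordinate, and read counting is strand-agnostic.  Reads in
  regions shared by two genes are discarded, not split.

## Known limitations

Type-I error control is approximate at small sample sizes (the exact test
is applied to quantile-adjusted sums, and within-gene Bonferroni is
conservative for correlated read types); the method is intended for
designs with roughly 15+ samples per condition.  Paired-end mates are
treated as two single-end reads.  Dispersion is estimated per read-type
group with no information sharing across groups — no empirical-Bayes
moderation — so very low counts give noisy $\hat\phi$.
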