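---
title: "Measuring homoeolog-specific retention and use: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring homoeolog-specific retention and use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

An allotetraploid carries two complete parental genomes — here called At
(the genome the tiling array was designed against) and Aa — joined in one
nucleus. Over time some genes lose one parental copy (a *homoeolog
deletion*) and many genes transcribe the two copies unequally
(*homoeolog expression bias*). Neither quantity is directly observable
on a single-reference tiling array: every probe measures the sum of both
homoeologs' hybridization. The package recovers the parental
decomposition from two regularities:

* probes whose 25-mer is identical in both parents (*conserved
  features*) report the combined signal of both homoeologs equally;
* probes overlapping sequence differences hybridize more weakly to the
  Aa homoeolog, each mismatch attenuating its contribution
  (*diagnostic features*, DFs).

Four genotypes anchor the analysis: the two parents (At, Aa), the
evolved natural allotetraploid (As), and a resynthesised F1
allotetraploid (F1As) whose homoeolog dose is exactly equal by
construction — the "unevolved" null against which As is compared.

## The two-source mixture model

For a gene with $n$ diagnostic features, let $A_i$ and $T_i$ be the
replicate-mean (rescaled) intensities of probe $i$ in Aa and At. A
hybrid sample's intensities are modelled as

$$S_{ij} = \alpha_1 A_i + \beta_1 T_i + \varepsilon_{ij},
  \qquad \alpha_1 + \beta_1 = 1,$$

with $j$ indexing the three biological replicates and
$\varepsilon_{ij}$ i.i.d. normal errors. The constraint
$\alpha + \beta = 1$ is legitimate once the sample is normalized to the
parental mixture level (below); $\alpha$ is then the fractional Aa
contribution. The constrained least-squares estimate has the closed form

$$\hat\alpha \;=\;
  \frac{\sum_{ij} (S_{ij} - T_i)(A_i - T_i)}{\sum_{ij} (A_i - T_i)^2},$$

implemented in `estimate_alpha()` and checked in the test suite against
a brute-force minimizer of the residual sum of squares.

Whether the share in the sample of interest ($\hat\alpha_1$) differs
from the share in a null reference ($\hat\alpha_2$; F1As DNA for
retention, As DNA for expression) is tested with

$$X \;=\; \frac{\tfrac12 (\hat\alpha_1 - \hat\alpha_2)^2
  \sum_{i=1}^{3n} (A_i - T_i)^2}
  {\left[\mathrm{RSS}_S + \mathrm{RSS}_F\right] / (6n - 1)},$$

where the sums run over the $3n$ flattened probe-by-replicate terms and
RSS are the residual sums of squares of the two constrained fits. Under
the null $X$ is referred to $F(1,\, 6n-1)$. Two conventions are followed
as published rather than "improved": the index flattening (so $A_i,
T_i$ repeat across replicates) and the denominator degrees of freedom
$6n-1$, although two fitted parameters would suggest $6n-2$. The
null-calibration test in the suite simulates 10,000 null genes at
$n = 5$ and verifies that the resulting type-I error at nominal 0.05
stays within [0.04, 0.06]; the $6n-1$ convention costs roughly half a
percentage point of anti-conservatism at this $n$ and vanishes as $n$
grows. Estimates of $\alpha$ outside $[0,1]$ are reported as-is, never
truncated: they flag model violations (for example an unrescaled dose
change) rather than estimation failure.

## Gene-wise scaling and diagnostic features

Arrays of different genotypes are not on a common scale per gene. Two
distinct normalizations are involved, and keeping them apart matters:

**Parental scaling (`scaling_factor()`).** Per gene, the ratios
$X_i = T_i / A_i$ form a distribution whose peak is driven by conserved
probes; the kernel-density mode $x_{\max}$ rescales all Aa intensities
($a_{ij} \mapsto x_{\max} a_{ij}$). The density uses the Sheather–Jones
plug-in bandwidth: the ratio distribution is a sharp conserved-probe
peak with a one-sided tail of attenuated probes, and the rule-of-thumb
bandwidth over-smooths exactly that structure, dragging the argmax into
the tail shoulder. Genes whose log2 ratios fail a Shapiro–Wilk screen
(default $\alpha = 0.05$) are excluded — the mode is then not a reliable
scaling factor. At 5% parental divergence this screen is strict: a
substantial fraction of genes is excluded (they genuinely have more
diverged than conserved probes), mirroring the exclusion of
fast-evolving genes in this assay family. Exclusions are enumerated in a
per-gene ledger (`analyzed` / `too_few_probes` / `failed_normality` /
`too_many_dfs`), each gene exactly once.

**DF detection (`find_diagnostic_features()`).** Per probe, a Welch
t-test of log2 values (At vs rescaled Aa) under genome-wide
Benjamini–Hochberg control, plus two robustness rules: the sign of the
difference must be unanimous across every replicate pairing, and — by
default — the reference (At) signal must be the stronger one. The sign
rule encodes the physics of a parental-reference array (mismatches can
only weaken the non-reference parent's hybridization) and makes DF
calls immune to small errors in $x_{\max}$, which can only create
artifacts of the opposite sign.

**Dose scaling (the per-gene dose factor).** The mixture model needs
$S$ on the scale where a both-retained gene reads $\alpha = 0.5$. The
package estimates each sample's per-gene scale from the unconstrained
two-source fit $S_{ij} \approx u A_i + v T_i$ over *all* probes of the
gene: $c = u + v$ is the total dose relative to the parental references
(1 for a retained gene at F1 dose, 1/2 for a hemizygous deletion, the
expression level in DNA units for RNA), and $S / c$ is on the mixture
scale. Compared with a ratio-mode over conserved probes only, this uses
three times more data and no density estimation, and the factor's error
enters both compared samples through the same design, so most of it
cancels in $\hat\alpha_1 - \hat\alpha_2$. It also makes
$\hat\alpha_1$ directly interpretable as the transcript share even for
genes carrying a deletion.

## Classification rules

**Retention (`classify_retention()`).** As DNA against F1As DNA at the
parental DFs, BH-controlled across tested genes, residual-normality
screened (Shapiro–Wilk on the pooled fit residuals, $\alpha = 0.05$).
Labels additionally require $|\Delta\alpha| \ge 0.25$: retention states
are discrete dose classes with Aa shares 0.5 (both), 1 (At deleted) and
0 (Aa deleted), so the midpoint between classes is the natural decision
boundary — statistical significance alone would admit share shifts far
too small to represent any dose change, exactly as a fold-change
threshold guards differential-expression calls.

**Expression (`classify_expression()`).** As RNA against As DNA — the
null reference is the gene's own genomic dose, so a deletion gene with
proportional transcription is (correctly) not called biased. Both
samples are put on the parental mixture scale by their dose factors. By
default the model is evaluated at the parental DF set: those are the
probes where the two homoeolog signals are distinguishable, whichever
sample is decomposed. The alternative mode that re-identifies DFs
between RNA and DNA is implemented (`df_mode = "rna_dna"`) but is far
less sensitive with three replicates: a gene transcribing its
homoeologs in proportion to dose shows *no* RNA-vs-DNA difference at
any probe, and the 4-df Welch tests rarely clear genome-wide BH
control, so at desk scale it tests almost nothing. Expression labels
use no $\Delta\alpha$ floor (bias is continuous). Genes are tested only
if called expressed: the median gene-level RNA intensity must exceed
the 95th percentile of the background-probe RNA intensities
(`expression_call()`); this intergenic-percentile rule is a documented
stand-in for an unstated criterion and is fully config-exposed.

## Preprocessing

Background correction subtracts a low-quantile floor per array
(default: 5th percentile, re-floored at 1) — an intentionally simple
stand-in for convolution-model background correction, sufficient because
every downstream statistic needs only comparable positive intensities.
Quantile normalization (via limma) is applied within replicate groups,
where exchangeability makes forcing identical distributions exactly
right. Normalizing the As and F1As arrays *jointly* is supported
(`join_as_f1as = TRUE`) but off by default: when an appreciable
fraction of genes changed copy number, the two genotypes' intensity
distributions genuinely differ, and the joint quantile map measurably
distorts the per-probe As-vs-F1As contrasts under study (in simulation
it inflates the retention test's null type-I error from ~0.05 to ~0.17
at 20% deleted genes).

## Multi-gene alteration scan

`gene_diff_test()` compares replicate-averaged per-probe intensities of
As and F1As with a Wilcoxon signed-rank test on the paired differences
(zero differences dropped; exact null up to 25 informative pairs,
normal approximation with continuity correction above). The sliding
scan (`scan_alteration_windows()`) flags every 30-gene window, step 1,
in which at least 27 genes shift in one direction and at least 9 of
those are significant at FDR 0.05, then merges overlapping windows of
equal direction. The sliding step and the no-merging-across-direction
rule are choices this package documents (the thresholds themselves are
the published ones). Genes with fewer than 5 testable probes are
excluded from both the FDR adjustment and the gene order.

## Spatial clusters and network co-bias

`permutation_cluster_test()` computes centered running averages of
$\Delta\alpha$ (window 11 genes, ends truncated) along each chromosome
and builds the null by shuffling $\Delta\alpha$ across all gene
positions genome-wide, recording each permutation's global maximum of
the absolute running mean. Clusters are maximal runs above the null's
97.5th percentile with a common sign; each cluster's empirical p uses
the add-one estimator against the cluster's mean. Window, permutation
count, and quantile are all exposed; genome-wide (rather than
per-chromosome) shuffling is the implemented reading of a genome-wide
permutation test.

The network stage offers both natural readings of "do partners share
their bias": `concordance_by_bin()` bins labelled gene pairs by
connectedness (20 equal-count bins, undersized bins merged leftward)
and fits the concordant fraction on mean connectedness by OLS;
`partition_networks()` classifies connected components of the
thresholded interaction graph (threshold 0.5 by default) with at least
two biased members as co-At / mixed / co-Aa and tests the partition
against a per-network binomial expectation: with $p$ the global At
fraction among biased genes, a network with $k$ biased members
contributes $p^k$ to the co-At expectation and $(1-p)^k$ to co-Aa, so
expected counts sum to the classified total by construction. The
$\chi^2$ itself (`cobias_chisq()`, df = 2) also accepts externally
supplied expected counts, so published tables can be tested without
committing to this expectation model.

## Read-based validation

`align_ortholog_pair()` produces a Needleman–Wunsch global alignment
(match +1, mismatch −1, gap of length $L$ costing $3 + (L-1)$; N
scores 0 against everything and never becomes a variant), from which
SNP and indel variants and the per-gene divergence (variant columns /
aligned columns) are extracted. `assign_reads()` places each mate on
both orthologs by global-local alignment (placements with more than 10
mismatches are unmapped), lets the read base vote At or Aa at every
overlapped diagnostic SNP in the better-scoring frame, pools votes
across mates, and calls a fragment At/Aa only if the opposing support
does not exceed the conflict tolerance (default 0 — the strictest
reading). Indel variants are recorded but do not vote: at realistic
divergence SNP votes carry essentially all the signal, and indel voting
would require arbitrating alignment ambiguity around gaps for a
negligible gain. `fpk_quantify()` counts called fragments per kilobase
of the respective ortholog model — deliberately without a per-million
term, because the two orthologs are compared within one library where
the library size cancels. Pre-mapped SAM/BAM input is accepted through
`read_sam_reads()`.

## The synthetic-data generator

`sim_config()` fixes the study conditions: two parental genomes
diverged at 1 substitution per 20 bases, 25-base probes tiled every 35
bases across 1-kb gene bodies (~28 probes per gene), three biological
replicates, multiplicative log-normal intensity noise (log2 SD 0.12),
an additive optical background common to all probes plus a population
of signal-free background control probes, an F1 with exactly equal
homoeolog dose, and an evolved allotetraploid with 10% At-deleted and
10% Aa-deleted genes, uniformly distributed true transcript shares,
50% unexpressed genes, optional planted alteration clusters, and
network-correlated bias.

Per-mismatch hybridization loss is not a single constant: factors are
drawn from $1 - 0.6\,\mathrm{Beta}(2,4)$ (mean 0.8, fixed per probe),
reflecting that terminal mismatches barely perturb a 25-mer duplex
while central ones can be severe. This matters structurally: with a
constant per-mismatch factor the one-mismatch ratio class is as sharp
as — and at 5% divergence more populous than — the conserved class, and
any mode estimator locks onto the wrong peak; with the heterogeneous
continuum, conserved probes form the unique sharp peak the scaling
assumes, which is also what real hybridization data look like. A
consequence is that mismatch *count* no longer determines effect size,
so recovery properties are asserted against the planted *attenuation*
(probes attenuated to ≤ 0.6 are recovered as DFs with ≥ 80%
sensitivity; unattenuated probes stay within the FDR target).

The generator is seed-deterministic byte for byte, with per-assay
derived seeds so that generating a subset of assays reproduces exactly
the corresponding rows of the full table. Read truth (parental origin)
travels in read names; reads are 72-base pairs from ~250-base
fragments with a configurable substitution error rate (default 0.5%),
and short indels between orthologs (default rate 0.005) are enabled for
read simulations only — the array simulation assumes colinearity, and
the generator enforces that.

What the generator does *not* emulate: probe-affinity sequence effects
(GC content), spatial array artifacts, saturation, cross-hybridization
from paralogs, RNA secondary-structure effects on hybridization or
fragmentation bias in libraries. Passing recovery tests therefore shows
that the estimators invert the stated signal model at realistic noise,
not that the signal model captures every pathology of real arrays.

## Problem sizes and numerical choices

The validation suite uses 10,000 simulated genes for the null
calibration of $X$; a 2,000-gene cohort for retention/expression
recovery; 20 null genomes of 2,000 genes for the alteration-scan
false-positive rate; and a 100-gene all-expressed cohort for the
array-vs-read concordance (a resequencing validation is necessarily of
expressed genes). Tie-breaks and degeneracies are fixed as follows:
the KDE argmax breaks ties toward the smallest ratio; constant ratio
vectors are their own mode and pass the normality screen (no evidence
against); probes with zero variance in both genotypes and equal means
are untestable; a zero pooled residual with unequal shares is flagged
degenerate with $p = 0$; permutation p-values use the add-one
estimator so they are never exactly zero.

## Known limitations

The F-test inherits mild anti-conservatism from the published
$6n - 1$ convention and from gene-level scale estimation; the
$|\Delta\alpha|$ floor makes retention calls robust to it, but
expression p-values near the threshold should be read with that in
mind (the permutation cross-check `alpha_permutation_test()` is
available per gene). The mode-based parental scaling carries an upward
bias of a few percent when diverged probes dominate a gene; the DF sign
rule neutralizes its effect on DF calls, and its remainder cancels
between the compared samples. Linear-scale regression on
multiplicatively noisy intensities is heteroscedastic by construction —
faithful to the method, slightly heavy-tailed under the null.
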