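---
title: "Methods: flanking-context preferences, tile DMRs and CGI histone binning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flanking-context preferences, tile DMRs and CGI histone binning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methcontext)
```

# The scientific setting

Maintenance DNA methylation copies CpG methylation onto newly replicated
strands (DNMT1 guided by UHRF1), while de-novo methyltransferases
(DNMT3A/B) and demethylases (TETs) remodel the pattern between
replications. When one of these proteins is acutely removed with a degron,
the methylome decays over days, and *how* it decays carries information:
each enzyme prefers certain flanking sequences around the CpG, so its
activity leaves a sequence "footprint" that fades when the enzyme is gone.
This package quantifies that footprint, calls regional methylation loss,
and relates CpG-island (CGI) methylation loss to histone marks.

All coordinates follow two fixed conventions: cytosine reports are 1-based
(the plus-strand coordinate of the base, for both strands), interval files
are 0-based half-open (BED). Every function states which it consumes.

# Flanking-context preference correlation

For each cytosine retained by the coverage filter (≥ 10 reads by default,
the conventional threshold for per-cytosine level estimates), the NNCGNN
context is read from the genome: for a plus-strand cytosine at position
$p$, the plus-strand window $[p-2, p+3]$; for a minus-strand cytosine, the
reverse complement of the corresponding window, so the two strand
cytosines of one CpG always carry reverse-complementary contexts. Windows
that leave the contig, contain N, or whose center is not CG are excluded
(with a logged count).

The observed profile assigns each of the 256 contexts the **unweighted
mean of per-site levels** $n_\text{meth}/(n_\text{meth}+n_\text{unmeth})$.
We deliberately average levels rather than pooling reads: the per-cytosine
level is the primary estimand (it is what the coverage filter guarantees),
and read-pooling would weight deep sites more. Contexts with no
contributing site are missing and dropped pairwise from correlations, never
imputed.

`preference_correlation()` computes Pearson's $r$ between the observed
256-vector and an enzyme's in-vitro preference vector. Two operands are
supported because the analysis is sometimes drawn as a ranking workflow:
`pearson_values` (default — Pearson on the raw vectors, the conventional
calculation) and `pearson_ranks` (Pearson on average-tie ranks, which
equals Spearman's $\rho$ and is invariant to monotone transforms). At
least 3 shared non-missing contexts are required; a zero-variance vector
raises an error rather than returning a silent 0.

Symmetrization (`symmetrize_profile()`) averages each context with its
reverse complement — appropriate for enzymes whose recognition is
palindrome-symmetric across the CpG. It is applied by default only to the
de-novo enzymes' simulated profiles (`symmetric_profiles` config key),
since maintenance activity on hemimethylated DNA is intrinsically
strand-asymmetric; users can symmetrize any profile explicitly. The 256
contexts partition into 120 complementary pairs and 16 palindromes, so the
operation is idempotent and palindromic values are fixed points.

Strand cytosines are treated as separate observations throughout (no
CpG-pair merging): the coverage filter is defined per cytosine, and
merging would discard the strand-asymmetric information that
unsymmetrized profiles can capture.

# 1-kb tile differential methylation

`tile_genome()` produces non-overlapping adjacent tiles (default width
1000 bp; the terminal tile is truncated, and kept — short tiles are
legitimate observations and are protected by the min-CpG rule).
Replicates within a condition are pooled by summing counts per cytosine;
a cytosine at 1-based position $p$ belongs to the tile containing $p-1$ in
0-based space. Tiles with fewer than 3 covered cytosines in either
condition (configurable) are dropped as uninformative.

Each tile is tested with a two-sided exact test on the pooled table
[[meth_a, unmeth_a], [meth_b, unmeth_b]]: the p-value is the sum of
hypergeometric probabilities of all tables with fixed margins whose
probability does not exceed the observed one, with a relative tolerance of
1e-7 on the comparison (the standard guard against floating-point ties).
This pooled exact test was chosen over a per-replicate regression because
it is exact, deterministic and dependency-free at the depths tiles
accumulate; q-values come from Benjamini–Hochberg over all tested tiles.
A tile is a DMR only when **both** thresholds hold: |difference| ≥ 25
percentage points and q < 0.01. Classification is antisymmetric under
swapping conditions, and under the null (two read samples of one
methylome) the suite verifies that significant calls stay ≤ 2%.

Venn-style overlap counting is keyed by tile identity (all sets must come
from one tiling). Feature annotation labels a tile promoter if it overlaps
any TSS ± 1 kb window, else gene body if it overlaps a gene, else
intergenic — a priority rule, so the three labels partition the tiles.

# CGI histone binning and the coupling test

Per-CGI ChIP reads are counted with ≥ 1 bp overlap semantics (0-based
half-open). Normalization follows the counts-per-10-million convention
with a +0.5 offset added *before* scaling and input division, which keeps
scores finite and positive when the input sample has zero reads in a CGI:

$$\text{score} = \frac{(chip + 0.5)\cdot 10^7 / T_{chip}}{(input + 0.5)\cdot 10^7 / T_{input}}$$

CGIs with fewer than 4 raw ChIP reads (randomly-mapped background) or zero
coverage in both samples are excluded. Scores are ranked ascending into 10
equally sized bins (bin 1 = lowest histone level; sizes differ by at most
one, remainder to the lowest-index bins; ties broken by coordinates so the
binning is deterministic and permutation-invariant). Per-bin boxplot
statistics use type-7 (linearly interpolated) quartiles with whiskers at
quartile ± 1.5·IQR clipped to the data range.

The trend statistic is $dd = \Delta_{U} - \Delta_{D}$ per CGI: the
methylation change after UHRF1-type depletion minus that after DNMT1-type
depletion, from pooled counts per timepoint. The Spearman test runs
**across CGIs**, not across the 10 bins — ten points would have negligible
power; the bins exist for display summaries. The p-value uses the t
approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df; a seeded
permutation alternative (≥ 10,000 permutations) is available and
recommended for n ≤ 30.

# The synthetic data generator

The generator exists so that every stage of the pipeline can be exercised
and validated against planted ground truth. Per strand-cytosine with valid
context $c$:

$$m = \mathrm{logistic}\!\Big(\alpha_0 + \sum_e \delta_e\,\big(w_e\, z_e(c) + b_e\big) + \varepsilon\Big)$$

* $z_e(c)$: enzyme $e$'s preference profile standardized over the 256
  contexts (so $w_e$ is in logit units per preference SD);
* $\delta_e \in [0,1]$: depletion factor per condition/timepoint — degron
  depletion is modeled as multiplicative activity scaling (a UHRF1-type
  condition reduces several enzymes at once, a DNMT1-type condition one);
* $b_e$: optional bulk (context-free) contribution. With all $b_e = 0$
  (the default) depletion erases footprints but leaves genome-wide mean
  methylation unchanged — the cleanest setting for correlation tests.
  Nonzero $b_e$ couple depletion to bulk methylation loss, which is what
  lets 1-kb tiles cross the 25-point DMR threshold; the demo configuration
  uses this (day-0 level ≈ 90%, DNMT1-type day-4 loss just past the
  threshold, UHRF1-type far past it), mirroring the observation that
  UHRF1-type depletion demethylates far more tiles, a superset of the
  DNMT1-type tiles;
* $\varepsilon \sim N(0, \sigma^2)$ is drawn **once per CpG** and shared
  by the two strand cytosines — required for the strand-symmetry property
  (symmetric profiles ⇒ equal true levels on both strands) — and shared
  across samples/timepoints when `persistent_noise` is on (default),
  making depletion contrasts paired rather than confounded by noise
  redraws;
* at histone-coupled timepoints, sites in CGI $j$ are further reduced:
  $m \leftarrow m\,(1-\beta\,\tilde h_j)$ with $\tilde h_j$ the CGI's
  latent log-normal histone score min–max normalized to [0,1];
* reads: coverage ~ Poisson($\lambda$) (zero-coverage sites omitted),
  $n_\text{meth}$ ~ Binomial(coverage, $m + (1-m)f$) with $f$ the
  bisulfite non-conversion rate (default 0). Conversion failure inflates
  only the unmethylated molecules' apparent methylation; over-conversion
  is not modeled.

Genomes are i.i.d. bases at the configured GC content (default 0.42,
human-like) with non-overlapping CGI blocks into which CpG dinucleotides
are planted at the configured density (default 0.08/bp, an order of
magnitude above the background CpG frequency). ChIP counts are
Poisson(depth·length·$h_j$), input counts Poisson(depth·length), totals
the sums plus a constant background representing reads outside CGIs.

Default study conditions (chosen once): weights dnmt1 = 1.0, dnmt3a = 0.8,
dnmt3b = 0.1 — strong maintenance and de-novo-A footprints and a
near-absent de-novo-B footprint, the pattern a somatic colorectal line
shows before depletion; $\alpha_0$ set so baseline methylation is ≈ 80–90%;
$\sigma$ = 0.5 logit units; $\lambda$ = 30 (typical WGBS depth);
$\beta$ = 0.4. The UHRF1-type day-4 condition sets $\delta_{dnmt1}=0$ and
$\delta_{dnmt3a,b}=0.2$ with histone coupling on (loss of the cofactor
impairs both maintenance and, indirectly, de-novo deposition); the
DNMT1-type condition sets only $\delta_{dnmt1}=0$.

Determinism: every generator call seeds the RNG from the config seed plus
a fixed per-operation offset (plus a label hash for per-sample read
draws), and restores the caller's RNG state afterwards. Identical configs
therefore produce byte-identical output files; the run manifest records
wall-clock timestamps and is compared net of its timestamp line in
determinism checks.

**What the generator does not emulate:** read-level artifacts (sequencing
error, mapping bias, strand-specific conversion), regional methylation
domains and replication-timing structure (noise is per-CpG, so 1-kb tiles
are internally homogeneous), negative-binomial overdispersion of coverage
(Poisson by default), hemimethylation dynamics, and real CGI sequence
composition beyond CpG density. Passing tests therefore demonstrate the
*statistical machinery* — context accounting, test calibration, rank/bin
logic, coupling detection — not robustness to alignment-level artifacts of
real WGBS data.

# Numerical and design choices

* Exact-test tie tolerance 1e-7 (relative); BH via `p.adjust`.
* Observed-vs-preference correlation defaults to Pearson on raw values;
  ranks are one flag away. For depletion-series experiments the footprint
  weight should sit in the near-linear regime of the logit link
  (w ≈ 0.5): at saturating weights ($w \ge 2$) the sigmoid compresses the
  extremes, and Pearson-on-values can *rise* as depletion shrinks the
  effective weight into the linear regime even though the footprint is
  fading — a link-function artifact that rank correlation avoids. The
  validation suite plants w = 2 for recovery checks (where it still gives
  r > 0.96) and w = 0.5 for the monotone depletion series.
* Decile binning: ascending, remainder to low bins, coordinate tie-break.
* Degenerate inputs raise classed errors (`methcontext_format_error`,
  `methcontext_config_error`, `methcontext_data_error`) with line numbers
  where a file is at fault; empty methylomes yield all-missing profiles
  with a warning rather than an error.
* The ChIP read-count filter (< 4) is applied per ChIP sample; whether a
  log transform precedes ranking is immaterial to the binning (ranks are
  transform-invariant).
* Problem sizes in the shipped validation runs: 245,025 exact-test tables
  (margins ≤ 30), 1.2 Mb genome / ≈ 53,000 CpGs at 100× for footprint
  recovery, 10 seeds × 5 depletion levels on 200 kb genomes at 30×,
  500 tiles for the null DMR check, 500 CGIs × 11 seeds for the coupling
  contrast, and a 200 kb demo pipeline run twice for byte-identity. These
  finish in a few minutes on a single CPU while leaving the Monte-Carlo
  margins wide.

# Known limitations

The pooled exact test ignores replicate-level overdispersion (a
per-replicate binomial GLM would be the natural extension); the Spearman
p-value's t approximation is asymptotic (use the permutation flag for
small n); preference tables are treated as external inputs — the shipped
profiles are synthetic stand-ins, not measured enzyme kinetics; and the
generator's independence assumptions make calibration results (e.g. the
≤ 2% null DMR rate) a statement about the test machinery, not about
correlated real-data noise.
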