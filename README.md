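# methcontext

Analysis toolkit for whole-genome bisulfite sequencing (WGBS) time courses
from acute, degron-style depletion of DNA-methylation enzymes — the setting
in which a maintenance methyltransferase (DNMT1), its cofactor (UHRF1), or
de-novo methyltransferases (DNMT3A/B) are removed within days and the
methylome's decay is read out per cytosine.

It implements three analyses that together dissect *which enzymes shaped a
methylome*:

1. **Flanking-context preference correlation.** Every CpG sits in one of the
   256 possible NNCGNN hexamer contexts (two bases either side of the CpG,
   read 5'→3' on the cytosine's strand). DNMT and TET enzymes have measured
   in-vitro preferences over these contexts. For a WGBS sample, the package
   computes the mean methylation level of each context (per-cytosine levels
   `n_meth / (n_meth + n_unmeth)`, coverage ≥ 10) and the Pearson
   correlation *r* between that 256-vector and an enzyme's preference
   vector. A large *r* means the enzyme's favorite sites are the most
   methylated — its footprint is on the genome; depletion erases it.
   Profiles of palindrome-symmetric enzymes are symmetrized by averaging
   each context with its reverse complement (the 256 contexts split into
   120 complementary pairs + 16 palindromes).
2. **1-kb tile differential methylation.** The genome is segmented into
   adjacent 1-kb tiles; replicate read counts are pooled per condition; each
   tile is tested with a two-sided exact test on the pooled 2×2 count table
   and corrected by Benjamini–Hochberg. A tile is a hypo-/hyper-DMR when
   |Δmethylation| ≥ 25 percentage points **and** q < 0.01. Overlap (Venn)
   counts and promoter/gene-body/intergenic annotation are included.
3. **CpG-island histone binning.** Per-CGI ChIP signal is normalized as
   `(count + 0.5)·10⁷/total`, divided by the same quantity for the input
   sample (CGIs with < 4 raw ChIP reads are excluded); CGIs are ranked into
   10 equally sized bins by normalized histone level, and the per-CGI
   difference `dd = Δmeth(UHRF1-type) − Δmeth(DNMT1-type)` is tested for a
   monotone trend with histone level by Spearman correlation.

A deterministic synthetic generator (`sim_config()`, `simulate_experiment()`)
produces genomes with CpG islands, enzyme preference tables, cytosine
reports with planted enzyme footprints and depletion time courses, and
CGI ChIP counts with a planted histone–demethylation coupling, so the whole
pipeline runs and is testable without any external data. The methylation
model is logit-linear: `m = logistic(α₀ + Σₑ δₑ(wₑ·zₑ(context) + bₑ) + ε)`
with per-enzyme footprint weights `wₑ`, optional bulk contributions `bₑ`,
depletion factors `δₑ`, and per-CpG noise ε.

## Worked example

Run the shipped demo (simulate → context → DMR → CGI) from R:

```r
library(methcontext)
cfg <- read_sim_config(system.file("extdata", "demo_config.yaml",
                                   package = "methcontext"))
run_pipeline(cfg, out_dir = "demo_run")
read_tsv("demo_run/context_correlations.tsv")
```

or from the shell via the thin CLI wrapper:

```sh
Rscript exec/methcontext run --config inst/extdata/demo_config.yaml --out demo_run
```

The demo plants three enzyme footprints (weights dnmt1 = 1.0, dnmt3a = 0.8,
dnmt3b = 0.1) and depletes them in two conditions. The correlation table it
prints:

```
    sample_id enzyme         method   n         r
1  UHRF1_day0  dnmt1 pearson_values 256  0.733246
2  UHRF1_day0 dnmt3a pearson_values 256  0.538004
3  UHRF1_day0 dnmt3b pearson_values 256 -0.007579
4  UHRF1_day4  dnmt1 pearson_values 256 -0.009638
...
```

Before depletion the dnmt1 and dnmt3a footprints are clearly visible
(r ≈ 0.73 and 0.54) while dnmt3b, planted at near-zero weight, shows none —
and four days after depletion the dnmt1 correlation has collapsed to ≈ 0.
The DMR stage calls 200/200 tiles hypomethylated in the UHRF1-type condition
versus 29/200 in the DNMT1-type condition, with every DNMT1-hypo tile also
UHRF1-hypo (`dmr_hypo_overlap.tsv`), and the CGI stage recovers the planted
histone coupling (`cgi_trend.tsv`: rho = −0.69, p ≈ 1e-9): CGIs with more of
the histone mark lose more methylation specifically in the UHRF1-type
condition.

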