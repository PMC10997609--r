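Package: methcontext
Title: CpG Flanking-Context Preference, Tile DMR and CpG-Island Histone
    Analyses for Degron Methylome Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-genome bisulfite sequencing time
    courses from acute (degron) depletion of DNA-methylation enzymes.
    Implements strand-aware NNCGNN flanking-context extraction and Pearson
    correlation of observed per-context methylation against in-vitro enzyme
    preference profiles (with complementary-flank symmetrization); 1-kb tile
    differential-methylation calling by pooled-count exact tests with
    Benjamini-Hochberg correction at the >25 percentage point / q<0.01
    thresholds; CpG-island ChIP normalization (counts per 10 million, +0.5
    offset, input ratio), decile binning by histone level and Spearman trend
    testing of depletion-specific methylation loss; and a fully deterministic
    synthetic genome/methylome/ChIP generator so the whole pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
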