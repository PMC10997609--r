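# Shared fixture builders. Everything is generated in code; no binary files.

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  con <- file(f, "wb")
  writeLines(lines, con)
  close(con)
  f
}

# A tiny deterministic genome with known CpGs for hand-checkable cases.
toy_genome <- function() {
  c(c1 = "TTACGGTTACGTTT",  # CpGs at 3-4 and 10-11
    c2 = "AAAACGAAAACGAA")  # CpGs at 4-5 and 10-11
}

# Uniform random genome with enough CpGs to populate all 256 contexts.
random_genome <- function(n = 60000L, seed = 42L, name = "chrR") {
  withr::with_seed(seed, {
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    stats::setNames(s, name)
  })
}

toy_methylome <- function(chrom, pos, strand, n_meth, n_unmeth,
                          sample_id = "toy") {
  methylome_table(data.frame(chrom = chrom, pos = as.integer(pos),
                             strand = strand, n_meth = as.integer(n_meth),
                             n_unmeth = as.integer(n_unmeth),
                             stringsAsFactors = FALSE), sample_id)
}

# Uniform preference profile fixture with fixed values.
flat_profile <- function(value = 0.5, name = "flat") {
  v <- rep(value, 256)
  names(v) <- all_hexamers()
  hexamer_profile(v, name = name)
}

random_profile <- function(seed, name = paste0("p", seed)) {
  simulate_preference_profile(seed, symmetric = FALSE, name = name)
}

demo_config_path <- function() {
  system.file("extdata", "demo_config.yaml", package = "methcontext")
}

# Small config for fast end-to-end runs.
small_config <- function(seed = 11L, ...) {
  sim_config(seed = seed, genome_length = 6e4, n_contigs = 2L,
             cgi_count = 20L, cgi_length = 500L, coverage_mean = 20, ...)
}
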