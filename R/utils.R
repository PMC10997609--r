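# Internal helpers shared across modules.

# Classed error so callers/tests can distinguish format errors, configuration
# errors etc. from arbitrary failures.
mc_error <- function(msg, class, ...) {
  stop(errorCondition(msg, class = c(class, "methcontext_error"),
                      call. = FALSE, ...))
}

mc_format_error <- function(msg, line = NA_integer_) {
  if (!is.na(line)) msg <- sprintf("%s (line %d)", msg, as.integer(line))
  mc_error(msg, "methcontext_format_error", line = line)
}

mc_config_error <- function(msg) mc_error(msg, "methcontext_config_error")

mc_data_error <- function(msg) mc_error(msg, "methcontext_data_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validated genome container: named character vector over {A,C,G,T,N}.
validate_genome <- function(genome) {
  if (!is.character(genome) || is.null(names(genome)))
    mc_data_error("genome must be a named character vector of sequences")
  if (anyDuplicated(names(genome)) || any(!nzchar(names(genome))))
    mc_data_error("genome contig names must be unique and non-empty")
  if (any(!nzchar(genome)))
    mc_data_error("genome sequences must be non-empty")
  bad <- grepl("[^ACGTN]", genome)
  if (any(bad))
    mc_data_error(sprintf("contig '%s' contains characters outside {A,C,G,T,N}",
                          names(genome)[which(bad)[1]]))
  genome
}

contig_lengths <- function(genome) {
  vapply(genome, nchar, integer(1))
}

# 0-based half-open interval data.frame -> GRanges (1-based closed internally)
intervals_to_granges <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end))
}

# per-cytosine positions (1-based) -> width-1 GRanges
positions_to_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(seqnames = chrom, ranges = IRanges::IRanges(pos, pos))
}
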