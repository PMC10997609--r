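# Readers and writers for the formats the pipeline touches.
#
# Coordinate conventions, used consistently everywhere:
#   * cytosine reports are 1-based (position of the cytosine on the plus
#     strand's coordinate system, for both strands);
#   * all interval files (BED) are 0-based half-open.

#' Read a multi-contig FASTA file
#'
#' Sequences are uppercased, \code{U} is mapped to \code{T}, and every other
#' non-ACGT letter is mapped to \code{N}. Contig order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences over \{A,C,G,T,N\}.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L)
    mc_format_error(sprintf("empty FASTA file: %s", path))
  hdr <- startsWith(lines, ">")
  if (!hdr[1])
    mc_format_error("FASTA must start with a '>' header", line = 1L)
  names_raw <- sub("^>\\s*", "", lines[hdr])
  names_raw <- sub("\\s.*$", "", names_raw)  # keep first token, as samtools does
  if (any(!nzchar(names_raw))) {
    bad <- which(hdr)[!nzchar(names_raw)][1]
    mc_format_error("empty FASTA header", line = bad)
  }
  if (anyDuplicated(names_raw)) {
    dup <- names_raw[duplicated(names_raw)][1]
    bad <- which(hdr)[names_raw == dup][2]
    mc_format_error(sprintf("duplicate contig name '%s'", dup), line = bad)
  }
  grp <- cumsum(hdr)
  body <- !hdr
  seqs <- vapply(seq_along(names_raw), function(i) {
    paste(lines[body & grp == i], collapse = "")
  }, character(1))
  seqs <- toupper(seqs)
  seqs <- chartr("U", "T", seqs)
  seqs <- gsub("[^ACGTN]", "N", seqs)
  if (any(!nzchar(seqs))) {
    bad <- which(hdr)[!nzchar(seqs)][1]
    mc_format_error(sprintf("contig '%s' has an empty sequence",
                            names_raw[!nzchar(seqs)][1]), line = bad)
  }
  names(seqs) <- names_raw
  validate_genome(seqs)
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  genome <- validate_genome(genome)
  con <- file(path, "wb")  # binary mode forces LF endings
  on.exit(close(con))
  for (nm in names(genome)) {
    s <- genome[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", nm), substring(s, starts, pmin(starts + width - 1L, nchar(s)))),
               con)
  }
  invisible(path)
}

# -- cytosine reports ---------------------------------------------------------

#' Assemble a validated methylome table
#'
#' @param df data.frame with columns chrom, pos (1-based), strand, n_meth,
#'   n_unmeth.
#' @param sample_id Sample label stored as an attribute.
#' @return data.frame of class \code{methylome}, sorted by (chrom, pos,
#'   strand) with no duplicate sites.
#' @export
methylome_table <- function(df, sample_id = "sample") {
  need <- c("chrom", "pos", "strand", "n_meth", "n_unmeth")
  if (!all(need %in% names(df)))
    mc_data_error(paste("methylome table needs columns:", paste(need, collapse = ", ")))
  df <- as.data.frame(df)[need]
  df$chrom <- as.character(df$chrom)
  df$strand <- as.character(df$strand)
  if (any(!df$strand %in% c("+", "-")))
    mc_data_error("strand must be '+' or '-'")
  if (any(df$pos < 1L)) mc_data_error("positions must be >= 1")
  if (any(df$n_meth < 0L | df$n_unmeth < 0L))
    mc_data_error("read counts must be non-negative")
  df <- unique(df)
  key <- paste(df$chrom, df$pos, df$strand)
  if (anyDuplicated(key))
    mc_data_error(sprintf("conflicting duplicate records at %s",
                          key[duplicated(key)][1]))
  df <- df[order(df$chrom, df$pos, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "sample_id") <- sample_id
  class(df) <- c("methylome", "data.frame")
  df
}

#' Read a Bismark-style cytosine report
#'
#' Expects a tab-separated table with columns chrom, pos (1-based), strand
#' (+/-), methylated count, unmethylated count; extra columns are ignored.
#' A leading '#'-prefixed header line is allowed. Sites with total coverage
#' below \code{min_coverage} are dropped (the number dropped is reported via
#' \code{message}); output is sorted and de-duplicated.
#'
#' @param path Path to the report.
#' @param min_coverage Minimum read coverage for a cytosine to be retained
#'   (default 10).
#' @param sample_id Sample label; defaults to the file name.
#' @return A \code{methylome} data.frame.
#' @export
read_cytosine_report <- function(path, min_coverage = 10L,
                                 sample_id = sub("\\.[^.]*$", "", basename(path))) {
  if (min_coverage < 0) mc_config_error("min_coverage must be >= 0")
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          colClasses = "character", fill = TRUE,
                          blank.lines.skip = TRUE)
  offset <- 0L
  if (nrow(dt) && startsWith(dt[[1]][1], "#")) {
    dt <- dt[-1]
    offset <- 1L
  }
  if (nrow(dt) == 0L)
    return(methylome_table(data.frame(chrom = character(), pos = integer(),
                                      strand = character(), n_meth = integer(),
                                      n_unmeth = integer()), sample_id))
  if (ncol(dt) < 5L)
    mc_format_error(sprintf("cytosine report needs >= 5 tab-separated columns, found %d",
                            ncol(dt)), line = offset + 1L)
  lineno <- seq_len(nrow(dt)) + offset
  pos <- suppressWarnings(as.numeric(dt[[2]]))
  bad <- which(is.na(pos) | pos != floor(pos))
  if (length(bad))
    mc_format_error(sprintf("non-integer position '%s'", dt[[2]][bad[1]]),
                    line = lineno[bad[1]])
  bad <- which(!dt[[3]] %in% c("+", "-"))
  if (length(bad))
    mc_format_error(sprintf("strand must be '+' or '-', found '%s'", dt[[3]][bad[1]]),
                    line = lineno[bad[1]])
  nm <- suppressWarnings(as.numeric(dt[[4]]))
  nu <- suppressWarnings(as.numeric(dt[[5]]))
  bad <- which(is.na(nm) | is.na(nu) | nm < 0 | nu < 0 |
                 nm != floor(nm) | nu != floor(nu))
  if (length(bad))
    mc_format_error(sprintf("counts must be non-negative integers, found '%s'/'%s'",
                            dt[[4]][bad[1]], dt[[5]][bad[1]]),
                    line = lineno[bad[1]])
  df <- data.frame(chrom = dt[[1]], pos = as.integer(pos),
                   strand = dt[[3]], n_meth = as.integer(nm),
                   n_unmeth = as.integer(nu), stringsAsFactors = FALSE)
  keep <- df$n_meth + df$n_unmeth >= min_coverage
  if (any(!keep))
    message(sprintf("read_cytosine_report: dropped %d/%d sites below coverage %d",
                    sum(!keep), nrow(df), as.integer(min_coverage)))
  methylome_table(df[keep, , drop = FALSE], sample_id)
}

#' Write a methylome table as a cytosine report
#'
#' @param methylome A \code{methylome} data.frame.
#' @param path Output path.
#' @export
write_cytosine_report <- function(methylome, path) {
  write_tsv(as.data.frame(methylome), path,
            header = c("chrom", "pos", "strand", "n_meth", "n_unmeth"))
}

# -- preference tables --------------------------------------------------------

#' Read an enzyme flanking-preference table
#'
#' Tab-separated file with columns hexamer, value; must contain each of the
#' 256 NNCGNN contexts exactly once with finite values.
#'
#' @param path Path to the TSV.
#' @param name Profile label; defaults to the file name.
#' @return A \code{hexamer_profile}.
#' @export
read_preference_table <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          colClasses = "character", blank.lines.skip = TRUE)
  if (nrow(dt) && startsWith(dt[[1]][1], "#")) dt <- dt[-1]
  if (ncol(dt) < 2L)
    mc_format_error("preference table needs columns hexamer, value")
  vals <- suppressWarnings(as.numeric(dt[[2]]))
  if (anyNA(vals) || any(!is.finite(vals)))
    mc_format_error(sprintf("non-numeric or non-finite preference value '%s'",
                            dt[[2]][which(is.na(vals) | !is.finite(vals))[1]]))
  v <- vals
  names(v) <- toupper(dt[[1]])
  hexamer_profile(v, name = name)
}

#' Write a hexamer profile as a preference TSV
#'
#' @param profile A \code{hexamer_profile}.
#' @param path Output path.
#' @export
write_preference_table <- function(profile, path) {
  stopifnot(inherits(profile, "hexamer_profile"))
  df <- data.frame(hexamer = names(profile$values), value = unname(profile$values))
  write_tsv(df, path, header = c("hexamer", "value"))
}

# -- BED intervals ------------------------------------------------------------

#' Assemble a validated interval set
#'
#' @param df data.frame with columns chrom, start, end (0-based half-open) and
#'   optionally name and strand.
#' @return data.frame of class \code{interval_set} with unique names
#'   (unnamed intervals are auto-named \code{chrom:start-end}).
#' @export
interval_set <- function(df) {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)))
    mc_data_error("interval set needs columns chrom, start, end")
  df <- as.data.frame(df)
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$start < 0L)) mc_data_error("interval start must be >= 0")
  if (any(df$start >= df$end))
    mc_data_error(sprintf("empty or inverted interval %s:%d-%d",
                          df$chrom[df$start >= df$end][1],
                          df$start[df$start >= df$end][1],
                          df$end[df$start >= df$end][1]))
  if (is.null(df$name)) df$name <- rep(NA_character_, nrow(df))
  auto <- is.na(df$name) | df$name == "." | !nzchar(df$name)
  df$name[auto] <- sprintf("%s:%d-%d", df$chrom[auto], df$start[auto], df$end[auto])
  if (anyDuplicated(df$name))
    mc_data_error(sprintf("duplicate interval name '%s'",
                          df$name[duplicated(df$name)][1]))
  keep <- c("chrom", "start", "end", "name", if ("strand" %in% names(df)) "strand")
  df <- df[keep]
  rownames(df) <- NULL
  class(df) <- c("interval_set", "data.frame")
  df
}

#' Read a BED3+ interval file (0-based half-open)
#'
#' Columns beyond the fourth (name) are ignored except a sixth (strand),
#' which is kept when present. Unnamed intervals are auto-named
#' \code{chrom:start-end}.
#'
#' @param path Path to the BED file.
#' @return An \code{interval_set} data.frame.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          colClasses = "character", fill = TRUE,
                          blank.lines.skip = TRUE)
  if (nrow(dt) && (startsWith(dt[[1]][1], "#") || startsWith(dt[[1]][1], "track")))
    dt <- dt[-1]
  if (nrow(dt) == 0L)
    return(interval_set(data.frame(chrom = character(), start = integer(),
                                   end = integer())))
  if (ncol(dt) < 3L) mc_format_error("BED needs >= 3 columns", line = 1L)
  start <- suppressWarnings(as.integer(dt[[2]]))
  end <- suppressWarnings(as.integer(dt[[3]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    mc_format_error("non-integer BED coordinates", line = bad[1])
  bad <- which(start >= end)
  if (length(bad))
    mc_format_error(sprintf("empty interval %s:%d-%d", dt[[1]][bad[1]],
                            start[bad[1]], end[bad[1]]), line = bad[1])
  df <- data.frame(chrom = dt[[1]], start = start, end = end,
                   stringsAsFactors = FALSE)
  if (ncol(dt) >= 4L) df$name <- dt[[4]]
  if (ncol(dt) >= 6L && all(dt[[6]] %in% c("+", "-", ".")))
    df$strand <- dt[[6]]
  interval_set(df)
}

#' Write an interval set as BED
#'
#' @param intervals An \code{interval_set}.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  df <- as.data.frame(intervals)
  cols <- c("chrom", "start", "end", "name")
  if ("strand" %in% names(df)) {
    df$score <- "."
    cols <- c(cols, "score", "strand")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  utils::write.table(df[cols], con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# -- generic TSV --------------------------------------------------------------

#' Write a table as TSV with a '#'-prefixed header
#'
#' Deterministic row order (rows written as given), tab separation, '.' for
#' missing values, LF line endings.
#'
#' @param table data.frame to write.
#' @param path Output path.
#' @param header Column names to write; defaults to \code{names(table)}.
#' @export
write_tsv <- function(table, path, header = names(table)) {
  df <- as.data.frame(table)
  for (j in seq_along(df)) {
    x <- df[[j]]
    if (is.numeric(x)) x <- trimws(formatC(x, format = "g", digits = 15))
    x[is.na(df[[j]])] <- "."
    df[[j]] <- x
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste0("#", paste(header, collapse = "\t")), con)
  if (nrow(df))
    writeLines(do.call(paste, c(df, sep = "\t")), con)
  invisible(path)
}

#' Read a TSV written by \code{write_tsv}
#'
#' @param path Path to the TSV.
#' @return data.frame with '.' converted back to \code{NA}; numeric-looking
#'   columns are converted to numeric.
#' @export
read_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) mc_format_error(sprintf("empty TSV: %s", path))
  header <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  if (length(lines) == 1L) {
    df <- as.data.frame(matrix(character(), 0, length(header)))
    names(df) <- header
    return(df)
  }
  dt <- data.table::fread(text = lines[-1], sep = "\t", header = FALSE,
                          colClasses = "character")
  df <- as.data.frame(dt)
  names(df) <- header
  for (j in seq_along(df)) {
    x <- df[[j]]
    x[x == "."] <- NA
    num <- suppressWarnings(as.numeric(x))
    if (!anyNA(num[!is.na(x)])) x <- num
    df[[j]] <- x
  }
  df
}
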