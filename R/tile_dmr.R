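# 1-kb tile differential methylation: tiling, pooled-count aggregation,
# two-sided exact test, Benjamini-Hochberg correction, DMR classification
# at the >25 percentage point / q < 0.01 thresholds, overlap counting and
# feature annotation.

#' Segment a genome into fixed-width tiles
#'
#' Non-overlapping adjacent tiles per contig (0-based half-open); the final
#' tile is truncated at the contig end. Tiles are named
#' \code{chrom:start-end}.
#'
#' @param genome Named character vector of contig sequences, or a named
#'   integer vector of contig lengths.
#' @param width Tile width in bp (default 1000).
#' @return An \code{interval_set} of tiles.
#' @export
tile_genome <- function(genome, width = 1000L) {
  if (width < 1L) mc_config_error("tile width must be >= 1")
  lens <- if (is.numeric(genome)) {
    if (is.null(names(genome))) mc_data_error("contig lengths must be named")
    stats::setNames(as.integer(genome), names(genome))
  } else {
    contig_lengths(validate_genome(genome))
  }
  pieces <- lapply(names(lens), function(nm) {
    starts <- seq(0L, lens[[nm]] - 1L, by = width)
    data.frame(chrom = nm, start = starts,
               end = pmin(starts + as.integer(width), lens[[nm]]),
               stringsAsFactors = FALSE)
  })
  interval_set(do.call(rbind, pieces))
}

pool_methylomes <- function(methylomes) {
  if (inherits(methylomes, "methylome")) methylomes <- list(methylomes)
  if (!length(methylomes)) mc_config_error("a condition has no methylomes")
  dt <- data.table::rbindlist(lapply(methylomes, as.data.frame))
  dt <- dt[, list(n_meth = sum(n_meth), n_unmeth = sum(n_unmeth)),
           by = c("chrom", "pos", "strand")]
  as.data.frame(dt)
}

#' Pool replicate methylomes into per-tile counts for two conditions
#'
#' Replicates within a condition are pooled by summing read counts per
#' cytosine; a cytosine at 1-based position p belongs to the tile containing
#' p-1 in 0-based coordinates. Tiles with fewer than \code{min_cpg} covered
#' cytosines in either condition are dropped. The methylation difference is
#' computed from pooled counts, in percentage points (condition B minus
#' condition A).
#'
#' @param methylomes_a,methylomes_b \code{methylome} data.frames or lists of
#'   replicates, already coverage-filtered.
#' @param tiles Tile \code{interval_set} from \code{tile_genome}.
#' @param min_cpg Minimum covered cytosines per condition per tile
#'   (default 3).
#' @return data.frame of class \code{tile_methylation} with pooled counts,
#'   covered-CpG counts and diff per retained tile.
#' @export
aggregate_tile_counts <- function(methylomes_a, methylomes_b, tiles,
                                  min_cpg = 3L) {
  a <- pool_methylomes(methylomes_a)
  b <- pool_methylomes(methylomes_b)
  tile_gr <- intervals_to_granges(tiles)
  per_cond <- function(df) {
    gr <- positions_to_granges(df$chrom, df$pos)
    hit <- GenomicRanges::findOverlaps(gr, tile_gr)
    data.table::data.table(
      tile = S4Vectors::subjectHits(hit),
      n_meth = df$n_meth[S4Vectors::queryHits(hit)],
      n_unmeth = df$n_unmeth[S4Vectors::queryHits(hit)]
    )[, list(n_cpg = .N, meth = sum(n_meth), unmeth = sum(n_unmeth)),
      by = "tile"]
  }
  ca <- per_cond(a)
  cb <- per_cond(b)
  m <- merge(ca, cb, by = "tile", suffixes = c("_a", "_b"))
  m <- m[m$n_cpg_a >= min_cpg & m$n_cpg_b >= min_cpg, ]
  idx <- m$tile
  out <- data.frame(
    chrom = tiles$chrom[idx], start = tiles$start[idx], end = tiles$end[idx],
    name = tiles$name[idx],
    n_cpg_a = m$n_cpg_a, n_cpg_b = m$n_cpg_b,
    meth_a = m$meth_a, unmeth_a = m$unmeth_a,
    meth_b = m$meth_b, unmeth_b = m$unmeth_b,
    stringsAsFactors = FALSE)
  out$diff <- 100 * out$meth_b / (out$meth_b + out$unmeth_b) -
    100 * out$meth_a / (out$meth_a + out$unmeth_a)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tile_methylation", "data.frame")
  out
}

#' Two-sided exact test on pooled 2x2 methylation counts
#'
#' For a table [[meth_a, unmeth_a], [meth_b, unmeth_b]] with fixed margins,
#' the two-sided p-value is the sum of hypergeometric probabilities of all
#' tables at most as probable as the observed one (relative tolerance 1e-7,
#' as in the conventional definition of the exact test).
#'
#' @param meth_a,unmeth_a,meth_b,unmeth_b Non-negative integer count vectors
#'   (recycled to common length).
#' @return Numeric vector of p-values in (0, 1].
#' @export
fisher_exact_p <- function(meth_a, unmeth_a, meth_b, unmeth_b) {
  n <- max(length(meth_a), length(unmeth_a), length(meth_b), length(unmeth_b))
  a <- rep_len(as.numeric(meth_a), n); b <- rep_len(as.numeric(unmeth_a), n)
  c_ <- rep_len(as.numeric(meth_b), n); d <- rep_len(as.numeric(unmeth_b), n)
  if (any(a + b <= 0) || any(c_ + d <= 0))
    mc_data_error("zero pooled coverage in a condition; exact test undefined")
  vapply(seq_len(n), function(i) {
    m <- a[i] + c_[i]          # total methylated reads (column margin)
    r1 <- a[i] + b[i]          # condition A coverage (row margin)
    tot <- r1 + c_[i] + d[i]
    support <- max(0, m - (tot - r1)):min(r1, m)
    probs <- stats::dhyper(support, r1, tot - r1, m)
    p_obs <- stats::dhyper(a[i], r1, tot - r1, m)
    min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Test a tile table for differential methylation
#'
#' @param tiles A \code{tile_methylation} data.frame.
#' @return The same data.frame with a \code{p_value} column appended.
#' @export
test_tiles <- function(tiles) {
  tiles$p_value <- fisher_exact_p(tiles$meth_a, tiles$unmeth_a,
                                  tiles$meth_b, tiles$unmeth_b)
  tiles
}

#' Call differentially methylated regions
#'
#' Benjamini-Hochberg q-values over all tested tiles; a tile is a hypo-DMR
#' when its methylation difference is at or below \code{-diff_threshold}
#' percentage points with q below \code{q_threshold}, a hyper-DMR in the
#' mirrored case, otherwise not significant.
#'
#' @param tiles A \code{tile_methylation} data.frame; p-values are computed
#'   if absent.
#' @param diff_threshold Methylation-difference threshold in percentage
#'   points (default 25).
#' @param q_threshold q-value threshold (default 0.01).
#' @return data.frame of class \code{dmr_table}, sorted by coordinates, with
#'   p_value, q_value and class (hypo/hyper/ns) columns; summary counts in
#'   attribute \code{summary}.
#' @export
call_dmrs <- function(tiles, diff_threshold = 25, q_threshold = 0.01) {
  if (is.null(tiles$p_value)) tiles <- test_tiles(tiles)
  tiles$q_value <- stats::p.adjust(tiles$p_value, method = "BH")
  cls <- rep("ns", nrow(tiles))
  cls[tiles$diff <= -diff_threshold & tiles$q_value < q_threshold] <- "hypo"
  cls[tiles$diff >= diff_threshold & tiles$q_value < q_threshold] <- "hyper"
  tiles$class <- cls
  tiles <- tiles[order(tiles$chrom, tiles$start), , drop = FALSE]
  rownames(tiles) <- NULL
  summary <- c(n_hypo = sum(cls == "hypo"), n_hyper = sum(cls == "hyper"),
               n_ns = sum(cls == "ns"))
  message(sprintf("call_dmrs: %d hypo, %d hyper, %d ns",
                  summary[1], summary[2], summary[3]))
  attr(tiles, "summary") <- summary
  class(tiles) <- c("dmr_table", "data.frame")
  tiles
}

#' Count tiles in every overlap region of several DMR sets
#'
#' Given k named DMR sets derived from the same tiling, counts the tiles in
#' each of the 2^k - 1 membership combinations (the cells of a Venn
#' diagram), keyed by tile name.
#'
#' @param sets Named list; each element a \code{dmr_table} or a character
#'   vector of tile names.
#' @return data.frame with one row per non-empty membership combination and
#'   columns \code{combination} (e.g. "A&B") and \code{count}; all 2^k - 1
#'   combinations are listed, including empty ones.
#' @export
overlap_dmr_sets <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    mc_config_error("DMR sets must be named")
  ids <- lapply(sets, function(s) {
    if (is.character(s)) s else s$name
  })
  universe <- unique(unlist(ids))
  member <- vapply(ids, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  k <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(combos) <- names(sets)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    mask <- as.logical(combos[i, ])
    inside <- rowSums(member[, mask, drop = FALSE]) == sum(mask) &
      rowSums(member[, !mask, drop = FALSE]) == 0
    data.frame(combination = paste(names(sets)[mask], collapse = "&"),
               count = sum(inside), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annotate DMR tiles by genomic feature
#'
#' Each tile is labeled promoter when it overlaps a TSS window (TSS plus or
#' minus \code{promoter_flank} bp), else gene_body when it overlaps a gene,
#' else intergenic. Gene intervals must carry strand; the TSS is the 5' end
#' of the gene on its strand.
#'
#' @param dmrs A \code{dmr_table} (or any \code{interval_set}-like
#'   data.frame of tiles).
#' @param genes An \code{interval_set} with a strand column.
#' @param promoter_flank Promoter half-width around the TSS in bp
#'   (default 1000).
#' @return The input with a \code{feature} column; per-class counts in
#'   attribute \code{feature_counts}.
#' @export
annotate_tiles <- function(dmrs, genes, promoter_flank = 1000L) {
  if (is.null(genes$strand))
    mc_data_error("gene intervals must carry strand to locate the TSS")
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)  # 0-based
  prom <- interval_set(data.frame(
    chrom = genes$chrom,
    start = pmax(0L, tss - as.integer(promoter_flank)),
    end = tss + as.integer(promoter_flank) + 1L,
    name = paste0(genes$name, "_prom")))
  tile_gr <- intervals_to_granges(dmrs)
  in_prom <- GenomicRanges::countOverlaps(tile_gr, intervals_to_granges(prom)) > 0
  in_gene <- GenomicRanges::countOverlaps(tile_gr, intervals_to_granges(genes)) > 0
  feature <- rep("intergenic", nrow(dmrs))
  feature[in_gene] <- "gene_body"
  feature[in_prom] <- "promoter"
  dmrs$feature <- feature
  attr(dmrs, "feature_counts") <- c(
    promoter = sum(feature == "promoter"),
    gene_body = sum(feature == "gene_body"),
    intergenic = sum(feature == "intergenic"))
  dmrs
}
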