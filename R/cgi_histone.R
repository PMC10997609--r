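# CpG-island ChIP normalization, decile binning by histone level, per-bin
# summaries of depletion-specific methylation loss, and Spearman trend
# testing.

#' Count reads overlapping each target interval
#'
#' A read interval counts toward a target when they share at least one base
#' (0-based half-open overlap: read.start < target.end and
#' read.end > target.start); one read may count toward several targets.
#'
#' @param reads An \code{interval_set} of read intervals.
#' @param targets An \code{interval_set} of target intervals (e.g. CGIs).
#' @return Integer vector of counts, one per target, named by target.
#' @export
interval_read_count <- function(reads, targets) {
  counts <- GenomicRanges::countOverlaps(intervals_to_granges(targets),
                                         intervals_to_granges(reads))
  stats::setNames(as.integer(counts), targets$name)
}

#' Normalize ChIP read counts over CGIs against an input sample
#'
#' CGIs with fewer than \code{min_reads} raw ChIP reads are excluded (guards
#' against randomly mapped regions), as are CGIs with zero coverage in both
#' ChIP and input. Counts are scaled to counts per 10 million mapped reads
#' with an offset of 0.5 added before scaling (so regions with zero input
#' reads stay finite), then the ChIP value is divided by the input value:
#' \deqn{score = \frac{(chip + 0.5) \cdot 10^7 / T_{chip}}
#'                    {(input + 0.5) \cdot 10^7 / T_{input}}}
#'
#' @param cgis An \code{interval_set} of CGIs.
#' @param chip_counts,input_counts Integer read counts per CGI (same order
#'   as \code{cgis}).
#' @param chip_total,input_total Total mapped reads per sample.
#' @param min_reads Minimum raw ChIP reads per retained CGI (default 4).
#' @return data.frame of class \code{cgi_score_table} with raw counts and
#'   \code{norm_score} for the retained CGIs.
#' @export
normalize_cgi_signal <- function(cgis, chip_counts, input_counts,
                                 chip_total, input_total, min_reads = 4L) {
  if (chip_total <= 0 || input_total <= 0)
    mc_config_error("mapped-read totals must be positive")
  if (length(chip_counts) != nrow(cgis) || length(input_counts) != nrow(cgis))
    mc_config_error("counts must align with the CGI set")
  keep <- chip_counts >= min_reads & !(chip_counts == 0 & input_counts == 0)
  out <- data.frame(
    chrom = cgis$chrom[keep], start = cgis$start[keep], end = cgis$end[keep],
    name = cgis$name[keep],
    raw_count = as.integer(chip_counts[keep]),
    input_count = as.integer(input_counts[keep]),
    stringsAsFactors = FALSE)
  scaled_chip <- (out$raw_count + 0.5) * 1e7 / chip_total
  scaled_input <- (out$input_count + 0.5) * 1e7 / input_total
  out$norm_score <- scaled_chip / scaled_input
  rownames(out) <- NULL
  class(out) <- c("cgi_score_table", "data.frame")
  out
}

#' Per-CGI methylation change between two timepoints
#'
#' Pooled-count methylation percent at the later timepoint minus at the
#' earlier one, over the cytosines falling inside each CGI. Replicates
#' (lists of methylomes) are pooled per timepoint before differencing. CGIs
#' with no covered cytosine at either timepoint carry \code{NA}.
#'
#' @param methylome_day0,methylome_dayN \code{methylome} data.frames (or
#'   lists of replicates), already coverage-filtered.
#' @param cgis An \code{interval_set} of CGIs.
#' @return Numeric vector of deltas in percentage points, one per CGI, named
#'   by CGI.
#' @export
cgi_methylation_delta <- function(methylome_day0, methylome_dayN, cgis) {
  cgi_gr <- intervals_to_granges(cgis)
  percent <- function(methylomes) {
    df <- pool_methylomes(methylomes)
    gr <- positions_to_granges(df$chrom, df$pos)
    hit <- GenomicRanges::findOverlaps(gr, cgi_gr)
    meth <- unmeth <- numeric(nrow(cgis))
    q <- S4Vectors::queryHits(hit)
    s <- S4Vectors::subjectHits(hit)
    meth <- as.numeric(tapply(df$n_meth[q], factor(s, levels = seq_len(nrow(cgis))),
                              sum, default = 0))
    unmeth <- as.numeric(tapply(df$n_unmeth[q], factor(s, levels = seq_len(nrow(cgis))),
                                sum, default = 0))
    ifelse(meth + unmeth > 0, 100 * meth / (meth + unmeth), NA_real_)
  }
  delta <- percent(methylome_dayN) - percent(methylome_day0)
  stats::setNames(delta, cgis$name)
}

#' Assign scores to equally sized rank bins
#'
#' Values are ranked ascending (bin 1 = lowest, bin \code{n_bins} =
#' highest); bin sizes differ by at most one, with the remainder going to
#' the lowest-index bins. Ties are broken by the \code{tie_break} order
#' (e.g. CGI coordinates) for determinism.
#'
#' @param scores Numeric vector (e.g. per-CGI norm_score).
#' @param n_bins Number of bins (default 10, i.e. deciles).
#' @param tie_break Optional data.frame/list of vectors used to order tied
#'   scores.
#' @return Integer vector of bin indices (1..n_bins) aligned with
#'   \code{scores}.
#' @export
decile_bins <- function(scores, n_bins = 10L, tie_break = NULL) {
  n <- length(scores)
  if (n < n_bins)
    mc_data_error(sprintf("need at least %d scored CGIs to form %d bins",
                          n_bins, n_bins))
  ord <- if (is.null(tie_break)) order(scores)
         else do.call(order, c(list(scores), unname(as.list(tie_break))))
  sizes <- rep(n %/% n_bins, n_bins)
  rem <- n %% n_bins
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  bins <- integer(n)
  bins[ord] <- rep(seq_len(n_bins), times = sizes)
  bins
}

#' Per-bin distribution summary (boxplot statistics)
#'
#' For each bin: n, median, 25th and 75th percentiles (linear
#' interpolation), and whisker bounds at quartile plus/minus 1.5 IQR clipped
#' to the data range.
#'
#' @param values Numeric vector (e.g. per-CGI dd = delta_u - delta_d).
#' @param bins Integer bin assignment aligned with \code{values}.
#' @return data.frame with one row per bin.
#' @export
bin_summary <- function(values, bins) {
  levels <- sort(unique(bins))
  rows <- lapply(levels, function(b) {
    x <- values[bins == b & !is.na(values)]
    if (!length(x))
      return(data.frame(bin = b, n = 0L, median = NA_real_, q25 = NA_real_,
                        q75 = NA_real_, whisker_lo = NA_real_,
                        whisker_hi = NA_real_))
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(bin = b, n = length(x), median = q[2], q25 = q[1], q75 = q[3],
               whisker_lo = max(min(x), q[1] - 1.5 * iqr),
               whisker_hi = min(max(x), q[3] + 1.5 * iqr))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spearman correlation trend test
#'
#' Rho is the Pearson correlation of average-tie rank vectors. The two-sided
#' p-value uses the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on n-2 degrees of freedom;
#' \code{method = "permutation"} instead permutes one vector (seeded) and
#' reports the empirical two-sided p, recommended for n of 30 or fewer.
#'
#' @param x,y Paired numeric vectors; pairs with missing values are dropped.
#' @param method "t_approx" or "permutation".
#' @param n_perm Number of permutations (default 10000).
#' @param seed RNG seed for the permutation method.
#' @return data.frame with rho, p_value, n and method.
#' @export
spearman_trend_test <- function(x, y, method = c("t_approx", "permutation"),
                                n_perm = 10000L, seed = 1L) {
  method <- match.arg(method)
  use <- !is.na(x) & !is.na(y)
  x <- x[use]; y <- y[use]
  n <- length(x)
  if (n < 10L) mc_data_error("need at least 10 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    mc_data_error("constant vector; correlation undefined")
  rho_of <- function(yy) stats::cor(rank(x, ties.method = "average"),
                                    rank(yy, ties.method = "average"))
  rho <- rho_of(y)
  if (method == "t_approx") {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
    }
  } else {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    perm <- vapply(seq_len(n_perm), function(i) rho_of(sample(y)), numeric(1))
    p <- (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  data.frame(rho = rho, p_value = p, n = n, method = method,
             stringsAsFactors = FALSE)
}

#' Assemble the CGI histone/methylation score table
#'
#' Combines normalized ChIP scores with per-CGI methylation deltas for the
#' two depletion conditions, computes dd = delta_u - delta_d (how much more
#' methylation a CGI loses under UHRF1-type than under DNMT1-type
#' depletion), and assigns decile bins by histone score.
#'
#' @param scores A \code{cgi_score_table} from \code{normalize_cgi_signal}.
#' @param delta_u,delta_d Named per-CGI deltas (percentage points) from
#'   \code{cgi_methylation_delta} for the two conditions.
#' @param n_bins Number of histone-level bins (default 10).
#' @return The score table with delta_u, delta_d, dd and bin columns.
#' @export
cgi_score_table <- function(scores, delta_u, delta_d, n_bins = 10L) {
  scores$delta_u <- as.numeric(delta_u[scores$name])
  scores$delta_d <- as.numeric(delta_d[scores$name])
  scores$dd <- scores$delta_u - scores$delta_d
  scores$bin <- decile_bins(scores$norm_score, n_bins = n_bins,
                            tie_break = scores[c("chrom", "start")])
  scores
}
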