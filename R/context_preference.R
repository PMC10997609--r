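# Strand-aware NNCGNN context extraction and correlation of observed
# per-context methylation against in-vitro enzyme preference profiles.

#' Extract the NNCGNN flanking context of a cytosine
#'
#' For a plus-strand cytosine at 1-based position p (with the CpG's G at
#' p+1) the context is the plus-strand window [p-2, p+3]. For a minus-strand
#' cytosine at plus-strand coordinate q (opposite the G of the CpG) it is the
#' reverse complement of the plus-strand window [q-3, q+2]; the minus context
#' of a CpG is therefore always the reverse complement of its plus context.
#' Sites whose window runs off the contig, contains N, or whose central
#' dinucleotide is not CG yield \code{NA} (excluded).
#'
#' @param genome Named character vector of contig sequences.
#' @param chrom Contig name(s).
#' @param pos 1-based position(s) of the cytosine.
#' @param strand "+" or "-" per position.
#' @return Character vector of NNCGNN contexts, \code{NA} where excluded.
#' @export
extract_context <- function(genome, chrom, pos, strand) {
  genome <- validate_genome(genome)
  n <- max(length(chrom), length(pos), length(strand))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  strand <- rep_len(as.character(strand), n)
  if (any(!chrom %in% names(genome)))
    mc_data_error(sprintf("unknown contig '%s'", chrom[!chrom %in% names(genome)][1]))
  len <- contig_lengths(genome)[chrom]
  if (any(pos < 1L | pos > len))
    mc_data_error("position outside contig bounds")
  plus <- strand == "+"
  lo <- ifelse(plus, pos - 2L, pos - 3L)
  hi <- ifelse(plus, pos + 3L, pos + 2L)
  out <- rep(NA_character_, n)
  ok <- lo >= 1L & hi <= len
  if (any(ok)) {
    win <- substring(genome[chrom[ok]], lo[ok], hi[ok])
    neg <- !plus[ok]
    if (any(neg)) {
      rc <- chartr("ACGTN", "TGCAN", win[neg])
      win[neg] <- vapply(strsplit(rc, "", fixed = TRUE),
                         function(ch) paste(rev(ch), collapse = ""), character(1))
    }
    win[!is_valid_hexamer(win)] <- NA_character_
    out[ok] <- win
  }
  out
}

#' Per-context mean methylation observed in a methylome
#'
#' Each retained cytosine (coverage at least \code{min_coverage}, valid
#' NNCGNN context) contributes its methylation level
#' \code{n_meth / (n_meth + n_unmeth)}; the profile value of a context is the
#' unweighted mean of the levels of the sites carrying it. Contexts with no
#' contributing site carry \code{NA} and are dropped pairwise in
#' correlations.
#'
#' @param methylome A \code{methylome} data.frame.
#' @param genome Named character vector of contig sequences.
#' @param min_coverage Minimum coverage per cytosine (default 10).
#' @return A \code{hexamer_profile} with per-context means and site counts.
#' @export
build_observed_profile <- function(methylome, genome, min_coverage = 10L) {
  cov <- methylome$n_meth + methylome$n_unmeth
  keep <- cov >= min_coverage
  m <- methylome[keep, , drop = FALSE]
  if (nrow(m) == 0L) {
    warning("no cytosines pass the coverage filter; profile is all-missing")
    v <- rep(NA_real_, 256L)
    names(v) <- hexamer_universe
    return(hexamer_profile(v, name = attr(methylome, "sample_id") %||% "sample",
                           n_sites = integer(0)))
  }
  ctx <- extract_context(genome, m$chrom, m$pos, m$strand)
  ok <- !is.na(ctx)
  n_excluded <- sum(!ok)
  if (n_excluded > 0L)
    message(sprintf("build_observed_profile: excluded %d sites with invalid context",
                    n_excluded))
  level <- m$n_meth[ok] / (m$n_meth[ok] + m$n_unmeth[ok])
  ctx <- ctx[ok]
  means <- tapply(level, ctx, mean)
  counts <- table(ctx)
  v <- rep(NA_real_, 256L)
  names(v) <- hexamer_universe
  v[names(means)] <- as.numeric(means)
  ns <- as.integer(counts)
  names(ns) <- names(counts)
  hexamer_profile(v, name = attr(methylome, "sample_id") %||% "sample",
                  n_sites = ns)
}

#' Correlate observed methylation with an enzyme preference profile
#'
#' Pearson correlation between per-context observed methylation and in-vitro
#' preference, over the contexts non-missing in both profiles.
#' \code{method = "pearson_values"} correlates the raw values (the default);
#' \code{method = "pearson_ranks"} correlates average-tie rank vectors, which
#' equals Spearman's rho.
#'
#' @param observed Observation \code{hexamer_profile}.
#' @param preference Enzyme preference \code{hexamer_profile}.
#' @param method "pearson_values" or "pearson_ranks".
#' @return data.frame with sample_id, enzyme, method, n (contexts used) and r.
#' @export
preference_correlation <- function(observed, preference,
                                   method = c("pearson_values", "pearson_ranks")) {
  method <- match.arg(method)
  stopifnot(inherits(observed, "hexamer_profile"),
            inherits(preference, "hexamer_profile"))
  x <- observed$values
  y <- preference$values
  use <- !is.na(x) & !is.na(y)
  if (sum(use) < 3L)
    mc_data_error("fewer than 3 contexts shared by the two profiles")
  x <- x[use]
  y <- y[use]
  if (method == "pearson_ranks") {
    x <- rank(x, ties.method = "average")
    y <- rank(y, ties.method = "average")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    mc_data_error("zero variance in one profile; correlation undefined")
  data.frame(sample_id = observed$name, enzyme = preference$name,
             method = method, n = sum(use),
             r = stats::cor(x, y), stringsAsFactors = FALSE)
}

#' Preference correlations for every sample x enzyme combination
#'
#' Builds the observed per-context profile of each methylome against the
#' shared genome, then correlates it with every enzyme preference profile.
#' Row order is sample order times enzyme order.
#'
#' @param samples List of \code{methylome} data.frames (named or carrying
#'   sample_id attributes).
#' @param genome Named character vector of contig sequences.
#' @param enzymes List of preference \code{hexamer_profile}s.
#' @param method Correlation operand, as in \code{preference_correlation}.
#' @param min_coverage Coverage filter applied when building observed
#'   profiles.
#' @return data.frame with one row per (sample, enzyme).
#' @export
correlation_matrix <- function(samples, genome, enzymes,
                               method = c("pearson_values", "pearson_ranks"),
                               min_coverage = 10L) {
  method <- match.arg(method)
  if (!length(samples)) mc_config_error("no samples given")
  if (!length(enzymes)) mc_config_error("no enzyme profiles given")
  rows <- vector("list", length(samples) * length(enzymes))
  k <- 1L
  for (i in seq_along(samples)) {
    obs <- build_observed_profile(samples[[i]], genome, min_coverage)
    if (!is.null(names(samples)) && nzchar(names(samples)[i]))
      obs$name <- names(samples)[i]
    for (j in seq_along(enzymes)) {
      rows[[k]] <- preference_correlation(obs, enzymes[[j]], method)
      k <- k + 1L
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
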