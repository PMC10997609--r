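# One-command orchestration: simulate -> context correlation -> tile DMR ->
# CGI histone binning, with a run manifest.

canonicalize <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x))) x <- x[order(names(x))]
    lapply(x, canonicalize)
  } else if (is.numeric(x) && !is.null(names(x))) {
    as.list(x[order(names(x))])
  } else x
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical serialization; invariant under key reordering.
#'
#' @param config A \code{sim_config} or plain list.
#' @return Character MD5 digest.
#' @export
config_hash <- function(config) {
  canon <- canonicalize(unclass(config))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  con <- file(tmp, "wb")
  writeLines(paste(deparse(canon), collapse = ""), con)
  close(con)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(path, files, seed, cfg_hash) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(
    sprintf("#methcontext_version=%s",
            as.character(utils::packageVersion("methcontext"))),
    sprintf("#seed=%d", as.integer(seed)),
    sprintf("#config_hash=%s", cfg_hash),
    sprintf("#timestamp=%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    "#file\tmd5\tbytes"), con)
  for (f in files) {
    writeLines(sprintf("%s\t%s\t%d", basename(f), unname(tools::md5sum(f)),
                       file.info(f)$size), con)
  }
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order and writes per-stage
#' TSV outputs plus a run manifest (file list with checksums, seed, config
#' hash, timestamp) into \code{out_dir}. Stages after \code{simulate} read
#' their inputs from \code{out_dir}, so a previous simulate run (or files a
#' user placed there under the same names) can be reused.
#'
#' @param config A \code{sim_config}, or the path to a YAML config file.
#' @param stages Subset of c("simulate", "context", "dmr", "cgi").
#' @param out_dir Output directory (created if needed).
#' @param min_coverage Per-cytosine coverage filter (default 10).
#' @param tile_width DMR tile width in bp (default 1000).
#' @param diff_threshold DMR methylation-difference threshold in percentage
#'   points (default 25).
#' @param q_threshold DMR q-value threshold (default 0.01).
#' @param min_cpg Minimum covered CpGs per tile and condition (default 3).
#' @param min_reads Minimum raw ChIP reads per CGI (default 4).
#' @param n_bins Histone-level bins (default 10).
#' @param method Correlation operand for the context stage.
#' @return Invisibly, the manifest path; stage outputs are files in
#'   \code{out_dir}.
#' @export
run_pipeline <- function(config, stages = c("simulate", "context", "dmr", "cgi"),
                         out_dir, min_coverage = 10L, tile_width = 1000L,
                         diff_threshold = 25, q_threshold = 0.01,
                         min_cpg = 3L, min_reads = 4L, n_bins = 10L,
                         method = c("pearson_values", "pearson_ranks")) {
  method <- match.arg(method)
  known <- c("simulate", "context", "dmr", "cgi")
  bad <- setdiff(stages, known)
  if (length(bad))
    mc_config_error(paste("unknown stage(s):", paste(bad, collapse = ", ")))
  if (is.character(config)) config <- read_sim_config(config)
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(name) {
    f <- file.path(out_dir, name)
    outputs <<- c(outputs, f)
    f
  }
  sample_ids <- unlist(lapply(names(config$conditions), function(cond)
    paste(cond, names(config$conditions[[cond]]), sep = "_")))

  if ("simulate" %in% stages) {
    message("stage simulate")
    ex <- simulate_experiment(config)
    write_fasta(ex$genome, emit("genome.fa"))
    write_bed(ex$cgis, emit("cgis.bed"))
    for (e in names(ex$profiles))
      write_preference_table(ex$profiles[[e]], emit(sprintf("pref_%s.tsv", e)))
    for (id in names(ex$methylomes))
      write_cytosine_report(ex$methylomes[[id]], emit(sprintf("report_%s.tsv", id)))
    write_tsv(data.frame(cgi = ex$cgis$name,
                         chip_count = ex$chip$chip_counts,
                         input_count = ex$chip$input_counts,
                         histone_norm = ex$chip$histone_norm),
              emit("chip_counts.tsv"))
    write_tsv(data.frame(sample = c("chip", "input"),
                         total = c(ex$chip$chip_total, ex$chip$input_total)),
              emit("chip_totals.tsv"))
  }

  need_file <- function(name) {
    f <- file.path(out_dir, name)
    if (!file.exists(f))
      mc_config_error(sprintf("missing input %s (run the simulate stage first)", f))
    f
  }
  load_methylomes <- function() {
    ms <- lapply(sample_ids, function(id)
      read_cytosine_report(need_file(sprintf("report_%s.tsv", id)),
                           min_coverage = min_coverage, sample_id = id))
    stats::setNames(ms, sample_ids)
  }

  if (any(c("context", "dmr", "cgi") %in% stages)) {
    genome <- read_fasta(need_file("genome.fa"))
    methylomes <- load_methylomes()
  }

  if ("context" %in% stages) {
    message("stage context")
    enzymes <- lapply(names(config$enzyme_weights), function(e)
      read_preference_table(need_file(sprintf("pref_%s.tsv", e)), name = e))
    corr <- correlation_matrix(methylomes, genome, enzymes, method = method,
                               min_coverage = min_coverage)
    write_tsv(corr, emit("context_correlations.tsv"))
  }

  if ("dmr" %in% stages) {
    message("stage dmr")
    tiles <- tile_genome(genome, width = tile_width)
    hypo_sets <- list()
    for (cond in names(config$conditions)) {
      tps <- names(config$conditions[[cond]])
      if (length(tps) < 2L) next
      a <- methylomes[[paste(cond, tps[1], sep = "_")]]
      b <- methylomes[[paste(cond, tps[length(tps)], sep = "_")]]
      tm <- aggregate_tile_counts(a, b, tiles, min_cpg = min_cpg)
      dmrs <- call_dmrs(tm, diff_threshold = diff_threshold,
                        q_threshold = q_threshold)
      write_tsv(dmrs[c("chrom", "start", "end", "name", "n_cpg_a", "n_cpg_b",
                       "diff", "p_value", "q_value", "class")],
                emit(sprintf("dmr_%s.tsv", cond)))
      hypo_sets[[cond]] <- dmrs$name[dmrs$class == "hypo"]
    }
    if (length(hypo_sets) >= 2L)
      write_tsv(overlap_dmr_sets(hypo_sets), emit("dmr_hypo_overlap.tsv"))
  }

  if ("cgi" %in% stages) {
    message("stage cgi")
    cgis <- read_bed(need_file("cgis.bed"))
    chip <- read_tsv(need_file("chip_counts.tsv"))
    totals <- read_tsv(need_file("chip_totals.tsv"))
    chip <- chip[match(cgis$name, chip$cgi), , drop = FALSE]
    scores <- normalize_cgi_signal(
      cgis, chip$chip_count, chip$input_count,
      chip_total = totals$total[totals$sample == "chip"],
      input_total = totals$total[totals$sample == "input"],
      min_reads = min_reads)
    conds <- names(config$conditions)
    if (length(conds) < 2L)
      mc_config_error("cgi stage needs two depletion conditions")
    delta_for <- function(cond) {
      tps <- names(config$conditions[[cond]])
      cgi_methylation_delta(methylomes[[paste(cond, tps[1], sep = "_")]],
                            methylomes[[paste(cond, tps[length(tps)], sep = "_")]],
                            cgis)
    }
    delta_u <- delta_for(conds[1])
    delta_d <- delta_for(conds[2])
    tab <- cgi_score_table(scores, delta_u, delta_d, n_bins = n_bins)
    write_tsv(tab[c("chrom", "start", "end", "name", "raw_count", "input_count",
                    "norm_score", "delta_u", "delta_d", "dd", "bin")],
              emit("cgi_scores.tsv"))
    write_tsv(bin_summary(tab$dd, tab$bin), emit("cgi_bin_summary.tsv"))
    ok <- !is.na(tab$dd)
    trend <- spearman_trend_test(tab$norm_score[ok], tab$dd[ok])
    write_tsv(trend, emit("cgi_trend.tsv"))
  }

  manifest <- file.path(out_dir, "manifest.tsv")
  write_manifest(manifest, outputs, config$seed, config_hash(config))
  invisible(manifest)
}
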