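# Synthetic genome / methylome / ChIP generator.
#
# Generative model for per-CpG methylation: each strand cytosine with valid
# NNCGNN context c has true level
#     m = logistic(alpha0 + sum_e delta_e * (w_e * z_e(c) + b_e) + eps)
# where z_e is the enzyme's preference profile standardized over the 256
# contexts, w_e the enzyme's footprint weight, b_e its bulk (context-free)
# contribution in logit units, delta_e in [0,1] scales the enzyme's
# activity (degron depletion), and eps ~ N(0, sigma^2) is drawn once per
# CpG (shared by the two strand cytosines, and by all samples when
# persistent noise is on). With all b_e = 0 (the default) depletion erases
# an enzyme's sequence footprint without moving bulk methylation; nonzero
# b_e additionally couple depletion to global methylation loss, which is
# what makes tiles cross DMR thresholds.
# At depletion timepoints coupled to a histone mark, sites inside CGI j are
# further demethylated: m <- m * (1 - beta * h_j), with h_j the CGI's
# latent histone score min-max normalized to [0,1]. Read sampling is
# coverage ~ Poisson(lambda) and n_meth ~ Binomial(coverage, m') with
# m' = m + (1 - m) * conversion_failure.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

label_hash <- function(label) {
  v <- utf8ToInt(label)
  sum(v * seq_along(v)) %% 100000L
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic genome, methylome, depletion and
#' ChIP generators. Identical configurations (including \code{seed}) produce
#' byte-identical outputs.
#'
#' @param seed Integer RNG seed.
#' @param genome_length Total genome length in bp.
#' @param n_contigs Number of contigs (lengths split evenly).
#' @param gc_content Background GC fraction.
#' @param cgi_count,cgi_length,cgi_cpg_density CpG islands: how many, their
#'   length in bp, and the CpG dinucleotides planted per bp of island.
#' @param enzyme_weights Named numeric: per-enzyme footprint weight w_e in
#'   logit units per standardized preference unit.
#' @param enzyme_bulk Named numeric: per-enzyme bulk (context-free)
#'   contribution b_e in logit units, scaled by the same depletion factor
#'   as the footprint. Defaults to 0 for every enzyme, in which case
#'   depletion changes the methylation pattern but not its genome-wide
#'   mean.
#' @param symmetric_profiles Names of enzymes whose simulated preference
#'   profiles are symmetrized over complementary flanks.
#' @param baseline Logit-scale intercept alpha0 (0 gives 50\% methylation;
#'   the default 1.4 gives ~80\%, a typical somatic baseline).
#' @param site_noise_sd Per-CpG logit-scale noise sd (sigma).
#' @param persistent_noise Logical; share per-CpG noise across all samples
#'   and timepoints (default TRUE), so depletion contrasts are paired.
#' @param coverage_mean Mean sequencing coverage lambda (Poisson).
#' @param conversion_failure Fraction of unmethylated cytosines read as
#'   methylated (bisulfite non-conversion; default 0).
#' @param conditions Named list of depletion conditions; each condition is a
#'   named list of timepoints, each timepoint a list with elements
#'   \code{depletion} (named numeric delta per enzyme; enzymes omitted keep
#'   delta 1) and \code{coupled} (logical: apply histone coupling).
#' @param histone_coupling Coupling strength beta in [0,1): extra relative
#'   methylation loss at the highest-histone CGI at coupled timepoints.
#' @param chip_depth Expected ChIP/input reads per kb of CGI at unit histone
#'   score.
#' @param chip_background Reads mapped outside CGIs, added to the totals.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 1e6,
                       n_contigs = 2L,
                       gc_content = 0.42,
                       cgi_count = 200L,
                       cgi_length = 1000L,
                       cgi_cpg_density = 0.08,
                       enzyme_weights = c(dnmt1 = 1.0, dnmt3a = 0.8, dnmt3b = 0.1),
                       enzyme_bulk = NULL,
                       symmetric_profiles = c("dnmt3a", "dnmt3b"),
                       baseline = 1.4,
                       site_noise_sd = 0.5,
                       persistent_noise = TRUE,
                       coverage_mean = 30,
                       conversion_failure = 0,
                       conditions = default_conditions(names(enzyme_weights)),
                       histone_coupling = 0.4,
                       chip_depth = 200,
                       chip_background = 1e6) {
  if (is.null(names(enzyme_weights)))
    mc_config_error("enzyme_weights must be named")
  bulk <- stats::setNames(rep(0, length(enzyme_weights)), names(enzyme_weights))
  if (!is.null(enzyme_bulk)) {
    unknown <- setdiff(names(enzyme_bulk), names(enzyme_weights))
    if (length(unknown))
      mc_config_error(paste("enzyme_bulk names unknown enzyme(s):",
                            paste(unknown, collapse = ", ")))
    bulk[names(enzyme_bulk)] <- enzyme_bulk
  }
  cfg <- list(seed = as.integer(seed), genome_length = genome_length,
              n_contigs = as.integer(n_contigs), gc_content = gc_content,
              cgi_count = as.integer(cgi_count),
              cgi_length = as.integer(cgi_length),
              cgi_cpg_density = cgi_cpg_density,
              enzyme_weights = enzyme_weights,
              enzyme_bulk = bulk,
              symmetric_profiles = symmetric_profiles,
              baseline = baseline, site_noise_sd = site_noise_sd,
              persistent_noise = isTRUE(persistent_noise),
              coverage_mean = coverage_mean,
              conversion_failure = conversion_failure,
              conditions = conditions,
              histone_coupling = histone_coupling,
              chip_depth = chip_depth, chip_background = chip_background)
  frac <- c(gc_content = gc_content, cgi_cpg_density = cgi_cpg_density,
            conversion_failure = conversion_failure)
  bad <- names(frac)[frac < 0 | frac > 1]
  if (length(bad))
    mc_config_error(paste("fraction out of [0,1]:", paste(bad, collapse = ", ")))
  if (coverage_mean <= 0) mc_config_error("coverage_mean must be > 0")
  if (site_noise_sd < 0) mc_config_error("site_noise_sd must be >= 0")
  if (histone_coupling < 0 || histone_coupling >= 1)
    mc_config_error("histone_coupling must be in [0,1)")
  for (cond in conditions) for (tp in cond) {
    unknown <- setdiff(names(tp$depletion %||% numeric(0)), names(enzyme_weights))
    if (length(unknown))
      mc_config_error(paste("depletion names unknown enzyme:",
                            paste(unknown, collapse = ", ")))
    if (any(tp$depletion < 0 | tp$depletion > 1))
      mc_config_error("depletion factors must be in [0,1]")
  }
  if (cfg$cgi_count * cfg$cgi_length > genome_length)
    mc_config_error("total CGI length exceeds the genome")
  structure(cfg, class = "sim_config")
}

#' Default two-condition degron depletion design
#'
#' A UHRF1-type condition (maintenance cofactor lost: the maintenance enzyme
#' fully depleted, de-novo enzymes strongly reduced, histone-coupled extra
#' CGI demethylation) and a DNMT1-type condition (maintenance enzyme only),
#' each with a pre-depletion day0 and a depleted day4.
#'
#' @param enzymes Enzyme names; the first is treated as the maintenance
#'   enzyme.
#' @return Nested condition list as consumed by \code{sim_config}.
#' @export
default_conditions <- function(enzymes = c("dnmt1", "dnmt3a", "dnmt3b")) {
  maint <- enzymes[1]
  denovo <- setdiff(enzymes, maint)
  uhrf1_day4 <- c(stats::setNames(0, maint), stats::setNames(rep(0.2, length(denovo)), denovo))
  dnmt1_day4 <- stats::setNames(0, maint)
  list(
    UHRF1 = list(day0 = list(depletion = NULL, coupled = FALSE),
                 day4 = list(depletion = uhrf1_day4, coupled = TRUE)),
    DNMT1 = list(day0 = list(depletion = NULL, coupled = FALSE),
                 day4 = list(depletion = dnmt1_day4, coupled = FALSE)))
}

#' Read a simulation configuration from YAML
#'
#' Keys mirror the arguments of \code{sim_config}; unknown keys raise a
#' configuration error naming the key.
#'
#' @param path Path to a YAML file.
#' @return A \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    mc_config_error(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  for (k in c("enzyme_weights", "enzyme_bulk")) {
    if (!is.null(raw[[k]])) raw[[k]] <- unlist(raw[[k]])
  }
  if (!is.null(raw$conditions)) {
    raw$conditions <- lapply(raw$conditions, function(cond) {
      lapply(cond, function(tp) {
        list(depletion = if (!is.null(tp$depletion)) unlist(tp$depletion),
             coupled = isTRUE(tp$coupled))
      })
    })
  }
  do.call(sim_config, raw)
}

#' Simulate a genome with CpG islands
#'
#' Background bases are drawn independently at the configured GC content;
#' CGI blocks are placed non-overlapping and CpG dinucleotides are planted
#' inside them at the configured density.
#'
#' @param config A \code{sim_config}.
#' @return List with \code{genome} (named character vector) and \code{cgis}
#'   (an \code{interval_set}).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    p <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
           G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
    len_each <- config$genome_length %/% config$n_contigs
    lens <- rep(len_each, config$n_contigs)
    lens[config$n_contigs] <- config$genome_length - len_each * (config$n_contigs - 1L)
    contigs <- paste0("chr", seq_len(config$n_contigs))
    chars <- lapply(lens, function(L) sample(names(p), L, replace = TRUE, prob = p))
    names(chars) <- contigs
    # place CGIs non-overlapping, contigs weighted by length
    cgis <- data.frame(chrom = character(0), start = integer(0), end = integer(0))
    if (config$cgi_count > 0) {
      placed <- lapply(contigs, function(x) integer(0))
      names(placed) <- contigs
      attempts <- 0L
      while (nrow(cgis) < config$cgi_count) {
        attempts <- attempts + 1L
        if (attempts > 1000L * config$cgi_count)
          mc_config_error("could not place the requested CGIs without overlap")
        ctg <- sample(contigs, 1L, prob = lens)
        L <- lens[match(ctg, contigs)]
        if (L < config$cgi_length) next
        s <- sample.int(L - config$cgi_length + 1L, 1L) - 1L  # 0-based start
        ex <- cgis[cgis$chrom == ctg, , drop = FALSE]
        if (any(s < ex$end & s + config$cgi_length > ex$start)) next
        cgis <- rbind(cgis, data.frame(chrom = ctg, start = s,
                                       end = s + config$cgi_length))
      }
      cgis <- cgis[order(cgis$chrom, cgis$start), , drop = FALSE]
      cgis$name <- sprintf("CGI_%04d", seq_len(nrow(cgis)))
      n_cpg <- round(config$cgi_length * config$cgi_cpg_density)
      for (i in seq_len(nrow(cgis))) {
        ch <- chars[[cgis$chrom[i]]]
        local_starts <- seq(1L, config$cgi_length - 1L, by = 2L)
        pick <- sort(sample(local_starts, min(n_cpg, length(local_starts))))
        at <- cgis$start[i] + pick  # 1-based positions of the C
        ch[at] <- "C"
        ch[at + 1L] <- "G"
        chars[[cgis$chrom[i]]] <- ch
      }
    }
    genome <- vapply(chars, paste, character(1), collapse = "")
    list(genome = validate_genome(genome),
         cgis = interval_set(cgis))
  })
}

#' Simulate an enzyme flanking-preference profile
#'
#' 256 independent standard-normal draws, min-max rescaled to [0,1];
#' optionally symmetrized over complementary flanks.
#'
#' @param seed RNG seed.
#' @param symmetric Average each context with its reverse complement.
#' @param name Profile label.
#' @return A \code{hexamer_profile}.
#' @export
simulate_preference_profile <- function(seed, symmetric = FALSE, name = "enzyme") {
  with_seed(seed, {
    v <- stats::rnorm(256)
    v <- (v - min(v)) / (max(v) - min(v))
    names(v) <- hexamer_universe
    prof <- hexamer_profile(v, name = name)
    if (symmetric) prof <- symmetrize_profile(prof)
    prof
  })
}

# Locate every CpG of the genome: plus-strand C position p (1-based) and the
# shared plus-strand context window [p-2, p+3]. The minus-strand cytosine of
# the pair sits at p+1 and its context is the reverse complement.
find_cpgs <- function(genome) {
  pieces <- lapply(names(genome), function(nm) {
    hits <- gregexpr("CG", genome[[nm]], fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(NULL)
    p <- as.integer(hits)
    ctx <- substring(genome[[nm]], p - 2L, p + 3L)
    ctx[!is_valid_hexamer(ctx)] <- NA_character_
    data.frame(chrom = nm, pos = p, context_plus = ctx, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = integer(0),
                      context_plus = character(0))
  out
}

#' Simulate a WGBS cytosine report
#'
#' Applies the logit-linear preference mixture described at the top of this
#' file to every strand cytosine of every CpG with a valid context, then
#' samples reads. CpGs whose context window leaves the contig or contains N
#' are excluded; strand cytosines drawing zero coverage are omitted from
#' the report.
#'
#' @param genome Named character vector (from \code{simulate_genome}).
#' @param cgis CGI \code{interval_set} (used for histone coupling).
#' @param profiles Named list of \code{hexamer_profile}s, one per enzyme in
#'   \code{config$enzyme_weights}.
#' @param config A \code{sim_config}.
#' @param depletion Named numeric delta per enzyme in [0,1]; enzymes omitted
#'   keep delta 1. \code{NULL} means no depletion.
#' @param histone_norm Per-CGI histone scores normalized to [0,1] (from
#'   \code{simulate_chip}); when non-NULL and \code{config$histone_coupling
#'   > 0}, CGI methylation is reduced by \code{beta * h}.
#' @param sample_id Sample label (also seeds the read-sampling RNG, so
#'   different samples get independent reads).
#' @return A \code{methylome} data.frame; true per-site levels in attribute
#'   \code{true_level}, excluded-context count in attribute
#'   \code{n_excluded}.
#' @export
simulate_methylome <- function(genome, cgis, profiles, config,
                               depletion = NULL, histone_norm = NULL,
                               sample_id = "sample") {
  stopifnot(inherits(config, "sim_config"))
  missing_prof <- setdiff(names(config$enzyme_weights), names(profiles))
  if (length(missing_prof))
    mc_config_error(paste("no preference profile for enzyme(s):",
                          paste(missing_prof, collapse = ", ")))
  if (!is.null(depletion)) {
    unknown <- setdiff(names(depletion), names(config$enzyme_weights))
    if (length(unknown))
      mc_config_error(paste("depletion names unknown enzyme(s):",
                            paste(unknown, collapse = ", ")))
  }
  delta <- stats::setNames(rep(1, length(config$enzyme_weights)),
                           names(config$enzyme_weights))
  if (!is.null(depletion)) delta[names(depletion)] <- depletion

  cpgs <- find_cpgs(genome)
  valid <- !is.na(cpgs$context_plus)
  n_excluded <- sum(!valid)
  cpgs <- cpgs[valid, , drop = FALSE]
  if (nrow(cpgs) == 0L) mc_data_error("genome contains no CpG with valid context")

  # linear predictor per CpG and strand
  eta_of <- function(ctx) {
    eta <- rep(config$baseline, length(ctx))
    for (e in names(config$enzyme_weights)) {
      v <- profiles[[e]]$values
      z <- (v - mean(v)) / stats::sd(v)
      eta <- eta + delta[[e]] * (config$enzyme_weights[[e]] * unname(z[ctx]) +
                                   config$enzyme_bulk[[e]])
    }
    eta
  }
  eta_plus <- eta_of(cpgs$context_plus)
  eta_minus <- eta_of(unname(hexamer_revcomp_map[cpgs$context_plus]))

  # per-CpG noise: persistent noise is seeded from the config alone so that
  # every sample/timepoint shares it (paired design)
  eps_seed <- if (config$persistent_noise) config$seed + 2L
              else config$seed + 2L + label_hash(sample_id)
  eps <- with_seed(eps_seed, stats::rnorm(nrow(cpgs), 0, config$site_noise_sd))

  m_plus <- stats::plogis(eta_plus + eps)
  m_minus <- stats::plogis(eta_minus + eps)

  if (!is.null(histone_norm) && config$histone_coupling > 0 && nrow(cgis) > 0) {
    hit <- GenomicRanges::findOverlaps(
      positions_to_granges(cpgs$chrom, cpgs$pos), intervals_to_granges(cgis))
    q <- S4Vectors::queryHits(hit)
    h <- histone_norm[S4Vectors::subjectHits(hit)]
    fac <- 1 - config$histone_coupling * h
    m_plus[q] <- m_plus[q] * fac
    m_minus[q] <- m_minus[q] * fac
  }

  # expand to strand cytosines: plus record at p, minus record at p+1
  n <- nrow(cpgs)
  chrom <- rep(cpgs$chrom, each = 2L)
  pos <- as.integer(rbind(cpgs$pos, cpgs$pos + 1L))
  strand <- rep(c("+", "-"), n)
  m <- as.numeric(rbind(m_plus, m_minus))

  f <- config$conversion_failure
  p_read <- m + (1 - m) * f

  with_seed(config$seed + 10L + label_hash(sample_id), {
    coverage <- stats::rpois(2L * n, config$coverage_mean)
    n_meth <- stats::rbinom(2L * n, coverage, p_read)
  })
  keep <- coverage > 0L
  out <- methylome_table(
    data.frame(chrom = chrom[keep], pos = pos[keep], strand = strand[keep],
               n_meth = n_meth[keep], n_unmeth = coverage[keep] - n_meth[keep],
               stringsAsFactors = FALSE),
    sample_id = sample_id)
  # methylome_table sorts; carry true levels in the same order
  ord <- order(chrom[keep], pos[keep], strand[keep])
  attr(out, "true_level") <- m[keep][ord]
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Simulate CGI ChIP-seq and input read counts
#'
#' Each CGI gets a latent histone score h ~ LogNormal(0,1); ChIP counts are
#' Poisson with mean \code{chip_depth * length/1000 * h}, input counts
#' Poisson with mean \code{chip_depth * length/1000}. Totals are the column
#' sums plus the configured background (reads outside CGIs).
#'
#' @param cgis CGI \code{interval_set}.
#' @param config A \code{sim_config}.
#' @return List with histone (latent), histone_norm (min-max to [0,1]),
#'   chip_counts, input_counts, chip_total, input_total.
#' @export
simulate_chip <- function(cgis, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(cgis) == 0L) mc_config_error("no CGIs to simulate ChIP for")
  with_seed(config$seed + 3L, {
    h <- stats::rlnorm(nrow(cgis), 0, 1)
    lam <- config$chip_depth * (cgis$end - cgis$start) / 1000
    chip <- stats::rpois(nrow(cgis), lam * h)
    input <- stats::rpois(nrow(cgis), lam)
    list(histone = h,
         histone_norm = (h - min(h)) / (max(h) - min(h)),
         chip_counts = chip, input_counts = input,
         chip_total = sum(chip) + config$chip_background,
         input_total = sum(input) + config$chip_background)
  })
}

#' Simulate a full depletion experiment
#'
#' Generates the genome with CGIs, one preference profile per configured
#' enzyme (symmetrized where configured), the CGI ChIP data, and one
#' cytosine report per condition x timepoint of \code{config$conditions}.
#'
#' @param config A \code{sim_config}.
#' @return List with genome, cgis, profiles, chip and methylomes (named
#'   \code{condition_timepoint}).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gen <- simulate_genome(config)
  profiles <- list()
  for (i in seq_along(config$enzyme_weights)) {
    e <- names(config$enzyme_weights)[i]
    profiles[[e]] <- simulate_preference_profile(
      config$seed + 100L + i, symmetric = e %in% config$symmetric_profiles,
      name = e)
  }
  chip <- simulate_chip(gen$cgis, config)
  methylomes <- list()
  for (cond in names(config$conditions)) {
    for (tp in names(config$conditions[[cond]])) {
      spec_tp <- config$conditions[[cond]][[tp]]
      id <- paste(cond, tp, sep = "_")
      methylomes[[id]] <- simulate_methylome(
        gen$genome, gen$cgis, profiles, config,
        depletion = spec_tp$depletion,
        histone_norm = if (isTRUE(spec_tp$coupled)) chip$histone_norm,
        sample_id = id)
    }
  }
  list(genome = gen$genome, cgis = gen$cgis, profiles = profiles,
       chip = chip, methylomes = methylomes)
}
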