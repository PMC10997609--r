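# Independent oracle: two-sided exact p by direct lchoose enumeration.
oracle_fisher_p <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; m <- a + c_; tot <- r1 + r2
  support <- max(0, m - r2):min(r1, m)
  logp <- lchoose(r1, support) + lchoose(r2, m - support) - lchoose(tot, m)
  p <- exp(logp)
  sum(p[p <= p[support == a] * (1 + 1e-7)])
}

test_that("genome tiling covers every position exactly once", {
  tiles <- tile_genome(c(c1 = 2500L), width = 1000)
  expect_equal(tiles$start, c(0L, 1000L, 2000L))
  expect_equal(tiles$end, c(1000L, 2000L, 2500L))

  one <- tile_genome(c(c1 = 1000L), width = 1000)
  expect_equal(nrow(one), 1L)

  withr::with_seed(4, {
    for (i in 1:5) {
      len <- sample(500:5000, 2)
      names(len) <- c("a", "b")
      w <- sample(c(250, 999, 1000), 1)
      tiles <- tile_genome(len, width = w)
      for (nm in names(len)) {
        tt <- tiles[tiles$chrom == nm, ]
        cover <- integer(len[[nm]])
        for (j in seq_len(nrow(tt)))
          cover[(tt$start[j] + 1):tt$end[j]] <- cover[(tt$start[j] + 1):tt$end[j]] + 1L
        expect_true(all(cover == 1L))
      }
    }
  })
})

test_that("tile aggregation pools counts and applies the min-CpG rule", {
  tiles <- tile_genome(c(c1 = 1000L), width = 1000)
  a <- toy_methylome(c("c1", "c1"), c(10, 20), c("+", "+"), c(8, 10), c(2, 0))
  b <- toy_methylome("c1", 30, "+", 1, 9)
  tm <- aggregate_tile_counts(a, b, tiles, min_cpg = 1)
  expect_equal(tm$meth_a, 18); expect_equal(tm$unmeth_a, 2)
  expect_equal(tm$meth_b, 1);  expect_equal(tm$unmeth_b, 9)
  expect_equal(tm$diff, 10 - 90)

  # fewer covered CpGs than min_cpg in one condition -> tile dropped
  tm3 <- aggregate_tile_counts(a, b, tiles, min_cpg = 3)
  expect_equal(nrow(tm3), 0L)

  # 1-based report position maps to the 0-based tile containing pos-1
  tiles2 <- tile_genome(c(c1 = 2000L), width = 1000)
  edge_a <- toy_methylome("c1", 1000, "+", 5, 5)   # 0-based 999 -> tile 1
  edge_b <- toy_methylome("c1", 1000, "-", 5, 5)
  tm_e <- aggregate_tile_counts(edge_a, edge_b, tiles2, min_cpg = 1)
  expect_equal(tm_e$start, 0L)
})

test_that("replicate pooling is order-invariant", {
  withr::with_seed(8, {
    reps <- lapply(1:3, function(i)
      toy_methylome("c1", sample(1:500, 40), "+",
                    stats::rbinom(40, 20, 0.7), stats::rbinom(40, 20, 0.3),
                    sample_id = paste0("r", i)))
    b <- toy_methylome("c1", 1:40 * 10, "+", 10, 10)
    tiles <- tile_genome(c(c1 = 500L), width = 250)
    t1 <- aggregate_tile_counts(reps, b, tiles)
    t2 <- aggregate_tile_counts(rev(reps), b, tiles)
    expect_equal(t1, t2)
  })
})

test_that("exact test matches enumeration and fisher.test", {
  expect_equal(fisher_exact_p(10, 0, 0, 10), oracle_fisher_p(10, 0, 0, 10))
  expect_equal(fisher_exact_p(5, 5, 5, 5), 1.0)
  # symmetry under swapping conditions
  expect_equal(fisher_exact_p(8, 2, 3, 7), fisher_exact_p(3, 7, 8, 2))

  withr::with_seed(21, {
    for (i in 1:200) {
      tab <- stats::rpois(4, 8) + c(1, 0, 1, 0)
      p_pkg <- fisher_exact_p(tab[1], tab[2], tab[3], tab[4])
      expect_equal(p_pkg, oracle_fisher_p(tab[1], tab[2], tab[3], tab[4]),
                   tolerance = 1e-12)
      p_ref <- stats::fisher.test(matrix(tab, 2, byrow = TRUE))$p.value
      expect_equal(p_pkg, p_ref, tolerance = 1e-7)
    }
  })
  expect_error(fisher_exact_p(0, 0, 5, 5), class = "methcontext_data_error")
})

test_that("DMR classification enforces both thresholds", {
  base <- data.frame(chrom = "c1", start = 0L, end = 1000L, name = "t",
                     n_cpg_a = 5L, n_cpg_b = 5L)
  one <- cbind(base, meth_a = 90, unmeth_a = 10, meth_b = 50, unmeth_b = 50,
               diff = -40, p_value = 1e-6)
  suppressMessages(d <- call_dmrs(one))
  expect_equal(d$q_value, 1e-6)       # BH with m = 1 is the identity
  expect_equal(d$class, "hypo")

  # large difference but q above threshold stays ns
  two <- one
  two$p_value <- 0.02
  suppressMessages(d2 <- call_dmrs(two))
  expect_equal(d2$class, "ns")

  # hyper side
  three <- one
  three$diff <- 40
  suppressMessages(d3 <- call_dmrs(three))
  expect_equal(d3$class, "hyper")
})

test_that("planted hypo tiles are called and only they", {
  # 10 tiles; 3 planted with a -40 point drop at deep coverage, 7 null
  tiles <- tile_genome(c(c1 = 10000L), width = 1000)
  mk <- function(pct, tile_idx) {
    pos <- (tile_idx - 1) * 1000 + seq(1, 900, by = 100)
    list(pos = pos, n_meth = round(200 * pct), n_unmeth = 200 - round(200 * pct))
  }
  rows_a <- rows_b <- NULL
  for (k in 1:10) {
    pa <- 0.8
    pb <- if (k <= 3) 0.4 else 0.8
    a <- mk(pa, k); b <- mk(pb, k)
    rows_a <- rbind(rows_a, data.frame(chrom = "c1", pos = a$pos, strand = "+",
                                       n_meth = a$n_meth, n_unmeth = a$n_unmeth))
    rows_b <- rbind(rows_b, data.frame(chrom = "c1", pos = b$pos, strand = "+",
                                       n_meth = b$n_meth, n_unmeth = b$n_unmeth))
  }
  ma <- methylome_table(rows_a, "a"); mb <- methylome_table(rows_b, "b")
  tm <- aggregate_tile_counts(ma, mb, tiles)
  suppressMessages(d <- call_dmrs(tm))
  expect_equal(sum(d$class == "hypo"), 3L)
  expect_equal(sum(d$class == "hyper"), 0L)
  expect_equal(attr(d, "summary")[["n_hypo"]], 3L)
})

test_that("BH q-values are monotone and order-invariant", {
  withr::with_seed(33, {
    tm <- data.frame(chrom = "c1", start = (0:49) * 1000, end = (1:50) * 1000,
                     name = paste0("t", 1:50), n_cpg_a = 5L, n_cpg_b = 5L,
                     meth_a = 50, unmeth_a = 50, meth_b = 50, unmeth_b = 50,
                     diff = 0, p_value = stats::runif(50))
    suppressMessages(d <- call_dmrs(tm))
    o <- order(d$p_value)
    expect_true(all(diff(d$q_value[o]) >= -1e-15))
    expect_true(all(d$q_value >= d$p_value))
    perm <- tm[sample(50), ]
    suppressMessages(dp <- call_dmrs(perm))
    expect_equal(dp[order(dp$name), "q_value"], d[order(d$name), "q_value"])
  })
})

test_that("diff and classes are antisymmetric under condition swap", {
  tiles <- tile_genome(c(c1 = 3000L), width = 1000)
  a <- toy_methylome("c1", seq(1, 2900, 50), "+", 18, 2)
  b <- toy_methylome("c1", seq(1, 2900, 50), "+", 2, 18)
  tab <- aggregate_tile_counts(a, b, tiles)
  rev_tab <- aggregate_tile_counts(b, a, tiles)
  expect_equal(tab$diff, -rev_tab$diff)
  suppressMessages({
    d1 <- call_dmrs(tab)
    d2 <- call_dmrs(rev_tab)
  })
  expect_equal(d1$p_value, d2$p_value)
  expect_equal(d1$class == "hypo", d2$class == "hyper")
})

test_that("null comparisons stay within the FDR bound", {
  # identical generative conditions, independent reads, 500 tiles
  cfg <- sim_config(seed = 91, genome_length = 5e5, n_contigs = 1L,
                    cgi_count = 0L, coverage_mean = 20)
  gen <- simulate_genome(cfg)
  profs <- lapply(stats::setNames(seq_along(cfg$enzyme_weights),
                                  names(cfg$enzyme_weights)),
                  function(i) simulate_preference_profile(cfg$seed + 100L + i,
                                                          name = paste0("e", i)))
  ma <- simulate_methylome(gen$genome, gen$cgis, profs, cfg, sample_id = "nullA")
  mb <- simulate_methylome(gen$genome, gen$cgis, profs, cfg, sample_id = "nullB")
  tiles <- tile_genome(gen$genome)
  tm <- aggregate_tile_counts(ma, mb, tiles)
  expect_gte(nrow(tm), 450)
  suppressMessages(d <- call_dmrs(tm))
  frac <- mean(d$class != "ns")
  expect_lte(frac, 0.02)
})

test_that("overlap counts partition the union of DMR sets", {
  out <- overlap_dmr_sets(list(A = c("t1", "t2"), B = c("t2", "t3")))
  get <- function(comb) out$count[out$combination == comb]
  expect_equal(get("A"), 1L)
  expect_equal(get("B"), 1L)
  expect_equal(get("A&B"), 1L)

  same <- overlap_dmr_sets(list(A = c("t1", "t2"), B = c("t1", "t2")))
  expect_equal(same$count[same$combination == "A&B"], 2L)
  expect_equal(sum(same$count), 2L)

  withr::with_seed(55, {
    for (i in 1:10) {
      sets <- lapply(1:3, function(j) sample(paste0("t", 1:30), sample(5:20, 1)))
      names(sets) <- c("X", "Y", "Z")
      res <- overlap_dmr_sets(sets)
      expect_equal(sum(res$count), length(unique(unlist(sets))))
      expect_equal(nrow(res), 7L)  # 2^3 - 1 combinations
    }
  })
})

test_that("tiles are annotated promoter > gene body > intergenic", {
  genes <- interval_set(data.frame(chrom = "c1", start = c(5000L, 20000L),
                                   end = c(9000L, 26000L), name = c("g1", "g2"),
                                   strand = c("+", "-")))
  tiles <- interval_set(data.frame(
    chrom = "c1",
    start = c(4500L, 7000L, 14000L, 25500L),
    end = c(5500L, 8000L, 15000L, 26500L),
    name = paste0("t", 1:4)))
  ann <- annotate_tiles(tiles, genes, promoter_flank = 1000)
  # t1 spans the TSS of g1 (plus strand, TSS at 5000)
  # t2 is inside g1 without touching the promoter window [4000, 6001)
  # t3 touches nothing; t4 spans the TSS of g2 (minus strand, TSS at 25999)
  expect_equal(ann$feature, c("promoter", "gene_body", "intergenic", "promoter"))
  counts <- attr(ann, "feature_counts")
  expect_equal(sum(counts), nrow(tiles))

  expect_error(annotate_tiles(tiles, interval_set(data.frame(
    chrom = "c1", start = 1L, end = 10L))), class = "methcontext_data_error")
})
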