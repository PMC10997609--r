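test_that("read counting uses >=1 bp half-open overlap", {
  targets <- interval_set(data.frame(chrom = "c1", start = 50L, end = 150L,
                                     name = "cgi"))
  reads <- interval_set(data.frame(chrom = "c1",
                                   start = c(10L, 150L, 149L, 0L),
                                   end = c(60L, 200L, 151L, 50L),
                                   name = paste0("r", 1:4)))
  counts <- interval_read_count(reads, targets)
  # r1 overlaps, r2 starts exactly at the target end (no overlap, half-open),
  # r3 overlaps the last base, r4 ends exactly at the target start
  expect_equal(unname(counts), 2L)
})

test_that("read counts match a brute-force all-pairs scan", {
  withr::with_seed(14, {
    reads <- interval_set(data.frame(
      chrom = sample(c("c1", "c2"), 500, TRUE),
      start = s <- sample(0:9000, 500, TRUE),
      end = s + sample(30:300, 500, TRUE),
      name = paste0("r", 1:500)))
    targets <- interval_set(data.frame(
      chrom = sample(c("c1", "c2"), 100, TRUE),
      start = t <- sample(0:9000, 100, TRUE),
      end = t + sample(200:1500, 100, TRUE),
      name = paste0("g", 1:100)))
    got <- interval_read_count(reads, targets)
    brute <- vapply(seq_len(nrow(targets)), function(i) {
      sum(reads$chrom == targets$chrom[i] &
            reads$start < targets$end[i] & reads$end > targets$start[i])
    }, integer(1))
    expect_equal(unname(got), brute)
  })
})

test_that("CGI normalization follows the counts-per-10M + 0.5 offset formula", {
  cgis <- interval_set(data.frame(chrom = "c1", start = (0:3) * 2000,
                                  end = (0:3) * 2000 + 1000,
                                  name = paste0("cgi", 1:4)))
  scores <- normalize_cgi_signal(cgis, chip_counts = c(5L, 3L, 10L, 0L),
                                 input_counts = c(10L, 10L, 0L, 0L),
                                 chip_total = 5e7, input_total = 1e7,
                                 min_reads = 4)
  # cgi2 has 3 < 4 chip reads -> excluded; cgi4 zero everywhere -> excluded
  expect_equal(scores$name, c("cgi1", "cgi3"))
  # scaled chip for cgi1: (5 + 0.5) * 1e7 / 5e7 = 1.1
  expect_equal(scores$norm_score[1], 1.1 / ((10 + 0.5) * 1e7 / 1e7))
  # zero input reads still give a finite positive score
  expect_true(is.finite(scores$norm_score[2]) && scores$norm_score[2] > 0)

  expect_error(normalize_cgi_signal(cgis, 1:4, 1:4, 0, 1),
               class = "methcontext_config_error")
})

test_that("normalization is monotone in chip count for fixed input", {
  cgis <- interval_set(data.frame(chrom = "c1", start = (0:9) * 100,
                                  end = (0:9) * 100 + 50,
                                  name = paste0("g", 1:10)))
  sc <- normalize_cgi_signal(cgis, chip_counts = 4:13,
                             input_counts = rep(5L, 10),
                             chip_total = 1e7, input_total = 1e7)
  expect_true(all(diff(sc$norm_score) > 0))
})

test_that("CGI methylation deltas difference pooled percentages", {
  cgis <- interval_set(data.frame(chrom = "c1", start = c(0L, 100L),
                                  end = c(50L, 200L), name = c("x", "y")))
  d0 <- toy_methylome(c("c1", "c1"), c(10, 20), c("+", "-"), c(9, 9), c(1, 1))
  d4 <- toy_methylome(c("c1", "c1"), c(10, 20), c("+", "-"), c(4, 4), c(6, 6))
  delta <- cgi_methylation_delta(d0, d4, cgis)
  expect_equal(unname(delta["x"]), 40 - 90)
  expect_true(is.na(delta["y"]))  # no covered site in y at either timepoint
  # antisymmetry
  expect_equal(unname(cgi_methylation_delta(d4, d0, cgis)["x"]), 50)
})

test_that("decile bins are equally sized with remainder to low bins", {
  b20 <- decile_bins(stats::rnorm(20))
  expect_equal(as.integer(table(b20)), rep(2L, 10))

  withr::with_seed(2, {
    x <- stats::rnorm(23)
    b23 <- decile_bins(x)
    expect_equal(as.integer(table(b23)), c(3L, 3L, 3L, rep(2L, 7)))
    # sortedness: every value in bin k <= every value in bin k+1
    for (k in 1:9)
      expect_lte(max(x[b23 == k]), min(x[b23 == k + 1]))
  })
  expect_error(decile_bins(1:5), class = "methcontext_data_error")
})

test_that("bin assignment is deterministic under ties and permutation", {
  scores <- rep(c(1, 2), each = 10)
  tie <- data.frame(chrom = rep("c1", 20), start = c(10 * (10:1), 10 * (20:11)))
  b <- decile_bins(scores, tie_break = tie)
  # within the tied low block, lower coordinates get lower bins
  low <- order(tie$start[1:10])
  expect_equal(b[1:10][low], rep(1:5, each = 2))

  perm <- sample(20)
  b2 <- decile_bins(scores[perm], tie_break = tie[perm, ])
  expect_equal(b2, b[perm])
})

test_that("bin summaries reproduce order-statistic quartiles and whiskers", {
  s <- bin_summary(c(-1, -2, -3), rep(1L, 3))
  expect_equal(s$median, -2)

  s2 <- bin_summary(rep(7, 5), rep(1L, 5))
  expect_equal(s2$q25, 7)
  expect_equal(s2$whisker_lo, 7)
  expect_equal(s2$whisker_hi, 7)

  withr::with_seed(6, {
    x <- stats::rnorm(1000)
    bins <- rep(1:4, each = 250)
    s3 <- bin_summary(x, bins)
    for (k in 1:4) {
      xs <- sort(x[bins == k])
      # type-7 quartile by direct interpolation on order statistics
      hq <- function(p) {
        h <- (length(xs) - 1) * p + 1
        xs[floor(h)] + (h - floor(h)) * (xs[floor(h) + 1] - xs[floor(h)])
      }
      expect_equal(s3$q25[k], hq(0.25), tolerance = 1e-12)
      expect_equal(s3$q75[k], hq(0.75), tolerance = 1e-12)
      iqr <- s3$q75[k] - s3$q25[k]
      expect_equal(s3$whisker_lo[k], max(min(xs), s3$q25[k] - 1.5 * iqr))
      expect_equal(s3$whisker_hi[k], min(max(xs), s3$q75[k] + 1.5 * iqr))
    }
  })
})

test_that("Spearman trend test matches theory on simple cases", {
  x <- 1:20
  y <- -x + 0
  res <- spearman_trend_test(x, y)
  expect_equal(res$rho, -1)
  expect_lt(res$p_value, 1e-6)

  withr::with_seed(17, {
    res_null <- spearman_trend_test(stats::rnorm(1000), stats::rnorm(1000))
    expect_lt(abs(res_null$rho), 0.1)
  })

  expect_error(spearman_trend_test(rep(1, 20), stats::rnorm(20)),
               class = "methcontext_data_error")
})

test_that("trend-test rho agrees with cor.test and with pearson_ranks", {
  withr::with_seed(19, {
    x <- round(stats::rnorm(256), 1)
    y <- round(stats::rnorm(256), 1)
    res <- spearman_trend_test(x, y)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    expect_equal(res$rho, unname(ref$estimate), tolerance = 1e-12)

    px <- hexamer_profile(stats::setNames(x, all_hexamers()), "x")
    py <- hexamer_profile(stats::setNames(y, all_hexamers()), "y")
    expect_equal(res$rho,
                 preference_correlation(px, py, method = "pearson_ranks")$r)
  })
})

test_that("permutation p agrees with the t approximation at moderate effect", {
  withr::with_seed(23, {
    x <- stats::rnorm(25)
    y <- 0.6 * x + stats::rnorm(25)
    t_res <- spearman_trend_test(x, y, method = "t_approx")
    p_res <- spearman_trend_test(x, y, method = "permutation",
                                 n_perm = 4000, seed = 5)
    expect_equal(p_res$rho, t_res$rho)
    expect_lt(abs(p_res$p_value - t_res$p_value), 0.05)
    # determinism under the seed
    p_res2 <- spearman_trend_test(x, y, method = "permutation",
                                  n_perm = 4000, seed = 5)
    expect_equal(p_res, p_res2)
  })
})

test_that("planted histone coupling is recovered and absent under the null", {
  run_one <- function(seed, beta) {
    cfg <- sim_config(seed = seed, genome_length = 6e5, n_contigs = 1L,
                      cgi_count = 150L, cgi_length = 800L,
                      enzyme_weights = c(e = 0), symmetric_profiles = character(0),
                      site_noise_sd = 0, coverage_mean = 20,
                      histone_coupling = beta,
                      conditions = list(
                        U = list(day0 = list(depletion = NULL, coupled = FALSE),
                                 day4 = list(depletion = NULL, coupled = TRUE)),
                        D = list(day0 = list(depletion = NULL, coupled = FALSE),
                                 day4 = list(depletion = NULL, coupled = FALSE))))
    ex <- simulate_experiment(cfg)
    scores <- normalize_cgi_signal(ex$cgis, ex$chip$chip_counts,
                                   ex$chip$input_counts,
                                   ex$chip$chip_total, ex$chip$input_total)
    du <- cgi_methylation_delta(ex$methylomes$U_day0, ex$methylomes$U_day4, ex$cgis)
    dd <- cgi_methylation_delta(ex$methylomes$D_day0, ex$methylomes$D_day4, ex$cgis)
    tab <- cgi_score_table(scores, du, dd)
    ok <- !is.na(tab$dd)
    spearman_trend_test(tab$norm_score[ok], tab$dd[ok])
  }
  coupled <- run_one(101, beta = 0.4)
  expect_lte(coupled$rho, -0.5)
  expect_lt(coupled$p_value, 0.01)

  null_res <- run_one(101, beta = 0)
  expect_lt(abs(null_res$rho), 0.15)
})
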