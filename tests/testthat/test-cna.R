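test_that("LOWESS normalization defaults and degenerate inputs", {
  expect_equal(formals(lowess_normalize)$window_fraction, 0.30)
  expect_equal(formals(lowess_normalize)$iterations, 4)
  # flat profile: nothing to remove
  x <- rep(0.4, 50)
  out <- lowess_normalize(x)
  expect_equal(out, x - median(x), tolerance = 1e-9)
  # constant covariate: identity with warning
  expect_warning(out2 <- lowess_normalize(rnorm(20), covariate = rep(1, 20)),
                 "constant covariate")
  expect_equal(length(out2), 20)
  expect_error(lowess_normalize(rnorm(5)), "at least 10")
})

test_that("LOWESS removes a planted sinusoidal bias", {
  set.seed(7)
  n <- 500
  bias <- 0.3 * sin(2 * pi * seq_len(n) / n)
  vals <- bias + rnorm(n, 0, 0.05)
  out <- lowess_normalize(vals, covariate = seq_len(n))
  resid_bias <- (vals - out) - bias      # fit minus true bias
  resid_bias <- resid_bias - mean(resid_bias)
  expect_lt(sqrt(mean(resid_bias^2)), 0.03)
})

test_that("CBS returns one segment on flat profiles", {
  set.seed(1)
  for (r in 1:3) {
    s <- cbs_segment(rnorm(120, 0, 0.01), alpha = 0.05, n_perm = 200)
    expect_equal(nrow(s), 1)
    expect_equal(s$n_probes, 120)
  }
  # degenerate: fewer probes than 2*min_width
  s1 <- cbs_segment(c(0, 5, 0), min_width = 2)
  expect_equal(nrow(s1), 1)
})

test_that("CBS localizes a single step and matches the exhaustive
           single-change-point maximizer", {
  one_cp_oracle <- function(x) {
    n <- length(x)
    stat <- vapply(1:(n - 1), function(t)
      abs(mean(x[1:t]) - mean(x[(t + 1):n])) / sqrt(1 / t + 1 / (n - t)),
      numeric(1))
    which.max(stat)
  }
  set.seed(12)
  hits <- 0
  for (r in 1:20) {
    x <- c(rnorm(50, 0, 0.1), rnorm(50, 1.0, 0.1))
    s <- cbs_segment(x, alpha = 0.05, n_perm = 200)
    bps <- s$end_probe[-nrow(s)]
    expect_true(any(abs(bps - 50) <= 2))
    expect_true(any(abs(bps - one_cp_oracle(x)) <= 2))
    if (length(bps) == 1 && bps == one_cp_oracle(x)) hits <- hits + 1
  }
  expect_gte(hits, 15)  # usually identical to the oracle split
})

test_that("CBS recovers three planted segment means", {
  set.seed(3)
  x <- c(rnorm(100, 0, 0.1), rnorm(100, 0.8, 0.1), rnorm(100, -0.8, 0.1))
  s <- cbs_segment(x, alpha = 0.05, n_perm = 500, seed = 4)
  # the three major segments carry the planted means
  big <- s[s$n_probes >= 20, ]
  expect_equal(nrow(big), 3)
  expect_equal(big$seg_mean, c(0, 0.8, -0.8), tolerance = 0.1)
  # partition invariant
  expect_equal(sum(s$n_probes), 300)
  expect_equal(s$start_probe[-1], s$end_probe[-nrow(s)] + 1)
})

test_that("segmentation partitions every profile", {
  coh <- generate_cohort(sim_config(n_samples = 4, n_probes_per_chrom = 60,
                                    planted_aberrations = data.frame(
                                      chrom = "chr2", start = 2e7, end = 4e7,
                                      shift = 1, carrier_frac = 0.5),
                                    seed = 17))
  segs <- segment_profiles(coh$probes, alpha = 0.05, n_perm = 100, seed = 2)
  per <- tapply(segs$n_probes, list(segs$sample_id, segs$chrom), sum)
  expect_true(all(per == 60))
})

test_that("noise model matches hand arithmetic", {
  expect_error(estimate_noise(numeric(0)), "empty")
  nm <- estimate_noise(rep(0.3, 5))
  expect_equal(nm$median, 0.3)
  expect_equal(nm$sd, 0)
  nm2 <- estimate_noise(c(-1, 0, 1))
  expect_equal(nm2$median, 0)
  expect_equal(nm2$sd, 1)   # sample SD convention
  expect_equal(nm2$k, 2)    # default multiplier
})

test_that("aberration calls follow the median +/- k*SD rule", {
  nm <- structure(list(median = 0, sd = 0.1, k = 2), class = "noise_model")
  seg <- rbind(seg_row("s1", "chr1", 0, 10, 0.25, "neutral"),
               seg_row("s1", "chr1", 10, 20, -0.25, "neutral"),
               seg_row("s1", "chr1", 20, 30, 0.15, "neutral"))
  called <- call_aberrations(seg, nm)
  expect_equal(called$call, c("gain", "loss", "neutral"))

  # monotone in seg_mean: raising a mean never demotes the call
  rank_call <- c(loss = 1, neutral = 2, gain = 3)
  means <- seq(-0.5, 0.5, by = 0.01)
  calls <- call_aberrations(
    do.call(rbind, lapply(means, function(m)
      seg_row("s", "chr1", 0, 1, m, "neutral"))), nm)$call
  expect_true(all(diff(rank_call[calls]) >= 0))

  nm0 <- structure(list(median = 0, sd = 0, k = 2), class = "noise_model")
  expect_warning(z <- call_aberrations(seg, nm0), "zero cohort SD")
  expect_equal(z$call, c("gain", "loss", "gain"))
})

test_that("gene mapping uses majority base-pair overlap", {
  ann <- data.frame(gene_id = c("gA", "gB", "gC"),
                    chrom = c("chr1", "chr1", "chr9"),
                    start = c(100, 180, 0), end = c(150, 280, 50))
  seg <- rbind(
    seg_row("s1", "chr1", 0, 200, 0.8, "gain"),     # covers gA, 20% of gB
    seg_row("s1", "chr1", 200, 400, 0.0, "neutral")) # 80% of gB
  gc <- suppressMessages(map_genes_to_calls(seg, ann))
  expect_equal(gc$call["gA", "s1"], "gain")       # fully inside
  expect_equal(gc$call["gB", "s1"], "neutral")    # majority 80/20
  expect_true(is.na(gc$call["gC", "s1"]))         # chromosome absent
})

test_that("gene mapping matches the brute-force per-base tally", {
  set.seed(41)
  for (r in 1:30) {
    n_genes <- sample(3:8, 1)
    ann <- data.frame(gene_id = paste0("g", seq_len(n_genes)),
                      chrom = "chr1",
                      start = sort(sample(0:900, n_genes)))
    ann$end <- ann$start + sample(20:150, n_genes, replace = TRUE)
    segs <- list()
    for (s in c("s1", "s2")) {
      bounds <- sort(c(0, sample(50:950, sample(1:4, 1)), 1100))
      for (i in seq_len(length(bounds) - 1))
        segs[[length(segs) + 1]] <- seg_row(
          s, "chr1", bounds[i], bounds[i + 1],
          round(rnorm(1), 2),
          sample(c("gain", "loss", "neutral"), 1))
    }
    segs <- do.call(rbind, segs)
    got <- suppressMessages(map_genes_to_calls(segs, ann))
    expect_identical(got$call, bf_gene_map(segs, ann))
  }
})
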