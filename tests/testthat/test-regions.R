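test_that("minimal common regions honor the recurrence threshold", {
  # one carrier out of 10 qualifies at min_freq 0.10 (ceil(1) = 1)
  seg <- seg_row("s1", "chr1", 100, 200, 1, "gain")
  r <- minimal_common_regions(seg, 10, 0.10, "gain")
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end), c(100, 200))
  expect_equal(r$frequency, 0.1)

  # overlap of two carriers at min_freq 0.2 -> the intersection
  seg2 <- rbind(seg_row("s1", "chr1", 100, 200, 1, "gain"),
                seg_row("s2", "chr1", 150, 250, 1, "gain"))
  r2 <- minimal_common_regions(seg2, 10, 0.2, "gain")
  expect_equal(nrow(r2), 1)
  expect_equal(c(r2$start, r2$end), c(150, 200))
  expect_setequal(r2$carriers[[1]], c("s1", "s2"))

  # disjoint gains never reach 2 carriers
  seg3 <- rbind(seg_row("s1", "chr1", 100, 200, 1, "gain"),
                seg_row("s2", "chr1", 300, 400, 1, "gain"))
  expect_equal(nrow(minimal_common_regions(seg3, 10, 0.2, "gain")), 0)

  # no calls -> empty
  expect_equal(nrow(minimal_common_regions(
    seg_row("s1", "chr1", 0, 10, 0, "neutral"), 10, 0.1, "gain")), 0)
})

test_that("regions match the brute-force per-base counter", {
  set.seed(23)
  for (r in 1:40) {
    n_samp <- sample(4:10, 1)
    segs <- list()
    for (s in paste0("s", seq_len(n_samp))) {
      k <- sample(0:3, 1)
      if (k == 0) next
      starts <- sort(sample(seq(0, 180, by = 5), k))
      for (st in starts)
        segs[[length(segs) + 1]] <- seg_row(
          s, "chr1", st, st + sample(seq(5, 40, by = 5), 1), 1, "gain")
    }
    if (!length(segs)) next
    segs <- do.call(rbind, segs)
    # merge per-sample overlapping intervals to keep the counting premise
    # (one sample counts once): drop samples with self-overlapping segments
    ok <- vapply(split(segs, segs$sample_id), function(d) {
      d <- d[order(d$start), ]
      all(diff(as.vector(rbind(d$start, d$end))) >= 0)
    }, logical(1))
    segs <- segs[segs$sample_id %in% names(ok)[ok], , drop = FALSE]
    if (!nrow(segs)) next
    mf <- sample(c(0.1, 0.2, 0.3), 1)
    got <- minimal_common_regions(segs, n_samp, mf, "gain")
    want <- bf_regions(segs, n_samp, mf, "gain")
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      # every reported region is at threshold everywhere, and disjoint/sorted
      if (nrow(got) > 1)
        expect_true(all(got$start[-1] >= got$end[-nrow(got)]))
    }
  }
})

test_that("CNV filter applies the more-than-10 exclusion rule exactly", {
  ann <- data.frame(gene_id = c("g10", "g11"), chrom = "chr1",
                    start = c(1000, 5000), end = c(2000, 6000))
  mk_cat <- function(gene_start, n)
    data.frame(chrom = "chr1", start = gene_start + seq_len(n),
               end = gene_start + 500 + seq_len(n))
  cat10 <- rbind(mk_cat(1000, 10), mk_cat(5000, 11))
  kept <- cnv_filter(ann, cat10, max_cnv = 10)
  expect_true("g10" %in% kept)      # exactly 10: retained
  expect_false("g11" %in% kept)     # 11: excluded
  expect_equal(unname(attr(kept, "cnv_counts")), c(10, 11))

  # empty catalogue retains all
  expect_setequal(cnv_filter(ann, NULL), c("g10", "g11"))
})

test_that("CNV filter matches the quadratic oracle and is monotone", {
  set.seed(9)
  for (r in 1:30) {
    n_g <- sample(3:8, 1); n_c <- sample(0:40, 1)
    ann <- data.frame(gene_id = paste0("g", 1:n_g),
                      chrom = sample(c("chr1", "chr2"), n_g, TRUE),
                      start = sample(0:5000, n_g))
    ann$end <- ann$start + sample(50:800, n_g, TRUE)
    cat <- data.frame(chrom = sample(c("chr1", "chr2"), max(n_c, 1), TRUE),
                      start = sample(0:5000, max(n_c, 1), TRUE))
    cat$end <- cat$start + sample(10:2000, max(n_c, 1), TRUE)
    cat <- cat[seq_len(n_c), , drop = FALSE]
    kept <- cnv_filter(ann, cat, max_cnv = 3)
    counts <- attr(kept, "cnv_counts")
    expect_equal(unname(counts), bf_cnv_counts(ann, cat))
    # monotone: adding records never un-excludes a gene
    extra <- rbind(cat, data.frame(chrom = "chr1", start = 0, end = 6000))
    kept2 <- cnv_filter(ann, extra, max_cnv = 3)
    expect_true(all(kept2 %in% kept))
  }
})

test_that("recurrence filter counts aberrant samples per direction", {
  calls <- rbind(g1 = c("gain", "gain", "gain", "neutral"),
                 g2 = c("gain", "gain", "neutral", "neutral"),
                 g3 = c("loss", "loss", "loss", "loss"),
                 g4 = rep("neutral", 4))
  colnames(calls) <- paste0("s", 1:4)
  gc <- make_gene_cna(calls)
  expect_equal(recurrence_filter(gc, 3, "gain"), "g1")
  expect_equal(recurrence_filter(gc, 5, "gain"), character(0))
  expect_equal(recurrence_filter(gc, 4, "loss"), "g3")
  expect_false("g4" %in% recurrence_filter(gc, 1, "gain"))
})

test_that("subgroup frequency test is exact, symmetric and degenerate-safe", {
  # equal proportions -> p = 1
  carrier <- rep(c(TRUE, FALSE), c(4, 16))
  group <- rep(c("GCB", "nonGCB"), 10)
  t1 <- subgroup_frequency_test(carrier, group)
  expect_equal(t1$p, 1)

  # matches hypergeometric enumeration on fixed margins
  carrier2 <- c(rep(TRUE, 3), rep(FALSE, 7), rep(FALSE, 10))
  group2 <- rep(c("a", "b"), each = 10)
  t2 <- subgroup_frequency_test(carrier2, group2)
  expect_equal(t2$p, bf_fisher_p(t2$table), tolerance = 1e-10)

  # degenerate margins -> p = 1
  t3 <- subgroup_frequency_test(rep(FALSE, 20), rep(c("a", "b"), each = 10))
  expect_equal(t3$p, 1)

  # symmetry under label and outcome swaps
  set.seed(2)
  for (r in 1:20) {
    carr <- sample(c(TRUE, FALSE), 30, TRUE)
    grp <- sample(c("x", "y"), 30, TRUE)
    if (length(unique(grp)) < 2) next
    p1 <- subgroup_frequency_test(carr, grp)$p
    p2 <- subgroup_frequency_test(carr, factor(grp,
                                               levels = c("y", "x")))$p
    p3 <- subgroup_frequency_test(!carr, grp)$p
    expect_equal(p1, p2, tolerance = 1e-12)
    expect_equal(p1, p3, tolerance = 1e-12)
  }
  expect_error(subgroup_frequency_test(carrier, rep("a", 20)), "two levels")
})
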