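test_that("noise-free limit plants exact segment means", {
  cfg <- sim_config(n_samples = 10, n_probes_per_chrom = 50,
                    probe_noise_sd = 1e-12, bias_amplitude = 0,
                    planted_aberrations = data.frame(
                      chrom = "chr2", start = 2e7, end = 6e7,
                      shift = 1.0, carrier_frac = 0.5),
                    seed = 11)
  coh <- generate_cohort(cfg)
  carriers <- rownames(coh$truth$carrier_map)[coh$truth$carrier_map[, 1]]
  expect_length(carriers, 5)
  mid <- (coh$probes$start + coh$probes$end) / 2
  inside <- coh$probes$chrom == "chr2" & mid >= 2e7 & mid < 6e7
  for (s in carriers) {
    expect_equal(coh$probes[[s]][inside], rep(1, sum(inside)),
                 tolerance = 1e-6)
    expect_equal(coh$probes[[s]][!inside], rep(0, sum(!inside)),
                 tolerance = 1e-6)
  }
  non <- setdiff(rownames(coh$truth$carrier_map), carriers)
  expect_equal(max(abs(as.matrix(coh$probes[, non]))), 0, tolerance = 1e-6)
})

test_that("generation is deterministic given the seed", {
  cfg <- sim_config(n_samples = 12, n_probes_per_chrom = 30, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(sim_config(n_samples = 12, n_probes_per_chrom = 30,
                                   seed = 100))
  expect_false(identical(a$expression, c2$expression))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(probe_noise_sd = 0), "probe_noise_sd")
  expect_error(sim_config(planted_aberrations = data.frame(
    chrom = "chr2", start = 2e7, end = 2e9, shift = 1, carrier_frac = 0.2)),
    "chromosome bounds")
  expect_error(sim_config(planted_aberrations = data.frame(
    chrom = "chr2", start = 2e7, end = 3e7, shift = 1, carrier_frac = 1.5)),
    "carrier_frac")
  expect_error(sim_config(n_samples = 4, planted_aberrations = data.frame(
    chrom = "chr2", start = 2e7, end = 3e7, shift = 1,
    carrier_frac = 0.1)), "at least 1")
})

test_that("probe noise SD is reproduced in neutral regions", {
  cfg <- sim_config(n_samples = 2, n_probes_per_chrom = 5000,
                    bias_amplitude = 0, probe_noise_sd = 0.1,
                    planted_aberrations = NULL, n_cnv_records = 0,
                    seed = 5)
  coh <- generate_cohort(cfg)
  vals <- as.matrix(coh$probes[, c("S001", "S002")])
  expect_equal(sd(vals), 0.1, tolerance = 0.05)
})

test_that("driver expression shift is recovered within 3 SE at n = 100", {
  cfg <- sim_config(n_samples = 100, n_probes_per_chrom = 20,
                    expression_sd = 0.5, seed = 21)
  coh <- generate_cohort(cfg)
  g <- coh$truth$driver_ids[1]
  carr <- coh$truth$carrier_map[, 1]
  est <- mean(coh$expression[g, carr]) - mean(coh$expression[g, !carr])
  se <- sqrt(0.25 / sum(carr) + 0.25 / sum(!carr))
  expect_lt(abs(est - 1.0), 3 * se)
})

test_that("with no censoring the KM curve equals the empirical survival", {
  cfg <- sim_config(n_samples = 50, n_probes_per_chrom = 20,
                    censoring_rate = 0, followup_max = 1e7,
                    other_death_rate = 0.01, seed = 31)
  coh <- generate_cohort(cfg)
  ep <- derive_endpoints(coh$clinical)
  expect_true(all(ep$os_event == 1))
  km <- km_estimate(ep$os_time, ep$os_event)
  emp <- vapply(km$time, function(t) mean(ep$os_time > t), numeric(1))
  expect_equal(km$surv, emp, tolerance = 1e-12)
})

test_that("null hazard gives nominal log-rank size over replicates", {
  ## drivers decoupled from hazard: expression-dichotomized groups should
  ## reject at ~ the nominal 5% level
  n_rep <- 500
  rej <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_samples = 40, n_probes_per_chrom = 10,
                      chromosomes = c(chr1 = 1e8),
                      planted_aberrations = data.frame(
                        chrom = "chr1", start = 1e7, end = 5e7,
                        shift = 1, carrier_frac = 0.3),
                      driver_genes = data.frame(
                        gene_id = "chr1_g03", delta = 1, log_hr = 0),
                      n_cnv_records = 0, n_panel_genes = 0,
                      seed = 40000 + r)
    coh <- generate_cohort(cfg)
    ep <- derive_endpoints(coh$clinical)
    x <- coh$expression["chr1_g03", ]
    grp <- ifelse(x > median(x), "high", "low")
    rej[r] <- logrank_test(ep$pfs_time, ep$pfs_event, grp)$p < 0.05
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("clinical dates are internally consistent", {
  coh <- generate_cohort(sim_config(seed = 3))
  cl <- coh$clinical
  expect_true(all(is.na(cl$progression_date) |
                    cl$progression_date >= cl$registration_date))
  expect_true(all(is.na(cl$death_date) |
                    cl$death_date >= cl$registration_date))
  expect_true(all(cl$last_followup_date >= cl$registration_date))
  expect_true(all((cl$cause == "alive") == is.na(cl$death_date)))
})

test_that("IHC image composition is exact and truth is retained", {
  f <- generate_ihc_image(100, 100, c(0.25, 0.75, 0, 0), jitter_sd = 0,
                          seed = 1)
  expect_identical(unname(f$composition),
                   c(2500L, 7500L, 0L, 0L))
  expect_equal(f$true_coverage, 0.25)
  expect_equal(sum(f$class_map == "brown"), 2500)

  f0 <- generate_ihc_image(20, 20, c(0, 0, 0, 1), seed = 1)
  expect_equal(f0$true_coverage, 0)

  expect_error(generate_ihc_image(10, 10, c(0.5, 0.5, 0.1, 0)), "sum to 1")
  expect_warning(
    generate_ihc_image(10, 10, c(0.5, 0.5, 0, 0), jitter_sd = 60, seed = 1),
    "jitter")
})

test_that("cohort round-trips through plain-text files", {
  coh <- generate_cohort(sim_config(n_samples = 6, n_probes_per_chrom = 20,
                                    seed = 8))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  probes <- read_probe_matrix(file.path(dir, "probes.tsv"))
  expect_equal(probes$start, coh$probes$start)
  expect_equal(probes$S001, coh$probes$S001, tolerance = 1e-12)
  expr <- read_expression_matrix(file.path(dir, "expression.tsv"))
  expect_equal(expr, coh$expression, tolerance = 1e-12)
  bed <- read_bed(file.path(dir, "genes.bed"))
  expect_equal(bed$gene_id, coh$annotation$gene_id)
})
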