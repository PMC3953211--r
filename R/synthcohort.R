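#' Configuration for a synthetic lymphoma cohort
#'
#' Defines the generative model for a complete synthetic cohort: probe-level
#' aCGH log2-ratio profiles with planted aberrations, intensity-dependent bias
#' and Gaussian probe noise; gene-level expression coupled to copy-number
#' status for designated driver genes (and decoupled for passengers);
#' proportional-hazards survival with driver-dependent hazard and independent
#' censoring; a germline CNV catalogue; and molecular-subtype structure on a
#' dedicated expression panel.
#'
#' Defaults emulate a high-risk DLBCL cohort: 40 dual-platform samples, one
#' planted chromosome-2 gain carried by 20% of samples shifting probe log2
#' ratios by +1, a single driver gene inside the gain whose expression rises
#' by 1 log2 unit in carriers, and a per-expression-unit log hazard ratio of
#' log(3.2) on progression (hazard ratio ~3 between carriers and
#' non-carriers, the order of effect reported for copy-number-driven
#' prognostic genes in this disease). Baseline progression hazard 0.006 per
#' month yields roughly 70% five-year progression-free survival for an
#' average non-carrier.
#'
#' @param n_samples Number of samples.
#' @param chromosomes Named numeric vector of chromosome lengths in bp.
#' @param n_probes_per_chrom Probes per chromosome (evenly spaced).
#' @param probe_noise_sd Gaussian probe noise SD, log2-ratio units (> 0).
#' @param bias_amplitude Amplitude of the smooth intensity-dependent bias
#'   (sinusoid over global probe index), log2-ratio units.
#' @param bias_cycles Number of sinusoid cycles across the array.
#' @param planted_aberrations data.frame with columns `chrom`, `start`, `end`
#'   (bp, 0-based half-open), `shift` (log2 units) and `carrier_frac` in
#'   (0, 1].
#' @param n_genes_per_chrom Regular (non-panel) genes tiled per chromosome.
#' @param driver_genes Optional data.frame with columns `gene_id`, `delta`
#'   (log2 expression shift in carriers) and `log_hr` (log hazard ratio per
#'   expression unit). `NULL` picks, for each planted aberration, the gene
#'   with the largest overlap; the first gets `delta` 1.0 and `log_hr`
#'   log(3.2), the rest `delta` 1.0 and `log_hr` 0.
#' @param passenger_effect Expression shift for non-driver genes in carriers
#'   (kept at 0: passengers are decoupled from copy number).
#' @param expression_sd Gaussian expression noise SD, log2 units.
#' @param baseline_hazard Progression hazard per month at expression 0.
#' @param post_progression_rate Hazard per month of lymphoma death after
#'   progression.
#' @param other_death_rate Hazard per month of death from other causes.
#' @param censoring_rate Hazard per month of random loss to follow-up.
#' @param followup_max Administrative censoring time, months.
#' @param accrual_window Accrual window for registration dates, months.
#' @param contamination Multiplier in (0, 1] on planted segment means,
#'   modelling dilution of the tumour signal by normal cells (1 = pure
#'   tumour).
#' @param n_cnv_records Number of random germline CNV catalogue intervals.
#' @param cnv_max_len Maximum CNV interval length, bp.
#' @param subtype_shift Mean log-ratio separation between GCB and non-GCB
#'   samples on the subtype panel genes.
#' @param n_panel_genes Number of subtype-panel genes (44-gene panel scale).
#' @param seed Integer seed; a fixed seed makes every generated output
#'   byte-identical across calls.
#'
#' @return A list of class `sim_config`.
#' @seealso [generate_cohort()]
#' @export
sim_config <- function(n_samples = 40,
                       chromosomes = c(chr1 = 1e8, chr2 = 1e8, chr3 = 1e8),
                       n_probes_per_chrom = 200,
                       probe_noise_sd = 0.1,
                       bias_amplitude = 0.2,
                       bias_cycles = 2,
                       planted_aberrations = data.frame(
                         chrom = "chr2", start = 2e7, end = 3.5e7,
                         shift = 1.0, carrier_frac = 0.2),
                       n_genes_per_chrom = 20,
                       driver_genes = NULL,
                       passenger_effect = 0,
                       expression_sd = 0.5,
                       baseline_hazard = 0.006,
                       post_progression_rate = 0.05,
                       other_death_rate = 0.002,
                       censoring_rate = 0.002,
                       followup_max = 84,
                       accrual_window = 24,
                       contamination = 1,
                       n_cnv_records = 300,
                       cnv_max_len = 5e5,
                       subtype_shift = 2,
                       n_panel_genes = 44,
                       seed = 1L) {
  cfg <- list(n_samples = n_samples, chromosomes = chromosomes,
              n_probes_per_chrom = n_probes_per_chrom,
              probe_noise_sd = probe_noise_sd,
              bias_amplitude = bias_amplitude, bias_cycles = bias_cycles,
              planted_aberrations = planted_aberrations,
              n_genes_per_chrom = n_genes_per_chrom,
              driver_genes = driver_genes,
              passenger_effect = passenger_effect,
              expression_sd = expression_sd,
              baseline_hazard = baseline_hazard,
              post_progression_rate = post_progression_rate,
              other_death_rate = other_death_rate,
              censoring_rate = censoring_rate,
              followup_max = followup_max,
              accrual_window = accrual_window,
              contamination = contamination,
              n_cnv_records = n_cnv_records, cnv_max_len = cnv_max_len,
              subtype_shift = subtype_shift, n_panel_genes = n_panel_genes,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$n_samples)) stop("n_samples must be a positive integer")
  if (is.null(names(cfg$chromosomes)) || any(cfg$chromosomes <= 0))
    stop("chromosomes must be a named vector of positive lengths")
  if (!is.numeric(cfg$probe_noise_sd) || cfg$probe_noise_sd <= 0)
    stop("probe_noise_sd must be > 0")
  ab <- cfg$planted_aberrations
  if (!is.null(ab) && nrow(ab)) {
    stopifnot_cols(ab, c("chrom", "start", "end", "shift", "carrier_frac"),
                   "planted_aberrations")
    if (any(!ab$chrom %in% names(cfg$chromosomes)))
      stop("aberration on unknown chromosome")
    len <- cfg$chromosomes[ab$chrom]
    if (any(ab$start < 0) || any(ab$end > len) || any(ab$start >= ab$end))
      stop("aberration interval outside chromosome bounds")
    if (any(ab$carrier_frac <= 0) || any(ab$carrier_frac > 1))
      stop("carrier_frac must be in (0, 1]")
    if (any(ab$carrier_frac * cfg$n_samples < 1))
      stop("carrier_frac times n_samples must be at least 1")
  }
  if (cfg$contamination <= 0 || cfg$contamination > 1)
    stop("contamination must be in (0, 1]")
  invisible(cfg)
}

# Deterministic gene bodies: n_genes_per_chrom genes of 200 kb tiled per
# chromosome, plus subtype-panel genes offset on the last chromosome.
# Coordinates are 0-based half-open.
build_annotation <- function(cfg) {
  chroms <- names(cfg$chromosomes)
  per <- lapply(chroms, function(ch) {
    L <- cfg$chromosomes[[ch]]
    k <- cfg$n_genes_per_chrom
    centre <- (seq_len(k) - 0.5) / k * L
    data.frame(gene_id = sprintf("%s_g%02d", ch, seq_len(k)),
               chrom = ch,
               start = pmax(0, round(centre - 1e5)),
               end = pmin(L, round(centre + 1e5)),
               panel = FALSE, stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, per)
  if (cfg$n_panel_genes > 0) {
    ch <- chroms[length(chroms)]
    L <- cfg$chromosomes[[ch]]
    k <- cfg$n_panel_genes
    centre <- (seq_len(k) - 0.25) / k * L
    pan <- data.frame(gene_id = sprintf("PANEL%02d", seq_len(k)),
                      chrom = ch,
                      start = pmax(0, round(centre - 2e4)),
                      end = pmin(L, round(centre + 2e4)),
                      panel = TRUE, stringsAsFactors = FALSE)
    ann <- rbind(ann, pan)
  }
  rownames(ann) <- ann$gene_id
  ann
}

# Resolve driver genes: user-specified or auto-picked per aberration
resolve_drivers <- function(cfg, ann) {
  ab <- cfg$planted_aberrations
  if (is.null(ab) || !nrow(ab)) return(
    data.frame(gene_id = character(), delta = numeric(),
               log_hr = numeric(), aberration = integer()))
  overlap_bp <- function(gs, ge, as_, ae) pmax(0, pmin(ge, ae) - pmax(gs, as_))
  if (is.null(cfg$driver_genes)) {
    rows <- lapply(seq_len(nrow(ab)), function(k) {
      cand <- ann[!ann$panel & ann$chrom == ab$chrom[k], ]
      ov <- overlap_bp(cand$start, cand$end, ab$start[k], ab$end[k])
      if (!any(ov > 0)) stop("no gene overlaps planted aberration ", k)
      data.frame(gene_id = cand$gene_id[which.max(ov)],
                 delta = 1.0,
                 log_hr = if (k == 1) log(3.2) else 0,
                 aberration = k, stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  dg <- cfg$driver_genes
  stopifnot_cols(dg, c("gene_id", "delta", "log_hr"), "driver_genes")
  dg$aberration <- vapply(dg$gene_id, function(g) {
    if (!g %in% ann$gene_id) stop("unknown driver gene: ", g)
    gi <- ann[g, ]
    ov <- ifelse(ab$chrom == gi$chrom,
                 overlap_bp(gi$start, gi$end, ab$start, ab$end), 0)
    if (!any(ov > 0)) stop("driver gene ", g,
                           " overlaps no planted aberration")
    which.max(ov)
  }, integer(1))
  dg
}

#' Generate a complete synthetic cohort with known ground truth
#'
#' Produces, from one seed, every input the screening pipeline consumes:
#' probe-level copy-number log2 ratios, a gene expression matrix, a clinical
#' table with registration/progression/death dates, a germline CNV catalogue,
#' gene annotation, and a `truth` record (planted breakpoints, carrier map,
#' driver genes, subtype labels, bias vector) against which every downstream
#' stage can be scored.
#'
#' Probe values are segment mean (0 for non-carriers) times the
#' `contamination` multiplier, plus a smooth sinusoidal intensity bias over
#' probe index, plus Gaussian noise. Driver-gene expression in carriers is
#' shifted by `delta`; passenger expression is independent of copy number.
#' Progression times are exponential with log hazard
#' `log(baseline_hazard) + sum(log_hr_g * expression_g)` over driver genes;
#' lymphoma death follows progression with its own exponential hazard;
#' other-cause death and loss to follow-up are independent exponentials, with
#' administrative censoring at `followup_max` months.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `synthetic_cohort` with elements `probes`
#'   (data.frame: probe_id, chrom, start, end, one column per sample),
#'   `expression` (genes x samples matrix), `clinical` (data.frame),
#'   `cnv_catalogue` (data.frame: chrom, start, end), `annotation`
#'   (data.frame), `truth` (list) and `config`.
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  ann <- build_annotation(cfg)
  drivers <- resolve_drivers(cfg, ann)
  ab <- cfg$planted_aberrations
  n_ab <- if (is.null(ab)) 0L else nrow(ab)

  ## carrier map: exactly round(frac * n) carriers per aberration (>= 1)
  carrier_map <- matrix(FALSE, n, n_ab,
                        dimnames = list(samples,
                                        if (n_ab) paste0("ab", seq_len(n_ab))))
  for (k in seq_len(n_ab)) {
    n_c <- max(1L, round(ab$carrier_frac[k] * n))
    carrier_map[sample.int(n, n_c), k] <- TRUE
  }

  ## probes: evenly spaced 60 bp probes per chromosome
  chroms <- names(cfg$chromosomes)
  np <- cfg$n_probes_per_chrom
  probe_list <- lapply(chroms, function(ch) {
    L <- cfg$chromosomes[[ch]]
    w <- floor(L / np)
    start <- as.numeric(0:(np - 1)) * w
    data.frame(probe_id = sprintf("%s_p%04d", ch, seq_len(np)),
               chrom = ch, start = start, end = start + 60,
               stringsAsFactors = FALSE)
  })
  probes <- do.call(rbind, probe_list)
  rownames(probes) <- NULL
  n_probes <- nrow(probes)
  mid <- (probes$start + probes$end) / 2
  idx <- seq_len(n_probes)
  bias <- cfg$bias_amplitude *
    sin(2 * pi * cfg$bias_cycles * idx / n_probes)

  ## per-sample planted means
  base <- matrix(0, n_probes, n)
  for (k in seq_len(n_ab)) {
    in_ab <- probes$chrom == ab$chrom[k] & mid >= ab$start[k] &
      mid < ab$end[k]
    if (any(in_ab))
      base[in_ab, carrier_map[, k]] <- base[in_ab, carrier_map[, k]] +
        ab$shift[k] * cfg$contamination
  }
  log2r <- base + bias + matrix(rnorm(n_probes * n, 0, cfg$probe_noise_sd),
                                n_probes, n)
  colnames(log2r) <- samples
  probes <- cbind(probes, as.data.frame(log2r))

  ## expression: baseline 0 log-ratio + driver/panel structure + noise
  genes <- ann$gene_id
  expr <- matrix(rnorm(length(genes) * n, 0, cfg$expression_sd),
                 length(genes), n, dimnames = list(genes, samples))
  for (r in seq_len(nrow(drivers))) {
    carr <- carrier_map[, drivers$aberration[r]]
    expr[drivers$gene_id[r], carr] <- expr[drivers$gene_id[r], carr] +
      drivers$delta[r]
  }
  subtype <- sample(c("GCB", "nonGCB"), n, replace = TRUE)
  panel_sig <- NULL
  if (cfg$n_panel_genes > 0) {
    pan <- ann$gene_id[ann$panel]
    dirs <- rep(c(1, -1), length.out = length(pan))
    names(dirs) <- pan
    shift <- cfg$subtype_shift / 2 * ifelse(subtype == "GCB", 1, -1)
    expr[pan, ] <- expr[pan, ] + outer(dirs, shift)
    panel_sig <- dirs
  }

  ## survival: exponential progression hazard driven by driver expression
  lin <- rep(0, n)
  for (r in seq_len(nrow(drivers)))
    lin <- lin + drivers$log_hr[r] * expr[drivers$gene_id[r], ]
  t_prog <- rexp(n, rate = cfg$baseline_hazard * exp(lin))
  t_ldeath <- t_prog + rexp(n, rate = cfg$post_progression_rate)
  t_odeath <- rexp(n, rate = max(cfg$other_death_rate, 1e-12))
  if (cfg$other_death_rate <= 0) t_odeath <- rep(Inf, n)
  t_cens <- if (cfg$censoring_rate > 0) rexp(n, rate = cfg$censoring_rate)
            else rep(Inf, n)
  t_cens <- pmin(t_cens, cfg$followup_max)

  prog_obs <- t_prog < pmin(t_odeath, t_cens)
  death_t <- ifelse(prog_obs, pmin(t_ldeath, t_odeath), t_odeath)
  death_obs <- death_t < t_cens
  cause <- ifelse(!death_obs, "alive",
                  ifelse(prog_obs & t_ldeath <= t_odeath, "lymphoma",
                         "other"))
  end_t <- ifelse(death_obs, death_t, t_cens)

  reg <- as.Date("2011-01-01") + round(runif(n, 0, cfg$accrual_window) * 30.44)
  days <- function(m) pmax(1, round(m * 30.44))
  clinical <- data.frame(
    sample_id = samples,
    registration_date = reg,
    progression_date = as.Date(ifelse(prog_obs, reg + days(t_prog), NA),
                               origin = "1970-01-01"),
    death_date = as.Date(ifelse(death_obs, reg + days(death_t), NA),
                         origin = "1970-01-01"),
    last_followup_date = reg + days(end_t),
    cause = cause,
    subtype = subtype,
    ipi = sample(2:3, n, replace = TRUE, prob = c(0.7, 0.3)),
    stringsAsFactors = FALSE)

  ## germline CNV catalogue: random intervals, length-weighted chromosome
  cnv <- NULL
  if (cfg$n_cnv_records > 0) {
    ch <- sample(chroms, cfg$n_cnv_records, replace = TRUE,
                 prob = cfg$chromosomes / sum(cfg$chromosomes))
    len <- runif(cfg$n_cnv_records, 1e3, cfg$cnv_max_len)
    st <- floor(runif(cfg$n_cnv_records) *
                  (cfg$chromosomes[ch] - len))
    cnv <- data.frame(chrom = ch, start = floor(st),
                      end = floor(st + len), stringsAsFactors = FALSE)
    rownames(cnv) <- NULL
  } else {
    cnv <- data.frame(chrom = character(), start = numeric(),
                      end = numeric())
  }

  ## truth record
  breakpoints <- lapply(samples, function(s) {
    bl <- lapply(chroms, function(ch) {
      bp <- numeric()
      for (k in seq_len(n_ab)) {
        if (ab$chrom[k] == ch && carrier_map[s, k])
          bp <- c(bp, ab$start[k], ab$end[k])
      }
      sort(unique(bp[bp > 0 & bp < cfg$chromosomes[[ch]]]))
    })
    names(bl) <- chroms
    bl
  })
  names(breakpoints) <- samples

  truth <- list(breakpoints = breakpoints, carrier_map = carrier_map,
                drivers = drivers, driver_ids = drivers$gene_id,
                true_log_hr = stats::setNames(drivers$log_hr,
                                              drivers$gene_id),
                subtype = stats::setNames(subtype, samples),
                panel_signature = panel_sig,
                bias = stats::setNames(bias, probes$probe_id),
                linear_predictor = stats::setNames(lin, samples))

  out <- list(probes = probes, expression = expr, clinical = clinical,
              cnv_catalogue = cnv, annotation = ann, truth = truth,
              config = cfg)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", x$config$n_samples, "samples,",
      nrow(x$probes), "probes,", nrow(x$annotation), "genes\n")
  cat("Planted aberrations:", nrow(x$config$planted_aberrations) %||% 0,
      " driver genes:", paste(x$truth$driver_ids, collapse = ", "), "\n")
  invisible(x)
}
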