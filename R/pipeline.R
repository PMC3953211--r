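#' Screen configuration
#'
#' Thresholds and permutation settings for [run_screen()]. Defaults mirror
#' the published screen design: aberration calling at 2 cohort SDs from the
#' median, minimal common regions at 10% recurrence, exclusion of genes with
#' more than 10 overlapping germline CNVs, expression integration for genes
#' aberrant in at least 3 samples at p < 0.05, and survival analysis for
#' genes aberrant in at least 5 samples.
#'
#' @param alpha Significance level for association and survival tests.
#' @param min_freq Minimal-common-region recurrence fraction.
#' @param max_cnv Maximum tolerated overlapping CNV records per gene.
#' @param min_cna Minimum aberrant samples for expression integration.
#' @param min_surv Minimum aberrant samples for survival analysis.
#' @param k SD multiplier for aberration calling.
#' @param cbs_alpha Split acceptance level for segmentation.
#' @param n_perm_cbs Permutations per segmentation split test.
#' @param n_perm_assoc Permutations per gene association test.
#' @param endpoint Survival endpoint: "pfs", "os" or "lsos".
#' @param lowess_window,lowess_iterations Normalization parameters
#'   (30% window, four iterations).
#' @param min_width Minimum probes per segment.
#' @param seed Root seed; all stage randomness derives from it.
#' @return List of class `screen_config`.
#' @export
screen_config <- function(alpha = 0.05, min_freq = 0.10, max_cnv = 10,
                          min_cna = 3, min_surv = 5, k = 2,
                          cbs_alpha = 0.05, n_perm_cbs = 200,
                          n_perm_assoc = 1000,
                          endpoint = c("pfs", "os", "lsos"),
                          lowess_window = 0.30, lowess_iterations = 4,
                          min_width = 2, seed = 1L) {
  endpoint <- match.arg(endpoint)
  stopifnot(alpha > 0, min_freq > 0, min_freq <= 1, max_cnv >= 0,
            min_cna >= 1, min_surv >= 1, k > 0)
  structure(list(alpha = alpha, min_freq = min_freq, max_cnv = max_cnv,
                 min_cna = min_cna, min_surv = min_surv, k = k,
                 cbs_alpha = cbs_alpha, n_perm_cbs = n_perm_cbs,
                 n_perm_assoc = n_perm_assoc, endpoint = endpoint,
                 lowess_window = lowess_window,
                 lowess_iterations = lowess_iterations,
                 min_width = min_width, seed = as.integer(seed)),
            class = "screen_config")
}

#' Classify molecular subtype from a gene-expression panel
#'
#' Complete-linkage agglomerative hierarchical clustering on Euclidean
#' distances between samples over a panel of subtype-signature genes
#' (log-ratio scale); the tree is cut into two branches. If per-gene
#' signature directions are supplied (+1 for genes up in GCB, -1 for genes
#' down), the branch with the higher mean signed panel expression is
#' labelled "GCB" and the other "nonGCB"; otherwise neutral labels
#' "cluster1"/"cluster2" are returned and the caller maps them.
#'
#' @param expression Genes x samples matrix.
#' @param panel_genes Panel gene ids; panel genes absent from the matrix are
#'   dropped with a warning.
#' @param signature Optional named vector of +1/-1 per panel gene.
#' @return Named factor of per-sample labels.
#' @export
classify_subtype_gep <- function(expression, panel_genes,
                                 signature = NULL) {
  present <- intersect(panel_genes, rownames(expression))
  if (length(present) < length(panel_genes))
    warning("dropping ", length(panel_genes) - length(present),
            " panel gene(s) absent from the expression matrix")
  if (length(present) < 2) stop("fewer than 2 panel genes available")
  if (ncol(expression) < 4) stop("need at least 4 samples")
  X <- expression[present, , drop = FALSE]
  if (nrow(unique(t(X))) < 2)
    stop("fewer than 2 distinct expression profiles")
  hc <- stats::hclust(stats::dist(t(X)), method = "complete")
  ct <- stats::cutree(hc, k = 2)
  if (is.null(signature)) {
    lab <- factor(paste0("cluster", ct), levels = c("cluster1", "cluster2"))
  } else {
    sg <- signature[present]
    score <- colMeans(X * sg)
    gcb_cluster <- which.max(tapply(score, ct, mean))
    lab <- factor(ifelse(ct == as.integer(names(gcb_cluster)),
                         "GCB", "nonGCB"), levels = c("GCB", "nonGCB"))
  }
  names(lab) <- colnames(expression)
  lab
}

# genes whose bodies overlap a region of the matching direction
genes_in_regions <- function(annotation, regions) {
  if (is.null(regions) || !nrow(regions)) return(character(0))
  genes_gr <- gr_from_intervals(annotation$chrom, annotation$start,
                                annotation$end)
  reg_gr <- gr_from_intervals(regions$chrom, regions$start, regions$end)
  hits <- GenomicRanges::findOverlaps(genes_gr, reg_gr)
  unique(annotation$gene_id[S4Vectors::queryHits(hits)])
}

#' Run the full integrative screen on a cohort
#'
#' Executes normalization, segmentation, noise estimation, aberration
#' calling, minimal-common-region detection, CNV filtering, copy-number /
#' expression integration, and survival analysis, in order, with the
#' configured thresholds. Survival is tested two ways, mirroring the
#' two-step design of the published screen: (a) per region with at least
#' `min_surv` carriers, carriers vs rest by Kaplan-Meier/log-rank; (b) per
#' selected gene aberrant in at least `min_surv` samples, expression as a
#' continuous Cox covariate followed by ROC-cutoff dichotomized
#' Kaplan-Meier/log-rank. Selected biomarkers are association-selected genes
#' with continuous Cox p below `alpha`.
#'
#' @param cohort A [generate_cohort()] result, or any list with elements
#'   `probes`, `expression`, `clinical`, `annotation`, `cnv_catalogue` in
#'   the same formats.
#' @param config A [screen_config()].
#' @return List of class `screen_report`: `segments`, `noise`, `regions`,
#'   `association`, `region_survival`, `gene_survival`, `biomarkers`,
#'   `endpoints`, `tested_genes`, `config`, `n_samples`.
#' @export
run_screen <- function(cohort, config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  stage_seeds <- with_seed(config$seed,
                           sample.int(.Machine$integer.max %/% 2, 3))

  samples <- setdiff(names(cohort$probes),
                     c("probe_id", "chrom", "start", "end"))
  n_samples <- length(samples)

  norm <- normalize_profiles(cohort$probes, samples,
                             window_fraction = config$lowess_window,
                             iterations = config$lowess_iterations)
  segments <- segment_profiles(norm, samples, alpha = config$cbs_alpha,
                               n_perm = config$n_perm_cbs,
                               min_width = config$min_width,
                               seed = stage_seeds[1])
  noise <- estimate_noise(segment_residuals(norm, segments), k = config$k)
  segments <- call_aberrations(segments, noise)

  regions <- rbind(
    minimal_common_regions(segments, n_samples, config$min_freq, "gain"),
    minimal_common_regions(segments, n_samples, config$min_freq, "loss"))

  gene_cna <- map_genes_to_calls(segments, cohort$annotation)
  retained <- cnv_filter(cohort$annotation, cohort$cnv_catalogue,
                         config$max_cnv)
  region_genes <- genes_in_regions(cohort$annotation, regions)
  tested_genes <- intersect(intersect(region_genes, retained),
                            rownames(cohort$expression))

  association <- associate(gene_cna, cohort$expression,
                           genes = tested_genes, alpha = config$alpha,
                           min_samples = config$min_cna,
                           n_perm = config$n_perm_assoc,
                           seed = stage_seeds[2])

  endpoints <- derive_endpoints(cohort$clinical)
  rownames(endpoints) <- endpoints$sample_id
  endpoints <- endpoints[samples, , drop = FALSE]
  tm <- endpoints[[paste0(config$endpoint, "_time")]]
  ev <- endpoints[[paste0(config$endpoint, "_event")]]

  ## (a) per-region survival: carriers vs rest
  region_surv <- data.frame(chrom = character(), start = numeric(),
                            end = numeric(), direction = character(),
                            n_carriers = integer(), chisq = numeric(),
                            p = numeric())
  if (nrow(regions)) {
    rows <- lapply(seq_len(nrow(regions)), function(i) {
      carr <- samples %in% regions$carriers[[i]]
      if (sum(carr) < config$min_surv || sum(!carr) == 0) return(NULL)
      lr <- logrank_test(tm, ev, ifelse(carr, "carrier", "rest"))
      data.frame(chrom = regions$chrom[i], start = regions$start[i],
                 end = regions$end[i], direction = regions$direction[i],
                 n_carriers = regions$n_carriers[i], chisq = lr$chisq,
                 p = lr$p, stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) region_surv <- do.call(rbind, rows)
  }
  if (nrow(region_surv)) region_surv$fdr <- p.adjust(region_surv$p, "BH")

  ## (b) per selected gene: continuous Cox, then ROC-dichotomized KM
  sel <- association[association$selected, , drop = FALSE]
  gene_surv <- data.frame(gene_id = character(), direction = character(),
                          n_cna = integer(), cox_log_hr = numeric(),
                          cox_p = numeric(), cutoff = numeric(),
                          logrank_p = numeric())
  if (nrow(sel) && sum(ev) >= 1) {
    rows <- lapply(seq_len(nrow(sel)), function(i) {
      g <- sel$gene_id[i]
      n_dir <- sum(gene_cna$call[g, samples] == sel$direction[i],
                   na.rm = TRUE)
      if (n_dir < config$min_surv) return(NULL)
      x <- cohort$expression[g, samples]
      if (length(unique(x)) < 2) return(NULL)
      cx <- cox_fit(x, tm, ev)
      cut <- tryCatch(roc_cutoff(x, ev, name = g), error = function(e) NULL)
      lrp <- NA_real_
      cc <- NA_real_
      if (!is.null(cut)) {
        cc <- cut$cutoff
        grp <- ifelse(x > cc, "high", "low")
        if (length(unique(grp)) == 2)
          lrp <- logrank_test(tm, ev, grp)$p
      }
      data.frame(gene_id = g, direction = sel$direction[i], n_cna = n_dir,
                 cox_log_hr = cx$log_hr, cox_p = cx$p, cutoff = cc,
                 logrank_p = lrp, stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) gene_surv <- do.call(rbind, rows)
  }
  if (nrow(gene_surv)) gene_surv$cox_fdr <- p.adjust(gene_surv$cox_p, "BH")

  biomarkers <- gene_surv$gene_id[!is.na(gene_surv$cox_p) &
                                    gene_surv$cox_p < config$alpha]

  structure(list(segments = segments, noise = noise, regions = regions,
                 association = association, region_survival = region_surv,
                 gene_survival = gene_surv,
                 biomarkers = sort(unique(biomarkers)),
                 endpoints = endpoints, tested_genes = sort(tested_genes),
                 config = config, n_samples = n_samples,
                 sample_ids = samples),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Integrative CNA screen:", x$n_samples, "samples\n")
  cat(sprintf("  segments: %d  regions: %d (gain %d / loss %d)\n",
              nrow(x$segments), nrow(x$regions),
              sum(x$regions$direction == "gain"),
              sum(x$regions$direction == "loss")))
  cat(sprintf("  genes tested: %d  association-selected: %d\n",
              length(x$tested_genes), sum(x$association$selected)))
  cat(sprintf("  survival endpoint: %s  biomarkers: %s\n",
              x$config$endpoint,
              if (length(x$biomarkers)) paste(x$biomarkers, collapse = ", ")
              else "(none)"))
  invisible(x)
}
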