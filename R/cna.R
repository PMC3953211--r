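#' LOWESS normalization of a probe profile
#'
#' Removes a smooth, covariate-dependent trend from log2 ratios by robust
#' locally weighted scatterplot smoothing, returning the residuals. Defaults
#' (30% window, four robustifying iterations) follow standard aCGH
#' preprocessing practice.
#'
#' @param values Numeric log2 ratios (>= 10 probes).
#' @param covariate Per-probe covariate the bias depends on (e.g. probe
#'   intensity or array position); defaults to probe index.
#' @param window_fraction Smoother span in (0, 1].
#' @param iterations Number of robustifying iterations.
#' @return Numeric vector: `values` minus the LOWESS fit. If the covariate is
#'   constant the input is returned unchanged with a warning.
#' @export
lowess_normalize <- function(values, covariate = seq_along(values),
                             window_fraction = 0.30, iterations = 4) {
  if (length(values) < 10) stop("need at least 10 probes")
  if (window_fraction <= 0 || window_fraction > 1)
    stop("window_fraction must be in (0, 1]")
  if (length(covariate) != length(values))
    stop("covariate and values lengths differ")
  if (diff(range(covariate)) == 0) {
    warning("constant covariate: returning values unchanged")
    return(values)
  }
  fit <- stats::lowess(covariate, values, f = window_fraction,
                       iter = iterations)
  fitted <- stats::approx(fit$x, fit$y, xout = covariate, rule = 2,
                          ties = mean)$y
  values - fitted
}

#' Normalize all sample columns of a probe matrix
#'
#' Applies [lowess_normalize()] per sample against the global probe index
#' (proxy for the array's intensity-dependent trend). Probes with missing
#' values in any sample are dropped first, with a message stating the count.
#'
#' @param probes Probe data.frame: `probe_id`, `chrom`, `start`, `end`, one
#'   numeric column per sample.
#' @param samples Sample column names; default: all non-coordinate columns.
#' @inheritParams lowess_normalize
#' @return The probe data.frame with normalized sample columns.
#' @export
normalize_profiles <- function(probes, samples = NULL,
                               window_fraction = 0.30, iterations = 4) {
  stopifnot_cols(probes, c("probe_id", "chrom", "start", "end"), "probes")
  samples <- samples %||%
    setdiff(names(probes), c("probe_id", "chrom", "start", "end"))
  keep <- complete.cases(probes[, samples, drop = FALSE])
  if (!all(keep)) {
    message("dropping ", sum(!keep), " probe(s) with missing values")
    probes <- probes[keep, , drop = FALSE]
  }
  for (s in samples)
    probes[[s]] <- lowess_normalize(probes[[s]],
                                    covariate = seq_len(nrow(probes)),
                                    window_fraction = window_fraction,
                                    iterations = iterations)
  probes
}

#' Circular binary segmentation of one ordered probe sequence
#'
#' Recursive binary splitting on the circularized sequence: at each step the
#' arc maximizing the two-sample mean-difference statistic between the arc
#' and its complement is found, and the split is accepted iff its permutation
#' p-value is below `alpha`. No undo/pruning step is applied. Every probe is
#' assigned to exactly one segment whose mean is the mean of its member
#' probes.
#'
#' @param values Ordered numeric log2 ratios for one chromosome.
#' @param alpha Split acceptance level for the permutation test.
#' @param n_perm Permutations per split test.
#' @param min_width Minimum probes per segment.
#' @param seed Optional integer seed.
#' @return data.frame with one row per segment: `start_probe`, `end_probe`
#'   (1-based inclusive probe indices), `n_probes`, `seg_mean`.
#' @export
cbs_segment <- function(values, alpha = 0.05, n_perm = 1000, min_width = 2,
                        seed = NULL) {
  stopifnot(is.numeric(values), length(values) >= 1)
  with_seed(seed, {
    segs <- list()
    stack <- list(c(1L, length(values)))
    # if the exceedance count reaches this, p >= alpha is already certain
    max_exceed <- ceiling(alpha * (1 + n_perm) - 1)
    while (length(stack)) {
      rng <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      lo <- rng[1]; hi <- rng[2]
      n <- hi - lo + 1L
      split_at <- integer(0)
      if (n >= 2 * min_width) {
        x <- values[lo:hi]
        ms <- .cbs_max_stat(x, as.integer(min_width))
        pc <- .cbs_perm_count(x, as.integer(min_width), as.integer(n_perm),
                              ms$stat, as.integer(max_exceed))
        significant <- pc$n_done == n_perm &&
          (1 + pc$count) / (1 + n_perm) < alpha
        if (significant) {
          cuts <- c(ms$i, ms$j)
          split_at <- sort(unique(cuts[cuts > 0 & cuts < n]))
        }
      }
      if (length(split_at)) {
        bounds <- c(0L, split_at, n)
        # push in reverse so left-most is processed first
        for (b in rev(seq_len(length(bounds) - 1)))
          stack[[length(stack) + 1]] <- c(lo + bounds[b],
                                          lo + bounds[b + 1] - 1L)
      } else {
        segs[[length(segs) + 1]] <- c(lo, hi)
      }
    }
    segs <- do.call(rbind, segs)
    segs <- segs[order(segs[, 1]), , drop = FALSE]
    data.frame(start_probe = segs[, 1], end_probe = segs[, 2],
               n_probes = segs[, 2] - segs[, 1] + 1L,
               seg_mean = vapply(seq_len(nrow(segs)), function(i)
                 mean(values[segs[i, 1]:segs[i, 2]]), numeric(1)))
  })
}

#' Segment every sample and chromosome of a probe matrix
#'
#' Runs [cbs_segment()] per sample per chromosome and maps segment
#' boundaries back to genomic coordinates (0-based half-open; a segment runs
#' from the start of its first probe to the end of its last probe).
#'
#' @inheritParams normalize_profiles
#' @inheritParams cbs_segment
#' @return data.frame of segments: `sample_id`, `chrom`, `start`, `end`,
#'   `start_probe`, `end_probe` (chromosome-local), `n_probes`, `seg_mean`,
#'   `call` (initialized to "neutral"; see [call_aberrations()]).
#' @export
segment_profiles <- function(probes, samples = NULL, alpha = 0.05,
                             n_perm = 1000, min_width = 2, seed = NULL) {
  stopifnot_cols(probes, c("probe_id", "chrom", "start", "end"), "probes")
  samples <- samples %||%
    setdiff(names(probes), c("probe_id", "chrom", "start", "end"))
  chroms <- unique(probes$chrom)
  with_seed(seed, {
    out <- list()
    for (s in samples) {
      for (ch in chroms) {
        sub <- probes[probes$chrom == ch, , drop = FALSE]
        sub <- sub[order(sub$start), , drop = FALSE]
        segs <- cbs_segment(sub[[s]], alpha = alpha, n_perm = n_perm,
                            min_width = min_width, seed = NULL)
        segs$sample_id <- s
        segs$chrom <- ch
        segs$start <- sub$start[segs$start_probe]
        segs$end <- sub$end[segs$end_probe]
        out[[length(out) + 1]] <- segs
      }
    }
    res <- do.call(rbind, out)
    res$call <- "neutral"
    rownames(res) <- NULL
    res[, c("sample_id", "chrom", "start", "end", "start_probe",
            "end_probe", "n_probes", "seg_mean", "call")]
  })
}

#' Cohort noise model from pooled probe values
#'
#' Estimates the cohort background level and noise scale as the median and
#' sample SD of a pool of per-probe values. The pipeline feeds this the
#' per-probe residuals (probe value minus its segment mean, see
#' [segment_residuals()]) so that true aberrations do not inflate the noise
#' estimate; raw probe values may be supplied instead.
#'
#' @param values Numeric pool of probe-level values across all arrays.
#' @param k SD multiplier used for aberration calling (default 2).
#' @return List of class `noise_model`: `median`, `sd`, `k`.
#' @export
estimate_noise <- function(values, k = 2) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty probe pool")
  structure(list(median = median(values),
                 sd = if (length(values) > 1) sd(values) else 0,
                 k = k),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("Cohort noise model: median %.4f, sd %.4f, k = %g\n",
              x$median, x$sd, x$k))
  invisible(x)
}

#' Per-probe residuals around segment means
#'
#' @param probes Probe data.frame (as in [normalize_profiles()]).
#' @param segments Segment data.frame from [segment_profiles()].
#' @return Numeric vector pooling, over all samples and chromosomes, each
#'   probe's value minus the mean of the segment containing it.
#' @export
segment_residuals <- function(probes, segments) {
  samples <- unique(segments$sample_id)
  res <- numeric(0)
  for (s in samples) {
    for (ch in unique(segments$chrom[segments$sample_id == s])) {
      sub <- probes[probes$chrom == ch, , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      seg <- segments[segments$sample_id == s & segments$chrom == ch, ,
                      drop = FALSE]
      seg <- seg[order(seg$start_probe), , drop = FALSE]
      means <- rep(seg$seg_mean, seg$n_probes)
      res <- c(res, sub[[s]] - means)
    }
  }
  res
}

#' Call gains and losses against the cohort noise model
#'
#' A segment is called a gain if its mean exceeds `median + k * sd`, a loss
#' if below `median - k * sd`, and neutral otherwise.
#'
#' @param segments Segment data.frame from [segment_profiles()].
#' @param noise A [estimate_noise()] model.
#' @return The segment data.frame with its `call` column set to one of
#'   "gain", "loss", "neutral".
#' @export
call_aberrations <- function(segments, noise) {
  stopifnot(inherits(noise, "noise_model"), noise$sd >= 0)
  if (noise$sd == 0)
    warning("zero cohort SD: any deviation from the median is called")
  up <- noise$median + noise$k * noise$sd
  dn <- noise$median - noise$k * noise$sd
  segments$call <- ifelse(segments$seg_mean > up, "gain",
                          ifelse(segments$seg_mean < dn, "loss", "neutral"))
  segments
}

gr_from_intervals <- function(chrom, start, end) {
  # internal 0-based half-open -> 1-based inclusive GRanges
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
}

#' Map gene loci onto per-sample segment calls
#'
#' Assigns to each gene, per sample, the call and mean of the segment with
#' the largest base-pair overlap with the gene body. Ties are broken toward
#' the segment with the larger absolute mean (conservative toward detecting
#' an aberration). Genes overlapping no segment (e.g. on a chromosome absent
#' from the profile) get `NA` status.
#'
#' @param segments Called segment data.frame ([call_aberrations()]).
#' @param annotation Gene annotation data.frame: `gene_id`, `chrom`, `start`,
#'   `end` (0-based half-open).
#' @return List of class `gene_cna`: `call` (genes x samples character
#'   matrix), `seg_mean` (numeric matrix), `genes` (the annotation).
#' @export
map_genes_to_calls <- function(segments, annotation) {
  stopifnot_cols(annotation, c("gene_id", "chrom", "start", "end"),
                 "annotation")
  samples <- unique(segments$sample_id)
  genes <- annotation$gene_id
  call_m <- matrix(NA_character_, length(genes), length(samples),
                   dimnames = list(genes, samples))
  mean_m <- matrix(NA_real_, length(genes), length(samples),
                   dimnames = list(genes, samples))
  genes_gr <- gr_from_intervals(annotation$chrom, annotation$start,
                                annotation$end)
  seg_gr <- gr_from_intervals(segments$chrom, segments$start, segments$end)
  hits <- GenomicRanges::findOverlaps(genes_gr, seg_gr)
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- GenomicRanges::width(GenomicRanges::pintersect(genes_gr[qh],
                                                         seg_gr[sh]))
    si <- match(segments$sample_id[sh], samples)
    # best segment per (gene, sample): largest overlap, ties toward the
    # segment with larger |seg_mean|
    ord <- order(si, qh, -ov, -abs(segments$seg_mean[sh]))
    first <- !duplicated(cbind(si, qh)[ord, , drop = FALSE])
    pick <- ord[first]
    idx <- cbind(qh[pick], si[pick])
    call_m[idx] <- segments$call[sh[pick]]
    mean_m[idx] <- segments$seg_mean[sh[pick]]
  }
  n_unmapped <- sum(is.na(call_m))
  if (n_unmapped > 0)
    message(n_unmapped, " gene-sample pair(s) overlap no segment")
  structure(list(call = call_m, seg_mean = mean_m, genes = annotation),
            class = "gene_cna")
}
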