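#' Minimal common copy-number aberration regions
#'
#' Sweep-line over segment boundaries: per chromosome, the number of samples
#' carrying an aberration of `direction` is counted at every genomic
#' position, and maximal runs where the count reaches
#' `ceiling(min_freq * n_samples)` are merged into regions. A region's
#' carriers are the union of samples aberrant anywhere within it.
#'
#' @param segments Called segment data.frame ([call_aberrations()]).
#' @param n_samples Cohort size the frequency is computed over.
#' @param min_freq Minimum carrier fraction, in (0, 1].
#' @param direction "gain" or "loss".
#' @return data.frame: `chrom`, `start`, `end` (0-based half-open),
#'   `direction`, `n_carriers`, `frequency`, and `carriers` (list column of
#'   sample ids). Zero rows if no position reaches the threshold.
#' @export
minimal_common_regions <- function(segments, n_samples,
                                   min_freq = 0.10,
                                   direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  stopifnot(is_count(n_samples))
  if (min_freq <= 0 || min_freq > 1) stop("min_freq must be in (0, 1]")
  threshold <- ceiling(min_freq * n_samples)
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), direction = character(),
                      n_carriers = integer(), frequency = numeric())
  empty$carriers <- list()
  ab <- segments[segments$call == direction, , drop = FALSE]
  if (!nrow(ab)) return(empty)

  out <- list()
  for (ch in unique(ab$chrom)) {
    sub <- ab[ab$chrom == ch, , drop = FALSE]
    # segments are disjoint within a sample, so coverage count = carrier count
    pos <- c(sub$start, sub$end)
    delta <- c(rep(1L, nrow(sub)), rep(-1L, nrow(sub)))
    agg <- rowsum(delta, pos)
    p <- as.numeric(rownames(agg))
    o <- order(p)
    p <- p[o]
    cov <- cumsum(agg[o])
    # coverage over elementary interval [p[i], p[i+1]) is cov[i]
    qual <- cov >= threshold
    i <- 1
    while (i <= length(qual)) {
      if (qual[i]) {
        j <- i
        while (j + 1 <= length(qual) && qual[j + 1]) j <- j + 1
        rs <- p[i]; re <- p[j + 1]
        inreg <- sub$start < re & sub$end > rs
        carr <- sort(unique(sub$sample_id[inreg]))
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = rs, end = re, direction = direction,
          n_carriers = length(carr),
          frequency = length(carr) / n_samples,
          carriers = I(list(carr)), stringsAsFactors = FALSE)
        i <- j + 1
      }
      i <- i + 1
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Filter genes by germline CNV catalogue overlap
#'
#' A gene is retained iff the number of catalogue intervals overlapping its
#' locus by at least 1 bp is at most `max_cnv`. Raw records are counted (no
#' merging). An empty catalogue retains every gene.
#'
#' @param annotation Gene annotation data.frame: `gene_id`, `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param catalogue CNV catalogue data.frame: `chrom`, `start`, `end`.
#' @param max_cnv Maximum tolerated overlapping CNV count (default 10; genes
#'   with more than 10 overlapping records are excluded).
#' @return Character vector of retained gene ids, plus an attribute
#'   `cnv_counts` with the per-gene overlap counts.
#' @export
cnv_filter <- function(annotation, catalogue, max_cnv = 10) {
  stopifnot_cols(annotation, c("gene_id", "chrom", "start", "end"),
                 "annotation")
  if (is.null(catalogue) || !nrow(catalogue)) {
    counts <- stats::setNames(rep(0L, nrow(annotation)), annotation$gene_id)
  } else {
    stopifnot_cols(catalogue, c("chrom", "start", "end"), "catalogue")
    if (any(catalogue$start >= catalogue$end))
      stop("catalogue has invalid intervals")
    genes_gr <- gr_from_intervals(annotation$chrom, annotation$start,
                                  annotation$end)
    cnv_gr <- gr_from_intervals(catalogue$chrom, catalogue$start,
                                catalogue$end)
    counts <- GenomicRanges::countOverlaps(genes_gr, cnv_gr)
    names(counts) <- annotation$gene_id
  }
  retained <- annotation$gene_id[counts <= max_cnv]
  attr(retained, "cnv_counts") <- counts
  retained
}

#' Filter genes by aberration recurrence
#'
#' @param gene_cna A [map_genes_to_calls()] table.
#' @param min_samples Minimum number of samples with the aberration (the
#'   screen uses 3 for expression integration and 5 for survival analysis).
#' @param direction "gain" or "loss".
#' @return Character vector of gene ids aberrant in at least `min_samples`
#'   samples.
#' @export
recurrence_filter <- function(gene_cna, min_samples,
                              direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  stopifnot(is_count(min_samples))
  n_ab <- rowSums(gene_cna$call == direction, na.rm = TRUE)
  names(n_ab)[n_ab >= min_samples]
}

#' Compare aberration frequency between two subgroups
#'
#' Builds the 2x2 group-by-carrier contingency table and tests it with
#' Fisher's exact test (two-sided; exact p by summing hypergeometric
#' probabilities no larger than the observed table's) or the chi-square
#' test.
#'
#' @param carrier Logical carrier status per sample.
#' @param group Two-level factor (e.g. GCB vs non-GCB) per sample.
#' @param method "fisher" (default) or "chisq".
#' @return List: `table` (2x2), `p`, `method`.
#' @export
subgroup_frequency_test <- function(carrier, group,
                                    method = c("fisher", "chisq")) {
  method <- match.arg(method)
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if (any(table(group) == 0)) stop("a group has size 0")
  tab <- table(group, factor(carrier, levels = c(TRUE, FALSE),
                             labels = c("carrier", "non-carrier")))
  p <- if (method == "fisher") stats::fisher.test(tab)$p.value
       else stats::chisq.test(tab)$p.value
  list(table = tab, p = p, method = method)
}
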