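# Brute-force / closed-form oracles, independent of the package internals.
# All coordinates 0-based half-open, as in the package.

# per-base carrier count of `direction` intervals; returns regions where the
# count of distinct samples covering a base reaches `threshold`
bf_regions <- function(segments, n_samples, min_freq, direction,
                       resolution = 1) {
  ab <- segments[segments$call == direction, , drop = FALSE]
  threshold <- ceiling(min_freq * n_samples)
  out <- list()
  for (ch in unique(ab$chrom)) {
    sub <- ab[ab$chrom == ch, , drop = FALSE]
    if (!nrow(sub)) next
    lo <- min(sub$start); hi <- max(sub$end)
    pos <- seq(lo, hi - 1, by = resolution)
    cnt <- vapply(pos, function(p)
      length(unique(sub$sample_id[sub$start <= p & sub$end > p])),
      integer(1))
    qual <- cnt >= threshold
    r <- rle(qual)
    ends <- cumsum(r$lengths)
    starts <- c(1, head(ends, -1) + 1)
    for (k in which(r$values)) {
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = pos[starts[k]],
        end = pos[ends[k]] + resolution)
    }
  }
  if (!length(out)) return(data.frame(chrom = character(),
                                      start = numeric(), end = numeric()))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

# quadratic all-pairs interval overlap counts per gene
bf_cnv_counts <- function(annotation, catalogue) {
  vapply(seq_len(nrow(annotation)), function(i) {
    g <- annotation[i, ]
    sum(catalogue$chrom == g$chrom & catalogue$start < g$end &
          catalogue$end > g$start)
  }, integer(1))
}

# two-sided Fisher p by exhaustive enumeration over tables with fixed margins
bf_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) stats::dhyper(x, m, n, k), numeric(1))
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# AUC as the fraction of concordant case/control pairs (ties credit 0.5)
bf_auc <- function(marker, outcome) {
  pos <- marker[as.logical(outcome)]
  neg <- marker[!as.logical(outcome)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# per-base overlap tally: best segment per gene per sample
bf_gene_map <- function(segments, annotation) {
  samples <- unique(segments$sample_id)
  res <- matrix(NA_character_, nrow(annotation), length(samples),
                dimnames = list(annotation$gene_id, samples))
  for (s in samples) {
    seg <- segments[segments$sample_id == s, , drop = FALSE]
    for (i in seq_len(nrow(annotation))) {
      g <- annotation[i, ]
      ov <- ifelse(seg$chrom == g$chrom,
                   pmax(0, pmin(seg$end, g$end) - pmax(seg$start, g$start)),
                   0)
      if (all(ov == 0)) next
      best <- which(ov == max(ov))
      if (length(best) > 1)
        best <- best[which.max(abs(seg$seg_mean[best]))]
      res[i, s] <- seg$call[best]
    }
  }
  res
}

# hand product-limit estimator
bf_km <- function(times, events) {
  ts <- sort(unique(times[events == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(times >= ts[i])
    d <- sum(times == ts[i] & events == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = ts, surv = surv)
}

# exhaustive permutation p for the SNR statistic (one-sided greater),
# enumerating all distinct group-1 index sets
bf_perm_p_exact <- function(values, flags) {
  n <- length(values); n1 <- sum(flags)
  obs <- snr_statistic(values[flags], values[!flags])
  sets <- utils::combn(n, n1)
  stats <- apply(sets, 2, function(ix)
    snr_statistic(values[ix], values[-ix]))
  mean(stats >= obs - 1e-12)
}

# direct BH step-up
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# small segment table builder (0-based half-open)
seg_row <- function(sample_id, chrom, start, end, seg_mean, call) {
  data.frame(sample_id = sample_id, chrom = chrom, start = start, end = end,
             start_probe = 1L, end_probe = 1L, n_probes = 1L,
             seg_mean = seg_mean, call = call, stringsAsFactors = FALSE)
}

# minimal gene_cna object from a call matrix
make_gene_cna <- function(call_matrix, seg_mean = NULL, annotation = NULL) {
  if (is.null(seg_mean)) {
    seg_mean <- matrix(0, nrow(call_matrix), ncol(call_matrix),
                       dimnames = dimnames(call_matrix))
    seg_mean[call_matrix == "gain"] <- 1
    seg_mean[call_matrix == "loss"] <- -1
  }
  structure(list(call = call_matrix, seg_mean = seg_mean,
                 genes = annotation), class = "gene_cna")
}
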