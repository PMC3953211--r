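#' Signal-to-noise statistic between two expression groups
#'
#' `(mean1 - mean2) / (sd1 + sd2)` with sample (n-1) standard deviations,
#' where group 1 is the copy-number-aberrant samples and group 2 the rest.
#' Large spread in either group shrinks the statistic, so "stable expression
#' in non-aberrant samples" is rewarded by construction.
#'
#' @param values_cna Expression values of the aberrant group (>= 2).
#' @param values_non Expression values of the non-aberrant group (>= 2).
#' @return The statistic; `+/-Inf` if both SDs are zero but the means differ,
#'   0 if both groups are constant and equal.
#' @export
snr_statistic <- function(values_cna, values_non) {
  if (length(values_cna) < 2 || length(values_non) < 2)
    stop("each group needs at least 2 values")
  m1 <- mean(values_cna); m2 <- mean(values_non)
  den <- sd(values_cna) + sd(values_non)
  if (den == 0) {
    if (m1 == m2) return(0)
    return(sign(m1 - m2) * Inf)
  }
  (m1 - m2) / den
}

# vectorized SNR over columns of permuted value matrices
snr_columns <- function(xm, n1) {
  n <- nrow(xm)
  g1 <- xm[seq_len(n1), , drop = FALSE]
  g2 <- xm[-seq_len(n1), , drop = FALSE]
  m1 <- colMeans(g1); m2 <- colMeans(g2)
  v1 <- pmax(0, (colSums(g1^2) - n1 * m1^2) / (n1 - 1))
  v2 <- pmax(0, (colSums(g2^2) - (n - n1) * m2^2) / (n - n1 - 1))
  den <- sqrt(v1) + sqrt(v2)
  out <- ifelse(den == 0, ifelse(m1 == m2, 0, sign(m1 - m2) * Inf),
                (m1 - m2) / den)
  out
}

#' Permutation p-value for the signal-to-noise statistic
#'
#' Permutes the group labels uniformly at random, preserving group sizes, and
#' reports the add-one p-value `(1 + #extreme) / (1 + n_perm)` so that p is
#' never 0.
#'
#' @param values Expression values.
#' @param flags Logical labels (TRUE = aberrant group); both classes must be
#'   present with at least two members each.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional integer seed.
#' @param sided "two" (|stat| as or more extreme), "greater" or "less"
#'   (one-sided).
#' @return List: `p`, `observed` statistic, `n_perm`.
#' @export
permutation_pvalue <- function(values, flags, n_perm = 10000, seed = NULL,
                               sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  stopifnot(is_count(n_perm))
  flags <- as.logical(flags)
  if (length(flags) != length(values)) stop("values/flags lengths differ")
  n1 <- sum(flags)
  if (n1 < 2 || sum(!flags) < 2)
    stop("both label classes must have at least two members")
  obs <- snr_statistic(values[flags], values[!flags])
  with_seed(seed, {
    n <- length(values)
    idx <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
    xm <- matrix(values[idx], n, n_perm)
    stat <- snr_columns(xm, n1)
    extreme <- switch(sided,
                      two = abs(stat) >= abs(obs),
                      greater = stat >= obs,
                      less = stat <= obs)
    list(p = (1 + sum(extreme)) / (1 + n_perm), observed = obs,
         n_perm = n_perm)
  })
}

#' Associate gene expression with copy-number status
#'
#' For each gene and direction (gain, loss) the samples are split into
#' aberrant and non-aberrant groups, the signal-to-noise statistic is
#' computed on expression, and a one-sided permutation p-value is taken in
#' the direction implied by the aberration (gain: up-regulation, loss:
#' down-regulation). A gene/direction is `selected` iff p < `alpha`, it is
#' aberrant in at least `min_samples` samples, and the statistic's sign
#' matches the direction. Benjamini-Hochberg FDR is computed across all
#' tested gene/direction pairs.
#'
#' @param gene_cna A [map_genes_to_calls()] table.
#' @param expression Genes x samples expression matrix (log2 units).
#' @param genes Optional gene ids to restrict to (e.g. genes in minimal
#'   common regions passing the CNV filter).
#' @param alpha Significance level for selection.
#' @param min_samples Minimum aberrant-sample count for selection (default
#'   3).
#' @param n_perm Permutations per gene.
#' @param seed Optional integer seed.
#' @param sided "directional" (default: one-sided per aberration direction)
#'   or "two".
#' @return data.frame: `gene_id`, `direction`, `n_cna`, `snr`, `p`, `fdr`,
#'   `selected`. Gene/direction pairs with fewer than two samples in either
#'   group carry `NA` statistics and are never selected.
#' @export
associate <- function(gene_cna, expression, genes = NULL, alpha = 0.05,
                      min_samples = 3, n_perm = 1000, seed = NULL,
                      sided = c("directional", "two")) {
  sided <- match.arg(sided)
  samples <- intersect(colnames(gene_cna$call), colnames(expression))
  if (length(samples) < 4) stop("need at least 4 shared samples")
  genes <- genes %||% rownames(gene_cna$call)
  genes <- intersect(intersect(genes, rownames(gene_cna$call)),
                     rownames(expression))
  calls <- gene_cna$call[genes, samples, drop = FALSE]
  expr <- expression[genes, samples, drop = FALSE]

  n_skipped <- 0L
  rows <- list()
  with_seed(seed, {
    for (g in genes) {
      cl <- calls[g, ]
      ok <- !is.na(cl)
      if (!any(ok)) { n_skipped <- n_skipped + 1L; next }
      for (dir in c("gain", "loss")) {
        flags <- ok & cl == dir
        n_cna <- sum(flags)
        if (n_cna == 0) next
        x <- expr[g, ok]
        f <- flags[ok]
        if (n_cna >= 2 && sum(!f) >= 2) {
          one_sided <- if (sided == "two") "two"
                       else if (dir == "gain") "greater" else "less"
          pv <- permutation_pvalue(x, f, n_perm = n_perm, seed = NULL,
                                   sided = one_sided)
          snr <- pv$observed
          p <- pv$p
        } else {
          snr <- NA_real_; p <- NA_real_
        }
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = g, direction = dir, n_cna = n_cna, snr = snr, p = p,
          stringsAsFactors = FALSE)
      }
    }
  })
  if (n_skipped > 0)
    message(n_skipped, " gene(s) skipped: copy-number status missing for ",
            "all samples")
  if (!length(rows))
    return(data.frame(gene_id = character(), direction = character(),
                      n_cna = integer(), snr = numeric(), p = numeric(),
                      fdr = numeric(), selected = logical()))
  res <- do.call(rbind, rows)
  res$fdr <- p.adjust(res$p, method = "BH")
  dirsign <- ifelse(res$direction == "gain", 1, -1)
  res$selected <- !is.na(res$p) & res$p < alpha &
    res$n_cna >= min_samples & sign(res$snr) == dirsign
  rownames(res) <- NULL
  res
}

#' Pearson concordance between two expression measurements
#'
#' Product-moment correlation with its t-distribution p-value, for checking
#' agreement between platforms (e.g. microarray vs qRT-PCR values of the
#' same gene).
#'
#' @param x,y Paired numeric vectors, length >= 3.
#' @return List: `r`, `p`, `n`.
#' @export
expression_concordance <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 3) stop("need at least 3 pairs")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
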