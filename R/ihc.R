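as_pixel_matrix <- function(image) {
  if (inherits(image, "ihc_field")) image <- image$image
  if (length(dim(image)) != 3 || dim(image)[3] < 3)
    stop("image must be a height x width x 3 RGB array")
  if (max(image, na.rm = TRUE) <= 1) image <- image * 255
  n <- dim(image)[1] * dim(image)[2]
  list(px = cbind(c(image[, , 1]), c(image[, , 2]), c(image[, , 3])),
       h = dim(image)[1], w = dim(image)[2])
}

#' Classify image pixels by nearest exemplar colour
#'
#' Assigns every pixel to the colour class (brown, blue, white, background)
#' of its nearest exemplar in Euclidean RGB distance. Ties are broken
#' deterministically by the fixed class order brown, blue, white,
#' background. The function is pixelwise, hence idempotent and invariant to
#' pixel permutation.
#'
#' @param image RGB array (height x width x 3, 0-255 or 0-1) or an
#'   `ihc_field` from [generate_ihc_image()].
#' @param palette Exemplar colours ([default_ihc_palette()] format).
#' @return Character matrix (height x width) of class labels.
#' @export
classify_pixels <- function(image, palette = default_ihc_palette()) {
  validate_palette(palette)
  pm <- as_pixel_matrix(image)
  ex <- do.call(rbind, palette[ihc_classes])
  cls <- rep(ihc_classes, vapply(palette[ihc_classes], nrow, integer(1)))
  ex2 <- rowSums(ex^2)
  n <- nrow(pm$px)
  lab <- character(n)
  chunk <- 200000L
  for (from in seq(1, n, by = chunk)) {
    to <- min(from + chunk - 1L, n)
    px <- pm$px[from:to, , drop = FALSE]
    # per-pixel constant rowSums(px^2) omitted: it does not move the argmin
    d2 <- -2 * (px %*% t(ex)) +
      matrix(ex2, nrow(px), length(ex2), byrow = TRUE)
    lab[from:to] <- cls[max.col(-d2, ties.method = "first")]
  }
  matrix(lab, pm$h, pm$w)
}

#' Staining coverage from a pixel class map
#'
#' Coverage is the brown (positively stained) pixel fraction. Under the
#' default denominator `"all"` every pixel counts; under `"tissue"` only
#' brown + blue + white pixels do (background excluded). Both conventions
#' are always reported.
#'
#' @param class_map Character matrix from [classify_pixels()].
#' @param denominator "all" (default) or "tissue".
#' @return List of class `coverage_result`: `counts` (named, sums to the
#'   pixel total), `coverage` (under the chosen denominator),
#'   `coverage_all`, `coverage_tissue`, `denominator`.
#' @export
staining_coverage <- function(class_map, denominator = c("all", "tissue")) {
  denominator <- match.arg(denominator)
  lab <- factor(c(class_map), levels = ihc_classes)
  if (any(is.na(lab))) stop("class map contains labels outside the 4 classes")
  counts <- table(lab)
  counts <- stats::setNames(as.integer(counts), names(counts))
  total <- sum(counts)
  tissue <- sum(counts[c("brown", "blue", "white")])
  cov_all <- counts[["brown"]] / total
  cov_tis <- if (tissue > 0) counts[["brown"]] / tissue else 0
  structure(list(counts = counts,
                 coverage = if (denominator == "all") cov_all else cov_tis,
                 coverage_all = cov_all, coverage_tissue = cov_tis,
                 denominator = denominator),
            class = "coverage_result")
}

#' Aggregate field coverages per patient
#'
#' The patient score is the arithmetic mean of the per-field coverages
#' (typically one to three high-power fields per patient; more fields are
#' accepted with a warning).
#'
#' @param coverage Numeric per-field coverage fractions.
#' @param patient_id Patient identifier per field.
#' @return data.frame: `patient_id`, `coverage` (mean), `n_fields`.
#' @export
aggregate_patient <- function(coverage, patient_id) {
  if (length(coverage) != length(patient_id)) stop("lengths differ")
  nf <- table(patient_id)
  if (any(nf > 3))
    warning("patient(s) with more than 3 fields: ",
            paste(names(nf)[nf > 3], collapse = ", "))
  agg <- tapply(coverage, patient_id, mean)
  data.frame(patient_id = names(agg), coverage = as.numeric(agg),
             n_fields = as.integer(nf[names(agg)]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Dichotomize patient coverages into high/low expression groups
#'
#' Either derives the cutoff from a ROC analysis of coverage against the
#' endpoint events ([roc_cutoff()], Youden criterion), or applies a fixed
#' externally derived cutoff (e.g. a training-cohort cutoff such as 0.089
#' applied to a validation cohort). Patients with coverage strictly above
#' the cutoff are labelled "high".
#'
#' @param coverage Numeric patient coverages.
#' @param events Binary endpoint events (required when `cutoff` is NULL).
#' @param cutoff Optional fixed cutoff; NULL derives it by ROC.
#' @return List: `labels` (factor low/high), `cutoff`, `cutoff_result`
#'   (NULL when a fixed cutoff was supplied).
#' @export
dichotomize <- function(coverage, events = NULL, cutoff = NULL) {
  cr <- NULL
  if (is.null(cutoff)) {
    if (is.null(events)) stop("supply events or a fixed cutoff")
    if (length(unique(coverage)) < 2)
      stop("all coverages are equal: no discriminative cutoff exists")
    cr <- roc_cutoff(coverage, events, name = "coverage")
    cutoff <- cr$cutoff
  }
  labels <- factor(ifelse(coverage > cutoff, "high", "low"),
                   levels = c("low", "high"))
  list(labels = labels, cutoff = cutoff, cutoff_result = cr)
}
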