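ihc_classes <- c("brown", "blue", "white", "background")

#' Default four-class IHC colour specification
#'
#' Fifteen exemplar RGB colours for each of the four expected colour
#' populations of a hematoxylin-counterstained DAB brightfield field: brown
#' (specific staining), blue (counterstained nuclei), white (lumen/empty
#' tissue) and background (faint unspecific brown/blue). Exemplars are a
#' deterministic lattice around a class base colour.
#'
#' @return Named list of 15 x 3 integer matrices (`brown`, `blue`, `white`,
#'   `background`), 8-bit RGB.
#' @export
default_ihc_palette <- function() {
  mk <- function(base, spread) {
    off <- as.matrix(expand.grid(r = c(-1, 0, 1), g = c(-1, 0, 1),
                                 b = c(-1, 0, 1))) * spread
    off <- off[round(seq(1, 27, length.out = 15)), , drop = FALSE]
    m <- sweep(off, 2, base, "+")
    m <- pmin(pmax(round(m), 0), 255)
    dimnames(m) <- list(NULL, c("r", "g", "b"))
    m
  }
  list(brown = mk(c(130, 75, 45), 12),
       blue = mk(c(70, 85, 160), 12),
       white = mk(c(238, 238, 242), 4),
       background = mk(c(195, 185, 168), 8))
}

validate_palette <- function(palette) {
  if (!all(ihc_classes %in% names(palette)))
    stop("palette must contain classes: ", paste(ihc_classes, collapse = ", "))
  for (cl in ihc_classes) {
    m <- palette[[cl]]
    if (is.null(dim(m)) || ncol(m) != 3 || nrow(m) < 1)
      stop("palette class '", cl, "' must be a non-empty n x 3 RGB matrix")
    if (any(m < 0) || any(m > 255) || any(is.na(m)))
      stop("palette class '", cl, "' has invalid 8-bit RGB values")
  }
  invisible(palette)
}

# smallest Euclidean RGB distance between exemplars of different classes
min_interclass_distance <- function(palette) {
  ex <- do.call(rbind, palette[ihc_classes])
  cl <- rep(seq_along(ihc_classes),
            vapply(palette[ihc_classes], nrow, integer(1)))
  d <- as.matrix(dist(ex))
  d[outer(cl, cl, "==")] <- Inf
  min(d)
}

#' Generate a synthetic IHC field image with known class composition
#'
#' Composes an RGB raster from the four staining colour classes at exact
#' pixel fractions (largest-remainder apportionment), drawing each pixel from
#' a random exemplar of its class, optionally perturbed by Gaussian RGB
#' jitter. The true per-pixel class map and the true brown coverage are
#' retained for recovery tests.
#'
#' @param width,height Image size in pixels.
#' @param class_fractions Numeric length-4 vector (brown, blue, white,
#'   background) summing to 1 within 1e-9.
#' @param palette Exemplar colours, as from [default_ihc_palette()].
#' @param jitter_sd SD of Gaussian jitter added per RGB channel (8-bit
#'   units); a warning is issued if the jitter is large relative to the
#'   separation between class palettes.
#' @param seed Optional integer seed.
#'
#' @return List of class `ihc_field`: `image` (height x width x 3 integer
#'   array, 0-255), `class_map` (height x width factor matrix, the truth),
#'   `true_coverage` (true brown fraction of all pixels) and `composition`
#'   (named pixel counts).
#' @export
generate_ihc_image <- function(width, height, class_fractions,
                               palette = default_ihc_palette(),
                               jitter_sd = 0, seed = NULL) {
  stopifnot(is_count(width), is_count(height))
  if (length(class_fractions) != 4 || any(class_fractions < 0))
    stop("class_fractions must be 4 non-negative fractions")
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("class_fractions must sum to 1")
  validate_palette(palette)
  if (jitter_sd > 0 && min_interclass_distance(palette) < 4 * jitter_sd)
    warning("jitter_sd is large relative to palette separation; ",
            "classes may cross boundaries")

  n <- width * height
  ## largest-remainder apportionment: exact counts for exact fractions
  raw <- class_fractions * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    take <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[take] <- cnt[take] + 1
  }
  cnt <- as.integer(cnt)
  names(cnt) <- ihc_classes

  with_seed(seed, {
    lab <- factor(rep(ihc_classes, cnt), levels = ihc_classes)
    lab <- lab[sample.int(n)]
    px <- matrix(0, n, 3)
    for (cl in ihc_classes) {
      sel <- which(lab == cl)
      if (!length(sel)) next
      ex <- palette[[cl]]
      px[sel, ] <- ex[sample.int(nrow(ex), length(sel), replace = TRUE), ,
                      drop = FALSE]
    }
    if (jitter_sd > 0)
      px <- px + matrix(rnorm(3 * n, 0, jitter_sd), n, 3)
    px <- pmin(pmax(round(px), 0), 255)
    img <- array(0L, dim = c(height, width, 3))
    img[, , 1] <- as.integer(px[, 1])
    img[, , 2] <- as.integer(px[, 2])
    img[, , 3] <- as.integer(px[, 3])
    out <- list(image = img,
                class_map = matrix(as.character(lab), height, width),
                true_coverage = unname(cnt["brown"] / n),
                composition = cnt)
    class(out) <- "ihc_field"
    out
  })
}
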