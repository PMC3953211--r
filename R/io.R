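#' Write segment calls in SEG format
#'
#' Tab-delimited SEG (IGV dialect): Sample, Chromosome, Start, End,
#' Num_Probes, Seg.Mean, Call, with 1-based inclusive coordinates (internal
#' coordinates are 0-based half-open).
#'
#' @param segments Segment data.frame from [segment_profiles()] /
#'   [call_aberrations()].
#' @param path Output file.
#' @export
write_seg <- function(segments, path) {
  out <- data.frame(Sample = segments$sample_id,
                    Chromosome = segments$chrom,
                    Start = segments$start + 1,
                    End = segments$end,
                    Num_Probes = segments$n_probes,
                    Seg.Mean = segments$seg_mean,
                    Call = segments$call)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SEG file written by [write_seg()]
#'
#' @param path SEG file path.
#' @return Segment data.frame with internal 0-based half-open coordinates.
#' @export
read_seg <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  data.frame(sample_id = x$Sample, chrom = x$Chromosome,
             start = x$Start - 1, end = x$End,
             n_probes = x$Num_Probes, seg_mean = x$Seg.Mean,
             call = if ("Call" %in% names(x)) x$Call else "neutral",
             stringsAsFactors = FALSE)
}

#' Read a BED-like annotation or CNV catalogue
#'
#' Expects at least chrom/start/end in the first three columns (0-based
#' half-open, as BED); a fourth column is taken as the gene id.
#'
#' @param path File path.
#' @return data.frame with `chrom`, `start`, `end` and, if present,
#'   `gene_id`.
#' @export
read_bed <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  comment.char = "#")
  out <- data.frame(chrom = x[[1]], start = x[[2]], end = x[[3]],
                    stringsAsFactors = FALSE)
  if (ncol(x) >= 4) out$gene_id <- x[[4]]
  out
}

write_bed <- function(df, path, name_col = NULL) {
  cols <- df[, c("chrom", "start", "end"), drop = FALSE]
  if (!is.null(name_col)) cols$name <- df[[name_col]]
  write.table(cols, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Writes `probes.tsv`, `expression.tsv`, `clinical.tsv`, `genes.bed`
#' (4th column = gene id), `cnv_catalogue.bed`, `truth.json`, and one PNG
#' per requested IHC field.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(cohort$probes, file.path(dir, "probes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expr <- data.frame(gene_id = rownames(cohort$expression),
                     cohort$expression, check.names = FALSE)
  write.table(expr, file.path(dir, "expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$clinical, file.path(dir, "clinical.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_bed(cohort$annotation, file.path(dir, "genes.bed"),
            name_col = "gene_id")
  write_bed(cohort$cnv_catalogue, file.path(dir, "cnv_catalogue.bed"))
  truth <- cohort$truth
  truth$carrier_map <- as.data.frame(truth$carrier_map)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a probe matrix TSV
#'
#' @param path File with columns probe_id, chrom, start, end and one numeric
#'   column per sample.
#' @return Probe data.frame.
#' @export
read_probe_matrix <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot_cols(x, c("probe_id", "chrom", "start", "end"), "probe matrix")
  x
}

#' Read an expression TSV into a genes x samples matrix
#'
#' @param path File with a `gene_id` column plus one column per sample.
#' @return Numeric matrix with gene ids as rownames.
#' @export
read_expression_matrix <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot_cols(x, "gene_id", "expression matrix")
  m <- as.matrix(x[, setdiff(names(x), "gene_id"), drop = FALSE])
  rownames(m) <- x$gene_id
  m
}

#' Write an IHC field image as PNG
#'
#' @param image RGB array (0-255 integers or 0-1 doubles) or `ihc_field`.
#' @param path Output PNG path.
#' @export
write_ihc_png <- function(image, path) {
  if (inherits(image, "ihc_field")) image <- image$image
  if (max(image) > 1) image <- image / 255
  png::writePNG(image, path)
  invisible(path)
}

#' Read an IHC field image from PNG
#'
#' @param path PNG path.
#' @return RGB array with 0-255 values.
#' @export
read_ihc_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3 && dim(img)[3] == 4)
    img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' Read a colour palette JSON (class name -> list of RGB triplets)
#'
#' @param path JSON path.
#' @return Palette list of RGB matrices.
#' @export
read_palette <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pal <- lapply(raw, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  validate_palette(pal)
  pal
}

#' Write a colour palette JSON
#'
#' @param palette Palette list ([default_ihc_palette()] format).
#' @param path JSON path.
#' @export
write_palette <- function(palette, path) {
  validate_palette(palette)
  jsonlite::write_json(lapply(palette, function(m) unname(as.matrix(m))),
                       path, digits = NA)
  invisible(path)
}
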