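#' Construct a spatial transcriptomics spot dataset
#'
#' The universal input record for the package: a spots-by-genes count matrix
#' together with spot spatial coordinates, optional image-pixel coordinates
#' (with a registered image), and an optional per-spot batch label.
#'
#' @param counts non-negative integer matrix, spots in rows, genes in columns.
#'   A sparse \code{Matrix} is accepted and kept sparse.
#' @param coords numeric matrix of spot coordinates, spots x d with d in
#'   \{2, 3\}, in platform length units (array units for Visium). Geometry
#'   (neighbour radius, kNN graph) always uses these, never pixel coordinates.
#' @param spot_ids,gene_ids unique character vectors naming rows/columns.
#'   Default: taken from \code{dimnames(counts)}.
#' @param pixel_coords optional spots x 2 numeric matrix of image pixel
#'   coordinates; requires \code{image}.
#' @param batch optional per-spot batch label (coerced to factor).
#' @param platform one of \code{"generic"} or \code{"visium"}.
#' @param image optional image array (H x W or H x W x channels, values in
#'   [0,1]) registered to \code{pixel_coords}.
#'
#' @return an object of class \code{spot_dataset}.
#' @export
spot_dataset <- function(counts, coords, spot_ids = rownames(counts),
                         gene_ids = colnames(counts), pixel_coords = NULL,
                         batch = NULL, platform = c("generic", "visium"),
                         image = NULL) {
  platform <- match.arg(platform)
  if (is.null(spot_ids)) spot_ids <- paste0("spot_", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(counts)))
  spot_ids <- as.character(spot_ids)
  gene_ids <- as.character(gene_ids)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(counts) != nrow(coords) || nrow(counts) != length(spot_ids))
    stop("counts, coords and spot_ids disagree on the number of spots (",
         nrow(counts), ", ", nrow(coords), ", ", length(spot_ids), ")")
  if (length(gene_ids) != ncol(counts))
    stop("gene_ids length does not match the number of genes")
  if (anyDuplicated(spot_ids)) stop("duplicate spot ids")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (!ncol(coords) %in% c(2L, 3L))
    stop("coords must have 2 or 3 columns, got ", ncol(coords))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(pixel_coords)) {
    pixel_coords <- as.matrix(pixel_coords)
    if (nrow(pixel_coords) != length(spot_ids) || ncol(pixel_coords) != 2L)
      stop("pixel_coords must be spots x 2")
    if (is.null(image))
      stop("pixel_coords require a registered image")
  }
  if (!is.null(batch)) {
    if (length(batch) != length(spot_ids))
      stop("batch must have one label per spot")
    batch <- factor(batch)
  }
  rownames(counts) <- spot_ids
  colnames(counts) <- gene_ids
  rownames(coords) <- spot_ids
  structure(list(counts = counts, coords = coords, spot_ids = spot_ids,
                 gene_ids = gene_ids, pixel_coords = pixel_coords,
                 batch = batch, platform = platform, image = image),
            class = "spot_dataset")
}

#' @export
print.spot_dataset <- function(x, ...) {
  cat(sprintf("spot_dataset: %d spots x %d genes (%s, %dD coordinates)\n",
              length(x$spot_ids), length(x$gene_ids), x$platform,
              ncol(x$coords)))
  if (!is.null(x$image)) cat("  image registered;",
                             if (!is.null(x$pixel_coords)) "pixel coordinates present\n"
                             else "no pixel coordinates\n")
  if (!is.null(x$batch))
    cat("  batches:", paste(levels(x$batch), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spot_dataset <- function(x) c(length(x$spot_ids), length(x$gene_ids))

# internal: counts as a base dense matrix
dense_counts <- function(dataset) {
  m <- dataset$counts
  if (inherits(m, "Matrix")) m <- as.matrix(m)
  storage.mode(m) <- "double"
  m
}
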