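#' Read a Visium-style dataset directory
#'
#' Expects the 10x layout: \code{matrix.mtx(.gz)} + \code{barcodes.tsv(.gz)} +
#' \code{features.tsv(.gz)} (or a dense \code{counts.csv} with spots in rows),
#' a tissue position table (\code{tissue_positions.csv} with header, or the
#' older header-less \code{tissue_positions_list.csv}), and optionally a
#' tissue image (\code{*.png}/\code{*.tif{,f}}/\code{*.jpg}) with
#' \code{scalefactors_json.json}. MTX matrices stored genes x spots (the 10x
#' convention) are transposed to spots x genes on load. Spots flagged
#' out-of-tissue in the position table are dropped. Spot order follows the
#' position table restricted to barcodes present in the matrix.
#'
#' Spatial geometry uses the array row/column coordinates; pixel coordinates
#' are retained separately for image tile extraction.
#'
#' @param dir_path directory containing the dataset.
#' @return a [spot_dataset] with \code{platform = "visium"}.
#' @export
read_visium <- function(dir_path) {
  if (!dir.exists(dir_path)) stop("input error: no such directory: ", dir_path)
  find1 <- function(patterns) {
    for (p in patterns) {
      hit <- list.files(dir_path, pattern = p, full.names = TRUE,
                        recursive = TRUE)
      if (length(hit)) return(hit[[1L]])
    }
    NULL
  }
  mtx <- find1(c("^matrix\\.mtx$", "^matrix\\.mtx\\.gz$"))
  csv <- find1("^counts\\.csv$")
  pos <- find1(c("^tissue_positions\\.csv$", "^tissue_positions_list\\.csv$"))
  if (is.null(pos))
    stop("input error: missing tissue position table (tissue_positions.csv)")

  if (!is.null(mtx)) {
    bar <- find1(c("^barcodes\\.tsv$", "^barcodes\\.tsv\\.gz$"))
    fea <- find1(c("^features\\.tsv$", "^features\\.tsv\\.gz$",
                   "^genes\\.tsv$", "^genes\\.tsv\\.gz$"))
    if (is.null(bar)) stop("input error: missing barcodes.tsv")
    if (is.null(fea)) stop("input error: missing features.tsv")
    m <- Matrix::readMM(mtx)
    barcodes <- readLines(bar)
    feat <- utils::read.delim(fea, header = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(feat[[1L]])
    # 10x stores genes x spots; transpose so spots are rows
    transposed <- FALSE
    if (nrow(m) == length(genes) && ncol(m) == length(barcodes)) {
      m <- Matrix::t(m)
      transposed <- TRUE
    } else if (!(nrow(m) == length(barcodes) && ncol(m) == length(genes))) {
      stop("consistency error: matrix dimensions match neither barcodes x ",
           "features nor features x barcodes")
    }
    counts <- methods::as(m, "CsparseMatrix")
    rownames(counts) <- barcodes
    colnames(counts) <- genes
  } else if (!is.null(csv)) {
    tab <- utils::read.csv(csv, row.names = 1, check.names = FALSE)
    counts <- as.matrix(tab)
    transposed <- FALSE
  } else {
    stop("input error: missing count matrix (matrix.mtx or counts.csv)")
  }

  ptab <- read_positions(pos)
  missing_bc <- setdiff(ptab$barcode, rownames(counts))
  extra_bc <- setdiff(rownames(counts), ptab$barcode)
  if (length(missing_bc) && length(missing_bc) == nrow(ptab))
    stop("consistency error: no barcode overlap between matrix and positions; ",
         "examples: ", paste(utils::head(missing_bc, 3), collapse = ", "))
  if (length(extra_bc))
    stop("consistency error: barcodes in matrix absent from positions: ",
         paste(utils::head(extra_bc, 5), collapse = ", "))
  ptab <- ptab[ptab$barcode %in% rownames(counts), , drop = FALSE]
  ptab <- ptab[ptab$in_tissue == 1, , drop = FALSE]  # in-tissue filter
  counts <- counts[ptab$barcode, , drop = FALSE]

  img <- NULL
  pix <- NULL
  img_file <- find1(c("\\.png$", "\\.tiff?$"))
  if (!is.null(img_file)) {
    img <- read_image(img_file)
    pix <- cbind(ptab$pxl_col, ptab$pxl_row)
    rownames(pix) <- ptab$barcode
  }
  ds <- spot_dataset(counts,
                     coords = cbind(ptab$array_row, ptab$array_col),
                     spot_ids = ptab$barcode,
                     pixel_coords = pix, platform = "visium", image = img)
  attr(ds, "mtx_transposed") <- if (!is.null(mtx)) transposed else NA
  sf <- find1("^scalefactors_json\\.json$")
  if (!is.null(sf)) attr(ds, "scalefactors") <- jsonlite::read_json(sf)
  ds
}

# internal: both tissue position dialects -> data.frame(barcode, in_tissue,
# array_row, array_col, pxl_row, pxl_col)
read_positions <- function(path) {
  head1 <- readLines(path, n = 1L)
  has_header <- grepl("barcode", head1, ignore.case = TRUE)
  tab <- utils::read.csv(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(tab) < 6L) stop("input error: position table needs 6 columns")
  names(tab) <- c("barcode", "in_tissue", "array_row", "array_col",
                  "pxl_row", "pxl_col")
  for (j in 3:6) {
    v <- suppressWarnings(as.numeric(tab[[j]]))
    if (anyNA(v))
      stop("parse error: non-numeric coordinate in position table, row ",
           which(is.na(v))[1L])
    tab[[j]] <- v
  }
  tab
}

# internal: PNG/TIFF loader (array in [0,1], H x W x channels)
read_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG images requires the 'png' package")
    img <- png::readPNG(path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF images requires the 'tiff' package")
    img <- tiff::readTIFF(path)
  } else {
    stop("unsupported image format: ", path)
  }
  if (length(dim(img)) == 2L) img <- array(img, dim = c(dim(img), 1L))
  img
}

#' Read a generic counts + coordinates table pair
#'
#' Covers Stereo-seq / Slide-seq / MERFISH / 4i / MIBI-TOF style inputs: a
#' spots x features count table and a coordinate table with 2 or 3 numeric
#' columns, both keyed by spot id (first column or row names). 3D coordinates
#' are preserved as-is so consecutive imaging layers keep their z.
#'
#' @param counts_path CSV/TSV of counts, spots in rows, ids in first column
#'   or as row names.
#' @param coords_path CSV/TSV of coordinates keyed by spot id.
#' @param batch_col optional name of a batch-label column in the coordinate
#'   table.
#' @return a [spot_dataset] with \code{platform = "generic"}.
#' @export
read_generic <- function(counts_path, coords_path, batch_col = NULL) {
  for (p in c(counts_path, coords_path))
    if (!file.exists(p)) stop("input error: no such file: ", p)
  counts <- read_table_auto(counts_path)
  ctab <- read_table_auto(coords_path)
  batch <- NULL
  if (!is.null(batch_col)) {
    if (!batch_col %in% colnames(ctab))
      stop("input error: batch column '", batch_col, "' not in coords table")
    batch <- ctab[, batch_col]
    ctab <- ctab[, setdiff(colnames(ctab), batch_col), drop = FALSE]
  }
  if (!ncol(ctab) %in% c(2L, 3L))
    stop("input error: coordinate table must have 2 or 3 coordinate columns")
  coords <- matrix(NA_real_, nrow(ctab), ncol(ctab),
                   dimnames = list(rownames(ctab), colnames(ctab)))
  for (j in seq_len(ncol(ctab))) {
    v <- suppressWarnings(as.numeric(ctab[[j]]))
    if (anyNA(v))
      stop("parse error: non-numeric coordinate at row ",
           which(is.na(v))[1L], ", column ", colnames(ctab)[j])
    coords[, j] <- v
  }
  if (!setequal(rownames(counts), rownames(coords)))
    stop("consistency error: spot id sets differ between counts and ",
         "coordinates; e.g. ",
         paste(utils::head(c(setdiff(rownames(counts), rownames(coords)),
                             setdiff(rownames(coords), rownames(counts))), 3),
               collapse = ", "))
  coords <- coords[rownames(counts), , drop = FALSE]
  if (!is.null(batch)) names(batch) <- rownames(ctab)
  spot_dataset(as.matrix(counts), coords,
               batch = if (is.null(batch)) NULL else batch[rownames(counts)],
               platform = "generic")
}

# internal: delimiter-sniffing table reader returning a data.frame with
# spot ids as row names
read_table_auto <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  tab
}

#' Write a dataset as a Visium-style directory
#'
#' Writes \code{matrix.mtx}, \code{barcodes.tsv}, \code{features.tsv} and a
#' \code{tissue_positions.csv}, plus the image as PNG when present. The matrix
#' is stored genes x spots, following the 10x convention.
#'
#' @param dataset a [spot_dataset].
#' @param dir_path output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_visium <- function(dataset, dir_path) {
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  m <- methods::as(Matrix::t(Matrix::Matrix(dataset$counts, sparse = TRUE)),
                   "CsparseMatrix")
  paths <- file.path(dir_path, c("matrix.mtx", "barcodes.tsv", "features.tsv",
                                 "tissue_positions.csv"))
  Matrix::writeMM(m, paths[1L])
  writeLines(dataset$spot_ids, paths[2L])
  utils::write.table(data.frame(id = dataset$gene_ids,
                                name = dataset$gene_ids,
                                type = "Gene Expression"),
                     paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  pix <- dataset$pixel_coords
  if (is.null(pix)) pix <- matrix(0, nrow(dataset$coords), 2L)
  utils::write.table(
    data.frame(barcode = dataset$spot_ids, in_tissue = 1L,
               array_row = dataset$coords[, 1L],
               array_col = dataset$coords[, 2L],
               pxl_row_in_fullres = pix[, 2L],
               pxl_col_in_fullres = pix[, 1L]),
    paths[4L], sep = ",", quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$image) && requireNamespace("png", quietly = TRUE)) {
    ipath <- file.path(dir_path, "tissue_image.png")
    img <- dataset$image
    if (dim(img)[3L] == 1L) img <- img[, , 1L]
    png::writePNG(img, ipath)
    paths <- c(paths, ipath)
  }
  invisible(paths)
}

#' Write embeddings, domain labels and the resolved run configuration
#'
#' @param dataset the input [spot_dataset].
#' @param embedding a \code{latent_embedding} (or any spots x d matrix in its
#'   \code{z_joint} slot).
#' @param domains a \code{domain_assignment}.
#' @param out_dir output directory.
#' @param config optional named list of resolved run parameters (seed,
#'   resolution, weight modes, ...) serialized as JSON alongside the results.
#' @return character vector of written paths (the manifest).
#' @export
write_outputs <- function(dataset, embedding, domains, out_dir,
                          config = list()) {
  z <- embedding$z_joint
  labels <- domains$labels
  n <- length(dataset$spot_ids)
  if (nrow(z) != n || length(labels) != n)
    stop("consistency error: embedding/domains not row-aligned with dataset (",
         nrow(z), ", ", length(labels), " vs ", n, " spots)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, c("embedding.csv", "domains.csv",
                                "run_config.json"))
  emb <- data.frame(spot_id = dataset$spot_ids, z, check.names = FALSE)
  utils::write.csv(emb, paths[1L], row.names = FALSE)
  utils::write.csv(data.frame(spot_id = dataset$spot_ids,
                              domain = as.integer(labels)),
                   paths[2L], row.names = FALSE)
  config$resolution <- domains$resolution
  config$n_domains <- domains$n_domains
  config$mode <- domains$mode
  config$package_version <- as.character(utils::packageVersion("spadom"))
  jsonlite::write_json(config, paths[3L], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths
}
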