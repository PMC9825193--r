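#' Extract square image tiles centered on spot pixel coordinates
#'
#' Cuts one \code{tile_size_px} x \code{tile_size_px} tile per spot from the
#' registered image, centered on the spot's pixel coordinate. Tiles crossing
#' the image border are padded by reflection. Tile order equals spot order.
#'
#' @param dataset a [spot_dataset] with \code{pixel_coords} and an image.
#' @param tile_size_px side length in pixels; default is the spot diameter
#'   from the Visium scale factors rounded up to an even integer, falling
#'   back to 64.
#' @return array spots x tile x tile x channels.
#' @export
extract_tiles <- function(dataset, tile_size_px = NULL) {
  if (is.null(dataset$pixel_coords) || is.null(dataset$image))
    stop("dataset has no registered image / pixel coordinates")
  img <- dataset$image
  if (is.null(tile_size_px)) {
    sf <- attr(dataset, "scalefactors")
    tile_size_px <- if (!is.null(sf$spot_diameter_fullres))
      2L * ceiling(sf$spot_diameter_fullres / 2) else 64L
  }
  ts <- as.integer(tile_size_px)
  h <- dim(img)[1L]; w <- dim(img)[2L]; ch <- dim(img)[3L]
  n <- nrow(dataset$pixel_coords)
  half <- ts %/% 2L
  tiles <- array(0, dim = c(n, ts, ts, ch))
  reflect <- function(idx, m) {
    # reflect out-of-range indices back into 1..m
    idx <- abs(idx - 1L) %% (2L * m - 2L)
    ifelse(idx >= m, 2L * m - 2L - idx, idx) + 1L
  }
  for (i in seq_len(n)) {
    cx <- round(dataset$pixel_coords[i, 1L])  # column (x)
    cy <- round(dataset$pixel_coords[i, 2L])  # row (y)
    if (cx < 1 - ts || cx > w + ts || cy < 1 - ts || cy > h + ts)
      stop("geometry error: spot '", dataset$spot_ids[i],
           "' lies outside the image by more than one tile")
    rows <- reflect(seq.int(cy - half, length.out = ts), h)
    cols <- reflect(seq.int(cx - half, length.out = ts), w)
    tiles[i, , , ] <- img[rows, cols, , drop = FALSE]
  }
  attr(tiles, "tile_size_px") <- ts
  tiles
}

#' Deterministic channel-statistics tile extractor
#'
#' A hand-coded feature extractor used as the default when no pretrained
#' convolutional network is available: per channel, an intensity histogram
#' plus moments and quadrant means, tiled/truncated to \code{out_dim}
#' dimensions. Deterministic and dependency-free; intended for testing the
#' morphology pathway and for synthetic images whose colour encodes domain
#' identity.
#'
#' @param out_dim output feature length (default 2048, matching the width of
#'   common pretrained CNN feature layers).
#' @return a function mapping one tile (H x W x C) to a numeric vector of
#'   length \code{out_dim}.
#' @export
channel_stats_extractor <- function(out_dim = 2048) {
  force(out_dim)
  f <- function(tile) {
    ch <- dim(tile)[3L]
    h <- dim(tile)[1L]; w <- dim(tile)[2L]
    feats <- unlist(lapply(seq_len(ch), function(c3) {
      v <- as.vector(tile[, , c3])
      hs <- graphics::hist(v, breaks = seq(0, 1, length.out = 17),
                           plot = FALSE)$density / 16
      q <- c(mean(tile[seq_len(h %/% 2), seq_len(w %/% 2), c3]),
             mean(tile[seq_len(h %/% 2), (w %/% 2 + 1):w, c3]),
             mean(tile[(h %/% 2 + 1):h, seq_len(w %/% 2), c3]),
             mean(tile[(h %/% 2 + 1):h, (w %/% 2 + 1):w, c3]))
      c(mean(v), stats::sd(v), stats::quantile(v, c(.25, .5, .75),
                                               names = FALSE), hs, q)
    }))
    rep_len(feats, out_dim)
  }
  attr(f, "name") <- "channel_stats"
  attr(f, "out_dim") <- out_dim
  f
}

#' Compute per-spot morphology features from image tiles
#'
#' Applies a pluggable feature extractor to every tile (optionally averaging
#' the extractor output over rotated views) and reduces the raw feature
#' matrix to its leading principal components.
#'
#' @param tiles tile stack from [extract_tiles()].
#' @param extractor a function tile -> fixed-length numeric vector; default
#'   [channel_stats_extractor()].
#' @param n_components number of morphology PCs to keep (default 50).
#' @param augment_views average features over the 4 right-angle rotations of
#'   each tile (default FALSE).
#' @param seed reserved for stochastic extractors; the default pipeline is
#'   deterministic.
#' @return a \code{morphology_features} list: \code{raw_features} (spots x F),
#'   \code{reduced} (spots x min(n_components, spots, F)),
#'   \code{extractor_name}, \code{tile_size_px}.
#' @export
featurize <- function(tiles, extractor = channel_stats_extractor(),
                      n_components = 50, augment_views = FALSE, seed = 0L) {
  n <- dim(tiles)[1L]
  one <- function(i) {
    tile <- tiles[i, , , , drop = TRUE]
    if (length(dim(tile)) == 2L) tile <- array(tile, c(dim(tile), 1L))
    if (!augment_views) return(extractor(tile))
    views <- list(tile,
                  aperm(tile[, rev(seq_len(dim(tile)[2L])), , drop = FALSE],
                        c(2L, 1L, 3L)),                       # 90 deg
                  tile[rev(seq_len(dim(tile)[1L])),
                       rev(seq_len(dim(tile)[2L])), , drop = FALSE],  # 180
                  aperm(tile[rev(seq_len(dim(tile)[1L])), , , drop = FALSE],
                        c(2L, 1L, 3L)))                       # 270 deg
    rowMeans(vapply(views, extractor, extractor(tile)))
  }
  first <- one(1L)
  raw <- matrix(NA_real_, n, length(first))
  raw[1L, ] <- first
  if (n > 1L) for (i in 2L:n) {
    v <- one(i)
    if (length(v) != ncol(raw))
      stop("contract error: extractor output length varies across tiles (",
           length(v), " vs ", ncol(raw), ")")
    raw[i, ] <- v
  }
  k <- min(n_components, dim(raw))
  red <- pca_fit(raw, k)$scores
  structure(list(raw_features = raw, reduced = red,
                 extractor_name = attr(extractor, "name") %||% "custom",
                 tile_size_px = attr(tiles, "tile_size_px")),
            class = "morphology_features")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise morphological similarity weights
#'
#' Cosine of the reduced morphology feature vectors for each spot pair.
#' Default \code{"similarity"} mode clips the cosine to [0, 1];
#' \code{"paper_literal"} returns the cosine distance \code{1 - cos} in
#' [0, 2]. Zero-norm feature vectors get weight 0 with a warning.
#'
#' @param features a \code{morphology_features} object (or a plain spots x P
#'   matrix used as the reduced features).
#' @param pairs two-column integer matrix of spot index pairs.
#' @param mode \code{"similarity"} (default) or \code{"paper_literal"}.
#' @return numeric vector, one weight per pair.
#' @export
morph_similarity <- function(features, pairs,
                             mode = c("similarity", "paper_literal")) {
  mode <- match.arg(mode)
  s <- if (inherits(features, "morphology_features")) features$reduced
       else as.matrix(features)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  nrm <- sqrt(rowSums(s^2))
  zero <- nrm == 0
  if (any(zero[unique(as.vector(pairs))]))
    warning("zero-norm morphology feature vector; weight set to 0")
  nrm[zero] <- 1
  cs <- rowSums(s[pairs[, 1L], , drop = FALSE] *
                s[pairs[, 2L], , drop = FALSE]) /
        (nrm[pairs[, 1L]] * nrm[pairs[, 2L]])
  cs[zero[pairs[, 1L]] | zero[pairs[, 2L]]] <- if (mode == "similarity") 0 else 1
  unname(if (mode == "similarity") pmin(pmax(cs, 0), 1) else 1 - cs)
}
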