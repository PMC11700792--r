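## neighbor offsets, clockwise from top-left; first = most significant bit
LBP_OFFSETS <- cbind(dr = c(-1, -1, -1, 0, 1, 1, 1, 0),
                     dc = c(-1, 0, 1, 1, 1, 0, -1, -1))

#' Local binary pattern code of one 3x3 neighborhood
#'
#' Each of the 8 neighbors contributes a bit: 1 if its intensity is
#' strictly greater than the centre, 0 otherwise (ties count as 0).
#' Neighbors are read clockwise from the top-left corner, first neighbor in
#' the most significant bit, so the code is `sum(b_i * 2^(7-i))`.
#'
#' @param neighborhood a 3x3 numeric matrix.
#' @return integer code in \[0, 255\].
#' @export
lbp_code <- function(neighborhood) {
  if (!is.matrix(neighborhood) || any(dim(neighborhood) != c(3L, 3L))) {
    stopf("neighborhood must be a 3x3 matrix")
  }
  if (anyNA(neighborhood) || any(!is.finite(neighborhood))) {
    stopf("neighborhood contains non-finite intensities")
  }
  center <- neighborhood[2, 2]
  nb <- neighborhood[cbind(2 + LBP_OFFSETS[, "dr"], 2 + LBP_OFFSETS[, "dc"])]
  sum(as.integer(nb > center) * 2L^(7:0))
}

#' LBP code image
#'
#' Computes the LBP code at every pixel with a complete 3x3 neighborhood
#' inside the selected region; border pixels are skipped, not padded. The
#' region is the ROI bounding box when `roi` is given, non-empty and at
#' least 3x3 (otherwise the whole image is used) — so nodule-free images,
#' whose segmentation comes back empty, still yield a descriptor.
#'
#' @param image numeric matrix, at least 3x3.
#' @param roi optional `roi_mask` from [extract_roi()].
#' @return integer matrix of codes in \[0, 255\], two rows/columns smaller
#'   than the region.
#' @export
lbp_image <- function(image, roi = NULL) {
  if (!is.matrix(image) || anyNA(image) || any(!is.finite(image))) {
    stopf("image must be a finite numeric matrix")
  }
  if (nrow(image) < 3L || ncol(image) < 3L) {
    stopf("image must be at least 3x3, got %dx%d", nrow(image), ncol(image))
  }
  reg <- image
  if (!is.null(roi) && inherits(roi, "roi_mask") && !roi$empty) {
    bb <- roi$bounding_box
    if ((bb["row_max"] - bb["row_min"] >= 2) && (bb["col_max"] - bb["col_min"] >= 2)) {
      reg <- image[bb["row_min"]:bb["row_max"], bb["col_min"]:bb["col_max"], drop = FALSE]
    }
  }
  nr <- nrow(reg); nc <- ncol(reg)
  center <- reg[2:(nr - 1), 2:(nc - 1), drop = FALSE]
  codes <- matrix(0L, nr - 2L, nc - 2L)
  for (i in seq_len(8L)) {
    dr <- LBP_OFFSETS[i, "dr"]; dc <- LBP_OFFSETS[i, "dc"]
    nb <- reg[(2 + dr):(nr - 1 + dr), (2 + dc):(nc - 1 + dc), drop = FALSE]
    codes <- codes + (nb > center) * 2L^(8L - i)
  }
  storage.mode(codes) <- "integer"
  codes
}

#' LBP code histogram (the texture feature vector)
#'
#' @param codes integer code matrix from [lbp_image()].
#' @param normalize divide by the number of coded pixels so the 256 bins sum
#'   to 1 (the classifier's input); raw counts otherwise.
#' @return numeric vector of length 256 (bin k holds code k-1).
#' @export
lbp_histogram <- function(codes, normalize = TRUE) {
  if (length(codes) == 0L) stopf("empty code image")
  v <- as.integer(codes)
  if (anyNA(v) || any(v < 0L | v > 255L)) stopf("codes must be integers in [0, 255]")
  h <- tabulate(v + 1L, nbins = 256L)
  if (normalize) h / sum(h) else h
}

#' LBP features for a list of samples
#'
#' Runs enhancement, segmentation and LBP extraction per sample and stacks
#' the 256-bin normalized histograms into a feature matrix. Segmentation is
#' computed on the raw image, whose intensity strata are calibrated;
#' texture is then read from the contrast-enhanced image inside the ROI
#' bounding box (adaptive equalization redistributes grey levels per tile,
#' which would blur the global strata fuzzy C-means separates).
#'
#' @param samples list of `labeled_sample` objects.
#' @param enhance_cfg a [clahe_config()]; `NULL` skips enhancement.
#' @param fcm_cfg an [fcm_config()]; `NULL` skips segmentation (whole-image
#'   features).
#' @param use_roi compute LBP over the ROI bounding box when segmentation
#'   finds one (default), else always over the whole enhanced image.
#' @param normalize normalized histograms (default) or raw counts.
#' @return list with `features` (N x 256 matrix, rownames = sample ids),
#'   `labels` (character), `sample_ids`, and `roi_empty` (logical per
#'   sample).
#' @export
extract_features <- function(samples, enhance_cfg = clahe_config(),
                             fcm_cfg = fcm_config(), use_roi = TRUE,
                             normalize = TRUE) {
  n <- length(samples)
  feats <- matrix(0, n, 256L)
  labels <- character(n)
  ids <- character(n)
  roi_empty <- logical(n)
  for (i in seq_len(n)) {
    s <- samples[[i]]
    roi <- NULL
    if (use_roi && !is.null(fcm_cfg)) {
      roi <- extract_roi(s$image, fcm_cluster(as.numeric(s$image), fcm_cfg))
      roi_empty[i] <- roi$empty
    }
    img <- if (!is.null(enhance_cfg)) clahe(s$image, enhance_cfg) else s$image
    feats[i, ] <- lbp_histogram(lbp_image(img, roi), normalize = normalize)
    labels[i] <- s$label
    ids[i] <- s$sample_id
  }
  rownames(feats) <- ids
  list(features = feats, labels = labels, sample_ids = ids, roi_empty = roi_empty)
}

#' Write / read a feature matrix as CSV
#'
#' Schema: `sample_id,label,b0..b255`. The reader validates the 256 bin
#' columns.
#'
#' @param features N x 256 matrix.
#' @param labels character vector of class labels.
#' @param sample_ids character vector of identifiers.
#' @param path CSV path.
#' @return `write_features`: the path, invisibly. `read_features`: list
#'   with `features`, `labels`, `sample_ids`.
#' @export
write_features <- function(features, labels, sample_ids, path) {
  stopifnot(ncol(features) == 256L, nrow(features) == length(labels),
            length(labels) == length(sample_ids))
  df <- data.frame(sample_id = sample_ids, label = labels, features,
                   stringsAsFactors = FALSE)
  names(df) <- c("sample_id", "label", paste0("b", 0:255))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  bins <- paste0("b", 0:255)
  if (!all(c("sample_id", "label", bins) %in% names(df))) {
    stopf("feature file %s must have columns sample_id,label,b0..b255", path)
  }
  f <- as.matrix(df[, bins])
  rownames(f) <- df$sample_id
  colnames(f) <- NULL
  list(features = f, labels = df$label, sample_ids = df$sample_id)
}
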