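#' CLAHE configuration
#'
#' @param tile_grid integer `(rows, cols)` of contextual regions.
#' @param clip_limit histogram clip limit as a multiple of the uniform
#'   histogram height (`tile_pixels / 256`); must be > 0. Larger values
#'   allow more contrast amplification; `Inf` disables clipping.
#' @return object of class `clahe_config`.
#' @export
clahe_config <- function(tile_grid = c(8, 8), clip_limit = 2.0) {
  tile_grid <- as.integer(tile_grid)
  if (length(tile_grid) != 2L || any(tile_grid < 1L)) {
    stopf("tile_grid must be two positive integers")
  }
  if (!is.numeric(clip_limit) || length(clip_limit) != 1L || clip_limit <= 0) {
    stopf("clip_limit must be a positive number")
  }
  structure(list(tile_grid = tile_grid, clip_limit = clip_limit),
            class = "clahe_config")
}

#' Contrast limited adaptive histogram equalization
#'
#' Partitions the image into a grid of tiles (edge-padding by reflection
#' when the grid does not divide the image, cropping afterwards), clips each
#' tile's 256-bin histogram at `clip_limit * tile_pixels / 256` with the
#' excess redistributed uniformly over all bins, maps intensities through
#' the cumulative clipped histogram scaled to \[0, 255\] with floor
#' rounding, and blends per-tile mappings by bilinear interpolation between
#' tile centres. With one tile and an unreached clip limit this reduces
#' exactly to global histogram equalization.
#'
#' @param image numeric matrix with intensities in \[0, 255\].
#' @param config a [clahe_config()].
#' @return enhanced image, same dimensions, integer grey levels in
#'   \[0, 255\].
#' @export
clahe <- function(image, config = clahe_config()) {
  check_gray_image(image)
  stopifnot(inherits(config, "clahe_config"))
  nr <- nrow(image); nc <- ncol(image)
  gr <- config$tile_grid[1]; gc <- config$tile_grid[2]
  if (nr < gr || nc < gc) {
    stopf("image (%dx%d) is smaller than the tile grid (%dx%d)", nr, nc, gr, gc)
  }

  tile_h <- ceiling(nr / gr); tile_w <- ceiling(nc / gc)
  pr <- tile_h * gr - nr; pc <- tile_w * gc - nc
  img <- image
  ## reflect rows nr-1, nr-2, ... and columns nc-1, nc-2, ...
  if (pr > 0) img <- rbind(img, img[nr - seq_len(pr), , drop = FALSE])
  if (pc > 0) img <- cbind(img, img[, nc - seq_len(pc), drop = FALSE])
  NR <- nrow(img); NC <- ncol(img)
  vi <- matrix(as.integer(floor(img)), NR, NC)

  tp <- tile_h * tile_w
  luts <- array(0, dim = c(256L, gr, gc))
  for (i in seq_len(gr)) {
    rs <- ((i - 1L) * tile_h + 1L):(i * tile_h)
    for (j in seq_len(gc)) {
      cs <- ((j - 1L) * tile_w + 1L):(j * tile_w)
      h <- tabulate(vi[rs, cs] + 1L, nbins = 256L)
      clip <- config$clip_limit * tp / 256
      if (is.finite(clip)) {
        excess <- sum(pmax(h - clip, 0))
        h <- pmin(h, clip) + excess / 256
      }
      luts[, i, j] <- floor(cumsum(h) / tp * 255)
    }
  }

  ## bilinear blend of the tile mappings at each pixel
  interp_axis <- function(coord, tile, g) {
    t_real <- (coord - 0.5) / tile + 0.5
    i0 <- floor(t_real)
    w <- t_real - i0
    w[i0 < 1] <- 0; i0[i0 < 1] <- 1L
    w[i0 >= g] <- 0; i0[i0 >= g] <- g
    i1 <- pmin(i0 + 1L, g)
    list(i0 = as.integer(i0), i1 = as.integer(i1), w = w)
  }
  ry <- interp_axis(seq_len(NR), tile_h, gr)
  cx <- interp_axis(seq_len(NC), tile_w, gc)

  gather <- function(iv, jv) {
    ## linear index into luts[256, gr, gc]
    idx <- (vi + 1L) + 256L * ((matrix(iv, NR, NC) - 1L) +
                               gr * (matrix(jv, NR, NC, byrow = TRUE) - 1L))
    matrix(luts[idx], NR, NC)
  }
  wy <- matrix(ry$w, NR, NC)
  wx <- matrix(cx$w, NR, NC, byrow = TRUE)
  out <- (1 - wy) * (1 - wx) * gather(ry$i0, cx$i0) +
         wy * (1 - wx) * gather(ry$i1, cx$i0) +
         (1 - wy) * wx * gather(ry$i0, cx$i1) +
         wy * wx * gather(ry$i1, cx$i1)

  out <- round_half_up(out, 0)
  out[seq_len(nr), seq_len(nc), drop = FALSE]
}
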