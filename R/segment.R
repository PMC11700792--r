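#' Fuzzy C-means configuration
#'
#' @param c number of clusters (>= 2); the default 3 matches the intensity
#'   strata of lung CT slices (air/lung, body tissue, bright lesion).
#' @param m fuzzifier (> 1); 2 is the classical choice.
#' @param tol convergence threshold on the maximum absolute membership
#'   change between iterations.
#' @param max_iter iteration cap.
#' @param seed seed for the centroid initialization jitter.
#' @return object of class `fcm_config`.
#' @export
fcm_config <- function(c = 3, m = 2.0, tol = 1e-4, max_iter = 200, seed = 1) {
  if (c < 2) stopf("number of clusters c must be >= 2")
  if (m <= 1) stopf("fuzzifier m must be > 1")
  if (tol <= 0) stopf("tol must be > 0")
  if (max_iter < 1) stopf("max_iter must be >= 1")
  structure(list(c = as.integer(c), m = m, tol = tol,
                 max_iter = as.integer(max_iter), seed = as.integer(seed)),
            class = "fcm_config")
}

#' Fuzzy C-means clustering of intensities
#'
#' Alternates the standard FCM updates on a 1-D intensity sample: membership
#' `u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1))` and centroid
#' `v_i = sum_k u_ik^m x_k / sum_k u_ik^m`, until the maximum membership
#' change falls below `tol` or `max_iter` is reached. A pixel at zero
#' distance from a centroid receives membership 1 there (lowest such index
#' on ties) and 0 elsewhere. Centroids are initialized at the
#' `seq(0, 1, length.out = c)` quantiles of the data (extremes included, so
#' a small bright mode can claim its own centroid) plus a tiny seeded
#' jitter; duplicated quantiles share one jitter draw so exactly degenerate
#' data stay degenerate. Output clusters are canonicalized by sorting
#' centroids ascending.
#'
#' @param values numeric vector of pixel intensities (length >= `c`).
#' @param config an [fcm_config()].
#' @return `fcm_result`: list with `centroids` (ascending), `memberships`
#'   (N x c, rows summing to 1), `objective_trace` (per-iteration
#'   `J_m = sum u^m d^2`, non-increasing), `iterations`, `converged`.
#' @export
fcm_cluster <- function(values, config = fcm_config()) {
  x <- as.numeric(values)
  if (anyNA(x) || any(!is.finite(x))) stopf("values contain non-finite entries")
  cc <- config$c; m <- config$m
  if (length(x) < cc) stopf("need at least c = %d values, got %d", cc, length(x))

  v <- quantile(x, probs = seq(0, 1, length.out = cc), names = FALSE, type = 7)
  v <- with_seed(config$seed, {
    jit <- rnorm(length(unique(v)), 0, (diff(range(x)) + 1e-12) / 200)
    v + jit[match(v, unique(v))]
  })

  n <- length(x)
  u_old <- NULL
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  expo <- 1 / (m - 1)
  for (it in seq_len(config$max_iter)) {
    d2 <- outer(x, v, function(a, b) (a - b)^2)
    zero <- d2 < 1e-24
    w <- (1 / pmax(d2, 1e-24))^expo
    u <- w / rowSums(w)
    zr <- which(rowSums(zero) > 0L)
    if (length(zr)) {
      u[zr, ] <- 0
      u[cbind(zr, max.col(zero[zr, , drop = FALSE] * 1, ties.method = "first"))] <- 1
    }
    um <- u^m
    wsum <- colSums(um)
    v_new <- ifelse(wsum > 0, colSums(um * x) / pmax(wsum, 1e-300), v)
    v <- v_new
    trace[it] <- sum(um * outer(x, v, function(a, b) (a - b)^2))
    if (!is.null(u_old) && max(abs(u - u_old)) < config$tol) {
      converged <- TRUE
      break
    }
    u_old <- u
  }

  ord <- order(v)
  structure(list(centroids = v[ord], memberships = u[, ord, drop = FALSE],
                 objective_trace = trace, iterations = it, converged = converged),
            class = "fcm_result")
}

## label 4-connected components of a logical matrix; returns integer matrix
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      cl <- (frontier - 1L) %/% nr + 1L
      nb <- c(frontier[r > 1L] - 1L, frontier[r < nr] + 1L,
              frontier[cl > 1L] - nr, frontier[cl < nc] + nr)
      nb <- unique(nb[mask[nb] & lab[nb] == 0L])
      lab[nb] <- cur
      frontier <- nb
    }
  }
  lab
}

#' Extract the candidate nodule region of interest
#'
#' Hard-assigns every pixel to its maximum-membership cluster (lowest index
#' on ties), selects the cluster with the highest centroid, and keeps the
#' largest 4-connected component of that cluster. The ROI is flagged empty
#' — the nodule-free (normal lung) case — when (a) that component has fewer
#' than 9 pixels, or (b) the top centroid is not separated from the rest:
#' the gap fraction `(v_c - v_(c-1)) / (v_c - v_1)` is below `min_gap`.
#' The separation guard is what lets a lesion-free image, whose brightest
#' cluster is only the upper noise tail of body tissue, come back empty.
#'
#' @param image the image the clustering was computed on.
#' @param result the [fcm_cluster()] result for `as.numeric(image)`.
#' @param min_size minimum component pixel count (default 9).
#' @param min_gap minimum top-centroid gap fraction (default 0.2).
#' @return `roi_mask`: list with `empty` flag, logical `mask` (same shape as
#'   the image) and `bounding_box` = `c(row_min, col_min, row_max, col_max)`
#'   (1-based, inclusive; `NULL` when empty).
#' @export
extract_roi <- function(image, result, min_size = 9L, min_gap = 0.2) {
  check_gray_image(image)
  stopifnot(inherits(result, "fcm_result"))
  if (nrow(result$memberships) != length(image)) {
    stopf("membership rows (%d) do not match image pixels (%d)",
          nrow(result$memberships), length(image))
  }
  v <- result$centroids
  cc <- length(v)
  empty <- function() {
    structure(list(empty = TRUE, mask = matrix(FALSE, nrow(image), ncol(image)),
                   bounding_box = NULL), class = "roi_mask")
  }
  spread <- v[cc] - v[1]
  gap <- if (spread > 0) (v[cc] - v[cc - 1]) / spread else 0
  if (gap < min_gap) return(empty())

  hard <- max.col(result$memberships, ties.method = "first")
  top <- which.max(v)  # lowest index wins on exact centroid ties
  mask <- matrix(hard == top, nrow(image), ncol(image))
  if (!any(mask)) return(empty())
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  if (max(sizes) < min_size) return(empty())
  keep <- which.max(sizes)
  mask <- lab == keep
  rr <- range(which(rowSums(mask) > 0))
  rc <- range(which(colSums(mask) > 0))
  structure(list(empty = FALSE, mask = mask,
                 bounding_box = c(row_min = rr[1], col_min = rc[1],
                                  row_max = rr[2], col_max = rc[2])),
            class = "roi_mask")
}
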