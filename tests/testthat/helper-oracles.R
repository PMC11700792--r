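# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# per-pixel LBP by explicit neighbor enumeration (clockwise from top-left,
# MSB first), looping pixels one at a time
oracle_lbp_image <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(NA_integer_, nr - 2L, nc - 2L)
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  for (r in 2:(nr - 1)) {
    for (cl in 2:(nc - 1)) {
      code <- 0L
      for (k in 1:8) {
        nb <- img[r + offs[[k]][1], cl + offs[[k]][2]]
        code <- code * 2L + as.integer(nb > img[r, cl])
      }
      out[r - 1L, cl - 1L] <- code
    }
  }
  out
}

# global histogram equalization via an explicit cumulative histogram
oracle_global_he <- function(img) {
  n <- length(img)
  cdf <- cumsum(tabulate(as.integer(img) + 1L, nbins = 256L))
  lut <- floor(cdf / n * 255)
  matrix(lut[as.integer(img) + 1L], nrow(img), ncol(img))
}

# FCM objective J_m(v) with memberships eliminated in closed form:
# J(v) = sum_k (sum_i d_ik^(-2/(m-1)))^-(m-1) for points off the centroids
oracle_fcm_objective <- function(x, v, m = 2) {
  total <- 0
  for (xk in x) {
    d2 <- (xk - v)^2
    if (any(d2 < 1e-20)) next  # zero-distance point contributes 0
    total <- total + sum(d2^(-1 / (m - 1)))^(-(m - 1))
  }
  total
}
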