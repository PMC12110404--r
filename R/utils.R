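#' @useDynLib drlroi, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Bilinear resampling of a matrix
#'
#' Resamples an intensity matrix to a new size by separable bilinear
#' interpolation with the align-corners convention: the first and last
#' samples of each axis map exactly onto the first and last input samples,
#' so resizing to the same size is the identity.  Used for the spatial
#' gating grid, class-activation-map upsampling, and crop resizing.
#'
#' @param x numeric matrix.
#' @param out_h,out_w target number of rows / columns.
#' @return numeric matrix of dimension `out_h` x `out_w`.
#' @export
resize_bilinear <- function(x, out_h, out_w) {
  stopifnot(is.matrix(x), out_h >= 1, out_w >= 1)
  Rw <- .interp_weights(nrow(x), out_h)
  Cw <- .interp_weights(ncol(x), out_w)
  Rw %*% x %*% t(Cw)
}

# Sparse-in-spirit interpolation operator: (m x n) with two nonzeros per row.
.interp_weights <- function(n, m) {
  W <- matrix(0, m, n)
  if (n == 1L) {
    W[, 1L] <- 1
    return(W)
  }
  src <- if (m == 1L) (1 + n) / 2 else 1 + (seq_len(m) - 1) * (n - 1) / (m - 1)
  lo <- pmin(floor(src), n - 1L)
  frac <- src - lo
  W[cbind(seq_len(m), lo)] <- 1 - frac
  W[cbind(seq_len(m), lo + 1L)] <- W[cbind(seq_len(m), lo + 1L)] + frac
  W
}

# Clip values into [lo, hi].
clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# Checksum of a serialized R object: two independent polynomial rolling
# hashes modulo Mersenne prime 2^31 - 1 (exact in double arithmetic).
# Used to stamp artifacts with the configuration that produced them and to
# audit the freeze contract of the alternating training.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, connection = NULL, version = 2))
  p <- 2147483647
  h1 <- 17; h2 <- 29
  for (b in bytes) {
    h1 <- (h1 * 257 + b) %% p
    h2 <- (h2 * 131 + b) %% p
  }
  sprintf("%08x%08x", h1, h2)
}

# Derive a bounded child seed from a base seed and a stream label, so that
# independent components (data order, init, action sampling) draw from
# distinct but reproducible streams.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  s <- (abs(seed) + 1) %% 2147480000
  for (ch in utf8ToInt(as.character(stream))) {
    s <- (s * 69069 + ch) %% 2147480000
  }
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
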