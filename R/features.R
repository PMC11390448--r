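# block-average pooling matrix: `out` rows, each averaging one block of the
# `n` inputs; the last block absorbs any remainder
avg_pool_matrix <- function(n, block) {
  out <- max(1L, n %/% block)
  A <- matrix(0, out, n)
  for (j in seq_len(out)) {
    idx <- if (j < out) ((j - 1) * block + 1):(j * block) else ((j - 1) * block + 1):n
    A[j, idx] <- 1 / length(idx)
  }
  A
}

#' Instance feature extractors
#'
#' Both extractors map a 2D instance to a fixed-length feature vector and are
#' deterministic once constructed, as the pseudo-labeling stage requires.
#'
#' `extractor_pool()` is the mean-pooling baseline: non-overlapping block
#' averages of the instance (a constant image `c` yields a feature vector of
#' all `c`).
#'
#' `extractor_cnn()` is the default richer extractor: a small 3-block
#' convolutional network (3x3 kernels, ReLU, 2x2 average pooling per block)
#' with fixed random weights drawn once from `seed`, followed by a final
#' average pooling with `pool_size` and flattening. Random convolutional
#' features stand in for a pretrained backbone at desk scale; nothing in the
#' extractor is fit to the data, so instance features cannot leak bag labels.
#' When `extrema = TRUE` the vector is extended with block-minimum
#' and block-maximum pooling of the raw instance on an 8x8 grid: focal
#' lesions are intensity extrema (hypo- or hyperdense), and extremum pooling
#' detects a small blob wherever it sits inside a block, which averaged
#' responses wash out.
#'
#' @param pool length-2 block size for the pooling baseline.
#' @param seed integer; fixes the random convolution weights.
#' @param channels convolution channels per block.
#' @param blocks number of conv + pool blocks.
#' @param pool_size final average-pooling block (default 4x4, applied before
#'   flattening).
#' @return an object of class `milct_extractor`; pass to [extract_features()].
#' @export
extractor_pool <- function(pool = c(8, 8)) {
  pool <- as.integer(rep(pool, length.out = 2))
  if (any(pool < 1L)) stop_config("pool", "must be >= 1")
  fn <- function(img) {
    A <- avg_pool_matrix(nrow(img), pool[1]) %*% img %*% t(avg_pool_matrix(ncol(img), pool[2]))
    as.numeric(A)
  }
  structure(list(name = "pool", fn = fn, pool = pool), class = "milct_extractor")
}

conv3x3_same <- function(x, W, relu_out = TRUE) {
  d <- dim(x); h <- d[1]; w <- d[2]; cin <- d[3]
  cout <- dim(W)[2]
  pad <- array(0, c(h + 2, w + 2, cin))
  pad[2:(h + 1), 2:(w + 1), ] <- x
  M <- matrix(0, h * w, 9 * cin)
  col <- 1L
  for (ci in seq_len(cin)) {
    for (dj in 0:2) {
      for (di in 0:2) {
        M[, col] <- pad[(1 + di):(h + di), (1 + dj):(w + dj), ci]
        col <- col + 1L
      }
    }
  }
  out <- M %*% W
  if (relu_out) out <- relu(out)
  array(out, c(h, w, cout))
}

pool2x2 <- function(x) {
  d <- dim(x)
  Ar <- avg_pool_matrix(d[1], 2L)
  Ac <- avg_pool_matrix(d[2], 2L)
  out <- array(0, c(nrow(Ar), nrow(Ac), d[3]))
  for (c in seq_len(d[3])) out[, , c] <- Ar %*% x[, , c] %*% t(Ac)
  out
}

# block-extremum pooling of a matrix on a grid of `n_blocks` per axis
block_extrema <- function(img, n_blocks = 8L) {
  cuts_r <- ceiling(seq_len(nrow(img)) / (nrow(img) / n_blocks))
  cuts_c <- ceiling(seq_len(ncol(img)) / (ncol(img) / n_blocks))
  mins <- maxs <- matrix(0, n_blocks, n_blocks)
  for (i in seq_len(n_blocks)) {
    ri <- cuts_r == i
    for (j in seq_len(n_blocks)) {
      v <- img[ri, cuts_c == j]
      mins[i, j] <- min(v)
      maxs[i, j] <- max(v)
    }
  }
  c(mins, maxs)
}

#' @rdname extractor_pool
#' @param extrema append block-min/max pooling of the raw instance
#'   (`extractor_cnn()` only).
#' @export
extractor_cnn <- function(seed = 42, channels = 8, blocks = 3, pool_size = c(4, 4),
                          extrema = FALSE) {
  channels <- as.integer(channels)
  blocks <- as.integer(blocks)
  pool_size <- as.integer(rep(pool_size, length.out = 2))
  if (channels < 1L || blocks < 1L || any(pool_size < 1L)) {
    stop_config("channels/blocks/pool_size", "must be >= 1")
  }
  weights <- with_seed(seed, {
    lapply(seq_len(blocks), function(b) {
      cin <- if (b == 1L) 1L else channels
      matrix(stats::rnorm(9 * cin * channels, 0, sqrt(2 / (9 * cin))),
             9 * cin, channels)
    })
  })
  fn <- function(img) {
    x <- array(img, c(dim(img), 1L))
    for (b in seq_len(blocks)) x <- pool2x2(conv3x3_same(x, weights[[b]]))
    Ar <- avg_pool_matrix(dim(x)[1], pool_size[1])
    Ac <- avg_pool_matrix(dim(x)[2], pool_size[2])
    out <- vapply(seq_len(dim(x)[3]),
                  function(c) as.numeric(Ar %*% x[, , c] %*% t(Ac)),
                  numeric(nrow(Ar) * nrow(Ac)))
    if (extrema) c(as.numeric(out), block_extrema(img)) else as.numeric(out)
  }
  structure(list(name = "cnn", fn = fn, seed = seed, channels = channels,
                 blocks = blocks, pool_size = pool_size, extrema = isTRUE(extrema)),
            class = "milct_extractor")
}

#' Dihedral transform of a 2D instance
#'
#' The eight symmetries of the square (4 rotations x optional horizontal
#' flip), used to augment training instances: lesions occur at arbitrary
#' positions in the organ, and the augmented copies teach the
#' location-sensitive feature head that a lesion is a lesion wherever it
#' sits.
#'
#' @param m numeric matrix (square instance).
#' @param k transform index in `1..8` (1 = identity, 2-4 = rotations,
#'   5-8 = the same after a flip).
#' @return transformed matrix.
#' @export
dihedral_transform <- function(m, k) {
  k <- as.integer(k)
  if (k < 1L || k > 8L) stop_config("k", "must be in 1..8")
  r <- switch(((k - 1L) %% 4L) + 1L,
              m,
              t(m[nrow(m):1, , drop = FALSE]),
              m[nrow(m):1, ncol(m):1, drop = FALSE],
              t(m)[nrow(m):1, , drop = FALSE])
  if (k > 4L) r[, ncol(r):1, drop = FALSE] else r
}

#' Extract features for a stack of instances
#'
#' @param instances an `instance_stack` from [build_instances()] or a 3D array
#'   `h x w x n` of instances sharing one shape.
#' @param extractor a `milct_extractor` ([extractor_cnn()] by default).
#' @return numeric matrix, one row per instance, constant width.
#' @export
extract_features <- function(instances, extractor = extractor_cnn()) {
  if (!inherits(extractor, "milct_extractor")) {
    stop("`extractor` must be a milct_extractor", call. = FALSE)
  }
  arr <- if (inherits(instances, "instance_stack")) instances$instances else instances
  if (!is.array(arr) || length(dim(arr)) != 3L) {
    stop("instances must share one 2D shape (3D array h x w x n)", call. = FALSE)
  }
  n <- dim(arr)[3]
  feats <- lapply(seq_len(n), function(k) extractor$fn(arr[, , k, drop = TRUE]))
  lens <- lengths(feats)
  if (length(unique(lens)) > 1L) stop("extractor returned ragged features", call. = FALSE)
  do.call(rbind, feats)
}
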