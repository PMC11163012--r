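# Minimal CPU tensor ops on C x H x W arrays. These are the only numeric
# primitives the backbone and attention modules use, so the reshape dialect
# (row-major spatial flattening, see map_to_matrix) is fixed in one place.

new_conv2d <- function(in_channels, out_channels, kernel = 3L, stride = 1L,
                       pad = (kernel - 1L) %/% 2L, init = c("he", "zero")) {
  init <- match.arg(init)
  fan_in <- in_channels * kernel * kernel
  w <- if (init == "he") {
    matrix(stats::rnorm(out_channels * fan_in, sd = sqrt(2 / fan_in)),
           nrow = out_channels)
  } else {
    matrix(0, nrow = out_channels, ncol = fan_in)
  }
  structure(list(W = w, b = numeric(out_channels),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 pad = as.integer(pad)),
            class = "rbpnn_conv2d")
}

# 1x1 convolution whose weight matrix is the identity (used in tests and in
# deliberately transparent configurations).
identity_conv2d <- function(channels, kernel = 1L) {
  cv <- new_conv2d(channels, channels, kernel = kernel, init = "zero")
  k <- cv$kernel
  centre <- ((k * k - 1L) %/% 2L) * channels   # centre tap block, channel-fastest
  for (c in seq_len(channels)) cv$W[c, centre + c] <- 1
  cv
}

pad_map <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1L], d[2L] + 2L * p, d[3L] + 2L * p))
  out[, p + seq_len(d[2L]), p + seq_len(d[3L])] <- x
  out
}

# im2col: patches matrix with rows ordered channel-fastest, then kernel row u,
# then kernel column v; columns ordered by output position (row-major).
im2col <- function(x, kernel, stride, pad) {
  d <- dim(x)
  ch <- d[1L]
  h_out <- (d[2L] + 2L * pad - kernel) %/% stride + 1L
  w_out <- (d[3L] + 2L * pad - kernel) %/% stride + 1L
  if (h_out < 1L || w_out < 1L) {
    stop_rbpnn("convolution input %dx%d too small for kernel %d / stride %d",
               d[2L], d[3L], kernel, stride)
  }
  xp <- pad_map(x, pad)
  p <- matrix(0, nrow = ch * kernel * kernel, ncol = h_out * w_out)
  for (v in seq_len(kernel)) {
    for (u in seq_len(kernel)) {
      rows <- u + (seq_len(h_out) - 1L) * stride
      cols <- v + (seq_len(w_out) - 1L) * stride
      block <- xp[, rows, cols, drop = FALSE]
      r0 <- ((v - 1L) * kernel + (u - 1L)) * ch
      p[r0 + seq_len(ch), ] <- map_to_matrix(block)
    }
  }
  attr(p, "out_size") <- c(h_out, w_out)
  p
}

conv2d_forward <- function(x, cv) {
  check_feature_map(x)
  if (dim(x)[1L] != cv$in_channels) {
    stop_rbpnn("conv2d expected %d input channels, got %d",
               cv$in_channels, dim(x)[1L])
  }
  if (cv$kernel == 1L && cv$stride == 1L && cv$pad == 0L) {
    out <- cv$W %*% map_to_matrix(x) + cv$b
    return(matrix_to_map(out, dim(x)[2L], dim(x)[3L]))
  }
  p <- im2col(x, cv$kernel, cv$stride, cv$pad)
  sz <- attr(p, "out_size")
  matrix_to_map(cv$W %*% p + cv$b, sz[1L], sz[2L])
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Batch normalization buffers. Heads-only training never updates them, so in
# evaluation mode with fresh buffers (mean 0, var 1, gamma 1, beta 0) the op
# is the identity; the buffers are kept so a checkpoint round-trips.
new_batchnorm <- function(channels) {
  list(mean = numeric(channels), var = rep(1, channels),
       gamma = rep(1, channels), beta = numeric(channels), eps = 1e-5)
}

batchnorm_forward <- function(x, bn) {
  d <- dim(x)
  scale <- bn$gamma / sqrt(bn$var + bn$eps)
  shift <- bn$beta - bn$mean * scale
  x * array(scale, dim = d) + array(shift, dim = d)
}

# Interpolation matrix for 1-D bilinear resizing with half-pixel centers
# (corner-aligned sampling disabled). Rows sum to 1.
interp_matrix <- function(n_in, n_out) {
  m <- matrix(0, nrow = n_out, ncol = n_in)
  s <- n_in / n_out
  for (i in seq_len(n_out)) {
    si <- (i - 0.5) * s + 0.5
    si <- min(max(si, 1), n_in)
    i0 <- floor(si)
    i1 <- min(i0 + 1, n_in)
    t <- si - i0
    m[i, i0] <- m[i, i0] + (1 - t)
    m[i, i1] <- m[i, i1] + t
  }
  m
}

#' Bilinear resize of a feature map
#'
#' Bilinear interpolation with half-pixel sample centers (the
#' `align_corners = FALSE` dialect). Used for top-down pyramid upsampling and
#' pyramid-pooling branch restoration.
#'
#' @param x A `C x H x W` array.
#' @param h_out,w_out Target spatial size.
#' @return A `C x h_out x w_out` array.
#' @export
bilinear_resize <- function(x, h_out, w_out) {
  check_feature_map(x)
  d <- dim(x)
  if (d[2L] == h_out && d[3L] == w_out) return(x)
  rh <- interp_matrix(d[2L], h_out)
  rw <- interp_matrix(d[3L], w_out)
  out <- array(0, dim = c(d[1L], h_out, w_out))
  for (c in seq_len(d[1L])) out[c, , ] <- rh %*% x[c, , ] %*% t(rw)
  out
}

#' Adaptive average pooling of a feature map
#'
#' Pools each channel to a `grid x grid` output; output cell `i` averages
#' input rows `floor((i-1)*H/g)+1 .. ceiling(i*H/g)` (and likewise columns),
#' so `grid == H == W` is an exact identity.
#'
#' @param x A `C x H x W` array.
#' @param grid Output grid size (positive integer, `<=` spatial size).
#' @return A `C x grid x grid` array.
#' @export
adaptive_avg_pool <- function(x, grid) {
  check_feature_map(x)
  d <- dim(x)
  grid <- check_count(grid, "grid")
  if (grid > d[2L] || grid > d[3L]) {
    stop_rbpnn("pooling grid %d exceeds spatial size %dx%d", grid, d[2L], d[3L])
  }
  pool_matrix <- function(n_in, g) {
    a <- matrix(0, nrow = g, ncol = n_in)
    for (i in seq_len(g)) {
      lo <- floor((i - 1) * n_in / g) + 1L
      hi <- ceiling(i * n_in / g)
      a[i, lo:hi] <- 1 / (hi - lo + 1L)
    }
    a
  }
  ah <- pool_matrix(d[2L], grid)
  aw <- pool_matrix(d[3L], grid)
  out <- array(0, dim = c(d[1L], grid, grid))
  for (c in seq_len(d[1L])) out[c, , ] <- ah %*% x[c, , ] %*% t(aw)
  out
}

global_avg_pool <- function(x) {
  check_feature_map(x)
  apply(x, 1L, mean)
}
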