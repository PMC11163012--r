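# Mixed self-attention: a spatial attention module (SAM) relating every pixel
# position to every other, a channel attention module (CAM) relating channel
# pairs, and their aggregation into the enhanced feature map that is
# flattened into the comprehensive feature matrix.

#' Initialize mixed-attention state
#'
#' The SAM query/key/value projections are 1x1 convolutions (He init); the
#' residual scale gates `delta` (spatial) and `epsilon` (channel) start at
#' exactly 0, so both attention operators are exact identities at
#' initialization and are phased in by learning. The aggregation head holds a
#' 3x3 convolution + batch norm + ReLU per branch, and a dropout + 1x1
#' convolution fusion; the branch and fusion convolutions also initialize as
#' identities (when shapes permit), extending the same start-as-identity
#' principle so the untrained head is information-preserving.
#'
#' @param channels Input channel count `C`.
#' @param reduction_ratio Channel reduction of the query/key projections
#'   (1 = keep `C` channels).
#' @param dropout_rate Dropout rate of the aggregation head, in `[0, 1)`.
#' @param out_channels Channels after the final 1x1 convolution (default `C`).
#' @return An object of class `attention_state`.
#' @export
init_attention <- function(channels, reduction_ratio = 1L, dropout_rate = 0.1,
                           out_channels = channels) {
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_rbpnn("dropout_rate must lie in [0, 1)")
  }
  inner <- max(channels %/% reduction_ratio, 1L)
  structure(list(
    channels = as.integer(channels),
    proj_b = new_conv2d(channels, inner, kernel = 1L),
    proj_c = new_conv2d(channels, inner, kernel = 1L),
    proj_d = new_conv2d(channels, channels, kernel = 1L),
    delta = 0,
    epsilon = 0,
    mu = list(conv = identity_conv2d(channels, kernel = 3L),
              bn = new_batchnorm(channels)),
    nu = list(conv = identity_conv2d(channels, kernel = 3L),
              bn = new_batchnorm(channels)),
    eta = list(dropout_rate = dropout_rate,
               conv = if (out_channels == channels) {
                 identity_conv2d(channels)
               } else {
                 new_conv2d(channels, out_channels, kernel = 1L)
               })),
    class = "attention_state")
}

#' Spatial attention module (SAM)
#'
#' Projects the input `T_A` through 1x1 convolutions into query/key maps
#' `T_B`, `T_C` and a value map `T_D`; the spatial attention map
#' `T_S[j, i] = softmax_i(T_B_i . T_C_j)` (each row `j` sums to 1) weights the
#' value at every source position `i` for each target position `j`, and the
#' output is the gated residual `T_P = delta * (sum_i T_S[j,i] T_D_i) + T_A`.
#' With `delta = 0` the output equals the input bit-exactly.
#'
#' @param t_a A `C x H x W` feature map.
#' @param state An [init_attention()] state.
#' @param return_map Also return the `HW x HW` attention map `T_S`.
#' @return The output map `T_P`, or a list `(T_P, T_S)` when `return_map`.
#' @export
spatial_attention <- function(t_a, state, return_map = FALSE) {
  check_feature_map(t_a)
  if (!all(is.finite(t_a))) stop_rbpnn("spatial_attention: non-finite input")
  d <- dim(t_a)
  x <- map_to_matrix(t_a)
  b <- state$proj_b$W %*% x + state$proj_b$b   # C' x N
  cc <- state$proj_c$W %*% x + state$proj_c$b  # C' x N
  v <- state$proj_d$W %*% x + state$proj_d$b   # C  x N
  energy <- crossprod(cc, b)                   # [j, i] = C_j . B_i
  t_s <- row_softmax(energy)
  out <- v %*% t(t_s)                          # column j = sum_i S[j,i] D_i
  t_p <- state$delta * matrix_to_map(out, d[2L], d[3L]) + t_a
  if (return_map) list(t_p = t_p, t_s = t_s) else t_p
}

#' Channel attention module (CAM)
#'
#' Flattens the input to `C x HW`; the channel attention map
#' `T_X[j, i] = softmax_i(X_i . X_j)` (rows sum to 1) mixes the channels, and
#' the output is the gated residual `T_Q = epsilon * (T_X X) + T_A`. With
#' `epsilon = 0` the output equals the input bit-exactly.
#'
#' @param t_a A `C x H x W` feature map.
#' @param state An [init_attention()] state.
#' @param return_map Also return the `C x C` attention map `T_X`.
#' @return The output map `T_Q`, or a list `(T_Q, T_X)` when `return_map`.
#' @export
channel_attention <- function(t_a, state, return_map = FALSE) {
  check_feature_map(t_a)
  if (!all(is.finite(t_a))) stop_rbpnn("channel_attention: non-finite input")
  d <- dim(t_a)
  x <- map_to_matrix(t_a)
  energy <- tcrossprod(x)                      # [j, i] = X_j . X_i
  t_x <- row_softmax(energy)
  out <- t_x %*% x
  t_q <- state$epsilon * matrix_to_map(out, d[2L], d[3L]) + t_a
  if (return_map) list(t_q = t_q, t_x = t_x) else t_q
}

#' Aggregate spatial and channel attention branches
#'
#' `T_R = eta( mu(SAM(T_A)) + nu(CAM(T_A)) )` where `mu` and `nu` are
#' 3x3 convolution + batch norm + ReLU branches and `eta` is dropout followed
#' by a 1x1 convolution. Dropout is disabled in evaluation mode; in training
#' mode it is an inverted-dropout Bernoulli mask drawn deterministically from
#' `seed`.
#'
#' @param t_a A `C x H x W` feature map.
#' @param state An [init_attention()] state.
#' @param train Training mode flag (enables dropout).
#' @param seed Integer seed for the dropout mask (training mode only).
#' @return The aggregated map `T_R`.
#' @export
aggregate_attention <- function(t_a, state, train = FALSE, seed = 1L) {
  sp <- spatial_attention(t_a, state)
  ch <- channel_attention(t_a, state)
  branch <- function(x, pars) {
    relu(batchnorm_forward(conv2d_forward(x, pars$conv), pars$bn))
  }
  merged <- branch(sp, state$mu) + branch(ch, state$nu)
  rate <- state$eta$dropout_rate
  if (train && rate > 0) {
    d <- dim(merged)
    mask <- with_local_seed(seed, {
      array(stats::rbinom(prod(d), 1L, 1 - rate), dim = d)
    })
    merged <- merged * mask / (1 - rate)
  }
  conv2d_forward(merged, state$eta$conv)
}

#' Flatten an enhanced feature map into the comprehensive feature matrix
#'
#' Adaptively average-pools the map to `grid x grid` and flattens each
#' channel row-major, producing the `C x L` comprehensive feature matrix
#' (`L = grid^2`) that the CSA metric, prototype clustering and the RBPN
#' layer operate on. Every sample yields an identically shaped matrix.
#'
#' @param t_r A `C x H x W` feature map.
#' @param profile_grid Pooling grid (positive, at most the spatial size);
#'   equal to the spatial size gives an exact row-major flattening.
#' @return A `C x grid^2` numeric matrix.
#' @export
to_feature_matrix <- function(t_r, profile_grid) {
  pooled <- adaptive_avg_pool(t_r, profile_grid)
  map_to_matrix(pooled)
}
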