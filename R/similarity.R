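# Channel cosine-similarity attention (CSA): per-channel cosine similarity,
# the channel similarity matrix and its mean profile, average-pooled channel
# attention weights, feature fusion, and the scalar CSA distance that the
# clustering stage and the RBPN kernel both consume.

#' Cosine similarity between two vectors
#'
#' `A . B / (||A|| ||B||)`, in `[-1, 1]`. If either vector is all zero the
#' similarity is defined as 0 (maximally non-collinear) and a warning is
#' emitted, so degenerate channels never produce NaN.
#'
#' @param a,b Numeric vectors of equal length.
#' @return A single number in `[-1, 1]`.
#' @export
cosine_sim <- function(a, b) {
  if (length(a) != length(b)) {
    stop_rbpnn("cosine_sim: lengths differ (%d vs %d)", length(a), length(b))
  }
  na <- sqrt(sum(a * a))
  nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) {
    warning("cosine_sim: zero vector; returning 0 by convention", call. = FALSE)
    return(0)
  }
  sum(a * b) / (na * nb)
}

# Unit-normalize the rows of a feature matrix; all-zero rows stay zero (their
# cosine against anything is the 0 convention).
normalize_rows <- function(x) {
  n <- sqrt(rowSums(x * x))
  nz <- n > 0
  x[nz, ] <- x[nz, , drop = FALSE] / n[nz]
  list(x = x, zero = !nz)
}

#' Channel similarity matrix and mean similarity profile
#'
#' Computes the `C x C` matrix `M[i, j] = cos(F_i, F_j)` over the channel
#' rows of a feature matrix, shifts entries into `[0, 1]` via `(x + 1)/2`,
#' normalizes each row to sum to 1, and returns the per-channel mean of the
#' normalized rows as the overall channel similarity profile `M_C`.
#'
#' @param x A `C x L` feature matrix (rows are channels).
#' @return A list with `M` (raw cosine matrix), `M_norm` (shifted,
#'   row-normalized matrix) and `M_C` (row means of `M_norm`).
#' @export
similarity_matrix <- function(x) {
  if (!is.matrix(x) || nrow(x) < 1L) {
    stop_rbpnn("similarity_matrix expects a matrix with at least one row")
  }
  nr <- normalize_rows(x)
  m <- tcrossprod(nr$x)
  if (any(nr$zero)) {
    warning("similarity_matrix: zero channel row(s); cosine set to 0",
            call. = FALSE)
    m[nr$zero, ] <- 0
    m[, nr$zero] <- 0
  }
  m <- pmin(pmax(m, -1), 1)
  diag(m)[!nr$zero] <- 1
  m01 <- (m + 1) / 2
  rs <- rowSums(m01)
  mn <- m01
  pos <- rs > 0
  mn[pos, ] <- m01[pos, , drop = FALSE] / rs[pos]
  mn[!pos, ] <- 1 / ncol(m01)
  list(M = m, M_norm = mn, M_C = rowMeans(mn))
}

#' Average-pooled channel attention weights
#'
#' The attention coefficient of channel `c` is its spatial mean: for a
#' `C x H x W` map, `A_c = sum(x_ij) / (H*W)`; for a `C x L` feature matrix
#' (no spatial extent) it is the row mean, the matrix analogue.
#'
#' @param x A `C x H x W` array or a `C x L` matrix.
#' @return A length-`C` numeric vector.
#' @export
channel_weights <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) == 0L) stop_rbpnn("channel_weights: zero-width feature matrix")
    return(rowMeans(x))
  }
  check_feature_map(x)
  d <- dim(x)
  if (d[2L] == 0L || d[3L] == 0L) stop_rbpnn("channel_weights: zero-area map")
  apply(x, 1L, mean)
}

#' CSA feature fusion
#'
#' Scales each channel row of a feature matrix by its mean similarity
#' `M_C[c]` and attention coefficient `A_C[c]`:
#' `fused row c = X_c * M_C[c] * A_C[c]`.
#'
#' @param x A `C x L` feature matrix.
#' @param m_c Length-`C` mean similarity profile (see [similarity_matrix()]).
#' @param a_c Length-`C` channel attention weights (see [channel_weights()]).
#' @return The fused `C x L` feature matrix.
#' @export
csa_fuse <- function(x, m_c, a_c) {
  if (!is.matrix(x)) stop_rbpnn("csa_fuse expects a feature matrix")
  if (length(m_c) != nrow(x) || length(a_c) != nrow(x)) {
    stop_rbpnn("csa_fuse: weight length (%d / %d) does not match %d channels",
               length(m_c), length(a_c), nrow(x))
  }
  x * (m_c * a_c)
}

#' Reference-side CSA channel weights
#'
#' The weight profile a prototype (kernel center) feature matrix `z` induces
#' on the CSA distance: `w_c` is proportional to `M_C[c] * A_c[c]` of `z`,
#' with negative products clamped to zero and the vector renormalized to sum
#' to 1. If every product is non-positive the profile falls back to uniform
#' weights with a warning.
#'
#' @param z A `C x L` reference feature matrix.
#' @return A length-`C` non-negative weight vector summing to 1.
#' @export
csa_weights <- function(z) {
  m_c <- similarity_matrix(z)$M_C
  a_c <- channel_weights(z)
  w <- pmax(m_c * a_c, 0)
  s <- sum(w)
  if (s <= .Machine$double.eps) {
    warning("csa_weights: non-positive channel profile; using uniform weights",
            call. = FALSE)
    return(rep(1 / nrow(z), nrow(z)))
  }
  w / s
}

#' CSA distance between a feature matrix and a reference prototype
#'
#' The weighted cosine dissimilarity
#' `d = sum_c w_c * (1 - cos(F_c, Z_c))` over channel rows, with the weights
#' `w_c` taken from the reference (prototype) side via [csa_weights()] so each
#' prototype defines its own channel attention profile. The distance lies in
#' `[0, 2]`, is 0 iff every channel pair is positively collinear, and its
#' cosine terms are invariant to positive per-row rescaling of either
#' argument.
#'
#' @param f A `C x L` feature matrix (the query).
#' @param z A `C x L` reference feature matrix (the prototype).
#' @param w Optional precomputed reference weights (length `C`, sums to 1);
#'   computed from `z` when `NULL`.
#' @return A single number in `[0, 2]`.
#' @export
csa_distance <- function(f, z, w = NULL) {
  if (!is.matrix(f) || !is.matrix(z) || any(dim(f) != dim(z))) {
    stop_rbpnn("csa_distance: feature matrices must share one shape")
  }
  if (is.null(w)) w <- csa_weights(z)
  nf <- normalize_rows(f)$x
  nz <- normalize_rows(z)$x
  cosines <- rowSums(nf * nz)
  sum(w * (1 - cosines))
}

# Pairwise CSA distances within a list of feature matrices.
# D[i, k] = csa_distance(features[[i]], features[[k]]), reference = column k.
# Shared per-channel Gram matrices make this O(C * N^2 * L).
csa_distance_matrix <- function(features, weights = NULL) {
  n <- length(features)
  if (n < 1L) stop_rbpnn("csa_distance_matrix: empty feature list")
  ch <- nrow(features[[1L]])
  if (is.null(weights)) weights <- lapply(features, csa_weights)
  w <- matrix(unlist(weights), nrow = ch)
  normed <- lapply(features, function(f) normalize_rows(f)$x)
  d <- matrix(0, n, n)
  for (c in seq_len(ch)) {
    xc <- t(vapply(normed, function(f) f[c, ], numeric(ncol(features[[1L]]))))
    g <- tcrossprod(xc)
    d <- d + sweep(1 - g, 2L, w[c, ], "*")
  }
  pmax(d, 0)
}

# Distances from each of a list of query features to each of a list of
# prototypes (columns). Reference weights come from the prototype side.
csa_cross_distance <- function(features, centers, center_weights = NULL) {
  if (is.null(center_weights)) center_weights <- lapply(centers, csa_weights)
  ch <- nrow(centers[[1L]])
  len <- ncol(centers[[1L]])
  w <- matrix(unlist(center_weights), nrow = ch)
  normed_f <- lapply(features, function(f) normalize_rows(f)$x)
  normed_z <- lapply(centers, function(z) normalize_rows(z)$x)
  d <- matrix(0, length(features), length(centers))
  for (c in seq_len(ch)) {
    fc <- t(vapply(normed_f, function(f) f[c, ], numeric(len)))
    zc <- t(vapply(normed_z, function(z) z[c, ], numeric(len)))
    g <- tcrossprod(fc, zc)
    d <- d + sweep(1 - g, 2L, w[c, ], "*")
  }
  pmax(d, 0)
}
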