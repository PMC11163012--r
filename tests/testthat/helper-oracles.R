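# Explicit-loop reference implementations, kept deliberately naive and
# independent of the package's vectorized code paths.

oracle_cosine <- function(a, b) {
  num <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    num <- num + a[i] * b[i]
    na <- na + a[i]^2
    nb <- nb + b[i]^2
  }
  if (na == 0 || nb == 0) return(0)
  num / (sqrt(na) * sqrt(nb))
}

oracle_similarity_matrix <- function(x) {
  ch <- nrow(x)
  m <- matrix(0, ch, ch)
  for (i in seq_len(ch)) for (j in seq_len(ch)) {
    m[i, j] <- oracle_cosine(x[i, ], x[j, ])
  }
  m01 <- (m + 1) / 2
  mn <- m01
  for (i in seq_len(ch)) {
    s <- sum(m01[i, ])
    mn[i, ] <- if (s > 0) m01[i, ] / s else rep(1 / ch, ch)
  }
  list(M = m, M_norm = mn, M_C = rowMeans(mn))
}

oracle_channel_weights <- function(x) {
  if (is.matrix(x)) return(apply(x, 1L, function(r) sum(r) / length(r)))
  apply(x, 1L, function(sl) sum(sl) / length(sl))
}

oracle_csa_weights <- function(z) {
  w <- oracle_similarity_matrix(z)$M_C * oracle_channel_weights(z)
  w[w < 0] <- 0
  if (sum(w) <= .Machine$double.eps) return(rep(1 / nrow(z), nrow(z)))
  w / sum(w)
}

oracle_csa_distance <- function(f, z, w = NULL) {
  if (is.null(w)) w <- oracle_csa_weights(z)
  d <- 0
  for (c in seq_len(nrow(f))) {
    d <- d + w[c] * (1 - oracle_cosine(f[c, ], z[c, ]))
  }
  d
}

oracle_csa_fuse <- function(x, m_c, a_c) {
  out <- x
  for (c in seq_len(nrow(x))) out[c, ] <- x[c, ] * m_c[c] * a_c[c]
  out
}

# Dense evaluation of the spatial attention equations on one map.
oracle_spatial_attention <- function(t_a, state) {
  d <- dim(t_a)
  n <- d[2L] * d[3L]
  # flatten row-major (position p = (i-1)*W + j)
  x <- matrix(0, d[1L], n)
  for (i in seq_len(d[2L])) for (j in seq_len(d[3L])) {
    x[, (i - 1L) * d[3L] + j] <- t_a[, i, j]
  }
  b <- state$proj_b$W %*% x + state$proj_b$b
  cc <- state$proj_c$W %*% x + state$proj_c$b
  v <- state$proj_d$W %*% x + state$proj_d$b
  t_s <- matrix(0, n, n)
  for (jj in seq_len(n)) {
    e <- numeric(n)
    for (ii in seq_len(n)) e[ii] <- exp(sum(b[, ii] * cc[, jj]) - max(sapply(seq_len(n), function(k) sum(b[, k] * cc[, jj]))))
    t_s[jj, ] <- e / sum(e)
  }
  out <- matrix(0, d[1L], n)
  for (jj in seq_len(n)) {
    acc <- numeric(d[1L])
    for (ii in seq_len(n)) acc <- acc + t_s[jj, ii] * v[, ii]
    out[, jj] <- acc
  }
  t_p <- t_a
  for (i in seq_len(d[2L])) for (j in seq_len(d[3L])) {
    p <- (i - 1L) * d[3L] + j
    t_p[, i, j] <- state$delta * out[, p] + t_a[, i, j]
  }
  list(t_p = t_p, t_s = t_s)
}

oracle_channel_attention <- function(t_a, state) {
  d <- dim(t_a)
  n <- d[2L] * d[3L]
  x <- matrix(0, d[1L], n)
  for (i in seq_len(d[2L])) for (j in seq_len(d[3L])) {
    x[, (i - 1L) * d[3L] + j] <- t_a[, i, j]
  }
  ch <- d[1L]
  t_x <- matrix(0, ch, ch)
  for (jj in seq_len(ch)) {
    e <- sapply(seq_len(ch), function(ii) sum(x[ii, ] * x[jj, ]))
    e <- exp(e - max(e))
    t_x[jj, ] <- e / sum(e)
  }
  out <- t_x %*% x
  t_q <- t_a
  for (i in seq_len(d[2L])) for (j in seq_len(d[3L])) {
    p <- (i - 1L) * d[3L] + j
    t_q[, i, j] <- state$epsilon * out[, p] + t_a[, i, j]
  }
  list(t_q = t_q, t_x = t_x)
}

oracle_density <- function(dmat) {
  n <- nrow(dmat)
  total <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) total <- total + dmat[i, k]^2
  r_d <- 0.5 * sqrt(total / (n * (n - 1)))
  f_d <- 4 / r_d^2
  d_vec <- numeric(n)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) d_vec[i] <- d_vec[i] + 1 / (1 + f_d * dmat[i, k]^2)
  }
  d_vec
}

oracle_coupling <- function(membership, centers, dmat) {
  n <- nrow(dmat)
  total <- 0
  for (i in seq_len(n)) total <- total + dmat[i, centers[membership[i]]]^2
  total / n
}

oracle_separation <- function(centers, dmat) {
  k <- length(centers)
  total <- 0
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
    d <- (dmat[centers[i], centers[j]] + dmat[centers[j], centers[i]]) / 2
    total <- total + d^2
  }
  total / (k * (k - 1) / 2)
}

oracle_rbpn_h <- function(d, sigma_k, a, c_smooth) {
  1 / (1 + exp(-a * (-(d^2) / sigma_k^2) - c_smooth))
}

oracle_softmax <- function(q, theta) {
  k <- nrow(theta)
  logits <- sapply(seq_len(k), function(l) sum(theta[l, ] * q))
  e <- exp(logits - max(logits))
  e / sum(e)
}
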