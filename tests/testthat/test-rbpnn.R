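# A minimal bank over explicit prototype features, used across head tests.
toy_bank <- function(centers, classes) {
  omega <- split(seq_along(classes), classes)
  names(omega) <- NULL
  structure(list(centers = centers, class = as.integer(classes),
                 omega = omega, m_k = vapply(omega, length, integer(1)),
                 m = length(centers), n_classes = max(classes),
                 center_weights = lapply(centers, function(z) {
                   suppressWarnings(csa_weights(z))
                 })),
            class = "kernel_center_bank")
}

test_that("sigma estimation is the RMS nearest-center distance with a floor", {
  c1 <- matrix(c(1, 0, 0, 1), 2, 2)
  bank <- toy_bank(list(c1, -c1), c(1L, 2L))
  # all class samples exactly at their centers -> floor
  sig <- suppressWarnings(
    estimate_sigma(list(c1, c1, -c1), c(1L, 1L, 2L), bank))
  expect_equal(sig, c(1e-6, 1e-6))
  # distances {1, 1} from the center -> sigma 1
  f_orth <- matrix(c(0, 1, 1, 0), 2, 2)   # rows orthogonal to c1's rows
  sig2 <- suppressWarnings(
    estimate_sigma(list(f_orth, f_orth, -c1), c(1L, 1L, 2L), bank))
  expect_equal(sig2[1], 1, tolerance = 1e-12)
  # order invariance
  feats <- lapply(1:6, function(i) random_feature(2, 2, seed = i,
                                                  positive = TRUE))
  labs <- c(1L, 1L, 1L, 2L, 2L, 2L)
  s_a <- suppressWarnings(estimate_sigma(feats, labs, bank))
  perm <- c(3L, 1L, 2L, 6L, 4L, 5L)
  s_b <- suppressWarnings(estimate_sigma(feats[perm], labs[perm], bank))
  expect_equal(s_a, s_b, tolerance = 1e-14)
  expect_error(suppressWarnings(estimate_sigma(feats[1:3], c(1L, 1L, 1L),
                                               bank)), "class 2")
})

test_that("the RBPN kernel matches scalar evaluation and is monotone", {
  c1 <- matrix(c(1, 0, 0, 1), 2, 2)
  f_orth <- matrix(c(0, 1, 1, 0), 2, 2)     # csa distance exactly 1
  bank <- toy_bank(list(c1), 1L)
  cfg <- rbpn_config(a = 1, c_smooth = 0, sigma = 1, calibrate = FALSE)
  h0 <- suppressWarnings(rbpn_forward(c1, bank, cfg))
  expect_equal(h0, 0.5)                     # d = 0 -> sigmoid at 0
  h1 <- suppressWarnings(rbpn_forward(f_orth, bank, cfg))
  expect_equal(h1, oracle_rbpn_h(1, 1, 1, 0), tolerance = 1e-12)
  # grid of distances: h strictly decreasing in d for a > 0
  dgrid <- seq(0, 2, by = 0.25)
  hvals <- 1 / (1 + exp(1 * dgrid^2 / 1 - 0))
  expect_true(all(diff(hvals) < 0))
  expect_error(suppressWarnings(rbpn_forward(matrix(1, 3, 2), bank, cfg)),
               "shape")
  expect_error(rbpn_forward(c1, bank, rbpn_config(a = 1)), "sigma")
})

test_that("kernel activations match the explicit oracle on random instances", {
  set.seed(77)
  for (rep in 1:10) {
    m <- sample(3:10, 1)
    classes <- sort(c(1:3, sample(1:3, m - 3, replace = TRUE)))[seq_len(m)]
    classes <- sort(classes)
    classes[1] <- 1L; classes[m] <- 3L
    if (!all(1:3 %in% classes)) classes[2] <- 2L
    classes <- sort(classes)
    centers <- lapply(seq_len(m), function(i) random_feature(3, 6,
                                                             seed = rep * 20 + i,
                                                             positive = TRUE))
    bank <- toy_bank(centers, classes)
    sigma <- runif(3, 0.2, 1.5)
    cfg <- rbpn_config(a = runif(1, 0.5, 2), c_smooth = runif(1, -1, 1),
                       sigma = sigma, calibrate = FALSE)
    f <- random_feature(3, 6, seed = rep + 500, positive = TRUE)
    h <- suppressWarnings(rbpn_forward(f, bank, cfg))
    expect_true(all(h > 0 & h < 1))
    for (j in seq_len(m)) {
      d <- suppressWarnings(csa_distance(f, centers[[j]],
                                         bank$center_weights[[j]]))
      expect_equal(h[j], oracle_rbpn_h(d, sigma[classes[j]], cfg$a,
                                       cfg$c_smooth), tolerance = 1e-9)
    }
    # aggregation is the selective per-class sum
    q <- pattern_aggregate(h, bank)
    for (k in 1:3) expect_equal(q[k], sum(h[classes == k]), tolerance = 1e-12)
    expect_true(all(q < bank$m_k))
    # permuting centers within a class leaves q unchanged
    perm <- seq_len(m)
    k1 <- which(classes == classes[1])
    if (length(k1) > 1) {
      perm[k1] <- rev(perm[k1])
      bank_p <- toy_bank(centers[perm], classes[perm])
      cfg_p <- cfg
      h_p <- suppressWarnings(rbpn_forward(f, bank_p, cfg_p))
      expect_equal(pattern_aggregate(h_p, bank_p), q, tolerance = 1e-12)
    }
  }
})

test_that("pattern aggregation sums constants exactly", {
  bank <- toy_bank(lapply(1:5, function(i) matrix(i, 2, 2)),
                   c(1L, 1L, 1L, 2L, 2L))
  expect_equal(pattern_aggregate(rep(0.5, 5), bank), c(1.5, 1.0))
})

test_that("softmax classification is stabilized, normalized and tie-broken", {
  theta <- diag(4)
  out <- rbpn_classify(rep(0, 4), theta)
  expect_equal(out$p, rep(0.25, 4))
  expect_equal(out$y, 1L)                   # tie -> smallest index
  out2 <- rbpn_classify(c(2, 1), diag(2))
  expect_equal(out2$p[1], exp(2) / (exp(2) + exp(1)), tolerance = 1e-12)
  expect_equal(out2$y, 1L)
  set.seed(99)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    q <- rnorm(k, sd = 5)
    th <- matrix(rnorm(k * k), k, k)
    got <- rbpn_classify(q, th)
    expect_equal(sum(got$p), 1, tolerance = 1e-9)
    expect_equal(got$p, oracle_softmax(q, th), tolerance = 1e-9)
  }
  # extreme magnitudes do not overflow thanks to max subtraction
  big <- rbpn_classify(c(1e4, 1e4 - 1), diag(2))
  expect_true(all(is.finite(big$p)))
  expect_error(rbpn_classify(c(NaN, 1), diag(2)), "non-finite")
})

test_that("head training descends, is seed-deterministic and honours lr = 0", {
  xor <- make_xor_features(30, seed = 21)
  bank <- suppressWarnings(
    select_typical_features(xor$features, xor$labels, dcm_config(),
                            fixed_c = 2))
  rb <- rbpn_config(calibrate = FALSE)
  rb$sigma <- suppressWarnings(estimate_sigma(xor$features, xor$labels, bank))
  d_tr <- suppressWarnings(csa_cross_distance_matrixed(xor$features, bank))
  fit <- train_rbpnn_head(d_tr, xor$labels, bank, rb, max_epochs = 5L,
                          seed = 2)
  expect_true(all(diff(fit$trace$loss[1:5]) < 0))
  fit2 <- train_rbpnn_head(d_tr, xor$labels, bank, rb, max_epochs = 5L,
                           seed = 2)
  expect_identical(fit$theta, fit2$theta)
  expect_identical(fit$rbpn$a, fit2$rbpn$a)
  frozen <- train_rbpnn_head(d_tr, xor$labels, bank, rb, learning_rate = 0,
                             max_epochs = 2L, seed = 2)
  expect_equal(frozen$theta, matrix(0, 2, 2))
  expect_equal(frozen$rbpn$a, rb$a)
  expect_error(train_rbpnn_head(d_tr[0, , drop = FALSE], integer(0), bank,
                                rb), "empty")
})

test_that("kernel and classifier gradients stay finite", {
  xor <- make_xor_features(10, seed = 31)
  bank <- suppressWarnings(
    select_typical_features(xor$features, xor$labels, dcm_config(),
                            fixed_c = 2))
  rb <- rbpn_config(calibrate = FALSE)
  rb$sigma <- suppressWarnings(estimate_sigma(xor$features, xor$labels, bank))
  d_tr <- suppressWarnings(csa_cross_distance_matrixed(xor$features, bank))
  fit <- train_rbpnn_head(d_tr, xor$labels, bank, rb, max_epochs = 3L,
                          seed = 5)
  expect_true(all(is.finite(fit$theta)))
  expect_true(is.finite(fit$rbpn$a) && fit$rbpn$a > 0)
  expect_true(is.finite(fit$rbpn$c_smooth))
  # numerical gradient of the kernel in d is finite across the domain
  eps <- 1e-6
  for (d in c(0, 0.1, 0.5, 1, 1.9)) {
    g <- (oracle_rbpn_h(d + eps, 0.7, 1.3, 0.2) -
            oracle_rbpn_h(d - eps, 0.7, 1.3, 0.2)) / (2 * eps)
    expect_true(is.finite(g))
  }
  # numerical gradient of the CSA distance in a feature entry is finite
  f <- random_feature(2, 4, seed = 1, positive = TRUE)
  z <- random_feature(2, 4, seed = 2, positive = TRUE)
  w <- suppressWarnings(csa_weights(z))
  f2 <- f; f2[1, 1] <- f2[1, 1] + eps
  f3 <- f; f3[1, 1] <- f3[1, 1] - eps
  gd <- (suppressWarnings(csa_distance(f2, z, w)) -
           suppressWarnings(csa_distance(f3, z, w))) / (2 * eps)
  expect_true(is.finite(gd))
})

test_that("kernel calibration places activations in the responsive range", {
  xor <- make_xor_features(30, seed = 41)
  bank <- suppressWarnings(
    select_typical_features(xor$features, xor$labels, dcm_config(),
                            fixed_c = 2))
  sigma <- suppressWarnings(estimate_sigma(xor$features, xor$labels, bank))
  d_tr <- suppressWarnings(csa_cross_distance_matrixed(xor$features, bank))
  cal <- calibrate_kernel(d_tr, xor$labels, bank, sigma)
  expect_gt(cal$a, 0)
  e <- sweep(d_tr^2, 2, sigma[bank$class]^2, "/")
  h <- 1 / (1 + exp(cal$a * e - cal$c_smooth))
  own <- vapply(seq_len(nrow(h)), function(i) {
    max(h[i, bank$class == xor$labels[i]])
  }, numeric(1))
  cross <- vapply(seq_len(nrow(h)), function(i) {
    max(h[i, bank$class != xor$labels[i]])
  }, numeric(1))
  expect_gt(median(own), 0.75)
  expect_lt(median(cross), 0.25)
})

test_that("metrics match the hand-computed confusion matrix example", {
  truth <- c(rep(1, 4), rep(2, 6))
  pred <- c(1, 1, 1, 2, 1, 1, 2, 2, 2, 2)
  cm <- confusion_matrix(truth, pred)
  expect_equal(cm, matrix(c(3L, 2L, 1L, 4L), 2, 2))
  m <- classification_metrics(cm)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$per_class$recall[1], 0.75)
  expect_equal(m$per_class$precision[1], 0.6)
  # permuting the test order changes nothing
  perm <- sample(10)
  expect_equal(classification_metrics(confusion_matrix(truth[perm],
                                                       pred[perm]))$f1,
               m$f1)
  # perfect predictions -> everything 1 and a diagonal matrix
  p <- classification_metrics(confusion_matrix(1:3, 1:3))
  expect_equal(p$accuracy, 1)
  expect_equal(p$f1, 1)
  expect_true(all(p$confusion[upper.tri(p$confusion)] == 0))
  # zero-denominator classes contribute 0 with a warning
  expect_warning(z <- classification_metrics(confusion_matrix(c(1, 1), c(1, 1),
                                                              n_classes = 2)),
                 "zero")
  expect_equal(z$per_class$recall[2], 0)
  expect_error(confusion_matrix(c(1, 5), c(1, 1), n_classes = 2), "labels")
  # weighted averaging weights by class support
  w <- classification_metrics(cm, average = "weighted")
  expect_equal(w$recall, (4 * 0.75 + 6 * (4 / 6)) / 10)
})
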