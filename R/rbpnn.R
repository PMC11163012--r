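# The RBPN layer and classifier head: per-class kernel width estimation, the
# exponential-sigmoid radial basis forward pass over embedded prototype
# centers, selective pattern aggregation by class, the softmax classifier,
# mini-batch gradient-descent training, and evaluation metrics.

#' RBPN kernel configuration
#'
#' @param a Kernel slope (smoothing parameter), positive. Larger `a` makes
#'   the activation decay faster with CSA distance.
#' @param c_smooth Kernel offset (smoothing parameter); the activation at
#'   distance 0 is `sigmoid(c_smooth)`.
#' @param sigma Per-class kernel widths `sigma_k` (positive); usually
#'   estimated from training data via [estimate_sigma()].
#' @param trainable_kernel_params Whether [train_rbpnn_head()] updates `a`
#'   and `c_smooth` by gradient descent alongside the softmax weights.
#' @param calibrate Whether the fitting pipeline re-initializes `a` and
#'   `c_smooth` from training-set margin statistics before gradient descent
#'   (see [calibrate_kernel()]).
#' @return An object of class `rbpn_config`.
#' @export
rbpn_config <- function(a = 1, c_smooth = 0, sigma = NULL,
                        trainable_kernel_params = TRUE, calibrate = TRUE) {
  if (!is.numeric(a) || length(a) != 1L || a <= 0) {
    stop_rbpnn("kernel slope 'a' must be a single positive number")
  }
  if (!is.null(sigma) && any(sigma <= 0)) {
    stop_rbpnn("all sigma_k must be positive")
  }
  structure(list(a = a, c_smooth = c_smooth, sigma = sigma,
                 trainable_kernel_params = isTRUE(trainable_kernel_params),
                 calibrate = isTRUE(calibrate)),
            class = "rbpn_config")
}

#' Estimate per-class kernel widths
#'
#' `sigma_k^2` is the mean, over class-`k` training features, of the squared
#' CSA distance to the nearest class-`k` kernel center; `sigma_k` is floored
#' at `1e-6` so classes whose samples coincide with their centers keep a
#' positive width.
#'
#' @param features List of `C x L` feature matrices (training set).
#' @param class_labels Integer class labels in `1..K`.
#' @param bank A `kernel_center_bank`.
#' @return Length-`K` numeric vector of kernel widths.
#' @export
estimate_sigma <- function(features, class_labels, bank) {
  class_labels <- as.integer(class_labels)
  sigma <- numeric(bank$n_classes)
  for (k in seq_len(bank$n_classes)) {
    idx <- which(class_labels == k)
    if (length(idx) == 0L) stop_rbpnn("class %d has no training features", k)
    ctr <- bank$omega[[k]]
    d <- csa_cross_distance(features[idx], bank$centers[ctr],
                            bank$center_weights[ctr])
    d_min <- apply(d, 1L, min)
    sigma[k] <- max(sqrt(mean(d_min^2)), 1e-6)
  }
  sigma
}

#' Calibrate kernel smoothing parameters from training margins
#'
#' Places the exponential sigmoid's transition between the two distance
#' scales the classifier must separate. With kernel exponents
#' `e = d^2 / sigma_k^2`, let `m_own` be the median exponent from a training
#' feature to its nearest same-class center and `m_cross` the median to its
#' nearest other-class center. The slope and offset are set to
#' `a = 4 / (m_cross - m_own)` and `c_smooth = a (m_cross + m_own) / 2`, so a
#' typical same-class query activates at about `sigmoid(2) = 0.88` and a
#' typical cross-class query at about `0.12`. This is a bandwidth-style
#' initialization (the smoothing parameters remain trainable); without it the
#' activations of all centers sit in the sigmoid's exponential tail, where a
#' class with several moderately distant centers can outsum the correct
#' class's single near center.
#'
#' @param d_train `n x m` matrix of CSA distances from training features to
#'   kernel centers.
#' @param labels Integer class labels in `1..K`.
#' @param bank A `kernel_center_bank`.
#' @param sigma Length-`K` kernel widths (see [estimate_sigma()]).
#' @return A list with `a` and `c_smooth`.
#' @export
calibrate_kernel <- function(d_train, labels, bank, sigma) {
  labels <- as.integer(labels)
  e <- sweep(d_train^2, 2L, sigma[bank$class]^2, "/")
  n <- nrow(e)
  own <- vapply(seq_len(n), function(i) {
    min(e[i, bank$class == labels[i]])
  }, numeric(1))
  cross <- vapply(seq_len(n), function(i) {
    min(e[i, bank$class != labels[i]])
  }, numeric(1))
  m_own <- stats::median(own)
  m_cross <- stats::median(cross)
  a <- 4 / max(m_cross - m_own, 1e-3)
  list(a = a, c_smooth = a * (m_cross + m_own) / 2)
}

#' RBPN layer forward pass
#'
#' For every kernel center `z_kl` in the bank, with `d` the CSA distance from
#' the input feature to the center, the activation is the exponential sigmoid
#' `h_kl = 1 / (1 + exp(a * d^2 / sigma_k^2 - c_smooth))`: maximal
#' (`sigmoid(c_smooth)`) at `d = 0` and strictly decreasing in `d`, so the
#' neuron behaves as a bounded similarity in `(0, 1)`. Scaling the squared
#' distance by the squared class width `sigma_k^2` (the radial-basis form)
#' makes the kernel self-normalizing: a query at a typical within-subclass
#' distance sees an exponent near `a`, whatever the absolute distance scale.
#'
#' @param f A `C x L` feature matrix, or a list of them.
#' @param bank A `kernel_center_bank`.
#' @param config An [rbpn_config()] whose `sigma` is set.
#' @return For a single feature, a length-`m` activation vector ordered like
#'   the bank; for a list, an `n x m` matrix.
#' @export
rbpn_forward <- function(f, bank, config) {
  if (is.null(config$sigma)) stop_rbpnn("config$sigma is not set")
  single <- is.matrix(f)
  feats <- if (single) list(f) else f
  if (any(dim(feats[[1L]]) != dim(bank$centers[[1L]]))) {
    stop_rbpnn("feature shape %s does not match kernel center shape %s",
               paste(dim(feats[[1L]]), collapse = "x"),
               paste(dim(bank$centers[[1L]]), collapse = "x"))
  }
  d <- csa_cross_distance(feats, bank$centers, bank$center_weights)
  sig2 <- config$sigma[bank$class]^2
  z <- sweep(d^2, 2L, sig2, "/") * config$a - config$c_smooth
  h <- 1 / (1 + exp(z))
  if (single) h[1L, ] else h
}

#' Pattern aggregation layer
#'
#' Selectively sums RBPN activations whose kernel centers share a class:
#' `q_k = sum_{j in Omega_k} h_j`, merging subclass responses into one class
#' response (and subclass boundaries into a possibly non-convex class
#' boundary).
#'
#' @param h Length-`m` activation vector or `n x m` activation matrix.
#' @param bank A `kernel_center_bank`.
#' @return Length-`K` vector or `n x K` matrix of aggregated responses.
#' @export
pattern_aggregate <- function(h, bank) {
  if (is.matrix(h)) {
    q <- vapply(bank$omega,
                function(idx) rowSums(h[, idx, drop = FALSE]),
                numeric(nrow(h)))
    matrix(q, nrow = nrow(h))
  } else {
    vapply(bank$omega, function(idx) sum(h[idx]), numeric(1))
  }
}

#' Softmax classification of aggregated pattern responses
#'
#' `p_k = exp(theta_k . q) / sum_l exp(theta_l . q)` with max-subtraction
#' stabilization; the predicted class is the argmax of `p`, ties breaking
#' toward the smallest class index.
#'
#' @param q Length-`K` vector or `n x K` matrix of pattern responses.
#' @param theta `K x K` weight matrix (row `k` holds `theta_k`).
#' @return A list with `p` (probabilities, rows sum to 1) and `y` (predicted
#'   class indices).
#' @export
rbpn_classify <- function(q, theta) {
  qm <- if (is.matrix(q)) q else matrix(q, nrow = 1L)
  if (!all(is.finite(qm))) stop_rbpnn("non-finite pattern responses")
  logits <- qm %*% t(theta)
  p <- row_softmax(logits)
  y <- max.col(p, ties.method = "first")
  if (is.matrix(q)) list(p = p, y = y) else list(p = p[1L, ], y = y[1L])
}

#' Train the RBPNN head by mini-batch gradient descent
#'
#' Minimizes multinomial cross-entropy over the softmax weights `theta`
#' (and, when `rbpn$trainable_kernel_params` is `TRUE`, the kernel smoothing
#' parameters `a` and `c_smooth`, whose gradients flow through the
#' exponential-sigmoid activations) while the kernel centers stay frozen.
#' Each epoch visits a seeded shuffle of the training set in mini-batches;
#' training stops when the epoch loss drops to `error_tolerance` or after
#' `max_epochs`.
#'
#' @param d_train `n x m` matrix of CSA distances from training features to
#'   the bank's kernel centers (as produced inside [rbpn_forward()]); kept
#'   fixed during training since centers and features are frozen.
#' @param labels Integer class labels in `1..K`.
#' @param bank A `kernel_center_bank`.
#' @param rbpn An [rbpn_config()] with `sigma` set.
#' @param learning_rate Positive step size (default 0.01).
#' @param batch_size Mini-batch size (default 10).
#' @param max_epochs Maximum epochs (default 20).
#' @param error_tolerance Stop when mean epoch loss falls below this value
#'   (default 0.05).
#' @param seed Integer seed for the per-epoch shuffles.
#' @return A list with `theta`, the updated `rbpn` config, and `trace`
#'   (data frame of per-epoch loss and accuracy).
#' @export
train_rbpnn_head <- function(d_train, labels, bank, rbpn,
                             learning_rate = 0.01, batch_size = 10L,
                             max_epochs = 20L, error_tolerance = 0.05,
                             seed = 1L) {
  if (!is.numeric(learning_rate) || learning_rate < 0) {
    stop_rbpnn("learning_rate must be non-negative")
  }
  batch_size <- check_count(batch_size, "batch_size")
  n <- nrow(d_train)
  if (n == 0L) stop_rbpnn("empty training set")
  k_classes <- bank$n_classes
  labels <- as.integer(labels)
  y_onehot <- matrix(0, n, k_classes)
  y_onehot[cbind(seq_len(n), labels)] <- 1
  theta <- matrix(0, k_classes, k_classes)
  a <- rbpn$a
  c_smooth <- rbpn$c_smooth
  sig2 <- rbpn$sigma[bank$class]^2
  d_scaled <- sweep(d_train^2, 2L, sig2, "/") # d^2 / sigma_k^2, fixed
  agg <- matrix(0, bank$m, k_classes)          # aggregation operator
  agg[cbind(seq_len(bank$m), bank$class)] <- 1

  forward <- function(idx) {
    z <- d_scaled[idx, , drop = FALSE] * a - c_smooth
    h <- 1 / (1 + exp(z))
    q <- h %*% agg
    p <- row_softmax(q %*% t(theta))
    list(h = h, q = q, p = p)
  }
  epoch_stats <- function() {
    fw <- forward(seq_len(n))
    loss <- -mean(log(pmax(fw$p[cbind(seq_len(n), labels)], 1e-12)))
    acc <- mean(max.col(fw$p, ties.method = "first") == labels)
    c(loss, acc)
  }

  trace_loss <- numeric(0)
  trace_acc <- numeric(0)
  with_local_seed(seed, {
    for (epoch in seq_len(max_epochs)) {
      order_idx <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- order_idx[start:min(start + batch_size - 1L, n)]
        b <- length(idx)
        fw <- forward(idx)
        if (!all(is.finite(fw$p))) {
          stop_rbpnn("training diverged (non-finite probabilities) at epoch %d",
                     epoch)
        }
        err <- fw$p - y_onehot[idx, , drop = FALSE]       # b x K
        grad_theta <- t(err) %*% fw$q / b                 # K x K
        if (rbpn$trainable_kernel_params) {
          grad_q <- err %*% theta                         # b x K
          grad_h <- grad_q %*% t(agg)                     # b x m
          dh_dz <- -fw$h * (1 - fw$h)
          gz <- grad_h * dh_dz
          grad_a <- sum(gz * d_scaled[idx, , drop = FALSE]) / b
          grad_c <- -sum(gz) / b
          a <- max(a - learning_rate * grad_a, 1e-6)
          c_smooth <- c_smooth - learning_rate * grad_c
        }
        theta <- theta - learning_rate * grad_theta
      }
      st <- epoch_stats()
      trace_loss <- c(trace_loss, st[1L])
      trace_acc <- c(trace_acc, st[2L])
      if (st[1L] <= error_tolerance) break
    }
  })
  rbpn$a <- a
  rbpn$c_smooth <- c_smooth
  list(theta = theta, rbpn = rbpn,
       trace = data.frame(epoch = seq_along(trace_loss),
                          loss = trace_loss, accuracy = trace_acc))
}

#' Confusion matrix
#'
#' @param truth,pred Integer class labels in `1..K`.
#' @param n_classes Number of classes `K` (default: max label seen).
#' @return A `K x K` matrix, rows = true class, columns = predicted class.
#' @export
confusion_matrix <- function(truth, pred, n_classes = max(truth, pred)) {
  truth <- as.integer(truth)
  pred <- as.integer(pred)
  if (any(truth < 1L | truth > n_classes) || any(pred < 1L | pred > n_classes)) {
    stop_rbpnn("labels outside 1..%d", n_classes)
  }
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(truth)) cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  cm
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is `trace / total`; per-class precision, recall and F1 are
#' combined by macro (unweighted mean) or weighted (by class support)
#' averaging. A class with a zero denominator contributes 0 to the average,
#' with a warning.
#'
#' @param cm Confusion matrix (rows = truth, columns = prediction).
#' @param average `"macro"` (default) or `"weighted"`.
#' @return A list with `accuracy`, `precision`, `recall`, `f1` (averaged),
#'   `per_class` (data frame), and the confusion matrix.
#' @export
classification_metrics <- function(cm, average = c("macro", "weighted")) {
  average <- match.arg(average)
  k <- nrow(cm)
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  zero_den <- predicted == 0 | support == 0
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1_den <- precision + recall
  f1 <- ifelse(f1_den > 0, 2 * precision * recall / f1_den, 0)
  if (any(zero_den)) {
    warning("classification_metrics: class(es) with zero support or zero ",
            "predictions contribute 0", call. = FALSE)
  }
  w <- if (average == "macro") rep(1 / k, k) else support / sum(support)
  list(accuracy = sum(tp) / sum(cm),
       precision = sum(w * precision),
       recall = sum(w * recall),
       f1 = sum(w * f1),
       per_class = data.frame(class = seq_len(k), support = support,
                              precision = precision, recall = recall, f1 = f1),
       confusion = cm)
}
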