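# Fixture builders shared across test files; everything is generated in code
# under fixed seeds.

with_seed_env <- function(seed, expr) rbpnn:::with_local_seed(seed, expr)

random_map <- function(ch, h, w, seed = 1) {
  set.seed(seed)
  array(rnorm(ch * h * w), dim = c(ch, h, w))
}

random_feature <- function(ch, len, seed = 1, positive = FALSE) {
  set.seed(seed)
  m <- matrix(rnorm(ch * len), ch, len)
  if (positive) abs(m) else m
}

# Two-class XOR arrangement in a 1-channel, 2-column feature space: class 1
# occupies two opposite angular modes, class 2 the two modes in between.
# Angle is all the CSA metric sees, so each class is a non-convex union.
make_xor_features <- function(n_per_mode, noise_sd = 0.5, seed = 1) {
  modes <- list(c(-7, 7), c(7, -7), c(7, 7), c(-7, -7))
  mode_class <- c(1L, 1L, 2L, 2L)
  set.seed(seed)
  feats <- list()
  labels <- integer(0)
  for (m in seq_along(modes)) {
    for (i in seq_len(n_per_mode)) {
      feats[[length(feats) + 1L]] <- matrix(modes[[m]] + rnorm(2, sd = noise_sd),
                                            1, 2)
      labels <- c(labels, mode_class[m])
    }
  }
  list(features = feats, labels = labels)
}

# Fit the RBPN head on precomputed features with a bank of fixed_c prototypes
# per class and reference kernel parameters, then return test accuracy.
xor_accuracy <- function(train, test, prototypes_per_class, seed = 3) {
  bank <- suppressWarnings(
    select_typical_features(train$features, train$labels, dcm_config(),
                            fixed_c = prototypes_per_class))
  rb <- rbpn_config(calibrate = FALSE)
  rb$sigma <- suppressWarnings(estimate_sigma(train$features, train$labels, bank))
  d_tr <- suppressWarnings(
    csa_cross_distance_matrixed(train$features, bank))
  fit <- train_rbpnn_head(d_tr, train$labels, bank, rb, seed = seed)
  d_te <- suppressWarnings(csa_cross_distance_matrixed(test$features, bank))
  sig2 <- fit$rbpn$sigma[bank$class]^2
  h <- 1 / (1 + exp(sweep(d_te^2, 2, sig2, "/") * fit$rbpn$a - fit$rbpn$c_smooth))
  q <- pattern_aggregate(h, bank)
  mean(rbpn_classify(q, fit$theta)$y == test$labels)
}

# Distances from features to a bank's centers via exported primitives.
csa_cross_distance_matrixed <- function(features, bank) {
  t(vapply(features, function(f) {
    vapply(seq_along(bank$centers), function(j) {
      csa_distance(f, bank$centers[[j]], bank$center_weights[[j]])
    }, numeric(1))
  }, numeric(length(bank$centers))))
}

# Small labeled image experiment shared by pipeline tests.
tiny_image_split <- function(n_train = 50L, n_test = 17L, seed = 101L) {
  full <- generate_image_set(synthetic_spec(
    n_classes = 4L, subclasses_per_class = 3L,
    samples_per_subclass = n_train + n_test, seed = seed))
  split_image_set(full, n_train)
}
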