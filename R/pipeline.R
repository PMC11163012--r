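# End-to-end model: preprocessing -> backbone stages -> FPN -> PPM -> mixed
# attention -> comprehensive feature matrix -> DCM prototype bank -> RBPN
# layer -> pattern aggregation -> softmax head. The extractor weights are
# initialized deterministically and frozen; the prototype bank is built from
# the frozen features; mini-batch gradient descent trains the head-side
# parameters (softmax weights and, by default, the kernel smoothing
# parameters).

#' Full pipeline configuration
#'
#' @param backbone A [backbone_config()].
#' @param dcm A [dcm_config()].
#' @param rbpn An [rbpn_config()].
#' @param learning_rate,batch_size,max_epochs,error_tolerance Mini-batch
#'   gradient-descent settings (defaults 0.01, 10, 20, 0.05).
#' @param normalize_mean,normalize_sd Per-channel intensity normalization
#'   applied after resizing. `NULL` (default) computes the statistics from
#'   the training images at fit time, the standard dataset-statistics
#'   normalization (of which the familiar ImageNet constants are an
#'   instance); pass explicit vectors (e.g. the ImageNet values) to override.
#' @param seed Integer seed controlling weight initialization, training
#'   shuffles and dropout.
#' @return An object of class `rbpnn_pipeline_config`.
#' @export
rbpnn_pipeline_config <- function(backbone = backbone_config("tiny"),
                                  dcm = dcm_config(),
                                  rbpn = rbpn_config(),
                                  learning_rate = 0.01, batch_size = 10L,
                                  max_epochs = 20L, error_tolerance = 0.05,
                                  normalize_mean = NULL, normalize_sd = NULL,
                                  seed = 1L) {
  structure(list(backbone = backbone, dcm = dcm, rbpn = rbpn,
                 learning_rate = learning_rate,
                 batch_size = check_count(batch_size, "batch_size"),
                 max_epochs = check_count(max_epochs, "max_epochs"),
                 error_tolerance = error_tolerance,
                 normalize_mean = normalize_mean,
                 normalize_sd = normalize_sd,
                 seed = as.integer(seed)),
            class = "rbpnn_pipeline_config")
}

# Per-channel mean and standard deviation over a list of images, used as the
# default intensity normalization (dataset statistics).
dataset_channel_stats <- function(images, in_channels) {
  sums <- numeric(in_channels)
  sq <- numeric(in_channels)
  count <- 0
  for (img in images) {
    x <- image_to_channels(img, in_channels)
    px <- prod(dim(x)[2:3])
    sums <- sums + apply(x, 1L, sum)
    sq <- sq + apply(x, 1L, function(v) sum(v^2))
    count <- count + px
  }
  mu <- sums / count
  sd_ <- sqrt(pmax(sq / count - mu^2, 1e-12))
  list(mean = mu, sd = sd_)
}

# Arrange an image as a channels-first array with the backbone's channel
# count (grayscale replicated if a 3-channel backbone is used).
image_to_channels <- function(img, in_channels) {
  if (is.matrix(img)) {
    x <- array(img, dim = c(1L, nrow(img), ncol(img)))
  } else if (is.array(img) && length(dim(img)) == 3L) {
    d <- dim(img)
    x <- if (d[3L] <= 4L && d[1L] > 4L) aperm(img, c(3L, 1L, 2L)) else img
  } else {
    stop_rbpnn("unsupported image shape")
  }
  if (dim(x)[1L] == 1L && in_channels == 3L) x <- abind_channels(x, x, x)
  if (dim(x)[1L] != in_channels) {
    stop_rbpnn("image has %d channels; backbone expects %d",
               dim(x)[1L], in_channels)
  }
  x
}

# Bring a user image (H x W matrix, H x W x ch array, or C x H x W array
# already in channel-first order) to the C x H x W, resized, normalized form
# the backbone expects.
preprocess_image <- function(img, config) {
  cfg <- config$backbone
  if (is.null(config$normalize_mean) || is.null(config$normalize_sd)) {
    stop_rbpnn("normalization statistics unset; fit the pipeline or pass them")
  }
  x <- image_to_channels(img, cfg$in_channels)
  x <- bilinear_resize(x, cfg$input_size, cfg$input_size)
  (x - config$normalize_mean) / config$normalize_sd
}

#' Extract comprehensive feature matrices for a batch of images
#'
#' Runs preprocessing, the stage stack, FPN fusion, pyramid pooling on the
#' finest fused level, mixed attention aggregation, and the profile-grid
#' flattening, returning one `C x L` comprehensive feature matrix per image.
#'
#' @param images List of images (`H x W` matrices or `H x W x ch` arrays).
#' @param extractor An initialized `rbpnn_backbone` (see [init_backbone()]).
#' @param config An [rbpnn_pipeline_config()].
#' @return List of `fpn_channels x profile_grid^2` feature matrices.
#' @export
extract_features <- function(images, extractor, config) {
  cfg <- config$backbone
  lapply(images, function(img) {
    x <- preprocess_image(img, config)
    stages <- vector("list", length(extractor$stages))
    for (s in seq_along(extractor$stages)) {
      x <- stage_forward(x, extractor$stages[[s]])
      stages[[s]] <- x
    }
    pyramid <- fpn_fuse(stages, extractor)
    context <- ppm_forward(pyramid[[1L]], extractor$ppm)
    enhanced <- aggregate_attention(context, extractor$attention)
    to_feature_matrix(enhanced, cfg$profile_grid)
  })
}

#' Fit a prototype-embedded RBPNN image classifier
#'
#' Initializes the frozen feature extractor, extracts comprehensive feature
#' matrices for the training images, selects the per-class prototype bank
#' with density-seeded dynamic C-means, estimates the per-class kernel
#' widths, and trains the classifier head by mini-batch gradient descent on
#' cross-entropy. Kernel centers stay frozen throughout.
#'
#' @param images List of training images.
#' @param labels Integer class labels in `1..K`.
#' @param config An [rbpnn_pipeline_config()].
#' @return An object of class `rbpnn_model`.
#' @export
rbpnn_fit <- function(images, labels, config = rbpnn_pipeline_config()) {
  if (length(images) == 0L) stop_rbpnn("empty training set")
  if (length(images) != length(labels)) {
    stop_rbpnn("images and labels lengths differ")
  }
  labels <- as.integer(labels)
  if (is.null(config$normalize_mean) || is.null(config$normalize_sd)) {
    stats <- dataset_channel_stats(images, config$backbone$in_channels)
    if (is.null(config$normalize_mean)) config$normalize_mean <- stats$mean
    if (is.null(config$normalize_sd)) config$normalize_sd <- stats$sd
  }
  extractor <- init_backbone(config$backbone, seed = config$seed)
  features <- extract_features(images, extractor, config)
  bank <- select_typical_features(features, labels, config$dcm)
  rbpn <- config$rbpn
  rbpn$sigma <- estimate_sigma(features, labels, bank)
  d_train <- csa_cross_distance(features, bank$centers, bank$center_weights)
  if (rbpn$calibrate) {
    cal <- calibrate_kernel(d_train, labels, bank, rbpn$sigma)
    rbpn$a <- cal$a
    rbpn$c_smooth <- cal$c_smooth
  }
  fit <- train_rbpnn_head(d_train, labels, bank, rbpn,
                          learning_rate = config$learning_rate,
                          batch_size = config$batch_size,
                          max_epochs = config$max_epochs,
                          error_tolerance = config$error_tolerance,
                          seed = config$seed)
  structure(list(config = config, extractor = extractor, bank = bank,
                 rbpn = fit$rbpn, theta = fit$theta, trace = fit$trace),
            class = "rbpnn_model")
}

#' @export
print.rbpnn_model <- function(x, ...) {
  cat("Prototype-embedded RBPNN classifier\n")
  cat("  classes:", x$bank$n_classes,
      "| prototypes per class:", paste(x$bank$m_k, collapse = ", "), "\n")
  cat("  kernel: a =", signif(x$rbpn$a, 4),
      "c =", signif(x$rbpn$c_smooth, 4),
      "| sigma =", paste(signif(x$rbpn$sigma, 4), collapse = ", "), "\n")
  if (nrow(x$trace) > 0L) {
    last <- x$trace[nrow(x$trace), ]
    cat(sprintf("  training: %d epochs, final loss %.4f, accuracy %.3f\n",
                last$epoch, last$loss, last$accuracy))
  }
  invisible(x)
}

#' Predict classes for new images
#'
#' @param object A fitted `rbpnn_model`.
#' @param images List of images.
#' @param ... Unused.
#' @return A list with `p` (`n x K` class probability matrix), `y`
#'   (predicted classes), `q` (pattern-aggregation responses), and `h`
#'   (RBPN activations).
#' @export
predict.rbpnn_model <- function(object, images, ...) {
  features <- extract_features(images, object$extractor, object$config)
  h <- rbpn_forward(features, object$bank, object$rbpn)
  q <- pattern_aggregate(h, object$bank)
  out <- rbpn_classify(q, object$theta)
  list(p = out$p, y = out$y, q = q, h = h)
}

#' Evaluate a fitted model on a labeled test set
#'
#' @param model A fitted `rbpnn_model`.
#' @param images List of test images.
#' @param labels Integer true labels in `1..K`.
#' @param average Metric averaging, `"macro"` (default) or `"weighted"`.
#' @return A [classification_metrics()] result.
#' @export
rbpnn_evaluate <- function(model, images, labels, average = "macro") {
  if (length(images) == 0L) stop_rbpnn("empty test set")
  pred <- predict(model, images)
  cm <- confusion_matrix(as.integer(labels), pred$y,
                         n_classes = model$bank$n_classes)
  classification_metrics(cm, average = average)
}

#' Fit and evaluate from a YAML configuration (command-line entry point)
#'
#' Thin driver used by the `inst/cli/rbpnn-cli.R` script: reads a YAML
#' configuration describing the synthetic data (or a manifest of images on
#' disk) plus pipeline settings, fits the model, and evaluates it on the test
#' split. All randomness derives from the single `seed`.
#'
#' @param config_path Path to a YAML file. Recognized keys mirror
#'   [rbpnn_pipeline_config()] and [synthetic_spec()]; see the packaged CLI
#'   script for an example.
#' @param seed Integer seed overriding the file's seed when non-`NULL`.
#' @return A list with `model`, `metrics`, and the parsed `config`.
#' @export
rbpnn_run <- function(config_path, seed = NULL) {
  raw <- yaml::read_yaml(config_path)
  if (!is.null(seed)) raw$seed <- as.integer(seed)
  if (is.null(raw$seed)) raw$seed <- 1L
  bk <- do.call(backbone_config, c(list(variant = raw$variant %||% "tiny"),
                                   raw$backbone %||% list()))
  dc <- do.call(dcm_config, c(raw$dcm %||% list(), list(seed = raw$seed)))
  rb <- do.call(rbpn_config, raw$rbpn %||% list())
  cfg <- rbpnn_pipeline_config(
    backbone = bk, dcm = dc, rbpn = rb,
    learning_rate = raw$learning_rate %||% 0.01,
    batch_size = raw$batch_size %||% 10L,
    max_epochs = raw$max_epochs %||% 20L,
    error_tolerance = raw$error_tolerance %||% 0.05,
    seed = raw$seed)
  if (!is.null(raw$train_manifest)) {
    train <- read_image_set(raw$train_manifest)
    test <- read_image_set(raw$test_manifest)
  } else {
    syn <- raw$synthetic %||% list()
    n_train <- syn$train_per_subclass %||% 50L
    n_test <- syn$test_per_subclass %||% 17L
    full <- generate_image_set(synthetic_spec(
      n_classes = syn$n_classes %||% 4L,
      subclasses_per_class = syn$subclasses_per_class %||% 3L,
      samples_per_subclass = n_train + n_test,
      image_size = bk$input_size,
      noise_sigma = syn$noise_sigma %||% 0.1,
      seed = raw$seed))
    halves <- split_image_set(full, n_train)
    train <- halves$train
    test <- halves$test
  }
  model <- rbpnn_fit(train$images, train$class_labels, cfg)
  metrics <- rbpnn_evaluate(model, test$images, test$class_labels)
  list(model = model, metrics = metrics, config = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
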