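# Synthetic labeled data with planted multi-subclass structure. Each class is
# a mixture of visually distinct sub-modes ("one disease, multiple
# symptoms"): a subclass is a fixed motif of a few small low-contrast
# Gaussian blobs, rendered with per-sample jitter and additive noise. Feature
# sets plant the analogous structure directly in feature-matrix space, with
# sparse non-negative channel profiles per cluster (mimicking post-ReLU
# activations) so clusters are separated in both the Euclidean and the CSA
# sense.

#' Specification of a synthetic labeled image set
#'
#' @param n_classes Number of classes `K >= 2`.
#' @param subclasses_per_class Integer vector (length 1 or `K`) of sub-mode
#'   counts per class, each `>= 1`.
#' @param samples_per_subclass Images rendered per sub-mode.
#' @param image_size Square image size in pixels.
#' @param target_radius_range Length-2 range of blob radii in pixels.
#' @param noise_sigma Additive Gaussian noise standard deviation on the
#'   `[0, 1]` intensity scale (default 0.1, a low-SNR regime relative to the
#'   0.35--0.65 blob amplitudes).
#' @param layout `"random"` places motif blobs at subclass-specific random
#'   positions; `"xor"` (2 classes x 2 subclasses only) places one blob per
#'   image in the XOR quadrant arrangement (class 1: top-left or
#'   bottom-right; class 2: top-right or bottom-left).
#' @param seed Integer seed; identical spec + seed gives a bit-identical set.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes, subclasses_per_class,
                           samples_per_subclass, image_size = 32L,
                           target_radius_range = c(2, 5), noise_sigma = 0.1,
                           layout = c("random", "xor"), seed = 1L) {
  layout <- match.arg(layout)
  n_classes <- check_count(n_classes, "n_classes", min = 2L)
  if (length(subclasses_per_class) == 1L) {
    subclasses_per_class <- rep(subclasses_per_class, n_classes)
  }
  if (length(subclasses_per_class) != n_classes) {
    stop_rbpnn("subclasses_per_class must have length 1 or n_classes")
  }
  subclasses_per_class <- vapply(seq_along(subclasses_per_class), function(i) {
    check_count(subclasses_per_class[i], sprintf("subclasses_per_class[%d]", i))
  }, integer(1))
  if (!is.numeric(noise_sigma) || length(noise_sigma) != 1L || noise_sigma < 0) {
    stop_rbpnn("noise_sigma must be a single number >= 0")
  }
  if (length(target_radius_range) != 2L || any(target_radius_range <= 0) ||
      target_radius_range[1L] > target_radius_range[2L]) {
    stop_rbpnn("target_radius_range must be an increasing pair of positive pixels")
  }
  if (layout == "xor" && (n_classes != 2L || any(subclasses_per_class != 2L))) {
    stop_rbpnn("layout 'xor' requires 2 classes with 2 subclasses each")
  }
  structure(list(n_classes = n_classes,
                 subclasses_per_class = subclasses_per_class,
                 samples_per_subclass = check_count(samples_per_subclass,
                                                    "samples_per_subclass"),
                 image_size = check_count(image_size, "image_size", min = 8L),
                 target_radius_range = as.numeric(target_radius_range),
                 noise_sigma = noise_sigma, layout = layout,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Render a sum of Gaussian blobs on an image_size^2 canvas.
render_blobs <- function(size, cx, cy, radius, amp, background = 0.1) {
  xs <- matrix(rep(seq_len(size), each = size), nrow = size)   # column index
  ys <- matrix(rep(seq_len(size), times = size), nrow = size)  # row index
  img <- matrix(background, size, size)
  for (b in seq_along(cx)) {
    img <- img + amp[b] * exp(-((xs - cx[b])^2 + (ys - cy[b])^2) / (2 * radius[b]^2))
  }
  img
}

#' Generate a labeled synthetic image set
#'
#' Draws one motif template per (class, subclass): a small set of Gaussian
#' blobs with fixed base positions, radii and amplitudes. Each sample jitters
#' the positions (+-1.5 px), radii (+-0.5 px) and amplitudes (+-0.05), adds
#' Gaussian pixel noise at `noise_sigma`, and clips to `[0, 1]`. Subclass
#' labels are ground truth for testing only; the training pipeline never
#' reads them.
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `labeled_image_set`: `images` (list of
#'   `H x W` matrices in `[0, 1]`), `class_labels` and `subclass_labels`
#'   (1-based integers; subclasses numbered globally), and `spec`.
#' @export
generate_image_set <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    stop_rbpnn("generate_image_set expects a synthetic_spec")
  }
  size <- spec$image_size
  rr <- spec$target_radius_range
  with_local_seed(spec$seed, {
    images <- list()
    class_labels <- integer(0)
    subclass_labels <- integer(0)
    global_sub <- 0L
    for (k in seq_len(spec$n_classes)) {
      for (s in seq_len(spec$subclasses_per_class[k])) {
        global_sub <- global_sub + 1L
        if (spec$layout == "xor") {
          q <- size / 4
          quadrants <- list(c(q, q), c(3 * q, 3 * q),     # class 1: TL, BR
                            c(3 * q, q), c(q, 3 * q))     # class 2: TR, BL
          centre <- quadrants[[(k - 1L) * 2L + s]]
          n_blobs <- 1L
          base_cx <- centre[1L]
          base_cy <- centre[2L]
        } else {
          n_blobs <- sample(1:3, 1L)
          margin <- rr[2L] + 1
          base_cx <- stats::runif(n_blobs, margin, size - margin)
          base_cy <- stats::runif(n_blobs, margin, size - margin)
        }
        base_r <- stats::runif(n_blobs, rr[1L], rr[2L])
        base_amp <- stats::runif(n_blobs, 0.35, 0.65)
        for (i in seq_len(spec$samples_per_subclass)) {
          cx <- base_cx + stats::runif(n_blobs, -1.5, 1.5)
          cy <- base_cy + stats::runif(n_blobs, -1.5, 1.5)
          r <- pmax(base_r + stats::runif(n_blobs, -0.5, 0.5), 0.5)
          amp <- base_amp + stats::runif(n_blobs, -0.05, 0.05)
          img <- render_blobs(size, cx, cy, r, amp)
          if (spec$noise_sigma > 0) {
            img <- img + matrix(stats::rnorm(size * size, sd = spec$noise_sigma),
                                size, size)
          }
          images[[length(images) + 1L]] <- pmin(pmax(img, 0), 1)
          class_labels <- c(class_labels, k)
          subclass_labels <- c(subclass_labels, global_sub)
        }
      }
    }
    structure(list(images = images, class_labels = class_labels,
                   subclass_labels = subclass_labels, spec = spec),
              class = "labeled_image_set")
  })
}

#' @export
print.labeled_image_set <- function(x, ...) {
  cat("Labeled image set:", length(x$images), "images,",
      x$spec$n_classes, "classes,", max(x$subclass_labels), "subclasses\n")
  invisible(x)
}

#' Stratified train/test split of a labeled image set
#'
#' Splits by subclass so train and test contain samples of every motif: the
#' first `train_per_subclass` samples of each subclass (generation order)
#' form the training set and the rest the test set. Both halves therefore
#' share the class definitions (templates) and differ only in per-sample
#' jitter and noise.
#'
#' @param set A `labeled_image_set`.
#' @param train_per_subclass Training samples kept per subclass.
#' @return A list with `train` and `test` (`labeled_image_set`s).
#' @export
split_image_set <- function(set, train_per_subclass) {
  train_per_subclass <- check_count(train_per_subclass, "train_per_subclass")
  take <- logical(length(set$images))
  for (s in unique(set$subclass_labels)) {
    idx <- which(set$subclass_labels == s)
    if (length(idx) <= train_per_subclass) {
      stop_rbpnn("subclass %d has %d samples; cannot keep %d for training",
                 s, length(idx), train_per_subclass)
    }
    take[idx[seq_len(train_per_subclass)]] <- TRUE
  }
  subset_set <- function(keep) {
    structure(list(images = set$images[keep],
                   class_labels = set$class_labels[keep],
                   subclass_labels = set$subclass_labels[keep],
                   spec = set$spec),
              class = "labeled_image_set")
  }
  list(train = subset_set(take), test = subset_set(!take))
}

#' Write an image set as PNG files plus a manifest
#'
#' @param set A `labeled_image_set`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path. The manifest CSV has columns
#'   `path`, `class`, `subclass`.
#' @export
write_image_set <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(set$images)
  paths <- file.path(dir, sprintf("img_%05d.png", seq_len(n)))
  for (i in seq_len(n)) png::writePNG(set$images[[i]], paths[i])
  manifest <- data.frame(path = basename(paths),
                         class = set$class_labels,
                         subclass = set$subclass_labels)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read an image set from a manifest
#'
#' @param manifest_path Path to a manifest CSV written by [write_image_set()]
#'   (columns `path`, `class`, optional `subclass`; image paths relative to
#'   the manifest).
#' @return A `labeled_image_set` (grayscale: multi-channel PNGs are averaged).
#' @export
read_image_set <- function(manifest_path) {
  manifest <- utils::read.csv(manifest_path)
  base <- dirname(manifest_path)
  images <- lapply(file.path(base, manifest$path), function(p) {
    img <- png::readPNG(p)
    if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), mean)
    img
  })
  structure(list(images = images,
                 class_labels = as.integer(manifest$class),
                 subclass_labels = if ("subclass" %in% names(manifest)) {
                   as.integer(manifest$subclass)
                 } else rep(NA_integer_, nrow(manifest)),
                 spec = NULL),
            class = "labeled_image_set")
}

#' Generate a labeled synthetic feature-matrix set
#'
#' Plants `n_clusters` cluster means in `C x L` feature space. Each mean has,
#' per channel, a sparse non-negative profile (amplitudes uniform on
#' `[0.5, 1]`) whose active positions come from a per-channel shuffled
#' partition, so different clusters activate disjoint position sets whenever
#' capacity allows -- echoing post-ReLU activations where distinct sub-modes
#' excite distinct units. Clusters therefore differ in channel direction
#' (large CSA distance), not only in magnitude. All means are rescaled by a
#' common factor so the minimum pairwise Euclidean distance is at least
#' `separation`. Samples are `mean + N(0, noise_sd)` elementwise.
#'
#' @param n_clusters Number of planted clusters (`>= 1`).
#' @param dim Length-2 vector `(channels, length)` of the feature matrices.
#' @param separation Minimum pairwise Euclidean distance between cluster
#'   means (positive).
#' @param n_per_cluster Samples drawn per cluster.
#' @param noise_sd Isotropic noise standard deviation (default 0.5).
#' @param seed Integer seed; identical arguments + seed give an identical set.
#' @return A list of class `labeled_feature_set`: `features` (list of
#'   `C x L` matrices), `cluster` (ground-truth assignment), `means` (list of
#'   cluster mean matrices).
#' @export
generate_feature_set <- function(n_clusters, dim, separation, n_per_cluster,
                                 noise_sd = 0.5, seed = 1L) {
  n_clusters <- check_count(n_clusters, "n_clusters")
  if (length(dim) != 2L) stop_rbpnn("dim must be (channels, length)")
  ch <- check_count(dim[1L], "dim[channels]")
  len <- check_count(dim[2L], "dim[length]")
  if (!is.numeric(separation) || separation <= 0) {
    stop_rbpnn("separation must be positive")
  }
  n_per_cluster <- check_count(n_per_cluster, "n_per_cluster")
  with_local_seed(seed, {
    k_active <- max(1L, len %/% max(4L, n_clusters))
    # per-channel shuffled position pool; cluster k takes the k-th stretch
    # (wrapping when n_clusters * k_active exceeds the row length)
    pools <- lapply(seq_len(ch), function(c) sample.int(len))
    means <- lapply(seq_len(n_clusters), function(k) {
      m <- matrix(0, ch, len)
      for (c in seq_len(ch)) {
        slots <- ((k - 1L) * k_active + seq_len(k_active) - 1L) %% len + 1L
        active <- pools[[c]][slots]
        m[c, active] <- stats::runif(k_active, 0.5, 1)
      }
      m
    })
    if (n_clusters > 1L) {
      flat <- t(vapply(means, as.vector, numeric(ch * len)))
      min_d <- min(stats::dist(flat))
      if (min_d <= 0) {
        # coincident supports are vanishingly unlikely; nudge deterministically
        means[[1L]] <- means[[1L]] + 0.01
        flat <- t(vapply(means, as.vector, numeric(ch * len)))
        min_d <- min(stats::dist(flat))
      }
      if (min_d < separation) {
        scale <- separation / min_d
        means <- lapply(means, function(m) m * scale)
      }
    }
    features <- list()
    cluster <- integer(0)
    for (k in seq_len(n_clusters)) {
      for (i in seq_len(n_per_cluster)) {
        noise <- matrix(stats::rnorm(ch * len, sd = noise_sd), ch, len)
        features[[length(features) + 1L]] <- means[[k]] + noise
        cluster <- c(cluster, k)
      }
    }
    structure(list(features = features, cluster = cluster, means = means),
              class = "labeled_feature_set")
  })
}

#' Write a labeled feature set as a portable text container
#'
#' Features go to a CSV (one row per sample, flattened column-major) next to
#' a JSON sidecar holding the matrix dimensions and ground-truth labels.
#'
#' @param set A `labeled_feature_set` (or list with `features` and labels).
#' @param path CSV output path; the sidecar is `<path>.json`.
#' @param labels Optional label vector (defaults to `set$cluster`).
#' @return Invisibly, `path`.
#' @export
write_feature_set <- function(set, path, labels = NULL) {
  if (is.null(labels)) labels <- set$cluster
  d <- dim(set$features[[1L]])
  flat <- t(vapply(set$features, as.vector, numeric(prod(d))))
  utils::write.table(flat, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  sidecar <- sprintf('{"channels": %d, "length": %d, "labels": [%s]}',
                     d[1L], d[2L], paste(as.integer(labels), collapse = ", "))
  writeLines(sidecar, paste0(path, ".json"))
  invisible(path)
}

#' Read a labeled feature set written by [write_feature_set()]
#'
#' @param path CSV path (expects `<path>.json` sidecar).
#' @return A `labeled_feature_set` (without `means`).
#' @export
read_feature_set <- function(path) {
  meta <- parse_sidecar(paste0(path, ".json"))
  flat <- as.matrix(utils::read.table(path, sep = ","))
  features <- lapply(seq_len(nrow(flat)), function(i) {
    matrix(flat[i, ], meta$channels, meta$length)
  })
  structure(list(features = features, cluster = meta$labels, means = NULL),
            class = "labeled_feature_set")
}

# Tiny single-purpose reader for the sidecar written above (flat JSON object
# with two scalars and one integer array).
parse_sidecar <- function(path) {
  txt <- paste(readLines(path), collapse = " ")
  grab <- function(key) {
    m <- regmatches(txt, regexpr(sprintf('"%s"\\s*:\\s*[0-9]+', key), txt))
    as.integer(sub(".*:\\s*", "", m))
  }
  arr <- regmatches(txt, regexpr('"labels"\\s*:\\s*\\[[^]]*\\]', txt))
  labels <- as.integer(strsplit(gsub(".*\\[|\\]", "", arr), ",")[[1L]])
  list(channels = grab("channels"), length = grab("length"), labels = labels)
}
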