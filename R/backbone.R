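# Multi-scale convolutional feature extraction: a ResNet-style stage stack,
# top-down feature-pyramid fusion (FPN) with lateral 1x1 connections, and the
# pyramid pooling module (PPM) that attaches multi-grid global context.

#' Backbone configuration
#'
#' @param variant `"tiny"` (4 halving stages, narrow channels, 32x32 inputs;
#'   sized so a forward pass runs in well under a second on one CPU core) or
#'   `"standard"` (5 halving stages mirroring the stage/stride layout of a
#'   ResNet-50 front end at 224x224). All fusion convolutions initialize as
#'   exact identities and every residual branch starts at zero, extending the
#'   zero-initialized attention gates: the whole enhancement pipeline begins
#'   as an information-preserving transform and learns to deviate.
#' @param stage_channels Channel count per stage; defaults depend on variant.
#' @param input_size Square input size in pixels.
#' @param in_channels Image channels (1 = grayscale, 3 = RGB).
#' @param fpn_channels Uniform channel width of the fused pyramid levels.
#' @param ppm_scales Pooled grid sizes of the pyramid pooling module;
#'   non-empty and strictly increasing.
#' @param profile_grid Adaptive-pooling grid used when a feature map is
#'   flattened into the comprehensive feature matrix (columns `L = grid^2`).
#' @param reduction_ratio Channel reduction of the spatial-attention query /
#'   key projections (1 = none).
#' @param dropout_rate Dropout rate of the attention aggregation head.
#' @return An object of class `backbone_config`.
#' @export
backbone_config <- function(variant = c("tiny", "standard"),
                            stage_channels = NULL, input_size = NULL,
                            in_channels = NULL, fpn_channels = NULL,
                            ppm_scales = c(1L, 2L, 3L, 6L),
                            profile_grid = NULL,
                            reduction_ratio = 1L, dropout_rate = 0.1) {
  variant <- match.arg(variant)
  if (variant == "tiny") {
    if (is.null(stage_channels)) stage_channels <- c(16L, 32L, 64L, 128L)
    if (is.null(input_size)) input_size <- 32L
    if (is.null(in_channels)) in_channels <- 1L
    if (is.null(fpn_channels)) fpn_channels <- 32L
    if (is.null(profile_grid)) profile_grid <- 4L
  } else {
    if (is.null(stage_channels)) stage_channels <- c(64L, 256L, 512L, 1024L, 2048L)
    if (is.null(input_size)) input_size <- 224L
    if (is.null(in_channels)) in_channels <- 3L
    if (is.null(fpn_channels)) fpn_channels <- 256L
    if (is.null(profile_grid)) profile_grid <- 7L
  }
  ppm_scales <- as.integer(ppm_scales)
  if (length(ppm_scales) == 0L || any(diff(ppm_scales) <= 0)) {
    stop_rbpnn("ppm_scales must be non-empty and strictly increasing")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_rbpnn("dropout_rate must lie in [0, 1)")
  }
  structure(list(variant = variant,
                 stage_channels = as.integer(stage_channels),
                 input_size = check_count(input_size, "input_size"),
                 in_channels = check_count(in_channels, "in_channels"),
                 fpn_channels = check_count(fpn_channels, "fpn_channels"),
                 ppm_scales = ppm_scales,
                 profile_grid = check_count(profile_grid, "profile_grid"),
                 reduction_ratio = check_count(reduction_ratio, "reduction_ratio"),
                 dropout_rate = dropout_rate),
            class = "backbone_config")
}

# One stage: a 3x3 stride-2 halving convolution followed by a residual basic
# block (two 3x3 convolutions with identity skip). The block's second
# convolution starts at zero (zero-init residual), so at initialization each
# stage is just the halving convolution + ReLU and activation variance stays
# controlled through depth.
init_stage <- function(in_ch, out_ch) {
  list(down = new_conv2d(in_ch, out_ch, kernel = 3L, stride = 2L, pad = 1L),
       res1 = new_conv2d(out_ch, out_ch, kernel = 3L, stride = 1L, pad = 1L),
       res2 = new_conv2d(out_ch, out_ch, kernel = 3L, stride = 1L, pad = 1L,
                         init = "zero"))
}

# Deterministic lateral 1x1 convolution: channel replication when widening,
# channel-group averaging when narrowing. Like the other fusion
# initializations this keeps the frozen pyramid information-preserving
# instead of mixing channels at random.
group_lateral_conv <- function(in_ch, out_ch) {
  cv <- new_conv2d(in_ch, out_ch, kernel = 1L, init = "zero")
  for (i in seq_len(in_ch)) {
    j <- ((i - 1L) %% out_ch) + 1L
    cv$W[j, i] <- 1
  }
  cv$W <- cv$W / pmax(rowSums(cv$W), 1)
  cv
}

stage_forward <- function(x, stage) {
  y <- relu(conv2d_forward(x, stage$down))
  r <- conv2d_forward(relu(conv2d_forward(y, stage$res1)), stage$res2)
  relu(y + r)
}

#' Initialize backbone weights
#'
#' He-initialized stage, lateral, pyramid-pooling and attention weights,
#' deterministic under `seed`. Attention residual gates start at exactly 0.
#'
#' @param config A [backbone_config()].
#' @param seed Integer seed.
#' @return An object of class `rbpnn_backbone` holding all weights.
#' @export
init_backbone <- function(config, seed = 1L) {
  with_local_seed(seed, {
    chans <- c(config$in_channels, config$stage_channels)
    stages <- lapply(seq_along(config$stage_channels), function(i) {
      init_stage(chans[i], chans[i + 1L])
    })
    laterals <- lapply(config$stage_channels, function(ch) {
      group_lateral_conv(ch, config$fpn_channels)
    })
    ppm <- init_ppm(config$fpn_channels, config$ppm_scales)
    attention <- init_attention(config$fpn_channels,
                                reduction_ratio = config$reduction_ratio,
                                dropout_rate = config$dropout_rate)
    structure(list(config = config, stages = stages, laterals = laterals,
                   ppm = ppm, attention = attention),
              class = "rbpnn_backbone")
  })
}

#' Extract hierarchical stage features
#'
#' Runs the stage stack over a batch of images. Each stage halves the spatial
#' size and maps to its configured channel count.
#'
#' @param images A list of `C x H x W` arrays with `H = W = input_size` (an
#'   empty list yields empty per-stage lists).
#' @param backbone An initialized `rbpnn_backbone`.
#' @return A list with one element per stage; each element is a list of
#'   per-image feature maps (bottom-up order `C1..Cn`).
#' @export
extract_stages <- function(images, backbone) {
  cfg <- backbone$config
  n_stages <- length(backbone$stages)
  if (length(images) == 0L) {
    return(replicate(n_stages, list(), simplify = FALSE))
  }
  per_image <- lapply(images, function(img) {
    check_feature_map(img, "input image")
    d <- dim(img)
    if (d[1L] != cfg$in_channels || d[2L] != cfg$input_size ||
        d[3L] != cfg$input_size) {
      stop_rbpnn("expected input %dx%dx%d, got %dx%dx%d",
                 cfg$in_channels, cfg$input_size, cfg$input_size,
                 d[1L], d[2L], d[3L])
    }
    out <- vector("list", n_stages)
    x <- img
    for (s in seq_len(n_stages)) {
      x <- stage_forward(x, backbone$stages[[s]])
      out[[s]] <- x
    }
    out
  })
  lapply(seq_len(n_stages), function(s) lapply(per_image, `[[`, s))
}

#' Top-down feature-pyramid fusion
#'
#' Projects every stage map through its lateral 1x1 convolution to the
#' uniform pyramid width, then fuses top-down: each level adds the
#' bilinearly upsampled next-coarser fused level to its lateral projection.
#' Each fused level keeps the spatial size of its stage.
#'
#' @param stage_maps List of per-stage `C x H x W` maps for one image
#'   (bottom-up order, at least 2 levels).
#' @param backbone An initialized `rbpnn_backbone`.
#' @return A list of fused maps `P1..Pn` (bottom-up order), all with
#'   `fpn_channels` channels.
#' @export
fpn_fuse <- function(stage_maps, backbone) {
  n <- length(stage_maps)
  if (n < 2L) stop_rbpnn("fpn_fuse needs at least 2 stage maps")
  lat <- lapply(seq_len(n), function(i) {
    conv2d_forward(stage_maps[[i]], backbone$laterals[[i]])
  })
  p <- vector("list", n)
  p[[n]] <- lat[[n]]
  for (i in seq.int(n - 1L, 1L)) {
    d <- dim(lat[[i]])
    up <- bilinear_resize(p[[i + 1L]], d[2L], d[3L])
    p[[i]] <- lat[[i]] + up
  }
  p
}

init_ppm <- function(channels, scales) {
  n <- length(scales)
  branch_ch <- max(channels %/% n, 1L)
  # the fusing 1x1 convolution starts as the identity on the input-channel
  # block and zero on the pooled-context block: the module begins as an exact
  # identity (like the zero-initialized attention gates) and mixes context in
  # only through learning
  fuse <- new_conv2d(channels + n * branch_ch, channels, kernel = 1L,
                     init = "zero")
  fuse$W[, seq_len(channels)] <- diag(channels)
  list(scales = as.integer(scales), branch_ch = branch_ch,
       reduce = lapply(scales, function(s) new_conv2d(channels, branch_ch, kernel = 1L)),
       fuse = fuse)
}

#' Pyramid pooling module
#'
#' For each configured grid size `s`, adaptively average-pools the input to
#' `s x s`, reduces channels to `C/N` (N = number of scales) with a 1x1
#' convolution, and bilinearly upsamples back to the input size. The input
#' map and all branches (ascending scale) are concatenated along channels and
#' compressed back to `C` by a final 1x1 convolution, so the output has the
#' same shape as the input.
#'
#' @param x A `C x H x W` feature map.
#' @param ppm PPM weights (from [init_backbone()], element `ppm`).
#' @param scales Optional override of the pooled grid sizes.
#' @return A feature map with the same shape as `x`.
#' @export
ppm_forward <- function(x, ppm, scales = NULL) {
  check_feature_map(x)
  if (is.null(scales)) scales <- ppm$scales
  d <- dim(x)
  if (any(scales > min(d[2L], d[3L]))) {
    stop_rbpnn("ppm scale %d exceeds spatial size %dx%d",
               max(scales), d[2L], d[3L])
  }
  branches <- lapply(seq_along(scales), function(i) {
    pooled <- adaptive_avg_pool(x, scales[i])
    reduced <- conv2d_forward(pooled, ppm$reduce[[i]])
    bilinear_resize(reduced, d[2L], d[3L])
  })
  stacked <- do.call(abind_channels, c(list(x), branches))
  conv2d_forward(stacked, ppm$fuse)
}

# Concatenate feature maps along the channel dimension.
abind_channels <- function(...) {
  maps <- list(...)
  d <- dim(maps[[1L]])
  total <- sum(vapply(maps, function(m) dim(m)[1L], integer(1)))
  out <- array(0, dim = c(total, d[2L], d[3L]))
  at <- 0L
  for (m in maps) {
    cm <- dim(m)[1L]
    out[at + seq_len(cm), , ] <- m
    at <- at + cm
  }
  out
}
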