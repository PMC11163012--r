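# Dynamic C-means (DCM) prototype selection: per-sample density in CSA
# distance space, density-ranked farthest-point seeding, medoid refinement,
# the coupling/separation cluster-validity index GD(c), and per-class
# selection of diverse "typical sample" features as RBPN kernel centers.

#' Dynamic C-means configuration
#'
#' @param alpha Coupling weight factor in `[0, 1]` balancing within-cluster
#'   compactness against between-center separation in the validity index
#'   `GD(c) = alpha * C_d(c) + (1 - alpha) / S_d(c)`. The default 0.8 weights
#'   compactness above separation: for prototype selection the costs are
#'   asymmetric -- under-segmentation leaves a sub-mode without any kernel
#'   center, making it invisible to the RBPN layer, while over-segmentation
#'   merely adds redundant centers.
#' @param c_range Inclusive candidate cluster counts (minimum 2). `NULL`
#'   defaults, per class of `N` samples, to `2:min(10, floor(N/2))`.
#' @param keep_rule Density keep fraction: points with density below
#'   `keep_rule * max(D)` are excluded from seeding (they still take part in
#'   assignment and refinement). Isolated outliers have densities near 1
#'   while mode members sit near `N`, so the default 0.5 removes genuinely
#'   sparse points without ever deleting a uniform-density mode.
#' @param max_iter Maximum refinement sweeps.
#' @param tol Unused by the hard-assignment updates (kept for interface
#'   stability); must be positive.
#' @param seed Integer seed controlling any tie-free randomized step.
#' @return An object of class `dcm_config`.
#' @export
dcm_config <- function(alpha = 0.8, c_range = NULL, keep_rule = 0.5,
                       max_iter = 100L, tol = 1e-8, seed = 1L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop_rbpnn("alpha must be a single number in [0, 1]")
  }
  if (!is.null(c_range)) {
    c_range <- sort(unique(as.integer(c_range)))
    if (min(c_range) < 2L) stop_rbpnn("c_range minimum must be >= 2")
  }
  if (tol <= 0) stop_rbpnn("tol must be positive")
  if (!is.numeric(keep_rule) || keep_rule < 0 || keep_rule >= 1) {
    stop_rbpnn("keep_rule must lie in [0, 1)")
  }
  structure(list(alpha = alpha, c_range = c_range,
                 keep_rule = keep_rule,
                 max_iter = check_count(max_iter, "max_iter"),
                 tol = tol, seed = as.integer(seed)),
            class = "dcm_config")
}

#' Density of each sample feature point
#'
#' For `N` features with pairwise CSA distances `d(X_i, X_k)`, the effective
#' neighborhood radius is
#' `r_d = (1/2) * sqrt( sum_{i,k} d(X_i, X_k)^2 / (N (N - 1)) )`, the decay
#' coefficient is `f_d = 4 / r_d^2`, and the density at point `i` is
#' `D_i = sum_k 1 / (1 + f_d * d(X_i, X_k)^2)`, which always lies in
#' `[1, N]` (the self term contributes 1). If all pairwise distances are zero
#' the limit `D_i = N` is returned with a warning.
#'
#' @param features A list of `C x L` feature matrices (may be `NULL` when
#'   `dmat` is supplied).
#' @param dmat Optional precomputed pairwise CSA distance matrix.
#' @return A list with `D` (length-`N` densities), `r_d` and `f_d`.
#' @export
feature_density <- function(features = NULL, dmat = NULL) {
  if (is.null(dmat)) {
    if (is.null(features) || length(features) < 2L) {
      stop_rbpnn("feature_density needs at least 2 features (r_d undefined)")
    }
    dmat <- csa_distance_matrix(features)
  }
  n <- nrow(dmat)
  if (n < 2L) stop_rbpnn("feature_density needs at least 2 points")
  d2 <- dmat^2
  total <- sum(d2)
  if (total <= 0) {
    warning("feature_density: all pairwise distances are zero; D_i = N limit",
            call. = FALSE)
    return(list(D = rep(as.numeric(n), n), r_d = 0, f_d = Inf))
  }
  r_d <- 0.5 * sqrt(total / (n * (n - 1)))
  f_d <- 4 / r_d^2
  list(D = rowSums(1 / (1 + f_d * d2)), r_d = r_d, f_d = f_d)
}

#' Density-ranked farthest-point seeding
#'
#' Points with density below `keep_rule * max(D)` are pruned from the
#' candidate pool; the first seed is the highest-density survivor, the second
#' the survivor farthest from it, and each further seed maximizes the minimum
#' CSA distance to the seeds already chosen. Distance ties break toward the
#' lowest sample index, so seeding is deterministic on symmetric inputs.
#'
#' @param d_vec Length-`N` density vector (see [feature_density()]).
#' @param c Number of seeds.
#' @param dmat Pairwise CSA distance matrix (`d[i, k]`, reference `k`).
#' @param keep_rule Density keep fraction relative to the maximum density
#'   (default 0.5).
#' @return Integer vector of `c` distinct sample indices.
#' @export
seed_centers <- function(d_vec, c, dmat, keep_rule = 0.5) {
  c <- check_count(c, "c")
  thr <- keep_rule * max(d_vec)
  pool <- which(d_vec >= thr)
  if (length(pool) < c) {
    stop_rbpnn(paste0("only %d points survive density pruning but c = %d; ",
                      "use a smaller c or a looser keep rule"),
               length(pool), c)
  }
  seeds <- pool[which.max(d_vec[pool])]
  while (length(seeds) < c) {
    cand <- setdiff(pool, seeds)
    min_d <- apply(dmat[cand, seeds, drop = FALSE], 1L, min)
    seeds <- c(seeds, cand[which.max(min_d)])
  }
  seeds
}

#' Medoid refinement of a seeded partition
#'
#' Alternates hard assignment of every sample to its nearest center (CSA
#' distance, reference = center side) with a medoid update: the new center of
#' a cluster is the member minimizing the summed distance from its
#' co-members. Centers therefore always remain actual sample features. An
#' emptied cluster is re-seeded with the point farthest (max-min distance)
#' from the current centers. Iteration stops when assignments stop changing
#' or `max_iter` is reached; the per-sweep objective
#' `sum_i d(X_i, center(i))` never increases.
#'
#' @param center_idx Integer vector of initial center sample indices.
#' @param dmat Pairwise CSA distance matrix over all samples.
#' @param max_iter Maximum sweeps.
#' @return A list of class `dcm_partition`: `membership` (cluster id per
#'   sample), `centers` (sample indices), `objective` (per-sweep trace),
#'   `iterations`, `converged`.
#' @export
dcm_refine <- function(center_idx, dmat, max_iter = 100L) {
  n <- nrow(dmat)
  centers <- as.integer(center_idx)
  k <- length(centers)
  membership <- integer(n)
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    dc <- dmat[, centers, drop = FALSE]
    new_membership <- max.col(-dc, ties.method = "first")
    # re-seed emptied clusters with the point farthest from current centers
    for (j in seq_len(k)) {
      if (!any(new_membership == j)) {
        min_d <- apply(dc, 1L, min)
        far <- which.max(min_d)
        centers[j] <- far
        new_membership[far] <- j
        dc <- dmat[, centers, drop = FALSE]
      }
    }
    objective <- c(objective, sum(dc[cbind(seq_len(n), new_membership)]))
    unchanged <- iter > 1L && all(new_membership == membership)
    membership <- new_membership
    if (unchanged) { converged <- TRUE; break }
    for (j in seq_len(k)) {
      members <- which(membership == j)
      within <- colSums(dmat[members, members, drop = FALSE])
      centers[j] <- members[which.min(within)]
    }
    if (iter >= max_iter) break
  }
  structure(list(membership = membership, centers = centers,
                 objective = objective, iterations = iter,
                 converged = converged),
            class = "dcm_partition")
}

#' Coupling degree of a partition
#'
#' Mean squared sample-to-center CSA distance under hard memberships:
#' `C_d(c) = (1/N) * sum_i d(X_i, center(i))^2`. Smaller is more compact.
#'
#' @param partition A `dcm_partition`.
#' @param dmat Pairwise CSA distance matrix.
#' @return A single non-negative number.
#' @export
coupling_degree <- function(partition, dmat) {
  n <- nrow(dmat)
  d <- dmat[cbind(seq_len(n), partition$centers[partition$membership])]
  mean(d^2)
}

#' Separation degree of a set of centers
#'
#' Mean squared between-center CSA distance with each unordered pair counted
#' once: `S_d(c) = sum_{i<k} d_ik^2 / (c (c - 1) / 2)`. The CSA distance is
#' mildly direction-dependent (weights come from the reference side), so each
#' pair's distance is the average of the two directions. Larger is better
#' separated; undefined for fewer than 2 centers.
#'
#' @param centers Integer vector of center sample indices (length >= 2).
#' @param dmat Pairwise CSA distance matrix.
#' @return A single non-negative number.
#' @export
separation_degree <- function(centers, dmat) {
  k <- length(centers)
  if (k < 2L) stop_rbpnn("separation_degree needs at least 2 centers")
  total <- 0
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      d <- (dmat[centers[i], centers[j]] + dmat[centers[j], centers[i]]) / 2
      total <- total + d^2
    }
  }
  total / (k * (k - 1) / 2)
}

#' Cluster-validity index GD(c)
#'
#' `GD(c) = alpha * C_d(c) + (1 - alpha) / S_d(c)`; smaller indicates a
#' better clustering. A non-positive separation degree (coincident centers)
#' returns `Inf` so degenerate partitions are never selected.
#'
#' @param c_d Coupling degree.
#' @param s_d Separation degree.
#' @param alpha Coupling weight factor in `[0, 1]`.
#' @return A single number (possibly `Inf`).
#' @export
gd_index <- function(c_d, s_d, alpha = 0.5) {
  if (s_d <= 0) return(Inf)
  alpha * c_d + (1 - alpha) / s_d
}

# Run seeding + refinement for one candidate c on a precomputed distance
# matrix; returns the partition plus validity quantities.
dcm_run_single <- function(c, dmat, density, config) {
  seeds <- seed_centers(density$D, c, dmat, config$keep_rule)
  part <- dcm_refine(seeds, dmat, config$max_iter)
  c_d <- coupling_degree(part, dmat)
  s_d <- if (length(part$centers) >= 2L) separation_degree(part$centers, dmat) else NA_real_
  gd <- if (is.na(s_d)) NA_real_ else gd_index(c_d, s_d, config$alpha)
  list(partition = part, coupling = c_d, separation = s_d, gd = gd)
}

#' Select diverse per-class prototype features (kernel center bank)
#'
#' For every class, runs density-seeded dynamic C-means over each candidate
#' cluster count in `c_range`, evaluates the validity index `GD(c)`, keeps
#' the count minimizing it (ties break toward the smaller count), and emits
#' the medoid features of the winning partition as that class's kernel
#' centers. Centers are actual training-sample features, ordered class by
#' class, with the per-class index sets recorded for pattern aggregation.
#'
#' Before the validity index is evaluated, each class's pairwise distance
#' matrix is rescaled to unit root-mean-square distance. Density, seeding and
#' medoid refinement are invariant to this rescaling, but the index's two
#' terms carry units of squared distance and inverse squared distance, so its
#' compactness/separation balance otherwise depends on the absolute distance
#' scale; normalizing makes the selected cluster count scale-free.
#'
#' @param features List of `C x L` feature matrices.
#' @param class_labels Integer class label per feature, in `1..K`.
#' @param config A [dcm_config()].
#' @param fixed_c Optional single cluster count applied to every class,
#'   bypassing validity selection (permits `c = 1`; used e.g. for degenerate
#'   one-prototype-per-class baselines).
#' @return An object of class `kernel_center_bank`: `centers` (list of
#'   feature matrices), `class` (class id per center), `omega` (per-class
#'   center index sets), `m_k` (centers per class), `m` (total), `source`
#'   (per-class training-sample indices of the centers), `center_weights`
#'   (precomputed CSA reference weights), `selection` (per-class GD table).
#' @export
select_typical_features <- function(features, class_labels, config = dcm_config(),
                                    fixed_c = NULL) {
  class_labels <- as.integer(class_labels)
  k_classes <- max(class_labels)
  centers <- list()
  center_class <- integer(0)
  source_idx <- list()
  selection <- list()
  for (k in seq_len(k_classes)) {
    idx <- which(class_labels == k)
    n_k <- length(idx)
    feats_k <- features[idx]
    c_range <- if (!is.null(fixed_c)) {
      check_count(fixed_c, "fixed_c")
    } else if (is.null(config$c_range)) {
      seq.int(2L, max(2L, min(10L, n_k %/% 2L)))
    } else {
      config$c_range
    }
    if (n_k < max(2L, min(c_range))) {
      stop_rbpnn("class %d has %d samples; needs at least %d for clustering",
                 k, n_k, max(2L, min(c_range)))
    }
    dmat <- csa_distance_matrix(feats_k)
    rms <- sqrt(mean(dmat[row(dmat) != col(dmat)]^2))
    if (rms > 0) dmat <- dmat / rms
    density <- feature_density(dmat = dmat)
    runs <- lapply(c_range, function(cc) {
      if (cc == 1L) {
        part <- dcm_refine(which.max(density$D), dmat, config$max_iter)
        list(partition = part, coupling = coupling_degree(part, dmat),
             separation = NA_real_, gd = NA_real_)
      } else {
        dcm_run_single(cc, dmat, density, config)
      }
    })
    best <- if (!is.null(fixed_c)) 1L else {
      gds <- vapply(runs, function(r) r$gd, numeric(1))
      which.min(gds)   # first minimum -> smaller c on ties
    }
    part <- runs[[best]]$partition
    centers <- c(centers, feats_k[part$centers])
    center_class <- c(center_class, rep(k, length(part$centers)))
    source_idx[[k]] <- idx[part$centers]
    selection[[k]] <- data.frame(
      c = c_range,
      coupling = vapply(runs, function(r) r$coupling, numeric(1)),
      separation = vapply(runs, function(r) r$separation, numeric(1)),
      gd = vapply(runs, function(r) r$gd, numeric(1)))
  }
  omega <- split(seq_along(center_class), center_class)
  names(omega) <- NULL
  structure(list(centers = centers, class = center_class, omega = omega,
                 m_k = vapply(omega, length, integer(1)),
                 m = length(centers), n_classes = k_classes,
                 source = source_idx,
                 center_weights = lapply(centers, csa_weights),
                 selection = selection),
            class = "kernel_center_bank")
}

#' @export
print.kernel_center_bank <- function(x, ...) {
  cat("Kernel center bank:", x$m, "prototypes over", x$n_classes, "classes\n")
  cat("  per class:", paste(x$m_k, collapse = ", "), "\n")
  invisible(x)
}
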