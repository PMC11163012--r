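test_that("density matches the hand-computed three-point example", {
  dm <- matrix(c(0, 1, 2,
                 1, 0, 2,
                 2, 2, 0), 3, 3, byrow = TRUE)
  den <- feature_density(dmat = dm)
  # r_d = 0.5*sqrt(18/6), f_d = 16/3
  expect_equal(den$r_d, 0.5 * sqrt(3), tolerance = 1e-12)
  expect_equal(den$f_d, 16 / 3, tolerance = 1e-12)
  expect_equal(den$D, c(1 + 3 / 19 + 3 / 67,
                        1 + 3 / 19 + 3 / 67,
                        1 + 6 / 67), tolerance = 1e-12)
})

test_that("density respects its bounds and the degenerate limit", {
  for (s in 1:10) {
    feats <- lapply(1:8, function(i) random_feature(3, 6, seed = s * 10 + i,
                                                    positive = TRUE))
    den <- feature_density(feats)
    expect_true(all(den$D >= 1 - 1e-9 & den$D <= 8 + 1e-9))
    expect_equal(den$D, oracle_density(rbpnn:::csa_distance_matrix(feats)),
                 tolerance = 1e-9)
  }
  same <- lapply(1:4, function(i) matrix(1, 2, 3))
  expect_warning(den <- feature_density(same), "zero")
  expect_equal(den$D, rep(4, 4))
  expect_error(feature_density(same[1]), "at least 2")
})

test_that("seeding lands in distinct blobs and breaks ties deterministically", {
  fs <- generate_feature_set(2, c(3, 8), separation = 10, n_per_cluster = 15,
                             noise_sd = 0.5, seed = 4)
  dm <- rbpnn:::csa_distance_matrix(fs$features)
  den <- feature_density(dmat = dm)
  seeds <- seed_centers(den$D, 2, dm)
  expect_setequal(fs$cluster[seeds], 1:2)
  # c = 1 is just the density argmax
  expect_equal(seed_centers(den$D, 1, dm), which.max(den$D))
  # fully symmetric distances -> lowest-index ties
  sym <- matrix(1, 4, 4); diag(sym) <- 0
  dsym <- feature_density(dmat = sym)
  expect_equal(seed_centers(dsym$D, 3, sym, keep_rule = 0), c(1L, 2L, 3L))
  expect_error(seed_centers(c(10, rep(1, 9)), 3, matrix(0, 10, 10),
                            keep_rule = 0.9), "smaller c")
})

test_that("refinement recovers planted blobs, descends and is deterministic", {
  fs <- generate_feature_set(2, c(3, 8), separation = 10, n_per_cluster = 20,
                             noise_sd = 0.5, seed = 6)
  dm <- rbpnn:::csa_distance_matrix(fs$features)
  den <- feature_density(dmat = dm)
  part <- dcm_refine(seed_centers(den$D, 2, dm), dm)
  # memberships equal ground truth up to label permutation
  tab <- table(part$membership, fs$cluster)
  expect_equal(sum(apply(tab, 1, max)), 40)
  # objective never increases
  expect_true(all(diff(part$objective) <= 1e-12))
  # fixed point: restarting from the found medoids changes nothing
  again <- dcm_refine(part$centers, dm)
  expect_equal(again$membership, part$membership)
  expect_equal(again$centers, part$centers)
  # determinism
  expect_identical(part, dcm_refine(seed_centers(den$D, 2, dm), dm))
  # every sample belongs to exactly one non-empty cluster
  expect_true(all(part$membership %in% 1:2))
  expect_true(all(table(part$membership) > 0))
})

test_that("coupling, separation and GD match direct arithmetic", {
  # every sample exactly at its center -> coupling 0
  z <- matrix(0, 3, 3)
  p0 <- structure(list(membership = c(1L, 1L, 1L), centers = 1L),
                  class = "dcm_partition")
  expect_equal(coupling_degree(p0, z), 0)
  # 2 samples, 1 cluster, distances 1 and 3 to the center (column 3)
  dm2 <- matrix(c(0, 0.2, 1,
                  0.2, 0, 3), 2, 3, byrow = TRUE)
  p2 <- structure(list(membership = c(1L, 1L), centers = 3L),
                  class = "dcm_partition")
  expect_equal(coupling_degree(p2, dm2), (1 + 9) / 2)
  # separation: 2 centers at distance 1; 3 centers pairwise distance 2
  d2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(separation_degree(1:2, d2), 1)
  d3 <- matrix(2, 3, 3); diag(d3) <- 0
  expect_equal(separation_degree(1:3, d3), (4 + 4 + 4) / 3)
  expect_equal(separation_degree(1:3, d3 * 0), 0)
  expect_error(separation_degree(1L, d2), "at least 2")
  # GD limit cases and arithmetic
  expect_equal(gd_index(2, 4, alpha = 1), 2)
  expect_equal(gd_index(2, 4, alpha = 0), 0.25)
  expect_equal(gd_index(2, 4, alpha = 0.5), 1.125)
  expect_equal(gd_index(1, 0), Inf)
})

test_that("coupling strictly increases when a far outlier joins", {
  fs <- generate_feature_set(1, c(3, 8), separation = 5, n_per_cluster = 10,
                             noise_sd = 0.3, seed = 9)
  feats <- fs$features
  dm <- rbpnn:::csa_distance_matrix(feats)
  part <- dcm_refine(1L, dm)
  base <- coupling_degree(part, dm)
  outlier <- -feats[[1]]                      # anti-collinear rows: far away
  feats2 <- c(feats, list(outlier))
  dm2 <- suppressWarnings(rbpnn:::csa_distance_matrix(feats2))
  part2 <- structure(list(membership = rep(1L, 11), centers = part$centers),
                     class = "dcm_partition")
  expect_gt(coupling_degree(part2, dm2), base)
})

test_that("oracle equivalence holds for coupling and separation", {
  for (s in 1:10) {
    feats <- lapply(1:9, function(i) random_feature(3, 5, seed = s * 31 + i,
                                                    positive = TRUE))
    dm <- rbpnn:::csa_distance_matrix(feats)
    den <- feature_density(dmat = dm)
    part <- dcm_refine(seed_centers(den$D, 3, dm, keep_rule = 0), dm)
    expect_equal(coupling_degree(part, dm),
                 oracle_coupling(part$membership, part$centers, dm),
                 tolerance = 1e-12)
    expect_equal(separation_degree(part$centers, dm),
                 oracle_separation(part$centers, dm), tolerance = 1e-12)
  }
})

test_that("typical-feature selection recovers planted subclass counts", {
  cfg <- dcm_config(c_range = 2:6)
  # two classes, each planted with 3 well-separated subclasses
  hits <- 0L
  for (s in 1:5) {
    fs1 <- generate_feature_set(3, c(4, 16), separation = 10,
                                n_per_cluster = 25, noise_sd = 0.5, seed = s)
    fs2 <- generate_feature_set(3, c(4, 16), separation = 10,
                                n_per_cluster = 25, noise_sd = 0.5,
                                seed = s + 50)
    feats <- c(fs1$features, fs2$features)
    labels <- rep(1:2, each = 75)
    bank <- select_typical_features(feats, labels, cfg)
    hits <- hits + sum(bank$m_k == 3L)
    # bank invariants
    expect_equal(sort(unlist(bank$omega)), seq_len(bank$m))
    expect_equal(sum(bank$m_k), bank$m)
    expect_true(all(vapply(seq_len(bank$m), function(j) {
      src <- unlist(bank$source)[j]
      identical(bank$centers[[j]], feats[[src]])
    }, logical(1))))
  }
  expect_gte(hits, 9L)   # at least 9 of 10 class-level selections
})

test_that("selection validates class sizes and honours fixed_c", {
  feats <- lapply(1:12, function(i) random_feature(3, 6, seed = i,
                                                   positive = TRUE))
  labels <- rep(1:2, each = 6)
  bank <- select_typical_features(feats, labels, dcm_config(c_range = 2:3),
                                  fixed_c = 1)
  expect_equal(bank$m_k, c(1L, 1L))
  small <- select_typical_features(feats, labels, dcm_config(c_range = 2:3))
  expect_true(all(small$m_k %in% 2:3))
  expect_error(select_typical_features(feats[1:7], c(rep(1L, 6), 2L),
                                       dcm_config(c_range = 2:3)), "class 2")
})

test_that("selection is deterministic under identical config", {
  fs <- generate_feature_set(3, c(4, 12), separation = 10, n_per_cluster = 15,
                             noise_sd = 0.5, seed = 13)
  cfg <- dcm_config(c_range = 2:5)
  b1 <- select_typical_features(fs$features, rep(1L, 45), cfg)
  b2 <- select_typical_features(fs$features, rep(1L, 45), cfg)
  expect_identical(b1, b2)
})
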