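# The distortion statistics: hand-computed cases, brute-force oracle
# equivalence on random instances, and the declared invariances.

test_that("knn_index: hand cases, tie-breaks, metric agreement in 1D", {
  pts <- matrix(c(0, 1, 10), ncol = 1)
  idx <- knn_index(pts, 1)
  expect_equal(as.integer(idx$ids), c(2L, 1L, 2L))
  # L1 and L2 coincide in 1D
  set.seed(1)
  x <- matrix(rnorm(25), ncol = 1)
  expect_identical(knn_index(x, 3, "L1")$ids, knn_index(x, 3, "L2")$ids)
  # duplicated points: nearest neighbor is the twin at distance 0
  dup <- matrix(c(0, 0, 5, 5, 9, 9), ncol = 1)
  i2 <- knn_index(dup, 1)
  expect_equal(as.integer(i2$ids[1:4]), c(2L, 1L, 4L, 3L))
  expect_equal(as.numeric(i2$dists[1:4]), rep(0, 4))
  expect_error(knn_index(pts, 3), "< n_points")
})

test_that("knn_index matches brute force on random instances (both norms)", {
  set.seed(20)
  for (rep in 1:20) {
    n <- sample(8:30, 1); d <- sample(1:6, 1); k <- sample(1:5, 1)
    pts <- matrix(rnorm(n * d), n, d)
    for (metric in c("L1", "L2"))
      expect_identical(knn_index(pts, k, metric)$ids, bf_knn(pts, k, metric),
                       info = sprintf("rep %d metric %s", rep, metric))
  }
})

test_that("jaccard_neighbor_distance: set-arithmetic cases and invariance", {
  pts <- matrix(rnorm(60), 30, 2)
  ia <- knn_index(pts, 5)
  expect_equal(unname(jaccard_neighbor_distance(ia, ia)), rep(0, 30))
  # scale invariance: neighbors unchanged under uniform scaling
  ib <- knn_index(pts * 7, 5)
  expect_equal(unname(jaccard_neighbor_distance(ia, ib)), rep(0, 30))
  # A = {1,2,3}, B = {2,3,4}: 1 - 2/4 = 0.5 via hand-built indices
  mk <- function(ids) structure(list(ids = matrix(ids, 1), dists = matrix(0, 1, 3),
                                     k = 3, metric = "L2", cell_ids = "c1",
                                     source_space = list()),
                                class = "neighbor_index")
  expect_equal(unname(jaccard_neighbor_distance(mk(c(1L, 2L, 3L)), mk(c(2L, 3L, 4L)))),
               0.5)
  # disjoint sets give 1
  expect_equal(unname(jaccard_neighbor_distance(mk(c(1L, 2L, 3L)), mk(c(7L, 8L, 9L)))),
               1)
  expect_error(jaccard_neighbor_distance(ia, knn_index(pts, 6)), "different k")
})

test_that("type_distance_matrix: enumerable cases and homogeneity", {
  pts <- matrix(c(0, 0, 3, 3), ncol = 1)
  lab <- c("a", "a", "b", "b")
  m <- type_distance_matrix(pts, lab)
  expect_equal(unname(m["a", "b"]), 3)
  expect_equal(unname(diag(m)), c(0, 0))
  # permutation invariance
  perm <- c(3, 1, 4, 2)
  m2 <- type_distance_matrix(pts[perm, , drop = FALSE], lab[perm])
  expect_equal(unname(m2), unname(m))
  # homogeneity under scaling
  set.seed(2)
  pts3 <- matrix(rnorm(40), 20, 2)
  lab3 <- rep(c("a", "b", "c", "d"), 5)
  expect_equal(unname(type_distance_matrix(pts3 * 4, lab3)),
               unname(type_distance_matrix(pts3, lab3)) * 4, tolerance = 1e-9)
  expect_warning(type_distance_matrix(rbind(pts, 9), c(lab, "solo")), "singleton")
})

test_that("type_ranking_correlation: identity, reversal, hand Spearman", {
  set.seed(3)
  pts <- matrix(rnorm(60), 30, 2)
  lab <- rep(letters[1:5], 6)
  m <- type_distance_matrix(pts, lab)
  expect_equal(unname(type_ranking_correlation(m, m)), rep(1, 5))
  # reciprocal distances reverse every ranking
  inv <- m
  inv[] <- 1 / m
  diag(inv) <- diag(m)
  class(inv) <- class(m)
  expect_equal(unname(type_ranking_correlation(m, inv)), rep(-1, 5))
  # 4 types; for type A the ref ranks (B,C,D) = (1,2,3), test = (2,1,3):
  # Spearman 0.5
  mk <- function(v) {
    x <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
    x[1, 2:4] <- v; x[2:4, 1] <- v
    x[2, 3] <- x[3, 2] <- 5; x[2, 4] <- x[4, 2] <- 6; x[3, 4] <- x[4, 3] <- 7
    structure(x, metric = "L2", class = c("type_distance_matrix", "matrix"))
  }
  rc <- type_ranking_correlation(mk(c(1, 2, 3)), mk(c(2, 1, 3)))
  expect_equal(unname(rc["A"]), 0.5)
  two <- m[1:2, 1:2]
  class(two) <- class(m)
  expect_error(type_ranking_correlation(two, two), "3 types")
})

test_that("max_min_ratio: hand cases", {
  tri <- generate_equidistant_simplex(3, 2, scale = 2)
  expect_equal(max_min_ratio(tri, 1:3), 1, tolerance = 1e-9)
  line <- matrix(c(0, 1, 3), ncol = 1)
  expect_equal(max_min_ratio(line, 1:3), 3)
  expect_equal(max_min_ratio(line, 1:2), 1)
  expect_warning(r <- max_min_ratio(matrix(c(0, 0, 1), ncol = 1), 1:3), "coincident")
  expect_equal(r, Inf)
})

test_that("find_equidistant_groups: simplex, collinear, oracle equivalence", {
  # regular 4-simplex: exactly one maximal group holding all 5 vertices
  s <- generate_equidistant_simplex(5, 4, scale = 2)
  g <- find_equidistant_groups(s, target_distance = 2, epsilon = 0.01)
  expect_length(g$groups, 1)
  expect_equal(g$groups[[1]], 1:5)
  # collinear 0,1,3 with band around 1: only one pair in band, no group >= 3
  line <- matrix(c(0, 1, 3), ncol = 1)
  g2 <- find_equidistant_groups(line, target_distance = 1, epsilon = 0.05)
  expect_length(g2$groups, 0)
  # exhaustive oracle on random instances
  set.seed(30)
  for (rep in 1:25) {
    n <- sample(8:14, 1)
    pts <- matrix(rnorm(n * 3), n, 3)
    D <- as.matrix(dist(pts))
    target <- stats::median(D[upper.tri(D)])
    eps <- runif(1, 0.1, 0.4)
    got <- find_equidistant_groups(pts, target_distance = target, epsilon = eps)
    want <- bf_equidistant_groups(D, target, eps)
    expect_identical(group_key(got$groups), group_key(want),
                     info = sprintf("instance %d (n=%d eps=%.2f)", rep, n, eps))
  }
  # every returned group satisfies the band invariant
  set.seed(31)
  pts <- matrix(rnorm(60), 20, 3)
  D <- as.matrix(dist(pts))
  t0 <- stats::median(D[upper.tri(D)])
  g3 <- find_equidistant_groups(pts, target_distance = t0, epsilon = 0.3)
  for (grp in g3$groups) {
    dd <- D[grp, grp][upper.tri(D[grp, grp])]
    expect_true(all(dd >= t0 * 0.7 - 1e-12 & dd <= t0 * 1.3 + 1e-12))
  }
})

test_that("ratio_distortion: identity, scale freedom, 2D projection inflates", {
  s <- generate_equidistant_simplex(6, 5, scale = 1)
  g <- find_equidistant_groups(s, target_distance = 1, epsilon = 0.01)
  expect_equal(unname(ratio_distortion(g, s, s)$fold), 1, tolerance = 1e-12)
  expect_equal(unname(ratio_distortion(g, s, s * 2)$fold), 1, tolerance = 1e-12)
  # random 2D projection of a 5-simplex cannot stay equidistant
  set.seed(4)
  inflated <- replicate(20, {
    q <- qr.Q(qr(matrix(rnorm(5 * 2), 5, 2)))
    ratio_distortion(g, s, s %*% q)$fold[1]
  })
  expect_true(all(inflated > 1))
})

test_that("mixing_fractions: degenerate and alternating-label cases", {
  pts <- matrix(seq_len(10), ncol = 1)
  idx <- knn_index(pts, 2)
  expect_equal(unname(mixing_fractions(idx, rep("x", 10))), rep(1, 10))
  # alternating labels on the integer line, k = 2: interior cells get 0
  alt <- rep(c("a", "b"), 5)
  mf <- mixing_fractions(idx, alt)
  expect_equal(unname(mf[2:9]), rep(0, 8))
  # two widely separated batches: no mixing
  tb <- two_blobs(n_per = 30, sep = 50)
  mf2 <- mixing_fractions(knn_index(tb$points, 10), tb$labels)
  expect_equal(unname(mf2), rep(1, 60))
  expect_error(mixing_fractions(idx, c(alt[-1], NA)), "cover")
})

test_that("knn_label_predict: separable data, binomial null, validation", {
  tb <- two_blobs(n_per = 60, sep = 40)
  acc <- knn_label_predict(tb$points, tb$labels, k = 10, seed = 1)
  expect_equal(as.numeric(acc), 1.0)
  # random labels, two classes: accuracy near 0.5 over 10 seeds
  set.seed(5)
  pts <- matrix(rnorm(1000 * 4), 1000, 4)
  lab <- sample(c("u", "v"), 1000, replace = TRUE)
  accs <- vapply(1:10, function(s)
    as.numeric(knn_label_predict(pts, lab, k = 25, seed = s)), 0)
  expect_lt(abs(mean(accs) - 0.5), 0.05)
  expect_error(knn_label_predict(tb$points, tb$labels, k = 100, seed = 1),
               "training size")
  expect_warning(knn_label_predict(tb$points, c(rep("a", 110), rep("b", 10)),
                                   k = 20, seed = 1), "reducing k")
})

test_that("inter_intra_ks: hand ECDF cases and oracle equivalence", {
  # identical pools -> 0; disjoint supports -> 1; hand case -> 0.5
  expect_equal(embedaudit:::ks_statistic(c(1, 2), c(1, 2)), 0)
  expect_equal(embedaudit:::ks_statistic(c(10, 10.5, 11), c(0, 0.5, 1)), 1)
  expect_equal(embedaudit:::ks_statistic(c(1, 2), c(1.5, 2.5)), 0.5)
  # ks.test oracle on random pools
  set.seed(6)
  for (rep in 1:20) {
    a <- rnorm(sample(5:30, 1)); b <- rnorm(sample(5:30, 1), mean = runif(1, 0, 2))
    expect_equal(embedaudit:::ks_statistic(a, b), bf_ks(a, b), tolerance = 1e-12)
  }
  # end-to-end on labeled points
  tb <- two_blobs(n_per = 25, sep = 30)
  ks <- inter_intra_ks(tb$points, tb$labels)
  expect_equal(ks$statistic, 1)          # fully separated types
  expect_error(inter_intra_ks(tb$points, rep("one", 50)), "2 types")
})

test_that("inter_intra_correlation: self, scaling, permutation null", {
  set.seed(7)
  pts <- matrix(rnorm(400), 100, 4)
  lab <- rep(paste0("t", 1:20), 5)
  self <- inter_intra_correlation(pts, pts, lab)
  expect_equal(self$inter_corr, 1)
  expect_equal(self$intra_corr, 1)
  sc <- inter_intra_correlation(pts * 2, pts, lab)
  expect_equal(sc$inter_corr, 1, tolerance = 1e-9)
  expect_equal(sc$intra_corr, 1, tolerance = 1e-9)
  # permuting cells destroys the correlation on average
  cors <- vapply(1:100, function(i) {
    perm <- sample(nrow(pts))
    inter_intra_correlation(pts[perm, ], pts, lab)$inter_corr
  }, 0)
  expect_lt(mean(abs(cors)), 0.3)
})

test_that("relative_contrast: hand cases and high-dimensional L1 > L2", {
  # query at origin with two other points at equal distance: RC = 0
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1))
  rc <- relative_contrast(pts, query_count = 3, seed = 1)
  expect_equal(unname(rc[attr(rc, "queries") == 1]), 0)
  # distances 1 and 3 from the query: RC = 2
  pts2 <- rbind(c(0, 0), c(1, 0), c(3, 0))
  rc2 <- relative_contrast(pts2, query_count = 3, seed = 1)
  expect_equal(unname(rc2[attr(rc2, "queries") == 1]), 2)
  # L1 contrast exceeds L2 in high dimension (uniform hypercube)
  ratios <- vapply(1:5, function(s) {
    u <- generate_uniform_points(200, 400, seed = s)
    mean(log2(relative_contrast(u, 25, 1, seed = s) /
              relative_contrast(u, 25, 2, seed = s)))
  }, 0)
  expect_gt(mean(ratios), 0)
  # duplicate of the query is flagged and resampled
  dup <- rbind(c(0, 0), c(0, 0), c(1, 1), c(2, 2), c(3, 5))
  expect_warning(relative_contrast(dup, query_count = 3, seed = 2), "duplicates")
})

test_that("hvg_subset_contrast_protocol: bookkeeping and degenerate sampling", {
  g <- small_mixture(n_cells = 150, n_genes = 60, seed = 12)
  out <- hvg_subset_contrast_protocol(g$counts, n_subsets = 3, subset_size = 20,
                                      pool_size = 40, query_count = 10, seed = 1)
  expect_length(out, 30)
  expect_equal(attr(out, "subset"), rep(1:3, each = 10))
  # subset_size == pool_size: all subsets identical
  out2 <- hvg_subset_contrast_protocol(g$counts, n_subsets = 2, subset_size = 40,
                                       pool_size = 40, query_count = 5, seed = 1)
  expect_equal(out2[1:5], out2[6:10], ignore_attr = TRUE)
  expect_error(hvg_subset_contrast_protocol(g$counts, subset_size = 50,
                                            pool_size = 40), "<= pool_size")
  expect_error(hvg_subset_contrast_protocol(g$counts, pool_size = 100), "exceeds")
})

test_that("jl_min_dimension: printed values and monotonicity", {
  expect_equal(jl_min_dimension(10000, 0.2)$dimensions, 1842L)
  expect_equal(jl_min_dimension(100, 0.2)$dimensions, 921L)
  expect_equal(jl_min_dimension(10000, 0.2)$bound, 8 * log(1e4) / 0.04)
  # strictly increasing in n, decreasing in eps
  b <- function(n, e) jl_min_dimension(n, e)$bound
  expect_true(b(1000, 0.2) < b(2000, 0.2))
  expect_true(b(1000, 0.3) < b(1000, 0.2))
  expect_error(jl_min_dimension(100, 1.5), "in \\(0, 1\\)")
})

test_that("metrics stay in their declared ranges on random labeled data", {
  set.seed(8)
  for (rep in 1:5) {
    n <- sample(40:80, 1)
    pts <- matrix(rnorm(n * 5), n, 5)
    lab <- sample(paste0("t", 1:4), n, replace = TRUE)
    for (metric in c("L1", "L2")) {
      ia <- knn_index(pts, 8, metric)
      ib <- knn_index(matrix(rnorm(n * 2), n, 2), 8, metric)
      j <- jaccard_neighbor_distance(ia, ib)
      expect_true(all(j >= 0 & j <= 1))
      mf <- mixing_fractions(ia, lab)
      expect_true(all(mf >= 0 & mf <= 1))
      ks <- inter_intra_ks(pts, lab, metric)
      expect_true(ks$statistic >= 0 && ks$statistic <= 1 && is.finite(ks$statistic))
      rc <- suppressWarnings(type_ranking_correlation(
        type_distance_matrix(pts, lab, metric),
        type_distance_matrix(pts + rnorm(length(pts)), lab, metric)))
      expect_true(all(rc >= -1 & rc <= 1))
    }
  }
})
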