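# Global- and distance-preservation statistics: type distance matrices and
# ranking correlations, equidistant-group search (Bron-Kerbosch on the
# distance-band graph), max/min ratio inflation, inter/intra-type K-S
# separation, relative contrast of Lk norms, and the Johnson-Lindenstrauss
# minimum-dimension bound.

#' Mean inter- and intra-type distance matrix
#'
#' Symmetric types x types matrix whose off-diagonal (s, t) entry is the mean
#' pairwise distance over all cross-type cell pairs and whose diagonal (t, t)
#' is the mean over within-type pairs (self-pairs excluded). Types with a
#' single cell are excluded with a warning.
#'
#' @param points matrix / `expression_matrix` / `embedding_matrix`.
#' @param labels per-cell type labels (vector or data.frame with `cell_id`).
#' @param metric `"L1"` or `"L2"`.
#' @return a `type_distance_matrix`: numeric matrix with type dimnames and a
#'   `metric` attribute.
#' @export
type_distance_matrix <- function(points, labels, metric = "L2") {
  metric <- check_metric(metric)
  pts <- as_points(points)
  ids <- point_ids(points) %||% paste0("cell", seq_len(nrow(pts)))
  lab <- resolve_labels(labels, ids)
  tab <- table(lab)
  singletons <- names(tab)[tab < 2]
  if (length(singletons)) {
    warnf("excluding %d singleton type(s): %s", length(singletons),
          paste(singletons, collapse = ", "))
    keep <- !(lab %in% singletons)
    pts <- pts[keep, , drop = FALSE]; lab <- lab[keep]
  }
  types <- sort(unique(lab))
  if (length(types) < 2) stopf("need at least 2 types with >= 2 cells")
  D <- pairwise_distances(pts, metric)
  groups <- split(seq_along(lab), lab)
  m <- matrix(0, length(types), length(types), dimnames = list(types, types))
  for (a in seq_along(types)) {
    ga <- groups[[types[a]]]
    sub <- D[ga, ga, drop = FALSE]
    m[a, a] <- mean(sub[upper.tri(sub)])
    if (a < length(types)) for (b in (a + 1):length(types)) {
      gb <- groups[[types[b]]]
      m[a, b] <- m[b, a] <- mean(D[ga, gb])
    }
  }
  structure(m, metric = metric, class = c("type_distance_matrix", "matrix"))
}

#' Correlation of cell-type neighbor rankings between two spaces
#'
#' For each type, all other types are ranked by mean inter-type distance in
#' the reference and in the test space; the Spearman rank correlation
#' (average ranks on ties) between the two rankings is reported per type.
#' Low values mean the embedding has rearranged which types look close to
#' which.
#'
#' @param ref,test `type_distance_matrix` objects over the same types.
#' @return named numeric vector (one correlation in `[-1, 1]` per type).
#' @export
type_ranking_correlation <- function(ref, test) {
  if (!inherits(ref, "type_distance_matrix") || !inherits(test, "type_distance_matrix"))
    stopf("ref and test must be type_distance_matrix objects")
  types <- rownames(ref)
  if (!setequal(types, rownames(test))) stopf("type sets differ between spaces")
  test <- test[types, types]
  if (length(types) < 3) stopf("ranking correlation needs at least 3 types")
  out <- vapply(seq_along(types), function(i) {
    stats::cor(ref[i, -i], test[i, -i], method = "spearman")
  }, 0)
  names(out) <- types
  out
}

#' Max/min pairwise-distance ratio of a cell group
#'
#' Ratio D/d of the largest to smallest pairwise distance within a group;
#' equals 1 for perfectly equidistant points. Coincident points (d = 0) give
#' an infinite ratio with a warning.
#'
#' @param points matrix / `expression_matrix` / `embedding_matrix`.
#' @param group indices or cell ids of the group members (>= 2).
#' @param metric `"L1"` or `"L2"`.
#' @return ratio `>= 1` (possibly `Inf`).
#' @export
max_min_ratio <- function(points, group, metric = "L2") {
  pts <- as_points(points)
  ids <- point_ids(points) %||% paste0("cell", seq_len(nrow(pts)))
  if (is.character(group)) group <- match(group, ids)
  if (anyNA(group)) stopf("group members missing from the point set")
  if (length(group) < 2) stopf("group must have at least 2 members")
  d <- stats::dist(pts[group, , drop = FALSE],
                   method = if (check_metric(metric) == "L1") "manhattan" else "euclidean")
  dmin <- min(d)
  if (dmin == 0) { warnf("coincident points in group: ratio is infinite"); return(Inf) }
  max(d) / dmin
}

#' Find equidistant groups of cells
#'
#' Searches for groups of 3-8 cells whose pairwise distances all lie within a
#' relative band `[target * (1 - epsilon), target * (1 + epsilon)]`. Groups
#' are maximal cliques of the band graph (edges = in-band pairs), enumerated
#' by Bron-Kerbosch with pivoting; cliques larger than `size_max` are
#' truncated to their `size_max` lowest-index members, and enumeration stops
#' after `limit` groups. If `target_distance` is `NULL` it defaults to the
#' 5th (`regime = "near"`) or 95th (`regime = "far"`) percentile of a
#' subsampled pairwise-distance distribution.
#'
#' @param points matrix / container, or a precomputed square distance matrix.
#' @param target_distance center of the distance band (positive), or `NULL`.
#' @param epsilon relative half-width of the band, in (0, 0.5).
#' @param size_min,size_max group size bounds (defaults 3 and 8).
#' @param limit cap on the number of groups returned.
#' @param metric `"L1"` or `"L2"`.
#' @param regime `"near"` or `"far"`, used when `target_distance` is `NULL`.
#' @param node_cap cap on band-graph vertices (lowest-index kept).
#' @param max_pairs subsample cap for the percentile estimate.
#' @param seed seed for the percentile subsample.
#' @return object of class `equidistant_group_set`: list with `groups`
#'   (list of integer index vectors), `target_distance`, `epsilon`, `regime`,
#'   `cell_ids`.
#' @export
find_equidistant_groups <- function(points, target_distance = NULL, epsilon = 0.05,
                                    size_min = 3, size_max = 8, limit = 100000,
                                    metric = "L2", regime = c("near", "far"),
                                    node_cap = 2000, max_pairs = 1e6, seed = 0) {
  regime <- match.arg(regime)
  if (epsilon <= 0 || epsilon >= 0.5) stopf("epsilon must be in (0, 0.5)")
  size_min <- check_positive_int(size_min, "size_min")
  size_max <- check_positive_int(size_max, "size_max")
  if (size_min < 2 || size_max < size_min) stopf("need 2 <= size_min <= size_max")
  is_dist <- is.matrix(points) && nrow(points) == ncol(points) &&
    isTRUE(all.equal(unname(points), unname(t(points)), tolerance = 1e-8)) &&
    all(diag(points) == 0) && min(points) >= 0 && ncol(points) > 2
  D <- if (is_dist) points else pairwise_distances(points, metric)
  n <- nrow(D)
  ids <- if (is_dist) rownames(points) %||% paste0("cell", seq_len(n)) else
    point_ids(points) %||% paste0("cell", seq_len(n))
  if (is.null(target_distance)) {
    pr <- pair_index(n)
    if (nrow(pr) > max_pairs)
      pr <- pr[with_seed(seed, sample.int(nrow(pr), max_pairs)), , drop = FALSE]
    q <- if (regime == "near") 0.05 else 0.95
    target_distance <- unname(stats::quantile(D[pr], q))
  }
  if (!is.finite(target_distance) || target_distance <= 0)
    stopf("target_distance must be positive")
  lo <- target_distance * (1 - epsilon); hi <- target_distance * (1 + epsilon)
  A <- D >= lo & D <= hi
  diag(A) <- FALSE
  keep <- which(rowSums(A) > 0)
  if (length(keep) > node_cap) keep <- keep[seq_len(node_cap)]
  groups <- list()
  if (length(keep) >= size_min) {
    Ak <- A[keep, keep, drop = FALSE]
    adj <- lapply(seq_along(keep), function(i) which(Ak[i, ]))
    found <- new.env(parent = emptyenv())
    found$g <- vector("list", min(limit, 4096)); found$n <- 0
    add_group <- function(g) {
      if (found$n >= limit) return(invisible())
      if (found$n >= length(found$g)) found$g <- c(found$g, vector("list", length(found$g)))
      found$n <- found$n + 1
      found$g[[found$n]] <- g
    }
    # Bron-Kerbosch with pivoting; vertices are indices into `keep`.
    bk <- function(R, P, X) {
      if (found$n >= limit) return(invisible())
      if (!length(P) && !length(X)) {
        if (length(R) >= size_min)
          add_group(sort(keep[R])[seq_len(min(length(R), size_max))])
        return(invisible())
      }
      pivot_pool <- c(P, X)
      pivot <- pivot_pool[which.max(vapply(pivot_pool, function(u) sum(P %in% adj[[u]]), 0L))]
      for (v in P[!(P %in% adj[[pivot]])]) {
        bk(c(R, v), intersect(P, adj[[v]]), intersect(X, adj[[v]]))
        P <- setdiff(P, v)
        X <- c(X, v)
        if (found$n >= limit) return(invisible())
      }
    }
    bk(integer(0), seq_along(keep), integer(0))
    groups <- found$g[seq_len(found$n)]
    groups <- unique(groups)
  }
  structure(list(groups = groups, target_distance = target_distance,
                 epsilon = epsilon, regime = regime, size_min = size_min,
                 size_max = size_max, cell_ids = ids),
            class = "equidistant_group_set")
}

#' @export
print.equidistant_group_set <- function(x, ...) {
  cat(sprintf("<equidistant_group_set> %d groups (%s regime), target %.4g +/- %.0f%%\n",
              length(x$groups), x$regime, x$target_distance, 100 * x$epsilon))
  invisible(x)
}

#' Distortion of max/min ratios between two spaces
#'
#' For each equidistant group (defined in space A), the fold change of its
#' max/min pairwise-distance ratio in space B relative to space A. Fold
#' changes near 1 mean the group's internal distance structure survived the
#' embedding; large values are the distance-distortion signature. A
#' size-stratified summary tests whether distortion grows with group size.
#'
#' @param groups an `equidistant_group_set` (defined in `space_a`).
#' @param space_a,space_b point containers sharing the same cells.
#' @param metric `"L1"` or `"L2"`.
#' @return list with `fold` (per-group fold change), `size` (group sizes) and
#'   `by_size` (data.frame: size, n, median_fold).
#' @export
ratio_distortion <- function(groups, space_a, space_b, metric = "L2") {
  if (!inherits(groups, "equidistant_group_set"))
    stopf("`groups` must be an equidistant_group_set")
  pa <- as_points(space_a); pb <- as_points(space_b)
  if (nrow(pa) != nrow(pb)) stopf("spaces have different numbers of cells")
  n <- nrow(pa)
  fold <- vapply(groups$groups, function(g) {
    if (max(g) > n) stopf("group member missing from space B")
    max_min_ratio(pb, g, metric) / max_min_ratio(pa, g, metric)
  }, 0)
  size <- lengths(groups$groups)
  by_size <- if (length(size)) {
    agg <- vapply(split(fold, size), stats::median, 0)
    data.frame(size = as.integer(names(agg)), n = as.integer(table(size)),
               median_fold = unname(agg))
  } else data.frame(size = integer(), n = integer(), median_fold = numeric())
  list(fold = fold, size = size, by_size = by_size)
}

ks_statistic <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  grid <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(grid) - stats::ecdf(b)(grid)))
}

#' Inter- versus intra-type distance separation (K-S statistic)
#'
#' Pools all inter-type pairwise distances and all intra-type pairwise
#' distances (each pool subsampled to `max_pairs` with a recorded seed) and
#' returns their two-sample Kolmogorov-Smirnov statistic. Higher values mean
#' more separated cell types.
#'
#' @param points matrix / container, or a precomputed square distance matrix.
#' @param labels per-cell type labels.
#' @param metric `"L1"` or `"L2"`.
#' @param max_pairs subsample cap per pool.
#' @param seed subsample seed.
#' @return list with `statistic` in `[0, 1]`, `inter` and `intra` distance
#'   pools.
#' @export
inter_intra_ks <- function(points, labels, metric = "L2", max_pairs = 1e6,
                           seed = 0) {
  is_dist <- is.matrix(points) && nrow(points) == ncol(points) &&
    all(diag(points) == 0) && isTRUE(all.equal(unname(points), unname(t(points)),
                                               tolerance = 1e-8)) && ncol(points) > 2
  D <- if (is_dist) points else pairwise_distances(points, metric)
  n <- nrow(D)
  ids <- point_ids(points) %||% rownames(D) %||% paste0("cell", seq_len(n))
  lab <- resolve_labels(labels, ids)
  if (length(unique(lab)) < 2) stopf("need at least 2 types")
  pr <- pair_index(n)
  same <- lab[pr[, 1]] == lab[pr[, 2]]
  inter <- D[pr[!same, , drop = FALSE]]
  intra <- D[pr[same, , drop = FALSE]]
  if (length(inter) < 2 || length(intra) < 2)
    stopf("fewer than 2 distances in a pool")
  sub <- function(x, s) if (length(x) > max_pairs)
    with_seed(s, x[sample.int(length(x), max_pairs)]) else x
  inter <- sub(inter, seed); intra <- sub(intra, seed + 1)
  list(statistic = ks_statistic(inter, intra), inter = inter, intra = intra)
}

#' Correlation of inter- and intra-type distances between two spaces
#'
#' Pearson correlation between the vectors of mean inter-type distances
#' (off-diagonal entries of the [type_distance_matrix()]) and, separately,
#' between the mean intra-type distances (diagonals) of a test and a
#' reference space. These are the quantities usually read off 2D visuals:
#' inter-type correlation tracks between-cluster relationships, intra-type
#' correlation tracks apparent cluster spread.
#'
#' @param test,ref point containers over the same cells.
#' @param labels per-cell type labels.
#' @param metric `"L1"` or `"L2"`.
#' @return list with `inter_corr` and `intra_corr`, both in `[-1, 1]`.
#' @export
inter_intra_correlation <- function(test, ref, labels, metric = "L2") {
  tdm_t <- type_distance_matrix(test, labels, metric)
  tdm_r <- type_distance_matrix(ref, labels, metric)
  types <- rownames(tdm_r)
  if (!setequal(types, rownames(tdm_t))) stopf("type sets differ between spaces")
  tdm_t <- tdm_t[types, types]
  if (length(types) < 3) stopf("need at least 3 types")
  ut <- upper.tri(tdm_r)
  list(inter_corr = stats::cor(tdm_r[ut], tdm_t[ut]),
       intra_corr = stats::cor(diag(tdm_r), diag(tdm_t)))
}

#' Relative contrast of an Lk norm
#'
#' For each of `query_count` randomly chosen query points, the relative
#' contrast `RC = (Dmax - Dmin) / Dmin`, where Dmax/Dmin are the farthest and
#' nearest Lk distances from the query to all other points. RC near 0 means
#' the norm no longer distinguishes near from far (the curse-of-
#' dimensionality regime); larger RC means more usable proximity structure.
#' Queries duplicating another point (Dmin = 0) are flagged and resampled.
#'
#' @param points matrix / container.
#' @param query_count number of random query points.
#' @param norm_order 1 (L1) or 2 (L2).
#' @param seed query-sampling seed.
#' @return numeric vector of per-query RC values (attribute `queries` holds
#'   the query indices).
#' @export
relative_contrast <- function(points, query_count = 50, norm_order = 2, seed = 0) {
  pts <- as_points(points)
  n <- nrow(pts)
  if (n < 3) stopf("need at least 3 points")
  if (!norm_order %in% c(1, 2)) stopf("norm_order must be 1 or 2")
  metric <- if (norm_order == 1) "L1" else "L2"
  query_count <- check_positive_int(query_count, "query_count")
  with_seed(seed, {
    pool <- sample.int(n)
    rc <- numeric(0); qs <- integer(0); i <- 1
    while (length(rc) < query_count && i <= n) {
      q <- pool[i]; i <- i + 1
      d <- cross_distances(pts[q, , drop = FALSE], pts[-q, , drop = FALSE], metric)[1, ]
      dmin <- min(d)
      if (dmin == 0) { warnf("query %d duplicates another point; resampled", q); next }
      rc <- c(rc, (max(d) - dmin) / dmin); qs <- c(qs, q)
    }
    if (length(rc) < query_count)
      stopf("could not find %d queries with nonzero nearest distance", query_count)
    attr(rc, "queries") <- qs
    rc
  })
}

#' L1-vs-L2 relative contrast over random HVG subsets
#'
#' The protocol behind the norm-comparison violin plots: select the top
#' `pool_size` highly variable genes, draw `n_subsets` random subsets of
#' `subset_size` genes, and for each subset compute relative contrast under
#' L1 and L2 (same queries for both norms) in the ambient gene space,
#' reporting `log2(RC_L1 / RC_L2)` per query. Positive values mean L1
#' delineates proximity better.
#'
#' @param matrix an `expression_matrix` (counts are log-normalized first).
#' @param n_subsets number of random gene subsets (default 5).
#' @param subset_size genes per subset (default 1000).
#' @param pool_size HVG pool size (default 2000), `>= subset_size` and
#'   `<= n_genes`.
#' @param query_count queries per subset (default 50).
#' @param seed integer seed.
#' @return numeric vector of length `n_subsets * query_count` of log2 contrast
#'   ratios, with attribute `subset` mapping entries to subsets.
#' @export
hvg_subset_contrast_protocol <- function(matrix, n_subsets = 5, subset_size = 1000,
                                         pool_size = 2000, query_count = 50,
                                         seed = 0) {
  if (!inherits(matrix, "expression_matrix")) stopf("`matrix` must be an expression_matrix")
  if (matrix$layer == "counts") matrix <- lognormalize(matrix)
  if (pool_size > ncol(matrix$values))
    stopf("pool_size (%d) exceeds the number of genes (%d)", pool_size, ncol(matrix$values))
  if (subset_size > pool_size) stopf("subset_size must be <= pool_size")
  pool <- select_hvg(matrix, pool_size)
  v <- as_points(pool)
  out <- numeric(0); tag <- integer(0)
  for (s in seq_len(n_subsets)) {
    genes <- with_seed(seed + s, sample.int(pool_size, subset_size))
    sub <- v[, genes, drop = FALSE]
    # queries are pinned per protocol run (same cells for every subset and
    # both norms) so that subset and norm are the only varying factors
    rc1 <- relative_contrast(sub, query_count, norm_order = 1, seed = seed + 100)
    rc2 <- relative_contrast(sub, query_count, norm_order = 2, seed = seed + 100)
    out <- c(out, log2(rc1 / rc2)); tag <- c(tag, rep.int(s, query_count))
  }
  attr(out, "subset") <- tag
  out
}

#' Johnson-Lindenstrauss minimum embedding dimension
#'
#' The minimum dimension `8 ln(n) / eps^2` guaranteeing preservation of all
#' pairwise distances among n points within relative error eps by a linear
#' (random-projection) embedding. For n = 10,000 cells and eps = 0.2 this is
#' 1,842 dimensions - vastly more than 2.
#'
#' @param n number of points (>= 2).
#' @param eps relative distance-error margin, in (0, 1).
#' @return list with `bound` (the real value) and `dimensions` (its floor).
#' @export
jl_min_dimension <- function(n, eps) {
  n <- check_positive_int(n, "n")
  if (n < 2) stopf("n must be >= 2")
  if (!is.finite(eps) || eps <= 0 || eps >= 1) stopf("eps must be in (0, 1)")
  bound <- 8 * log(n) / eps^2
  list(bound = bound, dimensions = as.integer(floor(bound)))
}
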