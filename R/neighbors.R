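# Neighbor-based distortion metrics: exact kNN index, Jaccard neighbor
# dissimilarity between spaces, same-label mixing fractions, and kNN label
# prediction.

#' Exact k-nearest-neighbor index
#'
#' Exact k nearest neighbors of every point under the L1 or L2 norm, self
#' excluded, ties broken by ascending point index. Computed from the full
#' pairwise distance matrix, which is exact (no approximate search) and fast
#' at desk scale.
#'
#' @param points matrix / `expression_matrix` / `embedding_matrix`.
#' @param k number of neighbors, `< n_points`.
#' @param metric `"L1"` or `"L2"`.
#' @return object of class `neighbor_index`: list with `ids` (n x k integer
#'   matrix of neighbor indices, nearest first), `dists`, `k`, `metric`,
#'   `cell_ids`, `source_space`.
#' @export
knn_index <- function(points, k, metric = "L2") {
  metric <- check_metric(metric)
  k <- check_positive_int(k, "k")
  pts <- as_points(points)
  n <- nrow(pts)
  if (k >= n) stopf("k (%d) must be < n_points (%d)", k, n)
  D <- pairwise_distances(pts, metric)
  ids <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  idx <- seq_len(n)
  for (i in idx) {
    d <- D[i, ]
    d[i] <- Inf                                   # exclude self
    ord <- order(d, idx)[seq_len(k)]              # stable: ties by index
    ids[i, ] <- ord
    dst[i, ] <- d[ord]
  }
  src <- if (inherits(points, "embedding_matrix")) points$provenance else
    list(method = if (inherits(points, "expression_matrix")) "ambient" else "points")
  structure(list(ids = ids, dists = dst, k = k, metric = metric,
                 cell_ids = point_ids(points) %||% paste0("cell", idx),
                 source_space = src),
            class = "neighbor_index")
}

#' @export
print.neighbor_index <- function(x, ...) {
  cat(sprintf("<neighbor_index> %d cells, k = %d, metric %s\n",
              nrow(x$ids), x$k, x$metric))
  invisible(x)
}

#' Jaccard distance between neighbor sets in two spaces
#'
#' Per cell, `1 - |A intersect B| / |A union B|` over the cell's k-nearest-
#' neighbor sets in two spaces; 1.0 denotes no overlap. This is the local-
#' preservation statistic: a faithful embedding keeps it near 0.
#'
#' @param idx_a,idx_b `neighbor_index` objects over the same cells with the
#'   same k.
#' @return named numeric vector of per-cell Jaccard distances in `[0, 1]`;
#'   the mean over cells is the usual summary.
#' @export
jaccard_neighbor_distance <- function(idx_a, idx_b) {
  if (!inherits(idx_a, "neighbor_index") || !inherits(idx_b, "neighbor_index"))
    stopf("both arguments must be neighbor_index objects")
  if (idx_a$k != idx_b$k) stopf("neighbor indices have different k (%d vs %d)", idx_a$k, idx_b$k)
  if (nrow(idx_a$ids) != nrow(idx_b$ids) || !identical(idx_a$cell_ids, idx_b$cell_ids))
    stopf("neighbor indices cover different cell sets")
  n <- nrow(idx_a$ids); k <- idx_a$k
  out <- numeric(n)
  for (i in seq_len(n)) {
    inter <- sum(idx_a$ids[i, ] %in% idx_b$ids[i, ])
    out[i] <- 1 - inter / (2 * k - inter)
  }
  names(out) <- idx_a$cell_ids
  out
}

resolve_labels <- function(labels, cell_ids) {
  if (is.data.frame(labels)) {
    if (!"cell_id" %in% names(labels)) stopf("label table needs a cell_id column")
    col <- setdiff(names(labels), "cell_id")[1]
    lab <- labels[[col]][match(cell_ids, labels$cell_id)]
  } else {
    lab <- if (!is.null(names(labels))) labels[cell_ids] else labels
  }
  if (length(lab) != length(cell_ids) || anyNA(lab))
    stopf("labels must cover every cell")
  as.character(lab)
}

#' Fraction of nearest neighbors sharing a cell's label
#'
#' Per cell, the fraction of its k nearest neighbors carrying the same
#' condition/batch label; 1.0 is no mixing. The full distribution is the
#' mixing diagnostic; `restrict_to` limits the report to one label's cells
#' (e.g. only query-batch cells).
#'
#' @param idx a `neighbor_index`.
#' @param labels per-cell labels: a vector (optionally named by cell id) or a
#'   data.frame with `cell_id` plus one label column.
#' @param restrict_to optional label value; return fractions only for cells
#'   with this label.
#' @return named numeric vector of per-cell same-label fractions in `[0, 1]`.
#' @export
mixing_fractions <- function(idx, labels, restrict_to = NULL) {
  if (!inherits(idx, "neighbor_index")) stopf("`idx` must be a neighbor_index")
  lab <- resolve_labels(labels, idx$cell_ids)
  nbr_lab <- matrix(lab[idx$ids], nrow = nrow(idx$ids))
  frac <- rowMeans(nbr_lab == lab)
  names(frac) <- idx$cell_ids
  if (!is.null(restrict_to)) frac <- frac[lab == restrict_to]
  frac
}

#' k-nearest-neighbor label prediction accuracy
#'
#' Splits the cells into training and test sets (stratified by label),
#' predicts each test cell's label by majority vote of its k nearest
#' training cells, and reports the fraction predicted correctly. Vote ties
#' are broken by the smaller mean neighbor distance. If some label has fewer
#' than k training cells, k is reduced with a warning.
#'
#' @param points matrix / `expression_matrix` / `embedding_matrix`.
#' @param labels per-cell labels (vector or data.frame as in
#'   [mixing_fractions()]).
#' @param test_fraction fraction of cells held out (default 0.3).
#' @param k neighbors used in the vote (default 50).
#' @param metric `"L1"` or `"L2"`.
#' @param seed integer seed for the split.
#' @return accuracy in `[0, 1]`, with attributes `predicted`, `truth` and
#'   `test_idx`.
#' @export
knn_label_predict <- function(points, labels, test_fraction = 0.3, k = 50,
                              metric = "L2", seed = 0) {
  metric <- check_metric(metric)
  pts <- as_points(points)
  n <- nrow(pts)
  ids <- point_ids(points) %||% paste0("cell", seq_len(n))
  lab <- resolve_labels(labels, ids)
  if (test_fraction <= 0 || test_fraction >= 1) stopf("test_fraction must be in (0,1)")
  test_idx <- with_seed(seed, {
    unlist(lapply(split(seq_len(n), lab), function(g) {
      m <- max(1, floor(test_fraction * length(g)))
      if (m >= length(g)) m <- length(g) - 1
      sample(g, m)
    }), use.names = FALSE)
  })
  train_idx <- setdiff(seq_len(n), test_idx)
  if (k >= length(train_idx)) stopf("k (%d) must be < training size (%d)", k, length(train_idx))
  min_class <- min(table(lab[train_idx]))
  if (min_class < k) {
    warnf("reducing k from %d to %d (smallest training class)", k, min_class)
    k <- min_class
  }
  D <- cross_distances(pts[test_idx, , drop = FALSE], pts[train_idx, , drop = FALSE], metric)
  train_lab <- lab[train_idx]
  pred <- character(length(test_idx))
  for (i in seq_along(test_idx)) {
    ord <- order(D[i, ], seq_along(train_lab))[seq_len(k)]
    votes <- table(train_lab[ord])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      meand <- vapply(top, function(l) mean(D[i, ord[train_lab[ord] == l]]), 0)
      top <- top[order(meand, top)][1]
    }
    pred[i] <- top
  }
  acc <- mean(pred == lab[test_idx])
  attr(acc, "predicted") <- pred
  attr(acc, "truth") <- lab[test_idx]
  attr(acc, "test_idx") <- test_idx
  acc
}
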