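# Internal helpers: seed scoping, validation, distance kernels.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
# Every generator/stochastic operation routes its randomness through this so
# that it is a pure function of its arguments (including seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

check_positive_int <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x < 1 || x != round(x))
    stopf("`%s` must be a single positive integer (got %s)", name, paste(x, collapse = ","))
  as.integer(x)
}

check_metric <- function(metric) {
  metric <- toupper(metric[1])
  if (!metric %in% c("L1", "L2")) stopf("`metric` must be \"L1\" or \"L2\"")
  metric
}

# Coerce any of the package's point containers to a dense numeric matrix
# (rows = cells/points).
as_points <- function(x) {
  if (inherits(x, "expression_matrix")) {
    m <- x$values
    if (inherits(m, "Matrix")) m <- as.matrix(m)
    rownames(m) <- x$cell_ids
    return(m)
  }
  if (inherits(x, "embedding_matrix")) return(x$coords)
  if (inherits(x, "Matrix")) return(as.matrix(x))
  if (is.data.frame(x)) return(as.matrix(x))
  if (is.matrix(x)) return(x)
  if (is.numeric(x)) return(matrix(x, ncol = 1))
  stopf("cannot interpret object of class %s as a point matrix", class(x)[1])
}

point_ids <- function(x) {
  if (inherits(x, "expression_matrix")) return(x$cell_ids)
  if (inherits(x, "embedding_matrix")) return(rownames(x$coords))
  rownames(as_points(x))
}

#' Pairwise distances between rows of a matrix
#'
#' Full dense distance matrix under the L1 (Manhattan) or L2 (Euclidean)
#' norm. L2 uses the BLAS Gram-matrix identity; L1 goes through the C
#' implementation in [stats::dist()].
#'
#' @param x numeric matrix (or an `expression_matrix`/`embedding_matrix`);
#'   rows are points.
#' @param metric `"L1"` or `"L2"`.
#' @return dense symmetric numeric matrix of distances.
#' @keywords internal
pairwise_distances <- function(x, metric = "L2") {
  metric <- check_metric(metric)
  x <- as_points(x)
  if (metric == "L2") {
    sq <- rowSums(x * x)
    d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
    d2[d2 < 0] <- 0
    d <- sqrt(d2)
    diag(d) <- 0
    # enforce exact symmetry (tcrossprod round-off)
    d[lower.tri(d)] <- t(d)[lower.tri(d)]
    d
  } else {
    as.matrix(stats::dist(x, method = "manhattan"))
  }
}

# Distances from every row of `x` to every row of `y` (m x n).
cross_distances <- function(x, y, metric = "L2") {
  metric <- check_metric(metric)
  x <- as_points(x); y <- as_points(y)
  if (ncol(x) != ncol(y)) stopf("dimension mismatch: %d vs %d columns", ncol(x), ncol(y))
  if (metric == "L2") {
    d2 <- outer(rowSums(x * x), rowSums(y * y), "+") - 2 * tcrossprod(x, y)
    d2[d2 < 0] <- 0
    sqrt(d2)
  } else {
    ty <- t(y)
    out <- matrix(0, nrow(x), nrow(y))
    for (i in seq_len(nrow(x))) out[i, ] <- colSums(abs(ty - x[i, ]))
    out
  }
}

# Upper-triangle (i < j) pair index matrix for n points.
pair_index <- function(n) {
  i <- rep.int(seq_len(n - 1), times = (n - 1):1)
  j <- sequence((n - 1):1) + i
  cbind(i = i, j = j)
}
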