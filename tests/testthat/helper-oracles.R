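# Independent brute-force oracles used to validate the package's
# implementations on small instances, plus small fixture builders.

# exact kNN by full enumeration with explicit stable tie-break
bf_knn <- function(pts, k, metric = "L2") {
  n <- nrow(pts)
  ids <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d <- vapply(seq_len(n), function(j) {
      if (metric == "L1") sum(abs(pts[i, ] - pts[j, ])) else
        sqrt(sum((pts[i, ] - pts[j, ])^2))
    }, 0)
    d[i] <- Inf
    ids[i, ] <- order(d, seq_len(n))[seq_len(k)]
  }
  ids
}

# all maximal cliques of an adjacency matrix by exhaustive subset checking
# (feasible up to ~16 vertices), then the same size filter/truncation rule
# as find_equidistant_groups: cliques of size in [size_min, size_max] kept,
# larger maximal cliques truncated to their size_max lowest-index members.
bf_equidistant_groups <- function(D, target, eps, size_min = 3, size_max = 8) {
  n <- nrow(D)
  A <- D >= target * (1 - eps) & D <= target * (1 + eps)
  diag(A) <- FALSE
  is_clique <- function(s) all(A[s, s][upper.tri(A[s, s])])
  maximal <- list()
  for (sz in 2:n) {
    for (s in utils::combn(n, sz, simplify = FALSE)) {
      if (!is_clique(s)) next
      ext <- any(vapply(setdiff(seq_len(n), s), function(v) all(A[v, s]), TRUE))
      if (!ext) maximal[[length(maximal) + 1]] <- s
    }
  }
  out <- lapply(maximal[lengths(maximal) >= size_min], function(g)
    sort(g)[seq_len(min(length(g), size_max))])
  unique(out)
}

# canonical string form for comparing group sets regardless of order
group_key <- function(groups) sort(vapply(groups, function(g)
  paste(sort(g), collapse = "-"), ""))

# two-sample KS statistic via stats::ks.test (independent of ks_statistic)
bf_ks <- function(a, b) unname(suppressWarnings(stats::ks.test(a, b)$statistic))

# small synthetic mixture shared across unit tests
small_mixture <- function(n_cells = 300, n_genes = 150, n_types = 4, seed = 11) {
  generate_mixture_counts(mixture_spec(n_cells = n_cells, n_genes = n_genes,
                                       n_types = n_types, seed = seed))
}

# two well-separated Gaussian blobs in d dims
two_blobs <- function(n_per = 60, d = 10, sep = 30, sd = 1, seed = 5) {
  set.seed(seed)
  pts <- rbind(matrix(rnorm(n_per * d, 0, sd), n_per),
               matrix(rnorm(n_per * d, sep, sd), n_per))
  list(points = pts, labels = rep(c("a", "b"), each = n_per))
}
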