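# The embedding harness: PCA preprocessing, delegated nonlinear 2D
# reduction (UMAP via uwot, t-SNE via Rtsne) with pinned seeds, standard
# chains (ambient, PCA-d, PCA-d->2D, direct 2D), parameter sweeps and
# out-of-sample transform.

#' Construct an embedding matrix with provenance
#'
#' @param coords cells x d numeric matrix; rownames are cell identifiers.
#' @param provenance named list recording how the coordinates were made
#'   (method, preprocessing, neighbor_param, metric, seed, replicate).
#' @return object of class `embedding_matrix`.
#' @export
embedding_matrix <- function(coords, provenance = list()) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stopf("embedding coordinates must be finite")
  if (ncol(coords) < 1) stopf("embedding must have d >= 1")
  if (is.null(rownames(coords))) rownames(coords) <- paste0("cell", seq_len(nrow(coords)))
  defaults <- list(method = NA_character_, preprocessing = "none",
                   neighbor_param = NA_real_, metric = "L2", seed = NA_integer_,
                   replicate = NA_integer_)
  provenance <- utils::modifyList(defaults, provenance)
  structure(list(coords = coords, d = ncol(coords), provenance = provenance),
            class = "embedding_matrix")
}

#' @export
dim.embedding_matrix <- function(x) dim(x$coords)

#' @export
print.embedding_matrix <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<embedding_matrix> %d cells x %d dims [%s%s, metric %s, seed %s]\n",
              nrow(x$coords), x$d, p$method,
              if (!is.na(p$neighbor_param)) sprintf("(%g)", p$neighbor_param) else "",
              p$metric, p$seed))
  invisible(x)
}

#' Principal component scores
#'
#' Column-centered PCA of an expression or point matrix, returning the top
#' `d` component scores. The sign of each component is fixed so that its
#' largest-magnitude gene loading is positive, making results reproducible
#' across runs and backends. Uses truncated SVD ([irlba::irlba()]) for large
#' matrices and exact SVD otherwise.
#'
#' @param matrix `expression_matrix`, `embedding_matrix` or numeric matrix.
#' @param d number of components, `<= min(n_cells, n_genes)`.
#' @param seed integer seed (irlba initialization).
#' @param scale. z-score columns before the decomposition (default off).
#' @return an `embedding_matrix` with method `"pca"`; the rotation matrix
#'   and column centers are attached as attributes `rotation` / `center`.
#' @export
run_pca <- function(matrix, d = 50, seed = 0, scale. = FALSE) {
  x <- as_points(matrix)
  d <- check_positive_int(d, "d")
  if (d > min(dim(x))) stopf("d (%d) exceeds min(n_cells, n_genes) = %d", d, min(dim(x)))
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  if (isTRUE(scale.)) {
    sds <- apply(xc, 2, stats::sd)
    sds[sds == 0] <- 1
    xc <- sweep(xc, 2, sds, "/")
  }
  small <- min(dim(xc)) < 200 || d > 0.5 * min(dim(xc))
  if (small) {
    sv <- svd(xc, nu = d, nv = d)
    scores <- sv$u %*% diag(sv$d[seq_len(d)], d, d)
    rot <- sv$v
  } else {
    sv <- with_seed(seed, irlba::irlba(xc, nv = d))
    scores <- sv$u %*% diag(sv$d, d, d)
    rot <- sv$v
  }
  # sign convention: largest-|loading| entry of each component is positive
  for (j in seq_len(d)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) { rot[, j] <- -rot[, j]; scores[, j] <- -scores[, j] }
  }
  rownames(scores) <- point_ids(matrix) %||% rownames(x)
  colnames(scores) <- paste0("PC", seq_len(d))
  out <- embedding_matrix(scores, provenance = list(
    method = "pca", preprocessing = sprintf("center%s", if (isTRUE(scale.)) "+scale" else ""),
    metric = "L2", seed = seed))
  attr(out, "rotation") <- rot
  attr(out, "center") <- ctr
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Nonlinear reduction to 2D
#'
#' Delegates to an established backend: [uwot::umap()] or [Rtsne::Rtsne()].
#' Runs single-threaded with a pinned seed so that identical inputs give
#' identical coordinates; replicate runs differ only by seed. For
#' `metric = "L1"`, UMAP uses its Manhattan metric and t-SNE is fed a
#' precomputed L1 distance matrix.
#'
#' @param x `expression_matrix`, `embedding_matrix` or numeric matrix.
#' @param method `"umap"` or `"tsne"`.
#' @param neighbor_param `n_neighbors` for UMAP (default 15) or perplexity
#'   for t-SNE (default 30); must be `< n_cells`.
#' @param metric `"L1"` or `"L2"`.
#' @param seed integer seed.
#' @param ret_model keep the fitted UMAP model for out-of-sample transform
#'   via [transform_new_points()] (UMAP only).
#' @return an `embedding_matrix` with two columns and full provenance.
#' @export
run_nonlinear_2d <- function(x, method = c("umap", "tsne"), neighbor_param = NULL,
                             metric = "L2", seed = 0, ret_model = FALSE) {
  method <- match.arg(method)
  metric <- check_metric(metric)
  pts <- as_points(x)
  n <- nrow(pts)
  if (is.null(neighbor_param)) neighbor_param <- if (method == "umap") 15 else 30
  if (neighbor_param >= n) stopf("neighbor_param (%g) must be < n_cells (%d)", neighbor_param, n)
  prep <- if (inherits(x, "embedding_matrix")) {
    sprintf("%s-%dD", x$provenance$method, x$d)
  } else "ambient"
  if (method == "umap") {
    if (!requireNamespace("uwot", quietly = TRUE))
      stopf("UMAP backend (uwot) is not available")
    fit <- with_seed(seed, uwot::umap(pts, n_neighbors = neighbor_param,
                                      metric = if (metric == "L1") "manhattan" else "euclidean",
                                      n_threads = 1, n_sgd_threads = 0,
                                      ret_model = ret_model))
    coords <- if (ret_model) fit$embedding else fit
  } else {
    if (!requireNamespace("Rtsne", quietly = TRUE))
      stopf("t-SNE backend (Rtsne) is not available")
    if (ret_model) stopf("t-SNE does not support out-of-sample transform")
    if (3 * neighbor_param >= n - 1)
      stopf("perplexity too large for %d cells", n)
    res <- if (metric == "L1") {
      D <- pairwise_distances(pts, "L1")
      with_seed(seed, Rtsne::Rtsne(D, is_distance = TRUE, perplexity = neighbor_param,
                                   pca = FALSE, check_duplicates = FALSE, num_threads = 1))
    } else {
      with_seed(seed, Rtsne::Rtsne(pts, perplexity = neighbor_param, pca = FALSE,
                                   check_duplicates = FALSE, num_threads = 1))
    }
    coords <- res$Y
  }
  rownames(coords) <- point_ids(x) %||% rownames(pts)
  colnames(coords) <- c("dim1", "dim2")
  out <- embedding_matrix(coords, provenance = list(
    method = method, preprocessing = prep, neighbor_param = neighbor_param,
    metric = metric, seed = seed))
  if (ret_model) {
    attr(out, "reducer_state") <- fit
    attr(out, "train_dim") <- ncol(pts)
  }
  out
}

parse_chain <- function(chain) {
  if (chain == "ambient") return(list(kind = "ambient"))
  m <- regmatches(chain, regexec("^pca-([0-9]+)$", chain))[[1]]
  if (length(m)) return(list(kind = "pca", d = as.integer(m[2])))
  m <- regmatches(chain, regexec("^pca-([0-9]+)-(umap|tsne)$", chain))[[1]]
  if (length(m)) return(list(kind = "pca2d", d = as.integer(m[2]), method = m[3]))
  if (chain %in% c("umap", "tsne")) return(list(kind = "direct2d", method = chain))
  stopf("unknown chain \"%s\" (use ambient, pca-<d>, pca-<d>-umap/tsne, umap, tsne)", chain)
}

#' Run the standard preprocessing and embedding chains
#'
#' Mimics standard single-cell practice: log-normalize the counts (optionally
#' restrict to highly variable genes) to obtain the ambient space, then embed
#' through each requested chain. Chain names: `"ambient"` (identity),
#' `"pca-<d>"` (e.g. `"pca-50"`), `"pca-<d>-umap"` / `"pca-<d>-tsne"`
#' (PCA preprocessing then nonlinear 2D), and `"umap"` / `"tsne"` (direct 2D
#' from ambient). Stochastic (nonlinear) chains are run `n_replicates` times
#' with seeds `seed, seed + 1, ...`, recorded in provenance.
#'
#' @param counts `expression_matrix`; layer `"counts"` is log-normalized
#'   first, layer `"lognorm"` is used as the ambient space directly.
#' @param config list with any of: `chains` (character, default
#'   `c("ambient", "pca-50", "pca-50-umap")`), `n_replicates` (default 3),
#'   `seed` (default 0), `target_sum` (default 1e4), `n_hvg` (optional),
#'   `scale` (default FALSE), `metric` (default `"L2"`), `umap_neighbors`
#'   (default 15), `tsne_perplexity` (default 30).
#' @return named list (one entry per chain) of lists of `embedding_matrix`
#'   replicates; deterministic chains have one replicate. The ambient entry
#'   is the log-normalized coordinate matrix itself (identity chain).
#' @export
pipeline_embed <- function(counts, config = list()) {
  cfg <- utils::modifyList(list(
    chains = c("ambient", "pca-50", "pca-50-umap"), n_replicates = 3, seed = 0,
    target_sum = 1e4, n_hvg = NULL, scale = FALSE, metric = "L2",
    umap_neighbors = 15, tsne_perplexity = 30), config)
  if (!length(cfg$chains)) stopf("config must name at least one chain")
  parsed <- lapply(cfg$chains, parse_chain)
  names(parsed) <- cfg$chains
  ambient <- if (inherits(counts, "expression_matrix") && counts$layer == "counts")
    lognormalize(counts, cfg$target_sum) else counts
  if (!is.null(cfg$n_hvg)) ambient <- select_hvg(ambient, cfg$n_hvg)
  amb_mat <- as_points(ambient)
  ambient_emb <- embedding_matrix(amb_mat, provenance = list(
    method = "identity", preprocessing = "ambient", metric = cfg$metric, seed = cfg$seed))
  pca_dims <- unique(unlist(lapply(parsed, function(p) p$d)))
  pcas <- list()
  for (d in pca_dims) pcas[[as.character(d)]] <- run_pca(ambient, d = d, seed = cfg$seed,
                                                         scale. = cfg$scale)
  run_stochastic <- function(input, method) {
    np <- if (method == "umap") cfg$umap_neighbors else cfg$tsne_perplexity
    lapply(seq_len(cfg$n_replicates), function(r) {
      e <- run_nonlinear_2d(input, method = method, neighbor_param = np,
                            metric = cfg$metric, seed = cfg$seed + r - 1)
      e$provenance$replicate <- r
      e
    })
  }
  out <- vector("list", length(parsed))
  names(out) <- names(parsed)
  for (nm in names(parsed)) {
    p <- parsed[[nm]]
    out[[nm]] <- switch(p$kind,
      ambient = list(ambient_emb),
      pca = list(pcas[[as.character(p$d)]]),
      pca2d = run_stochastic(pcas[[as.character(p$d)]], p$method),
      direct2d = run_stochastic(ambient_emb, p$method))
  }
  attr(out, "ambient") <- ambient
  attr(out, "config") <- cfg
  out
}

#' Sweep the neighbor parameter of a nonlinear reducer
#'
#' One embedding per value in `neighbor_params`, all from the same input and
#' seed, so that differences between the embeddings are attributable to the
#' parameter alone.
#'
#' @inheritParams run_nonlinear_2d
#' @param neighbor_params nonempty list/vector of neighbor settings
#'   (n_neighbors for UMAP, perplexity for t-SNE).
#' @return list of `embedding_matrix`, named by parameter value.
#' @export
parameter_sweep <- function(x, method = c("umap", "tsne"), neighbor_params,
                            metric = "L2", seed = 0) {
  method <- match.arg(method)
  if (!length(neighbor_params)) stopf("neighbor_params must be nonempty")
  out <- lapply(neighbor_params, function(np)
    run_nonlinear_2d(x, method = method, neighbor_param = np, metric = metric,
                     seed = seed))
  names(out) <- as.character(unlist(neighbor_params))
  out
}

#' Transform new points through a fitted 2D reducer
#'
#' Projects out-of-sample points into a fitted UMAP space (the reference-
#' mapping operation). The embedding must have been produced with
#' `ret_model = TRUE` in [run_nonlinear_2d()].
#'
#' @param fit an `embedding_matrix` carrying a fitted reducer state.
#' @param new_points matrix of new points in the reducer's training space.
#' @param seed integer seed for the transform's stochastic refinement.
#' @return an `embedding_matrix` of coordinates for the new points.
#' @export
transform_new_points <- function(fit, new_points, seed = 0) {
  state <- attr(fit, "reducer_state")
  if (is.null(state)) stopf("`fit` carries no reducer state; rerun run_nonlinear_2d(ret_model = TRUE)")
  pts <- as_points(new_points)
  if (is.null(dim(pts)) || nrow(pts) == 0) stopf("new_points is empty")
  if (ncol(pts) != attr(fit, "train_dim"))
    stopf("new points have %d columns but the reducer was trained on %d",
          ncol(pts), attr(fit, "train_dim"))
  coords <- with_seed(seed, uwot::umap_transform(pts, state, n_threads = 1))
  rownames(coords) <- rownames(pts) %||% paste0("new", seq_len(nrow(pts)))
  colnames(coords) <- c("dim1", "dim2")
  embedding_matrix(coords, provenance = utils::modifyList(
    fit$provenance, list(preprocessing = paste0(fit$provenance$preprocessing, "+transform"),
                         seed = seed)))
}
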