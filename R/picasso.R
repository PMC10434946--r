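# Picasso: a shape-constrained embedding. An encoder MLP maps each cell to
# 2D; training minimizes a symmetric Chamfer distance between the embedded
# cloud and an arbitrary target shape, plus (1 - Pearson correlation)
# between ambient and embedded pairwise distances on minibatches. The point
# is that the resulting arbitrary-shaped embedding preserves ambient
# distance structure about as well as t-SNE/UMAP - demonstrating that the
# shapes those methods produce are not evidence of data structure.

#' Configuration for a Picasso fit
#'
#' @param shape_weight,distance_weight nonnegative loss weights (their sum
#'   must be positive). `shape_weight = 0` gives a pure distance-preserving
#'   embedding; `distance_weight = 0` collapses the cloud onto the shape
#'   regardless of data geometry.
#' @param encoder_layout hidden-layer widths of the encoder MLP
#'   (default `c(128, 64)`).
#' @param epochs,batch_size,learning_rate training schedule (Adam).
#' @param seed integer seed (weight init and minibatch order).
#' @return object of class `picasso_config`.
#' @export
picasso_config <- function(shape_weight = 1, distance_weight = 1,
                           encoder_layout = c(128, 64), epochs = 150,
                           batch_size = 512, learning_rate = 3e-3, seed = 0) {
  if (shape_weight < 0 || distance_weight < 0) stopf("loss weights must be nonnegative")
  if (shape_weight + distance_weight <= 0) stopf("shape_weight + distance_weight must be > 0")
  epochs <- check_positive_int(epochs, "epochs")
  batch_size <- check_positive_int(batch_size, "batch_size")
  if (learning_rate <= 0) stopf("learning_rate must be positive")
  structure(list(shape_weight = shape_weight, distance_weight = distance_weight,
                 encoder_layout = as.integer(encoder_layout), epochs = epochs,
                 batch_size = batch_size, learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "picasso_config")
}

# --- shape normalization and Chamfer distance ------------------------------

# exact diameter of a 2D cloud via its convex hull
cloud_diameter <- function(p) {
  if (nrow(p) > 3) p <- p[grDevices::chull(p), , drop = FALSE]
  max(stats::dist(p))
}

normalize_cloud <- function(p) {
  p <- sweep(p, 2, colMeans(p))
  dia <- if (ncol(p) == 2) cloud_diameter(p) else max(stats::dist(p))
  if (dia <= 0) stopf("degenerate point cloud (zero diameter)")
  p / dia
}

# symmetric Chamfer distance: mean nearest-point distance in both directions,
# averaged. `a`, `b` are n x 2 matrices.
chamfer_distance <- function(a, b) {
  D <- cross_distances(a, b, "L2")
  (mean(apply(D, 1, min)) + mean(apply(D, 2, min))) / 2
}

#' Normalized shape-fit error of a 2D embedding
#'
#' Symmetric Chamfer distance between the embedded point cloud and the target
#' shape after both are centered and scaled to unit diameter, so translation
#' and uniform scaling do not count as error. 0 iff the point sets coincide
#' as sets.
#'
#' @param embedding a `picasso` fit, `embedding_matrix` or 2-column matrix.
#' @param shape a [shape2d()].
#' @return nonnegative Chamfer error (units of the shape diameter).
#' @export
shape_fit_error <- function(embedding, shape) {
  if (inherits(embedding, "picasso")) embedding <- embedding$embedding
  pts <- as_points(embedding)
  if (ncol(pts) != 2) stopf("shape_fit_error needs a 2D embedding (got d = %d)", ncol(pts))
  if (!inherits(shape, "shape2d")) stopf("`shape` must be a shape2d")
  chamfer_distance(normalize_cloud(pts), normalize_cloud(shape$points))
}

# --- encoder forward/backward ----------------------------------------------

# He-initialized ReLU MLP with a linear 2D head.
init_mlp <- function(d_in, layout, seed) {
  dims <- c(d_in, layout, 2L)
  with_seed(seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(dims) - 1)) {
      W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1], 0, sqrt(2 / dims[l])),
                       dims[l], dims[l + 1])
      b[[l]] <- numeric(dims[l + 1])
    }
    list(W = W, b = b)
  })
}

mlp_forward <- function(par, X) {
  L <- length(par$W)
  H <- vector("list", L + 1)
  H[[1]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(H[[l]] %*% par$W[[l]], 2, par$b[[l]], "+")
    H[[l + 1]] <- if (l < L) pmax(Z, 0) else Z     # ReLU hidden, linear head
  }
  H
}

mlp_backward <- function(par, H, dE) {
  L <- length(par$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- dE
  for (l in L:1) {
    gW[[l]] <- crossprod(H[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) delta <- (delta %*% t(par$W[[l]])) * (H[[l]] > 0)
  }
  list(W = gW, b = gb)
}

# gradient of the symmetric Chamfer loss wrt the embedded batch E (b x 2)
chamfer_grad <- function(E, S) {
  D <- cross_distances(E, S, "L2")
  b <- nrow(E); m <- nrow(S); eps <- 1e-8
  jA <- max.col(-D, ties.method = "first")         # nearest shape point per cell
  diffA <- E - S[jA, , drop = FALSE]
  dA <- pmax(D[cbind(seq_len(b), jA)], eps)
  G <- diffA / (dA * b) / 2
  iB <- max.col(-t(D), ties.method = "first")      # nearest cell per shape point
  diffB <- E[iB, , drop = FALSE] - S
  dB <- pmax(D[cbind(iB, seq_len(m))], eps)
  contrib <- diffB / (dB * m) / 2
  agg <- rowsum(contrib, group = iB)
  rows <- as.integer(rownames(agg))
  G[rows, ] <- G[rows, ] + agg
  loss <- (mean(dA) + mean(dB)) / 2
  list(loss = loss, grad = G)
}

# loss 1 - cor(a, d) over within-batch pairs and its gradient wrt E
distance_corr_grad <- function(E, a, pairs) {
  diff <- E[pairs[, 1], , drop = FALSE] - E[pairs[, 2], , drop = FALSE]
  d <- sqrt(rowSums(diff * diff))
  d <- pmax(d, 1e-8)
  ac <- a - mean(a); dc <- d - mean(d)
  Saa <- sum(ac * ac); Sdd <- sum(dc * dc); Sad <- sum(ac * dc)
  if (Saa < 1e-12 || Sdd < 1e-12) return(list(loss = 1, grad = matrix(0, nrow(E), 2)))
  r <- Sad / sqrt(Saa * Sdd)
  dr_dd <- (ac - (Sad / Sdd) * dc) / sqrt(Saa * Sdd)
  g_d <- -dr_dd                                    # d(1 - r)/dd
  u <- diff / d                                    # unit pair directions
  contrib <- u * g_d
  G <- matrix(0, nrow(E), 2)
  agg1 <- rowsum(contrib, group = pairs[, 1])
  G[as.integer(rownames(agg1)), ] <- G[as.integer(rownames(agg1)), ] + agg1
  agg2 <- rowsum(contrib, group = pairs[, 2])
  G[as.integer(rownames(agg2)), ] <- G[as.integer(rownames(agg2)), ] - agg2
  list(loss = 1 - r, grad = G)
}

#' Fit a Picasso shape-constrained embedding
#'
#' Trains an encoder MLP mapping each cell's input profile to 2D under a
#' two-term loss: `shape_weight` times the symmetric Chamfer distance between
#' the embedded cloud and the target shape (shape normalized to unit
#' diameter), plus `distance_weight` times `1 - cor(ambient, embedded)`
#' pairwise distances on each minibatch. Deterministic per seed; training
#' uses Adam with a fixed minibatch order derived from the seed.
#'
#' @param x input space for the cells: an `expression_matrix` (log-normalized
#'   ambient space; counts are log-normalized first) or an
#'   `embedding_matrix` (e.g. PCA-50 scores). At least 100 cells.
#' @param shape target [shape2d()].
#' @param config a [picasso_config()].
#' @return object of class `picasso`: list with `embedding` (an
#'   `embedding_matrix`), `shape`, `config`, `loss` (per-epoch means of the
#'   total, shape and distance terms) and the trained encoder parameters.
#' @export
fit_picasso <- function(x, shape, config = picasso_config()) {
  if (!inherits(shape, "shape2d")) stopf("`shape` must be a shape2d")
  if (!inherits(config, "picasso_config")) stopf("`config` must be a picasso_config")
  if (inherits(x, "expression_matrix") && x$layer == "counts") x <- lognormalize(x)
  X <- as_points(x)
  n <- nrow(X)
  if (n < 100) stopf("fit_picasso needs at least 100 cells (got %d)", n)
  # ambient pairwise distances for the correlation term use X as given;
  # the network input is z-scored per column for optimization conditioning
  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  x_scale[x_scale < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  S <- normalize_cloud(shape$points)
  par <- init_mlp(ncol(Xs), config$encoder_layout, config$seed)
  # Adam state
  mW <- lapply(par$W, function(w) w * 0); vW <- mW
  mb <- lapply(par$b, function(b) b * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8; step <- 0
  ws <- config$shape_weight; wd <- config$distance_weight
  bs <- min(config$batch_size, n)
  # precompute ambient pairwise distances once at desk scale; batches index
  # into it instead of recomputing a Gram product per step
  D_amb <- if (wd > 0 && n <= 6000) pairwise_distances(X, "L2") else NULL
  loss_hist <- matrix(NA_real_, config$epochs, 3,
                      dimnames = list(NULL, c("total", "shape", "distance")))
  order_rng <- with_seed(config$seed + 1,
                         lapply(seq_len(config$epochs), function(e) sample.int(n)))
  for (epoch in seq_len(config$epochs)) {
    # cosine learning-rate decay: settles the minibatch-noise floor of the
    # Chamfer term without touching the loss definition
    lr_epoch <- config$learning_rate *
      0.5 * (1 + cos(pi * (epoch - 1) / config$epochs))
    ord <- order_rng[[epoch]]
    starts <- seq(1, n, by = bs)
    ep_loss <- c(0, 0, 0); nb <- 0
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + bs - 1, n)]
      if (length(idx) < 3) next
      Xb <- Xs[idx, , drop = FALSE]
      H <- mlp_forward(par, Xb)
      E <- H[[length(H)]]
      if (!all(is.finite(E)))
        stopf("Picasso training diverged at epoch %d (non-finite embedding); try a smaller learning_rate", epoch)
      dE <- matrix(0, nrow(E), 2)
      l_shape <- 0; l_dist <- 0
      if (ws > 0) {
        ch <- chamfer_grad(E, S)
        l_shape <- ch$loss
        dE <- dE + ws * ch$grad
      }
      if (wd > 0) {
        pairs <- pair_index(length(idx))
        a <- if (is.null(D_amb)) {
          pairwise_distances(X[idx, , drop = FALSE], "L2")[pairs]
        } else {
          D_amb[idx, idx][pairs]
        }
        dc <- distance_corr_grad(E, a, pairs)
        l_dist <- dc$loss
        dE <- dE + wd * dc$grad
      }
      g <- mlp_backward(par, H, dE)
      step <- step + 1
      lr_t <- lr_epoch * sqrt(1 - beta2^step) / (1 - beta1^step)
      for (l in seq_along(par$W)) {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * g$W[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * g$W[[l]]^2
        par$W[[l]] <- par$W[[l]] - lr_t * mW[[l]] / (sqrt(vW[[l]]) + adam_eps)
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * g$b[[l]]
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * g$b[[l]]^2
        par$b[[l]] <- par$b[[l]] - lr_t * mb[[l]] / (sqrt(vb[[l]]) + adam_eps)
      }
      ep_loss <- ep_loss + c(ws * l_shape + wd * l_dist, l_shape, l_dist)
      nb <- nb + 1
    }
    loss_hist[epoch, ] <- ep_loss / nb
  }
  coords <- mlp_forward(par, Xs)[[length(par$W) + 1]]
  rownames(coords) <- point_ids(x) %||% paste0("cell", seq_len(n))
  colnames(coords) <- c("dim1", "dim2")
  emb <- embedding_matrix(coords, provenance = list(
    method = "picasso", preprocessing = if (inherits(x, "embedding_matrix"))
      sprintf("%s-%dD", x$provenance$method, x$d) else "ambient",
    metric = "L2", seed = config$seed))
  structure(list(embedding = emb, shape = shape, config = config,
                 loss = loss_hist, parameters = par,
                 input_dim = ncol(X), input_center = x_center,
                 input_scale = x_scale),
            class = "picasso")
}

#' @export
print.picasso <- function(x, ...) {
  cat(sprintf("<picasso> %d cells fit to shape \"%s\" (%d epochs)\n",
              nrow(x$embedding$coords), x$shape$name, x$config$epochs))
  cat(sprintf("  final loss %.4f (shape %.4f, distance %.4f); Chamfer fit error %.4f\n",
              x$loss[nrow(x$loss), 1], x$loss[nrow(x$loss), 2],
              x$loss[nrow(x$loss), 3], shape_fit_error(x, x$shape)))
  invisible(x)
}

#' @export
summary.picasso <- function(object, ...) {
  cat("Picasso shape-constrained embedding\n")
  print(object)
  cat(sprintf("  loss trajectory: %.4f -> %.4f over %d epochs\n",
              object$loss[1, 1], object$loss[nrow(object$loss), 1],
              nrow(object$loss)))
  invisible(object)
}

#' Embed new cells through a trained Picasso encoder
#'
#' @param object a `picasso` fit.
#' @param newdata matrix (or container) of new cells in the training input
#'   space.
#' @param ... unused.
#' @return an `embedding_matrix` of 2D coordinates.
#' @export
predict.picasso <- function(object, newdata, ...) {
  Xn <- as_points(newdata)
  if (ncol(Xn) != object$input_dim)
    stopf("newdata has %d columns but the encoder was trained on %d",
          ncol(Xn), object$input_dim)
  Xn <- sweep(sweep(Xn, 2, object$input_center), 2, object$input_scale, "/")
  coords <- mlp_forward(object$parameters, Xn)[[length(object$parameters$W) + 1]]
  rownames(coords) <- rownames(Xn) %||% paste0("new", seq_len(nrow(Xn)))
  colnames(coords) <- c("dim1", "dim2")
  embedding_matrix(coords, provenance = utils::modifyList(
    object$embedding$provenance, list(preprocessing = "picasso+transform")))
}

#' @export
plot.picasso <- function(x, ...) {
  emb <- normalize_cloud(x$embedding$coords)
  shp <- normalize_cloud(x$shape$points)
  plot(emb, pch = 16, cex = 0.3, col = "grey40", asp = 1,
       xlab = "dim1", ylab = "dim2",
       main = sprintf("Picasso fit to \"%s\"", x$shape$name), ...)
  graphics::points(shp, pch = 16, cex = 0.4, col = "tomato")
  invisible(x)
}
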