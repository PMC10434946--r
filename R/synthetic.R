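# Synthetic data with known ground truth: negative-binomial scRNA-seq-like
# count mixtures, batch shifts, and the geometric benchmarks (Swiss roll,
# uniform hypercube, regular simplices, parametric 2D shapes).

#' Specification of a synthetic cell-type mixture
#'
#' Describes a discrete mixture of cell types whose counts are drawn from a
#' negative binomial around type-specific per-gene log-means, with per-cell
#' library sizes drawn log-normally. Defaults give the package's reference
#' synthetic dataset: 5,000 cells x 2,000 genes, 20 equiproportional types,
#' shared dispersion 2, median library size 5,000.
#'
#' @param n_cells,n_genes,n_types positive integers.
#' @param type_proportions probability vector of length `n_types` (sums to 1);
#'   default equal proportions.
#' @param mean_log_expression optional `n_types x n_genes` matrix of per-type
#'   per-gene log-means. If `NULL` it is built by [build_type_means()] with
#'   `marker_fraction`/`marker_shift`.
#' @param dispersion negative-binomial shape (size) parameter, shared across
#'   genes; must be positive.
#' @param library_size_log_mean,library_size_log_sd log-normal parameters of
#'   the per-cell library-size factor.
#' @param marker_fraction,marker_shift fraction of genes upshifted per type
#'   and the log-scale shift applied to them (used only when
#'   `mean_log_expression` is `NULL`).
#' @param seed integer seed making the generator deterministic.
#' @return object of class `mixture_spec`.
#' @export
mixture_spec <- function(n_cells = 5000, n_genes = 2000, n_types = 20,
                         type_proportions = NULL, mean_log_expression = NULL,
                         dispersion = 2,
                         library_size_log_mean = log(5000),
                         library_size_log_sd = 0.3,
                         marker_fraction = 0.1, marker_shift = 1.0,
                         seed = 0) {
  n_cells <- check_positive_int(n_cells, "n_cells")
  n_genes <- check_positive_int(n_genes, "n_genes")
  n_types <- check_positive_int(n_types, "n_types")
  if (is.null(type_proportions)) type_proportions <- rep(1 / n_types, n_types)
  if (length(type_proportions) != n_types)
    stopf("type_proportions must have length n_types = %d", n_types)
  if (any(type_proportions < 0) || abs(sum(type_proportions) - 1) > 1e-9)
    stopf("type_proportions must be nonnegative and sum to 1 (within 1e-9)")
  if (!is.finite(dispersion) || dispersion <= 0) stopf("dispersion must be > 0")
  if (!is.null(mean_log_expression)) {
    mean_log_expression <- as.matrix(mean_log_expression)
    if (!all(dim(mean_log_expression) == c(n_types, n_genes)))
      stopf("mean_log_expression must be %d x %d", n_types, n_genes)
  }
  if (marker_fraction < 0 || marker_fraction > 1) stopf("marker_fraction must be in [0,1]")
  structure(list(n_cells = n_cells, n_genes = n_genes, n_types = n_types,
                 type_proportions = type_proportions,
                 mean_log_expression = mean_log_expression,
                 dispersion = dispersion,
                 library_size_log_mean = library_size_log_mean,
                 library_size_log_sd = library_size_log_sd,
                 marker_fraction = marker_fraction, marker_shift = marker_shift,
                 seed = as.integer(seed)),
            class = "mixture_spec")
}

#' Build per-type per-gene log-means
#'
#' Draws a global per-gene baseline log-mean from a Gaussian, adds small
#' type-specific Gaussian wiggle, and upshifts a random `marker_fraction` of
#' genes per type by `marker_shift` log units. This gives the discrete
#' cell-type geometry the distortion metrics assume without prescribing any
#' real dataset.
#'
#' @param n_genes,n_types dimensions.
#' @param baseline_mean,baseline_sd Gaussian for the gene baseline.
#' @param type_sd sd of the per-type wiggle around the baseline.
#' @param marker_fraction,marker_shift marker genes per type and their shift.
#' @param seed integer seed.
#' @return `n_types x n_genes` matrix of log-means.
#' @export
build_type_means <- function(n_genes, n_types, baseline_mean = 0,
                             baseline_sd = 1, type_sd = 0.1,
                             marker_fraction = 0.1, marker_shift = 1.0,
                             seed = 0) {
  n_genes <- check_positive_int(n_genes, "n_genes")
  n_types <- check_positive_int(n_types, "n_types")
  with_seed(seed, {
    base <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
    m <- matrix(rep(base, each = n_types), nrow = n_types) +
      matrix(stats::rnorm(n_types * n_genes, 0, type_sd), nrow = n_types)
    n_mark <- round(marker_fraction * n_genes)
    if (n_mark > 0) {
      for (t in seq_len(n_types)) {
        idx <- sample.int(n_genes, n_mark)
        m[t, idx] <- m[t, idx] + marker_shift
      }
    }
    m
  })
}

#' Generate negative-binomial mixture counts
#'
#' Draws an integer count matrix from the mixture described by a
#' [mixture_spec()]: each cell is assigned one type (multinomially from
#' `type_proportions`), a log-normal library-size factor, and per-gene counts
#' from a negative binomial whose mean is the cell's library size times the
#' type's normalized expression profile `exp(mean_log_expression)`. Identical
#' spec (including seed) gives bitwise-identical output.
#'
#' @param spec a [mixture_spec()].
#' @return list with `counts` (an `expression_matrix`, layer `"counts"`) and
#'   `annotations` (data.frame with columns `cell_id`, `type`, `condition`,
#'   `batch`; condition and batch are two balanced random levels, available
#'   for batch/mixing experiments).
#' @export
generate_mixture_counts <- function(spec) {
  if (!inherits(spec, "mixture_spec")) stopf("`spec` must be a mixture_spec")
  with_seed(spec$seed, {
    mlog <- spec$mean_log_expression
    if (is.null(mlog))
      mlog <- build_type_means(spec$n_genes, spec$n_types,
                               marker_fraction = spec$marker_fraction,
                               marker_shift = spec$marker_shift,
                               seed = stats::runif(1, 0, 2^30))
    types <- sample.int(spec$n_types, spec$n_cells, replace = TRUE,
                        prob = spec$type_proportions)
    lib <- exp(stats::rnorm(spec$n_cells, spec$library_size_log_mean,
                            spec$library_size_log_sd))
    prof <- exp(mlog)
    prof <- prof / rowSums(prof)           # per-type expression proportions
    mu <- prof[types, , drop = FALSE] * lib
    counts <- matrix(stats::rnbinom(length(mu), size = spec$dispersion, mu = mu),
                     nrow = spec$n_cells)
    batch <- sample(c("batch1", "batch2"), spec$n_cells, replace = TRUE)
    ann <- data.frame(cell_id = paste0("cell", seq_len(spec$n_cells)),
                      type = paste0("type", types),
                      condition = batch, batch = batch,
                      stringsAsFactors = FALSE)
    list(counts = expression_matrix(counts, cell_ids = ann$cell_id,
                                    layer = "counts"),
         annotations = ann)
  })
}

#' Add a batch effect to a count matrix
#'
#' Applies per-gene additive shifts in log space to the cells of one batch
#' (the last batch level): `log1p`-transform, add `N(0, shift_sd)` shifts to
#' an `affected_fraction` of genes, re-exponentiate and round back to
#' integer counts. `shift_sd = 0` or `affected_fraction = 0` return the
#' input unchanged.
#'
#' @param matrix `expression_matrix` with layer `"counts"`.
#' @param annotations data.frame with `cell_id` and `batch` columns covering
#'   all cells; the batch column must have at least two levels.
#' @param shift_sd nonnegative sd of the per-gene log-space shift.
#' @param affected_fraction fraction of genes receiving a shift.
#' @param seed integer seed.
#' @return an `expression_matrix` (counts layer) with the shifted batch.
#' @export
add_batch_effect <- function(matrix, annotations, shift_sd, affected_fraction = 1,
                             seed = 0) {
  if (!inherits(matrix, "expression_matrix") || matrix$layer != "counts")
    stopf("`matrix` must be an expression_matrix with layer \"counts\"")
  if (shift_sd < 0) stopf("shift_sd must be nonnegative")
  if (affected_fraction < 0 || affected_fraction > 1)
    stopf("affected_fraction must be in [0,1]")
  if (!all(c("cell_id", "batch") %in% names(annotations)))
    stopf("annotations must have cell_id and batch columns")
  batch <- annotations$batch[match(matrix$cell_ids, annotations$cell_id)]
  if (anyNA(batch)) stopf("annotations do not cover all cells")
  lev <- sort(unique(batch))
  if (length(lev) < 2) stopf("batch annotation must have at least 2 levels")
  if (shift_sd == 0 || affected_fraction == 0) return(matrix)
  with_seed(seed, {
    p <- ncol(matrix$values)
    n_aff <- round(affected_fraction * p)
    genes <- sample.int(p, n_aff)
    shifts <- stats::rnorm(n_aff, 0, shift_sd)
    v <- matrix$values
    if (inherits(v, "Matrix")) v <- as.matrix(v)
    rows <- which(batch == lev[length(lev)])
    block <- log1p(v[rows, genes, drop = FALSE])
    block <- sweep(block, 2, shifts, "+")
    v[rows, genes] <- pmax(round(expm1(block)), 0)
    expression_matrix(v, cell_ids = matrix$cell_ids, gene_ids = matrix$gene_ids,
                      layer = "counts")
  })
}

#' Generate a 3D Swiss roll with intrinsic coordinates
#'
#' Points `(t cos t, h, t sin t)` plus isotropic Gaussian noise, with the
#' roll parameter `t` spanning `turns` full revolutions starting at
#' `t = pi/2`, and height `h` uniform on `[0, 21]`. The intrinsic 2D
#' coordinates returned as ground truth are the arc length
#' `s(t) = (t sqrt(1+t^2) + asinh(t)) / 2` and `h`; `s` is strictly
#' increasing in `t`, so it parametrizes the unrolled plane.
#'
#' @param n_points at least 10.
#' @param turns number of revolutions (positive real).
#' @param noise_sd nonnegative sd of the 3D Gaussian noise.
#' @param seed integer seed.
#' @return list with `points` (`n x 3`), `intrinsic` (`n x 2`, columns
#'   `arc_length`, `height`), and `t` (the roll parameter).
#' @export
generate_swiss_roll <- function(n_points, turns = 1.5, noise_sd = 0, seed = 0) {
  n_points <- check_positive_int(n_points, "n_points")
  if (n_points < 10) stopf("n_points must be >= 10")
  if (!is.finite(turns) || turns <= 0) stopf("turns must be positive")
  if (noise_sd < 0) stopf("noise_sd must be nonnegative")
  with_seed(seed, {
    t0 <- pi / 2
    t <- sort(t0 + 2 * pi * turns * stats::runif(n_points))
    h <- 21 * stats::runif(n_points)
    pts <- cbind(t * cos(t), h, t * sin(t))
    if (noise_sd > 0)
      pts <- pts + matrix(stats::rnorm(3 * n_points, 0, noise_sd), ncol = 3)
    arc <- (t * sqrt(1 + t^2) + asinh(t)) / 2
    colnames(pts) <- c("x", "y", "z")
    intrinsic <- cbind(arc_length = arc, height = h)
    list(points = pts, intrinsic = intrinsic, t = t)
  })
}

#' Uniform points in the unit hypercube
#'
#' @param n,d number of points and dimension.
#' @param seed integer seed.
#' @return `n x d` matrix of i.i.d. Uniform(0,1) coordinates.
#' @export
generate_uniform_points <- function(n, d, seed = 0) {
  n <- check_positive_int(n, "n"); d <- check_positive_int(d, "d")
  with_seed(seed, matrix(stats::runif(n * d), nrow = n, ncol = d))
}

#' Vertices of a regular simplex (an equidistant point group)
#'
#' `m` points in `d >= m - 1` dimensions whose pairwise distances all equal
#' `scale`, optionally jittered with isotropic Gaussian noise. Construction:
#' the standard-basis simplex `e_1..e_m` in m-space projected onto its
#' (m-1)-dimensional affine hull, rescaled, and padded with zeros.
#'
#' @param m number of vertices (>= 2).
#' @param d embedding dimension (>= m - 1).
#' @param scale common pairwise distance (positive).
#' @param jitter_sd nonnegative Gaussian jitter sd.
#' @param seed integer seed (used only when `jitter_sd > 0`).
#' @return `m x d` matrix.
#' @export
generate_equidistant_simplex <- function(m, d = m - 1, scale = 1, jitter_sd = 0,
                                         seed = 0) {
  m <- check_positive_int(m, "m")
  d <- check_positive_int(d, "d")
  if (m < 2) stopf("m must be >= 2")
  if (d < m - 1) stopf("d must be >= m - 1 to hold a regular %d-simplex", m - 1)
  if (!is.finite(scale) || scale <= 0) stopf("scale must be positive")
  if (jitter_sd < 0) stopf("jitter_sd must be nonnegative")
  v <- diag(m)                       # e_i: pairwise distance sqrt(2)
  v <- sweep(v, 2, colMeans(v))      # center; now rank m-1
  # orthonormal basis of the affine hull
  basis <- svd(t(v))$u[, seq_len(m - 1), drop = FALSE]
  pts <- v %*% basis * (scale / sqrt(2))
  if (d > m - 1) pts <- cbind(pts, matrix(0, m, d - m + 1))
  if (jitter_sd > 0)
    pts <- pts + with_seed(seed, matrix(stats::rnorm(m * d, 0, jitter_sd), m, d))
  unname(pts)
}

#' Construct a 2D shape
#'
#' @param name shape name.
#' @param points `n x 2` matrix (or data.frame) of coordinates, ordered along
#'   the outline.
#' @param closed whether the outline is a closed curve.
#' @return object of class `shape2d`.
#' @export
shape2d <- function(name, points, closed = TRUE) {
  points <- as.matrix(points)
  if (ncol(points) != 2) stopf("shape points must be 2D")
  if (nrow(points) < 3) stopf("a shape needs at least 3 points")
  if (!all(is.finite(points))) stopf("shape coordinates must be finite")
  if (max(stats::dist(points[seq_len(min(nrow(points), 512)), ])) <= 0)
    stopf("shape has zero diameter")
  colnames(points) <- c("x", "y")
  structure(list(name = as.character(name), points = points,
                 closed = isTRUE(closed)),
            class = "shape2d")
}

#' @export
print.shape2d <- function(x, ...) {
  cat(sprintf("<shape2d> \"%s\", %d points, %s\n", x$name, nrow(x$points),
              if (x$closed) "closed" else "open"))
  invisible(x)
}

# Fourier sum sum_k Re(c_k) cos(kt) + Im(c_k) sin(kt), k = 0..length(c)-1.
fourier_curve <- function(t, coef) {
  out <- numeric(length(t))
  for (k in seq_along(coef) - 1)
    out <- out + Re(coef[k + 1]) * cos(k * t) + Im(coef[k + 1]) * sin(k * t)
  out
}

#' The four-parameter elephant curve
#'
#' Closed 2D outline of an elephant drawn from the published
#' four-complex-parameter Fourier parametrization
#' (p1 = 50 - 30i, p2 = 18 + 8i, p3 = 12 - 10i, p4 = -14 - 60i), sampled
#' uniformly in the curve parameter. The fifth ("wiggling trunk") parameter
#' is omitted.
#'
#' @param n_points number of samples along the curve (>= 16).
#' @return a closed [shape2d()].
#' @export
elephant_shape <- function(n_points = 400) {
  n_points <- check_positive_int(n_points, "n_points")
  if (n_points < 16) stopf("n_points must be >= 16")
  p1 <- complex(real = 50, imaginary = -30)
  p2 <- complex(real = 18, imaginary = 8)
  p3 <- complex(real = 12, imaginary = -10)
  p4 <- complex(real = -14, imaginary = -60)
  cx <- c(0, Re(p1) * 1i, Re(p2) * 1i, complex(real = Re(p3)), 0,
          complex(real = Re(p4)))
  cy <- c(0, complex(real = Im(p4), imaginary = Im(p1)), Im(p2) * 1i,
          Im(p3) * 1i, 0, 0)
  t <- seq(0, 2 * pi, length.out = n_points + 1)[seq_len(n_points)]
  # orientation: trunk to the left, feet down
  shape2d("elephant", cbind(fourier_curve(t, cy), -fourier_curve(t, cx)),
          closed = TRUE)
}

#' Bundled shape library
#'
#' Parametric 2D target shapes for shape-constrained embedding: `"elephant"`
#' (see [elephant_shape()]), `"circle"`, `"flower"` (five-petal rose curve
#' `r = 1 + 0.9 cos(5t)`), and `"grid"` (a square lattice; the only open
#' shape).
#'
#' @param name one of `"elephant"`, `"circle"`, `"flower"`, `"grid"`.
#' @param n_points approximate number of points.
#' @return a [shape2d()].
#' @export
shape_library <- function(name = c("elephant", "circle", "flower", "grid"),
                          n_points = 400) {
  name <- match.arg(name)
  n_points <- check_positive_int(n_points, "n_points")
  t <- seq(0, 2 * pi, length.out = n_points + 1)[seq_len(n_points)]
  switch(name,
    elephant = elephant_shape(n_points),
    circle = shape2d("circle", cbind(cos(t), sin(t)), closed = TRUE),
    flower = {
      r <- 1 + 0.9 * cos(5 * t)
      shape2d("flower", cbind(r * cos(t), r * sin(t)), closed = TRUE)
    },
    grid = {
      side <- max(2, round(sqrt(n_points)))
      g <- as.matrix(expand.grid(x = seq(0, 1, length.out = side),
                                 y = seq(0, 1, length.out = side)))
      shape2d("grid", g, closed = FALSE)
    })
}
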