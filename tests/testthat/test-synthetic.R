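# Generators: determinism, label conservation, closed-form moments, and the
# exact geometric identities of the benchmark shapes.

test_that("mixture generator is deterministic and conserves labels", {
  spec <- mixture_spec(n_cells = 200, n_genes = 80, n_types = 3, seed = 42)
  g1 <- generate_mixture_counts(spec)
  g2 <- generate_mixture_counts(spec)
  expect_identical(as.matrix(g1$counts$values), as.matrix(g2$counts$values))
  expect_identical(g1$annotations, g2$annotations)
  expect_equal(nrow(g1$annotations), 200)
  expect_setequal(unique(g1$annotations$type), paste0("type", 1:3))
  # single-component mixture: every cell carries the same label
  g3 <- generate_mixture_counts(mixture_spec(n_cells = 50, n_genes = 20,
                                             n_types = 1, seed = 1))
  expect_equal(unique(g3$annotations$type), "type1")
  # counts are nonnegative integers
  v <- as.matrix(g1$counts$values)
  expect_true(all(v >= 0) && all(v == round(v)))
})

test_that("mixture spec validates its invariants", {
  expect_error(mixture_spec(n_cells = 0), "positive integer")
  expect_error(mixture_spec(dispersion = -1), "dispersion")
  expect_error(mixture_spec(n_types = 2, type_proportions = c(0.7, 0.6)), "sum to 1")
})

test_that("observed mean library size matches the log-normal closed form", {
  sd_ <- 0.3
  g <- generate_mixture_counts(mixture_spec(n_cells = 2000, n_genes = 300,
                                            n_types = 4, dispersion = 2,
                                            library_size_log_mean = log(5000),
                                            library_size_log_sd = sd_, seed = 7))
  obs <- mean(Matrix::rowSums(g$counts$values))
  expected <- 5000 * exp(sd_^2 / 2)     # E[exp(N(mu, sd))] = exp(mu + sd^2/2)
  expect_lt(abs(obs - expected) / expected, 0.10)
})

test_that("batch effect: identity cases and mixing increase at large shift", {
  g <- small_mixture(n_cells = 400, n_genes = 120, seed = 3)
  expect_identical(add_batch_effect(g$counts, g$annotations, shift_sd = 0),
                   g$counts)
  expect_identical(add_batch_effect(g$counts, g$annotations, shift_sd = 2,
                                    affected_fraction = 0),
                   g$counts)
  one_batch <- g$annotations
  one_batch$batch <- "only"
  expect_error(add_batch_effect(g$counts, one_batch, 1), "2 levels")
  # strong shift raises the same-batch neighbor fraction above the no-shift value
  same_batch_mix <- function(counts) {
    ln <- lognormalize(counts)
    mean(mixing_fractions(knn_index(ln, 30),
                          g$annotations[, c("cell_id", "batch")]))
  }
  m0 <- same_batch_mix(g$counts)
  m3 <- same_batch_mix(add_batch_effect(g$counts, g$annotations, shift_sd = 3,
                                        affected_fraction = 1, seed = 1))
  expect_gt(m3, m0)
})

test_that("swiss roll satisfies its parametric identities", {
  roll <- generate_swiss_roll(200, turns = 2, noise_sd = 0, seed = 4)
  t <- roll$t
  # noiseless points lie exactly on (t cos t, h, t sin t)
  expect_equal(roll$points[, "x"], t * cos(t), tolerance = 1e-12)
  expect_equal(roll$points[, "z"], t * sin(t), tolerance = 1e-12)
  expect_equal(roll$points[, "y"], roll$intrinsic[, "height"], tolerance = 1e-12)
  # arc length strictly increasing in t
  expect_true(all(diff(roll$intrinsic[, "arc_length"]) > 0))
  # chord <= arc between consecutive points (holding height aside)
  chord <- sqrt(diff(t * cos(t))^2 + diff(t * sin(t))^2)
  arc <- diff(roll$intrinsic[, "arc_length"])
  expect_true(all(chord <= arc + 1e-9))
  # t spans `turns` revolutions
  expect_lt(diff(range(t)), 2 * pi * 2)
  expect_gt(diff(range(t)), 2 * pi * 2 * 0.9)
  expect_error(generate_swiss_roll(5), ">= 10")
})

test_that("uniform points: support, determinism, CLT bound on the mean", {
  u1 <- generate_uniform_points(500, 3, seed = 9)
  u2 <- generate_uniform_points(500, 3, seed = 9)
  expect_identical(u1, u2)
  expect_true(all(u1 >= 0 & u1 <= 1))
  n <- 20000
  x <- generate_uniform_points(n, 1, seed = 10)
  expect_lt(abs(mean(x) - 0.5), 3 / sqrt(12 * n))
})

test_that("regular simplex is exactly equidistant at zero jitter", {
  for (m in c(2, 4, 7)) {
    s <- generate_equidistant_simplex(m, d = max(m - 1, 1), scale = 2.5)
    d <- dist(s)
    expect_equal(max(d), 2.5, tolerance = 1e-9)
    expect_equal(min(d), 2.5, tolerance = 1e-9)
    if (m > 2) expect_equal(max_min_ratio(s, seq_len(m)), 1, tolerance = 1e-9)
  }
  expect_error(generate_equidistant_simplex(5, d = 2), ">= m - 1")
  # padding into higher d keeps equidistance
  s <- generate_equidistant_simplex(4, d = 10, scale = 1)
  expect_equal(as.numeric(dist(s)), rep(1, 6), tolerance = 1e-9)
})

test_that("elephant curve: sampling contract, closure, stable bounding box", {
  e <- elephant_shape(128)
  expect_s3_class(e, "shape2d")
  expect_equal(nrow(e$points), 128)
  expect_true(e$closed)
  # closed curve: endpoints one parameter step apart
  gap <- sqrt(sum((e$points[1, ] - e$points[128, ])^2))
  typical <- stats::median(sqrt(rowSums(diff(e$points)^2)))
  expect_lt(gap, 10 * typical)
  # bounding box invariant under refinement
  e2 <- elephant_shape(256)
  dense <- elephant_shape(4096)
  bb <- function(s) c(apply(s$points, 2, range))
  expect_equal(bb(e2), bb(dense), tolerance = 2e-2)
  expect_equal(bb(elephant_shape(2048)), bb(dense), tolerance = 1e-3)
  expect_error(elephant_shape(8), ">= 16")
})

test_that("shape library shapes are valid", {
  for (nm in c("elephant", "circle", "flower", "grid")) {
    s <- shape_library(nm, 100)
    expect_s3_class(s, "shape2d")
    expect_true(all(is.finite(s$points)))
  }
  expect_false(shape_library("grid")$closed)
})
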