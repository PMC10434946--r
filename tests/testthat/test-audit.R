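# End-to-end audit orchestration, the canned experiments, report
# serialization/reproducibility, and the CLI verbs.

make_small_audit_cfg <- function(out_dir = NULL) {
  audit_config(list(
    input = list(type = "synthetic", n_cells = 400, n_genes = 150, n_types = 5),
    chains = c("ambient", "pca-20", "pca-20-umap"),
    metrics = c("jaccard", "mixing"),
    n_replicates = 2, seed = 3, k_jaccard = 10, k_mixing = 10,
    out_dir = out_dir))
}

test_that("run_audit produces the expected tables and property tags", {
  rep_ <- run_audit(make_small_audit_cfg())
  expect_s3_class(rep_, "distortion_report")
  expect_setequal(names(rep_$tables), c("jaccard", "mixing"))
  # jaccard rows: 2 comparison pairs for the 2D chain (vs ambient, vs pca-20)
  # plus pca-20 vs ambient, x replicates
  j <- rep_$tables$jaccard
  expect_setequal(unique(j$space), c("pca-20", "pca-20-umap"))
  expect_equal(sum(j$space == "pca-20-umap" & j$reference == "ambient"), 2)
  expect_equal(sum(j$space == "pca-20-umap" & j$reference == "pca-20"), 2)
  expect_true(all(j$property == "local"))
  m <- rep_$tables$mixing
  expect_setequal(unique(m$space), c("ambient", "pca-20", "pca-20-umap"))
  expect_true(all(m$mean >= 0 & m$mean <= 1))
  # summary has one row per space/metric/statistic
  expect_true(all(c("space", "metric", "statistic", "value", "property")
                  %in% names(rep_$summary)))
})

test_that("audit reports are reproducible: identical config, identical hashes", {
  td1 <- withr::local_tempdir(); td2 <- withr::local_tempdir()
  run_audit(make_small_audit_cfg(td1))
  run_audit(make_small_audit_cfg(td2))
  m1 <- jsonlite::read_json(file.path(td1, "manifest.json"), simplifyVector = TRUE)
  m2 <- jsonlite::read_json(file.path(td2, "manifest.json"), simplifyVector = TRUE)
  expect_identical(unname(unlist(m1$tables)), unname(unlist(m2$tables)))
  expect_true(file.exists(file.path(td1, "jaccard.csv")))
  expect_true(file.exists(file.path(td1, "summary.csv")))
})

test_that("audit config validation rejects bad chains and metrics", {
  expect_error(audit_config(list(chains = character(0))), "at least one chain")
  expect_error(audit_config(list(chains = "pca50")), "unknown chain")
  expect_error(audit_config(list(metrics = "foo")), "unknown metric")
  expect_error(audit_config(list(input = list(type = "nope"))), "synthetic")
})

test_that("mixing_experiment: baseline at zero shift, concentration at large", {
  base_cfg <- list(n_cells = 500, n_genes = 120, n_types = 4,
                   chains = "pca-20-umap", k = 10, seed = 2)
  # shift_sd = 0: ambient mixing sits near the label-proportion baseline
  # (balanced two-batch labels -> same-batch fraction around 0.5)
  r0 <- mixing_experiment(utils::modifyList(base_cfg, list(shift_sd = 0)))
  expect_lt(abs(mean(r0$distributions$ambient) - 0.5), 0.1)
  # large shift: ambient distribution concentrates at 1
  r3 <- mixing_experiment(utils::modifyList(base_cfg, list(shift_sd = 4,
                                                           affected_fraction = 1)))
  expect_gt(mean(r3$distributions$ambient), mean(r0$distributions$ambient))
  # the embedded-vs-ambient K-S statistic is reported for every chain
  expect_equal(nrow(r0$table), 1)
  expect_true(all(c("chain", "replicate", "ks") %in% names(r0$table)))
  expect_true(r0$table$ks >= 0 && r0$table$ks <= 1)
})

test_that("swissroll_experiment: self-comparison near zero, full bookkeeping", {
  # ground-truth self-comparison: intrinsic coordinates vs themselves
  roll <- generate_swiss_roll(300, turns = 2, seed = 1)
  idx <- knn_index(roll$intrinsic, 15)
  expect_lte(mean(jaccard_neighbor_distance(idx, idx)), 0.05)
  df <- swissroll_experiment(list(turns = c(1, 2), n_neighbors = c(10, 30),
                                  n_points = 300, seeds = 0:1, k = 15))
  expect_equal(nrow(df), 2 * 2 * 2)   # one row per (turns, neighbors, seed)
  expect_true(all(df$mean_jaccard >= 0 & df$mean_jaccard <= 1))
  # coherence loss does not improve with a tighter roll (per seed/neighbors)
  agg <- stats::aggregate(median_jaccard ~ turns, df, stats::median)
  expect_gte(agg$median_jaccard[2], agg$median_jaccard[1] - 0.05)
})

test_that("CLI verbs: simulate writes MTX + labels; metrics consumes embeddings", {
  td <- withr::local_tempdir()
  suppressMessages(audit_cli(c("simulate", "--cells", "60", "--genes", "30",
                               "--types", "3", "--seed", "1", "--out", td)))
  expect_true(file.exists(file.path(td, "counts.mtx")))
  expect_true(file.exists(file.path(td, "labels.tsv")))
  back <- read_counts_mtx(file.path(td, "counts"))
  expect_equal(dim(back$values), c(60, 30))
  # embed a stored dataset through a tiny chain, then score it
  ed <- file.path(td, "emb")
  suppressMessages(audit_cli(c("embed", "--counts", file.path(td, "counts"),
                               "--chains", "ambient,pca-5", "--seed", "1",
                               "--out", ed)))
  expect_true(file.exists(file.path(ed, "pca-5.rep1.csv")))
  md <- file.path(td, "met")
  suppressMessages(audit_cli(c("metrics",
                               "--embedding", file.path(ed, "pca-5.rep1.csv"),
                               "--reference", file.path(ed, "ambient.rep1.csv"),
                               "--k", "5", "--out", md)))
  out <- utils::read.csv(file.path(md, "metrics.csv"))
  expect_equal(out$metric[1], "jaccard")
  expect_true(out$mean[1] >= 0 && out$mean[1] <= 1)
  expect_error(suppressMessages(audit_cli("frobnicate")), "unknown verb")
  expect_error(suppressMessages(audit_cli(character(0))), "usage")
})
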