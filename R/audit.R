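# The audit pipeline: orchestrates generators, the embedding harness and
# the distortion metrics into a reproducible end-to-end report, plus the
# two canned experiments (batch mixing, Swiss roll).

property_tag <- c(jaccard = "local", mixing = "local", ranking = "global",
                  accuracy = "global", ks = "global", ratio = "distance")

#' Build / validate an audit configuration
#'
#' @param config named list, or path to a YAML file holding one. Recognized
#'   fields: `input` (either `list(type = "synthetic", ...mixture_spec args)`
#'   or `list(type = "files", counts =, labels =)`), `chains` (character
#'   vector of chain names, see [pipeline_embed()]), `metrics` (subset of
#'   `jaccard`, `mixing`, `ranking`, `accuracy`, `ks`, `ratio`),
#'   `n_replicates`, `seed`, `k_jaccard`, `k_mixing`, `k_predict`,
#'   `test_fraction`, `metric`, `out_dir`.
#' @return validated config list of class `audit_config`.
#' @export
audit_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    input = list(type = "synthetic"),
    chains = c("ambient", "pca-50", "pca-50-umap"),
    metrics = c("jaccard", "mixing"),
    n_replicates = 3, seed = 0,
    k_jaccard = 30, k_mixing = 30, k_predict = 50, test_fraction = 0.3,
    metric = "L2", out_dir = NULL), config)
  if (!length(cfg$chains)) stopf("config must name at least one chain")
  lapply(cfg$chains, parse_chain)
  if (!length(cfg$metrics)) stopf("config must name at least one metric")
  bad <- setdiff(cfg$metrics, names(property_tag))
  if (length(bad)) stopf("unknown metric(s): %s", paste(bad, collapse = ", "))
  if (!cfg$input$type %in% c("synthetic", "files"))
    stopf("input$type must be \"synthetic\" or \"files\"")
  structure(cfg, class = c("audit_config", "list"))
}

audit_load_input <- function(cfg) {
  if (cfg$input$type == "synthetic") {
    args <- cfg$input[setdiff(names(cfg$input), "type")]
    if (is.null(args$seed)) args$seed <- cfg$seed
    gen <- generate_mixture_counts(do.call(mixture_spec, args))
    list(counts = gen$counts, annotations = gen$annotations)
  } else {
    counts <- read_counts_mtx(cfg$input$counts)
    ann <- read_annotations(cfg$input$labels)
    list(counts = counts, annotations = ann)
  }
}

# reference spaces each 2D chain is compared against
comparison_pairs <- function(chains) {
  pairs <- list()
  for (nm in chains) {
    p <- parse_chain(nm)
    if (p$kind %in% c("pca2d", "direct2d")) {
      pairs[[length(pairs) + 1]] <- c(space = nm, reference = "ambient")
      if (p$kind == "pca2d") {
        parent <- sprintf("pca-%d", p$d)
        if (parent %in% chains)
          pairs[[length(pairs) + 1]] <- c(space = nm, reference = parent)
      }
    } else if (p$kind == "pca") {
      pairs[[length(pairs) + 1]] <- c(space = nm, reference = "ambient")
    }
  }
  pairs
}

#' Run an end-to-end distortion audit
#'
#' Loads or generates the input, embeds it through every requested chain
#' (with replicates for the stochastic ones), computes every requested
#' metric for every comparison pair (each reduced space against the ambient
#' space, and each PCA-preprocessed 2D space additionally against its parent
#' PCA space), and assembles a `distortion_report`. Each metric row carries
#' the geometric property it probes (`local`, `global`, `distance`). If
#' `out_dir` is set, the report is serialized there as CSV tables plus a
#' JSON manifest.
#'
#' @param config an [audit_config()] (or list / YAML path coercible to one).
#' @return object of class `distortion_report`: list with `tables` (one
#'   data.frame per metric), `summary` (one row per space/metric/statistic),
#'   `config`, `seeds`.
#' @export
run_audit <- function(config = list()) {
  cfg <- if (inherits(config, "audit_config")) config else audit_config(config)
  inp <- audit_load_input(cfg)
  spaces <- pipeline_embed(inp$counts, list(
    chains = cfg$chains, n_replicates = cfg$n_replicates, seed = cfg$seed,
    metric = cfg$metric))
  ambient <- attr(spaces, "ambient")
  labels <- inp$annotations[match(ambient$cell_ids, inp$annotations$cell_id), ]
  types <- labels$type
  conditions <- labels$condition
  pairs <- comparison_pairs(cfg$chains)
  # cache one neighbor index and type-distance matrix per (space, replicate)
  knn_cache <- new.env(parent = emptyenv())
  get_knn <- function(space, rep, k) {
    key <- sprintf("%s.%d.k%d", space, rep, k)
    if (is.null(knn_cache[[key]]))
      knn_cache[[key]] <- knn_index(spaces[[space]][[rep]], k, cfg$metric)
    knn_cache[[key]]
  }
  tdm_cache <- new.env(parent = emptyenv())
  get_tdm <- function(space, rep) {
    key <- sprintf("%s.%d", space, rep)
    if (is.null(tdm_cache[[key]]))
      tdm_cache[[key]] <- type_distance_matrix(spaces[[space]][[rep]], types, cfg$metric)
    tdm_cache[[key]]
  }
  tables <- list()
  add_rows <- function(metric, df) {
    df$property <- unname(property_tag[metric])
    tables[[metric]] <<- rbind(tables[[metric]], df)
  }
  for (pr in pairs) {
    sp <- pr["space"]; ref <- pr["reference"]
    for (rep in seq_along(spaces[[sp]])) {
      for (metric in cfg$metrics) {
        if (metric == "jaccard") {
          j <- jaccard_neighbor_distance(get_knn(sp, rep, cfg$k_jaccard),
                                         get_knn(ref, 1, cfg$k_jaccard))
          add_rows("jaccard", data.frame(space = sp, reference = ref, replicate = rep,
                                         mean = mean(j), median = stats::median(j)))
        } else if (metric == "ranking") {
          rc <- type_ranking_correlation(get_tdm(ref, 1), get_tdm(sp, rep))
          add_rows("ranking", data.frame(space = sp, reference = ref, replicate = rep,
                                         mean = mean(rc), median = stats::median(rc)))
        } else if (metric == "ratio") {
          grp <- find_equidistant_groups(as_points(spaces[[ref]][[1]]),
                                         metric = cfg$metric, limit = 2000,
                                         seed = cfg$seed)
          if (length(grp$groups)) {
            rd <- ratio_distortion(grp, spaces[[ref]][[1]], spaces[[sp]][[rep]],
                                   cfg$metric)
            add_rows("ratio", data.frame(space = sp, reference = ref, replicate = rep,
                                         n_groups = length(grp$groups),
                                         median_fold = stats::median(rd$fold)))
          }
        }
      }
    }
  }
  # space-level metrics (no reference pair needed)
  for (metric in intersect(cfg$metrics, c("mixing", "accuracy", "ks"))) {
    for (sp in cfg$chains) {
      for (rep in seq_along(spaces[[sp]])) {
        if (metric == "mixing") {
          mf <- mixing_fractions(get_knn(sp, rep, cfg$k_mixing), conditions)
          add_rows("mixing", data.frame(space = sp, reference = NA, replicate = rep,
                                        mean = mean(mf), median = stats::median(mf)))
        } else if (metric == "accuracy") {
          acc <- knn_label_predict(spaces[[sp]][[rep]], types,
                                   test_fraction = cfg$test_fraction,
                                   k = cfg$k_predict, metric = cfg$metric,
                                   seed = cfg$seed + rep)
          add_rows("accuracy", data.frame(space = sp, reference = NA, replicate = rep,
                                          accuracy = as.numeric(acc)))
        } else if (metric == "ks") {
          ks <- inter_intra_ks(as_points(spaces[[sp]][[rep]]), types, cfg$metric,
                               max_pairs = 1e5, seed = cfg$seed)
          add_rows("ks", data.frame(space = sp, reference = NA, replicate = rep,
                                    statistic = ks$statistic))
        }
      }
    }
  }
  summary <- do.call(rbind, lapply(names(tables), function(m) {
    df <- tables[[m]]
    stat_cols <- setdiff(names(df), c("space", "reference", "replicate", "property"))
    do.call(rbind, lapply(split(df, df$space), function(g) {
      do.call(rbind, lapply(stat_cols, function(sc) data.frame(
        space = g$space[1], metric = m, statistic = sc,
        value = mean(g[[sc]]), property = g$property[1])))
    }))
  }))
  rownames(summary) <- NULL
  report <- structure(list(tables = tables, summary = summary, config = cfg,
                           seeds = cfg$seed + seq_len(cfg$n_replicates) - 1),
                      class = "distortion_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.distortion_report <- function(x, ...) {
  cat(sprintf("<distortion_report> %d metric table(s): %s\n",
              length(x$tables), paste(names(x$tables), collapse = ", ")))
  print(x$summary)
  invisible(x)
}

#' Serialize a distortion report
#'
#' Writes each metric table as CSV plus a `manifest.json` carrying the run
#' configuration, seeds, package version and the MD5 hash of every table
#' file (the reproducibility contract: identical config and seeds give
#' identical hashes for deterministic stages).
#'
#' @param report a `distortion_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (m in names(report$tables)) {
    p <- file.path(dir, paste0(m, ".csv"))
    utils::write.csv(report$tables[[m]], p, row.names = FALSE)
    paths[m] <- p
  }
  sp <- file.path(dir, "summary.csv")
  utils::write.csv(report$summary, sp, row.names = FALSE)
  paths["summary"] <- sp
  manifest <- list(config = unclass(report$config), seeds = report$seeds,
                   package_version = as.character(utils::packageVersion("embedaudit")),
                   tables = as.list(tools::md5sum(paths)))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, null = "null", na = "null",
                       digits = NA)
  invisible(mp)
}

#' Batch-mixing distortion experiment
#'
#' Generates a two-batch synthetic mixture, applies a log-space batch shift
#' of `shift_sd`, computes the same-batch mixing-fraction distribution in
#' the ambient space and in every 2D chain, and reports the K-S statistic
#' between the ambient and each embedded mixing distribution. Large K-S
#' values mean the embedding misrepresents how mixed the batches are.
#'
#' @param config list with any of: `n_cells` (2000), `n_genes` (1000),
#'   `n_types` (8), `shift_sd` (0.4; an intermediate shift leaving the
#'   batches partially mixed in ambient space - mean same-batch fraction
#'   around 0.8 - between the no-shift baseline and the fully separated
#'   large-shift limit), `affected_fraction` (0.5), `chains`
#'   (`"pca-50-umap"`), `k` (30), `n_replicates` (1), `seed` (0).
#' @return list with `table` (chain, replicate, ks, mean mixing in both
#'   spaces) and `distributions` (the per-space mixing fractions).
#' @export
mixing_experiment <- function(config = list()) {
  cfg <- utils::modifyList(list(
    n_cells = 2000, n_genes = 1000, n_types = 8, shift_sd = 0.4,
    affected_fraction = 0.5, chains = "pca-50-umap", k = 30,
    n_replicates = 1, seed = 0), config)
  gen <- generate_mixture_counts(mixture_spec(
    n_cells = cfg$n_cells, n_genes = cfg$n_genes, n_types = cfg$n_types,
    seed = cfg$seed))
  counts <- add_batch_effect(gen$counts, gen$annotations, cfg$shift_sd,
                             cfg$affected_fraction, seed = cfg$seed)
  spaces <- pipeline_embed(counts, list(chains = unique(c("ambient", cfg$chains)),
                                        n_replicates = cfg$n_replicates,
                                        seed = cfg$seed))
  batch <- gen$annotations$batch
  names(batch) <- gen$annotations$cell_id
  amb_mix <- mixing_fractions(knn_index(spaces[["ambient"]][[1]], cfg$k), batch)
  dists <- list(ambient = amb_mix)
  rows <- list()
  for (ch in setdiff(cfg$chains, "ambient")) {
    for (rep in seq_along(spaces[[ch]])) {
      mix <- mixing_fractions(knn_index(spaces[[ch]][[rep]], cfg$k), batch)
      dists[[sprintf("%s.%d", ch, rep)]] <- mix
      rows[[length(rows) + 1]] <- data.frame(
        chain = ch, replicate = rep,
        ks = ks_statistic(amb_mix, mix),
        mean_ambient = mean(amb_mix), mean_embedded = mean(mix))
    }
  }
  list(table = do.call(rbind, rows), distributions = dists,
       shift_sd = cfg$shift_sd)
}

#' Swiss-roll coherence experiment
#'
#' Generates Swiss rolls at several tightness (`turns`) values, embeds each
#' in 2D at several neighbor settings, and reports the mean Jaccard
#' dissimilarity between each embedding's k-nearest neighbors and the
#' neighbors in the known intrinsic 2D coordinates. Rising dissimilarity
#' with `turns` is the loss-of-coherence trend.
#'
#' @param config list with any of: `turns` (`c(1, 2, 3)`), `n_neighbors`
#'   (`c(5, 15, 50)`), `n_points` (1000), `noise_sd` (0.05), `k` (30),
#'   `method` (`"umap"`), `seeds` (`0:2`).
#' @return data.frame with one row per (turns, neighbor setting, seed).
#' @export
swissroll_experiment <- function(config = list()) {
  cfg <- utils::modifyList(list(
    turns = c(1, 2, 3), n_neighbors = c(5, 15, 50), n_points = 1000,
    noise_sd = 0.05, k = 30, method = "umap", seeds = 0:2), config)
  rows <- list()
  for (tu in cfg$turns) for (sd_ in cfg$seeds) {
    roll <- generate_swiss_roll(cfg$n_points, turns = tu, noise_sd = cfg$noise_sd,
                                seed = sd_)
    idx_true <- knn_index(roll$intrinsic, cfg$k)
    for (nn in cfg$n_neighbors) {
      emb <- run_nonlinear_2d(roll$points, method = cfg$method,
                              neighbor_param = nn, seed = sd_)
      j <- jaccard_neighbor_distance(knn_index(as_points(emb), cfg$k), idx_true)
      rows[[length(rows) + 1]] <- data.frame(
        turns = tu, n_neighbors = nn, seed = sd_,
        mean_jaccard = mean(j), median_jaccard = stats::median(j))
    }
  }
  do.call(rbind, rows)
}
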