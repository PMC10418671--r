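# End-to-end orchestration: simulate (optional) -> preprocess -> block
# building -> composite scores -> hierarchical PLS-DA with validation ->
# block and feature selection -> partial-correlation network -> enrichment
# -> run manifest. Every intermediate is written as CSV; the run is fully
# deterministic given the config seed.

#' Run the full multiblock discrimination pipeline
#'
#' @param config an `analysis_config`
#' @param out_dir output directory (created); all stage outputs and the
#'   run manifest are written here
#' @param table a `feature_table`, or `NULL` to simulate one
#' @param spec a `synthetic_spec` used when `table` is `NULL`; defaults to
#'   the standard synthetic cohort with the config seed
#' @param truth optional ground truth matching `table` (attached to the
#'   manifest for recovery scoring)
#' @param catalog optional `pathway_catalog`; simulated runs generate one
#' @param block_map_path optional path to a functional block map; by
#'   default the table's `block_id` feature metadata is used
#' @return a `run_manifest` list (also written as `manifest.json`)
#' @export
run_all <- function(config = analysis_config(), out_dir, table = NULL,
                    spec = NULL, truth = NULL, catalog = NULL,
                    block_map_path = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s (partial outputs in %s)", name,
            conditionMessage(e), out_dir))
  }

  # -- simulate ------------------------------------------------------------
  if (is.null(table)) {
    if (is.null(spec)) spec <- synthetic_spec(seed = config$seed)
    sim <- stage("simulate", generate_table(spec))
    table <- sim$table; truth <- sim$truth
    if (is.null(catalog))
      catalog <- generate_pathway_catalog(table, truth, n_pathways = 20L,
                                          seed = child_seed(config$seed, 7L))
    files <- c(files, write_feature_table(table, file.path(out_dir, "input")))
    tp <- file.path(out_dir, "input", "ground_truth.csv")
    utils::write.csv(data.frame(feature_id = names(truth$true_fold_change),
                                true_fold_change = truth$true_fold_change,
                                affected = names(truth$true_fold_change) %in%
                                  truth$affected_feature_ids,
                                row.names = NULL), tp, row.names = FALSE)
    files <- c(files, ground_truth = tp)
    cp <- file.path(out_dir, "input", "pathway_catalog.tsv")
    write_pathway_catalog(catalog, cp)
    files <- c(files, pathway_catalog = cp)
  }
  validate_feature_table(table)

  # -- preprocess ----------------------------------------------------------
  prep <- stage("preprocess", preprocess_table(table, config))
  proc <- prep$table
  files <- c(files, write_feature_table(proc, file.path(out_dir, "processed")))
  counts <- do.call(rbind, lapply(names(prep$reports), function(nm) {
    r <- prep$reports[[nm]]
    data.frame(step = nm, n_in = r$n_features_in, n_out = r$n_features_out,
               stringsAsFactors = FALSE)
  }))
  rp <- file.path(out_dir, "preprocess_report.csv")
  utils::write.csv(counts, rp, row.names = FALSE)
  files <- c(files, preprocess_report = rp)

  # -- block building ------------------------------------------------------
  fm <- proc$feature_meta
  maps <- list()
  if (!is.null(block_map_path)) {
    maps$functional <- stage("block_map", load_block_map(block_map_path, proc))
  } else if (any(fm$assay == "metabolomics" & !is.na(fm$block_id))) {
    met <- fm[fm$assay == "metabolomics" & !is.na(fm$block_id), ]
    maps$functional <- block_map(data.frame(feature_id = met$feature_id,
                                            block_id = met$block_id),
                                 "functional")
  }
  if (any(fm$assay == "lipidomics")) {
    k <- min(config$n_lipid_clusters, sum(fm$assay == "lipidomics"))
    maps$lipid <- stage("cluster_lipids", cluster_lipids(proc, k))
  }
  if (!length(maps)) stopf("no blocks could be built (no block_id metadata, no lipids)")
  comb <- do.call(rbind, lapply(maps, function(m)
    data.frame(feature_id = unlist(m$blocks, use.names = FALSE),
               block_id = rep(names(m$blocks), lengths(m$blocks)),
               stringsAsFactors = FALSE)))
  full_map <- block_map(comb, "functional")
  bp <- file.path(out_dir, "block_map.tsv")
  write_block_map(full_map, bp)
  files <- c(files, block_map = bp)

  # -- composite scores & hierarchical model -------------------------------
  sc <- stage("scale", {
    s <- scale_for_model(impute_missing(proc), "unit_variance")
    rownames(s$X) <- proc$sample_meta$sample_id[study_idx(proc)]
    s
  })
  y <- study_groups(proc)
  bs_raw <- stage("block_scores", block_scores(sc$X, y, full_map, n_orthogonal = 1L))
  bs <- weight_blocks(bs_raw, "sqrt_size")
  sp <- file.path(out_dir, "block_scores.csv")
  utils::write.csv(data.frame(sample_id = rownames(bs$scores), bs$scores,
                              check.names = FALSE), sp, row.names = FALSE)
  files <- c(files, block_scores = sp)

  A <- stage("select_components",
             select_components(bs$scores, y, A_max = 5L,
                               n_folds = config$n_folds,
                               seed = child_seed(config$seed, 11L)))
  hier <- stage("hierarchical", fit_hierarchical(bs, y, A))
  # fold-honest validation: block compression re-derived per fold/permutation
  val <- stage("validation",
               hierarchical_permutation_test(
                 sc$X, y, full_map, A,
                 n_permutations = config$n_permutations,
                 n_folds = config$n_folds,
                 seed = child_seed(config$seed, 13L)))
  cva <- cv_anova(hierarchical_cv(sc$X, y, full_map, A, config$n_folds,
                                  child_seed(config$seed, 13L)))
  blocks_sel <- stage("select_blocks",
                      select_blocks(hier$vip, bs, y,
                                    config$vip_threshold, config$alpha))
  bsel <- file.path(out_dir, "block_selection.csv")
  utils::write.csv(blocks_sel, bsel, row.names = FALSE)
  files <- c(files, block_selection = bsel)

  # -- feature-level selection ---------------------------------------------
  flat <- stage("flat_plsda", {
    m <- fit_plsda(sc$X, y, A = 2L)
    rownames(m$W) <- colnames(sc$X)
    m
  })
  feat_vip <- compute_vip(flat)
  sel <- stage("select_features",
               select_features(proc, feat_vip, config$vip_threshold,
                               config$alpha))
  fsel <- file.path(out_dir, "feature_selection.csv")
  utils::write.csv(sel$records, fsel, row.names = FALSE)
  files <- c(files, feature_selection = fsel)

  # -- network -------------------------------------------------------------
  pc <- stage("network", partial_correlations(bs_raw$scores))
  net <- build_network(pc, config$network_p_threshold,
                       node_stats = blocks_sel[, c("block_id", "p", "q")])
  bt <- node_betweenness(net)
  np <- file.path(out_dir, "network_nodes.csv")
  utils::write.csv(data.frame(block_id = names(bt), betweenness = bt,
                              q = blocks_sel$q[match(names(bt), blocks_sel$block_id)],
                              row.names = NULL), np, row.names = FALSE)
  ep <- file.path(out_dir, "network_edges.csv")
  utils::write.csv(net$edges, ep, row.names = FALSE)
  gp <- file.path(out_dir, "network.graphml")
  export_graph(net, gp)
  files <- c(files, network_nodes = np, network_edges = ep, graphml = gp)

  # -- enrichment ----------------------------------------------------------
  enr <- NULL
  if (!is.null(catalog)) {
    met_ids <- fm$feature_id[fm$assay == "metabolomics"]
    sel_met <- sel$records$annotation[sel$records$selected &
                                        sel$records$feature_id %in% met_ids]
    enr <- stage("enrich", enrich(sel_met, catalog))
    epth <- file.path(out_dir, "enrichment.csv")
    utils::write.csv(enr, epth, row.names = FALSE)
    files <- c(files, enrichment = epth)
  }

  # -- manifest ------------------------------------------------------------
  cfgp <- file.path(out_dir, "config.yaml")
  write_config(config, cfgp)
  files <- c(files, config = cfgp)
  manifest <- list(
    package_version = as.character(utils::packageVersion("omniblock")),
    seed = config$seed,
    config = unclass(config),
    n_samples = nrow(table$intensities),
    n_features_in = ncol(table$intensities),
    n_features_retained = ncol(proc$intensities),
    n_blocks = ncol(bs$scores),
    n_components = A,
    R2Y = hier$model$R2Y,
    Q2 = val$Q2,
    permutation_p = val$p_value,
    cv_anova_p = cva$p_value,
    n_blocks_selected = sum(blocks_sel$selected),
    n_features_selected = sum(sel$records$selected),
    n_network_edges = nrow(net$edges),
    files = as.list(files),
    file_md5 = as.list(tools::md5sum(unname(files))),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$truth <- truth
  invisible(structure(manifest, class = "run_manifest"))
}

# Median-impute residual missing cells (per feature, study-median) so the
# multivariate stage sees a complete matrix. PQN and the univariate tests
# upstream are NA-tolerant; imputation touches only the latent models.
impute_missing <- function(ft) {
  x <- ft$intensities
  if (!anyNA(x)) return(ft)
  si <- study_idx(ft)
  med <- apply(x[si, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
  for (j in which(colSums(is.na(x)) > 0L)) x[is.na(x[, j]), j] <- med[j]
  ft$intensities <- x
  validate_feature_table(ft)
  ft
}

#' Render a human-readable run report
#'
#' Summarizes a completed run from its output directory: feature counts
#' per preprocessing step, the hierarchical model's fit and validation,
#' the top selected blocks and features, network hubs and top enriched
#' pathways. Sections whose output file is missing are skipped with a
#' notice. Reported numbers are read back from the stage CSVs, so the
#' report cannot drift from the written artifacts.
#'
#' @param manifest a `run_manifest` from [run_all()], or the path of a run
#'   output directory
#' @return character vector of report lines, invisibly; also printed
#' @export
render_report <- function(manifest) {
  dir <- if (is.character(manifest)) manifest
         else dirname(manifest$files$config)
  lines <- c("== multiblock discrimination run ==")
  grab <- function(name) {
    p <- file.path(dir, name)
    if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE) else NULL
  }
  pre <- grab("preprocess_report.csv")
  if (!is.null(pre)) {
    lines <- c(lines, "-- preprocessing --",
               sprintf("  %-40s %4d -> %4d", pre$step, pre$n_in, pre$n_out))
  } else lines <- c(lines, "[preprocess report missing: section skipped]")
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) {
    m <- jsonlite::read_json(mf)
    lines <- c(lines, "-- hierarchical PLS-DA --",
               sprintf("  components: %d   R2Y = %.3f   Q2 = %.3f", m$n_components,
                       m$R2Y, m$Q2),
               sprintf("  permutation p = %.4g   CV-ANOVA p = %.4g",
                       m$permutation_p, m$cv_anova_p))
  }
  bsel <- grab("block_selection.csv")
  if (!is.null(bsel)) {
    nsel <- sum(bsel$selected)
    lines <- c(lines, sprintf("-- blocks: %d selected of %d --", nsel, nrow(bsel)))
    top <- utils::head(bsel[bsel$selected, ], 5L)
    if (nrow(top)) lines <- c(lines, sprintf(
      "  %-6s size=%3d VIP=%.2f q=%.3g %s", top$block_id, top$size, top$VIP,
      top$q, top$direction))
  } else lines <- c(lines, "[block selection missing: section skipped]")
  fsel <- grab("feature_selection.csv")
  if (!is.null(fsel)) {
    nsel <- sum(fsel$selected)
    if (nsel == 0L) {
      lines <- c(lines, "-- features: none selected --")
    } else {
      lines <- c(lines, sprintf("-- features: %d selected of %d, top 4 --",
                                nsel, nrow(fsel)))
      top <- utils::head(fsel[fsel$selected, ], 4L)
      lines <- c(lines, sprintf("  %-20s FC=%+.2f VIP=%.2f p=%.3g",
                                top$annotation, top$fold_change, top$VIP, top$p))
    }
  } else lines <- c(lines, "[feature selection missing: section skipped]")
  nn <- grab("network_nodes.csv")
  if (!is.null(nn)) {
    hub <- nn[order(-nn$betweenness), ][1L, ]
    lines <- c(lines, sprintf("-- network: top hub %s (betweenness %.1f) --",
                              hub$block_id, hub$betweenness))
  }
  en <- grab("enrichment.csv")
  if (!is.null(en) && nrow(en)) {
    lines <- c(lines, sprintf("-- enrichment: top pathway %s (k=%d/K=%d, p=%.3g) --",
                              en$pathway_id[1L], en$k[1L], en$K[1L], en$p[1L]))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
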