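# Synthetic cohort generator.
#
# Emulates a matched two-group untargeted LC-MS study: log-normal feature
# intensities with a shared latent factor per block (within-block
# correlation), signed group fold changes on a subset of blocks, per-feature
# analytical noise calibrated to a target QC coefficient of variation,
# smooth multiplicative injection-order drift, pooled QC injections every
# qc_interval-th position, and low-level blank injections.

#' Specification of a synthetic cohort
#'
#' Defaults emulate the study design the pipeline targets: 97 samples per
#' group, 228 annotated metabolites in 54 functional blocks, 335 lipid
#' species in 11 clusters, QC injections at every 5th position, signed
#' fold-change magnitudes between 1.05 and 1.9, QC CVs spanning 10-40%
#' (straddling the 30% filter), and 20% multiplicative drift.
#'
#' @param n_per_group samples per group (case and control)
#' @param n_metabolite_features number of metabolomics features
#' @param n_lipid_features number of lipidomics features
#' @param n_functional_blocks number of functional metabolite blocks
#' @param n_lipid_clusters_true number of true lipid clusters
#' @param within_block_correlation pairwise correlation of features sharing
#'   a block, in `[0, 1)`
#' @param affected_block_fraction fraction of blocks (functional and lipid)
#'   carrying a group effect
#' @param effect_fold_changes numeric vector; fold-change magnitudes are
#'   drawn uniformly between its min and max (a single value gives a
#'   constant magnitude)
#' @param feature_cv_range length-2 vector, range of target QC CVs
#' @param drift_amplitude relative amplitude of the injection-order drift
#' @param qc_interval a QC sample occupies every `qc_interval`-th injection
#' @param n_blanks number of blank injections at the head of the run
#' @param missing_rate fraction of cells set missing completely at random
#' @param seed integer seed; the whole generation is deterministic given it
#' @return a `synthetic_spec` list
#' @export
synthetic_spec <- function(n_per_group = 97L,
                           n_metabolite_features = 228L,
                           n_lipid_features = 335L,
                           n_functional_blocks = 54L,
                           n_lipid_clusters_true = 11L,
                           within_block_correlation = 0.5,
                           affected_block_fraction = 0.5,
                           effect_fold_changes = c(1.05, 1.9),
                           feature_cv_range = c(0.10, 0.40),
                           drift_amplitude = 0.2,
                           qc_interval = 5L,
                           n_blanks = 5L,
                           missing_rate = 0,
                           seed = 1L) {
  spec <- list(n_per_group = as.integer(n_per_group),
               n_metabolite_features = as.integer(n_metabolite_features),
               n_lipid_features = as.integer(n_lipid_features),
               n_functional_blocks = as.integer(n_functional_blocks),
               n_lipid_clusters_true = as.integer(n_lipid_clusters_true),
               within_block_correlation = within_block_correlation,
               affected_block_fraction = affected_block_fraction,
               effect_fold_changes = effect_fold_changes,
               feature_cv_range = feature_cv_range,
               drift_amplitude = drift_amplitude,
               qc_interval = as.integer(qc_interval),
               n_blanks = as.integer(n_blanks),
               missing_rate = missing_rate,
               seed = as.integer(seed))
  if (spec$n_per_group < 2L) stopf("n_per_group must be >= 2")
  if (spec$qc_interval < 2L) stopf("qc_interval must be >= 2")
  if (spec$within_block_correlation < 0 || spec$within_block_correlation >= 1)
    stopf("within_block_correlation must be in [0, 1)")
  if (any(spec$effect_fold_changes < 1))
    stopf("effect fold-change magnitudes must be >= 1")
  if (spec$affected_block_fraction == 0 && length(spec$effect_fold_changes))
    warnf("affected_block_fraction is 0: no block carries a group effect")
  if (spec$n_functional_blocks > spec$n_metabolite_features)
    stopf("more functional blocks than metabolite features")
  if (spec$n_lipid_clusters_true > spec$n_lipid_features)
    stopf("more lipid clusters than lipid features")
  structure(spec, class = "synthetic_spec")
}

# Assign n features to k blocks with every block non-empty.
assign_blocks <- function(n, k, ids) {
  stopifnot(n >= k)
  memb <- c(seq_len(k), sample(seq_len(k), n - k, replace = TRUE))
  memb <- sample(memb)  # shuffle which features land where
  ids[memb]
}

#' Generate a synthetic feature table with ground truth
#'
#' See [synthetic_spec()] for the generative model. The returned ground
#' truth records affected blocks and features, true signed fold changes,
#' true lipid-cluster memberships, target QC CVs and the per-feature drift
#' parameters, for recovery testing.
#'
#' @param spec a `synthetic_spec`
#' @return list with elements `table` (a `feature_table`) and `truth`
#' @export
generate_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, generate_table_impl(spec))
}

generate_table_impl <- function(spec) {
  n_study <- 2L * spec$n_per_group
  p_met <- spec$n_metabolite_features
  p_lip <- spec$n_lipid_features
  p <- p_met + p_lip
  fid <- c(sprintf("M%03d", seq_len(p_met)), sprintf("L%03d", seq_len(p_lip)))
  assay <- rep(c("metabolomics", "lipidomics"), c(p_met, p_lip))
  annotation <- c(sprintf("metabolite %03d", seq_len(p_met)),
                  sprintf("lipid %03d", seq_len(p_lip)))

  fun_ids <- sprintf("F%02d", seq_len(spec$n_functional_blocks))
  lip_ids <- sprintf("LC%02d", seq_len(spec$n_lipid_clusters_true))
  block_id <- c(assign_blocks(p_met, spec$n_functional_blocks, fun_ids),
                assign_blocks(p_lip, spec$n_lipid_clusters_true, lip_ids))

  # baseline log-intensities and noise scales from target QC CVs
  mu <- stats::rnorm(p, mean = log(1e6), sd = 1)
  cv_target <- stats::runif(p, spec$feature_cv_range[1L], spec$feature_cv_range[2L])
  sigma <- sqrt(log(1 + cv_target^2))
  rho <- spec$within_block_correlation
  tau <- sigma * sqrt(rho / (1 - rho))  # shared-factor loading

  # group effects on a sampled fraction of blocks (both assays)
  all_blocks <- c(fun_ids, lip_ids)
  n_aff <- round(spec$affected_block_fraction * length(all_blocks))
  affected_blocks <- if (n_aff > 0) sort(sample(all_blocks, n_aff)) else character(0)
  block_sign <- stats::setNames(sample(c(-1, 1), length(all_blocks), replace = TRUE),
                                all_blocks)
  fc_mag <- rep(1, p)
  aff_feat <- block_id %in% affected_blocks
  lo <- min(spec$effect_fold_changes); hi <- max(spec$effect_fold_changes)
  fc_mag[aff_feat] <- if (lo == hi) lo else stats::runif(sum(aff_feat), lo, hi)
  # signed convention: +mag for increases in cases, -mag for decreases
  fc_signed <- ifelse(aff_feat, block_sign[block_id] * fc_mag, 1)
  delta <- log(fc_mag) * block_sign[block_id] * aff_feat  # log effect, case vs control

  # injection design: blanks first, then study with a QC after every
  # (qc_interval - 1) study injections
  n_qc <- n_study %/% (spec$qc_interval - 1L)
  study_ids <- sprintf("S%03d", seq_len(n_study))
  group <- rep(c("control", "case"), each = spec$n_per_group)
  pair_id <- rep(sprintf("P%03d", seq_len(spec$n_per_group)), 2L)
  study_order_perm <- sample(n_study)  # injection order of study samples

  roles <- character(0); ids <- character(0)
  run <- character(0); run_roles <- character(0)
  k <- 0L
  for (i in seq_len(n_study)) {
    run <- c(run, study_ids[study_order_perm[i]])
    run_roles <- c(run_roles, "study")
    if (i %% (spec$qc_interval - 1L) == 0L && k < n_qc) {
      k <- k + 1L
      run <- c(run, sprintf("QC%02d", k))
      run_roles <- c(run_roles, "qc")
    }
  }
  ids <- c(sprintf("BL%d", seq_len(spec$n_blanks)), run)
  roles <- c(rep("blank", spec$n_blanks), run_roles)
  inj <- seq_along(ids)
  n_total <- length(ids)

  sm <- data.frame(sample_id = ids, role = roles, injection_order = inj,
                   group = NA_character_, pair_id = NA_character_,
                   stringsAsFactors = FALSE)
  m <- match(sm$sample_id, study_ids)
  sm$group[!is.na(m)] <- group[m[!is.na(m)]]
  sm$pair_id[!is.na(m)] <- pair_id[m[!is.na(m)]]

  # log-intensity matrix
  logx <- matrix(NA_real_, n_total, p)
  is_study <- sm$role == "study"
  is_qc <- sm$role == "qc"
  is_blank <- sm$role == "blank"
  # shared block factors for study samples
  zmat <- matrix(stats::rnorm(sum(is_study) * length(all_blocks)),
                 sum(is_study), length(all_blocks),
                 dimnames = list(NULL, all_blocks))
  caseflag <- as.numeric(sm$group[is_study] == "case")
  eps <- matrix(stats::rnorm(sum(is_study) * p), sum(is_study), p)
  logx[is_study, ] <- rep(mu, each = sum(is_study)) +
    zmat[, block_id, drop = FALSE] * rep(tau, each = sum(is_study)) +
    outer(caseflag, delta) +
    eps * rep(sigma, each = sum(is_study))
  if (any(is_qc)) {
    epsq <- matrix(stats::rnorm(sum(is_qc) * p), sum(is_qc), p)
    logx[is_qc, ] <- rep(mu, each = sum(is_qc)) + epsq * rep(sigma, each = sum(is_qc))
  }
  if (any(is_blank)) {
    blank_mu <- log(exp(stats::median(mu)) / 20)
    logx[is_blank, ] <- blank_mu + stats::rnorm(sum(is_blank) * p, sd = 0.3)
  }
  x <- exp(logx)

  # smooth multiplicative drift, per feature
  freq <- stats::runif(p, 0.5, 1.5)
  phase <- stats::runif(p)
  if (spec$drift_amplitude > 0) {
    s <- sin(2 * pi * (outer(inj / n_total, freq) + rep(phase, each = n_total)))
    x <- x * (1 + spec$drift_amplitude * s)
  }

  if (spec$missing_rate > 0) {
    drop <- stats::runif(length(x)) < spec$missing_rate
    x[drop] <- NA_real_
  }

  fm <- data.frame(feature_id = fid, assay = assay, annotation = annotation,
                   block_id = ifelse(assay == "metabolomics", block_id, NA_character_),
                   lipid_class = ifelse(assay == "lipidomics", block_id, NA_character_),
                   stringsAsFactors = FALSE)
  ft <- feature_table(x, sm, fm)
  truth <- list(
    affected_block_ids = affected_blocks,
    affected_feature_ids = fid[aff_feat],
    true_fold_change = stats::setNames(fc_signed, fid),
    block_map = data.frame(feature_id = fid, block_id = block_id,
                           stringsAsFactors = FALSE),
    lipid_cluster = stats::setNames(block_id[assay == "lipidomics"],
                                    fid[assay == "lipidomics"]),
    target_cv = stats::setNames(cv_target, fid),
    drift = data.frame(feature_id = fid, amplitude = spec$drift_amplitude,
                       freq = freq, phase = phase, stringsAsFactors = FALSE)
  )
  list(table = ft, truth = truth)
}

#' Generate a synthetic pathway catalog
#'
#' Samples pathways over the table's metabolite annotations. The first
#' pathway is constructed to coincide with one affected functional block
#' (a true enriched set), so enrichment recovery can be tested against the
#' ground truth.
#'
#' @param table a `feature_table` from [generate_table()]
#' @param truth the matching ground truth
#' @param n_pathways number of pathways (>= 1)
#' @param seed integer seed
#' @return a `pathway_catalog` (see [pathway_catalog()])
#' @export
generate_pathway_catalog <- function(table, truth, n_pathways = 20L, seed = 1L) {
  if (n_pathways < 1L) stopf("n_pathways must be >= 1")
  fm <- table$feature_meta
  met <- fm[fm$assay == "metabolomics", , drop = FALSE]
  universe <- met$annotation
  if (n_pathways == 1L)  # degenerate catalog: one pathway spanning everything
    return(pathway_catalog(list(pathway_all = universe), universe))
  with_seed(seed, {
    paths <- list()
    aff_fun <- intersect(truth$affected_block_ids, unique(met$block_id))
    if (length(aff_fun)) {
      b <- aff_fun[[1L]]
      paths[["pathway_true"]] <- met$annotation[met$block_id %in% b]
    } else {
      paths[["pathway_true"]] <- sample(universe, min(8L, length(universe)))
    }
    i <- 1L
    while (length(paths) < n_pathways) {
      sz <- sample(4:min(20L, length(universe)), 1L)
      paths[[sprintf("pathway_%02d", i)]] <- sample(universe, sz)
      i <- i + 1L
    }
    pathway_catalog(paths, universe)
  })
}
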