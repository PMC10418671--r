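# Preprocessing chain for untargeted LC-MS feature tables:
#   blank removal -> QC-anchored LOESS drift correction -> QC-CV filter
#   -> probabilistic quotient normalization -> scaling / PCA outlier check.
# Metabolomics and lipidomics columns are preprocessed separately (their
# QC and blank series differ) and rejoined on sample_id by preprocess_table().

new_report <- function(step, n_in, n_out, detail = list()) {
  structure(c(list(step = step, n_features_in = n_in, n_features_out = n_out),
              detail),
            class = "preprocess_report")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf("[%s] features %d -> %d\n", x$step, x$n_features_in, x$n_features_out))
  invisible(x)
}

#' Remove features not rising above blank injections
#'
#' A feature is kept iff its mean QC intensity is at least `blank_ratio`
#' times its mean blank intensity (boundary inclusive; missing values are
#' skipped). Features present in blanks at comparable intensity are
#' carry-over or solvent artifacts, not biological signal.
#'
#' @param ft a `feature_table` containing QC and blank rows
#' @param blank_ratio required QC/blank mean ratio, > 0 (default 3)
#' @return list with the filtered `table` and a `report`
#' @export
remove_blank_features <- function(ft, blank_ratio = 3) {
  if (blank_ratio <= 0) stopf("blank_ratio must be > 0")
  bi <- blank_idx(ft); qi <- qc_idx(ft)
  p <- ncol(ft$intensities)
  if (!length(bi)) {
    warnf("no blank rows: blank-feature removal skipped")
    return(list(table = ft, report = new_report("remove_blank_features", p, p,
                list(skipped = TRUE))))
  }
  qc_mean <- colMeans(ft$intensities[qi, , drop = FALSE], na.rm = TRUE)
  bl_mean <- colMeans(ft$intensities[bi, , drop = FALSE], na.rm = TRUE)
  qc_mean[is.nan(qc_mean)] <- 0
  bl_mean[is.nan(bl_mean)] <- 0
  keep <- qc_mean >= blank_ratio * bl_mean
  out <- subset_table(ft, features = which(keep))
  list(table = out,
       report = new_report("remove_blank_features", p, sum(keep),
                           list(removed = ft$feature_meta$feature_id[!keep],
                                qc_mean = qc_mean, blank_mean = bl_mean)))
}

#' QC-anchored LOESS drift correction
#'
#' Per feature, a local-linear LOESS curve of QC intensity versus injection
#' order is fitted and evaluated at every sample's injection order
#' (interpolating between QCs, constant beyond the terminal QCs); each
#' intensity is multiplied by (median QC intensity / fitted value). A final
#' per-feature rescale pins the post-correction QC median to its
#' pre-correction value, so QC medians are preserved by construction.
#' Features whose fitted curve is non-positive anywhere, or with fewer than
#' 4 non-missing QC values, are left uncorrected and flagged.
#'
#' @param ft a `feature_table` with at least 4 QC rows
#' @param span LOESS span in (0, 1]; spans >= 1 use all QCs in every local fit
#' @return list with the corrected `table` and a `report` whose
#'   `uncorrected` element names the flagged features
#' @export
drift_correct <- function(ft, span = 0.75) {
  qi <- qc_idx(ft)
  if (length(qi) < 4L)
    stopf("drift correction needs >= 4 QC rows (got %d); skip the step or supply more QCs",
          length(qi))
  ord <- ft$sample_meta$injection_order
  qc_ord <- ord[qi]
  x <- ft$intensities
  p <- ncol(x)
  flagged <- character(0)
  # evaluation orders clamped to the observed QC range (constant extrapolation)
  for (j in seq_len(p)) {
    yq <- x[qi, j]
    ok <- !is.na(yq)
    if (sum(ok) < 4L) { flagged <- c(flagged, colnames(x)[j]); next }
    med <- stats::median(yq[ok])
    fit <- try(stats::loess(y ~ o,
                            data = data.frame(y = yq[ok], o = qc_ord[ok]),
                            span = span, degree = 1, family = "gaussian",
                            control = stats::loess.control(surface = "direct")),
               silent = TRUE)
    if (inherits(fit, "try-error")) { flagged <- c(flagged, colnames(x)[j]); next }
    o_eval <- pmin(pmax(ord, min(qc_ord[ok])), max(qc_ord[ok]))
    fitted_all <- stats::predict(fit, newdata = data.frame(o = o_eval))
    if (any(!is.finite(fitted_all)) || any(fitted_all <= 0)) {
      flagged <- c(flagged, colnames(x)[j]); next
    }
    corr <- x[, j] * (med / fitted_all)
    # pin the QC median exactly
    med_post <- stats::median(corr[qi], na.rm = TRUE)
    if (is.finite(med_post) && med_post > 0) corr <- corr * (med / med_post)
    x[, j] <- corr
  }
  out <- ft
  out$intensities <- x
  validate_feature_table(out)
  list(table = out,
       report = new_report("drift_correct", p, p,
                           list(uncorrected = flagged, span = span)))
}

#' Filter features by QC coefficient of variation
#'
#' Per feature, CV = sd/mean over non-missing QC intensities; a feature is
#' kept iff CV < `cv_cutoff` (strict). Features with fewer than 2
#' non-missing QC values cannot be assessed and are removed, counted
#' separately in the report.
#'
#' @param ft a `feature_table` with at least 2 QC rows
#' @param cv_cutoff CV cutoff fraction (default 0.30)
#' @return list with the filtered `table` and a `report` carrying the
#'   per-feature CVs
#' @export
cv_filter <- function(ft, cv_cutoff = 0.30) {
  qi <- qc_idx(ft)
  if (length(qi) < 2L) stopf("cv_filter needs >= 2 QC rows")
  cvs <- apply(ft$intensities[qi, , drop = FALSE], 2L, cv_of)
  unassessable <- is.na(cvs)
  keep <- !unassessable & cvs < cv_cutoff
  out <- subset_table(ft, features = which(keep))
  list(table = out,
       report = new_report("cv_filter", ncol(ft$intensities), sum(keep),
                           list(qc_cv = cvs,
                                removed = ft$feature_meta$feature_id[!keep],
                                n_unassessable = sum(unassessable))))
}

#' Probabilistic quotient normalization
#'
#' The reference spectrum is the per-feature median over study rows. Each
#' sample's quotient is the median, over features positive in both sample
#' and reference, of sample/reference; every intensity of the sample is
#' divided by that quotient. Because dividing by the quotients shifts the
#' median reference itself, the quotient step is iterated to its fixed
#' point (a handful of fast iterations); the recorded quotient per sample
#' is the accumulated product. At the fixed point every sample's quotient
#' against the recomputed reference is 1, which makes the operation
#' idempotent.
#'
#' @param ft a `feature_table` with >= 1 study row and >= 1 feature
#' @param tol fixed-point tolerance on the per-iteration quotients
#' @param max_iter iteration cap (convergence is geometric; a dozen
#'   iterations typically suffice)
#' @return list with the normalized `table` and a `report` carrying the
#'   per-sample quotients
#' @export
pqn_normalize <- function(ft, tol = 1e-12, max_iter = 100L) {
  si <- study_idx(ft)
  if (!length(si)) stopf("pqn_normalize needs >= 1 study row")
  if (!ncol(ft$intensities)) stopf("pqn_normalize needs >= 1 feature")
  x <- ft$intensities
  fastmed <- function(v) {
    v <- v[!is.na(v) & is.finite(v) & v > 0]
    n <- length(v)
    if (!n) return(NA_real_)
    h <- (n + 1L) %/% 2L
    if (n %% 2L == 1L) sort(v, partial = h)[h]
    else { s <- sort(v, partial = c(h, h + 1L)); (s[h] + s[h + 1L]) / 2 }
  }
  quotient_step <- function(m, rows) {
    ref <- apply(m[si, , drop = FALSE], 2L, fastmed)
    vapply(rows, function(i) {
      q <- fastmed(m[i, ] / ref)
      if (is.na(q)) stopf("sample '%s' shares no positive feature with the reference",
                          ft$sample_meta$sample_id[i])
      q
    }, numeric(1))
  }
  # the fixed point depends only on the study rows: iterate on those, with
  # Aitken extrapolation on the log-quotients to accelerate the slow
  # geometric tail, then apply one exact quotient step to every row
  q_study <- rep(1, length(si))
  xs <- x[si, , drop = FALSE]
  si_local <- si
  si <- seq_len(nrow(xs))  # quotient_step reads `si` for the reference rows
  for (it in seq_len(max_iter)) {
    q1 <- quotient_step(xs, si); xs <- xs / q1; q_study <- q_study * q1
    if (max(abs(q1 - 1)) < tol) break
    q2 <- quotient_step(xs, si); xs <- xs / q2; q_study <- q_study * q2
    if (max(abs(q2 - 1)) < tol) break
    d1 <- log(q1); d2 <- log(q2)
    r <- sum(abs(d2)) / max(sum(abs(d1)), .Machine$double.xmin)
    if (r > 0 && r < 0.95) {  # shared contraction ratio, clamped
      qx <- exp(d2 * r / (1 - r))
      xs <- xs / qx; q_study <- q_study * qx
    }
  }
  si <- si_local
  x[si, ] <- xs
  q_all <- rep(1, nrow(x))
  q_all[si] <- q_study
  # one final step against the converged reference; for non-study rows this
  # makes their quotient exactly 1 on any re-application
  q_fin <- quotient_step(x, seq_len(nrow(x)))
  x <- x / q_fin
  q_all <- q_all * q_fin
  out <- ft
  out$intensities <- x
  validate_feature_table(out)
  list(table = out,
       report = new_report("pqn_normalize", ncol(x), ncol(x),
                           list(quotients = stats::setNames(q_all,
                                                            ft$sample_meta$sample_id),
                                iterations = it)))
}

#' Center and scale study rows for multivariate modeling
#'
#' Column-mean centering plus unit-variance scaling (divide by sd), Pareto
#' scaling (divide by sqrt(sd)) or centering only. Zero-variance columns
#' are dropped with a warning. The centering/scaling vectors are returned
#' so new samples can be projected into the model space.
#'
#' @param ft a `feature_table` (study rows are used)
#' @param mode `"unit_variance"` (default), `"pareto"` or `"none"`
#' @return list with `X` (scaled study matrix), `center`, `scale`,
#'   `dropped` (zero-variance feature ids) and `feature_ids`
#' @export
scale_for_model <- function(ft, mode = c("unit_variance", "pareto", "none")) {
  mode <- match.arg(mode)
  si <- study_idx(ft)
  X <- ft$intensities[si, , drop = FALSE]
  ctr <- colMeans(X, na.rm = TRUE)
  sds <- apply(X, 2L, stats::sd, na.rm = TRUE)
  zero <- !is.na(sds) & sds == 0
  if (any(zero)) {
    warnf("dropping %d zero-variance feature(s)", sum(zero))
    X <- X[, !zero, drop = FALSE]; ctr <- ctr[!zero]; sds <- sds[!zero]
  }
  scl <- switch(mode, unit_variance = sds, pareto = sqrt(sds),
                none = rep(1, length(sds)))
  Xs <- sweep(sweep(X, 2L, ctr, "-"), 2L, scl, "/")
  list(X = Xs, center = ctr, scale = scl, mode = mode,
       dropped = names(zero)[zero], feature_ids = colnames(Xs))
}

#' Project samples with stored centering/scaling vectors
#'
#' @param x matrix (samples x features) on the original intensity scale
#' @param scaling the list returned by [scale_for_model()]
#' @return the scaled matrix
#' @export
apply_scaling <- function(x, scaling) {
  x <- x[, scaling$feature_ids, drop = FALSE]
  sweep(sweep(x, 2L, scaling$center, "-"), 2L, scaling$scale, "/")
}

#' Flag multivariate outlier samples by Hotelling's T2
#'
#' PCA on the scaled study rows; each sample's Hotelling T2 over the first
#' `n_components` scores is compared with the F-distribution-based limit at
#' the given quantile. Samples above the limit are flagged, never removed:
#' exclusion is an explicit user decision.
#'
#' @param ft a `feature_table`
#' @param n_components number of PCA components (>= 1)
#' @param limit quantile of the T2 limit (default 0.99)
#' @return a `preprocess_report` with `flagged` ids and per-sample `t2`
#' @export
flag_outliers <- function(ft, n_components = 2L, limit = 0.99) {
  if (n_components < 1L) stopf("n_components must be >= 1")
  si <- study_idx(ft)
  if (length(si) < n_components + 2L)
    stopf("flag_outliers needs >= n_components + 2 study rows")
  sc <- scale_for_model(ft, "unit_variance")
  pca <- fit_pca(sc$X, A = n_components)
  T <- pca$T
  s2 <- apply(T, 2L, stats::var)
  t2 <- rowSums(sweep(T^2, 2L, s2, "/"))
  n <- nrow(T); A <- ncol(T)
  t2_lim <- A * (n - 1) / (n - A) * stats::qf(limit, A, n - A)
  flagged <- ft$sample_meta$sample_id[si][t2 > t2_lim]
  new_report("flag_outliers", ncol(ft$intensities), ncol(ft$intensities),
             list(flagged = flagged,
                  t2 = stats::setNames(t2, ft$sample_meta$sample_id[si]),
                  t2_limit = t2_lim, n_components = A, quantile = limit))
}

#' Run the full preprocessing chain
#'
#' Applies, per assay (metabolomics and lipidomics columns separately,
#' since their QC/blank series come from different runs): blank-feature
#' removal, LOESS drift correction, QC-CV filtering and PQN; the assays are
#' then rejoined on sample_id. The step order is fixed.
#'
#' @param ft a `feature_table`
#' @param config an `analysis_config`
#' @return list with the processed `table` and `reports` (list of
#'   `preprocess_report`, named by assay and step)
#' @export
preprocess_table <- function(ft, config = analysis_config()) {
  reports <- list()
  parts <- list()
  for (a in intersect(ASSAYS, unique(ft$feature_meta$assay))) {
    sub <- subset_table(ft, features = which(ft$feature_meta$assay == a))
    st1 <- remove_blank_features(sub, config$blank_ratio)
    st2 <- drift_correct(st1$table, config$loess_span)
    st3 <- cv_filter(st2$table, config$cv_cutoff)
    st4 <- pqn_normalize(st3$table)
    reports[[paste0(a, ".remove_blank_features")]] <- st1$report
    reports[[paste0(a, ".drift_correct")]] <- st2$report
    reports[[paste0(a, ".cv_filter")]] <- st3$report
    reports[[paste0(a, ".pqn_normalize")]] <- st4$report
    parts[[a]] <- st4$table
  }
  if (!length(parts)) stopf("table has no recognised assay")
  joined <- parts[[1L]]
  if (length(parts) > 1L) {
    for (k in 2L:length(parts)) {
      other <- parts[[k]]
      stopifnot(identical(joined$sample_meta$sample_id, other$sample_meta$sample_id))
      joined <- feature_table(cbind(joined$intensities, other$intensities),
                              joined$sample_meta,
                              rbind(joined$feature_meta, other$feature_meta))
    }
  }
  reports[["flag_outliers"]] <- flag_outliers(joined)
  list(table = joined, reports = reports)
}
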