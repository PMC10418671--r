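# Feature-level statistics: signed fold changes, univariate tests,
# Benjamini-Yekutieli FDR, VIP-and-significance selection, and signature
# (Venn) comparison across subgroup analyses.

#' Signed fold change of group means
#'
#' `r = mean(case)/mean(control)`; reported as `r` when `r >= 1` and as
#' `-1/r` otherwise, so a 12% decrease prints as -1.12 and the magnitude is
#' always >= 1.
#'
#' @param case positive intensities of the case group
#' @param control positive intensities of the control group
#' @return signed fold change (scalar)
#' @export
signed_fold_change <- function(case, control) {
  mc <- mean(case, na.rm = TRUE); m0 <- mean(control, na.rm = TRUE)
  if (!is.finite(mc) || !is.finite(m0) || mc <= 0 || m0 <= 0)
    stopf("signed_fold_change needs positive group means")
  r <- mc / m0
  if (r >= 1) r else -1 / r
}

#' Two-sided univariate group test
#'
#' Welch t, Student t, paired t (requires complete pairs matched by
#' `pair_case`/`pair_control`) or Mann-Whitney (normal approximation under
#' ties).
#'
#' @param case,control numeric vectors (>= 2 values each)
#' @param method one of `"welch_t"`, `"student_t"`, `"paired_t"`,
#'   `"mann_whitney"`
#' @param pair_case,pair_control pair identifiers, required for `paired_t`
#' @return list with `statistic`, `p_value`, `method`
#' @export
univariate_test <- function(case, control,
                            method = c("welch_t", "student_t", "paired_t",
                                       "mann_whitney"),
                            pair_case = NULL, pair_control = NULL) {
  method <- match.arg(method)
  if (length(case) < 2L || length(control) < 2L)
    stopf("univariate_test needs >= 2 values per group")
  res <- switch(method,
    welch_t = stats::t.test(case, control, var.equal = FALSE),
    student_t = stats::t.test(case, control, var.equal = TRUE),
    paired_t = {
      if (is.null(pair_case) || is.null(pair_control))
        stopf("paired_t requires pair ids for both groups")
      m <- match(pair_control, pair_case)
      missing_pairs <- unique(c(pair_control[is.na(m)],
                                setdiff(pair_case, pair_control)))
      if (length(missing_pairs))
        stopf("incomplete pairs for paired_t: %s",
              paste(utils::head(missing_pairs, 10L), collapse = ", "))
      stats::t.test(case[m], control, paired = TRUE)
    },
    mann_whitney = suppressWarnings(
      stats::wilcox.test(case, control, exact = FALSE, correct = TRUE)))
  list(statistic = unname(res$statistic), p_value = res$p.value, method = method)
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Yekutieli by default: the step-up rule with the harmonic
#' inflation `c(m) = sum(1/i)`, valid under arbitrary dependence between
#' the tests. Input order is preserved on return.
#'
#' @param p numeric vector of p-values in `[0, 1]`
#' @param method `"BY"` (default) or `"BH"`
#' @return vector of adjusted q-values, capped at 1
#' @export
adjust_by <- function(p, method = c("BY", "BH")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1] with no NA")
  stats::p.adjust(p, method = method)
}

#' Select features by VIP and univariate significance
#'
#' Runs the univariate test and signed fold change per feature on the
#' normalized study intensities (log-transformed for the t-tests so the
#' signed-FC convention is symmetric), attaches B-Y q-values, and selects
#' features with `VIP > vip_threshold` and (q if `use_adjusted`, else raw
#' p) `< alpha`. Records are sorted by VIP, descending.
#'
#' @param ft a preprocessed `feature_table`
#' @param vips named per-feature VIP vector (e.g. from a flat PLS-DA)
#' @param vip_threshold VIP cutoff (default 1.0)
#' @param alpha significance level (default 0.05)
#' @param use_adjusted select on B-Y q instead of raw p (default FALSE,
#'   matching feature-level reporting conventions; block-level claims use
#'   adjusted values)
#' @param method univariate test, see [univariate_test()]
#' @param case_level group label treated as "case"; defaults to the second
#'   factor level
#' @return list with `signature` (a `signature` object) and `records`
#'   (data.frame: feature_id, annotation, VIP, fold_change, p, q,
#'   direction, selected)
#' @export
select_features <- function(ft, vips, vip_threshold = 1.0, alpha = 0.05,
                            use_adjusted = FALSE, method = "welch_t",
                            case_level = NULL) {
  si <- study_idx(ft)
  grp <- factor(ft$sample_meta$group[si])
  if (is.null(case_level)) case_level <- levels(grp)[2L]
  ctl_level <- setdiff(levels(grp), case_level)
  ids <- intersect(names(vips), ft$feature_meta$feature_id)
  if (!length(ids)) stopf("no overlap between VIP names and table features")
  X <- ft$intensities[si, ids, drop = FALSE]
  is_case <- grp == case_level
  logx <- log(X)
  out <- lapply(ids, function(fid) {
    xc <- X[is_case, fid]; x0 <- X[!is_case, fid]
    fc <- signed_fold_change(xc, x0)
    ut <- univariate_test(logx[is_case, fid], logx[!is_case, fid], method)
    c(fc = fc, p = ut$p_value)
  })
  fc <- vapply(out, `[[`, numeric(1), "fc")
  p <- vapply(out, `[[`, numeric(1), "p")
  q <- adjust_by(p, "BY")
  crit <- if (use_adjusted) q else p
  rec <- data.frame(feature_id = ids,
                    annotation = ft$feature_meta$annotation[
                      match(ids, ft$feature_meta$feature_id)],
                    VIP = as.numeric(vips[ids]), fold_change = fc,
                    p = p, q = q,
                    direction = ifelse(fc >= 1, "up", "down"),
                    selected = as.numeric(vips[ids]) > vip_threshold & crit < alpha,
                    stringsAsFactors = FALSE)
  rec <- rec[order(-rec$VIP), ]
  rownames(rec) <- NULL
  list(signature = signature_set(paste(case_level, "vs", ctl_level),
                                 rec$feature_id[rec$selected]),
       records = rec)
}

#' Construct a named feature signature
#' @param name signature label (e.g. a subgroup comparison)
#' @param ids character vector of selected feature ids (may be empty)
#' @return a `signature` object
#' @export
signature_set <- function(name, ids) {
  if (is.null(name) || is.na(name) || !nzchar(name)) stopf("signature needs a name")
  structure(list(name = name, ids = unique(as.character(ids))),
            class = "signature")
}

#' Compare 2-4 signatures (Venn regions)
#'
#' Enumerates every intersection region (which signatures contain a
#' feature, which do not) with counts and member ids. Region counts sum to
#' the size of the union.
#'
#' @param signatures list of 2-4 `signature` objects
#' @return data.frame with one row per region: the membership pattern
#'   (one logical column per signature), `count`, and comma-separated `ids`
#' @export
compare_signatures <- function(signatures) {
  if (length(signatures) < 2L || length(signatures) > 4L)
    stopf("compare_signatures takes 2-4 signatures (use the membership table beyond 4)")
  nms <- vapply(signatures, function(s) s$name, character(1))
  if (anyDuplicated(nms)) stopf("signature names must be unique")
  sets <- lapply(signatures, function(s) s$ids)
  univ <- unique(unlist(sets))
  memb <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 1L) memb <- matrix(memb, nrow = 1L)
  colnames(memb) <- nms
  patt <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  names(patt) <- nms
  patt <- patt[rowSums(patt) > 0L, , drop = FALSE]
  rows <- lapply(seq_len(nrow(patt)), function(i) {
    want <- as.logical(patt[i, ])
    inreg <- apply(memb, 1L, function(r) all(r == want))
    ids <- univ[inreg]
    cbind(patt[i, , drop = FALSE],
          data.frame(count = length(ids),
                     ids = paste(sort(ids), collapse = ","),
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
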