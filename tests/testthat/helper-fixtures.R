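# Fixtures are built in code; nothing is read from disk.

# Small hand-made table: 6 study (3 vs 3), 4 QC, 1 blank, 4 features.
make_tiny_table <- function() {
  sm <- data.frame(
    sample_id = c("S1", "S2", "S3", "S4", "S5", "S6", "Q1", "Q2", "Q3", "Q4", "B1"),
    role = c(rep("study", 6), rep("qc", 4), "blank"),
    injection_order = 1:11,
    group = c(rep("control", 3), rep("case", 3), rep(NA, 5)),
    stringsAsFactors = FALSE)
  set.seed(99)
  x <- matrix(stats::runif(11 * 4, 50, 150), 11, 4)
  x[11, ] <- c(1, 2, 1, 2)  # blank near zero
  fm <- data.frame(
    feature_id = c("f1", "f2", "f3", "f4"),
    assay = c("metabolomics", "metabolomics", "lipidomics", "lipidomics"),
    annotation = c("alanine", "tryptophan", "PC 34:1", "SM d18:1"),
    stringsAsFactors = FALSE)
  feature_table(x, sm, fm)
}

# Random valid table of arbitrary size, deterministic given seed.
random_table <- function(n_study = 10, n_qc = 4, n_blank = 1, p = 6,
                         seed = 1, missing_rate = 0) {
  set.seed(seed)
  n <- n_study + n_qc + n_blank
  sm <- data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    role = c(rep("study", n_study), rep("qc", n_qc), rep("blank", n_blank)),
    injection_order = sample(n),
    group = c(rep(c("control", "case"), length.out = n_study),
              rep(NA, n_qc + n_blank)),
    stringsAsFactors = FALSE)
  x <- matrix(stats::rlnorm(n * p, meanlog = 5), n, p)
  if (missing_rate > 0) x[stats::runif(length(x)) < missing_rate] <- NA
  fm <- data.frame(
    feature_id = sprintf("f%02d", seq_len(p)),
    assay = rep(c("metabolomics", "lipidomics"), length.out = p),
    annotation = sprintf("compound %02d", seq_len(p)),
    stringsAsFactors = FALSE)
  feature_table(x, sm, fm)
}

# Reduced synthetic cohort for fast tests.
small_spec <- function(seed = 1, ...) {
  args <- list(n_per_group = 30L, n_metabolite_features = 40L,
               n_lipid_features = 30L, n_functional_blocks = 8L,
               n_lipid_clusters_true = 4L, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_spec, args)
}
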