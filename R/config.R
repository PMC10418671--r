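# Analysis configuration: the tunable settings shared by all stages.

config_defaults <- function() {
  list(
    cv_cutoff = 0.30,          # QC coefficient-of-variation filter, strict "<"
    blank_ratio = 3.0,         # QC-mean / blank-mean signal requirement
    loess_span = 0.75,         # span of the QC drift LOESS
    n_folds = 7L,              # cross-validation folds
    n_permutations = 200L,     # label permutations for model validation
    vip_threshold = 1.0,       # VIP > threshold for selection
    alpha = 0.05,              # significance level
    network_p_threshold = 0.25,# edge p cutoff of the initial network
    n_lipid_clusters = 11L,    # Ward clusters for lipid blocking
    seed = 1L
  )
}

#' Build an analysis configuration
#'
#' All arguments default to the pipeline's standard settings: CV filter at
#' 30%, blank ratio 3, 7-fold cross-validation, 200 permutations,
#' VIP threshold 1.0, alpha 0.05, network edge p-threshold 0.25 and
#' 11 lipid clusters.
#'
#' @param ... named overrides of the defaults listed above
#' @return a validated `analysis_config` (a named list)
#' @export
analysis_config <- function(...) {
  cfg <- config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_config <- function(cfg) {
  frac01 <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v > 1)
      stopf("config key '%s' must be a fraction in (0, 1], got %s", key,
            paste(cfg[[key]], collapse = ","))
  }
  count1 <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 || v != round(v))
      stopf("config key '%s' must be an integer >= 1, got %s", key,
            paste(cfg[[key]], collapse = ","))
  }
  for (k in c("cv_cutoff", "loess_span", "alpha", "network_p_threshold")) frac01(k)
  for (k in c("n_folds", "n_permutations", "n_lipid_clusters")) count1(k)
  if (!is.numeric(cfg$blank_ratio) || cfg$blank_ratio <= 0)
    stopf("config key 'blank_ratio' must be > 0")
  if (!is.numeric(cfg$vip_threshold) || cfg$vip_threshold < 0)
    stopf("config key 'vip_threshold' must be >= 0")
  invisible(cfg)
}

#' Load an analysis configuration from a YAML file
#'
#' Keys absent from the file take their defaults; unknown or out-of-range
#' keys raise an error naming the key. An empty file yields the full
#' default configuration.
#'
#' @param path path to a YAML key/value file
#' @return an `analysis_config`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(analysis_config, vals)
}

#' Write a resolved configuration to YAML
#'
#' @param cfg an `analysis_config`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
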