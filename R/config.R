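#' Pipeline configuration
#'
#' Bundles every threshold used across the pipeline. The defaults are the
#' method's published operating point: a 17-of-20 spaced k-mer seed match
#' followed by a 55-of-100 confirmation window, 10 kb candidate target
#' windows, consensus clusters kept only above an average depth of 250 reads,
#' a 1% sequencing-error model for ambiguity calls, a 50% reliable-site
#' threshold, a 14-base misalignment masking run, 25 sequences required per
#' retained site, removal of loci represented by less than 50% of the panel,
#' probe tiling at 3.5x coverage depth, and a 98% barcode identity
#' assignment threshold.
#'
#' @param ... Named overrides of any configuration field.
#' @return A `pipeline_config` object (named list).
#' @examples
#' cfg <- pipeline_config(tiling_density = 2)
#' cfg$seed_min_matches
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed_window = 20L,
    seed_min_matches = 17L,
    confirm_window = 100L,
    confirm_min_matches = 55L,
    target_window = 10000L,
    kmer_k = 20L,
    min_avg_depth = 250,
    error_rate = 0.01,
    alpha = 0.05,
    reliable_site_threshold = 0.5,
    mask_run_length = 14L,
    min_sequences_per_site = 25L,
    min_locus_fraction = 0.5,
    tiling_density = 3.5,
    probe_length = 120L,
    identity_assign_threshold = 0.98,
    cluster_linkage = "average",
    cluster_cutoff = 0.995,
    elevation_factor = 5,
    min_overlap = 12L,
    max_mismatch_rate = 0.1,
    ambiguity_margin = 5L,
    min_extension_depth = 3L,
    confirm_mode = "aligned",
    rng_seed = 1L
  )
  overrides <- list(...)
  if (length(overrides) == 1 && is.list(overrides[[1]]) && is.null(names(overrides))) {
    overrides <- overrides[[1]]
  }
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration key(s): ", paste(unknown, collapse = ", ")))
  }
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  num_fields <- c(
    "seed_window", "seed_min_matches", "confirm_window", "confirm_min_matches",
    "target_window", "kmer_k", "min_avg_depth", "error_rate", "alpha",
    "reliable_site_threshold", "mask_run_length", "min_sequences_per_site",
    "min_locus_fraction", "tiling_density", "probe_length",
    "identity_assign_threshold", "cluster_cutoff", "elevation_factor",
    "min_overlap", "max_mismatch_rate"
  )
  for (nm in num_fields) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) {
      abort(paste0("configuration field '", nm, "' must be a single number"))
    }
    if (v <= 0) abort(paste0("configuration field '", nm, "' must be positive"))
  }
  if (cfg$seed_min_matches > cfg$seed_window) {
    abort("seed_min_matches must not exceed seed_window")
  }
  if (cfg$confirm_min_matches > cfg$confirm_window) {
    abort("confirm_min_matches must not exceed confirm_window")
  }
  for (nm in c("error_rate", "alpha", "reliable_site_threshold",
               "min_locus_fraction", "identity_assign_threshold",
               "max_mismatch_rate")) {
    if (cfg[[nm]] > 1) abort(paste0("configuration field '", nm, "' must be <= 1"))
  }
  if (!cfg$confirm_mode %in% c("aligned", "consecutive")) {
    abort("confirm_mode must be 'aligned' or 'consecutive'")
  }
  if (!cfg$cluster_linkage %in% c("single", "average")) {
    abort("cluster_linkage must be 'single' or 'average'")
  }
  invisible(cfg)
}

#' Load a configuration file
#'
#' Reads a flat key-value YAML file; any key not present takes its default
#' (see [pipeline_config()]). Unknown keys and non-numeric thresholds are
#' errors so a typo cannot silently fall back to a default.
#'
#' @param path Path to a YAML config file, or `NULL` for all defaults.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(pipeline_config())
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# resolve a config argument: NULL -> defaults, list -> coerced
as_config <- function(config) {
  if (is.null(config)) return(pipeline_config())
  if (inherits(config, "pipeline_config")) return(config)
  do.call(pipeline_config, as.list(config))
}
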