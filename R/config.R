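## Pipeline configuration: a YAML key-value file with defaults, range
## validation and aggregated error reporting.

config_defaults <- function() {
  list(adapter = "TCGTATGCCGTCTTCTGCTTG", min_len = 18L, min_overlap = 6L,
       max_mismatch_frac = 0.1, keep_untrimmed = TRUE,
       max_mismatch_db = 2L, max_mismatch_mirna = 1L,
       alpha = 0.05, correction = "bh",
       identity_min = 0.9, coverage_min = 50L, min_reads = 10L,
       seed = 1L, db_fasta = NULL)
}

CONFIG_KEYS <- c("species", "reads", "genome_fasta", "maf", "precursor_fasta",
                 "arms_bed", "db_fasta", "adapter", "min_len", "min_overlap",
                 "max_mismatch_frac", "keep_untrimmed", "max_mismatch_db",
                 "max_mismatch_mirna", "alpha", "correction", "identity_min",
                 "coverage_min", "min_reads", "seed")

#' Load and validate a pipeline configuration file
#'
#' Reads a YAML configuration, fills defaults, resolves input paths relative
#' to the configuration file, and validates keys, ranges and path existence.
#' All validation errors are aggregated and reported together.
#'
#' @param path Configuration file (YAML).
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  errs <- character(0)
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown))
    errs <- c(errs, sprintf("unknown key(s): %s", paste(unknown, collapse = ", ")))
  cfg <- config_defaults()
  cfg[names(raw)] <- raw

  required <- c("species", "reads", "genome_fasta", "maf", "precursor_fasta", "arms_bed")
  missing <- required[!required %in% names(raw)]
  if (length(missing))
    errs <- c(errs, sprintf("missing required key(s): %s", paste(missing, collapse = ", ")))

  rng <- function(key, lo, hi) {
    v <- cfg[[key]]
    if (!is.null(v) && (!is.numeric(v) || v < lo || v > hi))
      errs <<- c(errs, sprintf("%s = %s out of range [%s, %s]", key,
                               format(v), format(lo), format(hi)))
  }
  rng("max_mismatch_db", 0, 3); rng("max_mismatch_mirna", 0, 3)
  rng("alpha", 1e-12, 1); rng("identity_min", 0, 1)
  rng("max_mismatch_frac", 0, 1); rng("min_len", 1, Inf)
  rng("min_overlap", 4, Inf); rng("coverage_min", 0, Inf); rng("min_reads", 0, Inf)
  if (!cfg$correction %in% c("bh", "none"))
    errs <- c(errs, sprintf("correction = '%s' (must be 'bh' or 'none')", cfg$correction))
  if (length(missing) == 0L) {
    if (length(cfg$species) < 2L)
      errs <- c(errs, "species must list at least 2 species")
    if (is.null(names(cfg$reads)) || !all(cfg$species %in% names(cfg$reads)))
      errs <- c(errs, "reads must be a mapping with one path per species")
  }

  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(startsWith(p, "/"), p, file.path(base, p))
  }
  for (key in c("genome_fasta", "maf", "precursor_fasta", "arms_bed", "db_fasta")) {
    if (!is.null(cfg[[key]])) {
      cfg[[key]] <- resolve(cfg[[key]])
      if (!file.exists(cfg[[key]]))
        errs <- c(errs, sprintf("%s: file not found: %s", key, cfg[[key]]))
    }
  }
  if (is.list(cfg$reads)) {
    for (sp in names(cfg$reads)) {
      cfg$reads[[sp]] <- resolve(cfg$reads[[sp]])
      if (!file.exists(cfg$reads[[sp]]))
        errs <- c(errs, sprintf("reads[%s]: file not found: %s", sp, cfg$reads[[sp]]))
    }
  }
  if (length(errs))
    stopf("invalid configuration %s:\n  - %s", path, paste(errs, collapse = "\n  - "))
  structure(cfg, class = "run_config")
}
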