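## Hierarchical annotation filtering and known-miRNA expression profiling.
## Reads are first removed if they hit an annotation database (rRNA, sc/sn/
## snoRNA, tRNA, coding regions) within the configured mismatch bound, then
## the survivors are profiled over known hairpin precursors with per-arm
## (5p/3p) assignment; reads hitting no precursor are exported for external
## novel-miRNA prediction.

#' Filtering and profiling configuration
#'
#' @param max_mismatch_db Mismatch bound for the annotation-database filter
#'   (0-3; the classic pipelines call this $MIS, default 2).
#' @param max_mismatch_mirna Mismatch bound for precursor profiling (fixed at
#'   1 in the reference settings).
#' @param sense_only_mirna Profile precursors sense-strand only.
#' @param fractional_counts Split a multi-mapping read's count evenly across
#'   its best-stratum precursors instead of giving the full count to each.
#' @return A `filter_config` list.
#' @export
filter_config <- function(max_mismatch_db = 2L, max_mismatch_mirna = 1L,
                          sense_only_mirna = TRUE, fractional_counts = FALSE) {
  if (max_mismatch_db < 0L || max_mismatch_db > 3L)
    stopf("max_mismatch_db must be in 0..3")
  structure(list(max_mismatch_db = as.integer(max_mismatch_db),
                 max_mismatch_mirna = as.integer(max_mismatch_mirna),
                 sense_only_mirna = isTRUE(sense_only_mirna),
                 fractional_counts = isTRUE(fractional_counts)),
            class = "filter_config")
}

#' Discard reads matching an annotation database
#'
#' A read is discarded iff it has at least one alignment (either strand)
#' to the database within `cfg$max_mismatch_db` mismatches. The partition is
#' exhaustive and disjoint.
#'
#' @param reads A `collapsed_reads` data.frame.
#' @param db Named character vector of annotation sequences (rRNA, tRNA, ...).
#' @param cfg A [filter_config()].
#' @return list(discarded = , retained = ) of `collapsed_reads` subsets.
#' @export
filter_by_db <- function(reads, db, cfg = filter_config()) {
  if (length(db) == 0L) stopf("annotation database is empty")
  index <- build_index(db, k = min(6L, min(nchar(db))))
  hit <- vapply(seq_len(nrow(reads)), function(i) {
    nrow(align(reads$sequence[i], index, max_mismatch = cfg$max_mismatch_db,
               sense_only = FALSE)) > 0L
  }, logical(1L))
  list(discarded = reads[hit, , drop = FALSE],
       retained = reads[!hit, , drop = FALSE])
}

#' Precursor annotations with mature arm intervals
#'
#' Intervals are 0-based half-open on the (ungapped) precursor. The 5p arm
#' must precede the 3p arm when both are present.
#'
#' @param precursor_id,sequence Precursor records.
#' @param arm5_start,arm5_end,arm3_start,arm3_end Arm intervals (NA = absent).
#' @return A `precursor_annotation` data.frame.
#' @export
precursor_annotation <- function(precursor_id, sequence,
                                 arm5_start = NA_integer_, arm5_end = NA_integer_,
                                 arm3_start = NA_integer_, arm3_end = NA_integer_) {
  sequence <- normalize_nt(sequence, "precursor")
  df <- data.frame(precursor_id = as.character(precursor_id), sequence = sequence,
                   arm5_start = as.integer(arm5_start), arm5_end = as.integer(arm5_end),
                   arm3_start = as.integer(arm3_start), arm3_end = as.integer(arm3_end),
                   stringsAsFactors = FALSE)
  n <- nchar(df$sequence)
  for (i in seq_len(nrow(df))) {
    for (arm in c("5", "3")) {
      s <- df[[paste0("arm", arm, "_start")]][i]; e <- df[[paste0("arm", arm, "_end")]][i]
      if (!is.na(s) && (s < 0L || is.na(e) || e <= s || e > n[i]))
        stopf("invalid %sp arm interval for %s", arm, df$precursor_id[i])
    }
    if (!is.na(df$arm5_end[i]) && !is.na(df$arm3_start[i]) &&
        df$arm5_end[i] > df$arm3_start[i])
      stopf("5p arm must precede 3p arm for %s", df$precursor_id[i])
  }
  class(df) <- c("precursor_annotation", "data.frame")
  df
}

#' Read arm intervals from a BED6 file keyed by precursor id
#'
#' BED columns: precursor_id, start, end, arm name ("5p"/"3p"), score, strand.
#'
#' @param precursors data.frame of `id`, `sequence` (as from [read_fasta()]).
#' @param bed_path BED6 path.
#' @return A `precursor_annotation` data.frame.
#' @export
read_arms_bed <- function(precursors, bed_path) {
  bed <- read.table(bed_path, sep = "\t", stringsAsFactors = FALSE,
                    col.names = c("chrom", "start", "end", "name", "score", "strand"))
  ann <- precursor_annotation(precursors$id, precursors$sequence)
  for (i in seq_len(nrow(bed))) {
    j <- match(bed$chrom[i], ann$precursor_id)
    if (is.na(j)) stopf("%s: arm interval for unknown precursor '%s'", bed_path, bed$chrom[i])
    arm <- if (grepl("5p", bed$name[i])) "5" else if (grepl("3p", bed$name[i])) "3" else
      stopf("%s: arm name '%s' is neither 5p nor 3p", bed_path, bed$name[i])
    ann[[paste0("arm", arm, "_start")]][j] <- bed$start[i]
    ann[[paste0("arm", arm, "_end")]][j] <- bed$end[i]
  }
  precursor_annotation(ann$precursor_id, ann$sequence, ann$arm5_start,
                       ann$arm5_end, ann$arm3_start, ann$arm3_end)
}

## Assign a read placement [start, start+len) to an arm. >= 50% of the read
## must overlap the arm interval; if both arms qualify (an exact straddle),
## the larger overlap wins, ties to 5p.
assign_arm <- function(start, len, ann_row) {
  ov <- function(s, e) {
    if (is.na(s)) return(0L)
    max(0L, min(start + len, e) - max(start, s))
  }
  o5 <- ov(ann_row$arm5_start, ann_row$arm5_end)
  o3 <- ov(ann_row$arm3_start, ann_row$arm3_end)
  half <- len / 2
  if (o5 >= half && o5 >= o3) "5p" else if (o3 >= half) "3p" else "unassigned"
}

#' Profile expression over known miRNA precursors
#'
#' Reads are aligned to precursors (sense-only, best stratum, at most
#' `cfg$max_mismatch_mirna` mismatches). Each aligning read contributes its
#' collapsed count to each best-stratum precursor (or an even fraction with
#' `cfg$fractional_counts`). A read is assigned to the 5p (3p) arm when at
#' least half of it overlaps that arm interval, otherwise it is unassigned
#' (e.g. loop-spanning reads).
#'
#' @param reads A `collapsed_reads` data.frame.
#' @param annots A `precursor_annotation` data.frame.
#' @param cfg A [filter_config()].
#' @return list(expression = per-precursor record table with `total_count`,
#'   `count_5p`, `count_3p`, `unassigned_count`; leftover = reads hitting no
#'   precursor, input for external novel-miRNA prediction).
#' @export
profile_known <- function(reads, annots, cfg = filter_config()) {
  stopifnot(inherits(annots, "precursor_annotation"))
  index <- build_index(setNames(annots$sequence, annots$precursor_id))
  expr <- data.frame(precursor_id = annots$precursor_id,
                     total_count = 0, count_5p = 0, count_3p = 0,
                     unassigned_count = 0, stringsAsFactors = FALSE)
  matched <- logical(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    hits <- align(reads$sequence[i], index,
                  max_mismatch = cfg$max_mismatch_mirna,
                  sense_only = cfg$sense_only_mirna,
                  query_id = reads$tag_id[i])
    if (nrow(hits) == 0L) next
    matched[i] <- TRUE
    w <- if (cfg$fractional_counts) reads$count[i] / nrow(hits) else reads$count[i]
    len <- nchar(reads$sequence[i])
    for (h in seq_len(nrow(hits))) {
      j <- match(hits$target_id[h], expr$precursor_id)
      expr$total_count[j] <- expr$total_count[j] + w
      arm <- assign_arm(hits$start[h], len, annots[j, ])
      col <- switch(arm, "5p" = "count_5p", "3p" = "count_3p", "unassigned_count")
      expr[[col]][j] <- expr[[col]][j] + w
    }
  }
  list(expression = expr, leftover = reads[!matched, , drop = FALSE])
}
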