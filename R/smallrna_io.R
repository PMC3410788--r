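## Small-RNA sequencing I/O: adapter trimming, read collapsing, FASTA/FASTQ
## readers and the collapsed-FASTA dialect (">lib_rank_xCOUNT").

#' Trim the 3' sequencing adapter from a small-RNA read
#'
#' Searches for the leftmost position where a suffix of the read matches a
#' prefix of the adapter with at least `min_overlap` aligned bases and a
#' mismatch fraction of at most `max_mismatch_frac`. Full internal adapter
#' occurrences also trigger trimming. The read prefix before the match (the
#' "insert") is returned; inserts shorter than `min_len` are discarded.
#'
#' @param sequence Read sequence(s), ACGTUN alphabet (U is normalized to T).
#' @param adapter 3' adapter sequence.
#' @param min_overlap Minimum suffix/prefix overlap to call a match (>= 4).
#' @param min_len Minimum insert length; shorter inserts are discarded.
#' @param max_mismatch_frac Maximum fraction of mismatching bases in the
#'   overlap.
#' @return A data.frame with columns `sequence` (trimmed insert, or original
#'   read when untrimmed) and `status` (`"trimmed"`, `"untrimmed"` or
#'   `"discarded"`).
#' @examples
#' trim_adapter("ACGTACGTTCGTATGCCGTCTTCTGCTTG", "TCGTATGCCGTCTTCTGCTTG",
#'              min_len = 8)
#' @export
trim_adapter <- function(sequence, adapter, min_overlap = 6L, min_len = 18L,
                         max_mismatch_frac = 0.1) {
  if (length(adapter) != 1L || !nzchar(adapter)) stopf("adapter must be a non-empty string")
  adapter <- normalize_nt(adapter, "adapter")
  if (min_overlap < 4L) stopf("min_overlap must be >= 4")
  if (nchar(adapter) < min_overlap) stopf("adapter shorter than min_overlap")
  sequence <- normalize_nt(sequence, "read")
  ac <- strsplit(adapter, "")[[1L]]
  alen <- length(ac)

  trim_one <- function(s) {
    sc <- strsplit(s, "")[[1L]]
    n <- length(sc)
    for (pos in seq_len(n)) {
      ov <- min(alen, n - pos + 1L)
      if (ov < min_overlap) break
      mm <- sum(sc[pos:(pos + ov - 1L)] != ac[seq_len(ov)])
      if (mm / ov <= max_mismatch_frac) {
        insert <- if (pos == 1L) "" else substr(s, 1L, pos - 1L)
        if (nchar(insert) < min_len) return(c(insert, "discarded"))
        return(c(insert, "trimmed"))
      }
    }
    c(s, "untrimmed")
  }
  out <- t(vapply(sequence, trim_one, character(2L), USE.NAMES = FALSE))
  data.frame(sequence = out[, 1L], status = out[, 2L], stringsAsFactors = FALSE)
}

#' Collapse identical reads into unique tags with counts
#'
#' Identical sequences are merged into one record carrying the multiplicity.
#' Records are ranked by count (descending), ties broken lexicographically by
#' sequence, and tagged `"<lib_label>_<rank>_x<count>"`.
#'
#' @param sequences Character vector of read sequences (already trimmed).
#' @param lib_label Library label used as the tag prefix.
#' @return A `collapsed_reads` data.frame with columns `tag_id`, `sequence`,
#'   `count`.
#' @examples
#' collapse_reads(c("ACGT", "ACGT", "TTTT"), "lib")
#' @export
collapse_reads <- function(sequences, lib_label = "lib") {
  if (length(sequences) == 0L) {
    return(collapsed_reads(character(), character(), integer()))
  }
  sequences <- normalize_nt(sequences, "read")
  tab <- table(sequences)
  cnt <- as.integer(tab)
  sq <- names(tab)
  ord <- order(-cnt, sq)
  sq <- sq[ord]; cnt <- cnt[ord]
  collapsed_reads(sprintf("%s_%d_x%d", lib_label, seq_along(sq), cnt), sq, cnt)
}

collapsed_reads <- function(tag_id, sequence, count) {
  df <- data.frame(tag_id = as.character(tag_id), sequence = as.character(sequence),
                   count = as.integer(count), stringsAsFactors = FALSE)
  class(df) <- c("collapsed_reads", "data.frame")
  df
}

#' @export
print.collapsed_reads <- function(x, ...) {
  cat(sprintf("collapsed_reads: %d unique sequences, %d reads total\n",
              nrow(x), sum(x$count)))
  print.data.frame(head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

## ---- FASTA / FASTQ ---------------------------------------------------------

validate_fasta_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) stopf("%s: empty FASTA file", path)
  if (!startsWith(lines[nonempty[1L]], ">"))
    stopf("%s: malformed FASTA at line %d (expected '>')", path, nonempty[1L])
  invisible(lines)
}

#' Read a FASTA file
#'
#' @param path FASTA file path.
#' @return A data.frame with columns `id` (first word of header) and
#'   `sequence` (uppercase, U normalized to T).
#' @export
read_fasta <- function(path) {
  validate_fasta_lines(path)
  x <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(x))
  data.frame(id = ids, sequence = normalize_nt(as.character(x), path),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write sequences as FASTA
#'
#' @param ids Record identifiers.
#' @param sequences Sequences (one per id).
#' @param path Output path.
#' @param rna Render T as U (RNA convention) on output.
#' @export
write_fasta <- function(ids, sequences, path, rna = FALSE) {
  if (length(ids) != length(sequences)) stopf("ids and sequences differ in length")
  if (rna) sequences <- as_rna(sequences)
  x <- Biostrings::BStringSet(setNames(sequences, ids))
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Read a FASTQ file (qualities ignored)
#'
#' @param path FASTQ file path.
#' @return A data.frame with columns `id` and `sequence`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 4L != 0L)
    stopf("%s: malformed FASTQ, %d lines is not a multiple of 4 (near line %d)",
          path, length(lines), length(lines))
  rec1 <- seq(1L, length(lines), by = 4L)
  bad <- rec1[!startsWith(lines[rec1], "@")]
  if (length(bad)) stopf("%s: malformed FASTQ record at line %d (expected '@')", path, bad[1L])
  plus <- rec1 + 2L
  badp <- plus[!startsWith(lines[plus], "+")]
  if (length(badp)) stopf("%s: malformed FASTQ record at line %d (expected '+')", path, badp[1L])
  data.frame(id = sub("\\s.*$", "", sub("^@", "", lines[rec1])),
             sequence = normalize_nt(lines[rec1 + 1L], path),
             stringsAsFactors = FALSE)
}

#' Write reads as FASTQ with constant quality
#'
#' @param ids,sequences Records to write.
#' @param path Output path.
#' @param quality_char Constant per-base quality character.
#' @export
write_fastq <- function(ids, sequences, path, quality_char = "I") {
  quals <- vapply(nchar(sequences), function(n) strrep(quality_char, n), character(1L))
  writeLines(as.vector(rbind(paste0("@", ids), sequences, "+", quals)), path)
  invisible(path)
}

#' Write collapsed reads in the collapsed-FASTA dialect
#'
#' Headers follow `">lib_rank_xCOUNT"` so counts survive a round trip.
#'
#' @param reads A `collapsed_reads` data.frame.
#' @param path Output path.
#' @export
write_collapsed_fasta <- function(reads, path) {
  write_fasta(reads$tag_id, reads$sequence, path)
}

#' Read collapsed-FASTA (counts encoded in headers)
#'
#' @param path Collapsed-FASTA file with `_x<count>` header suffixes.
#' @return A `collapsed_reads` data.frame.
#' @export
read_collapsed_fasta <- function(path) {
  fa <- read_fasta(path)
  m <- regmatches(fa$id, regexpr("_x(\\d+)$", fa$id))
  if (length(m) != nrow(fa) || any(!nzchar(m)))
    stopf("%s: header without _x<count> suffix (not collapsed-FASTA)", path)
  collapsed_reads(fa$id, fa$sequence, as.integer(sub("_x", "", m)))
}

#' Preprocess a raw small-RNA library: trim, filter, collapse
#'
#' @param sequences Raw read sequences.
#' @param adapter 3' adapter.
#' @param lib_label Library label for collapsed tag ids.
#' @param keep_untrimmed Keep reads in which no adapter was found.
#' @inheritParams trim_adapter
#' @return A list with `reads` (collapsed_reads) and `stats` (named counts of
#'   trimmed / untrimmed / discarded input reads).
#' @export
preprocess_library <- function(sequences, adapter, lib_label = "lib",
                               min_overlap = 6L, min_len = 18L,
                               max_mismatch_frac = 0.1, keep_untrimmed = TRUE) {
  tr <- trim_adapter(sequences, adapter, min_overlap = min_overlap,
                     min_len = min_len, max_mismatch_frac = max_mismatch_frac)
  keep <- tr$status == "trimmed" | (keep_untrimmed & tr$status == "untrimmed")
  list(reads = collapse_reads(tr$sequence[keep], lib_label),
       stats = c(trimmed = sum(tr$status == "trimmed"),
                 untrimmed = sum(tr$status == "untrimmed"),
                 discarded = sum(tr$status == "discarded")))
}
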