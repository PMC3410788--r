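## Mismatch-bounded, exhaustive short-read aligner with best-stratum all-hit
## reporting (the option subset "-v MIS -a --best --strata [--norc]" of the
## classic ungapped aligners, implemented internally so the pipeline is
## self-contained). Seeds are exact k-mers; partitioning a query into
## max_mismatch + 1 disjoint blocks guarantees by pigeonhole that every
## placement within the mismatch bound has at least one exact seed block.

#' Build a k-mer index over a set of target sequences
#'
#' @param targets Named character vector of target sequences (ACGTUN).
#' @param k Seed length (>= 4, at most the shortest target length).
#' @return A `target_index` object holding the targets and a k-mer posting
#'   table mapping each length-k substring to its (target, offset) positions.
#' @export
build_index <- function(targets, k = 6L) {
  if (length(targets) == 0L) stopf("empty target list")
  if (is.null(names(targets)) || any(!nzchar(names(targets))))
    stopf("targets must be named")
  k <- as.integer(k)
  if (k < 4L) stopf("k must be >= 4")
  targets <- normalize_nt(targets, "target")
  lens <- nchar(targets)
  if (k > min(lens)) stopf("k (%d) longer than shortest target (%d nt)", k, min(lens))

  kmer <- character(0); tgt <- integer(0); off <- integer(0)
  for (i in seq_along(targets)) {
    n <- lens[i]
    starts <- seq_len(n - k + 1L)
    kmer <- c(kmer, substring(targets[i], starts, starts + k - 1L))
    tgt <- c(tgt, rep.int(i, length(starts)))
    off <- c(off, starts)
  }
  postings <- split(seq_along(kmer), kmer)
  lookup <- new.env(parent = emptyenv(), size = length(postings))
  for (km in names(postings)) {
    idx <- postings[[km]]
    assign(km, cbind(tgt[idx], off[idx]), envir = lookup)
  }
  structure(list(names = names(targets), seqs = unname(targets),
                 chars = seq_chars(unname(targets)), lens = unname(lens),
                 k = k, lookup = lookup),
            class = "target_index")
}

#' @export
print.target_index <- function(x, ...) {
  cat(sprintf("target_index: %d targets (%d-%d nt), k = %d\n",
              length(x$names), min(x$lens), max(x$lens), x$k))
  invisible(x)
}

## Hamming mismatch counts of a query placed at 1-based offsets on one target.
## N on either side counts as a mismatch.
mismatches_at <- function(tchars, offsets, qchars) {
  L <- length(qchars)
  idx <- outer(offsets - 1L, seq_len(L), "+")
  tm <- matrix(tchars[idx], nrow = length(offsets), ncol = L)
  qm <- matrix(qchars, nrow = length(offsets), ncol = L, byrow = TRUE)
  as.integer(rowSums(tm != qm | tm == "N" | qm == "N"))
}

## All placements of one oriented query sequence within the mismatch bound.
placements_one_strand <- function(qseq, index, max_mismatch) {
  qchars <- strsplit(qseq, "")[[1L]]
  L <- length(qchars)
  k <- index$k
  nblocks <- max_mismatch + 1L
  hits_t <- integer(0); hits_s <- integer(0); hits_m <- integer(0)
  for (ti in seq_along(index$seqs)) {
    n <- index$lens[ti]
    if (n < L) next
    if (L >= nblocks * k) {
      # pigeonhole seeding: one exact k-mer block per potential hit
      bstarts <- as.integer(floor((0:(nblocks - 1L)) * L / nblocks)) + 1L
      cand <- integer(0)
      for (b in bstarts) {
        post <- get0(substr(qseq, b, b + k - 1L), envir = index$lookup)
        if (!is.null(post)) {
          sel <- post[, 1L] == ti
          if (any(sel)) cand <- c(cand, post[sel, 2L] - b + 1L)
        }
      }
      cand <- unique(cand)
      cand <- cand[cand >= 1L & cand + L - 1L <= n]
    } else {
      cand <- seq_len(n - L + 1L)
    }
    if (length(cand) == 0L) next
    mm <- mismatches_at(index$chars[[ti]], cand, qchars)
    ok <- mm <= max_mismatch
    if (any(ok)) {
      hits_t <- c(hits_t, rep.int(ti, sum(ok)))
      hits_s <- c(hits_s, cand[ok])
      hits_m <- c(hits_m, mm[ok])
    }
  }
  list(t = hits_t, s = hits_s, m = hits_m)
}

#' Align one query end-to-end against an index, best stratum, all hits
#'
#' Reports every placement whose mismatch count equals the minimum over all
#' end-to-end placements with at most `max_mismatch` mismatches. Reverse
#' complement placements are considered unless `sense_only`. N counts as a
#' mismatch on either side.
#'
#' @param query Query sequence (>= index k).
#' @param index A `target_index`.
#' @param max_mismatch Maximum mismatches allowed (the stratum bound).
#' @param sense_only Skip reverse-complement placements.
#' @param query_id Identifier to report in the hit table.
#' @return A data.frame of hits: `query_id`, `target_id`, `start` (0-based,
#'   forward strand), `strand`, `mismatches`, ordered by (target_id, start,
#'   strand). Zero rows when nothing places within the bound.
#' @export
align <- function(query, index, max_mismatch = 1L, sense_only = FALSE,
                  query_id = "query") {
  stopifnot(inherits(index, "target_index"))
  query <- normalize_nt(query, "query")
  if (nchar(query) < index$k) stopf("query shorter than index k")
  fw <- placements_one_strand(query, index, max_mismatch)
  strands <- rep.int("+", length(fw$t))
  if (!sense_only) {
    rv <- placements_one_strand(revcomp(query), index, max_mismatch)
    fw$t <- c(fw$t, rv$t); fw$s <- c(fw$s, rv$s); fw$m <- c(fw$m, rv$m)
    strands <- c(strands, rep.int("-", length(rv$t)))
  }
  if (length(fw$t) == 0L) return(empty_hits())
  best <- min(fw$m)
  keep <- fw$m == best
  out <- data.frame(query_id = query_id,
                    target_id = index$names[fw$t[keep]],
                    start = as.integer(fw$s[keep]) - 1L,
                    strand = strands[keep],
                    mismatches = fw$m[keep],
                    stringsAsFactors = FALSE)
  out[order(out$target_id, out$start, out$strand), , drop = FALSE]
}

empty_hits <- function() {
  data.frame(query_id = character(), target_id = character(),
             start = integer(), strand = character(), mismatches = integer(),
             stringsAsFactors = FALSE)
}

#' Align a collapsed read set against an index
#'
#' @param reads A `collapsed_reads` data.frame (or any data.frame with
#'   `tag_id` and `sequence`).
#' @inheritParams align
#' @return One hit table (as [align()]) for all queries combined.
#' @export
align_reads <- function(reads, index, max_mismatch = 1L, sense_only = FALSE) {
  res <- lapply(seq_len(nrow(reads)), function(i) {
    align(reads$sequence[i], index, max_mismatch = max_mismatch,
          sense_only = sense_only, query_id = reads$tag_id[i])
  })
  out <- do.call(rbind, c(list(empty_hits()), res))
  rownames(out) <- NULL
  out
}
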