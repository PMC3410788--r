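## Hairpin secondary structure by weighted base-pair maximization (Nussinov-
## style non-crossing DP; GC = 3, AU = 2, GU = 1, minimum loop 3), bracket
## projection across homolog alignments, per-base read coverage, and a
## configurable hairpin plausibility filter. Thermodynamic nearest-neighbor
## folding is deliberately not reimplemented: the weighted DP gives a
## deterministic, testable stand-in, and an externally computed dot-bracket
## string can be supplied wherever a fold result is consumed.

pair_weight_matrix <- function(chars) {
  w <- c(GC = 3, CG = 3, AT = 2, TA = 2, GT = 1, TG = 1)
  n <- length(chars)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    wij <- w[paste0(chars[i], chars)]
    wij[is.na(wij)] <- 0
    m[i, ] <- wij
  }
  m
}

#' Fold a sequence by weighted base-pair maximization
#'
#' Maximizes the total pair weight (GC = 3, AU = 2, GU wobble = 1) over all
#' non-crossing structures with hairpin loops of at least 3 nt. Traceback is
#' deterministic: pairing the two ends is preferred over leaving an end
#' unpaired, which is preferred over bifurcation (smallest split point).
#'
#' @param sequence Nucleotide sequence (ACGTU).
#' @return A `fold_result`: `sequence`, `dot_bracket`, `score`, `pairs`
#'   (0-based two-column matrix).
#' @examples
#' fold("GGGAAACCC")$dot_bracket # "(((...)))"
#' @export
fold <- function(sequence) {
  seqn <- normalize_nt(sequence, "sequence")
  chars <- strsplit(seqn, "")[[1L]]
  n <- length(chars)
  if (n < 1L) stopf("empty sequence")
  db <- rep(".", n)
  if (n < 5L) {
    return(structure(list(sequence = sequence, dot_bracket = paste(db, collapse = ""),
                          score = 0, pairs = matrix(integer(0), ncol = 2L)),
                     class = "fold_result"))
  }
  W <- pair_weight_matrix(chars)
  M <- matrix(0, n, n)
  for (span in 4:(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- max(M[i + 1L, j], M[i, j - 1L])
      if (W[i, j] > 0) best <- max(best, W[i, j] + M[i + 1L, j - 1L])
      if (j - 2L >= i + 1L) {
        ks <- (i + 1L):(j - 2L)
        best <- max(best, max(M[i, ks] + M[ks + 1L, j]))
      }
      M[i, j] <- best
    }
  }
  pairs <- matrix(integer(0), ncol = 2L)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- ij[1L]; j <- ij[2L]
    if (j - i < 4L || M[i, j] == 0) next
    m <- M[i, j]
    if (W[i, j] > 0 && m == W[i, j] + M[i + 1L, j - 1L]) {
      pairs <- rbind(pairs, c(i, j))
      db[i] <- "("; db[j] <- ")"
      stack[[length(stack) + 1L]] <- c(i + 1L, j - 1L)
    } else if (m == M[i + 1L, j]) {
      stack[[length(stack) + 1L]] <- c(i + 1L, j)
    } else if (m == M[i, j - 1L]) {
      stack[[length(stack) + 1L]] <- c(i, j - 1L)
    } else {
      for (k in (i + 1L):(j - 2L)) {
        if (M[i, k] + M[k + 1L, j] == m) {
          stack[[length(stack) + 1L]] <- c(i, k)
          stack[[length(stack) + 1L]] <- c(k + 1L, j)
          break
        }
      }
    }
  }
  score <- M[1L, n]
  if (nrow(pairs)) pairs <- pairs[order(pairs[, 1L]), , drop = FALSE] - 1L
  structure(list(sequence = sequence, dot_bracket = paste(db, collapse = ""),
                 score = score, pairs = pairs),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(as_rna(x$sequence), "\n", x$dot_bracket, "\n",
      sprintf("score %g, %d pairs\n", x$score, nrow(x$pairs)), sep = "")
  invisible(x)
}

#' Project dot-bracket structures onto a homolog alignment
#'
#' Reinserts `-` at gap columns of each species row so that bracket strings
#' align column-wise with the sequence alignment.
#'
#' @param hs A `homolog_set`.
#' @param folds Named list (by species) of `fold_result` objects or plain
#'   dot-bracket strings computed on the ungapped homolog sequences.
#' @return Named character vector of aligned bracket strings.
#' @export
project_structure <- function(hs, folds) {
  out <- character(0)
  for (sp in names(folds)) {
    db <- folds[[sp]]
    if (inherits(db, "fold_result")) db <- db$dot_bracket
    row <- hs$alignment[[sp]]
    if (is.null(row)) stopf("species '%s' not in homolog set", sp)
    chars <- strsplit(row, "")[[1L]]
    nongap <- chars != "-"
    if (sum(nongap) != nchar(db))
      stopf("structure length %d != ungapped row length %d for '%s'",
            nchar(db), sum(nongap), sp)
    proj <- rep("-", length(chars))
    proj[nongap] <- strsplit(db, "")[[1L]]
    out[sp] <- paste(proj, collapse = "")
  }
  out
}

#' Per-base read coverage over a hairpin precursor
#'
#' @param precursor Precursor sequence (or its length).
#' @param hits Sense-strand hit table for this precursor (as from
#'   [align_reads()], already subset to one target).
#' @param reads The `collapsed_reads` the hits came from (provides counts and
#'   read lengths by `tag_id`).
#' @return Integer vector of per-base coverage (counts summed).
#' @export
hairpin_coverage <- function(precursor, hits, reads) {
  n <- if (is.numeric(precursor)) as.integer(precursor) else nchar(precursor)
  cov <- integer(n)
  if (nrow(hits) == 0L) return(cov)
  idx <- match(hits$query_id, reads$tag_id)
  if (anyNA(idx)) stopf("hit query_id not found in reads")
  for (h in seq_len(nrow(hits))) {
    s <- hits$start[h] + 1L
    e <- min(n, hits$start[h] + nchar(reads$sequence[idx[h]]))
    cov[s:e] <- cov[s:e] + reads$count[idx[h]]
  }
  cov
}

#' Hairpin filter parameter presets
#'
#' The plant preset allows longer precursors and larger loops, reflecting the
#' broader length distribution of plant pre-miRNAs. All values are
#' provisional defaults and fully configurable.
#'
#' @param preset `"animal"` or `"plant"`.
#' @param ... Named overrides of individual thresholds.
#' @return Parameter list: `min_len`, `max_len` (nt), `max_loop_len` (nt),
#'   `min_score_per_nt` (pairing score per base), `min_paired_frac_mature`.
#' @export
hairpin_params <- function(preset = c("animal", "plant"), ...) {
  preset <- match.arg(preset)
  p <- switch(preset,
    animal = list(min_len = 50L, max_len = 150L, max_loop_len = 40L,
                  min_score_per_nt = 0.6, min_paired_frac_mature = 0.6),
    plant = list(min_len = 60L, max_len = 300L, max_loop_len = 150L,
                 min_score_per_nt = 0.5, min_paired_frac_mature = 0.6))
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stopf("unknown hairpin parameter(s): %s", paste(bad, collapse = ", "))
  p[names(over)] <- over
  p
}

#' Plausibility filter for candidate hairpin precursors
#'
#' Restricts precursor length, structural stability (pairing score per nt),
#' terminal loop size and mature-arm pairedness.
#'
#' @param fr A `fold_result` for the candidate precursor.
#' @param arms Optional `precursor_annotation` row giving mature arm
#'   intervals (enables the mature-pairedness check).
#' @param params Thresholds from [hairpin_params()].
#' @return list(pass = logical, reasons = character vector of failed checks:
#'   "length", "unstable", "loop", "mature_pairing").
#' @export
hairpin_filter <- function(fr, arms = NULL, params = hairpin_params("animal")) {
  stopifnot(inherits(fr, "fold_result"))
  n <- nchar(fr$sequence)
  reasons <- character(0)
  if (n < params$min_len || n > params$max_len) reasons <- c(reasons, "length")
  if (fr$score == 0 || fr$score / n < params$min_score_per_nt)
    reasons <- c(reasons, "unstable")
  if (nrow(fr$pairs)) {
    # hairpin loops: pairs enclosing no other pair
    loop_lens <- vapply(seq_len(nrow(fr$pairs)), function(k) {
      i <- fr$pairs[k, 1L]; j <- fr$pairs[k, 2L]
      inner <- fr$pairs[, 1L] > i & fr$pairs[, 2L] < j
      if (any(inner)) NA_integer_ else j - i - 1L
    }, integer(1L))
    if (any(loop_lens > params$max_loop_len, na.rm = TRUE))
      reasons <- c(reasons, "loop")
  }
  if (!is.null(arms) && nrow(fr$pairs)) {
    paired <- sort(c(fr$pairs[, 1L], fr$pairs[, 2L]))  # 0-based paired positions
    a <- as.data.frame(arms)[1L, ]
    for (arm in c("5", "3")) {
      s <- a[[paste0("arm", arm, "_start")]]; e <- a[[paste0("arm", arm, "_end")]]
      if (is.na(s)) next
      frac <- sum(paired >= s & paired < e) / (e - s)
      if (frac < params$min_paired_frac_mature) {
        reasons <- c(reasons, "mature_pairing")
        break
      }
    }
  }
  list(pass = length(reasons) == 0L, reasons = unique(reasons))
}
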