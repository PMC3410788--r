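## Independent oracles used across the suite. Each is a direct, brute-force
## restatement of the operation it checks and shares no code with the package
## internals.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]), collapse = "")
}

## Brute-force Hamming scan over all offsets and strands, best stratum kept.
oracle_align <- function(query, targets, max_mismatch, sense_only = FALSE) {
  qs <- list("+" = query)
  if (!sense_only) qs[["-"]] <- oracle_revcomp(query)
  rows <- list()
  for (tn in names(targets)) {
    tc <- strsplit(targets[[tn]], "")[[1L]]
    n <- length(tc)
    for (strand in names(qs)) {
      qc <- strsplit(qs[[strand]], "")[[1L]]
      L <- length(qc)
      if (n < L) next
      for (s in 0:(n - L)) {
        w <- tc[(s + 1L):(s + L)]
        mm <- sum(w != qc | w == "N" | qc == "N")
        if (mm <= max_mismatch) {
          rows[[length(rows) + 1L]] <- data.frame(
            target_id = tn, start = s, strand = strand, mismatches = mm,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(target_id = character(), start = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, rows)
  hits <- hits[hits$mismatches == min(hits$mismatches), , drop = FALSE]
  hits <- hits[order(hits$target_id, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

## Exhaustive enumeration of all non-crossing structures (min loop 3);
## returns the maximum total pair weight. Exponential, for length <= 12.
oracle_fold_max <- function(sequence) {
  chars <- strsplit(chartr("U", "T", toupper(sequence)), "")[[1L]]
  wtab <- c(GC = 3, CG = 3, AT = 2, TA = 2, GT = 1, TG = 1)
  best <- function(idx) {
    if (length(idx) < 2L) return(0)
    i <- idx[1L]
    rest <- idx[-1L]
    b <- best(rest)  # i unpaired
    for (jpos in seq_along(rest)) {
      j <- rest[jpos]
      if (j - i - 1L < 3L) next
      wij <- wtab[paste0(chars[i], chars[j])]
      if (is.na(wij)) next
      inside <- if (jpos > 1L) rest[seq_len(jpos - 1L)] else integer(0)
      outside <- if (jpos < length(rest)) rest[(jpos + 1L):length(rest)] else integer(0)
      b <- max(b, wij + best(inside) + best(outside))
    }
    b
  }
  best(seq_along(chars))
}

## Per-column scan: reference characters of a MAF block falling inside a
## 0-based half-open reference interval, in column order.
oracle_block_ref_chars <- function(block, qstart, qend) {
  r <- block$rows[1L, ]
  chars <- strsplit(r$text, "")[[1L]]
  out <- character(0)
  pos <- r$start
  for (ch in chars) {
    if (ch != "-") {
      if (pos >= qstart && pos < qend) out <- c(out, ch)
      pos <- pos + 1L
    }
  }
  paste(out, collapse = "")
}

## Independent Needleman-Wunsch (match 1, mismatch 0, gap -1); returns the
## identity (matches over alignment columns) of one optimal alignment.
oracle_global_identity <- function(a, b) {
  A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1L] <- -(0:n); S[1L, ] <- -(0:m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    S[i + 1L, j + 1L] <- max(S[i, j] + (A[i] == B[j]),
                             S[i, j + 1L] - 1, S[i + 1L, j] - 1)
  }
  # traceback counting matches and columns
  i <- n; j <- m; matches <- 0L; cols <- 0L
  while (i > 0L || j > 0L) {
    cols <- cols + 1L
    if (i > 0L && j > 0L && S[i + 1L, j + 1L] == S[i, j] + (A[i] == B[j])) {
      matches <- matches + (A[i] == B[j]); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] - 1) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  matches / cols
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## Random fixture MAF over a small genome plus mutated species, via the
## package generators (the oracle checks the slicing, not the generation).
random_fixture_maf <- function(seed, len = 300L) {
  cfg <- simulation_config(seed = seed, genome_length = len,
                           transition_rate = 0.08, transversion_rate = 0.04,
                           indel_rate = 0.02)
  g <- make_genome(cfg)
  v1 <- mutate_genome(g, cfg, seed = seed + 1L)
  v2 <- mutate_genome(g, cfg, seed = seed + 2L)
  maf <- make_maf("ref", g, list(list(name = "spB", alignment = v1$alignment),
                                 list(name = "spC", alignment = v2$alignment)),
                  block_cols = 120L)
  list(genome = g[[1L]], maf = maf)
}

interval_query <- function(chrom, start, end, strand = "+") {
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genome_interval")
}
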