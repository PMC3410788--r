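## Cross-species expression divergence of orthologous miRNAs: per-arm read
## counting against species-specific homolog references, tags-per-million
## normalization, a closed-form Poisson likelihood-ratio test (equivalent to
## the Poisson GLM with log-offset for two groups), Benjamini-Hochberg
## correction, and a Yates-corrected chi-square for comparing detection
## proportions between methods.

## Project an ungapped reference interval [s, e) into a species' ungapped
## homolog coordinates via the alignment columns. NULL when nothing aligns.
project_arm_interval <- function(hs, sp, s, e) {
  cols <- ref_interval_columns(hs$alignment[[hs$ref_species]], s, e)
  if (is.null(cols)) return(NULL)
  chars <- strsplit(hs$alignment[[sp]], "")[[1L]]
  ng <- chars != "-"
  sp_start <- sum(ng[seq_len(cols[1L] - 1L)])
  sp_end <- sum(ng[seq_len(cols[2L])])
  if (sp_end <= sp_start) NULL else c(sp_start, sp_end)
}

#' Count per-arm ortholog expression in each species
#'
#' For every species with a read library, the ungapped homolog sequences are
#' used as the alignment reference (sense-only, at most 1 mismatch, best
#' stratum). Arm intervals are projected from the reference precursor through
#' the homolog alignment into each species' coordinates; a read is assigned
#' to an arm when at least half of it overlaps the projected interval. The
#' normalization total N is the summed collapsed count of reads mapped to the
#' homolog reference set (an externally supplied total can replace it).
#'
#' @param libraries Named list (by species) of `collapsed_reads`.
#' @param homolog_sets List of `homolog_set` objects (one per precursor).
#' @param annots `precursor_annotation` for the reference precursors.
#' @param totals Optional named vector of external library totals to use as N.
#' @param max_mismatch Mismatch bound for read placement.
#' @return ArmExpression data.frame: `precursor_id`, `species`, `arm`, `x`,
#'   `N`, `tpm`.
#' @export
count_orthologs <- function(libraries, homolog_sets, annots, totals = NULL,
                            max_mismatch = 1L) {
  out <- list()
  for (sp in names(libraries)) {
    reads <- libraries[[sp]]
    if (nrow(reads) == 0L || sum(reads$count) == 0L)
      stopf("empty library for species '%s'", sp)
    refs <- character(0)
    arm_iv <- list()  # [[precursor]][[arm]] = c(start, end) in species coords
    for (hs in homolog_sets) {
      if (!(sp %in% hs$species) || hs$status[[sp]] == "absent") {
        message(sprintf("count_orthologs: %s absent for species %s; skipped",
                        hs$precursor_id, sp))
        next
      }
      refs[hs$precursor_id] <- gsub("-", "", hs$alignment[[sp]], fixed = TRUE)
      a <- as.data.frame(annots)
      a <- a[a$precursor_id == hs$precursor_id, , drop = FALSE]
      iv <- list()
      if (nrow(a) == 1L) {
        if (!is.na(a$arm5_start))
          iv[["5p"]] <- project_arm_interval(hs, sp, a$arm5_start, a$arm5_end)
        if (!is.na(a$arm3_start))
          iv[["3p"]] <- project_arm_interval(hs, sp, a$arm3_start, a$arm3_end)
      }
      arm_iv[[hs$precursor_id]] <- iv
    }
    if (length(refs) == 0L) next
    index <- build_index(refs, k = min(6L, min(nchar(refs))))
    x <- list()
    N <- 0L
    for (i in seq_len(nrow(reads))) {
      hits <- align(reads$sequence[i], index, max_mismatch = max_mismatch,
                    sense_only = TRUE, query_id = reads$tag_id[i])
      if (nrow(hits) == 0L) next
      N <- N + reads$count[i]
      len <- nchar(reads$sequence[i])
      for (h in seq_len(nrow(hits))) {
        iv <- arm_iv[[hits$target_id[h]]]
        ovl <- vapply(c("5p", "3p"), function(arm) {
          if (is.null(iv[[arm]])) return(0)
          max(0, min(hits$start[h] + len, iv[[arm]][2L]) - max(hits$start[h], iv[[arm]][1L]))
        }, numeric(1L))
        arm <- if (ovl[["5p"]] >= len / 2 && ovl[["5p"]] >= ovl[["3p"]]) "5p"
               else if (ovl[["3p"]] >= len / 2) "3p" else next
        key <- paste(hits$target_id[h], arm, sep = "\r")
        x[[key]] <- (x[[key]] %||% 0L) + reads$count[i]
      }
    }
    if (!is.null(totals)) N <- totals[[sp]]
    for (pre in names(arm_iv)) {
      for (arm in c("5p", "3p")) {
        if (is.null(arm_iv[[pre]][[arm]])) next
        xv <- x[[paste(pre, arm, sep = "\r")]] %||% 0L
        out[[length(out) + 1L]] <- data.frame(
          precursor_id = pre, species = sp, arm = arm, x = xv, N = N,
          tpm = tpm(xv, N), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(list(data.frame(precursor_id = character(), species = character(),
                                   arm = character(), x = integer(), N = integer(),
                                   tpm = numeric(), stringsAsFactors = FALSE)), out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tags per million mapped reads
#'
#' @param x Read count.
#' @param N Library normalization total (mapped reads, > 0).
#' @return x / N * 1e6.
#' @export
tpm <- function(x, N) {
  if (any(N <= 0)) stopf("normalization total N must be positive")
  if (any(x < 0)) stopf("counts must be non-negative")
  x / N * 1e6
}

#' Poisson likelihood-ratio test for two count libraries
#'
#' Tests equality of per-library rates x1/N1 and x2/N2 under Poisson
#' sampling. The null fits a common rate, giving expected counts
#' e_i = N_i (x1+x2)/(N1+N2) and deviance G = 2 sum x_i log(x_i/e_i)
#' (0 log 0 = 0), compared to chi-square with 1 df. This is the closed form
#' of the Poisson regression (log-offset) likelihood-ratio test for two
#' groups.
#'
#' @param x1,x2 Read counts (vectorized).
#' @param N1,N2 Library totals (> 0).
#' @return data.frame with `G`, `p`, and `undefined` (TRUE when x1+x2 == 0,
#'   where the test is undefined and p = 1 is returned).
#' @examples
#' poisson_lrt(10, 1e6, 30, 1e6) # G = 10.46496, p = 0.0012
#' @export
poisson_lrt <- function(x1, N1, x2, N2) {
  if (any(N1 <= 0) || any(N2 <= 0)) stopf("library totals must be positive")
  if (any(x1 < 0) || any(x2 < 0)) stopf("counts must be non-negative")
  tot <- x1 + x2
  e1 <- N1 * tot / (N1 + N2)
  e2 <- N2 * tot / (N1 + N2)
  term <- function(x, e) ifelse(x == 0, 0, x * log(x / e))
  G <- 2 * (term(x1, e1) + term(x2, e2))
  G <- pmax(G, 0)  # guard tiny negative rounding at x1/N1 == x2/N2
  undefined <- tot == 0
  p <- ifelse(undefined, 1, pchisq(G, df = 1L, lower.tail = FALSE))
  data.frame(G = ifelse(undefined, 0, G), p = p, undefined = undefined)
}

#' Differential expression table for two species
#'
#' Matches arm records across two species, applies the Poisson LRT per
#' (precursor, arm), adjusts p-values (Benjamini-Hochberg by default) and
#' attaches log2 TPM columns for scatter plotting (one pseudocount read is
#' added before the log for plotting only; the test uses raw counts).
#'
#' @param arm_expr ArmExpression table (from [count_orthologs()]) containing
#'   exactly two species.
#' @param alpha Significance level.
#' @param correction `"bh"` (q < alpha) or `"none"` (raw p < alpha).
#' @return A data.frame with counts, totals, `G`, `p`, `q`, `significant`,
#'   `log2_tpm_1`, `log2_tpm_2`; species order recorded in attributes
#'   `species_1`/`species_2`.
#' @export
diff_table <- function(arm_expr, alpha = 0.05, correction = c("bh", "none")) {
  correction <- match.arg(correction)
  sps <- unique(arm_expr$species)
  if (length(sps) != 2L) stopf("need exactly 2 species, got %d", length(sps))
  a <- arm_expr[arm_expr$species == sps[1L], ]
  b <- arm_expr[arm_expr$species == sps[2L], ]
  key <- function(df) paste(df$precursor_id, df$arm, sep = "\r")
  m <- match(key(a), key(b))
  a <- a[!is.na(m), , drop = FALSE]
  b <- b[m[!is.na(m)], , drop = FALSE]
  if (nrow(a) == 0L) stopf("no (precursor, arm) records shared between species")
  lrt <- poisson_lrt(a$x, a$N, b$x, b$N)
  q <- p.adjust(lrt$p, method = "BH")
  significant <- if (correction == "bh") q < alpha else lrt$p < alpha
  out <- data.frame(precursor_id = a$precursor_id, arm = a$arm,
                    x1 = a$x, N1 = a$N, x2 = b$x, N2 = b$N,
                    G = lrt$G, p = lrt$p, q = q, significant = significant,
                    log2_tpm_1 = log2(tpm(a$x + 1, a$N)),
                    log2_tpm_2 = log2(tpm(b$x + 1, b$N)),
                    stringsAsFactors = FALSE)
  attr(out, "species_1") <- sps[1L]
  attr(out, "species_2") <- sps[2L]
  out
}

#' Yates-corrected chi-square test on a 2x2 table
#'
#' Used to compare detection proportions between two screening methods.
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return list(chi2, p).
#' @examples
#' yates_chisq(matrix(c(93, 147, 66, 174), 2, byrow = TRUE))
#' @export
yates_chisq <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stopf("need a 2x2 table")
  if (any(table < 0) || any(table != floor(table))) stopf("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) stopf("zero margin in table")
  res <- suppressWarnings(chisq.test(table, correct = TRUE))
  list(chi2 = unname(res$statistic), p = res$p.value)
}
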