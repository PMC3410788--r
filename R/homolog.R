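## miRNA homolog identification from whole-genome alignments: place a
## precursor on the reference genome, excise the matching MAF columns and
## stitch per-species homolog sequences, then screen candidate orthologs on
## identity, alignment coverage and read support.

#' Locate a precursor on a reference genome
#'
#' Exact substring search on both strands first; when that fails, a seeded
#' ungapped search (11-mer seeds, full-length extension, >= 95\% identity)
#' stands in for an external placement tool. The placement must be unique.
#'
#' @param precursor Precursor sequence (>= 40 nt).
#' @param genome Named character vector of chromosome sequences.
#' @param min_identity Identity threshold for the seeded fallback.
#' @return A `genome_interval` list: `chrom`, `start`, `end` (0-based
#'   half-open, forward strand), `strand`.
#' @export
locate_precursor <- function(precursor, genome, min_identity = 0.95) {
  precursor <- normalize_nt(precursor, "precursor")
  if (nchar(precursor) < 40L) stopf("precursor shorter than 40 nt")
  genome <- normalize_nt(genome, "genome")
  if (is.null(names(genome))) stopf("genome sequences must be named")
  L <- nchar(precursor)

  hits <- list()
  add_hit <- function(chrom, start0, strand, identity) {
    hits[[length(hits) + 1L]] <<- list(chrom = chrom, start = start0,
                                       end = start0 + L, strand = strand,
                                       identity = identity)
  }
  queries <- c("+" = precursor, "-" = revcomp(precursor))

  # exact pass
  for (chrom in names(genome)) {
    subject <- Biostrings::DNAString(genome[[chrom]])
    for (strand in c("+", "-")) {
      m <- Biostrings::matchPattern(queries[[strand]], subject)
      for (s in Biostrings::start(m)) add_hit(chrom, s - 1L, strand, 1)
    }
  }

  if (length(hits) == 0L) {
    # seeded fallback: exact 11-mer seeds anchor candidate diagonals,
    # verified by full-length ungapped identity
    k <- 11L
    seed_starts <- unique(c(seq(1L, L - k + 1L, by = k), L - k + 1L))
    for (chrom in names(genome)) {
      subject <- Biostrings::DNAString(genome[[chrom]])
      tchars <- strsplit(genome[[chrom]], "")[[1L]]
      n <- length(tchars)
      for (strand in c("+", "-")) {
        q <- queries[[strand]]
        qchars <- strsplit(q, "")[[1L]]
        cand <- integer(0)
        for (b in seed_starts) {
          m <- Biostrings::matchPattern(substr(q, b, b + k - 1L), subject)
          cand <- c(cand, Biostrings::start(m) - b + 1L)
        }
        cand <- unique(cand)
        cand <- cand[cand >= 1L & cand + L - 1L <= n]
        if (length(cand) == 0L) next
        mm <- mismatches_at(tchars, cand, qchars)
        ident <- 1 - mm / L
        for (i in which(ident >= min_identity)) {
          add_hit(chrom, cand[i] - 1L, strand, ident[i])
        }
      }
    }
  }

  if (length(hits) == 0L)
    stopf("precursor not found in genome (no placement at >= %g identity)", min_identity)
  best <- max(vapply(hits, `[[`, numeric(1L), "identity"))
  hits <- Filter(function(h) h$identity == best, hits)
  if (length(hits) > 1L) {
    loci <- vapply(hits, function(h)
      sprintf("%s:%d-%d(%s)", h$chrom, h$start, h$end, h$strand), character(1L))
    stopf("ambiguous placement: %d equally good loci: %s",
          length(hits), paste(loci, collapse = ", "))
  }
  structure(hits[[1L]][c("chrom", "start", "end", "strand")], class = "genome_interval")
}

## Does the reference row of a block belong to the queried chromosome?
ref_matches_chrom <- function(src, chrom) {
  src == chrom || sub("^[^.]*\\.", "", src) == chrom
}

#' Excise the MAF columns covering a reference interval
#'
#' For each block overlapping the query, returns the sub-block spanning the
#' columns from the first to the last column whose reference (first-row)
#' character is a non-gap base inside `[start, end)`. Interior columns where
#' the reference carries a gap are retained. Per-row starts and sizes are
#' recomputed; rows reduced to pure gap keep size 0.
#'
#' @param blocks List of `maf_block` (reference species as first row, plus
#'   strand, multiz layout).
#' @param query A `genome_interval` on the reference assembly.
#' @return List of sliced `maf_block` objects (possibly empty).
#' @export
slice_maf <- function(blocks, query) {
  out <- list()
  for (b in blocks) {
    r <- b$rows
    if (!ref_matches_chrom(r$src[1L], query$chrom)) next
    if (r$strand[1L] != "+") stopf("reference row on '-' strand is not supported")
    refchars <- strsplit(r$text[1L], "")[[1L]]
    nongap <- refchars != "-"
    pos0 <- cumsum(nongap) - 1L + r$start[1L]  # ref position of each column
    sel <- nongap & pos0 >= query$start & pos0 < query$end
    if (!any(sel)) next
    c1 <- which(sel)[1L]; c2 <- max(which(sel))
    newr <- r
    for (i in seq_len(nrow(r))) {
      chars <- strsplit(r$text[i], "")[[1L]]
      ng <- chars != "-"
      newr$start[i] <- r$start[i] + sum(ng[seq_len(c1 - 1L)])
      newr$text[i] <- substr(r$text[i], c1, c2)
      newr$size[i] <- sum(ng[c1:c2])
    }
    out[[length(out) + 1L]] <- maf_block(b$score, newr$src, newr$start,
                                         newr$size, newr$strand, newr$srcSize,
                                         newr$text)
  }
  out
}

#' Stitch sliced MAF blocks into a per-species homolog set
#'
#' Blocks are concatenated in reference order. Species missing from some
#' blocks are padded with gap columns there and flagged `partial`; species
#' missing everywhere are flagged `absent`.
#'
#' @param sliced Output of [slice_maf()] (single-coverage on the reference).
#' @param species Species names to extract (MAF src prefix before the first
#'   dot). The reference species is always included.
#' @param query The `genome_interval` that produced the slice.
#' @param precursor_id Identifier carried through to downstream tables.
#' @return A `homolog_set`: gapped `alignment` rows over a common column
#'   count, per-species `status` (complete/partial/absent), source `src`,
#'   `strand` and forward-strand `interval`s.
#' @export
extract_homologs <- function(sliced, species, query, precursor_id = "precursor") {
  if (length(sliced) == 0L) {
    return(structure(list(precursor_id = precursor_id, ref_species = NA_character_,
                          species = species, alignment = setNames(character(0), character(0)),
                          status = setNames(rep("absent", length(species)), species),
                          src = setNames(rep(NA_character_, length(species)), species),
                          strand = setNames(rep(NA_character_, length(species)), species),
                          interval = setNames(rep(list(NULL), length(species)), species),
                          ref_interval = query),
                     class = "homolog_set"))
  }
  ref_species <- maf_species(sliced[[1L]]$rows$src[1L])
  species <- union(ref_species, species)

  starts <- vapply(sliced, function(b) b$rows$start[1L], integer(1L))
  ord <- order(starts)
  sliced <- sliced[ord]
  ends <- vapply(sliced, function(b) b$rows$start[1L] + b$rows$size[1L], integer(1L))
  starts <- starts[ord]
  if (any(starts[-1L] < ends[-length(ends)]))
    stopf("overlapping blocks on the reference: MAF is not single-coverage")

  widths <- vapply(sliced, function(b) nchar(b$rows$text[1L]), integer(1L))
  aln <- list(); status <- src <- strand <- character(0); interval <- list()
  for (sp in species) {
    pieces <- character(length(sliced))
    present <- logical(length(sliced))
    sp_src <- sp_strand <- NA_character_
    fwd <- NULL
    for (bi in seq_along(sliced)) {
      r <- sliced[[bi]]$rows
      j <- which(maf_species(r$src) == sp)[1L]
      if (!is.na(j)) {
        pieces[bi] <- r$text[j]
        present[bi] <- TRUE
        f <- maf_row_forward(r$start[j], r$size[j], r$strand[j], r$srcSize[j])
        if (is.na(sp_src)) { sp_src <- r$src[j]; sp_strand <- r$strand[j]; fwd <- f }
        else if (identical(sp_src, r$src[j]) && identical(sp_strand, r$strand[j]))
          fwd <- c(min(fwd[1L], f[1L]), max(fwd[2L], f[2L]))
        else fwd <- NULL  # rearranged across blocks: no single interval
      } else {
        pieces[bi] <- strrep("-", widths[bi])
      }
    }
    aln[[sp]] <- paste(pieces, collapse = "")
    status[sp] <- if (!any(present)) "absent" else if (all(present)) "complete" else "partial"
    src[sp] <- sp_src; strand[sp] <- sp_strand
    interval[[sp]] <- fwd
  }
  structure(list(precursor_id = precursor_id, ref_species = ref_species,
                 species = species, alignment = unlist(aln),
                 status = status, src = src, strand = strand,
                 interval = interval, ref_interval = query),
            class = "homolog_set")
}

#' @export
print.homolog_set <- function(x, ...) {
  cat(sprintf("homolog_set '%s' (reference: %s): %d species, %d columns\n",
              x$precursor_id, x$ref_species, length(x$species),
              if (length(x$alignment)) nchar(x$alignment[[1L]]) else 0L))
  for (sp in x$species) cat(sprintf("  %-12s %s\n", sp, x$status[[sp]]))
  invisible(x)
}

#' Ungapped homolog sequences of a homolog set
#'
#' @param hs A `homolog_set`.
#' @return Named character vector (absent species omitted).
#' @export
ungapped_homologs <- function(hs) {
  keep <- hs$status[hs$species] != "absent"
  gsub("-", "", hs$alignment[hs$species[keep]], fixed = TRUE)
}

#' Screen candidate orthologs on identity, coverage and read support
#'
#' Mirrors the genome-wide screening rule used for ortholog detection:
#' identity of at least `identity_min` over a compared length greater than
#' `coverage_min` nt, supported by at least `min_reads` sequencing reads in
#' the target species.
#'
#' @param dist_table Distance table with `precursor_id`, `species`,
#'   `identity`, `coverage` columns (e.g. precursor-region rows of
#'   [region_distances()], with `species_b` renamed `species`).
#' @param expr_table Read-support table with `precursor_id`, `species`,
#'   `reads` columns.
#' @param identity_min Minimum identity (fraction).
#' @param coverage_min Compared length must exceed this many nt.
#' @param min_reads Minimum read support.
#' @return list(table = retained rows, n_total, n_retained, proportion).
#' @export
screen_orthologs <- function(dist_table, expr_table, identity_min = 0.9,
                             coverage_min = 50, min_reads = 10L) {
  key <- function(df) paste(df$precursor_id, df$species, sep = "\r")
  reads <- expr_table$reads[match(key(dist_table), key(expr_table))]
  reads[is.na(reads)] <- 0L
  keep <- !is.na(dist_table$identity) &
    dist_table$identity >= identity_min &
    dist_table$coverage > coverage_min &
    reads >= min_reads
  tab <- dist_table[keep, , drop = FALSE]
  tab$reads <- reads[keep]
  list(table = tab, n_total = nrow(dist_table), n_retained = sum(keep),
       proportion = if (nrow(dist_table)) sum(keep) / nrow(dist_table) else NA_real_)
}
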