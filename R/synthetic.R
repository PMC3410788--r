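## Deterministic synthetic-data generators: toy genomes, mutated orthologous
## genomes with known transition/transversion/indel rates (with the true
## column-wise alignment), MAF whole-genome alignments, hairpin precursors,
## and Poisson-sampled small-RNA read libraries. These emulate the inputs of
## the real pipeline (genome + MAF + annotation + sequencing libraries) at
## desk scale; they are first-class, tested code, and the test bed for every
## other module.

#' Simulation configuration
#'
#' @param seed RNG seed (all generator randomness is derived from it).
#' @param genome_length Reference genome length (nt).
#' @param gc_content GC fraction of the background genome.
#' @param transition_rate,transversion_rate Per-site substitution rates p*
#'   and q* applied by [mutate_genome()] (p* + q* < 0.5).
#' @param indel_rate Per-site indel initiation rate (lengths 1-3).
#' @param n_precursors Number of hairpin precursors planted by
#'   [write_demo_fixtures()].
#' @param library_depth Sampling depth scale for [simulate_library()].
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, genome_length = 10000L,
                              gc_content = 0.5, transition_rate = 0.10,
                              transversion_rate = 0.05, indel_rate = 0.005,
                              n_precursors = 4L, library_depth = 1e5) {
  rates <- c(gc_content, transition_rate, transversion_rate, indel_rate)
  if (any(rates < 0) || any(rates > 1)) stopf("rates must lie in [0, 1]")
  if (transition_rate + transversion_rate >= 0.5)
    stopf("transition_rate + transversion_rate must be < 0.5")
  if (library_depth <= 0) stopf("library_depth must be positive")
  if (genome_length < 1L) stopf("genome_length must be >= 1")
  structure(list(seed = as.integer(seed), genome_length = as.integer(genome_length),
                 gc_content = gc_content, transition_rate = transition_rate,
                 transversion_rate = transversion_rate, indel_rate = indel_rate,
                 n_precursors = as.integer(n_precursors),
                 library_depth = library_depth),
            class = "simulation_config")
}

#' Generate a random genome sequence
#'
#' @param cfg A [simulation_config()].
#' @param name Chromosome name.
#' @return Named character vector of length 1. Reproducible for a fixed seed.
#' @export
make_genome <- function(cfg, name = "chr1") {
  stopifnot(inherits(cfg, "simulation_config"))
  withr::with_seed(cfg$seed, {
    p <- c(A = (1 - cfg$gc_content) / 2, C = cfg$gc_content / 2,
           G = cfg$gc_content / 2, T = (1 - cfg$gc_content) / 2)
    setNames(paste(sample(names(p), cfg$genome_length, replace = TRUE, prob = p),
                   collapse = ""), name)
  })
}

TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS_OF <- list(A = c("C", "T"), G = c("C", "T"),
                         C = c("A", "G"), T = c("A", "G"))

#' Mutate a genome with known substitution and indel rates
#'
#' Each site independently receives a transition with probability p*, a
#' transversion with probability q* (the two transversion targets equally
#' likely), and initiates an indel (insertion or deletion, length 1-3) at
#' `indel_rate`. The true column-wise alignment between the original and the
#' mutated sequence is returned, providing ground truth for distance
#' estimation.
#'
#' @param genome Reference sequence (single string; names ignored).
#' @param cfg A [simulation_config()] (rates and seed).
#' @param seed Overrides `cfg$seed` so several species can be derived from
#'   one reference.
#' @param protect Optional list/matrix of 0-based half-open intervals where
#'   indels are suppressed (e.g. planted mature arms, so arm projection
#'   stays interpretable); substitutions still apply.
#' @return list(genome = mutated sequence, alignment = c(ref = gapped ref
#'   row, alt = gapped mutated row)).
#' @export
mutate_genome <- function(genome, cfg, seed = cfg$seed, protect = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  ref <- strsplit(normalize_nt(genome[[1L]], "genome"), "")[[1L]]
  n <- length(ref)
  protected <- logical(n)
  if (!is.null(protect)) {
    if (is.matrix(protect)) protect <- asplit(protect, 1L)
    for (iv in protect) {
      lo <- max(1L, iv[1L] + 1L - 3L)  # indels up to 3 nt back can reach in
      hi <- min(n, iv[2L])
      protected[lo:hi] <- TRUE
    }
  }
  withr::with_seed(seed, {
    u <- runif(n)
    alt <- ref
    ts <- u < cfg$transition_rate
    tv <- !ts & u < cfg$transition_rate + cfg$transversion_rate
    alt[ts] <- TRANSITION_OF[ref[ts]]
    if (any(tv)) {
      pick <- sample.int(2L, sum(tv), replace = TRUE)
      alt[tv] <- mapply(function(b, k) TRANSVERSIONS_OF[[b]][k], ref[tv], pick,
                        USE.NAMES = FALSE)
    }
    indel_at <- runif(n) < cfg$indel_rate & !protected
    ref_pieces <- ref
    alt_pieces <- alt
    pos <- which(indel_at)
    if (length(pos)) {
      types <- sample(c("ins", "del"), length(pos), replace = TRUE)
      lens <- sample.int(3L, length(pos), replace = TRUE)
      blocked_until <- 0L
      for (k in seq_along(pos)) {
        i <- pos[k]
        if (i <= blocked_until) next
        if (types[k] == "del") {
          span <- i:min(n, i + lens[k] - 1L)
          if (any(protected[span])) next
          alt_pieces[span] <- "-"
          blocked_until <- max(span)
        } else {
          ins <- paste(sample(c("A", "C", "G", "T"), lens[k], replace = TRUE),
                       collapse = "")
          ref_pieces[i] <- paste0(ref_pieces[i], strrep("-", lens[k]))
          alt_pieces[i] <- paste0(alt_pieces[i], ins)
        }
      }
    }
    ref_row <- paste(ref_pieces, collapse = "")
    alt_row <- paste(alt_pieces, collapse = "")
    list(genome = gsub("-", "", alt_row, fixed = TRUE),
         alignment = c(ref = ref_row, alt = alt_row))
  })
}

#' Build a multi-species MAF from reference-threaded pairwise alignments
#'
#' Pairwise alignments (each against the same reference) are merged into a
#' joint alignment by threading on reference positions: species-specific
#' insertions become columns gapped in every other row. The joint alignment
#' is chopped into blocks of at most `block_cols` columns tiling the
#' reference, satisfying all MAF invariants and round-tripping through
#' [parse_maf()].
#'
#' @param ref_name Reference species name (MAF src becomes
#'   `"<name>.<chrom>"`).
#' @param reference Reference sequence.
#' @param variants List of `list(name =, alignment = c(ref, alt))` entries as
#'   produced by [mutate_genome()].
#' @param chrom Chromosome name shared by all rows.
#' @param block_cols Maximum columns per block.
#' @return List of `maf_block` objects.
#' @export
make_maf <- function(ref_name, reference, variants, chrom = "chr1",
                     block_cols = 500L) {
  reference <- normalize_nt(reference[[1L]], "reference")
  n <- nchar(reference)
  refc <- strsplit(reference, "")[[1L]]

  # per species: split alignment into one piece per reference position
  # (the aligned char plus any insertion columns that follow it)
  piece <- list()
  for (v in variants) {
    rr <- strsplit(v$alignment[["ref"]], "")[[1L]]
    aa <- strsplit(v$alignment[["alt"]], "")[[1L]]
    if (paste(rr[rr != "-"], collapse = "") != reference)
      stopf("variant '%s': alignment reference row does not match the reference", v$name)
    grp <- cumsum(rr != "-")
    if (any(grp == 0L)) stopf("variant '%s': alignment starts with an insertion", v$name)
    al <- vapply(split(aa, grp), paste, character(1L), collapse = "")
    piece[[v$name]] <- unname(al)
  }
  spp <- names(piece)

  # joint columns per reference position: each species' insertions first
  # (others gapped), then the shared reference column
  ref_out <- character(n)
  sp_out <- setNames(rep(list(character(n)), length(spp)), spp)
  for (i in seq_len(n)) {
    ins_len <- vapply(spp, function(s) nchar(piece[[s]][i]) - 1L, integer(1L))
    tot_ins <- sum(ins_len)
    ref_out[i] <- paste0(strrep("-", tot_ins), refc[i])
    before <- 0L
    for (s in spp) {
      p <- piece[[s]][i]
      sp_out[[s]][i] <- paste0(strrep("-", before), substr(p, 2L, nchar(p)),
                               strrep("-", tot_ins - before - ins_len[[s]]),
                               substr(p, 1L, 1L))
      before <- before + ins_len[[s]]
    }
  }

  widths <- nchar(ref_out)
  src_size <- c(setNames(n, ref_name),
                vapply(sp_out, function(x) sum(nchar(gsub("-", "", x))), integer(1L)))
  blocks <- list()
  i0 <- 1L
  starts <- setNames(integer(length(spp) + 1L), c(ref_name, spp))
  while (i0 <= n) {
    w <- cumsum(widths[i0:n])
    i1 <- i0 + max(1L, sum(w <= block_cols)) - 1L
    idx <- i0:i1
    texts <- c(paste(ref_out[idx], collapse = ""),
               vapply(spp, function(s) paste(sp_out[[s]][idx], collapse = ""), character(1L)))
    sizes <- nchar(gsub("-", "", texts, fixed = TRUE))
    blocks[[length(blocks) + 1L]] <- validate_maf_block(maf_block(
      score = NA_real_,
      src = paste(c(ref_name, spp), chrom, sep = "."),
      start = unname(starts), size = sizes,
      strand = rep("+", length(texts)),
      srcSize = unname(src_size[c(ref_name, spp)]),
      text = texts))
    starts <- starts + sizes
    i0 <- i1 + 1L
  }
  blocks
}

#' Construct a synthetic hairpin precursor
#'
#' A random 5p mature arm, a loop, and the reverse complement of the arm as
#' the 3p side: a perfect stem-loop that folds and passes the hairpin
#' filter, with known arm coordinates.
#'
#' @param seed RNG seed.
#' @param arm_len Mature arm length (nt).
#' @param loop_len Loop length (nt).
#' @return list(sequence, arm5 = c(start, end), arm3 = c(start, end))
#'   (0-based half-open).
#' @export
make_hairpin <- function(seed = 1L, arm_len = 22L, loop_len = 12L) {
  withr::with_seed(seed, {
    arm <- paste(sample(c("A", "C", "G", "T"), arm_len, replace = TRUE,
                        prob = c(.2, .3, .3, .2)), collapse = "")
    loop <- paste(sample(c("A", "T"), loop_len, replace = TRUE), collapse = "")
    seqn <- paste0(arm, loop, revcomp(arm))
    list(sequence = seqn,
         arm5 = c(0L, arm_len),
         arm3 = c(arm_len + loop_len, arm_len + loop_len + arm_len))
  })
}

#' Simulate a small-RNA library from annotated precursors
#'
#' Per arm, the read count is Poisson(rate * depth). Reads are mature-arm
#' substrings with up to `wobble` nt of independent end wobble (clamped to
#' the precursor), with the 3' sequencing adapter appended so preprocessing
#' is exercised end to end.
#'
#' @param annots `precursor_annotation` (sequences + arm intervals).
#' @param rates data.frame with `precursor_id`, `arm` ("5p"/"3p"), `rate`
#'   (expected reads per unit depth).
#' @param depth Library depth scale.
#' @param seed RNG seed.
#' @param adapter 3' adapter sequence appended to every read.
#' @param wobble Maximum end shift (nt) at each read end.
#' @return data.frame of raw reads: `id`, `sequence`.
#' @export
simulate_library <- function(annots, rates, depth, seed = 1L,
                             adapter = "TCGTATGCCGTCTTCTGCTTG", wobble = 2L) {
  stopifnot(inherits(annots, "precursor_annotation"))
  withr::with_seed(seed, {
    ids <- character(0); seqs <- character(0)
    for (r in seq_len(nrow(rates))) {
      pre <- rates$precursor_id[r]
      j <- match(pre, annots$precursor_id)
      if (is.na(j)) stopf("rates reference unknown precursor '%s'", pre)
      arm <- rates$arm[r]
      s <- annots[[if (arm == "5p") "arm5_start" else "arm3_start"]][j]
      e <- annots[[if (arm == "5p") "arm5_end" else "arm3_end"]][j]
      if (is.na(s)) stopf("precursor '%s' has no %s arm", pre, arm)
      n_reads <- rpois(1L, rates$rate[r] * depth)
      if (n_reads == 0L) next
      plen <- nchar(annots$sequence[j])
      d5 <- sample(-wobble:wobble, n_reads, replace = TRUE)
      d3 <- sample(-wobble:wobble, n_reads, replace = TRUE)
      rs <- pmax(0L, pmin(s + d5, e - 10L))
      re <- pmin(plen, pmax(e + d3, rs + 10L))
      seqs <- c(seqs, paste0(substr(rep(annots$sequence[j], n_reads),
                                    rs + 1L, re), adapter))
      ids <- c(ids, sprintf("sim_%s_%s_%d", pre, arm, seq_len(n_reads)))
    }
    data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
  })
}

#' Write a complete demonstration fixture set
#'
#' Generates a reference genome with planted hairpin precursors, a mutated
#' second species, the MAF alignment between them, precursor/arm annotation,
#' a small ncRNA decoy database, one Poisson-sampled FASTQ library per
#' species and a ready-to-run pipeline configuration. Byte-reproducible for
#' a fixed seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Master RNG seed.
#' @param cfg A [simulation_config()]; its seed is replaced by `seed`.
#' @param ref_name,alt_name Species names.
#' @return Invisibly, the path of the written configuration file.
#' @export
write_demo_fixtures <- function(dir, seed = 1L, cfg = NULL,
                                ref_name = "speciesA", alt_name = "speciesB") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cfg)) {
    cfg <- simulation_config(seed = seed, genome_length = 6000L,
                             transition_rate = 0.04, transversion_rate = 0.02,
                             indel_rate = 0.003, n_precursors = 4L,
                             library_depth = 2e4)
  } else {
    cfg$seed <- as.integer(seed)
  }
  genome <- make_genome(cfg)

  # plant hairpins at evenly spaced loci
  hp <- lapply(seq_len(cfg$n_precursors), function(i) make_hairpin(seed + 100L + i))
  plen <- nchar(hp[[1L]]$sequence)
  gap <- (cfg$genome_length - cfg$n_precursors * plen) %/% (cfg$n_precursors + 1L)
  gseq <- genome[[1L]]
  loci <- integer(cfg$n_precursors)
  for (i in seq_len(cfg$n_precursors)) {
    at <- gap * i + plen * (i - 1L)  # 0-based
    loci[i] <- at
    substr(gseq, at + 1L, at + plen) <- hp[[i]]$sequence
  }
  genome[[1L]] <- gseq

  pre_ids <- sprintf("pre-mir-%d", seq_len(cfg$n_precursors))
  annots <- precursor_annotation(
    pre_ids, vapply(hp, `[[`, character(1L), "sequence"),
    arm5_start = vapply(hp, function(h) h$arm5[1L], integer(1L)),
    arm5_end = vapply(hp, function(h) h$arm5[2L], integer(1L)),
    arm3_start = vapply(hp, function(h) h$arm3[1L], integer(1L)),
    arm3_end = vapply(hp, function(h) h$arm3[2L], integer(1L)))

  protect <- lapply(seq_len(cfg$n_precursors), function(i) {
    c(loci[i], loci[i] + plen)  # keep planted precursors indel-free
  })
  mut <- mutate_genome(genome, cfg, seed = seed + 1L, protect = protect)
  maf <- make_maf(ref_name, genome, list(list(name = alt_name,
                                              alignment = mut$alignment)))

  paths <- list(genome = file.path(dir, "genome.fa"),
                maf = file.path(dir, "alignment.maf"),
                precursors = file.path(dir, "precursors.fa"),
                arms = file.path(dir, "arms.bed"),
                db = file.path(dir, "ncrna_db.fa"),
                reads_ref = file.path(dir, paste0(ref_name, ".fastq")),
                reads_alt = file.path(dir, paste0(alt_name, ".fastq")),
                config = file.path(dir, "config.yaml"))

  write_fasta(names(genome), genome, paths$genome)
  write_maf(maf, paths$maf)
  write_fasta(annots$precursor_id, annots$sequence, paths$precursors)
  bed <- rbind(
    data.frame(chrom = annots$precursor_id, start = annots$arm5_start,
               end = annots$arm5_end, name = "5p", score = 0, strand = "+"),
    data.frame(chrom = annots$precursor_id, start = annots$arm3_start,
               end = annots$arm3_end, name = "3p", score = 0, strand = "+"))
  bed <- bed[order(bed$chrom, bed$start), ]
  write.table(bed, paths$arms, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  # decoy ncRNA database, disjoint from the planted hairpins
  db_cfg <- simulation_config(seed = seed + 2L, genome_length = 300L)
  write_fasta(c("decoy-trna-1", "decoy-rrna-1"),
              c(substr(make_genome(db_cfg)[[1L]], 1L, 80L),
                substr(make_genome(db_cfg)[[1L]], 101L, 220L)),
              paths$db)

  adapter <- "TCGTATGCCGTCTTCTGCTTG"
  base_rates <- function(sd) {
    withr::with_seed(sd, {
      expand <- expand.grid(precursor_id = pre_ids, arm = c("5p", "3p"),
                            stringsAsFactors = FALSE)
      expand$rate <- round(runif(nrow(expand), 5e-4, 5e-3), 6L)
      expand
    })
  }
  rates_ref <- base_rates(seed + 3L)
  rates_alt <- rates_ref
  rates_alt$rate[1L] <- rates_alt$rate[1L] * 4  # one planted expression shift
  lib_ref <- simulate_library(annots, rates_ref, cfg$library_depth,
                              seed = seed + 4L, adapter = adapter)
  # the second species' reads come from its own (mutated) homolog sequences
  hs_annots <- annots
  for (i in seq_len(cfg$n_precursors)) {
    blocks <- slice_maf(maf, structure(list(chrom = "chr1", start = loci[i],
                                            end = loci[i] + plen, strand = "+"),
                                       class = "genome_interval"))
    hs <- extract_homologs(blocks, alt_name,
                           structure(list(chrom = "chr1", start = loci[i],
                                          end = loci[i] + plen, strand = "+"),
                                     class = "genome_interval"),
                           precursor_id = pre_ids[i])
    hs_annots$sequence[i] <- gsub("-", "", hs$alignment[[alt_name]], fixed = TRUE)
  }
  # arm intervals carry over: indels were suppressed inside the precursors
  lib_alt <- simulate_library(hs_annots, rates_alt, cfg$library_depth,
                              seed = seed + 5L, adapter = adapter)
  write_fastq(lib_ref$id, lib_ref$sequence, paths$reads_ref)
  write_fastq(lib_alt$id, lib_alt$sequence, paths$reads_alt)

  config <- list(
    species = c(ref_name, alt_name),
    genome_fasta = "genome.fa", maf = "alignment.maf",
    precursor_fasta = "precursors.fa", arms_bed = "arms.bed",
    db_fasta = "ncrna_db.fa",
    reads = setNames(list(paste0(ref_name, ".fastq"), paste0(alt_name, ".fastq")),
                     c(ref_name, alt_name)),
    adapter = adapter, min_len = 18L, max_mismatch_db = 2L,
    alpha = 0.05, correction = "bh",
    identity_min = 0.9, coverage_min = 50L, min_reads = 10L,
    seed = as.integer(seed))
  yaml::write_yaml(config, paths$config)
  invisible(paths$config)
}
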