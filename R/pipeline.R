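## Multi-stage pipeline driver: preprocess -> filter -> profile -> homolog ->
## distance -> diffexp, each stage writing plain-text outputs so any stage
## can be run standalone. A manifest of output checksums makes reruns
## verifiable: identical configuration and fixtures reproduce identical
## manifests byte for byte.

PIPELINE_STAGES <- c("preprocess", "filter", "profile", "homolog", "distance", "diffexp")

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the analysis pipeline on a configuration
#'
#' Executes the requested stages in dependency order. Stages not requested
#' are reloaded from their files in `out_dir` when a later stage needs them;
#' a missing prerequisite is an error naming the stage to run first.
#'
#' @param cfg A `run_config` from [load_config()], or a configuration file
#'   path.
#' @param out_dir Output directory.
#' @param stages Subset of `r paste(PIPELINE_STAGES, collapse = ", ")`.
#' @return Invisibly, the manifest data.frame (`stage`, `file`, `md5`), also
#'   written to `manifest.tsv`.
#' @export
run_pipeline <- function(cfg, out_dir, stages = PIPELINE_STAGES) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env(parent = emptyenv())
  outputs <- list()
  note <- function(stage, files) {
    outputs[[length(outputs) + 1L]] <<- data.frame(stage = stage,
                                                   file = basename(files),
                                                   stringsAsFactors = FALSE)
  }
  path_of <- function(f) file.path(out_dir, f)
  fcfg <- filter_config(max_mismatch_db = cfg$max_mismatch_db,
                        max_mismatch_mirna = cfg$max_mismatch_mirna)

  need_collapsed <- function(who) {
    if (!is.null(state$collapsed)) return(state$collapsed)
    files <- path_of(paste0(cfg$species, ".collapsed.fa"))
    if (!all(file.exists(files)))
      stopf("stage '%s' requires outputs of 'preprocess'; run it first", who)
    state$collapsed <- setNames(lapply(files, read_collapsed_fasta), cfg$species)
    state$collapsed
  }
  need_retained <- function(who) {
    if (!is.null(state$retained)) return(state$retained)
    if (is.null(cfg$db_fasta)) return(need_collapsed(who))
    files <- path_of(paste0(cfg$species, ".retained.fa"))
    if (!all(file.exists(files)))
      stopf("stage '%s' requires outputs of 'filter'; run it first", who)
    state$retained <- setNames(lapply(files, read_collapsed_fasta), cfg$species)
    state$retained
  }
  need_annots <- function() {
    if (is.null(state$annots)) {
      pre <- read_fasta(cfg$precursor_fasta)
      state$annots <- read_arms_bed(pre, cfg$arms_bed)
    }
    state$annots
  }
  need_homologs <- function(who) {
    if (!is.null(state$homologs)) return(state$homologs)
    annots <- need_annots()
    files <- path_of(paste0(annots$precursor_id, ".slice.maf"))
    if (!all(file.exists(files)))
      stopf("stage '%s' requires outputs of 'homolog'; run it first", who)
    state$homologs <- lapply(seq_len(nrow(annots)), function(i) {
      blocks <- parse_maf(files[i])
      r1 <- blocks[[1L]]$rows[1L, ]
      rn <- blocks[[length(blocks)]]$rows[1L, ]
      query <- structure(list(chrom = sub("^[^.]*\\.", "", r1$src),
                              start = r1$start, end = rn$start + rn$size,
                              strand = "+"), class = "genome_interval")
      extract_homologs(blocks, cfg$species, query, annots$precursor_id[i])
    })
    state$homologs
  }

  for (stage in stages) {
    message(sprintf("[%s]", stage))
    switch(stage,
      preprocess = {
        state$collapsed <- list()
        for (sp in cfg$species) {
          raw <- read_fastq(cfg$reads[[sp]])
          pp <- preprocess_library(raw$sequence, cfg$adapter, lib_label = sp,
                                   min_overlap = cfg$min_overlap,
                                   min_len = cfg$min_len,
                                   max_mismatch_frac = cfg$max_mismatch_frac,
                                   keep_untrimmed = cfg$keep_untrimmed)
          state$collapsed[[sp]] <- pp$reads
          f <- path_of(paste0(sp, ".collapsed.fa"))
          write_collapsed_fasta(pp$reads, f)
          note("preprocess", f)
        }
      },
      filter = {
        collapsed <- need_collapsed("filter")
        if (is.null(cfg$db_fasta)) {
          state$retained <- collapsed
        } else {
          db <- read_fasta(cfg$db_fasta)
          state$retained <- list()
          for (sp in cfg$species) {
            parts <- filter_by_db(collapsed[[sp]], setNames(db$sequence, db$id), fcfg)
            state$retained[[sp]] <- parts$retained
            f1 <- path_of(paste0(sp, ".retained.fa"))
            f2 <- path_of(paste0(sp, ".discarded.fa"))
            write_collapsed_fasta(parts$retained, f1)
            write_collapsed_fasta(parts$discarded, f2)
            note("filter", c(f1, f2))
          }
        }
      },
      profile = {
        retained <- need_retained("profile")
        annots <- need_annots()
        for (sp in cfg$species) {
          pr <- profile_known(retained[[sp]], annots, fcfg)
          f1 <- path_of(paste0(sp, ".expression.tsv"))
          f2 <- path_of(paste0(sp, ".leftover.fa"))
          write_tsv(pr$expression, f1)
          write_collapsed_fasta(pr$leftover, f2)
          note("profile", c(f1, f2))
        }
      },
      homolog = {
        annots <- need_annots()
        genome <- read_fasta(cfg$genome_fasta)
        genome <- setNames(genome$sequence, genome$id)
        blocks <- parse_maf(cfg$maf)
        state$homologs <- list()
        hs_rows <- list()
        for (i in seq_len(nrow(annots))) {
          query <- locate_precursor(annots$sequence[i], genome)
          sliced <- slice_maf(blocks, query)
          hs <- extract_homologs(sliced, cfg$species, query, annots$precursor_id[i])
          state$homologs[[i]] <- hs
          f1 <- path_of(paste0(annots$precursor_id[i], ".slice.maf"))
          f2 <- path_of(paste0(annots$precursor_id[i], ".homologs.fa"))
          write_maf(sliced, f1)
          ug <- ungapped_homologs(hs)
          write_fasta(paste(annots$precursor_id[i], names(ug), sep = "|"), ug, f2)
          note("homolog", c(f1, f2))
          for (sp in hs$species) {
            iv <- hs$interval[[sp]]
            hs_rows[[length(hs_rows) + 1L]] <- data.frame(
              precursor_id = annots$precursor_id[i], species = sp,
              status = hs$status[[sp]], src = hs$src[[sp]],
              strand = hs$strand[[sp]],
              start = if (is.null(iv)) NA_integer_ else iv[1L],
              end = if (is.null(iv)) NA_integer_ else iv[2L],
              stringsAsFactors = FALSE)
          }
        }
        f3 <- path_of("homologs.tsv")
        write_tsv(do.call(rbind, hs_rows), f3)
        note("homolog", f3)
      },
      distance = {
        hs_list <- need_homologs("distance")
        annots <- need_annots()
        dist <- do.call(rbind, lapply(hs_list, region_distances, arms = annots))
        f <- path_of("distances.tsv")
        write_tsv(dist, f)
        state$distances <- dist
        note("distance", f)
      },
      diffexp = {
        retained <- need_retained("diffexp")
        hs_list <- need_homologs("diffexp")
        annots <- need_annots()
        sp2 <- cfg$species[1:2]
        arm_expr <- count_orthologs(retained[sp2], hs_list, annots)
        dt <- diff_table(arm_expr, alpha = cfg$alpha, correction = cfg$correction)
        f1 <- path_of("diffexp.tsv")
        f2 <- path_of("scatter.tsv")
        write_tsv(dt, f1)
        write_tsv(dt[, c("precursor_id", "arm", "log2_tpm_1", "log2_tpm_2",
                         "significant")], f2)
        note("diffexp", c(f1, f2))
      })
  }

  out <- do.call(rbind, outputs)
  inputs <- c(genome_fasta = cfg$genome_fasta, maf = cfg$maf,
              precursor_fasta = cfg$precursor_fasta, arms_bed = cfg$arms_bed,
              db_fasta = cfg$db_fasta %||% NULL, unlist(cfg$reads))
  manifest <- rbind(
    data.frame(stage = "input", file = basename(unname(inputs)),
               md5 = unname(tools::md5sum(unname(inputs))),
               stringsAsFactors = FALSE),
    data.frame(stage = out$stage, file = out$file,
               md5 = unname(tools::md5sum(file.path(out_dir, out$file))),
               stringsAsFactors = FALSE))
  manifest <- manifest[order(manifest$stage, manifest$file), ]
  rownames(manifest) <- NULL
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}
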