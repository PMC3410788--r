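write_toy_maf <- function(lines) {
  path <- withr::local_tempfile(fileext = ".maf", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("MAF parsing handles blocks, ignores i/e/q lines, and round-trips", {
  path <- write_toy_maf(c(
    "##maf version=1",
    "a score=12.5",
    "s ref.chr1 0 10 + 100 ACGT-ACGTAC",
    "s spB.chr2 5 11 + 50 ACGTTACGTAC",
    "i spB.chr2 N 0 C 0",
    "",
    "a",
    "s ref.chr1 10 4 + 100 ACGT",
    "q ref.chr1 99999999"))
  blocks <- parse_maf(path)
  expect_length(blocks, 2L)
  expect_equal(blocks[[1]]$score, 12.5)
  expect_equal(nrow(blocks[[1]]$rows), 2L)
  expect_equal(blocks[[1]]$rows$start, c(0L, 5L))
  out <- withr::local_tempfile(fileext = ".maf")
  write_maf(blocks, out)
  expect_equal(parse_maf(out), blocks)
})

test_that("MAF invariant violations error with the block index", {
  expect_error(parse_maf(write_toy_maf(c(
    "a score=1",
    "s ref.chr1 0 9 + 100 ACGT-ACGTAC",   # 10 non-gaps, size says 9
    "s spB.chr2 5 11 + 50 ACGTTACGTAC"))),
    "non-gap count 10 != size 9.*block 1")
  expect_error(parse_maf(write_toy_maf(c(
    "a",
    "s ref.chr1 0 4 + 100 ACGT",
    "s spB.chr2 0 6 + 50 ACGTAC"))),
    "differ in length")
})

test_that("precursor location finds exact, reverse-complement and mutated plants", {
  withr::with_seed(41, {
    background <- random_seq(500)
    pre <- random_seq(60)
    plant <- function(g, s, what) {
      substr(g, s + 1, s + nchar(what)) <- what
      g
    }
    g1 <- c(chr1 = plant(background, 100, pre))
    iv <- locate_precursor(pre, g1)
    expect_equal(iv[c("chrom", "start", "end", "strand")],
                 list(chrom = "chr1", start = 100L, end = 160L, strand = "+"),
                 ignore_attr = TRUE)
    g2 <- c(chr1 = plant(background, 100, oracle_revcomp(pre)))
    iv2 <- locate_precursor(pre, g2)
    expect_equal(iv2$start, 100L)
    expect_equal(iv2$strand, "-")
    g3 <- c(chr1 = plant(plant(background, 50, pre), 300, pre))
    expect_error(locate_precursor(pre, g3), "ambiguous.*2 equally good")
    # two substitutions: exact search fails, seeded fallback succeeds
    mut <- strsplit(pre, "")[[1]]
    mut[c(20, 40)] <- vapply(mut[c(20, 40)],
                             function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
    g4 <- c(chr1 = plant(background, 200, paste(mut, collapse = "")))
    iv4 <- locate_precursor(pre, g4)
    expect_equal(c(iv4$start, iv4$end), c(200L, 260L))
    expect_error(locate_precursor(random_seq(60), c(chr1 = background)), "not found")
  })
})

test_that("slicing keeps interior reference-gap columns and recomputes coordinates", {
  blocks <- parse_maf(write_toy_maf(c(
    "a score=1",
    "s ref.chr1 10 4 + 100 AC-GT",
    "s spB.chr2 0 5 + 50 ACTGT")))
  sl <- slice_maf(blocks, interval_query("chr1", 11, 13))
  expect_length(sl, 1L)
  expect_equal(sl[[1]]$rows$text, c("C-G", "CTG"))
  expect_equal(sl[[1]]$rows$start, c(11L, 1L))
  expect_equal(sl[[1]]$rows$size, c(2L, 3L))
  expect_length(slice_maf(blocks, interval_query("chr1", 90, 95)), 0L)
})

test_that("sliced reference content equals the genome substring (column-scan oracle)", {
  withr::with_seed(51, {
    for (rep in 1:20) {
      fx <- random_fixture_maf(seed = 5000 + rep)
      n <- nchar(fx$genome)
      qs <- sort(sample(0:(n - 1), 2))
      if (qs[1] == qs[2]) qs[2] <- qs[2] + 1
      query <- interval_query("chr1", qs[1], qs[2])
      sl <- slice_maf(fx$maf, query)
      got <- paste(gsub("-", "", vapply(sl, function(b) b$rows$text[1], "")),
                   collapse = "")
      expect_equal(got, substr(fx$genome, qs[1] + 1, qs[2]))
      # per-block column-scan oracle agrees too
      want <- paste(vapply(fx$maf, oracle_block_ref_chars, "", qs[1], qs[2]),
                    collapse = "")
      expect_equal(got, want)
    }
  })
})

test_that("homolog stitching pads missing species and tracks coverage flags", {
  blocks <- parse_maf(write_toy_maf(c(
    "a",
    "s ref.chr1 0 4 + 8 ACGT",
    "s spB.chr2 0 4 + 9 AGGT",
    "s spC.chr3 2 4 - 40 TTGT",
    "",
    "a",
    "s ref.chr1 4 4 + 8 TTA-A",
    "s spB.chr2 4 5 + 9 TTAGA")))
  hs <- extract_homologs(blocks, c("spB", "spC"), interval_query("chr1", 0, 8), "pre-x")
  expect_equal(hs$ref_species, "ref")
  expect_equal(unname(nchar(hs$alignment)), rep(9L, 3))
  expect_equal(hs$alignment[["spB"]], "AGGTTTAGA")
  expect_equal(hs$alignment[["spC"]], "TTGT-----")
  expect_equal(unname(hs$status[c("ref", "spB", "spC")]),
               c("complete", "complete", "partial"))
  # minus-strand forward-interval conversion: [40-2-4, 40-2) = [34, 38)
  expect_equal(hs$interval[["spC"]], c(34L, 38L))
  expect_equal(ungapped_homologs(hs)[["spB"]], "AGGTTTAGA")
  # absent species flagged
  hs2 <- extract_homologs(blocks, c("spB", "spD"), interval_query("chr1", 0, 8))
  expect_equal(unname(hs2$status[["spD"]]), "absent")
  # empty slice: everything absent
  hs3 <- extract_homologs(list(), c("spB"), interval_query("chr1", 0, 8))
  expect_equal(unname(hs3$status[["spB"]]), "absent")
})

test_that("overlapping reference blocks are rejected", {
  blocks <- parse_maf(write_toy_maf(c(
    "a", "s ref.chr1 0 6 + 20 ACGTAC", "",
    "a", "s ref.chr1 4 6 + 20 ACTTAA")))
  expect_error(extract_homologs(blocks, character(0), interval_query("chr1", 0, 10)),
               "single-coverage")
})

test_that("ortholog screening applies identity, coverage and read thresholds", {
  base <- data.frame(precursor_id = "p1", species = "spB",
                     identity = 0.95, coverage = 60, stringsAsFactors = FALSE)
  expr <- data.frame(precursor_id = "p1", species = "spB", reads = 12L)
  expect_equal(screen_orthologs(base, expr)$n_retained, 1L)
  low <- base; low$identity <- 0.89
  expect_equal(screen_orthologs(low, expr)$n_retained, 0L)
  short <- base; short$coverage <- 50    # "greater than 50" is strict
  expect_equal(screen_orthologs(short, expr)$n_retained, 0L)
  few <- expr; few$reads <- 9L
  expect_equal(screen_orthologs(base, few)$n_retained, 0L)

  # 240 candidates planted so that 93 pass all three criteria
  withr::with_seed(61, {
    n <- 240
    pass <- rep(FALSE, n); pass[sample(n, 93)] <- TRUE
    tab <- data.frame(precursor_id = sprintf("p%03d", 1:n), species = "spB",
                      identity = ifelse(pass, runif(n, 0.9, 1), runif(n, 0.5, 0.89)),
                      coverage = ifelse(pass, 60, sample(c(30, 60), n, TRUE)),
                      stringsAsFactors = FALSE)
    ex <- data.frame(precursor_id = tab$precursor_id, species = "spB",
                     reads = ifelse(pass, 10L + rpois(n, 5), 3L))
    res <- screen_orthologs(tab, ex)
    expect_equal(res$n_retained, 93L)
    expect_equal(res$proportion, 93 / 240)
  })
})
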