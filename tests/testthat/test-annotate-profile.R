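## A precursor with known arm intervals drives the profiling tests. The two
## arms are deliberately NOT reverse complements of each other, so antisense
## placements are distinguishable from sense 3p placements.
make_test_precursor <- function() {
  arm5 <- "TGAGGTAGTAGGTTGTATAGTT"       # 22 nt
  loop <- "ATATACAATATA"                 # 12 nt
  arm3 <- "CTGTACAGCCTCCTAGCTTTCC"       # 22 nt
  precursor_annotation("pre-1", paste0(arm5, loop, arm3),
                       arm5_start = 0L, arm5_end = 22L,
                       arm3_start = 34L, arm3_end = 56L)
}

test_that("database filtering partitions reads exhaustively and disjointly", {
  db <- c(trna = "GGGCCCGGGAAATTTCCCGGGCCCAAATTTGGGCCCAAATTT")
  reads <- collapse_reads(c(substr(db[[1]], 3, 24),        # exact db substring
                            "ACACACACACACACACACAC",        # matches nothing
                            oracle_revcomp(substr(db[[1]], 5, 26))), "lib")
  parts <- filter_by_db(reads, db, filter_config(max_mismatch_db = 2))
  expect_equal(nrow(parts$discarded) + nrow(parts$retained), nrow(reads))
  expect_equal(nrow(parts$discarded), 2L)  # antisense hit also discards
  expect_equal(parts$retained$sequence, "ACACACACACACACACACAC")
})

test_that("reads one mismatch beyond the bound are retained", {
  withr::with_seed(21, {
    db <- c(x = random_seq(200))
    q <- strsplit(substr(db[[1]], 50, 71), "")[[1]]
    flip <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
    for (i in c(3, 10, 17)) q[i] <- flip(q[i])  # 3 mismatches
    reads <- collapse_reads(paste(q, collapse = ""), "lib")
    # brute-force confirms the best db placement has 3 mismatches
    best <- oracle_align(reads$sequence, db, 3)
    expect_equal(min(best$mismatches), 3L)
    parts <- filter_by_db(reads, db, filter_config(max_mismatch_db = 2))
    expect_equal(nrow(parts$retained), 1L)
  })
})

test_that("precursor profiling assigns arms by the half-overlap rule", {
  ann <- make_test_precursor()
  pre <- ann$sequence
  reads <- collapse_reads(c(rep(substr(pre, 1, 22), 2),   # 5p exact
                            substr(pre, 2, 23),           # 5p, 21/22 inside
                            rep(substr(pre, 35, 56), 4)), "lib")
  out <- profile_known(reads, ann)
  e <- out$expression
  expect_equal(e$count_5p, 3)
  expect_equal(e$count_3p, 4)
  expect_equal(e$total_count, 7)
  expect_equal(e$count_5p + e$count_3p + e$unassigned_count, e$total_count)
  expect_equal(nrow(out$leftover), 0L)
})

test_that("antisense reads are not counted and loop-spanners are unassigned", {
  ann <- make_test_precursor()
  pre <- ann$sequence
  anti <- collapse_reads(oracle_revcomp(substr(pre, 1, 22)), "lib")
  out <- profile_known(anti, ann)
  expect_equal(out$expression$total_count, 0)
  expect_equal(nrow(out$leftover), 1L)  # exported for novel prediction
  # read centered on the loop: < 50% overlap with each arm
  spanner <- collapse_reads(substr(pre, 18, 39), "lib")  # covers 17..38 0-based
  out2 <- profile_known(spanner, ann)
  expect_equal(out2$expression$unassigned_count, 1)
  expect_equal(out2$expression$count_5p + out2$expression$count_3p, 0)
})

test_that("multi-mapping reads count fully per precursor, or fractionally on request", {
  ann0 <- make_test_precursor()
  ann <- precursor_annotation(c("pre-1", "pre-2"), rep(ann0$sequence, 2),
                              arm5_start = rep(0L, 2), arm5_end = rep(22L, 2),
                              arm3_start = rep(34L, 2), arm3_end = rep(56L, 2))
  reads <- collapse_reads(rep(substr(ann0$sequence, 1, 22), 6), "lib")
  full <- profile_known(reads, ann)$expression
  expect_equal(full$count_5p, c(6, 6))
  frac <- profile_known(reads, ann, filter_config(fractional_counts = TRUE))$expression
  expect_equal(frac$count_5p, c(3, 3))
})

test_that("annotation database order does not change profiling counts", {
  ann0 <- make_test_precursor()
  withr::with_seed(31, {
    ann <- precursor_annotation(c("a", "b", "c"),
                                c(ann0$sequence, random_seq(60), random_seq(60)),
                                arm5_start = c(0L, 0L, 0L),
                                arm5_end = c(22L, 20L, 20L),
                                arm3_start = c(34L, 40L, 40L),
                                arm3_end = c(56L, 60L, 60L))
    reads <- collapse_reads(c(substr(ann0$sequence, 1, 22),
                              substr(ann$sequence[2], 1, 20)), "lib")
    e1 <- profile_known(reads, ann)$expression
    perm <- ann[c(3, 1, 2), ]
    e2 <- profile_known(reads, precursor_annotation(
      perm$precursor_id, perm$sequence, perm$arm5_start, perm$arm5_end,
      perm$arm3_start, perm$arm3_end))$expression
    m <- match(e1$precursor_id, e2$precursor_id)
    expect_equal(e1$total_count, e2$total_count[m])
    expect_equal(e1$count_5p, e2$count_5p[m])
  })
})

test_that("annotation constructor enforces interval invariants", {
  expect_error(precursor_annotation("p", "ACGTACGT", arm5_start = 0L, arm5_end = 20L),
               "invalid 5p")
  expect_error(precursor_annotation("p", strrep("ACGT", 20),
                                    arm5_start = 30L, arm5_end = 52L,
                                    arm3_start = 10L, arm3_end = 30L),
               "precede")
})
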