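test_that("substitution counting classifies matches, transitions, transversions, gaps", {
  sc <- count_substitutions("ACGT", "ACGT")
  expect_equal(sc$matches, 4L)
  expect_equal(sc$compared_columns, 4L)
  sc <- count_substitutions("ACGT", "GCGT")
  expect_equal(c(sc$matches, sc$transitions, sc$transversions), c(3L, 1L, 0L))
  sc <- count_substitutions("AC-T", "ACTT")
  expect_equal(c(sc$gap_columns, sc$compared_columns), c(1L, 3L))
  sc <- count_substitutions("ACNT", "ACGT")
  expect_equal(sc$ambiguous_columns, 1L)
  # transversions: purine <-> pyrimidine
  sc <- count_substitutions("AACC", "CTGA")
  expect_equal(sc$transversions, 4L)
  expect_error(count_substitutions("ACG", "AC"), "differ in length")
  # bookkeeping identity across random pairs
  withr::with_seed(71, {
    for (i in 1:10) {
      a <- random_seq(50, c("A", "C", "G", "T", "N", "-"))
      b <- random_seq(50, c("A", "C", "G", "T", "N", "-"))
      sc <- count_substitutions(a, b)
      expect_equal(sc$compared_columns + sc$gap_columns + sc$ambiguous_columns, 50L)
      expect_equal(sc$matches + sc$transitions + sc$transversions, sc$compared_columns)
    }
  })
})

test_that("K2P distance matches the analytic form and flags saturation", {
  expect_equal(k2p(0, 0)$kmir, 0)
  expect_equal(k2p(0.25, 0)$kmir, 0.3465736, tolerance = 1e-6)
  expect_equal(k2p(0.1, 0.05)$kmir, 0.1701812, tolerance = 1e-6)
  expect_true(k2p(0.5, 0.2)$saturated)
  expect_true(k2p(0, 0.5)$saturated)
  expect_error(k2p(-0.1, 0), "non-negative")
  expect_error(k2p(0.7, 0.6), "exceed")
  # Q = 0 reduces to the two-state correction; K >= P + Q; monotone in P
  grid <- seq(0.01, 0.4, by = 0.01)
  two_state <- vapply(grid, function(p) k2p(p, 0)$kmir, numeric(1))
  expect_equal(two_state, -0.5 * log(1 - 2 * grid), tolerance = 1e-12)
  for (q in c(0, 0.05, 0.1)) {
    ks <- vapply(grid[grid + q < 0.45], function(p) k2p(p, q)$kmir, numeric(1))
    ps <- grid[grid + q < 0.45]
    expect_true(all(ks >= ps + q))
    expect_true(all(diff(ks) > 0))
  }
})

test_that("K2P agrees with the phylogenetics reference implementation", {
  skip_if_not_installed("ape")
  withr::with_seed(81, {
    for (i in 1:5) {
      a <- random_seq(400)
      bc <- strsplit(a, "")[[1]]
      mut <- sample(400, 60)
      bc[mut] <- vapply(bc[mut], function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
      b <- paste(bc, collapse = "")
      sc <- count_substitutions(a, b)
      mine <- k2p(sc$transitions / sc$compared_columns,
                  sc$transversions / sc$compared_columns)$kmir
      bin <- ape::as.DNAbin(rbind(x = strsplit(tolower(a), "")[[1]],
                                  y = strsplit(tolower(b), "")[[1]]))
      expect_equal(mine, as.numeric(ape::dist.dna(bin, model = "K80")),
                   tolerance = 1e-9)
    }
  })
})

test_that("region distances map arm intervals through gapped reference rows", {
  # reference precursor of 56 nt with a 22 nt mature on each arm
  arm5 <- "TGAGGTAGTAGGTTGTATAGTT"
  pre <- paste0(arm5, "ATATACAATATA", oracle_revcomp(arm5))
  ann <- precursor_annotation("pre-1", pre, 0L, 22L, 34L, 56L)
  # homolog with 2 transitions planted inside the mature 5p region
  other <- strsplit(pre, "")[[1]]
  other[c(3, 10)] <- "G"  # two A->G transitions inside the 5p mature
  hs <- structure(list(precursor_id = "pre-1", ref_species = "ref",
                       species = c("ref", "spB"),
                       alignment = c(ref = pre, spB = paste(other, collapse = "")),
                       status = c(ref = "complete", spB = "complete"),
                       src = c(ref = "ref.chr1", spB = "spB.chr1"),
                       strand = c(ref = "+", spB = "+"),
                       interval = list(ref = c(0L, 56L), spB = c(0L, 56L)),
                       ref_interval = interval_query("chr1", 0, 56)),
                  class = "homolog_set")
  d <- region_distances(hs, ann)
  mat5 <- d[d$region == "mature_5p", ]
  expect_equal(mat5$P, 2 / 22)
  expect_equal(mat5$kmir, k2p(2 / 22, 0)$kmir)
  prec <- d[d$region == "precursor", ]
  expect_equal(prec$P, 2 / 56)
  expect_lt(prec$P, mat5$P)
  expect_equal(d[d$region == "seed_5p", ]$coverage, 7L)
  # identical homolog: all regions at distance 0
  hs0 <- hs; hs0$alignment[["spB"]] <- pre
  d0 <- region_distances(hs0, ann)
  expect_true(all(d0$kmir == 0))
  expect_true(all(d0$identity == 1))

  # a reference gap before the mature start shifts the column mapping by 1
  hsg <- hs
  hsg$alignment <- c(ref = paste0("-", pre), spB = paste0("A", paste(other, collapse = "")))
  dg <- region_distances(hsg, ann)
  expect_equal(dg[dg$region == "mature_5p", ]$P, mat5$P)
  expect_equal(dg[dg$region == "precursor", ]$coverage, 56L)
  expect_error(region_distances(hs, precursor_annotation("pre-1", pre, 0L, 22L, 40L, 60L)))
})

test_that("planted substitution rates are recovered within binomial error", {
  cfg <- simulation_config(seed = 91, genome_length = 10000L,
                           transition_rate = 0.10, transversion_rate = 0.05,
                           indel_rate = 0)
  g <- make_genome(cfg)
  mut <- mutate_genome(g, cfg)
  sc <- count_substitutions(mut$alignment[["ref"]], mut$alignment[["alt"]])
  n <- sc$compared_columns
  se <- function(p) sqrt(p * (1 - p) / n)
  expect_lt(abs(sc$transitions / n - 0.10), 3 * se(0.10))
  expect_lt(abs(sc$transversions / n - 0.05), 3 * se(0.05))
})

test_that("Kmir/Ks ratio is a guarded division", {
  expect_equal(kmir_ks_ratio(0.5, 1.0), 0.5)
  expect_equal(kmir_ks_ratio(0, 0.3), 0)
  expect_equal(kmir_ks_ratio(0.3, 0.2), 1.5)
  expect_error(kmir_ks_ratio(0.5, 0), "positive")
})
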