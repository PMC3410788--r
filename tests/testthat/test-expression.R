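test_that("TPM normalization is exact and scale-invariant", {
  expect_equal(tpm(50, 1e6), 50)
  expect_equal(tpm(0, 123), 0)
  expect_equal(tpm(3, 2e6), 1.5)
  expect_error(tpm(5, 0), "positive")
  expect_equal(tpm(7 * 10, 1e5 * 10), tpm(7, 1e5))
})

test_that("Poisson LRT matches closed-form worked values and is symmetric", {
  r <- poisson_lrt(10, 1e6, 10, 1e6)
  expect_equal(r$G, 0)
  expect_equal(r$p, 1)
  r <- poisson_lrt(10, 1e6, 30, 1e6)
  expect_equal(r$G, 10.46496, tolerance = 1e-6)
  expect_equal(r$p, 0.001217, tolerance = 1e-3)
  r <- poisson_lrt(0, 1e6, 5, 1e6)     # 0 log 0 convention
  expect_equal(r$G, 6.93147, tolerance = 1e-5)
  expect_equal(r$p, 0.00847, tolerance = 1e-3)
  r0 <- poisson_lrt(0, 1e5, 0, 2e5)
  expect_true(r0$undefined)
  expect_equal(r0$p, 1)
  # symmetry under swapping libraries
  withr::with_seed(131, {
    x1 <- rpois(50, 40); x2 <- rpois(50, 60)
    a <- poisson_lrt(x1, 1e5, x2, 3e5)
    b <- poisson_lrt(x2, 3e5, x1, 1e5)
    expect_equal(a$G, b$G)
    expect_equal(a$p, b$p)
  })
  expect_error(poisson_lrt(5, 0, 5, 10), "positive")
})

test_that("closed-form LRT equals the Poisson regression deviance test", {
  withr::with_seed(141, {
    for (i in 1:10) {
      N <- c(2e5, 5e5)
      x <- rpois(2, c(30, 80))
      mine <- poisson_lrt(x[1], N[1], x[2], N[2])
      fit1 <- stats::glm(x ~ factor(1:2) + offset(log(N)), family = stats::poisson())
      fit0 <- stats::glm(x ~ 1 + offset(log(N)), family = stats::poisson())
      dev <- as.numeric(stats::anova(fit0, fit1)$Deviance[2])
      expect_equal(mine$G, dev, tolerance = 1e-8)
    }
  })
})

test_that("LRT type-I error is calibrated under the null", {
  withr::with_seed(151, {
    n <- 4000
    N1 <- 2e5; N2 <- 3e5; lambda <- 1e-4   # expected counts 20 and 30
    x1 <- rpois(n, lambda * N1); x2 <- rpois(n, lambda * N2)
    res <- poisson_lrt(x1, N1, x2, N2)
    rate <- mean(res$p < 0.05)
    expect_gt(rate, 0.035)
    expect_lt(rate, 0.065)
  })
})

test_that("per-arm ortholog counting follows projected coordinates", {
  hp <- make_hairpin(seed = 8)
  ann <- precursor_annotation("pre-1", hp$sequence,
                              hp$arm5[1], hp$arm5[2], hp$arm3[1], hp$arm3[2])
  n <- nchar(hp$sequence)
  # species B homolog: 2-nt insertion in the reference before the mature 3p arm
  ref_row <- paste0(substr(hp$sequence, 1, 30), "--", substr(hp$sequence, 31, n))
  alt_seq <- paste0(substr(hp$sequence, 1, 30), "CA", substr(hp$sequence, 31, n))
  hs <- structure(list(precursor_id = "pre-1", ref_species = "ref",
                       species = c("ref", "spB"),
                       alignment = c(ref = ref_row, spB = alt_seq),
                       status = c(ref = "complete", spB = "complete"),
                       src = c(ref = "ref.chr1", spB = "spB.chr1"),
                       strand = c(ref = "+", spB = "+"),
                       interval = list(ref = c(0L, n), spB = c(0L, n + 2L)),
                       ref_interval = interval_query("chr1", 0, n)),
                  class = "homolog_set")
  reads_a <- collapse_reads(rep(substr(hp$sequence, 1, 22), 7), "ra")
  # B's 3p reads sit 2 nt downstream in B coordinates
  reads_b <- collapse_reads(c(rep(substr(alt_seq, hp$arm3[1] + 3, hp$arm3[2] + 2), 4),
                              rep(substr(alt_seq, 1, 22), 2)), "rb")
  ae <- count_orthologs(list(ref = reads_a, spB = reads_b), list(hs), ann)
  expect_equal(ae[ae$species == "ref" & ae$arm == "5p", "x"], 7L)
  expect_equal(ae[ae$species == "ref" & ae$arm == "3p", "x"], 0L)
  expect_equal(ae[ae$species == "spB" & ae$arm == "3p", "x"], 4L)
  expect_equal(ae[ae$species == "spB" & ae$arm == "5p", "x"], 2L)
  expect_equal(unique(ae$N[ae$species == "spB"]), 6L)
  expect_equal(ae$tpm, ae$x / ae$N * 1e6)
  expect_error(count_orthologs(list(ref = collapse_reads(character(), "e")),
                               list(hs), ann), "empty library")
})

test_that("differential expression table flags planted changes under BH", {
  withr::with_seed(161, {
    n_arms <- 100
    N <- 1e5
    base_rate <- 2e-4                    # expected count 20
    changed <- sample(n_arms, 10)
    lam1 <- rep(base_rate, n_arms)
    lam2 <- lam1
    lam2[changed] <- lam2[changed] * 4   # planted 4-fold changes
    x1 <- rpois(n_arms, lam1 * N); x2 <- rpois(n_arms, lam2 * N)
    ae <- rbind(
      data.frame(precursor_id = sprintf("p%03d", 1:n_arms), species = "A",
                 arm = "5p", x = x1, N = N, tpm = x1 / N * 1e6),
      data.frame(precursor_id = sprintf("p%03d", 1:n_arms), species = "B",
                 arm = "5p", x = x2, N = N, tpm = x2 / N * 1e6))
    dt <- diff_table(ae, alpha = 0.05, correction = "bh")
    flagged <- which(dt$significant)
    expect_true(all(changed %in% flagged))
    expect_lte(length(setdiff(flagged, changed)), 2L)
    # q-values: monotone in p-rank, and q >= p
    ord <- order(dt$p)
    expect_true(all(diff(dt$q[ord]) >= -1e-12))
    expect_true(all(dt$q >= dt$p - 1e-12))
  })
})

test_that("diff_table handles edge cases: equal rates, single arm, bad input", {
  ae <- rbind(data.frame(precursor_id = "p1", species = "A", arm = "5p",
                         x = 20L, N = 1e5, tpm = 200),
              data.frame(precursor_id = "p1", species = "B", arm = "5p",
                         x = 40L, N = 2e5, tpm = 200))
  dt <- diff_table(ae)
  expect_equal(dt$p, 1)
  expect_equal(dt$q, dt$p)               # BH with m = 1
  expect_false(dt$significant)
  expect_error(diff_table(ae[1, ]), "2 species")
  # pseudocount applies to the log-scale columns only
  expect_equal(dt$log2_tpm_1, log2((20 + 1) / 1e5 * 1e6))
})

test_that("Yates chi-square reproduces worked values and rejects bad tables", {
  res <- yates_chisq(matrix(c(93, 147, 66, 174), 2, byrow = TRUE))
  expect_equal(signif(res$p, 2), 0.012)
  same <- yates_chisq(matrix(c(50, 30, 50, 30), 2, byrow = TRUE))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  diag <- yates_chisq(matrix(c(20, 0, 0, 20), 2))
  expect_equal(diag$chi2, 36.1, tolerance = 1e-10)
  expect_error(yates_chisq(matrix(c(5, 0, 5, 0), 2)), "margin")
  expect_error(yates_chisq(matrix(1:6, 2)), "2x2")
})
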