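test_that("fisher_exact matches symmetry, closed form, and stats oracle", {
  r <- fisher_exact(10, 10, 10, 10)
  expect_equal(r$p_value, 1.0)
  expect_equal(r$odds_ratio, 1.0)
  # closed-form hypergeometric tail: [[5,0],[0,5]] -> 2 / C(10,5)
  expect_equal(fisher_exact(5, 0, 0, 5)$p_value, 2 / choose(10, 5))
  # degenerate margins
  expect_equal(fisher_exact(0, 0, 3, 4)$p_value, 1.0)
  # random tables vs both stats::fisher.test and explicit enumeration
  set.seed(14)
  for (i in 1:300) {
    n <- sample(1:200, 1)
    cells <- as.vector(stats::rmultinom(1, n, runif(4, 0.05, 1)))
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    p <- fisher_exact(a, b, c, d)$p_value
    expect_equal(p, oracle_fisher_p(a, b, c, d), tolerance = 1e-12)
    if ((a + b) > 0 && (c + d) > 0 && (a + c) > 0 && (b + d) > 0)
      expect_equal(p, stats::fisher.test(
        matrix(c(a, c, b, d), 2))$p.value, tolerance = 1e-9)
    # two-sided symmetry under swapping the groups
    expect_equal(p, fisher_exact(c, d, a, b)$p_value, tolerance = 1e-12)
  }
})

make_two_stage_prof <- function(counts) {
  # counts: list(site1 = c(A, B), site2 = c(A, B))
  cc <- rbindlist(lapply(seq_along(counts), function(i)
    data.table(gene_id = "G", chrom = "chr1", strand = "+",
               position = 1000L + 100L * (i - 1L),
               sample_id = c("sA", "sB"), n = counts[[i]])))
  build_pas_profiles(cc, min_usage = 0)
}

test_that("contingency tables assemble site vs rest by stage", {
  prof <- make_two_stage_prof(list(c(90L, 50L), c(10L, 50L)))
  tab <- apa_contingency(prof, "G:1", "sA", "sB")
  expect_equal(unname(tab), matrix(c(90, 10, 50, 50), 2, byrow = TRUE))
  # single-site gene -> NULL with message
  cc1 <- data.table(gene_id = "G", chrom = "chr1", strand = "+",
                    position = 1000L, sample_id = "sA", n = 5L)
  p1 <- build_pas_profiles(cc1)
  expect_message(out <- apa_contingency(p1, "G:1", "sA", "sB"), "single")
  expect_null(out)
  # zero reads in one group -> NULL with message
  expect_message(out2 <- apa_contingency(prof, "G:1", "sA", "missing"),
                 "zero reads")
  expect_null(out2)
})

test_that("differential_apa calls, effect sign, BH column, edge cases", {
  prof <- make_two_stage_prof(list(c(90L, 50L), c(10L, 50L)))
  sheet <- data.table(sample_id = c("sA", "sB"),
                      stage = c("S1", "S2"), replicate = 1L,
                      library_size = 100L)
  calls <- differential_apa(prof, sheet)
  expect_equal(nrow(calls), 2L)
  c1 <- calls[site_id == "G:1"]
  expect_equal(c1$comparison, "S1vsS2")
  expect_equal(c1$usage_a, 0.9)
  expect_equal(c1$effect, -0.4)
  expect_equal(c1$p_value, fisher_exact(90, 10, 50, 50)$p_value)
  expect_true(c1$significant)
  expect_true(all(calls$padj >= calls$p_value))
  # single stage -> empty, with message
  expect_message(
    e <- differential_apa(prof, sheet[1], alpha = 0.05), "fewer")
  expect_equal(nrow(e), 0L)
})

test_that("replicates pool within stage and comparisons are consecutive", {
  cc <- rbindlist(lapply(1:2, function(i)
    data.table(gene_id = "G", chrom = "chr1", strand = "+",
               position = 1000L + 100L * (i - 1L),
               sample_id = c("a1", "a2", "b1", "b2", "c1"),
               n = c(20L, 25L, 30L, 35L, 40L) + i)))
  prof <- build_pas_profiles(cc, min_usage = 0)
  sheet <- data.table(sample_id = c("a1", "a2", "b1", "b2", "c1"),
                      stage = c("S1", "S1", "S2", "S2", "S3"),
                      replicate = c(1L, 2L, 1L, 2L, 1L),
                      library_size = 100L)
  calls <- differential_apa(prof, sheet)
  expect_setequal(unique(calls$comparison), c("S1vsS2", "S2vsS3"))
  c1 <- calls[site_id == "G:1" & comparison == "S1vsS2"]
  expect_equal(c1$site_a, 21 + 26)   # pooled replicates
  expect_equal(c1$site_b, 31 + 36)
})

test_that("type-I error of the Fisher screen is near alpha under the null", {
  set.seed(5)
  n_tests <- 600L
  reject <- logical(n_tests)
  for (i in seq_len(n_tests)) {
    xa <- stats::rbinom(1, 500, 0.6)
    xb <- stats::rbinom(1, 500, 0.6)
    reject[i] <- fisher_exact(xa, 500 - xa, xb, 500 - xb)$p_value < 0.05
  }
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / n_tests)
  expect_gt(mean(reject), ci[1] - 0.01)
  expect_lt(mean(reject), ci[2])
})

test_that("a planted 0.7 -> 0.3 usage shift is detected", {
  set.seed(8)
  hits <- vapply(1:50, function(i) {
    xa <- stats::rbinom(1, 500, 0.7)
    xb <- stats::rbinom(1, 500, 0.3)
    fisher_exact(xa, 500 - xa, xb, 500 - xb)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("psi permutation test: identity, exhaustive oracle, determinism", {
  expect_equal(psi_permutation_test(c(0.5, 0.5), c(0.5, 0.5))$p_value, 1.0)
  # exhaustive enumeration for 3 vs 3 equals a combn oracle
  a <- c(0.9, 0.9, 0.9); b <- c(0.1, 0.1, 0.1)
  res <- psi_permutation_test(a, b)
  expect_true(res$exhaustive)
  pool <- c(a, b)
  deltas <- apply(combn(6, 3), 2, function(ii)
    abs(mean(pool[-ii]) - mean(pool[ii])))
  expect_equal(res$p_value, mean(deltas >= abs(mean(b) - mean(a)) - 1e-12))
  expect_equal(res$delta_psi, -0.8)
  # random mode is deterministic under a fixed seed
  set.seed(NULL)
  x <- runif(12); y <- runif(12, 0.2, 1)
  r1 <- psi_permutation_test(x, y, n_perm = 200, seed = 77)
  r2 <- psi_permutation_test(x, y, n_perm = 200, seed = 77)
  expect_false(r1$exhaustive)
  expect_identical(r1$p_value, r2$p_value)
  # undefined PSI -> untestable with message
  expect_message(r3 <- psi_permutation_test(NA_real_, c(0.5)), "untestable")
  expect_true(is.na(r3$p_value))
})
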