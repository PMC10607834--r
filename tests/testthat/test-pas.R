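test_that("cluster_cleavage_sites follows the greedy/merge rules", {
  # hand-traced: 100(50) absorbs 105(10); 160(30) stands alone
  out <- cluster_cleavage_sites(c(100, 105, 160), c(50, 10, 30))
  expect_equal(out$position, c(100, 160))
  expect_equal(out$count, c(60, 30))
  # 25 nt apart (< min 30): weaker representative merges into winner
  out <- cluster_cleavage_sites(c(100, 125), c(50, 40))
  expect_equal(out$position, 100)
  expect_equal(out$count, 90)
  # identity case
  out <- cluster_cleavage_sites(200, 7)
  expect_equal(out, data.table(position = 200, count = 7),
               ignore_attr = TRUE)
  expect_error(cluster_cleavage_sites(1, 1, assignment_halfwidth = 0),
               "positive")
  expect_error(cluster_cleavage_sites(1, 1, min_separation = -1),
               "positive")
})

test_that("clustering equals the independent trace oracle", {
  set.seed(21)
  for (i in 1:300) {
    k <- sample(1:20, 1)
    pos <- sort(sample(1:300, k))
    cnt <- sample(1:50, k, replace = TRUE)
    got <- cluster_cleavage_sites(pos, cnt)
    want <- oracle_cluster(pos, cnt)
    expect_equal(got$position, want$pos)
    expect_equal(got$count, want$cnt)
    # separation invariant and read conservation
    if (nrow(got) > 1) expect_gt(min(diff(got$position)), 30)
    expect_equal(sum(got$count), sum(cnt))
    # assignment partitions all positions
    asg <- attr(got, "assignment")
    expect_setequal(asg$position, pos)
    expect_true(all(asg$site_position %in% got$position))
  }
})

test_that("collect_cleavage_counts tallies exactly and tracks unassigned", {
  cl <- data.table(read_id = paste0("r", 1:4), chrom = "chr1",
                   position = c(100L, 100L, 100L, 200L), strand = "+",
                   gene_id = c("G", "G", "G", NA), sample_id = "S")
  cc <- collect_cleavage_counts(cl)
  expect_equal(cc$counts$n, 3L)
  expect_equal(cc$counts$position, 100L)
  expect_equal(cc$n_unassigned, 1L)
  empty <- collect_cleavage_counts(cl[0])
  expect_equal(nrow(empty$counts), 0L)
})

test_that("simulator ledger totals match collected counts", {
  s <- small_sim()
  cl <- suppressMessages(read_end_sites(s$exp$reads, s$sim$annotation))
  cc <- collect_cleavage_counts(cl)
  expect_equal(sum(cc$counts$n) + cc$n_unassigned,
               sum(s$exp$ledger$n_reads))
  # per-gene conservation into clustered sites (pre-filter)
  prof <- suppressMessages(build_pas_profiles(cc$counts, min_usage = 0))
  per_gene_sites <- prof$sites[, .(n = sum(count)), by = gene_id]
  per_gene_reads <- cc$counts[, .(n = sum(n)), by = gene_id]
  m <- merge(per_gene_sites, per_gene_reads, by = "gene_id")
  expect_equal(m$n.x, m$n.y)
})

test_that("usage filter is strict, single-pass, renormalizing", {
  mk_prof <- function(counts) {
    cc <- data.table(gene_id = "G", chrom = "chr1", strand = "+",
                     position = seq(1000, by = 100,
                                    length.out = length(counts)),
                     sample_id = "s1", n = counts)
    build_pas_profiles(cc)
  }
  p <- mk_prof(c(96, 4))          # 0.04 <= 0.05 -> removed
  expect_equal(nrow(p$sites), 1L)
  expect_equal(p$sites$usage, 1.0)
  p <- mk_prof(c(50, 45, 5))      # 0.05 is not > 0.05 -> removed
  expect_equal(p$sites$usage, c(50 / 95, 45 / 95))
  p <- mk_prof(7)                 # single site retained, usage 1
  expect_equal(p$sites$usage, 1.0)
  # gene with all sites at threshold is dropped with a message
  cc0 <- data.table(gene_id = "G", chrom = "chr1", strand = "+",
                    position = c(1000L, 1100L, 1200L, 1300L,
                                 1400L, 1500L, 1600L, 1700L,
                                 1800L, 1900L, 2000L, 2100L,
                                 2200L, 2300L, 2400L, 2500L,
                                 2600L, 2700L, 2800L, 2900L),
                    sample_id = "s1", n = rep(5L, 20))
  expect_message(p0 <- build_pas_profiles(cc0), "dropped")
  expect_equal(nrow(p0$sites), 0L)
  expect_equal(p0$dropped_genes, "G")
})

test_that("major site selection and the 3'-most tie-break", {
  mk <- function(counts, strand) {
    cc <- data.table(gene_id = "G", chrom = "chr1", strand = strand,
                     position = seq(1000, by = 100,
                                    length.out = length(counts)),
                     sample_id = "s1", n = counts)
    build_pas_profiles(cc)
  }
  p <- mk(c(80, 20), "+")
  expect_equal(p$sites[is_major == TRUE]$position, 1000)
  expect_equal(sum(p$sites$is_major), 1L)
  # tie: 3'-most in transcription direction
  p <- mk(c(50, 50), "+")
  expect_equal(p$sites[is_major == TRUE]$position, 1100)
  p <- mk(c(50, 50), "-")
  expect_equal(p$sites[is_major == TRUE]$position, 1000)
  # site ordinals run 5' -> 3' in transcription direction
  expect_equal(p$sites[order(position)]$site_ord, c(2L, 1L))
})

test_that("normalization scales by median library size; ratios to major", {
  cc <- data.table(gene_id = "G", chrom = "chr1", strand = "+",
                   position = rep(c(1000L, 1100L), each = 2),
                   sample_id = rep(c("A", "B"), 2),
                   n = c(5L, 5L, 45L, 45L))
  prof <- build_pas_profiles(cc)
  expect_error(normalize_abundance(prof, c(A = 0, B = 1)), "positive")
  # equal library sizes: normalized equals raw
  p1 <- normalize_abundance(prof, c(A = 100, B = 100))
  expect_equal(p1$counts$normalized, p1$counts$count)
  # worked example: libs 100/200, median 150, raw 10 -> 15 and 7.5
  cc2 <- data.table(gene_id = "G", chrom = "chr1", strand = "+",
                    position = 1000L, sample_id = c("A", "B"),
                    n = c(10L, 10L))
  p2 <- normalize_abundance(build_pas_profiles(cc2),
                            c(A = 100, B = 200))
  expect_equal(p2$counts[sample_id == "A"]$normalized, 15)
  expect_equal(p2$counts[sample_id == "B"]$normalized, 7.5)
  expect_equal(p2$sites$major_ratio, 1.0)
  expect_equal(p1$sites[is_major == TRUE]$major_ratio, 1.0)
})

test_that("APA classification and histogram", {
  cc <- rbindlist(list(
    data.table(gene_id = "G1", chrom = "chr1", strand = "+",
               position = 1000L, sample_id = "s", n = 50L),
    data.table(gene_id = "G2", chrom = "chr1", strand = "+",
               position = c(2000L, 2100L, 2200L), sample_id = "s",
               n = c(30L, 30L, 40L))))
  cls <- classify_apa_genes(build_pas_profiles(cc))
  expect_equal(cls$n_single, 1L)
  expect_equal(cls$n_apa, 1L)
  expect_equal(cls$classes[gene_id == "G2"]$n_sites, 3L)
  expect_equal(cls$histogram[n_sites == 3]$n_genes, 1L)
})

test_that("intronic flags equal a brute-force membership oracle", {
  s <- small_sim()
  cl <- suppressMessages(read_end_sites(s$exp$reads, s$sim$annotation))
  prof <- build_pas_profiles(collect_cleavage_counts(cl)$counts)
  prof <- locate_intronic_pas(prof, s$sim$annotation)
  # oracle: longest transcript per gene, test strict containment
  ann <- s$sim$annotation
  for (i in seq_len(nrow(prof$sites))) {
    g <- prof$sites$gene_id[i]; p <- prof$sites$position[i]
    tx <- ann$transcripts[gene_id == g]
    ref <- tx$transcript_id[order(-tx$exonic_length, tx$transcript_id)][1]
    ints <- extract_introns(ann, ref)
    want <- nrow(ints) > 0 && any(ints$start <= p & p <= ints$end)
    expect_equal(prof$sites$is_intronic[i], want)
  }
  expect_gt(sum(prof$sites$is_intronic), 0L)
})

test_that("intron length comparison recovers the planted long-intron bias", {
  s <- small_sim()
  cl <- suppressMessages(read_end_sites(s$exp$reads, s$sim$annotation))
  prof <- build_pas_profiles(collect_cleavage_counts(cl)$counts)
  prof <- locate_intronic_pas(prof, s$sim$annotation)
  cmp <- intron_length_comparison(s$sim$annotation, prof)
  expect_gt(cmp$median_pas, cmp$median_other)
  expect_lt(cmp$p_value, 0.05)
  # two-intron worked case
  ann <- make_ann(list(g = list(t1 = list(c(1, 100), c(201, 300),
                                          c(10301, 10400)))))
  cc <- data.table(gene_id = "g", chrom = "chr1", strand = "+",
                   position = c(5000L, 10400L), sample_id = "s",
                   n = c(10L, 90L))
  p <- locate_intronic_pas(build_pas_profiles(cc), ann)
  out <- intron_length_comparison(ann, p)
  expect_equal(out$median_pas, 10000)
  expect_equal(out$median_other, 100)
  # identical groups -> p about 1
  expect_gt(suppressWarnings(
    stats::wilcox.test(c(1, 2, 3), c(1, 2, 3))$p.value), 0.9)
})

test_that("profiles mirror under strand reflection", {
  set.seed(33)
  pos <- sort(sample(1000:1500, 40))
  n <- sample(1:30, 40, replace = TRUE)
  n <- n + seq_along(n) %% 2          # break count ties deterministically
  cc_p <- data.table(gene_id = "G", chrom = "chr1", strand = "+",
                     position = pos, sample_id = "s", n = n)
  L <- 3000L
  cc_m <- data.table(gene_id = "G", chrom = "chr1", strand = "-",
                     position = L + 1L - pos, sample_id = "s", n = n)
  p_p <- build_pas_profiles(cc_p)
  p_m <- build_pas_profiles(cc_m)
  sp <- p_p$sites[order(position)]
  sm <- p_m$sites[order(-position)]
  expect_equal(sp$count, sm$count)
  expect_equal(L + 1L - sp$position, sm$position)
  expect_equal(sp$usage, sm$usage)
  expect_equal(sp$is_major, sm$is_major)
  expect_equal(sp$site_ord, sm$site_ord)
})

test_that("BED6 and site-table writers emit gene:ordinal names", {
  cc <- data.table(gene_id = "G", chrom = "chr1", strand = "+",
                   position = c(1000L, 1100L), sample_id = "s",
                   n = c(60L, 40L))
  prof <- build_pas_profiles(cc)
  f <- tempfile(fileext = ".bed")
  write_bed6(prof$sites, f)
  bed <- fread(f, header = FALSE)
  expect_equal(bed$V4, c("G:1", "G:2"))
  expect_equal(bed$V2, c(999L, 1099L))  # BED is 0-based half-open
  expect_equal(bed$V5, c(60L, 40L))
  f2 <- tempfile(fileext = ".tsv")
  write_pas_table(prof, f2)
  tab <- fread(f2)
  expect_equal(tab$s, c(60L, 40L))
})
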