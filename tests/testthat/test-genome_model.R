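test_that("GTF parsing converts and orders exons, builds gene spans", {
  gtf <- c(
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t1";',
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t1";',
    'chr1\tsrc\texon\t101\t500\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t2";')
  f <- tempfile(fileext = ".gtf")
  writeLines(gtf, f)
  ann <- parse_annotation(f)
  t1 <- ann$exons[transcript_id == "g1.t1"]
  expect_equal(t1$start, c(101L, 301L))
  expect_equal(t1$end, c(200L, 400L))
  ints <- extract_introns(ann, "g1.t1")
  expect_equal(ints$start, 201L)
  expect_equal(ints$end, 300L)
  # gene span covers both transcripts
  expect_equal(ann$genes[gene_id == "g1", .(start, end)],
               data.table(start = 101L, end = 500L))
  expect_equal(ann$genes$n_transcripts, 2L)
})

test_that("annotation round-trips through GTF", {
  s <- small_sim()
  ann <- s$sim$annotation
  f <- tempfile(fileext = ".gtf")
  write_annotation(ann, f)
  ann2 <- parse_annotation(f)
  expect_equal(ann$exons, ann2$exons)
  expect_equal(ann$transcripts, ann2$transcripts)
  expect_equal(ann$genes, ann2$genes)
})

test_that("malformed exons are rejected or skipped with a warning", {
  f <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t300\t400\t.\t+\t.\tgene_id "g2";'), f)
  expect_warning(ann <- parse_annotation(f), "skipped")
  expect_equal(nrow(ann$exons), 1L)
  expect_error(tx_annotation(data.table(
    gene_id = "g", transcript_id = "t", chrom = "c", strand = "+",
    start = 10L, end = 5L)), "end < start")
})

test_that("extract_introns handles gaps, single exons, and counts", {
  ann <- make_ann(list(g = list(t1 = list(c(1, 100), c(201, 300),
                                          c(501, 600)),
                                t2 = list(c(1, 600)))))
  ints <- extract_introns(ann, "g.t1")
  expect_equal(ints$start, c(101L, 301L))
  expect_equal(ints$end, c(200L, 500L))
  expect_equal(nrow(extract_introns(ann, "g.t2")), 0L)
  # property: intron count = exon count - 1 on random models
  set.seed(7)
  for (i in 1:25) {
    n <- sample(2:9, 1)
    bnd <- sort(sample(1:5000, 2 * n))
    exs <- lapply(seq_len(n), function(k) c(bnd[2 * k - 1], bnd[2 * k]))
    a <- make_ann(setNames(list(list(t1 = exs)), paste0("g", i)))
    expect_equal(nrow(extract_introns(a)), n - 1L)
  }
})

test_that("read 3' termini follow strand convention", {
  ann <- make_ann(list(gp = list(t1 = list(c(500, 2500))),
                       gm = list(t1 = list(c(5000, 7000)))),
                  strand = c("+", "-"))
  reads <- data.table(
    read_id = c("r1", "r1", "r2"),
    chrom = "chr1", strand = c("+", "+", "-"),
    start = c(1000L, 1500L, 5500L), end = c(1200L, 2000L, 6500L))
  cl <- read_end_sites(reads, ann)
  expect_equal(cl[read_id == "r1"]$position, 2000L)  # highest coord on +
  expect_equal(cl[read_id == "r2"]$position, 5500L)  # lowest coord on -
  expect_equal(cl[read_id == "r1"]$gene_id, "gp")
  expect_equal(cl[read_id == "r2"]$gene_id, "gm")
})

test_that("gene assignment: containment, slack, ambiguity rules", {
  # overlapping same-strand genes: closest annotated 3' end wins
  ann <- make_ann(list(gA = list(t1 = list(c(100, 1000))),
                       gB = list(t1 = list(c(600, 2000)))))
  reads <- data.table(read_id = c("a", "b"), chrom = "chr1", strand = "+",
                      start = c(700L, 700L), end = c(950L, 1900L))
  cl <- read_end_sites(reads, ann)
  expect_equal(cl[read_id == "a"]$gene_id, "gA")  # 950 closer to 1000
  expect_equal(cl[read_id == "b"]$gene_id, "gB")
  # downstream slack: terminus past annotated end still assigned
  r2 <- data.table(read_id = "c", chrom = "chr1", strand = "+",
                   start = 2100L, end = 2400L)
  expect_equal(suppressMessages(read_end_sites(r2, ann))$gene_id, "gB")
  r3 <- data.table(read_id = "d", chrom = "chr1", strand = "+",
                   start = 2100L, end = 3500L)
  expect_true(is.na(suppressMessages(read_end_sites(r3, ann))$gene_id))
  # exact tie in 3' distance -> unassigned
  ann2 <- make_ann(list(gA = list(t1 = list(c(100, 1000))),
                        gB = list(t1 = list(c(200, 1000)))))
  r4 <- data.table(read_id = "e", chrom = "chr1", strand = "+",
                   start = 300L, end = 900L)
  expect_true(is.na(suppressMessages(read_end_sites(r4, ann2))$gene_id))
  # unknown chromosome -> unassigned, not an error
  r5 <- data.table(read_id = "f", chrom = "chrX", strand = "+",
                   start = 1L, end = 50L)
  expect_true(is.na(suppressMessages(read_end_sites(r5, ann))$gene_id))
})

test_that("simulated reads are assigned to their planted genes", {
  s <- small_sim()
  cl <- suppressMessages(read_end_sites(s$exp$reads, s$sim$annotation))
  truth_gene <- sub("^[^:]+:([^:]+):.*$", "\\1", cl$read_id)
  expect_true(mean(cl$gene_id == truth_gene, na.rm = TRUE) > 0.999)
  expect_lt(mean(is.na(cl$gene_id)), 0.005)
})

test_that("read_end_sites mirrors under strand reflection", {
  ann_p <- make_ann(list(g = list(t1 = list(c(101, 300), c(401, 600)))))
  reads_p <- data.table(read_id = paste0("r", 1:3), chrom = "chr1",
                        strand = "+", start = c(150L, 120L, 200L),
                        end = c(580L, 560L, 600L))
  L <- 1000L
  refl <- function(x) L + 1L - x
  ann_m <- make_ann(list(g = list(t1 = list(
    c(refl(600), refl(401)), c(refl(300), refl(101))))), strand = "-")
  reads_m <- copy(reads_p)[, `:=`(strand = "-", start = refl(end),
                                  end = refl(start))]
  cl_p <- read_end_sites(reads_p, ann_p)
  cl_m <- read_end_sites(reads_m, ann_m)
  expect_equal(refl(cl_p$position), cl_m$position)
  expect_equal(cl_p$gene_id, cl_m$gene_id)
})

test_that("extract_sequence slices and reverse-complements", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTTG"))
  expect_equal(extract_sequence(g, "chr1", 1, 4, "+"), "ACGT")
  expect_equal(extract_sequence(g, "chr1", 1, 4, "-"), "ACGT") # palindrome
  expect_equal(extract_sequence(g, "chr1", 7, 10, "-"),
               oracle_revcomp("GTTG"))
  set.seed(3)
  gen <- make_genome(c(c1 = 500L), seed = 3)
  for (i in 1:20) {
    a <- sample(1:480, 1); b <- a + sample(0:19, 1)
    fwd <- substr(as.character(gen[["c1"]]), a, b)
    expect_equal(extract_sequence(gen, "c1", a, b, "+"), fwd)
    expect_equal(extract_sequence(gen, "c1", a, b, "-"),
                 oracle_revcomp(fwd))
  }
  expect_error(extract_sequence(g, "chr1", 5, 20, "+"), "out of bounds")
  expect_error(extract_sequence(g, "chr2", 1, 2, "+"), "absent")
})

test_that("BED12 round-trip preserves read exon chains", {
  s <- small_sim()
  sub <- s$exp$reads[sample_id == "DAP10-1"]
  f <- tempfile(fileext = ".bed")
  write_bed12(sub, f)
  back <- read_bed12(f, sample_id = "DAP10-1")
  cols <- c("read_id", "chrom", "strand", "start", "end")
  a <- setorderv(sub[, ..cols], cols)
  b <- setorderv(back[, ..cols], cols)
  expect_equal(a, b)
})
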