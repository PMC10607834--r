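#' @import data.table
#' @importFrom stats median setNames rnorm runif wilcox.test p.adjust
#'   quantile dhyper complete.cases
#' @importFrom utils head tail combn
NULL

# Internal coordinate convention: 1-based, closed intervals on both ends,
# i.e. the native GRanges/GTF convention.  BED input/output converts at the
# boundary (BED is 0-based half-open).

#' Build a transcript annotation object from an exon table
#'
#' The central annotation container used throughout the package.  It holds
#' one row per exon plus derived per-transcript and per-gene tables.  All
#' coordinates are 1-based closed.
#'
#' @param exons data.frame/data.table with columns `gene_id`,
#'   `transcript_id`, `chrom`, `strand` (`"+"` or `"-"`), `start`, `end`
#'   (1-based closed).
#' @return An object of class `tx_annotation`: a list with elements
#'   `exons` (exon table with `exon_rank` in genomic order), `transcripts`
#'   (one row per transcript: span, exon count, summed exon length) and
#'   `genes` (one row per gene: span over all transcripts).
#' @export
tx_annotation <- function(exons) {
  ex <- as.data.table(exons)
  need <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  miss <- setdiff(need, names(ex))
  if (length(miss))
    stop("exon table missing columns: ", paste(miss, collapse = ", "))
  ex <- ex[, .(gene_id = as.character(gene_id),
               transcript_id = as.character(transcript_id),
               chrom = as.character(chrom), strand = as.character(strand),
               start = as.integer(start), end = as.integer(end))]
  if (any(ex$end < ex$start)) stop("exon with end < start")
  if (!all(ex$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  setorder(ex, gene_id, transcript_id, start)
  ex[, exon_rank := seq_len(.N), by = transcript_id]
  bad <- ex[, .(bad = .N > 1 &&
                  (uniqueN(chrom) > 1 || uniqueN(strand) > 1 ||
                     any(start[-1] <= end[-.N]))), by = transcript_id]
  if (any(bad$bad))
    stop("transcript(s) with overlapping exons or mixed chrom/strand: ",
         paste(head(bad[bad == TRUE]$transcript_id, 5), collapse = ", "))
  tx <- ex[, .(gene_id = gene_id[1], chrom = chrom[1], strand = strand[1],
               start = min(start), end = max(end), n_exons = .N,
               exonic_length = sum(end - start + 1L)),
           by = transcript_id]
  gn <- tx[, .(chrom = chrom[1], strand = strand[1],
               start = min(start), end = max(end),
               n_transcripts = .N), by = gene_id]
  structure(list(exons = ex, transcripts = tx, genes = gn),
            class = "tx_annotation")
}

#' @export
print.tx_annotation <- function(x, ...) {
  cat("tx_annotation:", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts,", nrow(x$exons), "exons\n")
  invisible(x)
}

#' Parse a GTF/GFF3 annotation into a `tx_annotation`
#'
#' Exon features are read via rtracklayer; 1-based closed file coordinates
#' are kept as-is (the internal convention).  Exons lacking a
#' `transcript_id` (GTF) or a `Parent` (GFF3) are skipped with a warning.
#'
#' @param path GTF or GFF3 file path (format auto-detected by extension;
#'   override with `format`).
#' @param format `"gtf"`, `"gff3"` or `NULL` (auto).
#' @return A [tx_annotation] object.
#' @export
parse_annotation <- function(path, format = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "gtf"
  }
  gr <- rtracklayer::import(path, format = format)
  gr <- gr[!is.na(gr$type) & tolower(as.character(gr$type)) == "exon"]
  if (!length(gr)) stop("no exon features in ", path)
  if (format == "gff3") {
    txid <- sub("^transcript:", "", vapply(gr$Parent, function(p)
      if (length(p)) as.character(p[1]) else NA_character_, character(1)))
    gid <- if (!is.null(gr$gene_id)) as.character(gr$gene_id) else txid
  } else {
    txid <- if (!is.null(gr$transcript_id)) as.character(gr$transcript_id)
            else rep(NA_character_, length(gr))
    gid <- if (!is.null(gr$gene_id)) as.character(gr$gene_id) else txid
  }
  keep <- !is.na(txid)
  if (any(!keep))
    warning(sum(!keep), " exon feature(s) without transcript attribute skipped")
  ex <- data.table(gene_id = gid[keep], transcript_id = txid[keep],
                   chrom = as.character(GenomicRanges::seqnames(gr))[keep],
                   strand = as.character(GenomicRanges::strand(gr))[keep],
                   start = GenomicRanges::start(gr)[keep],
                   end = GenomicRanges::end(gr)[keep])
  ex[is.na(gene_id) | gene_id == "", gene_id := transcript_id]
  tx_annotation(ex)
}

#' Write a `tx_annotation` to GTF
#'
#' Emits transcript and exon features with `gene_id`/`transcript_id`
#' attributes; coordinates written 1-based closed.  A subsequent
#' [parse_annotation] reproduces the models exactly.
#'
#' @param ann A [tx_annotation].
#' @param path Output file.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, source = "isoAPA") {
  ex <- ann$exons
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(ex$start, ex$end),
    strand = ex$strand,
    type = "exon", source = source,
    gene_id = ex$gene_id, transcript_id = ex$transcript_id)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Extract introns from transcript models
#'
#' Introns are the gaps between consecutive exons of one transcript,
#' reported in genomic order with 1-based closed coordinates.
#' Single-exon transcripts contribute no rows.
#'
#' @param ann A [tx_annotation].
#' @param transcript_id Optional subset of transcript ids.
#' @return data.table with `gene_id`, `transcript_id`, `chrom`, `strand`,
#'   `start`, `end`, `intron_rank` (genomic order).
#' @export
extract_introns <- function(ann, transcript_id = NULL) {
  ex <- ann$exons
  if (!is.null(transcript_id)) {
    tid <- transcript_id
    ex <- ex[ex$transcript_id %in% tid]
  }
  ints <- ex[, if (.N >= 2L) .(gene_id = gene_id[1], chrom = chrom[1],
                               strand = strand[1],
                               start = end[-.N] + 1L, end = start[-1] - 1L)
             else NULL,
             by = transcript_id]
  if (!nrow(ints))
    return(data.table(gene_id = character(), transcript_id = character(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      intron_rank = integer()))
  ints[, intron_rank := seq_len(.N), by = transcript_id]
  setcolorder(ints, c("gene_id", "transcript_id", "chrom", "strand",
                      "start", "end", "intron_rank"))
  ints[]
}

#' Read BED12 read alignments
#'
#' Each BED12 record is one aligned read; blocks give its exon chain.
#' Coordinates are converted from BED (0-based half-open) to the internal
#' 1-based closed convention.
#'
#' @param path BED12 file.
#' @param sample_id Optional sample label attached to every read.
#' @return data.table with one row per read exon: `read_id`, `chrom`,
#'   `strand`, `start`, `end`, `exon_rank`, `sample_id`.
#' @export
read_bed12 <- function(path, sample_id = NA_character_) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$blocks))
    stop("BED file lacks block structure (need BED12): ", path)
  blk <- gr$blocks  # IRangesList, relative 1-based within each read
  n <- S4Vectors::elementNROWS(blk)
  ir <- unlist(blk, use.names = FALSE)
  dt <- data.table(
    read_id = rep(as.character(gr$name), n),
    chrom = rep(as.character(GenomicRanges::seqnames(gr)), n),
    strand = rep(as.character(GenomicRanges::strand(gr)), n),
    start = rep(GenomicRanges::start(gr), n) + IRanges::start(ir) - 1L,
    end = rep(GenomicRanges::start(gr), n) + IRanges::end(ir) - 1L,
    sample_id = sample_id)
  setorder(dt, read_id, start)
  dt[, exon_rank := seq_len(.N), by = read_id]
  dt[]
}

#' Write read exon chains as BED12
#'
#' @param reads Read exon table as produced by [read_bed12] or the
#'   simulator (`read_id`, `chrom`, `strand`, `start`, `end`).
#' @param path Output BED12 file.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(reads, path) {
  rd <- as.data.table(reads)
  setorder(rd, chrom, read_id, start)
  per <- rd[, .(chrom = chrom[1], strand = strand[1],
                start0 = min(start) - 1L, end0 = max(end),
                n_blocks = .N,
                sizes = paste(end - start + 1L, collapse = ","),
                offsets = paste(start - min(start), collapse = ",")),
            by = read_id]
  out <- per[, .(chrom, start0, end0, read_id, score = 0L, strand,
                 thickStart = start0, thickEnd = end0, rgb = "0,0,0",
                 n_blocks, sizes, offsets)]
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE,
         scipen = 50L)
  invisible(path)
}

#' Locate read 3' termini and assign them to genes
#'
#' The cleavage position of a read is its 3'-most transcribed base:
#' the highest aligned coordinate on the plus strand, the lowest on the
#' minus strand.  A terminus is assigned to the same-strand gene whose
#' span (extended by `downstream_slack` nt past the annotated 3' end)
#' contains it; when several genes qualify, the gene with the closest
#' annotated 3' end wins and exact ties are left unassigned.
#'
#' @param reads Read exon table (`read_id`, `chrom`, `strand`, `start`,
#'   `end`, optional `sample_id`).
#' @param ann A [tx_annotation].
#' @param downstream_slack Extension (nt) of each gene span past its
#'   annotated 3' end; cleavage frequently occurs beyond annotated ends.
#' @return data.table of cleavage records: `read_id`, `chrom`, `position`,
#'   `strand`, `gene_id` (`NA` if unassigned), `sample_id`.
#' @export
read_end_sites <- function(reads, ann, downstream_slack = 1000L) {
  rd <- as.data.table(reads)
  if (!"sample_id" %in% names(rd)) rd[, sample_id := NA_character_]
  ends <- rd[, .(chrom = chrom[1], strand = strand[1],
                 position = if (strand[1] == "+") max(end) else min(start),
                 sample_id = sample_id[1]),
             by = read_id]
  gn <- copy(ann$genes)
  gn[, `:=`(win_start = ifelse(strand == "+", start, start - downstream_slack),
            win_end = ifelse(strand == "+", end + downstream_slack, end),
            end3 = ifelse(strand == "+", end, start))]
  ggr <- GenomicRanges::GRanges(gn$chrom,
                                IRanges::IRanges(gn$win_start, gn$win_end),
                                strand = gn$strand)
  egr <- GenomicRanges::GRanges(ends$chrom,
                                IRanges::IRanges(ends$position, ends$position),
                                strand = ends$strand)
  # reads on chromosomes absent from the annotation share no seqlevels
  # with the gene index; they are simply left unassigned
  ov <- suppressWarnings(GenomicRanges::findOverlaps(egr, ggr))
  hit <- data.table(qi = S4Vectors::queryHits(ov),
                    gi = S4Vectors::subjectHits(ov))
  ends[, gene_id := NA_character_]
  if (nrow(hit)) {
    hit[, dist3 := abs(ends$position[qi] - gn$end3[gi])]
    hit[, gene_id := gn$gene_id[gi]]
    setorder(hit, qi, dist3)
    pick <- hit[, {
      if (.N == 1L || dist3[1] < dist3[2]) .(gene_id = gene_id[1])
      else .(gene_id = NA_character_)   # ambiguous tie -> unassigned
    }, by = qi]
    ends[pick$qi, gene_id := pick$gene_id]
  }
  n_un <- sum(is.na(ends$gene_id))
  if (n_un) message(n_un, " read 3' termini left unassigned")
  ends[, .(read_id, chrom, position, strand, gene_id, sample_id)]
}

#' Write poly(A) sites as BED6
#'
#' One line per retained site: name `gene:ordinal` (ordinal in
#' transcription direction), score = pooled read count.
#'
#' @param sites Site table with `chrom`, `position`, `strand`, `gene_id`,
#'   `count` and `site_ord`.
#' @param path Output BED6 file.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(sites, path) {
  st <- as.data.table(sites)
  out <- st[, .(chrom, start0 = position - 1L, end0 = position,
                name = paste0(gene_id, ":", site_ord),
                score = count, strand)]
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE,
         scipen = 50L)
  invisible(path)
}
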