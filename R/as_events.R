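# Local alternative-splicing event classification in the SUPPA style:
# events are defined between pairs of isoforms of one gene, typed into
# RI, SE, A5, A3, AF, AL and MX, and deduplicated by
# (gene, type, defining coordinates).  A5/A3 and AF/AL are typed relative
# to transcription direction, so on the minus strand the genomically
# right-hand variable donor boundary is still A5.
#
# Inclusion-form conventions (documented, needed for a signed PSI):
#   RI  inclusion = intron-retaining isoform
#   SE  inclusion = exon-containing isoform
#   A5/A3 inclusion = isoform with the shorter intron (more exonic)
#   AF  inclusion = isoform whose first exon is 5'-most in transcription
#   AL  inclusion = isoform whose last exon is 3'-most in transcription
#   MX  inclusion = isoform using the 5'-most (transcription) exon

#' Classify local alternative-splicing events of a gene set
#'
#' All isoform pairs within each gene are compared and local events are
#' emitted, deduplicated by their defining coordinates; identical events
#' found between different pairs merge their isoform sets.
#' Single-transcript genes yield no events.
#'
#' @param ann A [tx_annotation] (reference, collapsed isoforms, or both).
#' @param gene_id Optional subset of gene ids.
#' @return data.table with `event_id`, `gene_id`, `event_type`, `chrom`,
#'   `strand`, `coords` (comma-separated defining coordinates),
#'   `inclusion` and `exclusion` (comma-separated transcript ids).
#' @export
classify_as_events <- function(ann, gene_id = NULL) {
  genes <- if (is.null(gene_id)) ann$genes$gene_id else gene_id
  ex <- ann$exons
  out <- vector("list", length(genes))
  for (k in seq_along(genes)) {
    g <- genes[k]
    gex <- ex[ex$gene_id == g]
    txs <- split(gex[, .(start, end)], gex$transcript_id)
    if (length(txs) < 2L) next
    strand <- gex$strand[1]; chrom <- gex$chrom[1]
    out[[k]] <- classify_gene_events(g, chrom, strand, txs)
  }
  res <- rbindlist(out)
  if (!nrow(res))
    return(data.table(event_id = character(), gene_id = character(),
                      event_type = character(), chrom = character(),
                      strand = character(), coords = character(),
                      inclusion = character(), exclusion = character()))
  res[]
}

# txs: named list of data.tables (start, end) sorted by start
classify_gene_events <- function(gene, chrom, strand, txs) {
  txs <- lapply(txs, function(d) d[order(d$start)])
  introns <- lapply(txs, function(d) {
    n <- nrow(d)
    if (n < 2L) data.table(start = integer(), end = integer())
    else data.table(start = d$end[-n] + 1L, end = d$start[-1] - 1L)
  })
  acc <- new.env(parent = emptyenv())
  add <- function(type, coords, inc_tx, exc_tx) {
    key <- paste(type, paste(sort(coords), collapse = ","), sep = "|")
    cur <- acc[[key]]
    if (is.null(cur))
      cur <- list(type = type, coords = sort(coords),
                  inc = character(), exc = character())
    cur$inc <- union(cur$inc, inc_tx)
    cur$exc <- union(cur$exc, exc_tx)
    acc[[key]] <- cur
  }
  ids <- names(txs)
  n <- length(ids)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pair_events(txs[[i]], introns[[i]], ids[i],
                txs[[j]], introns[[j]], ids[j], strand, add)
    pair_events(txs[[j]], introns[[j]], ids[j],
                txs[[i]], introns[[i]], ids[i], strand, add)
  }
  # MX needs the never-co-occur check over the whole gene
  mx_events(txs, introns, ids, strand, add)
  keys <- ls(acc)
  if (!length(keys)) return(NULL)
  rbindlist(lapply(keys, function(key) {
    ev <- acc[[key]]
    inc <- setdiff(ev$inc, intersect(ev$inc, ev$exc))
    exc <- setdiff(ev$exc, intersect(acc[[key]]$inc, ev$exc))
    if (!length(inc) || !length(exc)) return(NULL)
    data.table(event_id = paste0(ev$type, ":", chrom, ":",
                                 paste(ev$coords, collapse = "-"),
                                 ":", strand),
               gene_id = gene, event_type = ev$type,
               chrom = chrom, strand = strand,
               coords = paste(ev$coords, collapse = ","),
               inclusion = paste(sort(inc), collapse = ","),
               exclusion = paste(sort(exc), collapse = ","))
  }))
}

# Directed comparison: events where tA plays the "inclusion-like"
# structural role.  Called for both orderings of each pair.
pair_events <- function(exA, inA, idA, exB, inB, idB, strand, add) {
  nA <- nrow(exA); nB <- nrow(exB)
  # --- RI: exon of A spans an intron of B with matching outer boundaries
  if (nrow(inB)) for (q in seq_len(nrow(inB))) {
    is <- inB$start[q]; ie <- inB$end[q]
    up <- which(exB$end == is - 1L); dn <- which(exB$start == ie + 1L)
    if (!length(up) || !length(dn)) next
    a <- exB$start[up[1]]; b <- exB$end[dn[1]]
    if (any(exA$start == a & exA$end == b))
      add("RI", c(a, is, ie, b), idA, idB)
  }
  # --- SE: consecutive introns of A vs single intron of B
  if (nrow(inA) >= 2L && nrow(inB)) for (q in seq_len(nrow(inA) - 1L)) {
    i1s <- inA$start[q]; i1e <- inA$end[q]
    i2s <- inA$start[q + 1L]; i2e <- inA$end[q + 1L]
    if (any(inB$start == i1s & inB$end == i2e))
      add("SE", c(i1s, i1e, i2s, i2e), idA, idB)
  }
  # --- A5/A3: introns sharing exactly one boundary, variable boundary
  # exonic in the shorter-intron transcript
  if (nrow(inA) && nrow(inB)) for (q in seq_len(nrow(inA))) {
    sA <- inA$start[q]; eA <- inA$end[q]
    # shared start, A's intron shorter (eA < eB): region eA+1..eB must be
    # inside A's downstream exon
    hit <- which(inB$start == sA & inB$end > eA)
    for (h in hit) {
      eB <- inB$end[h]
      dnA <- which(exA$start == eA + 1L)
      if (length(dnA) && exA$end[dnA[1]] >= eB + 1L) {
        type <- if (strand == "+") "A3" else "A5"
        add(type, c(sA, eA, eB), idA, idB)   # A = shorter intron = inclusion
      }
    }
    # shared end, A's intron shorter (sA > sB): region sB..sA-1 inside
    # A's upstream exon
    hit <- which(inB$end == eA & inB$start < sA)
    for (h in hit) {
      sB <- inB$start[h]
      upA <- which(exA$end == sA - 1L)
      if (length(upA) && exA$start[upA[1]] <= sB - 1L) {
        type <- if (strand == "+") "A5" else "A3"
        add(type, c(sB, sA, eA), idA, idB)
      }
    }
  }
  # --- AF / AL: alternative terminal exons, non-overlapping, sharing the
  # splice boundary into/out of the shared exon
  if (nA >= 2L && nB >= 2L) {
    if (strand == "+") {
      # first exon = leftmost; shared second-exon start
      fA <- c(exA$start[1], exA$end[1]); fB <- c(exB$start[1], exB$end[1])
      if (exA$start[2] == exB$start[2] && fA[2] < fB[1])
        add("AF", c(fA, fB, exA$start[2]), idA, idB)  # A's first exon 5'-most
      lA <- c(exA$start[nA], exA$end[nA]); lB <- c(exB$start[nB], exB$end[nB])
      if (exA$end[nA - 1L] == exB$end[nB - 1L] && lB[2] < lA[1])
        add("AL", c(lB, lA, exA$end[nA - 1L]), idA, idB) # A's last exon 3'-most
    } else {
      # minus strand: first exon = rightmost
      fA <- c(exA$start[nA], exA$end[nA]); fB <- c(exB$start[nB], exB$end[nB])
      if (exA$end[nA - 1L] == exB$end[nB - 1L] && fB[2] < fA[1])
        add("AF", c(fB, fA, exA$end[nA - 1L]), idA, idB)
      lA <- c(exA$start[1], exA$end[1]); lB <- c(exB$start[1], exB$end[1])
      if (exA$start[2] == exB$start[2] && lA[2] < lB[1])
        add("AL", c(lA, lB, exA$start[2]), idA, idB)
    }
  }
  invisible(NULL)
}

mx_events <- function(txs, introns, ids, strand, add) {
  n <- length(ids)
  # collect internal exons with their flanking boundaries per transcript
  flanked <- lapply(seq_len(n), function(i) {
    d <- txs[[i]]; m <- nrow(d)
    if (m < 3L) return(NULL)
    data.table(tx = ids[i], s = d$start[2:(m - 1L)], e = d$end[2:(m - 1L)],
               prev_end = d$end[1:(m - 2L)], next_start = d$start[3:m])
  })
  fl <- rbindlist(flanked)
  if (is.null(fl) || !nrow(fl)) return(invisible(NULL))
  exon_sets <- lapply(txs, function(d) paste(d$start, d$end, sep = "-"))
  for (i in seq_len(nrow(fl) - 1L)) for (j in (i + 1L):nrow(fl)) {
    a <- fl[i]; b <- fl[j]
    if (a$tx == b$tx) next
    if (a$prev_end != b$prev_end || a$next_start != b$next_start) next
    if (!(a$e < b$s || b$e < a$s)) next        # must not overlap
    k1 <- paste(a$s, a$e, sep = "-"); k2 <- paste(b$s, b$e, sep = "-")
    cooccur <- any(vapply(exon_sets, function(s)
      k1 %in% s && k2 %in% s, logical(1)))
    if (cooccur) next
    coords <- c(a$prev_end, a$s, a$e, b$s, b$e, a$next_start)
    # inclusion = 5'-most exon in transcription direction
    first <- if (strand == "+") (if (a$s < b$s) a else b)
             else (if (a$s > b$s) a else b)
    second <- if (identical(first, a)) b else a
    add("MX", coords, first$tx, second$tx)
  }
  invisible(NULL)
}

#' Percent spliced in (PSI) for AS events
#'
#' PSI = inclusion abundance / (inclusion + exclusion abundance), computed
#' from per-isoform abundances (e.g. collapse support counts or any
#' expression estimate).  PSI is `NA` when the denominator is zero.
#'
#' @param events Event table from [classify_as_events].
#' @param abundances Named non-negative numeric vector of per-transcript
#'   abundances; must cover every isoform named in the events.
#' @return data.table `event_id`, `psi`, `inclusion_abundance`,
#'   `exclusion_abundance`.
#' @export
compute_psi <- function(events, abundances) {
  ev <- as.data.table(events)
  ev[, {
    inc <- strsplit(inclusion, ",", fixed = TRUE)[[1]]
    exc <- strsplit(exclusion, ",", fixed = TRUE)[[1]]
    miss <- setdiff(c(inc, exc), names(abundances))
    if (length(miss))
      stop("abundance missing for transcript(s): ",
           paste(miss, collapse = ", "))
    ia <- sum(abundances[inc]); ea <- sum(abundances[exc])
    .(psi = if (ia + ea > 0) ia / (ia + ea) else NA_real_,
      inclusion_abundance = ia, exclusion_abundance = ea)
  }, by = event_id]
}

#' PSI table over samples
#'
#' @param events Event table from [classify_as_events].
#' @param abundance_matrix Numeric matrix, transcripts x samples.
#' @return data.table `event_id` x one PSI column per sample.
#' @export
psi_table <- function(events, abundance_matrix) {
  stopifnot(!is.null(rownames(abundance_matrix)),
            !is.null(colnames(abundance_matrix)))
  res <- data.table(event_id = events$event_id)
  for (s in colnames(abundance_matrix)) {
    ab <- setNames(abundance_matrix[, s], rownames(abundance_matrix))
    res[, (s) := compute_psi(events, ab)$psi]
  }
  res[]
}

#' Write events in an ioe-style tab-separated format
#'
#' Columns: seqname, gene_id, event_id, inclusion transcripts,
#' total (inclusion + exclusion) transcripts.
#'
#' @param events Event table from [classify_as_events].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_events_ioe <- function(events, path) {
  ev <- as.data.table(events)
  out <- ev[, .(seqname = chrom, gene_id,
                event_id = paste0(gene_id, ";", event_id),
                alternative_transcripts = inclusion,
                total_transcripts = paste(inclusion, exclusion, sep = ","))]
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
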