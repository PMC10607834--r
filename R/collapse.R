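# Collapse of FLNC read alignments into distinct splice isoforms.
# Two intron-containing reads belong to the same isoform iff their intron
# chains (ordered intron coordinates on one chrom/strand) are identical;
# the representative model takes the widest 5'/3' termini among its
# supporting reads.  Mono-exonic reads carry no intron chain and are
# grouped separately by reciprocal overlap.

#' Collapse reads into isoforms by intron chain
#'
#' @param reads Read exon table (`read_id`, `chrom`, `strand`, `start`,
#'   `end`), e.g. from [read_bed12] or [simulate_flnc_reads].
#' @param gene_ids Optional named character vector mapping `read_id` to a
#'   gene id; collapsed isoforms are then grouped per gene (reads of
#'   different genes never collapse together).  Unnamed isoforms get a
#'   locus id derived from their chain.
#' @param mono_min_overlap Minimum reciprocal overlap fraction for
#'   mono-exonic reads to be grouped into one mono-exonic isoform.
#' @return List with `isoforms` (a [tx_annotation] of collapsed models,
#'   transcript ids `<gene>.iso<k>` carrying a `support` column on
#'   `$transcripts`), `support` (data.table `transcript_id`, `read_id`)
#'   and `n_input` counts per class (intron-containing / mono-exonic).
#' @export
collapse_by_intron_chain <- function(reads, gene_ids = NULL,
                                     mono_min_overlap = 0.5) {
  rd <- as.data.table(reads)
  setorder(rd, read_id, start)
  nex <- rd[, .N, by = read_id]
  multi <- rd[read_id %in% nex[N >= 2L]$read_id]
  mono <- rd[read_id %in% nex[N == 1L]$read_id]

  per <- if (nrow(multi))
    multi[, .(chrom = chrom[1], strand = strand[1],
              start = min(start), end = max(end),
              chain = paste(end[-.N] + 1L, start[-1] - 1L,
                            sep = "-", collapse = ";")),
          by = read_id]
  else data.table(read_id = character(), chrom = character(),
                  strand = character(), start = integer(),
                  end = integer(), chain = character())
  if (!is.null(gene_ids)) {
    per[, gene_id := gene_ids[read_id]]
    if (nrow(mono)) mono[, gene_id := gene_ids[read_id]]
  } else {
    per[, gene_id := NA_character_]
    if (nrow(mono)) mono[, gene_id := NA_character_]
  }
  per[is.na(gene_id), gene_id := paste0("LOC_", chrom, "_", strand, "_",
                                        substr(chain, 1, 20))]
  iso <- if (nrow(per))
    per[, .(chrom = chrom[1], strand = strand[1],
            start = min(start), end = max(end),
            support = .N, reads = list(read_id)),
        by = .(gene_id, chain)]
  else data.table(gene_id = character(), chain = character(),
                  chrom = character(), strand = character(),
                  start = integer(), end = integer(),
                  support = integer(), reads = list())
  setorder(iso, gene_id, start, chain)
  iso[, transcript_id := paste0(gene_id, ".iso", seq_len(.N)), by = gene_id]

  # mono-exonic grouping: single-linkage on >= mono_min_overlap reciprocal
  # overlap within (gene, chrom, strand); greedy left-to-right scan
  mono_iso <- NULL
  if (nrow(mono)) {
    setorder(mono, gene_id, chrom, strand, start, end)
    mono[, grp := {
      g <- integer(.N); cur <- 1L; g[1] <- 1L
      if (.N > 1L) for (i in 2:.N) {
        prev <- which(g == cur)
        ps <- min(start[prev]); pe <- max(end[prev])
        ov <- min(pe, end[i]) - max(ps, start[i]) + 1L
        rec <- ov / pmax(pe - ps + 1L, end[i] - start[i] + 1L)
        if (ov > 0 && rec >= mono_min_overlap) g[i] <- cur
        else { cur <- cur + 1L; g[i] <- cur }
      }
      g
    }, by = .(gene_id, chrom, strand)]
    mono_iso <- mono[, .(chrom = chrom[1], strand = strand[1],
                         start = min(start), end = max(end),
                         support = .N, reads = list(read_id)),
                     by = .(gene_id, chrom2 = chrom, strand2 = strand, grp)]
    mono_iso[, `:=`(chrom2 = NULL, strand2 = NULL, grp = NULL)]
    mono_iso[is.na(gene_id),
             gene_id := paste0("LOC_", chrom, "_", strand, "_", start)]
    mono_iso[, transcript_id := paste0(gene_id, ".mono", seq_len(.N)),
             by = gene_id]
  }

  exon_rows <- if (nrow(iso)) iso[, {
    iv <- chain_to_introns(chain)
    es <- c(start, iv$end + 1L)
    ee <- c(iv$start - 1L, end)
    .(gene_id = gene_id, chrom = chrom, strand = strand,
      start = es, end = ee)
  }, by = transcript_id]
  else data.table(transcript_id = character(), gene_id = character(),
                  chrom = character(), strand = character(),
                  start = integer(), end = integer())
  if (!is.null(mono_iso))
    exon_rows <- rbind(exon_rows,
                       mono_iso[, .(transcript_id, gene_id, chrom, strand,
                                    start, end)])
  ann <- tx_annotation(exon_rows)
  supp <- rbind(iso[, .(transcript_id, support)],
                if (!is.null(mono_iso)) mono_iso[, .(transcript_id, support)])
  ann$transcripts[supp, support := i.support, on = "transcript_id"]
  read_map <- rbind(
    if (nrow(iso))
      iso[, .(read_id = unlist(reads)), by = transcript_id],
    if (!is.null(mono_iso))
      mono_iso[, .(read_id = unlist(reads)), by = transcript_id])
  list(isoforms = ann, support = read_map,
       n_input = c(intron_containing = length(unique(multi$read_id)),
                   mono_exonic = length(unique(mono$read_id))))
}

# "e1-s1;e2-s2" chain string -> data.table(start, end) of introns
chain_to_introns <- function(chain) {
  if (length(chain) != 1L || is.na(chain) || chain == "")
    return(data.table(start = integer(), end = integer()))
  parts <- strsplit(strsplit(chain, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  data.table(start = as.integer(vapply(parts, `[`, "", 1L)),
             end = as.integer(vapply(parts, `[`, "", 2L)))
}

#' Position frequency matrices and consensus around splice sites
#'
#' Extracts strand-aware windows around intron donor (5') and acceptor
#' (3') sites and tallies per-position base frequencies.  The default
#' windows mirror the usual exon|intron consensus display: 6 exonic +
#' 5 intronic bases at the donor, 5 intronic + 6 exonic at the acceptor.
#' Columns are renormalized after excluding N.
#'
#' @param introns Intron table (`chrom`, `strand`, `start`, `end`) from
#'   [extract_introns].
#' @param genome `DNAStringSet`.
#' @param donor_flank `c(exonic, intronic)` window widths at the donor.
#' @param acceptor_flank `c(intronic, exonic)` widths at the acceptor.
#' @return List with `donor` and `acceptor` 4 x width probability
#'   matrices (rows A,C,G,T), `donor_consensus` / `acceptor_consensus`
#'   strings with a `|` at the exon-intron boundary, and `n_introns`.
#'   Consensus ties resolve in fixed base order A < C < G < T.
#' @export
splice_site_matrices <- function(introns, genome,
                                 donor_flank = c(6L, 5L),
                                 acceptor_flank = c(5L, 6L)) {
  ints <- as.data.table(introns)
  if (!nrow(ints)) stop("empty intron set")
  pos <- ints$strand == "+"
  don <- ifelse(pos, ints$start, ints$end)     # first intronic base
  acc <- ifelse(pos, ints$end, ints$start)     # last intronic base
  dw <- sum(donor_flank); aw <- sum(acceptor_flank)
  don_seq <- extract_sequence(
    genome, ints$chrom,
    ifelse(pos, don - donor_flank[1], don - donor_flank[2] + 1L),
    ifelse(pos, don + donor_flank[2] - 1L, don + donor_flank[1]),
    ints$strand)
  acc_seq <- extract_sequence(
    genome, ints$chrom,
    ifelse(pos, acc - acceptor_flank[1] + 1L, acc - acceptor_flank[2]),
    ifelse(pos, acc + acceptor_flank[2], acc + acceptor_flank[1] - 1L),
    ints$strand)
  don_m <- pfm_from_strings(don_seq, dw)
  acc_m <- pfm_from_strings(acc_seq, aw)
  list(donor = don_m, acceptor = acc_m,
       donor_consensus = consensus_string(don_m, donor_flank[1]),
       acceptor_consensus = consensus_string(acc_m, acceptor_flank[1]),
       n_introns = nrow(ints))
}

pfm_from_strings <- function(seqs, width) {
  stopifnot(all(nchar(seqs) == width))
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs))
  m <- matrix(0, 4, width, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (b in rownames(m)) if (b %in% rownames(cm)) m[b, ] <- cm[b, ]
  tot <- colSums(m)   # excludes N
  m <- sweep(m, 2, pmax(tot, 1), "/")
  m
}

consensus_string <- function(pfm, boundary_after) {
  bases <- rownames(pfm)
  cons <- bases[apply(pfm, 2, which.max)]  # which.max: first max = A<C<G<T
  paste0(paste(cons[seq_len(boundary_after)], collapse = ""), "|",
         paste(cons[-seq_len(boundary_after)], collapse = ""))
}
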