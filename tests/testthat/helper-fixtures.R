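library(data.table)

# hand-built annotation from a compact spec:
# list(gene = list(tx = list(c(s1,e1), c(s2,e2), ...), ...)) on one
# chrom/strand per gene
make_ann <- function(genes, chrom = "chr1", strand = "+") {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(genes))
  if (length(strand) == 1L) strand <- rep(strand, length(genes))
  rows <- list()
  for (gi in seq_along(genes)) {
    g <- names(genes)[gi]
    for (ti in seq_along(genes[[gi]])) {
      exs <- genes[[gi]][[ti]]
      tid <- names(genes[[gi]])[ti]
      tid <- if (is.null(tid) || tid == "") paste0(g, ".t", ti)
             else paste0(g, ".", tid)
      for (e in exs)
        rows[[length(rows) + 1L]] <- data.table(
          gene_id = g, transcript_id = tid, chrom = chrom[gi],
          strand = strand[gi], start = e[1], end = e[2])
    }
  }
  tx_annotation(rbindlist(rows))
}

# random DNAStringSet genome
make_genome <- function(lens, seed = 1) {
  set.seed(seed)
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(lens)
  g
}

# random multi-isoform gene for the classifier property test: up to 8
# master exon slots with boundary variants, isoforms as random subsets
# with optional adjacent-exon merges (retained introns)
random_gene_txs <- function(n_iso = sample(2:5, 1), n_slots = sample(3:8, 1)) {
  base_start <- (seq_len(n_slots) - 1L) * 400L + 1L
  txs <- list()
  for (t in seq_len(n_iso)) {
    k <- sample(2:n_slots, 1)
    slots <- sort(sample(n_slots, k))
    sv <- sample(c(0L, 40L), k, replace = TRUE)   # acceptor variants
    ev <- sample(c(0L, 40L), k, replace = TRUE)   # donor variants
    st <- base_start[slots] + sv
    en <- base_start[slots] + 120L + ev
    # random merges of adjacent chosen slots (retained introns)
    m <- length(st)
    if (m > 1) {
      merge_at <- which(runif(m - 1) < 0.2)
      for (j in rev(merge_at)) {
        en[j] <- en[j + 1]
        st <- st[-(j + 1)]; en <- en[-(j + 1)]
      }
    }
    txs[[paste0("t", t)]] <- Map(c, st, en)
  }
  # drop duplicate chains
  keys <- vapply(txs, function(x) paste(unlist(x), collapse = ","), "")
  txs[!duplicated(keys)]
}

# simulated small dataset shared by several tests (built once per run)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_genes = 40, reads_per_gene = 60)
      sim <- simulate_transcriptome(cfg, seed = 101)
      exp <- suppressMessages(simulate_experiment(sim, seed = 101))
      cache <<- list(sim = sim, exp = exp)
    }
    cache
  }
})
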