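# Independent oracles.  These re-derive expected results by a different
# route than the package code and are deliberately simple/slow.

# ---- AS events: brute-force pairwise enumerator ----------------------
# Works entirely in transcription-direction coordinates: minus-strand
# exons are mapped x -> -x so every rule is written once for the "+"
# orientation, then defining coordinates are mapped back and sorted.
oracle_as_events <- function(ann, gene) {
  ex <- ann$exons[gene_id == gene]
  strand <- ex$strand[1]
  txs <- lapply(split(ex, ex$transcript_id), function(d) {
    m <- cbind(d$start, d$end)
    if (strand == "-") m <- cbind(-d$end, -d$start)
    m[order(m[, 1]), , drop = FALSE]
  })
  back <- function(v) sort(abs(v))
  res <- list()
  emit <- function(type, coords) {
    res[[length(res) + 1L]] <<- paste(gene, type,
                                      paste(back(coords), collapse = ","))
  }
  tint <- lapply(txs, function(m) {
    if (nrow(m) < 2) return(NULL)
    cbind(m[-nrow(m), 2] + 1, m[-1, 1] - 1)
  })
  ids <- names(txs)
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i == j) next
    A <- txs[[i]]; B <- txs[[j]]
    IA <- tint[[i]]; IB <- tint[[j]]
    # RI: A retains an intron of B (A has an exon exactly spanning B's
    # two flanking exons)
    if (!is.null(IB)) for (q in seq_len(nrow(IB))) {
      ui <- which(B[, 2] == IB[q, 1] - 1); di <- which(B[, 1] == IB[q, 2] + 1)
      if (!length(ui) || !length(di)) next
      a <- B[ui[1], 1]; b <- B[di[1], 2]
      if (any(A[, 1] == a & A[, 2] == b))
        emit("RI", c(a, IB[q, 1], IB[q, 2], b))
    }
    # SE: A includes an exon between two introns; B splices straight over
    if (!is.null(IA) && nrow(IA) >= 2 && !is.null(IB))
      for (q in seq_len(nrow(IA) - 1))
        if (any(IB[, 1] == IA[q, 1] & IB[, 2] == IA[q + 1, 2]))
          emit("SE", c(IA[q, ], IA[q + 1, ]))
    if (!is.null(IA) && !is.null(IB)) {
      for (q in seq_len(nrow(IA))) for (w in seq_len(nrow(IB))) {
        # A5: same acceptor (intron end), different donor; the inter-donor
        # region must lie inside the upstream exon of the shorter intron
        if (IA[q, 2] == IB[w, 2] && IA[q, 1] > IB[w, 1]) {
          up <- which(A[, 2] == IA[q, 1] - 1)
          if (length(up) && A[up[1], 1] <= IB[w, 1] - 1)
            emit("A5", c(IB[w, 1], IA[q, 1], IA[q, 2]))
        }
        # A3: same donor, different acceptor
        if (IA[q, 1] == IB[w, 1] && IA[q, 2] < IB[w, 2]) {
          dn <- which(A[, 1] == IA[q, 2] + 1)
          if (length(dn) && A[dn[1], 2] >= IB[w, 2] + 1)
            emit("A3", c(IA[q, 1], IA[q, 2], IB[w, 2]))
        }
      }
    }
    # AF: different non-overlapping first exons spliced to one acceptor
    if (nrow(A) >= 2 && nrow(B) >= 2 &&
        A[2, 1] == B[2, 1] && A[1, 2] < B[1, 1])
      emit("AF", c(A[1, ], B[1, ], A[2, 1]))
    # AL: different non-overlapping last exons from one donor
    na <- nrow(A); nb <- nrow(B)
    if (na >= 2 && nb >= 2 &&
        A[na - 1, 2] == B[nb - 1, 2] && A[na, 2] < B[nb, 1])
      emit("AL", c(A[na, ], B[nb, ], A[na - 1, 2]))
    # MX: internal exons, same flanking boundaries, non-overlapping,
    # never co-occurring in any isoform of the gene
    if (na >= 3 && nb >= 3)
      for (q in 2:(na - 1)) for (w in 2:(nb - 1)) {
        if (A[q - 1, 2] != B[w - 1, 2] || A[q + 1, 1] != B[w + 1, 1]) next
        if (A[q, 2] >= B[w, 1]) next  # overlap or wrong order
        both <- vapply(txs, function(m)
          any(m[, 1] == A[q, 1] & m[, 2] == A[q, 2]) &&
            any(m[, 1] == B[w, 1] & m[, 2] == B[w, 2]), logical(1))
        if (!any(both))
          emit("MX", c(A[q - 1, 2], A[q, ], B[w, ], A[q + 1, 1]))
      }
  }
  out <- unlist(res)
  if (is.null(out)) character() else sort(unique(out))
}

event_keys <- function(events) {
  if (!nrow(events)) return(character())
  sort(unique(paste(events$gene_id, events$event_type, events$coords)))
}

# ---- clustering: independent greedy trace ----------------------------
oracle_cluster <- function(positions, counts, hw = 12, sep = 30) {
  df <- data.frame(pos = positions, cnt = counts, taken = FALSE)
  reps <- data.frame(pos = numeric(), cnt = numeric())
  repeat {
    open <- which(!df$taken)
    if (!length(open)) break
    o <- open[order(-df$cnt[open], df$pos[open])][1]
    grab <- which(!df$taken & abs(df$pos - df$pos[o]) <= hw)
    reps <- rbind(reps, data.frame(pos = df$pos[o],
                                   cnt = sum(df$cnt[grab])))
    df$taken[grab] <- TRUE
  }
  reps <- reps[order(-reps$cnt, reps$pos), ]
  final <- data.frame(pos = numeric(), cnt = numeric())
  for (r in seq_len(nrow(reps))) {
    d <- abs(final$pos - reps$pos[r])
    if (nrow(final) && any(d <= sep)) {
      w <- which.min(d)
      final$cnt[w] <- final$cnt[w] + reps$cnt[r]
    } else final <- rbind(final, reps[r, ])
  }
  final[order(final$pos), ]
}

# ---- Fisher: explicit enumeration over margin-preserving tables ------
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lp <- function(x) lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  xs <- max(0, c1 - r2):min(c1, r1)
  probs <- exp(lp(xs))
  sum(probs[probs <= exp(lp(a)) * (1 + 1e-7)])
}

# ---- sequences -------------------------------------------------------
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

oracle_pfm <- function(seqs) {
  mat <- matrix(0, 4, nchar(seqs[1]), dimnames = list(c("A","C","G","T"),
                                                      NULL))
  for (s in seqs) {
    ch <- strsplit(s, "")[[1]]
    for (i in seq_along(ch))
      if (ch[i] %in% rownames(mat)) mat[ch[i], i] <- mat[ch[i], i] + 1
  }
  sweep(mat, 2, pmax(colSums(mat), 1), "/")
}
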