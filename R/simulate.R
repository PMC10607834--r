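# Synthetic transcriptome and FLNC-alignment simulator with ground
# truth.  The generator plants, per gene: 1-3 terminal poly(A) sites
# spaced at least `min_pas_spacing` nt apart in the last exon (the
# annotated transcript end sits on the distal site), optionally one
# intronic poly(A) site centred in a deliberately long intron, an AATAAA
# signal at offsets -30..-25 upstream of each cleavage site for a
# configurable fraction of genes, and GT..AG dinucleotides at every
# intron boundary.  Seven dedicated genes carry one canonical
# alternative-splicing event each (RI, SE, A5, A3, AF, AL, MX).
# Reads pick an isoform, then a poly(A) site from the stage's usage
# vector, receive rounded-Gaussian 3' jitter and a uniform 5'
# truncation, and are emitted as exon chains ready for BED12 export.

#' Simulation configuration
#'
#' Defaults describe the stated world of the package's validation suite:
#' 200 genes, four stages (DAP10/18/26/34) with three replicates each,
#' 200 reads per gene per replicate, poly(A)-site usage 0.7/0.3 for
#' two-site genes, cleavage jitter sd 5 nt, AATAAA planted for 60% of
#' genes, and intronic poly(A) sites (in long introns) for 15%.
#'
#' @param n_genes Number of regular genes (in addition to the AS genes).
#' @param stages Stage labels, in developmental order.
#' @param replicates Replicates per stage.
#' @param reads_per_gene Reads per gene per replicate.
#' @param pas_per_gene_probs Named probabilities for 1, 2, 3 terminal
#'   poly(A) sites per gene.
#' @param min_pas_spacing Minimum spacing between planted sites (nt).
#' @param jitter_sd Gaussian sd of 3'-end cleavage jitter (nt).
#' @param signal_fraction Fraction of genes with AATAAA planted at
#'   -30..-25 of each of their sites.
#' @param intronic_fraction Fraction of regular genes carrying one
#'   additional intronic poly(A) site inside a long intron.
#' @param intronic_usage Usage of the intronic site (terminal-site
#'   usages are scaled by 1 - intronic_usage).
#' @param diff_fraction Fraction of APA genes whose usage vector shifts
#'   across stages (proximal/distal usages interpolate to their
#'   reverse); the rest keep constant usage.
#' @param n_as_genes 0 or 7: number of canonical AS-event genes.
#' @param exon_count_range,exon_length_range,intron_length_range,
#'   long_intron_range Structure ranges (nt).
#' @param seed Default seed used by [simulate_experiment].
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200L,
                       stages = c("DAP10", "DAP18", "DAP26", "DAP34"),
                       replicates = 3L,
                       reads_per_gene = 200L,
                       pas_per_gene_probs = c("1" = 0.6, "2" = 0.3,
                                              "3" = 0.1),
                       min_pas_spacing = 60L,
                       jitter_sd = 5,
                       signal_fraction = 0.6,
                       intronic_fraction = 0.15,
                       intronic_usage = 0.15,
                       diff_fraction = 0.3,
                       n_as_genes = 7L,
                       exon_count_range = c(2L, 6L),
                       exon_length_range = c(100L, 300L),
                       intron_length_range = c(150L, 600L),
                       long_intron_range = c(2000L, 4000L),
                       seed = 20260911L) {
  cfg <- as.list(environment())
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (!n_as_genes %in% c(0L, 7L)) stop("n_as_genes must be 0 or 7")
  if (min_pas_spacing < 1L) stop("min_pas_spacing must be positive")
  if (abs(sum(pas_per_gene_probs) - 1) > 1e-8)
    stop("pas_per_gene_probs must sum to 1")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  max_sites <- max(as.integer(names(pas_per_gene_probs)))
  if ((max_sites - 1L) * min_pas_spacing + 150L > 10000L)
    stop("infeasible config: planted sites cannot fit in a terminal exon")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate the synthetic genome, annotation and ground truth
#'
#' Deterministic for a fixed seed.  Genes are laid out on four
#' chromosomes with 500-nt spacers, strands alternating pseudo-randomly.
#'
#' @param config A [sim_config].
#' @param seed Integer seed (default taken from the config).
#' @return List of class `sim_truth`: `genome` (`DNAStringSet`),
#'   `annotation` ([tx_annotation]), `pas` (data.table with per-stage
#'   usage columns `usage_<stage>`), `as_events` (planted events:
#'   `gene_id`, `event_type`, `coords`), `gene_info` (per gene: class,
#'   differential flag, is_apa), and `config`.
#' @export
simulate_transcriptome <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  cfg <- config
  spacer <- 500L
  n_chrom <- 4L
  as_types <- if (cfg$n_as_genes == 7L)
    c("RI", "SE", "A5", "A3", "AF", "AL", "MX") else character()
  n_total <- cfg$n_genes + length(as_types)
  # per-chromosome growing state
  chrom_seq <- replicate(n_chrom, character(), simplify = FALSE)
  chrom_len <- rep(0L, n_chrom)
  exon_rows <- list(); pas_rows <- list(); ev_rows <- list()
  info_rows <- list()
  n_stage <- length(cfg$stages)

  for (gi in seq_len(n_total)) {
    gene <- sprintf("G%04d", gi)
    is_as <- gi <= length(as_types)
    strand <- sample(c("+", "-"), 1L)
    ci <- ((gi - 1L) %% n_chrom) + 1L
    if (is_as) {
      gb <- build_as_gene(as_types[gi], cfg)
    } else {
      gb <- build_regular_gene(cfg)
    }
    # sequence: random bases then planted features (local sense coords)
    L <- gb$len
    s <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                prob = c(0.3, 0.2, 0.2, 0.3))
    for (iv in gb$introns_all) {        # GT..AG at every planted intron
      s[iv[1]] <- "G"; s[iv[1] + 1L] <- "T"
      s[iv[2] - 1L] <- "A"; s[iv[2]] <- "G"
    }
    has_signal <- runif(1) < cfg$signal_fraction
    if (has_signal) for (p in gb$pas$pos) {
      if (p - 30L >= 1L)
        s[(p - 30L):(p - 25L)] <- c("A", "A", "T", "A", "A", "A")
    }
    offset <- chrom_len[ci] + spacer
    loc2gen <- function(x) if (strand == "+") offset + x
                           else offset + (L - x + 1L)
    # exons per isoform
    for (ti in seq_along(gb$isoforms)) {
      exl <- gb$isoforms[[ti]]
      gs <- loc2gen(exl[, 2]); ge <- loc2gen(exl[, 1])
      if (strand == "+") { gs <- loc2gen(exl[, 1]); ge <- loc2gen(exl[, 2]) }
      exon_rows[[length(exon_rows) + 1L]] <- data.table(
        gene_id = gene, transcript_id = paste0(gene, ".t", ti),
        chrom = paste0("chr", ci), strand = strand,
        start = pmin(gs, ge), end = pmax(gs, ge))
    }
    # usage matrix: sites x stages
    um <- gb$usage_by_stage(n_stage)
    pas_dt <- data.table(gene_id = gene, chrom = paste0("chr", ci),
                         strand = strand,
                         position = vapply(gb$pas$pos, loc2gen, integer(1)),
                         local_pos = gb$pas$pos,
                         site_ord = seq_len(nrow(gb$pas)),
                         is_intronic = gb$pas$intronic,
                         isoform = gb$pas$isoform,
                         has_signal = has_signal)
    for (si in seq_len(n_stage))
      pas_dt[, (paste0("usage_", cfg$stages[si])) := um[, si]]
    pas_rows[[length(pas_rows) + 1L]] <- pas_dt
    if (is_as) {
      cg <- sort(vapply(gb$event_coords, loc2gen, integer(1)))
      ev_rows[[length(ev_rows) + 1L]] <- data.table(
        gene_id = gene, event_type = as_types[gi],
        chrom = paste0("chr", ci), strand = strand,
        coords = paste(cg, collapse = ","))
    }
    info_rows[[length(info_rows) + 1L]] <- data.table(
      gene_id = gene, class = if (is_as) "as" else "regular",
      chrom = paste0("chr", ci), strand = strand,
      gene_local_len = L, offset = offset,
      n_sites = nrow(gb$pas), is_apa = nrow(gb$pas) >= 2L,
      differential = gb$differential, has_signal = has_signal)
    gseq <- if (strand == "+") paste(s, collapse = "")
            else as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(paste(s, collapse = ""))))
    chrom_seq[[ci]] <- c(chrom_seq[[ci]],
                         paste(rep("ACGT", spacer / 4L), collapse = ""),
                         gseq)
    chrom_len[ci] <- offset + L
  }
  # trailing spacer so downstream flanks stay in bounds
  genome <- Biostrings::DNAStringSet(vapply(seq_len(n_chrom), function(ci)
    paste0(paste(chrom_seq[[ci]], collapse = ""),
           paste(rep("ACGT", spacer / 4L), collapse = "")), character(1)))
  names(genome) <- paste0("chr", seq_len(n_chrom))
  ann <- tx_annotation(rbindlist(exon_rows))
  structure(list(genome = genome, annotation = ann,
                 pas = rbindlist(pas_rows, fill = TRUE),
                 as_events = rbindlist(ev_rows),
                 gene_info = rbindlist(info_rows),
                 config = cfg, seed = seed),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", nrow(x$gene_info), "genes,", nrow(x$pas),
      "planted poly(A) sites,", nrow(x$as_events), "planted AS events\n")
  invisible(x)
}

# --- gene builders (transcription-direction local coordinates) ---------

# returns list(len, isoforms = list of matrix(start,end), introns_all =
# list of c(s,e), pas = data.table(pos, intronic, isoform),
# usage_by_stage = function(n_stage) -> matrix sites x stages,
# differential, event_coords (AS genes only))
build_regular_gene <- function(cfg) {
  n_ex <- sample(cfg$exon_count_range[1]:cfg$exon_count_range[2], 1L)
  ex_len <- sample(cfg$exon_length_range[1]:cfg$exon_length_range[2],
                   n_ex, replace = TRUE)
  n_pas <- as.integer(sample(names(cfg$pas_per_gene_probs), 1L,
                             prob = cfg$pas_per_gene_probs))
  # terminal exon must hold all terminal sites
  ex_len[n_ex] <- (n_pas - 1L) * cfg$min_pas_spacing +
    sample(150:250, 1L)
  in_len <- if (n_ex > 1L)
    sample(cfg$intron_length_range[1]:cfg$intron_length_range[2],
           n_ex - 1L, replace = TRUE) else integer()
  has_ipa <- n_ex >= 2L && runif(1) < cfg$intronic_fraction
  ipa_intron <- NA_integer_
  if (has_ipa) {
    ipa_intron <- sample(seq_len(n_ex - 1L), 1L)
    in_len[ipa_intron] <- sample(cfg$long_intron_range[1]:
                                   cfg$long_intron_range[2], 1L)
  }
  # local layout
  starts <- integer(n_ex); ends <- integer(n_ex); pos <- 1L
  introns <- list()
  for (i in seq_len(n_ex)) {
    starts[i] <- pos; ends[i] <- pos + ex_len[i] - 1L
    pos <- ends[i] + 1L
    if (i < n_ex) {
      introns[[i]] <- c(pos, pos + in_len[i] - 1L)
      pos <- pos + in_len[i]
    }
  }
  L <- ends[n_ex]
  # terminal sites, proximal..distal, distal at the annotated end
  term <- ends[n_ex] - (n_pas - seq_len(n_pas)) * cfg$min_pas_spacing
  pas <- data.table(pos = term, intronic = FALSE, isoform = 1L)
  if (has_ipa) {
    iv <- introns[[ipa_intron]]
    ipa_pos <- as.integer((iv[1] + iv[2]) %/% 2L)
    pas <- rbind(data.table(pos = ipa_pos, intronic = TRUE, isoform = 1L),
                 pas)
    setorder(pas, pos)
  }
  base_u <- switch(as.character(n_pas), "1" = 1, "2" = c(0.7, 0.3),
                   "3" = c(0.5, 0.3, 0.2))
  differential <- n_pas >= 2L && runif(1) < cfg$diff_fraction
  iu <- cfg$intronic_usage
  usage_by_stage <- local({
    n_pas_l <- n_pas; has_ipa_l <- has_ipa; base_l <- base_u
    diff_l <- differential; iu_l <- iu; ord <- order(pas$pos)
    intr_l <- pas$intronic
    function(n_stage) {
      m <- matrix(0, nrow(pas), n_stage)
      for (si in seq_len(n_stage)) {
        w <- if (diff_l && n_stage > 1L) (si - 1L) / (n_stage - 1L) else 0
        tu <- (1 - w) * base_l + w * rev(base_l)
        full <- if (has_ipa_l) {
          u <- numeric(nrow(pas)); u[intr_l] <- iu_l
          u[!intr_l] <- tu * (1 - iu_l); u
        } else tu
        m[, si] <- full
      }
      m
    }
  })
  list(len = L, isoforms = list(cbind(starts, ends)),
       introns_all = introns, pas = pas,
       usage_by_stage = usage_by_stage, differential = differential,
       event_coords = NULL)
}

build_as_gene <- function(type, cfg) {
  E <- 200L; I <- 300L   # canonical block sizes
  seg <- function(...) { # cumulative layout helper: returns boundaries
    lens <- c(...); ends <- cumsum(lens)
    cbind(ends - lens + 1L, ends)
  }
  iso <- list(); introns <- list(); ev <- NULL
  if (type == "RI") {
    b <- seg(E, I, E)                       # exon1 intron exon2
    iso[[1]] <- rbind(c(b[1, 1], b[1, 2]), c(b[3, 1], b[3, 2]))
    iso[[2]] <- rbind(c(b[1, 1], b[3, 2])) # retained
    introns <- list(c(b[2, 1], b[2, 2]))
    ev <- c(b[1, 1], b[2, 1], b[2, 2], b[3, 2])
  } else if (type == "SE") {
    b <- seg(E, I, E, I, E)
    iso[[1]] <- rbind(b[1, ], b[3, ], b[5, ])
    iso[[2]] <- rbind(b[1, ], b[5, ])
    introns <- list(c(b[2, 1], b[2, 2]), c(b[4, 1], b[4, 2]),
                    c(b[2, 1], b[4, 2]))
    ev <- c(b[2, 1], b[2, 2], b[4, 1], b[4, 2])
  } else if (type == "A5") {
    d <- 40L
    b <- seg(E, I, E)
    iso[[1]] <- rbind(b[1, ], b[3, ])                 # long exon1
    iso[[2]] <- rbind(c(b[1, 1], b[1, 2] - d), b[3, ])
    introns <- list(c(b[2, 1], b[2, 2]), c(b[2, 1] - d, b[2, 2]))
    ev <- c(b[2, 1] - d, b[2, 1], b[2, 2])
  } else if (type == "A3") {
    d <- 40L
    b <- seg(E, I, E)
    iso[[1]] <- rbind(b[1, ], b[3, ])                 # short intron
    iso[[2]] <- rbind(b[1, ], c(b[3, 1] + d, b[3, 2]))
    introns <- list(c(b[2, 1], b[2, 2]), c(b[2, 1], b[2, 2] + d))
    ev <- c(b[2, 1], b[2, 2], b[2, 2] + d)
  } else if (type == "AF") {
    b <- seg(E, I, E, I, E)  # F1 gap F2 gap E2
    iso[[1]] <- rbind(b[1, ], b[5, ])
    iso[[2]] <- rbind(b[3, ], b[5, ])
    introns <- list(c(b[2, 1], b[4, 2]), c(b[4, 1], b[4, 2]))
    ev <- c(b[1, 1], b[1, 2], b[3, 1], b[3, 2], b[5, 1])
  } else if (type == "AL") {
    b <- seg(E, I, E, I, E)  # E1 gap L1 gap L2
    iso[[1]] <- rbind(b[1, ], b[3, ])
    iso[[2]] <- rbind(b[1, ], b[5, ])
    introns <- list(c(b[2, 1], b[2, 2]), c(b[2, 1], b[4, 2]))
    ev <- c(b[3, 1], b[3, 2], b[5, 1], b[5, 2], b[1, 2])
  } else if (type == "MX") {
    b <- seg(E, I, E, I, E, I, E)  # A gap X1 gap X2 gap B
    iso[[1]] <- rbind(b[1, ], b[3, ], b[7, ])
    iso[[2]] <- rbind(b[1, ], b[5, ], b[7, ])
    introns <- list(c(b[2, 1], b[2, 2]), c(b[4, 1], b[6, 2]),
                    c(b[2, 1], b[4, 2]), c(b[6, 1], b[6, 2]))
    ev <- c(b[1, 2], b[3, 1], b[3, 2], b[5, 1], b[5, 2], b[7, 1])
  } else stop("unknown AS type: ", type)
  L <- max(vapply(iso, function(m) max(m[, 2]), integer(1)))
  # one poly(A) site per distinct isoform end
  ends3 <- vapply(iso, function(m) max(m[, 2]), integer(1))
  pas <- unique(data.table(pos = ends3,
                           intronic = FALSE,
                           isoform = seq_along(iso)))
  pas <- pas[, .(isoform = isoform[1]), by = .(pos, intronic)]
  setorder(pas, pos)
  setcolorder(pas, c("pos", "intronic", "isoform"))
  usage_by_stage <- local({
    np <- nrow(pas)
    function(n_stage) matrix(1 / np, np, n_stage)
  })
  list(len = L, isoforms = iso, introns_all = introns, pas = pas,
       usage_by_stage = usage_by_stage, differential = FALSE,
       event_coords = ev)
}

# --- read simulation ---------------------------------------------------

#' Simulate FLNC read alignments for one stage and replicate
#'
#' Each read picks an isoform (uniform over the gene's isoforms), then a
#' poly(A) site from the stage's usage vector; its 3' terminus is the
#' site plus rounded Gaussian jitter, its 5' start is uniformly
#' truncated within the first exon.  Reads ending at an intronic site
#' retain the host intron's upstream exons and run into the intron
#' (unspliced 3' portion).  Deterministic for a fixed seed.
#'
#' @param sim A `sim_truth` from [simulate_transcriptome].
#' @param stage Stage label (must be one of the config's stages).
#' @param replicate Replicate index.
#' @param seed Integer seed.
#' @return List with `reads` (exon-chain data.table: `read_id`, `chrom`,
#'   `strand`, `start`, `end`, `sample_id`) and `ledger` (data.table
#'   `gene_id`, `stage`, `replicate`, `site_ord`, `n_reads`).
#' @export
simulate_flnc_reads <- function(sim, stage, replicate, seed) {
  stopifnot(inherits(sim, "sim_truth"), stage %in% sim$config$stages)
  set.seed(seed)
  cfg <- sim$config
  sample_id <- paste0(stage, "-", replicate)
  ucol <- paste0("usage_", stage)
  reads_l <- list(); ledger_l <- list()
  info <- sim$gene_info
  ann_ex <- sim$annotation$exons
  for (gi in seq_len(nrow(info))) {
    gene <- info$gene_id[gi]
    gpas <- sim$pas[gene_id == gene]
    n <- cfg$reads_per_gene
    # local-coordinate isoform structures for this gene
    strand <- info$strand[gi]; L <- info$gene_local_len[gi]
    off <- info$offset[gi]
    gen2loc <- function(x) if (strand == "+") x - off else off + L + 1L - x
    gex <- ann_ex[gene_id == gene]
    iso_ids <- unique(gex$transcript_id)
    iso_loc <- lapply(iso_ids, function(tid) {
      e <- gex[transcript_id == tid]
      a <- gen2loc(e$start); b <- gen2loc(e$end)
      m <- cbind(pmin(a, b), pmax(a, b))
      m[order(m[, 1]), , drop = FALSE]
    })
    if (length(iso_loc) > 1L) {
      # multi-isoform (AS) gene: isoform chosen uniformly per read; the
      # read ends at its isoform's own site when one exists, else at the
      # shared terminal site
      iso_pick <- sample.int(length(iso_loc), n, replace = TRUE)
      term_site <- which(!gpas$is_intronic)
      pick <- vapply(iso_pick, function(u) {
        w <- which(gpas$isoform == u & !gpas$is_intronic)
        if (length(w)) w[1] else term_site[1]
      }, integer(1))
    } else {
      pick <- sample.int(nrow(gpas), n, replace = TRUE,
                         prob = gpas[[ucol]])
      iso_pick <- rep(1L, n)
    }
    ledger_l[[gi]] <- data.table(gene_id = gene, stage = stage,
                                 replicate = replicate,
                                 site_ord = gpas$site_ord,
                                 n_reads = tabulate(pick, nrow(gpas)))
    jit <- as.integer(round(rnorm(n, 0, cfg$jitter_sd)))
    blocks <- simulate_gene_reads(gpas, pick, iso_pick, jit, iso_loc, cfg)
    bl <- blocks$blocks
    bl[, `:=`(read_id = paste0(sample_id, ":", gene, ":", rid),
              chrom = info$chrom[gi], strand = strand,
              sample_id = sample_id)]
    if (strand == "+") {
      bl[, `:=`(gstart = off + ls, gend = off + le)]
    } else {
      bl[, `:=`(gstart = off + L + 1L - le, gend = off + L + 1L - ls)]
    }
    reads_l[[gi]] <- bl[, .(read_id, chrom, strand, start = gstart,
                            end = gend, sample_id)]
  }
  reads <- rbindlist(reads_l)
  setorder(reads, chrom, start, read_id)
  list(reads = reads, ledger = rbindlist(ledger_l))
}

# per-gene block construction in local coordinates; reads sharing one
# (isoform, site) pair are laid out together (vectorized)
simulate_gene_reads <- function(gpas, pick, iso_pick, jit, iso_loc, cfg) {
  grp <- paste(iso_pick, pick)
  out <- list()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    p <- pick[idx[1]]
    iso <- iso_loc[[iso_pick[idx[1]]]]
    if (gpas$is_intronic[p]) {
      # keep exons strictly upstream of the site; the read's last block
      # runs unspliced from its exon into the host intron up to the site
      keep <- which(iso[, 2] < gpas$local_pos[p])
      m <- iso[keep, , drop = FALSE]
      last_min <- m[nrow(m), 2] + 1L
      upper <- if (length(keep) < nrow(iso))
        iso[length(keep) + 1L, 1] - 1L else .Machine$integer.max
    } else {
      m <- iso
      last_min <- m[nrow(m), 1] + 1L
      upper <- .Machine$integer.max
    }
    nb <- nrow(m); nr <- length(idx)
    term <- pmin(pmax(gpas$local_pos[p] + jit[idx], last_min), upper)
    first_len <- iso[1, 2] - iso[1, 1] + 1L
    trunc5 <- sample.int(max(min(40L, first_len - 20L), 1L), nr,
                         replace = TRUE) - 1L
    ls <- rep(m[, 1], nr); le <- rep(m[, 2], nr)
    last_i <- seq(nb, by = nb, length.out = nr)
    first_i <- seq(1L, by = nb, length.out = nr)
    le[last_i] <- term
    ls[first_i] <- ls[first_i] + trunc5
    out[[length(out) + 1L]] <- data.table(rid = rep(idx, each = nb),
                                          ls = ls, le = le)
  }
  list(blocks = rbindlist(out))
}

#' Simulate the full multi-stage experiment
#'
#' Convenience wrapper over [simulate_flnc_reads] for every
#' stage/replicate; per-run seeds are derived from `seed` as
#' `seed + 100*stage_index + replicate`.
#'
#' @param sim A `sim_truth`.
#' @param seed Base integer seed.
#' @return List with `reads` (all samples), `ledger`, and
#'   `sample_sheet` (`sample_id`, `stage`, `replicate`, `library_size` =
#'   emitted read count).
#' @export
simulate_experiment <- function(sim, seed = sim$seed) {
  cfg <- sim$config
  reads_l <- list(); ledger_l <- list(); sheet <- list()
  k <- 0L
  for (si in seq_along(cfg$stages)) for (ri in seq_len(cfg$replicates)) {
    k <- k + 1L
    res <- simulate_flnc_reads(sim, cfg$stages[si], ri,
                               seed = seed + 100L * si + ri)
    reads_l[[k]] <- res$reads
    ledger_l[[k]] <- res$ledger
    sheet[[k]] <- data.table(sample_id = paste0(cfg$stages[si], "-", ri),
                             stage = cfg$stages[si], replicate = ri,
                             library_size = length(unique(res$reads$read_id)))
  }
  list(reads = rbindlist(reads_l), ledger = rbindlist(ledger_l),
       sample_sheet = rbindlist(sheet))
}

# --- recovery scoring --------------------------------------------------

#' Score pipeline calls against the simulation ground truth
#'
#' Poly(A) sites match one-to-one (greedy by distance, closest pairs
#' first) when on the same gene and strand within `tolerance` nt.
#' AS events match on identical type and defining coordinates.
#'
#' @param called List with any of: `pas` (a `pas_profiles`), `events`
#'   (from [classify_as_events]), `apa` (from [classify_apa_genes]),
#'   `differential` (from [differential_apa]).
#' @param truth A `sim_truth`.
#' @param tolerance Matching tolerance for sites (nt, default 12).
#' @return List of per-component data.tables and a `summary` table of
#'   precision/recall values.
#' @export
score_recovery <- function(called, truth, tolerance = 12L) {
  out <- list()
  summ <- list()
  if (!is.null(called$pas)) {
    st <- called$pas$sites
    m <- match_pas(st, truth$pas, tolerance)
    out$pas_matches <- m
    prec <- sum(!is.na(m$true_position)) / nrow(st)
    rec <- sum(!is.na(m$true_position)) / nrow(truth$pas)
    summ$pas <- data.table(component = "pas", precision = prec,
                           recall = rec)
    # intronic flag scoring on matched sites (only when flags were set)
    mm <- m[!is.na(true_position)]
    if (nrow(mm) && !anyNA(mm$called_intronic)) {
      tp <- sum(mm$called_intronic & mm$true_intronic)
      summ$intronic <- data.table(
        component = "intronic_pas",
        precision = if (sum(mm$called_intronic)) tp / sum(mm$called_intronic)
                    else NA_real_,
        recall = if (sum(mm$true_intronic)) tp / sum(mm$true_intronic)
                 else NA_real_)
    }
  }
  if (!is.null(called$apa)) {
    truth_apa <- truth$gene_info[, .(gene_id, true_apa = is_apa)]
    cl <- merge(called$apa$classes, truth_apa, by = "gene_id")
    tp <- sum(cl$is_apa & cl$true_apa)
    summ$apa <- data.table(component = "apa_genes",
                           precision = if (sum(cl$is_apa))
                             tp / sum(cl$is_apa) else NA_real_,
                           recall = if (sum(cl$true_apa))
                             tp / sum(cl$true_apa) else NA_real_)
    out$apa_table <- cl
  }
  if (!is.null(called$events)) {
    ev <- as.data.table(called$events)
    key_c <- ev[, paste(gene_id, event_type, coords)]
    key_t <- truth$as_events[, paste(gene_id, event_type, coords)]
    tp <- length(intersect(key_c, key_t))
    summ$events <- data.table(component = "as_events",
                              precision = if (length(key_c))
                                tp / length(key_c) else NA_real_,
                              recall = if (length(key_t))
                                tp / length(key_t) else NA_real_)
    out$event_keys <- list(called = key_c, truth = key_t)
  }
  if (!is.null(called$differential)) {
    dif <- as.data.table(called$differential)
    called_genes <- unique(dif[significant == TRUE]$gene_id)
    true_genes <- truth$gene_info[differential == TRUE]$gene_id
    tp <- length(intersect(called_genes, true_genes))
    summ$diff <- data.table(component = "differential_apa",
                            precision = if (length(called_genes))
                              tp / length(called_genes) else NA_real_,
                            recall = if (length(true_genes))
                              tp / length(true_genes) else NA_real_)
  }
  out$summary <- rbindlist(summ, fill = TRUE)
  out
}

# greedy one-to-one matching of called to true sites by distance
match_pas <- function(called_sites, truth_pas, tolerance) {
  cs <- as.data.table(called_sites)[, .(gene_id, strand,
                                        called_position = position,
                                        called_intronic = is_intronic,
                                        called_usage = usage,
                                        site_id)]
  tp <- as.data.table(truth_pas)
  ucols <- grep("^usage_", names(tp), value = TRUE)
  tp <- tp[, .(gene_id, strand, true_position = position,
               true_intronic = is_intronic,
               true_usage = rowMeans(as.matrix(.SD)),
               true_ord = site_ord), .SDcols = ucols]
  pairs <- merge(cs, tp, by = c("gene_id", "strand"),
                 allow.cartesian = TRUE)
  pairs[, dist := abs(called_position - true_position)]
  pairs <- pairs[dist <= tolerance]
  setorder(pairs, dist, site_id)
  used_c <- character(); used_t <- character()
  keep <- logical(nrow(pairs))
  if (nrow(pairs)) for (i in seq_len(nrow(pairs))) {
    ck <- pairs$site_id[i]
    tk <- paste(pairs$gene_id[i], pairs$true_position[i])
    if (ck %in% used_c || tk %in% used_t) next
    keep[i] <- TRUE
    used_c <- c(used_c, ck); used_t <- c(used_t, tk)
  }
  matched <- pairs[keep]
  res <- merge(cs, matched[, .(site_id, true_position, true_intronic,
                               true_usage, true_ord, dist)],
               by = "site_id", all.x = TRUE)
  res[]
}
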