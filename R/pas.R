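# Poly(A)-site calling from read 3' termini.
#
# Per gene: exact cleavage-position histograms are clustered greedily
# (descending count, ties by ascending coordinate); each representative
# absorbs all positions within +/- assignment_halfwidth nt; afterwards
# any representative within min_separation nt of a stronger one is merged
# into it, so retained sites of one gene are pairwise > min_separation
# apart.  Sites with pooled usage strictly greater than min_usage are
# retained and usages renormalized; the most abundant site per gene is
# flagged major (ties -> the 3'-most site in transcription direction).

#' Tally exact cleavage positions per gene and sample
#'
#' @param cleavage Cleavage records from [read_end_sites].
#' @return List with `counts` (data.table `gene_id`, `chrom`, `strand`,
#'   `position`, `sample_id`, `n`) and `n_unassigned`.
#' @export
collect_cleavage_counts <- function(cleavage) {
  cl <- as.data.table(cleavage)
  n_un <- sum(is.na(cl$gene_id))
  cl <- cl[!is.na(gene_id)]
  cnt <- cl[, .(n = .N), by = .(gene_id, chrom, strand, position, sample_id)]
  setorder(cnt, gene_id, position, sample_id)
  list(counts = cnt[], n_unassigned = n_un)
}

#' Greedy clustering of cleavage positions into poly(A) sites
#'
#' @param positions Integer vector of distinct cleavage positions.
#' @param counts Positive read counts parallel to `positions`.
#' @param assignment_halfwidth Reads ending within this many nt of a
#'   site are assigned to it (default 12).
#' @param min_separation Retained sites must be more than this many nt
#'   apart (default 30).
#' @return data.table `position` (representative), `count` (absorbed
#'   reads), sorted by position, with attribute `"assignment"`: a
#'   data.table mapping every input `position` to its `site_position`.
#' @export
cluster_cleavage_sites <- function(positions, counts,
                                   assignment_halfwidth = 12L,
                                   min_separation = 30L) {
  if (assignment_halfwidth <= 0L || min_separation <= 0L)
    stop("assignment_halfwidth and min_separation must be positive")
  stopifnot(length(positions) == length(counts), all(counts > 0),
            !anyDuplicated(positions))
  ord <- order(-counts, positions)
  pos <- positions[ord]; cnt <- counts[ord]
  m <- length(pos)
  consumed <- rep(FALSE, m)
  rep_of <- integer(m)             # index (into pos) of each position's rep
  rep_idx <- integer()
  for (i in seq_len(m)) {
    if (consumed[i]) next
    grab <- !consumed & abs(pos - pos[i]) <= assignment_halfwidth
    rep_of[grab] <- i
    rep_idx <- c(rep_idx, i)
    consumed <- consumed | grab
  }
  rep_cnt <- vapply(rep_idx, function(i) sum(cnt[rep_of == i]), numeric(1))
  # merge pass: a representative within min_separation of a stronger one
  # hands its positions to the nearest retained (stronger) representative
  ord2 <- order(-rep_cnt, pos[rep_idx])
  keep <- integer()
  for (k in ord2) {
    i <- rep_idx[k]
    d <- abs(pos[keep] - pos[i])
    if (length(keep) && any(d <= min_separation)) {
      w <- keep[which.min(d)]
      rep_of[rep_of == i] <- w
    } else keep <- c(keep, i)
  }
  out <- data.table(position = pos[keep],
                    count = vapply(keep, function(i)
                      sum(cnt[rep_of == i]), numeric(1)))
  setorder(out, position)
  asg <- data.table(position = pos, site_position = pos[rep_of])
  setorder(asg, position)
  setattr(out, "assignment", asg)
  out
}

#' Build per-gene poly(A)-site profiles
#'
#' Runs clustering per gene on pooled counts (all samples), applies the
#' usage filter once, orders sites 5' to 3' in transcription direction,
#' flags the major site, and carries a per-sample count table.
#'
#' @param cleavage_counts `$counts` from [collect_cleavage_counts].
#' @param min_usage Sites with pooled usage strictly greater than this
#'   are retained (default 0.05); usages renormalized afterwards.
#' @param assignment_halfwidth,min_separation See
#'   [cluster_cleavage_sites].
#' @return Object of class `pas_profiles`: list with `sites` (data.table
#'   `site_id`, `gene_id`, `chrom`, `position`, `strand`, `site_ord`,
#'   `count`, `usage`, `is_major`, `is_intronic` (NA until
#'   [locate_intronic_pas])), `counts` (long data.table `site_id`,
#'   `sample_id`, `count`), and `dropped_genes` (genes whose every site
#'   failed the usage filter).
#' @export
build_pas_profiles <- function(cleavage_counts, min_usage = 0.05,
                               assignment_halfwidth = 12L,
                               min_separation = 30L) {
  cc <- as.data.table(cleavage_counts)
  pooled <- cc[, .(n = sum(n)), by = .(gene_id, chrom, strand, position)]
  spl <- split(pooled, by = "gene_id", keep.by = TRUE)
  site_l <- vector("list", length(spl))
  asg_l <- vector("list", length(spl))
  for (k in seq_along(spl)) {
    g <- spl[[k]]
    cl <- cluster_cleavage_sites(g$position, g$n, assignment_halfwidth,
                                 min_separation)
    site_l[[k]] <- data.table(gene_id = g$gene_id[1], chrom = g$chrom[1],
                              strand = g$strand[1],
                              position = cl$position, count = cl$count)
    asg_l[[k]] <- cbind(gene_id = g$gene_id[1], attr(cl, "assignment"))
  }
  sites <- rbindlist(site_l)
  assignment <- rbindlist(asg_l)
  sites[, usage := count / sum(count), by = gene_id]
  prof <- structure(list(sites = sites[], counts = NULL,
                         assignment = assignment,
                         position_counts = cc,
                         dropped_genes = character(),
                         params = list(min_usage = min_usage,
                                       assignment_halfwidth =
                                         assignment_halfwidth,
                                       min_separation = min_separation)),
                    class = "pas_profiles")
  prof <- filter_by_usage(prof, min_usage)
  select_major_site(prof)
}

#' Apply the usage filter to poly(A)-site profiles
#'
#' Retains sites whose pooled usage is strictly greater than `min_usage`
#' (usage denominator = the gene's total assigned reads across all
#' samples, computed before filtering), renormalizes usages over the
#' survivors, and rebuilds site ids, ordinals and the per-sample count
#' table.  Applied once, not iteratively.  Genes losing all sites are
#' dropped with a message.
#'
#' @param profiles A `pas_profiles`.
#' @param min_usage Strict usage threshold (default 0.05).
#' @return The filtered `pas_profiles`.
#' @export
filter_by_usage <- function(profiles, min_usage = 0.05) {
  sites <- copy(profiles$sites)
  if (is.null(sites$usage)) sites[, usage := count / sum(count),
                                  by = gene_id]
  dropped <- sites[, .(all_fail = all(usage <= min_usage)), by = gene_id]
  dropped_genes <- dropped[all_fail == TRUE]$gene_id
  if (length(dropped_genes))
    message(length(dropped_genes),
            " gene(s) dropped: no site above usage threshold")
  sites <- sites[usage > min_usage & !gene_id %in% dropped_genes]
  sites[, usage := count / sum(count), by = gene_id]
  if (nrow(sites)) {
    sites[, site_ord := if (strand[1] == "+") seq_len(.N)
          else rev(seq_len(.N)), by = gene_id]
  } else sites[, site_ord := integer()]
  sites[, site_id := paste0(gene_id, ":", site_ord)]
  if (is.null(sites$is_intronic)) sites[, is_intronic := NA]
  # per-sample counts via the exact position -> site assignment from
  # clustering; positions of usage-filtered sites drop out here
  persamp <- NULL
  if (!is.null(profiles$position_counts)) {
    cc2 <- merge(profiles$position_counts, profiles$assignment,
                 by = c("gene_id", "position"))
    cc2 <- merge(cc2,
                 sites[, .(gene_id, site_position = position, site_id)],
                 by = c("gene_id", "site_position"))
    persamp <- cc2[, .(count = sum(n)), by = .(site_id, sample_id)]
    setorder(persamp, site_id, sample_id)
  }
  profiles$sites <- sites[]
  profiles$counts <- persamp
  profiles$dropped_genes <- union(profiles$dropped_genes, dropped_genes)
  profiles
}

#' Flag the major poly(A) site of each gene
#'
#' The major site is the one with the highest pooled read count; ties go
#' to the 3'-most site in transcription direction (deterministic).
#'
#' @param profiles A `pas_profiles`.
#' @return The profiles with `$sites$is_major` set (exactly one per
#'   gene).
#' @export
select_major_site <- function(profiles) {
  sites <- copy(profiles$sites)
  if (nrow(sites)) {
    sites[, is_major := {
      best <- which(count == max(count))
      pick <- best[which.max(site_ord[best])]
      seq_len(.N) == pick
    }, by = gene_id]
  } else sites[, is_major := logical()]
  setcolorder(sites, c("site_id", "gene_id", "chrom", "position", "strand",
                       "site_ord", "count", "usage", "is_major",
                       "is_intronic"))
  profiles$sites <- sites[]
  profiles
}

#' @export
print.pas_profiles <- function(x, ...) {
  cat("pas_profiles:", nrow(x$sites), "sites in",
      length(unique(x$sites$gene_id)), "genes\n")
  invisible(x)
}

#' Normalize per-sample site abundances by library size
#'
#' normalized = raw x (median library size / library size of the sample);
#' additionally a per-gene ratio of each site's pooled count to its major
#' site's count is attached to `$sites$major_ratio`.
#'
#' @param profiles A `pas_profiles`.
#' @param library_sizes Named positive numeric vector, one per sample.
#' @return The profiles with `$counts$normalized` and
#'   `$sites$major_ratio` added.
#' @export
normalize_abundance <- function(profiles, library_sizes) {
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  cts <- profiles$counts
  miss <- setdiff(unique(cts$sample_id), names(library_sizes))
  if (length(miss))
    stop("library size missing for sample(s): ", paste(miss, collapse = ", "))
  med <- median(library_sizes)
  cts[, normalized := count * med / library_sizes[sample_id]]
  profiles$counts <- cts
  st <- profiles$sites
  st[, major_ratio := count / count[is_major], by = gene_id]
  profiles$sites <- st
  profiles
}

#' Partition genes into single-PAS and APA classes
#'
#' @param profiles A `pas_profiles` (post-filter).
#' @return List with `classes` (data.table `gene_id`, `n_sites`,
#'   `is_apa`), `n_apa`, `n_single`, and `histogram` (sites-per-gene
#'   counts).
#' @export
classify_apa_genes <- function(profiles) {
  tab <- profiles$sites[, .(n_sites = .N), by = gene_id]
  tab[, is_apa := n_sites >= 2L]
  hist <- tab[, .(n_genes = .N), by = n_sites][order(n_sites)]
  list(classes = tab[], n_apa = sum(tab$is_apa),
       n_single = sum(!tab$is_apa), histogram = hist[])
}

#' Flag intronic poly(A) sites
#'
#' A site is intronic when its position falls strictly within an intron
#' of the gene's reference transcript, taken as the transcript with the
#' largest summed exon length (ties by transcript id).
#'
#' @param profiles A `pas_profiles`.
#' @param ann A [tx_annotation].
#' @return The profiles with `$sites$is_intronic` filled in.
#' @export
locate_intronic_pas <- function(profiles, ann) {
  tx <- as.data.table(ann$transcripts)
  setorder(tx, gene_id, -exonic_length, transcript_id)
  ref <- tx[, .SD[1], by = gene_id][, .(gene_id, transcript_id)]
  ints <- extract_introns(ann, transcript_id = ref$transcript_id)
  st <- profiles$sites
  st[, is_intronic := FALSE]
  if (nrow(ints)) {
    hit <- ints[st, on = .(gene_id, start <= position, end >= position),
                nomatch = NULL, .(site_id = i.site_id)]
    st[site_id %in% hit$site_id, is_intronic := TRUE]
  }
  profiles$sites <- st
  profiles
}

#' Compare lengths of PAS-containing introns with other introns
#'
#' @param ann A [tx_annotation]; introns of each gene's reference
#'   transcript (largest summed exon length) form the universe.
#' @param profiles A `pas_profiles` after [locate_intronic_pas].
#' @return List with `pas_introns` / `other_introns` length vectors,
#'   their medians and quartiles, and a two-sided Wilcoxon rank-sum
#'   `p_value` (`NA` with a message when a group is empty).
#' @export
intron_length_comparison <- function(ann, profiles) {
  tx <- as.data.table(ann$transcripts)
  setorder(tx, gene_id, -exonic_length, transcript_id)
  ref <- tx[, .SD[1], by = gene_id][, .(gene_id, transcript_id)]
  ints <- extract_introns(ann, transcript_id = ref$transcript_id)
  st <- profiles$sites[is_intronic == TRUE]
  ints[, has_pas := FALSE]
  if (nrow(st)) {
    hit <- ints[st, on = .(gene_id, start <= position, end >= position),
                nomatch = NULL,
                .(transcript_id = transcript_id, rank = intron_rank)]
    ints[hit, has_pas := TRUE, on = .(transcript_id, intron_rank = rank)]
  }
  ints[, len := end - start + 1L]
  a <- ints[has_pas == TRUE]$len
  b <- ints[has_pas == FALSE]$len
  p <- NA_real_
  if (length(a) && length(b))
    p <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided")$p.value)
  else message("intron length comparison: a group is empty; no test")
  list(pas_introns = a, other_introns = b,
       median_pas = if (length(a)) median(a) else NA_real_,
       median_other = if (length(b)) median(b) else NA_real_,
       quartiles_pas = if (length(a)) quantile(a, c(.25, .5, .75)) else NULL,
       quartiles_other = if (length(b)) quantile(b, c(.25, .5, .75)) else NULL,
       p_value = p)
}

#' Write the poly(A)-site table as TSV
#'
#' @param profiles A `pas_profiles`.
#' @param path Output TSV (site table; per-sample counts wide).
#' @return `path`, invisibly.
#' @export
write_pas_table <- function(profiles, path) {
  wide <- dcast(profiles$counts, site_id ~ sample_id, value.var = "count",
                fill = 0)
  out <- merge(profiles$sites, wide, by = "site_id", all.x = TRUE)
  setorder(out, gene_id, site_ord)
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
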