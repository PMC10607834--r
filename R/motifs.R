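# Nucleotide composition around poly(A) cleavage sites and fixed k-mer
# counting for poly(A) signals (AAUAAA, UGUA; RNA U mapped to T).
# All windows are strand-aware: for minus-strand sites the extracted
# sequence is reverse-complemented so negative offsets always mean
# upstream in transcription direction.

#' Nucleotide composition profile around poly(A) sites
#'
#' @param sites Site table (`chrom`, `position`, `strand`), e.g.
#'   `profiles$sites` or a subset (proximal/distal sites of APA genes).
#' @param genome `DNAStringSet`.
#' @param flank Window half-width in nt (default 50): offsets run from
#'   `-flank` to `+flank` with 0 at the cleavage position.
#' @return List of class `pfm_profile`: `freqs` (4 x (2*flank+1)
#'   probability matrix, rows A,C,G,T, columns renormalized after N
#'   exclusion), `offsets`, `n_sequences` (sites used) and `n_skipped`
#'   (windows out of chromosome bounds).
#' @export
nucleotide_composition <- function(sites, genome, flank = 50L) {
  st <- as.data.table(sites)
  if (!nrow(st)) stop("empty site set")
  lens <- Biostrings::width(genome)[match(st$chrom, names(genome))]
  ok <- !is.na(lens) & st$position - flank >= 1L &
    st$position + flank <= lens
  n_skip <- sum(!ok)
  st <- st[ok]
  if (!nrow(st)) stop("all windows out of bounds")
  seqs <- extract_sequence(genome, st$chrom, st$position - flank,
                           st$position + flank, st$strand)
  m <- pfm_from_strings(seqs, 2L * flank + 1L)
  colnames(m) <- as.character(seq(-flank, flank))
  structure(list(freqs = m, offsets = seq(-flank, flank),
                 n_sequences = nrow(st), n_skipped = n_skip),
            class = "pfm_profile")
}

#' @export
print.pfm_profile <- function(x, ...) {
  cat("pfm_profile:", x$n_sequences, "sequences, offsets",
      min(x$offsets), "..", max(x$offsets), "\n")
  invisible(x)
}

#' Write a composition profile as TSV (offset, A, C, G, T)
#' @param profile A `pfm_profile`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(profile, path) {
  dt <- data.table(offset = profile$offsets, t(profile$freqs))
  fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Count poly(A)-signal k-mers in a window upstream of cleavage sites
#'
#' Overlapping occurrences are counted within the configured offset
#' window (transcription-direction coordinates relative to cleavage;
#' the default -40..-10 covers the canonical plant poly(A)-signal
#' placement).
#'
#' @param sites Site table (`chrom`, `position`, `strand`).
#' @param genome `DNAStringSet`.
#' @param kmers Character vector of signals; RNA alphabet accepted
#'   (U -> T).  Default `c("AATAAA", "TGTA")`.
#' @param window `c(from, to)` offsets, `from < to <= 0`, relative to
#'   cleavage (position 0).
#' @return data.table per k-mer: `kmer`, `total_hits` (overlapping
#'   occurrences summed over sites), `sites_with_hit`, `fraction`
#'   (of usable sites), plus attribute `n_sites`.
#' @export
kmer_window_counts <- function(sites, genome, kmers = c("AATAAA", "TGTA"),
                               window = c(-40L, -10L)) {
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be c(from, to) with from < to")
  kmers_dna <- toupper(chartr("Uu", "Tt", kmers))
  wlen <- window[2] - window[1] + 1L
  if (any(nchar(kmers_dna) > wlen))
    stop("k-mer longer than the search window")
  st <- as.data.table(sites)
  if (!nrow(st)) stop("empty site set")
  # transcription-direction offsets: on '+' offset o is position + o,
  # on '-' it is position - o
  pos <- st$strand == "+"
  ws <- ifelse(pos, st$position + window[1], st$position - window[2])
  we <- ifelse(pos, st$position + window[2], st$position - window[1])
  lens <- Biostrings::width(genome)[match(st$chrom, names(genome))]
  ok <- !is.na(lens) & ws >= 1L & we <= lens
  st <- st[ok]; ws <- ws[ok]; we <- we[ok]
  seqs <- extract_sequence(genome, st$chrom, ws, we, st$strand)
  subj <- Biostrings::DNAStringSet(seqs)
  res <- rbindlist(lapply(seq_along(kmers_dna), function(i) {
    hits <- Biostrings::vcountPattern(kmers_dna[i], subj)
    data.table(kmer = kmers[i], total_hits = sum(hits),
               sites_with_hit = sum(hits > 0),
               fraction = mean(hits > 0))
  }))
  setattr(res, "n_sites", nrow(st))
  res
}
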