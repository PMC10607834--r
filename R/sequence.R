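# Genome sequence access.  The genome is held as a Biostrings
# DNAStringSet; soft-masked (lowercase) bases are uppercased on read and
# N bases are permitted and propagated.

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return A `DNAStringSet`, uppercased, named by the first whitespace
#'   token of each header.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  gen <- Biostrings::readDNAStringSet(path)
  names(gen) <- sub("\\s.*$", "", names(gen))
  Biostrings::DNAStringSet(toupper(gen))
}

#' Extract genomic subsequences, strand-aware
#'
#' Returns the forward-strand subsequence for `+` intervals and its
#' reverse complement for `-` intervals, so the result always reads
#' 5' to 3' in transcription direction.  Coordinates are 1-based closed.
#'
#' @param genome A `DNAStringSet` from [read_genome].
#' @param chrom,start,end,strand Parallel vectors describing intervals.
#' @return Character vector of uppercase sequences.
#' @export
extract_sequence <- function(genome, chrom, start, end, strand) {
  n <- length(chrom)
  stopifnot(length(start) == n, length(end) == n, length(strand) == n)
  if (!all(chrom %in% names(genome)))
    stop("chromosome(s) absent from genome: ",
         paste(unique(setdiff(chrom, names(genome))), collapse = ", "))
  lens <- Biostrings::width(genome)[match(chrom, names(genome))]
  bad <- which(start < 1L | end > lens | start > end)
  if (length(bad))
    stop("interval out of bounds: ", chrom[bad[1]], ":",
         start[bad[1]], "-", end[bad[1]])
  seqs <- character(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    v <- Biostrings::extractAt(genome[[ch]],
                               IRanges::IRanges(start[i], end[i]))
    neg <- strand[i] == "-"
    if (any(neg)) v[neg] <- Biostrings::reverseComplement(v[neg])
    seqs[i] <- as.character(v)
  }
  seqs
}
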