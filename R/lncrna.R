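# Structural pre-filters for lncRNA candidate transcripts and the
# exon-length comparison between candidate and coding sets.  Coding
# potential prediction is deliberately not part of this package.

#' Structural filter for lncRNA candidates
#'
#' Default (conjunctive) reading: remove transcripts that are mono-exonic
#' AND shorter than `min_exon_length` nt.  The disjunctive reading
#' (remove if mono-exonic OR shorter) is available via `rule`.
#' The boundary is strict: a transcript of exactly `min_exon_length` nt
#' is retained.
#'
#' @param ann A [tx_annotation].
#' @param min_exon_length Length threshold in nt (default 200).
#' @param rule `"conjunctive"` (default) or `"disjunctive"`.
#' @return List of class `filter_report`: `input_count`, `retained`
#'   (transcript ids), `removed` (data.table `transcript_id`, `reason`),
#'   `filtered` (a [tx_annotation] of survivors, `NULL` if none).
#' @export
structural_filter <- function(ann, min_exon_length = 200L,
                              rule = c("conjunctive", "disjunctive")) {
  rule <- match.arg(rule)
  tx <- as.data.table(ann$transcripts)
  mono <- tx$n_exons == 1L
  short <- tx$exonic_length < min_exon_length
  drop <- if (rule == "conjunctive") mono & short else mono | short
  reasons <- character(sum(drop))
  reasons[] <- "mono_exonic_and_short"
  if (rule == "disjunctive") {
    reasons <- ifelse(mono[drop] & short[drop], "mono_exonic_and_short",
                      ifelse(mono[drop], "mono_exonic", "short"))
  }
  removed <- data.table(transcript_id = tx$transcript_id[drop],
                        reason = reasons)
  kept <- tx$transcript_id[!drop]
  filtered <- if (length(kept))
    tx_annotation(ann$exons[transcript_id %in% kept]) else NULL
  structure(list(input_count = nrow(tx), retained = kept,
                 removed = removed, filtered = filtered,
                 params = list(min_exon_length = min_exon_length,
                               rule = rule)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:", x$input_count, "in,", length(x$retained),
      "retained,", nrow(x$removed), "removed\n")
  invisible(x)
}

#' Exon-length comparison between two transcript sets
#'
#' Pools per-exon lengths of each set (e.g. lncRNA candidates vs coding
#' transcripts) and compares them with a two-sided Wilcoxon rank-sum
#' test.
#'
#' @param ann_a,ann_b Two [tx_annotation] objects (or exon tables with
#'   `start`/`end`).
#' @param labels Names for the two sets in the output.
#' @return List with per-set length vectors, medians, quartiles and
#'   `p_value`.
#' @export
exon_length_density <- function(ann_a, ann_b,
                                labels = c("lncRNA", "coding")) {
  get_lens <- function(x) {
    ex <- if (inherits(x, "tx_annotation")) x$exons else as.data.table(x)
    as.numeric(ex$end - ex$start + 1L)
  }
  a <- get_lens(ann_a); b <- get_lens(ann_b)
  if (!length(a) || !length(b)) stop("both exon sets must be non-empty")
  p <- if (length(a) > 1L || length(b) > 1L)
    suppressWarnings(wilcox.test(a, b)$p.value) else NA_real_
  out <- list(lengths = setNames(list(a, b), labels),
              medians = setNames(c(median(a), median(b)), labels),
              quartiles = setNames(list(quantile(a, c(.25, .5, .75)),
                                        quantile(b, c(.25, .5, .75))),
                                   labels),
              p_value = p)
  out
}
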