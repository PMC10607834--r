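# Differential poly(A)-site usage between consecutive developmental
# stages.  For each retained site and stage pair a 2x2 table is built
# (site reads vs all other reads of the gene, replicates pooled within
# stage) and tested with a two-sided Fisher exact test; calls use an
# uncorrected alpha (a BH-adjusted column is always emitted alongside).

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p by hypergeometric enumeration: the sum of probabilities of all
#' tables with the same margins whose probability does not exceed that of
#' the observed table (with the customary 1e-7 relative slack against
#' floating-point ties).  Degenerate margins give p = 1 by convention.
#'
#' @param a,b,c,d Non-negative integer counts; rows are groups, columns
#'   are (this site, other sites).
#' @return List with `p_value` and `odds_ratio` (sample odds ratio
#'   `ad/bc`, `Inf`/`NaN` preserved).
#' @export
fisher_exact <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0)
    return(list(p_value = 1, odds_ratio = NaN))
  lo <- max(0L, k - n); hi <- min(k, m)
  x <- lo:hi
  dens <- dhyper(x, m, n, k)
  p <- sum(dens[dens <= dhyper(a, m, n, k) * (1 + 1e-7)])
  list(p_value = min(p, 1), odds_ratio = (a * d) / (b * c))
}

#' Assemble the 2x2 contingency table for one site and two groups
#'
#' @param profiles A `pas_profiles`.
#' @param site_id Site to test.
#' @param samples_a,samples_b Sample ids of the two groups (replicates
#'   are pooled).
#' @return 2x2 integer matrix (rows = groups, columns = c(site, other)),
#'   or `NULL` with a message when the gene has a single site or one
#'   group has zero reads for the gene.
#' @export
apa_contingency <- function(profiles, site_id, samples_a, samples_b) {
  sid <- site_id
  st <- profiles$sites
  gene <- st[site_id == sid]$gene_id
  if (!length(gene)) stop("unknown site_id: ", sid)
  gsites <- st[gene_id == gene]$site_id
  if (length(gsites) < 2L) {
    message("gene ", gene, " has a single site; nothing to test")
    return(NULL)
  }
  cts <- profiles$counts[site_id %in% gsites]
  tot_a <- sum(cts[sample_id %in% samples_a]$count)
  tot_b <- sum(cts[sample_id %in% samples_b]$count)
  site_a <- sum(cts[site_id == sid & sample_id %in% samples_a]$count)
  site_b <- sum(cts[site_id == sid & sample_id %in% samples_b]$count)
  if (tot_a == 0 || tot_b == 0) {
    message("site ", sid, ": a group has zero reads; untestable")
    return(NULL)
  }
  matrix(c(site_a, tot_a - site_a, site_b, tot_b - site_b),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("groupA", "groupB"), c("site", "other")))
}

#' Differential poly(A)-site usage across consecutive stages
#'
#' @param profiles A `pas_profiles`.
#' @param sample_sheet data.frame with `sample_id`, `stage` and
#'   `replicate`; stage order follows first appearance unless `stage` is
#'   a factor.
#' @param alpha Uncorrected significance level (default 0.05).
#' @return data.table with one row per testable (site, consecutive-stage
#'   comparison): counts, per-stage usages, `effect` (usageB - usageA),
#'   `p_value`, `padj` (BH within comparison) and `significant`
#'   (`p_value < alpha`).
#' @export
differential_apa <- function(profiles, sample_sheet, alpha = 0.05) {
  ss <- as.data.table(sample_sheet)
  stages <- if (is.factor(ss$stage)) levels(ss$stage) else unique(ss$stage)
  if (length(stages) < 2L) {
    message("fewer than two stages; no comparisons")
    return(data.table(site_id = character(), gene_id = character(),
                      comparison = character(), site_a = numeric(),
                      other_a = numeric(), site_b = numeric(),
                      other_b = numeric(), usage_a = numeric(),
                      usage_b = numeric(), effect = numeric(),
                      odds_ratio = numeric(), p_value = numeric(),
                      padj = numeric(), significant = logical()))
  }
  st <- profiles$sites
  multi <- st[, .N, by = gene_id][N >= 2L]$gene_id
  cts <- merge(profiles$counts,
               st[, .(site_id, gene_id)], by = "site_id")
  cts <- merge(cts, ss[, .(sample_id, stage)], by = "sample_id")
  stage_site <- cts[, .(count = sum(count)), by = .(gene_id, site_id, stage)]
  res <- list()
  for (ci in seq_len(length(stages) - 1L)) {
    sa <- stages[ci]; sb <- stages[ci + 1L]
    cmp <- paste0(sa, "vs", sb)
    sub <- stage_site[stage %in% c(sa, sb) & gene_id %in% multi]
    wide <- dcast(sub, gene_id + site_id ~ stage, value.var = "count",
                  fill = 0)
    for (s in c(sa, sb)) if (!s %in% names(wide)) wide[, (s) := 0]
    wide[, `:=`(gene_a = sum(get(sa)), gene_b = sum(get(sb))), by = gene_id]
    wide <- wide[gene_a > 0 & gene_b > 0]
    if (!nrow(wide)) next
    rows <- wide[, {
      fa <- get(sa); fb <- get(sb)
      ft <- mapply(function(x, y, ga, gb) {
        r <- fisher_exact(x, ga - x, y, gb - y)
        c(r$p_value, r$odds_ratio)
      }, fa, fb, gene_a, gene_b)
      .(site_id = site_id, gene_id = gene_id,
        site_a = fa, other_a = gene_a - fa,
        site_b = fb, other_b = gene_b - fb,
        usage_a = fa / gene_a, usage_b = fb / gene_b,
        effect = fb / gene_b - fa / gene_a,
        odds_ratio = ft[2, ], p_value = ft[1, ])
    }]
    rows[, comparison := cmp]
    rows[, padj := p.adjust(p_value, "BH")]
    rows[, significant := p_value < alpha]
    res[[cmp]] <- rows
  }
  out <- rbindlist(res, use.names = TRUE)
  if (nrow(out))
    setcolorder(out, c("site_id", "gene_id", "comparison"))
  out[]
}

#' Permutation test for a PSI difference between two groups
#'
#' A transparent substitute for distribution-based differential-splicing
#' tests: the statistic is the absolute difference in group mean PSI;
#' labels are permuted (exhaustively when the number of distinct
#' assignments is at most `n_perm`, otherwise `n_perm` random draws with
#' an add-one correction).  Deterministic for a fixed seed.
#'
#' @param psi_a,psi_b Numeric PSI values per group (NAs dropped).
#' @param n_perm Permutation budget (default 1000).
#' @param seed Integer seed.
#' @return List with `delta_psi` (mean B - mean A), `p_value`, and
#'   `exhaustive` (logical).
#' @export
psi_permutation_test <- function(psi_a, psi_b, n_perm = 1000L, seed = 1L) {
  a <- psi_a[!is.na(psi_a)]; b <- psi_b[!is.na(psi_b)]
  if (!length(a) || !length(b)) {
    message("a group has no defined PSI; untestable")
    return(list(delta_psi = NA_real_, p_value = NA_real_,
                exhaustive = NA))
  }
  pool <- c(a, b); na <- length(a); n <- length(pool)
  obs <- abs(mean(b) - mean(a))
  n_arr <- choose(n, na)
  if (n_arr <= n_perm) {
    idx <- combn(n, na)
    deltas <- apply(idx, 2, function(ii)
      abs(mean(pool[-ii]) - mean(pool[ii])))
    p <- mean(deltas >= obs - 1e-12)
    exhaustive <- TRUE
  } else {
    set.seed(seed)
    deltas <- replicate(n_perm, {
      ii <- sample.int(n, na)
      abs(mean(pool[-ii]) - mean(pool[ii]))
    })
    p <- (1 + sum(deltas >= obs - 1e-12)) / (n_perm + 1)
    exhaustive <- FALSE
  }
  list(delta_psi = mean(b) - mean(a), p_value = p, exhaustive = exhaustive)
}
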