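# Orchestration: a validated run configuration, subcommands mirroring
# the pipeline stages, and a manifest (full parameter echo) written next
# to every output so a run can be reproduced exactly.

#' Build and validate a run configuration
#'
#' @param genome,annotation,alignments,sample_sheet Input paths
#'   (`alignments` is a directory of `<sample_id>.bed` BED12 files).
#' @param out_dir Output directory (created if needed).
#' @param min_usage,min_separation,assignment_halfwidth,alpha,flank,
#'   min_exon_length,downstream_slack Stage parameters (defaults 0.05,
#'   30, 12, 0.05, 50, 200, 1000).
#' @param seed Integer seed used wherever randomness enters.
#' @param sim Named list of overrides passed to [sim_config] by the
#'   `simulate` subcommand.
#' @return List of class `run_config`.
#' @export
run_config <- function(genome = NULL, annotation = NULL,
                       alignments = NULL, sample_sheet = NULL,
                       out_dir = "isoapa_out",
                       min_usage = 0.05, min_separation = 30L,
                       assignment_halfwidth = 12L, alpha = 0.05,
                       flank = 50L, min_exon_length = 200L,
                       downstream_slack = 1000L, seed = 1L,
                       sim = list()) {
  cfg <- as.list(environment())
  num_pos <- c("min_separation", "assignment_halfwidth", "flank",
               "min_exon_length", "downstream_slack")
  for (k in num_pos)
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L || cfg[[k]] <= 0)
      stop("configuration error: '", k, "' must be a positive number")
  for (k in c("min_usage", "alpha"))
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0 || cfg[[k]] >= 1)
      stop("configuration error: '", k, "' must be in [0, 1)")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L)
    stop("configuration error: 'seed' must be a single integer")
  class(cfg) <- "run_config"
  cfg
}

check_inputs <- function(config, what) {
  for (k in what) {
    p <- config[[k]]
    if (is.null(p)) stop("configuration error: '", k, "' not set")
    if (!file.exists(p)) stop("missing input ", k, ": ", p)
  }
}

write_manifest <- function(config, name, outputs) {
  cfg <- unclass(config)
  cfg$subcommand <- name
  cfg$outputs <- outputs
  cfg$package_version <- as.character(utils::packageVersion("isoAPA"))
  path <- file.path(config$out_dir, paste0("manifest_", name, ".json"))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

load_alignments <- function(config, sheet) {
  rl <- lapply(sheet$sample_id, function(s) {
    p <- file.path(config$alignments, paste0(s, ".bed"))
    if (!file.exists(p)) stop("missing alignment file: ", p)
    read_bed12(p, sample_id = s)
  })
  rbindlist(rl)
}

# shared: reads -> filtered pas profiles with per-sample counts
pas_from_inputs <- function(config, ann, reads, sheet) {
  cleav <- read_end_sites(reads, ann,
                          downstream_slack = config$downstream_slack)
  cc <- collect_cleavage_counts(cleav)
  prof <- build_pas_profiles(cc$counts, min_usage = config$min_usage,
                             assignment_halfwidth =
                               as.integer(config$assignment_halfwidth),
                             min_separation =
                               as.integer(config$min_separation))
  libs <- setNames(sheet$library_size, sheet$sample_id)
  normalize_abundance(prof, libs)
}

#' Run one pipeline subcommand
#'
#' Subcommands: `simulate` (synthetic genome/annotation/reads with
#' ground truth), `collapse` (isoform collapse by intron chain),
#' `call-pas` (poly(A)-site catalog), `diff-apa` (stage-pair Fisher
#' tests), `classify-as` (AS events from the annotation), `psi`
#' (per-sample PSI from collapse support), `motif-profile` (composition
#' and poly(A)-signal windows), `filter-lncrna` (structural filter),
#' `score` (recovery against simulated ground truth).  Each writes its
#' outputs plus a `manifest_<name>.json` parameter echo into
#' `config$out_dir`.
#'
#' @param name Subcommand name.
#' @param config A [run_config].
#' @return Invisibly, a character vector of written files.
#' @export
run_subcommand <- function(name, config) {
  stopifnot(inherits(config, "run_config"))
  name <- match.arg(name, c("simulate", "collapse", "call-pas", "diff-apa",
                            "classify-as", "psi", "motif-profile",
                            "filter-lncrna", "score"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- config$out_dir
  outs <- character()

  if (name == "simulate") {
    scfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
    sim <- simulate_transcriptome(scfg, seed = config$seed)
    exp <- simulate_experiment(sim, seed = config$seed)
    gpath <- file.path(od, "genome.fa")
    Biostrings::writeXStringSet(sim$genome, gpath)
    apath <- file.path(od, "annotation.gtf")
    write_annotation(sim$annotation, apath)
    adir <- file.path(od, "alignments")
    dir.create(adir, showWarnings = FALSE)
    bednames <- character()
    for (s in unique(exp$sample_sheet$sample_id)) {
      bp <- file.path(adir, paste0(s, ".bed"))
      write_bed12(exp$reads[sample_id == s], bp)
      bednames <- c(bednames, bp)
    }
    spath <- file.path(od, "sample_sheet.tsv")
    fwrite(exp$sample_sheet, spath, sep = "\t", quote = FALSE)
    lpath <- file.path(od, "ledger.tsv")
    fwrite(exp$ledger, lpath, sep = "\t", quote = FALSE)
    tpath <- file.path(od, "ground_truth.json")
    jsonlite::write_json(list(pas = sim$pas, as_events = sim$as_events,
                              gene_info = sim$gene_info),
                         tpath, digits = NA, na = "null")
    outs <- c(gpath, apath, bednames, spath, lpath, tpath)
  } else if (name == "collapse") {
    check_inputs(config, c("annotation", "alignments", "sample_sheet"))
    ann <- parse_annotation(config$annotation)
    sheet <- fread(config$sample_sheet)
    reads <- load_alignments(config, sheet)
    cleav <- read_end_sites(reads, ann,
                            downstream_slack = config$downstream_slack)
    gmap <- setNames(cleav$gene_id, cleav$read_id)
    col <- collapse_by_intron_chain(reads, gene_ids = gmap)
    cpath <- file.path(od, "collapsed.gtf")
    write_annotation(col$isoforms, cpath)
    smap <- merge(col$support,
                  unique(reads[, .(read_id, sample_id)]), by = "read_id")
    sup <- dcast(smap[, .N, by = .(transcript_id, sample_id)],
                 transcript_id ~ sample_id, value.var = "N", fill = 0)
    spath <- file.path(od, "collapse_support.tsv")
    fwrite(sup, spath, sep = "\t", quote = FALSE)
    outs <- c(cpath, spath)
  } else if (name == "call-pas") {
    check_inputs(config, c("annotation", "alignments", "sample_sheet"))
    ann <- parse_annotation(config$annotation)
    sheet <- fread(config$sample_sheet)
    reads <- load_alignments(config, sheet)
    prof <- pas_from_inputs(config, ann, reads, sheet)
    prof <- locate_intronic_pas(prof, ann)
    bpath <- file.path(od, "pas_sites.bed")
    write_bed6(prof$sites, bpath)
    tpath <- file.path(od, "pas_sites.tsv")
    write_pas_table(prof, tpath)
    apa <- classify_apa_genes(prof)
    hpath <- file.path(od, "pas_gene_histogram.tsv")
    fwrite(apa$histogram, hpath, sep = "\t", quote = FALSE)
    outs <- c(bpath, tpath, hpath)
  } else if (name == "diff-apa") {
    check_inputs(config, c("annotation", "alignments", "sample_sheet"))
    ann <- parse_annotation(config$annotation)
    sheet <- fread(config$sample_sheet)
    reads <- load_alignments(config, sheet)
    prof <- pas_from_inputs(config, ann, reads, sheet)
    calls <- differential_apa(prof, sheet, alpha = config$alpha)
    for (cmp in unique(calls$comparison)) {
      p <- file.path(od, paste0("diff_apa_", cmp, ".tsv"))
      fwrite(calls[comparison == cmp], p, sep = "\t", quote = FALSE)
      outs <- c(outs, p)
    }
  } else if (name == "classify-as") {
    check_inputs(config, "annotation")
    ann <- parse_annotation(config$annotation)
    ev <- classify_as_events(ann)
    epath <- file.path(od, "as_events.ioe")
    write_events_ioe(ev, epath)
    outs <- epath
  } else if (name == "psi") {
    check_inputs(config, c("annotation", "alignments", "sample_sheet"))
    ann <- parse_annotation(config$annotation)
    sheet <- fread(config$sample_sheet)
    reads <- load_alignments(config, sheet)
    cleav <- read_end_sites(reads, ann,
                            downstream_slack = config$downstream_slack)
    gmap <- setNames(cleav$gene_id, cleav$read_id)
    col <- collapse_by_intron_chain(reads, gene_ids = gmap)
    ev <- classify_as_events(col$isoforms)
    smap <- merge(col$support,
                  unique(reads[, .(read_id, sample_id)]), by = "read_id")
    cnt <- dcast(smap[, .N, by = .(transcript_id, sample_id)],
                 transcript_id ~ sample_id, value.var = "N", fill = 0)
    ab <- as.matrix(cnt, rownames = "transcript_id")
    pt <- psi_table(ev, ab)
    ppath <- file.path(od, "psi.tsv")
    fwrite(pt, ppath, sep = "\t", quote = FALSE)
    outs <- ppath
  } else if (name == "motif-profile") {
    check_inputs(config, c("genome", "annotation", "alignments",
                           "sample_sheet"))
    gen <- read_genome(config$genome)
    ann <- parse_annotation(config$annotation)
    sheet <- fread(config$sample_sheet)
    reads <- load_alignments(config, sheet)
    prof <- pas_from_inputs(config, ann, reads, sheet)
    comp <- nucleotide_composition(prof$sites, gen,
                                   flank = as.integer(config$flank))
    cpath <- file.path(od, "pas_composition.tsv")
    write_pfm(comp, cpath)
    km <- kmer_window_counts(prof$sites, gen)
    kpath <- file.path(od, "pas_kmers.tsv")
    fwrite(km, kpath, sep = "\t", quote = FALSE)
    ints <- extract_introns(ann)
    ssm <- splice_site_matrices(ints, gen)
    dpath <- file.path(od, "splice_donor_pfm.tsv")
    fwrite(data.table(pos = seq_len(ncol(ssm$donor)), t(ssm$donor)),
           dpath, sep = "\t", quote = FALSE)
    apath2 <- file.path(od, "splice_acceptor_pfm.tsv")
    fwrite(data.table(pos = seq_len(ncol(ssm$acceptor)), t(ssm$acceptor)),
           apath2, sep = "\t", quote = FALSE)
    outs <- c(cpath, kpath, dpath, apath2)
  } else if (name == "filter-lncrna") {
    check_inputs(config, "annotation")
    ann <- parse_annotation(config$annotation)
    rep <- structural_filter(ann,
                             min_exon_length =
                               as.integer(config$min_exon_length))
    rpath <- file.path(od, "lncrna_filter_report.tsv")
    fwrite(rbind(data.table(transcript_id = rep$retained,
                            status = "retained", reason = ""),
                 data.table(transcript_id = rep$removed$transcript_id,
                            status = "removed",
                            reason = rep$removed$reason)),
           rpath, sep = "\t", quote = FALSE)
    outs <- rpath
    if (!is.null(rep$filtered)) {
      fpath <- file.path(od, "lncrna_filtered.gtf")
      write_annotation(rep$filtered, fpath)
      outs <- c(outs, fpath)
    }
  } else if (name == "score") {
    check_inputs(config, c("annotation", "alignments", "sample_sheet"))
    tpath <- file.path(od, "ground_truth.json")
    if (!is.null(config$ground_truth)) tpath <- config$ground_truth
    if (!file.exists(tpath)) stop("missing input ground_truth: ", tpath)
    gt <- jsonlite::fromJSON(tpath)
    truth <- list(pas = as.data.table(gt$pas),
                  as_events = as.data.table(gt$as_events),
                  gene_info = as.data.table(gt$gene_info))
    ann <- parse_annotation(config$annotation)
    sheet <- fread(config$sample_sheet)
    reads <- load_alignments(config, sheet)
    prof <- pas_from_inputs(config, ann, reads, sheet)
    prof <- locate_intronic_pas(prof, ann)
    calls <- differential_apa(prof, sheet, alpha = config$alpha)
    ev <- classify_as_events(ann)
    sc <- score_recovery(list(pas = prof, events = ev,
                              apa = classify_apa_genes(prof),
                              differential = calls),
                         truth,
                         tolerance = as.integer(config$assignment_halfwidth))
    spath <- file.path(od, "recovery_summary.tsv")
    fwrite(sc$summary, spath, sep = "\t", quote = FALSE)
    outs <- spath
  }
  write_manifest(config, name, outs)
  message("[", name, "] wrote ", length(outs), " file(s) to ", od)
  invisible(outs)
}

#' Run the full pipeline on simulated data
#'
#' `simulate` followed by every analysis stage, each reading the files
#' the previous stages wrote.
#'
#' @param config A [run_config]; `genome`, `annotation`, `alignments`
#'   and `sample_sheet` are filled in from the simulate outputs.
#' @return Invisibly, the final config.
#' @export
run_pipeline <- function(config) {
  run_subcommand("simulate", config)
  od <- config$out_dir
  config$genome <- file.path(od, "genome.fa")
  config$annotation <- file.path(od, "annotation.gtf")
  config$alignments <- file.path(od, "alignments")
  config$sample_sheet <- file.path(od, "sample_sheet.tsv")
  for (s in c("collapse", "call-pas", "diff-apa", "classify-as", "psi",
              "motif-profile", "filter-lncrna", "score"))
    run_subcommand(s, config)
  invisible(config)
}
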