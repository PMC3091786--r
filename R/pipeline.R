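#' Default pipeline configuration
#'
#' A single flat-ish list controlling every stage. Override entries via
#' `...` or edit the returned list; [read_config()] loads the same
#' structure from JSON. Keys:
#' \describe{
#'   \item{vector}{`ad_suffix`, `b1_tail`, `b2_tail`, `stop_codon`.}
#'   \item{thresholds}{`window`, `phred_threshold`, `min_fraction`,
#'     `junction_min_score`, `nt_min_score`, `aa_min_score`, `gs_len`,
#'     `tail_aa`.}
#'   \item{simulate}{Generator parameters: `n_proteins`, `class_probs`,
#'     `splice_form_rate`, `mean_protein_len`, `n_domain_proteins`,
#'     `total_domains`, `n_edges`, `mean_clones`, `consensus_bias`,
#'     `decoy_rate`, `read_error_params`, `read_len`.}
#' }
#'
#' @param ... Named overrides, e.g. `simulate = list(n_edges = 10)`
#'   (merged recursively).
#' @return Configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    vector = list(
      ad_suffix = GAL4_AD_SUFFIX,
      b1_tail = ATTB1_TAIL,
      b2_tail = ATTB2_TAIL,
      stop_codon = "TAA"
    ),
    thresholds = list(
      window = 10L,
      phred_threshold = 20,
      min_fraction = 0.15,
      junction_min_score = NA,  # NA: 60% of the AD suffix length
      nt_min_score = 60L,
      aa_min_score = 20L,
      gs_len = 21L,
      tail_aa = 10L
    ),
    simulate = list(
      n_proteins = 150L,
      class_probs = c(0.08, 0.18, 0.05, 0.69),
      splice_form_rate = 0.1,
      mean_protein_len = 400,
      n_domain_proteins = 20L,
      total_domains = 30L,
      n_edges = 40L,
      mean_clones = 2,
      consensus_bias = 2.2,
      decoy_rate = 0.1,
      read_error_params = list(frame_shift_rate = 0.05,
                               low_quality_rate = 0.05,
                               chimera_rate = 0.03,
                               reporter_fail_rate = 0.05,
                               single_band_fail_rate = 0.05),
      read_len = 700L
    )
  )
  utils::modifyList(cfg, list(...))
}

#' Load a pipeline configuration from JSON
#' @param path JSON file with (a subset of) the [pipeline_config()] keys.
#' @return Configuration list (defaults filled in).
#' @export
read_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  utils::modifyList(pipeline_config(), user)
}

cfg_junction_min <- function(config) {
  j <- config$thresholds$junction_min_score
  if (is.null(j) || is.na(j)) ceiling(0.6 * nchar(config$vector$ad_suffix))
  else j
}

stage_paths <- function(out_dir) {
  file.path(out_dir, c(
    proteome_aa = "proteome.fasta", proteome_cds = "proteome_cds.fasta",
    splice = "splice_forms.tsv", annotations = "annotations.tsv",
    catalog = "catalog.tsv", regions = "clone_regions.tsv",
    primers = "primers.tsv",
    cdna_fastq = "screen_cDNA.fastq", orf_fastq = "screen_ORFeome.fastq",
    cdna_colonies = "colonies_cDNA.tsv", orf_colonies = "colonies_ORFeome.tsv",
    cdna_truth = "truth_cDNA.json", orf_truth = "truth_ORFeome.json",
    cdna_read_truth = "read_truth_cDNA.tsv",
    orf_read_truth = "read_truth_ORFeome.tsv",
    cdna_retest = "retest_cDNA.tsv", orf_retest = "retest_ORFeome.tsv",
    qc = "qc_%s.tsv", calls = "prey_calls_%s.tsv",
    interactions = "interactions_%s.tsv",
    consensus = "consensus_calls.tsv", class_table = "proteome_classes.tsv",
    graphml = "network_%s.graphml", sif = "network_%s.sif",
    report = "report.txt", manifest = "run_manifest.json"
  )) |> stats::setNames(c(
    "proteome_aa", "proteome_cds", "splice", "annotations", "catalog",
    "regions", "primers", "cdna_fastq", "orf_fastq", "cdna_colonies",
    "orf_colonies", "cdna_truth", "orf_truth", "cdna_read_truth",
    "orf_read_truth", "cdna_retest", "orf_retest", "qc", "calls",
    "interactions", "consensus", "class_table", "graphml", "sif",
    "report", "manifest"))
}

log_msg <- function(...) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...))
}

require_inputs <- function(stage, paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0)
    stop(sprintf("stage '%s': missing input(s): %s", stage,
                 paste(missing, collapse = ", ")), call. = FALSE)
}

#' Run a pipeline stage
#'
#' Subcommands: `simulate` (synthetic proteome, domain catalog inputs and
#' two simulated screens), `catalog` (merge annotations, assign ids,
#' extend boundaries, design primers), `qc` (trace quality filter), `call`
#' (junction location, identity, frame call, interaction aggregation),
#' `classify` (consensus classes), `network` (GraphML/SIF export),
#' `report` (degree/coverage statistics, class-proportion tables, overlap
#' and pooled counts), `all` (the full chain). Every stage writes plain
#' TSV/FASTA/FASTQ/GraphML artifacts under `out_dir`; re-running a stage on
#' unchanged inputs and config yields byte-identical primary artifacts.
#'
#' @param name Subcommand name.
#' @param config Configuration list, see [pipeline_config()].
#' @param out_dir Output (and inter-stage input) directory.
#' @param seed Integer seed used by `simulate`.
#' @return Invisibly, a named list of artifact paths (for `report`, also
#'   the computed statistics).
#' @export
run_subcommand <- function(name = c("all", "simulate", "catalog", "qc",
                                    "call", "classify", "network", "report"),
                           config = pipeline_config(), out_dir = "pdzome_out",
                           seed = 1L) {
  name <- match.arg(name)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- stage_paths(out_dir)
  if (name == "all") {
    for (stage in c("simulate", "catalog", "qc", "call", "classify",
                    "network", "report"))
      res <- run_subcommand(stage, config, out_dir, seed)
    return(invisible(res))
  }
  result <- switch(name,
    simulate = stage_simulate(config, p, seed),
    catalog = stage_catalog(config, p),
    qc = stage_qc(config, p),
    call = stage_call(config, p),
    classify = stage_classify(config, p),
    network = stage_network(config, p),
    report = stage_report(config, p)
  )
  manifest <- list(stage = name, seed = seed,
                   config_md5 = digest_config(config),
                   out_dir = out_dir)
  jsonlite::write_json(manifest, p[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(result)
}

digest_config <- function(config) {
  # stable content hash of the effective configuration
  as.character(tools::md5sum(
    {f <- tempfile(); writeLines(jsonlite::toJSON(config, auto_unbox = TRUE,
                                                  digits = NA), f); f}))
}

stage_simulate <- function(config, p, seed) {
  s <- config$simulate
  log_msg("simulate: proteome of %d proteins", s$n_proteins)
  prot <- generate_proteome(
    n_proteins = s$n_proteins, class_probs = s$class_probs,
    splice_form_rate = s$splice_form_rate,
    mean_protein_len = s$mean_protein_len, seed = seed)
  write_proteome_fasta(prot, p[["proteome_aa"]], p[["proteome_cds"]])
  write_tsv(prot$proteins[c("protein_id", "gene_id", "is_splice_form",
                            "cterm_confirmed")], p[["splice"]])
  planted <- plant_bait_domains(
    prot, n_domain_proteins = s$n_domain_proteins,
    total_domains = s$total_domains, seed = seed + 1L)
  write_annotation_tsv(planted$annotations, p[["annotations"]])
  cat_obj <- build_domain_catalog(planted$annotations, prot,
                                  tail_aa = config$thresholds$tail_aa)
  for (lib in c("cDNA", "ORFeome")) {
    pre <- if (lib == "cDNA") "cdna" else "orf"
    truth <- make_screen_truth(
      prot, cat_obj$catalog, library_kind = lib, n_edges = s$n_edges,
      mean_clones = s$mean_clones, consensus_bias = s$consensus_bias,
      decoy_rate = s$decoy_rate, read_error_params = s$read_error_params,
      seed = seed + if (lib == "cDNA") 2L else 3L)
    scr <- generate_screen(prot, truth, ad_suffix = config$vector$ad_suffix,
                           read_len = s$read_len)
    scr$reads$read_id <- paste0(pre, "_", scr$reads$read_id)
    scr$colonies$read_id <- scr$reads$read_id
    scr$read_truth$read_id <- scr$reads$read_id
    write_reads_fastq(scr$reads, p[[paste0(pre, "_fastq")]])
    write_tsv(scr$colonies, p[[paste0(pre, "_colonies")]])
    write_tsv(scr$read_truth, p[[paste0(pre, "_read_truth")]])
    write_tsv(scr$retest, p[[paste0(pre, "_retest")]])
    write_screen_truth_json(truth, p[[paste0(pre, "_truth")]])
    log_msg("simulate: %s screen, %d reads", lib, nrow(scr$reads))
  }
  invisible(p)
}

stage_catalog <- function(config, p) {
  require_inputs("catalog", p[c("proteome_aa", "proteome_cds", "splice",
                                "annotations")])
  prot <- read_proteome_fasta(p[["proteome_aa"]], p[["proteome_cds"]],
                              p[["splice"]])
  ann <- read_annotation_tsv(p[["annotations"]])
  obj <- build_domain_catalog(
    ann, prot, tail_aa = config$thresholds$tail_aa,
    b1_tail = config$vector$b1_tail, b2_tail = config$vector$b2_tail,
    stop_codon = config$vector$stop_codon, gs_len = config$thresholds$gs_len)
  write_tsv(obj$catalog, p[["catalog"]])
  write_tsv(obj$regions[c("domain_id", "protein_id", "ext_start", "ext_end",
                          "nt_start", "nt_end")], p[["regions"]])
  write_tsv(obj$primers, p[["primers"]])
  log_msg("catalog: %d domains in %d proteins", nrow(obj$catalog),
          length(unique(obj$catalog$protein_id)))
  invisible(obj)
}

stage_qc <- function(config, p) {
  th <- config$thresholds
  out <- list()
  for (pre in c("cdna", "orf")) {
    fq <- p[[paste0(pre, "_fastq")]]
    require_inputs("qc", fq)
    reads <- read_reads_fastq(fq)
    qc <- qc_filter(reads, window = th$window, threshold = th$phred_threshold,
                    min_fraction = th$min_fraction)
    write_tsv(qc, sprintf(p[["qc"]], pre))
    log_msg("qc (%s): kept %d / %d reads", pre, sum(qc$kept), nrow(qc))
    out[[pre]] <- qc
  }
  invisible(out)
}

stage_call <- function(config, p) {
  th <- config$thresholds
  require_inputs("call", p[c("proteome_aa", "proteome_cds", "splice")])
  prot <- read_proteome_fasta(p[["proteome_aa"]], p[["proteome_cds"]],
                              p[["splice"]])
  out <- list()
  for (pre in c("cdna", "orf")) {
    require_inputs("call", c(p[[paste0(pre, "_fastq")]],
                             p[[paste0(pre, "_colonies")]]))
    reads <- read_reads_fastq(p[[paste0(pre, "_fastq")]])
    colonies <- read_tsv(p[[paste0(pre, "_colonies")]])
    calls <- call_preys(reads, colonies, prot,
                        ad_suffix = config$vector$ad_suffix,
                        window = th$window, threshold = th$phred_threshold,
                        min_fraction = th$min_fraction,
                        junction_min_score = cfg_junction_min(config),
                        nt_min_score = th$nt_min_score,
                        aa_min_score = th$aa_min_score)
    retest_path <- p[[paste0(pre, "_retest")]]
    retest <- if (file.exists(retest_path)) read_tsv(retest_path) else NULL
    inter <- aggregate_interactions(calls, retest)
    write_tsv(calls, sprintf(p[["calls"]], pre))
    write_tsv(inter, sprintf(p[["interactions"]], pre))
    log_msg("call (%s): %d InFrame reads -> %d interactions", pre,
            sum(calls$frame_status == "InFrame"), nrow(inter))
    out[[pre]] <- list(calls = calls, interactions = inter)
  }
  invisible(out)
}

stage_classify <- function(config, p) {
  require_inputs("classify", p[c("proteome_aa", "proteome_cds", "splice")])
  prot <- read_proteome_fasta(p[["proteome_aa"]], p[["proteome_cds"]],
                              p[["splice"]])
  calls <- classify_proteome(prot)
  write_tsv(calls, p[["consensus"]])
  tab <- proteome_class_table(prot)
  write_tsv(data.frame(class = names(tab$counts), count = tab$counts,
                       proportion = unname(tab$proportions)),
            p[["class_table"]])
  log_msg("classify: %d proteins, %d with consensus terminus",
          tab$n, tab$total_consensus[["count"]])
  invisible(calls)
}

load_networks <- function(p) {
  catalog <- read_tsv(p[["catalog"]])
  nets <- list()
  for (pre in c("cdna", "orf")) {
    ipath <- sprintf(p[["interactions"]], pre)
    require_inputs("network", c(p[["catalog"]], ipath))
    inter <- read_tsv(ipath)
    nets[[pre]] <- assemble_network(
      inter, catalog, library = if (pre == "cdna") "cDNA" else "ORFeome")
  }
  nets
}

stage_network <- function(config, p) {
  require_inputs("network", p[["consensus"]])
  nets <- load_networks(p)
  cons <- read_tsv(p[["consensus"]])
  for (pre in names(nets)) {
    export_graph(nets[[pre]], cons,
                 graphml_path = sprintf(p[["graphml"]], pre),
                 sif_path = sprintf(p[["sif"]], pre))
  }
  log_msg("network: exported %d graphs", length(nets))
  invisible(nets)
}

stage_report <- function(config, p) {
  require_inputs("report", p[["consensus"]])
  nets <- load_networks(p)
  cons <- read_tsv(p[["consensus"]])
  stats_cdna <- degree_stats(nets$cdna, mean_digits = 0)
  stats_orf <- degree_stats(nets$orf, mean_digits = 1)
  ov <- network_overlap(nets$cdna, nets$orf)
  pooled <- pool_networks(nets)
  bg <- if (file.exists(p[["class_table"]])) {
    ct <- read_tsv(p[["class_table"]])
    list(counts = stats::setNames(ct$count, ct$class),
         proportions = stats::setNames(ct$proportion, ct$class),
         total_consensus = c(
           count = sum(ct$count[ct$class != "none"]),
           proportion = sum(ct$proportion[ct$class != "none"])),
         n = sum(ct$count))
  } else NULL
  tables <- lapply(nets, class_proportion_table, consensus_calls = cons,
                   proteome_table = bg)
  lines <- c(
    "== Screen statistics ==",
    sprintf("cDNA: %d interactions, %d/%d productive domains (coverage %g%%), mean %g interactions/domain (median %g)",
            stats_cdna$n_edges, stats_cdna$n_domains_productive,
            stats_cdna$n_catalog, stats_cdna$coverage_pct,
            stats_cdna$mean_degree_display, stats_cdna$median_degree),
    sprintf("ORFeome: %d interactions, %d/%d productive domains (coverage %g%%), mean %g interactions/domain (median %g)",
            stats_orf$n_edges, stats_orf$n_domains_productive,
            stats_orf$n_catalog, stats_orf$coverage_pct,
            stats_orf$mean_degree_display, stats_orf$median_degree),
    sprintf("Overlap: %d shared pairs (%g%% of the smaller screen)",
            ov$shared, ov$percent),
    sprintf("Pooled: %d interactions, %d proteins, %d domains",
            pooled$n_interactions, pooled$n_preys, pooled$n_domains),
    "", "== Consensus-class proportions (cDNA) ==",
    utils::capture.output(print(tables$cdna)),
    "", "== Consensus-class proportions (ORFeome) ==",
    utils::capture.output(print(tables$orf)))
  writeLines(lines, p[["report"]])
  log_msg("report: written to %s", p[["report"]])
  invisible(list(cdna = stats_cdna, orf = stats_orf, overlap = ov,
                 pooled = pooled, class_tables = tables,
                 report_path = p[["report"]]))
}
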