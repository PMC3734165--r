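# End-to-end orchestration: enrich -> AGO1 filter -> profile -> scan ->
# degradome validate -> expression contrast -> network.  Stages exchange
# data through files under out_dir; the run writes a machine-readable
# summary (counts at every stage plus the thresholds used) and the resolved
# configuration beside the outputs.

#' Assemble a pipeline configuration
#'
#' @param data_dir directory holding the inputs in the layout written by
#'   [generate_synthetic_data()]: `libraries.tsv` manifest (library_id,
#'   group, path, total_reads), `transcripts.fasta`, `expression.tsv`,
#'   `zones.tsv`.
#' @param out_dir directory for stage outputs (created if needed).
#' @param min_rpm,fold enrichment thresholds (both filters); defaults 3, 3.
#' @param max_penalty target-scan penalty cutoff; default 3.0.
#' @param window degradome cleavage window (sRNA positions); default 8:12.
#' @param min_signatures minimum distinct degradome signatures; default 2.
#' @param max_category worst accepted t-plot category; default 1.
#' @param min_fold contrary-expression fold threshold; default 1.0.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(data_dir, out_dir, min_rpm = 3, fold = 3,
                            max_penalty = 3.0, window = 8:12,
                            min_signatures = 2L, max_category = 1L,
                            min_fold = 1.0) {
  stopifnot(min_rpm > 0, fold > 0, max_penalty >= 0,
            all(window >= 1), all(window <= 30), min_signatures >= 1,
            max_category >= 0, min_fold > 0)
  structure(list(data_dir = data_dir, out_dir = out_dir,
                 min_rpm = min_rpm, fold = fold,
                 max_penalty = max_penalty, window = as.integer(window),
                 min_signatures = as.integer(min_signatures),
                 max_category = as.integer(max_category),
                 min_fold = min_fold),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' The file holds the same fields as [pipeline_config()] arguments; missing
#' fields take the defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
  message(sprintf("[%s] done in %.2fs", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full pipeline
#'
#' Executes every stage over the inputs named by the configuration and
#' writes per-stage TSVs, network exports (SIF, GraphML, edge TSV), a JSON
#' run summary and the resolved configuration to `out_dir`.
#'
#' @param config a [pipeline_config()], or the path to a YAML file for
#'   [read_pipeline_config()].
#' @return the run summary, invisibly: stage counts, thresholds and output
#'   paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dd <- config$data_dir
  od <- config$out_dir
  dir.create(od, recursive = TRUE, showWarnings = FALSE)

  manifest <- read.delim(file.path(dd, "libraries.tsv"),
                         stringsAsFactors = FALSE)
  libs <- stage("load", {
    lapply(seq_len(nrow(manifest)), function(i) {
      read_srna_library(file.path(dd, manifest$path[i]),
                        manifest$library_id[i], manifest$group[i],
                        total_reads = manifest$total_reads[i])
    })
  })
  groups <- setNames(manifest$group, manifest$library_id)
  ids_of <- function(g) manifest$library_id[manifest$group %in% g]
  tissue <- libs[groups %in% c("root_tip", "whole_root")]
  agoset <- libs[groups %in% c("ago1", "ago_control")]
  degset <- libs[groups %in% "degradome"]
  if (length(ids_of("root_tip")) == 0 || length(ids_of("whole_root")) == 0)
    stop("manifest must provide root_tip and whole_root libraries")

  enr <- stage("enrich", {
    rpm <- normalize_rpm(tissue)
    rt <- filter_compartment_enriched(rpm, ids_of("root_tip"),
                                      ids_of("whole_root"),
                                      config$min_rpm, config$fold)
    wr <- filter_compartment_enriched(rpm, ids_of("whole_root"),
                                      ids_of("root_tip"),
                                      config$min_rpm, config$fold)
    write_tsv(rt, file.path(od, "enriched_root_tip.tsv"))
    write_tsv(wr, file.path(od, "enriched_whole_root.tsv"))
    list(rt = rt$sequence[rt$passed], wr = wr$sequence[wr$passed],
         n_input = nrow(rt))
  })

  ago <- stage("ago1_filter", {
    if (length(agoset) == 0) {
      list(rt = enr$rt, wr = enr$wr, filtered = FALSE)
    } else {
      rpm <- normalize_rpm(agoset)
      a_rt <- filter_ago1_enriched(rpm, ids_of("ago1"),
                                   ids_of("ago_control"),
                                   config$min_rpm, config$fold,
                                   candidates = enr$rt)
      a_wr <- filter_ago1_enriched(rpm, ids_of("ago1"),
                                   ids_of("ago_control"),
                                   config$min_rpm, config$fold,
                                   candidates = enr$wr)
      a_rt$compartment <- rep("root_tip", nrow(a_rt))
      a_wr$compartment <- rep("whole_root", nrow(a_wr))
      out <- rbind(a_rt, a_wr)
      write_tsv(out, file.path(od, "ago1_enriched.tsv"))
      list(rt = a_rt$sequence[a_rt$passed],
           wr = a_wr$sequence[a_wr$passed], filtered = TRUE)
    }
  })

  srnas <- stage("name_srnas", {
    rt <- sort(ago$rt); wr <- sort(ago$wr)
    data.frame(
      srna_id = c(sprintf("RT_High_sRNA%d", seq_along(rt)),
                  sprintf("WR_High_sRNA%d", seq_along(wr))),
      sequence = c(rt, wr),
      compartment = c(rep("root_tip", length(rt)),
                      rep("whole_root", length(wr))),
      stringsAsFactors = FALSE)
  })

  stage("profile", {
    sets <- list(RT_enriched = enr$rt, RT_AGO1 = ago$rt,
                 WR_enriched = enr$wr, WR_AGO1 = ago$wr)
    profs <- lapply(names(sets)[lengths(sets) > 0], function(nm)
      profile_set(sets[[nm]], nm))
    if (length(profs)) {
      write_tsv(profile_table(profs), file.path(od, "profiles.tsv"))
    }
    NULL
  })

  transcripts <- stage("transcriptome", {
    read_transcriptome(file.path(dd, "transcripts.fasta"))
  })

  sites <- stage("scan", {
    s <- scan_targets(setNames(srnas$sequence, srnas$srna_id),
                      transcripts, max_penalty = config$max_penalty)
    write_tsv(s, file.path(od, "sites.tsv"))
    s
  })

  interactions <- stage("validate", {
    signals <- do.call(rbind, lapply(degset, map_degradome, transcripts))
    if (is.null(signals)) {
      signals <- map_degradome(srna_library(setNames(numeric(0),
                                                     character(0)),
                                            "none", "degradome"),
                               transcripts)
    }
    ints <- validate_sites(sites, signals, config$window,
                           config$min_signatures, config$max_category)
    comp <- setNames(srnas$compartment, srnas$srna_id)
    ints$srna_compartment <- if (nrow(ints)) comp[ints$srna_id]
      else character(0)
    write_tsv(ints, file.path(od, "interactions.tsv"))
    ints
  })

  contrasts <- stage("contrast", {
    zf <- read.delim(file.path(dd, "zones.tsv"),
                     stringsAsFactors = FALSE)
    em <- read_expression_matrix(file.path(dd, "expression.tsv"),
                                 setNames(zf$zone, zf$sample_id))
    comp <- setNames(srnas$compartment, srnas$srna_id)
    ct <- contrast_interactions(em, interactions, comp,
                                min_fold = config$min_fold)
    write_tsv(ct, file.path(od, "contrasts.tsv"))
    ct
  })

  net <- stage("network", {
    n <- build_network(interactions, contrasts)
    write_network(n, file.path(od, "network.sif"), "sif")
    write_network(n, file.path(od, "network.graphml"), "graphml")
    write_network(n, file.path(od, "network_edges.tsv"), "tsv")
    n
  })

  summary <- list(
    thresholds = config[c("min_rpm", "fold", "max_penalty", "window",
                          "min_signatures", "max_category", "min_fold")],
    counts = list(
      sequences_profiled = enr$n_input,
      root_tip_enriched = length(enr$rt),
      whole_root_enriched = length(enr$wr),
      ago1_enriched_root_tip = length(ago$rt),
      ago1_enriched_whole_root = length(ago$wr),
      predicted_sites = nrow(sites),
      validated_interactions = nrow(interactions),
      validated_pairs = nrow(net$edges),
      contrary_targets = sum(contrasts$contrary, na.rm = TRUE),
      network_srna_nodes = length(net$srna_nodes),
      network_transcript_nodes = length(net$transcript_nodes),
      network_gene_nodes = length(net$gene_nodes),
      network_edges = nrow(net$edges)))
  jsonlite::write_json(summary, file.path(od, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(unclass(config), file.path(od, "resolved_config.yaml"))
  invisible(summary)
}
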