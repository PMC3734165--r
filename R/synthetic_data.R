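# Synthetic-data generator with planted ground truth.  It emits every input
# the pipeline consumes -- a transcriptome FASTA, per-library sRNA count
# TSVs, degradome tag libraries, a zone-resolved expression matrix -- plus
# truth tables, so enrichment, scanning, degradome validation and the
# contrary-expression check can all be scored against known answers.
#
# What it emulates: compartment-enriched sRNA species on a background of
# equally-expressed species; the AGO1 loading footprint (5'-U bias, 21-nt
# length mode vs the 24-nt bulk mode); binding sites embedded in transcripts
# as (near-)reverse complements; degradome tags whose 5' ends sit at the
# canonical cleavage position (opposite sRNA position 10) with >= 2 distinct
# signatures, over low uniform background tags; and oriented contrary
# expression for true targets.  Plantings are verified against the real
# filter implementations at emit time, so recovery tests are not hostage to
# construction mistakes.

#' Configuration for the synthetic-data generator
#'
#' Defaults are the package's reference study conditions; see the methods
#' vignette for the rationale behind each value.
#'
#' @param seed integer RNG seed; identical seed and config give
#'   byte-identical output files.
#' @param n_transcripts number of transcripts (one gene each).
#' @param transcript_len_range inclusive length range in nt.
#' @param n_background_srnas background species, present at equal counts in
#'   every tissue library (so they fail the fold rule).
#' @param n_planted_rt,n_planted_wr species planted to pass the root-tip /
#'   whole-root compartment filter.
#' @param ago1_loaded_fraction fraction of each planted set that also
#'   passes the AGO1 filter.
#' @param five_prime_u_prob_loaded probability that a loaded sRNA starts
#'   with U.
#' @param loaded_len_mode,unloaded_len_mode modal lengths (nt) of loaded
#'   and unloaded/background species.
#' @param n_true_interactions planted sRNA-target interactions (must not
#'   exceed `n_transcripts`).
#' @param canonical_signal_rpm_range RPM range of planted cleavage signals
#'   (per degradome library).
#' @param noise_tag_rate expected background degradome tags per transcript
#'   kilobase per library.
#' @param expression_noise_sd sd of the multiplicative log-normal noise on
#'   expression cells.
#' @param planted_contrary_fold minimum oriented expression fold planted
#'   for true-target genes (draws are in `[fold, fold + 1]`).
#' @param cleavage_srna_position sRNA position (from the 5' end) opposite
#'   which planted tag 5' ends are placed; 10 is the canonical slicing
#'   position, other values probe the acceptance window.
#' @param library_design named integer vector: libraries per group.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_transcripts = 200L,
                             transcript_len_range = c(600L, 2000L),
                             n_background_srnas = 2000L,
                             n_planted_rt = 40L,
                             n_planted_wr = 40L,
                             ago1_loaded_fraction = 0.5,
                             five_prime_u_prob_loaded = 0.55,
                             loaded_len_mode = 21L,
                             unloaded_len_mode = 24L,
                             n_true_interactions = 30L,
                             canonical_signal_rpm_range = c(20, 200),
                             noise_tag_rate = 0.5,
                             expression_noise_sd = 0.15,
                             planted_contrary_fold = 2,
                             cleavage_srna_position = 10L,
                             library_design = c(root_tip = 3L,
                                                whole_root = 2L,
                                                ago1 = 3L,
                                                ago_control = 1L,
                                                degradome = 2L)) {
  cfg <- list(seed = as.integer(seed), n_transcripts = n_transcripts,
              transcript_len_range = transcript_len_range,
              n_background_srnas = n_background_srnas,
              n_planted_rt = n_planted_rt, n_planted_wr = n_planted_wr,
              ago1_loaded_fraction = ago1_loaded_fraction,
              five_prime_u_prob_loaded = five_prime_u_prob_loaded,
              loaded_len_mode = loaded_len_mode,
              unloaded_len_mode = unloaded_len_mode,
              n_true_interactions = n_true_interactions,
              canonical_signal_rpm_range = canonical_signal_rpm_range,
              noise_tag_rate = noise_tag_rate,
              expression_noise_sd = expression_noise_sd,
              planted_contrary_fold = planted_contrary_fold,
              cleavage_srna_position = as.integer(cleavage_srna_position),
              library_design = library_design)
  with(cfg, {
    stopifnot(n_transcripts > 0, n_background_srnas > 0,
              n_planted_rt > 0, n_planted_wr > 0,
              ago1_loaded_fraction >= 0, ago1_loaded_fraction <= 1,
              five_prime_u_prob_loaded >= 0, five_prime_u_prob_loaded <= 1,
              n_true_interactions >= 0, planted_contrary_fold >= 1,
              cleavage_srna_position >= 1,
              all(library_design >= c(1L, 1L, 1L, 1L, 1L)))
  })
  if (cfg$n_true_interactions > cfg$n_transcripts) {
    stop("infeasible config: more true interactions than transcripts")
  }
  n_loaded <- round(cfg$ago1_loaded_fraction * cfg$n_planted_rt) +
    round(cfg$ago1_loaded_fraction * cfg$n_planted_wr)
  if (cfg$n_true_interactions > 0 && n_loaded == 0) {
    stop("infeasible config: interactions requested but no AGO1-loaded sRNAs")
  }
  structure(cfg, class = "synthetic_config")
}

# n unique random RNA sequences with given lengths; `first` optionally fixes
# the 5' base per sequence.
random_rna <- function(n, lengths, first = NULL, avoid = character(0)) {
  draw <- function(len, fb) {
    body <- sample(RNA_BASES, len, replace = TRUE)
    if (!is.na(fb)) body[1] <- fb
    paste(body, collapse = "")
  }
  if (is.null(first)) first <- rep(NA_character_, n)
  out <- character(n)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (s in avoid) assign(s, TRUE, envir = seen)
  for (i in seq_len(n)) {
    repeat {
      s <- draw(lengths[i], first[i])
      if (!exists(s, envir = seen, inherits = FALSE)) {
        assign(s, TRUE, envir = seen); out[i] <- s; break
      }
    }
  }
  out
}

srna_lengths <- function(n, mode) {
  sample(c(mode - 1L, mode, mode + 1L), n, replace = TRUE,
         prob = c(0.2, 0.6, 0.2))
}

srna_first_base <- function(n, u_prob) {
  ifelse(runif(n) < u_prob, "U",
         sample(c("A", "C", "G"), n, replace = TRUE))
}

#' Generate a synthetic data set with planted ground truth
#'
#' Writes all pipeline inputs to `out_dir` (transcriptome FASTA, one count
#' TSV per library, a `libraries.tsv` manifest with group labels and library
#' totals, expression matrix + zone map, and truth tables) and returns the
#' truth in memory.  Plantings are checked against the package's own
#' enrichment filters before anything is written.
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `truth` (planted sRNA table, true
#'   interactions, contrary genes), `dir`, `manifest` and `config`.
#' @export
generate_synthetic_data <- function(config = synthetic_config(),
                                    out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  ## --- transcriptome -------------------------------------------------
  n_tx <- config$n_transcripts
  tx_len <- sample(seq(config$transcript_len_range[1],
                       config$transcript_len_range[2]), n_tx,
                   replace = TRUE)
  tx_id <- sprintf("LOC_Syn%04dg.1", seq_len(n_tx))
  tx_seq <- vapply(tx_len, function(l)
    paste(sample(RNA_BASES, l, replace = TRUE), collapse = ""), "")

  ## --- sRNA species ---------------------------------------------------
  n_rt <- config$n_planted_rt; n_wr <- config$n_planted_wr
  n_rt_loaded <- round(config$ago1_loaded_fraction * n_rt)
  n_wr_loaded <- round(config$ago1_loaded_fraction * n_wr)
  mk_set <- function(n, n_loaded, avoid) {
    lens <- c(srna_lengths(n_loaded, config$loaded_len_mode),
              srna_lengths(n - n_loaded, config$unloaded_len_mode))
    first <- c(srna_first_base(n_loaded, config$five_prime_u_prob_loaded),
               rep(NA_character_, n - n_loaded))
    list(seq = random_rna(n, lens, first, avoid),
         loaded = c(rep(TRUE, n_loaded), rep(FALSE, n - n_loaded)))
  }
  rt <- mk_set(n_rt, n_rt_loaded, character(0))
  wr <- mk_set(n_wr, n_wr_loaded, rt$seq)
  bg_len <- srna_lengths(config$n_background_srnas,
                         config$unloaded_len_mode)
  bg_seq <- random_rna(config$n_background_srnas, bg_len,
                       avoid = c(rt$seq, wr$seq))

  ## --- tissue and AGO1 libraries --------------------------------------
  des <- config$library_design
  rt_libs <- sprintf("RT%d", seq_len(des[["root_tip"]]))
  wr_libs <- sprintf("WR%d", seq_len(des[["whole_root"]]))
  ago_libs <- sprintf("AGO1%s", letters[seq_len(des[["ago1"]])])
  ctrl_libs <- sprintf("CTRL%d", seq_len(des[["ago_control"]]))
  deg_libs <- sprintf("DEG%d", seq_len(des[["degradome"]]))

  bg_base <- sample(1:20, config$n_background_srnas, replace = TRUE)
  # a handful of planted species leak at count 1 into the other compartment
  rt_leak <- seq_len(n_rt) %in% sample(seq_len(n_rt), min(5L, n_rt))
  wr_leak <- seq_len(n_wr) %in% sample(seq_len(n_wr), min(5L, n_wr))

  tissue_counts <- function(target_ids, other_ids, planted_target,
                            planted_other, leak_other) {
    libs <- list()
    for (id in target_ids) {
      cnt <- setNames(c(bg_base,
                        sample(10:60, length(planted_target),
                               replace = TRUE)),
                      c(bg_seq, planted_target))
      libs[[id]] <- cnt
    }
    for (id in other_ids) {
      cnt <- setNames(bg_base, bg_seq)
      cnt <- c(cnt, setNames(rep(1, sum(leak_other)),
                             planted_other[leak_other]))
      libs[[id]] <- cnt
    }
    libs
  }
  rt_side <- tissue_counts(rt_libs, character(0), rt$seq, NULL, NULL)
  wr_side <- tissue_counts(wr_libs, character(0), wr$seq, NULL, NULL)
  # leaks: planted RT species appearing at count 1 in WR libraries and v.v.
  for (id in wr_libs) {
    wr_side[[id]] <- c(wr_side[[id]],
                       setNames(rep(1, sum(rt_leak)), rt$seq[rt_leak]))
  }
  for (id in rt_libs) {
    rt_side[[id]] <- c(rt_side[[id]],
                       setNames(rep(1, sum(wr_leak)), wr$seq[wr_leak]))
  }
  tissue_libraries <- c(
    lapply(rt_libs, function(id)
      srna_library(rt_side[[id]], id, "root_tip")),
    lapply(wr_libs, function(id)
      srna_library(wr_side[[id]], id, "whole_root")))

  loaded_seq <- c(rt$seq[rt$loaded], wr$seq[wr$loaded])
  unloaded_seq <- c(rt$seq[!rt$loaded], wr$seq[!wr$loaded])
  bg_ago_idx <- seq_len(min(500L, config$n_background_srnas))
  bg_ago <- setNames(bg_base[bg_ago_idx], bg_seq[bg_ago_idx])
  ctrl_leak <- seq_along(loaded_seq) %in%
    sample(seq_along(loaded_seq), min(5L, length(loaded_seq)))
  ago_libraries <- lapply(ago_libs, function(id) {
    cnt <- c(bg_ago,
             setNames(sample(10:60, length(loaded_seq), replace = TRUE),
                      loaded_seq))
    srna_library(cnt, id, "ago1")
  })
  ctrl_libraries <- lapply(ctrl_libs, function(id) {
    cnt <- c(bg_ago,
             setNames(sample(5:20, length(unloaded_seq), replace = TRUE),
                      unloaded_seq),
             setNames(rep(1, sum(ctrl_leak)), loaded_seq[ctrl_leak]))
    srna_library(cnt, id, "ago_control")
  })

  ## --- self-check against the real filters ----------------------------
  rpm_tissue <- normalize_rpm(tissue_libraries)
  res_rt <- filter_compartment_enriched(rpm_tissue, rt_libs, wr_libs)
  res_wr <- filter_compartment_enriched(rpm_tissue, wr_libs, rt_libs)
  pass_rt <- res_rt$sequence[res_rt$passed]
  pass_wr <- res_wr$sequence[res_wr$passed]
  if (!setequal(pass_rt, rt$seq) || !setequal(pass_wr, wr$seq)) {
    stop("generator self-check failed: compartment filter does not recover ",
         "exactly the planted sets")
  }
  rpm_ago <- normalize_rpm(c(ago_libraries, ctrl_libraries))
  res_ago <- filter_ago1_enriched(rpm_ago, ago_libs, ctrl_libs,
                                  candidates = c(pass_rt, pass_wr))
  pass_ago <- res_ago$sequence[res_ago$passed]
  if (!setequal(pass_ago, loaded_seq)) {
    stop("generator self-check failed: AGO1 filter does not recover ",
         "exactly the loaded subset")
  }

  ## --- true interactions and embedded sites ---------------------------
  n_int <- config$n_true_interactions
  p0 <- config$cleavage_srna_position
  interactions <- data.frame(srna_id = character(0), srna_seq = character(0),
                             transcript_id = character(0),
                             start = integer(0), end = integer(0),
                             cleavage_position = integer(0),
                             srna_compartment = character(0),
                             stringsAsFactors = FALSE)
  if (n_int > 0) {
    loaded_ids <- c(sprintf("RTgen%03d", which(rt$loaded)),
                    sprintf("WRgen%03d", which(wr$loaded)))
    loaded_comp <- c(rep("root_tip", sum(rt$loaded)),
                     rep("whole_root", sum(wr$loaded)))
    pick_s <- sample(seq_along(loaded_seq), n_int, replace = TRUE)
    pick_t <- sample(seq_len(n_tx), n_int)
    starts <- integer(n_int)
    for (k in seq_len(n_int)) {
      L <- nchar(loaded_seq[pick_s[k]])
      starts[k] <- sample(seq(30L, tx_len[pick_t[k]] - L - 35L), 1L)
      site <- rna_revcomp(loaded_seq[pick_s[k]])
      substr(tx_seq[pick_t[k]], starts[k], starts[k] + L - 1L) <- site
    }
    L_all <- nchar(loaded_seq[pick_s])
    interactions <- data.frame(
      srna_id = loaded_ids[pick_s],
      srna_seq = loaded_seq[pick_s],
      transcript_id = tx_id[pick_t],
      start = starts, end = starts + L_all - 1L,
      cleavage_position = starts + L_all - p0,
      srna_compartment = loaded_comp[pick_s],
      stringsAsFactors = FALSE)
  }

  ## --- degradome libraries --------------------------------------------
  deg_libraries <- lapply(deg_libs, function(id) {
    tag_seq <- character(0); tag_cnt <- numeric(0)
    if (n_int > 0) {
      for (k in seq_len(n_int)) {
        cp <- interactions$cleavage_position[k]
        tx <- tx_seq[match(interactions$transcript_id[k], tx_id)]
        r <- round(runif(1, config$canonical_signal_rpm_range[1],
                         config$canonical_signal_rpm_range[2]))
        tag_seq <- c(tag_seq, substr(tx, cp, cp + 19L),
                     substr(tx, cp, cp + 20L))
        tag_cnt <- c(tag_cnt, ceiling(r / 2), floor(r / 2))
      }
    }
    for (j in seq_len(n_tx)) {
      n_noise <- stats::rpois(1, config$noise_tag_rate * tx_len[j] / 1000)
      if (n_noise == 0) next
      ns <- sample(seq_len(tx_len[j] - 19L), n_noise, replace = TRUE)
      tag_seq <- c(tag_seq, substr(rep(tx_seq[j], n_noise), ns, ns + 19L))
      tag_cnt <- c(tag_cnt, sample(1:5, n_noise, replace = TRUE))
    }
    srna_library(setNames(tag_cnt, tag_seq), id, "degradome",
                 total_reads = 1e6)
  })
  names(deg_libraries) <- deg_libs

  ## --- expression matrix ----------------------------------------------
  zones <- c("root_cap", "division_zone", "elongation_zone",
             paste0("maturation_zone_", c("I", "II", "III", "IV", "V")))
  samples <- as.vector(t(outer(zones, 1:3, function(z, r)
    paste0(z, "_rep", r))))
  zone_map <- setNames(rep(zones, each = 3), samples)
  gene_id <- gene_from_transcript(tx_id)
  base <- exp(rnorm(n_tx, 0, 0.5))
  zone_mean <- matrix(base, nrow = n_tx, ncol = length(zones),
                      dimnames = list(gene_id, zones))
  contrary_genes <- unique(data.frame(
    gene_id = gene_from_transcript(interactions$transcript_id),
    srna_compartment = interactions$srna_compartment,
    stringsAsFactors = FALSE))
  contrary_genes$fold <- if (nrow(contrary_genes)) {
    runif(nrow(contrary_genes), config$planted_contrary_fold,
          config$planted_contrary_fold + 1)
  } else numeric(0)
  rt_zones <- c("root_cap", "division_zone")
  n_rt_z <- length(rt_zones); n_z <- length(zones)
  for (k in seq_len(nrow(contrary_genes))) {
    g <- contrary_genes$gene_id[k]
    f <- contrary_genes$fold[k]
    b <- base[match(g, gene_id)]
    if (contrary_genes$srna_compartment[k] == "root_tip") {
      # target up in whole root: mean(all zones) = f * mean(tip zones)
      zone_mean[g, rt_zones] <- b
      zone_mean[g, setdiff(zones, rt_zones)] <-
        (n_z * f - n_rt_z) * b / (n_z - n_rt_z)
    } else {
      # target up in root tip: mean(tip) = f * mean(all)
      zone_mean[g, rt_zones] <- b
      zone_mean[g, setdiff(zones, rt_zones)] <-
        (n_z / f - n_rt_z) * b / (n_z - n_rt_z)
    }
  }
  vals <- zone_mean[, zone_map[samples], drop = FALSE] *
    exp(matrix(rnorm(n_tx * length(samples), 0,
                     config$expression_noise_sd),
               nrow = n_tx))
  colnames(vals) <- samples
  em <- expression_matrix(vals, zone_map)

  ## --- write files ------------------------------------------------------
  write_transcriptome(data.frame(transcript_id = tx_id, gene_id = gene_id,
                                 sequence = tx_seq),
                      file.path(out_dir, "transcripts.fasta"))
  all_libs <- c(tissue_libraries, ago_libraries, ctrl_libraries,
                deg_libraries)
  manifest <- data.frame(
    library_id = vapply(all_libs, `[[`, "", "library_id"),
    group = vapply(all_libs, `[[`, "", "group"),
    path = paste0(vapply(all_libs, `[[`, "", "library_id"), ".tsv"),
    total_reads = vapply(all_libs, `[[`, 0, "total_reads"),
    stringsAsFactors = FALSE)
  for (lib in all_libs) {
    write_srna_library(lib, file.path(out_dir,
                                      paste0(lib$library_id, ".tsv")))
  }
  write_tsv(manifest, file.path(out_dir, "libraries.tsv"))
  write_expression_matrix(em, file.path(out_dir, "expression.tsv"))
  write_tsv(data.frame(sample_id = samples, zone = zone_map[samples]),
            file.path(out_dir, "zones.tsv"))
  truth_srnas <- data.frame(
    sequence = c(rt$seq, wr$seq, bg_seq),
    set = c(rep("root_tip", n_rt), rep("whole_root", n_wr),
            rep("background", config$n_background_srnas)),
    ago1_loaded = c(rt$loaded, wr$loaded,
                    rep(FALSE, config$n_background_srnas)),
    stringsAsFactors = FALSE)
  write_tsv(truth_srnas, file.path(out_dir, "truth_srnas.tsv"))
  write_tsv(interactions, file.path(out_dir, "truth_interactions.tsv"))
  write_tsv(contrary_genes, file.path(out_dir, "truth_contrary.tsv"))

  invisible(list(
    truth = list(srnas = truth_srnas, interactions = interactions,
                 contrary_genes = contrary_genes,
                 ago1_loaded = loaded_seq),
    dir = out_dir, manifest = manifest, config = config))
}
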