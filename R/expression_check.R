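# Contrary-expression check: a cleavage-regulated target should be
# expressed higher where its repressing sRNA is lower.  Following the
# zone-resolved microarray design the pipeline emulates, the "root tip"
# category is the mean over the root-cap and division-zone samples and the
# "whole root" category is the mean over ALL samples (the whole root
# contains the tip).  The fold is oriented by the regulating sRNA's
# compartment: for a root-tip-enriched sRNA the target should be higher in
# the whole roots (fold = whole/tip), and conversely.

#' Contrast zone expression for a set of genes
#'
#' @param em an [expression_matrix()] whose zone labels include the
#'   root-tip zones.
#' @param genes character vector of gene ids.
#' @param srna_compartment `"root_tip"` or `"whole_root"` for each gene
#'   (recycled if scalar): the compartment in which the regulating sRNA is
#'   enriched.
#' @param min_fold oriented fold at or above which the gene is flagged
#'   contrary; default 1.0 (any contrary direction counts).
#' @param root_tip_zones zone labels pooled into the root-tip category;
#'   default root cap + division zone.
#' @return data.frame with one row per distinct (gene, compartment):
#'   `gene_id`, `srna_compartment`, `mean_root_tip`, `mean_whole_root`,
#'   `fold` (oriented), `contrary` (NA when the gene is absent from the
#'   matrix) and `missing`.
#' @export
contrast_expression <- function(em, genes, srna_compartment,
                                min_fold = 1.0,
                                root_tip_zones = c("root_cap",
                                                   "division_zone")) {
  stopifnot(inherits(em, "expression_matrix"))
  srna_compartment <- rep_len(as.character(srna_compartment),
                              length(genes))
  if (!all(srna_compartment %in% c("root_tip", "whole_root"))) {
    stop("srna_compartment must be 'root_tip' or 'whole_root'")
  }
  combo <- unique(data.frame(gene_id = genes,
                             srna_compartment = srna_compartment,
                             stringsAsFactors = FALSE))
  rt_cols <- em$zones %in% root_tip_zones
  if (!any(rt_cols)) {
    stop(sprintf("no samples labeled with root-tip zones (%s)",
                 paste(root_tip_zones, collapse = ", ")))
  }
  mean_rt_all <- rowMeans(em$values[, rt_cols, drop = FALSE])
  mean_wr_all <- rowMeans(em$values)
  present <- combo$gene_id %in% rownames(em$values)
  mean_rt <- ifelse(present, mean_rt_all[combo$gene_id], NA_real_)
  mean_wr <- ifelse(present, mean_wr_all[combo$gene_id], NA_real_)
  fold <- ifelse(combo$srna_compartment == "root_tip",
                 mean_wr / mean_rt, mean_rt / mean_wr)
  contrary <- ifelse(present, !is.na(fold) & fold >= min_fold, NA)
  out <- data.frame(gene_id = combo$gene_id,
                    srna_compartment = combo$srna_compartment,
                    mean_root_tip = mean_rt, mean_whole_root = mean_wr,
                    fold = fold, contrary = contrary,
                    missing = !present, stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$srna_compartment), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Contrast expression for validated interactions
#'
#' Maps each validated target transcript to its gene and runs
#' [contrast_expression()] once per distinct (gene, sRNA-compartment)
#' combination.
#'
#' @param em an [expression_matrix()].
#' @param interactions data.frame from [validate_sites()].
#' @param srna_compartments named character vector srna_id -> compartment
#'   (`"root_tip"`/`"whole_root"`).
#' @inheritParams contrast_expression
#' @return see [contrast_expression()].
#' @export
contrast_interactions <- function(em, interactions, srna_compartments,
                                  min_fold = 1.0,
                                  root_tip_zones = c("root_cap",
                                                     "division_zone")) {
  if (nrow(interactions) == 0L) {
    return(contrast_expression(em, character(0), character(0), min_fold,
                               root_tip_zones))
  }
  comp <- srna_compartments[interactions$srna_id]
  if (any(is.na(comp))) {
    stop("compartment unknown for sRNA(s): ",
         paste(unique(interactions$srna_id[is.na(comp)]), collapse = ", "))
  }
  contrast_expression(em, gene_from_transcript(interactions$transcript_id),
                      comp, min_fold, root_tip_zones)
}
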