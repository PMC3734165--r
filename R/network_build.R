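# Bipartite sRNA-target network assembly.  The transcript-level network is
# primary (one edge per distinct validated sRNA-transcript pair); the
# gene-collapsed view is derived from it on the fly.  Edge attributes carry
# the best evidence's canonical flag and t-plot category, and the contrary-
# expression flag when contrasts are supplied.

#' Build a bipartite regulatory network from validated interactions
#'
#' @param interactions data.frame from [validate_sites()]; several sites of
#'   one (sRNA, transcript) pair collapse to one edge keeping the best
#'   category and an any-canonical flag.
#' @param contrasts optional data.frame from [contrast_interactions()];
#'   joined onto edges by target gene (and compartment when the
#'   interactions carry an `srna_compartment` column).
#' @return object of class `regulatory_network`: list with `edges`
#'   (attributed edge data.frame), `graph` (directed bipartite igraph,
#'   vertex attribute `type` in srna/transcript), `srna_nodes`,
#'   `transcript_nodes`, `gene_nodes`, `degree_srna`, `degree_transcript`
#'   and `hubs` (transcripts with >= 2 distinct sRNA regulators).
#' @export
build_network <- function(interactions, contrasts = NULL) {
  if (nrow(interactions) == 0L) {
    edges <- data.frame(srna_id = character(0),
                        transcript_id = character(0),
                        gene_id = character(0), canonical = logical(0),
                        category = integer(0), stringsAsFactors = FALSE)
  } else {
    key <- paste(interactions$srna_id, interactions$transcript_id,
                 sep = "\r")
    o <- order(key, interactions$category,
               -as.integer(interactions$canonical))
    first <- interactions[o, , drop = FALSE]
    first <- first[!duplicated(paste(first$srna_id, first$transcript_id,
                                     sep = "\r")), , drop = FALSE]
    canon_any <- tapply(interactions$canonical, key, any)
    edges <- data.frame(
      srna_id = first$srna_id,
      transcript_id = first$transcript_id,
      gene_id = gene_from_transcript(first$transcript_id),
      canonical = as.logical(canon_any[paste(first$srna_id,
                                             first$transcript_id,
                                             sep = "\r")]),
      category = first$category,
      stringsAsFactors = FALSE)
  }
  if (!is.null(contrasts) && nrow(edges) > 0L) {
    cn <- contrasts[!is.na(contrasts$contrary), , drop = FALSE]
    flag <- tapply(cn$contrary, cn$gene_id, any)
    edges$contrary <- as.logical(flag[edges$gene_id])
  }
  edges <- edges[order(edges$srna_id, edges$transcript_id), , drop = FALSE]
  rownames(edges) <- NULL
  g <- network_graph(edges[, setdiff(colnames(edges), "gene_id"),
                           drop = FALSE])
  deg_s <- table(edges$srna_id)
  deg_t <- table(edges$transcript_id)
  structure(list(
    edges = edges,
    graph = g,
    srna_nodes = sort(unique(edges$srna_id)),
    transcript_nodes = sort(unique(edges$transcript_id)),
    gene_nodes = sort(unique(edges$gene_id)),
    degree_srna = setNames(as.integer(deg_s), names(deg_s)),
    degree_transcript = setNames(as.integer(deg_t), names(deg_t)),
    hubs = sort(names(deg_t)[deg_t >= 2])),
    class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf(paste0("<regulatory_network: %d sRNAs -> %d transcripts",
                     " (%d genes), %d edges, %d shared-target hubs>\n"),
              length(x$srna_nodes), length(x$transcript_nodes),
              length(x$gene_nodes), nrow(x$edges), length(x$hubs)))
  invisible(x)
}
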