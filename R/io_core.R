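# Readers/writers for every external format the pipeline touches, plus the
# shared coordinate conventions: internal alphabet is RNA (T mapped to U on
# read) and all transcript coordinates are 1-based inclusive.

#' Construct a small RNA library
#'
#' A library is a map from distinct RNA species (18-30 nt typically, any
#' non-empty A/C/G/U string accepted) to raw read counts, together with the
#' library total used for reads-per-million normalization.  The total
#' defaults to the table sum; an explicit total may exceed it when the
#' library contains reads beyond those tabulated (e.g. only
#' transcriptome-matched tags were kept).
#'
#' @param counts named numeric vector: names are sequences (T accepted,
#'   normalized to U), values are non-negative integer read counts.
#'   Duplicate sequences (after normalization) are summed.
#' @param library_id character scalar identifier.
#' @param group one of `"root_tip"`, `"whole_root"`, `"ago1"`,
#'   `"ago_control"`, `"degradome"`.
#' @param total_reads optional explicit library total; must be at least the
#'   table sum.  Default: the table sum.
#' @return an object of class `srna_library` with elements `library_id`,
#'   `group`, `counts` (named, sorted by sequence) and `total_reads`.
#' @export
srna_library <- function(counts, library_id, group, total_reads = NULL) {
  group <- match.arg(group, LIBRARY_GROUPS)
  stopifnot(is.character(library_id), length(library_id) == 1L)
  if (length(counts) == 0L) {
    counts <- setNames(numeric(0), character(0))
  }
  if (is.null(names(counts)) && length(counts) > 0L) {
    stop("'counts' must be a named vector (names are sequences)")
  }
  seqs <- as_rna(names(counts))
  assert_rna(seqs, sprintf("library '%s'", library_id))
  vals <- as.numeric(counts)
  if (any(is.na(vals)) || any(vals < 0) || any(vals != round(vals))) {
    stop(sprintf("library '%s': counts must be non-negative integers",
                 library_id))
  }
  if (length(seqs)) {
    agg <- tapply(vals, seqs, sum)
    counts <- setNames(as.numeric(agg), names(agg))
    counts <- counts[order(names(counts))]
  } else {
    counts <- setNames(numeric(0), character(0))
  }
  tab_sum <- sum(counts)
  if (is.null(total_reads)) {
    total_reads <- tab_sum
  } else {
    total_reads <- as.numeric(total_reads)
    if (length(total_reads) != 1L || is.na(total_reads) ||
        total_reads < tab_sum) {
      stop(sprintf("library '%s': total_reads (%s) below table sum (%s)",
                   library_id, total_reads, tab_sum))
    }
  }
  structure(list(library_id = library_id, group = group,
                 counts = counts, total_reads = total_reads),
            class = "srna_library")
}

#' @export
print.srna_library <- function(x, ...) {
  cat(sprintf("<srna_library '%s' (%s): %d species, %s reads>\n",
              x$library_id, x$group, length(x$counts),
              format(x$total_reads, big.mark = ",")))
  invisible(x)
}

#' Read a small RNA count library from TSV or FASTA
#'
#' Two formats are auto-detected: a two-column TSV (sequence, raw count) or
#' FASTA with the read count encoded in the header as a `_xN` suffix
#' (e.g. `>s1_x12`).  T characters are normalized to U.
#'
#' @inheritParams srna_library
#' @param path path to the file.
#' @return an [srna_library()].
#' @export
read_srna_library <- function(path, library_id, group, total_reads = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    return(srna_library(setNames(numeric(0), character(0)),
                        library_id, group, total_reads))
  }
  if (startsWith(trimws(lines[nonblank[1]]), ">")) {
    recs <- parse_counted_fasta(lines, path)
    counts <- setNames(recs$count, recs$sequence)
  } else {
    counts <- numeric(0)
    seqs <- character(0)
    for (i in nonblank) {
      fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(fields) != 2L) {
        stop(sprintf("%s: malformed line %d (expected 2 tab-separated fields)",
                     path, i))
      }
      cnt <- suppressWarnings(as.numeric(fields[2]))
      if (is.na(cnt) || cnt < 0 || cnt != round(cnt)) {
        stop(sprintf("%s: line %d: count '%s' is not a non-negative integer",
                     path, i, fields[2]))
      }
      seqs <- c(seqs, fields[1])
      counts <- c(counts, cnt)
    }
    counts <- setNames(counts, seqs)
  }
  srna_library(counts, library_id, group, total_reads)
}

parse_counted_fasta <- function(lines, path) {
  hdr_idx <- grep("^>", lines)
  if (length(hdr_idx) == 0L) stop(sprintf("%s: no FASTA headers found", path))
  ends <- c(hdr_idx[-1] - 1L, length(lines))
  seqs <- character(length(hdr_idx))
  cnts <- numeric(length(hdr_idx))
  for (k in seq_along(hdr_idx)) {
    hdr <- sub("^>", "", trimws(lines[hdr_idx[k]]))
    m <- regmatches(hdr, regexpr("_x[0-9]+$", hdr))
    if (length(m) == 0L) {
      stop(sprintf("%s: FASTA header '%s' lacks a _xN count suffix",
                   path, hdr))
    }
    cnts[k] <- as.numeric(sub("_x", "", m))
    body <- lines[seq(hdr_idx[k] + 1L, ends[k])]
    body <- body[!grepl("^>", body)]
    seqs[k] <- paste(trimws(body), collapse = "")
  }
  list(sequence = seqs, count = cnts)
}

#' Write a small RNA library as a two-column TSV
#'
#' @param lib an [srna_library()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_srna_library <- function(lib, path) {
  stopifnot(inherits(lib, "srna_library"))
  writeLines(paste(names(lib$counts), format_num(lib$counts), sep = "\t"),
             path)
  invisible(path)
}

# Fixed-format numeric rendering so written files are byte-stable.
format_num <- function(x) {
  out <- format(x, trim = TRUE, scientific = FALSE, digits = 15)
  out[x == round(x) & abs(x) < 1e15] <-
    format(round(x[x == round(x) & abs(x) < 1e15]), trim = TRUE,
           scientific = FALSE)
  out
}

#' Read a transcriptome FASTA
#'
#' One record per transcript.  The gene id is derived from the transcript id
#' by stripping a single trailing `.<integer>` isoform suffix if present
#' (TIGR-style naming, e.g. `LOC_Os02g43370.1` -> `LOC_Os02g43370`);
#' otherwise gene id equals transcript id.
#'
#' @param path FASTA file.
#' @return data.frame with columns `transcript_id`, `gene_id`, `sequence`
#'   (RNA alphabet).
#' @export
read_transcriptome <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate transcript id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- as_rna(as.character(ss))
  if (any(!nzchar(seqs))) stop("empty transcript sequence in FASTA")
  data.frame(transcript_id = ids,
             gene_id = gene_from_transcript(ids),
             sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Derive gene ids from isoform-suffixed transcript ids
#'
#' @param transcript_id character vector of transcript ids.
#' @return character vector with one trailing `.digits` group stripped.
#' @export
gene_from_transcript <- function(transcript_id) {
  sub("\\.[0-9]+$", "", transcript_id)
}

#' Write a transcriptome FASTA
#'
#' @param transcripts data.frame as returned by [read_transcriptome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transcriptome <- function(transcripts, path) {
  writeLines(paste0(">", transcripts$transcript_id, "\n",
                    transcripts$sequence), path)
  invisible(path)
}

#' Read a gene-by-sample expression matrix with zone labels
#'
#' The TSV's first column holds gene ids; remaining columns are samples.
#' Every sample must appear in `zone_map`, which assigns it to a root zone
#' (e.g. root cap, division zone, elongation zone, maturation zones).
#'
#' @param path rectangular TSV.
#' @param zone_map named character vector mapping sample_id to zone label.
#' @return object of class `expression_matrix`: list with `values` (numeric
#'   gene x sample matrix) and `zones` (named character vector aligned to
#'   the matrix columns).
#' @export
read_expression_matrix <- function(path, zone_map) {
  raw <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) stop("expression matrix needs a gene column plus samples")
  genes <- raw[[1]]
  samples <- colnames(raw)[-1]
  missing <- setdiff(samples, names(zone_map))
  if (length(missing) > 0L) {
    stop(sprintf("sample(s) missing from zone_map: %s",
                 paste(missing, collapse = ", ")))
  }
  vals <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(genes, samples))
  if (any(is.na(vals))) stop("non-numeric cell in expression matrix")
  if (any(vals < 0)) stop("negative value in expression matrix")
  expression_matrix(vals, zone_map[samples])
}

#' Construct an expression matrix object
#'
#' @param values numeric gene x sample matrix (row/col names required).
#' @param zones named character vector of zone labels, one per column.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, zones) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  zones <- zones[colnames(values)]
  if (any(is.na(zones))) stop("every sample needs a zone label")
  structure(list(values = values, zones = zones),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix: %d genes x %d samples, %d zones>\n",
              nrow(x$values), ncol(x$values), length(unique(x$zones))))
  invisible(x)
}

#' Write an expression matrix (values only) as TSV
#'
#' @param em an [expression_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(em, path) {
  df <- data.frame(gene_id = rownames(em$values),
                   em$values, check.names = FALSE)
  write_tsv(df, path)
  invisible(path)
}

# write.table wrapper with the package's fixed conventions
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], format_num)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a set of sRNA-transcript interactions as a network file
#'
#' @param edges data.frame with columns `srna_id` and `transcript_id`, plus
#'   optional edge-attribute columns (`canonical`, `category`, `contrary`),
#'   or a [build_network()] result.
#' @param path output path.
#' @param format `"sif"` (lines `srna cleaves transcript`), `"graphml"`
#'   (node attribute `type` in srna/transcript) or `"tsv"` (edge list with
#'   attributes).  Lines/edges are ordered lexicographically by
#'   (srna_id, transcript_id) in every format.
#' @return `path`, invisibly.
#' @export
write_network <- function(edges, path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  if (inherits(edges, "regulatory_network")) edges <- edges$edges
  stopifnot(all(c("srna_id", "transcript_id") %in% colnames(edges)))
  if (nrow(edges) > 0 &&
      (any(!nzchar(edges$srna_id)) || any(!nzchar(edges$transcript_id)))) {
    stop("empty node id in edge list")
  }
  edges <- edges[order(edges$srna_id, edges$transcript_id), , drop = FALSE]
  if (format == "sif") {
    writeLines(if (nrow(edges)) {
      paste(edges$srna_id, "cleaves", edges$transcript_id)
    } else character(0), path)
  } else if (format == "tsv") {
    write_tsv(edges, path)
  } else {
    g <- network_graph(edges)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

network_graph <- function(edges) {
  nodes <- data.frame(
    name = c(sort(unique(edges$srna_id)),
             sort(unique(edges$transcript_id))),
    type = c(rep("srna", length(unique(edges$srna_id))),
             rep("transcript", length(unique(edges$transcript_id)))),
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
}

#' Read a GraphML network export back as an edge data.frame
#'
#' @param path GraphML file written by [write_network()].
#' @return data.frame with `srna_id`, `transcript_id` and any edge
#'   attributes, ordered as written.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  names(el)[1:2] <- c("srna_id", "transcript_id")
  if ("category" %in% names(el)) el$category <- as.integer(el$category)
  el <- el[order(el$srna_id, el$transcript_id), , drop = FALSE]
  rownames(el) <- NULL
  el
}
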