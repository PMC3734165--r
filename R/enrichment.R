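# RPM normalization and the two serial enrichment filters: compartment
# (root tip vs whole root, and the reverse) and AGO1 immunoprecipitation
# vs total-extract control.  Both filters share one rule shape:
#   (1) the species is present in at least one library of the target group;
#   (2) in that same library its level is >= min_rpm AND >= fold x its level
#       in EVERY library of the reference group.
# Absent species count as 0 RPM; all comparisons are inclusive (>=).

#' Normalize libraries to reads per million
#'
#' RPM = raw count / library total x 1e6.  The result covers the union of
#' all sequences; a sequence absent from a library has RPM 0 there.
#'
#' @param libraries list of [srna_library()] objects with distinct ids and
#'   positive totals.
#' @return numeric matrix, rows = sequences (sorted), columns = library ids,
#'   with a `groups` attribute (named character vector library_id -> group).
#' @export
normalize_rpm <- function(libraries) {
  stopifnot(length(libraries) > 0,
            all(vapply(libraries, inherits, TRUE, "srna_library")))
  ids <- vapply(libraries, `[[`, "", "library_id")
  if (anyDuplicated(ids)) stop("duplicate library ids")
  totals <- vapply(libraries, `[[`, 0, "total_reads")
  if (any(totals <= 0)) {
    stop(sprintf("library '%s' has total_reads = 0; cannot normalize",
                 ids[which(totals <= 0)[1]]))
  }
  seqs <- sort(unique(unlist(lapply(libraries,
                                    function(l) names(l$counts)))))
  mat <- matrix(0, nrow = length(seqs), ncol = length(ids),
                dimnames = list(seqs, ids))
  for (k in seq_along(libraries)) {
    cn <- libraries[[k]]$counts
    if (length(cn)) mat[names(cn), k] <- cn / totals[k] * 1e6
  }
  attr(mat, "groups") <- setNames(
    vapply(libraries, `[[`, "", "group"), ids)
  mat
}

#' Generic two-group enrichment filter
#'
#' A sequence passes when some target-group library shows it at
#' `min_rpm` or more and at `fold` times or more its level in every
#' reference-group library.  Qualifying libraries are all target libraries
#' satisfying both conditions.
#'
#' @param rpm matrix from [normalize_rpm()] (rows sequences, columns
#'   libraries).
#' @param target_libs,reference_libs disjoint, non-empty character vectors
#'   of column names.
#' @param min_rpm minimum level (reads per million) in the qualifying
#'   library; default 3.
#' @param fold minimum ratio against every reference library; default 3.
#' @param candidates optional character vector of sequences to restrict the
#'   test to (e.g. survivors of an upstream filter).
#' @return data.frame with columns `sequence`, `passed`,
#'   `qualifying_libraries` (comma-separated) and one RPM column per
#'   involved library, sorted by sequence.
#' @export
filter_enriched <- function(rpm, target_libs, reference_libs,
                            min_rpm = 3, fold = 3, candidates = NULL) {
  stopifnot(length(target_libs) > 0, length(reference_libs) > 0)
  if (length(intersect(target_libs, reference_libs)) > 0) {
    stop("target and reference library groups must be disjoint")
  }
  miss <- setdiff(c(target_libs, reference_libs), colnames(rpm))
  if (length(miss)) {
    stop(sprintf("libraries absent from RPM matrix: %s",
                 paste(miss, collapse = ", ")))
  }
  if (!is.null(candidates)) {
    keep <- intersect(rownames(rpm), candidates)
    rpm <- rpm[keep, , drop = FALSE]
  }
  n <- nrow(rpm)
  if (n == 0L) {
    out <- data.frame(sequence = character(0), passed = logical(0),
                      qualifying_libraries = character(0),
                      stringsAsFactors = FALSE)
    libs <- c(target_libs, reference_libs)
    out <- cbind(out, as.data.frame(
      matrix(numeric(0), nrow = 0, ncol = length(libs),
             dimnames = list(NULL, libs))))
    return(out)
  }
  a <- rpm[, target_libs, drop = FALSE]
  b <- rpm[, reference_libs, drop = FALSE]
  ref_max <- if (n) apply(b, 1L, max) else numeric(0)
  qual <- a > 0 & a >= min_rpm & a >= fold * ref_max
  qualifying <- apply(qual, 1L, function(q) {
    paste(target_libs[q], collapse = ",")
  })
  out <- data.frame(sequence = rownames(rpm),
                    passed = unname(rowSums(qual) > 0),
                    qualifying_libraries = unname(as.character(qualifying)),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(rpm[, c(target_libs, reference_libs),
                                      drop = FALSE]))
  rownames(out) <- NULL
  out[order(out$sequence), , drop = FALSE]
}

#' Compartment-enrichment filter (root tip vs whole root)
#'
#' Extracts the sequences highly accumulated in the target compartment:
#' present in at least one target-compartment library at `min_rpm` reads per
#' million or more, and at `fold` times or more their level in every library
#' of the other compartment.  Running it with the groups swapped yields the
#' other compartment's enriched set.
#'
#' @inheritParams filter_enriched
#' @param group_a_libs target-compartment library ids (e.g. root tip).
#' @param group_b_libs other-compartment library ids (e.g. whole root).
#' @return see [filter_enriched()].
#' @export
filter_compartment_enriched <- function(rpm, group_a_libs, group_b_libs,
                                        min_rpm = 3, fold = 3) {
  filter_enriched(rpm, group_a_libs, group_b_libs, min_rpm, fold)
}

#' AGO1-enrichment filter
#'
#' Same rule shape against the immunoprecipitation control: detectable in at
#' least one AGO1 library at `min_rpm` or more and `fold` times or more its
#' control level.  In the pipeline it consumes the compartment-filter
#' survivors (pass `candidates`); standalone use is allowed by leaving
#' `candidates` NULL.
#'
#' @inheritParams filter_enriched
#' @param ago_libs AGO1 immunoprecipitation library ids.
#' @param control_libs control library id(s).
#' @return see [filter_enriched()].
#' @export
filter_ago1_enriched <- function(rpm, ago_libs, control_libs,
                                 min_rpm = 3, fold = 3, candidates = NULL) {
  filter_enriched(rpm, ago_libs, control_libs, min_rpm, fold,
                  candidates = candidates)
}
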