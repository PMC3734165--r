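# Independent re-implementations of the pipeline's two scored rules, used
# as oracles.  They share no code with the package paths they check: the
# filter oracle is plain nested loops over the written rules, the scan
# oracle rescores windows position by position in R.

# Brute-force application of the enrichment rules: a sequence passes iff
# some target library shows it (> 0) at >= min_rpm and >= fold x its level
# in every reference library.
oracle_pass_set <- function(rpm, target_libs, reference_libs,
                            min_rpm = 3, fold = 3) {
  passed <- character(0)
  for (s in rownames(rpm)) {
    ok <- FALSE
    for (L in target_libs) {
      v <- rpm[s, L]
      if (v > 0 && v >= min_rpm) {
        all_ok <- TRUE
        for (M in reference_libs) {
          if (v < fold * rpm[s, M]) all_ok <- FALSE
        }
        if (all_ok) ok <- TRUE
      }
    }
    if (ok) passed <- c(passed, s)
  }
  passed
}

# Exhaustive enumeration of every window of one transcript against one
# sRNA, scored per position: match 0, G:U wobble 0.5, mismatch 1, doubled
# over sRNA positions core[1]..core[2]; windows with penalty <= max_penalty
# returned with 1-based start coordinates.
oracle_scan_one <- function(srna, tx, max_penalty = 3, core = c(2L, 13L)) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  s <- strsplit(srna, "")[[1]]
  t <- strsplit(tx, "")[[1]]
  L <- length(s); n <- length(t)
  if (n < L) return(data.frame(start = integer(0), penalty = numeric(0)))
  starts <- seq_len(n - L + 1L)
  pen <- numeric(length(starts))
  for (p in seq_len(L)) {
    tb <- t[starts + L - p]
    sb <- s[p]
    cost <- ifelse(tb == comp[[sb]], 0,
                   ifelse((sb == "G" & tb == "U") |
                            (sb == "U" & tb == "G"), 0.5, 1))
    w <- if (p >= core[1] && p <= core[2]) 2 else 1
    pen <- pen + w * cost
  }
  keep <- pen <= max_penalty + 1e-9
  data.frame(start = starts[keep], penalty = pen[keep])
}

# Full oracle site table over sRNA and transcript sets, in the same key
# ordering as scan_targets().
oracle_scan <- function(srnas, transcripts, max_penalty = 3) {
  out <- do.call(rbind, lapply(names(srnas), function(id) {
    do.call(rbind, lapply(seq_len(nrow(transcripts)), function(j) {
      hits <- oracle_scan_one(srnas[[id]], transcripts$sequence[j],
                              max_penalty)
      if (nrow(hits) == 0L) return(NULL)
      data.frame(srna_id = id,
                 transcript_id = transcripts$transcript_id[j],
                 start = hits$start,
                 penalty = hits$penalty, stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(out)) {
    return(data.frame(srna_id = character(0), transcript_id = character(0),
                      start = integer(0), penalty = numeric(0)))
  }
  out <- out[order(out$srna_id, out$transcript_id, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random RPM profile matrix exercising the thresholds' neighborhoods
# (zeros, values straddling min_rpm and the fold boundary).
random_rpm_matrix <- function(n_seq, lib_ids) {
  vals <- matrix(0, n_seq, length(lib_ids),
                 dimnames = list(sprintf("seq%04d", seq_len(n_seq)),
                                 lib_ids))
  for (j in seq_along(lib_ids)) {
    kind <- sample(3, n_seq, replace = TRUE)
    vals[, j] <- ifelse(kind == 1, 0,
                        ifelse(kind == 2, runif(n_seq, 0, 4),
                               runif(n_seq, 0, 15)))
  }
  vals
}
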