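# Sequence characteristics of an sRNA set: 5' terminal nucleotide
# composition and length distribution, both as percentages over distinct
# species (each sequence counted once, unweighted by read abundance).
# AGO1 loading leaves a recognizable footprint here: 5'-U bias and a
# 19-21 nt length preference versus the 24 nt mode of the bulk population.

#' Profile the 5' composition and length distribution of an sRNA set
#'
#' @param sequences character vector of RNA sequences; duplicates are
#'   collapsed (profiles describe species lists, not read stacks).
#' @param set_label label carried into the result.
#' @return object of class `sequence_profile`: list with `set_label`,
#'   `n_sequences`, `five_prime_pct` (named A/C/G/U, sums to 100) and
#'   `length_pct` (named by observed length in nt, sums to 100).
#' @export
profile_set <- function(sequences, set_label = "set") {
  if (length(sequences) == 0L) stop("cannot profile an empty sequence set")
  seqs <- unique(as_rna(sequences))
  assert_rna(seqs, set_label)
  n <- length(seqs)
  five <- table(factor(substr(seqs, 1L, 1L), levels = RNA_BASES))
  five_pct <- setNames(as.numeric(five) / n * 100, RNA_BASES)
  lens <- table(nchar(seqs))
  len_pct <- setNames(as.numeric(lens) / n * 100, names(lens))
  structure(list(set_label = set_label, n_sequences = n,
                 five_prime_pct = five_pct, length_pct = len_pct),
            class = "sequence_profile")
}

#' @export
print.sequence_profile <- function(x, ...) {
  cat(sprintf("<sequence_profile '%s': %d species>\n", x$set_label,
              x$n_sequences))
  cat("  5' composition (%):",
      paste(sprintf("%s=%.2f", names(x$five_prime_pct), x$five_prime_pct),
            collapse = " "), "\n")
  cat("  lengths (%):",
      paste(sprintf("%snt=%.2f", names(x$length_pct), x$length_pct),
            collapse = " "), "\n")
  invisible(x)
}

#' Flatten one or more sequence profiles to a long table
#'
#' @param profiles a `sequence_profile` or list of them.
#' @return data.frame with columns `set_label`, `metric`
#'   (`five_prime`/`length`), `key` and `percent`.
#' @export
profile_table <- function(profiles) {
  if (inherits(profiles, "sequence_profile")) profiles <- list(profiles)
  do.call(rbind, lapply(profiles, function(p) {
    rbind(
      data.frame(set_label = p$set_label, metric = "five_prime",
                 key = names(p$five_prime_pct),
                 percent = as.numeric(p$five_prime_pct)),
      data.frame(set_label = p$set_label, metric = "length",
                 key = names(p$length_pct),
                 percent = as.numeric(p$length_pct)))
  }))
}
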