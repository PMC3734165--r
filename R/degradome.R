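# Degradome (PARE) validation of predicted binding sites.  Tags are mapped
# to transcripts by exact full-length forward-strand matching; signals are
# aggregated per (transcript, 5' position, library).  A site is validated
# when, in any library, a signal with two or more distinct tag sequences
# sits opposite sRNA position 8-12 (transcript position end - p + 1) and
# stands out on the transcript's t-plot.  The manual t-plot inspection of
# classical degradome workflows is replaced by an automated category:
#   0 = unique maximum on the transcript (in that library)
#   1 = equal to the maximum, shared with at most two other positions
#   2 = above the median positive signal but not maximal
#   3 = otherwise
# The default cutoff (category <= 1) keeps only signals that dominate their
# transcript, the signals a curator would call easy to recognize.

#' Map degradome tags onto transcripts
#'
#' Each tag is placed at every transcript position where it matches exactly
#' (full length, forward strand); unmatched tags are dropped (a message
#' reports how many).  Signals are aggregated per (transcript, 5' position):
#' RPM summed over all matching tags, distinct tag sequences counted.
#'
#' @param tags an [srna_library()] of degradome tags (counts normalized by
#'   the library's `total_reads`).
#' @param transcripts data.frame from [read_transcriptome()].
#' @return data.frame with columns `transcript_id`, `five_prime_pos`
#'   (1-based), `library_id`, `rpm`, `n_distinct_signatures`, sorted by
#'   (transcript_id, five_prime_pos).
#' @export
map_degradome <- function(tags, transcripts) {
  stopifnot(inherits(tags, "srna_library"))
  empty <- data.frame(transcript_id = character(0),
                      five_prime_pos = integer(0),
                      library_id = character(0), rpm = numeric(0),
                      n_distinct_signatures = integer(0),
                      stringsAsFactors = FALSE)
  if (length(tags$counts) == 0L || nrow(transcripts) == 0L) return(empty)
  if (tags$total_reads <= 0) stop("degradome library has zero total reads")
  tag_seq <- names(tags$counts)
  tag_rpm <- tags$counts / tags$total_reads * 1e6
  # exact matching is done in DNA space with Biostrings PDict (U -> T)
  subjects <- Biostrings::DNAStringSet(chartr("U", "T",
                                              as_rna(transcripts$sequence)))
  names(subjects) <- transcripts$transcript_id
  dna_tags <- chartr("U", "T", tag_seq)
  widths <- nchar(dna_tags)
  hit_tag <- integer(0); hit_tx <- integer(0); hit_pos <- integer(0)
  for (w in sort(unique(widths))) {
    grp <- which(widths == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(dna_tags[grp]))
    for (j in seq_along(subjects)) {
      m <- Biostrings::matchPDict(pd, subjects[[j]])
      starts <- Biostrings::startIndex(m)
      nh <- lengths(starts)
      if (sum(nh) == 0L) next
      hit_tag <- c(hit_tag, rep(grp, nh))
      hit_tx <- c(hit_tx, rep.int(j, sum(nh)))
      hit_pos <- c(hit_pos, unlist(starts, use.names = FALSE))
    }
  }
  n_unmatched <- length(tag_seq) - length(unique(hit_tag))
  if (n_unmatched > 0) {
    message(sprintf("map_degradome [%s]: %d of %d tags matched no transcript",
                    tags$library_id, n_unmatched, length(tag_seq)))
  }
  if (length(hit_tag) == 0L) return(empty)
  key <- paste(hit_tx, hit_pos, sep = "@")
  rpm <- tapply(tag_rpm[hit_tag], key, sum)
  nsig <- tapply(tag_seq[hit_tag], key, function(s) length(unique(s)))
  parts <- strsplit(names(rpm), "@", fixed = TRUE)
  tx_i <- as.integer(vapply(parts, `[`, "", 1L))
  pos <- as.integer(vapply(parts, `[`, "", 2L))
  out <- data.frame(transcript_id = transcripts$transcript_id[tx_i],
                    five_prime_pos = pos,
                    library_id = tags$library_id,
                    rpm = as.numeric(rpm),
                    n_distinct_signatures = as.integer(nsig),
                    stringsAsFactors = FALSE)
  out <- out[order(out$transcript_id, out$five_prime_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify one degradome signal by its t-plot standing
#'
#' @param signal_rpm the query signal's RPM.
#' @param profile_rpm RPM of every signal on the same transcript in the same
#'   library (must contain the query).
#' @return integer category 0-3 (see the module description above).
#' @export
classify_tplot <- function(signal_rpm, profile_rpm) {
  if (length(profile_rpm) == 0L || !any(profile_rpm == signal_rpm)) {
    stop("query signal is not part of the transcript profile")
  }
  mx <- max(profile_rpm)
  if (signal_rpm == mx) {
    n_at_max <- sum(profile_rpm == mx)
    if (n_at_max == 1L) return(0L)
    if (n_at_max <= 3L) return(1L)  # shared with at most 2 other positions
    return(3L)
  }
  med <- median(profile_rpm[profile_rpm > 0])
  if (signal_rpm > med) 2L else 3L
}

# vectorized category for a whole profile at once
classify_profile <- function(rpm) {
  mx <- max(rpm)
  n_at_max <- sum(rpm == mx)
  med <- median(rpm[rpm > 0])
  ifelse(rpm == mx,
         ifelse(n_at_max == 1L, 0L, ifelse(n_at_max <= 3L, 1L, 3L)),
         ifelse(rpm > med, 2L, 3L))
}

#' Validate predicted binding sites against degradome signals
#'
#' For each site, library and sRNA position `p` in `window`, cleavage
#' evidence is recorded when a signal with at least `min_signatures`
#' distinct tag sequences sits at transcript position `end - p + 1`.  An
#' interaction is retained when any of its evidence reaches t-plot category
#' `max_category` or better; evidence at p 10-11 is flagged canonical.
#'
#' @param sites data.frame from [scan_targets()].
#' @param signals data.frame from [map_degradome()] (rows from several
#'   libraries may be concatenated).
#' @param window integer vector of sRNA positions to accept cleavage at;
#'   default `8:12`.
#' @param min_signatures minimum distinct tag sequences supporting the
#'   position; default 2.
#' @param max_category worst t-plot category still accepted; default 1.
#' @return data.frame of validated interactions, one row per retained site:
#'   site columns plus `best_library`, `p`, `transcript_position`,
#'   `signal_rpm`, `n_signatures`, `canonical`, `category`,
#'   `supporting_libraries` (comma-separated) and `n_evidence`.  The best
#'   evidence maximizes `signal_rpm` (ties: lower category, then lower p).
#' @export
validate_sites <- function(sites, signals, window = 8:12,
                           min_signatures = 2L, max_category = 1L) {
  if (length(window) == 0L) stop("empty cleavage window")
  window <- sort(unique(as.integer(window)))
  empty <- cbind(
    sites[0, , drop = FALSE],
    data.frame(best_library = character(0), p = integer(0),
               transcript_position = integer(0), signal_rpm = numeric(0),
               n_signatures = integer(0), canonical = logical(0),
               category = integer(0), supporting_libraries = character(0),
               n_evidence = integer(0), stringsAsFactors = FALSE))
  if (nrow(sites) == 0L || nrow(signals) == 0L) return(empty)

  prof_key <- paste(signals$library_id, signals$transcript_id, sep = "\r")
  signals$category <- as.integer(
    stats::ave(signals$rpm, prof_key, FUN = classify_profile))

  ev <- do.call(rbind, lapply(window, function(p) {
    data.frame(site_idx = seq_len(nrow(sites)), p = p,
               transcript_id = sites$transcript_id,
               transcript_position = sites$end - p + 1L,
               stringsAsFactors = FALSE)
  }))
  ev <- merge(ev, signals,
              by.x = c("transcript_id", "transcript_position"),
              by.y = c("transcript_id", "five_prime_pos"))
  ev <- ev[ev$n_distinct_signatures >= min_signatures, , drop = FALSE]
  if (nrow(ev) == 0L) return(empty)
  ev$canonical <- ev$p %in% c(10L, 11L)
  ev$qualifies <- ev$category <= max_category

  kept_idx <- sort(unique(ev$site_idx[ev$qualifies]))
  if (length(kept_idx) == 0L) return(empty)
  evq <- ev[ev$qualifies, , drop = FALSE]
  evq <- evq[order(evq$site_idx, -evq$rpm, evq$category, evq$p), ,
             drop = FALSE]
  best <- evq[!duplicated(evq$site_idx), , drop = FALSE]
  support <- vapply(split(evq$library_id, evq$site_idx),
                    function(l) paste(sort(unique(l)), collapse = ","), "")
  n_ev <- vapply(split(evq$library_id, evq$site_idx), length, 0L)
  out <- cbind(
    sites[best$site_idx, , drop = FALSE],
    data.frame(best_library = best$library_id, p = best$p,
               transcript_position = best$transcript_position,
               signal_rpm = best$rpm,
               n_signatures = best$n_distinct_signatures,
               canonical = best$canonical, category = best$category,
               supporting_libraries = unname(support),
               n_evidence = as.integer(unname(n_ev)),
               stringsAsFactors = FALSE))
  out <- out[order(out$srna_id, out$transcript_id, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export the data behind a t-plot panel
#'
#' Returns per-position signal intensities for one transcript in one
#' library, plus the spans of any predicted binding sites on it, ready for
#' plotting signal RPM against transcript position.
#'
#' @param transcript_id,library_id the panel to export.
#' @param signals data.frame from [map_degradome()].
#' @param sites data.frame from [scan_targets()] (may be empty).
#' @return data.frame with columns `type` (`signal` or `site`), `position`
#'   (signal rows), `start`/`end` (site rows), `rpm` and `srna_id`.
#' @export
export_tplot_data <- function(transcript_id, library_id, signals, sites) {
  sig <- signals[signals$transcript_id == transcript_id &
                   signals$library_id == library_id, , drop = FALSE]
  if (nrow(sig) == 0L) {
    stop(sprintf("no degradome signals for transcript '%s' in library '%s'",
                 transcript_id, library_id))
  }
  rows <- data.frame(type = "signal", position = sig$five_prime_pos,
                     start = NA_integer_, end = NA_integer_,
                     rpm = sig$rpm, srna_id = NA_character_,
                     stringsAsFactors = FALSE)
  st <- sites[sites$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(st) > 0L) {
    rows <- rbind(rows, data.frame(
      type = "site", position = NA_integer_, start = st$start,
      end = st$end, rpm = NA_real_, srna_id = st$srna_id,
      stringsAsFactors = FALSE))
  }
  rownames(rows) <- NULL
  rows
}
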