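# Complementarity scanner: penalty scheme, coordinates and oracle parity.

# build a transcript holding a window whose pairing against `srna` is fully
# controlled: perfect reverse complement, then optional per-position edits
site_for <- function(srna) rna_revcomp(srna)

test_that("a perfect reverse complement scores penalty 0 at 1..L", {
  srna <- "UGACAGAAGAGAGUGAGCACA"
  tx <- data.frame(transcript_id = "t1", gene_id = "t1",
                   sequence = site_for(srna))
  hits <- scan_targets(c(s1 = srna), tx)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 1L)
  expect_equal(hits$end, nchar(srna))
  expect_equal(hits$penalty, 0)
  expect_equal(hits$pairing, strrep("M", nchar(srna)))
})

test_that("a core G:U wobble costs 0.5 x 2", {
  srna <- "AGACAGAAGAGAGUGAGCACA"  # position 5 is A
  site <- site_for(srna)
  # sRNA position p sits opposite site position L - p + 1; make the base
  # opposite position 5 a G so that A:G is... use G:U instead: sRNA pos 5
  # is A; set sRNA pos 5 to G and transcript base to U for a wobble
  srna_w <- srna
  substr(srna_w, 5, 5) <- "G"
  site_w <- site
  L <- nchar(srna)
  substr(site_w, L - 5 + 1, L - 5 + 1) <- "U"   # G (sRNA) : U (transcript)
  tx <- data.frame(transcript_id = "t1", gene_id = "t1",
                   sequence = site_w)
  hits <- scan_targets(c(s = srna_w), tx)
  expect_equal(hits$penalty, 1.0)
  expect_equal(substr(hits$pairing, 5, 5), "W")
})

test_that("mismatches at non-core p1 and core p10 sum to 3.0, boundary inclusive", {
  srna <- "UGACAGAAGAGAGUGAGCACA"
  site <- site_for(srna)
  L <- nchar(srna)
  mismatch_at <- function(site, p, srna) {
    # replace the transcript base opposite sRNA position p with a base that
    # neither pairs nor wobbles with the sRNA base
    sb <- substr(srna, p, p)
    bad <- setdiff(c("A", "C", "G", "U"),
                   c(chartr("ACGU", "UGCA", sb),
                     if (sb == "G") "U", if (sb == "U") "G", sb))[1]
    substr(site, L - p + 1, L - p + 1) <- bad
    site
  }
  site2 <- mismatch_at(mismatch_at(site, 1, srna), 10, srna)
  tx <- data.frame(transcript_id = "t1", gene_id = "t1", sequence = site2)
  hits <- scan_targets(c(s = srna), tx, max_penalty = 3.0)
  expect_equal(hits$penalty, 3.0)          # 1x1 non-core + 1x2 core
  expect_equal(substr(hits$pairing, 1, 1), "X")
  expect_equal(substr(hits$pairing, 10, 10), "X")
  expect_equal(nrow(scan_targets(c(s = srna), tx, max_penalty = 2.9)), 0L)
})

test_that("embedding a site mid-transcript reports correct coordinates", {
  set.seed(5)
  srna <- paste(sample(c("A", "C", "G", "U"), 21, TRUE), collapse = "")
  pad <- function(n) paste(sample(c("A", "C"), n, TRUE), collapse = "")
  tx_seq <- paste0(pad(100), site_for(srna), pad(80))
  tx <- data.frame(transcript_id = "t1", gene_id = "t1", sequence = tx_seq)
  hits <- scan_targets(c(s = srna), tx, max_penalty = 0)
  expect_equal(hits$start, 101L)
  expect_equal(hits$end, 121L)
})

test_that("scanner agrees exactly with exhaustive oracle enumeration", {
  set.seed(23)
  tx <- toy_transcriptome()
  srnas <- setNames(
    c(vapply(1:3, function(i) paste(sample(c("A", "C", "G", "U"), 21, TRUE),
                                    collapse = ""), ""),
      # guaranteed hits: near-complements of real windows
      rna_revcomp(substr(tx$sequence[1], 50, 70)),
      rna_revcomp(substr(tx$sequence[2], 120, 140))),
    paste0("q", 1:5))
  got <- scan_targets(srnas, tx, max_penalty = 3.0)
  want <- oracle_scan(srnas, tx, max_penalty = 3.0)
  expect_equal(got[, c("srna_id", "transcript_id", "start", "penalty")],
               want, tolerance = 1e-12)
})

test_that("site set grows monotonically with max_penalty", {
  set.seed(29)
  tx <- toy_transcriptome()
  srna <- setNames(rna_revcomp(substr(tx$sequence[3], 30, 50)), "q")
  sets <- lapply(c(0, 2, 4, 6), function(mp)
    scan_targets(srna, tx, max_penalty = mp))
  key <- function(df) paste(df$transcript_id, df$start)
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(key(sets[[i]]) %in% key(sets[[i + 1]])))
  }
})

test_that("invalid sRNA input is rejected", {
  tx <- toy_transcriptome()
  expect_error(scan_targets(c(s = "UGACNGAAGAGAGUGAGCACA"), tx), "A/C/G/U")
  expect_error(scan_targets(c(s = "UGAC"), tx), "18 and 26")
})
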