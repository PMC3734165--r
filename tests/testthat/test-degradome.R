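# Degradome mapping, t-plot categories and window validation.

test_that("tags map at exact positions with closed-form RPM", {
  tx <- toy_transcriptome()
  tag <- substr(tx$sequence[1], 101, 120)
  lib <- srna_library(setNames(10, tag), "D1", "degradome",
                      total_reads = 1e6)
  sig <- map_degradome(lib, tx)
  hit <- sig[sig$transcript_id == "TX0001.1" & sig$five_prime_pos == 101, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$rpm, 10)
  expect_equal(hit$n_distinct_signatures, 1L)
})

test_that("distinct tags sharing a 5' end aggregate into one signal", {
  tx <- toy_transcriptome()
  t20 <- substr(tx$sequence[1], 101, 120)
  t21 <- substr(tx$sequence[1], 101, 121)
  lib <- srna_library(setNames(c(6, 4), c(t20, t21)), "D1", "degradome",
                      total_reads = 1e6)
  sig <- map_degradome(lib, tx)
  hit <- sig[sig$five_prime_pos == 101 & sig$transcript_id == "TX0001.1", ]
  expect_equal(hit$rpm, 10)
  expect_equal(hit$n_distinct_signatures, 2L)
})

test_that("a tag matching several transcripts signals on each", {
  shared <- paste(rep(c("A", "C", "G", "U"), 5), collapse = "")
  tx <- data.frame(transcript_id = c("a.1", "b.1"), gene_id = c("a", "b"),
                   sequence = paste0(strrep("A", 30), shared,
                                     strrep("C", 30)))
  lib <- srna_library(setNames(5, shared), "D", "degradome",
                      total_reads = 1e6)
  sig <- map_degradome(lib, tx)
  expect_equal(sig$transcript_id, c("a.1", "b.1"))
  expect_equal(sig$five_prime_pos, c(31L, 31L))
})

test_that("t-plot categories follow the declared definitions", {
  expect_equal(classify_tplot(50, c(50, 5, 1)), 0L)       # unique max
  expect_equal(classify_tplot(50, c(50, 50)), 1L)         # shared max
  expect_equal(classify_tplot(2, c(2, 50, 10, 1)), 3L)    # <= median (6)
  expect_equal(classify_tplot(10, c(2, 50, 10, 1)), 2L)   # above median
  # a maximum diluted over many positions is no longer prominent
  expect_equal(classify_tplot(5, rep(5, 5)), 3L)
  expect_error(classify_tplot(7, c(1, 2)), "not part")
})

# one controlled site + signal constellation used by the window tests
window_fixture <- function(signal_pos, n_sig = 2L, rpm = 50) {
  set.seed(101)
  srna <- paste(sample(c("A", "C", "G", "U"), 20, TRUE), collapse = "")
  body <- paste(sample(c("A", "C", "G", "U"), 400, TRUE), collapse = "")
  tx_seq <- body
  substr(tx_seq, 101, 120) <- rna_revcomp(srna)   # site at 101..120, L=20
  tx <- data.frame(transcript_id = "t.1", gene_id = "t",
                   sequence = tx_seq, stringsAsFactors = FALSE)
  sites <- scan_targets(c(s1 = srna), tx, max_penalty = 0)
  tags <- c(substr(tx_seq, signal_pos, signal_pos + 19L),
            substr(tx_seq, signal_pos, signal_pos + 20L))[seq_len(n_sig)]
  lib <- srna_library(setNames(rep(rpm / n_sig, n_sig), tags), "D1",
                      "degradome", total_reads = 1e6)
  list(sites = sites, signals = map_degradome(lib, tx), tx = tx)
}

test_that("signal at end - p + 1 creates canonical evidence at p = 10", {
  fx <- window_fixture(111)     # end 120: p = 120 - 111 + 1 = 10
  got <- validate_sites(fx$sites, fx$signals)
  expect_equal(nrow(got), 1L)
  expect_equal(got$p, 10L)
  expect_equal(got$transcript_position, 111L)
  expect_true(got$canonical)
  expect_equal(got$category, 0L)
})

test_that("signals outside the 8-12 window are not evidence", {
  fx <- window_fixture(114)     # p = 7, just past the window edge
  expect_equal(nrow(validate_sites(fx$sites, fx$signals)), 0L)
  fx13 <- window_fixture(108)   # p = 13, other edge
  expect_equal(nrow(validate_sites(fx13$sites, fx13$signals)), 0L)
  fx8 <- window_fixture(113)    # p = 8: in-window, non-canonical
  got <- validate_sites(fx8$sites, fx8$signals)
  expect_equal(got$p, 8L)
  expect_false(got$canonical)
})

test_that("fewer than two distinct signatures is not evidence", {
  fx <- window_fixture(111, n_sig = 1L)
  expect_equal(nrow(validate_sites(fx$sites, fx$signals)), 0L)
  expect_equal(nrow(validate_sites(fx$sites, fx$signals,
                                   min_signatures = 1L)), 1L)
})

test_that("category cutoff suppresses sites buried in noise", {
  fx <- window_fixture(111, rpm = 4)
  # drown the site signal under bigger peaks elsewhere
  noise <- data.frame(transcript_id = "t.1",
                      five_prime_pos = c(10L, 300L, 350L),
                      library_id = "D1", rpm = c(50, 40, 30),
                      n_distinct_signatures = 1L)
  signals <- rbind(fx$signals, noise)
  expect_equal(nrow(validate_sites(fx$sites, signals)), 0L)
  got <- validate_sites(fx$sites, signals, max_category = 3L)
  expect_equal(got$category, 3L)
})

test_that("window coordinates invert exactly for all p in 8..12", {
  end <- 200L
  for (p in 8:12) {
    tpos <- end - p + 1L
    expect_equal(end - tpos + 1L, p)
  }
  fx <- window_fixture(111)
  expect_error(validate_sites(fx$sites, fx$signals, window = integer(0)),
               "empty")
})

test_that("t-plot export returns signal rows plus site spans", {
  fx <- window_fixture(111)
  tab <- export_tplot_data("t.1", "D1", fx$signals, fx$sites)
  expect_equal(sum(tab$type == "signal"), nrow(fx$signals))
  expect_equal(sum(tab$type == "site"), 1L)
  expect_equal(tab$start[tab$type == "site"], 101L)
  expect_error(export_tplot_data("nope.1", "D1", fx$signals, fx$sites),
               "no degradome signals")
})
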