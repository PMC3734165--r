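# RPM normalization and the two-group enrichment rules.

make_rpm <- function(tab) {
  # tab: named list sequence -> named rpm vector; build matrix directly
  libs <- unique(unlist(lapply(tab, names)))
  m <- matrix(0, length(tab), length(libs),
              dimnames = list(names(tab), libs))
  for (s in names(tab)) m[s, names(tab[[s]])] <- tab[[s]]
  m
}

test_that("RPM follows count / total x 1e6, absent species scoring 0", {
  l1 <- srna_library(c(AAGG = 30), "L1", "root_tip",
                     total_reads = 10000000)
  l2 <- srna_library(c(CCGG = 1), "L2", "whole_root")
  rpm <- normalize_rpm(list(l1, l2))
  expect_equal(rpm["AAGG", "L1"], 3.0)
  expect_equal(rpm["AAGG", "L2"], 0)
  expect_equal(rpm["CCGG", "L2"], 1e6)  # count 1, total 1
  expect_error(normalize_rpm(list(
    srna_library(setNames(numeric(0), character(0)), "Z", "root_tip"))),
    "total_reads = 0")
})

test_that("per-library RPM sums to 1e6 x table sum / total", {
  set.seed(7)
  cnt <- setNames(sample(1:50, 100, replace = TRUE),
                  replicate(100, paste(sample(c("A", "C", "G", "U"), 21,
                                              replace = TRUE),
                                       collapse = "")))
  lib <- srna_library(cnt, "L", "root_tip")
  rpm <- normalize_rpm(list(lib))
  expect_equal(sum(rpm[, "L"]), 1e6, tolerance = 1e-9)
  # explicit total beyond the table scales the sum down proportionally
  lib2 <- srna_library(cnt, "L", "root_tip",
                       total_reads = 2 * lib$total_reads)
  expect_equal(sum(normalize_rpm(list(lib2))), 5e5, tolerance = 1e-9)
})

test_that("compartment rule: one library must clear both thresholds", {
  rpm <- make_rpm(list(
    s1 = c(A1 = 9, A2 = 0, A3 = 0, B1 = 2.9, B2 = 1.0),  # passes via A1
    s2 = c(A1 = 9, B1 = 3.1, B2 = 0),                     # 9 < 3 x 3.1
    s3 = c(A1 = 3.0, B1 = 0, B2 = 0),                     # boundary pass
    s4 = c(A1 = 2.9, A2 = 2.9, A3 = 2.9, B1 = 0)))        # below min_rpm
  res <- filter_compartment_enriched(rpm, c("A1", "A2", "A3"),
                                     c("B1", "B2"))
  expect_equal(res$passed[match(paste0("s", 1:4), res$sequence)],
               c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(res$qualifying_libraries[res$sequence == "s1"], "A1")
})

test_that("AGO1 rule matches the same shape against the control", {
  rpm <- make_rpm(list(
    s1 = c(G1 = 10, G2 = 0, G3 = 0, C1 = 3),   # 10 >= 3 x 3
    s2 = c(G1 = 0, G2 = 0, G3 = 0, C1 = 5)))   # undetectable in AGO
  res <- filter_ago1_enriched(rpm, c("G1", "G2", "G3"), "C1")
  expect_true(res$passed[res$sequence == "s1"])
  expect_false(res$passed[res$sequence == "s2"])
  # candidates restrict the tested universe (serial pipeline wiring)
  res2 <- filter_ago1_enriched(rpm, c("G1", "G2", "G3"), "C1",
                               candidates = "s2")
  expect_equal(res2$sequence, "s2")
})

test_that("filter matches a brute-force oracle on random profiles", {
  set.seed(11)
  rpm <- random_rpm_matrix(300, c("A1", "A2", "B1", "B2"))
  res <- filter_enriched(rpm, c("A1", "A2"), c("B1", "B2"))
  expect_setequal(res$sequence[res$passed],
                  oracle_pass_set(rpm, c("A1", "A2"), c("B1", "B2")))
})

test_that("raising thresholds never adds sequences (monotonicity)", {
  set.seed(13)
  rpm <- random_rpm_matrix(200, c("A1", "A2", "B1"))
  base <- filter_enriched(rpm, c("A1", "A2"), "B1", 3, 3)
  for (params in list(c(5, 3), c(3, 5), c(6, 6))) {
    tight <- filter_enriched(rpm, c("A1", "A2"), "B1",
                             params[1], params[2])
    expect_true(all(tight$sequence[tight$passed] %in%
                      base$sequence[base$passed]))
  }
})

test_that("swapped groups give the other compartment; pass sets disjoint", {
  set.seed(17)
  rpm <- random_rpm_matrix(400, c("A1", "A2", "B1", "B2"))
  fwd <- filter_compartment_enriched(rpm, c("A1", "A2"), c("B1", "B2"))
  rev <- filter_compartment_enriched(rpm, c("B1", "B2"), c("A1", "A2"))
  expect_length(intersect(fwd$sequence[fwd$passed],
                          rev$sequence[rev$passed]), 0L)
})

test_that("group misuse is rejected", {
  rpm <- make_rpm(list(s1 = c(A1 = 5, B1 = 1)))
  expect_error(filter_enriched(rpm, "A1", "A1"), "disjoint")
  expect_error(filter_enriched(rpm, character(0), "B1"))
  expect_error(filter_enriched(rpm, "A1", "missing_lib"), "absent")
})
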