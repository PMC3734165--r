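# Contrary-expression contrasts: grouping, oriented folds, planted recovery.

# small matrix builder: one gene per row of `zone_means` (8 zones x 3 reps)
zones8 <- c("root_cap", "division_zone", "elongation_zone",
            paste0("maturation_zone_", c("I", "II", "III", "IV", "V")))

em_from_zone_means <- function(zone_means) {
  samples <- paste0(rep(zones8, each = 3), "_rep", 1:3)
  vals <- zone_means[, rep(seq_along(zones8), each = 3), drop = FALSE]
  colnames(vals) <- samples
  expression_matrix(vals, setNames(rep(zones8, each = 3), samples))
}

test_that("root-tip mean pools root cap + division zone; whole-root all", {
  zm <- matrix(c(0.028, 0.028, rep((8 * 0.125 - 2 * 0.028) / 6, 6)),
               nrow = 1, dimnames = list("g1", zones8))
  # whole-root mean = (2 x 0.028 + 6 x other)/8 = 0.125 by construction
  em <- em_from_zone_means(zm)
  ct <- contrast_expression(em, "g1", "root_tip")
  expect_equal(ct$mean_root_tip, 0.028, tolerance = 1e-12)
  expect_equal(ct$mean_whole_root, 0.125, tolerance = 1e-9)
  # quotient of the tip and whole-root means, as recomputed from them
  expect_equal(ct$fold, 0.125 / 0.028, tolerance = 1e-9)
  expect_true(ct$contrary)
})

test_that("whole-root-enriched regulators orient the fold the other way", {
  zm <- matrix(c(4.185, 4.185, rep((8 * 1.736 - 2 * 4.185) / 6, 6)),
               nrow = 1, dimnames = list("g1", zones8))
  em <- em_from_zone_means(zm)
  ct <- contrast_expression(em, "g1", "whole_root")
  expect_equal(ct$mean_root_tip, 4.185, tolerance = 1e-9)
  expect_equal(ct$mean_whole_root, 1.736, tolerance = 1e-9)
  expect_equal(ct$fold, 4.185 / 1.736, tolerance = 1e-9)
  expect_equal(round(ct$fold, 2), 2.41)
  expect_true(ct$contrary)
})

test_that("equal means sit exactly on the min_fold = 1 boundary", {
  zm <- matrix(1, nrow = 1, ncol = 8, dimnames = list("g1", zones8))
  em <- em_from_zone_means(zm)
  ct <- contrast_expression(em, "g1", "root_tip", min_fold = 1.0)
  expect_equal(ct$fold, 1.0)
  expect_true(ct$contrary)
  expect_false(contrast_expression(em, "g1", "root_tip",
                                   min_fold = 1.0001)$contrary)
})

test_that("folds are invariant to global rescaling of the matrix", {
  set.seed(31)
  zm <- matrix(exp(rnorm(3 * 8)), nrow = 3,
               dimnames = list(paste0("g", 1:3), zones8))
  em1 <- em_from_zone_means(zm)
  em2 <- em_from_zone_means(zm * 37.5)
  ct1 <- contrast_expression(em1, paste0("g", 1:3), "root_tip")
  ct2 <- contrast_expression(em2, paste0("g", 1:3), "root_tip")
  expect_equal(ct1$fold, ct2$fold, tolerance = 1e-12)
  expect_equal(ct1$contrary, ct2$contrary)
})

test_that("genes absent from the matrix are marked, not counted", {
  zm <- matrix(1, nrow = 1, ncol = 8, dimnames = list("g1", zones8))
  em <- em_from_zone_means(zm)
  ct <- contrast_expression(em, c("g1", "ghost"), "root_tip")
  expect_true(ct$missing[ct$gene_id == "ghost"])
  expect_true(is.na(ct$contrary[ct$gene_id == "ghost"]))
  expect_equal(sum(ct$contrary, na.rm = TRUE), 1)
})

test_that("planted contrary genes are recovered; non-planted stay quiet", {
  synth <- default_synth()
  zf <- read.delim(file.path(synth$data_dir, "zones.tsv"))
  em <- read_expression_matrix(file.path(synth$data_dir, "expression.tsv"),
                               setNames(zf$zone, zf$sample_id))
  truth <- synth$gen$truth$contrary_genes
  ct <- contrast_expression(em, truth$gene_id, truth$srna_compartment,
                            min_fold = 1.5)
  expect_true(all(ct$contrary))
  others <- setdiff(rownames(em$values), truth$gene_id)
  for (comp in c("root_tip", "whole_root")) {
    ct0 <- contrast_expression(em, others, comp, min_fold = 2.0)
    expect_false(any(ct0$contrary))
  }
})
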