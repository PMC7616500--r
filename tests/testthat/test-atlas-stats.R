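test_that("qc_filter applies the three strict boundary rules in order", {
  res <- qc_filter(qc_fixture())
  expect_setequal(res$kept_cells, c(paste0("S", 1:6), "C200", "CM_keep"))
  expect_false("C199" %in% res$kept_cells)   # fewer than 200 genes
  expect_false("CM_drop" %in% res$kept_cells) # over 10% mito
  expect_false("H4" %in% res$kept_genes)     # less than five cells
  expect_true("H5" %in% res$kept_genes)
  expect_equal(res$report$order,
               c("cell_gene_count", "gene_cell_count", "mito_fraction"))
  expect_equal(res$report$cells_removed_low_genes, 1L)
  expect_equal(res$report$genes_removed_low_cells, 1L)
  expect_equal(res$report$cells_removed_mito, 1L)

  # second pass removes nothing on this cascade-free fixture
  res2 <- qc_filter(res$counts)
  expect_identical(dim(res2$counts), dim(res$counts))

  # no mito genes: filter skipped with a recorded warning
  nm <- qc_fixture()[setdiff(rownames(qc_fixture()), "MT-ND1"), ]
  resn <- qc_filter(nm)
  expect_match(resn$report$warnings, "mito filter skipped")
  expect_true("CM_drop" %in% resn$kept_cells)

  expect_error(qc_filter(matrix(0, 0, 0)), "empty")
})

test_that("estimate_age evaluates the CRL formula and PCW rendering", {
  a <- estimate_age(15.1)
  expect_equal(a$days, 0.9022 * 15.1 + 27.372)
  expect_equal(a$pcw, "PCW5.6")   # round(40.995) = 41 = 5*7 + 6
  expect_equal(a$pcw_week, 5)
  expect_equal(a$pcw_day, 6)
  # divmod boundary: days exactly 35 -> PCW5.0
  crl35 <- (35 - 27.372) / 0.9022
  expect_equal(estimate_age(crl35)$pcw, "PCW5.0")
  expect_error(estimate_age(0), "positive")
})

test_that("fraction_odds_ratio matches hand arithmetic and corrects zeros", {
  expect_equal(as.numeric(fraction_odds_ratio(30, 100, 30, 100)), 1)
  or <- fraction_odds_ratio(60, 100, 10, 100)
  expect_equal(as.numeric(or), (0.6 / 0.4) / (0.1 / 0.9))  # 13.5
  expect_false(attr(or, "corrected"))
  orz <- fraction_odds_ratio(10, 100, 0, 100)
  expect_true(attr(orz, "corrected"))
  expect_true(is.finite(orz) && orz > 0)
  expect_equal(as.numeric(orz), (10.5 / 90.5) / (0.5 / 100.5))
  # reciprocal symmetry when no correction triggers
  set.seed(8)
  for (i in 1:10) {
    k <- sample(1:99, 2)
    expect_equal(as.numeric(fraction_odds_ratio(k[1], 100, k[2], 100)) *
                   as.numeric(fraction_odds_ratio(k[2], 100, k[1], 100)), 1)
  }
  expect_error(fraction_odds_ratio(5, 0, 1, 10), "positive")
  expect_error(fraction_odds_ratio(11, 10, 1, 10), "0 <= k <= n")
})

test_that("select_biased_genes recovers exactly the planted OR sets", {
  fx <- biased_fixture()
  sm <- group_expression_summary(fx$counts, fx$groups)
  expect_equal(sm$odds_ratio[sm$gene == "PLANT13"], 13.5)
  expect_equal(sm$odds_ratio[sm$gene == "PLANT30"],
               (0.5 / 0.5) / ((3 / 100) / (97 / 100)))
  pd <- select_biased_genes(sm, "proximal_distal")
  expect_identical(pd$up, "PLANT30")
  expect_length(pd$down, 0)
  fh <- select_biased_genes(sm, "fore_hind")
  expect_setequal(fh$up, c("PLANT30", "PLANT13"))
  # OR exactly at the cut-off is selected (inclusive semantics)
  sm30 <- data.frame(gene = "EDGE", odds_ratio = 30)
  expect_identical(select_biased_genes(sm30, "proximal_distal")$up, "EDGE")
  expect_error(select_biased_genes(sm, "dorsoventral"))
})

test_that("run_nmf recovers planted block structure deterministically", {
  set.seed(10)
  ab <- rbind(cbind(matrix(runif(40, 4, 6), 20, 2), matrix(0, 20, 2)),
              cbind(matrix(0, 20, 2), matrix(runif(40, 4, 6), 20, 2)))
  colnames(ab) <- paste0("ct", 1:4)
  nmf <- run_nmf(ab, n_environments = 2, seed = 5)
  expect_identical(nmf$loadings, run_nmf(ab, 2, seed = 5)$loadings)
  expect_true(all(nmf$loadings >= 0))
  expect_equal(colSums(nmf$fractions), rep(1, 4), ignore_attr = TRUE)
  # each block's cell types put >= 0.95 of their mass on one environment
  expect_true(all(apply(nmf$fractions, 2, max) >= 0.95))
  blk1 <- which.max(nmf$fractions[, "ct1"])
  expect_equal(which.max(nmf$fractions[, "ct2"]), blk1)
  expect_true(which.max(nmf$fractions[, "ct3"]) != blk1)

  # reconstruction error non-increasing with more environments
  errs <- vapply(1:3, function(k) run_nmf(ab, k, seed = 2)$reconstruction_error,
                 numeric(1))
  expect_true(all(diff(errs) <= 1e-6))

  expect_error(run_nmf(ab, 4), "smaller")
  expect_error(run_nmf(-ab, 2), "nonnegative")
})

test_that("microenvironment membership uses strict per-cell-type fractions", {
  H <- matrix(c(0.5, 0.3, 0.2), 3, 1,
              dimnames = list(paste0("env", 1:3), "ct1"))
  m <- microenvironment_membership(H)
  expect_identical(as.vector(m), c(TRUE, TRUE, FALSE))  # 0.2 excluded, strict
  expect_true(microenvironment_membership(matrix(2, 1, 1))[1, 1])
  expect_identical(as.vector(microenvironment_membership(matrix(1, 4, 1))),
                   rep(TRUE, 4))  # four 0.25 fractions all members
  # threshold 0 equals the support; threshold 1 is empty
  H2 <- matrix(c(0, 1, 2, 0, 0, 3), 3, 2)
  expect_identical(microenvironment_membership(H2, 0), H2 > 0)
  expect_false(any(microenvironment_membership(H2, 1)))
  expect_error(microenvironment_membership(matrix(0, 2, 1)), "all-zero")
})
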