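test_that("truth labelling accepts boundary mismatches and flags novel exons", {
  ann <- tibble::tibble(seq_id = "s", start = c(100L, 500L),
                        end = c(200L, 600L), strand = c("+", "-"))
  pred <- tibble::tibble(seq_id = "s",
                         start = c(100L, 199L, 300L, 510L, 510L),
                         end = c(200L, 260L, 360L, 590L, 590L),
                         strand = c("+", "+", "+", "-", "+"))
  lab <- label_predictions(pred, ann)
  expect_equal(lab$truth, c("true_positive",  # exact match
                            "true_positive",  # 1 bp overlap accepted
                            "false_positive", # unannotated sequence
                            "true_positive",  # inside, same strand
                            "false_positive")) # inside but wrong strand
  # unstranded annotations match both strands
  ann2 <- dplyr::mutate(ann, strand = "*")
  expect_equal(label_predictions(pred, ann2)$truth[5], "true_positive")
  expect_error(label_predictions(dplyr::mutate(pred, end = start), ann),
               class = "codonscan_malformed_interval")
})

test_that("evaluation metrics reproduce the printed-count arithmetic", {
  tab <- evaluation_table(1818L, 1243L)
  expect_equal(tab$ppv, 1818 / 3061, tolerance = 1e-12)
  expect_true(is.na(tab$sensitivity))
  tab2 <- evaluation_table(1345L, 262L, fn = 100L)
  expect_equal(tab2$sensitivity, 1345 / 1445)
  expect_equal(tab2$fpr, 262 / 1445)
})

test_that("filter-effect chi-square equals the hand-computed Pearson statistic", {
  chi_hand <- function(m) {
    E <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - E)^2 / E)
  }
  got <- chi_square_filter_effect(c(1818, 1243), c(1345, 262))
  expect_equal(got$statistic,
               chi_hand(rbind(c(1818, 1243), c(1345, 262))),
               tolerance = 1e-9)
  expect_equal(got$statistic, 284.9239, tolerance = 1e-4)
  expect_equal(got$df, 1)
  expect_lt(got$p_value, 1e-10)

  # identical proportions give statistic 0; swapping rows changes nothing
  expect_equal(chi_square_filter_effect(c(100, 50), c(200, 100))$statistic,
               0, tolerance = 1e-9)
  expect_equal(chi_square_filter_effect(c(1345, 262), c(1818, 1243))$statistic,
               got$statistic, tolerance = 1e-9)
  expect_error(chi_square_filter_effect(c(0, 0), c(1, 2)),
               class = "codonscan_degenerate_table")
})

test_that("exon testing passes coding windows and rejects null windows", {
  mat <- fx_matrix()
  calib <- fx_calibration()
  spec <- mosaic_spec(9000L,
                      tibble::tibble(start = c(1500L, 5100L),
                                     n_codons = c(100L, 80L),
                                     strand = c("+", "-")),
                      seed = 404L)
  mz <- build_mosaic(spec)
  calls <- tibble::tibble(
    seq_id = "mosaic",
    start = c(1500L, 5100L, 7500L, 20000L),
    end = c(1800L, 5340L, 7800L, 20300L),
    strand = c("+", "-", "+", "+"))
  tested <- test_exons(calls, mz$alignment, mat, calib, alpha = 0.01)
  expect_equal(tested$verdict[1:2], c("pass", "pass"))
  # minus-strand coding block is found on the reverse strand
  expect_equal(tested$best_strand[2], "-")
  # pure-null window fails
  expect_equal(tested$verdict[3], "fail")
  # out-of-range exon is unmappable, not an error
  expect_equal(tested$verdict[4], "fail")
  expect_equal(tested$reason[4], "unmappable")
  expect_true(is.na(tested$p_value[4]))

  # a zero-contrast matrix yields no positive segment and p = 1
  flat <- mat
  flat$scores[] <- 0
  tested0 <- test_exons(calls[1, ], mz$alignment, flat, calib)
  expect_equal(tested0$verdict, "fail")
  expect_equal(tested0$reason, "no_positive_segment")
  expect_equal(tested0$p_value, 1)
})

test_that("evaluation before/after filtering shrinks componentwise", {
  mat <- fx_matrix()
  calib <- fx_calibration()
  spec <- mosaic_spec(12000L,
                      tibble::tibble(start = c(1200L, 4800L, 8700L),
                                     n_codons = c(120L, 90L, 100L),
                                     strand = c("+", "+", "-")),
                      seed = 505L)
  mz <- build_mosaic(spec)
  preds <- simulate_predictions(mz$annotations, 12000L, n_false = 6L,
                                seed = 506L)
  calls <- label_predictions(preds, mz$annotations)
  calls <- test_exons(calls, mz$alignment, mat, calib, alpha = 0.01)
  ev <- evaluate_calls(calls, mz$annotations)
  expect_equal(ev$phase, c("before", "after"))
  expect_lte(ev$tp[2], ev$tp[1])
  expect_lte(ev$fp[2], ev$fp[1])
  expect_gte(ev$fn[2], ev$fn[1])
  expect_equal(ev$ppv, ev$tp / (ev$tp + ev$fp))

  # when everything passes, before equals after
  all_pass <- dplyr::mutate(calls, verdict = "pass")
  ev2 <- evaluate_calls(all_pass, mz$annotations)
  expect_equal(ev2[ev2$phase == "before", -1], ev2[ev2$phase == "after", -1])
})

test_that("ROC points are threshold-nested and reproduce the unfiltered endpoint", {
  mat <- fx_matrix()
  calib <- fx_calibration()
  spec <- mosaic_spec(9000L,
                      tibble::tibble(start = c(900L, 4200L),
                                     n_codons = c(110L, 130L),
                                     strand = c("+", "+")),
                      seed = 606L)
  mz <- build_mosaic(spec)
  preds <- simulate_predictions(mz$annotations, 9000L, n_false = 5L,
                                seed = 607L)
  calls <- label_predictions(preds, mz$annotations)
  calls <- test_exons(calls, mz$alignment, mat, calib)
  roc <- roc_points(calls, mz$annotations,
                    alpha_grid = c(1e-6, 1e-3, 0.01, 0.1, 1),
                    total_length = 9000L)
  expect_true(!is.unsorted(roc$tpr))
  expect_true(!is.unsorted(roc$fp))
  # alpha = 1 admits every mappable prediction: the unfiltered point
  pred_ir <- IRanges::reduce(IRanges::IRanges(calls$start + 1L, calls$end))
  ann_ir <- IRanges::reduce(IRanges::IRanges(mz$annotations$start + 1L,
                                             mz$annotations$end))
  tp_all <- sum(IRanges::width(IRanges::intersect(pred_ir, ann_ir)))
  expect_equal(roc$tp[roc$alpha == 1], tp_all)
  expect_true(all(roc$fpr_std >= 0 & roc$fpr_std <= 1, na.rm = TRUE))
})

test_that("length-binned PPV is consistent with the global evaluation", {
  calls <- tibble::tibble(
    seq_id = "s",
    start = c(0L, 400L, 900L, 1500L) * 3L,
    end = c(0L, 400L, 900L, 1500L) * 3L + c(60L, 90L, 600L, 360L),
    strand = "+",
    truth = c("false_positive", "true_positive", "true_positive",
              "false_positive"),
    verdict = c("fail", "pass", "pass", "fail"))
  one_bin <- bin_ppv_by_exon_length(calls, c(0, Inf))
  expect_equal(one_bin$ppv_before, 0.5)
  expect_equal(one_bin$ppv_after, 1)
  binned <- bin_ppv_by_exon_length(calls, c(0, 100, 200, Inf))
  expect_equal(nrow(binned), 3L)
  # middle bin (100-200 codons) holds only the filtered-out 120-codon FP
  expect_equal(binned$n_before, c(2L, 1L, 1L))
  expect_true(is.na(binned$ppv_after[2]))
})
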