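test_that("frame extraction yields six views with block-wise framing", {
  fv <- frame_views(pairwise_alignment("ATGAAATTT", "ATGAAATTC"))
  expect_length(fv, 6L)
  expect_named(fv, c("+0", "+1", "+2", "-0", "-1", "-2"))
  expect_equal(vapply(fv, nrow, 0L), c(`+0` = 3L, `+1` = 2L, `+2` = 2L,
                                       `-0` = 3L, `-1` = 2L, `-2` = 2L))

  # a gap column splits the alignment; framing restarts per gap-free block
  aln <- pairwise_alignment("ATGA-AATTTGG", "ATGACAATTTGG")
  v0 <- frame_views(aln)[["+0"]]
  expect_equal(nrow(v0), 3L)
  expect_equal(v0$col_start, c(1L, 6L, 9L))
  expect_true(all(diff(v0$col_start) > 0))

  # too short for any codon: zero-row views, no error
  tiny <- frame_views(pairwise_alignment("AT", "AT"))
  expect_true(all(vapply(tiny, nrow, 0L) == 0L))
})

test_that("reverse-strand views are the reverse complement's forward views", {
  aln <- pairwise_alignment("ATGAAATTTCC", "ATGAAATTCCC")
  rc <- reverse_complement_alignment(aln)
  fwd_of_rc <- frame_views(rc)[["+0"]]
  rev_view <- frame_views(aln)[["-0"]]
  expect_equal(rev_view$codon_a, fwd_of_rc$codon_a)
  expect_equal(rev_view$codon_b, fwd_of_rc$codon_b)
  # reverse-strand origin columns are mirrored into original coordinates
  L <- alignment_length(aln)
  expect_equal(sort(rev_view$col_start),
               sort(L + 1L - fwd_of_rc$col_end))
})

test_that("region scores are additive sums of codon-pair scores", {
  mat <- fx_matrix()
  view <- frame_views(simulate_coding_alignment(
    coding_model(n_codons = 30L, seed = 7L)))[["+0"]]
  expect_identical(region_score(view, mat, 0L, 0L), 0)
  whole <- region_score(view, mat)
  expect_equal(region_score(view, mat, 0L, 12L) +
                 region_score(view, mat, 12L, nrow(view)),
               whole, tolerance = 1e-9)
  percodon <- score_codon_pair(mat, view$codon_a, view$codon_b)
  expect_equal(whole, sum(percodon), tolerance = 1e-9)
  expect_error(region_score(view, mat, 0L, nrow(view) + 1L),
               class = "codonscan_range_error")
})

test_that("all_maximal_segments matches hand-worked cases", {
  out <- all_maximal_segments(c(1, -2, 3, -1, 2))
  expect_equal(out$start, c(0L, 2L))
  expect_equal(out$end, c(1L, 5L))
  expect_equal(out$score, c(1, 4))
  expect_equal(nrow(all_maximal_segments(c(-1, -0.5, -2))), 0L)
  allpos <- all_maximal_segments(c(0.5, 1, 2))
  expect_equal(allpos$start, 0L)
  expect_equal(allpos$end, 3L)
  expect_equal(allpos$score, 3.5)
})

test_that("all_maximal_segments agrees with brute force and is monotone in cutoff", {
  withr::local_seed(314)
  for (rep in 1:150) {
    n <- sample(1:120, 1L)
    x <- if (rep %% 2) random_dyadic_scores(n) else sample(-3:3, n, TRUE)
    got <- as.data.frame(all_maximal_segments(x))
    expect_equal(got, oracle_maximal_segments(x), tolerance = 1e-12,
                 ignore_attr = TRUE)
    hi <- all_maximal_segments(x, cutoff = 1.5)
    expect_true(all(hi$score > 1.5))
    expect_true(nrow(hi) <= nrow(got))
    # every high-cutoff segment also appears at cutoff 0
    if (nrow(hi) > 0) {
      key <- paste(got$start, got$end)
      expect_true(all(paste(hi$start, hi$end) %in% key))
    }
  }
})

test_that("best_msp finds the maximum segment with deterministic ties", {
  mat <- fx_matrix()
  # hand-worked: per-codon scores (-1, 4, -2, 3) -> segment (1, 4), score 5
  fake_view <- tibble::tibble(strand = "+", frame = 0L,
                              codon_a = c("AAA", "ATG", "AAA", "ATG"),
                              codon_b = c("CCC", "ATG", "CCC", "ATG"),
                              col_start = c(1L, 4L, 7L, 10L),
                              col_end = c(3L, 6L, 9L, 12L))
  s <- score_codon_pair(mat, fake_view$codon_a, fake_view$codon_b)
  expect_true(s[2] > 0 && s[1] < 0)  # identity ATG pos, mismatch neg
  got <- best_msp(fake_view, mat)
  want <- oracle_best_segment(s)
  expect_equal(got$start_codon, want[1])
  expect_equal(got$end_codon, want[2])
  expect_equal(got$score, want[3], tolerance = 1e-9)

  # all non-positive -> no MSP
  neg_view <- fake_view[c(1L, 3L), ]
  expect_null(best_msp(neg_view, mat))

  withr::local_seed(99)
  for (rep in 1:100) {
    x <- if (rep %% 2) random_dyadic_scores(sample(1:40, 1))
         else sample(-3:3, sample(1:40, 1), TRUE)
    got <- codonscan:::best_subarray_cpp(x)
    expect_equal(as.numeric(got), as.numeric(oracle_best_segment(x)))
  }
})

test_that("best_msp dominates every enumerated segment of the same view", {
  mat <- fx_matrix()
  withr::local_seed(55)
  aln <- simulate_noncoding_pair(null_model(seq_length = 3000L))
  for (view in frame_views(aln)) {
    s <- score_codon_pair(mat, view$codon_a, view$codon_b)
    segs <- all_maximal_segments(s, 0)
    bm <- best_msp(view, mat)
    if (nrow(segs) > 0) {
      expect_gte(bm$score, max(segs$score) - 1e-12)
    }
  }
})

test_that("scan_alignment composes views, coordinates and strand symmetry", {
  mat <- fx_matrix()
  cds <- simulate_coding_alignment(coding_model(n_codons = 120L, seed = 13L))
  hits <- scan_alignment(cds, mat)
  expect_true(nrow(hits) > 0)
  f0 <- dplyr::filter(hits, strand == "+", frame == 0L)
  expect_gte(nrow(f0), 1L)
  # the frame-0 forward hit covers (nearly) the whole CDS
  expect_gte(max(f0$end_codon - f0$start_codon), 110L)
  expect_true(all(hits$col_start >= 1L & hits$col_end <= 360L))
  expect_true(!is.unsorted(hits$col_start))

  # reverse-complementing both rows mirrors coordinates, flips strand,
  # and preserves scores
  rc_hits <- scan_alignment(reverse_complement_alignment(cds), mat)
  expect_equal(nrow(rc_hits), nrow(hits))
  L <- alignment_length(cds)
  mirrored <- dplyr::arrange(
    dplyr::mutate(rc_hits,
                  m_start = L + 1L - col_end,
                  m_strand = ifelse(strand == "+", "-", "+")),
    m_start, m_strand, frame)
  orig <- dplyr::arrange(hits, col_start, strand, frame)
  expect_equal(mirrored$m_start, orig$col_start)
  expect_equal(mirrored$m_strand, orig$strand)
  expect_equal(sort(rc_hits$score), sort(hits$score), tolerance = 1e-9)

  # degenerate input
  expect_equal(nrow(scan_alignment(pairwise_alignment("", ""), mat)), 0L)

  # a calibration attaches p-values and a significance-derived cutoff
  calib <- fx_calibration()
  hits_p <- scan_alignment(cds, mat, calibration = calib, cutoff_p = 0.05)
  expect_true(all(hits_p$p_value <= 0.05 + 1e-12))
  expect_true(all(hits_p$p_value >= 0 & hits_p$p_value <= 1))
})
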