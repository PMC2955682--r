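test_that("codon-pair counting follows the indel/ambiguity exclusion rule", {
  cc <- count_codon_pairs(pairwise_alignment("ATG", "ATG"))
  expect_equal(cc$counts["ATG", "ATG"], 1L)
  expect_equal(cc$total_pairs, 1L)

  # gap anywhere in a codon column knocks out that column only
  cc <- count_codon_pairs(pairwise_alignment("ATG-AA", "ATGCAA"))
  expect_equal(cc$total_pairs, 1L)
  expect_equal(cc$counts["ATG", "ATG"], 1L)

  # ambiguity codes are excluded the same way
  cc <- count_codon_pairs(pairwise_alignment("ATGNTT", "ATGCTT"))
  expect_equal(cc$total_pairs, 1L)

  # counts accumulate across alignments; trailing partial codons ignored
  cc <- count_codon_pairs(list(pairwise_alignment("ATGAAAC", "ATGAAGC"),
                               pairwise_alignment("TTT", "TTT")))
  expect_equal(cc$total_pairs, 3L)
  expect_equal(cc$counts["AAA", "AAG"], 1L)
  expect_equal(sum(cc$counts), cc$total_pairs)
})

test_that("malformed and empty count inputs are handled per contract", {
  expect_error(pairwise_alignment("ATGC", "ATG"),
               class = "codonscan_malformed_alignment")
  cc <- count_codon_pairs(list())
  expect_equal(cc$total_pairs, 0L)
  expect_true(all(cc$counts == 0L))
  expect_error(codon_matrix(cc), class = "codonscan_empty_counts")
})

test_that("log-odds scores follow the ln(observed/expected) definition", {
  # uniform counts: observed equals expected everywhere, all scores 0
  cc <- count_codon_pairs(pairwise_alignment("ATG", "ATG"))
  cc$counts <- matrix(2L, 64L, 64L, dimnames = dimnames(cc$counts))
  cc$total_pairs <- sum(cc$counts)
  m <- codon_matrix(cc, pseudocount = 0.5)
  expect_equal(max(abs(m$scores)), 0, tolerance = 1e-12)
  expect_equal(sum(m$marginals), 1, tolerance = 1e-9)

  # two-codon toy table with q(a,b) = 2 f(a) f(b): score is ln 2, and the
  # never-observed diagonal hits the -Inf sentinel at pseudocount 0
  cc$counts[] <- 0L
  cc$counts["AAA", "AAC"] <- 1L
  cc$counts["AAC", "AAA"] <- 1L
  cc$total_pairs <- 2L
  m0 <- codon_matrix(cc, pseudocount = 0)
  expect_equal(m0$scores["AAA", "AAC"], log(2), tolerance = 1e-12)
  expect_identical(m0$scores["AAA", "AAA"], -Inf)
})

test_that("matrix is symmetric, zero-preserving and order-invariant", {
  mat <- fx_matrix()
  expect_equal(mat$scores, t(mat$scores), tolerance = 1e-12)
  expect_equal(sum(mat$marginals), 1, tolerance = 1e-9)
  expect_gt(mean(diag(mat$scores)), 0)
  expect_gt(score_codon_pair(mat, "ATG", "ATG"), 0)
  expect_equal(score_codon_pair(mat, "AAA", "GAA"),
               score_codon_pair(mat, "GAA", "AAA"))

  # permuting the input alignments changes nothing
  tr <- fx_training()[1:40]
  m1 <- build_codon_matrix(tr)
  m2 <- build_codon_matrix(rev(tr))
  expect_identical(m1$scores, m2$scores)
})

test_that("synonymous pairs outscore nonsynonymous pairs at equal distance", {
  mat <- fx_matrix()
  gc <- Biostrings::GENETIC_CODE
  labs <- codon_labels()
  aa <- as.character(gc)[match(labs, names(gc))]
  syn <- numeric(0)
  non <- numeric(0)
  for (i in seq_along(labs)) {
    for (j in seq_along(labs)) {
      if (i == j || aa[i] == "*" || aa[j] == "*") next
      ndiff <- sum(strsplit(labs[i], "")[[1]] != strsplit(labs[j], "")[[1]])
      if (ndiff != 1L) next
      s <- mat$scores[i, j]
      if (aa[i] == aa[j]) syn <- c(syn, s) else non <- c(non, s)
    }
  }
  expect_gt(mean(syn), mean(non))
})

test_that("score_codon_pair rejects gapped or ambiguous triplets", {
  mat <- fx_matrix()
  expect_error(score_codon_pair(mat, "AT-", "ATG"),
               class = "codonscan_invalid_codon")
  expect_error(score_codon_pair(mat, "ATG", "ANG"),
               class = "codonscan_invalid_codon")
})

test_that("matrix TSV serialisation round-trips and validates", {
  mat <- fx_matrix()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_codon_matrix(mat, path)
  back <- read_codon_matrix(path)
  expect_equal(back$scores, mat$scores, tolerance = 1e-12)
  expect_equal(back$marginals, mat$marginals, tolerance = 1e-12)
  expect_equal(back$pseudocount, mat$pseudocount)
  expect_equal(back$total_pairs, mat$total_pairs)
  expect_equal(back$provenance, mat$provenance)

  # rewrite of the re-read matrix is byte-identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_codon_matrix(back, path2)
  expect_identical(readLines(path), readLines(path2))

  # permuted columns are mapped by codon label, not file position
  lines <- readLines(path)
  hdr_i <- grep("^codon\t", lines)
  fields <- strsplit(lines[-seq_len(hdr_i)], "\t", fixed = TRUE)
  perm <- c(2:64, 1)  # rotate data columns
  lines[hdr_i] <- paste(c("codon", strsplit(lines[hdr_i], "\t")[[1]][-1][perm]),
                        collapse = "\t")
  for (r in seq_along(fields)) {
    lines[hdr_i + r] <- paste(c(fields[[r]][1], fields[[r]][-1][perm]),
                              collapse = "\t")
  }
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, path3)
  expect_equal(read_codon_matrix(path3)$scores, mat$scores,
               tolerance = 1e-12)

  # truncated and corrupted files name a line
  path4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(head(readLines(path), -1L), path4)
  expect_error(read_codon_matrix(path4), class = "codonscan_matrix_parse")
  lines5 <- readLines(path)
  lines5[hdr_i + 3L] <- sub("\t[-0-9.e]+$", "\tnot_a_number", lines5[hdr_i + 3L])
  path5 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines5, path5)
  expect_error(read_codon_matrix(path5), class = "codonscan_matrix_parse",
               regexp = "line")
})
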