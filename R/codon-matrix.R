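#' Count aligned codon pairs in in-frame CDS alignments
#'
#' Walks each alignment in steps of three columns starting at column 1 (the
#' reading frame of the first row), and counts one codon pair per codon
#' column in which both triplets consist solely of `A C G T`. Codon columns
#' overlapping a gap or an ambiguity code contribute nothing, matching the
#' exclusion of insertions, deletions and undetermined sequence from matrix
#' training. Counts accumulate across alignments.
#'
#' @param alignments A [pairwise_alignment()] or a list of them, each an
#'   in-frame aligned CDS pair.
#' @return An object of class `codon_pair_counts`: a list with `counts`
#'   (64 x 64 integer matrix, rows = codon of the first row, columns = codon
#'   of the second) and `total_pairs`.
#' @export
#' @examples
#' cc <- count_codon_pairs(pairwise_alignment("ATGAAA", "ATGAAG"))
#' cc$total_pairs
count_codon_pairs <- function(alignments) {
  if (inherits(alignments, "pairwise_alignment")) alignments <- list(alignments)
  counts <- matrix(0L, 64L, 64L, dimnames = list(codons, codons))
  total <- 0L
  for (aln in alignments) {
    if (!inherits(aln, "pairwise_alignment")) {
      abort("count_codon_pairs() expects pairwise_alignment objects")
    }
    ia <- encode_dna(aln$seq_a)
    ib <- encode_dna(aln$seq_b)
    n3 <- length(ia) %/% 3L
    if (n3 == 0L) next
    p1 <- 3L * seq_len(n3) - 2L
    ca <- 16L * ia[p1] + 4L * ia[p1 + 1L] + ia[p1 + 2L] + 1L
    cb <- 16L * ib[p1] + 4L * ib[p1 + 1L] + ib[p1 + 2L] + 1L
    ok <- !is.na(ca) & !is.na(cb)
    if (!any(ok)) next
    tab <- tabulate((cb[ok] - 1L) * 64L + ca[ok], nbins = 4096L)
    counts <- counts + matrix(tab, 64L, 64L)
    total <- total + sum(ok)
  }
  structure(list(counts = counts, total_pairs = as.integer(total)),
            class = "codon_pair_counts")
}

#' @export
print.codon_pair_counts <- function(x, ...) {
  cat(sprintf("<codon_pair_counts> %d codon pairs, %d non-zero cells\n",
              x$total_pairs, sum(x$counts > 0)))
  invisible(x)
}

#' Build a codon-pair log-odds matrix from codon-pair counts
#'
#' Counts are symmetrised (the direction of comparison between two genomes
#' is arbitrary), pseudocount mass is spread over cells in proportion to
#' the expected frequency of each pair, frequencies are formed, and each
#' cell is scored as the natural-log ratio of its observed frequency to the
#' product of the marginal codon frequencies:
#' `score(a, b) = ln(q(a, b) / (f(a) f(b)))`. A score of zero means the
#' pair is seen exactly as often as expected under independence; positive
#' scores mark pairs over-represented in coding alignments. Pairs never
#' observed in training (stop-codon pairs, for CDS training data) share a
#' uniform negative floor of `ln(4096 p / (T + 4096 p))` where `T` is the
#' total pair count.
#'
#' @param counts A `codon_pair_counts` object from [count_codon_pairs()].
#' @param pseudocount Total pseudocount mass per cell-equivalent, `p`
#'   (default 0.5): `4096 p` pseudo-observations are distributed over the
#'   64 x 64 table in proportion to expected pair frequencies. With
#'   `pseudocount = 0`, cells with zero counts score `-Inf`.
#' @param provenance Free-text metadata recorded with the matrix.
#' @return An object of class `codon_matrix`: a list with `scores` (64 x 64,
#'   nats), `marginals` (64 codon frequencies summing to 1), `pseudocount`,
#'   `total_pairs` and `provenance`.
#' @export
codon_matrix <- function(counts, pseudocount = 0.5, provenance = "") {
  stopifnot(inherits(counts, "codon_pair_counts"))
  if (counts$total_pairs <= 0L) {
    abort("cannot build a matrix from empty counts (total_pairs = 0)",
          class = "codonscan_empty_counts")
  }
  if (pseudocount < 0) abort("pseudocount must be >= 0")
  cc <- counts$counts
  sym <- (cc + t(cc)) / 2
  # Pseudocount mass is distributed in proportion to the expected frequency
  # of each pair (product of smoothed marginals), not flatly per cell: a
  # flat pseudocount gives never-observed codons (stop codons in CDS
  # training data) vanishing marginals and hence inflated log-odds, whereas
  # this scheme floors every unobserved pair at ln(4096 p / (T + 4096 p)).
  total <- counts$total_pairs
  f_hat <- (rowSums(sym) + 64 * pseudocount) / (total + 4096 * pseudocount)
  q <- (sym + 4096 * pseudocount * outer(f_hat, f_hat)) /
    (total + 4096 * pseudocount)
  scores <- log(q) - log(outer(f_hat, f_hat))
  dimnames(scores) <- list(codons, codons)
  structure(list(scores = scores, marginals = setNames(f_hat, codons),
                 pseudocount = pseudocount,
                 total_pairs = counts$total_pairs,
                 provenance = as.character(provenance)),
            class = "codon_matrix")
}

#' @export
print.codon_matrix <- function(x, ...) {
  cat(sprintf(paste0("<codon_matrix> 64 x 64 lod scores (nats), ",
                     "%d training pairs, pseudocount %g\n"),
              x$total_pairs, x$pseudocount))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Build a codon-pair matrix straight from alignments
#'
#' Convenience wrapper: [count_codon_pairs()] then [codon_matrix()].
#'
#' @inheritParams count_codon_pairs
#' @inheritParams codon_matrix
#' @return A `codon_matrix`.
#' @export
build_codon_matrix <- function(alignments, pseudocount = 0.5,
                               provenance = "") {
  codon_matrix(count_codon_pairs(alignments), pseudocount = pseudocount,
               provenance = provenance)
}

#' Score one codon pair
#'
#' Symmetric in its arguments (the matrix is symmetrised at build time).
#'
#' @param matrix A `codon_matrix`.
#' @param codon_a,codon_b Triplets over `A C G T` (vectors recycle).
#' @return Numeric scores in nats.
#' @export
score_codon_pair <- function(matrix, codon_a, codon_b) {
  stopifnot(inherits(matrix, "codon_matrix"))
  codon_a <- toupper(codon_a)
  codon_b <- toupper(codon_b)
  ia <- match(codon_a, codons)
  ib <- match(codon_b, codons)
  if (anyNA(ia) || anyNA(ib)) {
    bad <- unique(c(codon_a[is.na(ia)], codon_b[is.na(ib)]))
    abort(sprintf("invalid codon(s): %s (must be triplets over A/C/G/T)",
                  paste(bad, collapse = ", ")),
          class = "codonscan_invalid_codon")
  }
  matrix$scores[cbind(ia, ib)]
}

#' Tidy a codon matrix into a long tibble
#'
#' @param x A `codon_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `codon_a`, `codon_b`, `score`.
#' @export
tidy.codon_matrix <- function(x, ...) {
  tibble(codon_a = rep(codons, times = 64L),
         codon_b = rep(codons, each = 64L),
         score = as.vector(x$scores))
}

#' Write a codon matrix as TSV
#'
#' The format is plain TSV with `#` metadata lines (`log_base`,
#' `pseudocount`, `total_pairs`, `provenance`, and the 64 `marginal` values),
#' a header row of the 64 codon labels, and 64 data rows of a row label
#' followed by 64 scores. Scores survive a round trip to at least 12
#' significant digits.
#'
#' @param matrix A `codon_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_codon_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "codon_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# codonscan codon substitution matrix",
               "# log_base=e",
               sprintf("# pseudocount=%.17g", matrix$pseudocount),
               sprintf("# total_pairs=%d", matrix$total_pairs),
               sprintf("# provenance=%s", matrix$provenance),
               sprintf("# marginals=%s",
                       paste(sprintf("%.17g", matrix$marginals),
                             collapse = ","))), con)
  writeLines(paste(c("codon", codons), collapse = "\t"), con)
  for (i in seq_len(64L)) {
    writeLines(paste(c(codons[i], sprintf("%.17g", matrix$scores[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a codon matrix written by [write_codon_matrix()]
#'
#' Rows and columns are mapped by codon label, not file position, so a file
#' with a permuted header still loads correctly.
#'
#' @param path Path to the TSV file.
#' @return A `codon_matrix`.
#' @export
read_codon_matrix <- function(path) {
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta <- lines[meta_idx]
  body_idx <- setdiff(seq_along(lines), meta_idx)
  body_idx <- body_idx[nzchar(trimws(lines[body_idx]))]
  if (length(body_idx) != 65L) {
    abort(sprintf("matrix parse error: expected 65 non-comment lines (header + 64 rows), found %d",
                  length(body_idx)),
          class = "codonscan_matrix_parse")
  }
  get_meta <- function(key, default = "") {
    m <- grep(sprintf("^# %s=", key), meta, value = TRUE)
    if (length(m) == 0L) default else sub(sprintf("^# %s=", key), "", m[[1L]])
  }
  header <- strsplit(lines[body_idx[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) != 65L || header[1L] != "codon" ||
      !setequal(header[-1L], codons)) {
    abort(sprintf("matrix parse error at line %d: header must be 'codon' plus the 64 codon labels",
                  body_idx[1L]),
          class = "codonscan_matrix_parse")
  }
  col_map <- match(codons, header[-1L])
  scores <- matrix(NA_real_, 64L, 64L, dimnames = list(codons, codons))
  seen <- character(0)
  for (r in 2:65) {
    ln <- body_idx[r]
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 65L) {
      abort(sprintf("matrix parse error at line %d: expected 65 fields, found %d",
                    ln, length(fields)),
            class = "codonscan_matrix_parse")
    }
    lab <- fields[1L]
    if (!lab %in% codons || lab %in% seen) {
      abort(sprintf("matrix parse error at line %d: bad or duplicated row label '%s'",
                    ln, lab),
            class = "codonscan_matrix_parse")
    }
    vals <- suppressWarnings(as.numeric(fields[-1L]))
    bad <- which(is.na(vals) & !(fields[-1L] %in% c("Inf", "-Inf", "NaN", "NA")))
    if (length(bad) > 0L) {
      abort(sprintf("matrix parse error at line %d: non-numeric cell in column %d",
                    ln, bad[1L] + 1L),
            class = "codonscan_matrix_parse")
    }
    seen <- c(seen, lab)
    scores[lab, ] <- vals[col_map]
  }
  marg <- suppressWarnings(as.numeric(strsplit(get_meta("marginals"), ",",
                                               fixed = TRUE)[[1L]]))
  if (length(marg) != 64L || anyNA(marg)) {
    abort("matrix parse error: missing or malformed '# marginals=' metadata",
          class = "codonscan_matrix_parse")
  }
  structure(list(scores = scores, marginals = setNames(marg, codons),
                 pseudocount = as.numeric(get_meta("pseudocount", "NA")),
                 total_pairs = as.integer(get_meta("total_pairs", "0")),
                 provenance = get_meta("provenance")),
            class = "codon_matrix")
}
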