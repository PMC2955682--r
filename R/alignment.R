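#' Construct a pairwise DNA alignment
#'
#' A light container for two gapped DNA sequences of equal length, the unit
#' on which the codon-pair scanner operates. Sequences may contain `A C G T
#' N -`; other IUPAC ambiguity codes are normalised to `N`.
#'
#' @param seq_a,seq_b Gapped DNA strings of equal length.
#' @param id_a,id_b Record identifiers.
#' @return An object of class `pairwise_alignment`: a list with elements
#'   `seq_a`, `seq_b`, `id_a`, `id_b`.
#' @export
#' @examples
#' pairwise_alignment("ATG-AA", "ATGCAA")
pairwise_alignment <- function(seq_a, seq_b, id_a = "seq_a", id_b = "seq_b") {
  stopifnot(is.character(seq_a), is.character(seq_b),
            length(seq_a) == 1L, length(seq_b) == 1L)
  seq_a <- toupper(seq_a)
  seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) {
    abort(sprintf("malformed alignment: rows have unequal length (%d vs %d)",
                  nchar(seq_a), nchar(seq_b)),
          class = "codonscan_malformed_alignment")
  }
  seq_a <- gsub("[^ACGT-]", "N", seq_a)
  seq_b <- gsub("[^ACGT-]", "N", seq_b)
  structure(list(seq_a = seq_a, seq_b = seq_b,
                 id_a = as.character(id_a), id_b = as.character(id_b)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  L <- alignment_length(x)
  cat(sprintf("<pairwise_alignment> %s / %s, %d columns\n", x$id_a, x$id_b, L))
  show <- function(s) if (L > 60) paste0(substr(s, 1, 57), "...") else s
  cat(" ", show(x$seq_a), "\n ", show(x$seq_b), "\n")
  invisible(x)
}

#' Number of columns in a pairwise alignment
#' @param aln A [pairwise_alignment()].
#' @return Integer column count (gapped length).
#' @export
alignment_length <- function(aln) nchar(aln$seq_a)

#' Reverse-complement both rows of an alignment
#'
#' Both rows are complemented and reversed together, so column
#' correspondence is preserved; column `j` of the result is column
#' `L + 1 - j` of the input.
#'
#' @param aln A [pairwise_alignment()].
#' @return A `pairwise_alignment`.
#' @export
reverse_complement_alignment <- function(aln) {
  pairwise_alignment(revcomp_chr(aln$seq_a), revcomp_chr(aln$seq_b),
                     aln$id_a, aln$id_b)
}

#' Read pairwise alignments from aligned FASTA
#'
#' The file must contain an even number of records; consecutive records are
#' paired. With two records (the common case) a single alignment is
#' returned unless `paired = TRUE` forces a list.
#'
#' @param path Path to an aligned FASTA file (gaps as `-`).
#' @param paired If `TRUE`, always return a list of alignments.
#' @return A `pairwise_alignment`, or a list of them.
#' @export
read_pairwise_alignment <- function(path, paired = FALSE) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L || length(recs) %% 2L != 0L) {
    abort(sprintf("expected an even, positive number of FASTA records in '%s', got %d",
                  path, length(recs)),
          class = "codonscan_malformed_alignment")
  }
  ids <- names(recs)
  seqs <- as.character(recs)
  alns <- lapply(seq_len(length(recs) / 2L), function(i) {
    a <- 2L * i - 1L
    pairwise_alignment(seqs[[a]], seqs[[a + 1L]], ids[[a]], ids[[a + 1L]])
  })
  if (length(alns) == 1L && !paired) alns[[1L]] else alns
}

#' Write one or more pairwise alignments as aligned FASTA
#'
#' @param aln A `pairwise_alignment` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pairwise_alignment <- function(aln, path) {
  if (inherits(aln, "pairwise_alignment")) aln <- list(aln)
  seqs <- unlist(lapply(aln, function(a) {
    setNames(c(a$seq_a, a$seq_b), c(a$id_a, a$id_b))
  }))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

# Ungapped coordinate of each alignment column for one row: position of the
# base at that column, or the number of bases seen so far when the column is
# a gap. Monotone; invertible on non-gap columns.
column_to_position <- function(seq) {
  cumsum(strsplit(seq, "", fixed = TRUE)[[1]] != "-")
}

# Alignment column of each ungapped position (1-based) for one row.
position_to_column <- function(seq) {
  which(strsplit(seq, "", fixed = TRUE)[[1]] != "-")
}

# Extract the alignment columns lo..hi (1-based, inclusive) as a new
# pairwise_alignment.
subset_alignment <- function(aln, lo, hi) {
  L <- alignment_length(aln)
  stopifnot(lo >= 1L, hi <= L, lo <= hi)
  pairwise_alignment(substr(aln$seq_a, lo, hi), substr(aln$seq_b, lo, hi),
                     aln$id_a, aln$id_b)
}
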