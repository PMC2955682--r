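# Interval tables are tibbles with columns seq_id, start, end, strand and
# optionally type/source. Coordinates are 0-based half-open internally;
# GFF3 is 1-based closed and BED 0-based half-open on disk, handled here.

.intervals_to_granges <- function(x, default_type = "exon") {
  stopifnot(all(c("seq_id", "start", "end") %in% names(x)))
  strand <- if ("strand" %in% names(x)) x$strand else "*"
  strand[is.na(strand) | !strand %in% c("+", "-", "*")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = x$seq_id,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand)
  S4Vectors::mcols(gr)$type <- if ("type" %in% names(x)) x$type else default_type
  S4Vectors::mcols(gr)$source <- if ("source" %in% names(x)) x$source else "codonscan"
  gr
}

.granges_to_intervals <- function(gr) {
  tibble(seq_id = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr),
         strand = as.character(GenomicRanges::strand(gr)),
         type = if (!is.null(S4Vectors::mcols(gr)$type))
           as.character(S4Vectors::mcols(gr)$type) else "exon",
         source = if (!is.null(S4Vectors::mcols(gr)$source))
           as.character(S4Vectors::mcols(gr)$source) else NA_character_)
}

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) "gff3"
  else if (ext == "bed") "bed"
  else abort(sprintf("cannot guess interval format from extension '.%s'", ext))
}

#' Read exon intervals from GFF3 or BED
#'
#' @param path Path to a GFF3 or BED file.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @param types For GFF3, keep only these feature types (default `exon` and
#'   `CDS`); `NULL` keeps everything.
#' @return A tibble with columns `seq_id`, `start`, `end` (0-based
#'   half-open), `strand`, `type`, `source`.
#' @export
read_intervals <- function(path, format = c("auto", "gff3", "bed"),
                           types = c("exon", "CDS")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  gr <- rtracklayer::import(path, format = format)
  out <- .granges_to_intervals(gr)
  if (format == "gff3" && !is.null(types)) {
    keep <- out$type %in% types
    if (any(keep)) out <- out[keep, ]
  }
  out
}

#' Write exon intervals as GFF3 or BED
#'
#' @param x An interval tibble (`seq_id`, `start`, `end`, optionally
#'   `strand`, `type`, `source`).
#' @inheritParams read_intervals
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  gr <- .intervals_to_granges(x)
  if (format == "bed") {
    S4Vectors::mcols(gr)$name <- paste0("iv", seq_along(gr))
    S4Vectors::mcols(gr)$score <- 0L
  }
  rtracklayer::export(gr, path, format = format)
  invisible(path)
}

.check_intervals <- function(x, what = "interval") {
  bad <- which(!(x$start < x$end))
  if (length(bad) > 0L) {
    abort(sprintf("malformed %s: start >= end at row %d", what, bad[1L]),
          class = "codonscan_malformed_interval")
  }
  invisible(x)
}
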