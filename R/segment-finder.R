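# --- internal fast path -----------------------------------------------------

# Gap-free runs of >= 3 columns in which both rows are unambiguous bases.
.block_bounds <- function(valid) {
  r <- rle(valid)
  e <- cumsum(r$lengths)
  s <- e - r$lengths + 1L
  keep <- r$values & r$lengths >= 3L
  cbind(start = s[keep], end = e[keep])
}

# Codon start columns for one frame: framing restarts at the beginning of
# every gap-free block, so segments never span a gap or ambiguity.
.frame_codon_starts <- function(blocks, f) {
  if (nrow(blocks) == 0L) return(integer(0))
  out <- lapply(seq_len(nrow(blocks)), function(i) {
    s <- blocks[i, 1L] + f
    e <- blocks[i, 2L]
    if (s + 2L > e) integer(0) else seq.int(s, e - 2L, by = 3L)
  })
  unlist(out)
}

# The six framed codon-pair streams of an alignment, integer-coded.
# Each element: list(strand, frame, ca, cb, colmin, colmax) where ca/cb are
# 1..64 codon indices and colmin/colmax the original alignment columns
# (1-based, inclusive) of each codon pair.
.views_int <- function(aln) {
  L <- alignment_length(aln)
  ia <- encode_dna(aln$seq_a)
  ib <- encode_dna(aln$seq_b)
  views <- vector("list", 6L)
  pos <- 1L
  for (strand in c("+", "-")) {
    if (strand == "+") {
      a <- ia; b <- ib
    } else {
      a <- 3L - rev(ia); b <- 3L - rev(ib)
    }
    blocks <- .block_bounds(!is.na(a) & !is.na(b))
    for (f in 0:2) {
      st <- .frame_codon_starts(blocks, f)
      if (length(st) > 0L) {
        ca <- 16L * a[st] + 4L * a[st + 1L] + a[st + 2L] + 1L
        cb <- 16L * b[st] + 4L * b[st + 1L] + b[st + 2L] + 1L
        if (strand == "+") {
          colmin <- st
          colmax <- st + 2L
        } else {
          colmin <- L - st - 1L
          colmax <- L - st + 1L
        }
      } else {
        ca <- cb <- colmin <- colmax <- integer(0)
      }
      views[[pos]] <- list(strand = strand, frame = f, ca = ca, cb = cb,
                           colmin = colmin, colmax = colmax)
      pos <- pos + 1L
    }
  }
  views
}

# --- user-facing operations -------------------------------------------------

#' Extract the six framed codon-pair streams of a pairwise alignment
#'
#' Every alignment is read in three reading frames on the given strand and
#' three on the reverse strand (both rows complemented and reversed
#' together). Columns containing a gap or ambiguity in either row terminate
#' codon accumulation; framing restarts at the next gap-free run, so every
#' codon pair is gap-free and unambiguous.
#'
#' @param aln A [pairwise_alignment()].
#' @return A list of six tibbles (named `+0`, `+1`, `+2`, `-0`, `-1`, `-2`),
#'   each with columns `strand`, `frame`, `codon_a`, `codon_b`, `col_start`,
#'   `col_end` (original alignment columns, 1-based inclusive). A framing
#'   with fewer than 3 usable columns yields a zero-row tibble.
#' @export
#' @examples
#' frame_views(pairwise_alignment("ATGAAATTT", "ATGAAATTC"))[["+0"]]
frame_views <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  vs <- .views_int(aln)
  out <- lapply(vs, function(v) {
    tibble(strand = v$strand, frame = v$frame,
           codon_a = codons[v$ca], codon_b = codons[v$cb],
           col_start = as.integer(v$colmin), col_end = as.integer(v$colmax))
  })
  names(out) <- vapply(vs, function(v) paste0(v$strand, v$frame), "")
  out
}

#' Region score of a codon-pair stream
#'
#' The region score is the sum of the individual codon-pair scores over a
#' half-open codon range.
#'
#' @param view One tibble from [frame_views()].
#' @param matrix A `codon_matrix`.
#' @param start,end 0-based half-open codon range; the empty range scores 0.
#' @return A single numeric score (nats).
#' @export
region_score <- function(view, matrix, start = 0L, end = nrow(view)) {
  n <- nrow(view)
  if (start < 0L || end > n || start > end) {
    abort(sprintf("codon range [%d, %d) out of bounds for a view of %d codons",
                  start, end, n),
          class = "codonscan_range_error")
  }
  if (start == end) return(0)
  sum(score_codon_pair(matrix, view$codon_a[(start + 1L):end],
                       view$codon_b[(start + 1L):end]))
}

#' All locally maximal scoring segments of a score sequence
#'
#' Enumerates every maximal scoring subsequence in the Ruzzo-Tompa sense: a
#' segment whose score cannot be increased by extending or shortening
#' either end, and which is not contained in a higher-scoring such segment.
#' Segments are disjoint and returned left to right. Ties are resolved to
#' the leftmost start, then the shortest extent.
#'
#' @param scores Numeric vector of per-position (here, per-codon-pair)
#'   scores; must be finite.
#' @param cutoff Only segments with score strictly greater than `cutoff`
#'   (default 0) are returned; must be non-negative.
#' @return A tibble with columns `start`, `end` (0-based half-open) and
#'   `score`.
#' @export
#' @examples
#' all_maximal_segments(c(1, -2, 3, -1, 2))
all_maximal_segments <- function(scores, cutoff = 0) {
  scores <- as.numeric(scores)
  if (length(scores) > 0L && !all(is.finite(scores))) {
    abort("scores must be finite (is the matrix pseudocount 0?)")
  }
  if (!is.finite(cutoff) || cutoff < 0) abort("cutoff must be >= 0")
  as_tibble(rt_segments_cpp(scores, cutoff))
}

#' Best maximal segment pair of one framed view
#'
#' The single maximum-score segment of the view's per-codon scores (ties:
#' leftmost start, then shortest), or `NULL` when no positive-score segment
#' exists.
#'
#' @inheritParams region_score
#' @return A one-row tibble with `strand`, `frame`, `start_codon`,
#'   `end_codon` (0-based half-open), `score`, `col_start`, `col_end`, or
#'   `NULL`.
#' @export
best_msp <- function(view, matrix) {
  if (nrow(view) == 0L) return(NULL)
  s <- score_codon_pair(matrix, view$codon_a, view$codon_b)
  r <- best_subarray_cpp(s)
  if (r[1L] < 0) return(NULL)
  i <- as.integer(r[1L]) + 1L   # first member codon (1-based row)
  j <- as.integer(r[2L])        # last member codon
  tibble(strand = view$strand[1L], frame = view$frame[1L],
         start_codon = as.integer(r[1L]), end_codon = as.integer(r[2L]),
         score = r[3L],
         col_start = min(view$col_start[i], view$col_start[j]),
         col_end = max(view$col_end[i], view$col_end[j]))
}

#' Scan a pairwise alignment for high-scoring codon-pair segments
#'
#' Runs [all_maximal_segments()] over the per-codon scores of all six
#' framings and maps every hit back to alignment columns and to ungapped
#' coordinates on both rows. When a calibration is supplied each hit gets a
#' Karlin-Altschul P-value for the scanned length, and the default score
#' cutoff is the score at which `P = cutoff_p` (so every reported segment
#' carries a meaningful P-value); otherwise the cutoff defaults to 0.
#'
#' @param aln A [pairwise_alignment()].
#' @param matrix A `codon_matrix`.
#' @param calibration Optional `ka_calibration` from [calibrate_null()] (or
#'   `NULL`).
#' @param cutoff Score cutoff; segments must exceed it strictly. Default:
#'   derived from `cutoff_p` when a calibration is given, else 0.
#' @param cutoff_p P-value used to derive the default cutoff (default 0.05).
#' @return A tibble sorted by alignment start with columns `strand`,
#'   `frame`, `start_codon`, `end_codon`, `n_codons`, `col_start`,
#'   `col_end`, `start_a`, `end_a`, `start_b`, `end_b`, `score` and (with a
#'   calibration) `p_value`. Coordinates `start_*`/`end_*` are 1-based
#'   inclusive positions on the ungapped rows.
#' @export
scan_alignment <- function(aln, matrix, calibration = NULL, cutoff = NULL,
                           cutoff_p = 0.05) {
  stopifnot(inherits(aln, "pairwise_alignment"), inherits(matrix, "codon_matrix"))
  L <- alignment_length(aln)
  if (is.null(cutoff)) {
    cutoff <- if (is.null(calibration)) 0 else {
      max(0, ka_score_cutoff(cutoff_p, L, calibration = calibration))
    }
  }
  hits <- .scan_views(.views_int(aln), matrix$scores, cutoff)
  if (nrow(hits) == 0L) {
    out <- tibble(strand = character(0), frame = integer(0),
                  start_codon = integer(0), end_codon = integer(0),
                  n_codons = integer(0), col_start = integer(0),
                  col_end = integer(0), start_a = integer(0),
                  end_a = integer(0), start_b = integer(0),
                  end_b = integer(0), score = numeric(0))
    if (!is.null(calibration)) out$p_value <- numeric(0)
    return(out)
  }
  cha <- strsplit(aln$seq_a, "", fixed = TRUE)[[1L]]
  chb <- strsplit(aln$seq_b, "", fixed = TRUE)[[1L]]
  cum_a <- cumsum(cha != "-")
  cum_b <- cumsum(chb != "-")
  hits <- hits %>%
    mutate(n_codons = .data$end_codon - .data$start_codon,
           start_a = as.integer(cum_a[.data$col_start]),
           end_a = as.integer(cum_a[.data$col_end]),
           start_b = as.integer(cum_b[.data$col_start]),
           end_b = as.integer(cum_b[.data$col_end])) %>%
    arrange(.data$col_start, .data$strand, .data$frame) %>%
    select("strand", "frame", "start_codon", "end_codon", "n_codons",
           "col_start", "col_end", "start_a", "end_a", "start_b", "end_b",
           "score")
  if (!is.null(calibration)) {
    hits$p_value <- ka_pvalue(hits$score, L, calibration = calibration)
  }
  hits
}

# Core of scan_alignment on integer-coded views; shared with the null
# simulation so calibration and querying use the identical six-frame scan.
.scan_views <- function(views, score_matrix, cutoff) {
  res <- lapply(views, function(v) {
    if (length(v$ca) == 0L) return(NULL)
    s <- score_matrix[cbind(v$ca, v$cb)]
    seg <- rt_segments_cpp(s, cutoff)
    if (nrow(seg) == 0L) return(NULL)
    i <- seg$start + 1L
    j <- seg$end
    tibble(strand = v$strand, frame = v$frame,
           start_codon = seg$start, end_codon = seg$end,
           col_start = pmin(v$colmin[i], v$colmin[j]),
           col_end = pmax(v$colmax[i], v$colmax[j]),
           score = seg$score)
  })
  bind_rows(res)
}

# Best segment score across all six framings; NA when none is positive.
.best_score_six_frames <- function(aln, score_matrix) {
  best <- -Inf
  for (v in .views_int(aln)) {
    if (length(v$ca) == 0L) next
    r <- best_subarray_cpp(score_matrix[cbind(v$ca, v$cb)])
    if (r[1L] >= 0 && r[3L] > best) best <- r[3L]
  }
  if (is.finite(best)) best else NA_real_
}
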