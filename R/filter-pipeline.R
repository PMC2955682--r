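#' Label predicted exons against a reference annotation
#'
#' Exon-level truth by overlap: a predicted exon is a true positive iff it
#' overlaps at least `min_overlap` nucleotides of an annotated exon on a
#' compatible strand (an unstranded record matches both strands), otherwise
#' a false positive. Boundary mismatches are therefore accepted.
#'
#' @param predictions,annotations Interval tibbles (`seq_id`, `start`,
#'   `end` 0-based half-open, `strand`), e.g. from [read_intervals()].
#' @param min_overlap Minimum overlap in nucleotides (default 1).
#' @return `predictions` with an added `truth` column
#'   (`"true_positive"` / `"false_positive"`).
#' @export
label_predictions <- function(predictions, annotations, min_overlap = 1L) {
  .check_intervals(predictions, "prediction")
  .check_intervals(annotations, "annotation")
  pg <- .intervals_to_granges(predictions)
  ag <- .intervals_to_granges(annotations)
  hit <- GenomicRanges::countOverlaps(pg, ag,
                                      minoverlap = as.integer(min_overlap)) > 0L
  dplyr::mutate(predictions,
                truth = ifelse(hit, "true_positive", "false_positive"))
}

# Best MSP across all six framings with its framing; NULL if none positive.
.best_msp_six_frames <- function(aln, score_matrix) {
  best <- NULL
  for (v in .views_int(aln)) {
    if (length(v$ca) == 0L) next
    r <- best_subarray_cpp(score_matrix[cbind(v$ca, v$cb)])
    if (r[1L] >= 0 && (is.null(best) || r[3L] > best$score)) {
      best <- list(score = r[3L], strand = v$strand, frame = v$frame)
    }
  }
  best
}

#' Test predicted exons against the codon-pair significance filter
#'
#' For each predicted exon, the alignment window spanning the exon (plus an
#' optional flank) is scanned in all six framings; the best maximal segment
#' pair gives a Karlin-Altschul P-value with `N` equal to the window's
#' nucleotide length. An exon passes when its P-value is at most `alpha`
#' (boundary inclusive) and a positive-scoring segment exists. Exons whose
#' interval does not map into the alignment get `verdict = "fail"` with
#' `reason = "unmappable"`. Exons with no positive-scoring segment get
#' `p_value = 1`.
#'
#' @param calls Interval tibble of predicted exons, coordinates on the
#'   ungapped first row of `aln` (0-based half-open).
#' @param aln The [pairwise_alignment()] covering the locus; the first row
#'   is the target sequence the exon coordinates refer to.
#' @param matrix A `codon_matrix`.
#' @param calibration A `ka_calibration`.
#' @param alpha Per-exon significance level (default 0.01).
#' @param flank Extra nucleotides scanned on each side of the exon
#'   (default 0).
#' @return `calls` with added columns `best_score`, `best_strand`,
#'   `best_frame`, `window_length`, `p_value`, `verdict`, `reason`.
#' @export
test_exons <- function(calls, aln, matrix, calibration, alpha = 0.01,
                       flank = 0L) {
  stopifnot(inherits(aln, "pairwise_alignment"),
            inherits(matrix, "codon_matrix"),
            inherits(calibration, "ka_calibration"))
  .check_intervals(calls, "predicted exon")
  p2c <- position_to_column(aln$seq_a)
  len_a <- length(p2c)
  one <- function(start, end) {
    if (start < 0L || end > len_a) {
      return(list(best_score = NA_real_, best_strand = NA_character_,
                  best_frame = NA_integer_, window_length = NA_integer_,
                  p_value = NA_real_, verdict = "fail",
                  reason = "unmappable"))
    }
    ps <- max(1L, start + 1L - flank)
    pe <- min(len_a, end + flank)
    lo <- p2c[ps]
    hi <- p2c[pe]
    sub <- subset_alignment(aln, lo, hi)
    n_window <- hi - lo + 1L
    best <- .best_msp_six_frames(sub, matrix$scores)
    if (is.null(best)) {
      return(list(best_score = NA_real_, best_strand = NA_character_,
                  best_frame = NA_integer_, window_length = n_window,
                  p_value = 1, verdict = "fail", reason = "no_positive_segment"))
    }
    p <- ka_pvalue(best$score, n_window, calibration = calibration)
    list(best_score = best$score, best_strand = best$strand,
         best_frame = best$frame, window_length = n_window,
         p_value = p,
         verdict = if (p <= alpha) "pass" else "fail",
         reason = if (p <= alpha) NA_character_ else "not_significant")
  }
  res <- purrr::map2(calls$start, calls$end, one)
  dplyr::bind_cols(calls, purrr::map_dfr(res, tibble::as_tibble))
}

#' Summary metrics from true/false positive and false negative counts
#'
#' Positive predictive value `TP / (TP + FP)`, sensitivity
#' `TP / (TP + FN)` and the false positive rate in the form
#' `FP / (TP + FN)`; where negatives are enumerable the conventional rate
#' `FP / (FP + TN)` can be derived separately (see [roc_points()]).
#'
#' @param tp,fp,fn Non-negative counts (`fn` may be `NA` when false
#'   negatives were not assessed).
#' @return A one-row tibble with `tp`, `fp`, `fn`, `ppv`, `sensitivity`,
#'   `fpr`.
#' @export
#' @examples
#' evaluation_table(1818, 1243)
evaluation_table <- function(tp, fp, fn = NA_integer_) {
  stopifnot(tp >= 0, fp >= 0, is.na(fn) || fn >= 0)
  tibble(tp = tp, fp = fp, fn = fn,
         ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         sensitivity = if (!is.na(fn) && tp + fn > 0) tp / (tp + fn) else NA_real_,
         fpr = if (!is.na(fn) && tp + fn > 0) fp / (tp + fn) else NA_real_)
}

#' Evaluate exon calls before and after filtering
#'
#' Exon-level counts: true/false positives from the `truth` labels, false
#' negatives as annotated exons not overlapped by any counted prediction.
#' The "before" row counts all predictions; the "after" row counts only
#' those with `verdict == "pass"`.
#'
#' @param calls Labeled, tested exon calls (from [label_predictions()] then
#'   [test_exons()]).
#' @param annotations Reference interval tibble (for false negatives);
#'   `NULL` leaves `fn` as `NA`.
#' @param min_overlap Minimum overlap in nucleotides (default 1).
#' @return A two-row tibble (`phase` = `"before"`, `"after"`) with the
#'   [evaluation_table()] columns.
#' @export
evaluate_calls <- function(calls, annotations = NULL, min_overlap = 1L) {
  stopifnot(all(c("truth", "verdict") %in% names(calls)))
  count_fn <- function(subset_calls) {
    if (is.null(annotations) || nrow(annotations) == 0L) return(NA_integer_)
    ag <- .intervals_to_granges(annotations)
    if (nrow(subset_calls) == 0L) return(length(ag))
    pg <- .intervals_to_granges(subset_calls)
    sum(GenomicRanges::countOverlaps(ag, pg,
                                     minoverlap = as.integer(min_overlap)) == 0L)
  }
  one <- function(subset_calls, phase) {
    dplyr::mutate(
      evaluation_table(sum(subset_calls$truth == "true_positive"),
                       sum(subset_calls$truth == "false_positive"),
                       count_fn(subset_calls)),
      phase = phase, .before = 1L)
  }
  bind_rows(one(calls, "before"),
            one(dplyr::filter(calls, .data$verdict == "pass"), "after"))
}

#' Chi-square test for the filtering effect
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2 x 2 table
#' of true/false positive counts before versus after filtering, testing
#' whether filtering changed the ratio of true positives to all positives.
#'
#' @param before,after Length-2 numeric vectors `c(tp, fp)`.
#' @return A one-row tibble with `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chi_square_filter_effect(c(1818, 1243), c(1345, 262))
chi_square_filter_effect <- function(before, after) {
  stopifnot(length(before) == 2L, length(after) == 2L,
            all(before >= 0), all(after >= 0))
  m <- rbind(before = before, after = after)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("degenerate 2x2 table: a margin is zero",
          class = "codonscan_degenerate_table")
  }
  ct <- stats::chisq.test(m, correct = FALSE)
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = unname(ct$p.value))
}

#' Nucleotide-level ROC points over a grid of significance levels
#'
#' P-values are computed once per exon ([test_exons()]); each `alpha`
#' re-thresholds them (boundary inclusive, so `alpha = 1` reproduces the
#' unfiltered predictor). Positives and negatives are counted by
#' nucleotide, ignoring strand: predicted bases inside annotated exons are
#' true positives, predicted bases outside are false positives, annotated
#' bases never predicted are false negatives.
#'
#' @param calls Tested, labeled exon calls with a `p_value` column.
#' @param annotations Reference interval tibble.
#' @param alpha_grid Significance levels to sweep.
#' @param total_length Optional target sequence length; when given, the
#'   conventional false positive rate `FP / (FP + TN)` is also reported as
#'   `fpr_std`.
#' @return A tibble with one row per alpha: `alpha`, `tp`, `fp`, `fn`,
#'   `tpr`, `fpr` (the `FP / (TP + FN)` form) and optionally `fpr_std`.
#' @export
roc_points <- function(calls, annotations,
                       alpha_grid = c(1e-4, 1e-3, 0.01, 0.05, 0.1, 0.5, 1),
                       total_length = NULL) {
  stopifnot("p_value" %in% names(calls))
  ann <- IRanges::reduce(IRanges::IRanges(annotations$start + 1L,
                                          annotations$end))
  ann_nt <- sum(IRanges::width(ann))
  one <- function(alpha) {
    keep <- !is.na(calls$p_value) & calls$p_value <= alpha
    pred <- IRanges::reduce(IRanges::IRanges(calls$start[keep] + 1L,
                                             calls$end[keep]))
    tp <- sum(IRanges::width(IRanges::intersect(pred, ann)))
    fp <- sum(IRanges::width(IRanges::setdiff(pred, ann)))
    fn <- ann_nt - tp
    out <- tibble(alpha = alpha, tp = tp, fp = fp, fn = fn,
                  tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                  fpr = if (tp + fn > 0) fp / (tp + fn) else NA_real_)
    if (!is.null(total_length)) {
      neg <- total_length - ann_nt
      out$fpr_std <- if (neg > 0) fp / neg else NA_real_
    }
    out
  }
  bind_rows(lapply(sort(alpha_grid), one))
}

#' Positive predictive value by exon length, before and after filtering
#'
#' Exon length is measured in codons, `floor((end - start) / 3)`.
#'
#' @param calls Labeled, tested exon calls.
#' @param bin_edges_codons Bin edges in codons; bins are left-closed
#'   (default `c(0, 25, 50, 100, 200, Inf)`).
#' @return A tibble with `length_bin`, `n_before`, `n_after`, `ppv_before`,
#'   `ppv_after` (`NA` for empty bins).
#' @export
bin_ppv_by_exon_length <- function(calls,
                                   bin_edges_codons = c(0, 25, 50, 100, 200, Inf)) {
  stopifnot(all(c("truth", "verdict") %in% names(calls)))
  df <- calls %>%
    mutate(length_codons = (.data$end - .data$start) %/% 3L,
           length_bin = cut(.data$length_codons, bin_edges_codons,
                            right = FALSE))
  df %>%
    group_by(.data$length_bin, .drop = FALSE) %>%
    summarise(
      n_before = n(),
      n_after = sum(.data$verdict == "pass"),
      ppv_before = if (n() > 0) mean(.data$truth == "true_positive")
                   else NA_real_,
      ppv_after = {
        pass <- .data$verdict == "pass"
        if (any(pass)) mean(.data$truth[pass] == "true_positive")
        else NA_real_
      },
      .groups = "drop")
}
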