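#' Describe the non-coding null model
#'
#' The null emulates aligned non-coding DNA between two diverged mammalian
#' genomes: an ancestral i.i.d. sequence with a given GC content, copied,
#' with a fixed fraction of sites substituted to a different nucleotide in
#' a way that preserves the expected base composition. Defaults match
#' genome-wide human-mouse figures: 40% GC and 70% nucleotide identity.
#'
#' @param gc_content Stationary GC fraction in `[0, 1]` (default 0.40).
#' @param divergence Fraction of substituted sites in `[0, 1]`
#'   (default 0.30).
#' @param seq_length Length of each simulated sequence in nucleotides
#'   (default 100000).
#' @param n_sequences Number of simulated alignments per calibration run
#'   (default 100).
#' @param seed Optional integer seed making runs reproducible.
#' @return An object of class `null_model`.
#' @export
null_model <- function(gc_content = 0.40, divergence = 0.30,
                       seq_length = 100000L, n_sequences = 100L,
                       seed = NULL) {
  stopifnot(gc_content >= 0, gc_content <= 1, divergence >= 0,
            divergence <= 1, seq_length >= 1, n_sequences >= 1)
  structure(list(gc_content = gc_content, divergence = divergence,
                 seq_length = as.integer(seq_length),
                 n_sequences = as.integer(n_sequences),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("<null_model> GC %.2f, divergence %.2f, %d x %d bp%s\n",
              x$gc_content, x$divergence, x$n_sequences, x$seq_length,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

# Substitution kernel over base codes (A=0, C=1, G=2, T=3) with zero
# diagonal that leaves the stationary composition p exactly invariant.
# Built from symmetric flows F(b, x) = F(x, b) with row sums p_b, so
# detailed balance holds: transitions (A<->G, C<->T) carry half the
# minority-composition mass, the remainder is split over transversions.
# (Simply renormalising p over the three alternatives does NOT preserve
# composition: its flows are unbalanced, enriching GC at GC < 0.5.)
.null_substitution_kernel <- function(gc) {
  u <- (1 - gc) / 2  # p(A) = p(T)
  v <- gc / 2        # p(C) = p(G)
  m <- min(u, v)
  f_ti <- m / 2      # A<->G and C<->T each
  f_x <- m / 4       # A<->C, G<->T, G<->C each
  f_at <- u - 3 * m / 4
  f_gc <- v - 3 * m / 4
  # flows indexed A, C, G, T
  FL <- matrix(0, 4, 4)
  FL[1, 3] <- FL[3, 1] <- f_ti   # A<->G
  FL[2, 4] <- FL[4, 2] <- f_ti   # C<->T
  FL[1, 4] <- FL[4, 1] <- f_at   # A<->T
  FL[2, 3] <- FL[3, 2] <- f_gc   # C<->G
  FL[1, 2] <- FL[2, 1] <- f_x    # A<->C
  FL[3, 4] <- FL[4, 3] <- f_x    # G<->T
  p <- c(u, v, v, u)
  R <- FL / ifelse(p > 0, p, 1)
  R[p == 0, ] <- 0
  R
}

# Integer-coded null pair (codes 0..3); draws from the current RNG stream.
.simulate_null_codes <- function(model) {
  L <- model$seq_length
  gc <- model$gc_content
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  anc <- sample.int(4L, L, replace = TRUE, prob = p) - 1L
  der <- anc
  n_sub <- round(model$divergence * L)
  if (n_sub > L) abort("divergence implies more substitutions than sites")
  if (n_sub > 0L) {
    pos <- sample.int(L, n_sub)
    old <- anc[pos]
    R <- .null_substitution_kernel(gc)
    new <- integer(n_sub)
    for (b in 0:3) {
      sel <- which(old == b)
      if (length(sel) == 0L) next
      w <- R[b + 1L, ]
      new[sel] <- sample.int(4L, length(sel), replace = TRUE,
                             prob = w) - 1L
    }
    der[pos] <- new
  }
  list(anc = anc, der = der)
}

#' Simulate one aligned non-coding sequence pair
#'
#' Uses the current RNG stream unless the model carries a seed, in which
#' case the draw is reproducible in isolation.
#'
#' @param model A [null_model()].
#' @return A gapless [pairwise_alignment()].
#' @export
#' @examples
#' aln <- simulate_noncoding_pair(null_model(seq_length = 300, seed = 1))
simulate_noncoding_pair <- function(model) {
  stopifnot(inherits(model, "null_model"))
  draw <- function() {
    z <- .simulate_null_codes(model)
    pairwise_alignment(decode_dna(z$anc), decode_dna(z$der),
                       "ancestral", "derived")
  }
  if (is.null(model$seed)) draw() else withr::with_seed(model$seed, draw())
}

#' Collect null segment scores for calibration
#'
#' Simulates `model$n_sequences` non-coding alignments and scans each with
#' the same six-frame maximal-segment search used on real queries,
#' recording every segment score above `cutoff`.
#'
#' @param matrix A `codon_matrix`.
#' @param model A [null_model()]; its `seed` (when set) makes the whole
#'   collection deterministic.
#' @param cutoff Score cutoff during collection (default 0: all positive
#'   maximal segments, giving the regression the widest score range).
#' @param per_sequence If `TRUE`, return a list of per-sequence score
#'   vectors instead of one flat vector.
#' @return A numeric vector of segment scores (or a list of them).
#' @export
collect_null_segments <- function(matrix, model, cutoff = 0,
                                  per_sequence = FALSE) {
  stopifnot(inherits(matrix, "codon_matrix"), inherits(model, "null_model"))
  run <- function() {
    out <- vector("list", model$n_sequences)
    for (i in seq_len(model$n_sequences)) {
      z <- .simulate_null_codes(model)
      aln <- structure(list(seq_a = decode_dna(z$anc),
                            seq_b = decode_dna(z$der),
                            id_a = "ancestral", id_b = "derived"),
                       class = "pairwise_alignment")
      out[[i]] <- .scan_views(.views_int(aln), matrix$scores, cutoff)$score
    }
    if (per_sequence) out else unlist(out)
  }
  if (is.null(model$seed)) run() else withr::with_seed(model$seed, run())
}

#' Fit Karlin-Altschul constants by log-linear regression
#'
#' Under the extreme-value law the expected number of null segments of
#' score at least `S` in a search of `N` nucleotides is `k N exp(-a S)`.
#' Scores are binned; for each bin center the mean number of segments per
#' simulated sequence with score at least that center is computed, and
#' ordinary least squares of its natural log on the bin center gives the
#' decay `a` (minus the slope) and `k` (exp(intercept) / N).
#'
#' Because one conserved stretch scores in several of the six framings at
#' once, raw segment counts overstate the per-sequence tail probability by
#' the inter-frame correlation factor; when per-sequence best scores are
#' supplied, `k` is therefore re-anchored so that `P(best >= S) = k N
#' exp(-a S)` matches the upper-half order statistics of the best scores
#' under the regression's decay (`a` is unchanged -- the count-based slope
#' is an accurate and much more precise estimate of the decay than the
#' best-score sample alone would give).
#'
#' @param scores Numeric vector of null segment scores (e.g. from
#'   [collect_null_segments()]).
#' @param n_sequences Number of simulated sequences the scores came from.
#' @param search_length Per-sequence search length N in nucleotides.
#' @param bin_width Score bin width (default 1.0 nat).
#' @param best_scores Optional per-sequence best segment scores used to
#'   anchor `k` (see Details).
#' @param model,matrix_id Optional provenance stored with the result.
#' @return An object of class `ka_calibration`: a list with `k`, `a`,
#'   `r_squared`, `points` (tibble of `score`, `exceedance`,
#'   `log_exceedance`, `fitted`), `best_points` (tibble or `NULL`),
#'   `n_segments`, `n_sequences`, `search_length`, `bin_width`, `model`,
#'   `matrix_id`.
#' @export
fit_karlin_altschul <- function(scores, n_sequences, search_length,
                                bin_width = 1.0, best_scores = NULL,
                                model = NULL, matrix_id = "") {
  stopifnot(length(scores) > 0, n_sequences >= 1, search_length >= 1,
            bin_width > 0)
  centers <- seq(bin_width / 2, max(max(scores), bin_width / 2),
                 by = bin_width)
  exceed <- vapply(centers, function(c0) sum(scores >= c0), 0) / n_sequences
  # sparse-tail trimming: bins supported by less than one segment per 20
  # sequences form noisy plateaus that flatten the fitted decay; the rule
  # is expressed on the per-sequence exceedance so that duplicating the
  # whole collection leaves the fit unchanged
  keep <- exceed >= 0.05
  if (sum(keep) < 2L) keep <- exceed > 0
  if (sum(keep) < 2L) {
    abort("calibration error: fewer than 2 non-empty score bins",
          class = "codonscan_calibration_error")
  }
  pts <- tibble(score = centers[keep], exceedance = exceed[keep],
                log_exceedance = log(exceed[keep]))
  fit <- lm(log_exceedance ~ score, data = pts)
  a <- -unname(coef(fit)[2L])
  k <- exp(unname(coef(fit)[1L])) / search_length
  if (!is.finite(a) || a <= 0 || !is.finite(k) || k <= 0) {
    abort("calibration error: fitted decay is not positive (null scores do not decay)",
          class = "codonscan_calibration_error")
  }
  pts$fitted <- unname(stats::fitted(fit))
  best_pts <- NULL
  if (!is.null(best_scores)) {
    b <- sort(best_scores[is.finite(best_scores)], decreasing = TRUE)
    m <- max(2L, floor(n_sequences / 2))
    m <- min(m, length(b))
    if (m >= 2L) {
      j <- seq_len(m)
      log_p <- log((j - 0.5) / n_sequences)
      # least-squares intercept with the regression's slope held fixed
      k <- exp(mean(log_p + a * b[j])) / search_length
      best_pts <- tibble(score = b[j], log_p = log_p)
    }
  }
  structure(list(k = k, a = a,
                 r_squared = summary(fit)$r.squared,
                 points = pts,
                 best_points = best_pts,
                 n_segments = length(scores),
                 n_sequences = as.integer(n_sequences),
                 search_length = as.integer(search_length),
                 bin_width = bin_width,
                 model = model, matrix_id = as.character(matrix_id)),
            class = "ka_calibration")
}

#' Calibrate the null score distribution for a matrix
#'
#' Convenience wrapper: [collect_null_segments()] then
#' [fit_karlin_altschul()].
#'
#' @inheritParams collect_null_segments
#' @inheritParams fit_karlin_altschul
#' @param matrix_id Provenance string recorded with the result (defaults to
#'   the matrix's own provenance).
#' @return A `ka_calibration`.
#' @export
calibrate_null <- function(matrix, model = null_model(), cutoff = 0,
                           bin_width = 1.0, matrix_id = matrix$provenance) {
  per_seq <- collect_null_segments(matrix, model, cutoff = cutoff,
                                   per_sequence = TRUE)
  bests <- vapply(per_seq, function(s) if (length(s)) max(s) else -Inf, 0)
  fit_karlin_altschul(unlist(per_seq), n_sequences = model$n_sequences,
                      search_length = model$seq_length,
                      bin_width = bin_width, best_scores = bests,
                      model = model, matrix_id = matrix_id)
}

#' @export
print.ka_calibration <- function(x, ...) {
  cat(sprintf(paste0("<ka_calibration> k = %.4g, a = %.4g (r^2 = %.4f; ",
                     "%d segments from %d x %d bp)\n"),
              x$k, x$a, x$r_squared, x$n_segments, x$n_sequences,
              x$search_length))
  invisible(x)
}

#' @rdname tidy.codon_matrix
#' @export
tidy.ka_calibration <- function(x, ...) x$points

#' One-row summary of a calibration fit
#'
#' @param x A `ka_calibration`.
#' @param ... Unused.
#' @return A one-row tibble with `k`, `a`, `r_squared`, `n_segments`,
#'   `n_sequences`, `search_length`, `bin_width`.
#' @export
glance.ka_calibration <- function(x, ...) {
  tibble(k = x$k, a = x$a, r_squared = x$r_squared,
         n_segments = x$n_segments, n_sequences = x$n_sequences,
         search_length = x$search_length, bin_width = x$bin_width)
}

#' Karlin-Altschul P-value of a segment score
#'
#' `P = min(1, k N exp(-a S))`: the probability that a non-coding region of
#' length `N` nucleotides contains a maximal segment pair scoring more than
#' `S` by chance.
#'
#' @param score Segment score(s) S in nats.
#' @param search_length Searched region length N in nucleotides.
#' @param k,a Karlin-Altschul constants; alternatively pass `calibration`.
#' @param calibration A `ka_calibration` supplying `k` and `a`.
#' @return P-values in `[0, 1]`, vectorised over `score`.
#' @export
#' @examples
#' ka_pvalue(20, 100000, k = 0.282, a = 1.219)
ka_pvalue <- function(score, search_length, k = NULL, a = NULL,
                      calibration = NULL) {
  if (!is.null(calibration)) {
    k <- calibration$k
    a <- calibration$a
  }
  if (is.null(k) || is.null(a) || k <= 0 || a <= 0 || search_length <= 0) {
    abort("k, a and search_length must be positive",
          class = "codonscan_parameter_error")
  }
  stopifnot(all(is.finite(score)))
  pmin(1, k * search_length * exp(-a * score))
}

#' Score cutoff corresponding to a P-value
#'
#' Inverts `P = k N exp(-a S)`: the score above which a segment is
#' significant at level `p` in a search of length `search_length`.
#'
#' @inheritParams ka_pvalue
#' @param p Target P-value in `(0, 1]`.
#' @return The score `S` solving the equation (may be negative for lenient
#'   `p` and short searches).
#' @export
ka_score_cutoff <- function(p, search_length, k = NULL, a = NULL,
                            calibration = NULL) {
  if (!is.null(calibration)) {
    k <- calibration$k
    a <- calibration$a
  }
  if (is.null(k) || is.null(a) || k <= 0 || a <= 0 || search_length <= 0 ||
      any(p <= 0) || any(p > 1)) {
    abort("need k, a, search_length > 0 and p in (0, 1]",
          class = "codonscan_parameter_error")
  }
  log(k * search_length / p) / a
}

#' Significance decision at a flat per-exon level
#'
#' Boundary inclusive: `p == alpha` is significant.
#'
#' @param p P-value(s) in `[0, 1]`.
#' @param alpha Significance level in `[0, 1]` (default 0.01).
#' @return Logical vector.
#' @export
is_significant <- function(p, alpha = 0.01) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), alpha >= 0, alpha <= 1)
  !is.na(p) & p <= alpha
}

#' Write / read a calibration as JSON
#'
#' @param calibration A `ka_calibration`.
#' @param path File path.
#' @return `path` invisibly, or the restored `ka_calibration`.
#' @export
write_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "ka_calibration"))
  obj <- calibration
  class(obj) <- NULL
  obj$points <- as.data.frame(obj$points)
  if (!is.null(obj$model)) {
    obj$model <- unclass(obj$model)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$points <- as_tibble(obj$points)
  if (!is.null(obj$model)) {
    obj$model <- structure(obj$model, class = "null_model")
  }
  structure(obj, class = "ka_calibration")
}
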