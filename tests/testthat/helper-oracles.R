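# Brute-force enumeration of all maximal scoring subsequences, independent
# of the linear-time implementation. A candidate (i, j] requires the
# cumulative sum before the segment to be the unique minimum, and at its
# end the unique maximum, over the segment's span; candidates contained in
# another candidate are dropped.
oracle_maximal_segments <- function(x, cutoff = 0) {
  n <- length(x)
  if (n == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      score = numeric(0)))
  }
  cs <- c(0, cumsum(x))
  cand <- list()
  for (i in 0:(n - 1L)) {
    # right ends c_j for j = i+1 .. n; (i, j] is a candidate iff c_i is the
    # strict minimum of c_i..c_j and c_j the strict maximum
    rest <- cs[(i + 2L):(n + 1L)]
    minok <- cs[i + 1L] < cummin(rest)
    prevmax <- cummax(c(cs[i + 1L], rest[-length(rest)]))
    maxok <- rest > prevmax
    for (jj in which(minok & maxok)) {
      cand[[length(cand) + 1L]] <- c(i, i + jj, rest[jj] - cs[i + 1L])
    }
  }
  if (length(cand) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      score = numeric(0)))
  }
  m <- do.call(rbind, cand)
  keep <- rep(TRUE, nrow(m))
  for (u in seq_len(nrow(m))) {
    for (w in seq_len(nrow(m))) {
      if (u != w && m[w, 1L] <= m[u, 1L] && m[u, 2L] <= m[w, 2L]) {
        keep[u] <- FALSE
      }
    }
  }
  m <- m[keep & m[, 3L] > cutoff, , drop = FALSE]
  m <- m[order(m[, 1L]), , drop = FALSE]
  data.frame(start = as.integer(m[, 1L]), end = as.integer(m[, 2L]),
             score = m[, 3L])
}

# Brute-force maximum-scoring segment with the package's tie-break rules
# (highest score, then leftmost start, then shortest extent).
oracle_best_segment <- function(x) {
  n <- length(x)
  best <- NULL
  if (n > 0L) {
    for (i in 1:n) {
      for (j in i:n) {
        sc <- sum(x[i:j])
        if (sc > 0 &&
            (is.null(best) || sc > best[3L] ||
             (sc == best[3L] && (i - 1L < best[1L] ||
                                 (i - 1L == best[1L] && j < best[2L]))))) {
          best <- c(i - 1L, j, sc)
        }
      }
    }
  }
  if (is.null(best)) c(-1, -1, 0) else best
}

# Score vectors whose values are exactly representable (eighths), so tie
# semantics are identical across accumulation orders and precisions.
random_dyadic_scores <- function(n) round(8 * stats::rnorm(n)) / 8

# Shared fixtures, built once per test run. The training set emulates the
# ortholog corpus the matrix is meant to be learned from at one tenth of
# its volume (760 pairs x 260 codons ~ 200k codon columns); much smaller
# sets give too flat a matrix for null scores to decay.
.fx <- new.env(parent = emptyenv())

fx_training <- function() {
  if (is.null(.fx$training)) {
    .fx$training <- build_training_set(coding_model(n_codons = 260L),
                                       760L, seed = 101L)
  }
  .fx$training
}

fx_matrix <- function() {
  if (is.null(.fx$matrix)) {
    .fx$matrix <- build_codon_matrix(fx_training(),
                                     provenance = "test fixture")
  }
  .fx$matrix
}

fx_calibration <- function() {
  if (is.null(.fx$calibration)) {
    .fx$calibration <- calibrate_null(
      fx_matrix(), null_model(seq_length = 10000L, n_sequences = 100L,
                              seed = 202L))
  }
  .fx$calibration
}
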