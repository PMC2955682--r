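# Genetic-code tables: amino acid per codon, sense codons, and for every
# codon its single-nucleotide synonymous and nonsynonymous neighbours with
# transition/transversion annotation. Stops are excluded from sampling;
# they can still appear in the scanning phase (off-frame), which is why the
# scoring matrix carries all 64 codons.
.code_env <- new.env(parent = emptyenv())

.is_transition <- function(b1, b2) {
  (b1 %in% c("A", "G") & b2 %in% c("A", "G")) |
    (b1 %in% c("C", "T") & b2 %in% c("C", "T"))
}

.genetic_code <- function() {
  if (is.null(.code_env$aa)) {
    gc <- Biostrings::GENETIC_CODE
    aa <- setNames(as.character(gc)[match(codons, names(gc))], codons)
    .code_env$aa <- aa
    .code_env$sense <- codons[aa != "*"]
    neighbours <- lapply(codons, function(cod) {
      out <- list(syn = character(0), syn_ti = logical(0),
                  non = character(0), non_ti = logical(0))
      for (pos in 1:3) {
        old <- substr(cod, pos, pos)
        for (new in setdiff(c("A", "C", "G", "T"), old)) {
          cand <- cod
          substr(cand, pos, pos) <- new
          if (aa[[cand]] == "*") next
          ti <- .is_transition(old, new)
          if (aa[[cand]] == aa[[cod]]) {
            out$syn <- c(out$syn, cand)
            out$syn_ti <- c(out$syn_ti, ti)
          } else {
            out$non <- c(out$non, cand)
            out$non_ti <- c(out$non_ti, ti)
          }
        }
      }
      out
    })
    names(neighbours) <- codons
    .code_env$neighbours <- neighbours
  }
  .code_env
}

#' Describe a synonymous-biased coding substitution model
#'
#' Coding alignments differ from non-coding ones through functional
#' constraint: synonymous changes (which preserve the amino acid, and
#' cluster at third codon positions) accumulate faster than nonsynonymous
#' ones, and both are transition-biased as in mammalian evolution. The
#' generator reproduces that signature per codon: a synonymous event
#' replaces the codon by a single-nucleotide neighbour encoding the same
#' amino acid, a nonsynonymous event by a single-nucleotide neighbour
#' encoding a different one; transitions are favoured `transition_bias` to
#' 1 over transversions. Stop codons are never sampled and never created,
#' so first and second codon positions stay strongly conserved while third
#' positions diverge -- the pattern the codon-pair matrix exploits.
#'
#' @param n_codons Codons per simulated CDS (default 100).
#' @param synonymous_rate Per-codon probability of a synonymous event
#'   (default 0.4); must exceed `nonsynonymous_rate` for the coding
#'   signature to hold.
#' @param nonsynonymous_rate Per-codon probability of a nonsynonymous
#'   single-nucleotide event (default 0.05).
#' @param codon_usage Optional 61-entry frequency vector named by sense
#'   codon (default uniform).
#' @param transition_bias Transition/transversion weight ratio for both
#'   event types (default 4, a typical mammalian value).
#' @param seed Optional integer seed.
#' @return An object of class `coding_model`.
#' @export
coding_model <- function(n_codons = 100L, synonymous_rate = 0.4,
                         nonsynonymous_rate = 0.05, codon_usage = NULL,
                         transition_bias = 4, seed = NULL) {
  if (synonymous_rate < 0 || synonymous_rate > 1 ||
      nonsynonymous_rate < 0 || nonsynonymous_rate > 1) {
    abort("substitution rates must lie in [0, 1] (per-codon event probabilities)",
          class = "codonscan_parameter_error")
  }
  code <- .genetic_code()
  if (is.null(codon_usage)) {
    codon_usage <- setNames(rep(1 / length(code$sense), length(code$sense)),
                            code$sense)
  }
  stopifnot(setequal(names(codon_usage), code$sense),
            abs(sum(codon_usage) - 1) < 1e-8, all(codon_usage >= 0))
  structure(list(n_codons = as.integer(n_codons),
                 synonymous_rate = synonymous_rate,
                 nonsynonymous_rate = nonsynonymous_rate,
                 codon_usage = codon_usage[code$sense],
                 transition_bias = transition_bias,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "coding_model")
}

# One synonymous single-nucleotide change: a neighbour codon encoding the
# same amino acid, transitions favoured by `kappa`. Codons with no
# synonymous neighbour (ATG, TGG) are returned unchanged.
.syn_change <- function(codon, kappa) {
  nb <- .genetic_code()$neighbours[[codon]]
  if (length(nb$syn) == 0L) return(codon)
  w <- ifelse(nb$syn_ti, kappa, 1)
  nb$syn[sample.int(length(nb$syn), 1L, prob = w)]
}

# One nonsynonymous single-nucleotide change avoiding stops, transitions
# favoured by `kappa`.
.nonsyn_change <- function(codon, kappa) {
  nb <- .genetic_code()$neighbours[[codon]]
  if (length(nb$non) == 0L) return(codon)
  w <- ifelse(nb$non_ti, kappa, 1)
  nb$non[sample.int(length(nb$non), 1L, prob = w)]
}

#' Simulate one in-frame aligned coding sequence pair
#'
#' Draws an ancestral codon sequence from the model's codon usage, then
#' derives the partner by applying synonymous class swaps and
#' nonsynonymous single-nucleotide changes at the stated per-codon
#' probabilities. The result is a gapless, in-frame alignment with no
#' in-frame stop codons in either row.
#'
#' @param model A [coding_model()]; draws from the current RNG stream
#'   unless the model carries a seed.
#' @return A [pairwise_alignment()].
#' @export
#' @examples
#' simulate_coding_alignment(coding_model(n_codons = 20, seed = 1))
simulate_coding_alignment <- function(model) {
  stopifnot(inherits(model, "coding_model"))
  draw <- function() {
    code <- .genetic_code()
    anc <- sample(code$sense, model$n_codons, replace = TRUE,
                  prob = model$codon_usage)
    der <- anc
    kappa <- model$transition_bias
    syn <- runif(model$n_codons) < model$synonymous_rate
    for (i in which(syn)) der[i] <- .syn_change(der[i], kappa)
    non <- runif(model$n_codons) < model$nonsynonymous_rate
    for (i in which(non)) der[i] <- .nonsyn_change(der[i], kappa)
    pairwise_alignment(paste(anc, collapse = ""), paste(der, collapse = ""),
                       "cds_a", "cds_b")
  }
  if (is.null(model$seed)) draw() else withr::with_seed(model$seed, draw())
}

#' Simulate a training set of coding alignments
#'
#' @param model A [coding_model()].
#' @param n_pairs Number of independent alignment pairs.
#' @param seed Optional seed for the whole set (takes precedence over the
#'   model's seed).
#' @return A list of [pairwise_alignment()] objects.
#' @export
build_training_set <- function(model, n_pairs, seed = model$seed) {
  stopifnot(inherits(model, "coding_model"), n_pairs >= 1)
  m <- model
  m$seed <- NULL
  run <- function() lapply(seq_len(n_pairs),
                           function(i) simulate_coding_alignment(m))
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Describe a genomic mosaic: coding blocks in a non-coding background
#'
#' Stands in for an annotated genomic locus: a non-coding background
#' alignment with in-frame coding blocks planted at known positions, so
#' downstream filtering can be evaluated against exact truth.
#'
#' @param total_length Alignment length in nucleotides.
#' @param exon_blocks Tibble with columns `start` (0-based), `n_codons`,
#'   `strand` (`"+"` or `"-"`); blocks must be disjoint and in bounds.
#' @param background A [null_model()] for the non-coding part (its
#'   `seq_length`/`n_sequences` are overridden to fit the mosaic).
#' @param seed Optional integer seed.
#' @return An object of class `mosaic_spec`.
#' @export
mosaic_spec <- function(total_length, exon_blocks, background = null_model(),
                        seed = NULL) {
  stopifnot(total_length >= 3, is.data.frame(exon_blocks))
  eb <- as_tibble(exon_blocks)
  stopifnot(all(c("start", "n_codons", "strand") %in% names(eb)))
  eb <- arrange(eb, .data$start)
  eb$end <- eb$start + 3L * eb$n_codons
  if (any(eb$start < 0) || any(eb$end > total_length)) {
    abort("exon blocks out of bounds", class = "codonscan_spec_error")
  }
  if (nrow(eb) > 1L && any(eb$start[-1L] < eb$end[-nrow(eb)])) {
    abort("exon blocks overlap", class = "codonscan_spec_error")
  }
  bg <- background
  bg$seq_length <- as.integer(total_length)
  bg$n_sequences <- 1L
  bg$seed <- NULL
  structure(list(total_length = as.integer(total_length), exon_blocks = eb,
                 background = bg,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "mosaic_spec")
}

#' Build a mosaic alignment with truth annotations
#'
#' The background is a simulated non-coding pair; each exon block is
#' replaced by an independently simulated coding alignment (both rows
#' reverse-complemented for minus-strand blocks), and the block coordinates
#' are emitted as truth annotations.
#'
#' @param spec A [mosaic_spec()].
#' @param coding A [coding_model()] providing the substitution rates and
#'   codon usage for the blocks (its `n_codons` and `seed` are ignored).
#' @return A list with `alignment` (a gapless [pairwise_alignment()]) and
#'   `annotations` (interval tibble with `seq_id`, `start`, `end`,
#'   `strand`, `type`, `source`).
#' @export
build_mosaic <- function(spec, coding = coding_model()) {
  stopifnot(inherits(spec, "mosaic_spec"), inherits(coding, "coding_model"))
  run <- function() {
    z <- .simulate_null_codes(spec$background)
    a <- strsplit(decode_dna(z$anc), "", fixed = TRUE)[[1L]]
    b <- strsplit(decode_dna(z$der), "", fixed = TRUE)[[1L]]
    cm <- coding
    cm$seed <- NULL
    for (i in seq_len(nrow(spec$exon_blocks))) {
      blk <- spec$exon_blocks[i, ]
      cm$n_codons <- blk$n_codons
      cds <- simulate_coding_alignment(cm)
      sa <- cds$seq_a
      sb <- cds$seq_b
      if (blk$strand == "-") {
        sa <- revcomp_chr(sa)
        sb <- revcomp_chr(sb)
      }
      idx <- (blk$start + 1L):blk$end
      a[idx] <- strsplit(sa, "", fixed = TRUE)[[1L]]
      b[idx] <- strsplit(sb, "", fixed = TRUE)[[1L]]
    }
    ann <- tibble(seq_id = "mosaic",
                  start = spec$exon_blocks$start,
                  end = spec$exon_blocks$end,
                  strand = spec$exon_blocks$strand,
                  type = "exon", source = "truth")
    list(alignment = pairwise_alignment(paste(a, collapse = ""),
                                        paste(b, collapse = ""),
                                        "mosaic", "mosaic_partner"),
         annotations = ann)
  }
  if (is.null(spec$seed)) run() else withr::with_seed(spec$seed, run())
}

#' Simulate exon predictions over a mosaic
#'
#' Emulates the output of an external gene finder: each true exon is
#' re-reported with jittered boundaries, and a controlled number of false
#' predictions is placed in unannotated sequence with lengths drawn from
#' the given codon range (short false exons dominate real predictors'
#' error profile, so the default range skews short).
#'
#' @param annotations Truth interval tibble (e.g. from [build_mosaic()]).
#' @param total_length Target sequence length.
#' @param n_false Number of false predictions (default 10).
#' @param false_codon_range Length range of false exons in codons
#'   (default `c(8, 60)`).
#' @param jitter Maximum boundary shift in nucleotides (default 6).
#' @param seed Optional integer seed.
#' @return An interval tibble with a `source` column.
#' @export
simulate_predictions <- function(annotations, total_length, n_false = 10L,
                                 false_codon_range = c(8L, 60L), jitter = 6L,
                                 seed = NULL) {
  run <- function() {
    truth <- annotations
    jit <- function(x, lo, hi) pmin(hi, pmax(lo, x + sample(seq.int(-jitter, jitter),
                                                            length(x), replace = TRUE)))
    preds <- tibble(seq_id = truth$seq_id,
                    start = jit(truth$start, 0L, total_length - 3L),
                    end = jit(truth$end, 3L, total_length),
                    strand = truth$strand,
                    type = "exon", source = "synthetic_predictor")
    fix <- preds$end - preds$start < 3L
    preds$start[fix] <- truth$start[fix]
    preds$end[fix] <- truth$end[fix]
    ann_ir <- IRanges::IRanges(truth$start + 1L, truth$end)
    false_list <- list()
    tries <- 0L
    while (length(false_list) < n_false && tries < 200L * n_false) {
      tries <- tries + 1L
      len <- 3L * sample(seq.int(false_codon_range[1L], false_codon_range[2L]), 1L)
      if (len >= total_length) next
      s <- sample.int(total_length - len, 1L) - 1L
      cand <- IRanges::IRanges(s + 1L, s + len)
      if (length(ann_ir) > 0L &&
          sum(IRanges::countOverlaps(cand, ann_ir)) > 0L) next
      false_list[[length(false_list) + 1L]] <-
        tibble(seq_id = truth$seq_id[1L] %||% "mosaic", start = s,
               end = s + len, strand = sample(c("+", "-"), 1L),
               type = "exon", source = "synthetic_predictor")
    }
    bind_rows(preds, bind_rows(false_list))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Run one complete synthetic filtering experiment
#'
#' Builds a mosaic locus with planted coding exons of mixed lengths,
#' simulates gene-finder-style predictions (jittered true exons plus short
#' false ones), labels them against the truth, applies the significance
#' filter, and evaluates. This is the package's end-to-end benchmark: over
#' replicate seeds, filtering should strictly reduce the false-positive
#' share of accepted exons, with the largest positive-predictive-value
#' gains among short exons.
#'
#' @param matrix A `codon_matrix`.
#' @param calibration A `ka_calibration` for the same matrix.
#' @param seed Integer seed for the whole experiment.
#' @param total_length Mosaic length in nucleotides (default 15000).
#' @param exon_codons Planted exon lengths in codons (default a short-heavy
#'   mixture from 20 to 150).
#' @param n_false Number of false predictions (default 8).
#' @param alpha Significance level for the filter (default 0.01).
#' @return A list with `calls` (labelled, tested exon tibble),
#'   `annotations`, `evaluation` (two-row before/after tibble) and
#'   `binned` (PPV by exon length).
#' @export
simulate_filter_experiment <- function(matrix, calibration, seed,
                                       total_length = 15000L,
                                       exon_codons = c(20L, 30L, 50L, 80L,
                                                       120L, 150L),
                                       n_false = 8L, alpha = 0.01) {
  k <- length(exon_codons)
  starts <- as.integer(round(seq(0.06, 0.82, length.out = k) * total_length))
  blocks <- tibble(start = starts, n_codons = as.integer(exon_codons),
                   strand = rep(c("+", "-"), length.out = k))
  spec <- mosaic_spec(total_length, blocks, seed = seed)
  mz <- build_mosaic(spec)
  preds <- simulate_predictions(mz$annotations, total_length,
                                n_false = n_false, seed = seed + 1L)
  calls <- label_predictions(preds, mz$annotations)
  calls <- test_exons(calls, mz$alignment, matrix, calibration,
                      alpha = alpha)
  list(calls = calls, annotations = mz$annotations,
       evaluation = evaluate_calls(calls, mz$annotations),
       binned = bin_ppv_by_exon_length(calls))
}

#' Write a complete miniature experiment to disk
#'
#' Generates, deterministically for a given seed, everything the pipeline
#' consumes: a training set of coding alignments, the codon-pair matrix
#' built from it, a null calibration, a mosaic alignment with truth
#' annotations, and synthetic predictions -- plus a manifest with MD5
#' checksums of every file.
#'
#' @param outdir Output directory (created if absent).
#' @param seed Integer master seed (default 42); sub-seeds are derived from
#'   it.
#' @param n_training_pairs,training_codons Size of the training set
#'   (default 760 pairs of 260 codons, one tenth of the ortholog training
#'   volume the matrix is meant to emulate; substantially smaller training
#'   sets give too flat a matrix for the null scores to decay).
#' @param mosaic_length Mosaic alignment length (default 30000 nt).
#' @return Invisibly, a named list of the written file paths.
#' @export
make_fixture_bundle <- function(outdir, seed = 42L, n_training_pairs = 760L,
                                training_codons = 260L,
                                mosaic_length = 30000L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) abort(sprintf("cannot create directory '%s'", outdir))
  seed <- as.integer(seed)
  paths <- list(
    training = file.path(outdir, "training.fa"),
    matrix = file.path(outdir, "matrix.tsv"),
    calibration = file.path(outdir, "calibration.json"),
    mosaic = file.path(outdir, "mosaic.fa"),
    annotations = file.path(outdir, "annotations.gff3"),
    predictions = file.path(outdir, "predictions.gff3"))

  cm <- coding_model(n_codons = training_codons)
  training <- build_training_set(cm, n_training_pairs, seed = seed)
  write_pairwise_alignment(training, paths$training)
  mat <- build_codon_matrix(training,
                            provenance = sprintf("synthetic training set, seed %d", seed))
  write_codon_matrix(mat, paths$matrix)

  calib <- calibrate_null(mat, null_model(seq_length = 5000L,
                                          n_sequences = 60L,
                                          seed = seed + 1L))
  write_calibration(calib, paths$calibration)

  blocks <- tibble(
    start = as.integer(round(seq(0.05, 0.9, length.out = 8L) * mosaic_length)),
    n_codons = c(20L, 150L, 40L, 60L, 25L, 100L, 35L, 80L),
    strand = c("+", "+", "-", "+", "+", "-", "+", "+"))
  spec <- mosaic_spec(mosaic_length, blocks, seed = seed + 2L)
  mz <- build_mosaic(spec, coding_model())
  write_pairwise_alignment(mz$alignment, paths$mosaic)
  write_intervals(mz$annotations, paths$annotations, format = "gff3")
  preds <- simulate_predictions(mz$annotations, mosaic_length,
                                n_false = 10L, seed = seed + 3L)
  write_intervals(preds, paths$predictions, format = "gff3")

  manifest <- list(
    seed = seed,
    files = lapply(paths, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    }))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  paths$manifest <- manifest_path
  invisible(paths)
}
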