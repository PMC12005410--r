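#' Specify a synthetic tailed or adapter-ligated library
#'
#' Describes everything needed to generate a synthetic single-end FASTQ
#' library with known ground truth: the target, the true 3'-end
#' distribution, library size, chemistry, tail-length distribution, read
#' length and error rate. Defaults emulate the experimental design the
#' package targets: 75-nt single-end reads, error-free bases, and tail
#' lengths uniform on 10..25 nt (within the tail-length range produced by
#' the tailing enzyme, and long enough that the tail signature always lies
#' inside the read).
#'
#' @param target A [target_seq()].
#' @param true_end_dist Data frame with columns `position` and
#'   `probability` (must sum to 1; no mass outside the target).
#' @param n_reads Number of reads to generate.
#' @param chemistry `"tail"` or `"adapter"`.
#' @param tail_base Tailing nucleotide (tail chemistry).
#' @param tail_len_dist Tail length distribution: `list("fixed", k)`,
#'   `list("uniform", lo, hi)` or `list("geometric", p, min)` (geometric
#'   shifted so `min` is the smallest value). Default `list("uniform", 10, 25)`.
#' @param adapter_seq Adapter appended 3' of the insert (adapter chemistry);
#'   default is the TruSeq 3'-adapter start.
#' @param read_len Read length in nt (default 75).
#' @param error_rate Per-base substitution probability (default 0).
#' @param start_dist For long targets, data frame (`position`,
#'   `probability`) of read 5'-start positions; default: every read starts
#'   at the first base of the 3'-proximal mapping window, covering the full
#'   anchor.
#' @param seed Integer seed making generation fully reproducible.
#' @return A `synth_spec` object.
#' @export
synth_spec <- function(target, true_end_dist, n_reads,
                       chemistry = c("tail", "adapter"),
                       tail_base = "A",
                       tail_len_dist = list("uniform", 10, 25),
                       adapter_seq = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                       read_len = 75, error_rate = 0,
                       start_dist = NULL, seed = 1L) {
  chemistry <- match.arg(chemistry)
  stopifnot(inherits(target, "target_seq"), n_reads >= 1,
            is.data.frame(true_end_dist),
            all(c("position", "probability") %in% names(true_end_dist)))
  if (abs(sum(true_end_dist$probability) - 1) > 1e-8) {
    abort("true_end_dist probabilities must sum to 1")
  }
  if (any(true_end_dist$position < 1 | true_end_dist$position > target$length)) {
    abort("true_end_dist has mass outside the target")
  }
  tail_base <- match.arg(toupper(tail_base), c("A", "C", "G", "T"))
  dist_kind <- tail_len_dist[[1]]
  if (!dist_kind %in% c("fixed", "uniform", "geometric")) {
    abort("tail_len_dist must be fixed, uniform or geometric")
  }
  if (chemistry == "tail") {
    min_tail <- switch(dist_kind,
      fixed = tail_len_dist[[2]],
      uniform = tail_len_dist[[2]],
      geometric = tail_len_dist[[3]]
    )
    # shorter tails cannot carry the default 5+4 signature
    if (min_tail < 9) {
      warn(sprintf(
        "minimum tail length %d is below run_len + lookahead = 9; some reads may be unselected",
        min_tail))
    }
  }
  structure(
    list(target = target, true_end_dist = true_end_dist,
         n_reads = as.integer(n_reads), chemistry = chemistry,
         tail_base = tail_base, tail_len_dist = tail_len_dist,
         adapter_seq = .as_dna(adapter_seq), read_len = as.integer(read_len),
         error_rate = error_rate, start_dist = start_dist,
         seed = as.integer(seed)),
    class = "synth_spec"
  )
}

# downstream filler mimicking sequencing into library scaffold once the
# insert plus tail/adapter is exhausted; content is irrelevant downstream
.filler <- "GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCTGTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT"

#' Generate a synthetic FASTQ library with known truth
#'
#' Each read is a target fragment ending at a position drawn from the true
#' 3'-end distribution, followed by a homonucleotide tail (or the adapter),
#' then filler, truncated to `read_len` and padded with filler if shorter.
#' Substitution errors are applied per base at `error_rate`. All random
#' draws happen in a fixed order (end positions, then tail lengths, then
#' error positions) under `spec$seed`, so output is byte-identical across
#' runs and platforms.
#'
#' @param spec A [synth_spec()].
#' @return List with `reads` (tibble `id`, `bases`, `quality`) and `truth`
#'   (tibble `position`, `count` of realized end positions).
#' @examples
#' tg <- target_seq("pRNA", "GTTCGGTCAAAACTAGGTG")
#' dist <- tibble::tibble(position = c(8, 9, 13), probability = c(0.5, 0.3, 0.2))
#' lib <- generate_library(synth_spec(tg, dist, n_reads = 100, tail_base = "A"))
#' lib$truth
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  target <- spec$target
  n <- spec$n_reads

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  # index-based draw: sample() on a length-one position vector would
  # otherwise be read as sample(1:position)
  dist <- spec$true_end_dist
  ends <- dist$position[sample.int(nrow(dist), n, replace = TRUE,
                                   prob = dist$probability)]

  if (target$mode == "short") {
    starts <- rep(1L, n)
  } else if (is.null(spec$start_dist)) {
    starts <- rep(target$length - target$window_len + 1L, n)
  } else {
    starts <- spec$start_dist$position[
      sample.int(nrow(spec$start_dist), n, replace = TRUE,
                 prob = spec$start_dist$probability)]
  }
  if (any(starts > ends)) abort("read start drawn 3' of the read end")
  inserts <- substring(target$bases, starts, ends)

  if (spec$chemistry == "tail") {
    d <- spec$tail_len_dist
    tail_len <- switch(d[[1]],
      fixed = rep(as.integer(d[[2]]), n),
      uniform = {
        lens <- seq.int(d[[2]], d[[3]])
        lens[sample.int(length(lens), n, replace = TRUE)]
      },
      geometric = as.integer(d[[3]]) + stats::rgeom(n, d[[2]])
    )
    suffix <- strrep(spec$tail_base, tail_len)
  } else {
    suffix <- rep(spec$adapter_seq, n)
  }

  filler <- strrep(.filler, ceiling(spec$read_len / nchar(.filler)))
  bases <- substr(paste0(inserts, suffix, filler), 1L, spec$read_len)

  if (spec$error_rate > 0) {
    bases <- .apply_substitutions(bases, spec$error_rate)
  }

  reads <- tibble(
    id = sprintf("synth_%s_%06d", spec$chemistry, seq_len(n)),
    bases = bases,
    quality = strrep("I", nchar(bases))
  )
  truth <- tibble(position = ends) |>
    count(.data$position, name = "count") |>
    arrange(.data$position)
  list(reads = reads, truth = truth)
}

.apply_substitutions <- function(bases, rate) {
  mat <- strsplit(bases, "", fixed = TRUE)
  alphabet <- c("A", "C", "G", "T")
  vapply(mat, function(ch) {
    hit <- stats::runif(length(ch)) < rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b) {
        sample(setdiff(alphabet, b), 1L)
      }, character(1))
    }
    paste(ch, collapse = "")
  }, character(1))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Expected collapsed profile of a synthetic tailed library
#'
#' Applies the analytic collapse oracle ([collapse_distribution()]) to the
#' realized end positions of a generated library: the per-position counts
#' the trim-and-profile pipeline must report exactly when the library is
#' error-free and every tail carries the full signature.
#'
#' @param spec A [synth_spec()] with tail chemistry.
#' @param truth The `truth` tibble returned by [generate_library()].
#' @return Tibble with columns `position` and `count`.
#' @export
truth_collapsed_profile <- function(spec, truth) {
  stopifnot(inherits(spec, "synth_spec"))
  if (spec$chemistry != "tail") {
    return(arrange(truth, .data$position))
  }
  amb <- annotate_ambiguity(spec$target, spec$tail_base)
  collapse_distribution(truth, amb)
}
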