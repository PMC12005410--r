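#' Tail and adapter trimming specifications
#'
#' A tailed small-RNA library carries a 3' homonucleotide tail on every read.
#' The tail signature used for trimming is a stretch of `run_len` consecutive
#' tail bases followed by at least `lookahead` further bases of which at least
#' `min_matches` are also the tail base; a read is cut immediately before the
#' first such stretch. The lookahead tolerates the occasional non-tail
#' incorporation near the start of the enzymatic tail while letting genuine
#' short genomic homopolymer runs survive.
#'
#' `N` bases never count as tail bases or adapter matches.
#'
#' @param tail_base Tailing nucleotide, one of `"A"`, `"C"`, `"G"`, `"T"`
#'   (a polyU tail is written `T`, as sequenced).
#' @param run_len Length of the seed homopolymer run (default 5).
#' @param lookahead Number of bases inspected after the run (default 4); the
#'   full window must exist, so a read ending in exactly `run_len` tail bases
#'   is not selected.
#' @param min_matches Minimum tail bases required inside the lookahead window
#'   (default 3).
#' @param min_retained_len Minimum trimmed-read length for a read to count as
#'   selected (default 4).
#' @return An object of class `tail_spec`.
#' @examples
#' spec <- tail_spec("A")
#' find_tail_start(c("GTTCGGTCAAAAAAAAAA", "GTTCGGTCAAAA"), spec)
#' @export
tail_spec <- function(tail_base, run_len = 5, lookahead = 4, min_matches = 3,
                      min_retained_len = 4) {
  tail_base <- match.arg(toupper(tail_base), c("A", "C", "G", "T"))
  stopifnot(run_len >= 1, min_retained_len >= 1, min_matches <= lookahead)
  structure(
    list(tail_base = tail_base, run_len = as.integer(run_len),
         lookahead = as.integer(lookahead), min_matches = as.integer(min_matches),
         min_retained_len = as.integer(min_retained_len)),
    class = "tail_spec"
  )
}

#' @rdname tail_spec
#' @param seed Exact adapter seed sequence matched with zero tolerated errors
#'   (default `"AGATCGG"`, the start of the TruSeq 3' adapter).
#' @export
adapter_spec <- function(seed = "AGATCGG", min_retained_len = 4) {
  seed <- .as_dna(seed)
  if (nchar(seed) < 4) abort("adapter seed must be at least 4 nt")
  structure(
    list(seed = seed, min_retained_len = as.integer(min_retained_len)),
    class = "adapter_spec"
  )
}

# Regex encoding of the tail signature: run_len literal tail bases with a
# lookahead of `lookahead` characters containing >= min_matches tail bases.
# Wildcard slots use [ACGTN] so alternatives are exactly `lookahead` long and
# the whole window must exist within the read.
.tail_signature_regex <- function(spec) {
  b <- spec$tail_base
  k <- spec$lookahead
  m <- spec$min_matches
  n_wild <- k - m
  if (n_wild == 0) {
    alts <- strrep(b, k)
  } else {
    slots <- utils::combn(k, n_wild, simplify = FALSE)
    alts <- vapply(slots, function(w) {
      chars <- rep(b, k)
      chars[w] <- "[ACGTN]"
      paste(chars, collapse = "")
    }, character(1))
  }
  paste0(strrep(b, spec$run_len), "(?=(?:", paste(alts, collapse = "|"), "))")
}

#' Locate the tail signature in reads
#'
#' Returns, for each read, the smallest 1-based position at which the tail
#' signature starts (the first base that will be removed), or `NA` when the
#' read carries no signature and is therefore unselected.
#'
#' @param bases Character vector of read sequences.
#' @param spec A [tail_spec()].
#' @return Integer vector of cut positions (`NA` = no signature).
#' @export
find_tail_start <- function(bases, spec) {
  stopifnot(inherits(spec, "tail_spec"))
  pos <- regexpr(.tail_signature_regex(spec), bases, perl = TRUE)
  out <- as.integer(pos)
  out[out == -1L] <- NA_integer_
  out
}

#' Trim 3' tails or adapters from reads
#'
#' `trim_reads()` removes homonucleotide tails at the tail signature;
#' `trim_adapter()` removes everything from the 5'-most exact occurrence of
#' the adapter seed onwards. Both classify every read as `selected`
#' (signature found, retained length sufficient), `too_short` (signature
#' found but the retained prefix is shorter than `min_retained_len`) or
#' `unselected` (no signature).
#'
#' @param reads Tibble with columns `id` and `bases` (e.g. from
#'   [read_fastq()]); extra columns are carried through.
#' @param spec A [tail_spec()] or [adapter_spec()].
#' @return The input tibble with added columns `status`, `cut_position`
#'   (1-based index of the first removed base, `NA` if unselected) and
#'   `trimmed` (the retained 5' prefix, `NA` unless selected or too_short).
#' @examples
#' reads <- tibble::tibble(id = "r1", bases = paste0("GTTCG", strrep("A", 12)))
#' trim_reads(reads, tail_spec("A"))
#' @export
trim_reads <- function(reads, spec) {
  stopifnot(is.data.frame(reads), all(c("id", "bases") %in% names(reads)),
            inherits(spec, "tail_spec"))
  cut <- find_tail_start(reads$bases, spec)
  .apply_cut(reads, cut, spec$min_retained_len)
}

#' @rdname trim_reads
#' @export
trim_adapter <- function(reads, spec = adapter_spec()) {
  stopifnot(is.data.frame(reads), all(c("id", "bases") %in% names(reads)),
            inherits(spec, "adapter_spec"))
  pos <- regexpr(spec$seed, reads$bases, fixed = TRUE)
  cut <- as.integer(pos)
  cut[cut == -1L] <- NA_integer_
  .apply_cut(reads, cut, spec$min_retained_len)
}

.apply_cut <- function(reads, cut, min_retained_len) {
  retained <- cut - 1L
  status <- dplyr::case_when(
    is.na(cut) ~ "unselected",
    retained < min_retained_len ~ "too_short",
    TRUE ~ "selected"
  )
  trimmed <- ifelse(is.na(cut), NA_character_, substr(reads$bases, 1L, retained))
  reads |>
    mutate(status = status, cut_position = cut, trimmed = trimmed)
}

#' Library selection statistics
#'
#' Partition of a trimmed library by selection status, with the percentage of
#' selected reads as a library-quality measure.
#'
#' @param outcomes Tibble with a `status` column, as returned by
#'   [trim_reads()] or [trim_adapter()].
#' @return One-row tibble with columns `total_reads`, `selected`,
#'   `too_short`, `unselected`, `pct_selected`.
#' @export
selection_stats <- function(outcomes) {
  stopifnot(is.data.frame(outcomes), "status" %in% names(outcomes))
  if (nrow(outcomes) == 0) abort("selection_stats() needs at least one read")
  tab <- table(factor(outcomes$status, levels = c("selected", "too_short", "unselected")))
  tibble(
    total_reads = nrow(outcomes),
    selected = as.integer(tab[["selected"]]),
    too_short = as.integer(tab[["too_short"]]),
    unselected = as.integer(tab[["unselected"]]),
    pct_selected = 100 * as.integer(tab[["selected"]]) / nrow(outcomes)
  )
}
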