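#' Map trimmed reads to a target 3' end
#'
#' `map_read_short()` implements prefix mapping for short targets: a trimmed
#' read is accepted iff it is at least `anchor_5p_len` bases long and an
#' exact prefix of the target; the mapped position is the read length.
#'
#' `map_read_long()` implements anchored mapping for long targets: the
#' 30-nt anchor (the first `anchor_len` of the last `window_len` target
#' bases) must occur exactly once in the read, every read base 3' of the
#' anchor must match the target, and the read must end at a target position
#' within the 3'-proximal end window. Reads in which the anchor occurs more
#' than once are rejected as ambiguous; reads extending past the target 3'
#' end are rejected, not clipped.
#'
#' @param trimmed Character vector of trimmed read sequences.
#' @param target A [target_seq()].
#' @return Integer vector of 1-based 3'-end target positions, `NA` where the
#'   read is rejected.
#' @export
map_read_short <- function(trimmed, target) {
  stopifnot(inherits(target, "target_seq"), target$mode == "short")
  len <- nchar(trimmed)
  ok <- !is.na(trimmed) &
    len >= target$anchor_5p_len &
    len <= target$length &
    trimmed == substring(target$bases, 1L, len)
  out <- ifelse(ok, len, NA_integer_)
  as.integer(out)
}

#' @rdname map_read_short
#' @export
map_read_long <- function(trimmed, target) {
  stopifnot(inherits(target, "target_seq"), target$mode == "long")
  L <- target$length
  w <- target$window_len
  a <- target$anchor_len
  anchor <- substr(target$bases, L - w + 1L, L - w + a)
  anchor_start_t <- L - w + 1L # target coordinate of anchor start
  min_end <- anchor_start_t + a - 1L # read may end flush with the anchor
  n_hits <- vapply(gregexpr(anchor, trimmed, fixed = TRUE),
                   function(m) sum(m > 0L), integer(1))
  hit <- as.integer(regexpr(anchor, trimmed, fixed = TRUE)) # read coord of anchor start
  len <- nchar(trimmed)
  # target coordinate of the read's final base if the anchor alignment holds
  end_pos <- anchor_start_t + (len - hit + 1L) - 1L
  # bases 3' of the anchor must match the target contiguously
  tail_read <- substring(trimmed, hit + a, len)
  tail_target <- substring(target$bases, min_end + 1L,
                           pmin.int(end_pos, L))
  ok <- !is.na(trimmed) & n_hits == 1L & hit > 0L &
    end_pos >= min_end & end_pos <= L &
    tail_read == tail_target
  out <- ifelse(ok, end_pos, NA_integer_)
  as.integer(out)
}

#' Build a normalized 3'-end profile
#'
#' Maps trimmed reads to the target (mode chosen automatically) and
#' aggregates accepted 3'-end positions into raw counts and per-mille
#' fractions `f1000[p] = 1000 * count[p] / total_mapped`. Dividing `f1000`
#' by 10 gives the percentage normalization used in per-library tables.
#'
#' @param trimmed Tibble with a `trimmed` column (from [trim_reads()] /
#'   [trim_adapter()]; rows with `status != "selected"` are ignored), or a
#'   character vector of trimmed sequences.
#' @param target A [target_seq()].
#' @param library_label Free-text library label (e.g. `"polyA"`).
#' @param tail_base Tailing nucleotide of the library, or `NULL` for
#'   adapter-ligated libraries.
#' @return An `end_profile` object: see [tidy.end_profile()] for the
#'   per-position table and [glance.end_profile()] for the summary row.
#' @examples
#' tg <- target_seq("pRNA", "GTTCGGTCAAAACTAGGTG")
#' build_profile(c("GTTCG", "GTTCGGTC", "GTTCGGTC"), tg, "demo", tail_base = "A")
#' @export
build_profile <- function(trimmed, target, library_label, tail_base = NULL) {
  stopifnot(inherits(target, "target_seq"))
  if (is.data.frame(trimmed)) {
    if (!"trimmed" %in% names(trimmed)) abort("expected a 'trimmed' column")
    if ("status" %in% names(trimmed)) {
      trimmed <- trimmed$trimmed[trimmed$status == "selected"]
    } else {
      trimmed <- trimmed$trimmed
    }
  }
  trimmed <- trimmed[!is.na(trimmed)]
  pos <- if (target$mode == "short") {
    map_read_short(trimmed, target)
  } else {
    map_read_long(trimmed, target)
  }
  accepted <- sum(!is.na(pos))
  if (accepted == 0) abort(sprintf("empty profile: no read mapped to target '%s'", target$id))
  counts <- tibble(position = pos[!is.na(pos)]) |>
    count(.data$position, name = "count") |>
    arrange(.data$position)
  end_profile_from_counts(
    target, counts,
    library_label = library_label, tail_base = tail_base,
    n_rejected = length(pos) - accepted
  )
}

#' Construct an end profile from a per-position count table
#'
#' Builds the same `end_profile` object as [build_profile()] directly from
#' counts, e.g. from a published per-library length-distribution table read
#' with [read_count_table()].
#'
#' @param target A [target_seq()].
#' @param counts Data frame with columns `position` and `count` (a
#'   `target_id` column, if present, must match the target).
#' @param library_label,tail_base As in [build_profile()].
#' @param n_rejected Number of reads rejected during mapping (bookkeeping
#'   only).
#' @return An `end_profile` object.
#' @export
end_profile_from_counts <- function(target, counts, library_label,
                                    tail_base = NULL, n_rejected = 0L) {
  stopifnot(inherits(target, "target_seq"), is.data.frame(counts),
            all(c("position", "count") %in% names(counts)))
  if ("target_id" %in% names(counts)) {
    if (!all(counts$target_id == target$id)) {
      abort(sprintf("count table is for target '%s', not '%s'",
                    counts$target_id[1], target$id))
    }
  }
  counts <- counts |>
    filter(.data$count > 0) |>
    arrange(.data$position)
  if (nrow(counts) == 0) abort("empty profile: all counts are zero")
  if (any(counts$position < 1 | counts$position > target$length)) {
    abort(sprintf("count position outside [1, %d] for target '%s'",
                  target$length, target$id))
  }
  if (anyDuplicated(counts$position)) abort("duplicated positions in count table")
  if (!is.null(tail_base)) tail_base <- match.arg(toupper(tail_base), c("A", "C", "G", "T"))
  total <- sum(counts$count)
  tb <- target_bases_vec(target)
  tab <- tibble(
    target_id = target$id,
    position = as.integer(counts$position),
    base = tb[counts$position],
    count = counts$count,
    f1000 = 1000 * counts$count / total
  )
  structure(
    list(
      target_id = target$id,
      library_label = library_label,
      tail_base = tail_base,
      positions = tab,
      total_mapped = total,
      n_rejected = as.integer(n_rejected)
    ),
    class = "end_profile"
  )
}

#' Dense f1000 vector over all target positions (0 where unobserved)
#' @noRd
profile_f1000_vector <- function(profile, target) {
  v <- numeric(target$length)
  v[profile$positions$position] <- profile$positions$f1000
  v
}

#' @export
print.end_profile <- function(x, ...) {
  cat(sprintf("<end_profile> target %s, library %s%s\n", x$target_id,
              x$library_label,
              if (!is.null(x$tail_base)) sprintf(" (tail %s)", x$tail_base) else " (adapter)"))
  cat(sprintf("  %d positions, %s mapped reads, %d rejected\n",
              nrow(x$positions), format(x$total_mapped), x$n_rejected))
  print(x$positions, n = 10)
  invisible(x)
}

#' Tidy an end profile
#'
#' @param x An `end_profile`.
#' @param ... Unused.
#' @return `tidy()`: the per-position tibble (`target_id`, `position`,
#'   `base`, `count`, `f1000`). `glance()`: a one-row summary with the
#'   library label, total mapped reads, number of occupied positions and the
#'   modal 3'-end position.
#' @export
tidy.end_profile <- function(x, ...) {
  x$positions
}

#' @rdname tidy.end_profile
#' @export
glance.end_profile <- function(x, ...) {
  tibble(
    target_id = x$target_id,
    library_label = x$library_label,
    tail_base = x$tail_base %||% NA_character_,
    total_mapped = x$total_mapped,
    n_positions = nrow(x$positions),
    n_rejected = x$n_rejected,
    modal_position = x$positions$position[which.max(x$positions$count)]
  )
}

#' Write / read an end profile as TSV
#'
#' Columns: `target_id`, `position`, `base`, `count`, `f1000`.
#' Reading requires the matching [target_seq()] to restore metadata.
#'
#' @param profile An `end_profile`.
#' @param path TSV path.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "end_profile"))
  readr::write_tsv(profile$positions, path)
  invisible(path)
}

#' @rdname write_profile
#' @param target A [target_seq()] matching the stored `target_id`.
#' @param library_label,tail_base Library metadata (not stored in the TSV).
#' @export
read_profile <- function(path, target, library_label, tail_base = NULL) {
  tbl <- readr::read_tsv(path, col_types = readr::cols())
  end_profile_from_counts(target, tbl, library_label = library_label,
                          tail_base = tail_base)
}

#' Histogram of trimmed read lengths
#'
#' @param trimmed Character vector of trimmed sequences, or a tibble with a
#'   `trimmed` column (only `status == "selected"` rows are used if a
#'   `status` column is present).
#' @return Tibble with columns `length` and `count`.
#' @export
length_histogram <- function(trimmed) {
  if (is.data.frame(trimmed)) {
    if ("status" %in% names(trimmed)) trimmed <- trimmed[trimmed$status == "selected", ]
    trimmed <- trimmed$trimmed
  }
  trimmed <- trimmed[!is.na(trimmed)]
  if (length(trimmed) == 0) {
    return(tibble(length = integer(), count = integer()))
  }
  tibble(length = nchar(trimmed)) |>
    count(.data$length, name = "count") |>
    arrange(.data$length)
}

#' Bar plot of an end profile
#'
#' @param object An `end_profile`.
#' @param ... Unused.
#' @return A ggplot object (f1000 by target position).
#' @export
autoplot.end_profile <- function(object, ...) {
  ggplot2::ggplot(object$positions,
                  ggplot2::aes(x = .data$position, y = .data$f1000)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(
      x = "3'-end position (nt)", y = expression(f[1000]),
      title = sprintf("%s / %s", object$target_id, object$library_label)
    ) +
    ggplot2::theme_minimal()
}
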