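#' Classify target positions by tailing ambiguity
#'
#' In a library tailed with base `tail_base`, any read ending inside a
#' maximal run of that base in the target — or ending at the run's 5'
#' neighbour (the *anchor*) — is trimmed back to the anchor, so all such
#' reads are indistinguishable and count at the anchor. This function
#' enumerates those collapse windows for one target/tail combination.
#'
#' A run starting at target position 1 has no anchor; its positions are
#' unresolvable in that library (such reads are trimmed away entirely).
#'
#' @param target A [target_seq()].
#' @param tail_base Tailing nucleotide.
#' @return An `ambiguity_map`: list with `positions` (tibble `position`,
#'   `base`, `class` in `direct`/`anchor`/`trimmed`/`unresolvable`,
#'   `window`) and `windows` (tibble `window`, `anchor`, `run_start`,
#'   `run_end`).
#' @examples
#' annotate_ambiguity(target_seq("pRNA", "GTTCGGTCAAAACTAGGTG"), "A")$windows
#' @export
annotate_ambiguity <- function(target, tail_base) {
  stopifnot(inherits(target, "target_seq"))
  tail_base <- match.arg(toupper(tail_base), c("A", "C", "G", "T"))
  tb <- target_bases_vec(target)
  r <- rle(tb == tail_base)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- r$values
  runs <- tibble(run_start = run_start[keep], run_end = run_end[keep])
  runs <- arrange(runs, .data$run_start)
  runs$anchor <- runs$run_start - 1L # 0 = anchorless (run at 5' terminus)
  runs$window <- seq_len(nrow(runs))

  class <- rep("direct", target$length)
  window <- rep(NA_integer_, target$length)
  for (i in seq_len(nrow(runs))) {
    idx <- runs$run_start[i]:runs$run_end[i]
    if (runs$anchor[i] >= 1L) {
      class[idx] <- "trimmed"
      class[runs$anchor[i]] <- "anchor"
      window[c(runs$anchor[i], idx)] <- runs$window[i]
    } else {
      class[idx] <- "unresolvable"
      window[idx] <- runs$window[i]
    }
  }
  structure(
    list(
      target_id = target$id,
      tail_base = tail_base,
      positions = tibble(position = seq_len(target$length), base = tb,
                         class = class, window = window),
      windows = select(runs, "window", "anchor", "run_start", "run_end")
    ),
    class = "ambiguity_map"
  )
}

#' @export
print.ambiguity_map <- function(x, ...) {
  cat(sprintf("<ambiguity_map> target %s, tail %s: %d window(s)\n",
              x$target_id, x$tail_base, nrow(x$windows)))
  print(x$windows)
  invisible(x)
}

#' Collapse a true 3'-end distribution under one tailing chemistry
#'
#' The analytic forward model of tail trimming: for each collapse window the
#' probability mass of the trimmed run positions is added to the anchor;
#' direct positions are unchanged. This is the profile a tailed library
#' would report if it sampled the true distribution without noise.
#'
#' @param true_dist Data frame with columns `position` and a mass column
#'   (`fraction`, `probability` or `count` — the first present is used).
#' @param ambiguity An `ambiguity_map` from [annotate_ambiguity()].
#' @return Tibble with columns `position` and the collapsed mass column,
#'   restricted to positions with non-zero mass.
#' @examples
#' amb <- annotate_ambiguity(target_seq("pRNA", "GTTCGGTCAAAACTAGGTG"), "A")
#' truth <- tibble::tibble(position = c(8, 9, 10, 13),
#'                         fraction = c(0.1, 0.4, 0.3, 0.2))
#' collapse_distribution(truth, amb)
#' @export
collapse_distribution <- function(true_dist, ambiguity) {
  stopifnot(inherits(ambiguity, "ambiguity_map"), is.data.frame(true_dist))
  mass_col <- intersect(c("fraction", "probability", "count"), names(true_dist))[1]
  if (is.na(mass_col)) abort("true_dist needs a 'fraction', 'probability' or 'count' column")
  pos_info <- ambiguity$positions
  if (any(!true_dist$position %in% pos_info$position)) {
    abort("true_dist has mass outside the target")
  }
  d <- left_join(true_dist, pos_info, by = "position")
  if (any(d$class == "unresolvable" & d[[mass_col]] > 0)) {
    abort("true_dist has mass on unresolvable positions (tail-base run at the 5' terminus)")
  }
  wins <- ambiguity$windows
  dest <- d$position
  trimmed <- d$class == "trimmed"
  dest[trimmed] <- wins$anchor[match(d$window[trimmed], wins$window)]
  tibble(position = dest, mass = d[[mass_col]]) |>
    group_by(.data$position) |>
    summarise(mass = sum(.data$mass), .groups = "drop") |>
    filter(.data$mass > 0) |>
    arrange(.data$position) |>
    rename(!!mass_col := "mass")
}
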