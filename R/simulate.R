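#' Simulate the profile a tailed library would report
#'
#' Deterministic forward simulation used for validation: given a reference
#' 3'-end profile assumed to be the truth (typically from a 3'-adapter
#' ligated library, which suffers no collapse), predict the per-position
#' counts a library tailed with `tail_base` and sequenced to `total_target`
#' mapped reads would report. Direct positions are scaled by
#' `SF = total_target / total_reference`; each collapse window reports the
#' SF-scaled sum of the reference counts over anchor plus run at the anchor,
#' and 0 over the run. Reference positions with zero counts inside a window
#' still belong to the window sum.
#'
#' @param reference An `end_profile`, or a data frame with columns
#'   `position` and `count`.
#' @param target A [target_seq()].
#' @param tail_base Tailing nucleotide of the simulated library.
#' @param total_target Mapped-read total of the simulated library.
#' @param total_reference Mapped-read total of the reference library.
#'   Defaults to the reference profile's `total_mapped` (or the sum of
#'   counts for a plain table); override when the supplied counts are a
#'   restricted view of a larger library.
#' @return A `simulated_profile` object with per-position real-valued
#'   counts and fractions, the scaling factor `sf`, and window annotations.
#' @examples
#' # tRNA 3' end CCA: reads ending at C74/C75 collapse under polyA tailing
#' tg <- target_seq("tRNA_3p", paste0(strrep("G", 72), "ACCA"),
#'                  window_len = 41)
#' ref <- tibble::tibble(position = 74:76, count = c(1, 21, 133))
#' simulate_tailed_profile(ref, tg, "A", total_target = 12038,
#'                         total_reference = 212)
#' @export
simulate_tailed_profile <- function(reference, target, tail_base, total_target,
                                    total_reference = NULL) {
  stopifnot(inherits(target, "target_seq"), total_target > 0)
  if (inherits(reference, "end_profile")) {
    ref_tbl <- reference$positions
    total_reference <- total_reference %||% reference$total_mapped
  } else {
    stopifnot(is.data.frame(reference),
              all(c("position", "count") %in% names(reference)))
    ref_tbl <- reference
    total_reference <- total_reference %||% sum(reference$count)
  }
  if (total_reference <= 0) abort("reference total must be positive")
  tail_base <- match.arg(toupper(tail_base), c("A", "C", "G", "T"))
  amb <- annotate_ambiguity(target, tail_base)
  pos_info <- amb$positions

  ref <- numeric(target$length)
  if (any(ref_tbl$position < 1 | ref_tbl$position > target$length)) {
    abort("reference counts outside the target")
  }
  ref[ref_tbl$position] <- ref_tbl$count
  if (any(ref[pos_info$class == "unresolvable"] > 0)) {
    abort("reference has mass on unresolvable positions (tail-base run at the 5' terminus)")
  }

  sf <- total_target / total_reference
  sim <- ref * sf
  wins <- filter(amb$windows, .data$anchor >= 1L)
  for (i in seq_len(nrow(wins))) {
    span <- c(wins$anchor[i], wins$run_start[i]:wins$run_end[i])
    sim[wins$anchor[i]] <- sum(ref[span]) * sf
    sim[wins$run_start[i]:wins$run_end[i]] <- 0
  }

  tab <- tibble(
    target_id = target$id,
    position = seq_len(target$length),
    base = pos_info$base,
    class = pos_info$class,
    window = pos_info$window,
    simulated_count = sim,
    fraction = sim / total_target
  )
  structure(
    list(
      target_id = target$id,
      tail_base = tail_base,
      sf = sf,
      total_target = total_target,
      total_reference = total_reference,
      positions = tab,
      windows = wins
    ),
    class = "simulated_profile"
  )
}

#' @export
print.simulated_profile <- function(x, ...) {
  cat(sprintf("<simulated_profile> target %s, tail %s, SF = %.3f\n",
              x$target_id, x$tail_base, x$sf))
  print(filter(x$positions, .data$simulated_count > 0))
  invisible(x)
}

#' @rdname tidy.end_profile
#' @export
tidy.simulated_profile <- function(x, ...) {
  x$positions
}

#' @rdname tidy.end_profile
#' @export
glance.simulated_profile <- function(x, ...) {
  tibble(
    target_id = x$target_id,
    tail_base = x$tail_base,
    sf = x$sf,
    total_target = x$total_target,
    total_reference = x$total_reference,
    sum_fraction = sum(x$positions$fraction)
  )
}

#' Convert a simulated profile to an end profile
#'
#' Rounds the real-valued simulated counts onto the `end_profile` container
#' so a simulated library can be fed to [merge_libraries()]. Counts are kept
#' real-valued (no rounding) to preserve exactness of downstream arithmetic.
#'
#' @param simulated A `simulated_profile`.
#' @param library_label Label for the derived profile.
#' @return An `end_profile`.
#' @export
as_end_profile <- function(simulated, library_label = NULL) {
  stopifnot(inherits(simulated, "simulated_profile"))
  tg_tbl <- filter(simulated$positions, .data$simulated_count > 0)
  lbl <- library_label %||% sprintf("simulated_poly%s", simulated$tail_base)
  # rebuild a minimal target context from the stored annotation
  structure(
    list(
      target_id = simulated$target_id,
      library_label = lbl,
      tail_base = simulated$tail_base,
      positions = tibble(
        target_id = simulated$target_id,
        position = tg_tbl$position,
        base = tg_tbl$base,
        count = tg_tbl$simulated_count,
        f1000 = 1000 * tg_tbl$simulated_count / simulated$total_target
      ),
      total_mapped = simulated$total_target,
      n_rejected = 0L
    ),
    class = "end_profile"
  )
}

#' Compare a simulated profile with an experimental one
#'
#' @param simulated A `simulated_profile`.
#' @param experimental An `end_profile` for the same target and tail base.
#' @return Tibble with columns `position`, `base`, `simulated_fraction`,
#'   `experimental_fraction`, `difference` (simulated minus experimental).
#' @export
compare_profiles <- function(simulated, experimental) {
  stopifnot(inherits(simulated, "simulated_profile"),
            inherits(experimental, "end_profile"))
  if (simulated$target_id != experimental$target_id) {
    abort("simulated and experimental profiles are for different targets")
  }
  if (!identical(simulated$tail_base, experimental$tail_base)) {
    abort("simulated and experimental profiles use different tail bases")
  }
  exp_frac <- numeric(max(simulated$positions$position))
  exp_frac[experimental$positions$position] <-
    experimental$positions$count / experimental$total_mapped
  simulated$positions |>
    mutate(
      simulated_fraction = .data$fraction,
      experimental_fraction = exp_frac[.data$position],
      difference = .data$simulated_fraction - .data$experimental_fraction
    ) |>
    select("position", "base", "simulated_fraction", "experimental_fraction",
           "difference")
}
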