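#' Merge two differently tailed 3'-end profiles
#'
#' The central algorithm of the package. Two libraries of the same RNA
#' population, tailed with different bases (typically polyA and polyC),
#' suffer complementary collapse ambiguities: reads ending in a run of the
#' tail base are trimmed back to the run's 5' anchor. Because the runs of
#' the two tail bases never overlap, each library retains per-position
#' information exactly where the other is collapsed, and the two can be
#' merged into one resolved per-mille distribution.
#'
#' The algorithm walks the target from the 3' end to the 5' start and
#' resolves each collapse window as it is encountered:
#'
#' * **case #1** — positions ambiguous in neither library: the merged value
#'   is the mean of the two f1000 values.
#' * **case #2** — a window whose anchor base is the *other* library's tail
#'   base (interlocking ambiguities): the run positions take the resolving
#'   library's values verbatim, and the collapsed library's estimate at the
#'   anchor is the collapsed total minus the resolving values summed over
#'   the run. The anchor itself is resolved by the next window 5' of it.
#' * **case #3** — the case #2 subtraction is negative (the libraries are
#'   incongruent): the anchor estimate is set to 0, the run receives the
#'   mean of the two competing totals (distributed proportionally when the
#'   run spans several positions), and a warning is recorded.
#' * **case #4** — a window whose anchor base is a non-tail base in both
#'   libraries: a scaling factor `SF = total_collapsed / total_resolved`
#'   rescales the resolving library's values over the whole anchor+run span
#'   into estimates for the collapsed library; the merged value is the
#'   per-position mean of the two estimates.
#'
#' Wherever two per-library estimates exist their sample standard deviation
#' `|x - y| / sqrt(2)` quantifies between-library disagreement; positions
#' carried by a single library are flagged and given sd 0.
#'
#' @param profile_x,profile_y `end_profile` objects for the same target with
#'   different `tail_base`s.
#' @param target The common [target_seq()].
#' @return A `merge_result` object; see [tidy.merge_result()] for the
#'   per-position table, [glance.merge_result()] for the summary, and
#'   [merged_read_counts()] for back-transformed counts.
#' @examples
#' tg <- target_seq("pRNA", "GTTCGGTCAAAACTAGGTG")
#' pa <- end_profile_from_counts(tg,
#'   tibble::tibble(position = c(5, 6, 7, 8, 13, 14),
#'                  count = c(4, 2, 4, 488, 48, 35)),
#'   "polyA", tail_base = "A")
#' pc <- end_profile_from_counts(tg,
#'   tibble::tibble(position = c(6, 7, 9, 10, 11, 12, 14, 15),
#'                  count = c(3, 200, 497, 368, 253, 98, 109, 2)),
#'   "polyC1", tail_base = "C")
#' merge_libraries(pa, pc, tg)
#' @export
merge_libraries <- function(profile_x, profile_y, target) {
  stopifnot(inherits(profile_x, "end_profile"), inherits(profile_y, "end_profile"),
            inherits(target, "target_seq"))
  if (profile_x$target_id != target$id || profile_y$target_id != target$id) {
    abort("profiles and target disagree on target_id")
  }
  if (is.null(profile_x$tail_base) || is.null(profile_y$tail_base)) {
    abort("both profiles must come from tailed libraries (tail_base set)")
  }
  if (profile_x$tail_base == profile_y$tail_base) {
    abort("identical tail bases: the two libraries must use different tails")
  }

  tb <- target_bases_vec(target)
  L <- target$length
  amb_x <- annotate_ambiguity(target, profile_x$tail_base)
  amb_y <- annotate_ambiguity(target, profile_y$tail_base)

  est_x <- .initial_estimates(profile_x, amb_x, target)
  est_y <- .initial_estimates(profile_y, amb_y, target)

  case <- rep("#1", L)
  single_source <- rep(FALSE, L)
  warnings <- character()

  # all collapse windows of both libraries, 3'-most run first
  wins <- bind_rows(
    mutate(amb_x$windows, lib = "x"),
    mutate(amb_y$windows, lib = "y")
  ) |>
    filter(.data$anchor >= 1L) |>
    arrange(dplyr::desc(.data$run_start))

  for (i in seq_len(nrow(wins))) {
    w <- wins[i, ]
    run <- w$run_start:w$run_end
    a <- w$anchor
    if (w$lib == "x") {
      coll <- est_x; res <- est_y
      tail_res <- profile_y$tail_base
      lab_coll <- profile_x$library_label; lab_res <- profile_y$library_label
    } else {
      coll <- est_y; res <- est_x
      tail_res <- profile_x$tail_base
      lab_coll <- profile_y$library_label; lab_res <- profile_x$library_label
    }
    total_coll <- coll[a]
    vals_res <- res[run]
    s_res <- sum(vals_res)

    if (tb[a] == tail_res) {
      # interlocking window: anchor itself is ambiguous in the resolving
      # library, so only the collapsed library's anchor estimate is formed
      corrected <- total_coll - s_res
      # tolerate float cancellation: only a genuinely negative remainder is
      # an incongruency between the libraries
      if (corrected < -1e-9) {
        mean_tot <- (total_coll + s_res) / 2
        scale <- mean_tot / s_res # s_res > total_coll >= 0, so s_res > 0
        coll[run] <- vals_res * scale
        res[run] <- vals_res * scale
        coll[a] <- 0
        case[run] <- "#3"
        single_source[run] <- TRUE
        warnings <- c(warnings, sprintf(
          paste0("incongruency at %s%d..%d (anchor %s%d): collapsed total ",
                 "%.2f in %s is below the resolved sum %.2f in %s; anchor ",
                 "estimate clamped to 0 and the mean of the totals assigned"),
          tb[w$run_start], w$run_start, w$run_end, tb[a], a,
          total_coll, lab_coll, s_res, lab_res))
      } else {
        coll[run] <- vals_res
        coll[a] <- max(corrected, 0)
        case[run] <- "#2"
        single_source[run] <- TRUE
      }
    } else {
      # anchor is a non-tail base in both libraries: local renormalization
      span <- c(a, run)
      vals_span <- res[span]
      total_res <- sum(vals_span)
      if (total_res > 0) {
        sf <- total_coll / total_res
        coll[span] <- vals_span * sf
        case[span] <- if (s_res == 0) "#1" else "#4"
      } else if (total_coll == 0) {
        coll[span] <- 0
        case[span] <- "#1"
      } else {
        # resolving library is empty over the span but the collapsed one is
        # not: nothing to scale; keep the mass at the anchor and warn
        coll[run] <- 0
        coll[a] <- total_coll
        res[a] <- 0
        case[span] <- "#4"
        warnings <- c(warnings, sprintf(
          paste0("incongruency at %s%d..%d (anchor %s%d): %s has no reads ",
                 "over the span but %s reports %.2f; mass kept at the anchor"),
          tb[w$run_start], w$run_start, w$run_end, tb[a], a,
          lab_res, lab_coll, total_coll))
      }
    }
    if (w$lib == "x") { est_x <- coll; est_y <- res } else { est_y <- coll; est_x <- res }
  }

  # positions never resolved in one library: tail-base runs at the 5'
  # terminus (no anchor). The other library's value is the only information.
  unres <- is.na(est_x) | is.na(est_y)
  case[unres] <- "unresolvable"
  single_source[unres] <- TRUE

  merged <- ifelse(unres,
                   dplyr::coalesce(est_x, est_y, 0),
                   (est_x + est_y) / 2)
  sd <- ifelse(unres | single_source, 0, abs(est_x - est_y) / sqrt(2))

  # guard renormalization over resolvable mass
  resolvable <- !unres
  total_f <- sum(merged[resolvable])
  renormalized <- FALSE
  if (abs(total_f - 1000) > 1e-6 && total_f > 0) {
    merged[resolvable] <- merged[resolvable] * 1000 / total_f
    sd[resolvable] <- sd[resolvable] * 1000 / total_f
    renormalized <- TRUE
    inform(sprintf("merged f1000 drifted to %.6f; renormalized to 1000", total_f))
  }

  merged_total <- (profile_x$total_mapped + profile_y$total_mapped) / 2
  tab <- tibble(
    target_id = target$id,
    position = seq_len(L),
    base = tb,
    merged_f1000 = merged,
    estimate_x = est_x,
    estimate_y = est_y,
    sd = sd,
    merged_count = merged / 1000 * merged_total,
    case = case,
    single_source = single_source
  )
  for (msg in warnings) warn(msg)
  structure(
    list(
      target_id = target$id,
      library_x = profile_x$library_label, tail_x = profile_x$tail_base,
      library_y = profile_y$library_label, tail_y = profile_y$tail_base,
      positions = tab,
      merged_total = merged_total,
      total_x = profile_x$total_mapped,
      total_y = profile_y$total_mapped,
      warnings = warnings,
      renormalized = renormalized
    ),
    class = "merge_result"
  )
}

#' @export
print.merge_result <- function(x, ...) {
  cat(sprintf("<merge_result> target %s: %s (tail %s) + %s (tail %s)\n",
              x$target_id, x$library_x, x$tail_x, x$library_y, x$tail_y))
  cat(sprintf("  merged_total = %.1f; %d incongruency warning(s)\n",
              x$merged_total, length(x$warnings)))
  print(filter(x$positions, .data$merged_f1000 > 0 | .data$case != "#1"), n = 25)
  invisible(x)
}

#' Per-position merged read counts
#'
#' Back-transforms the merged per-mille fractions to read counts by
#' `merged_f1000 / 1000 * merged_total`, where `merged_total` is the mean of
#' the two libraries' mapped-read totals.
#'
#' @param result A `merge_result`.
#' @return Tibble with columns `position`, `base`, `merged_count`.
#' @export
merged_read_counts <- function(result) {
  stopifnot(inherits(result, "merge_result"))
  select(result$positions, "position", "base", "merged_count")
}

#' Standard deviation of two per-library estimates
#'
#' Sample (n - 1) standard deviation of two values, `|x - y| / sqrt(2)`,
#' used for the per-position error bars of a merge.
#'
#' @param estimate_x,estimate_y Numeric vectors of per-library f1000
#'   estimates.
#' @return Numeric vector of standard deviations; `NA` in either input
#'   (single-source position) yields 0.
#' @export
position_sd <- function(estimate_x, estimate_y) {
  out <- abs(estimate_x - estimate_y) / sqrt(2)
  out[is.na(out)] <- 0
  out
}

#' Tidy a merge result
#'
#' @param x A `merge_result`.
#' @param ... Unused.
#' @return `tidy()`: per-position tibble with `merged_f1000`, the two
#'   per-library estimates, `sd`, `merged_count`, `case` label and the
#'   `single_source` flag. `glance()`: one-row summary (library labels,
#'   totals, f1000 sum, warning count).
#' @export
tidy.merge_result <- function(x, ...) {
  x$positions
}

#' @rdname tidy.merge_result
#' @export
glance.merge_result <- function(x, ...) {
  tibble(
    target_id = x$target_id,
    library_x = x$library_x, tail_x = x$tail_x,
    library_y = x$library_y, tail_y = x$tail_y,
    total_x = x$total_x, total_y = x$total_y,
    merged_total = x$merged_total,
    sum_f1000 = sum(x$positions$merged_f1000[x$positions$case != "unresolvable"]),
    n_warnings = length(x$warnings),
    n_case3 = sum(x$positions$case == "#3"),
    renormalized = x$renormalized
  )
}

#' Bar plot of a merged distribution with error bars
#'
#' @param object A `merge_result`.
#' @param ... Unused.
#' @return A ggplot object: merged f1000 per position with `sd` error bars.
#' @export
autoplot.merge_result <- function(object, ...) {
  d <- filter(object$positions, .data$merged_f1000 > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$merged_f1000)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$merged_f1000 - .data$sd, 0),
                   ymax = .data$merged_f1000 + .data$sd),
      width = 0.3
    ) +
    ggplot2::labs(
      x = "3'-end position (nt)", y = expression(merged ~ f[1000]),
      title = sprintf("%s: %s + %s merged", object$target_id,
                      object$library_x, object$library_y)
    ) +
    ggplot2::theme_minimal()
}

#' Write a merge result as TSV
#'
#' Columns: `target_id`, `position`, `base`, `merged_f1000`, `sd`,
#' `merged_count`, `case`, `single_source`.
#'
#' @param result A `merge_result`.
#' @param path TSV path.
#' @export
write_merge_result <- function(result, path) {
  stopifnot(inherits(result, "merge_result"))
  result$positions |>
    select("target_id", "position", "base", "merged_f1000", "sd",
           "merged_count", "case", "single_source") |>
    readr::write_tsv(path)
  invisible(path)
}

# dense estimate vector: reported f1000 at direct/anchor positions, NA at
# positions trimmed away in this library. Reported mass at trimmed positions
# is physically impossible for a correctly trimmed library; fold it into the
# window anchor with a warning so user-supplied tables stay usable.
.initial_estimates <- function(profile, amb, target) {
  est <- profile_f1000_vector(profile, target)
  pos_info <- amb$positions
  trimmed <- which(pos_info$class == "trimmed")
  bad <- trimmed[est[trimmed] > 0]
  if (length(bad) > 0) {
    wins <- amb$windows
    for (p in bad) {
      a <- wins$anchor[match(pos_info$window[p], wins$window)]
      est[a] <- est[a] + est[p]
    }
    warn(sprintf(
      "library %s reports mass at %d position(s) inside %s-runs; folded into the window anchors",
      profile$library_label, length(bad), amb$tail_base))
  }
  est[pos_info$class %in% c("trimmed")] <- NA_real_
  est[pos_info$class == "unresolvable"] <- NA_real_
  est
}
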