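#' Run the full trim / profile / merge pipeline
#'
#' Orchestrates the individual steps for a pair of differently tailed
#' libraries against one target: per-library trimming and selection
#' statistics, 3'-end profiling, and the two-library merge. Equivalent to
#' calling [trim_reads()], [build_profile()] and [merge_libraries()] in
#' sequence with the same parameters.
#'
#' @param config Named list (or path to a key-value config file read with
#'   [read_run_config()]) with entries:
#'   `targets` (FASTA path), `target_id` (optional; default first record),
#'   `reads_x`, `tail_x`, `label_x`, `reads_y`, `tail_y`, `label_y`
#'   (FASTQ paths, tail bases and labels of the two libraries),
#'   `min_retained_len` (optional, default 4),
#'   `out_dir` (optional; when set, TSV outputs are written there).
#' @return List with `stats_x`, `stats_y` (selection statistics),
#'   `profile_x`, `profile_y` (`end_profile`s), `merge` (`merge_result`),
#'   and `paths` (written files, if `out_dir` was set).
#' @export
run_all <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_run_config(config)
  }
  need <- c("targets", "reads_x", "tail_x", "reads_y", "tail_y")
  missing_keys <- setdiff(need, names(config))
  if (length(missing_keys) > 0) {
    abort(sprintf("run_all config is missing: %s", paste(missing_keys, collapse = ", ")))
  }
  if (toupper(config$tail_x) == toupper(config$tail_y)) {
    abort("identical tail bases: the two libraries passed to merge must differ")
  }
  min_len <- as.integer(config$min_retained_len %||% 4L)

  targets <- read_fasta(config$targets)
  if (nrow(targets) == 0) abort(sprintf("no targets in %s", config$targets))
  tid <- config$target_id %||% targets$id[1]
  row <- targets[targets$id == tid, ]
  if (nrow(row) == 0) abort(sprintf("target '%s' not found in %s", tid, config$targets))
  target <- target_seq(row$id, row$bases)

  run_side <- function(reads_path, tail, label) {
    reads <- read_fastq(reads_path)
    trimmed <- trim_reads(reads, tail_spec(tail, min_retained_len = min_len))
    list(
      stats = selection_stats(trimmed),
      profile = build_profile(trimmed, target, label, tail_base = tail)
    )
  }
  x <- run_side(config$reads_x, config$tail_x, config$label_x %||% "library_x")
  y <- run_side(config$reads_y, config$tail_y, config$label_y %||% "library_y")
  merged <- merge_libraries(x$profile, y$profile, target)

  paths <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      profile_x = file.path(config$out_dir, "profile_x.tsv"),
      profile_y = file.path(config$out_dir, "profile_y.tsv"),
      merged = file.path(config$out_dir, "merged.tsv"),
      stats = file.path(config$out_dir, "selection_stats.tsv")
    )
    write_profile(x$profile, paths$profile_x)
    write_profile(y$profile, paths$profile_y)
    write_merge_result(merged, paths$merged)
    readr::write_tsv(
      bind_rows(
        mutate(x$stats, library = x$profile$library_label, .before = 1),
        mutate(y$stats, library = y$profile$library_label, .before = 1)
      ),
      paths$stats
    )
  }
  list(
    target = target,
    stats_x = x$stats, stats_y = y$stats,
    profile_x = x$profile, profile_y = y$profile,
    merge = merged,
    paths = paths
  )
}

#' Packaged example data
#'
#' Paths to the small plain-text fixtures shipped with the package: the
#' 6S-1 pRNA target, the published per-library pRNA length-distribution
#' count tables for the polyA, polyC1 and polyC2 libraries, a synthetic
#' stand-in for the 3'-proximal part of tRNA-Glu with the adapter-library
#' reference counts at its 3' end, and the per-library mapped-read totals.
#'
#' @param file File name within `extdata`; with no argument, lists the
#'   available files.
#' @return A file path, or a character vector of file names.
#' @examples
#' tailend_example()
#' read_count_table(tailend_example("prna_polyA_counts.tsv"))
#' @export
tailend_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "tailend")))
  }
  path <- system.file("extdata", file, package = "tailend", mustWork = FALSE)
  if (!nzchar(path)) abort(sprintf("no packaged file '%s'", file))
  path
}
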