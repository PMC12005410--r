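#' Read target sequences from a FASTA file
#'
#' Sequences are case-folded to upper case and converted to the DNA alphabet
#' (`U` becomes `T`), so RNA-notation targets can be supplied directly.
#'
#' @param path Path to a FASTA file (plain or gzip-compressed).
#' @return A tibble with columns `id` and `bases`, one row per record.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">pRNA", "GUUCGGUCAAAACUAGGUG"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  x <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) abort(sprintf("malformed FASTA in %s: %s", path, conditionMessage(e)))
  )
  if (length(x) == 0) {
    return(tibble(id = character(), bases = character()))
  }
  tibble(
    id = sub("\\s.*$", "", names(x)),
    bases = unname(.as_dna(as.character(x)))
  )
}

#' Read sequencing reads from a FASTQ file
#'
#' Gzip compression is detected transparently. Base qualities are retained
#' verbatim but never interpreted by any downstream step in this package.
#'
#' @param path Path to a FASTQ or FASTQ.gz file.
#' @return A tibble with columns `id`, `bases` and `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTQ file not found: %s", path))
  parsed <- tryCatch(
    {
      x <- Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE)
      list(
        id = names(x),
        bases = unname(as.character(x)),
        qual = unname(as.character(S4Vectors::mcols(x)$qualities))
      )
    },
    error = function(e) abort(sprintf("malformed FASTQ in %s: %s", path, conditionMessage(e)))
  )
  bases <- .as_dna(parsed$bases)
  qual <- parsed$qual
  if (any(nchar(qual) != nchar(bases))) {
    bad <- which(nchar(qual) != nchar(bases))[1]
    abort(sprintf("FASTQ record '%s': quality length differs from sequence length",
                  parsed$id[bad]))
  }
  tibble(
    id = sub("\\s.*$", "", parsed$id),
    bases = bases,
    quality = qual
  )
}

#' Write reads to a FASTQ file
#'
#' @param reads Tibble with columns `id`, `bases` and optionally `quality`
#'   (missing qualities are filled with the constant character `"I"`).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads), all(c("id", "bases") %in% names(reads)))
  qual <- if ("quality" %in% names(reads)) reads$quality else strrep("I", nchar(reads$bases))
  x <- Biostrings::BStringSet(reads$bases)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path,
    format = "fastq",
    compress = grepl("\\.gz$", path),
    qualities = Biostrings::BStringSet(qual)
  )
  invisible(path)
}

#' Read and write per-position count tables
#'
#' Count tables are tab-separated files with columns `target_id`, `position`,
#' `base` and `count`, one row per occupied target position (1-based
#' coordinates along the target, 5' to 3'). For short targets sharing a 5'
#' end, position is numerically the RNA length.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `target_id`, `position`, `base`, `count`,
#'   positions sorted increasingly.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("count table not found: %s", path))
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    target_id = readr::col_character(),
    position = readr::col_integer(),
    base = readr::col_character(),
    count = readr::col_double()
  ))
  validate_count_table(tbl)
  arrange(tbl, .data$target_id, .data$position)
}

#' @rdname read_count_table
#' @param table Tibble with columns `target_id`, `position`, `base`, `count`.
#' @export
write_count_table <- function(table, path) {
  validate_count_table(table)
  readr::write_tsv(table, path)
  invisible(path)
}

validate_count_table <- function(tbl) {
  need <- c("target_id", "position", "base", "count")
  if (!all(need %in% names(tbl))) {
    abort(sprintf("count table must have columns %s", paste(need, collapse = ", ")))
  }
  if (nrow(tbl) == 0) abort("count table is empty (profiles must be non-empty)")
  if (any(tbl$count < 0)) abort("count table contains negative counts")
  dup <- tbl |> count(.data$target_id, .data$position) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicated position %d for target '%s'",
                  dup$position[1], dup$target_id[1]))
  }
  invisible(tbl)
}

#' Read a plain-text key-value run configuration
#'
#' One `key = value` (or `key value`) pair per line; `#` starts a comment.
#' Values are returned as character strings; consumers coerce as needed.
#'
#' @param path Path to the configuration file.
#' @return A named list of character values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*|\\s+")
  bad <- lengths(kv) < 2
  if (any(bad)) abort(sprintf("config line not in 'key = value' form: '%s'", lines[which(bad)[1]]))
  as.list(stats::setNames(
    vapply(kv, function(x) paste(x[-1], collapse = " "), character(1)),
    vapply(kv, `[[`, character(1), 1)
  ))
}
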