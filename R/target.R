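#' Define a profiling target
#'
#' A target is the reference sequence against which 3' ends are counted.
#' Two mapping modes exist, chosen by target length:
#'
#' * **short** (length < `window_len`, e.g. ultrashort pRNAs): reads must be
#'   an exact prefix of the target of at least `anchor_5p_len` bases; since
#'   all such RNAs share the 5' end, the mapped 3'-end position equals the
#'   trimmed read length.
#' * **long** (length >= `window_len`, e.g. tRNAs or long degradation
#'   fragments): reads must contain, mismatch-free, the first `anchor_len`
#'   bases of the last `window_len` bases of the target, and end at one of
#'   the final `window_len - anchor_len + 1` target positions.
#'
#' @param id Target identifier.
#' @param bases Target sequence (RNA notation accepted; stored as DNA).
#' @param anchor_5p_len Minimum exact 5' prefix for short-mode acceptance
#'   (default 5).
#' @param window_len 3'-proximal window length separating the two modes and
#'   bounding long-mode end positions (default 40).
#' @param anchor_len Length of the mismatch-free long-mode anchor (default 30).
#' @return An object of class `target_seq`.
#' @examples
#' target_seq("pRNA", "GUUCGGUCAAAACUAGGUG")
#' @export
target_seq <- function(id, bases, anchor_5p_len = 5, window_len = 40,
                       anchor_len = 30) {
  bases <- .as_dna(bases)
  stopifnot(nchar(bases) >= 1, anchor_len < window_len, anchor_5p_len >= 1)
  structure(
    list(
      id = id,
      bases = bases,
      length = nchar(bases),
      mode = if (nchar(bases) < window_len) "short" else "long",
      anchor_5p_len = as.integer(anchor_5p_len),
      window_len = as.integer(window_len),
      anchor_len = as.integer(anchor_len)
    ),
    class = "target_seq"
  )
}

#' @export
print.target_seq <- function(x, ...) {
  cat(sprintf("<target_seq> %s (%d nt, %s mode)\n", x$id, x$length, x$mode))
  cat(" ", x$bases, "\n")
  invisible(x)
}

target_bases_vec <- function(target) {
  strsplit(target$bases, "", fixed = TRUE)[[1]]
}
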