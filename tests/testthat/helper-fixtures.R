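# Shared fixtures: the 6S-1 pRNA target and the published per-library
# length-distribution counts used throughout the merge tests.

PRNA_SEQ <- "GTTCGGTCAAAACTAGGTG"

prna_target <- function() target_seq("pRNA_6S1", PRNA_SEQ)

polyA_counts <- function() {
  tibble::tibble(position = c(5L, 6L, 7L, 8L, 13L, 14L),
                 count = c(4, 2, 4, 488, 48, 35)) # total 581
}

polyC1_counts <- function() {
  tibble::tibble(position = c(6L, 7L, 9L, 10L, 11L, 12L, 14L, 15L),
                 count = c(3, 200, 497, 368, 253, 98, 109, 2)) # total 1530
}

polyA_profile <- function(tg = prna_target()) {
  end_profile_from_counts(tg, polyA_counts(), "polyA", tail_base = "A")
}

polyC1_profile <- function(tg = prna_target()) {
  end_profile_from_counts(tg, polyC1_counts(), "polyC1", tail_base = "C")
}

# random true 3'-end distribution on a target, avoiding positions that are
# unresolvable under either tail and (optionally) only on positions >= min_pos
random_true_dist <- function(target, tail_a = "A", tail_b = "C", min_pos = 5L) {
  bad <- unique(c(
    dplyr::filter(annotate_ambiguity(target, tail_a)$positions,
                  class == "unresolvable")$position,
    dplyr::filter(annotate_ambiguity(target, tail_b)$positions,
                  class == "unresolvable")$position
  ))
  pos <- setdiff(seq.int(min_pos, target$length), bad)
  w <- stats::runif(length(pos))
  keep <- w > 0.3
  if (!any(keep)) keep[1] <- TRUE
  pos <- pos[keep]
  w <- w[keep]
  tibble::tibble(position = pos, probability = w / sum(w))
}

# collapse a true distribution under one tail and scale it to a library of
# `total` mapped reads, yielding an end_profile with exact fractions
collapsed_profile <- function(target, true_dist, tail_base, total, label) {
  amb <- annotate_ambiguity(target, tail_base)
  coll <- collapse_distribution(true_dist, amb)
  end_profile_from_counts(
    target,
    tibble::tibble(position = coll$position,
                   count = coll$probability * total),
    label, tail_base = tail_base
  )
}
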