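test_that("library generation is byte-deterministic under a fixed seed", {
  tg <- prna_target()
  dist <- tibble::tibble(position = c(8, 9, 13), probability = c(0.5, 0.3, 0.2))
  spec <- synth_spec(tg, dist, n_reads = 200, tail_base = "A", seed = 7)
  l1 <- generate_library(spec)
  l2 <- generate_library(spec)
  expect_identical(l1$reads, l2$reads)
  expect_identical(l1$truth, l2$truth)
  expect_equal(sum(l1$truth$count), 200)
  expect_true(all(nchar(l1$reads$bases) == 75))
  # a different seed gives a different library
  l3 <- generate_library(synth_spec(tg, dist, n_reads = 200, tail_base = "A",
                                    seed = 8))
  expect_false(identical(l1$reads$bases, l3$reads$bases))
})

test_that("generation does not disturb the caller's RNG stream", {
  tg <- prna_target()
  dist <- tibble::tibble(position = 8, probability = 1)
  withr::local_seed(31)
  before <- stats::runif(1)
  set.seed(31)
  invisible(stats::runif(1))
  generate_library(synth_spec(tg, dist, n_reads = 10, seed = 1))
  after <- stats::runif(1)
  set.seed(31)
  ref <- stats::runif(2)
  expect_equal(c(before, after), ref)
})

test_that("error-free tailed libraries are fully selected and match the collapse oracle", {
  tg <- prna_target()
  dist <- tibble::tibble(position = c(7, 8, 9, 12, 13, 14),
                         probability = c(0.1, 0.4, 0.2, 0.1, 0.15, 0.05))
  for (seed in c(1, 23, 456)) {
    for (tail in c("A", "C")) {
      spec <- synth_spec(tg, dist, n_reads = 2000, tail_base = tail, seed = seed)
      lib <- generate_library(spec)
      trimmed <- trim_reads(lib$reads, tail_spec(tail))
      expect_equal(selection_stats(trimmed)$pct_selected, 100)
      prof <- build_profile(trimmed, tg, "synthetic", tail_base = tail)
      want <- truth_collapsed_profile(spec, lib$truth)
      expect_equal(tidy(prof)$position, want$position)
      expect_equal(tidy(prof)$count, want$count)
    }
  }
})

test_that("adapter-ligated synthetic libraries profile without collapse", {
  tg <- prna_target()
  dist <- tibble::tibble(position = c(8, 9, 12, 13), probability = c(.4, .3, .2, .1))
  spec <- synth_spec(tg, dist, n_reads = 1500, chemistry = "adapter", seed = 5)
  lib <- generate_library(spec)
  trimmed <- trim_adapter(lib$reads, adapter_spec())
  expect_equal(selection_stats(trimmed)$pct_selected, 100)
  prof <- build_profile(trimmed, tg, "adapter")
  expect_equal(tidy(prof)$count, lib$truth$count)
  expect_equal(tidy(prof)$position, lib$truth$position)
  # no collapse: truth_collapsed_profile is the identity for adapter libraries
  expect_equal(as.data.frame(truth_collapsed_profile(spec, lib$truth)),
               as.data.frame(lib$truth))
})

test_that("tail lengths below the signature length trigger a warning", {
  tg <- prna_target()
  dist <- tibble::tibble(position = 8, probability = 1)
  expect_warning(
    synth_spec(tg, dist, n_reads = 10, tail_base = "A",
               tail_len_dist = list("fixed", 6)),
    "unselected"
  )
})

test_that("long targets generate anchored fragments that map back", {
  withr::local_seed(17)
  # interleave non-A bases so the target carries no A-runs longer than 1 and
  # cannot itself contain the tail signature
  odd <- sample(c("C", "G", "T"), 30, replace = TRUE)
  even <- sample(c("A", "C", "G", "T"), 30, replace = TRUE)
  bases <- paste(as.vector(rbind(odd, even)), collapse = "")
  tg <- target_seq("long60", bases)
  amb <- annotate_ambiguity(tg, "A")$positions
  # programme ends on direct positions in the mapping window
  ok_pos <- amb$position[amb$class == "direct" & amb$position >= tg$length - 10]
  dist <- tibble::tibble(position = ok_pos,
                         probability = rep(1 / length(ok_pos), length(ok_pos)))
  spec <- synth_spec(tg, dist, n_reads = 500, tail_base = "A", seed = 2)
  lib <- generate_library(spec)
  trimmed <- trim_reads(lib$reads, tail_spec("A"))
  prof <- build_profile(trimmed, tg, "long-synth", tail_base = "A")
  expect_equal(tidy(prof)$position, lib$truth$position)
  expect_equal(tidy(prof)$count, lib$truth$count)
})
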