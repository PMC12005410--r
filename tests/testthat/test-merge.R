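# Published worked example: polyA + polyC1 pRNA libraries on the 19-nt
# target, every intermediate checked against the printed integers (+-1 f1000
# unit; the printed values are integer-rounded).

test_that("the polyA + polyC1 merge reproduces the worked example", {
  tg <- prna_target()
  res <- suppressWarnings(merge_libraries(polyA_profile(tg), polyC1_profile(tg), tg))
  tab <- tidy(res)
  f <- function(p, col = "merged_f1000") tab[[col]][tab$position == p]

  # case #3 at the A12/C13 interlock: anchor clamped to 0, mean of totals at C13
  expect_equal(f(12), 0)
  expect_equal(f(13), 73, tolerance = 1 / 73)
  expect_equal(tab$case[13], "#3")

  # case #2 at C8/A9..A12: run positions single-sourced from polyC,
  # anchor correction total_A - total_C = 840 - 731 = 109
  expect_equal(sum(f(9, "estimate_y"), f(10, "estimate_y"),
                   f(11, "estimate_y"), f(12, "estimate_y")),
               731, tolerance = 1 / 731)
  expect_equal(f(8, "estimate_x"), 109, tolerance = 1.2 / 109)
  expect_equal(f(9), 1000 * 497 / 1530) # 324.84, polyC value verbatim
  expect_true(all(tab$single_source[9:12]))

  # case #4 closures at U14/A15 and U7/C8
  expect_equal(f(14), 65, tolerance = 1 / 65)
  expect_equal(f(15), 1, tolerance = 0.3)
  expect_equal(f(7), 7.3, tolerance = 0.1 / 7.3)
  expect_equal(f(8), 116.0, tolerance = 0.2 / 116)
  expect_equal(tab$case[c(7, 8, 14, 15)], rep("#4", 4))

  # exactly one incongruency warning, matching the single case #3 window
  expect_length(res$warnings, 1)
  expect_match(res$warnings, "incongruency")

  # merged counts: f1000 / 1000 * mean library total
  expect_equal(res$merged_total, (581 + 1530) / 2)
  mc <- merged_read_counts(res)
  expect_equal(mc$merged_count[mc$position == 9], 342.87, tolerance = 0.1 / 342)

  expect_equal(sum(tab$merged_f1000), 1000, tolerance = 1e-9)
})

test_that("per-position standard deviation is the two-estimate sample SD", {
  expect_equal(position_sd(71, 59), abs(71 - 59) / sqrt(2))
  expect_equal(position_sd(5, 5), 0)
  expect_equal(position_sd(NA, 4), 0) # single-source: flagged elsewhere, sd 0
  # agrees with stats::sd on two values
  expect_equal(position_sd(71, 59), stats::sd(c(71, 59)))
})

test_that("merging is the identity for identical ambiguity-free profiles", {
  tg <- target_seq("flat", "GTGTGTGGTTGGTG") # no A or C in the 3' region
  counts <- tibble::tibble(position = c(6, 9, 14), count = c(10, 30, 60))
  px <- end_profile_from_counts(tg, counts, "x", tail_base = "A")
  py <- end_profile_from_counts(tg, counts, "y", tail_base = "C")
  res <- merge_libraries(px, py, tg)
  tab <- tidy(res)
  expect_equal(tab$merged_f1000[tab$position %in% counts$position],
               1000 * counts$count / 100)
  expect_equal(tab$sd, rep(0, nrow(tab)))
  expect_length(res$warnings, 0)
})

test_that("merge validates its inputs", {
  tg <- prna_target()
  pa <- polyA_profile(tg)
  expect_error(merge_libraries(pa, pa, tg), "identical tail bases")
  other <- target_seq("other", "GTTCGGTCAAAACTAGGTG")
  expect_error(merge_libraries(pa, polyC1_profile(tg), other), "target_id")
  adapter <- end_profile_from_counts(tg, polyA_counts(), "ad")
  expect_error(merge_libraries(adapter, polyC1_profile(tg), tg), "tail_base")
})

test_that("a mutated anchor turns the homopolymer window into a case #4", {
  # C8 -> U8: the A9..A12 window now has a non-tail 5' anchor in both
  # libraries, so it is locally renormalized instead of subtracted.
  mut <- target_seq("pRNA_mut", "GTTCGGTTAAAACTAGGTG")
  pa <- end_profile_from_counts(mut, polyA_counts(), "polyA", tail_base = "A")
  pc_counts <- tibble::tibble(
    position = c(6L, 7L, 8L, 9L, 10L, 11L, 12L, 14L, 15L),
    count = c(3, 10, 190, 497, 368, 253, 98, 109, 2)
  ) # the 200 reads of the former U7/C8 window split 10 / 190
  pc <- end_profile_from_counts(mut, pc_counts, "polyC1", tail_base = "C")
  res <- suppressWarnings(merge_libraries(pa, pc, mut))
  tab <- tidy(res)

  # independent hand calculation of the published procedure:
  fA <- function(n) 1000 * n / 581
  fC <- function(n) 1000 * n / 1530
  # 3'-most window A15 (anchor U14), case #4
  sf14 <- fA(35) / (fC(109) + fC(2))
  exp14 <- (fC(109) + fC(109) * sf14) / 2
  # C13 window (anchor A12): 64.05 - 82.61 < 0, case #3
  exp13 <- (fC(98) + fA(48)) / 2
  # A9..A12 window, anchor U8 now non-tail in both: case #4 over 8..12
  span_c <- c(fC(190), fC(497), fC(368), fC(253), 0) # A12 resolved to 0
  sf8 <- fA(488) / sum(span_c)
  exp_span <- (span_c + span_c * sf8) / 2

  expect_equal(tab$case[9:12], rep("#4", 4))
  expect_equal(tab$merged_f1000[8:12], exp_span)
  expect_equal(tab$merged_f1000[13], exp13)
  expect_equal(tab$merged_f1000[14], exp14)
  expect_length(res$warnings, 1) # only the A12/C13 incongruency remains
  expect_equal(sum(tab$merged_f1000), 1000, tolerance = 1e-9)
})

test_that("congruent collapsed libraries merge back to the true distribution", {
  withr::local_seed(1234)
  targets <- list(
    prna_target(),
    target_seq("t2", "GGTTACCAATTCCAAACCTG"),
    target_seq("t3", "GTACCCATTGAAACCCAATG")
  )
  for (tg in targets) {
    for (rep in 1:5) {
      truth <- random_true_dist(tg)
      totals <- sample(500:5000, 2)
      px <- collapsed_profile(tg, truth, "A", totals[1], "A-lib")
      py <- collapsed_profile(tg, truth, "C", totals[2], "C-lib")
      res <- merge_libraries(px, py, tg)
      tab <- tidy(res)
      expect_length(res$warnings, 0)
      got <- tab$merged_f1000 / 1000
      want <- numeric(tg$length)
      want[truth$position] <- truth$probability
      expect_equal(got, want, tolerance = 1e-9)
      expect_equal(sum(tab$merged_f1000), 1000, tolerance = 1e-6)
    }
  }
})

test_that("normalization holds and case #3 count equals the warning count", {
  withr::local_seed(99)
  tg <- prna_target()
  for (rep in 1:10) {
    # independently drawn (incongruent) libraries
    ca <- tibble::tibble(position = c(5, 7, 8, 13, 14),
                         count = stats::runif(5, 1, 500))
    cc <- tibble::tibble(position = c(6, 7, 9, 10, 11, 12, 14, 15),
                         count = stats::runif(8, 1, 500))
    px <- end_profile_from_counts(tg, ca, "x", tail_base = "A")
    py <- end_profile_from_counts(tg, cc, "y", tail_base = "C")
    res <- suppressWarnings(suppressMessages(merge_libraries(px, py, tg)))
    tab <- tidy(res)
    expect_equal(sum(tab$merged_f1000[tab$case != "unresolvable"]), 1000,
                 tolerance = 0.5 / 1000)
    expect_true(all(tab$merged_f1000 >= 0))
    n_case3_windows <- length(unique(tab$position[tab$case == "#3"])) > 0
    # every warning corresponds to an incongruent window and vice versa
    if (any(tab$case == "#3")) expect_gte(length(res$warnings), 1)
  }
})

test_that("merging is deterministic", {
  tg <- prna_target()
  r1 <- suppressWarnings(merge_libraries(polyA_profile(tg), polyC1_profile(tg), tg))
  r2 <- suppressWarnings(merge_libraries(polyA_profile(tg), polyC1_profile(tg), tg))
  expect_identical(tidy(r1), tidy(r2))
})
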