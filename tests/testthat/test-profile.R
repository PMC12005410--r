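test_that("short-mode mapping accepts exact prefixes of sufficient length", {
  tg <- prna_target()
  expect_equal(map_read_short("GTTCGGTCA", tg), 9L)
  expect_equal(map_read_short("GTTCGGTCAAAACTAGGTG", tg), 19L)
  expect_true(is.na(map_read_short("GTACGGTC", tg)))          # mismatch
  expect_true(is.na(map_read_short("GTTC", tg)))              # below 5' anchor
  expect_true(is.na(map_read_short("GTTCGGTCAAAACTAGGTGA", tg))) # longer than target
})

test_that("long-mode mapping anchors the first 30 of the last 40 nt", {
  withr::local_seed(3)
  bases <- paste(sample(c("A", "C", "G", "T"), 45, replace = TRUE), collapse = "")
  tg <- target_seq("toy45", bases)
  expect_equal(tg$mode, "long")
  anchor_start <- 45 - 40 + 1 # position 6
  # read covering target[1..40] ends at position 40 = L - 5
  expect_equal(map_read_long(substr(bases, 1, 40), tg), 40L)
  # read covering exactly the anchor ends flush at L - 10
  expect_equal(map_read_long(substr(bases, anchor_start, anchor_start + 29), tg), 35L)
  # one mismatch inside the anchor rejects the read
  mism <- substr(bases, 1, 40)
  flip <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  substr(mism, 20, 20) <- flip(substr(mism, 20, 20))
  expect_true(is.na(map_read_long(mism, tg)))
  # read extending 3' past the target end is rejected, not clipped
  expect_true(is.na(map_read_long(paste0(substr(bases, 6, 45), "ACGT"), tg)))
  # mismatch 3' of the anchor rejects too
  tail_mism <- substr(bases, 6, 42)
  substr(tail_mism, 33, 33) <- flip(substr(tail_mism, 33, 33))
  expect_true(is.na(map_read_long(tail_mism, tg)))
})

test_that("long-mode mapping rejects reads with an ambiguous anchor", {
  anchor <- strrep("ACGT", 8) # 32 nt; first 30 form the anchor
  bases <- paste0("GGGGG", anchor, substr("TTTCCCAA", 1, 8))
  tg <- target_seq("dup", bases)
  read <- paste0(substr(bases, 6, 45), "")
  doubled <- paste0(substr(bases, 6, 35), substr(bases, 6, 45))
  expect_true(is.na(map_read_long(doubled, tg)))
})

test_that("profiles aggregate counts and normalize to per-mille fractions", {
  tg <- prna_target()
  trimmed <- rep(
    c("GTTCG", "GTTCGG", "GTTCGGT", "GTTCGGTC", "GTTCGGTCAAAAC", "GTTCGGTCAAAACT"),
    c(4, 2, 4, 488, 48, 35)
  )
  prof <- build_profile(trimmed, tg, "polyA", tail_base = "A")
  expect_equal(prof$total_mapped, 581)
  tab <- tidy(prof)
  expect_equal(tab$position, c(5, 6, 7, 8, 13, 14))
  expect_equal(tab$count, c(4, 2, 4, 488, 48, 35))
  expect_equal(tab$f1000[tab$position == 8], 1000 * 488 / 581)
  expect_equal(sum(tab$f1000), 1000)
  expect_equal(glance(prof)$modal_position, 8)
  expect_error(build_profile("TTTTT", tg, "x"), "empty profile")
})

test_that("length histogram mirrors trimmed read lengths", {
  trimmed <- rep(c("GTTCG", "GTTCGGTC"), c(3, 2))
  h <- length_histogram(trimmed)
  expect_equal(h$length, c(5, 8))
  expect_equal(h$count, c(3, 2))
  expect_equal(nrow(length_histogram(character())), 0)
})

test_that("profile of a union equals the sum of profiles; counts are conserved", {
  tg <- prna_target()
  withr::local_seed(21)
  lens <- sample(5:19, 60, replace = TRUE)
  reads <- substring(PRNA_SEQ, 1, lens)
  junk <- rep("TTTTTTT", 10) # unmappable
  p_all <- build_profile(c(reads, junk), tg, "u")
  p1 <- build_profile(reads[1:30], tg, "a")
  p2 <- build_profile(reads[31:60], tg, "b")
  merged_counts <- dplyr::full_join(tidy(p1), tidy(p2), by = "position") |>
    dplyr::mutate(total = dplyr::coalesce(count.x, 0) + dplyr::coalesce(count.y, 0)) |>
    dplyr::arrange(position)
  expect_equal(tidy(p_all)$count, merged_counts$total)
  expect_equal(p_all$n_rejected, 10L)
  expect_equal(sum(tidy(p_all)$count) + p_all$n_rejected, 70)
})

test_that("profiles built from published counts match the table arithmetic", {
  tg <- prna_target()
  prof <- polyC1_profile(tg)
  expect_equal(prof$total_mapped, 1530)
  expect_equal(tidy(prof)$f1000[tidy(prof)$position == 9], 1000 * 497 / 1530)
  # the percentage normalization of the published table is f1000 / 10
  expect_equal(round(tidy(prof)$f1000[tidy(prof)$position == 9] / 10, 2), 32.48)
})
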