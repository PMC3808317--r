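MAT <- "TGGAGCTCCCTTTAGTCCAAC" # fixed 21-nt mature used across fixtures

test_that("precursor windows follow the flank arithmetic and truncate at bounds", {
  set.seed(51)
  ref <- tibble::tibble(
    id = "r1",
    sequence = paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                     collapse = ""))
  hit <- tibble::tibble(sequence = substr(ref$sequence, 200, 220),
                        ref_id = "r1", start = 200L, end = 220L,
                        strand = "+")
  w <- excise_candidate_precursors(hit, ref, flank_up = 20, flank_down = 160)
  expect_true(any(w$win_start == 180 & w$win_end == 200 + 21 + 160 - 1))
  expect_true(all(w$win_end - w$win_start + 1 >= 60 &
                    w$win_end - w$win_start + 1 <= 300))
  # hit at position 1: upstream flank truncated to the record start
  hit1 <- tibble::tibble(sequence = substr(ref$sequence, 1, 21),
                         ref_id = "r1", start = 1L, end = 21L, strand = "+")
  w1 <- excise_candidate_precursors(hit1, ref)
  expect_true(all(w1$win_start == 1))
  # record shorter than the minimum precursor: no windows
  tiny <- tibble::tibble(id = "t", sequence = strrep("ACGT", 10))
  expect_equal(nrow(excise_candidate_precursors(
    tibble::tibble(sequence = "ACGTACGTACGTACGTACGT", ref_id = "t",
                   start = 1L, end = 20L, strand = "+"), tiny)), 0L)
  # mature offset indexes the tag inside the strand-oriented precursor
  for (i in seq_len(nrow(w)))
    expect_equal(substr(w$precursor[i], w$mature_offset[i],
                        w$mature_offset[i] + 20), hit$sequence)
})

test_that("every planted hairpin interval is contained in an emitted window", {
  set.seed(52)
  hp <- perfect_hairpin(MAT)
  ref <- tibble::tibble(
    id = paste0("r", 1:3),
    sequence = vapply(1:3, function(i)
      paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE),
            collapse = ""), character(1)))
  starts <- c(100, 350, 600)
  for (i in 1:3)
    substr(ref$sequence[i], starts[i],
           starts[i] + nchar(hp$precursor) - 1) <- hp$precursor
  hits <- map_perfect(tibble::tibble(sequence = MAT), ref)
  w <- excise_candidate_precursors(hits, ref)
  for (i in 1:3) {
    iv <- c(starts[i], starts[i] + nchar(hp$precursor) - 1)
    contained <- any(w$ref_id == ref$id[i] & w$win_start <= iv[1] &
                       w$win_end >= iv[2])
    expect_true(contained, info = ref$id[i])
  }
})

test_that("hairpin evaluation applies the acceptance criteria in order", {
  hp <- perfect_hairpin(MAT)
  cand <- list(precursor = hp$precursor, mature_offset = hp$mature_offset,
               sequence = MAT)
  tags_with_star <- tibble::tibble(sequence = c(MAT, hp$star),
                                   count = c(50L, 2L))
  ok <- evaluate_hairpin_candidate(cand, tags_with_star)
  expect_true(ok$accepted)
  expect_equal(ok$star, hp$star)
  expect_equal(ok$star_count, 2L)
  expect_equal(ok$arm, "5p")
  expect_lt(ok$mfe, -18)

  # mature spanning the terminal loop
  f <- fold_mfe(hp$precursor)
  loop_mid <- nchar(hp$precursor) %/% 2
  spanning <- list(precursor = hp$precursor,
                   mature_offset = loop_mid - 10L, sequence = MAT)
  bad1 <- evaluate_hairpin_candidate(spanning, tags_with_star, fold = f)
  expect_false(bad1$accepted)
  expect_equal(bad1$reason, "loop overlap")

  # no star evidence: removing star reads never creates an acceptance
  no_star <- tibble::tibble(sequence = MAT, count = 50L)
  bad2 <- evaluate_hairpin_candidate(cand, no_star, fold = f)
  expect_false(bad2$accepted)
  expect_equal(bad2$reason, "no star evidence")

  # MFE threshold is checked last
  bad3 <- evaluate_hairpin_candidate(cand, tags_with_star, fold = f,
                                     mfe_max = -500)
  expect_false(bad3$accepted)
  expect_equal(bad3$reason, "mfe above threshold")
})

test_that("star-evidence monotonicity holds on a batch of random hairpins", {
  set.seed(53)
  for (i in 1:10) {
    m <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
               collapse = "")
    hp <- perfect_hairpin(m)
    cand <- list(precursor = hp$precursor, mature_offset = hp$mature_offset,
                 sequence = m)
    with_star <- evaluate_hairpin_candidate(
      cand, tibble::tibble(sequence = c(m, hp$star), count = c(20L, 3L)))
    without <- evaluate_hairpin_candidate(
      cand, tibble::tibble(sequence = m, count = 20L))
    expect_false(!with_star$accepted && without$accepted)
  }
})

test_that("aggregation merges identical matures and names by abundance", {
  tags <- tibble::tibble(sequence = c(MAT, "CCGGATTACCAGGATCCAGGT"),
                         count_CK = c(100L, 10L), count_Cd200 = c(50L, 5L))
  loci <- tibble::tibble(
    ref_id = c("r1", "r2", "r3", "r4", "r1"),
    strand = "+",
    win_start = c(1L, 1L, 1L, 1L, 500L),
    win_end = c(180L, 180L, 180L, 180L, 680L),
    precursor = strrep("A", 180), structure = strrep(".", 180),
    mfe = c(-40, -55, -42, -41, -30),
    mature = c(MAT, MAT, MAT, MAT, "CCGGATTACCAGGATCCAGGT"),
    arm = "5p", star = "X", star_count = 2L)
  agg <- aggregate_novel(loci, tags)
  expect_equal(nrow(agg), 2L)
  top <- agg[1, ]
  expect_equal(top$name, "miRn1")
  expect_equal(top$mature, chartr("T", "U", MAT))
  expect_equal(top$loci, 4L)          # four distinct loci, one entry
  expect_equal(top$mfe, -55)          # most stable representative
  expect_equal(agg$name[2], "miRn2")
  # overlapping windows on one record collapse into a single locus
  loci2 <- loci[c(1, 1), ]
  loci2$win_start <- c(1L, 50L); loci2$win_end <- c(180L, 230L)
  expect_equal(aggregate_novel(loci2, tags)$loci, 1L)
  # empty input
  empty <- aggregate_novel(tibble::tibble(), tags)
  expect_equal(nrow(empty), 0L)
})

test_that("discovery recovers a planted hairpin end to end", {
  set.seed(54)
  hp <- perfect_hairpin(MAT)
  ref <- tibble::tibble(
    id = "host",
    sequence = paste0(
      paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
            collapse = ""),
      hp$precursor,
      paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
            collapse = "")))
  tags <- tibble::tibble(sequence = c(MAT, hp$star),
                         count_CK = c(30L, 2L), count_Cd200 = c(10L, 1L))
  nd <- discover_novel_mirnas(tags, ref)
  expect_gte(nrow(nd$novel), 1L)
  expect_true(chartr("T", "U", MAT) %in% nd$novel$mature)
})
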