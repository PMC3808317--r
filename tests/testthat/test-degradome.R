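MIR <- "TGGAGCTCCTTAGTCCAACGA" # 21 nt; position 5 = G, position 10 = T

test_that("degradome filtering keeps 20-21 nt reads passing the quality rule", {
  reads <- tibble::tibble(
    sequence = c(paste0(strrep("ACGT", 5), "A"),  # 21 nt
                 substr(strrep("ACGT", 5), 1, 19),  # 19 nt
                 strrep("GTCA", 5)),          # 20 nt, no quality
    quality = c(strrep("I", 21), strrep("I", 19), NA))
  tags <- filter_degradome_reads(reads)
  expect_setequal(tags$sequence, c(paste0(strrep("ACGT", 5), "A"),
                                   strrep("GTCA", 5)))
  # low mean quality is dropped
  bad <- tibble::tibble(sequence = strrep("ACGT", 5),
                        quality = strrep("#", 20))
  expect_equal(nrow(filter_degradome_reads(bad)), 0L)
})

test_that("a mixed pool with 30% off-length reads retains exactly 70%", {
  set.seed(71)
  n <- 300
  mk <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                   replace = TRUE), collapse = "")
  lens <- rep(c(20, 21, 17), times = c(120, 90, 90))
  reads <- tibble::tibble(sequence = vapply(lens, mk, character(1)))
  tags <- filter_degradome_reads(reads)
  expect_equal(sum(tags$count), 210L)
})

test_that("alignment scoring follows the doubled-seed penalty scheme", {
  tx_perfect <- revcomp_chr(MIR)
  al <- align_mirna_to_transcript(MIR, tx_perfect)
  expect_equal(nrow(al), 1L)
  expect_equal(al$score, 0)
  expect_equal(al$cleavage_pos, 21 - 10 + 1)  # base opposite position 10

  # single G:U at miRNA position 5 (inside 2-13): 0.5 doubled = 1.0;
  # position 5 of MIR is 'G' so a target 'T' there gives G:U
  tv <- strsplit(tx_perfect, "")[[1]]
  tv[21 - 5 + 1] <- "T"
  al_gu <- align_mirna_to_transcript(MIR, paste(tv, collapse = ""))
  expect_equal(al_gu$score, 1.0)
  expect_equal(al_gu$gu, 1L)
  check <- rescore_window(MIR, paste(tv, collapse = ""))
  expect_equal(al_gu$score, check$score)

  # G:U at the cleavage site (position 10) is rejected outright
  tv10 <- strsplit(tx_perfect, "")[[1]]
  stopifnot(substr(MIR, 10, 10) == "T")
  tv10[21 - 10 + 1] <- "G"     # U:G wobble at position 10
  expect_equal(nrow(align_mirna_to_transcript(
    MIR, paste(tv10, collapse = ""))), 0L)

  # six mismatches exceed the allowance
  tv6 <- strsplit(tx_perfect, "")[[1]]
  for (p in c(1, 2, 3, 19, 20, 21)) {
    i <- 21 - p + 1
    tv6[i] <- setdiff(c("A", "C", "G", "T"),
                      c(tv6[i], "G", "T"))[1]  # avoid accidental wobble
  }
  expect_equal(nrow(align_mirna_to_transcript(
    MIR, paste(tv6, collapse = ""), max_score = 100)), 0L)

  # miRNA longer than the transcript: empty result
  expect_equal(nrow(align_mirna_to_transcript(MIR, "ACGTACGT")), 0L)
})

test_that("window scores equal an exhaustive per-window rescoring oracle", {
  set.seed(72)
  tx <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
              collapse = "")
  # plant a near-perfect site so at least one window passes
  site <- revcomp_chr(MIR)
  substr(tx, 150, 150 + nchar(site) - 1) <- site
  al <- align_mirna_to_transcript(MIR, tx, max_score = 6, max_mismatch = 5)
  expect_gte(nrow(al), 1L)
  for (i in seq_len(nrow(al))) {
    w <- substr(tx, al$start[i], al$end[i])
    o <- rescore_window(MIR, w)
    expect_equal(al$score[i], o$score)
    expect_equal(al$mismatches[i], o$mismatches)
    expect_true(o$wc_cleavage)
  }
  # oracle completeness: no window passing the filters is missed
  L <- nchar(MIR)
  for (s in seq_len(nchar(tx) - L + 1)) {
    o <- rescore_window(MIR, substr(tx, s, s + L - 1))
    passes <- o$score <= 6 && o$mismatches + o$gu <= 5 && o$wc_cleavage
    expect_equal(s %in% al$start, passes, info = s)
  }
})

test_that("t-plots conserve mass on the TP100M scale", {
  tp <- build_tplot(tibble::tibble(pos = 5L, count = 1L),
                    total_mapped = 1e8, transcript_id = "t")
  expect_equal(tp$tp100m, 1.0)
  set.seed(73)
  pos <- sample(500, 1000, replace = TRUE)
  d <- tibble::tibble(pos = pos, count = 1L)
  tp2 <- build_tplot(d, total_mapped = 4e4)
  expect_equal(sum(tp2$raw), 1000L)
  expect_equal(tp2$raw[match(as.integer(names(table(pos))), tp2$pos)],
               unname(as.integer(table(pos))))
  expect_equal(sum(tp2$tp100m), 1000 * 1e8 / 4e4)
})

test_that("cleavage categories follow the printed definitions", {
  as_tp <- function(profile) {
    build_tplot(tibble::tibble(pos = seq_along(profile),
                               count = as.integer(profile)),
                total_mapped = 100)
  }
  expect_equal(categorize_call(as_tp(c(0, 0, 9, 1, 1)), 3), "I")
  # max 9 elsewhere; median of occupied {9,5,1,1} = 3; 5 > 3 -> II
  expect_equal(categorize_call(as_tp(c(9, 0, 5, 1, 1)), 3), "II")
  # two maxima: never category I
  expect_true(categorize_call(as_tp(c(9, 9, 1, 0, 0)), 1) %in%
                c("II", "III"))
  # raw == 1 at a unique-max position is not category I
  expect_equal(categorize_call(as_tp(c(0, 1, 0, 0, 0)), 2), "III")
  # zero abundance: no call
  expect_true(is.na(categorize_call(as_tp(c(0, 2, 5)), 1)))
})

test_that("target calling integrates alignment, t-plot and category", {
  set.seed(74)
  tx <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
              collapse = "")
  substr(tx, 100, 120) <- revcomp_chr(MIR)
  transcripts <- tibble::tibble(id = "t1", sequence = tx)
  cleave <- 100 + 21 - 10   # transcript base opposite miRNA position 10
  sig_tag <- substr(tx, cleave, cleave + 19)
  other_tag <- substr(tx, 200, 219)
  deg <- tibble::tibble(sequence = c(sig_tag, other_tag),
                        count = c(50L, 10L))
  calls <- call_targets(tibble::tibble(id = "mirX", sequence = MIR),
                        transcripts, deg)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$cleavage_pos, cleave)
  expect_equal(calls$category, "I")
  expect_equal(calls$raw, 50L)
  expect_equal(calls$tp100m, 50 * 1e8 / 60)
  # empty degradome: empty call list
  expect_equal(nrow(call_targets(tibble::tibble(id = "mirX",
                                                sequence = MIR),
                                 transcripts,
                                 tibble::tibble(sequence = character(),
                                                count = integer()))), 0L)
})

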