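test_that("perfect mapping finds exact substring hits on both strands", {
  set.seed(21)
  ref <- tibble::tibble(
    id = "r1",
    sequence = paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                     collapse = ""))
  tag <- substr(ref$sequence, 10, 30)
  hits <- map_perfect(tibble::tibble(sequence = tag), ref)
  expect_true(any(hits$start == 10 & hits$strand == "+"))
  rc <- revcomp_chr(substr(ref$sequence, 50, 70))
  hits2 <- map_perfect(tibble::tibble(sequence = rc), ref)
  expect_true(any(hits2$start == 50 & hits2$strand == "-"))
  # empty reference: everything unmapped
  none <- map_perfect(tibble::tibble(sequence = tag),
                      tibble::tibble(id = character(),
                                     sequence = character()))
  expect_equal(nrow(none), 0L)
})

test_that("planted tags are recovered exactly as by a naive substring scan", {
  set.seed(22)
  ref <- tibble::tibble(
    id = paste0("r", 1:5),
    sequence = vapply(1:5, function(i)
      paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
            collapse = ""), character(1)))
  tags <- unique(vapply(1:50, function(i) {
    ri <- sample(5, 1); at <- sample(550, 1)
    s <- substr(ref$sequence[ri], at, at + 20)
    if (runif(1) < 0.3) revcomp_chr(s) else s
  }, character(1)))
  hits <- map_perfect(tibble::tibble(sequence = tags), ref)
  oracle <- do.call(rbind, lapply(tags, naive_hits, reference = ref))
  key <- function(d) sort(paste(d$sequence, d$ref_id, d$start, d$strand))
  expect_equal(key(hits), key(oracle))
})

test_that("ncRNA classes resolve by priority rRNA > tRNA > snRNA > snoRNA", {
  set.seed(23)
  shared <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                  collapse = "")
  db <- tibble::tibble(
    id = c("rrna1", "trna1", "snrna1"),
    class = c("rRNA", "tRNA", "snRNA"),
    sequence = c(paste0("GGGG", shared, "CCCC"),     # contains the tag too
                 paste0("AAAA", shared, "TTTT"),
                 paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                       collapse = "")))
  tags <- tibble::tibble(sequence = c(shared,
                                      substr(db$sequence[3], 5, 25),
                                      strrep("ACGT", 5)))
  out <- classify_ncrna(tags, db)
  expect_equal(out$nc_class, c("rRNA", "snRNA", NA))
  expect_error(classify_ncrna(tags, dplyr::mutate(db, class = "lncRNA")),
               "unknown ncRNA class")
})

test_that("planted ncRNA fragments are recovered at exactly the planted fraction", {
  set.seed(24)
  rr <- paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE),
              collapse = "")
  db <- tibble::tibble(id = "rrna1", class = "rRNA", sequence = rr)
  n_r <- 30; n_o <- 270
  frags <- vapply(seq_len(n_r), function(i) {
    at <- sample(770, 1); substr(rr, at, at + 20)
  }, character(1))
  others <- vapply(seq_len(n_o), function(i)
    paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE), collapse = ""),
    character(1))
  others <- setdiff(others, frags)
  tags <- tibble::tibble(sequence = unique(c(frags, others)))
  out <- classify_ncrna(tags, db)
  expect_equal(sum(out$nc_class %in% "rRNA"), length(unique(frags)))
})

test_that("known-miRNA assignment honours the mismatch threshold and ties", {
  db <- tibble::tibble(
    id = c("ath-miR1a", "ath-miR1b", "ath-miR2"),
    sequence = c("ACGTACGTACGTACGTACGTA",
                 "ACGTACGTACGTACGTACGTT",
                 "GGGGCCCCAAAATTTTGGGGC"))
  # exact hit
  t1 <- assign_known_mirna(tibble::tibble(sequence = db$sequence[3]), db)
  expect_equal(t1$mirna_id, "ath-miR2")
  expect_equal(t1$mismatches, 0L)
  # three substitutions from the closest member: unassigned
  far <- "TCGTACGTACGAACGTACGAA" # 3 mismatches vs miR1a, 4 vs miR1b
  t2 <- assign_known_mirna(tibble::tibble(sequence = far), db)
  expect_true(is.na(t2$mirna_id))
  # tie at 1 mismatch between miR1a and miR1b (differ only at last base):
  # lexicographically smallest member id wins
  tie <- "ACGTACGTACGTACGTACGTG"
  t3 <- assign_known_mirna(tibble::tibble(sequence = tie), db)
  expect_equal(t3$mirna_id, "ath-miR1a")
  expect_equal(t3$mismatches, 1L)
  expect_equal(t3$mirna_id, naive_best_member(tie, db))
  # overhanging bases each cost one mismatch
  t4 <- assign_known_mirna(tibble::tibble(
    sequence = paste0(db$sequence[1], "CA")), db)
  expect_equal(t4$mismatches, 2L)
  expect_error(assign_known_mirna(tibble::tibble(sequence = tie), db,
                                  max_mismatch = -1), "max_mismatch")
})

test_that("no unassigned tag is within the mismatch radius of any member", {
  set.seed(25)
  db <- tibble::tibble(
    id = paste0("fam-miR", 1:6),
    sequence = vapply(1:6, function(i)
      paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
            collapse = ""), character(1)))
  mutate_seq <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    at <- sample(length(v), k)
    v[at] <- vapply(v[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(v, collapse = "")
  }
  tags <- tibble::tibble(sequence = unique(vapply(1:60, function(i)
    mutate_seq(db$sequence[sample(6, 1)], sample(0:4, 1)), character(1))))
  out <- assign_known_mirna(tags, db, max_mismatch = 2)
  oracle <- vapply(tags$sequence, naive_best_member, character(1), db = db)
  expect_equal(out$mirna_id, unname(oracle))
})

test_that("family names parse from member identifiers", {
  expect_equal(parse_mirna_family(c("ath-miR156a-5p", "miR156d",
                                    "rsa-miRn5", "bna-miR5021", "foo")),
               c("miR156", "miR156", "miRn5", "miR5021", NA))
})

test_that("annotation assigns one class per tag and aggregates families", {
  set.seed(26)
  mir_db <- tibble::tibble(
    id = c("xx-miR9001a", "xx-miR9001b", "xx-miR9002"),
    sequence = c("ACCGTTGGAACCGGTTAACCG", "ACCGTTGGAACCGGTTAACCT",
                 "TGCATGCATGCATGCATGCAT"))
  rr <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
              collapse = "")
  nc_db <- tibble::tibble(id = "rrna1", class = "rRNA", sequence = rr)
  tags <- tibble::tibble(
    sequence = c(mir_db$sequence[1], mir_db$sequence[3],
                 substr(rr, 11, 31),
                 "CAGACCAGACCAGACCAGACC"),
    count_CK = c(10L, 5L, 7L, 3L),
    count_Cd200 = c(20L, 1L, 2L, 4L))
  ann <- annotate_tags(tags, ncrna_db = nc_db, mirna_db = mir_db)
  expect_equal(ann$class,
               c("known_miRNA", "known_miRNA", "rRNA", "unannotated"))
  # partition: every tag exactly one class; unique counts sum to total
  cd <- class_distribution(ann, "count_CK")
  expect_equal(sum(cd$unique[cd$class != "Total small RNAs"]),
               cd$unique[cd$class == "Total small RNAs"])
  expect_equal(sum(cd$total[cd$class != "Total small RNAs"]),
               cd$total[cd$class == "Total small RNAs"])
  fam <- family_table(ann)
  expect_equal(fam$family, c("miR9001", "miR9002"))
  # family aggregation mass: member reads sum to family reads
  expect_equal(fam$count_CK[fam$family == "miR9001"], 10L)
  expect_equal(fam$total, fam$count_CK + fam$count_Cd200)
  expect_equal(fam$ratio, round(fam$count_Cd200 / fam$count_CK, 2))
})
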