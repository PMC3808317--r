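# clean-read totals of the bundled control / treated libraries
N_CK <- 15779290
N_CD <- 13495250

test_that("per-million normalization matches the printed convention", {
  expect_equal(round(normalize_per_million(5, N_CK), 4), 0.3169)
  expect_equal(normalize_per_million(0, N_CK), 0)
  expect_equal(normalize_per_million(1234, 1234), 1e6)
  expect_error(normalize_per_million(5, 0), "total")
  expect_error(normalize_per_million(-1, 10), "count")
})

test_that("zero expression is floored at 0.001 and positives pass through", {
  expect_equal(pseudo_adjust(0), 0.001)
  expect_equal(pseudo_adjust(0.3169), 0.3169)
  expect_equal(pseudo_adjust(normalize_per_million(1, N_CK)),
               normalize_per_million(1, N_CK))
})

test_that("log2 fold changes reproduce the printed two-library values", {
  lfc <- function(ck, cd) {
    a <- pseudo_adjust(normalize_per_million(ck, N_CK))
    b <- pseudo_adjust(normalize_per_million(cd, N_CD))
    round(log2_fold_change(a, b), 2)
  }
  expect_equal(lfc(5, 0), -8.31)    # pseudo-count on the treated side
  expect_equal(lfc(65, 8), -2.80)
  expect_equal(lfc(0, 242), 14.13)  # pseudo-count on the control side
  expect_equal(log2_fold_change(3.5, 3.5), 0)
})

test_that("the count test is 1 at its symmetry point and matches the series", {
  for (x in c(0, 1, 7, 50))
    expect_equal(audic_claverie_pvalue(x, x, 1e6, 1e6), 1)
  # brute-force series value for (5, 0) at equal depths:
  # 2 * P(0|5) = 2 * (1/2)^6
  expect_equal(audic_claverie_pvalue(5, 0, 1e6, 1e6), 2 * 0.5^6)
  set.seed(61)
  for (i in 1:40) {
    x <- rpois(1, 60); y <- sample(0:max(0, x - 1), 1)
    n1 <- runif(1, 1e5, 2e6); n2 <- runif(1, 1e5, 2e6)
    expect_equal(audic_claverie_pvalue(x, y, n1, n2), # x > y: canonical
                 ac_series_p(x, y, n1, n2), tolerance = 1e-9)
    expect_equal(audic_claverie_pvalue(y, x, n2, n1), # swapped orientation
                 ac_series_p(x, y, n1, n2), tolerance = 1e-9)
  }
})

test_that("the count test agrees with the negative-binomial tail identity", {
  # P(k | x) with ratio r is the NB(size = x + 1, prob = 1/(1+r)) mass,
  # so the lower tail must match pnbinom
  set.seed(62)
  for (i in 1:25) {
    x <- rpois(1, 100); y <- sample(0:max(0, x - 1), 1)
    n1 <- runif(1, 5e5, 2e6); n2 <- runif(1, 5e5, 2e6)
    r <- n2 / n1
    lower <- stats::pnbinom(y, size = x + 1, prob = 1 / (1 + r))
    upper <- 1 - lower + stats::dnbinom(y, size = x + 1, prob = 1 / (1 + r))
    # tolerance covers accumulation differences between the term-by-term
    # sum and pnbinom's internal algorithm
    expect_equal(audic_claverie_pvalue(x, y, n1, n2),
                 min(1, 2 * min(lower, upper)), tolerance = 1e-6)
  }
})

test_that("regulation calls follow the ratio and significance thresholds", {
  expect_equal(classify_regulation(0.144, 1e-6), "down")
  expect_equal(classify_regulation(0.64, 1e-6), "ns")  # |log2fc| < 1
  expect_equal(classify_regulation(1, 0.001), "ns")
  expect_equal(classify_regulation(3.2, 0.2), "ns")    # not significant
  expect_equal(classify_regulation(3.2, 0.01), "up")
})

test_that("swapping libraries negates fold changes and swaps up and down", {
  counts <- tibble::tibble(id = paste0("m", 1:4),
                           count_ck = c(100L, 5L, 400L, 0L),
                           count_trt = c(100L, 80L, 40L, 60L))
  fwd <- mir_de(counts, 1e6, 2e6)
  rev <- mir_de(dplyr::rename(counts, count_ck = "count_trt",
                              count_trt = "count_ck"), 2e6, 1e6)
  expect_equal(fwd$log2fc, -rev$log2fc)
  expect_equal(fwd$pvalue, rev$pvalue)
  swap <- c(up = "down", down = "up", ns = "ns")
  expect_equal(unname(swap[fwd$regulation]), rev$regulation)
})

test_that("normalized values sum to one million over their own denominator", {
  set.seed(63)
  counts <- rpois(50, 200)
  expect_equal(sum(normalize_per_million(counts, sum(counts))), 1e6)
})

test_that("mir_de returns a tidy table with glance summary", {
  de <- mir_de(tibble::tibble(id = c("a", "b"),
                              count_ck = c(10L, 200L),
                              count_trt = c(90L, 210L)),
               total_ck = 1e6, total_trt = 1e6)
  td <- tidy(de)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "mir_de"))
  g <- glance(de)
  expect_equal(g$n, 2L)
  expect_equal(g$n_up, sum(de$regulation == "up"))
  expect_equal(de$significance[de$pvalue <= 0.01][1], "**")
})
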