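# Independent oracles used across the suite. These deliberately use
# naive algorithms (exhaustive enumeration, per-read rule application,
# direct series summation) so they share no code path with the
# implementations they check.

# --- folding: enumerate every nested structure -------------------------
enum_structures <- function(s, params = fold_params()) {
  b <- strsplit(s, "")[[1]]
  n <- length(b)
  valid <- rownames(params$stack)
  can <- function(i, j) {
    paste0(b[i], b[j]) %in% valid && j - i - 1 >= params$min_hairpin
  }
  rec <- function(i, j) {
    if (i >= j) return(list(integer(0)))
    out <- rec(i + 1, j) # i unpaired
    for (k in (i + 1):j) {
      if (!can(i, k)) next
      s1 <- rec(i + 1, k - 1)
      s2 <- if (k < j) rec(k + 1, j) else list(integer(0))
      for (a in s1) for (bb in s2) out <- c(out, list(c(i, k, a, bb)))
    }
    out
  }
  rec(1, n)
}

brute_force_mfe <- function(s, params = fold_params()) {
  s <- chartr("tT", "uU", toupper(s))
  n <- nchar(s)
  best <- 0
  for (pl in enum_structures(s, params)) {
    pr <- integer(n)
    if (length(pl)) {
      m <- matrix(pl, ncol = 2, byrow = TRUE)
      pr[m[, 1]] <- m[, 2]
      pr[m[, 2]] <- m[, 1]
    }
    e <- structure_energy(s, pr, params)
    if (e < best) best <- e
  }
  best
}

# --- cleaning: classify one read by direct rule application ------------
clean_rule_oracle <- function(seq, adapter3, adapter5 = NULL,
                              min_len = 15, max_len = 30) {
  seed <- substr(adapter3, 1, min(10, nchar(adapter3)))
  if (!is.null(adapter5) && grepl(adapter5, seq, fixed = TRUE))
    return("adapter5")
  if (nchar(seq) < nchar(seed)) return("no_insert")
  pos <- regexpr(seed, seq, fixed = TRUE)
  if (pos == 1) return("no_insert")
  insert <- if (pos > 1) substr(seq, 1, pos - 1) else seq
  na <- sum(strsplit(insert, "")[[1]] == "A")
  if (na / nchar(insert) >= 0.8 ||
      grepl(strrep("A", 10), insert, fixed = TRUE)) return("polya")
  if (nchar(insert) < min_len) return("short")
  if (nchar(insert) > max_len) return("long")
  "kept"
}

# --- annotation: naive substring scan ----------------------------------
naive_hits <- function(tag, reference) {
  revcomp <- function(x)
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  out <- list()
  for (i in seq_len(nrow(reference))) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") tag else revcomp(tag)
      s <- reference$sequence[i]
      p <- 1
      repeat {
        hit <- regexpr(pat, substr(s, p, nchar(s)), fixed = TRUE)
        if (hit < 0) break
        at <- p + hit - 1
        out[[length(out) + 1]] <- data.frame(
          sequence = tag, ref_id = reference$id[i],
          start = at, strand = strand)
        p <- at + 1
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(sequence = character(), ref_id = character(),
               start = integer(), strand = character())
}

# naive best-member search for known-miRNA assignment
naive_best_member <- function(tag, db, max_mismatch = 2) {
  dist1 <- function(a, b) {
    va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
    m <- min(length(va), length(vb))
    sum(va[seq_len(m)] != vb[seq_len(m)]) + abs(length(va) - length(vb))
  }
  d <- vapply(db$sequence, dist1, numeric(1), a = tag)
  best <- min(d)
  if (best > max_mismatch) return(NA_character_)
  sort(db$id[d == best])[1]
}

# --- degradome: independent per-window duplex scorer -------------------
rescore_window <- function(mirna, window) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  mv <- strsplit(mirna, "")[[1]]
  L <- length(mv)
  tv <- strsplit(window, "")[[1]]
  score <- 0; mm <- 0; gu <- 0; wc10 <- TRUE
  for (i in seq_len(L)) {
    tb <- tv[L - i + 1]
    mult <- if (i >= 2 && i <= 13) 2 else 1
    if (tb == comp[[mv[i]]]) {
    } else if ((mv[i] == "G" && tb == "T") || (mv[i] == "T" && tb == "G")) {
      gu <- gu + 1; score <- score + 0.5 * mult
      if (i %in% c(10, 11)) wc10 <- FALSE
    } else {
      mm <- mm + 1; score <- score + 1 * mult
      if (i %in% c(10, 11)) wc10 <- FALSE
    }
  }
  list(score = score, mismatches = mm, gu = gu, wc_cleavage = wc10)
}

# --- diff expr: direct series for the count test -----------------------
ac_series_p <- function(x, y, n1, n2) {
  # assumes the canonical orientation x > y; sums the posterior terms
  # one by one (each term computed stably on the log scale)
  r <- n2 / n1
  term <- function(k) exp(k * log(r) + lgamma(x + k + 1) - lgamma(x + 1) -
                            lgamma(k + 1) - (x + k + 1) * log1p(r))
  lower <- sum(vapply(0:y, term, numeric(1)))
  upper <- 1 - lower + term(y)
  min(1, 2 * min(lower, upper))
}

# --- small fixtures ----------------------------------------------------
revcomp_chr <- function(x)
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")

# a deterministic perfect hairpin around a given mature sequence;
# returns the precursor, the mature offset and the star sequence under
# the 2-nt 3' overhang rule
perfect_hairpin <- function(mature,
                            ext5 = "GATTCGAC", ext3 = "TCCGGA",
                            loop = "TTTCTTTCTTTC") {
  stem <- paste0(ext5, mature, ext3)
  pre <- paste0(stem, loop, revcomp_chr(stem))
  n <- nchar(pre)
  a <- nchar(ext5) + 1
  L <- nchar(mature)
  list(precursor = pre,
       mature_offset = a,
       star = substr(pre, n + 1 - (a + L - 3), n + 3 - a))
}

small_sim <- function(seed = 5) {
  sim_config(seed = seed, n_transcripts = 8L,
             transcript_len = c(400L, 900L), n_hairpins = 4L,
             depth = 2e4, degradome_depth = 5e3, n_target_mirnas = 3L,
             signature_reads = 40L)
}
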