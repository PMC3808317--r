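#' Excise candidate precursor windows around a mapped tag
#'
#' For each perfect reference hit of an unannotated tag, emits up to
#' two candidate precursor windows: one with the tag near the 5' end
#' of the window (downstream flank, tag on the 5p arm) and one with
#' the tag near the 3' end (upstream flank, tag on the 3p arm).
#' Windows are truncated at the reference bounds and kept only when
#' their length falls within `[min_precursor, max_precursor]`. Hits on
#' the minus strand are excised from the reverse complement.
#'
#' @param hits Tibble of perfect hits (`sequence`, `ref_id`, `start`,
#'   `end`, `strand`) from [map_perfect()].
#' @param reference Reference accepted by [as_reference()].
#' @param flank_up,flank_down Short and long flank lengths (defaults
#'   20 and 160 nt).
#' @param min_precursor,max_precursor Precursor length bounds
#'   (defaults 60-300 nt).
#' @return Tibble of candidate windows: `ref_id`, `strand`,
#'   `win_start`, `win_end` (reference coordinates), `precursor`
#'   (strand-oriented sequence), `mature_offset` (1-based position of
#'   the tag inside the precursor), `sequence` (the tag).
#' @export
excise_candidate_precursors <- function(hits, reference, flank_up = 20L,
                                        flank_down = 160L,
                                        min_precursor = 60L,
                                        max_precursor = 300L) {
  reference <- as_reference(reference)
  refseq <- setNames(reference$sequence, reference$id)
  hits <- as_tibble(hits)
  out <- vector("list", 0)
  for (i in seq_len(nrow(hits))) {
    rs <- refseq[[hits$ref_id[i]]]
    if (is.null(rs) || nchar(rs) < min_precursor) next
    n <- nchar(rs)
    s <- hits$start[i]; e <- hits$end[i]
    # in strand orientation, "upstream" of a minus hit is downstream in
    # reference coordinates
    if (hits$strand[i] == "+") {
      wins <- list(c(max(1L, s - flank_up), min(n, e + flank_down)),
                   c(max(1L, s - flank_down), min(n, e + flank_up)))
    } else {
      wins <- list(c(max(1L, s - flank_down), min(n, e + flank_up)),
                   c(max(1L, s - flank_up), min(n, e + flank_down)))
    }
    for (wn in unique(wins)) {
      len <- wn[2] - wn[1] + 1L
      if (len < min_precursor || len > max_precursor) next
      pre <- substr(rs, wn[1], wn[2])
      if (hits$strand[i] == "+") {
        off <- s - wn[1] + 1L
      } else {
        pre <- reverse_complement(pre)
        off <- wn[2] - e + 1L
      }
      out[[length(out) + 1]] <- tibble(
        ref_id = hits$ref_id[i], strand = hits$strand[i],
        win_start = wn[1], win_end = wn[2],
        precursor = pre, mature_offset = off,
        sequence = hits$sequence[i])
    }
  }
  if (length(out) == 0)
    return(tibble(ref_id = character(), strand = character(),
                  win_start = integer(), win_end = integer(),
                  precursor = character(), mature_offset = integer(),
                  sequence = character()))
  distinct(bind_rows(out))
}

# nearest paired position to `pos` within [lo, hi] of the pair vector,
# searching in direction `dir` (+1 or -1); NA when none
nearest_paired <- function(pairs, pos, lo, hi, dir) {
  p <- pos
  while (p >= lo && p <= hi) {
    if (pairs[p] > 0) return(p)
    p <- p + dir
  }
  NA_integer_
}

#' Evaluate one folded precursor candidate against miRNA criteria
#'
#' Applies the classic plant novel-miRNA screening criteria to a
#' folded candidate, in order: (i) the mature tag must lie on one arm
#' of the hairpin without spanning the terminal loop; (ii) at most
#' `max_duplex_mismatches` mature bases may be unpaired in the
#' miRNA/miRNA* duplex and no asymmetric bulge may exceed `max_bulge`
#' nt; (iii) a sequenced tag matching the star sequence (the duplex
#' partner with 2-nt 3' overhangs, computed from the pair table) must
#' be observed with at least one read; (iv) the precursor MFE must not
#' exceed `mfe_max`. Rejections carry the first failed criterion.
#'
#' @param candidate One row of [excise_candidate_precursors()] output
#'   (as a list or single-row tibble), or any list with `precursor`,
#'   `mature_offset` and `sequence`.
#' @param tags Tag table used for star evidence; its `count*` columns
#'   are summed per sequence.
#' @param fold Optional pre-computed [fold_mfe()] result for the
#'   precursor.
#' @param max_duplex_mismatches Maximum unpaired mature bases in the
#'   duplex (default 4).
#' @param max_bulge Maximum asymmetric bulge (default 2 nt).
#' @param mfe_max Maximum (least negative) acceptable MFE, kcal/mol
#'   (default -18).
#' @param params Folding parameters for [fold_mfe()].
#' @return A list: `accepted` (logical), `reason` (`NA` when
#'   accepted), and for accepted candidates `mature`, `arm`, `star`,
#'   `star_count`, `mfe`, `structure`.
#' @export
evaluate_hairpin_candidate <- function(candidate, tags, fold = NULL,
                                       max_duplex_mismatches = 4L,
                                       max_bulge = 2L, mfe_max = -18,
                                       params = fold_params()) {
  candidate <- as.list(candidate)
  pre <- normalize_nt(candidate$precursor)
  mstart <- candidate$mature_offset
  mlen <- nchar(candidate$sequence)
  mend <- mstart + mlen - 1L
  n <- nchar(pre)
  stopifnot(mstart >= 1, mend <= n)
  if (is.null(fold)) fold <- fold_mfe(pre, params)
  pairs <- fold$pairs
  reject <- function(reason) list(accepted = FALSE, reason = reason)

  # (i) mature on a single arm, not spanning the terminal loop
  mpos <- mstart:mend
  partners <- pairs[mpos]
  paired <- partners > 0
  if (!any(paired)) return(reject("loop overlap"))
  if (any(partners[paired] >= mstart & partners[paired] <= mend))
    return(reject("loop overlap"))
  side_up <- partners[paired] > mend
  if (length(unique(side_up)) > 1) return(reject("loop overlap"))

  # (ii) duplex quality
  if (sum(!paired) > max_duplex_mismatches)
    return(reject("duplex mismatches"))
  pp <- mpos[paired]
  if (length(pp) >= 2) {
    gaps_m <- diff(pp) - 1L
    gaps_s <- abs(diff(pairs[pp])) - 1L
    if (any(abs(gaps_m - gaps_s) > max_bulge))
      return(reject("asymmetric bulge"))
  }

  # (iii) star evidence: duplex partner with 2-nt 3' overhangs
  x1 <- nearest_paired(pairs, mstart, mstart, mend, +1L)
  x2 <- nearest_paired(pairs, mend - 2L, mstart, mend, -1L)
  if (is.na(x1) || is.na(x2)) return(reject("loop overlap"))
  star_lo <- max(1L, min(pairs[x1], pairs[x2]))
  star_hi <- min(n, max(pairs[x1], pairs[x2]) + 2L)
  star <- substr(pre, star_lo, star_hi)
  count_cols <- grep("^count", names(tags), value = TRUE)
  star_count <- sum(tags[tags$sequence == star, count_cols, drop = FALSE])
  if (!isTRUE(star_count >= 1)) return(reject("no star evidence"))

  # (iv) precursor stability
  if (fold$mfe > mfe_max) return(reject("mfe above threshold"))

  list(accepted = TRUE, reason = NA_character_,
       mature = candidate$sequence, arm = if (side_up[1]) "5p" else "3p",
       star = star, star_count = as.integer(star_count),
       mfe = fold$mfe, structure = fold$structure)
}

#' Discover novel miRNAs from unannotated tags
#'
#' Runs the full novel-miRNA screen: selects unannotated tags of
#' mature length (20-24 nt) with at least `min_reads` reads, maps them
#' perfectly to the reference, excises candidate precursor windows,
#' folds each window and applies the hairpin/star criteria of
#' [evaluate_hairpin_candidate()]. Accepted loci are merged with
#' [aggregate_novel()].
#'
#' @param tags Wide tag table (from [merge_tag_tables()] or
#'   [annotate_tags()]); when a `class` column is present only
#'   `unannotated` tags are considered.
#' @param reference Reference accepted by [as_reference()].
#' @param min_reads Minimum summed read count for a candidate mature
#'   tag (default 5).
#' @param mature_len Allowed mature lengths (default 20-24 nt).
#' @param max_loci Tags hitting more reference loci than this are
#'   treated as repeats and skipped (default 20).
#' @param flank_up,flank_down,min_precursor,max_precursor Window
#'   parameters, see [excise_candidate_precursors()].
#' @param max_duplex_mismatches,max_bulge,mfe_max Acceptance criteria,
#'   see [evaluate_hairpin_candidate()].
#' @param params Folding parameters.
#' @param name_prefix Serial-name prefix for accepted miRNAs.
#' @return A list of class `novel_discovery`: `novel` (the aggregated
#'   table from [aggregate_novel()]), `loci` (per-locus acceptances)
#'   and `rejections` (tibble of rejected candidates with reasons).
#' @export
discover_novel_mirnas <- function(tags, reference, min_reads = 5L,
                                  mature_len = 20:24, max_loci = 20L,
                                  flank_up = 20L, flank_down = 160L,
                                  min_precursor = 60L, max_precursor = 300L,
                                  max_duplex_mismatches = 4L, max_bulge = 2L,
                                  mfe_max = -18, params = fold_params(),
                                  name_prefix = "miRn") {
  tags <- as_tibble(tags)
  count_cols <- grep("^count", names(tags), value = TRUE)
  total <- rowSums(tags[, count_cols, drop = FALSE])
  cand <- tags[nchar(tags$sequence) %in% mature_len & total >= min_reads, ]
  if ("class" %in% names(tags))
    cand <- cand %>% filter(.data$class == "unannotated")
  hits <- map_perfect(cand, reference)
  if (nrow(hits)) {
    loci_per_tag <- hits %>% count(.data$sequence)
    keep <- loci_per_tag$sequence[loci_per_tag$n <= max_loci]
    hits <- hits %>% filter(.data$sequence %in% keep)
  }
  windows <- excise_candidate_precursors(hits, reference, flank_up,
                                         flank_down, min_precursor,
                                         max_precursor)
  acc <- vector("list", 0)
  rej <- vector("list", 0)
  # fold each distinct precursor once
  folds <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    key <- w$precursor
    f <- folds[[key]]
    if (is.null(f)) {
      f <- fold_mfe(w$precursor, params)
      folds[[key]] <- f
    }
    ev <- evaluate_hairpin_candidate(w, tags, fold = f,
                                     max_duplex_mismatches, max_bulge,
                                     mfe_max, params)
    if (ev$accepted) {
      acc[[length(acc) + 1]] <- tibble(
        ref_id = w$ref_id, strand = w$strand,
        win_start = w$win_start, win_end = w$win_end,
        precursor = w$precursor, structure = ev$structure, mfe = ev$mfe,
        mature = ev$mature, arm = ev$arm,
        star = ev$star, star_count = ev$star_count)
    } else {
      rej[[length(rej) + 1]] <- tibble(
        ref_id = w$ref_id, strand = w$strand, win_start = w$win_start,
        win_end = w$win_end, sequence = w$sequence, reason = ev$reason)
    }
  }
  loci <- if (length(acc)) bind_rows(acc) else tibble()
  structure(list(
    novel = aggregate_novel(loci, tags, name_prefix),
    loci = loci,
    rejections = if (length(rej)) bind_rows(rej) else tibble()),
    class = "novel_discovery")
}

# number of distinct genomic loci among candidate windows: windows on
# the same record whose intervals overlap (either strand; a hairpin
# and its reverse complement are the same locus) count once
count_distinct_loci <- function(d) {
  d <- d[order(d$ref_id, d$win_start), ]
  k <- 0L; cur_ref <- ""; cur_end <- -Inf
  for (r in seq_len(nrow(d))) {
    if (d$ref_id[r] != cur_ref || d$win_start[r] > cur_end) {
      k <- k + 1L; cur_ref <- d$ref_id[r]; cur_end <- d$win_end[r]
    } else cur_end <- max(cur_end, d$win_end[r])
  }
  k
}

#' Aggregate accepted hairpin loci into a unique novel-miRNA table
#'
#' Identical mature sequences from multiple loci merge into one entry
#' whose `loci` column counts the distinct source loci (windows
#' overlapping on the same record — either strand, since a hairpin and
#' its reverse complement describe the same locus — count once); the most
#' stable precursor (lowest MFE) represents the entry. Serial names
#' are assigned in order of descending total mature read count, ties
#' broken by mature sequence.
#'
#' @param loci Per-locus acceptance table (from
#'   [discover_novel_mirnas()]).
#' @param tags Wide tag table supplying per-library mature and star
#'   counts.
#' @param name_prefix Serial-name prefix (default `"miRn"`).
#' @return Tibble with `name`, `mature` (RNA alphabet), `length`,
#'   `precursor_length`, `mfe`, per-library mature counts, `star`,
#'   `star_count`, `loci`.
#' @export
aggregate_novel <- function(loci, tags, name_prefix = "miRn") {
  count_cols <- grep("^count", names(as_tibble(tags)), value = TRUE)
  if (is.null(loci) || nrow(loci) == 0) {
    out <- tibble(name = character(), mature = character(),
                  length = integer(), precursor_length = integer(),
                  mfe = numeric())
    for (cc in count_cols) out[[cc]] <- integer()
    out$star <- character(); out$star_count <- integer()
    out$loci <- integer()
    return(out)
  }
  tags <- as_tibble(tags)
  agg <- loci %>%
    group_by(.data$mature) %>%
    arrange(.data$mfe, .by_group = TRUE) %>%
    summarise(loci = count_distinct_loci(dplyr::pick("ref_id", "win_start",
                                                     "win_end")),
              mfe = dplyr::first(.data$mfe),
              precursor_length = nchar(dplyr::first(.data$precursor)),
              structure = dplyr::first(.data$structure),
              star = dplyr::first(.data$star),
              star_count = dplyr::first(.data$star_count),
              .groups = "drop")
  counts <- tags[match(agg$mature, tags$sequence), count_cols, drop = FALSE]
  counts[is.na(counts)] <- 0L
  agg <- bind_cols(agg, counts)
  agg$total <- rowSums(counts)
  agg <- agg %>%
    arrange(desc(.data$total), .data$mature) %>%
    mutate(name = paste0(name_prefix, row_number()),
           length = nchar(.data$mature),
           mature = to_rna(.data$mature))
  agg %>% select("name", "mature", "length", "precursor_length", "mfe",
                 dplyr::all_of(count_cols), "total", "star", "star_count",
                 "loci", "structure")
}

#' @export
print.novel_discovery <- function(x, ...) {
  cat("Novel miRNA discovery: ", nrow(x$novel), " unique miRNA(s) at ",
      sum(x$novel$loci), " distinct locus/loci (", nrow(x$loci),
      " accepted window(s)); ", nrow(x$rejections),
      " rejected candidate window(s)\n", sep = "")
  if (nrow(x$novel)) print(x$novel)
  invisible(x)
}

#' Mean minimum free energy of a set of precursors
#'
#' @param mfe Numeric vector of per-precursor MFE values (kcal/mol).
#' @param digits Rounding for the reported mean (default 1).
#' @return The rounded mean MFE.
#' @export
mean_precursor_mfe <- function(mfe, digits = 1) round(mean(mfe), digits)
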