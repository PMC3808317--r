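#' Filter and collapse degradome reads
#'
#' Retains 20-21 nt reads (the fragment size produced by MmeI-based
#' degradome protocols) whose mean base quality reaches `min_quality`
#' when qualities are present, and collapses them to unique tags.
#'
#' @param reads Tibble from [read_small_rna()] (columns `sequence`,
#'   optionally `count`, `quality`).
#' @param min_len,max_len Retained length window (defaults 20-21).
#' @param min_quality Minimum mean Phred quality (Sanger encoding) for
#'   reads that carry qualities; reads without qualities pass.
#' @return Tag table (`sequence`, `length`, `count`).
#' @export
filter_degradome_reads <- function(reads, min_len = 20L, max_len = 21L,
                                   min_quality = 20) {
  reads <- as_tibble(reads)
  if (!"count" %in% names(reads)) reads$count <- 1L
  if (!"quality" %in% names(reads)) reads$quality <- NA_character_
  reads$sequence <- normalize_nt(reads$sequence)
  len_ok <- nchar(reads$sequence) >= min_len & nchar(reads$sequence) <= max_len
  qual_ok <- vapply(reads$quality, function(q) {
    if (is.na(q) || !nzchar(q)) return(TRUE)
    mean(utf8ToInt(q) - 33) >= min_quality
  }, logical(1), USE.NAMES = FALSE)
  collapse_to_tags(reads[len_ok & qual_ok, ], library = "degradome") %>%
    select(-"library")
}

# penalty of pairing miRNA base (5'->3') against the target base it
# faces; both given in DNA alphabet. Returns the per-position state.
pair_state <- function(mir_base, target_base) {
  wc <- c(A = "T", C = "G", G = "C", T = "A")
  ifelse(target_base == wc[mir_base], "match",
         ifelse((mir_base == "G" & target_base == "T") |
                  (mir_base == "T" & target_base == "G"), "GU", "mismatch"))
}

#' Align a miRNA against a transcript for cleavage-target scoring
#'
#' Scans every window of the transcript for an ungapped antisense
#' duplex with the miRNA and scores it with the standard plant
#' target-prediction penalties: mismatch 1.0, G:U wobble 0.5, with
#' penalties doubled at miRNA positions 2-13 (the seed and central
#' region). Alignments are kept when the penalty does not exceed
#' `max_score`, the number of non-Watson-Crick positions (mismatches
#' plus G:U) does not exceed `max_mismatch`, and miRNA positions 10
#' and 11 are strict Watson-Crick pairs (the cleavage site tolerates
#' no wobble). The predicted cleavage position is the transcript base
#' paired to miRNA position 10, counted from the miRNA 5' end.
#'
#' @param mirna Mature miRNA sequence (18-26 nt, RNA or DNA alphabet).
#' @param transcript Transcript sequence (sense strand).
#' @param max_score Maximum penalty score (default 4.0).
#' @param max_mismatch Maximum number of non-match positions
#'   (default 5).
#' @return Tibble of alignments: `start`, `end` (target window,
#'   1-based), `cleavage_pos`, `score`, `mismatches`, `gu`, `states`
#'   (compact per-position string, miRNA 5'->3').
#' @export
align_mirna_to_transcript <- function(mirna, transcript, max_score = 4,
                                      max_mismatch = 5L) {
  mirna <- normalize_nt(mirna)
  transcript <- normalize_nt(transcript)
  L <- nchar(mirna)
  stopifnot(L >= 18, L <= 26)
  n <- nchar(transcript)
  empty <- tibble(start = integer(), end = integer(),
                  cleavage_pos = integer(), score = numeric(),
                  mismatches = integer(), gu = integer(),
                  states = character())
  if (n < L) return(empty)
  mv <- strsplit(mirna, "")[[1]]
  tv <- strsplit(transcript, "")[[1]]
  # weights per miRNA position: doubled in positions 2-13
  w <- ifelse(seq_len(L) >= 2 & seq_len(L) <= 13, 2, 1)
  out <- vector("list", 0)
  for (s in seq_len(n - L + 1)) {
    # miRNA position i faces target base s + L - i (antisense duplex)
    tb <- tv[s + L - seq_len(L)]
    st <- pair_state(mv, tb)
    if (st[10] != "match" || st[11] != "match") next
    mm <- sum(st == "mismatch")
    gu <- sum(st == "GU")
    if (mm + gu > max_mismatch) next
    score <- sum(w * (st == "mismatch") * 1.0 + w * (st == "GU") * 0.5)
    if (score > max_score) next
    out[[length(out) + 1]] <- tibble(
      start = s, end = s + L - 1L,
      cleavage_pos = s + L - 10L,
      score = score, mismatches = as.integer(mm), gu = as.integer(gu),
      states = paste(dplyr::case_when(st == "match" ~ "|",
                                      st == "GU" ~ "o",
                                      TRUE ~ "x"), collapse = ""))
  }
  if (length(out) == 0) empty else bind_rows(out)
}

#' Map degradome tags to transcripts (perfect, sense strand)
#'
#' @param tags Degradome tag table from [filter_degradome_reads()].
#' @param transcripts Reference accepted by [as_reference()].
#' @return List with `positions` (tibble `ref_id`, `pos` of the 5'
#'   end, `count`) and `total_mapped` (total mapped reads; each read
#'   is counted once no matter how many positions it matches).
#' @export
map_degradome <- function(tags, transcripts) {
  tags <- as_tibble(tags)
  hits <- match_tags_exact(tags$sequence, transcripts) %>%
    filter(.data$strand == "+")
  mapped <- hits %>%
    left_join(tags %>% select("sequence", "count"), by = "sequence")
  positions <- mapped %>%
    group_by(.data$ref_id, pos = .data$start) %>%
    summarise(count = sum(.data$count), .groups = "drop")
  total_mapped <- sum(tags$count[tags$sequence %in% hits$sequence])
  list(positions = positions, total_mapped = total_mapped)
}

#' Build the degradome signature profile (t-plot) of one transcript
#'
#' Accumulates the counts of degradome tags whose 5' end maps at each
#' transcript position and normalizes to transcripts per 100 million
#' mapped reads (TP100M = raw * 1e8 / total_mapped).
#'
#' @param positions Tibble with `pos` (1-based 5'-end position) and
#'   `count` for one transcript.
#' @param total_mapped Total degradome reads mapped across all
#'   transcripts (normalization denominator, > 0).
#' @param transcript_id Transcript identifier (metadata).
#' @return A `tplot` tibble: `pos`, `raw`, `tp100m`, ordered by
#'   position, with only occupied positions listed.
#' @export
build_tplot <- function(positions, total_mapped, transcript_id = NA) {
  stopifnot(total_mapped > 0)
  out <- as_tibble(positions) %>%
    group_by(.data$pos) %>%
    summarise(raw = sum(.data$count), .groups = "drop") %>%
    filter(.data$raw > 0) %>%
    mutate(tp100m = .data$raw * 1e8 / total_mapped) %>%
    arrange(.data$pos)
  attr(out, "transcript_id") <- transcript_id
  attr(out, "total_mapped") <- total_mapped
  class(out) <- c("tplot", class(out))
  out
}

#' Plot a degradome t-plot
#'
#' @param object A `tplot` from [build_tplot()].
#' @param cleavage Optional cleavage position(s) to highlight.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tplot <- function(object, cleavage = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$pos, y = .data$tp100m)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$pos, yend = 0)) +
    ggplot2::labs(x = "transcript position (nt)",
                  y = "signature abundance (TP100M)",
                  title = attr(object, "transcript_id")) +
    ggplot2::theme_minimal()
  if (!is.null(cleavage))
    p <- p + ggplot2::geom_point(
      data = as_tibble(object) %>% filter(.data$pos %in% cleavage),
      colour = "#d7301f", size = 2)
  p
}

#' Categorize a cleavage signature relative to its transcript profile
#'
#' Category I: the cleavage-position abundance equals the transcript
#' maximum, that maximum is attained at exactly one position, and the
#' raw count exceeds 1. Category II: abundance below the maximum but
#' above the median of occupied positions. Category III: everything
#' else. Positions with zero raw reads get no call (`NA`).
#'
#' @param tplot A `tplot` from [build_tplot()].
#' @param cleavage_pos Transcript position(s) to categorize.
#' @return Character vector over `{"I", "II", "III"}` (NA when the
#'   position carries no signature).
#' @export
categorize_call <- function(tplot, cleavage_pos) {
  raw <- setNames(tplot$raw, tplot$pos)
  mx <- max(tplot$raw)
  unique_max <- sum(tplot$raw == mx) == 1L
  med <- median(tplot$raw)
  vapply(cleavage_pos, function(p) {
    r <- raw[as.character(p)]
    if (is.na(r) || r < 1) return(NA_character_)
    if (r == mx && unique_max && r > 1) "I"
    else if (r < mx && r > med) "II"
    else "III"
  }, character(1), USE.NAMES = FALSE)
}

#' Call miRNA cleavage targets from degradome data
#'
#' For every miRNA/transcript alignment that passes the
#' complementarity filters ([align_mirna_to_transcript()]) and whose
#' predicted cleavage position carries degradome signature, emits a
#' cleavage call with the signature abundance (raw and TP100M) and
#' its category. Output rows are ordered by transcript id, cleavage
#' position, then miRNA id.
#'
#' @param mirnas Mature miRNAs: reference accepted by
#'   [as_reference()] (18-26 nt sequences).
#' @param transcripts Transcript reference.
#' @param degradome_tags Tag table from [filter_degradome_reads()].
#' @param max_score,max_mismatch Alignment thresholds, see
#'   [align_mirna_to_transcript()].
#' @return Tibble of cleavage calls: `mirna_id`, `target_id`,
#'   `cleavage_pos`, `category`, `raw`, `tp100m`, `score`,
#'   `mismatches`.
#' @export
call_targets <- function(mirnas, transcripts, degradome_tags,
                         max_score = 4, max_mismatch = 5L) {
  mirnas <- as_reference(mirnas)
  transcripts <- as_reference(transcripts)
  deg <- map_degradome(degradome_tags, transcripts)
  empty <- tibble(mirna_id = character(), target_id = character(),
                  cleavage_pos = integer(), category = character(),
                  raw = integer(), tp100m = numeric(), score = numeric(),
                  mismatches = integer())
  if (deg$total_mapped == 0) return(empty)
  tplots <- deg$positions %>%
    split(.$ref_id) %>%
    lapply(function(d) build_tplot(d, deg$total_mapped, d$ref_id[1]))
  out <- vector("list", 0)
  for (ti in seq_len(nrow(transcripts))) {
    tp <- tplots[[transcripts$id[ti]]]
    if (is.null(tp)) next
    for (mi in seq_len(nrow(mirnas))) {
      al <- align_mirna_to_transcript(mirnas$sequence[mi],
                                      transcripts$sequence[ti],
                                      max_score, max_mismatch)
      if (nrow(al) == 0) next
      al <- al %>% filter(.data$cleavage_pos %in% tp$pos)
      if (nrow(al) == 0) next
      raw <- setNames(tp$raw, tp$pos)[as.character(al$cleavage_pos)]
      out[[length(out) + 1]] <- tibble(
        mirna_id = mirnas$id[mi],
        target_id = transcripts$id[ti],
        cleavage_pos = al$cleavage_pos,
        category = categorize_call(tp, al$cleavage_pos),
        raw = as.integer(raw),
        tp100m = unname(raw) * 1e8 / deg$total_mapped,
        score = al$score,
        mismatches = al$mismatches)
    }
  }
  if (length(out) == 0) return(empty)
  bind_rows(out) %>%
    arrange(.data$target_id, .data$cleavage_pos, .data$mirna_id)
}
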