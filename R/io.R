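#' Read small-RNA reads from FASTA or FASTQ
#'
#' Reads a small-RNA library into a tibble. FASTQ qualities are kept as
#' character strings; collapsed-FASTA headers of the form
#' `seqN_xCOUNT` are recognised and their counts expanded into the
#' `count` column. U is normalised to T on ingest so all internal
#' sequences are DNA-alphabet.
#'
#' @param path Path to a FASTA or FASTQ file (optionally gzipped).
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @return A tibble with columns `id`, `sequence`, `count`, `quality`
#'   (`NA` when absent).
#' @export
read_small_rna <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  if (format == "fastq") {
    ss <- Biostrings::readBStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
    qual <- as.character(S4Vectors::mcols(ss)$qualities)
  } else {
    ss <- Biostrings::readBStringSet(path, format = "fasta")
    qual <- rep(NA_character_, length(ss))
  }
  ids <- names(ss)
  if (is.null(ids)) ids <- paste0("read", seq_along(ss))
  counts <- rep(1L, length(ss))
  collapsed <- grepl("_x\\d+$", ids)
  counts[collapsed] <- as.integer(sub(".*_x(\\d+)$", "\\1", ids[collapsed]))
  tibble(id = ids,
         sequence = normalize_nt(as.character(ss)),
         count = counts,
         quality = qual)
}

# uppercase and U -> T
normalize_nt <- function(x) chartr("uU", "TT", toupper(x))

# T -> U, for emitting mature miRNA sequences in RNA alphabet
to_rna <- function(x) chartr("tT", "UU", x)

reverse_complement <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", normalize_nt(s)), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Clean raw small-RNA reads
#'
#' Applies the standard small-RNA cleaning rules: reads containing the
#' 5' adapter are discarded as primer contaminants; the 3' adapter is
#' located by its leading bases and trimmed off; reads whose insert is
#' empty (adapter-dimer) or that are shorter than the adapter seed are
#' discarded as having no inserted tag; poly(A) inserts are discarded;
#' finally inserts outside `[min_len, max_len]` are discarded. A read
#' in which the 3' adapter is not found keeps its full sequence as the
#' insert (the length filter removes untrimmed long reads), which makes
#' cleaning idempotent. Each discarded read is tallied under the first
#' rule it fails, in the order adapter5 > no_insert > polya > short >
#' long.
#'
#' An insert counts as poly(A) when at least `polya_frac` of its bases
#' are A or it contains a run of at least `polya_run` consecutive A's.
#'
#' @param reads Tibble from [read_small_rna()] (columns `sequence`,
#'   optionally `id`, `count`, `quality`).
#' @param adapter3 3' adapter sequence (required, non-empty).
#' @param adapter5 Optional 5' adapter sequence; reads containing it
#'   are discarded.
#' @param min_len,max_len Retained insert length window (default 15-30
#'   nt).
#' @param polya_frac,polya_run Poly(A) rule parameters.
#' @param adapter_seed Number of leading adapter bases used to locate
#'   the 3' adapter.
#' @return A tibble of retained reads with the trimmed insert in
#'   `sequence`; the per-rule rejection tally (read counts) is attached
#'   as attribute `"tally"` and can be read with [clean_tally()].
#' @export
clean_reads <- function(reads, adapter3, adapter5 = NULL,
                        min_len = 15L, max_len = 30L,
                        polya_frac = 0.8, polya_run = 10L,
                        adapter_seed = 10L) {
  stopifnot(is.character(adapter3), nzchar(adapter3), min_len <= max_len)
  reads <- as_tibble(reads)
  if (!"count" %in% names(reads)) reads$count <- 1L
  if (!"id" %in% names(reads)) reads$id <- paste0("read", seq_len(nrow(reads)))
  if (!"quality" %in% names(reads)) reads$quality <- NA_character_
  tally_names <- c("adapter5", "no_insert", "polya", "short", "long", "kept")
  if (nrow(reads) == 0) {
    out <- reads[0, c("id", "sequence", "count", "quality")]
    attr(out, "tally") <- setNames(integer(6), tally_names)
    return(out)
  }
  seqs <- normalize_nt(reads$sequence)
  adapter3 <- normalize_nt(adapter3)
  seed <- substr(adapter3, 1L, min(adapter_seed, nchar(adapter3)))

  pos <- as.integer(regexpr(seed, seqs, fixed = TRUE))
  insert <- ifelse(pos > 0L, substr(seqs, 1L, pos - 1L), seqs)
  ins_len <- nchar(insert)

  fail_a5 <- if (!is.null(adapter5) && nzchar(adapter5))
    grepl(normalize_nt(adapter5), seqs, fixed = TRUE) else rep(FALSE, nrow(reads))
  fail_noins <- pos == 1L | nchar(seqs) < nchar(seed)
  a_frac <- ifelse(ins_len > 0,
                   nchar(gsub("[^A]", "", insert)) / ins_len, 0)
  fail_polya <- a_frac >= polya_frac |
    grepl(strrep("A", polya_run), insert, fixed = TRUE)
  fail_short <- ins_len < min_len
  fail_long <- ins_len > max_len

  rule <- dplyr::case_when(
    fail_a5 ~ "adapter5",
    fail_noins ~ "no_insert",
    fail_polya ~ "polya",
    fail_short ~ "short",
    fail_long ~ "long",
    TRUE ~ "kept")

  tally <- vapply(tally_names, function(r) sum(reads$count[rule == r]),
                  numeric(1))
  keep <- rule == "kept"
  out <- tibble(id = reads$id[keep],
                sequence = insert[keep],
                count = reads$count[keep],
                quality = ifelse(is.na(reads$quality[keep]), NA_character_,
                                 substr(reads$quality[keep], 1L,
                                        ins_len[keep])))
  attr(out, "tally") <- setNames(as.integer(round(tally)), tally_names)
  out
}

#' Rejection tally of a cleaning run
#'
#' @param cleaned Output of [clean_reads()].
#' @return Named integer vector with components `adapter5`,
#'   `no_insert`, `polya`, `short`, `long` and `kept` (read counts).
#' @export
clean_tally <- function(cleaned) attr(cleaned, "tally")

#' Collapse cleaned reads to unique sequence tags
#'
#' @param cleaned Tibble of cleaned reads (columns `sequence` and
#'   optionally `count`).
#' @param library Library label stored in the `library` column.
#' @return Tibble with one row per distinct sequence: `library`,
#'   `sequence`, `length`, `count`, ordered by decreasing count then
#'   sequence. The counts sum to the number of input reads.
#' @export
collapse_to_tags <- function(cleaned, library = "library") {
  cleaned <- as_tibble(cleaned)
  if (!"count" %in% names(cleaned)) cleaned$count <- 1L
  cleaned %>%
    mutate(sequence = normalize_nt(.data$sequence)) %>%
    group_by(.data$sequence) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    mutate(library = library, length = nchar(.data$sequence)) %>%
    arrange(desc(.data$count), .data$sequence) %>%
    select("library", "sequence", "length", "count")
}

#' Merge per-library tag tables into a wide tag table
#'
#' @param tag_list Named list of tag tables from [collapse_to_tags()];
#'   names become library labels.
#' @return Tibble with `sequence`, `length` and one `count_<label>`
#'   column per library (0 where a tag is absent).
#' @export
merge_tag_tables <- function(tag_list) {
  stopifnot(length(names(tag_list)) == length(tag_list))
  wide <- purrr::imap(tag_list, function(tags, label) {
    tags %>%
      select("sequence", "count") %>%
      rename(!!paste0("count_", label) := "count")
  }) %>%
    purrr::reduce(dplyr::full_join, by = "sequence")
  wide %>%
    mutate(dplyr::across(dplyr::starts_with("count_"),
                         ~ tidyr::replace_na(.x, 0L)),
           length = nchar(.data$sequence)) %>%
    select("sequence", "length", dplyr::everything())
}

#' Summarise two small-RNA libraries and their overlap
#'
#' Computes per-library totals, the length histogram and the
#' shared/specific partition of unique tags and of total reads, with
#' percentages over the two-library union (rounded to 2 decimals).
#'
#' @param tags_a,tags_b Tag tables from [collapse_to_tags()].
#' @param labels Length-2 character vector of library labels.
#' @return A `library_summary` object: list with tibbles `totals`,
#'   `overlap` and `length_histogram`.
#' @export
summarize_libraries <- function(tags_a, tags_b, labels = c("A", "B")) {
  stopifnot(length(labels) == 2)
  merged <- merge_tag_tables(setNames(list(tags_a, tags_b), labels))
  ca <- merged[[paste0("count_", labels[1])]]
  cb <- merged[[paste0("count_", labels[2])]]
  shared <- ca > 0 & cb > 0
  u_tot <- nrow(merged)
  t_tot <- sum(ca) + sum(cb)
  part <- function(sel) c(unique = sum(sel), total = sum(ca[sel] + cb[sel]))
  rows <- rbind(total = c(u_tot, t_tot),
                shared = part(shared),
                a_specific = part(ca > 0 & cb == 0),
                b_specific = part(ca == 0 & cb > 0))
  overlap <- tibble(
    class = c("total", "shared",
              paste0(labels[1], "_specific"), paste0(labels[2], "_specific")),
    unique = as.integer(unname(rows[, 1])),
    unique_pct = unname(round(rows[, 1] / u_tot * 100, 2)),
    total = as.integer(unname(rows[, 2])),
    total_pct = unname(round(rows[, 2] / t_tot * 100, 2)))
  totals <- tibble(
    library = labels,
    total_reads = c(sum(tags_a$count), sum(tags_b$count)),
    unique_tags = c(nrow(tags_a), nrow(tags_b)))
  hist <- bind_rows(tags_a, tags_b) %>%
    group_by(.data$library, .data$length) %>%
    summarise(reads = sum(.data$count), unique = dplyr::n(),
              .groups = "drop") %>%
    arrange(.data$library, .data$length)
  structure(list(labels = labels, totals = totals, overlap = overlap,
                 length_histogram = hist),
            class = "library_summary")
}

#' @export
print.library_summary <- function(x, ...) {
  cat("Small-RNA library summary (", paste(x$labels, collapse = " vs "),
      ")\n\n", sep = "")
  print(x$totals)
  cat("\nShared/specific partition:\n")
  print(x$overlap)
  invisible(x)
}

#' Write a tag table as TSV
#'
#' @param tags Tag table (any tibble).
#' @param path Output path.
#' @param comment Optional character vector of '#'-prefixed header
#'   metadata lines.
#' @export
write_tags_tsv <- function(tags, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  utils::write.table(tags, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write tags as collapsed FASTA
#'
#' Headers follow the `seqN_xCOUNT` convention.
#'
#' @param tags Tag table with `sequence` and `count`.
#' @param path Output path.
#' @param rna Emit sequences in RNA alphabet (U instead of T)?
#' @export
write_collapsed_fasta <- function(tags, path, rna = FALSE) {
  seqs <- if (rna) to_rna(tags$sequence) else tags$sequence
  lines <- paste0(">seq", seq_len(nrow(tags)), "_x", tags$count, "\n", seqs)
  writeLines(lines, path)
  invisible(path)
}

#' Write a reference set as FASTA
#'
#' @param reference Tibble with `id` and `sequence`.
#' @param path Output path.
#' @param rna Emit in RNA alphabet?
#' @export
write_fasta <- function(reference, path, rna = FALSE) {
  seqs <- if (rna) to_rna(reference$sequence) else reference$sequence
  writeLines(paste0(">", reference$id, "\n", seqs), path)
  invisible(path)
}
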