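#' Coerce a reference input to a tidy reference table
#'
#' Accepts a tibble with `id`/`sequence` (and optional `class` or
#' `kind` columns), a named character vector, a `DNAStringSet`, or a
#' FASTA path. ncRNA class labels may be carried either in a `class`
#' column or as a header token (`id class`, e.g. `">rrna1 rRNA"`).
#'
#' @param x Reference input.
#' @return Tibble with columns `id`, `sequence` and, when available,
#'   `class`.
#' @export
as_reference <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    ss <- Biostrings::readBStringSet(x)
    x <- setNames(as.character(ss), names(ss))
  }
  if (inherits(x, "XStringSet"))
    x <- setNames(as.character(x), names(x))
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("ref", seq_along(x))
    tok <- strsplit(ids, "\\s+")
    x <- tibble(id = vapply(tok, `[`, character(1), 1),
                class = vapply(tok, function(t)
                  if (length(t) > 1) t[2] else NA_character_, character(1)),
                sequence = unname(x))
    if (all(is.na(x$class))) x$class <- NULL
  }
  x <- as_tibble(x)
  stopifnot(all(c("id", "sequence") %in% names(x)),
            !anyDuplicated(x$id), all(nzchar(x$sequence)))
  x$sequence <- normalize_nt(x$sequence)
  x
}

# exact substring matching of a set of tags against reference records,
# both strands; returns tibble(sequence, ref_id, start, end, strand).
# Uses width-grouped PDicts so matching stays fast for large tag sets.
match_tags_exact <- function(sequences, reference) {
  reference <- as_reference(reference)
  sequences <- unique(normalize_nt(sequences))
  if (length(sequences) == 0 || nrow(reference) == 0)
    return(tibble(sequence = character(), ref_id = character(),
                  start = integer(), end = integer(), strand = character()))
  subjects <- Biostrings::DNAStringSet(setNames(reference$sequence,
                                                reference$id))
  widths <- nchar(sequences)
  out <- vector("list", 0)
  for (w in sort(unique(widths))) {
    grp <- sequences[widths == w]
    fwd <- Biostrings::DNAStringSet(grp)
    rev <- Biostrings::reverseComplement(fwd)
    pd_f <- Biostrings::PDict(fwd)
    pd_r <- Biostrings::PDict(rev)
    for (ri in seq_len(nrow(reference))) {
      subj <- subjects[[ri]]
      if (length(subj) < w) next
      for (strand in c("+", "-")) {
        pd <- if (strand == "+") pd_f else pd_r
        m <- Biostrings::matchPDict(pd, subj)
        hit_n <- S4Vectors::elementNROWS(m)
        if (sum(hit_n) == 0) next
        idx <- rep(seq_along(grp), hit_n)
        st <- unlist(lapply(seq_along(grp), function(k)
          BiocGenerics::start(m[[k]])), use.names = FALSE)
        out[[length(out) + 1]] <- tibble(
          sequence = grp[idx],
          ref_id = reference$id[ri],
          start = as.integer(st),
          end = as.integer(st + w - 1L),
          strand = strand)
      }
    }
  }
  if (length(out) == 0)
    return(tibble(sequence = character(), ref_id = character(),
                  start = integer(), end = integer(), strand = character()))
  bind_rows(out) %>% arrange(.data$sequence, .data$ref_id, .data$start)
}

#' Map tags to a reference by perfect matching
#'
#' Every hit is an exact substring match of the tag (plus strand) or of
#' its reverse complement (minus strand); coordinates are 1-based
#' inclusive on the reference.
#'
#' @param tags Tag table with a `sequence` column.
#' @param reference Reference accepted by [as_reference()].
#' @return Tibble of hits (`sequence`, `ref_id`, `start`, `end`,
#'   `strand`); tags with no row are unmapped.
#' @export
map_perfect <- function(tags, reference) {
  match_tags_exact(as_tibble(tags)$sequence, reference)
}

#' Classify tags against a non-coding RNA database
#'
#' A tag matching any ncRNA record (exact substring, either strand)
#' receives that record's class; tags matching several classes are
#' resolved by the priority rRNA > tRNA > snRNA > snoRNA.
#'
#' @param tags Tag table with `sequence`.
#' @param ncrna_db Reference whose records carry class labels (one of
#'   rRNA, tRNA, snRNA, snoRNA) in a `class` column or header token.
#' @return The tag table with an `nc_class` column (`NA` when
#'   unmatched).
#' @export
classify_ncrna <- function(tags, ncrna_db) {
  tags <- as_tibble(tags)
  ncrna_db <- as_reference(ncrna_db)
  stopifnot("class" %in% names(ncrna_db))
  priority <- c("rRNA", "tRNA", "snRNA", "snoRNA")
  bad <- setdiff(unique(ncrna_db$class), priority)
  if (length(bad))
    stop("unknown ncRNA class label(s): ", paste(bad, collapse = ", "))
  tags$nc_class <- NA_character_
  for (cl in priority) {
    db <- ncrna_db %>% filter(.data$class == cl)
    if (nrow(db) == 0) next
    open <- is.na(tags$nc_class)
    if (!any(open)) break
    hits <- match_tags_exact(tags$sequence[open], db)
    tags$nc_class[open & tags$sequence %in% hits$sequence] <- cl
  }
  tags
}

#' Derive the miRNA family name from a member identifier
#'
#' Strips the species prefix and member/arm suffixes, e.g.
#' `ath-miR156a-5p` and `miR156d` both give `miR156`; novel-style ids
#' such as `miRn5-3p` give `miRn5`.
#'
#' @param id Character vector of miRNA identifiers.
#' @return Character vector of family names (`NA` when no family
#'   pattern is found).
#' @export
parse_mirna_family <- function(id) {
  fam <- stringr::str_extract(id, stringr::regex("mirn?\\d+",
                                                 ignore_case = TRUE))
  ifelse(is.na(fam), NA_character_,
         sub("^mirn", "miRn",
             sub("^mir(?=\\d)", "miR", tolower(fam), perl = TRUE)))
}

# distance used for known-miRNA assignment: Hamming over the shared
# prefix plus one per overhanging base
prefix_overhang_distance <- function(a, b) {
  va <- utf8ToInt(a); vb <- utf8ToInt(b)
  m <- min(length(va), length(vb))
  sum(va[seq_len(m)] != vb[seq_len(m)]) + abs(length(va) - length(vb))
}

#' Assign tags to known miRNAs with mismatch tolerance
#'
#' Compares each tag end-to-end (ungapped) against every mature member
#' sequence: the distance is the Hamming distance over the shared
#' prefix plus one per overhanging base. A tag is assigned to the
#' member with the smallest distance not exceeding `max_mismatch`;
#' ties go to the lexicographically smallest member id. G:U is a plain
#' mismatch here.
#'
#' @param tags Tag table with `sequence`.
#' @param mirna_db Known mature miRNAs: reference accepted by
#'   [as_reference()] (miRBase-style ids; RNA alphabet fine).
#' @param max_mismatch Maximum allowed distance (default 2).
#' @return The tag table with columns `mirna_id`, `family` and
#'   `mismatches` (`NA` for unassigned tags).
#' @export
assign_known_mirna <- function(tags, mirna_db, max_mismatch = 2L) {
  if (max_mismatch < 0) stop("max_mismatch must be >= 0")
  tags <- as_tibble(tags)
  db <- as_reference(mirna_db) %>% arrange(.data$id)
  n <- nrow(tags)
  best_d <- rep(Inf, n)
  best_id <- rep(NA_character_, n)
  if (n > 0 && nrow(db) > 0) {
    tag_int <- lapply(tags$sequence, utf8ToInt)
    tag_len <- lengths(tag_int)
    for (mi in seq_len(nrow(db))) {
      mv <- utf8ToInt(db$sequence[mi])
      lm <- length(mv)
      d <- vapply(seq_len(n), function(k) {
        m <- min(tag_len[k], lm)
        sum(tag_int[[k]][seq_len(m)] != mv[seq_len(m)]) + abs(tag_len[k] - lm)
      }, numeric(1))
      upd <- d < best_d
      best_d[upd] <- d[upd]
      best_id[upd] <- db$id[mi]
    }
  }
  ok <- best_d <= max_mismatch
  tags$mirna_id <- ifelse(ok, best_id, NA_character_)
  tags$mismatches <- ifelse(ok, as.integer(best_d), NA_integer_)
  tags$family <- parse_mirna_family(tags$mirna_id)
  tags
}

#' Annotate tags: reference mapping, ncRNA removal, known-miRNA calls
#'
#' Runs the annotation cascade: perfect mapping to the reference,
#' ncRNA classification (classified tags are excluded from miRNA
#' calling), then known-miRNA assignment. Each tag receives exactly
#' one class: its ncRNA class if any, else `known_miRNA` if assigned,
#' else `unannotated`.
#'
#' @param tags Tag table (wide, from [merge_tag_tables()], or a single
#'   library from [collapse_to_tags()]).
#' @param reference Optional genomic/transcript reference for perfect
#'   mapping.
#' @param ncrna_db Optional ncRNA database with class labels.
#' @param mirna_db Optional known mature miRNA database.
#' @param max_mismatch Mismatch allowance for known-miRNA assignment.
#' @param strict_reference If `TRUE`, only tags with a perfect
#'   reference hit may be called known miRNAs.
#' @return The tag table with columns `mapped`, `class`, `mirna_id`,
#'   `family`, `mismatches`.
#' @export
annotate_tags <- function(tags, reference = NULL, ncrna_db = NULL,
                          mirna_db = NULL, max_mismatch = 2L,
                          strict_reference = FALSE) {
  tags <- as_tibble(tags)
  tags$mapped <- if (!is.null(reference)) {
    hits <- map_perfect(tags, reference)
    tags$sequence %in% hits$sequence
  } else NA
  tags$nc_class <- NA_character_
  if (!is.null(ncrna_db)) tags <- classify_ncrna(tags, ncrna_db)
  tags$mirna_id <- NA_character_
  tags$mismatches <- NA_integer_
  tags$family <- NA_character_
  open <- is.na(tags$nc_class)
  if (!is.null(mirna_db) && any(open)) {
    sub <- assign_known_mirna(tags[open, ], mirna_db, max_mismatch)
    tags$mirna_id[open] <- sub$mirna_id
    tags$mismatches[open] <- sub$mismatches
    tags$family[open] <- sub$family
  }
  if (isTRUE(strict_reference)) {
    drop <- !is.na(tags$mirna_id) & !tags$mapped %in% TRUE
    tags$mirna_id[drop] <- NA_character_
    tags$mismatches[drop] <- NA_integer_
    tags$family[drop] <- NA_character_
  }
  tags$class <- dplyr::coalesce(
    tags$nc_class,
    ifelse(is.na(tags$mirna_id), NA_character_, "known_miRNA"),
    "unannotated")
  tags %>% select(-"nc_class")
}

#' Per-class distribution of tags in a library
#'
#' Mirrors the classic small-RNA category table: unique-tag and total
#' read counts per class with percentages of the library total.
#'
#' @param annotated Output of [annotate_tags()].
#' @param count_col Name of the count column to summarise.
#' @return Tibble with `class`, `unique`, `unique_pct`, `total`,
#'   `total_pct`; a `total_small_RNAs` row leads the table.
#' @export
class_distribution <- function(annotated, count_col = "count") {
  counts <- annotated[[count_col]]
  classes <- c("miRNA" = "known_miRNA", "rRNA" = "rRNA", "snRNA" = "snRNA",
               "snoRNA" = "snoRNA", "tRNA" = "tRNA",
               "Unannotated" = "unannotated")
  u_tot <- nrow(annotated)
  t_tot <- sum(counts)
  rows <- lapply(names(classes), function(lbl) {
    sel <- annotated$class == classes[[lbl]]
    tibble(class = lbl, unique = sum(sel),
           unique_pct = round(sum(sel) / u_tot * 100, 2),
           total = sum(counts[sel]),
           total_pct = round(sum(counts[sel]) / t_tot * 100, 2))
  })
  bind_rows(
    tibble(class = "Total small RNAs", unique = u_tot, unique_pct = 100,
           total = t_tot, total_pct = 100),
    bind_rows(rows))
}

#' Aggregate known-miRNA tags into a family table
#'
#' Groups assigned tags by family and reports the member count,
#' per-library read totals, the row-sum total and the
#' treated/control abundance ratio (2 decimals).
#'
#' @param annotated Output of [annotate_tags()] with per-library
#'   `count_<label>` columns.
#' @param ck_col,trt_col Names of the control and treated count
#'   columns.
#' @return Tibble with `family`, `members`, per-library reads, `total`
#'   and `ratio`.
#' @export
family_table <- function(annotated, ck_col = "count_CK",
                         trt_col = "count_Cd200") {
  annotated %>%
    filter(.data$class == "known_miRNA") %>%
    group_by(.data$family) %>%
    summarise(members = dplyr::n_distinct(.data$mirna_id),
              !!ck_col := sum(.data[[ck_col]]),
              !!trt_col := sum(.data[[trt_col]]),
              .groups = "drop") %>%
    mutate(total = .data[[ck_col]] + .data[[trt_col]],
           ratio = family_ratio(.data[[ck_col]], .data[[trt_col]])) %>%
    arrange(.data$family)
}

#' Treated/control family abundance ratio
#'
#' @param ck,trt Per-family read totals in the control and treated
#'   libraries.
#' @param digits Rounding (default 2, the usual printed precision).
#' @return `round(trt / ck, digits)`.
#' @export
family_ratio <- function(ck, trt, digits = 2) round(trt / ck, digits)
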