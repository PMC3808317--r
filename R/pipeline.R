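#' Build a pipeline configuration
#'
#' Collects the input paths and every stage parameter of the full
#' analysis. All parameters carry the package defaults; the degradome
#' stage is optional and skipped when `degradome` is `NULL`.
#'
#' @param srna_ck,srna_trt Paths to the control and treated small-RNA
#'   libraries (FASTQ or FASTA).
#' @param reference Path to the reference FASTA.
#' @param adapter3 3' adapter sequence (required for cleaning).
#' @param adapter5 Optional 5' adapter.
#' @param ncrna Optional ncRNA FASTA with class tokens in the headers.
#' @param known_mirnas Optional known mature miRNA FASTA.
#' @param degradome Optional degradome FASTQ/FASTA.
#' @param outdir Output directory for report tables and the manifest.
#' @param labels Library labels (control, treated).
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @param min_len,max_len Cleaning length window.
#' @param max_mismatch Known-miRNA mismatch allowance.
#' @param min_reads,flank_up,flank_down,min_precursor,max_precursor,mfe_max
#'   Novel-discovery parameters, see [discover_novel_mirnas()].
#' @param ratio_up,ratio_down,alpha Differential-expression call
#'   thresholds.
#' @param max_score,max_target_mismatch Degradome alignment
#'   thresholds.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(srna_ck, srna_trt, reference, adapter3,
                            adapter5 = NULL, ncrna = NULL,
                            known_mirnas = NULL, degradome = NULL,
                            outdir = "mirpare_out",
                            labels = c("CK", "Cd200"), seed = 1L,
                            min_len = 15L, max_len = 30L,
                            max_mismatch = 2L, min_reads = 5L,
                            flank_up = 20L, flank_down = 160L,
                            min_precursor = 60L, max_precursor = 300L,
                            mfe_max = -18, ratio_up = 2, ratio_down = 0.5,
                            alpha = 0.05, max_score = 4,
                            max_target_mismatch = 5L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every config invariant and returns the violations instead of
#' stopping, so a caller can report them all at once.
#'
#' @param config A [pipeline_config()].
#' @return Character vector of violations, each naming the offending
#'   field; empty when the config is valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  for (f in c("srna_ck", "srna_trt", "reference")) {
    p <- config[[f]]
    if (is.null(p) || !is.character(p) || !nzchar(p))
      v <- c(v, paste0(f, ": path is required"))
    else if (!file.exists(p))
      v <- c(v, paste0(f, ": file not found (", p, ")"))
  }
  for (f in c("ncrna", "known_mirnas", "degradome")) {
    p <- config[[f]]
    if (!is.null(p) && !file.exists(p))
      v <- c(v, paste0(f, ": file not found (", p, ")"))
  }
  need(is.character(config$adapter3) && nzchar(config$adapter3) &&
         !grepl("[^ACGTUacgtu]", config$adapter3),
       "adapter3: must be a non-empty nucleotide string")
  need(config$min_len <= config$max_len,
       "min_len/max_len: min_len must be <= max_len")
  need(config$min_len >= 1, "min_len: must be >= 1")
  need(config$max_mismatch >= 0, "max_mismatch: must be >= 0")
  need(config$min_reads >= 1, "min_reads: must be >= 1")
  need(config$flank_up >= 0 && config$flank_down >= 0,
       "flank_up/flank_down: must be >= 0")
  need(config$min_precursor <= config$max_precursor,
       "min_precursor/max_precursor: min must be <= max")
  need(config$mfe_max < 0, "mfe_max: must be negative")
  need(config$ratio_down < config$ratio_up,
       "ratio_down/ratio_up: ratio_down must be < ratio_up")
  need(config$alpha > 0 && config$alpha <= 1, "alpha: must be in (0, 1]")
  need(config$max_score >= 0, "max_score: must be >= 0")
  need(config$max_target_mismatch >= 0,
       "max_target_mismatch: must be >= 0")
  need(length(config$labels) == 2 && !anyDuplicated(config$labels),
       "labels: need two distinct library labels")
  v
}

# write one report table with a '#'-prefixed metadata header
write_report <- function(x, path, title, config) {
  write_tags_tsv(x, path, comment = c(
    paste0("mirpare report v1: ", title),
    paste0("seed=", config$seed)))
}

#' Run the full small-RNA analysis pipeline
#'
#' Executes preprocess, annotation, novel discovery, differential
#' expression and (optionally) degradome target calling from one
#' configuration, writing the standard report tables to
#' `config$outdir`: library summary and overlap, read statistics,
#' per-class distribution, known-family table, novel-miRNA table,
#' differential-expression table and target-call tables, plus a JSON
#' manifest recording the package version, parameters and input
#' checksums. Reruns with identical inputs are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every result table, the manifest and
#'   the written paths.
#' @export
run_pipeline <- function(config) {
  viol <- validate_config(config)
  if (length(viol))
    stop("invalid pipeline config:\n  ", paste(viol, collapse = "\n  "))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  labels <- config$labels
  manifest <- list(
    tool = "mirpare",
    version = as.character(utils::packageVersion("mirpare")),
    seed = config$seed,
    parameters = config[!names(config) %in%
                          c("srna_ck", "srna_trt", "reference", "ncrna",
                            "known_mirnas", "degradome", "outdir")],
    inputs = lapply(config[c("srna_ck", "srna_trt", "reference", "ncrna",
                             "known_mirnas", "degradome")],
                    function(p) if (is.null(p)) NULL else
                      list(path = p, md5 = unname(tools::md5sum(p)))),
    stages = list())
  paths <- character(0)
  results <- list()
  stage <- function(name, code) {
    res <- tryCatch(code, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(config$outdir,
                                               "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA,
                           null = "null")
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }

  # --- preprocess -------------------------------------------------------
  results$tags <- stage("preprocess", {
    cleaned <- lapply(c(config$srna_ck, config$srna_trt), function(p)
      clean_reads(read_small_rna(p), adapter3 = config$adapter3,
                  adapter5 = config$adapter5, min_len = config$min_len,
                  max_len = config$max_len))
    names(cleaned) <- labels
    raw_counts <- vapply(cleaned, function(x) sum(clean_tally(x)),
                         numeric(1))
    tag_list <- purrr::imap(cleaned, collapse_to_tags)
    summary <- summarize_libraries(tag_list[[1]], tag_list[[2]], labels)
    merged <- merge_tag_tables(tag_list)
    list(cleaned_tally = lapply(cleaned, clean_tally),
         raw_counts = raw_counts, tag_list = tag_list,
         summary = summary, merged = merged)
  })
  s <- results$tags
  count_cols <- paste0("count_", labels)
  p1 <- file.path(config$outdir, "library_overlap.tsv")
  write_report(s$summary$overlap, p1, "shared/specific sequences", config)
  p2 <- file.path(config$outdir, "length_distribution.tsv")
  write_report(s$summary$length_histogram, p2,
               "size distribution of small RNAs", config)
  paths <- c(paths, p1, p2)

  # --- annotation -------------------------------------------------------
  results$annotated <- stage("annotate", {
    annotate_tags(s$merged, reference = config$reference,
                  ncrna_db = if (is.null(config$ncrna)) NULL else
                    config$ncrna,
                  mirna_db = config$known_mirnas,
                  max_mismatch = config$max_mismatch)
  })
  ann <- results$annotated
  stats_rows <- lapply(seq_along(labels), function(i) {
    cc <- ann[[count_cols[i]]]
    present <- cc > 0
    tibble(library = labels[i],
           metric = c("raw_reads", "clean_reads", "mapped", "known_miRNA",
                      "unannotated"),
           total = c(s$raw_counts[i], sum(cc),
                     sum(cc[ann$mapped %in% TRUE]),
                     sum(cc[ann$class == "known_miRNA"]),
                     sum(cc[ann$class == "unannotated"])),
           unique = c(NA, sum(present),
                      sum(present & ann$mapped %in% TRUE),
                      sum(present & ann$class == "known_miRNA"),
                      sum(present & ann$class == "unannotated")))
  })
  p <- file.path(config$outdir, "read_stats.tsv")
  write_report(bind_rows(stats_rows), p, "sequencing read statistics",
               config)
  paths <- c(paths, p)
  cls <- bind_rows(lapply(seq_along(labels), function(i)
    class_distribution(ann[ann[[count_cols[i]]] > 0, ], count_cols[i]) %>%
      rename(unique_tags = "unique", total_reads = "total") %>%
      mutate(library = labels[i], .before = 1)))
  p <- file.path(config$outdir, "class_distribution.tsv")
  write_report(cls, p, "distribution of small RNAs among categories",
               config)
  paths <- c(paths, p)
  fam <- family_table(ann, count_cols[1], count_cols[2])
  p <- file.path(config$outdir, "known_families.tsv")
  write_report(fam, p, "known miRNA families and abundance", config)
  paths <- c(paths, p)
  results$families <- fam

  # --- novel discovery --------------------------------------------------
  results$novel <- stage("novel", {
    discover_novel_mirnas(ann, config$reference,
                          min_reads = config$min_reads,
                          flank_up = config$flank_up,
                          flank_down = config$flank_down,
                          min_precursor = config$min_precursor,
                          max_precursor = config$max_precursor,
                          mfe_max = config$mfe_max)
  })
  p <- file.path(config$outdir, "novel_mirnas.tsv")
  write_report(results$novel$novel %>% select(-"structure"), p,
               "novel miRNAs and abundance", config)
  paths <- c(paths, p)

  # --- differential expression -----------------------------------------
  results$de <- stage("diff_expr", {
    totals <- vapply(seq_along(labels), function(i)
      sum(ann[[count_cols[i]]]), numeric(1))
    known_counts <- ann %>%
      filter(.data$class == "known_miRNA") %>%
      group_by(id = .data$mirna_id) %>%
      summarise(count_ck = sum(.data[[count_cols[1]]]),
                count_trt = sum(.data[[count_cols[2]]]),
                .groups = "drop")
    novel_counts <- results$novel$novel %>%
      mutate(id = .data$name,
             count_ck = .data[[count_cols[1]]],
             count_trt = .data[[count_cols[2]]]) %>%
      select("id", "count_ck", "count_trt")
    mir_de(bind_rows(known_counts, novel_counts),
           total_ck = totals[1], total_trt = totals[2],
           ratio_up = config$ratio_up, ratio_down = config$ratio_down,
           alpha = config$alpha)
  })
  p <- file.path(config$outdir, "diff_expr.tsv")
  write_report(tidy(results$de) %>%
                 mutate(dplyr::across(dplyr::starts_with("norm"),
                                      ~ round(.x, 4)),
                        log2fc = round(.data$log2fc, 2)),
               p, "differential expression (treated vs control)", config)
  paths <- c(paths, p)

  # --- degradome --------------------------------------------------------
  if (!is.null(config$degradome)) {
    results$targets <- stage("degradome", {
      deg_tags <- filter_degradome_reads(read_small_rna(config$degradome))
      mir_set <- bind_rows(
        if (!is.null(config$known_mirnas))
          as_reference(config$known_mirnas) %>% select("id", "sequence"),
        results$novel$novel %>%
          mutate(sequence = normalize_nt(.data$mature)) %>%
          select(id = "name", "sequence")) %>%
        distinct(.data$id, .keep_all = TRUE) %>%
        filter(nchar(.data$sequence) >= 18, nchar(.data$sequence) <= 26)
      call_targets(mir_set, config$reference, deg_tags,
                   max_score = config$max_score,
                   max_mismatch = config$max_target_mismatch)
    })
    p <- file.path(config$outdir, "target_calls.tsv")
    write_report(results$targets %>%
                   mutate(tp100m = round(.data$tp100m, 3)),
                 p, "degradome-validated cleavage targets", config)
    paths <- c(paths, p)
  } else {
    manifest$stages$degradome <- list(status = "skipped",
                                      reason = "no degradome input")
  }

  manifest$outputs <- lapply(paths, function(p)
    list(file = basename(p), md5 = unname(tools::md5sum(p))))
  mpath <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  results$manifest <- manifest
  results$paths <- c(paths, mpath)
  invisible(results)
}
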