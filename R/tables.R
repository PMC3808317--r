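#' Bundled summary tables from a radish cadmium small-RNA study
#'
#' The package ships the printed summary tables of a two-library
#' (control vs 200 mg/l CdCl2-treated root) radish small-RNA and
#' degradome experiment as plain TSV files, so the self-contained
#' arithmetic of the analysis — per-million normalization, fold
#' changes, family abundance ratios, shared/specific percentages and
#' precursor MFE summaries — can be recomputed and checked without the
#' raw sequencing data (which were never deposited).
#'
#' @return A named list of tibbles: `library_overlap` (shared/specific
#'   unique and total read counts), `read_stats` (per-library read
#'   statistics), `class_distribution` (per-class tag counts),
#'   `known_families` (per-family member counts and per-library
#'   reads), `novel_mirnas` (novel miRNAs with precursor length, MFE
#'   and per-library reads), `novel_de` (the Cd-responsive novel
#'   miRNAs with raw counts and calls), `degradome_summary` (degradome
#'   read totals).
#' @examples
#' tabs <- radish_tables()
#' family_ratio(tabs$known_families$reads_ck,
#'              tabs$known_families$reads_cd200)
#' @export
radish_tables <- function() {
  dir <- system.file("extdata", package = "mirpare")
  read1 <- function(f)
    as_tibble(utils::read.delim(file.path(dir, f), sep = "\t",
                                stringsAsFactors = FALSE))
  list(library_overlap = read1("radish_library_overlap.tsv"),
       read_stats = read1("radish_read_stats.tsv"),
       class_distribution = read1("radish_class_distribution.tsv"),
       known_families = read1("radish_known_families.tsv"),
       novel_mirnas = read1("radish_novel_mirnas.tsv"),
       novel_de = read1("radish_novel_de.tsv"),
       degradome_summary = read1("radish_degradome_summary.tsv"))
}

#' Percentage of a part over a whole, printed-table style
#'
#' @param part,whole Counts.
#' @param digits Decimals to keep (summary tables print 2; some text
#'   percentages print 1).
#' @return `round(part / whole * 100, digits)`.
#' @export
percent_of <- function(part, whole, digits = 2) {
  round(part / whole * 100, digits)
}
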