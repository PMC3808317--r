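# run code under a local, seeded RNG without disturbing the caller's
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_nt <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Configuration for the synthetic small-RNA study generator
#'
#' Bundles every knob of the simulator: the reference, the planted
#' hairpin loci, the two-condition expression table, the ncRNA
#' background, and the degradome design. Defaults describe a compact
#' two-library experiment — 20 transcripts of 0.5-3 kb, 12 hairpin
#' loci, 2e5 reads per small-RNA library and 5e4 degradome reads —
#' large enough for stable statistics while folding and calling stay
#' fast. A third of the planted miRNAs are 4-fold up under treatment,
#' a third 4-fold down, a third flat.
#'
#' @param seed Integer seed; identical seeds give byte-identical
#'   outputs.
#' @param n_transcripts Number of reference transcripts.
#' @param transcript_len Length-2 range of transcript lengths (nt).
#' @param n_hairpins Number of planted hairpin loci.
#' @param mature_lengths Pool of mature lengths sampled per hairpin
#'   (weighted towards 21 nt).
#' @param stem_wobble_rate Per-base rate of planted G:U wobbles in the
#'   extension stem (the mature/star duplex itself stays perfect so
#'   the star sequence is well defined).
#' @param base_expression Range of expected control-library mature
#'   reads per planted miRNA.
#' @param fold_change Linear fold change planted for up/down miRNAs.
#' @param star_reads Expected star reads per library.
#' @param ncrna_fractions Named fractions of library reads drawn from
#'   each ncRNA class.
#' @param depth Small-RNA reads per library.
#' @param adapter3 3' adapter appended to simulated reads.
#' @param events_per_mirna Planted cleavage events per targeted miRNA
#'   (the first `n_target_mirnas` planted miRNAs are targeted).
#' @param n_target_mirnas Number of planted miRNAs given cleavage
#'   targets.
#' @param signature_reads Degradome reads planted at each cleavage
#'   position.
#' @param degradome_depth Total degradome reads (signatures plus
#'   background).
#' @param background_per_kb Expected background degradome 5' ends per
#'   kb of transcript.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_transcripts = 20L,
                       transcript_len = c(500L, 3000L),
                       n_hairpins = 12L,
                       mature_lengths = c(21L, 21L, 21L, 22L, 24L),
                       stem_wobble_rate = 0.1,
                       base_expression = c(50L, 500L),
                       fold_change = 4,
                       star_reads = 3L,
                       ncrna_fractions = c(rRNA = 0.20, tRNA = 0.02,
                                           snRNA = 0.005, snoRNA = 0.002),
                       depth = 2e5,
                       adapter3 = "TCGTATGCCGTCTTCTGCTTG",
                       events_per_mirna = 1L,
                       n_target_mirnas = 8L,
                       signature_reads = 50L,
                       degradome_depth = 5e4,
                       background_per_kb = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$seed == as.integer(cfg$seed),
            length(cfg$transcript_len) == 2,
            all(cfg$ncrna_fractions >= 0), sum(cfg$ncrna_fractions) < 1,
            cfg$depth > 0, cfg$degradome_depth > 0,
            cfg$fold_change > 1, cfg$stem_wobble_rate >= 0,
            cfg$stem_wobble_rate <= 1)
  class(cfg) <- "sim_config"
  cfg
}

# build one hairpin precursor: ext5+mature+ext3 / loop / complement arm
# with optional wobbles facing the extensions; returns the precursor
# and the star sequence (duplex partner with 2-nt 3' overhangs)
build_hairpin <- function(mature, ext5 = 8L, ext3 = 6L,
                          loop_len = 12L, wobble_rate = 0.1) {
  L <- nchar(mature)
  stem <- paste0(random_nt(ext5), mature, random_nt(ext3))
  arm2 <- strsplit(reverse_complement(stem), "")[[1]]
  ns <- length(arm2)
  # positions of arm2 facing the extensions (not the mature duplex)
  facing_ext <- c(seq_len(ext3), (ns - ext5 + 1L):ns)
  for (p in facing_ext) {
    if (runif(1) < wobble_rate) {
      if (arm2[p] == "C") arm2[p] <- "T"        # G:C -> G:U (wobble)
      else if (arm2[p] == "A") arm2[p] <- "G"   # U:A -> U:G
    }
  }
  loop <- random_nt(loop_len)
  pre <- paste0(stem, loop, paste(arm2, collapse = ""))
  # star under the 2-nt 3' overhang rule on the perfect mature duplex:
  # partners of mature[1..L-2] plus two 3' bases
  n <- nchar(pre)
  a <- ext5 + 1L                       # mature start within precursor
  star_lo <- n + 1L - (a + L - 3L)
  star_hi <- n + 1L - a + 2L
  list(precursor = pre, mature_start = a,
       star = substr(pre, star_lo, star_hi))
}

#' Simulate a reference with planted hairpin loci and cleavage targets
#'
#' Generates random-composition transcripts, embeds `n_hairpins`
#' stem-loop precursors (perfect mature/star duplex, wobbled
#' extensions, 8-15 nt loop) at recorded coordinates, plants perfect
#' antisense target sites for the first `n_target_mirnas` miRNAs on
#' other transcripts, and builds a small labelled ncRNA database. All
#' coordinates and sequences are recorded in the truth table.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_study`: `reference` (tibble `id`,
#'   `sequence`, `kind`), `ncrna` (tibble with `class`), `truth`
#'   (list: `hairpins`, `expression`, `events`), `config`.
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_transcripts
    lens <- sample(seq(config$transcript_len[1], config$transcript_len[2]),
                   n, replace = TRUE)
    seqs <- vapply(lens, random_nt, character(1))
    ids <- sprintf("tx%02d", seq_len(n))

    # --- hairpin loci ---------------------------------------------------
    # hairpins live on the first half of the transcripts; cleavage-target
    # sites are planted on the untouched second half
    hp <- vector("list", config$n_hairpins)
    used_iv <- replicate(n, list())    # occupied intervals per transcript
    place <- function(tx, len, margin = 40L) {
      lo <- margin; hi <- nchar(seqs[tx]) - len - margin
      if (hi <= lo) return(NA_integer_)
      for (try in 1:50) {
        at <- sample(seq(lo, hi), 1)
        clash <- any(vapply(used_iv[[tx]], function(iv)
          at <= iv[2] + 10L && at + len - 1L >= iv[1] - 10L, logical(1)))
        if (!clash) {
          used_iv[[tx]] <<- c(used_iv[[tx]], list(c(at, at + len - 1L)))
          return(at)
        }
      }
      NA_integer_
    }
    hosts <- sample(rep_len(seq_len(max(1, n %/% 2)), config$n_hairpins))
    for (k in seq_len(config$n_hairpins)) {
      L <- sample(config$mature_lengths, 1)
      mature <- random_nt(L)
      b <- build_hairpin(mature, loop_len = sample(8:15, 1),
                         wobble_rate = config$stem_wobble_rate)
      host <- hosts[k]
      plen <- nchar(b$precursor)
      if (nchar(seqs[host]) < plen + 80) host <- which.max(nchar(seqs))
      at <- place(host, plen)
      if (is.na(at)) stop("could not place hairpin on its host transcript")
      substr(seqs[host], at, at + plen - 1L) <- b$precursor
      hp[[k]] <- tibble(
        mirna_id = sprintf("simn%02d", k),
        host = ids[host],
        precursor_start = at, precursor_end = at + plen - 1L,
        mature_start = at + b$mature_start - 1L,
        mature_end = at + b$mature_start + L - 2L,
        strand = "+", mature = mature, star = b$star,
        precursor = b$precursor)
    }
    empty_hairpins <- tibble(
      mirna_id = character(), host = character(),
      precursor_start = integer(), precursor_end = integer(),
      mature_start = integer(), mature_end = integer(),
      strand = character(), mature = character(), star = character(),
      precursor = character())
    hairpins <- if (length(hp)) bind_rows(hp) else empty_hairpins

    # --- expression truth ----------------------------------------------
    cls <- rep_len(c("up", "down", "flat"), config$n_hairpins)
    base <- round(runif(config$n_hairpins, config$base_expression[1],
                        config$base_expression[2]))
    fc <- config$fold_change
    expression <- tibble(
      mirna_id = hairpins$mirna_id, mature = hairpins$mature,
      true_class = cls,
      expected_ck = base,
      expected_cd = round(base * ifelse(cls == "up", fc,
                                        ifelse(cls == "down", 1 / fc, 1))),
      true_log2fc = log2(ifelse(cls == "up", fc,
                                ifelse(cls == "down", 1 / fc, 1))))

    # --- planted cleavage events ----------------------------------------
    targeted <- hairpins[seq_len(min(config$n_target_mirnas,
                                     nrow(hairpins))), ]
    ev <- vector("list", 0)
    decoys <- setdiff(seq_len(n), match(unique(hairpins$host), ids))
    # one event per decoy transcript while they last, so each planted
    # signature is the unique maximum of its t-plot
    decoy_pool <- if (length(decoys)) sample(decoys) else integer(0)
    next_decoy <- function() {
      if (length(decoy_pool) == 0) decoy_pool <<- sample(decoys)
      tx <- decoy_pool[1]
      decoy_pool <<- decoy_pool[-1]
      tx
    }
    for (k in seq_len(nrow(targeted))) {
      mir <- targeted[k, ]
      L <- nchar(mir$mature)
      for (e in seq_len(config$events_per_mirna)) {
        tx <- next_decoy()
        site <- place(tx, L, margin = 60L)
        if (is.na(site)) next
        substr(seqs[tx], site, site + L - 1L) <- reverse_complement(mir$mature)
        ev[[length(ev) + 1]] <- tibble(
          mirna_id = mir$mirna_id, mature = mir$mature,
          target_id = ids[tx], site_start = site,
          site_end = site + L - 1L,
          cleavage_pos = site + L - 10L,
          signature = config$signature_reads)
      }
    }
    events <- if (length(ev)) bind_rows(ev) else
      tibble(mirna_id = character(), mature = character(),
             target_id = character(), site_start = integer(),
             site_end = integer(), cleavage_pos = integer(),
             signature = integer())

    # --- ncRNA database --------------------------------------------------
    nc_spec <- list(rRNA = c(1500L, 800L), tRNA = c(76L, 75L, 74L),
                    snRNA = c(150L, 140L), snoRNA = c(120L, 110L))
    nc <- purrr::imap(nc_spec, function(ls, cl)
      tibble(id = paste0(tolower(cl), seq_along(ls)), class = cl,
             sequence = vapply(ls, random_nt, character(1)))) %>%
      bind_rows()

    structure(list(
      reference = tibble(id = ids, sequence = seqs, kind = "transcript"),
      ncrna = nc,
      truth = list(hairpins = hairpins, expression = expression,
                   events = events),
      config = config), class = "sim_study")
  })
}

# sample insert lengths with the canonical plant profile peaking at
# 21 and 24 nt
sample_srna_lengths <- function(n) {
  lens <- 15:30
  w <- c(1, 1, 2, 3, 4, 6, 14, 8, 6, 16, 5, 3, 2, 1, 1, 1)
  sample(lens, n, replace = TRUE, prob = w / sum(w))
}

# pools of fragment species for one class of background reads
fragment_pool <- function(sources, n_frags, lengths) {
  src <- sources[nchar(sources) >= max(lengths)]
  vapply(seq_len(n_frags), function(i) {
    s <- sample(src, 1)
    l <- sample(lengths, 1)
    at <- sample(nchar(s) - l + 1L, 1)
    substr(s, at, at + l - 1L)
  }, character(1))
}

#' Simulate the two small-RNA libraries of a synthetic study
#'
#' Draws reads for the control (CK) and treated (Cd200) libraries as a
#' single multinomial per library at the configured depth: mature and
#' star species at their expected expression, ncRNA fragments at the
#' configured class fractions, and unannotated degradation fragments
#' filling the remainder with a 21/24-nt-peaked length profile. The 3'
#' adapter is appended to every read; qualities are constant `I`.
#'
#' @param study A `sim_study` from [simulate_reference()].
#' @return List with tibbles `ck` and `cd` (columns `id`, `sequence`,
#'   `count`, `quality`; one row per read species, counts carrying the
#'   multiplicity) and the `species` expectation table.
#' @export
simulate_srna_libraries <- function(study) {
  stopifnot(inherits(study, "sim_study"))
  config <- study$config
  with_seed(config$seed + 1L, {
    tr <- study$truth
    # species table: sequence + expected reads per library
    mat <- tibble(kind = "mature", sequence = tr$hairpins$mature,
                  exp_ck = tr$expression$expected_ck,
                  exp_cd = tr$expression$expected_cd)
    star <- tibble(kind = "star", sequence = tr$hairpins$star,
                   exp_ck = config$star_reads, exp_cd = config$star_reads)
    ncf <- config$ncrna_fractions
    ncs <- purrr::imap(ncf, function(f, cl) {
      pool <- fragment_pool(study$ncrna$sequence[study$ncrna$class == cl],
                            30L, 15:30)
      tibble(kind = cl, sequence = pool,
             exp_ck = f * config$depth / length(pool),
             exp_cd = f * config$depth / length(pool))
    }) %>% bind_rows()
    used <- sum(mat$exp_ck + star$exp_ck) # roughly equal both libraries
    bg_n <- 400L
    bg <- tibble(kind = "background",
                 sequence = fragment_pool(study$reference$sequence, bg_n,
                                          sample_srna_lengths(bg_n)),
             exp_ck = max(0, config$depth - used -
                            sum(ncf) * config$depth) / bg_n)
    bg$exp_cd <- bg$exp_ck
    species <- bind_rows(mat, star, ncs, bg) %>%
      distinct(.data$sequence, .keep_all = TRUE)

    draw <- function(expected, label) {
      counts <- as.integer(rmultinom(1, config$depth,
                                     prob = pmax(expected, 1e-9)))
      keep <- counts > 0
      tibble(id = sprintf("%s_r%06d", label, seq_len(sum(keep))),
             sequence = paste0(species$sequence[keep], config$adapter3),
             count = counts[keep],
             quality = strrep("I", nchar(species$sequence[keep]) +
                                nchar(config$adapter3)))
    }
    list(ck = draw(species$exp_ck, "CK"),
         cd = draw(species$exp_cd, "Cd200"),
         species = species)
  })
}

#' Simulate a degradome read set for a synthetic study
#'
#' For each planted cleavage event, emits 20-21 nt sense tags whose 5'
#' end sits at the base opposite miRNA position 10, with the
#' configured signature count; adds background 5' ends uniformly along
#' every transcript at `background_per_kb`.
#'
#' @param study A `sim_study` from [simulate_reference()].
#' @return Tibble of degradome reads (`id`, `sequence`, `count`,
#'   `quality`).
#' @export
simulate_degradome <- function(study) {
  stopifnot(inherits(study, "sim_study"))
  config <- study$config
  with_seed(config$seed + 2L, {
    refseq <- setNames(study$reference$sequence, study$reference$id)
    ev <- study$truth$events
    out <- vector("list", 0)
    for (k in seq_len(nrow(ev))) {
      len <- 20L + (k %% 2L)
      s <- refseq[[ev$target_id[k]]]
      tag <- substr(s, ev$cleavage_pos[k], ev$cleavage_pos[k] + len - 1L)
      out[[length(out) + 1]] <- tibble(sequence = tag,
                                       count = ev$signature[k])
    }
    for (ti in seq_along(refseq)) {
      s <- refseq[[ti]]
      nbg <- rpois(1, config$background_per_kb * nchar(s) / 1000)
      if (nbg == 0) next
      pos <- sample(nchar(s) - 22L, nbg, replace = TRUE)
      lens <- sample(20:21, nbg, replace = TRUE)
      out[[length(out) + 1]] <- tibble(
        sequence = substr(rep(s, nbg), pos, pos + lens - 1L),
        count = 1L)
    }
    reads <- bind_rows(out) %>%
      group_by(.data$sequence) %>%
      summarise(count = sum(.data$count), .groups = "drop")
    tibble(id = sprintf("deg_r%06d", seq_len(nrow(reads))),
           sequence = reads$sequence, count = reads$count,
           quality = strrep("I", nchar(reads$sequence)))
  })
}

#' Write a simulated study to disk as FASTA/FASTQ plus truth tables
#'
#' @param study A `sim_study` from [simulate_reference()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_sim_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  libs <- simulate_srna_libraries(study)
  deg <- simulate_degradome(study)
  paths <- c(reference = file.path(dir, "reference.fa"),
             ncrna = file.path(dir, "ncrna.fa"),
             srna_ck = file.path(dir, "srna_CK.fastq"),
             srna_cd = file.path(dir, "srna_Cd200.fastq"),
             degradome = file.path(dir, "degradome.fastq"),
             hairpins = file.path(dir, "truth_hairpins.tsv"),
             expression = file.path(dir, "truth_expression.tsv"),
             events = file.path(dir, "truth_events.tsv"),
             config = file.path(dir, "sim_config.txt"))
  write_fasta(study$reference, paths["reference"])
  nc <- study$ncrna
  nc$id <- paste(nc$id, nc$class)
  write_fasta(nc, paths["ncrna"])
  write_fastq <- function(reads, path) {
    idx <- rep(seq_len(nrow(reads)), reads$count)
    rep_id <- paste0(reads$id[idx], "_", sequence_along_groups(idx))
    writeLines(paste0("@", rep_id, "\n", reads$sequence[idx], "\n+\n",
                      reads$quality[idx]), path)
  }
  write_fastq(libs$ck, paths["srna_ck"])
  write_fastq(libs$cd, paths["srna_cd"])
  write_fastq(deg, paths["degradome"])
  write_tags_tsv(study$truth$hairpins %>% select(-"precursor"),
                 paths["hairpins"])
  write_tags_tsv(study$truth$expression, paths["expression"])
  write_tags_tsv(study$truth$events, paths["events"])
  cfg <- study$config
  writeLines(paste0(names(cfg), "\t",
                    vapply(cfg, function(v) paste(format(v), collapse = ","),
                           character(1))), paths["config"])
  invisible(paths)
}

# per-group occurrence counter for an index vector (1,1,2 -> 1,2,1)
sequence_along_groups <- function(idx) {
  stats::ave(idx, idx, FUN = seq_along)
}
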