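#' Energy-model parameters for hairpin folding
#'
#' The folding engine uses a simplified nearest-neighbour model: a 6x6
#' stacking-energy table over the canonical pair types (AU, UA, CG, GC,
#' GU, UG) plus linear penalties for hairpin loops, internal
#' loops/bulges and multibranch loops. Stacking energies are derived
#' from per-pair strengths (CG/GC 2.0, AU/UA 1.1, GU/UG 0.6):
#' `stack(p1, p2) = -0.8 * (s(p1) + s(p2))` kcal/mol, so a CG-on-GC
#' stack contributes -3.2 and a GU-on-GU stack -0.96. A hairpin of u
#' unpaired bases costs `hairpin_a + hairpin_b * (u - 3)`; an internal
#' loop or bulge of u unpaired bases costs `internal_a + internal_b *
#' u`; a multiloop costs `multi_a + multi_b` per branch and `multi_c`
#' per unpaired base. Internal loops are capped at `max_internal`
#' unpaired bases and hairpin loops must contain at least
#' `min_hairpin` bases.
#'
#' @param hairpin_a,hairpin_b Hairpin-loop penalty intercept and slope
#'   (kcal/mol).
#' @param internal_a,internal_b Internal-loop/bulge penalty intercept
#'   and per-base slope.
#' @param multi_a,multi_b,multi_c Multiloop closing, per-branch and
#'   per-unpaired-base penalties.
#' @param min_hairpin Minimum hairpin-loop size (bases).
#' @param max_internal Maximum unpaired bases in an internal loop.
#' @return A list of model parameters accepted by [fold_mfe()] and
#'   [structure_energy()].
#' @export
fold_params <- function(hairpin_a = 5.0, hairpin_b = 0.3,
                        internal_a = 2.0, internal_b = 0.5,
                        multi_a = 4.0, multi_b = 0.4, multi_c = 0.3,
                        min_hairpin = 3L, max_internal = 30L) {
  strength <- c(AU = 1.1, UA = 1.1, CG = 2.0, GC = 2.0, GU = 0.6, UG = 0.6)
  stack <- -0.8 * outer(strength, strength, `+`)
  list(stack = stack,
       hairpin_a = hairpin_a, hairpin_b = hairpin_b,
       internal_a = internal_a, internal_b = internal_b,
       multi_a = multi_a, multi_b = multi_b, multi_c = multi_c,
       min_hairpin = as.integer(min_hairpin),
       max_internal = as.integer(max_internal))
}

#' Fold one RNA sequence to its minimum-free-energy structure
#'
#' Computes the minimum-free-energy nested secondary structure of a
#' single strand by Zuker-style dynamic programming under the model of
#' [fold_params()]. Deterministic for a fixed input and model. If no
#' structure has negative energy the open chain is returned with an
#' MFE of 0.
#'
#' @param sequence A single nucleotide string over A/C/G/T/U (case
#'   insensitive; T and U are equivalent).
#' @param params Energy-model parameters from [fold_params()].
#' @return A list of class `hairpin_structure` with elements
#'   `sequence`, `structure` (dot-bracket), `mfe` (kcal/mol, <= 0) and
#'   `pairs` (integer vector of 1-based partners, 0 = unpaired).
#' @examples
#' fold_mfe(paste0("GGGCGCGCCC", "AAAA", "GGGCGCGCCC"))
#' @export
fold_mfe <- function(sequence, params = fold_params()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (grepl("[^ACGTUacgtu]", sequence))
    stop("sequence contains characters outside A/C/G/T/U")
  res <- fold_mfe_cpp(sequence, params)
  structure(list(sequence = toupper(chartr("tT", "uU", sequence)),
                 structure = res$structure,
                 mfe = res$mfe,
                 pairs = as.integer(res$pairs)),
            class = "hairpin_structure")
}

#' @export
print.hairpin_structure <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, "\n",
      sprintf("MFE = %.2f kcal/mol", x$mfe), "\n", sep = "")
  invisible(x)
}

#' Score a given secondary structure under the folding energy model
#'
#' Evaluates the free energy of an explicit nested structure (given as
#' a pair vector) by decomposing it into loops, using exactly the same
#' model as [fold_mfe()] but without any optimisation. Useful for
#' checking the dynamic program against structures produced some other
#' way.
#'
#' @param sequence Nucleotide string.
#' @param pairs Integer vector of 1-based partner positions (0 =
#'   unpaired); must be symmetric and nested.
#' @param params Energy-model parameters from [fold_params()].
#' @return The structure's energy in kcal/mol (`Inf` if the structure
#'   is outside the model, e.g. an oversized internal loop or a
#'   non-canonical pair).
#' @export
structure_energy <- function(sequence, pairs, params = fold_params()) {
  s <- strsplit(toupper(chartr("tT", "uU", sequence)), "")[[1]]
  n <- length(s)
  stopifnot(length(pairs) == n)
  pair_name <- function(i, j) paste0(s[i], s[j])
  valid <- rownames(params$stack)
  # collect pairs (i < j)
  ii <- which(pairs > seq_len(n))
  total <- 0
  for (i in ii) {
    j <- pairs[i]
    if (!(pair_name(i, j) %in% valid)) return(Inf)
    if (j - i - 1 < params$min_hairpin) return(Inf)
    # direct children: pairs (p,q) inside (i,j) not nested in another pair
    inside <- ii[ii > i & ii < j & pairs[ii] < j]
    if (length(inside)) {
      keep <- vapply(inside, function(p) {
        !any(inside < p & pairs[inside] > pairs[p])
      }, logical(1))
      children <- inside[keep]
    } else children <- integer(0)
    k <- length(children)
    u <- (j - i - 1) - sum(pairs[children] - children + 1L)
    if (k == 0L) {
      total <- total + params$hairpin_a + params$hairpin_b * (u - 3)
    } else if (k == 1L && u == 0L) {
      total <- total +
        params$stack[pair_name(i, j), pair_name(children, pairs[children])]
    } else if (k == 1L) {
      if (u > params$max_internal) return(Inf)
      total <- total + params$internal_a + params$internal_b * u
    } else {
      total <- total + params$multi_a + params$multi_b * k + params$multi_c * u
    }
  }
  total
}

#' Convert a dot-bracket string to a partner vector
#'
#' @param db Dot-bracket string using `(`, `)` and `.`.
#' @return Integer vector of 1-based partners (0 = unpaired).
#' @export
dot_bracket_pairs <- function(db) {
  ch <- strsplit(db, "")[[1]]
  pairs <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[i] <- j
      pairs[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  pairs
}
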