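---
title: "Methods: small RNA miRNA discovery, differential expression and degradome target validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA miRNA discovery, differential expression and degradome target validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpare)
```

# Scope

`mirpare` implements the computational core of a classic plant
small-RNA study design: two sequencing libraries (a control and a
stressed condition, here labelled CK and Cd200 after the
cadmium-exposure experiment whose summary tables ship with the
package), a transcript/genomic reference, databases of non-coding RNAs
and known mature miRNAs, and a degradome (PARE) library for target
validation. The pipeline covers read cleaning, tag collapsing,
annotation, novel miRNA discovery by hairpin folding, two-library
differential expression, and cleavage-target calling with t-plots.
Because studies of this kind frequently leave no raw data behind, the
package also contains a first-class synthetic-data generator that
plants hairpins, fold changes and cleavage events with a full truth
table, so that every stage can be validated against known ground
truth.

# Read cleaning

Cleaning applies the standard rules in a fixed order so the rejection
tally is deterministic: reads containing the 5' adapter are discarded
as primer contaminants; then the 3' adapter is located by its first
10 bases and trimmed (a read equal to the adapter, starting with it,
or shorter than the seed has no insert); then poly(A) inserts are
discarded; finally the insert length is restricted to 15–30 nt. The
poly(A) rule — at least 80% A or a run of 10 consecutive A's — is our
own operationalisation; the convention in published pipelines is
stated but never defined. A read in which the 3' adapter is *not*
found keeps its full sequence as the insert. This choice makes
cleaning idempotent (cleaning its own output changes nothing), which
we consider more important than aggressively discarding untrimmable
reads: those are almost always removed by the length filter anyway.

U is normalised to T on ingest; every internal comparison is in DNA
alphabet. Mature miRNA sequences are re-emitted with U in reports.

# Annotation

Tags map to the reference by perfect substring matching on both
strands (width-grouped `Biostrings::PDict` dictionaries). ncRNA
classification uses exact matching against labelled rRNA/tRNA/
snRNA/snoRNA records with the priority rRNA > tRNA > snRNA > snoRNA
for multi-class hits; classified tags are excluded from miRNA
calling. Known-miRNA assignment is an ungapped end-to-end comparison:
Hamming distance over the shared prefix plus one per overhanging
base, with a default allowance of two mismatches. G:U counts as a
plain mismatch here (unlike degradome scoring, where it is a
half-penalty); an alignment-free distance keeps the contract exactly
testable by brute force. Ties go to the lexicographically smallest
member identifier. Family names parse by stripping the species prefix
and member/arm suffixes (`ath-miR156a-5p` → `miR156`).

By default a tag assigned to a known miRNA does not also need a
reference hit — the bundled study's own tallies imply the counts were
independent — but `strict_reference = TRUE` restores the conservative
behaviour.

# Novel miRNA discovery

Unannotated tags of mature length (20–24 nt, at least 5 reads) are
mapped to the reference and up to two candidate precursor windows are
excised per hit: tag near the 5' end with a 160-nt downstream flank,
and tag near the 3' end with the flank upstream (bounds 60–300 nt,
truncated at record ends). Each window is folded and screened:

1. the mature tag must lie on a single arm of the hairpin, not
   spanning the terminal loop;
2. at most 4 mature bases may be unpaired in the miRNA/miRNA* duplex
   and no asymmetric bulge may exceed 2 nt;
3. a sequenced tag equal to the star sequence — the duplex partner
   with 2-nt 3' overhangs, computed from the pair table — must be
   observed with at least one read;
4. the precursor MFE must be at most −18 kcal/mol (the weakest
   precursor printed in the bundled study's novel-miRNA table).

Rejections record the first failed criterion, which makes simulator
truth tables easy to compare against. Identical matures from several
loci merge into one reported miRNA; candidate windows that overlap on
the same record (either strand — a hairpin's reverse complement is
the same physical locus) count as one locus. Serial names are
assigned by descending total read count, ties broken by sequence.

## The folding engine

The minimum-free-energy folder is a Zuker-style dynamic program
(`src/fold.cpp`) over a deliberately simplified nearest-neighbour
model: stacking energies for the six canonical pair types derived
from per-pair strengths (CG/GC 2.0, AU/UA 1.1, GU/UG 0.6, stack
energy −0.8·(s₁+s₂) kcal/mol), linear hairpin (5.0 + 0.3·(u−3)),
internal/bulge (2.0 + 0.5·u, capped at 30 unpaired bases) and
multiloop (4.0 + 0.4/branch + 0.3/unpaired base) penalties, minimum
hairpin loop 3. The model is small enough that an independent
enumerator can score *every* nested structure of a short sequence;
the test suite verifies the DP optimum against exhaustive enumeration
on hundreds of seeded random sequences up to 14 nt, and
`structure_energy()` exposes the scorer so any structure can be
re-evaluated under the same model. Established thermodynamic folders
(Mfold, ViennaRNA) implement the full Turner parameter set; we chose
an exactly-testable model instead, and `fold_mfe()` is the single
seam through which such an external folder could be swapped in.
MFE values under this model are on the same scale as the full
parameter set for stable hairpins (planted perfect-stem precursors
fold in the −40 to −90 kcal/mol range) but are not numerically
comparable for marginal structures; the −18 kcal/mol acceptance
threshold should be recalibrated if the energy model is replaced.

# Differential expression

Counts are normalised to reads per million of the library's total
clean reads. The published methods sentence is ambiguous about the
denominator (miRNA reads vs all clean reads); the bundled tables
reproduce only under total clean reads, so that is the default and
the denominator is a parameter. Zero normalised values become 0.001
so fold changes stay defined; `log2fc = log2(treated/control)`.

Significance uses the Audic–Claverie exact test: with depth ratio
r = N₂/N₁, P(k|x) = rᵏ(x+k)!/(x!k!(1+r)^(x+k+1)), and the two-sided
p-value is twice the smaller tail at the observation, capped at 1,
with terms evaluated in log space. The raw tail formula is not
exactly invariant to swapping the two libraries (the conditional
normalises over different supports), so the implementation always
conditions on the library with the larger count (ties: the deeper
library). This makes `p(x, y, N₁, N₂) = p(y, x, N₂, N₁)` hold
exactly by construction while leaving the formula itself untouched
on the canonical orientation; empirical type-I error at α = 0.05
stays within [0.03, 0.07] under seeded null simulations. A
miRNA is called up- or down-regulated when the linear expression
ratio exceeds 2 (or falls below 0.5 — equivalently |log2fc| > 1) *and*
p ≤ 0.05. No multiple-testing correction is applied by default, to
match the single-library-pair design; `fdr = TRUE` switches the calls
to Benjamini–Hochberg-adjusted p-values.

# Degradome target calling

Degradome reads are restricted to 20–21 nt (the MmeI fragment size)
with mean Phred ≥ 20 where qualities exist, collapsed, and mapped to
transcripts by perfect sense-strand matching; each read counts once
in the normalisation total no matter how many positions it matches.
miRNA/transcript complementarity is scored ungapped over every
window: mismatch 1.0, G:U 0.5, doubled at miRNA positions 2–13;
alignments pass with penalty ≤ 4.0 (the largest score printed in the
bundled study's target tables), at most 5 non-matching positions, and
strict Watson–Crick pairs at miRNA positions 10 and 11 — the cleavage
site tolerates no wobble. The predicted cleavage position is the
transcript base opposite miRNA position 10; signature abundance is
reported raw and as TP100M (raw × 10⁸ / total mapped reads).

Categories follow the degradome convention: **I** — the signature
equals the transcript maximum, that maximum is unique, and the raw
count exceeds 1; **II** — below the maximum but above the median;
**III** — everything else. The median is taken over occupied
positions only (positions with at least one raw read); the published
definition leaves the median's support unstated, and the occupied
support is the choice that makes category II non-trivial on long,
sparsely covered transcripts.

# The synthetic study

`sim_config()` defaults describe the compact study the tests run: 20
transcripts of 0.5–3 kb, 12 planted hairpin loci, 2×10⁵ reads per
library, 5×10⁴ degradome reads, ncRNA fractions rRNA 0.20, tRNA 0.02,
snRNA 0.005, snoRNA 0.002, and a length profile peaked at 21/24 nt —
proportions chosen to resemble published plant root libraries while
keeping a full run in minutes on one CPU. Planted hairpins have a
perfect mature/star duplex (so the star sequence is exactly defined)
with G:U wobbles planted in the extension stems at rate 0.1; a third
of the planted miRNAs are 4-fold up, a third 4-fold down, a third
flat, with control-library expectations of 50–500 reads and star
expectations of 3 reads per library. Cleavage events go one per decoy
transcript (signature 50 reads at the base opposite miRNA position
10) so each planted event is the unique maximum of a quiet t-plot;
background degradome 5' ends arrive at 1 per kb. Reads are drawn as
one multinomial per library at the configured depth, so identical
seeds give byte-identical outputs.

What the simulator deliberately does **not** model: sequencing
errors, quality-score variation (qualities are constant `I`; the
quality filter is exercised by dedicated fixtures), isomiR end
variation, RNA editing, genome-scale repeat structure, and
multi-mapping ambiguity beyond what random sequence produces. Passing
the recovery suites therefore demonstrates the pipeline's logic is
correct under its stated assumptions, not that it is robust to every
artefact of real libraries.

# Numerical and reporting conventions

Percentages in summary tables round to 2 decimals (1 decimal where
the bundled study prints 1), normalized abundances to 4, fold changes
and family ratios to 2; all rounding happens at presentation, never
inside the computation. Report tables are TSV with `#`-prefixed
metadata headers; the run manifest records the package version,
parameters, seed and input/output MD5 checksums, and omits
timestamps so reruns are byte-identical. Ordering is deterministic
everywhere: tags by count then sequence, target calls by transcript,
position, then miRNA, novel miRNAs by total abundance then sequence.

The test suite sizes its problems to run comfortably on one CPU: the
end-to-end recovery suite uses the default synthetic study once, the
folding oracle enumerates structures for sequences up to 14 nt, and
the calibration suite draws 2,000 null count pairs.

# Known limitations

- The energy model is intentionally reduced; absolute MFE values are
  model-dependent (see above).
- Known-miRNA assignment is ungapped; indel isoforms of a member are
  found only within the overhang allowance.
- Degradome alignment is ungapped by design (`gap` penalties exist in
  the scoring convention but gapped scanning is not implemented);
  bulged target sites are missed.
- One library per condition: the Audic–Claverie test models sampling
  noise only, not biological replication.
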