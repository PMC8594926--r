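---
title: "Methods: 5'XP small RNA sequencing analysis with fivexp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 5'XP small RNA sequencing analysis with fivexp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fivexp)
library(dplyr)
```

## The problem

Conventional small RNA sequencing ligates the 5' adapter directly to the
RNA and therefore only captures molecules carrying a 5' monophosphate
(5'-P) — canonical miRNA and piRNA, but not the large population of
fragments with other 5' chemistries (5'-OH, capped, cyclic phosphate)
produced by tRNA and rRNA cleavage. 5'XP sRNA-seq addresses this by
ligating a short 11-nt oligonucleotide *tag* to 5'-P molecules before a
phosphorylation-independent adapter step, so that a single library contains
both populations and they can be separated bioinformatically: reads whose
insert begins with the tag form the phosphorylation-*sensitive* **5P-tag**
sub-library, all others the *insensitive* **5X-notag** sub-library.

`fivexp` implements the complete downstream workflow for such libraries:

1. **preprocess** — quality/adapter trimming and tag splitting,
2. **seqtable** — unique-sequence counting, abundance filters, cpm,
3. **annotate** — mismatch-tiered hierarchical biotype annotation,
4. **fragments** — tRNA/rRNA fragment terminal and loop classification,
5. **summarize** — composition, size, first-nucleotide, fold-change,
   correlation and saturation analytics,
6. a seeded **simulator** that generates reference bundles and
   tagged/untagged reads with ground truth, used throughout the test suite.

## Read preprocessing

Stages run in a fixed order: two-color quality trimming, 3' adapter
trimming with length bounds, 5'-tag splitting, whole-read quality
filtering. The originating protocol applies quality and adapter trimming in
one step and does not state whether quality filtering preceded tag
splitting; we filter last so both sub-libraries face identical criteria,
and document that as our choice.

**Two-color trimming** (`trim_two_color_tail()`). On two-color instruments
a dark cycle is read as G, so a trailing G run carries no information
regardless of its reported quality. We treat G as quality 0 and apply the
standard running-sum rule: walking from the 3' end accumulating
`qcut - q_effective` (default `qcut = 20`), the read is cut where the sum
is maximal; the walk stops when the sum turns negative. A read can become
empty; it is then discarded at the next stage.

**Adapter trimming** (`trim_three_prime_adapter()`). Candidates are every
ungapped occurrence of the full adapter and every adapter *prefix* of at
least `min_overlap = 5` bases flush with the 3' end, with a mismatch budget
of `floor(0.1 × matched length)` (the error tolerance of standard
trimmers; the protocol itself prints none). N never matches. Ties break
toward the longest match, then leftmost. Because an insert can itself end
with a short adapter-like motif, a single cut cannot guarantee that no
qualifying occurrence survives; trimming therefore iterates to a fixed
point, while the keep/discard decision is made on the first pass. Reads
with no qualifying occurrence are discarded (`--discard-untrimmed`
semantics), as are inserts outside 5–70 nt.

**Quality filter** (`quality_filter()`). Keep a read when ≥ 80% of bases
have Phred ≥ 20. The protocol's prose says "\>20 in more than 80%", but the
tool it cites implements ≥/≥; we follow the tool semantics for
reproducibility against the published command line, and expose both
thresholds.

**Tag splitting** (`split_by_tag()`). The 11-nt tag `TGGCAACGATC` is
matched as a read prefix. Default matching is exact
(`tag_max_mismatch = 0`): the published command line would tolerate ~1
mismatch at its default error rate, but a mismatched tag call moves a read
*between* sub-libraries — the central contrast of the method — so we
default strict and expose a flag to relax. De-tagged reads shorter than
`min_len` are discarded.

Every input read is accounted for exactly once: retained in one sub-library
or attributed to a named discard reason (`no_adapter`, `too_short`,
`too_long`, `short_after_tag`, `low_quality`). The per-stage accounting is
available via `tidy()` on the `preprocess_reads()` result.

## Sequence-based counting

Counting is over unique sequences, not genomic features: one row per
distinct retained sequence, so annotation mismatches never alter the count
table. Library totals are the per-sample retained read counts, fixed at
counting time. Two filters mirror common practice for such tables:
`filter_min_count()` (default ≥ 5 counts in 100% of scoped samples, the
noise filter) and, after `normalize_cpm()` (counts / library total × 10⁶),
`filter_min_cpm()` (default ≥ 10 cpm in every scoped sample, for analyses
of well-expressed sequences). The normalization denominator is always the
pre-filter library total; recomputing it after filtering would silently
change what "10 cpm" means. Column sums of an unfiltered cpm table are
exactly 10⁶, and filters commute with normalization.

## Hierarchical annotation

Annotation emulates alignment cycles of increasing mismatch allowance
(tiers 0–3): a sequence is assigned at the smallest tier at which *any*
reference set contains a full-length ungapped placement within the tier's
Hamming budget. When several biotypes match at that tier the fixed priority
ladder decides: miRNA > Mt_tRNA > tRNA > MT_rRNA > rRNA > piRNA >
other_sncRNA. So a 0-mismatch piRNA hit beats a 1-mismatch miRNA hit, while
at equal tier miRNA wins. Sequences unresolved after tier 3 are
`unannotated` and are carried as their own class in composition tables.

Choices the underlying protocol leaves open, declared here:

- **Full-length Hamming distance**, no indels, no seed heuristics — in the
  short-read/small-reference regime this makes the brute-force oracle exact
  and the tier definition unambiguous.
- **Sense strand only** by default (mature small RNA fragments derive from
  the annotated strand); `strand = "both"` searches the reverse complement
  for users mimicking a both-strand aligner.
- **Within-biotype representative**: fewest mismatches, then
  lexicographically smallest `ref_id`, then smallest (leftmost) start — a
  deterministic stand-in for an aligner's unstated multi-placement
  collapse.

## Fragment classification

**Terminals.** A fragment starting at base 1 of the mature reference is
`five_prime`, ending at the last base `three_prime`, both `full`, neither
`internal`. "Terminal" means the exact first/last base — no tolerance is
stated by the originating analysis, so none is applied (a configurable
`tolerance` exists, default 0). Full-length reads get their own class
rather than double-counting as 5' and 3'; `terminal_enrichment()`
accordingly reports cpm-weighted 5'/i'/3' fractions over fragments only,
with full-length cpm alongside.

**Loops.** Secondary-structure (ss) records pair a mature tRNA sequence
with an aligned string over `>`, `<`, `.`. Loops are maximal unpaired runs
*strictly enclosed* by a stem (the flanking `>` and `<` pair with each
other), labelled 5'→3' as D_loop, anticodon_loop, variable_loop (when a
fourth enclosed run precedes the T stem, i.e. a paired variable arm) and
T_loop. Records with fewer than three enclosed runs are flagged unusable.

**Boundary convention.** The 5' boundary of a fragment is the
phosphodiester bond before `start`; we place it in a loop when position
`start − 1` lies inside the loop interval, and the 3' boundary uses
position `end`. Boundaries at the reference termini carry no loop. Then:

- `tiRNA_half`: a 5' fragment ending in the anticodon loop, or a 3'
  fragment starting there — the signature of anticodon (angiogenin-style)
  cleavage;
- `nitRNA_like`: an internal fragment with a boundary in the T loop. The
  literature definition of these internal T-loop fragments is qualitative;
  this flag is a declared operational rule, not an inferred one, and is
  labelled as such in outputs.

**rRNA fragments.** On a precursor annotated with mature subunit intervals,
a fragment belongs to the subunit containing its midpoint
(`floor((start + end) / 2)`; the even-length tie rounds down — the
originating analysis states no spanning-fragment rule, so the midpoint rule
and its tie are ours). Terminal classes are then computed against that
subunit's boundaries.

**Coverage.** `compute_coverage()` sums, per reference position, the cpm of
covering fragments; a fragments × samples cpm matrix yields the per-sample
mean profile. Coverage conserves mass: the profile total equals
Σ cpm × fragment length.

## Analytics

- `size_distribution()`: per biotype and insert length, the mean over
  samples of summed cpm; cells total the mean per-sample cpm.
- `first_nt_bias()`: cpm-weighted base fractions at a position (default 1),
  reported in the RNA alphabet; N-weight is excluded from the four
  fractions and reported separately.
- `log2_fold()`: `log2((mean_A + pc) / (mean_B + pc))` with a default
  pseudocount of 1 cpm — the source analysis reports >20-fold tails for
  sequences absent from one method but prints no pseudocount, so 1 cpm (the
  smallest round unit on the normalized scale) is our choice. Direction is
  sign-only by default; a threshold parameter widens the `unchanged` band
  because the original pie-chart summaries state none.
- `correlation_cluster()`: Pearson on log2(cpm + 1) with average-linkage
  clustering on 1 − r. The source states only "correlation … hierarchical
  clustering"; coefficient and linkage are exposed.
- `saturation_curve()`: subsample without replacement at a fraction grid
  (3 replicates averaged, seeded), count distinct sequences at ≥ threshold
  copies, and fit `richness(d) = Asym + (R0 − Asym)·exp(−exp(lrc)·d)` with
  `stats::nls` + `stats::SSasymp`. If the self-starter fails,
  `minpack.lm::nlsLM` retries from heuristic starts (Asym = 1.05 × max
  richness, R0 = first point, lrc from the depth scale); a perfectly flat
  curve (e.g. a single-sequence library) is reported as the exact
  degenerate solution Asym = R0 with lrc = −∞; remaining failures return
  the raw points with `converged = FALSE`.

## The simulator

`make_reference_bundle()` draws per-biotype references: miRNA 22 ± 1 nt,
piRNA 26–30 nt with an 80% U start-bias, cloverleaf tRNA/Mt_tRNA of
85–88 nt, rRNA-like references ≥ 100 nt. Fixture tRNAs all carry a short
*paired* variable arm so their ss strings exercise the four-loop labelling
branch (D, anticodon, variable, T); real fly tRNAs are mostly type I
(unpaired variable region), which the parser handles and the tests cover
with a crafted record. The D-loop length (13–16 nt) is chosen so the
anticodon loop straddles the sequence midpoint, as in real tRNAs.
References are redrawn if they contain the adapter's 5-nt minimum-overlap
prefix: a reference carrying that motif would make its fragments
unrecoverable by *any* correct trimmer, so excluding it is a validity
condition of the ground truth, not a tuning knob.

`simulate_reads()` assembles each read as
`[tag] + insert + adapter + random tail`, truncated to the 75-nt read
length of the original instrument run, with per-base Phred scores
~N(35, 3) clamped to [2, 40] and a 2% admixture of low-quality reads
(mean Q10) to exercise the quality-control path — note that such reads are
usually consumed by the two-color trim (the running sum never turns
negative, the read trims to empty and is discarded as `no_adapter`); the
whole-read filter catches the milder failures whose 3' end survives. Insert rules per biotype: full mature
miRNA/piRNA; tRNA fragments drawn with designed terminal-class proportions
(default 60/10/30 five/internal/three) and, with probability 0.5,
loop-anchored breakpoints (anticodon-loop halves, anticodon→T-loop internal
fragments); rRNA fragments of 20–40 nt stratified uniformly by the same
proportions; fragment lengths are capped at 48 nt so a tagged read always
retains ≥ 5 nt of visible adapter. The default tagged fraction is 0.15,
the middle of the 10–20% that 5'-P molecules contribute in such libraries;
it is a free parameter, not an estimate. The per-base substitution rate
defaults to 0.001.

The in-memory truth table records, per read, the source reference, insert
coordinates, tag status and substitution count, plus the *designed*
terminal class and loop flags (decided before coordinates are drawn, so
classifier checks against them are not circular). The on-disk TSV carries
the seven core columns. All randomness flows through one seeded scope
(`withr::with_seed`), so identical parameters give byte-identical files.

What the simulator does **not** model — and hence what passing tests do not
show about real data: ligation sequence bias, PCR duplication,
RNA-modification-induced misincorporation and truncation (a major cause of
real mismatch tiers > 0), expression-level skew across references, and
genomic multimapping beyond the supplied reference sets.

## Problem sizes and numerical checks

The test suite validates the preprocessing partition on a 10⁵-read fixture;
the aligner against a brute-force Hamming oracle on 1,000 random pairs;
zero-noise round trips (biotype recovery at tier 0, exact tag agreement) on
5,000 reads; terminal-class recovery on 10⁴ fragments (designed 60/10/30
mix, recovered within 2 percentage points; loop flags at 100%); coverage
against a per-position truth tally, exactly; and saturation recovery of a
500-sequence pool at 10× depth (asymptote within 15%, typically within
1%). These sizes keep the full suite under two minutes while leaving each
estimate's sampling error well inside its tolerance.

## Known limitations

- Single-end reads only; no UMIs, no paired-end merging.
- Ungapped full-length matching cannot annotate reads spanning splice or
  processing junctions absent from the references.
- The nitRNA flag is an operational definition (internal fragment with a
  T-loop boundary) of a qualitatively described class.
- `isodecoder()` parses the `tRNA-<AminoAcid><Anticodon>-<n>` naming
  convention; other reference dialects need a custom regex.
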