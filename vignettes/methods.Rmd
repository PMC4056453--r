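---
title: "Methods: cross-species binding conservation, co-binding and repeat statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species binding conservation, co-binding and repeat statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primatecons)
```

# Scope and data model

`primatecons` implements the comparative analyses that are standard for
multi-species transcription-factor ChIP-seq panels — here modelled on a
seven-primate CTCF/YY1 comparison in lymphoblastoid cell lines. All
coordinates are 0-based half-open (BED convention); a RepeatMasker
`genoStart` is treated as already 0-based (UCSC table convention). Overlap
between two intervals means "same chromosome and at least `min_bp` shared
bases" with `min_bp = 1` by default; strand is never consulted for
overlap, because binding events are orientation-free summaries of ChIP
enrichment.

A binding event carries a score (proportional to ChIP enrichment), a
per-event FDR and a summit. Replicate peak sets within a species are
merged by intersection — events of the first replicate supported by a
≥ 1 bp overlap in every other replicate — plus replicate-unique peaks with
FDR < 0.05. Two conventions are ours where the procedure is otherwise
underdetermined: the intersection keeps the *first* replicate's
coordinates (any replicate's coordinates would be defensible; fixing one
makes the merge deterministic), and duplicated coordinate triples are
collapsed after merging.

# Projection and conservation classes

The projection substrate is a table of orthology blocks: each block has
one segment per member species, and within a species segments never
overlap. This abstracts a whole-genome multiple alignment (EPO-style)
down to the only structure the conservation analysis consumes. An
interval is projected by offset within the block; when segment lengths
differ the offset is scaled proportionally (`round()` at both ends, with
a one-base floor so a projection never collapses to zero width), and an
opposite-strand segment reverses coordinates within the block. The
brute-force per-base oracle in the test suite pins this arithmetic
exactly for equal-length blocks, which is also the only case the
synthetic generator produces.

An anchor event's class is determined by its sharing count: itself plus
every species where at least one projected piece overlaps (≥ 1 bp) a peak
of that species. Sharing counts map onto six classes — `UNALIGNED` (no
overlapping block carries any other species), `SPECIES_SPECIFIC`
(aligned, no partner), `TWO_WAY`, `THREE_TO_FIVE`, `SIX_WAY` (all but
one), `ALL`. Three conventions worth making explicit:

* an event projecting to several blocks is shared if *any* piece hits a
  peak (the most permissive reading of the ≥ 1 bp rule);
* the sharing count includes the event's own species, so "shared between
  two species" means self plus exactly one partner;
* `UNALIGNED` requires zero block coverage toward *all* other species;
  a block shared with only a subset still counts as "in the alignment".

Pairwise shared fractions are computed in both anchoring directions and
averaged, since the anchoring choice shifts counts by a small number of
events. Classifications, in contrast, are inherently per-anchor and are
reported that way. The FDR-sensitivity curve (fix the anchor species'
FDR, relax the partner's cutoff along a grid up to 0.5) is returned as
raw per-grid fractions without further aggregation, because any summary
of it (per species vs pooled) is a presentation choice, not part of the
statistic.

# Co-binding partition

A CTCF event is co-bound iff it overlaps ≥ 1 bp of any YY1 event, and
symmetrically; each event gets exactly one class, and a CTCF event over
several YY1 events contributes one pair per overlap but is tallied once.
Feature association reports, per species and class, the fraction of
events overlapping ≥ 1 feature, with the cross-species mean ± standard
error and a two-sided Wilcoxon rank-sum test of the CTCF-only vs CTCF–YY1
per-species fractions. The class collections are unpaired samples, so the
rank-sum (Mann–Whitney) test is the package's default throughout; a
`paired = TRUE` flag exposes the signed-rank variant for completeness,
but it requires equal sizes and an actual pairing, which these data do
not supply.

For expression, transcripts are assigned to classes by overlap with
priority CTCF–YY1 first (a transcript touching at least one co-bound pair
is co-bound regardless of what else it touches), then YY1-only, then
CTCF-only. The second tie-break is our choice: when a transcript overlaps
both single-factor classes, YY1 presence dominates, matching the way
YY1-containing classes behave as a unit in the expression comparison.

# Repeat enrichment and ages

For each repeat family, `k` counts events overlapping ≥ 1 element of the
family (an event over several elements counts once — `k` counts events,
not hits). The background probability is estimated by randomization:
events are re-placed uniformly on their own chromosome with lengths
preserved (overlaps among randomized events are allowed; this is the
simplest placement model consistent with "randomized binding events"),
and `p_bg` is the median over `n_rand = 100` randomizations of the
overlap count divided by `n`. Numerical guards: `p_bg` is floored at
`1/(n·n_rand + 1)` so an all-zero background cannot produce `p_bg = 0`,
and capped symmetrically below 1. The p-value is the exact binomial upper
tail `P(X ≥ k | Bin(n, p_bg))`, BH-corrected across families within a
species; significance is declared on the adjusted p ≤ 0.01 (a raw-p
option exists behind a flag). Reported `neg_log_p` is base 10.

Repeat age is the closed form `(milliDiv/1000) / μ` with μ = 2.2e−9
substitutions per bp per year for the mammalian lineage and 4.5e−9 for
rodents — rates interpreted as 10⁻⁹-scale per-bp-per-year values, the
only reading under which repeat ages land in the 10⁷–10⁸-year range where
known repeat families live.

Summit profiles quantify a track in 200 windows of 50 bp (a 10 kb span)
centred on each summit; coverage mode reports the fraction of window
bases covered by the merged track (elements are unioned first so
overlapping annotations cannot exceed 1), read-count mode counts
overlapping track intervals. Windows truncated by a chromosome end are
zero-filled and flagged.

# Motif words

PWM scanning scores a window as `Σ log2(p_i(base) / p_i(consensus))`, so
the consensus scores exactly 0 and everything else is negative; both
strands are scanned, windows containing `N` are skipped, and the default
cutoff is −15. Overlapping hits, including opposite-strand hits at one
locus, count separately — one hit, one count.

The word table restricts hits to those whose position lies inside a bound
region, counts raw occurrences per species, and normalizes by
`factor = bound bases / 10⁶`. The minimum-occurrence filter ("at least 5
in at least one species") is applied to *raw* counts; applying it to
normalized counts would make the threshold depend on the unit of
`factor`. The species-specificity score is
`normWord = log2((nocc(S)+1) / (max_{r∈R} nocc(r)+1))`; for a clade S,
`nocc(S)` aggregates as the clade maximum, mirroring the maximum over R.
Word selection fits a normal distribution by sample mean/SD to all
normWord values, converts each word to an upper-tail p, applies BH at the
target FDR (0.05), and reports the implied normWord cutoff (the smallest
selected score, `Inf` if nothing passes). BH is used for consistency with
the repeat module; the moment fit (rather than a robust fit) is the
simplest choice and is exercised by the null-calibration test.

# The synthetic generator

The generator is the package's stand-in for real multi-species ChIP-seq
data and defines the conditions under which the statistical properties
are demonstrated:

* **Species panel.** Seven species at divergence times 0, 6, 9, 16, 29,
  29, 40 My from the anchor — the great-ape / Old World / New World
  monkey structure of primate LCL panels. All species share a 10 Mb
  two-chromosome genome; orthology is simulated in a common ancestral
  frame with per-block jitter and 10% reversed segments.
* **Alignment map.** Blocks of 5 kb tile 80% of the anchor genome; every
  other species joins a block with probability `exp(-divergence/τ)`,
  τ = 100 My, so alignability — and with it pairwise sharing — decays
  with divergence.
* **Events.** 2000 CTCF events of 300 bp in non-overlapping slots;
  classes drawn from planted proportions (0.10 unaligned, 0.10
  species-specific, 0.10 two-way, 0.25 three-to-five, 0.15 six-way, 0.30
  all-species — a highly-shared-weighted mix of the kind seen for CTCF);
  orthologous copies are placed at exactly the projected coordinates of
  the drawn member species, so ground truth and geometry agree by
  construction. Co-binding probability rises linearly with sharing count
  from 0.15 to 0.50, reproducing the pattern that co-bound regions
  concentrate in the conserved classes; solo YY1 events (40% of the CTCF
  count) are placed clear of CTCF events so the YY1-only class is
  well-defined.
* **Repeats.** Each family places a computed fraction of its elements on
  event summits and the rest uniformly, so that the event-overlap
  probability is `enrichment ×` the uniform background; defaults plant a
  5× family (young, milliDiv ≈ 110) and a 3× family among four
  unenriched ones.
* **Words.** Background 14-mers occur Poisson(8) per species inside
  bound regions; the planted word has a 10× rate in the focal species.
  Hits are generated directly rather than via sequence scanning — the
  scan itself is tested separately on explicit sequences, and planting at
  the hit level keeps the word-statistic recovery tests independent of
  sequence composition.
* **Expression.** Log2 estimates are normal (baseline 4, SD 2) with a
  +2 shift for YY1-containing classes, the direction and magnitude that
  make the class comparison decisive at realistic transcript counts.

Everything is a pure function of the world seed; sub-generators derive
independent streams from it, so stages can be regenerated separately and
full runs are bit-reproducible.

What the generator does *not* emulate: read-level noise and peak-calling
artefacts, alignment gaps and indel structure within blocks, sequence
evolution of motifs, repeat-family phylogenies, and cell-line or
individual-level variability. Passing the recovery tests therefore shows
that the statistics are implemented correctly and are well-calibrated
under their own assumptions — not that those assumptions hold for any
particular real dataset.

# Problem sizes and test design

The test suite works at sizes chosen to make stochastic properties
crisp while staying comfortably interactive: recovery of planted class
proportions and the divergence trend use the default 2000-event
seven-species world; binomial-tail exactness is checked against
brute-force summation for every `k ≤ n ≤ 200`; type-I calibration of the
repeat test averages 20 fifty-family null worlds and its power is
measured over 50 seeds of a planted 5× family; word-expansion recovery
uses 50 seeded worlds (500 events each) plus 10 null worlds; expression
null calibration uses 200 replicates at 200 transcripts per class.
Projection is verified exactly against a per-base oracle on 1000 random
intervals over 100 random blocks, half of them strand-reversed.

# Limitations

* Projection assumes the block table is internally consistent; it does
  not detect conflicting segments.
* The conservation class names follow the seven-species design; for
  panels of other sizes the boundary classes keep their meaning
  (all-but-one, all), with `TWO_WAY` taking precedence for tiny panels.
* The binomial enrichment model treats events as exchangeable; clustered
  binding (e.g. tandem arrays) inflates `k` relative to the randomized
  background and is not corrected for.
* The normal fit behind word selection is a convenience null; heavy
  upper tails in real normWord distributions would make the implied
  cutoff anti-conservative, which is why the implied cutoff is reported
  alongside the selection.
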