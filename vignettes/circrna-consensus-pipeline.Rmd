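---
title: "Harmonizing six circRNA callers: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing six circRNA callers: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Circular RNAs (circRNAs) are covalently closed transcripts produced by
back-splicing: a downstream splice donor joins an upstream splice
acceptor, so reads spanning the back-splice junction identify the circle
by a pair of genomic coordinates. Because no single detection algorithm
is reliable on its own — the tools differ in aligners, annotation use,
junction-overlap requirements, and filtering — a common strategy for
building a high-confidence catalog from biofluid RNA-seq is to run
several callers and keep only junctions that all of them report.

`circbiofluid` implements that strategy as a reusable, testable pipeline
for six callers (CIRCexplorer, CIRI2, DCC, find_circ, KNIFE, MapSplice):
parsing each tool's native output, reconciling coordinate conventions,
applying detection filters, intersecting the per-tool catalogs,
quantifying expression, annotating genomic features, and measuring
longitudinal stability. A ground-truthed synthetic generator emulates the
whole study design so every stage is verifiable without controlled-access
data.

## Coordinate harmonization

CIRCexplorer, KNIFE and find_circ report 0-based coordinates; CIRI2,
MapSplice and DCC report 1-based inclusive coordinates. Everything is
converted on read-in to a single 0-based, half-open (BED-style)
convention: `start0` is the back-splice acceptor base, `end0` the
half-open end (the 1-based index of the donor base). A 1-based inclusive
pair `[s, e]` becomes `(s - 1, e)`. Half-open was chosen so that junction
keys align with BED output and interval arithmetic; the conversion is a
bijection, which the tests verify by round-trip.

Three details worth calling out:

* **Donor-first records.** MapSplice reports circular junctions with the
  donor coordinate first; readers reorder the two coordinates numerically
  before basis conversion.
* **Degenerate circles.** A circle narrower than 2 bp (donor base equal
  to acceptor base) is biologically meaningless and rejected; inside a
  file reader the record is skipped with a warning, and a file whose rows
  are mostly malformed aborts as a wrong-dialect signal.
* **Strand.** Junction matching is strand-blind by default
  (`strand_aware = FALSE` in `filter_config()`): find_circ infers strand
  without annotation and the callers disagree often enough that a
  strand-aware intersection would punish disagreement about an attribute
  the catalog does not need. The flag exists for sensitivity analyses.
  Chromosome names are normalized to the `chr`-prefixed dialect.

## Detection filters and the consensus catalog

Two filters are applied per tool, within each biofluid independently
(per-biofluid totals are what the per-tool summaries report):

1. a junction counts as *detected in a sample* when the tool reports it
   there with at least `min_reads = 2` back-spliced reads;
2. a junction is *retained for a tool* when detected in at least
   `min_samples = 5` samples of the biofluid.

The consensus catalog is the strict intersection of the six retained
sets. The intersection-pattern table uses exclusive (UpSet) semantics:
each junction of the union is counted once under its exact
tool-membership pattern, so pattern sizes sum to the union. A relaxed
`min_tools` variant exists but is not the default; the catalog definition
is the six-tool intersection.

The 18 nt minimum junction overlap that the callers were run with
upstream is carried as provenance metadata in `filter_config()`; it is a
caller parameter, not recomputable from their outputs.

**Prevalence tiers.** "Detected in X% of samples" is read as *at least*
`ceiling(X * n)` samples. Because the source analysis does not say
whether per-sample detection for these tiers required one tool or all
six, both rules are implemented (`combined_detection(mode = "any")` /
`"all"`); `"any"` is the default, as it is the only rule under which
near-total tiers at the 10% threshold are plausible.

**Expression pre-filters.** Before expression modelling, samples
detecting fewer than 300 junctions are dropped, then junctions detected
in under 50% of the remaining samples (a junction in exactly half the
samples survives). The 300 default matches the original cohort's scale;
on the synthetic study's 300-junction catalog the analysis drivers pass
`min_circ = 150`, a deliberate rescaling of the same rule.

## Quantification

Two complementary measures per junction per sample:

* **JRPM** (junction reads per million):
  `count / total_junction_reads * 1e6`, where the denominator is the
  sample's total junction reads — canonical linear plus chimeric — taken
  from an explicit per-sample totals table rather than re-derived, so the
  denominator is visible and testable.
* **CLR** (circular-to-linear ratio): `count / max(linear5, linear3)`,
  where `linear5`/`linear3` are the uniquely-mapping linear splice reads
  at the circle's acceptor and donor splice sites. When neither flank has
  linear reads the denominator is a pseudocount of 1, so
  `clr(count, 0, 0) = count`.

Flank matching is exact arithmetic on the shared splice site: a linear
intron ending at `start0` shares the acceptor (5' flank); one starting at
`end0 + 1` shares the donor (3' flank). Multiple linear junctions at one
splice site (alternative partners) are **summed**, since reads — not
junctions — are being counted; a nearest-single-junction alternative was
considered and rejected for that reason. Only the unique-read column of
the splice-junction tables contributes; multi-mapper counts are too
unreliable for quantification.

The consensus count matrix takes, per junction and sample, the **maximum
across the tools** reporting it. When the tools agree (as in the
noise-free synthetic case) this equals the shared value; under dropout it
avoids a single silent tool dragging a junction to zero. The per-sample
CLR>1 fraction is averaged over expressed junctions (count > 0) within
each sample, then across samples.

## Genomic-feature annotation

Genes are assigned by at least 1 bp of interval overlap between the
junction and a BED12 transcript (the default behaviour of standard
interval intersection). Each junction gets exactly one primary class:

| class | rule |
|---|---|
| `multi_exon_spanning_intron` | both boundaries in exons, ≥ 2 exons intersected |
| `single_exon` | both boundaries inside one exon |
| `intronic` | contained in a transcript but touching no exon |
| `boundary_outside_exon` | a gene overlaps, but a boundary falls in no exon |
| `intergenic` | no overlapping transcript |

plus optional 5'/3' UTR flags when the junction intersects exonic
sequence outside the CDS (oriented by transcript strand; transcripts with
a zero-width thick region get no UTR flags). When several transcripts
overlap, the chosen one prefers (1) both boundaries in exons, then
(2) the most exons intersected, then (3) the lexicographically smallest
name — an invented, deterministic tie-break, since the source analysis
does not state how multi-isoform overlaps were resolved. The exact
published per-class counts depend on a specific RefSeq snapshot and are
not a reproduction target.

## Longitudinal stability and cross-checks

For participants sampled at least `min_visits = 5` times in a biofluid,
the per-junction coefficient of variation (sample standard deviation over
mean; junctions with zero mean in a scope are excluded from that scope)
of JRPM is computed across that participant's samples, and across all
samples of the biofluid. Pooled within-participant CVs are compared to
the global CVs with a **two-sided Mann–Whitney rank-sum test** — the
comparison test is not named in the source analysis, and a
distribution-free test matches the presentation; per-participant tests
against the global distribution are also produced since either pooling
could have been meant. Sample (n−1) standard deviation is used; the
population alternative is not.

Inter-tool agreement is summarized as the Pearson correlation between
per-tool mean-JRPM profiles over the union of retained junctions,
zero-filled where a tool did not retain a junction; a flag switches to
flattened junction-by-sample vectors. Zero-variance profiles yield `NA`
for their pairs rather than an error.

Cross-platform rank concordance consumes the bundled table of mean
qRT-PCR Ct and mean JRPM values for the most highly expressed circRNA per
biofluid: Ct ranks ascend (lowest Ct is rank 1), JRPM ranks descend,
missing Ct values rank last in order of appearance, and Spearman's rho is
computed over complete pairs (equal, by construction, to the Pearson
correlation of the rank vectors — the tests use that identity as an
oracle).

## The synthetic study generator

`simulate_truth()` builds the entire study from a seed: synthetic
single-isoform BED12 transcripts tiled over four chromosomes; a truth
catalog planted at feature-true positions (class proportions roughly
matching a biofluid catalog: ~70% multi-exon, a few percent single-exon,
the rest split among intronic, boundary and intergenic); per-biofluid
log-normal base abundance on the JRPM scale; participant-specific
log-normal expression offsets; negative-binomial counts; linear flank
support; and each tool's observed calls with per-tool dropout and false
positives. Defaults and rationale:

* **Cohort**: 12 participants, 4 sampled 6 times (the longitudinal
  subset), the rest twice, in both biofluids (80 samples) — a scaled-down
  longitudinal design that still leaves a clear within- vs
  between-participant contrast. 300 truth junctions per biofluid, with
  85% of the urine catalog shared with plasma.
* **Library sizes** 2–8 × 10⁵ total junction reads; the totals table
  decomposes each sample's total into chimeric (the summed back-splice
  counts) and canonical reads, so JRPM closed forms are exact.
* **Abundance** log-normal (meanlog `log(15)`, sdlog 1) **floored at
  8 JRPM**: the floor guarantees that, with noise off, every planted
  junction passes the 2-read/5-sample filters, making "consensus equals
  truth" a sharp assertion; the spread above the floor produces a
  realistic prevalence-tier decline.
* **Counts** negative-binomial (size 8) rather than Poisson — biofluid
  RNA-seq is overdispersed, and without overdispersion the CV analysis
  degenerates.
* **Participant effect** sd 0.5 on the log scale: large enough that
  global CVs visibly exceed within-participant CVs, small enough not to
  dwarf the count noise.
* **Dropout** differs by tool (2–12%), echoing the real observation that
  some callers are far more conservative than others; **false positives**
  are drawn per tool from **disjoint decoy-locus pools** (rate 2% per
  locus per sample by default), so the strict six-tool intersection
  provably suppresses them — precisely the property that motivates
  multi-tool consensus. A `shared_fp_pool` switch exists for sensitivity
  work. Decoy linear junctions that flank no circle are added to the
  splice tables so flank matching is tested against distractors.
* **Geometry uniqueness**: acceptor and donor positions are unique across
  all planted and decoy loci, so each flanking linear junction matches
  exactly one circle and closed-form CLR values are exact.

What the generator does **not** emulate: read-level artifacts (no FASTQ,
no aligner behaviour), shared systematic errors between tools,
correlated dropout, multi-isoform transcripts, fragmented/3'-biased
extracellular RNA, or sequence content. Passing tests therefore
demonstrate the correctness of the harmonization, filtering and
statistics — not that any particular caller is accurate on real reads.

## Problem sizes and numerical choices

The bundled analyses and tests run the default 80-sample, 300-junction
study (seconds per simulation, ~half a minute for a full file-based
pipeline pass); repeated-seed properties (false-positive suppression
across 20 seeds, stability across 40 seeds) work from the in-memory
manifest, which is the same code path minus file serialization. Tie-break
and degenerate-input rules: prevalence thresholds use the ceiling;
detection at exactly `min_reads` counts; a junction in exactly half the
samples survives the prevalence pre-filter; constant expression yields a
degenerate (reported, not failing) stability test; an empty urine catalog
makes the overlap fraction `NA`; correlation against a zero-variance
profile is `NA`.

## Known limitations

* The consensus is exact-coordinate; near-miss junctions (±1–2 nt, as
  some callers produce around ambiguous breakpoints) are distinct keys.
  Fuzzy matching is deliberately out of scope.
* Quantification is junction-level; circRNA length and isoform structure
  are unknown from a junction, so no length normalization is attempted.
* The annotation taxonomy covers single-isoform geometry well; with rich
  multi-isoform annotation the transcript-choice tie-break becomes
  consequential and should be treated as one defensible convention among
  several.
* DCC's multi-sample `CircRNACount` and single-sample two-column layouts
  are both supported, but caller versions with renamed columns are not.
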