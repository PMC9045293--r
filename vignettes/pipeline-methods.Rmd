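---
title: "Methods: 16S Sanger identification pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 16S Sanger identification pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sanger16S)
```

This vignette documents the models, parameter choices and numerical
conventions behind `sanger16S`, in the spirit of a methods section: what
each stage computes, which knobs matter, where the design was genuinely
open and which way we went, and what the synthetic benchmark does and
does not demonstrate.

## The identification problem

Partial 16S rRNA sequencing (the first ~500 bp, variable regions V1–V3)
resolves most clinically relevant bacteria to genus level and many to
species level. The raw material is a pair of Sanger chromatograms per
isolate — forward and reverse reads with per-base Phred quality values
(QV = −10·log10 of the basecall error probability). The pipeline's job is
to (i) discard the unreliable read ends, (ii) combine the two reads into
one query sequence, (iii) measure how that query relates to a curated
reference database, and (iv) translate those measurements into a
defensible reported identification. The interpretive thresholds follow
CLSI-style guidance for sequence-based identification.

## Chromatogram IO

ABIF (`.ab1`) is a tagged binary container. `readABIF()`/`writeABIF()`
implement only the tags this pipeline consumes — basecalls (`PBAS`),
per-base QVs (`PCON`), peak locations (`PLOC`), the four processed trace
channels (`DATA` 9–12) and their channel order (`FWO_`), and the sample
name (`SMPL`) — and ignore everything else. Two assumptions are worth
stating. First, read direction is not recorded in ABIF, so it must come
from a manifest; guessing it from file names is deliberately not
attempted. Second, per-base qualities are taken from the common `PCON`
tag (basecaller variant 2, falling back to 1); files without it are
rejected because every downstream stage needs QVs. Written files
round-trip through the package's own reader and are also readable by
independent ABIF parsers (this is exercised in the test suite against
Biopython).

## Quality trimming

Two profiles are implemented, reflecting the two ways such data are
processed in practice.

**Automated profile.** The retained region is the *longest contiguous
window in which every full-size sliding sub-window has mean QV at or
above the cutoff* (defaults: cutoff 40, window 10 bp). Candidate regions
shorter than one window — including whole reads shorter than the window —
are judged by the mean over their available bases. A read passes if the
retained region reaches the minimum clear length (20 bp) and its mean QV
strictly exceeds 30. This longest-window formulation was chosen over
re-tracing any particular vendor tool's internal scan because it is a
complete specification: for every read there is exactly one answer
(ties on length break to the earliest start), and an exhaustive search
over all (start, end) pairs can verify it — the test suite does exactly
that on a thousand random reads per run.

**Manual profile.** Mimics interactive review software: the longest
window in which the fraction of bases with QV ≤ 30 stays *strictly below*
15 % and the fraction of undetermined (non-ACGT) bases stays at or below
10 %; a passing window additionally needs ≥ 50 bp clear length and at
most 20 mixed basecalls. The low-quality rule is stated in such software
as "<15 % of bp with a QV of >30", which is ambiguous as printed; we read
it as "at most 15 % of retained bases may be low-quality (QV ≤ 30)",
which is the only reading under which the parameter behaves as a trimming
cutoff. This interpretation is a documented choice, not a reverse
engineering of any vendor algorithm.

**Mixed-base calling** runs before trimming, so ambiguity codes count
toward the mixed-base cap: at each basecall peak, if the second-highest
trace channel reaches at least 0.33 of the highest, the call becomes the
two-channel IUPAC code. Reads without traces pass through unchanged.

## Consensus building

The reverse read is reverse-complemented and aligned to the forward read
with a free-end-gap (semiglobal) alignment (Biostrings'
`pairwiseAlignment`, type `"overlap"`, same scoring as the search
aligner). Per aligned column:

* both reads agree → keep the base with the **maximum** of the two QVs;
* reads disagree and the QV difference is ≥ 10 → keep the higher-QV
  base at its own QV;
* reads disagree with similar QVs → keep the IUPAC ambiguity code of the
  pair at the **minimum** QV, preserving the evidence of conflict;
* columns covered by one read only take that read's base.

The conflict policy is a design choice (chromatogram-viewer tools do not
publish theirs): the QV-gap rule uses base-level evidence where it is
decisive and refuses to guess where it is not. A merge is accepted only
if the aligned overlap spans ≥ 20 columns at ≥ 80 % identity; otherwise
the reads "do not form a contig" and the pipeline automatically falls
back to the single read with the better trimmed mean QV. Samples where
only one direction passes QC proceed single-read as a matter of course,
with the reverse read re-oriented to forward.

The consensus length then sets the QC category: > 440 bp (full
reporting), 400–440 bp inclusive (genus-capped), < 400 bp (excluded from
search). Both boundary conventions are taken literally from the
interpretive table the thresholds come from; 400 and 440 themselves fall
in the middle band.

## Reference search and metrics

The search aligns the query against *every* database record — at the
scale of a curated 16S set (hundreds to a few thousand records of
~0.5–1.5 kb) exhaustive alignment is cheap and removes heuristic-seeding
nondeterminism. The aligner is an affine-gap Smith–Waterman (Gotoh)
implemented in C++ with defaults match +1, mismatch −2, gap open 5,
gap extend 2 (a gap of length L costs 5 + 2L), chosen to approximate
nucleotide-BLAST behaviour; letters match only on exact equality, so
ambiguity codes count as mismatches, which keeps identity a conservative
measure. Reported metrics mirror BLAST tabular output at its printed
precision: percent identity = matches / alignment columns, rounded half
up to one decimal; query cover = aligned query span / full trimmed query
length, rounded half up to the nearest integer; aligned length =
alignment columns.

Everything about the alignment is deterministic, including ties: the
traceback prefers diagonal over gap moves, prefers opening a gap over
extending on equal score, and starts from the best cell with the
smallest query (then subject) index. These conventions are part of the
function's contract and are verified against an independent
dynamic-programming implementation in the tests. One subtlety follows
from tie-breaking: for *unrelated* sequences several distinct optimal
alignments may exist, so only the score is strand-symmetric; for
homologous pairs — the regime the pipeline operates in — the optimum is
unique and identity and span are strand-symmetric too.

**Distance to next species** is the gap in percentage points between the
best identity of the top species and the best identity among hits of any
other species; it is `NA` when the table contains no other species.
The "top species" is the species achieving the highest identity in the
table (ties resolved by hit rank), which makes the distance non-negative
by construction. Hits sharing a species-group label (e.g. a "mitis
group") count as one species, so closely related group members do not
collapse the distance to zero. The guidance this statistic derives from
does not define it operationally; this top-identity-difference
definition reproduces the worked examples bundled with the package and
is stated here as the package's operational definition. Note the
distance is computed within the retained hit table (default top 50), a
documented bound.

External BLAST runs can be substituted for the internal aligner via
`parseBlastTabular()` (outfmt-6 columns plus the query length); the
decision stage is agnostic to the hit source.

## The decision algorithm

`classify()` is a total function of four metrics. For aligned length
> 440 bp: species needs distance ≥ 0.8, identity ≥ 99 and cover ≥ 98;
genus needs cover ≥ 98 with identity in [97, 99), or identity ≥ 99 with
distance < 0.8; cover < 98 or identity < 97 is inconclusive. For
400–440 bp, the call is capped at genus (cover ≥ 98, identity ≥ 99);
below 400 bp the sequence is too short. Three conventions deserve
mention:

* the identity band for uncapped genus calls is half-open, [97, 99), so
  no metric point satisfies two columns of the table at once;
* an `NA` distance (no second species in the table) caps the call at
  genus rather than erroring — a species-level claim requires a
  *measurable* separation;
* `qcReasons` always lists every criterion that failed or capped the
  call, so a report row is self-justifying.

Genus-level calls are reported as "Genus sp." (or the species-group
label when one is attached) with the comment "most closely related to
*Genus species*". Concordance against a reference identification is
assessed at genus level; inconclusive and excluded results are omitted
from agreement calculations rather than counted discordant. References
above genus rank (e.g. a bare family name) are compared literally at
their stated rank, since a genus-level rule cannot apply to them.

## The simulator and what the benchmark shows

`simConfig()` defaults define the benchmark conditions: 3 genera × 3
species, 520-bp templates (the scale of a first-500-bp 16S amplicon),
~10 % divergence between genera and ~3 % within (about the separation at
which the 97/99 % identity thresholds are meaningful), reads covering the
full template with 25-base linear quality ramps from QV 10 to a QV 55
plateau, and a 0.5 % per-base miscall rate in the plateau (ramp bases
err at their Phred-implied rate, 10^(−QV/10)). Divergence is
substitution-only: with identity-threshold decisions, indels mainly
stress the aligner, which is exercised separately by the
dynamic-programming equivalence tests. Realized pairwise divergences are
checked to lie within ±20 % of the configured rates and redrawn
otherwise, so a benchmark database cannot accidentally sit on a decision
boundary. Traces, when requested, are Gaussian peaks on a
12-points-per-base raster with injectable secondary peaks for the
0.33-ratio rule.

`endToEndBenchmark()` (100 samples by default; the acceptance script
uses exactly that, plus a 20-sample noise-free run and 50 consensus
templates — sizes chosen to give stable fractions at interactive run
times) simulates pairs from randomly chosen species, runs the full
pipeline and scores genus- and species-level recovery against the truth.
Under the default conditions genus recovery is essentially complete and
a majority of samples meet the full species criteria; the remainder are
correct genus-level calls, usually because two plateau miscalls on
opposite reads leave an ambiguity code that costs ~0.2 % identity.

What passing this benchmark does *not* show: real chromatograms have
correlated error structure (dye blobs, compressions, mobility shifts),
mixed templates, and reference databases with uneven taxon coverage and
misannotations; none of these are modelled. The benchmark validates the
*logic* of the pipeline — trimming, merging, metric computation and
decision rules — not the sequencing error model of any instrument.

## Degenerate inputs and numerical conventions

* Empty or hopeless reads trim to an empty window (`start 1, end 0`) and
  fail QC with a reason; nothing errors on a per-sample basis.
* Rounding of reported percentages is half-up (not banker's), matching
  how such values are conventionally printed; comparisons against
  thresholds happen *after* rounding, again matching how printed values
  are interpreted.
* Hit tables sort by score, then identity, then accession — fully
  deterministic, including duplicate records.
* All simulation randomness flows from a single integer seed; fixed seed
  means byte-identical FASTA, chromatogram and report outputs.
* Batch runs treat per-sample failures as data (an `excluded` row with
  the error message), reserving non-zero exits for configuration errors.

## Known limitations

* The ABIF support is minimal by design: no raw traces, mobility or
  dye-set tags, no `.scf`/`.fastq` variants, no re-basecalling.
* The exhaustive aligner is meant for curated databases at desk scale;
  searching a nucleotide-collection-sized database needs an external
  BLAST run ingested through `parseBlastTabular()`.
* E-value statistics are intentionally absent — ranking and thresholds
  here use identity, cover and alignment length only.
* The distance statistic is only as good as the taxonomy of the hit
  table: unlabelled near-identical species (or missing group labels)
  inflate it, and sparse databases return `NA`.
* When the aligned query length sits exactly at 400–440 bp, the genus
  cap applies even if every species-level criterion is met; such rows
  are flagged so a reviewer can weigh the boundary case.
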