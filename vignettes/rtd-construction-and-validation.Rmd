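---
title: "Methods: RTD construction and splicing-ratio validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RTD construction and splicing-ratio validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtdkit)
library(dplyr)
```

## The problem

Alignment-free transcript quantifiers (Salmon, Sailfish, kallisto) are only as
good as the reference transcript dataset (RTD) they quantify against. Genome
annotations assembled from multiple sources — a curated reference annotation
plus transcripts discovered from RNA-seq — are redundant: the same isoform
appears several times with different untranslated-region (UTR) extents, and
low-coverage assemblies contribute truncated transcript fragments. Redundancy
spreads read support across duplicate entries and corrupts downstream
abundance estimates, so the duplicates have to be removed before
quantification, and the removal has to be auditable.

`rtdkit` implements the two halves of that workflow:

1. **Construction** — merge two annotation sources into one nonredundant RTD
   via gene-span reconciliation and intron-chain comparison, recording every
   removal in a decision ledger.
2. **Validation** — compute event-level splicing ratios from transcript
   abundances (TPM) and independently from RT-PCR peak areas, and correlate
   the two measurements across replicates.

All data structures are plain tibbles (one row per exon, one row per ratio
record), so every intermediate is inspectable with ordinary dplyr verbs.

## The data model

An annotation is a tibble with one row per exon and columns `chrom`, `start`,
`end`, `strand`, `gene_id`, `transcript_id`, `source`. Coordinates are
1-based inclusive on both ends, the GFF3 convention, and the same convention
is used everywhere — files, types, and printed output. Introns are derived,
never stored: intron *i* runs from `exon_i.end + 1` to `exon_{i+1}.start − 1`.
The ordered intron coordinate list (the *intron chain*) is the identity of a
spliced transcript: two transcripts of a gene with the same chain differ only
in UTR length.

```{r chain}
ann <- as_annotation(data.frame(
  chrom = "chr1", start = c(1, 201, 401), end = c(100, 300, 500),
  strand = "+", gene_id = "g1", transcript_id = "t1"
))
intron_chain(ann)
```

## Construction

`build_rtd(ref, alt, curated)` runs four fixed stages. The order matters and
is part of the contract: span reconciliation first, then the chain collapse,
then mono-exon collapse, then fragment removal; curated transcripts are
merged last and re-checked.

**1. Gene-span reconciliation** (`pair_genes()`, `resolve_spans()`,
`apply_resolutions()`). Genes are paired by shared `gene_id`. Where one
source's span contains the other's, the larger span is kept regardless of
which source holds it; where spans overlap partially, the reference source's
span wins; genes unique to one source pass through; disjoint same-id spans
keep the reference span with a warning (they usually indicate an upstream
annotation error, and deleting nothing keeps the step auditable). Transcripts
from both sources all survive into deduplication — reconciliation only
settles coordinates. Identifier collisions across sources are resolved
structurally: identical exon structure collapses to a single copy, different
structure suffixes both copies with their source label.

**2. Same-chain collapse** (`collapse_identical_chains()`). Among transcripts
of a gene sharing a nonempty intron chain, only the one with maximal spliced
length (sum of exon lengths) survives. Spliced length, not genomic span, is
the yardstick because identical chains imply identical internal structure —
any length difference is UTR sequence. Ties prefer a protected (curated)
transcript, then a reference-source transcript, then the lexicographically
smallest id, making builds reproducible.

**3. Mono-exon collapse** (`collapse_monoexon()`). Mono-exon transcripts have
an empty chain, so the chain rule cannot see them. Within a gene, mono-exon
transcripts that mutually overlap on the same strand (transitively — overlap
clusters) are UTR variants of one another; the longest per cluster survives.
Non-overlapping mono-exon transcripts are genuinely distinct and all kept.

**4. Fragment removal** (`remove_fragments()`, predicate `is_fragment()`).
A fragment is an incomplete model from low read coverage. The predicate is
deliberately three-sided: `short` is a fragment of `long` iff

- (a) `short`'s span is contained in `long`'s span with at least one end
  strictly inside,
- (b) every intron of `short` occurs in `long`'s chain, and
- (c) every intron of `long` lying strictly within `short`'s span occurs in
  `short`'s chain.

Condition (c) is the load-bearing one: an intron-retention (IR) isoform looks
exactly like a fragment under (a) and (b) — contained span, subset chain —
but the retained intron of `long` sits inside its span and is absent from its
chain, so (c) rejects it. Without (c) the pipeline would strip out the
alternative-splicing isoforms an RTD exists to capture. Removal proceeds per
gene in descending spliced-length order and each candidate is tested against
already-retained transcripts only, so a removed fragment can never shield
another fragment.

**5. Curated merge** (`merge_curated()`). Curated transcripts are added,
marked protected, and the three rules re-run: a curated transcript can
displace an unprotected duplicate (even a longer one) but is never removed
itself. Id collisions with different structure are a hard error.

The result object carries the annotation, the complete decision ledger
(`tidy()`), and a one-row summary (`glance()`). Nonredundancy is a testable
postcondition: rebuilding from the output yields zero decisions.

## Validation by paired measurement

For an alternative-splicing event — a primer-pair region on a gene —
`assign_event_transcripts()` partitions the gene's overlapping transcripts by
comparing their intron structure *within the region*:

- the **fully spliced (FS)** local chain is the one with the most introns in
  the region; among ties, the least total intron length. The second criterion
  matters: an alternative 3′/5′ splice-site isoform can splice *more*
  nucleotides than the canonical form, so "most spliced" would misidentify it
  as FS. The canonical form is the one that removes all introns at the most
  conservative extent.
- **positive** transcripts differ from the FS chain by the event's own type:
  a missing FS intron with no overlapping intron is intron retention; an
  intron sharing one boundary with an FS intron is an alternative 5′/3′
  splice site (donor/acceptor identity is strand-aware); an intron spanning
  an entire FS exon is exon skipping.
- **other** transcripts differ in some other way, and transcripts not
  overlapping the region are excluded entirely.

Two ratio conventions are implemented. `of_total` is the event-positive share
of everything assigned to the event, `pos / (pos + fs + other)`; `as_vs_fs`
compares the event-positive transcripts with the fully spliced ones only,
`pos / (pos + fs)`, which is bounded in [0, 1] and therefore robust to small
FS denominators; the unbounded quotient `pos / fs` is available behind
`raw_quotient = TRUE` for sensitivity analysis. Zero denominators produce
invalid records (`valid = FALSE`), not errors, and invalid records drop out
pairwise before correlation. The same formulas apply to RT-PCR peak areas
(`pcr_ratios()`), with products labelled by the class they represent.
`aggregate_replicates()` reports mean and sample standard deviation (n − 1)
per event/time point; `correlate_ratios()` computes Pearson and Spearman
(average ranks on ties) over individual replicate points.

## The synthetic study generator

Real construction inputs are genome-scale and the wet-lab side of the
validation cannot be regenerated, so the package ships a generator whose
ground truth is known by construction. `fixture_spec()` describes a study;
everything downstream is a pure function of it (same spec, byte-identical
output — the generator seeds its own private streams and never touches the
global RNG state).

Per gene, the generator lays out a mono-exon (probability `p_mono = 0.2`) or
spliced (2–6 exons of 80–300 bp, introns of 60–200 bp) base transcript, adds
genuine IR and alternative-splice-site isoforms with probabilities
`p_ir`/`p_alt` (the Alt isoform grows an intron into its flanking exon by
6–12 nt, the shape of a shifted acceptor site), then injects redundancy at
the spec's per-rule rates: UTR-trimmed chain duplicates, shorter overlapping
mono-exon copies, and truncated fragments built from a contiguous exon
sub-window with trimmed ends, so each injected transcript provably triggers
exactly one rule. Gene-model conflicts are realized through source placement:
a "contained" gene puts its truth isoforms in the reference source and its
injected variants in the discovery source; a "partial overlap" gene staggers
one isoform's span across the sources. Fragment injection and the IR/Alt
isoforms are mutually exclusive within a gene so that every ledger entry has
a deterministic surviving partner.

What the generator emulates: the redundancy classes the pipeline removes, the
two-source structure, the replicate design (3 biological replicates × 2 time
points by default), and the coupling between the two measurement methods —
peak areas are the true class abundances times multiplicative log-normal
noise of scale `noise_sd`. What it does not emulate: read-level sequencing
(no FASTQ, no coverage model), splice-site sequence motifs, expression
correlation between isoforms of a gene, or quantifier estimation error beyond
the log-normal replicate noise.

Numerical choices: abundances are log-normal (`meanlog = log 30`,
`sdlog = 1`) with per-time-point fold changes (`sdlog = 0.4`) and replicate
noise (`sdlog = 0.1`), then TPM-normalized per sample; `noise_sd = 0.15`
makes the default method correlation land around 0.98–0.99 — high but
visibly imperfect, so tests can distinguish "agrees exactly" from "agrees
approximately". At `noise_sd = 0` the two methods agree to machine precision,
which is the anchor for exact-recovery tests.

## Verification

The test suite asserts, among others:

- ground-truth recovery: across redundancy rates {0, 0.5, 1} and ten seeds at
  200 genes, `build_rtd()` reproduces the truth annotation exactly and its
  ledger matches the injected-redundancy ledger row for row;
- idempotence: rebuilding a built RTD fires no rule, on 100 generated sets;
- oracle equivalence: each dedup rule's survivor set equals an exhaustive
  brute-force evaluation of its predicate over all transcript pairs;
- IR safety: with fragment injection at rate 1 and IR isoforms everywhere,
  zero IR isoforms are removed;
- zero-noise agreement: Pearson and Spearman equal 1 within 1e-12 over a
  300-point design (50 events × 3 replicates × 2 time points), and ratios are
  invariant under positive per-sample rescaling.

The problem sizes above (gene counts, seed counts, event counts) are this
package's own test-design choices, sized to run in seconds on one CPU while
still exercising every code path.

## Limitations

- Genes are paired across sources by shared `gene_id` only; there is no
  positional matching, fusion/fission detection, or transcript re-assignment.
- The fragment predicate is a formalization of an informal curation rule;
  condition (a) requires only one strictly-inside end, which is the more
  conservative reading (fewer removals) of the containment requirement.
- Event classification assumes the FS isoform is present among the
  overlapping transcripts of the region; a region where every isoform carries
  the event would make the least-spliced variant the FS baseline.
- The AS-frequency denominator counts genes with at least one intron in any
  transcript; other definitions (e.g. CDS introns only) would shift the
  percentage.
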