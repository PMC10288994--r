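---
title: "Consensus fusion calling: merging, voting, filtering and benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus fusion calling: merging, voting, filtering and benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusemble)
library(dplyr)
```

## The problem

RNA-seq is now a routine way to find gene fusions in acute leukemia, but no
single fusion caller is a gold standard: each one misses real driver
rearrangements that another one finds, and each reports hundreds to
thousands of artifacts (library chimeras, mapping errors, read-through
transcription). fusemble implements the post-calling half of an ensemble
workflow: it consumes the native output files of five callers — Arriba,
CICERO, deFuse, FusionCatcher and STAR-Fusion — and turns them into one
auditable candidate list. Running the callers themselves (and the upstream
STAR alignment) is out of scope; the package starts where their output
files end.

The pipeline has four stages, each a plain function over tibbles:

1. **Standardize** (`parse_arriba()` … `parse_cicero()`, `parse_cohort()`):
   each caller's dialect becomes one call table with both breakpoints,
   split/spanning read support, the caller's confidence label and reading
   frame. Parsers are total — no row is dropped or filtered at parse time —
   so downstream thresholds remain configurable.
2. **Merge** (`harmonize_calls()`): calls that name the same canonical
   ordered gene pair in the same sample become one `FusionEvent` carrying
   all supporting calls as evidence.
3. **Vote** (`consensus_select()`): keep events reported by at least *k* of
   the 5 callers.
4. **Filter and audit** (`run_filter_cascade()`): remove artifact classes
   with machine-readable reasons, so the surviving list plus the audit file
   replace a manual curation pass.

`benchmark_methods()` then scores any call set against a truth list of
rearrangements previously confirmed by orthogonal clinical assays
(karyotype, FISH, RT-qPCR, targeted panels).

## Merging semantics

**Why gene pairs, not breakpoints.** The five callers use different aligners
and coordinate conventions and rarely agree on the exact junction base, but
clinical interpretation happens at gene-pair granularity (a KMT2A::AFF1 is a
KMT2A::AFF1 whichever KMT2A intron is broken). The merge key is therefore
the canonical *ordered* (5′, 3′) symbol pair per sample. The breakpoint
tolerance (`bp_tolerance`, default 100 bp) is used only to decide which
same-pair calls describe the *same junction* when electing a representative
breakpoint for reporting; it never splits an event.

**Symbol canonicalization.** Callers emit different vocabularies (legacy
"MLL" versus "KMT2A"). A small alias table (bundled, user-extensible)
resolves aliases before merging; chains are closed at construction so lookup
is idempotent.

**Representative breakpoint.** Within an event, junctions are clustered at
`bp_tolerance`; the cluster reported by the most distinct callers wins, ties
broken by total read support, then lowest coordinate; within the winning
cluster the best-supported call provides the coordinates. Every rule is
deterministic, so merging is invariant under permutation of the input (a
property the test suite checks by brute force).

**Reciprocal orientation.** Whether A::B and B::A in one sample are one
event or two is genuinely open; translocations often produce both products.
The default keeps them distinct (fusion direction is biologically
meaningful), and `collapse_reciprocal = TRUE` folds them into the majority
orientation for users who count unordered pairs.

## Consensus voting

`consensus_select(events, k)` is a threshold on the caller-agreement count,
so the call sets nest by construction: the 5-of-5 set is contained in
4-of-5, which is contained in 3-of-5. Agreement is always counted out of
five callers; if a caller's file is missing the pipeline warns and
proceeds, leaving the denominator at 5 so that "3-of-5" keeps its meaning.

## The filter cascade

Filters run in a fixed order — cheap evidence checks first,
annotation-dependent checks later — and every event gets exactly one
verdict with reason codes:

| step | reason code | default | rationale |
|---|---|---|---|
| read evidence | `low_support` | split+spanning ≥ 3 per caller | one-read chimeras are overwhelmingly ligation artifacts |
| caller confidence | `low_confidence` | Arriba {high, medium}; CICERO {HQ}; deFuse probability ≥ 0.7 | each caller's own classifier is informative; unknown/absent labels pass |
| read-through | `read_through` | gap ≤ 1 Mb | same-strand neighbours transcribed through the intergenic gap are not rearrangements |
| reading frame | `out_of_frame` | on | out-of-frame products rarely drive disease; "unknown" passes |
| splice sites | `non_splice_breakpoint` | on | both breakpoints must be at exon boundaries or inside coding exons; intronic/intergenic junctions are mapping noise |
| blacklist | `blacklisted_gene` | bundled list | HLA cluster, housekeeping genes: recurrent artifact partners |
| promiscuity | `promiscuous_gene` | ≥ 2 partners per sample | one gene fused to many partners in one sample is an alignment hub |

The per-caller thresholds are package conventions for typical short-read
depth, exposed through `filter_config()` and YAML overrides — they are
deliberately conservative defaults, not authoritative values, and should be
tuned per cohort.

**Whitelist rescue.** An event with a partner on the leukemia whitelist is
never discarded by the structural steps (read-through, frame, splice-site,
blacklist, promiscuity); it is retained and tagged `whitelist_rescue` for
human review. This encodes the clinical stance that a known driver pair is
worth a look whatever the rearrangement's shape — STIL::TAL1 and
P2RY8::CRLF2, which arise from interstitial deletions and look exactly like
read-throughs, are the canonical examples. Read evidence is *not*
rescuable: a whitelisted pair with no supporting reads is still discarded.

**Order-dependence of promiscuity.** Partner counting runs over the events
that survived the earlier steps of the same sample, so a pile of
already-discarded artifacts cannot condemn an otherwise clean gene.

**Degenerate inputs.** Events whose partners are absent from the annotation
skip the annotation-dependent tests and carry an `unannotated_gene` warning
tag rather than being guessed at; empty call tables flow through every
stage as empty results.

## Accuracy metrics

With a truth set of previously confirmed fusions, a retained event is a
true positive iff its (sample, canonical pair) matches a truth entry; each
truth entry counts once however many events match it. Unmatched truth
entries are false negatives; unmatched retained events are false positives
(in a discovery setting they would instead be candidates for orthogonal
confirmation — the package keeps the benchmark definition).

$$\mathrm{Sensitivity} = 100\cdot\frac{TP}{TP+FN},\qquad
\mathrm{Precision} = 100\cdot\frac{TP}{TP+FP},\qquad
F_1 = \frac{2\,S\,P}{S+P}$$

Percentages are reported to one decimal and F1 on the 0–1 scale to two
decimals, rounding half away from zero (so 14/19 prints as 73.7).
FP counting happens at event granularity after filtering, i.e. on the
curated list. When several datasets are benchmarked, the pooled "global"
row sums TP/FP/FN across datasets, and its denominator is the sum of the
supplied truth sets — the package always derives it from the truth files
it is given.

## The cohort simulator

`generate_cohort()` writes everything the pipeline consumes — a toy
GRCh38-labelled GTF, a truth TSV and five caller-native files per sample —
from a declarative `cohort_spec()`. It emulates exactly the features the
pipeline reads: which caller reports which fusion, read support on either
side of the evidence thresholds, confidence labels, reading frames,
breakpoints at (or deliberately off) splice sites, read-through geometry,
blacklisted partners and promiscuous hubs, plus caller-private singleton
noise. It does **not** simulate reads, alignments, expression levels,
breakpoint uncertainty or caller-internal behaviour — so green tests say
the *integration logic* is right, not that any caller performs as modelled
on real libraries.

Two canned scenarios encode the benchmark cohorts the package is tested
against: a 14-cell-line cohort with a 19-entry truth set and a 15-patient
cohort with a 22-entry truth set. The published description of those
cohorts fixes the anchor facts directly: three cell-line fusions
(NKX2-5::BCL11B, TLX3::BCL11B, LMO1::TRD) undetected by every caller with
FusionCatcher detecting all other 16; STIL::TAL1 and P2RY8::CRLF2 found by
exactly three callers in the patient cohort. The full per-caller detection
matrix is not recoverable, so the remaining agreement counts, the surviving
false positives and the per-threshold artifact loads are reconstructions,
chosen once so that the end-to-end consensus funnels and metric totals
match the reported per-threshold values (cell lines 28/49/100 candidates
reducing to 14/16/20; patients 23/43/74 reducing to 12/18/23). Scenario
detection flags are deterministic 0/1 rather than sampled, so these checks
are exact and independent of the seed; generic cohorts use sampled
detection for the statistical property tests. One consequence of deriving
the pooled denominator from the truth files (19 + 22 = 41) is that global
sensitivities differ slightly from figures computed over a 40-entry
denominator.

Determinism is a hard guarantee: the same spec and seed produce
byte-identical files, and the annotation generator takes no randomness at
all.

## Problem sizes

The test suite and acceptance script run the two scenario cohorts (14–15
samples, ~19–22 truth fusions, ~50–80 planted artifacts, a few hundred
calls per cohort) plus property checks on 40-sample sampled cohorts and a
584-row parser fixture; the whole suite completes in about a minute and a
half on one core. These sizes were chosen to exercise every code path at
the same order of magnitude as a real diagnostic cohort while staying
instant to iterate on.

## Known limitations

* Gene-pair granularity cannot separate distinct junctions of the same
  pair (isoform-level reporting) — by design.
* ITDs and other intragenic events some callers report are not modelled.
* The read-through test uses gene-body adjacency only; it does not inspect
  transcript structure between the partners.
* Frame handling trusts the callers' annotations; the consensus label is
  optimistic ("in-frame" if any caller says so).
* The bundled whitelist/blacklist are starter lists for pediatric acute
  leukemia; other tumor types need their own.
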