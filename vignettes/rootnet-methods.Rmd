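---
title: "Methods: small RNA regulatory network construction in rootnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA regulatory network construction in rootnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Plant root compartments differ sharply in their small RNA (sRNA)
complements: the root tip (root cap plus division zone, a few hundred
micrometres of tissue) accumulates a different sRNA population than the root
as a whole.  Many of these species are unclassified — they are not annotated
miRNAs — yet the subset that loads into Argonaute 1 (AGO1) complexes is
competent to slice mRNA targets the way miRNAs do.  `rootnet` implements a
complete desk pipeline for turning multi-library sRNA sequencing counts,
degradome (PARE) libraries, a transcriptome, and zone-resolved expression
data into a validated bipartite sRNA–target regulatory network:

1. **RPM normalization and compartment enrichment.**  Counts are normalized
   to reads per million (RPM = raw count / library total × 10⁶).  A species
   is *compartment-enriched* when at least one library of the target
   compartment shows it at ≥ `min_rpm` (default 3 RPM) **and** at ≥ `fold`
   (default 3×) its level in *every* library of the other compartment.
2. **AGO1 enrichment.**  The same rule shape applied to AGO1
   immunoprecipitation libraries against a total-extract control, run over
   the compartment-filter survivors (serial wiring; standalone use is
   possible).
3. **Sequence profiling.**  5′ terminal composition and length
   distribution of any sRNA set, as percentages over distinct species.
   AGO1 loading leaves a recognizable footprint here (5′-U bias, ~21-nt
   mode versus the 24-nt bulk mode).
4. **Target scanning.**  Ungapped antiparallel complementarity scoring of
   every transcript window (details below).
5. **Degradome validation.**  Tag 5′ ends must fall opposite sRNA positions
   8–12 of a predicted site, be supported by ≥ 2 distinct tag sequences,
   and stand out on the transcript's target plot (t-plot).
6. **Contrary expression.**  Validated targets should be expressed higher
   where their repressing sRNA is lower.
7. **Network assembly.**  Distinct validated (sRNA, transcript) pairs become
   edges of a bipartite directed graph with canonical/category/contrary
   attributes, exported as SIF, GraphML and TSV.

## Coordinate and alphabet conventions

All sequences are held in the RNA alphabet; DNA input is converted (T→U) on
read.  Transcript coordinates are 1-based inclusive.  A binding site of an
L-nt sRNA covers transcript positions `start..end` with
`end − start + 1 = L`, and sRNA position `p` (counted from the sRNA 5′ end)
pairs with transcript position `end − p + 1` (the duplex is antiparallel).
The expected slicing position is opposite sRNA positions 10–11
("canonical"); evidence there is flagged.

## The complementarity scorer

The classical plant-target scoring convention is implemented directly:
per-position penalty 0 for a Watson–Crick pair, 0.5 for a G:U wobble, 1.0
for a mismatch, all penalties doubled over the sRNA core (positions 2–13
from the 5′ end), sites kept at total penalty ≤ 3.0.  Every constant is an
argument of `scan_targets()`.  The scan is ungapped: bulges are excluded so
that site coordinates feed the degradome window unambiguously.  The scanner
is compiled code with early termination; its contract is pinned by an
independent, position-vectorized R rescorer used in the test suite, which
re-enumerates every window exhaustively.

Published plant target finders differ in their exact internals (several are
web services whose defaults are not fully specified); the scheme above is
the package's own fully-specified choice of that family, which is why
absolute site counts from other tools are not comparable and are not used as
expectations anywhere.

## Degradome validation and automated t-plot categories

Tags are matched to transcripts exactly, full-length, forward strand
(`Biostrings` dictionary matching; a BLAST-style heuristic prefilter would
change nothing but speed at this scale).  Signals aggregate per
(transcript, 5′ position, library): RPM summed over tags, distinct tag
*sequences* counted.  "Distinct signatures with accordant 5′ ends" is read
as distinct tag sequences sharing a 5′ position — necessarily of different
lengths — not as read counts; signature support is evaluated per library,
and an interaction passes if **any** library supports it.

Manual t-plot inspection is replaced by a reproducible category computed on
the per-transcript, per-library signal profile:

| category | meaning |
|---|---|
| 0 | unique maximum on the transcript |
| 1 | equal to the maximum, shared with ≤ 2 other positions |
| 2 | above the median positive signal, not maximal |
| 3 | otherwise |

The default cutoff `max_category = 1` keeps only signals that dominate
their transcript — the signals a curator would call unambiguous.  The best
evidence per site maximizes signal RPM, with ties broken by lower category
and then lower window position.  `export_tplot_data()` emits the
per-position table behind any panel for plotting.

## Contrary expression

The zone design emulated is 8 root zones × 3 replicates.  The root-tip mean
pools the root-cap and division-zone samples (6 values); the whole-root
mean pools **all** samples, because the whole root anatomically contains
the tip.  The fold is oriented by the regulating sRNA's compartment
(whole/tip for a tip-enriched regulator and vice versa); a gene is
*contrary* at oriented fold ≥ `min_fold`.  The default `min_fold = 1.0`
means any contrary direction counts, mirroring the qualitative use of such
evidence; it is exposed because no principled universal threshold exists.
Genes absent from the matrix are marked missing and excluded from contrary
counts rather than erroring, since expression platforms rarely cover every
target.

## Boundary and tie conventions

* All threshold comparisons are inclusive (≥): 3 RPM passes `min_rpm = 3`,
  a penalty of exactly 3.0 is reported at `max_penalty = 3.0`.
* A fold requirement against a 0-RPM reference is satisfied by any level ≥
  `min_rpm` (3 × 0 = 0); absent species count as 0 RPM with no pseudocount.
* The `min_rpm` and fold conditions must hold in the *same* target library
  (the most literal conjunction of the two filter rules); the brute-force
  oracle in the tests pins this reading.
* Floating-point: penalties are half-integers, so the scanner's ≤ cutoff
  uses a 10⁻⁹ slack that can never change a decision; RPM sums are checked
  to 10⁻⁹ relative tolerance.
* Outputs are sorted lexicographically at every stage, so runs are
  byte-deterministic given identical inputs.

## The synthetic-data generator

`generate_synthetic_data()` emits a complete input set with planted truth.
Its defaults are the package's reference study conditions:

* 200 transcripts of 600–2,000 nt; 2,000 background sRNA species;
  40 + 40 species planted to pass the root-tip / whole-root filter, half of
  each AGO1-loaded (`ago1_loaded_fraction = 0.5`).
* Library design mirrors a realistic compartment experiment: 3 root-tip,
  2 whole-root, 3 AGO1, 1 control and 2 degradome libraries.
* Loaded species draw 5′ U with probability 0.55 and lengths with a 21-nt
  mode; unloaded and background species use a 24-nt mode, matching the
  loading footprint the profiling stage is meant to detect.
* Background species carry identical counts across tissue libraries, so
  their cross-compartment fold sits near 1 and they genuinely exercise the
  fold rule rather than the detection rule; a handful of planted species
  "leak" into the other compartment at trace counts to exercise the
  fold-versus-nonzero branch.
* 30 true interactions: each site is embedded by overwriting a transcript
  window with the sRNA's reverse complement (coordinates stay in range by
  construction), and each degradome library receives two distinct tags (20
  and 21 nt — two distinct sequences cannot share a 5′ end *and* a length)
  whose 5′ ends sit at the canonical position, with per-library signal RPM
  drawn from 20–200.  Background tags are real transcript substrings at
  1–5 RPM, so they map but stay below every planted signal.
* Degradome libraries carry an explicit total of 10⁶ reads (tabulated tags
  are a subset of a real library), so planted counts are RPM directly;
  tissue and AGO libraries use table-derived totals.
* Expression: 8 zones × 3 replicates.  True-target genes get an oriented
  zone-mean fold drawn from [2, 3]; all other genes are flat.  Cells carry
  multiplicative log-normal noise (σ = 0.15), small enough that a planted
  fold ≥ 2 is never read below 1.5 and a flat gene never above 2 — the
  recovery margins the tests assert.
* The generator **verifies its plantings against the package's own
  filters** before writing anything and stops on any discrepancy, so
  recovery tests measure the pipeline, not the construction.

What the generator does *not* emulate: sequencing error, adapter artefacts,
abundance-realistic count distributions, isoform families, paralogous
binding sites, or any real rice sequence content.  Passing recovery tests
therefore demonstrates the pipeline's internal correctness and calibration,
not field performance on real libraries, where signal-to-noise is far
worse and manual review of borderline t-plots remains advisable.

## Problem sizes and determinism

The shipped tests and the acceptance script run the reference conditions
above: ~2,080 sRNA species across 11 libraries, a 200-transcript
transcriptome, and 30 planted interactions — sizes chosen so a full
end-to-end run completes in seconds while every rule still has boundary
cases to hit.  All randomness flows from a single seed
(`synthetic_config(seed = …)`); the pipeline itself is deterministic, and
two runs from the same seed produce byte-identical files at every stage.

## Known limitations

* The scorer is ungapped; genuine bulged sites are missed by design
  (a config hook is reserved for a gapped mode).
* Multi-mapping degradome tags contribute fully to every transcript they
  match; no fractional weighting is applied.
* The AGO1 filter treats the control as a simple reference group; no
  statistical model of IP efficiency is attempted (the upstream rule set
  uses none).
* Expression evidence is correlative: contrary expression supports, but
  cannot by itself establish, a cleavage relationship.
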