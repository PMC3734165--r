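# rootnet

Small RNA (sRNA) mediated gene regulatory network construction for plant
root tissues.

Root compartments accumulate distinct sRNA populations, and the subset that
loads into Argonaute 1 (AGO1) can slice mRNA targets the way miRNAs do.
`rootnet` is for researchers who have multi-library sRNA read counts
(tissue compartments plus AGO1 immunoprecipitation), degradome/PARE
libraries, a transcriptome, and zone-resolved expression data, and want a
reproducible route from raw count tables to a validated bipartite
sRNA–target network.

## The method

Writing `c_s^L` for the raw count of species *s* in library *L* with total
`N_L`, the pipeline computes RPM `r_s^L = c_s^L / N_L × 10⁶` and applies two
serial filters with the same rule shape (defaults `min_rpm = 3`,
`fold = 3`):

> *s* passes against reference group *B* iff some target library *L* has
> `r_s^L ≥ min_rpm` and `r_s^L ≥ fold · r_s^M` for **every** `M ∈ B`.

First root tip vs whole root (and the reverse), then AGO1 IP vs control.
Survivors are scanned against every transcript window (ungapped,
antiparallel): penalty 0 per Watson–Crick pair, 0.5 per G:U wobble, 1 per
mismatch, doubled over sRNA positions 2–13, sites kept at penalty ≤ 3.
A site is validated when a degradome library shows a signal whose 5′ end
lies at transcript position `end − p + 1` for some `p ∈ 8..12` (p ∈ {10,11}
is canonical), supported by ≥ 2 distinct tag sequences, and prominent on
the transcript's t-plot (automated categories 0–3; default cutoff: the
signal is a transcript maximum).  Validated targets are checked for
contrary expression (oriented fold between the root-tip zone mean and the
whole-root mean), and distinct (sRNA, transcript) pairs become the edges of
a bipartite network exported as SIF/GraphML/TSV.

A synthetic-data generator plants ground truth (enriched species, embedded
binding sites, canonical cleavage tags, contrary genes) and verifies the
plantings against the package's own filters at emit time, so the whole
pipeline is testable end to end without external data.  See
`vignettes/rootnet-methods.Rmd` for the full model description and design
rationale.

## Worked example

```r
library(rootnet)

dir <- tempfile("rootnet-demo-")
gen <- generate_synthetic_data(synthetic_config(seed = 1),
                               file.path(dir, "data"))
summary <- run_pipeline(pipeline_config(file.path(dir, "data"),
                                        file.path(dir, "run")))
str(summary$counts)
#> List of 13
#>  $ sequences_profiled      : int 2080
#>  $ root_tip_enriched       : int 40
#>  $ whole_root_enriched     : int 40
#>  $ ago1_enriched_root_tip  : int 20
#>  $ ago1_enriched_whole_root: int 20
#>  $ predicted_sites         : int 30
#>  $ validated_interactions  : int 30
#>  $ validated_pairs         : int 30
#>  $ contrary_targets        : int 30
#>  $ network_srna_nodes      : int 20
#>  $ network_transcript_nodes: int 30
#>  $ network_gene_nodes      : int 30
#>  $ network_edges           : int 30
```

Reading the counts: of 2,080 sRNA species across the tissue libraries, 40
pass the root-tip filter and 40 the whole-root filter (exactly the planted
sets); 20 + 20 of them survive the AGO1 filter (the planted loaded halves).
Scanning those 40 sRNAs over 200 transcripts predicts 30 binding sites —
the 30 embedded ones — and all 30 are validated by canonical degradome
evidence, show contrary expression, and form a 20-regulator,
30-target network.  Stage outputs land in `file.path(dir, "run")`:
`enriched_*.tsv`, `ago1_enriched.tsv`, `profiles.tsv`, `sites.tsv`,
`interactions.tsv`, `contrasts.tsv`, `network.sif`, `network.graphml`,
`network_edges.tsv`, `summary.json`.

Individual stages are plain functions (`normalize_rpm()`,
`filter_compartment_enriched()`, `filter_ago1_enriched()`,
`profile_set()`, `scan_targets()`, `map_degradome()`, `validate_sites()`,
`contrast_expression()`, `build_network()`) and can be used on real data
read with `read_srna_library()`, `read_transcriptome()` and
`read_expression_matrix()`.

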