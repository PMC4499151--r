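# aptrace

Analysis of multi-round HTS-SELEX aptamer selections in R: from
multiplexed sequencing reads of selection-round pools to ranked,
specificity-annotated, mutationally profiled aptamer candidates — plus a
generative SELEX simulator that produces fully ground-truthed synthetic
campaigns for validating every stage.

## Who this is for

Groups running in-vitro selections of oligonucleotide aptamers (RNA or
DNA) against protein targets, who sequence the bound pool of every
selection round and of parallel reference pools (carrier control,
pH-adjusted control, species ortholog), and need to decide *which*
sequences to synthesise and test.

## What it computes

**Censuses and classification.** Reads are demultiplexed by barcode,
the random region is extracted between the constant flanks, and each
pool becomes a prevalence table. A sequence seen once in the whole
dataset is a *bystander*; the rest are *true aptamers*, *clustered* when
they belong to a PCR-mutagenesis family.

**Clustering.** Greedy founder-first clustering: processing sequences by
decreasing abundance, each founder absorbs every sequence within 3
edits (substitutions/insertions/deletions, Levenshtein). A
base-composition and 4-mer-profile prefilter makes this fast; both
stages are provable upper bounds on edit distance, so the result is
identical to brute force (and tested to be).

**Enrichment dynamics.** For a sequence with prevalence `n_r` in round
`r`, the enrichment rate is `n_(r+1) / n_r`. Enrichment predicts
affinity better than prevalence; the combined ranking (worse of the two
ranks) finds candidates strong on both axes. GC-binned mean enrichment
between an emulsion-PCR and an open-PCR arm quantifies amplification
bias, and diversity accounting counts the rare sequences each arm loses.

**Specificity.** Ten-fold pseudocounted prevalence-ratio rules against
reference pools: target-specific / shared / control-preferential
patterns, exclusion of electrostatic binders that light up on a
pH-adjusted control, and cross-species calls for sequences enriched
equally well (within 3-fold) by a target and its ortholog.

**Mutational landscape.** Within a cluster, the substitution rate is
`sigma = derivative copies / (founder copies × L)`. Each
single-substitution variant's copies are attributed to its position;
positions at ≥ 3× the uniform expectation `founder × sigma` are flagged
high (candidate affinity-improving mutations), ≤ 1/3× low (likely
structurally required positions).

**Simulator.** Langmuir binding (`T/(T+Kd)` + carrier + background),
per-cycle PCR with GC-dependent efficiency in open mode (calibrated so a
GC-0.2 sequence amplifies ~3× more than the emulsion arm over 25
cycles) and per-base mutagenesis, sequencing without replacement, and
multi-round campaigns with parallel arms, reference pools and planted
ground truth.

## Worked example

The package bundles the representative round-4/round-5 prevalences of
the major clusters from a published IL-10RA selection:

```r
library(aptrace)
tab  <- il10ra_example()
core <- tab[tab$category == "core", ]
data.frame(cluster = core$cluster_id,
           rate = round(enrichment_rate(core$r4, core$r5), 1))
#>    cluster rate
#> 1        B  4.1
#> 2        C  4.0
#> 3        D  0.3
#> 4        K  0.2
#> 5        G  0.4
#> 6        H  0.3
#> 7        J  1.6
#> 8        Z 30.4
#> 9       #3  4.6
#> 10     #25  4.2
```

Cluster B is the most prevalent sequence (421 606 copies at round 5) but
only enriches 4.1-fold; cluster Z enriches 30.4-fold from modest
prevalence. Ranking by prevalence puts B's core sequence (401) first,
ranking by enrichment puts Z's (436) first — the motivation for the
combined rule.

The cluster-J mutational landscape from the same table:

```r
j  <- tab[tab$cluster_id == "J" & tab$category %in% c("core", "variant"), ]
m  <- data.frame(sequence = j$sequence, is_founder = j$sequence_id == "411",
                 total = j$r5)
substitution_rate(m)
#> [1] 0.0005625099
pr <- position_profile(m)
pr$per_position[pr$per_position$total_copies > 0,
                c("position", "ref", "total_copies", "flag")]
#>    position ref total_copies   flag
#> 1         1   A           47   high
#> 7         7   G           25   high
#> 19       19   A            2 normal
#> 28       28   C           17   high
#> 30       30   G           46   high
#> 39       39   A            5 normal
candidate_variants(pr)$sequence[1]
#> [1] "GGCCATGACGATGTCGTTACGTAGATGCAGAGACTCCTAA"
```

The top nominated variant is the position-1 A→G substitution — the
variant that in the published work bound twice as tightly as its
founder.

A full synthetic campaign, analysed end to end:

```r
dir  <- tempfile("campaign")
camp <- simulate_campaign(sim_config(seed = 1), out_dir = dir)
res  <- run_pipeline(dir, file.path(dir, "analysis"))
nrow(res$shortlist)   # ranked, specificity-screened candidates
```

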