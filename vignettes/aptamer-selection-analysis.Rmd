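---
title: "Analysing multi-round HTS-SELEX selections with aptrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing multi-round HTS-SELEX selections with aptrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptrace)
```

## The problem

SELEX couples rounds of affinity selection against an immobilised target
with PCR amplification of the retained oligonucleotides. With
high-throughput sequencing of every round's bound pool, selecting good
aptamer candidates becomes a data-analysis problem with several traps:

* **prevalence is a poor proxy for affinity** — a sequence can be abundant
  because it started abundant, because it amplifies well, or because it
  binds the bead carrier rather than the target;
* **open (bulk) PCR is GC-biased**, silently deleting rare high-GC
  candidates between rounds;
* **carrier and electrostatic binders** co-enrich through every round and
  look exactly like winners until they are compared against reference
  pools;
* **PCR mutagenesis** creates clouds of point variants around every
  abundant founder — noise for counting, but a free mutational scan of the
  aptamer once it is read position by position.

aptrace implements the corresponding analyses — prevalence censuses,
edit-distance clustering, enrichment-rate ranking, reference-pool
specificity screening and within-cluster mutational landscapes — plus a
generative simulator that produces fully ground-truthed campaigns for
validating every stage.

## From reads to censuses

A sequenced pool is described by one row of a pool sheet: barcode,
constant flanks, random-region length, barcode offset and orientation.
`demultiplex()` assigns reads to pools by best barcode match within a
mismatch tolerance (default 0; ties are never guessed — they go to
`unassigned`), after verifying that every pair of barcodes differs at more
than twice the tolerance. `extract_region()` then locates both flanks
(default tolerance 2 substitutions each) and accepts the enclosed
subsequence only when it has exactly the declared length and contains no
ambiguous base; every rejection is tallied by reason. `U` is normalised to
`T` on input, since an RNA selection is sequenced through cDNA and all
comparisons are alphabet-agnostic.

`build_census()` counts each pool's unique random regions. Classification
follows the standard bookkeeping: a **bystander** is a sequence seen
exactly once in the whole dataset; everything else is a **true aptamer**,
further split into **clustered** (member of a family of two or more) and
**unclustered**.

## Clustering around founders

PCR-mutagenesis families are recovered by greedy founder-first
clustering: sequences are visited in order of decreasing total copy
number (ties broken lexicographically); each unassigned sequence seeds a
cluster and absorbs every unassigned sequence within `max_dist = 3`
edits (substitutions, insertions or deletions) of it. Membership is
measured to the founder rather than transitively, matching the
founder-plus-variants structure that PCR mutagenesis actually produces;
with a per-round mutation load far below one edit per molecule, variants
of variants are rare and a distance-3 ball around the founder captures
the family.

Exact Levenshtein comparisons against every candidate would be quadratic,
so candidates pass two sound prefilters first: base-composition L1
distance (one edit changes the A/C/G/T counts by at most 2) and Euclidean
4-mer profile distance (one edit changes at most `k` k-mers per sequence,
so true neighbours satisfy `d2 <= 2 * k * max_dist`). Both are upper-bound
arguments, not heuristics: the tests verify that disabling the prefilter
never changes a clustering, and that the whole procedure equals a
brute-force all-pairs oracle on random planted-family instances.

## Enrichment dynamics

The enrichment rate of a sequence is the ratio of its prevalence in
consecutive rounds, computed on raw counts by default (that convention
reproduces the published one-decimal rates of the worked example
exactly); reads-per-million normalisation is available for pools of
unequal depth. A sequence absent from the earlier round receives a
pseudocount (default 0.5) in both numerator and denominator — orderings
are preserved and no rate is infinite.

```{r}
tab <- il10ra_example()
core <- tab[tab$category == "core", ]
data.frame(cluster = core$cluster_id,
           rate = round(enrichment_rate(core$r4, core$r5), 1),
           published = core$rate_printed)
```

`rank_candidates()` orders candidates by final-round prevalence, by final
enrichment rate, or by the **combined** rule: each sequence is scored by
the worse of its two individual ranks, so a top candidate must be good on
both axes. The combined rule is this package's operationalisation of the
observation that true high-affinity binders tend to rank high on both;
prevalence alone is dominated by amplification history, enrichment alone
is noisy for rare sequences.

`gc_binned_enrichment()` compares mean enrichment per GC bin between two
amplification arms, and `diversity_accounting()` performs the gain/loss
set algebra between an earlier and a later pool, overall and restricted
to low-abundance sequences (default cutoff 100 copies) — the sequences a
biased amplification loses first. `convergence_report()` flags the first
round in which the number of clusters falls while mean cluster size keeps
rising: the signature of a selection that has turned competitive, which
is the natural stopping point before useful diversity is extinguished.

## Specificity screening

All specificity rules are pseudocounted ratio tests with a default
ten-fold boundary:

* **pattern** vs a control pool: `target_specific` at ratio ≥ 10,
  `control_preferential` at ≤ 1/10, `shared` in between;
* **electrostatic filter**: a sequence whose prevalence on the control
  protein rises ten-fold when the buffer pH is adjusted to flip the
  control's net charge is binding electrostatically and is excluded;
* **cross-species call**: `target_specific` against the control in both
  the human-target and ortholog pools, with the two prevalences within a
  three-fold `similarity` bound ("enriched equally well"; no sharper
  value is established, and three-fold tolerates one round of modest
  affinity difference).

Counts are rescaled to a common depth when pool depths differ by more
than two-fold, since raw counts from a shallow control pool are not
comparable to a deep target pool. A sequence is excluded if it fails
against **any** configured control — carrier, pH-adjusted carrier, or an
unrelated protein.

## Mutational landscapes

For a cluster with founder copy number `n0` in a pool, the cluster
substitution rate is `sigma = (total derivative copies) / (n0 * L)` with
`L` the random-region length. Single-substitution variants are attributed
to their position and alternative base; variants at edit distance 2–3 and
indel variants are tallied in an `other` class that contributes to
`sigma` but not to positions. Under a uniform-mutagenesis null the
expected copy total per position is `n0 * sigma`; positions are flagged
`high` at ≥ 3× that expectation and `low` at ≤ 1/3×, with a one-sided
Poisson tail probability reported alongside as a rough significance
guide (the fold thresholds, not the Poisson tails, drive the flags).
`candidate_variants()` nominates the variants at high-flagged positions,
ranked by copy number, down-ranking positions where all three alternative
bases occur at about the average rate — a pattern more consistent with a
mutation-tolerant position than with a genuine affinity gain.

Two phrasings of the substitution-rate summary circulate for this kind of
data — a per-position rate of 0.001–0.005 and "10–50 variants per 10 000
founder copies" — which are not mutually consistent under one reading of
the formula; this package implements the formula literally
(denominator `n0 * L`) and reports `sigma` as such.

## The simulator

`simulate_campaign()` generates a complete multi-round campaign with
ground truth. Its components:

* **binding**: each molecule is retained independently with probability
  `T/(T + Kd) + carrier + background` (single-site Langmuir isotherm plus
  additive carrier-binding and bead-background terms, capped at 1).
* **amplification**: per cycle, each molecule duplicates with probability
  `e_base` (emulsion) or `e_base - gc_slope * (GC - 0.5)` (open). With
  the defaults (`e_base = 0.8`, 25 cycles, `gc_slope = 0.27`) a GC-0.2
  sequence amplifies ≈ 3-fold more in the open arm than in the emulsion
  arm — the calibration anchor — and a GC-0.8 sequence ≈ 3-fold less.
  Each newly synthesised molecule mutates with probability
  `1 - (1 - mu)^L` (`mu = 5e-5` per base per cycle), creating derivative
  species that inherit their parent's annotations with a lognormal
  (mostly deleterious) Kd penalty. Pools above `pool_cap` molecules are
  binomially thinned back to the cap — the aliquot carried forward —
  which preserves relative expectations.
* **sequencing**: `min(reads, pool size)` molecules drawn without
  replacement, emitted as `barcode + flank5 + region + flank3` FASTQ.

The default campaign mirrors a five-round selection with the target
concentration starting at 5 nM and declining 25% per round. The starting
concentration sits **below** the high-affinity Kd band (2–20 nM) because
selection only discriminates affinity in the sub-Kd regime; at saturating
target, every binder is retained and prevalence decouples from affinity.
The declining schedule also stands in for the salt-stringency ramp of a
real protocol, which is not modelled separately. Species are assigned to
affinity classes (3% high, 12% medium, 35% low, 50% nonbinder) with
log-uniform initial abundances; 5% bind the bead carrier (and therefore
enrich in every pool including controls), a disjoint 5% bind the control
only under adjusted pH, and a quarter of binders are cross-reactive with
the ortholog target at 0.7–1.4× their target Kd. One high-fitness single
substitution of an abundant mid-Kd founder is planted at 20 trace copies
— the stand-in for an early PCR-mutagenesis event — so that landscape
recovery can be scored against truth. At round 2 the bound pool is
amplified by both emulsion and open PCR and carried through one more
selection round, giving the paired-arm comparison; at the final round
parallel aliquots are bound to the carrier control, the pH-adjusted
control and the ortholog.

### What the simulator does and does not emulate

The scale is deliberately reduced: 3 000 initial species, a 10^6-molecule
pool cap and 10^5 reads per pool, versus ~10^14 molecules and ~3×10^6
reads per pool in a real campaign. Sampling without replacement keeps
read counts proportional to molecule counts at this scale; real
sequencing also re-samples through a library-preparation PCR, which is
not modelled. Also not modelled: secondary structure, reverse
transcription bias, droplet-level emulsion physics, sequencing error (off
by default, available as a uniform substitution rate), and inter-molecule
competition for limited target. Passing tests therefore demonstrate that
the analysis recovers planted truth under a faithful-but-small generative
model of the selection dynamics — not that any particular real dataset
would yield the same magnitudes. Because the whole scaled library is
detectable from round 1, the cluster count declines monotonically instead
of rising before convergence as a real campaign's does; the convergence
flag is exercised on constructed fixtures instead.

## Numerical and design choices

* Deterministic analysis: no analysis stage uses randomness; pipeline
  reruns are byte-identical, and all simulator randomness flows from one
  seed.
* Ties: abundance ties in clustering and ranking break
  lexicographically / by prevalence, so results are order-independent.
* Degenerate inputs: empty pools produce empty censuses; a founder absent
  from a pool yields an undefined (`NA`) substitution rate; a zero/zero
  enrichment rate is reported missing rather than pseudocounted.
* Barcode mismatch default is 0 (demultiplexing tolerances are not
  established for this protocol); flank tolerance defaults to 2.
* Bystanders (dataset-wide singletons) are excluded from clustering by
  the pipeline: a family, by definition, needs recurrence. Members of
  singleton clusters are reported `unclustered`.
* The problem sizes used by the validation suite — 20 replicate default
  campaigns for the dynamics properties, 20 random 300-sequence
  instances for the clustering oracle, an exhaustive 0–1000 count grid
  for the specificity rules — were chosen as the smallest sizes at which
  the stochastic properties have clear resolving power.

## Running a campaign end to end

```{r, eval = FALSE}
dir <- tempfile("campaign")
camp <- simulate_campaign(sim_config(seed = 1), out_dir = dir)
res <- run_pipeline(dir, file.path(dir, "analysis"))
head(res$shortlist[, c("sequence", "prevalence", "enrichment", "rank",
                       "pattern", "cross_species")])
```

Every stage writes a TSV checkpoint (`census.tsv`, `clusters.tsv`,
`enrichment.tsv`, `specificity.tsv`, `landscape_*.tsv`, `report.tsv`,
`shortlist.tsv`), so each stage can be inspected or re-run independently.

## Known limitations

* Cluster membership is founder-anchored; a real lineage could in
  principle chain farther than 3 edits from its founder and would be
  split into a second family.
* The expected-rate model for position flags is uniform across positions;
  sequence-context mutation biases of the polymerase would shift flags
  without reflecting selection.
* Specificity calls depend on pseudocounted ratios and are unreliable for
  sequences observed in only a handful of reads; the shipped thresholds
  assume depth-comparable pools after normalisation.
* The combined ranking rule and the three-fold cross-species similarity
  bound are pragmatic conventions of this package, not estimated
  quantities.
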