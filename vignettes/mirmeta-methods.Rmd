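---
title: "mirmeta: methods, models and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirmeta: methods, models and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirmeta)
```

mirmeta re-implements, as a reusable and fully tested pipeline, the
computational core of a small RNA study of ascidian larval
metamorphosis: read cleaning and annotation-based classification,
cross-species miRNA family clustering, Dollo-parsimony gain/loss
reconstruction on a species tree, comparative-Ct qPCR quantification,
and miRNA–target integration with over-representation analysis. This
vignette explains each model, the tunable parameters and their
defaults, what the synthetic generator does and does not emulate, and
the decisions taken where the underlying procedure was underspecified.

## Read cleaning

`filter_reads()` applies six filters in a fixed order, attributing each
removed read to the **first** failing filter so that per-filter counts
plus the clean count always equal the input count:

1. **poly-N** — any N base (`max_n = 1`);
2. **5′-adapter contaminant** — read prefix matches the 5′ adapter
   within `adapter_mismatches` (default 1);
3. **no 3′ adapter** — the adapter is located by best prefix–suffix
   overlap (overlap ≥ `min_adapter_overlap = 6`, mismatches ≤ 1 over
   the whole overlap; fewest mismatches wins, ties to the longest
   overlap) and trimmed when found;
4. **homopolymer** — a single base makes up ≥ `homopolymer_frac = 1`
   of the trimmed insert (i.e. pure poly-A/T/G/C; the fraction is
   configurable because "contains poly-X" is ambiguous);
5. **low quality** — mean Phred < `min_mean_q = 20` (skipped for FASTA
   input);
6. **length** — trimmed insert outside `[18, 32]` nt.

The source procedure lists these filters without order or thresholds;
the order and defaults above follow common small RNA practice and are
all exposed in `qc_params()`. An insert left empty by trimming is
counted under the adapter filter (there is no insert). Setting
`require_adapter3 = FALSE` keeps adapter-less reads untrimmed, which
makes filtering idempotent on already-trimmed inserts — the form in
which the "re-filtering removes nothing" invariant is tested.

## Annotation classification

`classify_reads()` assigns each clean read to the highest-priority
annotation category in which it occurs as an **exact full-length
substring** (exon/intron matched on both strands, with strand
recorded). Default priority: known_miRNA > rRNA > tRNA > snRNA >
snoRNA > repeat > exon > intron; unmatched reads are `other`. Exact
matching was chosen over a mismatch-tolerant mapper because the source
states no mapper or mismatch policy, exactness makes the brute-force
oracle trivial, and at small RNA read lengths it is how miRNA
quantifiers behave in practice. The bookkeeping convention of
`remove_annotated()` is `remaining = mapped − removed` restricted to
mapped reads, which reproduces the published totals identity
(11,283,372 − 2,544,546 = 8,738,826); the candidate set kept for miRNA
analysis is the known-miRNA reads plus the unannotated ones.

## Family clustering

Two mature miRNAs are in the same family when some ungapped alignment
with 5′ offset in {−1, 0, +1} has overlap ≥ 15 nt, ≤ 2 mismatches, and
covers the seed region (positions 2–8) of **both** sequences. Decisions:

* *Ungapped*: the criteria mention only mismatches; seed-anchored miRNA
  homology is conventionally ungapped.
* *"≤ 1 nt overhang between 5′ ends"* is read as the relative 5′ offset.
* *Seed coverage on both sequences* is the stricter of the two possible
  readings; `family_params(require_seed = "either")` relaxes it.
* *Single linkage*: families are connected components of the pairwise
  match graph, because the procedure describes clustering by pairwise
  similarity with no centroid notion. Family ids are the
  lexicographically smallest member id, making the partition
  order-independent.
* U/T are equivalent; all comparisons happen in RNA space.

## Dollo reconstruction and taxon assignment

Under Dollo parsimony a family is gained once and lost arbitrarily
often. Given a presence/absence row, `dollo_reconstruct()` places the
gain at the MRCA of the present leaves and one loss per maximal
carrier-free subtree below it. This is the unique single-gain optimum:
moving the gain above the MRCA only adds absent clades, and with the
gain fixed, one event per maximal absent clade is minimal. The test
suite verifies this against exhaustive enumeration of all single-gain
assignments and loss subsets on trees of up to 8 leaves.

"Acquired at the origin of taxon T" requires the family to be present
in ≥ 2 daughter lineages of T and absent in all ancestor and sister
lineages; since ancestors are unobservable, absence is evaluated over
extant species — the only computable reading. With the gain at the
MRCA both side conditions hold by construction (they are still
asserted). Single-species families are reported as terminal-branch
gains, matching per-species novel-family counts. Loss events are
attributed to the highest branch of each absent subtree.

The bundled 17-species tree (cnidarian outgroup, protostomes,
ambulacrarians, amphioxus, vertebrates, tunicates including
*C. savignyi*) is a conventional topology with internal nodes named for
the taxa of interest. The original figure's exact topology is not
published as newick, so the tree is replaceable input, and the package
does not claim to reproduce counts that depend on external database
contents.

## Expression analysis

`ddct()` implements comparative-Ct quantification: ΔCt = Ct(miRNA) −
Ct(U6) paired by replicate index within stage; ΔΔCt = ΔCt − mean
ΔCt(reference stage); relative expression = 2^−ΔΔCt. The mean-based
fold change is exactly 1 at the reference stage. Choices where the
source is silent or inconsistent:

* Tests run on ΔCt (log-scale) values, not on 2^−ΔΔCt, per standard
  qPCR statistics.
* The source says "paired Student's t-tests" in one place and
  "Student's t-test" in another; replicates across developmental stages
  are independent biological samples, so the default is the unpaired
  two-sided test with `paired = TRUE` available.
* A miRNA is significant only when the metamorphic stage differs from
  **every** earlier stage (`max p < alpha`, default α = 0.01), matching
  figures where both comparisons are starred. This compound flag is
  strictly more conservative than the nominal t-test level, so type-I
  calibration is tested on the single-comparison case.
* No multiple-testing correction is applied by default (the source
  applies none); `stage_test(adjust = "BH")` enables it.
* Heatmap clustering uses correlation distance (1 − Pearson) with
  average linkage; constant rows (undefined correlation) sit at
  distance 0 from identical rows and 1 from everything else.
* Zero variance in both groups with equal means gives p = 1 by
  convention (p = 0 when the constant means differ).

## Target integration

A (miRNA, gene) pair is kept iff it is in A ∩ B, or in A with Pearson
r(miRNA profile, gene profile) < `max_r`. Decisions: "negatively
correlated" is quantified as r < 0 with no significance attached (only
three stage values); the correlation clause is restricted to table A
because the methods text names only one predictor for that route
(`symmetric = TRUE` symmetrizes); duplex free energy is a pass-through
attribute of table A; the seed is fixed at positions 2–8 with
Watson–Crick pairing only. `enrich()` is a generic one-sided
hypergeometric ORA over any GMT collection with BH adjustment — no
pathway database is bundled.

## The synthetic world

The generator states its world once in `simulation_config()` and the
defaults are not tuned to test outcomes:

* **Stages and replicates**: 18/21/42 hpf, triplicates — the study
  design. The default qPCR panel plants 9 up-regulated (4×) and 3
  down-regulated (0.25×) miRNAs at 42 hpf plus 2 flat ones, mirroring
  the reported 9-up/3-down outcome; U6 has zero stage effect by
  definition. Ct noise defaults to 0.25 Ct (realistic qPCR triplicate
  scatter); recovery examples that specify 0.1 Ct use 0.1.
* **Reads**: 14 categories (9 clean annotation classes incl. `other`,
  plus poly-N, 5′-adapter, no-3′-adapter, homopolymer, low-quality
  contaminants). Counts are allocated by largest-remainder rounding, so
  count assertions are exact; only read order is random. Mature miRNAs
  are 21–24 nt with first-base U allocated at exactly the 0.8 bias.
  Inserts are re-drawn when they would collide with a higher-priority
  reference or contain a spurious adapter match — the generator plants
  *unambiguous* reads by construction.
* **Families**: each family's single gain is placed uniformly at random
  over all tree nodes; every branch below a surviving lineage then
  loses the family with probability `loss_rate = 0.1`. A per-branch
  *gain* probability was dropped from the configuration: under the
  single-gain constraint it adds nothing beyond the placement
  distribution. All-absent families are discarded and regenerated.
  Family members differ from their ancestor by ≤ 1 substitution;
  ancestors of different families are kept ≥ 6 mismatches apart at
  every allowed offset, so the planted partition is exactly the
  match-graph partition.
* **Predictions**: four planted classes (both-predictor, A-only
  anti-correlated, A-only positively correlated, B-only) over distinct
  genes, with profile correlations of planted sign.

What the generator does **not** emulate: positional sequencing error
models (substitutions only, and none by default), genome-scale
coordinates, expression-level read-count distributions, hairpin
precursor structure, or real database content. A green test therefore
establishes that the algorithms implement their stated contracts on
unambiguous data — not that the pipeline reproduces any published
figure that depends on undeposited raw reads or external databases.

## Numerical and interface choices

* Pipeline configs are JSON (jsonlite), not YAML — no YAML parser is a
  package dependency.
* Sequences travel as plain character vectors; files are DNA, miRNA
  work is RNA, conversion at parse time.
* FASTQ is read by a strict 4-line reader so malformed records can be
  reported with their record index; FASTA via Biostrings.
* All randomness is seeded from a single integer; reruns are
  byte-identical (manifest md5 hashes are compared in tests).
* Adapter-match ties: fewest mismatches, then longest overlap
  (leftmost start). Pairwise-match ties: fewest mismatches, then
  offset 0.

## Known limitations

* Exact-match classification cannot model cross-mapping or sequencing
  errors; real data would need a mismatch-tolerant mapper upstream.
* With only three stages, Pearson correlations take few values and the
  anti-correlation filter is a sign test in practice.
* Acquisition assignment is only as good as the input catalogs; taxa
  represented by a single sampled species can never satisfy the
  two-daughter-lineage rule.
* The soft published family count (150 families from 165 sequences)
  is not reproduced here because the underlying supplementary
  sequences are not machine-readable input; the clustering criteria
  themselves are fully tested on planted catalogs and brute-force
  oracles.
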