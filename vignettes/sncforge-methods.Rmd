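---
title: "Methods: harmonised sncRNA annotation, dual quantification and DE"
author: "sncforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonised sncRNA annotation, dual quantification and DE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sncforge)
```

## The problem

PIWI-interacting RNAs (piRNAs) are 21–35 nt small RNAs with a notoriously
inconsistent annotation landscape: the same mature sequence may carry many
database identifiers, piRNA-sized fragments of rRNA/tRNA/snoRNA/YRNA/miRNA
precursors are mislabelled as piRNAs, and databases disagree on coordinates
and biotypes. Quantifying them from small RNA-seq is further complicated by
heavy multimapping (clusters and transposon-derived copies). `sncforge`
addresses this with three coupled components:

1. **Annotation forging** — build one harmonised GTF/FASTA track from a
   piRNA database and a general sncRNA database.
2. **Dual quantification** — count each library twice, genomically
   (ungapped alignment + feature counting) and transcriptomically
   (equivalence-class EM), then reconcile the two views.
3. **Expression analysis** — filtering, normalisation, exploratory
   summaries, moderated-t differential expression with a cross-method
   consensus, plus piRNA-specific sequence signatures (1U/10A bias,
   ping-pong, length distributions) and complementarity-based target
   prediction.

## Annotation forging

The forge pipeline runs, in order: per-database sequence collapsing →
ungapped genome realignment → length filtering → biotype re-classification
→ database integration → standard-chromosome filtering → coding-overlap
exclusion → metadata derivation (embedded hosts, genomic regions,
transposable elements).

* **Collapsing.** One feature per distinct sequence string; all ids
  sharing a sequence become aliases. This is a sequence-level
  interpretation of duplicate/multi-mapped-id removal: genomic placements
  are attached to the single surviving record.
* **Realignment contract.** Every full-length ungapped placement on either
  strand with at least 16 matched bases and 0 mismatches is kept (read
  alignment later uses 14 matched bases and ≤1 mismatch). Sequences with
  more than 100 placements are treated as unmapped and dropped with a log
  entry, mirroring how a short-read aligner reports reads above its
  multimapping cap. The matcher is a seed-and-extend over a 7-mer
  positional index; two disjoint 7-mer seeds cover every placement of a
  ≥14 nt query at ≤1 mismatch (pigeonhole), and shorter queries or larger
  budgets fall back to a window scan. Tests hold it to exact agreement
  with an independent sliding-window oracle.
* **Length rules.** Database records of 100 nt or longer are discarded
  (the track targets mature sncRNAs); piRNA-database records must
  additionally be shorter than 69 nt to enter the merged track, since
  mature piRNAs are 21–35 nt and longer piRNA-database entries are almost
  always mis-deposited precursors or fragments. Records at the boundary
  are excluded (both bounds are exclusive).
* **Re-classification.** A piRNA-database sequence exactly matching a
  general-database record with a non-piRNA biotype takes that biotype. If
  a sequence matches two different non-piRNA biotypes the record is
  flagged ambiguous and left as piRNA in the re-classification log; when
  the general database itself carries several biotypes for one sequence,
  the merged record keeps the joined label so the ambiguity stays visible
  in the final GTF rather than being silently resolved.
* **Integration.** Records present in both databases become one feature
  carrying both provenance tags and all aliases; the general-database id
  wins as primary id (it is the completing database), the piRNA-database
  id is kept as an alias.
* **Coding exclusion.** In stringent mode (default) any feature interval
  overlapping a protein-coding gene's exon, or any CDS interval, by at
  least 1 bp is removed; overlap is strand-agnostic because a genomic
  fragment co-located with coding sequence is suspect regardless of
  orientation. Lenient mode keeps everything and flags the overlaps.
* **Metadata.** Embedded piRNAs are sense-contained features within
  sncRNA/lncRNA host intervals (sense, because a fragment of a host
  transcript is necessarily sense to it; the strand requirement can be
  switched off). Genomic regions are single-linkage merges of feature
  intervals within 1,000 bp (strand-agnostic, `region_gap` exposed);
  a region overlapping any gene interval is `genic`, otherwise `cluster`,
  and each sequence is labelled by the union of its hits' region labels
  (`both` when mixed). TE metadata lists every (feature, overlapping TE)
  pair with class/family/gene.

Internally all intervals are `GenomicRanges` objects (1-based closed, the
R/Bioconductor convention); BED input is converted from 0-based half-open
at the boundary and GTF is written 1-based closed with deterministic
ordering, so identical tracks serialise to identical bytes.

## Dual quantification

**Genomic.** Reads are adapter-trimmed (leftmost 3' occurrence, including
adapter prefixes at the read end, at ≤10% mismatches over the overlap and
≥3 bp overlap; inserts <15 nt are discarded), aligned ungapped and
splice-free (≥14 matched bases, ≤1 mismatch, ≤100 placements), and counted
against the forged track: a placement is assigned to a feature it overlaps
by ≥1 bp on the same strand, placements touching two distinct features are
ambiguous and dropped, and multi-placed reads contribute fractionally
(1/n placements; `all` and `unique` modes are exposed). Fractional
counting is the default because piRNA multimapping makes unique-only
counting lossy; a read hitting two copies of the same feature still
contributes exactly 1 to it.

**Transcriptomic.** Reads are mapped to every transcript containing them
as an ungapped near-substring (≤1 mismatch, sense strand — paralleling the
genomic contract) and collapsed into equivalence classes. Abundances start
uniform and are refined by EM until the largest change in the abundance
proportions falls below `em_tol = 1e-8` or 1,000 iterations; expected
counts conserve the mapped-read mass at every iteration and the class
log-likelihood is non-decreasing (both asserted in tests, together with
recovery of a planted 60/30/10 mixture within three bootstrap SDs and a
likelihood-grid oracle on a two-transcript instance). Uncertainty comes
from multinomially resampling the class counts 100 times and re-running
EM — resampling classes rather than raw reads is cheap and the SD is used
descriptively. GC/sequence-bias correction is out of scope.

**Consensus.** A feature is "expressed" in a track when it passes the CPM
filter there; the consensus is the union (sensitive) or intersection
(conservative) of the two expressed sets. The same union/intersection
logic applies to the significant sets after differential expression.

## Expression statistics and differential expression

Filtering keeps features with CPM ≥ 1 in at least `min_samples` samples
(default: the size of the smallest group). Normalisation offers TMM,
TMMwsp and RLE factors (all rescaled to geometric mean 1) and log2 CPM
with a proportional prior of 0.5; TMM/TMMwsp and the CPM transform are
delegated to edgeR, while RLE is the median-of-ratios size factor computed
directly (and cross-checked against DESeq2 in the tests) because its
contract here is the depth-sensitive size factor, not edgeR's
library-size-relative variant. Exploratory outputs are data tables:
RLE boxplot statistics, biotype detection summaries (genome share,
detected share, within-sample share, count quartiles — the within-sample
shares sum to 100 per sample), MDS (pairwise leading-logFC distance over
the top 500 features, the common practice when the choice is otherwise
open), PCA, hierarchical clustering (Ward/complete/average) and sample
correlation matrices.

Differential expression uses the precision-weight approach: log2 CPM with
observation weights from the lowess mean–variance trend (weight =
fitted^-4), weighted least squares per feature, empirical-Bayes variance
moderation, BH adjustment. The implementation is limma's voom/lmFit/eBayes
behind the package's module surface; one engine (rather than a second
NB-GLM engine) keeps the merge logic method-agnostic, and the engine is
validated by simulation: on seeded null NB data (2,000 features, 3 vs 3,
dispersion 0.2) the empirical type-I error at p ≤ 0.05 must land in
[0.035, 0.065], power must exceed the null rate with correct signs for
planted effects, and BH must equal a hand-written step-up oracle. Merged
tables carry per-method logFC/p side by side, a consensus label, and
union/intersection significant sets at raw and adjusted alpha. The
up/down classifier excludes features whose two logFC estimates disagree
in sign (`discordant`, reported separately) — the merge behaviour for such
features is otherwise undefined.

## Sequence signatures

Position frequency matrices cover the first 15 nt (shorter sequences
contribute the positions they cover); biases are tested per position with
an exact two-sided binomial test against a 0.25 background; logos are
drawn as information content with T, not U. The ping-pong profile counts
opposite-strand read pairs by the distance between their 5' ends plus one
— an overlap of k means the 5' ends are k−1 apart with the minus read's 5'
end (its rightmost genomic coordinate) downstream:

```
plus   5'-========>
minus       <========-5'
            |--10 nt--|
```

The hallmark of ping-pong amplification is k = 10; the statistic `z10`
is the 10-nt bin's z-score against the other bins. Multi-mapped reads
contribute 1/n weight to ping-pong and coverage, consistent with
fractional counting. Logos and length distributions use expressed features
unweighted by abundance (abundance weighting is available to the caller by
repeating sequences).

## Target prediction

Differentially expressed piRNAs are scanned against transcript regions
(5'UTR/CDS/3'UTR) for antiparallel duplexes: piRNA positions 2–11 (the
seed) must pair Watson–Crick; outside the seed up to 4 G:U wobbles and up
to 4 mismatches are tolerated; the score is matches + 0.5·wobbles. This
scheme is this package's own (versioned in the output header as
`seed2-11_wc+0.5wobble_v1`) — it captures the seed-anchored,
wobble-tolerant matching such tools use without claiming to reproduce any
specific tool's hit lists. Thermodynamic duplex energies and conservation
are out of scope.

## The synthetic fixtures

`make_genome_and_databases()` plants every rule the forge implements on a
toy genome: 2 chromosomes × 500 kb plus a 20 kb non-standard scaffold,
~300 sncRNA sequences across categories (shared/db-specific piRNAs, other
biotypes, ≥100 nt and 69–98 nt length-rule probes, biotype conflicts and
one two-biotype ambiguity, multi-locus sequences at 2–5 copies, one
sequence above the 100-locus cap, coding-overlap and intron-embedded
piRNAs, lncRNA hosts with one antisense control, TE overlaps, and four
spike-ins of 22/28 nt in methylated and non-methylated versions).
Inter-feature gaps (2 kb) exceed the region-merge window so every region
assignment is decidable by construction; cluster members sit 100–300 bp
apart. piRNA-like sequences carry a realised 90% 1U and 60% 10A bias.

`simulate_reads()` draws negative-binomial per-feature fragment counts
(gamma-distributed means scaled to 50,000 reads/sample, dispersion 0.2 —
typical bulk small RNA-seq values), renders fragments as insert + 3'
adapter + fill truncated to 50 cycles with 0.1% per-base substitution
errors, and emulates three designs: a 2×3 two-group study with 15 up- and
15 down-regulated piRNAs at |log2FC| = 2; a spike-in dilution series at
1:10:100 input ratios; and periodate treatment multiplying every
non-methylated species (including the non-methylated spike-ins) by
δ = 0.05, the depletion a strong oxidation/β-elimination gives. Spike-in
sequences are synthetic stand-ins generated with the same 1U/10A bias.
All generators are pure functions of `(spec, seed)`.

What passing these tests does **not** show about real data: the fixtures
have no ligation or PCR bias, no quality degradation, no isomiR-style
end-heterogeneity, uniform background, and planted sequences that are
(by construction) unique up to their intended copies — so the pipeline's
behaviour under pervasive near-duplicate families and biased library
chemistry must be judged on real libraries.

## Numerical choices and degenerate inputs

* EM tolerance 1e-8 on the proportion scale with a 1,000-iteration cap;
  bootstrap resampling is seeded and reproducible.
* CPM with all-zero libraries, filters demanding more samples than exist,
  all-zero samples in TMM, and RLE without an all-positive feature are
  errors, not silent results.
* MDS of identical samples returns the zero configuration instead of
  failing inside the distance decomposition.
* `pingpong()` with no opposite-strand pairs returns a zero profile with
  `defined = FALSE` rather than a spurious z-score.
* Ties in GTF serialisation are broken by (chromosome, start, end,
  gene id) so repeated runs are byte-identical.
* The problem sizes used by the test-suite and the acceptance script
  (500 kb × 2 chromosomes, 50k reads/sample, 2,000-feature DE
  simulations, 5,000-read EM mixtures) were chosen as the smallest sizes
  at which the statistical checks (type-I error bands, Poisson-error
  spike-in recovery, 3-SD EM recovery) are stable across seeds.

## Known limitations

* Exact matching only (no indels, no quality awareness, no splicing) —
  appropriate for ≤35 nt reads, not for longer RNA fragments.
* The naive-plus-indexed matcher targets genomes up to ~100 Mb; for full
  mammalian genomes an external aligner should produce the placements,
  which can be imported as a hits table.
* One DE engine; edgeR's exact test / QL F-test are not reimplemented.
* piRNA-cluster database joins are an optional metadata column, not a
  clustering method.
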