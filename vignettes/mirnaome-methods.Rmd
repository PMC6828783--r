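---
title: "Classifying small-RNA reads against miRNA hairpins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying small-RNA reads against miRNA hairpins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirnaome)
```

## The problem

Deep sequencing of the 17–30-nt RNA fraction yields tens of millions of
reads, of which a large share derives from miRNA hairpin loci. A single
hairpin does not produce a single sequence: besides the canonical mature
5p and 3p miRNAs, Drosha/Dicer cleavage heterogeneity, untemplated
nucleotide additions, editing/SNPs, and degradation of the flanking
primary transcript generate a family of related reads. `mirnaome`
implements the curation arithmetic for this read family: given a genome,
hairpin annotations (mature arms included), and collapsed read
libraries, it assigns every read at a hairpin locus to exactly one of
eleven classes and derives the downstream summaries a miRNAome survey
reports — arm dominance and switching, isomiR class ratios,
normalization, expression clustering, genomic clusters and
novel-hairpin screening.

## Read taxonomy

All comparisons happen in hairpin 5'→3' orientation ("locus
coordinates"): minus-strand loci are reverse-complemented once at
extraction, which makes every downstream rule strand-free. The classes
are:

| label | meaning |
|---|---|
| `MATURE` | read identical to an annotated mature arm |
| `ISO_3P_TEMPLATE` | mature 5' end; 3' deletions, or additions matching the genome continuation |
| `ISO_3P_NONTEMPLATE` | mature 5' end; ≥1 added 3' base disagreeing with the genome (typically A/U tails) |
| `ISO_SNP_NONSEED` | both mature ends; internal mismatch outside the seed |
| `ISO_5P_TEMPLATE` | mature 3' end; templated 5' shortening/extension |
| `ISO_5P_NONTEMPLATE` | mature 3' end; untemplated 5' additions |
| `ISO_SNP_SEED` | mismatch inside the seed (positions 2–7 of the mature 5' end) |
| `MOR_5P`, `MOR_3P` | offset reads flanking the 5p mature 5' end / 3p mature 3' end |
| `LOR` | reads from the terminal loop between the arms |
| `OTHER` | residual: both ends shifted without qualifying above |

The decision tree is ordered: exact mature, then 5'-anchored cases
(3' template / non-template / SNP), then 3'-anchored cases, then offset
reads, then loop reads, then the residual — with one override: any
residual read carrying a seed mismatch is reported as `ISO_SNP_SEED`,
because a seed change retargets the molecule regardless of how its ends
moved. Reads altered at *both* ends fall outside the classical groups,
each of which fixes one end; we report them as `OTHER` rather than
forcing them into a group.

Two parameter choices matter here:

* **Seed positions 2–7** (`classifier_params(seed_start, seed_end)`).
  Some definitions extend the seed to position 8; we default to 2–7 and
  expose the bounds.
* **Offset-read adjacency tolerance 2 nt**
  (`mor_max_start_offset`). Offset RNAs are "immediately adjacent" to
  the mature ends, but real stacks are ragged by a base or two; exact
  adjacency is recovered with tolerance 0. Reads that start outside a
  mature and end inside it (or mirror-image on the 3p side) cannot be
  isomiRs and are counted as offset reads too.

The **template check is a naive character-by-character comparison** of
the added/removed bases against the genome continuation at the anchored
end. This is deliberate and load-bearing: a 2-nt untemplated tail can
often be *re-aligned* more cheaply as an insertion plus a match, which
would silently convert a non-template variant into a template one. The
classifier therefore takes only the 5' anchor from the aligner and
re-derives all base-level decisions positionally.

## Locus alignment

Alignment is restricted to hairpin loci padded by 30 nt on each side
(enough room for offset reads); whole-genome mapping of real data is
delegated to SAM input (`read_sam_alignments()`). Costs follow common
read-mapper defaults: mismatch 2, insertion 3, deletion 3, with
acceptance requiring ≥ 0.85 of the read aligned and ≥ 0.8 identity over
the aligned part. The engine is `Biostrings::pairwiseAlignment`
(semi-global: whole read, free subject ends).

The search is **tiered**: ungapped placements first; if none passes the
filters, up to 3 terminal 3' bases are set aside as a candidate
non-template tail (soft-clip rescue); only then are gapped placements
considered under the full cost scheme. The rationale mirrors the
template-check argument above: every isomiR-defining event is a
substitution or an end-offset, and a minimum-cost gapped placement can
shift the 5' anchor of a read with an untemplated head (cost 3 for one
insertion beats cost 4 for two head mismatches), corrupting every
downstream rule. Gap support is retained for genuinely indel-containing
reads, which are rare in 17–30-nt data.

Multimapping reads are resolved by policy: `split_equally` divides a
read's count equally across tied best placements — the convention used
when two hairpins carry an identical mature sequence, and the reason
fractional counts flow through all tables — or `random`, one placement
chosen uniformly under the run seed. Ties within one hairpin resolve to
the engine's deterministic (leftmost) placement.

## Arm-level statistics

Arm totals count mature plus all six isomiR classes on that arm;
offset/loop reads and `OTHER` are excluded, since surveys report them
separately against the mature counts. The guide arm must hold strictly
more than 50% of the 5p+3p total; an exact tie leaves the guide
undefined rather than picking a side. Arms are *co-expressed* when
dominant/minor ratio is strictly below 2 (a zero minor arm is never
co-expressed — the ratio is effectively infinite, not an error). Arm
*switching* is flagged when the guide arm differs between any two
libraries with defined guides.

IsomiR ratios are computed per hairpin as each class's percentage of
the 5p+3p arm total, only for hairpins whose assigned count in that
library strictly exceeds 10 reads (hairpins at or below the threshold
stay in expression totals but not in ratio analysis; we apply the
threshold per library so each life stage is self-contained).
Cross-hairpin means are unweighted — each miRNA contributes equally —
so highly expressed loci do not dominate the class profile.

## Normalization and clustering

Library depth is corrected by median-of-ratios size factors: factor_j is
the median over hairpins (with all-positive counts) of count_ij divided
by the row's geometric mean. Size factors are only defined up to a
common scale — normalization uses ratios — and we report them under the
geometric-mean-1 convention. That convention makes re-estimating factors
from an already-normalized matrix return exactly 1 and leaves the
two-library worked example (rows 2,4 and 8,16 → factors 0.70711,
1.41421) unchanged. Note that scaling one library by *c* changes its
factor by *c* only relative to the other libraries: the recomputed
geometric means absorb c^(1/m) of the scale, so the equivariance
property holds in ratio form, not as a literal per-factor equality. A
count matrix with no all-positive row raises an error advising a
pseudo-count rather than silently degrading.

Expression profiles (normalized by default; a `cluster_profiles = "raw"`
flag is exposed because survey figures do not always state which matrix
they clustered) are clustered with Pearson distance `d = 1 − r`
(range [0, 2]) and unweighted average linkage (UPGMA) via
`stats::hclust`. Constant profiles have no defined correlation; their
distances are set to the maximum (2) and the rows flagged, rather than
propagating `NA`.

## Genomic clusters and novel candidates

Genomic miRNA clusters are chains of hairpins on one scaffold in which
consecutive members are separated by at most 10 kb (end-to-start,
single-linkage chaining — the transitive closure of the pairwise
within-10-kb relation). "Within 10 kb" does not itself define
transitivity; chaining is the common cluster-calling convention and is
what multi-member clusters imply.

Novel-hairpin candidates are screened against the standard annotation
criteria, each computed as an independent flag:

* **fold**: folding free energy below −20 kcal/mol (exposed as
  `dg_threshold`; the value is adopted as a default strength criterion,
  not asserted as universal);
* **reads**: ≥ 10 reads at the locus;
* **both arms**: reads on both stem sides;
* **duplex overhang**: the Dicer signature, measured between the modal
  5p-read 3' end and the modal 3p-read 5' end on the folded stem,
  expected 2 nt (±1);
* **5' homogeneity**: ≥ 90% of an arm's reads sharing the modal 5' end
  (precise Drosha/Dicer cleavage).

`PASS` requires all flags; a candidate failing only the both-arms flag
is `PROVISIONAL` (one-arm expression is common for lowly expressed
hairpins) unless `require_both_arms` is set; anything else is `FAIL`.
With one expressed arm the overhang is unmeasurable and does not count
against the candidate. The criteria literature does not pin exact
homogeneity fractions or count minima; ours are parameters, not claims
about any published setting.

Folding is pluggable. The built-in backend is a *surrogate*: it finds
the maximum-scoring contiguous stem-loop by complementary extension
with per-pair energies GC = −3, AU = −2, GU = −1 kcal/mol and a
terminal loop of ≥ 3 nt. It is a stem-counting score for ranking
candidates, not a thermodynamic nearest-neighbour model — bulges,
stacking and dangles are ignored. Where a true minimum-free-energy
structure is wanted, `fold_hairpin(..., backend = "rnafold")` shells
out to ViennaRNA's RNAfold; all bundled tests use the surrogate so the
package stands alone.

## The synthetic benchmark

`simulate_mirnaome()` generates the study conditions the recovery tests
run under: a random toy genome with planted hairpins and three
stage-labelled libraries (juvenile / subadult / adult).

* **Hairpin geometry.** A stem `X` of mature length + 2 is paired
  against its exact reverse complement around a random loop, with the
  3p mature offset by 2 nt — so planted duplexes carry the canonical
  2-nt 3' overhangs and any folding backend calls them hairpins.
  Mature arms are 20–24 nt, loops 8–20 nt; hairpins are planted on both
  strands with 0.4–9-kb gaps so some form genomic clusters.
* **Class mixture.** Defaults follow the proportions a miRNAome survey
  reports: mature reads ≈ 60%, 3' template variants the largest isomiR
  group (≈ 21%), then 5' template (≈ 4%), 3' non-template A/U tails
  (≈ 4%), seed/non-seed SNPs (≈ 3.5%/2%), 5' non-template rare
  (< 1%), plus a few percent of offset, loop and residual reads so all
  eleven classes occur.
* **Counts.** Per hairpin and library, totals are negative-binomial
  (default mean 150, dispersion 4); a per-hairpin arm bias sets the
  5p/3p split, and a bias matrix can plant arm-switching scenarios.
* **Guarantees.** Non-template tail/head bases are drawn from {A, U}
  and re-drawn until they differ from the genome continuation at their
  position; any generated sequence occurring more than once across the
  padded loci, or arising from two different (hairpin, class)
  origins, is rejected — so every retained read has a unique,
  well-defined truth label.
* **Sequencing error** is a per-base uniform substitution applied to
  each read copy (default 0). An altered copy is re-labelled to the
  class its final sequence represents, using a position-based labeller
  that shares no code with the alignment path: a substituted base is
  genuinely indistinguishable from a SNP isomiR, so ground truth
  describes the emitted sequence, not the pre-error template. Under the
  alternative convention (truth = pre-error class) a per-base error
  rate of 0.5% alters ~10% of 22-nt reads and no classifier could
  score above ~90% — the convention chosen makes the error benchmark a
  test of the aligner's and classifier's robustness, which is the
  property worth measuring.

What passing recovery tests show — and what they do not: the simulator
plants clean, unambiguous events on random sequence, so perfect recall
demonstrates that the alignment → classification path implements the
rules exactly, not that real libraries are free of ambiguity. Real data
add multimapping families, RNA editing, degradation products and
adapter artefacts that the generator deliberately omits (uniform
substitution is its only error model).

## Numerical choices

* Internal coordinates are 0-based half-open everywhere; GFF3 (1-based
  inclusive) and SAM are converted at the I/O boundary only.
* Genomes are stored as DNA (U→T on input); report tables print RNA.
* Report percentages are rounded half-up to one decimal (`round()`'s
  banker's rounding would print 92.4 where the accounting table says
  92.5).
* Fractional counts from equal splitting are carried as doubles through
  all tables; partition/conservation checks use a 1e-9 tolerance.
* Count thresholds are strict (`> 10`); dominance is strict (`> 50%`);
  co-expression is strict (`ratio < 2`).
* Ties: equal-cost placements within a hairpin resolve leftmost;
  cluster ordering is by scaffold then start; weighted modes (novel
  screen) break ties toward the smaller coordinate.

The bundled tests and the acceptance script run the recovery benchmark
at ~10,000 reads over 20 hairpins and the property suites on small
matrices (5×3) and locus sets (≤ 20) — sizes at which every oracle
(enumeration, brute-force UPGMA, transitive closure) is exact and the
whole suite completes in well under a minute.

## Known limitations

* The locus aligner is not a general-purpose read mapper; real
  libraries should be mapped genome-wide externally and imported as
  SAM.
* The surrogate folding energy is comparable only to itself; −20
  kcal/mol under RNAfold and under the surrogate are different scales
  (planted stems clear the threshold under both, by construction).
* A-to-I editing is reported only as the raw SNP class; no editing
  inference is attempted.
* Classification is hard (one label per read); no probabilistic
  ambiguity model.
* Differential expression is out of scope by design — with one library
  per life stage there is no replication to test against.
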