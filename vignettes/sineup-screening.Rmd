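---
title: "Screening for natural SINEUP antisense lncRNAs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for natural SINEUP antisense lncRNAs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sineupscreen)
```

## The biology being modelled

SINEUPs are natural antisense long non-coding RNAs that increase the
translation of their sense partner mRNA without changing its transcript
abundance. Their activity is modular and rests on two RNA domains:

* a **binding domain (BD)** — the region antisense-complementary to the
  sense mRNA around its translation-initiation site (TIS, the first ATG),
  which gives the lncRNA its target specificity; and
* an **effector domain (ED)** — an embedded transposable element of a SINE
  family (SINEB2 in mouse; Alu, FRAM or MIR elements in human) in
  *inverted* orientation relative to the transcript, which mediates the
  translational up-regulation.

Because this architecture is recognisable from annotation alone, candidate
natural SINEUPs can be screened for *in silico* among the genes that
respond to a perturbation — here, the knockdown of a chromatin regulator in
neural progenitor cells, where a dysregulated antisense lncRNA
(*RAB11B-AS1*-like architecture) is the canonical positive. `sineupscreen`
implements that screen, the domain annotation that follows it, the
deletion-mutant design used to validate the domains, and the expression
statistics used to characterise candidate pairs.

## The four-stage screen

Starting from a differential-expression (DEG) table, gene annotation (GTF)
and a RepeatMasker track, `run_screen()` composes four filters:

1. **lncRNA biotype** — DEGs whose gene biotype is in the configured lncRNA
   set. The default set `{lncRNA, antisense, lincRNA}` spans GENCODE
   releases, where the older `antisense`/`lincRNA` labels were later folded
   into `lncRNA`.
2. **Embedded inverted SINE element** — at least one transcript carries a
   repeat hit of an accepted family (default SINE/Alu, SINE/MIR, SINE/B2,
   SINE/B4) overlapping its exons by at least `min_exonic_nt` (default
   1 nt). *Inverted* is defined against the transcript strand, the
   convention of the SINEUP literature; a hit's genomic strand alone is
   never used. Purely intronic hits never count: the effector domain acts
   in the mature RNA. Inversion is required by default (`require_inverted`)
   since every functionally confirmed natural SINEUP carries an inverted
   element; the switch exists because a permissive variant of the screen is
   defensible when the inversion requirement cannot be established for an
   annotation.
3. **Antisense overlap** — the lncRNA gene exonically overlaps a
   protein-coding gene on the opposite strand by at least `min_overlap`
   (default 1 nt, i.e. any overlap) for at least one isoform pair. Exon
   sets, not gene spans, are intersected by default (`overlap_on`),
   because the downstream TIS stage is defined on exon coordinates; span
   overlap remains available for comparison.
4. **TIS overlap** — some lncRNA isoform's exons cover at least one base of
   the start codon of some coding isoform of the sense gene (so
   `tis_overlap_nt` is 1–3). When the annotation lacks explicit
   `start_codon` records, the codon is derived as the three 5′-most CDS
   bases in transcript orientation, including codons split across splice
   junctions.

Design choices that were genuinely open:

* **DEG status is required of the lncRNA only.** Sense genes are reported
  with whatever statistics they have (often `noreg`): the screen asks
  whether a *dysregulated antisense transcript* has SINEUP architecture,
  not whether its target also moved.
* **Isoform policy.** A gene passes a structural stage if *any* isoform
  (pair) passes, and the best-supporting isoform pair is recorded. Screens
  published at gene level rarely state isoform handling; "any isoform" is
  the most sensitive choice and the recorded pair keeps it auditable.
* **One output row per (lncRNA, sense) gene pair**, ordered
  lexicographically by gene ids so that reruns diff cleanly; per-stage
  survivor counts are part of the output contract.
* **Stage order is fixed** even though the predicates commute logically,
  so the stage counts are comparable between runs and datasets.

## Coordinate conventions

Internally every interval is a 1-based closed `IRanges` — the native
convention of the R genomics stack and of GTF itself. The alternative
(0-based half-open throughout, converting GTF on load) suits
Python-centric stacks; here it would have meant fighting the container
library at every call. Only lengths and overlap counts are contractual,
and those are convention-independent. BED export converts to 0-based at
the boundary, and the RepeatMasker reader maps its `C` (complement) strand
symbol to `-`.

Transcript ("spliced") coordinates are also 1-based closed, counted 5′→3′
along the mature RNA; on the minus strand position 1 is the exonic base
with the highest genomic coordinate. Deletion mutants are designed in
these coordinates because the cloned construct is the mature RNA.

## Domain annotation

`compute_binding_domain()` defines the BD as the **maximal contiguous run**
of the per-base exonic intersection of the two transcripts that contains at
least one start-codon base. The published BD of the canonical human
candidate is a single 96-nt region encompassing the TIS; a contiguous-run
definition makes that length well-defined, whereas "the whole scattered
intersection" would not be. If the codon is split across two runs the run
covering more codon bases wins (leftmost on a tie).

`compute_effector_domain()` merges genomically overlapping or *abutting*
hits (gap ≤ 0) into clusters — the human case is a FRAM monomer nested
inside an Alu hit, jointly 222 nt — and picks as ED the cluster nearest the
transcript 3′ end, reporting others as secondary. "Near the 3′ end" is
reported as a distance, never enforced: it is descriptive in the
literature. Both the raw union length (primary) and the exon-clipped
length are reported; they coincide for fully exonic elements.

## Expression statistics

* `delta_delta_cq()` implements 2^−ΔΔCq relative quantification: technical
  replicates are averaged **on the Cq scale** (standard ΔΔCq practice)
  before ΔCq against the reference gene (conventionally *NONO* for neural
  samples) and ΔΔCq against the calibrator sample. The calibrator comes
  out at exactly 1 by construction.
* `tissue_relative_matrix()` rescales each gene to its highest-expressing
  tissue (max-relative normalisation), the form used for tissue
  co-expression heatmaps.
* `pair_regression()` is ordinary least squares of one gene on another
  across samples, overall and per group, reporting slope, Pearson *R*,
  *R*² and the two-sided slope p-value. Both *R* and *R*² are emitted and
  labelled, since reports in this area mix the two. The companion
  `unpaired_ttest()` defaults to one-tailed, the convention for
  directional knockdown comparisons, with a two-sided switch.

## The synthetic-locus generator

`simulate_screen_fixture()` lays out one locus per requested pair along a
single contig, each in its own 3 kb window: a plus- or minus-strand coding
gene (600-nt exon, 280-nt CDS with annotated start codon) and an antisense
lncRNA with one exon across the TIS and one exon carrying the repeat.
Planted loci satisfy all four predicates; each **decoy class** flips
exactly one clause (`decoy_classes()`: absent from the DEG table, coding
biotype, wrong repeat family, non-inverted repeat, intronic repeat,
same-strand overlap, no overlap, overlap missing the codon) while passing
every earlier stage, so stage-level tests map one-to-one onto decoy
classes. Exon extents, repeat families/positions and locus orientation are
jittered under the seed; repeat records carry plausible Smith-Waterman
scores (300–3000) and divergences (5–25%) purely to exercise the parser.
Before returning, the generator re-runs the screen on its own output and
stops on any inconsistency, so the `truth` table is a verified contract.

`benchmark_screen_fixture()` plants the five published candidate pairs — with
their reported gene names, Ensembl ids, signed-linear fold changes and
p-values — among 30 decoys cycling through all eight classes. The
RAB11B-AS1 pair uses a fixed geometry whose BD is 96 nt and whose merged
FRAM-in-Alu effector cluster is 222 nt, mirroring the published locus;
`rab11b_like_locus()` exposes that single locus with a random genome
sequence for sequence-level work (the *sequence* is synthetic; only the
interval geometry mirrors the real locus).

`simulate_correlated_expression()` draws two gene rows from a bivariate
normal on the log-abundance scale at a target Pearson ρ.
`simulate_cq_table()` plants a linear fold change as a −log2(FC) shift of
the treated target Cq, with Gaussian cycle noise; the default noise of
0.2 cycles is a typical between-replicate SD for SYBR-green qPCR.

What the generator deliberately does **not** emulate: read-level RNA-seq
(the DEG table is an input, as in the original study), overdispersed count
noise, overlapping gene clusters on one locus, multi-isoform genes, and
realistic repeat sequence content. Passing tests therefore demonstrate the
correctness of the interval logic, the filter composition and the
statistical estimators under the stated noise models — not robustness to
annotation noise or mapping artefacts in real data.

## Problem sizes and numerical choices

The packaged checks run at desk scale by design: the benchmark fixture has
35 loci (70 genes); the monotone-filter property runs over 120 random
fixtures of up to 9 loci; oracle-equivalence fixtures hold 42 genes (under
the 50-gene cap at which exhaustive per-base enumeration stays exact);
ΔΔCq recovery uses 100 simulations at 0.2-cycle noise; correlation
recovery uses 500 draws of n = 500 samples per target ρ, judged against
the 3·(1−ρ²)/√n large-sample band. Ties in isoform-pair support are broken
lexicographically by transcript id; equality of floating-point Cq
arithmetic is exact where the algebra is exact (calibrator = 1, noise-free
recovery). Degenerate inputs error early and explicitly: non-coding sense
transcripts, zero-variance regression predictors, deletion intervals out
of range, intronic intervals in coordinate mapping.

## Known limitations

* The screen trusts its annotation: unannotated TISs, retained introns or
  mis-annotated biotypes propagate directly (the published screen itself
  confirmed TIS overlaps against a second annotation release).
* Candidate counts from poly-A-selected DEG inputs are a lower bound, as
  non-polyadenylated lncRNAs are under-sampled upstream of the screen.
* `2^−ΔΔCq` assumes perfect doubling per cycle; amplification-efficiency
  correction is out of scope.
* Orthology-based confirmation (e.g. a mouse locus with an inverted
  SINEB2) is out of scope; the accepted-family default merely keeps such
  loci screenable.
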