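---
title: "Methods: annotating and analysing Pin-II proteinase-inhibitor repeat domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating and analysing Pin-II proteinase-inhibitor repeat domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irdkit)
```

## The biological model

Pin-II type serine proteinase inhibitors of Solanaceae — in *Capsicum
annuum*, the CanPI gene family — are secreted precursors built from tandem
repeats of a ~50-residue **inhibitory repeat domain (IRD)** behind a
25-residue ER signal peptide (SP), with short linker peptides between
repeats. Each IRD carries eight conserved cysteines (four disulfides) and
one protease reactive site, a pentapeptide `C-[P/T]-P1-X-C` whose central
**P1 residue** sets specificity: Lys or Arg means a trypsin-inhibitory (TI)
domain, Leu or Pro a chymotrypsin-inhibitory (CI) domain. Endogenous
proteases cleave precursors at the linkers, releasing single-IRD peptides of
roughly 5.5–6.3 kDa that are visible as linear-mode MALDI peaks.

`irdkit` implements the computational side of a clone-library induction
study on this family: domain annotation, unique-domain and signal-peptide
cataloging, per-treatment clone-abundance statistics, processed-peptide mass
prediction and peak assignment, p-distance/UPGMA clustering, and a
synthetic-data generator that provides ground truth for all of it.

## Domain annotation

Annotation decomposes a precursor into SP + (linker + IRD)\* + linker
segments with 0-based, half-open coordinates throughout.

1. **Signal peptide.** The family's ER signal peptide is uniformly 25
   residues, so the SP is the fixed 25-residue prefix (`sp_length`,
   configurable). A precursor flagged partial and shorter than that is
   scanned whole, with the SP reported absent. No predictor is run; the
   fixed prefix removes an external-tool dependency and matches the
   family-wide SP length.
2. **Anchors.** Every occurrence of the reactive-site pattern
   `C[PT]..C` in the mature region — including overlapping occurrences — is
   a candidate anchor. The anchor cysteine is cysteine 2 of the scaffold;
   the motif's closing cysteine is cysteine 3.
3. **Scaffold growth.** From each anchor the eight-cysteine scaffold is
   grown over a spacing template (`ird_template()`: cysteine offsets
   3, 7, 11, 20, 25, 33, 39, 44 in the canonical 50-residue repeat, head of
   3 residues before cysteine 1, tail of 5 after cysteine 8). Each next
   cysteine is sought within the template gap ± a walk tolerance; a
   candidate that cannot complete the scaffold is discarded, which is what
   rejects chance `C[PT]..C` matches in linkers or loops. If the template
   runs off the sequence end mid-walk the domain is kept and flagged
   `is_partial`.
4. **Boundaries.** Domain boundaries are template constants around the
   scaffold: `start = cys1 − head`, `end = cys8 + tail + 1`. We considered
   splitting the inter-scaffold spacer at its midpoint instead, but that
   makes the extracted sequence of one and the same repeat depend on its
   neighbours, which would break exact-identity cataloging (identical
   repeats in different genes would no longer dedup) and exact recovery of
   generator coordinates; fixed head/tail constants keep the segmentation a
   function of the domain alone.
5. **Overlaps and leftovers.** Overlapping accepted candidates are resolved
   greedily left to right by anchor position (leftmost wins — deterministic
   and order-independent). All residues not in the SP or a domain become
   linkers, so the segments always concatenate back to the input exactly.

Two tolerances are involved. The **reporting tolerance** (default ±2
residues on each inter-cysteine gap) defines `scaffold_deviation`, the
cysteine-variant flag; it is also what `cysteine_profile()` uses. The
**walk tolerance** is the reporting tolerance +2: a point substitution that
creates a decoy cysteine near an expected position can displace one found
cysteine by up to the reporting tolerance, and the wider search window lets
the walk re-attach to the true scaffold afterwards instead of losing the
whole domain. `X` residues are accepted in input but never match cysteine
and never receive a P1 class.

Known limitation: a domain genuinely missing one of cysteines 4–8 (a real
cysteine-loss variant) fails the scaffold walk and is not annotated as a
domain; the walk requires the full chain precisely so that chance motifs do
not produce false domains. Cysteine variants *are* representable in
annotated output through the deviation flag when the count differs inside
recovered boundaries (e.g. extra cysteines, or truncated trailing repeats).

## Catalogs and clone-library statistics

Unique IRDs and SPs are deduplicated by **exact amino-acid identity** —
single-residue variants count as distinct domains, which is how "unique
IRDs" are counted in this family — with opaque integer labels in
first-occurrence order.

The clone-count table is a genes × treatments matrix with an expected
sequencing depth per treatment (60 clones per induced library; 25 for
uninduced leaves). `validate_table()` compares column sums against these
depths and flags shortfalls without raising: published tables of this kind
can tabulate fewer resolved clones than were sequenced. Percentages in
`class_abundance()` therefore divide by the sequencing depth, not the
column sum — that is the convention under which 23 of 60 clones prints as
38% — and fall back to the observed sum when no depth is recorded.
Percentages are rounded half-up to integers. Blank cells in the packaged
table are zero counts, not missing data.

In the packaged 47-gene table, two genes end in a partial trailing domain
(marked `p`); the marker counts toward the domain number but contributes no
label, which reproduces the published 9/20/15/3 split of 4/3/2/1-domain
genes.

The expression partition (`shared_unique_partition()`) is computed over the
three induced treatments only, with "expressed" meaning clone count > 0;
"unique" means present in exactly one induced treatment. Domain frequency
(`ird_frequency()`) counts clone-weighted multiplicity: a label occurring
twice in a clone's composition counts twice.

## Processed-peptide masses and peak assignment

`average_mass()` sums average residue masses plus one water and subtracts
2 × 1.008 Da per disulfide. The residue table is derived from the standard
residue elemental compositions with IUPAC atomic weights (C 12.011,
H 1.008, N 14.007, O 15.999, S 32.06); average masses are the right scale
for linear-mode MALDI of ~6 kDa peptides, and monoisotopic masses are
available behind a flag. Candidates are enumerated per annotated domain
with 0..`max_flank` linker residues borrowed on each side (bounded by the
residues actually available), deduplicated by sequence, and stored with
both oxidized (all scaffold disulfides formed, the default for matching)
and reduced masses. Peaks are treated as neutral masses with a
±3 Da default tolerance chosen from the spacing of typical single-IRD peak
sets; a proton-offset flag (−1.007 Da) reinterprets them as [M+H]+, since
published peak lists often do not say which they are. Assignment is
nearest-candidate within tolerance, ties to the smaller candidate mass.

## Distances and clustering

`p_distance()` aligns two sequences globally under unit edit costs
(match 0, mismatch 1, gap 1) and reports differing columns / alignment
length. Among co-optimal alignments the shortest is used — substitutions
preferred over indel pairs, the alignment a diagonal-preferring traceback
produces — making the statistic deterministic; the dynamic program
(in C++) minimises (cost, length) lexicographically, so no traceback is
materialised. `pairwise_matrix()` reports the mean off-diagonal distance,
the set's "average variance" when read as a percentage.

`upgma()` is standard average-linkage agglomeration with Lance–Williams
updates and ultrametric heights (half the merge distance). Ties at the
minimum are broken by the lexicographically smallest sorted pair of cluster
representative (minimum leaf) labels, so the topology is independent of
input order. The tests verify it against a naive reference that recomputes
every cluster distance from scratch from leaf pairs, and against
`phangorn::upgma` on tie-free matrices. This is a style-level
reconstruction of the family's published dendrogram analysis: the original
was produced with a commercial package whose algorithm is not stated, so
topology-exact reproduction is out of scope, as is model-based
phylogenetics.

## The synthetic generator

The generator's defaults are the study conditions of the clone-library
analysis: a pool of 28 unique domains with 21 TI (`ti_fraction = 21/28`),
reactive-site motifs drawn from the six observed pentapeptides
(TI: CPRNC, CPKNC, CPRYC, CPRDC; CI: CTLNC, CTPNC); 47 genes with 1–4
domains in the observed 3/15/20/9 ratio; ten signal-peptide variants;
sequencing depths of 25 (uninduced) and 60 (each induced treatment).
Values the study does not fix were chosen once as field-plausible:
linkers of 5–8 residues, domain length 50 ± 4 (jitter split over the two
long inter-cysteine loops, at most the spacing tolerance per loop, so clean
domains are never flagged deviant), Gaussian peak noise of σ = 1 Da
(a third of the matching tolerance), 8 peaks per list, and skewed
per-treatment clone proportions drawn gamma(0.8)-normalised
(Dirichlet-type), mimicking libraries dominated by a few genes.

Background residues are uniform over the 19 non-cysteine letters rather
than all 20: the eight-cysteine scaffold is placed explicitly, and a
random extra cysteine would turn a nominally clean domain into a scaffold
variant. For the same reason the position after cysteine 1 avoids P/T
(cysteines 1 and 2 are also four apart, so a P/T there would duplicate the
reactive-site motif within the domain), and linkers carry no cysteines.
Optional per-instance mutation (default rate 0, so genes are exact mosaics
of the pool) is position-weighted toward the reactive-site loop and the
C-terminal end — where real domain variation concentrates — and never
touches scaffold cysteines or the reactive-site pentapeptide.

One integer seed drives everything; each stage (pool, precursors, clone
table, peaks) derives its own stream from it, and the caller's RNG state is
restored afterwards.

What passing synthetic tests do **not** show: real precursors have
non-uniform residue composition, homologous (not independent) domains,
cysteine-variant domains, and linkers that resemble each other; mean
pairwise distances between synthetic genes are therefore far larger than
between real family members, and annotation performance on the generator is
an upper bound, not an estimate, of performance on real data.

```{r example}
cfg <- synth_config(seed = 42, n_genes = 6)
ds <- generate_dataset(cfg)
ann <- annotate_precursor(ds$sim$precursors[[1]])
ann
head(annotation_table(ann))
```

## Problem sizes and determinism

The test-suite and acceptance-script workloads are sized for quick
desk-scale runs while keeping estimates stable: 100 random architectures
for exact round-trip recovery; 20 seeded libraries (47 genes each) for
full-pipeline parameter recovery; 25 libraries × 10 peaks for the noisy
peak re-matching rate (the rate is a ratio near its 95% bound, so it is
estimated over 250 peaks); 1000 random peptides against the
elemental-composition mass oracle; 30 random matrices up to size 6 against
the brute-force UPGMA reference. Every stochastic step is seeded, so all
reported numbers are reproducible.
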