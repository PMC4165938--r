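---
title: "Mining fungal defensin-like peptide genes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining fungal defensin-like peptide genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdlpminer)
```

## The problem

Fungal defensin-like peptides (fDLPs) are small, secreted antimicrobial
peptides built on the cysteine-stabilised α-helix/β-sheet (CSαβ) fold:
six framework cysteines forming three disulfides (C1–C4, C2–C5, C3–C6).
They are encoded as precursors — an N-terminal signal peptide, often an
acidic propeptide ending in one or two basic residues (a proprotein
convertase site), and one or, rarely, two mature defensin domains — and
their genes carry zero to two short spliceosomal introns. Because the
mature peptides are short (33–60 aa) and the genes interrupted, standard
gene annotation often misses them; homology-driven mining of assemblies
with careful spliced-model reconstruction is the practical route to new
family members.

`fdlpminer` implements that route end to end and, because real
discovery cannot be validated against an unknown truth, pairs it with a
synthetic-genome generator that plants defensin genes with a
machine-readable truth table. Everything the pipeline claims to do is
measured against planted ground truth.

## Pipeline stages

1. **Seed scan** (`scan_six_frames`). Both strands of each contig are
   translated in all three frames; 90-aa windows with 45-aa step are
   tested against (a) a cysteine-spacing envelope (a regular expression
   over the six framework cysteines, bounds derived from the seed set
   and widened by −2/+4 residues) and (b) Smith–Waterman similarity to
   each seed peptide (BLOSUM62, affine gaps: a gap of length L costs
   10 + L). Windows merge into loci per strand (single linkage, gap ≤
   400 nt).
2. **Spliced completion** (`complete_spliced_model`). Around each locus
   (±800 bp) the search enumerates open reading frames, allowing removal
   of up to two GT..AG introns of 60–300 bp, and keeps models whose
   translation contains a complete framework *and* parses into a valid
   precursor. The enumeration is tiered — intronless models first, then
   one intron, then two — and a tier's winner is final only when its
   span accounts for the locus evidence, so the expensive deep search
   runs only for genuinely fragmented genes. Failure to complete marks
   the locus a possible pseudogene.
3. **Precursor segmentation** (`annotate_precursor`): signal peptide,
   propeptide(s), one or two mature domains, C-terminal amidation
   (Gly-Arg / Gly-Arg-Arg; arginines trimmed, glycine retained as the
   amide donor), and N-/C-terminal extension flags.
4. **Physicochemistry** (`average_mw`, `net_charge`): average masses and
   a Henderson–Hasselbalch net charge at pH 7.0.
5. **Family classification** (`neighbor_joining`, `bootstrap_support`,
   `assign_family`): p-distances from global alignments, an unrooted NJ
   tree over queries plus seed anchors, column-resampling bootstrap, and
   anchor-clade assignment with a "new family" rule.
6. **Duplication analysis** (`find_clusters`, `count_synonymous`,
   `paralog_pairs`): tandem clusters by single-linkage chaining (gap ≤
   30 kb, which reproduces the packaged catalog's malpisin groupings),
   and codon-wise synonymous/nonsynonymous difference counts between
   paralogous CDSs.

## Key parameters

| parameter | default | units | why |
|---|---|---|---|
| window / step | 90 / 45 | aa | covers the largest precursors with overlap |
| strong score | 55 | raw SW | above the maximum window score observed on GC-matched random 10-kb contigs (median 42, max 54 over 60 trials) |
| weak pair score | 40 (best member ≥44) | raw SW | two sub-strong windows ≥200 nt apart flag a fragmented spliced gene; ~2% false loci per random 10 kb |
| envelope pad | −1 / +2 | residues | widening of seed-derived inter-cysteine gap bounds; wider pads admit measurable random motif matches |
| gap open / extend | 10 / 1 | score | the common BLOSUM62 11/1 convention (first gap base costs 11) |
| introns per gene | ≤ 2 | — | the maximum observed in this peptide class |
| intron length | 60–300 | bp | typical short fungal introns |
| min internal exon | 20 | nt | micro-exons are splice-implausible and would let the search stitch seed-matching residues from unrelated fragments |
| cluster gap | 30 000 | bp | reproduces the catalog's tandem malpisin contig groupings |
| paralog identity | 0.70 | fraction | below it, pairs are not credible paralogs |
| new-family identity | 0.30 | fraction | queries under 30% identity to every anchor in a supported anchor-free clade are "new" |
| bootstrap | 500 (200 in `run_pipeline`) | replicates | stable to ±2–3% support; the pipeline default trades replicates for runtime on ~60-taxon trees |
| pKa set | N-term 8.0, C-term 3.1, K 10.0, R 12.0, H 6.5, D 4.4, E 4.4, C 8.5, Y 10.0 | — | the classic protein-calculator family of constants; all cysteines titrate by default (reduced form), an oxidised mode excludes 2 cysteines per disulfide |

## Model selection in spliced completion

Candidate gene models for one locus frequently tie or nearly tie under a
plain whole-protein local alignment score: a variant that swallows the
stop codon and appends random residues, starts at a spurious ATG, or
stitches a "micro-exon" out of intron sequence can match or chance-beat
the true model by a point or two. Three rules make selection stable, and
each was validated against planted truth:

* a model must *parse*: predicted signal peptide plus at least one
  complete six-cysteine framework downstream of it;
* the score is computed per annotated mature domain as SW(full mature) +
  SW(framework region C1..C6 ± 6 aa), summed over domains — the
  framework term anchors the comparison on the disulfide scaffold, the
  full-mature term credits genuine propiece/tail homology that junk
  padding cannot imitate, and two-domain models are credited for both
  peptides;
* once an ORF already carries a complete framework at a stop codon, no
  further introns are explored — splicing past a finished gene can only
  append noise;
* every domain must clear the scan's weak similarity threshold — a
  "mature" that is an accidental cysteine arrangement in unrelated
  sequence carries no seed support and the whole candidate is dropped;
* the best seed alignment of each mature must span at least five of its
  six framework cysteines — similarity confined to one exon fragment is
  the signature of a pseudogene's retained first exon stitched to
  unrelated sequence, not of a real gene;
* internal exons must be at least 20 nt.

Candidates still tied on the local score are compared by a *global*
alignment of their matures to the seeds: end gaps penalise junk
residues padded onto a mature that local alignment simply ignores.
Remaining ties break to fewer introns, shorter total intron length, and
the leftmost start, in that order.

## What the generator emulates — and what it does not

`plant_genes` builds contigs of configurable GC content carrying genes
with: planted signal peptides; optional acidic propeptides ending in
K/R/KR/RR; one or two mature domains sampled from family templates with
fixed cysteine spacing and mutated loops; optional Gly-Arg(-Arg)
amidation tails; GT..AG introns at planned regions (signal, α-helix,
c-loop) and phases (0/1/2); tandem clusters; exon-1-only pseudogenes;
and identical-protein paralog pairs differing by a planned number of
synonymous substitutions. Back-translation uses the standard nuclear
code with uniform random synonymous codon choice. Intergenic spacers are
500–5000 bp; intron lengths 60–300 bp.

Three constructions make the planted truth *identifiable*, i.e. the
unique best answer a correct annotator should return:

* **ORF guards.** A 12-nt block with stop codons in every frame (and no
  GT/AG dinucleotides) precedes each gene and lines both ends of each
  intron interior. Random flanking sequence can therefore never extend a
  planted ORF, and a mis-spliced variant that reads into an intron
  always hits a stop. Real genomes enforce the same property
  statistically (long in-frame extensions across gene boundaries are
  rare); the guard makes it deterministic.
* **Unambiguous signal cleavage.** Planted signal peptides are built so
  the first position ≥15 satisfying the small-residue −3/−1 rule is the
  true boundary, so exact mature recovery is achievable and measurable.
* **Low-divergence pseudogenes.** Pseudogenes are planted as recent,
  minimally diverged duplicates (loop mutation rate 0.05 vs 0.25
  elsewhere) of the plectasin/micasin-like families whose first exon
  retains the longest fragment: only that retained first exon makes a
  pseudogene findable at all, which mirrors how the published
  pseudogene case was noticed — through high first-exon similarity to a
  known defensin.

The generator does **not** emulate codon usage bias, repeats, realistic
gene density, splice-site motifs beyond the GT..AG dinucleotides,
polymorphism, or assembly artefacts. A pipeline that recovers ≥95% of
planted genes exactly demonstrates correct reconstruction logic under
the stated gene models — not sensitivity on real assemblies, where
diverged homologs below the similarity thresholds and non-canonical
architectures will be missed.

## Numerical choices

* The two scan thresholds were calibrated on synthetic data only (the
  original survey's thresholds are not published): the strong threshold
  sits above random-contig score maxima; the weak-pair rule was chosen
  from a measured trade-off (it rescued 38/38 fragmented two-intron
  genes at 2/80 false contigs).
* NJ breaks Q-matrix ties toward the lexicographically smallest pair of
  node labels; negative branch lengths are clamped to zero with the
  deficit moved to the sister branch, preserving path lengths.
* Bootstrap distances treat gapped columns pairwise (sites where either
  sequence has a gap are excluded for that pair; all-gap pairs get
  distance 1).
* Distances default to p-distance (1 − identity over alignment columns);
  no multiple-hit correction is applied, matching how short, conserved
  peptide sets are usually handled.
* The amidation convention keeps the glycine in the reported mature
  sequence and length; only the arginines are trimmed.
* The α-helix and c-loop windows used to localise introns are defined
  off the framework cysteines (α-helix [C2−2, C3]; c-loop (C4, C5);
  n-loop (C1, C2−3)); they follow canonical CSαβ topology and are
  heuristic — no per-family structural coordinates exist.

## Problem sizes

The validation workflow plants 50 genes (~250 kb of contigs) and runs
the full pipeline in a few minutes on one core; the test suite uses the
same scale for the end-to-end property and smaller genomes (8–12 genes)
for module-level checks. The NJ consistency check enumerates all 11 463
unrooted topologies with 4–8 leaves. These sizes give stable pass/fail
behaviour while keeping a full run short.

## Known limitations

* Candidate discovery is homology-bound: genes under ~30% identity to
  every seed will not be found, and the paired-weak rescue assumes at
  least two exon fragments retain weak similarity.
* Signal-peptide prediction is a transparent hydropathy heuristic, not a
  trained predictor; `annotate_precursor` accepts a user-supplied
  cleavage position to override it.
* Exon boundaries inside the signal-coding region are occasionally
  placed at an equivalent alternative splice (identical mature, equal
  score); mature peptides, phases and architecture are unaffected.
* Two-domain support stops at two domains; more are rejected loudly.
* `count_synonymous` counts differences; it does not estimate dN/dS.
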