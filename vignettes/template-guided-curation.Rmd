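---
title: "Template-guided curation of ortholog gene models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-guided curation of ortholog gene models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gstcurate)
```

## The problem

Automated gene prediction on draft genomes mis-annotates a substantial
fraction of gene-family members: translation starts are placed at the wrong
ATG, real exons are labelled intron (and vice versa), low-coverage
assemblies carry unresolved N runs and apparent single-nucleotide indels,
and decayed paralogs masquerade as genes. When a closely related,
well-curated reference species exists, each of these defects can be
diagnosed and usually repaired by comparing the candidate gene model with
its reference ("template") ortholog. The insect glutathione transferase
(GST) superfamily — six classes (Delta, Epsilon, Omega, Theta, Sigma, Zeta)
laid out in tandem clusters, coding sequences of roughly 600–800 nt — is
the motivating case: one well-annotated species serves as the template for
eleven draft-quality relatives.

`gstcurate` implements that comparison as an automated, testable pipeline:
model the genomes, align candidate against template, propose the minimal
structural or nucleotide-level corrections, classify every gene, project
alternative-splicing structures, compare gene order, and build distance
trees of the curated proteins. Because the original genome downloads are
out of scope, the package ships a deterministic synthetic-genome generator
with a ground-truth defect ledger, so every stage is exercised end-to-end
offline.

## Coordinate and translation conventions

All intervals are 0-based half-open on the forward strand; GFF3 I/O
converts to and from the 1-based inclusive convention at the border. Exons
of minus-strand transcripts are stored ascending and traversed descending
at extraction.

A coding sequence (CDS) *includes* its terminal stop codon, which is
*excluded* from the protein length: a CDS of $L$ nt encodes $L/3-1$
residues. This is the only convention consistent with all six worked
bp-to-aa pairs in the motivating study (669→222, 651→216, 636→211,
744→247, 663→220, 714→237); the one published pair it contradicts
(864 bp / "288 aa") is internally inconsistent by exactly one codon.
Translation uses the standard genetic code only; codons containing N
translate to `X` rather than failing, so assembly gaps flow through to the
sequencing-error classifier instead of aborting the run.

## Alignment machinery

Two scoring presets cover the two jobs:

* **curation** — BLOSUM62, affine gaps (open 11, extend 1). Sensitive
  ortholog comparison; used for all identity and score computations during
  curation.
* **tree** — BLOSUM62, linear gap penalty 1. The published tree
  settings, unusual but explicit; used only for distance matrices.

The global aligner is a Gotoh affine-gap Needleman–Wunsch in C++ with a
deterministic traceback (diagonal over up over left) and, internally, a
canonical argument order so that score, match counts and identity are
exactly invariant under swapping the two sequences — co-optimal tracebacks
would otherwise make identity order-dependent. It is cross-checked in the
test suite against `Biostrings::pairwiseAlignment` on random pairs and
against exhaustive enumeration of all alignments of short sequences.

Percent identity is reported over *mutually aligned columns* (both
residues non-gap). The source study never defines its convention; mutual
columns is reproducible and gap-robust, and match counts are reported
alongside so alternative conventions can be recomputed. One consequence
matters for design: mutual-column identity is blind to truncation, so
candidate corrected models are ranked primarily by alignment *score*, with
identity, shift size and edit counts as tie-breakers. That deviates from a
pure identity ranking deliberately — the annotated, N-terminally truncated
model in the worked start-rescue cases ties the true model on identity and
only the score separates them.

The codon-aware aligner (`codon_align`) is a dynamic program over
(nucleotides consumed, template residues consumed) whose transitions are
codon match/mismatch, whole-codon gaps, and ±1/±2 nt frameshifts at a
penalty (default twice the gap-open). Premature stops and frameshifts are
reported in DNA coordinates; trailing DNA (the terminal stop codon, or a
frameshifted remainder) is consumed free.

## The curation decision procedure

`curate_gene` applies a fixed precedence, mirroring the way a human
curator triages:

1. **Sequencing gaps.** Runs of ≥5 N overlapping the projected CDS give
   `SEQUENCING_ERROR` — the gene needs re-sequencing, whatever else is
   wrong with it.
2. **Structural re-annotation.** Start-site rescue enumerates in-frame ATG
   codons within 300 nt upstream (the largest published case is 255 nt)
   and downstream within exon 1; exon reassignment searches edit sets of
   size ≤ 2 drawn from drop-exon, merge-across-intron and extend-terminal-
   exon-to-next-stop. A candidate is accepted as `ANNOTATION_ERROR` only
   when it (a) uses at least one edit, (b) yields a stop-free in-frame ORF
   whose length is within ±5% of the template, and (c) strictly improves
   the alignment score. The length band is what keeps a frameshifted gene
   from being "repaired" by merging an intron whose length happens to
   restore frame.
3. **Virtual nucleotide edits.** At most `k_max = 2` single-nt virtual
   insertions/deletions, placed from the codon-aligner's frameshift
   events, give `AMBIGUOUS_INDEL`. The DP localizes a shift only to within
   about a codon, and a misplaced edit can forge a local stop codon, so
   all in-window offsets are tried and the best stop-free outcome kept.
   The category is deliberately distinct from `SEQUENCING_ERROR`: without
   coverage information one cannot distinguish a real indel mutation from
   a sequencing error, and the verdict says so.
4. **Pseudogene check.** A gene whose best *justified* stop-free ORF is
   shorter than 70% of the template (`length_frac`, chosen because the
   published pseudogenes range from ~25% to ~75% of template length while
   every corrected gene restores ~100%), or whose catalytic anchor
   residues fall in unaligned or deleted regions, is a `PSEUDOGENE`.
   "Justified" matters: a drop-exon candidate that merely excises a
   premature stop, or virtual edits that failed the correctability test,
   do not count as restorations.
5. Otherwise `ORTHOLOG_OK`. Identity is always reported; orthology above
   an identity floor (default 40%) is left to the caller, since the study
   treats values from ~54% to 100% as meaningful without a hard cutoff.

On corrected verdicts the reported identity can tick *down* by up to the
divergence noise (≤5 points) even though the correction is right, because
the restored residues carry their own mismatches; at 0% divergence the
increase is strict. The verdict invariant is therefore
`identity_after ≥ identity_before − 5` in general and strict at zero
divergence.

## Splice transfer

`project_isoforms` anchors every distinct template exon once in the target
locus by pattern-global/subject-local nucleotide alignment (so shared
exons get identical projected coordinates in all isoforms), infers introns
between anchors, and calls an isoform supported when all its exons anchor
at ≥60% nucleotide identity in consistent order, introns reach 40 nt, and
the spliced ORF is stop-free. Non-GT..AG boundaries demote support to
"weak" rather than rejecting — the study reports conserved intron-exon
boundaries, not splice-site sequences, and a 2-nt difference should not
erase an isoform. UTR intervals are scored (not discovered) by aligning
the template UTR against the anchored flank; identities under 55% are
flagged unconserved. Isoform-specific first exons (the Z2/T3/D11-like
pattern) and alternative terminal exons (the O2-like pattern) are both
generated and both projected; a variant that shares its whole CDS and
differs only in the 5′UTR is supportable only provisionally, since targets
carry no UTR annotation.

## Micro-synteny

Gene maps are ordered, stranded, ortholog-labeled lists. Labels
single-copy in both maps define a signed permutation (sign = strand
agreement); duplicated labels are excluded and surfaced as `DUPLICATION`
candidates, because a 1-1 order comparison is undefined for them, and
labels split across target scaffolds become `SCAFFOLD_SPLIT` events rather
than cross-scaffold "inversions" — fragmented assemblies must not
masquerade as rearrangements. The breakpoint distance counts
non-conserved signed adjacencies including both caps; it is 0 exactly for
the identity permutation. With linear caps that "zero iff identity"
property and exact invariance under whole-sequence reversal-with-sign-flip
cannot hold simultaneously; the package keeps the former, and the flip can
change only the two cap terms. Inversions are maximal descending uniformly
negative runs (exact recovery for single-block injections); transposition
calling is explicitly a greedy heuristic — remove a block whose absence
lowers the breakpoint count by ≥2 and which re-inserts contiguously — and
is documented, and tested, at ≥90% recovery rather than exactness.

## Trees

Distances are Jukes–Cantor-corrected mismatch fractions,
$d = -\frac{k-1}{k}\,\ln(1 - \frac{k\,p}{k-1})$, from pairwise alignments
under the tree preset; the alphabet size is a parameter (default
k = 20 for proteins) because the published tool's protein variant is
unspecified. Neighbor-joining is the Saitou–Nei algorithm with the
Q-criterion, deterministic lexicographic tie-breaks and negative branch
lengths clamped to zero (flagged); it recovers additive matrices exactly,
which the suite verifies on random trees, and is cross-checked against an
independent implementation (`ape::nj`). The source study mentions a
"parsimony tree" once in passing but its methods describe
neighbor-joining operationally; the package implements the methods
description.

## The synthetic world

The generator's defaults state the study world: six classes in tandem
clusters (one scaffold per class), CDS lengths uniform in 600–800 nt,
1–6 exons of ≥60 nt, GT..AG introns of 60–120 nt, intergenic spacers of
200–500 nt, a planted Ser-His-Ala-Ile catalytic anchor at residues 60–63,
and four spliced genes patterned on the family's isoform structures.
Values the study does not state (intron, spacer and exon minima) were
chosen once at realistic Drosophila scales and are not tuned.

Divergence simulation applies per-site substitutions with
Jukes–Cantor-symmetric replacement under purifying selection: proposed
substitutions that would create an internal in-frame stop, destroy the
start or terminal stop, or break a splice dinucleotide are rejected.
Without this, neutral 5% divergence would put roughly one premature stop
in every 700-nt CDS and a "defect-free ortholog" panel could not exist;
with it, the realized genome-wide mismatch rate still lands within
binomial noise of the requested rate because rejections touch only ~4% of
coding sites. There is no background indel mutation — indels exist only as
injected, ledgered defects — which keeps the ground truth unambiguous.

Each injected defect changes exactly what its ledger entry records:
annotation shifts for start errors and exon/intron misassignments,
sequence edits for indels, stops and N runs. Truncation scrambles the 3′
tail *and* places one in-frame stop just after the breakpoint: a purely
random tail would leave ~10% of truncated genes re-extendable past the
pseudogene threshold, a property of the tail lottery rather than of the
curation method. What a green panel does establish: category recovery
under clean, single-defect, coverage-uniform conditions at stated
divergence. What it does not: performance on real assemblies with
compound defects, background indels, paralog interference within clusters,
or non-uniform coverage.

## Reproducibility and limits

Every generator output is a pure function of (spec, seed); pipeline runs
rerun byte-identically, and reports carry a config hash. Known
limitations: transposition calling is heuristic, not minimal-distance;
orthology assignment above the identity floor is left to the caller; UTR
boundaries are scored, never discovered; the curation search is bounded
(two structural edits, two virtual nucleotide edits) and will hand a
sufficiently compound defect to the pseudogene stage rather than repair
it.

```{r example, eval = FALSE}
# the five-minute tour
panel <- build_panel(n_genes = 60, sub_rate = 0.05, seed = 11)
report <- curate_panel(panel$target$genome, panel$target$models,
                       panel$template$proteins, panel$template$anchors)
table(truth = truth_ledger(panel$target)$expected_category,
      called = report$category)
```
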