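# gstcurate

Template-guided curation of ortholog gene models in multi-species gene
families, with the insect glutathione transferase (GST) superfamily across
the twelve sequenced *Drosophila* genomes as the motivating case.

Automated gene prediction on draft genomes gets a lot wrong: translation
starts at the wrong ATG, exons annotated as introns and vice versa,
unresolved N runs, apparent single-nucleotide indels in low-coverage
assemblies, and decayed paralogs annotated as genes. When one well-curated
reference species exists, each defect can be diagnosed by comparing the
candidate model with its reference ("template") ortholog. `gstcurate`
automates that comparison end-to-end:

* **Curation** — start-site rescue (in-frame ATG search up/downstream),
  exon/intron reassignment (bounded search over drop / merge / extend
  edits), N-run detection, codon-aware frameshift-indel detection with
  virtual single-nucleotide edits, and pseudogene calling against template
  length and catalytic anchors. Every gene gets a verdict: `ORTHOLOG_OK`,
  `ANNOTATION_ERROR`, `SEQUENCING_ERROR`, `AMBIGUOUS_INDEL` or
  `PSEUDOGENE`, with identities before and after correction.
* **Splice transfer** — projection of a template gene's isoform structures
  (exon chains, shared/unique exons, UTR intervals) onto orthologous loci,
  with per-isoform support calls.
* **Micro-synteny** — signed-permutation gene maps: breakpoint distance,
  exact inversion-block detection, greedy transposition calling,
  duplication and scaffold-split reporting.
* **Trees** — BLOSUM62 pairwise alignments (linear gap penalty 1),
  Jukes-Cantor distances, $d = -\frac{k-1}{k}\ln(1-\frac{kp}{k-1})$, and a
  deterministic Saitou-Nei neighbor-joining implementation that recovers
  additive matrices exactly; Newick output via `ape`.
* **Synthetic data** — a deterministic generator for clustered multi-class
  gene families (CDS 600-800 nt, the usual GST gene length), divergence
  simulation under purifying selection, and injection of every defect and
  rearrangement class with a ground-truth ledger, so the whole pipeline is
  testable offline.

The key length convention, fixed by the published worked examples: a CDS
*includes* its terminal stop codon, which is *excluded* from the protein
length, so an *L*-nt CDS encodes *L*/3 − 1 residues.

## Worked example

Curate a 60-gene synthetic panel at 5% nucleotide divergence, one injected
defect per gene:

```r
library(gstcurate)
panel  <- build_panel(n_genes = 60, sub_rate = 0.05, seed = 11)
report <- curate_panel(panel$target$genome, panel$target$models,
                       panel$template$proteins, panel$template$anchors)
table(truth = truth_ledger(panel$target)$expected_category,
      called = report$category)
```

```
                  called
truth              AMBIGUOUS_INDEL ANNOTATION_ERROR PSEUDOGENE SEQUENCING_ERROR
  AMBIGUOUS_INDEL               14                0          0                0
  ANNOTATION_ERROR               0               28          0                0
  PSEUDOGENE                     0                0         12                0
  SEQUENCING_ERROR               0                0          0                6
```

Every injected defect lands in its true category: frameshift indels are
repaired by a single virtual nucleotide edit, start shifts and spurious
exons by structural re-annotation, truncations and premature stops are
called pseudogenes, and N runs take precedence as sequencing errors.

The classic single-gene case — a six-exon model whose annotated exons 2
and 3 are actually intron sequence:

```r
fx <- exon_shadow_fixture(true_cds_nt = 714, n_true_exons = 4,
                          fake_nt = c(78, 75), seed = 5)
v  <- curate_gene(fx$genome, fx$model, fx$template_protein)
v
#> <curation_verdict> fixture_gene: ANNOTATION_ERROR/EXON_IS_INTRON  identity 100.0% -> 100.0%
```

The annotated model translates to 288 aa; dropping the two spurious exons
restores a 714-nt CDS encoding 237 aa at 100% identity to the template.

## Analysis workflow

The `analysis/` directory holds the narrative drivers, each writing its
tables under `results/`:

1. `01_simulate.R` — template family, divergence ladder, defect panel.
2. `02_curate.R` — panel curation vs ground truth; worked-example table.
3. `03_splice.R` — isoform projection across divergence; isoform loss.
4. `04_synteny.R` — inversion/transposition injection-recovery.
5. `05_trees.R` — per-class distance matrices and NJ trees.

## Acceptance script

`scripts/acceptance.R` rebuilds the worked-example fixture loci from
scratch with the package's own generators, runs start-site rescue and exon
reassignment on them, translates the corrected models, and writes the
resulting protein lengths as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Not in scope

Live FlyBase/BLAST retrieval, reproduction of per-species gene counts from
real genomes, divergence-time estimation, de novo gene prediction, RNA-seq
evidence, and graphical genome maps (outputs are TSV/GFF3/Newick).
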