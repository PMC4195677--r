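#!/usr/bin/env Rscript
# Step 1: build the study world. One template "species" carrying a six-class
# clustered GST-like family (CDS 600-800 nt, 1-6 exons, tandem clusters, four
# alternatively spliced genes), plus eleven diverged target "species":
# ten clean orthologous genomes along a divergence ladder and one defect
# panel with an injected annotation/sequencing error in every gene.
# Writes FASTA/GFF3 bundles and the ground-truth ledger under results/.

suppressMessages(library(gstcurate))

seed <- 2024L
out <- "results/simulation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- family_spec(genes_per_cluster = c(4L, 4L, 3L, 3L, 2L, 2L),
                    n_spliced_genes = 4L, seed = seed)
template <- generate_family(spec)
write_fasta(template$genome, file.path(out, "template_genome.fasta"))
write_gff3(template$models, file.path(out, "template_models.gff3"))
write_fasta(template$proteins, file.path(out, "template_proteins.fasta"),
            protein = TRUE)

rates <- seq(0.02, 0.20, by = 0.02)
targets <- list()
for (i in seq_along(rates)) {
  tag <- sprintf("Sp%02d", i)
  targets[[tag]] <- evolve_target(template, rates[i], seed = seed + i,
                                  species_tag = tag)
  write_fasta(targets[[tag]]$genome,
              file.path(out, sprintf("%s_genome.fasta", tag)))
  write_gff3(targets[[tag]]$models,
             file.path(out, sprintf("%s_models.gff3", tag)))
}

panel <- build_panel(n_genes = 108L, sub_rate = 0.05, seed = seed + 100L)
write_fasta(panel$target$genome, file.path(out, "panel_genome.fasta"))
write_gff3(panel$target$models, file.path(out, "panel_models.gff3"))
ledger <- truth_ledger(panel$target)
write.table(ledger, file.path(out, "panel_ground_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(panel$target$truth,
                     file.path(out, "panel_ground_truth.json"),
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("template: %d genes on %d scaffolds (%d spliced)\n",
            length(template$models), length(template$genome$scaffolds),
            length(template$isoform_templates)))
cat(sprintf("targets: %d clean genomes at rates %.2f-%.2f\n",
            length(targets), min(rates), max(rates)))
cat(sprintf("defect panel: %d genes, %d defect kinds\n",
            nrow(ledger), length(unique(ledger$kind))))
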