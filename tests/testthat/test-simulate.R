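test_that("the generator is deterministic and respects the family spec", {
  a <- generate_family(family_spec(seed = 9, n_spliced_genes = 2))
  b <- generate_family(family_spec(seed = 9, n_spliced_genes = 2))
  expect_identical(a$genome$scaffolds, b$genome$scaffolds)
  expect_identical(a$models, b$models)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(a$genome, f1); write_fasta(b$genome, f2)
  expect_identical(readLines(f1), readLines(f2))

  # CDS lengths in the stated 600-800 nt range, divisible by 3; stop-free
  for (gm in a$models) {
    if (!is.na(gm$transcripts[[1]]$isoform_tag)) next
    cds <- extract_cds(a$genome, gm$transcripts[[1]], gm$scaffold_id,
                       gm$strand)
    expect_gte(nchar(cds), 600); expect_lte(nchar(cds), 800)
    expect_identical(nchar(cds) %% 3L, 0L)
    tr <- translate_cds(cds)
    expect_false(tr$premature_stop)
    expect_true(tr$has_terminal_stop)
    expect_identical(substr(cds, 1, 3), "ATG")
  }
  # catalytic anchor motif planted at the stated residues
  for (lab in names(a$anchors)) {
    pos <- a$anchors[[lab]]$positions
    expect_identical(substr(a$proteins[[lab]], pos[1], pos[4]), "SHAI")
  }
})

test_that("divergence simulation hits the requested rate without breaking genes", {
  tpl <- generate_family(family_spec(genes_per_cluster = c(4, 4), seed = 13))
  expect_error(evolve_target(tpl, 0.6), "out of")

  tgt0 <- evolve_target(tpl, 0, seed = 1)
  expect_identical(tgt0$genome$scaffolds, tpl$genome$scaffolds)

  rate <- 0.05
  tgt <- evolve_target(tpl, rate, seed = 2)
  n_tot <- 0L; n_mis <- 0L
  for (s in names(tpl$genome$scaffolds)) {
    x <- strsplit(tpl$genome$scaffolds[[s]], "")[[1]]
    y <- strsplit(tgt$genome$scaffolds[[s]], "")[[1]]
    n_tot <- n_tot + length(x); n_mis <- n_mis + sum(x != y)
  }
  expect_gt(n_tot, 10000)
  sdev <- sqrt(rate * (1 - rate) / n_tot)
  expect_lt(abs(n_mis / n_tot - rate), 3 * sdev + 0.003)

  # every evolved gene still translates stop-free (purifying selection)
  for (g in names(tgt$models)) {
    cds <- extract_cds(tgt$genome, tgt$models[[g]]$transcripts[[1]],
                       tgt$models[[g]]$scaffold_id, tgt$models[[g]]$strand)
    expect_false(translate_cds(cds)$premature_stop)
  }

  # protein identity decreases monotonically along a divergence series
  mean_id <- vapply(c(0, 0.05, 0.10, 0.20), function(r) {
    t2 <- evolve_target(tpl, r, seed = 3)
    mean(vapply(names(t2$models), function(g) {
      lab <- t2$models[[g]]$ortholog_label
      protein_identity(t2$proteins[[g]], tpl$proteins[[lab]])
    }, 0))
  }, 0)
  expect_identical(mean_id[1], 100)
  expect_true(all(diff(mean_id) < 0))
})

test_that("defect injection applies exactly the recorded change", {
  tpl <- generate_family(family_spec(genes_per_cluster = c(3, 3), seed = 17,
                                     exon_counts = 2:5))
  tgt <- evolve_target(tpl, 0.05, seed = 18)
  gid <- names(tgt$models)[1]
  gm <- tgt$models[[gid]]
  L <- cds_length(gm$transcripts[[1]])

  del <- inject_error(tgt, gid, "DELETE_NT", codon = 50)
  expect_identical(cds_length(del$models[[gid]]$transcripts[[1]]), L - 1L)
  expect_identical(truth_ledger(del)$expected_category, "AMBIGUOUS_INDEL")

  ins <- inject_error(tgt, gid, "INSERT_NT", codon = 50)
  expect_identical(cds_length(ins$models[[gid]]$transcripts[[1]]), L + 1L)

  # intronified terminal exon: CDS shrinks and loses its stop codon
  itr <- inject_error(tgt, gid, "INTRONIFY_EXON", m = 45)
  cds <- extract_cds(itr$genome, itr$models[[gid]]$transcripts[[1]],
                     gm$scaffold_id, gm$strand)
  expect_identical(nchar(cds), L - 45L)
  expect_false(translate_cds(cds)$has_terminal_stop)

  # exonified intron adds one exon, keeps frame, mirrors the 6-exon case
  multi <- names(Filter(function(m)
    nrow(m$transcripts[[1]]$cds_exons) > 1, tgt$models))[1]
  exo <- inject_error(tgt, multi, "EXONIFY_INTRON")
  expect_identical(nrow(exo$models[[multi]]$transcripts[[1]]$cds_exons),
                   nrow(tgt$models[[multi]]$transcripts[[1]]$cds_exons) + 1L)
  expect_identical(cds_length(exo$models[[multi]]$transcripts[[1]]) %% 3L, 0L)

  # premature stop: translation now stops at the chosen codon
  ps <- inject_error(tgt, gid, "PREMATURE_STOP", codon = 60)
  cdsp <- extract_cds(ps$genome, ps$models[[gid]]$transcripts[[1]],
                      gm$scaffold_id, gm$strand)
  expect_identical(translate_cds(cdsp)$stop_codons[1], 60L)

  # N-run lies inside the CDS
  nr <- inject_error(tgt, gid, "N_RUN", len = 24)
  gaps <- detect_sequence_gaps(nr$genome, nr$models[[gid]])
  expect_true(any(gaps$overlaps_cds & gaps$end - gaps$start >= 24))

  expect_error(inject_error(tgt, "nope", "DELETE_NT"), "unknown gene")
  expect_error(inject_error(tgt, gid, "MYSTERY"), "unknown defect")
})

test_that("map rearrangement injection produces the forced permutations", {
  tpl <- generate_family(family_spec(genes_per_cluster = c(5), seed = 23))
  ref <- bundle_gene_map(tpl)
  inv <- inject_rearrangement(ref, "INVERT_BLOCK", block = 2:4)
  expect_identical(build_signed_permutation(ref, inv$map)$perm,
                   c(1L, -4L, -3L, -2L, 5L))
  expect_error(inject_rearrangement(ref, "INVERT_BLOCK", block = 4:9),
               "range")
})

test_that("panel construction records one ground-truth entry per gene", {
  p <- build_panel(n_genes = 27, sub_rate = 0.05, seed = 101)
  tl <- truth_ledger(p$target)
  expect_identical(nrow(tl), 27L)
  expect_identical(anyDuplicated(tl$gene_id), 0L)
  expect_true(all(tl$expected_category %in%
    c("ANNOTATION_ERROR", "AMBIGUOUS_INDEL", "PSEUDOGENE",
      "SEQUENCING_ERROR")))
  # all defect classes represented
  expect_gte(length(unique(tl$kind)), 8L)
})
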