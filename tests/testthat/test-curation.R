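test_that("start-site rescue reproduces the published length arithmetic", {
  # (true CDS nt, annotated nt, expected protein aa)
  cases <- list(c(651, 603, 216),   # ATG 48 nt upstream of the annotated site
                c(636, 603, 211),   # 33 nt upstream
                c(744, 489, 247),   # 255 nt upstream
                c(669, 723, 222),   # next in-frame ATG downstream
                c(663, 666, 220))   # start just inside the annotated intron
  for (cs in cases) {
    fx <- rescue_fixture(cs[1], cs[2], seed = 123)
    r <- rescue_start_site(fx$genome, fx$model, fx$template_protein)
    expect_true(r$rescued)
    expect_identical(r$best$shift, as.integer(fx$true_start_shift))
    cds <- extract_cds(fx$genome, r$best$tx, "fixture_scaf", "+")
    expect_identical(nchar(cds), as.integer(cs[1]))
    expect_identical(translate_cds(cds)$length_aa, as.integer(cs[1] / 3 - 1))
  }

  # template-perfect annotated start: top candidate is the annotated model
  fx0 <- rescue_fixture(651, 651, seed = 9)
  r0 <- rescue_start_site(fx0$genome, fx0$model, fx0$template_protein)
  expect_identical(r0$best$shift, 0L)
  expect_length(r0$best$edits, 0L)
})

test_that("exon reassignment drops spurious exons and recovers read-through stops", {
  fx <- exon_shadow_fixture(714, 4, c(78, 75), seed = 5)
  annotated <- extract_cds(fx$genome, fx$model$transcripts[[1]],
                           "fixture_scaf", "+")
  expect_identical(nchar(annotated), 867L)    # 714 + 153 spurious
  expect_identical(translate_cds(annotated)$length_aa, 288L)
  r <- reassign_exons(fx$genome, fx$model, fx$template_protein)
  expect_true(r$edited)
  expect_match(paste(r$best$edits, collapse = ";"), "EXON_IS_INTRON")
  cds <- extract_cds(fx$genome, r$best$tx, "fixture_scaf", "+")
  expect_identical(nchar(cds), 714L)
  expect_identical(translate_cds(cds)$length_aa, 237L)
  expect_equal(r$best$identity, 100)

  # stop codon hidden in the annotated intron: terminal-exon extension
  p <- small_panel()
  tl <- truth_ledger(p$target)
  ids <- tl$gene_id[tl$kind == "INTRONIFY_EXON"]
  for (g in ids) {
    gm <- p$target$models[[g]]
    tp <- p$template$proteins[[gm$ortholog_label]]
    r2 <- reassign_exons(p$target$genome, gm, tp)
    expect_match(paste(r2$best$edits, collapse = ";"), "INTRON_IS_EXON")
    expect_true(r2$best$stop_free)
  }

  # an already-correct model needs no edits
  clean <- generate_family(family_spec(genes_per_cluster = c(2), seed = 55))
  gm <- clean$models[[1]]
  r3 <- reassign_exons(clean$genome, gm, clean$proteins[[gm$ortholog_label]])
  expect_false(r3$edited)
  expect_equal(r3$best$identity, 100)
})

test_that("sequencing gaps are reported with CDS-overlap flags", {
  tpl <- generate_family(family_spec(genes_per_cluster = c(1), seed = 66,
                                     exon_counts = 3))
  gm <- tpl$models[[1]]
  expect_identical(nrow(detect_sequence_gaps(tpl$genome, gm)), 0L)

  # 30-N run inside an exon
  ex <- gm$transcripts[[1]]$cds_exons
  big <- which.max(ex$end - ex$start)
  st <- ex$start[big] + 10
  s <- tpl$genome$scaffolds[[gm$scaffold_id]]
  substr(s, st + 1, st + 30) <- strrep("N", 30)
  g2 <- tpl$genome; g2$scaffolds[[gm$scaffold_id]] <- s
  gaps <- detect_sequence_gaps(g2, gm)
  expect_identical(nrow(gaps), 1L)
  expect_true(gaps$overlaps_cds)
  expect_identical(gaps$end - gaps$start, 30L)

  # N run wholly inside an intron: reported but non-overlapping
  intron_start <- ex$end[1] + 5
  s2 <- tpl$genome$scaffolds[[gm$scaffold_id]]
  substr(s2, intron_start + 1, intron_start + 20) <- strrep("N", 20)
  g3 <- tpl$genome; g3$scaffolds[[gm$scaffold_id]] <- s2
  gaps3 <- detect_sequence_gaps(g3, gm)
  expect_identical(nrow(gaps3), 1L)
  expect_false(gaps3$overlaps_cds)
})

test_that("frameshift-indel detection proposes bounded virtual edits", {
  p <- small_panel()
  tl <- truth_ledger(p$target)
  for (kind in c("DELETE_NT", "INSERT_NT")) {
    ids <- tl$gene_id[tl$kind == kind]
    expect_gt(length(ids), 0)
    for (g in ids) {
      gm <- p$target$models[[g]]
      tp <- p$template$proteins[[gm$ortholog_label]]
      fsi <- detect_frameshift_indels(p$target$genome, gm, tp)
      expect_identical(fsi$n_frameshifts, 1L)
      expect_true(fsi$correctable)
      expect_identical(fsi$edits$kind,
                       if (kind == "DELETE_NT") "NT_INSERTION" else "NT_DELETION")
      expect_gt(fsi$identity_after, fsi$identity_before)
    }
  }

  # clean gene: no edits
  clean_id <- names(p$template$models)[1]
  gm0 <- p$template$models[[clean_id]]
  fsi0 <- detect_frameshift_indels(p$template$genome, gm0,
                                   p$template$proteins[[gm0$ortholog_label]])
  expect_identical(fsi0$n_frameshifts, 0L)

  # two independent deletions exceed k_max = 1: uncorrectable signal
  cds <- random_clean_cds(220)
  tpl_prot <- translate_cds(cds)$sequence
  mut <- paste0(substr(cds, 1, 99), substr(cds, 101, 400),
                substr(cds, 402, nchar(cds)))
  g <- genome(c(s = paste0(strrep("A", 50), mut, strrep("A", 50))))
  gm2 <- gene_model("g2", "s", "+",
                    transcript_model("g2.t",
                                     data.frame(start = 50,
                                                end = 50 + nchar(mut))))
  fsi2 <- detect_frameshift_indels(g, gm2, tpl_prot,
                                   curation_config(k_max = 1))
  expect_gt(fsi2$n_frameshifts, 1L)
  expect_false(fsi2$correctable)
})

test_that("pseudogene check uses template length and catalytic anchors", {
  set.seed(12)
  tpl <- random_protein(215)
  # half-length model mirrors the published quarter-to-three-quarter cases
  frag <- substr(tpl, 1, 108)
  pg <- pseudogene_check(frag, tpl)
  expect_true(pg$is_pseudogene)
  expect_identical(pg$subtype, "TRUNCATION")

  anchors <- catalytic_anchor("tpl", 60:63)
  expect_false(pseudogene_check(tpl, tpl, anchors)$is_pseudogene)

  # full-length ORF with the catalytic anchor region deleted
  lost <- paste0(substr(tpl, 1, 55), substr(tpl, 70, 215),
                 paste(rep("A", 14), collapse = ""))
  pg2 <- pseudogene_check(lost, tpl, anchors)
  expect_true(pg2$is_pseudogene)
  expect_identical(pg2$subtype, "MOTIF_LOSS")
})

test_that("curate_gene applies the category precedence", {
  p <- small_panel()
  tl <- truth_ledger(p$target)

  # SEQUENCING_ERROR outranks a coexisting frameshift (low-coverage cases)
  g <- tl$gene_id[tl$kind == "DELETE_NT"][1]
  gm <- p$target$models[[g]]
  tp <- p$template$proteins[[gm$ortholog_label]]
  ex <- gm$transcripts[[1]]$cds_exons
  big <- which.max(ex$end - ex$start)
  s <- p$target$genome$scaffolds[[gm$scaffold_id]]
  st <- ex$start[big] + 5
  substr(s, st + 1, st + 25) <- strrep("N", 25)
  g2 <- p$target$genome; g2$scaffolds[[gm$scaffold_id]] <- s
  v <- curate_gene(g2, gm, tp, p$template$anchors[[gm$ortholog_label]])
  expect_identical(v$category, "SEQUENCING_ERROR")
  expect_identical(v$subtype, "N_RUN")

  # defect-free ortholog at 10% divergence is ORTHOLOG_OK
  tpl <- generate_family(family_spec(genes_per_cluster = c(3), seed = 81))
  tgt <- evolve_target(tpl, 0.10, seed = 82)
  for (g in names(tgt$models)) {
    lab <- tgt$models[[g]]$ortholog_label
    v <- curate_gene(tgt$genome, tgt$models[[g]], tpl$proteins[[lab]],
                     tpl$anchors[[lab]])
    expect_identical(v$category, "ORTHOLOG_OK")
  }

  expect_error(curate_gene(g2, gm, ""), "template")
})

test_that("panel curation recovers the ground-truth ledger", {
  p <- small_panel()
  rep <- curate_panel(p$target$genome, p$target$models, p$template$proteins,
                      p$template$anchors)
  m <- merge(truth_ledger(p$target), rep, by = "gene_id")
  expect_identical(nrow(m), 36L)
  expect_gte(mean(m$category == m$expected_category), 0.95)

  # precedence is a total order: exactly one category per gene
  expect_true(all(table(rep$gene_id) == 1))
  expect_true(all(rep$category %in%
    c("ORTHOLOG_OK", "ANNOTATION_ERROR", "SEQUENCING_ERROR",
      "AMBIGUOUS_INDEL", "PSEUDOGENE")))

  # identity reported on both sides for every verdict; corrected verdicts do
  # not lose identity beyond divergence noise (strict at 0% divergence)
  verd <- attr(rep, "verdicts")
  for (v in verd) if (!is.null(v$corrected_model))
    expect_gte(v$identity_after, v$identity_before - 5)

  # edit-consistency round trip: restoring the pre-defect genome turns an
  # injected indel verdict back into ORTHOLOG_OK
  clean <- build_panel(n_genes = 36, sub_rate = 0.05, seed = 404,
                       defect_free = TRUE)
  tl <- truth_ledger(p$target)
  g <- tl$gene_id[tl$kind == "DELETE_NT"][1]
  gm_before <- clean$target$models[[g]]
  lab <- gm_before$ortholog_label
  v1 <- curate_gene(p$target$genome, p$target$models[[g]],
                    p$template$proteins[[lab]], p$template$anchors[[lab]])
  expect_identical(v1$category, "AMBIGUOUS_INDEL")
  v2 <- curate_gene(clean$target$genome, gm_before,
                    p$template$proteins[[lab]], p$template$anchors[[lab]])
  expect_identical(v2$category, "ORTHOLOG_OK")
})

test_that("defect-free panels at 0% divergence are all perfect orthologs", {
  p0 <- build_panel(n_genes = 18, sub_rate = 0, seed = 31, defect_free = TRUE)
  rep <- curate_panel(p0$target$genome, p0$target$models,
                      p0$template$proteins, p0$template$anchors)
  expect_true(all(rep$category == "ORTHOLOG_OK"))
  expect_true(all(rep$identity_before == 100))
  verd <- attr(rep, "verdicts")
  for (v in verd) expect_gte(v$identity_after, v$identity_before)
})
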