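test_that("FASTA I/O keys records, normalizes case, and round-trips", {
  f <- withr::local_tempfile()
  writeLines(c(">s1 some description", "acgtACGT", ">s2", "NNNACGT"), f)
  g <- read_fasta(f, species_tag = "X")
  expect_named(g$scaffolds, c("s1", "s2"))
  expect_identical(unname(g$scaffolds[["s1"]]), "ACGTACGT")

  f2 <- withr::local_tempfile(); f3 <- withr::local_tempfile()
  set.seed(1)
  g2 <- genome(c(a = random_dna_seq(145), b = random_dna_seq(61)))
  write_fasta(g2, f2)
  write_fasta(read_fasta(f2), f3)
  expect_identical(readLines(f2), readLines(f3))

  writeLines(c(">d", "ACGT", ">d", "ACGT"), f)
  expect_error(read_fasta(f), "duplicate")
  expect_error(genome(c(x = "ACQT")), "illegal")
  expect_error(genome(c(x = "")), "empty")
})

test_that("GFF3 coordinates convert 1-based inclusive <-> 0-based half-open", {
  f <- withr::local_tempfile()
  writeLines(c(
    "##gff-version 3",
    "s1\t.\tgene\t10\t18\t.\t+\t.\tID=g1",
    "s1\t.\tmRNA\t10\t18\t.\t+\t.\tID=g1.t1;Parent=g1",
    "s1\t.\tCDS\t10\t18\t.\t+\t0\tParent=g1.t1",
    "s1\t.\tgene\t30\t60\t.\t-\t.\tID=g2",
    "s1\t.\tmRNA\t30\t60\t.\t-\t.\tID=g2.t1;Parent=g2",
    "s1\t.\tCDS\t30\t40\t.\t-\t0\tParent=g2.t1",
    "s1\t.\tmRNA\t30\t60\t.\t-\t.\tID=g2.t2;Parent=g2",
    "s1\t.\tCDS\t30\t60\t.\t-\t0\tParent=g2.t2"), f)
  ms <- read_gff3(f)
  expect_identical(ms$g1$transcripts[[1]]$cds_exons$start, 9L)
  expect_identical(ms$g1$transcripts[[1]]$cds_exons$end, 18L)
  expect_length(ms$g2$transcripts, 2L)

  writeLines(c("s1\t.\tCDS\t10\t18\t.\t+\t0\tID=orphan"), f)
  expect_error(read_gff3(f), "Parent")
})

test_that("GFF3 read-write-read is idempotent on synthetic annotation", {
  tpl <- generate_family(family_spec(genes_per_cluster = c(3, 2),
                                     n_spliced_genes = 1, seed = 77))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_gff3(tpl$models, f1)
  write_gff3(read_gff3(f1, tpl$genome), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("extract_cds respects strand and equals a slice-and-join oracle", {
  g <- genome(c(s = "ATGAAACCC"))
  tx <- transcript_model("t", data.frame(start = 0, end = 6))
  expect_identical(extract_cds(g, tx, "s", "+"), "ATGAAA")
  g2 <- genome(c(s = "TTTCATCCC"))
  expect_identical(extract_cds(g2, tx, "s", "-"), "ATGAAA")

  set.seed(11)
  for (i in 1:20) {
    seqs <- random_dna_seq(400)
    g3 <- genome(c(s = seqs))
    cuts <- sort(sample(10:390, 6))
    ex <- data.frame(start = cuts[c(1, 3, 5)], end = cuts[c(2, 4, 6)])
    tx3 <- transcript_model("t3", ex)
    oracle <- paste(substring(seqs, ex$start + 1, ex$end), collapse = "")
    expect_identical(extract_cds(g3, tx3, "s", "+"), oracle)
    # strand symmetry: minus-strand extraction from the reverse complement
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqs)))
    n <- nchar(seqs)
    ex_rc <- data.frame(start = n - rev(ex$end), end = n - rev(ex$start))
    g4 <- genome(c(s = rc))
    expect_identical(extract_cds(g4, transcript_model("t4", ex_rc), "s", "-"),
                     oracle)
  }
  expect_error(extract_cds(g, transcript_model("t", data.frame(start = 0, end = 99)),
                           "s", "+"), "bounds")
})

test_that("translate_cds follows the standard code with stop/N conventions", {
  tr <- translate_cds("ATGAAATAA")
  expect_identical(tr$sequence, "MK")
  expect_identical(tr$length_aa, 2L)
  expect_false(tr$premature_stop)
  expect_true(tr$has_terminal_stop)

  # a 744-nt coding sequence with terminal stop encodes 247 residues
  set.seed(2)
  cds744 <- random_clean_cds(744 / 3 - 1)
  expect_identical(nchar(cds744), 744L)
  expect_identical(translate_cds(cds744)$length_aa, 247L)

  # length law across sizes: L nt -> L/3 - 1 aa
  for (naa in c(199L, 222L, 266L)) {
    cds <- random_clean_cds(naa)
    expect_identical(translate_cds(cds)$length_aa, naa)
  }

  # independent oracle: Biostrings translation on a random 300-codon CDS
  dna <- random_dna_seq(900)
  mine <- translate_cds(dna)
  ref <- as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                            if.fuzzy.codon = "X"))
  ref_chars <- strsplit(ref, "")[[1]]
  body <- if (ref_chars[300] == "*") ref_chars[-300] else ref_chars
  expect_identical(mine$sequence, paste(body, collapse = ""))
  expect_identical(mine$stop_codons, which(body == "*"))

  expect_error(translate_cds("ATGA"), "divisible")
  # N-containing codons become X
  expect_identical(translate_cds("ATGANATAA")$sequence, "MX")
  expect_identical(translate_cds("ATGANATAA")$ambiguous_codons, 2L)
})

test_that("GST nomenclature builds names from species, class and number", {
  expect_identical(build_gst_name("simulans", "T", 4), "DsimGSTT4")
  expect_identical(build_gst_name("melanogaster", "D", 1), "DmelGSTD1")
  expect_identical(build_gst_name("virilis", "Z", 1), "DvirGSTZ1")
  expect_error(build_gst_name("sapiens", "D", 1), "unknown species")
  expect_error(build_gst_name("virilis", "Q", 1), "class")
  expect_error(build_gst_name("virilis", "D", 0), "positive")
})
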