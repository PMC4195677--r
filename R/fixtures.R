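# Single-gene fixture loci mirroring the published worked curation cases:
# mis-annotated translation starts rescued to an in-frame ATG, and spurious
# annotated exons that are really intron sequence.

#' Fixture locus with a mis-annotated translation start
#'
#' Builds a scaffold carrying one true gene of `true_cds_nt` (ATG .. stop,
#' stop-free, single exon) and annotates a CDS of `annotated_nt` instead:
#' shorter annotations start downstream of the true ATG (the 48/33/255 nt
#' upstream-rescue cases), longer ones extend upstream into flanking
#' sequence (the next-ATG-downstream case).
#'
#' @param true_cds_nt true CDS length in nt including the terminal stop
#'   (multiple of 3).
#' @param annotated_nt annotated CDS length in nt (`annotated_nt - true_cds_nt`
#'   is a multiple of 3).
#' @param seed integer seed.
#' @return list with `genome`, `model` (the mis-annotated gene),
#'   `template_protein`, `true_start_shift` (nt; negative = true start lies
#'   upstream of the annotated one).
#' @export
rescue_fixture <- function(true_cds_nt, annotated_nt, seed = 1L) {
  stopifnot(true_cds_nt %% 3L == 0L,
            (annotated_nt - true_cds_nt) %% 3L == 0L)
  with_seed(seed, {
    naa <- true_cds_nt %/% 3L - 1L
    cds <- random_cds(naa, integer())
    lead_len <- 300L
    # flanking sequence free of in-frame stop-less ATG traps is not needed:
    # rescue ranks by template score, so decoys lose on their own
    lead <- rand_dna(lead_len)
    locus <- paste0(lead, cds, rand_dna(300L))
    shift <- true_cds_nt - annotated_nt   # annotated start minus true start
    ann_start <- lead_len + shift
    ex <- data.frame(start = ann_start, end = lead_len + true_cds_nt)
    gm <- gene_model("fixture_gene", "fixture_scaf", "+",
                     transcript_model("fixture_gene-RA", ex),
                     ortholog_label = "template")
    list(genome = genome(c(fixture_scaf = locus), "Fix"),
         model = gm,
         template_protein = translate_cds(cds)$sequence,
         true_start_shift = -shift)
  })
}

#' Fixture locus with spurious annotated exons inside an intron
#'
#' Builds a gene whose true structure has `n_true_exons` coding exons and a
#' spliced CDS of `true_cds_nt`; the annotation additionally claims
#' `length(fake_nt)` exon(s) carved out of the first intron (in frame,
#' stop-free), mirroring the published six-exon case whose exons 2 and 3 are
#' intron in the template. Dropping the spurious exons restores the true
#' CDS.
#'
#' @param true_cds_nt true spliced CDS length (multiple of 3, incl. stop).
#' @param n_true_exons number of real coding exons (>= 2).
#' @param fake_nt integer vector of spurious exon lengths (multiples of 3).
#' @param seed integer seed.
#' @return list with `genome`, `model` (over-annotated), `template_protein`,
#'   `true_cds_nt`.
#' @export
exon_shadow_fixture <- function(true_cds_nt = 714L, n_true_exons = 4L,
                                fake_nt = c(78L, 75L), seed = 1L) {
  stopifnot(true_cds_nt %% 3L == 0L, all(fake_nt %% 3L == 0L),
            n_true_exons >= 2L)
  with_seed(seed, {
    naa <- true_cds_nt %/% 3L - 1L
    cds <- random_cds(naa, integer())
    sizes <- split_exons(true_cds_nt, n_true_exons, 60L)
    # exon 1 ends on a codon boundary so the spurious exons insert in frame
    sizes[1L] <- (sizes[1L] %/% 3L) * 3L
    sizes[2L] <- true_cds_nt - sum(sizes[-2L])
    exon_seqs <- substring(cds, cumsum(c(0L, sizes[-n_true_exons])) + 1L,
                           cumsum(sizes))
    fakes <- vapply(fake_nt, function(f)
      paste(sample(.sense_codons, f %/% 3L, replace = TRUE), collapse = ""),
      "")
    margin <- function() rand_dna(20L)
    intron1 <- paste0("GT", rand_dna(13L),
                      paste(vapply(fakes, function(f) paste0(f, margin()),
                                   ""), collapse = ""),
                      rand_dna(5L), "AG")
    other_introns <- vapply(seq_len(n_true_exons - 2L),
                            function(i) paste0("GT", rand_dna(66L), "AG"), "")
    body <- exon_seqs[1L]
    body <- paste0(body, intron1, exon_seqs[2L])
    if (n_true_exons > 2L)
      for (i in seq_len(n_true_exons - 2L))
        body <- paste0(body, other_introns[i], exon_seqs[i + 2L])
    lead <- rand_dna(300L)
    locus <- paste0(lead, body, rand_dna(300L))
    # coordinates
    off <- nchar(lead)
    starts <- integer(); ends <- integer()
    cursor <- off
    starts[1L] <- cursor; ends[1L] <- cursor + sizes[1L]
    cursor <- ends[1L] + 2L + 13L               # GT + margin prefix
    fk_starts <- integer(); fk_ends <- integer()
    for (k in seq_along(fakes)) {
      fk_starts[k] <- cursor
      fk_ends[k] <- cursor + nchar(fakes[k])
      cursor <- fk_ends[k] + 20L
    }
    cursor <- cursor + 5L + 2L                  # tail + AG
    for (i in 2:n_true_exons) {
      starts[i] <- cursor; ends[i] <- cursor + sizes[i]
      cursor <- ends[i] + if (i < n_true_exons)
        nchar(other_introns[i - 1L]) else 0L
    }
    ann <- data.frame(start = c(starts[1L], fk_starts, starts[-1L]),
                      end = c(ends[1L], fk_ends, ends[-1L]))
    gm <- gene_model("fixture_gene", "fixture_scaf", "+",
                     transcript_model("fixture_gene-RA", ann),
                     ortholog_label = "template")
    list(genome = genome(c(fixture_scaf = locus), "Fix"),
         model = gm,
         template_protein = translate_cds(cds)$sequence,
         true_cds_nt = true_cds_nt)
  })
}
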