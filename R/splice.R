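# Projection of a template gene's alternative-splicing isoform structures
# onto an orthologous target locus, with per-isoform support calls and UTR
# conservation scoring.

#' Splice-projection configuration
#'
#' @param min_intron minimum projected intron length in nt (default 40).
#' @param anchor_floor minimum nucleotide identity (percent) for an exon
#'   anchor to count (default 60; the deepest comparisons in the family are
#'   ~60 My diverged and still anchor).
#' @param canonical_policy `"warn"` demotes isoforms with non-GT..AG
#'   boundaries to weak support; `"strict"` rejects them.
#' @return a `splice_config` list.
#' @export
splice_config <- function(min_intron = 40L, anchor_floor = 60,
                          canonical_policy = "warn") {
  structure(list(min_intron = as.integer(min_intron),
                 anchor_floor = anchor_floor,
                 canonical_policy = canonical_policy),
            class = "splice_config")
}

.nuc_mat <- function() {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                baseOnly = FALSE)
  m * 1
}

# anchor a template DNA segment in a target locus: pattern-global /
# subject-local alignment; returns 0-based half-open subject interval and
# nucleotide identity over mutual columns
anchor_segment <- function(segment, locus_dna) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(segment), Biostrings::DNAString(locus_dna),
    substitutionMatrix = .nuc_mat(), gapOpening = 4, gapExtension = 1,
    type = "global-local")
  sa <- as.character(Biostrings::alignedPattern(pa))
  sb <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(sa, "")[[1L]]; cb <- strsplit(sb, "")[[1L]]
  mutual <- ca != "-" & cb != "-"
  idy <- if (sum(mutual)) 100 * sum(mutual & ca == cb) / sum(mutual) else 0
  list(start = Biostrings::start(Biostrings::subject(pa)) - 1L,
       end = Biostrings::end(Biostrings::subject(pa)),
       identity = idy, score = Biostrings::score(pa))
}

#' Project a template's isoform structures onto a target locus
#'
#' Every distinct template exon is anchored once by global-local alignment
#' of its sequence to the locus (so exons shared between isoforms receive
#' identical projected coordinates). An isoform is supported when all its
#' exons anchor at or above the identity floor in consistent order, all
#' inferred introns reach the minimum length with canonical GT..AG
#' boundaries (non-canonical demotes to weak support under the default
#' policy), and the spliced ORF is stop-free.
#'
#' @param template an `isoform_template` (see [generate_family()]), carrying
#'   its exon table, isoform chains, UTR intervals and template proteins.
#' @param template_locus_dna template locus sequence the exon intervals
#'   refer to.
#' @param target_locus_dna orthologous target locus sequence.
#' @param config a [splice_config()].
#' @return a `projection_result`: `support` data.frame (per isoform:
#'   `supported`, `weak`, `cds_identity` (nucleotide), `protein_identity`,
#'   `utr5_identity`, `utr3_identity`), `exon_anchors`, `projected`
#'   (per-isoform exon chains).
#' @export
project_isoforms <- function(template, template_locus_dna, target_locus_dna,
                             config = splice_config()) {
  exons <- template$exons
  anchors <- list()
  for (r in seq_len(nrow(exons))) {
    seg <- substr(template_locus_dna, exons$start[r] + 1L, exons$end[r])
    anchors[[exons$exon_id[r]]] <- anchor_segment(seg, target_locus_dna)
  }
  if (all(vapply(anchors, `[[`, 0, "identity") < config$anchor_floor))
    stop("no exon anchors in target locus (no-locus signal)")
  tags <- names(template$isoforms)
  rows <- list(); projected <- list()
  for (tag in tags) {
    chain <- template$isoforms[[tag]]
    an <- anchors[chain]
    idys <- vapply(an, `[[`, 0, "identity")
    starts <- vapply(an, `[[`, 0, "start")
    ends <- vapply(an, `[[`, 0, "end")
    ordered <- all(diff(starts) > 0) && all(ends[-length(ends)] <= starts[-1L])
    anchored <- all(idys >= config$anchor_floor)
    introns_ok <- TRUE; canonical <- TRUE
    if (length(chain) > 1L && ordered) {
      for (i in seq_len(length(chain) - 1L)) {
        ist <- ends[i]; ien <- starts[i + 1L]
        if (ien - ist < config$min_intron) introns_ok <- FALSE
        donor <- substr(target_locus_dna, ist + 1L, ist + 2L)
        accept <- substr(target_locus_dna, ien - 1L, ien)
        if (donor != "GT" || accept != "AG") canonical <- FALSE
      }
    }
    cds <- paste(vapply(seq_along(chain), function(i)
      substr(target_locus_dna, starts[i] + 1L, ends[i]), ""), collapse = "")
    tmpl_cds <- paste(vapply(chain, function(id) {
      r <- template$exons[template$exons$exon_id == id, ]
      substr(template_locus_dna, r$start + 1L, r$end)
    }, ""), collapse = "")
    n3 <- (nchar(cds) %/% 3L) * 3L
    orf_ok <- FALSE; cds_identity <- 0; prot_identity <- 0
    if (anchored && ordered && n3 >= 3L) {
      cds_identity <- anchor_segment(tmpl_cds, cds)$identity
      tr <- translate_cds(substr(cds, 1L, n3))
      orf_ok <- !tr$premature_stop
      tp <- template$proteins[[tag]]
      if (nzchar(tr$sequence) && !is.null(tp))
        prot_identity <- protein_identity(tr$sequence, tp)
    }
    supported <- anchored && ordered && introns_ok && orf_ok &&
      (canonical || config$canonical_policy == "warn")
    weak <- supported && !canonical
    if (config$canonical_policy == "strict" && !canonical) supported <- FALSE
    u5 <- template$utr5[[tag]]; u3 <- template$utr3[[tag]]
    utr5_id <- if (!is.null(u5) && supported)
      utr_identity(substr(template_locus_dna, u5[1L] + 1L, u5[2L]),
                   target_locus_dna, anchor = starts[1L], side = "5")
      else NA_real_
    utr3_id <- if (!is.null(u3) && supported)
      utr_identity(substr(template_locus_dna, u3[1L] + 1L, u3[2L]),
                   target_locus_dna, anchor = ends[length(ends)], side = "3")
      else NA_real_
    rows[[tag]] <- data.frame(
      isoform = tag, supported = supported, weak = weak,
      cds_identity = cds_identity, protein_identity = prot_identity,
      utr5_identity = utr5_id, utr3_identity = utr3_id)
    projected[[tag]] <- data.frame(exon_id = chain, start = unname(starts),
                                   end = unname(ends),
                                   identity = unname(idys))
  }
  structure(list(gene_id = template$gene_id,
                 support = do.call(rbind, c(rows, make.row.names = FALSE)),
                 exon_anchors = anchors, projected = projected),
            class = "projection_result")
}

#' Nucleotide identity of a template UTR against an anchored flank
#'
#' Aligns the template UTR sequence (pattern-global) against the target
#' flank adjacent to the anchored first/last coding exon; identities below
#' 55 percent are flagged unconserved.
#'
#' @param template_utr_seq UTR sequence from the template locus.
#' @param target_locus_dna target locus.
#' @param anchor 0-based coordinate the UTR abuts (start of the first coding
#'   exon for 5' UTRs, end of the last for 3' UTRs).
#' @param side `"5"` or `"3"`.
#' @return percentage with attribute `"conserved"`.
#' @export
utr_identity <- function(template_utr_seq, target_locus_dna, anchor,
                         side = "5") {
  if (is.na(anchor)) stop("anchor absent")
  len <- nchar(template_utr_seq)
  win <- len * 2L
  if (side == "5") {
    lo <- max(0L, anchor - win); hi <- anchor
  } else {
    lo <- anchor; hi <- min(nchar(target_locus_dna), anchor + win)
  }
  flank <- substr(target_locus_dna, lo + 1L, hi)
  if (!nzchar(flank)) stop("anchor flank empty")
  a <- anchor_segment(template_utr_seq, flank)
  structure(a$identity, conserved = a$identity >= 55)
}
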