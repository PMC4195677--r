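# Template-guided correction and classification of target gene models.
#
# The decision procedure mirrors the manual curation workflow: N-run
# (sequencing gap) detection first, then structural re-annotation (start-site
# rescue, exon/intron reassignment), then bounded virtual single-nucleotide
# edits for frameshift indels, then a pseudogene check against template
# length and catalytic anchors.

#' Curation configuration
#'
#' @param k_max maximum number of virtual single-nt edits for an
#'   AMBIGUOUS_INDEL call (default 2).
#' @param max_edits maximum number of structural edits searched (default 2).
#' @param length_frac pseudogene truncation threshold: a gene whose best
#'   stop-free ORF is shorter than `length_frac` x template length is a
#'   pseudogene (default 0.70).
#' @param full_frac fraction of template length a structurally corrected ORF
#'   must reach to count as full length (default 0.95).
#' @param rescue_window_nt upstream window searched for rescued ATG starts
#'   (default 300; the largest published case is 255 nt).
#' @param min_n_run minimum N-run length reported as a sequencing gap.
#' @param identity_floor minimum identity (percent) for orthology calls left
#'   to the caller; reported, not enforced.
#' @param scheme scoring scheme used for identities (curation preset).
#' @return a `curation_config` list.
#' @export
curation_config <- function(k_max = 2L, max_edits = 2L, length_frac = 0.70,
                            full_frac = 0.95, rescue_window_nt = 300L,
                            min_n_run = 5L, identity_floor = 40,
                            scheme = scoring_scheme("curation")) {
  stopifnot(k_max >= 1L, max_edits >= 1L, length_frac > 0, length_frac < 1,
            rescue_window_nt > 0L)
  structure(list(k_max = as.integer(k_max), max_edits = as.integer(max_edits),
                 length_frac = length_frac, full_frac = full_frac,
                 rescue_window_nt = as.integer(rescue_window_nt),
                 min_n_run = as.integer(min_n_run),
                 identity_floor = identity_floor, scheme = scheme),
            class = "curation_config")
}

#' Catalytic anchors of a template protein
#'
#' Residue positions of the conserved catalytic serine/tyrosine region and
#' the class motif (e.g. Ser-His-Ala-Ile in the Epsilon class). A curated
#' model that deletes these positions cannot encode an active enzyme.
#'
#' @param template_id template protein id.
#' @param positions integer residue indices (1-based) on the template.
#' @return a `catalytic_anchor` object.
#' @export
catalytic_anchor <- function(template_id, positions) {
  structure(list(template_id = template_id,
                 positions = as.integer(positions)),
            class = "catalytic_anchor")
}

# score a candidate protein against the template; higher is better
aln_score <- function(prot, template, scheme) {
  if (!nzchar(prot)) return(-Inf)
  global_align(prot, template, scheme)$score
}

# candidate = list(model, edits (character), shift, protein, score, identity,
# stop_free, n_changed)
evaluate_candidate <- function(gen, model, tx, template_protein, scheme,
                               edits = character(), shift = 0L,
                               n_changed = 0L) {
  dna <- extract_cds(gen, tx, model$scaffold_id, model$strand)
  n3 <- (nchar(dna) %/% 3L) * 3L
  prot <- ""; stop_free <- FALSE
  if (n3 >= 3L) {
    tr <- translate_cds(substr(dna, 1L, n3))
    stop_free <- !tr$premature_stop
    prot <- if (tr$premature_stop)
      substr(tr$sequence, 1L, tr$stop_codons[1L] - 1L) else tr$sequence
  }
  aln <- if (nzchar(prot)) global_align(prot, template_protein, scheme)
         else NULL
  list(model = model, tx = tx, edits = edits, shift = shift,
       protein = prot, stop_free = stop_free,
       frame_ok = nchar(dna) %% 3L == 0L,
       score = if (is.null(aln)) -Inf else aln$score,
       identity = if (is.null(aln)) 0 else percent_identity(aln),
       n_changed = n_changed, cds = dna)
}

with_first_exon_start <- function(model, tx_index, new_start) {
  tx <- model$transcripts[[tx_index]]
  ex <- tx$cds_exons
  if (model$strand == "+") ex$start[1L] <- new_start
  else ex$end[nrow(ex)] <- new_start
  tx2 <- transcript_model(tx$transcript_id, ex, tx$isoform_tag)
  model$transcripts[[tx_index]] <- tx2
  model
}

# genomic coordinate (0-based) of the first CDS base in transcript order
tx_start_coord <- function(model, tx) {
  ex <- tx$cds_exons
  if (model$strand == "+") ex$start[1L] else ex$end[nrow(ex)]
}

#' Rescue a mis-annotated translation start site
#'
#' Enumerates in-frame ATG codons within `window_nt` upstream of the annotated
#' start (contiguous genomic sequence) and downstream within the first coding
#' exon, builds a candidate model for each, and ranks candidates by template
#' alignment score (then identity, then `|shift|`, upstream before
#' downstream). Ranking by raw score rather than mutual-column identity is
#' deliberate: identity over mutually aligned columns cannot see N-terminal
#' truncation.
#'
#' @param genome target `genome`.
#' @param model annotated `gene_model` (first transcript is curated).
#' @param template_protein template amino-acid sequence.
#' @param config a [curation_config()].
#' @return list with `candidates` (ranked list), `best`, and `rescued`
#'   (logical: an ATG candidate exists).
#' @export
rescue_start_site <- function(genome, model, template_protein,
                              config = curation_config()) {
  tx <- model$transcripts[[1L]]
  scheme <- config$scheme
  scaf <- genome$scaffolds[[model$scaffold_id]]
  ex <- tx$cds_exons
  strand <- model$strand
  window <- config$rescue_window_nt

  # shift s (nt, multiple of 3): negative = upstream extension,
  # positive = downstream truncation within exon 1
  exon1_len <- if (strand == "+") ex$end[1L] - ex$start[1L]
               else ex$end[nrow(ex)] - ex$start[nrow(ex)]
  shifts <- as.integer(seq(-window, exon1_len - 3L, by = 3L))
  cands <- list()
  for (s in shifts) {
    if (strand == "+") {
      ns <- ex$start[1L] + s
      if (ns < 0L || ns + 3L > nchar(scaf)) next
      codon <- substr(scaf, ns + 1L, ns + 3L)
    } else {
      ns <- ex$end[nrow(ex)] - s
      if (ns > nchar(scaf) || ns - 3L < 0L) next
      codon <- revcomp(substr(scaf, ns - 2L, ns))
    }
    if (codon != "ATG") next
    m2 <- with_first_exon_start(model, 1L, ns)
    cand <- evaluate_candidate(genome, m2, m2$transcripts[[1L]],
                               template_protein, scheme,
                               edits = if (s == 0L) character() else
                                 sprintf("START_%s_%dnt",
                                         if (s < 0L) "UPSTREAM" else "DOWNSTREAM",
                                         abs(s)),
                               shift = s, n_changed = abs(s))
    cands[[length(cands) + 1L]] <- cand
  }
  if (!length(cands)) {
    annot <- evaluate_candidate(genome, model, tx, template_protein, scheme)
    return(list(candidates = list(annot), best = annot, rescued = FALSE))
  }
  ord <- order(-vapply(cands, `[[`, 0, "score"),
               -vapply(cands, `[[`, 0, "identity"),
               abs(vapply(cands, `[[`, 0L, "shift")),
               vapply(cands, `[[`, 0L, "shift"))  # upstream (negative) first
  cands <- cands[ord]
  list(candidates = cands, best = cands[[1L]], rescued = TRUE)
}

drop_exons <- function(tx, which_rows) {
  ex <- tx$cds_exons[-which_rows, , drop = FALSE]
  if (!nrow(ex)) return(NULL)
  transcript_model(tx$transcript_id, ex, tx$isoform_tag)
}

merge_exon_pair <- function(tx, i) {
  ex <- tx$cds_exons
  ex$end[i] <- ex$end[i + 1L]
  ex <- ex[-(i + 1L), , drop = FALSE]
  transcript_model(tx$transcript_id, ex, tx$isoform_tag)
}

# extend the terminal (3') exon into downstream genomic sequence until the
# next in-frame stop codon; returns NULL when none is found within `limit` nt
extend_terminal_exon <- function(genome, model, tx, limit = 600L) {
  scaf <- genome$scaffolds[[model$scaffold_id]]
  ex <- tx$cds_exons
  cds_len <- sum(ex$end - ex$start)
  frame_used <- cds_len %% 3L
  if (model$strand == "+") {
    from <- ex$end[nrow(ex)]
    avail <- min(limit, nchar(scaf) - from)
    if (avail < 3L) return(NULL)
    tail_dna <- substr(scaf, from + 1L - frame_used, from + avail)
  } else {
    from <- ex$start[1L]
    avail <- min(limit, from)
    if (avail < 3L) return(NULL)
    tail_dna <- revcomp(substr(scaf, from - avail + 1L, from + frame_used))
  }
  # scan codons of the extension (aligned to the CDS reading frame)
  n3 <- (nchar(tail_dna) %/% 3L) * 3L
  if (n3 < 3L) return(NULL)
  tr <- translate_cds(substr(tail_dna, 1L, n3))
  stop_at <- c(tr$stop_codons,
               if (tr$has_terminal_stop) n3 %/% 3L)[1L]
  if (is.na(stop_at)) return(NULL)
  add <- stop_at * 3L - frame_used   # nt appended after the annotated end
  if (add <= 0L) return(NULL)
  if (model$strand == "+") ex$end[nrow(ex)] <- ex$end[nrow(ex)] + add
  else ex$start[1L] <- ex$start[1L] - add
  transcript_model(tx$transcript_id, ex, tx$isoform_tag)
}

#' Reassign exon/intron structure against a template
#'
#' Bounded exhaustive search over structural edit sets of size at most
#' `max_edits` drawn from: drop an annotated exon (exon is really intron),
#' merge two adjacent exons reading through the intervening intron (intron is
#' really exon), and extend the terminal exon into the annotated intron /
#' downstream sequence until the next in-frame stop. The accepted edit set
#' maximizes template alignment score subject to a stop-free ORF; ties go to
#' fewest edits, then smallest total nucleotides changed.
#'
#' @inheritParams rescue_start_site
#' @return list with `best` candidate, `edited` (logical) and all scored
#'   `candidates`.
#' @export
reassign_exons <- function(genome, model, template_protein,
                           config = curation_config()) {
  tx <- model$transcripts[[1L]]
  scheme <- config$scheme
  n_ex <- nrow(tx$cds_exons)
  base <- evaluate_candidate(genome, model, tx, template_protein, scheme)
  cands <- list(base)

  add_cand <- function(tx2, edits, n_changed) {
    if (is.null(tx2)) return()
    m2 <- model
    m2$transcripts[[1L]] <- tx2
    cands[[length(cands) + 1L]] <<-
      evaluate_candidate(genome, m2, tx2, template_protein, scheme,
                         edits = edits, n_changed = n_changed)
  }

  exon_sets <- list()
  if (n_ex > 1L) {
    for (i in seq_len(n_ex)) exon_sets <- c(exon_sets, list(i))
    if (config$max_edits >= 2L && n_ex > 2L)
      for (i in seq_len(n_ex - 1L)) for (j in seq(i + 1L, n_ex))
        exon_sets <- c(exon_sets, list(c(i, j)))
  }
  for (set in exon_sets) {
    tx2 <- drop_exons(tx, set)
    if (is.null(tx2)) next
    nt <- sum(tx$cds_exons$end[set] - tx$cds_exons$start[set])
    add_cand(tx2, sprintf("EXON_IS_INTRON:%s", paste(set, collapse = "+")), nt)
  }
  if (n_ex > 1L) {
    for (i in seq_len(n_ex - 1L)) {
      tx2 <- merge_exon_pair(tx, i)
      nt <- tx$cds_exons$start[i + 1L] - tx$cds_exons$end[i]
      add_cand(tx2, sprintf("INTRON_IS_EXON:merge%d", i), nt)
      if (config$max_edits >= 2L && n_ex > 2L) {
        for (j in seq_len(nrow(tx2$cds_exons) - 1L)) {
          tx3 <- merge_exon_pair(tx2, j)
          add_cand(tx3, sprintf("INTRON_IS_EXON:merge%d+%d", i, j), nt)
        }
      }
    }
  }
  tx_ext <- extend_terminal_exon(genome, model, tx)
  if (!is.null(tx_ext))
    add_cand(tx_ext, "INTRON_IS_EXON:extend_terminal",
             cds_length(tx_ext) - cds_length(tx))
  if (config$max_edits >= 2L) {
    # drop-then-extend combinations (a spurious terminal exon can displace
    # the true stop codon)
    for (set in exon_sets) {
      tx2 <- drop_exons(tx, set)
      if (is.null(tx2)) next
      m2 <- model; m2$transcripts[[1L]] <- tx2
      tx3 <- extend_terminal_exon(genome, m2, tx2)
      if (!is.null(tx3))
        add_cand(tx3, sprintf("EXON_IS_INTRON:%s;INTRON_IS_EXON:extend_terminal",
                              paste(set, collapse = "+")),
                 sum(tx$cds_exons$end[set] - tx$cds_exons$start[set]))
    }
  }

  n_edits <- vapply(cands, function(c) length(strsplit(
    paste(c$edits, collapse = ";"), ";")[[1L]]), 0L)
  n_edits[vapply(cands, function(c) !length(c$edits), TRUE)] <- 0L
  ok <- vapply(cands, `[[`, TRUE, "stop_free") &
        vapply(cands, `[[`, TRUE, "frame_ok")
  pool <- if (any(ok)) cands[ok] else cands
  pe <- n_edits[if (any(ok)) ok else rep(TRUE, length(cands))]
  ord <- order(-vapply(pool, `[[`, 0, "score"), pe,
               vapply(pool, function(c) as.numeric(c$n_changed), 0))
  best <- pool[[ord[1L]]]
  list(best = best, edited = length(best$edits) > 0L,
       candidates = pool[ord], any_stop_free = any(ok))
}

#' Detect sequencing gaps (N runs) under a gene model
#'
#' Maximal runs of at least `min_run` consecutive `N` characters within the
#' gene span, flagged for overlap with the model's exon projection. A run
#' wholly inside introns is reported but flagged non-overlapping (it does not
#' affect the protein).
#'
#' @param genome target `genome`.
#' @param model `gene_model` to inspect.
#' @param min_run minimum run length (default 5).
#' @return data.frame with `start`, `end` (0-based half-open scaffold
#'   coordinates) and `overlaps_cds`.
#' @export
detect_sequence_gaps <- function(genome, model, min_run = 5L) {
  scaf <- genome$scaffolds[[model$scaffold_id]]
  sp <- gene_span(model)
  region <- substr(scaf, sp[1L] + 1L, sp[2L])
  hits <- gregexpr(sprintf("N{%d,}", min_run), region)[[1L]]
  empty <- data.frame(start = integer(), end = integer(),
                      overlaps_cds = logical())
  if (hits[1L] == -1L) return(empty)
  st <- sp[1L] + as.integer(hits) - 1L
  en <- st + attr(hits, "match.length")
  ex <- do.call(rbind, lapply(model$transcripts, function(t) t$cds_exons))
  overlaps <- vapply(seq_along(st), function(i)
    any(pmax(ex$start, st[i]) < pmin(ex$end, en[i])), TRUE)
  data.frame(start = st, end = en, overlaps_cds = overlaps)
}

#' Detect frameshift indels with virtual single-nucleotide edits
#'
#' Runs [codon_align()] of the annotated CDS against the template and, when
#' it reports at most `k_max` frameshift events, applies virtual edits (a
#' placeholder `N` insertion for each missing nucleotide, a deletion for each
#' extra one), re-derives the ORF and reports identities before and after.
#'
#' @inheritParams rescue_start_site
#' @return list with `edits` data.frame (`kind`, `dna_position`),
#'   `correctable`, `n_frameshifts`, `identity_before`, `identity_after`,
#'   `corrected_cds`, `corrected_protein`, `premature_stops`.
#' @export
detect_frameshift_indels <- function(genome, model, template_protein,
                                     config = curation_config()) {
  tx <- model$transcripts[[1L]]
  dna <- extract_cds(genome, tx, model$scaffold_id, model$strand)
  ca <- codon_align(dna, template_protein, config$scheme)
  ev <- ca$events
  fs <- ev[grepl("^FRAMESHIFT", ev$kind), , drop = FALSE]
  n_fs <- nrow(fs)
  out <- list(edits = data.frame(kind = character(), dna_position = integer()),
              correctable = FALSE, n_frameshifts = n_fs,
              identity_before = ca$raw_identity,
              identity_after = ca$raw_identity,
              corrected_cds = dna, corrected_protein = NULL,
              premature_stops = ev[ev$kind == "PREMATURE_STOP", , drop = FALSE],
              codon_alignment = ca)
  if (n_fs == 0L || n_fs > config$k_max) return(out)
  # The DP localizes each shift to within a codon or so; the exact offset of
  # the virtual edit inside that window matters (a misplaced edit can forge
  # a local stop codon), so all in-window offsets are tried and the best
  # stop-free outcome kept.
  apply_edits <- function(offsets) {
    corrected <- dna
    edits <- data.frame(kind = character(), dna_position = integer())
    ord <- order(-fs$dna_position)
    for (k in seq_along(ord)) {
      r <- ord[k]
      p <- fs$dna_position[r] + offsets[r]; s <- fs$shift[r]
      p <- max(1L, min(p, nchar(corrected)))
      if (s < 0L) {         # nucleotide(s) missing: insert placeholder N
        corrected <- paste0(substr(corrected, 1L, p - 1L), strrep("N", -s),
                            substr(corrected, p, nchar(corrected)))
        edits <- rbind(edits,
                       data.frame(kind = "NT_INSERTION", dna_position = p))
      } else {              # extra nucleotide(s): delete them
        corrected <- paste0(substr(corrected, 1L, p - 1L),
                            substr(corrected, p + s, nchar(corrected)))
        edits <- rbind(edits,
                       data.frame(kind = "NT_DELETION", dna_position = p))
      }
    }
    n3 <- (nchar(corrected) %/% 3L) * 3L
    tr <- translate_cds(substr(corrected, 1L, n3))
    prot <- if (tr$premature_stop)
      substr(tr$sequence, 1L, tr$stop_codons[1L] - 1L) else tr$sequence
    list(corrected = corrected, edits = edits, prot = prot,
         stop_free = !tr$premature_stop)
  }
  offset_grid <- do.call(expand.grid, rep(list(0:3), n_fs))
  best <- NULL
  for (g in seq_len(nrow(offset_grid))) {
    cand <- apply_edits(as.integer(offset_grid[g, ]))
    better <- is.null(best) ||
      (cand$stop_free && !best$stop_free) ||
      (cand$stop_free == best$stop_free &&
         nchar(cand$prot) > nchar(best$prot))
    if (better) best <- cand
    if (best$stop_free) break   # offsets are tried in DP-position order
  }
  prot <- best$prot
  out$edits <- best$edits[order(best$edits$dna_position), , drop = FALSE]
  out$corrected_cds <- best$corrected
  out$corrected_protein <- prot
  out$identity_after <- if (nzchar(prot))
    protein_identity(prot, template_protein, config$scheme) else 0
  out$correctable <- best$stop_free &&
    nchar(prot) >= config$full_frac * nchar(template_protein) &&
    out$identity_after >= out$identity_before
  out
}

#' Pseudogene check against template length and catalytic anchors
#'
#' A gene is a pseudogene when its longest restorable stop-free ORF is
#' shorter than `length_frac` x template length, or when a catalytic anchor
#' position falls in an unaligned or deleted region of the best model.
#'
#' @param best_protein best achievable protein from the earlier stages.
#' @param template_protein template amino-acid sequence.
#' @param anchors optional [catalytic_anchor()].
#' @param config a [curation_config()].
#' @param had_premature_stop logical: a premature stop was observed upstream.
#' @return list with `is_pseudogene`, `subtype`, `reasons`.
#' @export
pseudogene_check <- function(best_protein, template_protein, anchors = NULL,
                             config = curation_config(),
                             had_premature_stop = FALSE) {
  tlen <- nchar(template_protein)
  blen <- nchar(best_protein %||% "")
  reasons <- character()
  subtype <- "none"
  if (blen < config$length_frac * tlen) {
    reasons <- c(reasons, sprintf(
      "best ORF %d aa < %.0f%% of template %d aa", blen,
      100 * config$length_frac, tlen))
    subtype <- if (had_premature_stop) "PREMATURE_STOP" else "TRUNCATION"
  }
  if (!is.null(anchors) && nzchar(best_protein %||% "")) {
    aln <- global_align(best_protein, template_protein, config$scheme)
    tb <- strsplit(aln$aligned_b, "")[[1L]]
    ta <- strsplit(aln$aligned_a, "")[[1L]]
    tpos <- cumsum(tb != "-")
    lost <- vapply(anchors$positions, function(p) {
      col <- match(p, tpos)
      is.na(col) || ta[col] == "-"
    }, TRUE)
    if (any(lost)) {
      reasons <- c(reasons, sprintf("catalytic anchor(s) %s unaligned/deleted",
                                    paste(anchors$positions[lost],
                                          collapse = ",")))
      if (subtype == "none") subtype <- "MOTIF_LOSS"
    }
  }
  list(is_pseudogene = length(reasons) > 0L, subtype = subtype,
       reasons = reasons)
}

subtype_from_edits <- function(edits, shift = 0L) {
  if (shift < 0L) return("START_UPSTREAM")
  if (shift > 0L) return("START_DOWNSTREAM")
  e <- paste(edits, collapse = ";")
  if (grepl("EXON_IS_INTRON", e)) return("EXON_IS_INTRON")
  if (grepl("INTRON_IS_EXON", e)) return("INTRON_IS_EXON")
  "none"
}

#' Curate one gene against its template ortholog
#'
#' Applies the full decision procedure with the precedence: sequencing gaps
#' (N runs over the projected CDS) beat everything and give
#' `SEQUENCING_ERROR`; structural edits that alone restore a full-length
#' stop-free ORF give `ANNOTATION_ERROR`; at most `k_max` virtual nucleotide
#' edits give `AMBIGUOUS_INDEL`; the pseudogene check gives `PSEUDOGENE`;
#' otherwise `ORTHOLOG_OK`.
#'
#' @param genome target `genome`.
#' @param model annotated `gene_model`.
#' @param template_protein template amino-acid sequence.
#' @param anchors optional [catalytic_anchor()] on the template.
#' @param config a [curation_config()].
#' @return a `curation_verdict`: `gene_id`, `category`, `subtype`,
#'   `corrected_model` (or `NULL`), `identity_before`, `identity_after`,
#'   `edits`, `notes`.
#' @export
curate_gene <- function(genome, model, template_protein, anchors = NULL,
                        config = curation_config()) {
  if (is.null(template_protein) || !nzchar(template_protein))
    stop("template protein missing for ", model$gene_id)
  scheme <- config$scheme
  tx <- model$transcripts[[1L]]
  base <- evaluate_candidate(genome, model, tx, template_protein, scheme)
  identity_before <- base$identity
  tlen <- nchar(template_protein)

  verdict <- function(category, subtype, corrected, identity_after, edits,
                      notes = "") {
    structure(list(gene_id = model$gene_id, category = category,
                   subtype = subtype, corrected_model = corrected,
                   identity_before = identity_before,
                   identity_after = identity_after,
                   edits = edits, notes = notes),
              class = "curation_verdict")
  }

  # (1) sequencing gaps
  gaps <- detect_sequence_gaps(genome, model, config$min_n_run)
  if (nrow(gaps) && any(gaps$overlaps_cds)) {
    return(verdict("SEQUENCING_ERROR", "N_RUN", NULL, identity_before,
                   gaps[gaps$overlaps_cds, , drop = FALSE],
                   notes = "needs re-sequencing; CDS overlaps assembly gap"))
  }

  # (2) structural edits: start rescue and exon reassignment
  resc <- rescue_start_site(genome, model, template_protein, config)
  reas <- reassign_exons(genome, model, template_protein, config)
  structural <- list(resc$best, reas$best)
  structural <- structural[order(-vapply(structural, `[[`, 0, "score"))]
  sb <- structural[[1L]]
  # identity may tick down within divergence noise when a fix restores
  # residues (the restored stretch carries its own mismatches); the score
  # criterion is the discriminating one. Mutual-column identity of a short
  # garbage baseline is meaningless, so the identity guard only applies when
  # the annotated protein has real coverage of the template.
  identity_guard <- nchar(base$protein) < config$length_frac * tlen ||
    sb$identity >= identity_before - 5
  structural_fix <-
    (length(sb$edits) > 0L) && sb$stop_free && sb$frame_ok &&
    nchar(sb$protein) >= config$full_frac * tlen &&
    nchar(sb$protein) <= (2 - config$full_frac) * tlen &&
    sb$score > base$score && identity_guard
  base_clean <- base$stop_free && base$frame_ok &&
    nchar(base$protein) >= config$full_frac * tlen &&
    nchar(base$protein) <= (2 - config$full_frac) * tlen
  if (structural_fix && !(base_clean && sb$score <= base$score)) {
    return(verdict("ANNOTATION_ERROR",
                   subtype_from_edits(sb$edits, sb$shift),
                   sb$model, sb$identity, sb$edits))
  }

  # (3) bounded virtual nucleotide edits
  if (!base_clean) {
    fsi <- detect_frameshift_indels(genome, model, template_protein, config)
    if (fsi$n_frameshifts >= 1L && fsi$correctable) {
      return(verdict("AMBIGUOUS_INDEL", fsi$edits$kind[1L], model,
                     fsi$identity_after, fsi$edits,
                     notes = paste("virtual edits; sequencing coverage",
                                   "unknown, indel vs sequencing error",
                                   "unresolved")))
    }
    # (4) pseudogene check. Only corrections accepted upstream count as
    # "restorable": a drop-exon candidate that merely excises a premature
    # stop, or virtual edits that failed the correctability test, are not
    # evidence of a longer true ORF.
    best_prot <- base$protein
    had_stop <- base$frame_ok && !base$stop_free
    pg <- pseudogene_check(best_prot, template_protein, anchors, config,
                           had_premature_stop = had_stop)
    if (pg$is_pseudogene) {
      return(verdict("PSEUDOGENE", pg$subtype, NULL,
                     protein_identity(best_prot, template_protein, scheme),
                     data.frame(), notes = paste(pg$reasons, collapse = "; ")))
    }
  } else if (!is.null(anchors)) {
    pg <- pseudogene_check(base$protein, template_protein, anchors, config)
    if (pg$is_pseudogene)
      return(verdict("PSEUDOGENE", pg$subtype, NULL, identity_before,
                     data.frame(), notes = paste(pg$reasons, collapse = "; ")))
  }

  # (5) ortholog as annotated
  verdict("ORTHOLOG_OK", "none", NULL, identity_before, data.frame(),
          notes = if (identity_before < config$identity_floor)
            sprintf("identity %.0f%% below orthology floor %.0f%%",
                    identity_before, config$identity_floor) else "")
}

#' @export
print.curation_verdict <- function(x, ...) {
  cat(sprintf("<curation_verdict> %s: %s/%s  identity %.1f%% -> %.1f%%\n",
              x$gene_id, x$category, x$subtype,
              x$identity_before, x$identity_after))
  invisible(x)
}

#' Curate a panel of genes and write a report
#'
#' @param genome target `genome`.
#' @param models list of `gene_model`s.
#' @param templates named character vector of template proteins, keyed by
#'   ortholog label.
#' @param anchors optional named list of [catalytic_anchor()]s by label.
#' @param config a [curation_config()].
#' @return data.frame report, one row per gene, with the verdicts attached
#'   as attribute `"verdicts"`.
#' @export
curate_panel <- function(genome, models, templates, anchors = NULL,
                         config = curation_config()) {
  verdicts <- lapply(models, function(gm) {
    tp <- templates[[gm$ortholog_label]]
    an <- if (!is.null(anchors)) anchors[[gm$ortholog_label]] else NULL
    curate_gene(genome, gm, tp, an, config)
  })
  rep <- data.frame(
    gene_id = vapply(verdicts, `[[`, "", "gene_id"),
    category = vapply(verdicts, `[[`, "", "category"),
    subtype = vapply(verdicts, `[[`, "", "subtype"),
    identity_before = vapply(verdicts, `[[`, 0, "identity_before"),
    identity_after = vapply(verdicts, `[[`, 0, "identity_after"),
    n_edits = vapply(verdicts, function(v)
      if (is.data.frame(v$edits)) nrow(v$edits) else length(v$edits), 0L),
    notes = vapply(verdicts, `[[`, "", "notes"),
    row.names = NULL)
  attr(rep, "verdicts") <- verdicts
  rep
}
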