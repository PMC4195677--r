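# Deterministic synthetic genomes carrying a GST-like clustered gene family,
# divergence simulation, and injection of annotation/sequencing defects and
# rearrangements with a ground-truth ledger.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.bases <- c("A", "C", "G", "T")
.comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
.stops <- c("TAA", "TAG", "TGA")
.sense_codons <- {
  all64 <- as.vector(outer(outer(.bases, .bases, paste0), .bases, paste0))
  setdiff(all64, .stops)
}
.aa2codon <- c(S = "TCT", H = "CAT", A = "GCT", I = "ATT", M = "ATG")

rand_dna <- function(n) paste(sample(.bases, n, replace = TRUE), collapse = "")

#' Family specification for the synthetic generator
#'
#' Defaults describe a GST-like family: six classes laid out as tandem
#' clusters on separate scaffolds, coding sequences of 600-800 nt (the usual
#' GST gene length), 1-6 coding exons with introns of 60-120 nt, intergenic
#' spacers of 200-500 nt, and a planted Ser-His-Ala-Ile catalytic anchor.
#'
#' @param genes_per_cluster integer vector, genes per class cluster (length
#'   defines `n_classes`).
#' @param exon_counts candidate exon counts per gene.
#' @param cds_range CDS length range in nt (snapped to multiples of 3).
#' @param intron_range,spacer_range intron / intergenic length ranges.
#' @param min_exon_nt minimum exon length.
#' @param n_spliced_genes number of alternatively spliced template genes
#'   (patterned after the family's D11/Z2/T3/O2 isoform structures).
#' @param anchor_positions template residue indices of the catalytic motif.
#' @param seed integer seed; every generator output is a pure function of
#'   (spec, seed).
#' @return a `family_spec` list.
#' @export
family_spec <- function(genes_per_cluster = c(4L, 4L, 3L, 3L, 2L, 2L),
                        exon_counts = 1:6,
                        cds_range = c(600L, 800L),
                        intron_range = c(60L, 120L),
                        spacer_range = c(200L, 500L),
                        min_exon_nt = 60L,
                        n_spliced_genes = 0L,
                        anchor_positions = 60:63,
                        seed = 1L) {
  stopifnot(all(genes_per_cluster > 0L), cds_range[1L] >= 300L,
            intron_range[1L] >= 40L, spacer_range[1L] >= 100L)
  structure(list(genes_per_cluster = as.integer(genes_per_cluster),
                 n_classes = length(genes_per_cluster),
                 exon_counts = as.integer(exon_counts),
                 cds_range = as.integer(cds_range),
                 intron_range = as.integer(intron_range),
                 spacer_range = as.integer(spacer_range),
                 min_exon_nt = as.integer(min_exon_nt),
                 n_spliced_genes = as.integer(n_spliced_genes),
                 anchor_positions = as.integer(anchor_positions),
                 seed = as.integer(seed)),
            class = "family_spec")
}

# random CDS of naa residues (incl. leading Met, excl. stop) + terminal TAA,
# with the catalytic anchor motif planted at fixed residue positions
random_cds <- function(naa, anchor_positions) {
  codons <- c("ATG", sample(.sense_codons, naa - 1L, replace = TRUE))
  motif <- c("S", "H", "A", "I")
  for (k in seq_along(anchor_positions))
    codons[anchor_positions[k]] <- .aa2codon[[motif[(k - 1L) %% 4L + 1L]]]
  paste(c(codons, "TAA"), collapse = "")
}

# split length L into k exon sizes, each >= min_nt
split_exons <- function(L, k, min_nt) {
  extra <- L - k * min_nt
  if (extra < 0L) return(rep(L %/% k, k) + c(L %% k, rep(0L, k - 1L)))
  w <- as.vector(stats::rmultinom(1L, extra, rep(1 / k, k)))
  min_nt + w
}

make_intron <- function(range) {
  len <- sample(seq(range[1L], range[2L]), 1L)
  paste0("GT", rand_dna(len - 4L), "AG")
}

#' Generate a template genome with a clustered multi-class gene family
#'
#' Genes are placed in tandem clusters (one scaffold per class) with random
#' strands; every model translates stop-free; spliced genes follow the
#' family's isoform-sharing patterns (alternative first exons with a shared
#' tail, or a shared head with alternative terminal exons). Deterministic
#' for a fixed spec.
#'
#' @param spec a [family_spec()].
#' @param species_tag tag stored on the genome (default `"Tpl"`).
#' @return a bundle: list with `genome`, `models` (list of `gene_model`),
#'   `proteins` (named by ortholog label), `anchors` (named list of
#'   [catalytic_anchor()]), `isoform_templates`, `spec`.
#' @export
generate_family <- function(spec = family_spec(), species_tag = "Tpl") {
  with_seed(spec$seed, {
    class_letters <- c("D", "E", "O", "T", "S", "Z")
    scaffolds <- character(); models <- list()
    proteins <- character(); anchors <- list()
    for (ci in seq_len(spec$n_classes)) {
      letter <- class_letters[(ci - 1L) %% 6L + 1L]
      scaf_id <- sprintf("scaf_%s", letter)
      parts <- character(); cursor <- 0L
      for (gi in seq_len(spec$genes_per_cluster[ci])) {
        spacer <- rand_dna(sample(seq(spec$spacer_range[1L],
                                      spec$spacer_range[2L]), 1L))
        parts <- c(parts, spacer); cursor <- cursor + nchar(spacer)
        naa <- sample(seq(spec$cds_range[1L] %/% 3L,
                          spec$cds_range[2L] %/% 3L), 1L) - 1L
        cds <- random_cds(naa, spec$anchor_positions)
        k <- sample(spec$exon_counts, 1L)
        k <- min(k, nchar(cds) %/% spec$min_exon_nt)
        sizes <- split_exons(nchar(cds), k, spec$min_exon_nt)
        exon_seqs <- substring(cds, cumsum(c(0L, sizes[-k])) + 1L,
                               cumsum(sizes))
        introns <- if (k > 1L)
          vapply(seq_len(k - 1L), function(i) make_intron(spec$intron_range),
                 "") else character()
        block <- paste(c(rbind(exon_seqs, c(introns, ""))), collapse = "")
        strand <- sample(c("+", "-"), 1L)
        placed <- if (strand == "+") block else revcomp(block)
        # transcript-order exon offsets within the forward block
        off <- cumsum(c(0L, head(sizes, -1L) + nchar(c(introns, ""))[-k] *
                          (k > 1L)))
        if (k == 1L) off <- 0L
        starts_blk <- off; ends_blk <- off + sizes
        B <- nchar(block)
        ex <- if (strand == "+")
          data.frame(start = cursor + starts_blk, end = cursor + ends_blk)
        else
          data.frame(start = cursor + B - ends_blk,
                     end = cursor + B - starts_blk)
        label <- sprintf("GST%s%d", letter, gi)
        gid <- sprintf("%s_%s", species_tag, label)
        tx <- transcript_model(paste0(gid, "-RA"), ex)
        gm <- gene_model(gid, scaf_id, strand, list(tx),
                         ortholog_label = label,
                         class_label = c(D = "Delta", E = "Epsilon",
                                         O = "Omega", T = "Theta",
                                         S = "Sigma", Z = "Zeta")[[letter]])
        models[[gid]] <- gm
        proteins[[label]] <- translate_cds(cds)$sequence
        anchors[[label]] <- catalytic_anchor(label, spec$anchor_positions)
        parts <- c(parts, placed); cursor <- cursor + B
      }
      parts <- c(parts, rand_dna(200L))
      scaffolds[[scaf_id]] <- paste(parts, collapse = "")
    }
    iso_templates <- list()
    if (spec$n_spliced_genes > 0L) {
      patterns <- rep(c("alt_first", "alt_last"),
                      length.out = spec$n_spliced_genes)
      labels <- rep(c("GSTD11", "GSTZ2", "GSTT3", "GSTO2"),
                    length.out = spec$n_spliced_genes)
      n_isos <- rep(c(2L, 3L, 2L, 2L), length.out = spec$n_spliced_genes)
      for (si in seq_len(spec$n_spliced_genes)) {
        sg <- make_spliced_gene(labels[si], patterns[si], n_isos[si], spec,
                                species_tag)
        scaffolds[[sg$scaffold_id]] <- sg$sequence
        models[[sg$model$gene_id]] <- sg$model
        for (tag in names(sg$proteins))
          proteins[[paste0(labels[si], tag)]] <- sg$proteins[[tag]]
        iso_templates[[labels[si]]] <- sg$template
      }
    }
    list(genome = genome(scaffolds, species_tag = species_tag),
         models = models, proteins = proteins, anchors = anchors,
         isoform_templates = iso_templates, spec = spec)
  })
}

# Build one alternatively spliced gene on its own scaffold (forward strand).
# alt_first: isoform-specific first exons, shared tail (Z2/T3/D11 pattern).
# alt_last : shared head, alternative terminal exons (O2 pattern).
make_spliced_gene <- function(label, pattern, n_iso, spec, species_tag) {
  scaf_id <- sprintf("scaf_%s", label)
  gid <- sprintf("%s_%s", species_tag, label)
  tags <- LETTERS[seq_len(n_iso)]
  intr <- function() make_intron(spec$intron_range)
  utr_len <- 60L
  if (pattern == "alt_first") {
    shared_aa <- 150L
    first_aa <- sample(55:70, n_iso)
    shared1 <- paste(sample(.sense_codons, 70L, replace = TRUE),
                     collapse = "")
    shared2 <- paste(c(sample(.sense_codons, shared_aa - 70L - 1L,
                              replace = TRUE), "TAA"), collapse = "")
    firsts <- lapply(first_aa, function(na)
      paste(c("ATG", sample(.sense_codons, na - 1L, replace = TRUE)),
            collapse = ""))
    pieces <- list()
    for (i in seq_len(n_iso)) pieces <- c(pieces, firsts[i], list(intr()))
    pieces <- c(pieces, list(shared1, intr(), shared2))
    kinds <- c(rbind(paste0("first", seq_len(n_iso)), "intron"),
               "shared1", "intron", "shared2")
  } else {
    head1 <- paste(c("ATG", sample(.sense_codons, 69L, replace = TRUE)),
                   collapse = "")
    head2 <- paste(sample(.sense_codons, 80L, replace = TRUE), collapse = "")
    tails <- lapply(seq_len(n_iso), function(i)
      paste(c(sample(.sense_codons, sample(55:70, 1L), replace = TRUE),
              "TAA"), collapse = ""))
    pieces <- list(head1, intr(), head2)
    # proximal terminal exon belongs to the *last* tag (B), distal to A:
    # losing the distal exon leaves only the proximal isoform
    for (i in rev(seq_len(n_iso)))
      pieces <- c(pieces, list(intr()), tails[i])
    kinds <- c("head1", "intron", "head2",
               c(rbind("intron", paste0("tail", rev(seq_len(n_iso))))))
  }
  lead <- rand_dna(300L)
  seqs <- vapply(pieces, identity, "")
  starts <- nchar(lead) + cumsum(c(0L, head(nchar(seqs), -1L)))
  ends <- starts + nchar(seqs)
  exon_rows <- which(kinds != "intron")
  exons <- data.frame(exon_id = kinds[exon_rows],
                      start = starts[exon_rows], end = ends[exon_rows],
                      role = "unique", stringsAsFactors = FALSE)
  sequence <- paste0(lead, paste(seqs, collapse = ""), rand_dna(300L))
  if (pattern == "alt_first") {
    exons$role[exons$exon_id %in% c("shared1", "shared2")] <- "shared"
    isoforms <- lapply(seq_len(n_iso), function(i)
      c(paste0("first", i), "shared1", "shared2"))
  } else {
    exons$role[exons$exon_id %in% c("head1", "head2")] <- "shared"
    isoforms <- lapply(seq_len(n_iso), function(i)
      c("head1", "head2", paste0("tail", i)))
  }
  names(isoforms) <- tags
  utr5 <- lapply(seq_len(n_iso), function(i) {
    fe <- exons[exons$exon_id == isoforms[[i]][1L], ]
    c(fe$start - utr_len, fe$start)
  })
  utr3 <- lapply(seq_len(n_iso), function(i) {
    le <- exons[exons$exon_id == isoforms[[i]][length(isoforms[[i]])], ]
    c(le$end, le$end + utr_len)
  })
  names(utr5) <- names(utr3) <- tags
  exseq <- function(id) {
    r <- exons[exons$exon_id == id, ]
    substr(sequence, r$start + 1L, r$end)
  }
  prots <- lapply(isoforms, function(chain)
    translate_cds(paste(vapply(chain, exseq, ""), collapse = ""))$sequence)
  txs <- lapply(seq_len(n_iso), function(i) {
    rows <- exons[match(isoforms[[i]], exons$exon_id), ]
    transcript_model(sprintf("%s-R%s", gid, tags[i]),
                     rows[, c("start", "end")], isoform_tag = tags[i])
  })
  model <- gene_model(gid, scaf_id, "+", txs, ortholog_label = label)
  template <- structure(list(gene_id = gid, locus = scaf_id,
                             exons = exons, isoforms = isoforms,
                             utr5 = utr5, utr3 = utr3,
                             proteins = prots),
                        class = "isoform_template")
  list(scaffold_id = scaf_id, sequence = sequence, model = model,
       proteins = prots, template = template)
}

# scaffold positions (1-based) of a transcript's CDS in transcript order
tx_positions <- function(model, tx) {
  ex <- tx$cds_exons
  if (model$strand == "+")
    unlist(lapply(seq_len(nrow(ex)),
                  function(i) seq(ex$start[i] + 1L, ex$end[i])))
  else
    unlist(lapply(rev(seq_len(nrow(ex))),
                  function(i) seq(ex$end[i], ex$start[i] + 1L)))
}

tx_base <- function(chars, model, pos) {
  b <- chars[pos]
  if (model$strand == "+") b else unname(.comp[b])
}

#' Evolve a template bundle into a diverged target genome
#'
#' Per-site substitutions at `sub_rate` with Jukes-Cantor-symmetric
#' replacement, under purifying selection: substitutions that would create an
#' internal in-frame stop codon in any transcript, destroy the ATG start or
#' terminal stop, or break a GT..AG splice dinucleotide are rejected.
#' Annotation coordinates carry over unchanged (no background indels).
#'
#' @param bundle output of [generate_family()].
#' @param sub_rate substitution rate per site, `0 <= sub_rate < 0.5`.
#' @param seed integer seed.
#' @param species_tag tag for the target genome.
#' @return a bundle like the input with mutated `genome` and re-identified
#'   `models` (gene ids re-tagged), plus `proteins` of the evolved genes.
#' @export
evolve_target <- function(bundle, sub_rate, seed = 1L, species_tag = "Tgt") {
  if (sub_rate < 0 || sub_rate >= 0.5) stop("sub_rate out of [0, 0.5)")
  with_seed(seed, {
    scaffolds <- bundle$genome$scaffolds
    models <- bundle$models
    by_scaf <- split(models, vapply(models, `[[`, "", "scaffold_id"))
    for (scaf_id in names(scaffolds)) {
      chars <- strsplit(scaffolds[[scaf_id]], "")[[1L]]
      len <- length(chars)
      sms <- by_scaf[[scaf_id]]
      protected <- logical(len)
      txinfo <- list()
      for (gm in sms) for (tx in gm$transcripts) {
        pos <- tx_positions(gm, tx)
        L <- length(pos)
        protected[pos[1:3]] <- TRUE
        protected[pos[(L - 2L):L]] <- TRUE
        ex <- tx$cds_exons
        if (nrow(ex) > 1L) for (i in seq_len(nrow(ex) - 1L)) {
          protected[c(ex$end[i] + 1L, ex$end[i] + 2L,
                      ex$start[i + 1L] - 1L, ex$start[i + 1L])] <- TRUE
        }
        txinfo[[length(txinfo) + 1L]] <-
          list(gm = gm, pos = pos, span = range(pos))
      }
      if (sub_rate > 0) {
        sites <- which(stats::runif(len) < sub_rate & !protected &
                         chars != "N")
        for (p in sites) {
          newb <- sample(setdiff(.bases, chars[p]), 1L)
          ok <- TRUE
          for (ti in txinfo) {
            if (p < ti$span[1L] || p > ti$span[2L]) next
            q <- match(p, ti$pos)
            if (is.na(q)) next
            c0 <- ((q - 1L) %/% 3L) * 3L
            if (c0 + 3L >= length(ti$pos)) next  # terminal codon protected
            cpos <- ti$pos[(c0 + 1L):(c0 + 3L)]
            cc <- chars[cpos]
            cc[cpos == p] <- newb
            codon <- paste(if (ti$gm$strand == "+") cc else
              unname(.comp[cc]), collapse = "")
            if (codon %in% .stops) { ok <- FALSE; break }
          }
          if (ok) chars[p] <- newb
        }
      }
      scaffolds[[scaf_id]] <- paste(chars, collapse = "")
    }
    g <- genome(scaffolds, species_tag = species_tag)
    new_models <- lapply(models, function(gm) {
      gm$gene_id <- sub("^[^_]+_", paste0(species_tag, "_"), gm$gene_id)
      gm
    })
    names(new_models) <- vapply(new_models, `[[`, "", "gene_id")
    prots <- lapply(new_models, function(gm)
      translate_cds(extract_cds(g, gm$transcripts[[1L]], gm$scaffold_id,
                                gm$strand))$sequence)
    list(genome = g, models = new_models, proteins = prots,
         anchors = bundle$anchors, isoform_templates = bundle$isoform_templates,
         template_proteins = bundle$proteins, spec = bundle$spec,
         sub_rate = sub_rate)
  })
}

shift_models_after <- function(models, scaf_id, offset0, delta) {
  lapply(models, function(gm) {
    if (gm$scaffold_id != scaf_id) return(gm)
    gm$transcripts <- lapply(gm$transcripts, function(tx) {
      ex <- tx$cds_exons
      if (delta < 0L) {       # deletion at 0-based index offset0
        ex$start <- ex$start + ifelse(ex$start > offset0, delta, 0L)
        ex$end <- ex$end + ifelse(ex$end > offset0, delta, 0L)
      } else {                # insertion occupying 0-based index offset0;
                              # a base landing on an exon boundary joins the exon
        ex$start <- ex$start + ifelse(ex$start > offset0, delta, 0L)
        ex$end <- ex$end + ifelse(ex$end > offset0, delta, 0L)
      }
      transcript_model(tx$transcript_id, ex, tx$isoform_tag)
    })
    gm
  })
}

write_tx_bases <- function(chars, model, positions, bases) {
  b <- if (model$strand == "+") bases else unname(.comp[bases])
  chars[positions] <- b
  chars
}

#' Inject one annotation/sequencing defect into a target bundle
#'
#' Applies exactly the specified change to the sequence and/or annotation and
#' records a ground-truth entry carrying the expected curation category.
#'
#' Defect kinds: `START_SHIFT` (params `n`, `direction` `"true_upstream"` /
#' `"true_downstream"`), `EXONIFY_INTRON`, `INTRONIFY_EXON`, `DELETE_NT`
#' (`codon`), `INSERT_NT` (`codon`), `PREMATURE_STOP` (`codon`), `N_RUN`
#' (`codon`, `len`), `TRUNCATE` (`frac`).
#'
#' @param bundle target bundle from [evolve_target()].
#' @param gene_id gene to mutate.
#' @param kind defect kind (see Details).
#' @param ... kind-specific parameters.
#' @return the mutated bundle; the new ground-truth record is appended to
#'   `bundle$truth`.
#' @export
inject_error <- function(bundle, gene_id, kind, ...) {
  p <- list(...)
  gm <- bundle$models[[gene_id]]
  if (is.null(gm)) stop("unknown gene ", gene_id)
  tx <- gm$transcripts[[1L]]
  scaf_id <- gm$scaffold_id
  chars <- strsplit(bundle$genome$scaffolds[[scaf_id]], "")[[1L]]
  pos <- tx_positions(gm, tx)
  L <- length(pos)
  naa <- L %/% 3L - 1L
  rec <- list(gene_id = gene_id, kind = kind, params = p)

  if (kind == "START_SHIFT") {
    n <- p$n %||% (3L * sample(10:30, 1L))
    n <- (n %/% 3L) * 3L
    dir <- p$direction %||% "true_upstream"
    if (dir == "true_upstream") {
      # the shrunk first exon must keep at least 30 nt
      ex1 <- tx$cds_exons
      e1len <- if (gm$strand == "+") ex1$end[1L] - ex1$start[1L]
               else ex1$end[nrow(ex1)] - ex1$start[nrow(ex1)]
      n <- min(n, ((e1len - 30L) %/% 3L) * 3L)
      if (n < 9L) n <- 9L
    }
    cur <- tx_start_coord(gm, tx)
    new_start <- if (dir == "true_upstream") {
      if (gm$strand == "+") cur + n else cur - n
    } else {
      if (gm$strand == "+") cur - n else cur + n
    }
    gm2 <- with_first_exon_start(gm, 1L, new_start)
    bundle$models[[gene_id]] <- gm2
    rec$expected_category <- "ANNOTATION_ERROR"
    rec$expected_subtype <- if (dir == "true_upstream") "START_UPSTREAM"
                            else "START_DOWNSTREAM"
    rec$params$n <- n
  } else if (kind == "EXONIFY_INTRON") {
    ex <- tx$cds_exons
    if (nrow(ex) < 2L) stop("EXONIFY_INTRON needs a multi-exon gene")
    widths <- ex$start[-1L] - ex$end[-nrow(ex)]
    i <- which.max(widths)
    f <- min(60L, ((widths[i] - 30L) %/% 3L) * 3L)
    fs <- ex$end[i] + 15L
    ex2 <- rbind(ex[seq_len(i), ],
                 data.frame(start = fs, end = fs + f),
                 ex[seq(i + 1L, nrow(ex)), ])
    bundle$models[[gene_id]]$transcripts[[1L]] <-
      transcript_model(tx$transcript_id, ex2, tx$isoform_tag)
    rec$expected_category <- "ANNOTATION_ERROR"
    rec$expected_subtype <- "EXON_IS_INTRON"
    rec$params$fake_exon <- c(fs, fs + f)
  } else if (kind == "INTRONIFY_EXON") {
    m <- p$m %||% 45L
    ex <- tx$cds_exons
    term <- if (gm$strand == "+") nrow(ex) else 1L
    elen <- ex$end[term] - ex$start[term]
    m <- min(m, elen - 15L)
    if (gm$strand == "+") ex$end[term] <- ex$end[term] - m
    else ex$start[term] <- ex$start[term] + m
    bundle$models[[gene_id]]$transcripts[[1L]] <-
      transcript_model(tx$transcript_id, ex, tx$isoform_tag)
    rec$expected_category <- "ANNOTATION_ERROR"
    rec$expected_subtype <- "INTRON_IS_EXON"
    rec$params$m <- m
  } else if (kind %in% c("DELETE_NT", "INSERT_NT")) {
    codon <- p$codon %||% sample(seq(round(0.2 * naa), round(0.8 * naa)), 1L)
    sp <- pos[3L * (codon - 1L) + 1L]
    if (kind == "DELETE_NT") {
      chars <- chars[-sp]
      bundle$models <- shift_models_after(bundle$models, scaf_id, sp - 1L, -1L)
      rec$expected_subtype <- "NT_INSERTION"   # the restoring virtual edit
    } else {
      chars <- append(chars, sample(.bases, 1L), after = sp - 1L)
      bundle$models <- shift_models_after(bundle$models, scaf_id, sp - 1L, +1L)
      rec$expected_subtype <- "NT_DELETION"
    }
    rec$expected_category <- "AMBIGUOUS_INDEL"
    rec$params$codon <- codon
  } else if (kind == "PREMATURE_STOP") {
    codon <- p$codon %||% sample(seq(round(0.2 * naa), round(0.6 * naa)), 1L)
    cpos <- pos[(3L * (codon - 1L) + 1L):(3L * codon)]
    chars <- write_tx_bases(chars, gm,
                            if (gm$strand == "+") cpos else rev(cpos)[3:1],
                            c("T", "A", "A"))
    rec$expected_category <- "PSEUDOGENE"
    rec$expected_subtype <- "PREMATURE_STOP"
    rec$params$codon <- codon
  } else if (kind == "N_RUN") {
    len <- p$len %||% 24L
    ex <- tx$cds_exons
    big <- which.max(ex$end - ex$start)
    st <- ex$start[big] + ((ex$end[big] - ex$start[big]) - len) %/% 2L
    chars[(st + 1L):(st + len)] <- "N"
    rec$expected_category <- "SEQUENCING_ERROR"
    rec$expected_subtype <- "N_RUN"
    rec$params$interval <- c(st, st + len)
  } else if (kind == "TRUNCATE") {
    frac <- p$frac %||% 0.5
    c0 <- max(3L, floor(frac * naa))
    tail_q <- seq(3L * c0 + 1L, L)
    chars <- write_tx_bases(chars, gm, pos[tail_q],
                            sample(.bases, length(tail_q), replace = TRUE))
    spos <- pos[(3L * (c0 + 1L) + 1L):(3L * (c0 + 2L))]
    chars <- write_tx_bases(chars, gm,
                            if (gm$strand == "+") spos else rev(spos)[3:1],
                            c("T", "A", "A"))
    rec$expected_category <- "PSEUDOGENE"
    rec$expected_subtype <- "TRUNCATION"
    rec$params$frac <- frac
  } else stop("unknown defect kind: ", kind)

  bundle$genome$scaffolds[[scaf_id]] <- paste(chars, collapse = "")
  bundle$truth <- c(bundle$truth, list(rec))
  bundle
}

#' Ground-truth ledger as a data.frame
#' @param bundle a bundle with injected defects.
#' @return data.frame with `gene_id`, `kind`, `expected_category`,
#'   `expected_subtype`.
#' @export
truth_ledger <- function(bundle) {
  if (is.null(bundle$truth))
    return(data.frame(gene_id = character(), kind = character(),
                      expected_category = character(),
                      expected_subtype = character()))
  data.frame(
    gene_id = vapply(bundle$truth, `[[`, "", "gene_id"),
    kind = vapply(bundle$truth, `[[`, "", "kind"),
    expected_category = vapply(bundle$truth, `[[`, "", "expected_category"),
    expected_subtype = vapply(bundle$truth, `[[`, "", "expected_subtype"),
    row.names = NULL)
}

.defect_cycle <- c("START_SHIFT_UP", "START_SHIFT_DOWN", "EXONIFY_INTRON",
                   "INTRONIFY_EXON", "DELETE_NT", "INSERT_NT",
                   "PREMATURE_STOP", "N_RUN", "TRUNCATE")

#' Build a defect panel: template, evolved target, one defect per gene
#'
#' Generates a family of `n_genes`, evolves it at `sub_rate`, and injects one
#' defect per gene cycling through all defect classes (defects needing an
#' intron fall back to a start shift on single-exon genes). The ground truth
#' is recorded per gene.
#'
#' @param n_genes panel size.
#' @param sub_rate nucleotide divergence between template and target.
#' @param seed integer seed.
#' @param defect_free if `TRUE`, skip injection (clean ortholog panel).
#' @return list with `template` (bundle) and `target` (bundle with `truth`).
#' @export
build_panel <- function(n_genes = 200L, sub_rate = 0.05, seed = 1L,
                        defect_free = FALSE) {
  per <- diff(round(seq(0L, n_genes, length.out = 7L)))
  spec <- family_spec(genes_per_cluster = per, seed = seed)
  template <- generate_family(spec)
  target <- evolve_target(template, sub_rate, seed = seed + 1L)
  if (!defect_free) {
    target <- with_seed(seed + 2L, {
      tgt <- target
      ids <- names(tgt$models)
      for (i in seq_along(ids)) {
        kind <- .defect_cycle[(i - 1L) %% length(.defect_cycle) + 1L]
        gm <- tgt$models[[ids[i]]]
        multi <- nrow(gm$transcripts[[1L]]$cds_exons) > 1L
        if (kind == "EXONIFY_INTRON" && !multi) kind <- "START_SHIFT_UP"
        tgt <- switch(kind,
          START_SHIFT_UP = inject_error(tgt, ids[i], "START_SHIFT",
                                        n = 3L * sample(10:25, 1L),
                                        direction = "true_upstream"),
          START_SHIFT_DOWN = inject_error(tgt, ids[i], "START_SHIFT",
                                          n = 3L * sample(10:25, 1L),
                                          direction = "true_downstream"),
          inject_error(tgt, ids[i], kind))
      }
      tgt
    })
  }
  list(template = template, target = target)
}

#' Inject a rearrangement into a gene map
#'
#' `INVERT_BLOCK` flips the order and strands of entries `block` (indices
#' within one scaffold); `TRANSPOSE_GENE` moves entry `from` to after entry
#' `to`; `DISPERSE_CLUSTER` moves entries `block` onto a new scaffold.
#' Start coordinates are re-assigned so entry order reflects the new layout.
#'
#' @param map a `gene_map` (see [gene_map()]).
#' @param kind one of `"INVERT_BLOCK"`, `"TRANSPOSE_GENE"`,
#'   `"DISPERSE_CLUSTER"`.
#' @param ... `block` (integer indices) or `from`/`to`.
#' @return list with `map` (mutated) and `record` (ground-truth entry).
#' @export
inject_rearrangement <- function(map, kind, ...) {
  p <- list(...)
  e <- map$entries
  if (kind == "INVERT_BLOCK") {
    b <- p$block
    if (any(b < 1L) || any(b > nrow(e))) stop("block out of range")
    seg <- e[rev(b), ]
    seg$strand <- ifelse(seg$strand == "+", "-", "+")
    starts <- e$start[b]
    seg$start <- starts
    e[b, ] <- seg
    rec <- list(kind = "INVERT_BLOCK", labels = seg$label, block = b)
  } else if (kind == "TRANSPOSE_GENE") {
    from <- p$from; to <- p$to
    row <- e[from, , drop = FALSE]
    e <- e[-from, , drop = FALSE]
    at <- if (from <= to) to - 1L else to
    e <- rbind(e[seq_len(at), , drop = FALSE], row,
               e[seq_len(nrow(e)) > at, , drop = FALSE])
    e$start <- sort(map$entries$start)
    rec <- list(kind = "TRANSPOSE_GENE", labels = row$label,
                from = from, to = to)
  } else if (kind == "DISPERSE_CLUSTER") {
    b <- p$block
    new_scaf <- p$scaffold %||% paste0(e$scaffold_id[b[1L]], "_frag")
    e$scaffold_id[b] <- new_scaf
    rec <- list(kind = "DISPERSE_CLUSTER", labels = e$label[b],
                scaffold = new_scaf)
  } else stop("unknown rearrangement kind: ", kind)
  rownames(e) <- NULL
  map$entries <- e
  list(map = gene_map(map$species_tag, e), record = rec)
}
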