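#' @useDynLib gstcurate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# Internal coordinate convention: 0-based half-open intervals on the forward
# strand everywhere; GFF3 I/O converts to/from 1-based inclusive at the border.

#' Construct a genome
#'
#' A genome is a named set of scaffold sequences over the alphabet
#' `{A,C,G,T,N}`. Sequences are case-normalized to upper.
#'
#' @param scaffolds named character vector or list, scaffold_id -> DNA string.
#' @param species_tag short species tag, e.g. `"Dmel"`.
#' @return An object of class `genome` with fields `species_tag` and
#'   `scaffolds` (named character vector).
#' @export
genome <- function(scaffolds, species_tag = "unknown") {
  scaffolds <- unlist(scaffolds)
  if (is.null(names(scaffolds)) || anyDuplicated(names(scaffolds)))
    stop("scaffold ids must be present and unique")
  if (any(nchar(scaffolds) == 0L)) stop("empty scaffold sequence")
  scaffolds <- toupper(scaffolds)
  bad <- grepl("[^ACGTN]", scaffolds)
  if (any(bad))
    stop("illegal characters in scaffold(s): ",
         paste(names(scaffolds)[bad], collapse = ", "))
  structure(list(species_tag = species_tag, scaffolds = scaffolds),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %d scaffold(s), %s nt total\n",
              x$species_tag, length(x$scaffolds),
              format(sum(nchar(x$scaffolds)), big.mark = ",")))
  invisible(x)
}

#' Construct a transcript model
#'
#' @param transcript_id transcript identifier.
#' @param cds_exons matrix or data.frame with columns `start`, `end`
#'   (0-based half-open, forward-strand coordinates); rows are CDS exons.
#' @param isoform_tag optional isoform tag such as `"A"`.
#' @return A `transcript_model` object.
#' @export
transcript_model <- function(transcript_id, cds_exons, isoform_tag = NA_character_) {
  ex <- as.data.frame(cds_exons)[, c("start", "end")]
  ex <- ex[order(ex$start), , drop = FALSE]
  rownames(ex) <- NULL
  if (nrow(ex) < 1L) stop("transcript needs at least one CDS exon")
  if (any(ex$end <= ex$start)) stop("empty or inverted exon interval")
  if (nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)]))
    stop("overlapping exons in transcript ", transcript_id)
  structure(list(transcript_id = transcript_id, cds_exons = ex,
                 isoform_tag = isoform_tag),
            class = "transcript_model")
}

#' Total CDS length of a transcript in nucleotides
#' @param tx a `transcript_model`.
#' @return integer length.
#' @export
cds_length <- function(tx) sum(tx$cds_exons$end - tx$cds_exons$start)

#' Construct a gene model
#'
#' @param gene_id gene identifier.
#' @param scaffold_id scaffold the gene lies on.
#' @param strand `"+"` or `"-"`.
#' @param transcripts list of [transcript_model()] objects.
#' @param ortholog_label optional reference-ortholog label, e.g. `"GSTE6"`.
#' @param class_label GST class, one of Delta, Epsilon, Omega, Theta, Sigma,
#'   Zeta or `"unknown"`.
#' @return A `gene_model` object.
#' @export
gene_model <- function(gene_id, scaffold_id, strand, transcripts,
                       ortholog_label = NA_character_, class_label = "unknown") {
  stopifnot(strand %in% c("+", "-"))
  if (!class_label %in% c("Delta", "Epsilon", "Omega", "Theta", "Sigma",
                          "Zeta", "unknown"))
    stop("unknown class label: ", class_label)
  if (inherits(transcripts, "transcript_model")) transcripts <- list(transcripts)
  if (length(transcripts) < 1L) stop("gene needs at least one transcript")
  structure(list(gene_id = gene_id, scaffold_id = scaffold_id, strand = strand,
                 transcripts = transcripts, ortholog_label = ortholog_label,
                 class_label = class_label),
            class = "gene_model")
}

gene_span <- function(gm) {
  ex <- do.call(rbind, lapply(gm$transcripts, function(t) t$cds_exons))
  c(min(ex$start), max(ex$end))
}

validate_gene_model <- function(gm, gen) {
  len <- nchar(gen$scaffolds[[gm$scaffold_id]])
  for (tx in gm$transcripts) {
    if (any(tx$cds_exons$start < 0L) || any(tx$cds_exons$end > len))
      stop("transcript ", tx$transcript_id, " exceeds scaffold bounds")
  }
  invisible(TRUE)
}

# ---- FASTA ----------------------------------------------------------------

#' Read a DNA FASTA file into a genome
#'
#' Records are keyed by the first whitespace-delimited token of the header;
#' order is preserved and sequence is upper-cased.
#'
#' @param path FASTA file path.
#' @param species_tag species tag stored on the genome.
#' @return a `genome` object.
#' @export
read_fasta <- function(path, species_tag = "unknown") {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate record ids in ", path)
  seqs <- as.character(ss)
  names(seqs) <- ids
  genome(seqs, species_tag = species_tag)
}

#' Read a protein FASTA file
#' @param path FASTA file path.
#' @return named character vector of amino-acid sequences.
#' @export
read_protein_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate record ids in ", path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  seqs
}

#' Write sequences as FASTA (60-column wrap)
#' @param x a `genome`, or a named character vector of sequences.
#' @param path output path.
#' @param protein logical; write as amino acids.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, protein = FALSE) {
  seqs <- if (inherits(x, "genome")) x$scaffolds else unlist(x)
  set <- if (protein) Biostrings::AAStringSet(seqs) else
    Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

# ---- GFF3 -----------------------------------------------------------------

parse_gff_attrs <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
  parts <- parts[nzchar(parts)]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- vapply(kv, function(p) paste(p[-1L], collapse = "="), "")
  names(vals) <- vapply(kv, `[`, "", 1L)
  vals
}

#' Read gene models from a GFF3 file
#'
#' Accepts the gene -> mRNA -> CDS hierarchy with `ID`/`Parent` attributes
#' and 1-based inclusive coordinates; intervals are converted to the internal
#' 0-based half-open convention.
#'
#' @param path GFF3 path.
#' @param genome optional `genome`; if supplied, models are bounds-checked.
#' @return list of `gene_model` objects, keyed by gene id.
#' @export
read_gff3 <- function(path, genome = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) return(list())
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  if (ncol(f) != 9L) stop("malformed GFF3: expected 9 columns")
  df <- data.frame(seqid = f[, 1L], type = f[, 3L],
                   start = as.integer(f[, 4L]), end = as.integer(f[, 5L]),
                   strand = f[, 7L], attrs = f[, 9L],
                   stringsAsFactors = FALSE)
  attrs <- lapply(df$attrs, parse_gff_attrs)
  pick <- function(key) vapply(attrs, function(a)
    if (key %in% names(a)) a[[key]] else NA_character_, "")
  df$ID <- pick("ID")
  df$Parent <- pick("Parent")
  df$label <- pick("ortholog")
  df$class <- pick("gst_class")
  df$iso <- pick("isoform")

  genes <- df[df$type == "gene", ]
  mrnas <- df[df$type == "mRNA", ]
  cds   <- df[df$type == "CDS", ]
  if (any(is.na(cds$Parent))) stop("CDS feature without Parent")
  orphan <- setdiff(cds$Parent, mrnas$ID)
  if (length(orphan)) stop("CDS with unknown mRNA parent: ",
                           paste(orphan, collapse = ", "))
  models <- vector("list", nrow(genes))
  names(models) <- genes$ID
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gm_mrnas <- mrnas[mrnas$Parent == g$ID, , drop = FALSE]
    txs <- lapply(seq_len(nrow(gm_mrnas)), function(j) {
      m <- gm_mrnas[j, ]
      cx <- cds[cds$Parent == m$ID, , drop = FALSE]
      if (!nrow(cx)) stop("mRNA ", m$ID, " has no CDS")
      if (length(unique(cx$strand)) != 1L || cx$strand[1L] != g$strand)
        stop("mixed strands within transcript ", m$ID)
      transcript_model(m$ID,
                       data.frame(start = cx$start - 1L, end = cx$end),
                       isoform_tag = m$iso)
    })
    gm <- gene_model(g$ID, g$seqid, g$strand, txs,
                     ortholog_label = g$label,
                     class_label = if (is.na(g$class)) "unknown" else g$class)
    if (!is.null(genome)) validate_gene_model(gm, genome)
    models[[g$ID]] <- gm
  }
  models
}

#' Write gene models as GFF3
#'
#' Exact inverse of [read_gff3()]: internal 0-based half-open intervals are
#' written as 1-based inclusive.
#'
#' @param models list of `gene_model` objects.
#' @param path output path.
#' @param source source column value.
#' @param extra_gene_attrs optional named character vector gene_id -> extra
#'   attribute string appended to the gene line (e.g. curation status).
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path, source = "gstcurate",
                       extra_gene_attrs = NULL) {
  out <- c("##gff-version 3")
  for (gm in models) {
    sp <- gene_span(gm)
    at <- sprintf("ID=%s", gm$gene_id)
    if (!is.na(gm$ortholog_label))
      at <- paste0(at, ";ortholog=", gm$ortholog_label)
    if (!identical(gm$class_label, "unknown"))
      at <- paste0(at, ";gst_class=", gm$class_label)
    if (!is.null(extra_gene_attrs) && gm$gene_id %in% names(extra_gene_attrs))
      at <- paste0(at, ";", extra_gene_attrs[[gm$gene_id]])
    out <- c(out, sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\t%s",
                          gm$scaffold_id, source, sp[1L] + 1L, sp[2L],
                          gm$strand, at))
    for (tx in gm$transcripts) {
      ex <- tx$cds_exons
      mat <- sprintf("ID=%s;Parent=%s", tx$transcript_id, gm$gene_id)
      if (!is.na(tx$isoform_tag))
        mat <- paste0(mat, ";isoform=", tx$isoform_tag)
      out <- c(out, sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\t%s",
                            gm$scaffold_id, source, min(ex$start) + 1L,
                            max(ex$end), gm$strand, mat))
      phase <- 0L
      for (k in seq_len(nrow(ex))) {
        out <- c(out, sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
                              gm$scaffold_id, source, ex$start[k] + 1L,
                              ex$end[k], gm$strand, phase, tx$transcript_id))
        phase <- (3L - ((ex$end[k] - ex$start[k]) - phase) %% 3L) %% 3L
      }
    }
  }
  writeLines(out, path)
  invisible(path)
}

`%||%` <- function(a, b)
  if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

# ---- sequence extraction and translation ----------------------------------

revcomp <- function(dna)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))

#' Extract the spliced CDS of a transcript
#'
#' Exon substrings are concatenated in 5'->3' transcript order; on the minus
#' strand the ascending-stored exons are traversed descending and the
#' concatenation reverse-complemented.
#'
#' @param genome a `genome` object.
#' @param transcript a `transcript_model`.
#' @param scaffold_id scaffold the transcript lies on.
#' @param strand `"+"` or `"-"`.
#' @return DNA string of length `cds_length(transcript)`.
#' @export
extract_cds <- function(genome, transcript, scaffold_id, strand = "+") {
  seqs <- genome$scaffolds[[scaffold_id]]
  if (is.null(seqs)) stop("unknown scaffold ", scaffold_id)
  ex <- transcript$cds_exons
  if (any(ex$start < 0L) || any(ex$end > nchar(seqs)))
    stop("exon outside scaffold bounds")
  pieces <- substring(seqs, ex$start + 1L, ex$end)
  fwd <- paste(pieces, collapse = "")
  if (strand == "+") fwd else revcomp(fwd)
}

#' Translate a CDS with event flags
#'
#' Standard genetic code. A terminal stop codon is excluded from the protein
#' length; internal stops are flagged rather than fatal; codons containing N
#' translate to `X`.
#'
#' @param dna CDS string, length divisible by 3.
#' @return list with `sequence` (no terminal stop symbol; internal stops are
#'   kept as `*` in `raw` but removed region is visible via flags), `length_aa`,
#'   `premature_stop` (logical), `stop_codons` (1-based codon indices of
#'   internal stops), `ambiguous_codons` (codon indices translated to X),
#'   `has_terminal_stop`.
#' @export
translate_cds <- function(dna) {
  dna <- toupper(dna)
  if (nchar(dna) %% 3L != 0L)
    stop("CDS length not divisible by 3 (", nchar(dna), " nt)")
  ncod <- nchar(dna) %/% 3L
  codons <- substring(dna, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
  if (any(grepl("[^ACGTN]", codons))) stop("illegal characters in CDS")
  chars <- unname(Biostrings::GENETIC_CODE[codons])
  chars[is.na(chars)] <- "X"   # codons containing N
  n <- length(chars)
  terminal <- n > 0L && chars[n] == "*"
  body <- if (terminal) chars[-n] else chars
  stops <- which(body == "*")
  list(sequence = paste(body, collapse = ""),
       length_aa = length(body),
       premature_stop = length(stops) > 0L,
       stop_codons = stops,
       ambiguous_codons = which(chars == "X"),
       has_terminal_stop = terminal)
}

# Longest stop-free translation from the 5' end (protein up to first stop).
orf_prefix <- function(dna) {
  dna <- substr(dna, 1L, (nchar(dna) %/% 3L) * 3L)
  if (nchar(dna) < 3L) return("")
  tr <- translate_cds(dna)
  if (tr$premature_stop)
    substr(tr$sequence, 1L, tr$stop_codons[1L] - 1L)
  else tr$sequence
}

# ---- nomenclature ---------------------------------------------------------

.gst_species <- c("melanogaster", "simulans", "sechellia", "erecta", "yakuba",
                  "ananassae", "pseudoobscura", "persimilis", "willistoni",
                  "virilis", "mojavensis", "grimshawi")

#' Build a GST gene name from the unified nomenclature
#'
#' `"D"` + first three letters of the species epithet + `"GST"` + class letter
#' + number, e.g. `build_gst_name("simulans", "T", 4)` is `"DsimGSTT4"`.
#'
#' @param species_name Drosophila species epithet (e.g. `"virilis"`).
#' @param class_letter one of D, E, O, T, S, Z.
#' @param number positive integer isoform number.
#' @return character name.
#' @export
build_gst_name <- function(species_name, class_letter, number) {
  species_name <- tolower(species_name)
  if (!species_name %in% .gst_species)
    stop("unknown species: ", species_name)
  if (!class_letter %in% c("D", "E", "O", "T", "S", "Z"))
    stop("unknown GST class letter: ", class_letter)
  number <- as.integer(number)
  if (is.na(number) || number <= 0L) stop("number must be positive")
  paste0("D", substr(species_name, 1L, 3L), "GST", class_letter, number)
}
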