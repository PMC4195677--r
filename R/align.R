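# Pairwise protein alignment, identity metrics, codon-aware DNA-vs-protein
# alignment with frameshift states, and Jukes-Cantor distance correction.

.blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Scoring scheme for protein alignments
#'
#' Two presets are provided: `"curation"` (BLOSUM62, affine gap open 11 /
#' extend 1 — standard sensitive settings for ortholog comparison) and
#' `"tree"` (BLOSUM62, linear gap penalty 1 — the unusual but explicit
#' setting used for the published distance trees).
#'
#' @param preset `"curation"` or `"tree"`, or `NULL` with explicit args.
#' @param matrix_name substitution matrix name (only `"BLOSUM62"` shipped).
#' @param mode `"affine"` or `"linear"`.
#' @param gap_open,gap_extend non-negative penalties.
#' @return a `scoring_scheme` object.
#' @export
scoring_scheme <- function(preset = "curation", matrix_name = "BLOSUM62",
                           mode = NULL, gap_open = NULL, gap_extend = NULL) {
  if (!is.null(preset)) {
    if (preset == "curation") {
      mode <- mode %||% "affine"; gap_open <- gap_open %||% 11
      gap_extend <- gap_extend %||% 1
    } else if (preset == "tree") {
      mode <- mode %||% "linear"; gap_open <- gap_open %||% 0
      gap_extend <- gap_extend %||% 1
    } else stop("unknown preset: ", preset)
  }
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be >= 0")
  if (matrix_name != "BLOSUM62") stop("only BLOSUM62 is available")
  structure(list(matrix_name = matrix_name, matrix = .blosum62(),
                 mode = mode, gap_open = if (mode == "linear") 0 else gap_open,
                 gap_extend = gap_extend, preset = preset),
            class = "scoring_scheme")
}

#' Global (Needleman-Wunsch) protein alignment
#'
#' @param a,b protein strings (non-empty).
#' @param scheme a [scoring_scheme()].
#' @return an `alignment_result`: `aligned_a`, `aligned_b`, `score`,
#'   `n_match`, `n_mutual` (columns with both residues non-gap) and
#'   `identity_fraction = n_match / n_mutual`.
#' @export
global_align <- function(a, b, scheme = scoring_scheme()) {
  if (!nzchar(a) || !nzchar(b)) stop("empty input sequence")
  a <- toupper(a); b <- toupper(b)
  letters_ok <- rownames(scheme$matrix)
  bad_re <- sprintf("[^%s*]", paste(setdiff(letters_ok, "*"), collapse = ""))
  if (grepl(bad_re, a, fixed = FALSE) || grepl(bad_re, b, fixed = FALSE))
    stop("symbol outside substitution matrix")
  # canonical argument order internally so that score, matches and identity
  # are exactly invariant under swapping a and b (co-optimal tracebacks
  # would otherwise make identity order-dependent)
  swapped <- a > b
  r <- if (swapped)
    nw_align_cpp(b, a, scheme$matrix, scheme$gap_open, scheme$gap_extend)
  else nw_align_cpp(a, b, scheme$matrix, scheme$gap_open, scheme$gap_extend)
  if (swapped) {
    tmp <- r$aligned_a; r$aligned_a <- r$aligned_b; r$aligned_b <- tmp
  }
  structure(list(aligned_a = r$aligned_a, aligned_b = r$aligned_b,
                 score = r$score, n_match = r$n_match,
                 n_mutual = r$n_mutual,
                 identity_fraction = if (r$n_mutual > 0)
                   r$n_match / r$n_mutual else NA_real_),
            class = "alignment_result")
}

#' Percent identity of an alignment
#'
#' 100 x matches over mutually aligned (both non-gap) columns.
#'
#' @param aln an `alignment_result` from [global_align()].
#' @return percentage in `[0, 100]`.
#' @export
percent_identity <- function(aln) {
  if (aln$n_mutual == 0L) stop("no mutually aligned columns")
  100 * aln$n_match / aln$n_mutual
}

#' Percent identity of two proteins
#'
#' Convenience wrapper: [global_align()] then [percent_identity()]; returns 0
#' when either sequence is empty.
#'
#' @inheritParams global_align
#' @return percentage in `[0, 100]`.
#' @export
protein_identity <- function(a, b, scheme = scoring_scheme()) {
  if (!nzchar(a) || !nzchar(b)) return(0)
  percent_identity(global_align(a, b, scheme))
}

#' Codon-aware alignment of a CDS against a template protein
#'
#' Dynamic program over (nucleotides consumed, template residues consumed)
#' allowing codon match/mismatch, codon gaps in either sequence, and +-1/+-2 nt
#' frameshift transitions at a penalty. Frameshift and internal-stop events
#' are returned in DNA coordinates.
#'
#' @param dna CDS string (length >= 3; need not be a multiple of 3).
#' @param template_protein template amino-acid string.
#' @param scheme a [scoring_scheme()] supplying the substitution matrix.
#' @param frameshift_penalty penalty per frameshift event; default twice the
#'   curation gap-open penalty.
#' @param codon_gap_penalty penalty per whole-codon gap.
#' @return a `codon_alignment`: `events` data.frame (`kind`, `dna_position`
#'   1-based, `shift`, `detail`), `raw_identity`, `corrected_identity`,
#'   `score`, `path_protein` (translation along the chosen path).
#' @export
codon_align <- function(dna, template_protein, scheme = scoring_scheme(),
                        frameshift_penalty = NULL, codon_gap_penalty = 10) {
  dna <- toupper(dna)
  if (nchar(dna) < 3L) stop("dna shorter than one codon")
  if (!nzchar(template_protein)) stop("empty template")
  template_protein <- toupper(template_protein)
  if (is.null(frameshift_penalty))
    frameshift_penalty <- 2 * max(scheme$gap_open, 8)
  res <- codon_align_cpp(dna, template_protein, scheme$matrix,
                         as.numeric(frameshift_penalty),
                         as.numeric(codon_gap_penalty))
  events <- as.data.frame(res$events, stringsAsFactors = FALSE)
  raw_tr <- orf_to_codon_boundary(dna)
  raw_identity <- if (nzchar(raw_tr))
    protein_identity(raw_tr, template_protein, scheme) else 0
  corrected_identity <- if (nzchar(res$path_protein))
    protein_identity(res$path_protein, template_protein, scheme) else 0
  structure(list(events = events, score = res$score,
                 path_protein = res$path_protein,
                 raw_identity = raw_identity,
                 corrected_identity = corrected_identity),
            class = "codon_alignment")
}

# translate in annotated frame 0, trimming to codon boundary; stops become '*'
# and are kept so identity reflects the damage.
orf_to_codon_boundary <- function(dna) {
  n3 <- (nchar(dna) %/% 3L) * 3L
  if (n3 < 3L) return("")
  tr <- translate_cds(substr(dna, 1L, n3))
  gsub("\\*", "X", tr$sequence)  # '*' is outside BLOSUM62; score as X
}

#' Jukes-Cantor distance correction
#'
#' `d = -((k-1)/k) * ln(1 - k p / (k-1))` for mismatch fraction `p` over a
#' `k`-letter alphabet (`k = 20` proteins, `k = 4` nucleotides).
#'
#' @param p observed mismatch fraction, `0 <= p < (k-1)/k`.
#' @param k alphabet size.
#' @return corrected distance (>= p).
#' @export
jukes_cantor <- function(p, k = 20) {
  if (any(p < 0)) stop("negative mismatch fraction")
  bound <- (k - 1) / k
  if (any(p >= bound))
    stop(sprintf("mismatch fraction %.3f at/over JC saturation bound %.3f",
                 max(p), bound))
  -bound * log(1 - p / bound)
}
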