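# Shared oracles and fixture helpers, independent of the package internals.

blosum62_matrix <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Exhaustive enumeration of all global alignments (linear gap penalty),
# recursion without memoization: the independent oracle for small inputs.
brute_align_score <- function(a, b, mat = blosum62_matrix, gap = 1) {
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L)
      best <- max(best, rec(i - 1L, j - 1L) +
                    mat[substr(a, i, i), substr(b, j, j)])
    if (i > 0L) best <- max(best, rec(i - 1L, j) - gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) - gap)
    best
  }
  rec(nchar(a), nchar(b))
}

random_protein <- function(n) {
  paste(sample(rownames(blosum62_matrix)[1:20], n, replace = TRUE),
        collapse = "")
}

random_dna_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random stop-free CDS: ATG + sense codons + TAA
random_clean_cds <- function(naa) {
  all64 <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                 paste0), c("A", "C", "G", "T"), paste0))
  sense <- setdiff(all64, c("TAA", "TAG", "TGA"))
  paste(c("ATG", sample(sense, naa - 1L, replace = TRUE), "TAA"),
        collapse = "")
}

# random additive distance matrix from a random unrooted binary tree,
# together with the generating tree (ape)
random_additive_matrix <- function(n) {
  tr <- ape::unroot(ape::rtree(n, br = function(k) stats::runif(k, 0.05, 1)))
  D <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(D))
  list(tree = tr, D = D[ord, ord])
}

# a small panel shared by curation tests (built once per test run)
small_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_panel(n_genes = 36, sub_rate = 0.05,
                                              seed = 404)
    cache
  }
})
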