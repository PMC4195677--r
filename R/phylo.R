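# Distance-matrix construction from curated proteins and neighbor-joining
# trees, replicating the published settings (BLOSUM62-scored pairwise
# alignments, gap penalty 1, Jukes-Cantor correction, NJ).

#' Jukes-Cantor distance matrix of a protein set
#'
#' Pairwise global alignments under the `"tree"` preset (BLOSUM62,
#' linear gap penalty 1); `p` = mismatches over mutually aligned columns;
#' entries are `jukes_cantor(p, k)`.
#'
#' @param proteins named character vector of protein sequences (>= 3).
#' @param scheme a [scoring_scheme()]; default the tree preset.
#' @param k Jukes-Cantor alphabet size (20 for proteins).
#' @return symmetric matrix with zero diagonal and taxa dimnames.
#' @export
distance_matrix <- function(proteins, scheme = scoring_scheme("tree"),
                            k = 20) {
  n <- length(proteins)
  if (n < 3L) stop("need at least 3 sequences")
  ids <- names(proteins)
  if (is.null(ids) || anyDuplicated(ids)) stop("unique names required")
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    aln <- global_align(proteins[[i]], proteins[[j]], scheme)
    p <- 1 - aln$identity_fraction
    d <- tryCatch(jukes_cantor(p, k), error = function(e)
      stop(sprintf("saturated pair %s / %s (p = %.3f)", ids[i], ids[j], p),
           call. = FALSE))
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Standard NJ with the Q-criterion; ties are broken by the
#' lexicographically smallest taxon-id pair so output is deterministic.
#' Negative branch lengths are clamped to zero (recorded in the
#' `"clamped"` attribute). Recovers additive matrices exactly.
#'
#' @param D symmetric distance matrix with taxa dimnames (>= 3 taxa).
#' @return an unrooted `phylo` tree (ape) with a root trifurcation.
#' @export
neighbor_joining <- function(D) {
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("non-symmetric input")
  ids <- rownames(D)
  n <- length(ids)
  if (n < 3L) stop("need at least 3 taxa")
  frag <- ids                       # newick fragment per active node
  key <- ids                        # smallest member id, for tie-breaks
  clamped <- FALSE
  fmt <- function(x) sprintf("%.12g", x)
  clamp <- function(x) { if (x < 0) clamped <<- TRUE; max(x, 0) }
  while (n > 3L) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    m <- min(Q)
    cand <- which(Q - m < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pair_key <- apply(cand, 1L, function(ij)
      paste(sort(c(key[ij[1L]], key[ij[2L]])), collapse = "\r"))
    pick <- cand[order(pair_key)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    newf <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(clamp(li)),
                    frag[j], fmt(clamp(lj)))
    newkey <- min(key[i], key[j])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    frag <- c(frag[keep], newf)
    key <- c(key[keep], newkey)
    n <- n - 1L
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt(clamp(la)), frag[2], fmt(clamp(lb)),
                 frag[3], fmt(clamp(lc)))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

#' Newick serialization
#'
#' Branch lengths are written with 6 significant digits; parse-emit round
#' trips preserve the leaf set and pairwise path lengths.
#'
#' @param tree a `phylo` tree.
#' @return Newick string.
#' @export
to_newick <- function(tree) ape::write.tree(tree, digits = 6)

#' @rdname to_newick
#' @param text Newick string.
#' @export
parse_newick <- function(text) {
  tree <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                   error = function(e) NULL)
  if (is.null(tree) || is.null(tree$tip.label)) stop("malformed newick")
  tree
}

#' Write / read a square distance matrix as TSV
#'
#' Square format with a header row and id column (PHYLIP-style square).
#' @param D distance matrix (write).
#' @param path file path.
#' @return matrix (read) or `path` invisibly (write).
#' @export
write_distance_tsv <- function(D, path) {
  utils::write.table(cbind(id = rownames(D), as.data.frame(D)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  m
}
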