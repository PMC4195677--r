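# Ordered stranded ortholog-labeled gene maps and micro-rearrangement calls
# via signed permutations: breakpoints, inversions, transpositions.

#' Construct a gene map
#'
#' @param species_tag species tag.
#' @param entries data.frame with columns `label`, `scaffold_id`, `start`,
#'   `strand`; sorted by (scaffold, start).
#' @return a `gene_map` object.
#' @export
gene_map <- function(species_tag, entries) {
  e <- as.data.frame(entries)[, c("label", "scaffold_id", "start", "strand")]
  e <- e[order(e$scaffold_id, e$start), ]
  rownames(e) <- NULL
  structure(list(species_tag = species_tag, entries = e), class = "gene_map")
}

#' Gene map of a model bundle
#' @param bundle a bundle with `models` (e.g. from [generate_family()]).
#' @return a `gene_map` using ortholog labels.
#' @export
bundle_gene_map <- function(bundle) {
  ms <- bundle$models
  gene_map(bundle$genome$species_tag, data.frame(
    label = vapply(ms, `[[`, "", "ortholog_label"),
    scaffold_id = vapply(ms, `[[`, "", "scaffold_id"),
    start = vapply(ms, function(m) gene_span(m)[1L], 0),
    strand = vapply(ms, `[[`, "", "strand")))
}

#' Read / write gene maps as BED-like TSV
#'
#' Columns: scaffold, start, end, label, score (0), strand.
#' @param map a `gene_map` (for writing).
#' @param path file path.
#' @param species_tag tag for reading.
#' @return the map (read) or `path` invisibly (write).
#' @export
write_gene_map <- function(map, path) {
  e <- map$entries
  utils::write.table(
    data.frame(e$scaffold_id, e$start, e$start + 1L, e$label, 0L, e$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_map
#' @export
read_gene_map <- function(path, species_tag = "unknown") {
  d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  gene_map(species_tag, data.frame(label = d[[4L]], scaffold_id = d[[1L]],
                                   start = d[[2L]], strand = d[[6L]]))
}

#' Signed permutation of a target map relative to a reference map
#'
#' Labels single-copy in both maps define the permutation: reference order
#' assigns 1..n, the target order emits each as +-i with sign recording
#' strand agreement. Multi-copy labels are excluded and reported as
#' duplication candidates; labels spanning several target scaffolds while
#' co-resident on one reference scaffold are reported as scaffold splits.
#'
#' @param ref,target `gene_map` objects.
#' @return list with `perm` (signed integer vector), `labels` (reference
#'   order), `duplications`, `scaffold_splits` (list of
#'   `RearrangementEvent`-like records), `boundaries` (target scaffold of
#'   each permutation element).
#' @export
build_signed_permutation <- function(ref, target) {
  re <- ref$entries; te <- target$entries
  dup_labels <- union(re$label[duplicated(re$label)],
                      te$label[duplicated(te$label)])
  shared <- setdiff(intersect(re$label, te$label), dup_labels)
  if (length(shared) < 2L) stop("fewer than 2 shared single-copy labels")
  r <- re[re$label %in% shared, ]
  t <- te[te$label %in% shared, ]
  rank <- stats::setNames(seq_len(nrow(r)), r$label)
  sgn <- ifelse(t$strand == r$strand[match(t$label, r$label)], 1L, -1L)
  perm <- unname(sgn * rank[t$label])
  splits <- list()
  for (rs in unique(r$scaffold_id)) {
    lb <- r$label[r$scaffold_id == rs]
    ts <- unique(t$scaffold_id[match(lb, t$label)])
    if (length(ts) > 1L)
      splits[[length(splits) + 1L]] <-
        list(kind = "SCAFFOLD_SPLIT", ref_scaffold = rs,
             target_scaffolds = ts, labels = lb)
  }
  dups <- lapply(dup_labels[dup_labels %in% union(re$label, te$label)],
                 function(l) list(kind = "DUPLICATION", labels = l))
  list(perm = perm, labels = r$label, duplications = dups,
       scaffold_splits = splits,
       boundaries = t$scaffold_id)
}

#' Breakpoint distance of a signed permutation
#'
#' Number of adjacencies, including the two end caps `0` and `n+1`, that are
#' not conserved as signed adjacencies (`b - a != 1`). Zero exactly for the
#' identity permutation.
#'
#' @param perm signed permutation (each of 1..n appears once up to sign).
#' @return integer breakpoint count.
#' @export
breakpoint_distance <- function(perm) {
  n <- length(perm)
  ext <- c(0L, perm, n + 1L)
  sum(diff(ext) != 1L)
}

#' Detect inversion blocks in a signed permutation
#'
#' Maximal runs of consecutive, descending, uniformly negative elements are
#' one inversion each; isolated negative elements are single-gene inversions.
#' The returned blocks are disjoint and cover every negative element.
#'
#' @param perm signed permutation.
#' @param labels optional label vector (reference order) for reporting.
#' @return list of events: `kind = "INVERSION"`, `positions` (indices in the
#'   permutation), `members` (absolute values, ascending), `labels`.
#' @export
detect_inversions <- function(perm, labels = NULL) {
  events <- list()
  i <- 1L; n <- length(perm)
  while (i <= n) {
    if (perm[i] < 0L) {
      j <- i
      while (j < n && perm[j + 1L] < 0L && perm[j + 1L] == perm[j] + 1L)
        j <- j + 1L
      members <- as.integer(sort(abs(perm[i:j])))
      events[[length(events) + 1L]] <-
        list(kind = "INVERSION", positions = i:j, members = members,
             labels = if (!is.null(labels)) labels[members] else NULL)
      i <- j + 1L
    } else i <- i + 1L
  }
  events
}

# reinsert check: after removing block values v..w, does the remaining
# permutation carry the signed adjacency (v-1, w+1)?
.reinsertable <- function(rest, v, w, n) {
  ext <- c(0L, rest, n + 1L)
  any(ext[-length(ext)] == v - 1L & ext[-1L] == w + 1L)
}

#' Detect transpositions (greedy heuristic)
#'
#' Iteratively removes a positive run (or single element) whose removal
#' lowers the breakpoint distance by at least 2 and whose value range
#' re-inserts contiguously elsewhere; each acceptance is one TRANSPOSITION
#' event. Greedy, not a minimal rearrangement distance.
#'
#' @param perm signed permutation.
#' @param labels optional labels (reference order).
#' @return list of events: `kind = "TRANSPOSITION"`, `members`, `labels`.
#' @export
detect_transpositions <- function(perm, labels = NULL) {
  events <- list()
  n <- length(perm)
  repeat {
    b0 <- breakpoint_distance(perm)
    if (b0 == 0L) break
    # maximal runs of consecutive increasing positive elements
    runs <- list(); i <- 1L
    while (i <= length(perm)) {
      j <- i
      if (perm[i] > 0L)
        while (j < length(perm) && perm[j + 1L] == perm[j] + 1L) j <- j + 1L
      runs[[length(runs) + 1L]] <- i:j
      i <- j + 1L
    }
    best <- NULL
    for (r in runs) {
      if (any(perm[r] < 0L)) next
      v <- perm[r[1L]]; w <- perm[r[length(r)]]
      rest <- perm[-r]
      if (!.reinsertable(rest, v, w, n)) next
      drop_red <- b0 - breakpoint_distance_rest(rest, n)
      if (drop_red < 2L) next
      cand <- list(run = r, v = v, w = w, red = drop_red)
      if (is.null(best) || cand$red > best$red ||
          (cand$red == best$red && length(cand$run) < length(best$run)))
        best <- cand
    }
    if (is.null(best)) break
    members <- seq(best$v, best$w)
    events[[length(events) + 1L]] <-
      list(kind = "TRANSPOSITION", members = members,
           labels = if (!is.null(labels)) labels[members] else NULL)
    # re-insert the block at its home position and continue
    rest <- perm[-best$run]
    at <- if (best$v == 1L) 0L else which(rest == best$v - 1L)[1L]
    perm <- append(rest, seq(best$v, best$w), after = at)
    n <- length(perm)
  }
  events
}

# breakpoints of a reduced permutation: renumber remaining values by rank
# (keeping signs) and measure against the reduced identity
breakpoint_distance_rest <- function(rest, n) {
  vals <- sort(abs(rest))
  ranked <- match(abs(rest), vals) * sign(rest)
  breakpoint_distance(as.integer(ranked))
}

#' Summarize rearrangement events between two maps
#'
#' @param ref,target `gene_map` objects.
#' @return data.frame of events (`kind`, `labels`, `detail`) plus the
#'   breakpoint distance as attribute `"breakpoints"`.
#' @export
call_rearrangements <- function(ref, target) {
  sp <- build_signed_permutation(ref, target)
  inv <- detect_inversions(sp$perm, sp$labels)
  tra <- detect_transpositions(sp$perm, sp$labels)
  evs <- c(inv, tra, sp$scaffold_splits, sp$duplications)
  df <- data.frame(
    kind = vapply(evs, `[[`, "", "kind"),
    labels = vapply(evs, function(e)
      paste(e$labels %||% e$members %||% "", collapse = ","), ""),
    row.names = NULL)
  attr(df, "breakpoints") <- breakpoint_distance(sp$perm)
  attr(df, "perm") <- sp$perm
  df
}
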