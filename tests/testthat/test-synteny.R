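map_from_perm <- function(perm, tag = "T") {
  # target map realizing a signed permutation against labels L1..Ln
  gene_map(tag, data.frame(
    label = paste0("L", abs(perm)),
    scaffold_id = "s",
    start = seq_along(perm) * 1000,
    strand = ifelse(perm > 0, "+", "-")))
}
ref_map_n <- function(n) map_from_perm(seq_len(n), "R")

test_that("signed permutations are built from shared single-copy labels", {
  ref <- ref_map_n(5)
  expect_identical(build_signed_permutation(ref, ref)$perm, 1:5)

  tgt <- map_from_perm(c(1, -4, -3, -2, 5))
  expect_identical(build_signed_permutation(ref, tgt)$perm,
                   c(1L, -4L, -3L, -2L, 5L))

  # independent label-lookup oracle on random shuffles
  set.seed(19)
  for (i in 1:25) {
    n <- sample(5:12, 1)
    perm <- sample(n) * sample(c(-1L, 1L), n, replace = TRUE)
    got <- build_signed_permutation(ref_map_n(n), map_from_perm(perm))$perm
    expect_identical(got, as.integer(perm))
  }

  # duplicated labels are excluded and surfaced as duplication candidates
  te <- map_from_perm(1:4)$entries
  te <- rbind(te, data.frame(label = "L2", scaffold_id = "s",
                             start = 9000, strand = "+"))
  sp <- build_signed_permutation(ref_map_n(4), gene_map("T", te))
  expect_identical(sp$perm, 1:3)   # ranks renumbered without L2
  expect_true(any(vapply(sp$duplications, function(d) "L2" %in% d$labels,
                         TRUE)))

  expect_error(build_signed_permutation(ref_map_n(3), map_from_perm(99)),
               "shared")
})

test_that("breakpoint distance counts non-conserved signed adjacencies", {
  expect_identical(breakpoint_distance(1:8), 0L)
  expect_identical(breakpoint_distance(c(1, -4, -3, -2, 5)), 2L)

  # zero iff identity
  set.seed(23)
  for (i in 1:50) {
    n <- sample(4:10, 1)
    perm <- sample(n) * sample(c(-1L, 1L), n, replace = TRUE)
    expect_identical(breakpoint_distance(perm) == 0L,
                     identical(as.integer(perm), seq_len(n)))
  }

  # reversal-with-sign-flip changes only the two cap adjacencies
  for (i in 1:25) {
    n <- sample(4:10, 1)
    perm <- sample(n) * sample(c(-1L, 1L), n, replace = TRUE)
    flipped <- rev(-perm)
    expect_lte(abs(breakpoint_distance(perm) - breakpoint_distance(flipped)),
               2L)
  }
})

test_that("inversion blocks are detected exactly and cover negatives", {
  expect_length(detect_inversions(1:6), 0L)
  ev <- detect_inversions(c(1, -4, -3, -2, 5))
  expect_length(ev, 1L)
  expect_identical(ev[[1]]$members, 2:4)

  set.seed(29)
  for (i in 1:50) {
    n <- sample(6:15, 1)
    a <- sort(sample(n, 2))
    perm <- seq_len(n)
    perm[a[1]:a[2]] <- -rev(perm[a[1]:a[2]])
    ev <- detect_inversions(perm)
    expect_length(ev, 1L)
    expect_identical(ev[[1]]$members, a[1]:a[2])
    # blocks cover every negative element, disjointly
    covered <- unlist(lapply(ev, `[[`, "members"))
    expect_identical(sort(covered), sort(abs(perm[perm < 0])))
  }
})

test_that("greedy transposition calling recovers injected single-gene moves", {
  expect_length(detect_transpositions(1:6), 0L)
  ev <- detect_transpositions(c(1, 3, 4, 2, 5))
  expect_length(ev, 1L)
  expect_identical(ev[[1]]$members, 2L)

  set.seed(37)
  hits <- 0L
  for (i in 1:50) {
    n <- sample(8:14, 1)
    from <- sample(n, 1)
    to <- sample(setdiff(seq_len(n), from), 1)
    perm <- append(setdiff(seq_len(n), from), from,
                   after = to - (to > from))
    if (identical(as.integer(perm), seq_len(n))) { hits <- hits + 1L; next }
    ev <- detect_transpositions(perm)
    mem <- unlist(lapply(ev, `[[`, "members"))
    if (from %in% mem) hits <- hits + 1L
  }
  expect_gte(hits, 45L)   # >= 90%; greedy, documented as heuristic
})

test_that("map-level rearrangement injection round-trips through detection", {
  tpl <- generate_family(family_spec(genes_per_cluster = c(5), seed = 91))
  ref <- bundle_gene_map(tpl)

  inv <- inject_rearrangement(ref, "INVERT_BLOCK", block = 2:4)
  sp <- build_signed_permutation(ref, inv$map)
  expect_identical(sp$perm, c(1L, -4L, -3L, -2L, 5L))
  ev <- detect_inversions(sp$perm, sp$labels)
  expect_length(ev, 1L)
  expect_identical(sort(ev[[1]]$labels), sort(inv$record$labels))

  tra <- inject_rearrangement(ref, "TRANSPOSE_GENE", from = 2, to = 4)
  sp2 <- build_signed_permutation(ref, tra$map)
  ev2 <- detect_transpositions(sp2$perm, sp2$labels)
  expect_true(tra$record$labels %in% unlist(lapply(ev2, `[[`, "labels")))

  dis <- inject_rearrangement(ref, "DISPERSE_CLUSTER", block = 4:5)
  sp3 <- build_signed_permutation(ref, dis$map)
  expect_length(sp3$scaffold_splits, 1L)
  expect_identical(sp3$scaffold_splits[[1]]$kind, "SCAFFOLD_SPLIT")
})

test_that("gene maps round-trip through the BED-like TSV format", {
  tpl <- generate_family(family_spec(genes_per_cluster = c(3, 2), seed = 14))
  map <- bundle_gene_map(tpl)
  f <- withr::local_tempfile()
  write_gene_map(map, f)
  back <- read_gene_map(f, species_tag = map$species_tag)
  expect_equal(back$entries, map$entries, ignore_attr = TRUE)
})
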