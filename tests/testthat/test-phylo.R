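test_that("distance matrices are symmetric JC-corrected mismatch fractions", {
  prots <- c(a = random_protein(80), b = random_protein(80),
             c = random_protein(80))
  same <- c(x = prots[["a"]], y = prots[["a"]], z = prots[["a"]])
  expect_true(all(distance_matrix(same) == 0))

  set.seed(41)
  many <- stats::setNames(replicate(8, random_protein(60)), letters[1:8])
  D <- distance_matrix(many)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(is.finite(D)))

  # two sequences differing at 10% of columns -> jukes_cantor(0.10, 20).
  # Substitutions go to similar residues (BLOSUM62 score > -2) so the
  # optimal gap-penalty-1 alignment stays ungapped and p is exactly 0.10.
  conservative <- c(A = "S", R = "K", N = "S", D = "E", C = "S", Q = "E",
                    E = "D", G = "A", H = "N", I = "L", L = "I", K = "R",
                    M = "L", F = "Y", P = "A", S = "T", T = "S", W = "Y",
                    Y = "F", V = "I")
  a <- random_protein(100)
  chars <- strsplit(a, "")[[1]]
  idx <- sample(100, 10)
  for (i in idx) chars[i] <- conservative[[chars[i]]]
  b <- paste(chars, collapse = "")
  D2 <- distance_matrix(c(a = a, b = b, c = a))
  expect_equal(D2["a", "b"], jukes_cantor(0.10, 20))

  expect_error(distance_matrix(c(a = a, b = b)), "at least 3")
})

test_that("neighbor joining has the 3-taxon closed form and recovers additivity", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  # (d_ab + d_ac - d_bc)/2 etc.
  lens <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(lens[c("A", "B", "C")]), c(0.5, 1.5, 2.5))

  set.seed(53)
  for (i in 1:30) {
    gen <- random_additive_matrix(sample(6:10, 1))
    nj <- neighbor_joining(gen$D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(nj), gen$tree)), 0)
    P <- ape::cophenetic.phylo(nj)[rownames(gen$D), colnames(gen$D)]
    expect_lt(max(abs(P - gen$D)), 1e-9)
  }

  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2,
                                       dimnames = list(c("a", "b"),
                                                       c("a", "b")))),
               "symmetric|taxa")
})

test_that("NJ agrees with an independent implementation on generic matrices", {
  set.seed(59)
  for (i in 1:10) {
    n <- sample(5:9, 1)
    prots <- stats::setNames(replicate(n, random_protein(70)),
                             paste0("t", seq_len(n)))
    D <- distance_matrix(prots)
    mine <- neighbor_joining(D)
    ref <- ape::nj(stats::as.dist(D))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(mine),
                                           ape::unroot(ref))), 0)
  }
})

test_that("trees built from synthetic families cluster orthologs by gene", {
  # two diverged species per ortholog: leaves must pair by ortholog label
  tpl <- generate_family(family_spec(genes_per_cluster = c(4), seed = 71))
  t1 <- evolve_target(tpl, 0.05, seed = 72, species_tag = "SpA")
  t2 <- evolve_target(tpl, 0.20, seed = 73, species_tag = "SpB")
  labs <- vapply(tpl$models, `[[`, "", "ortholog_label")
  prots <- c()
  for (lab in labs) {
    prots[paste0("SpA_", lab)] <- t1$proteins[[paste0("SpA_", lab)]]
    prots[paste0("SpB_", lab)] <- t2$proteins[[paste0("SpB_", lab)]]
  }
  tr <- neighbor_joining(distance_matrix(prots))
  for (lab in labs) {
    pair <- paste0(c("SpA_", "SpB_"), lab)
    sub <- ape::getMRCA(tr, pair)
    tips <- ape::extract.clade(tr, sub)$tip.label
    expect_identical(sort(tips), sort(pair))
  }
})

test_that("newick serialization round-trips leaf sets and path lengths", {
  set.seed(61)
  for (i in 1:20) {
    gen <- random_additive_matrix(sample(5:12, 1))
    tr <- neighbor_joining(gen$D)
    back <- parse_newick(to_newick(tr))
    expect_identical(sort(back$tip.label), sort(tr$tip.label))
    P1 <- ape::cophenetic.phylo(tr); P2 <- ape::cophenetic.phylo(back)
    ord <- rownames(P1)
    expect_lt(max(abs(P1 - P2[ord, ord])), 1e-4)   # 6 significant digits
    expect_identical(phangorn::RF.dist(tr, back), 0L)
  }
  expect_error(parse_newick("not a tree"), "malformed")
})

test_that("distance matrices round-trip through square TSV", {
  set.seed(67)
  prots <- stats::setNames(replicate(4, random_protein(50)),
                           c("w", "x", "y", "z"))
  D <- distance_matrix(prots)
  f <- withr::local_tempfile()
  write_distance_tsv(D, f)
  expect_equal(read_distance_tsv(f), D, tolerance = 1e-12)
})
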