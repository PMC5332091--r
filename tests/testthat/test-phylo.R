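test_that("p-distances and Poisson correction follow the definitions", {
  a <- c(x = "AAAA", y = "AAAT", z = "TTTT")
  dp <- pairwise_distance(a, correction = "p", coverage = 0)
  expect_equal(dp["x", "x"], 0)
  expect_equal(dp["x", "y"], 0.25)
  expect_equal(dp["x", "z"], 1 * 0 + dp["z", "x"]) # symmetry
  dpois <- pairwise_distance(a, correction = "poisson", coverage = 0)
  expect_equal(dpois["x", "y"], -log(0.75), tolerance = 1e-9)

  # all-gap columns do not change distances (partial deletion drops them)
  b <- c(x = "AA--AA", y = "AA--AT", z = "TT--TT")
  expect_equal(pairwise_distance(b, "p", coverage = 0.9)["x", "y"], 0.25)

  # a pair with no comparable columns is an error naming the pair
  g <- c(x = "AA--", y = "--AA", z = "AAAA")
  expect_error(pairwise_distance(g, "p", coverage = 0), "'x' and 'y'")
})

test_that("neighbor joining recovers additive and ultrametric topologies", {
  # 3 taxa: closed-form branch lengths x = (dab + dac - dbc)/2 etc.
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(dm)
  expect_s3_class(tr, "phylo")
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["a"]), (3 + 4 - 5) / 2)
  expect_equal(unname(bl["b"]), (3 + 5 - 4) / 2)
  expect_equal(unname(bl["c"]), (4 + 5 - 3) / 2)

  # 4-taxon additive matrix from tree ((a,b),(c,d)): split recovered
  skip_if_not_installed("phangorn")
  true4 <- ape::read.tree(text = "((a:1,b:2):1,(c:1,d:3):0);")
  dm4 <- ape::cophenetic.phylo(true4)
  tr4 <- nj_tree(dm4[c("a", "c", "b", "d"), c("a", "c", "b", "d")])
  expect_equal(phangorn::RF.dist(ape::unroot(tr4), ape::unroot(true4)), 0)

  # ultrametric distances: NJ topology matches average-linkage clustering
  set.seed(5)
  hc_tree <- ape::rcoal(8)
  dmu <- ape::cophenetic.phylo(hc_tree)
  nj8 <- nj_tree(dmu)
  upgma <- ape::as.phylo(stats::hclust(stats::as.dist(dmu), "average"))
  expect_equal(phangorn::RF.dist(ape::unroot(nj8), ape::unroot(upgma)), 0)

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), ">= 3")
  bad <- matrix(c(0, 1, 2, 3, 0, 1, 2, 1, 0), 3, 3,
                dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(bad), "symmetric")
})

test_that("bootstrap supports count bipartitions and are deterministic", {
  # two clearly separated blocks of identical sequences: the separating
  # edge is certain
  aln <- c(a1 = "AAAAAAAAAACCCCC", a2 = "AAAAAAAAAACCCCC",
           a3 = "AAAAAAAAAACCCCC", b1 = "TTTTTTTTTTGGGGG",
           b2 = "TTTTTTTTTTGGGGG", b3 = "TTTTTTTTTTGGGGG")
  tr <- bootstrap_support(aln, n_replicates = 50, seed = 4)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(any(sup == 100, na.rm = TRUE))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))

  # fixed seed reproduces supports; the supports equal a direct recount
  scn <- noiseless_scenario()
  sub <- scn$proteome$truth$alignment[
    c(scn$proteome$truth$members$gene_id[c(1, 2, 7, 8, 11, 12, 14, 15)],
      names(scn$proteome$truth$anchors))]
  t1 <- bootstrap_support(sub, n_replicates = 60, seed = 9)
  t2 <- bootstrap_support(sub, n_replicates = 60, seed = 9)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_error(bootstrap_support(sub, n_replicates = 0), ">= 1")

  # supports invariant under taxon order permutation
  set.seed(10)
  t3 <- bootstrap_support(sub[sample(names(sub))], n_replicates = 60,
                          seed = 9)
  key_sup <- function(tr) {
    keys <- hdzipr:::split_keys(tr)
    sup <- tr$node.label[as.integer(names(keys)) - length(tr$tip.label)]
    sort(paste(keys, sup))
  }
  expect_identical(key_sup(t1), key_sup(t3))
})

test_that("subfamily assignment follows anchored clades and the rule table", {
  # architecture rule table is total over the four archetypes
  arch <- tibble::tibble(
    protein_id = c("g1", "g2", "g3", "g4"),
    HD = TRUE, LZ = TRUE,
    CPSCE = c(FALSE, TRUE, FALSE, FALSE),
    START = c(FALSE, FALSE, TRUE, TRUE),
    MEKHLA = c(FALSE, FALSE, TRUE, FALSE)
  )
  long <- tidyr::pivot_longer(arch, -protein_id, names_to = "domain",
                              values_to = "present")
  calls <- architecture_calls(long)
  expect_equal(unname(calls[c("g1", "g2", "g3", "g4")]),
               c("I", "II", "III", "IV"))

  # noiseless cohort: tree and architecture agree for every gene
  scn <- noiseless_scenario()
  aln <- scn$proteome$truth$alignment
  tree <- nj_tree(pairwise_distance(aln))
  members <- scn$proteome$truth$members
  arch_map <- setNames(members$subfamily, members$gene_id)
  asg <- assign_subfamily(tree, scn$proteome$truth$anchors, arch_map)
  expect_equal(nrow(asg), nrow(members))
  expect_true(all(asg$subfamily == arch_map[asg$gene_id]))
  expect_true(all(asg$architecture_agrees))

  # a gene tied to anchors of mixed subfamilies is ambiguous, not an error
  tiny <- ape::read.tree(text = "((ANCHOR_I:1,ANCHOR_II:1):1,(g:1,ANCHOR_III:1):1,ANCHOR_IV:1);")
  res <- assign_subfamily(
    tiny, setNames(c("I", "II", "III", "IV"),
                   paste0("ANCHOR_", c("I", "II", "III", "IV"))))
  expect_equal(res$subfamily[res$gene_id == "g"], "III")
})
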