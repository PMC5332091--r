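test_that("local alignment handles the self and disjoint base cases", {
  sch <- scoring_scheme(match = 2, mismatch = -3)
  blk <- smith_waterman("ACGT", "ACGT", sch)
  expect_equal(blk$score, 8)
  expect_equal(blk$identity, 1.0)
  expect_equal(blk$length, 4)
  expect_equal(c(blk$qstart, blk$qend), c(0, 4))

  empty <- smith_waterman("AAAA", "CCCC", sch)
  expect_equal(empty$score, 0)
  expect_equal(empty$length, 0)

  expect_error(smith_waterman("", "ACGT", sch), "nonempty")
})

test_that("alignment score matches the full-matrix oracle and is symmetric", {
  sch <- scoring_scheme(match = 2, mismatch = -3, gap_open = 4,
                        gap_extend = 1)
  smat <- sch$matrix
  set.seed(17)
  for (i in 1:60) {
    a <- random_nt(sample(3:30, 1))
    b <- random_nt(sample(3:30, 1))
    got <- smith_waterman(a, b, sch)
    expect_equal(got$score,
                 sw_score_oracle(a, b, smat, sch$gap_open, sch$gap_extend))
    # symmetry under argument swap
    expect_equal(got$score, smith_waterman(b, a, sch)$score)
  }
  # protein mode against the same oracle with the BLOSUM matrix
  psch <- scoring_scheme("protein")
  for (i in 1:15) {
    a <- random_protein(sample(3:20, 1))
    b <- random_protein(sample(3:20, 1))
    expect_equal(
      smith_waterman(a, b, psch)$score,
      sw_score_oracle(a, b, psch$matrix, psch$gap_open, psch$gap_extend))
  }
})

test_that("seeded alignment recovers verbatim and mutated copies", {
  set.seed(23)
  q <- random_nt(30000)
  s <- paste0(random_nt(4000), substr(q, 5001, 25000), random_nt(4000))
  blocks <- seeded_local_align(q, s)
  expect_gte(nrow(blocks), 1)
  expect_equal(blocks$identity[1], 1.0)
  expect_gte(blocks$length[1], 20000)
  # deterministic: identical rerun
  expect_identical(blocks, seeded_local_align(q, s))

  # 10% per-base mutated copy: overall identity of recovered blocks within
  # 3 SD of 0.90 (binomial over the copied span)
  copy <- strsplit(substr(q, 5001, 25000), "")[[1]]
  hit <- runif(length(copy)) < 0.10
  subs <- vapply(copy[hit], function(ch) sample(setdiff(DNA4, ch), 1), "")
  copy[hit] <- subs
  s2 <- paste0(random_nt(2000), paste(copy, collapse = ""),
               random_nt(2000))
  b2 <- seeded_local_align(q, s2)
  big <- b2[b2$length > 200, ]
  expect_gt(sum(big$length), 10000)
  pooled <- sum(big$matches) / sum(big$length)
  expect_lt(abs(pooled - 0.90), 3 * sqrt(0.9 * 0.1 / sum(big$length)) + 0.01)
})

test_that("unrelated sequences never produce a passing block", {
  set.seed(29)
  for (i in 1:20) {
    blocks <- seeded_local_align(random_nt(50000), random_nt(50000))
    passing <- blocks[blocks$length > 200 & blocks$identity > 0.85, ]
    expect_equal(nrow(passing), 0)
  }
  expect_error(seeded_local_align("ACGTQ", "ACGT"), "invalid nucleotide")
  expect_error(seeded_local_align("ACGTACGT", "ACGTACGT", k = 4), ">= 8")
})

test_that("the optimal score bounds every seeded block on short pairs", {
  sch <- scoring_scheme()
  set.seed(31)
  for (i in 1:10) {
    a <- random_nt(300)
    b <- paste0(substr(a, 50, 250), random_nt(80))
    full <- smith_waterman(a, b, sch)$score
    blocks <- seeded_local_align(a, b, scheme = sch)
    if (nrow(blocks) > 0) expect_true(all(blocks$score <= full + 1e-9))
  }
})
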