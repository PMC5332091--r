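planted_motif_set <- function(n = 20, motif = "WRKYGQKLVDHWFPE",
                              flank = 40, seed = 9) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    paste0(random_protein(flank), motif, random_protein(flank))
  }, character(1))
  setNames(seqs, paste0("s", seq_len(n)))
}

test_that("a planted motif is recovered exactly at its width", {
  motif <- "WRKYGQKLVDHWFPE"
  seqs <- planted_motif_set(motif = motif)
  found <- discover_motifs(seqs, widths = 15, max_motifs = 1, seed = 4)
  expect_length(found, 1)
  expect_equal(motif_consensus(found[[1]]), motif)
  expect_equal(nrow(found[[1]]$sites), 20)
  # every site points at the planted offset (flank = 40)
  expect_true(all(found[[1]]$sites$offset == 40))

  # with a width grid, the winning motif still lies inside the planted one
  found2 <- discover_motifs(seqs, widths = c(11, 15), max_motifs = 1,
                            seed = 4)
  expect_true(grepl(motif_consensus(found2[[1]]), motif, fixed = TRUE))
})

test_that("EM objective is non-decreasing and runs are seed-deterministic", {
  seqs <- planted_motif_set(n = 12, seed = 13)
  m1 <- discover_motifs(seqs, widths = 15, max_motifs = 1, seed = 8)
  expect_true(all(diff(m1[[1]]$ll_trace) > -1e-6))
  m2 <- discover_motifs(seqs, widths = 15, max_motifs = 1, seed = 8)
  expect_identical(m1[[1]]$pwm, m2[[1]]$pwm)
  expect_identical(m1[[1]]$sites, m2[[1]]$sites)
})

test_that("masking prevents rediscovery and the floor stops the search", {
  seqs <- planted_motif_set(n = 15, seed = 21)
  found <- discover_motifs(seqs, widths = c(11, 15), max_motifs = 3,
                           seed = 2)
  expect_gte(length(found), 2)
  # the second motif's sites never overlap the first motif's masked spans
  s1 <- found[[1]]$sites
  s2 <- found[[2]]$sites
  both <- merge(s1, s2, by = "seq_id")
  overlaps <- with(both, pmax(offset.x, offset.y) <
                     pmin(offset.x + found[[1]]$width,
                          offset.y + found[[2]]$width))
  expect_false(any(overlaps))

  # i.i.d. random sequences: best achievable information content sits
  # below an elevated floor, so no motif is reported
  set.seed(33)
  rnd <- setNames(vapply(1:12, function(i) random_protein(80), ""),
                  paste0("r", 1:12))
  base <- discover_motifs(rnd, widths = c(11, 15), max_motifs = 1,
                          seed = 5, ic_floor = 0)
  null_ic <- base[[1]]$ic_per_column
  none <- discover_motifs(rnd, widths = c(11, 15), max_motifs = 3,
                          seed = 5, ic_floor = null_ic + 0.1)
  expect_length(none, 0)
  # while the planted set clears the same floor
  planted <- discover_motifs(planted_motif_set(n = 12, seed = 3),
                             widths = 15, max_motifs = 1, seed = 5,
                             ic_floor = null_ic + 0.1)
  expect_length(planted, 1)

  # a width longer than every sequence is skipped with a warning
  short <- setNames(vapply(1:4, function(i) random_protein(20), ""),
                    paste0("t", 1:4))
  expect_warning(discover_motifs(short, widths = 50, max_motifs = 1),
                 "skipped")
  expect_error(discover_motifs(short[1]), ">= 2")
  expect_error(discover_motifs(short, widths = 8), "11..50")
})
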