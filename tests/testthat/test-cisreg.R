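test_that("promoter extraction is strand-aware with edge truncation", {
  chr <- random_nt(10000)
  genome <- c(ChrP = chr)
  plus <- list(gene_id = "p", chromosome = "ChrP", strand = "+",
               start = 2000, end = 3000)
  pr <- extract_promoter(genome, plus, length = 1500)
  expect_equal(nchar(pr), 1500)
  expect_equal(as.character(pr), substr(chr, 501, 2000))
  expect_false(attr(pr, "truncated"))

  # minus strand: reverse complement of the 1500 bp after the gene end
  minus <- list(gene_id = "m", chromosome = "ChrP", strand = "-",
                start = 2000, end = 3000)
  pm <- extract_promoter(genome, minus, length = 1500)
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  expect_equal(as.character(pm), rc(substr(chr, 3001, 4500)))
  # involution: reverse complementing twice returns the genomic stretch
  expect_equal(rc(as.character(pm)), substr(chr, 3001, 4500))

  # short upstream region truncates with a flag
  near <- list(gene_id = "n", chromosome = "ChrP", strand = "+",
               start = 800, end = 900)
  pn <- extract_promoter(genome, near, length = 1500)
  expect_equal(nchar(pn), 800)
  expect_true(attr(pn, "truncated"))
  expect_error(extract_promoter(genome, list(chromosome = "nope",
                                             strand = "+", start = 1,
                                             end = 2)), "absent")
})

test_that("element scanning honors IUPAC codes, strands and case", {
  catalog <- tibble::tibble(
    name = c("pal", "plain", "degen"),
    pattern = c("CACGTG", "AACGAC", "AGAANWTTC"),
    class = "x")
  # a promoter equal to the pattern: exactly one forward hit at offset 0
  hits <- scan_elements(c(g = "AACGAC"), catalog, both_strands = FALSE)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$offset, 0L)
  expect_equal(hits$match, "AACGAC")

  # palindromic pattern: forward and reverse at the same offset, deduped
  hits_p <- scan_elements(c(g = "TTCACGTGTT"), catalog,
                          both_strands = TRUE, dedupe_palindromes = TRUE)
  pal <- hits_p[hits_p$element == "pal", ]
  expect_equal(nrow(pal), 1)
  hits_p2 <- scan_elements(c(g = "TTCACGTGTT"), catalog,
                           both_strands = TRUE,
                           dedupe_palindromes = FALSE)
  expect_equal(nrow(hits_p2[hits_p2$element == "pal", ]), 2)

  # case-insensitive; N in the sequence never matches
  expect_equal(nrow(scan_elements(c(g = "aacgac"), catalog,
                                  both_strands = FALSE)), 1)
  expect_equal(nrow(scan_elements(c(g = "AACGNC"), catalog,
                                  both_strands = FALSE)), 0)
  # overlapping occurrences are all reported
  ovl <- scan_elements(c(g = "AACGACGAC"), tibble::tibble(
    name = "r", pattern = "ACGAC", class = "x"), both_strands = FALSE)
  expect_equal(ovl$offset, c(1L, 4L))
  expect_error(
    scan_elements(c(g = "ACGT"), tibble::tibble(
      name = "bad", pattern = "ACZT", class = "x")), "invalid IUPAC")
  expect_error(read_element_catalog(), NA)
})

test_that("random-promoter hit counts match the degeneracy expectation", {
  catalog <- tibble::tibble(name = "degen", pattern = "AGAANWTTC",
                            class = "x")
  # per-site match probability: product over pattern of |options| / 4
  # (AGAA fixed, N = 4 options, W = 2, TTC fixed)
  w <- 9
  opts <- c(1, 1, 1, 1, 4, 2, 1, 1, 1)
  p_site <- prod(opts / 4)
  n_prom <- 400
  set.seed(51)
  proms <- setNames(vapply(seq_len(n_prom), function(i) random_nt(1500),
                           ""), paste0("g", seq_len(n_prom)))
  hits <- scan_elements(proms, catalog, both_strands = FALSE)
  expected <- n_prom * (1500 - w + 1) * p_site
  expect_lt(abs(nrow(hits) - expected), 3 * sqrt(expected) + 1)
})

test_that("exact binomial enrichment matches the summed-pmf oracle", {
  # hand values
  expect_equal(binom_upper_oracle(8, 10, 0.5), 56 / 1024)
  hits <- tibble::tibble(gene_id = paste0("g", 1:8), element = "E")
  sf <- setNames(rep(c("I", "II"), each = 10), paste0("g", 1:20))
  res <- suppressWarnings(enrichment_test(hits, sf))
  row1 <- res[res$subfamily == "I" & res$element == "E", ]
  # k = 8 of n = 10, p0 = 8/20
  expect_equal(row1$k, 8)
  expect_equal(row1$p0, 0.4)
  expect_equal(row1$p_value, binom_upper_oracle(8, 10, 0.4),
               tolerance = 1e-12)
  # k = 0 has upper-tail p = 1
  row2 <- res[res$subfamily == "II", ]
  expect_equal(row2$p_value, 1)
  expect_true(all(res$q_value >= res$p_value - 1e-12))

  # randomized battery against the oracle, 1e-12
  set.seed(61)
  for (i in 1:200) {
    n <- sample(1:60, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1)
    got <- pbinom(k - 1, n, p0, lower.tail = FALSE)
    expect_equal(got, binom_upper_oracle(k, n, p0), tolerance = 1e-12)
  }
  # monotone non-increasing in k for fixed n, p0
  ps <- vapply(0:15, function(k) pbinom(k - 1, 15, 0.3, FALSE), 0)
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("planted subfamily elements attain the smallest q-values", {
  scn <- noiseless_scenario()
  gm <- scn$genome$gene_models
  genome <- scn$genome$genome
  proms <- setNames(vapply(seq_len(nrow(gm)), function(i) {
    as.character(extract_promoter(genome, gm[i, ]))
  }, ""), gm$gene_id)
  # every planted element occurrence is found at its planted offset
  hits <- scan_elements(proms, read_element_catalog())
  planted <- scn$genome$truth$planted_elements
  key_hit <- paste(hits$gene_id, hits$element, hits$offset)
  key_tru <- paste(planted$gene_id, planted$element, planted$offset)
  expect_true(all(key_tru %in% key_hit))

  sf <- setNames(scn$proteome$truth$members$subfamily,
                 scn$proteome$truth$members$gene_id)
  res <- enrichment_test(hits, sf)
  plan <- c(I = "ABRE", II = "HSE", III = "GARE-motif", IV = "MBS")
  for (s in c("I", "II")) { # the larger subfamilies give stable ranks
    sub <- res[res$subfamily == s, ]
    expect_equal(sub$element[which.min(sub$q_value)], unname(plan[s]))
  }
})
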