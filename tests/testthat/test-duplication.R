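loci_tbl <- function(...) {
  tibble::tribble(~gene_id, ~chromosome, ~start, ~end, ~strand, ...)
}

test_that("tandem calls respect the 50-kb same-chromosome rule", {
  # 30 kb apart, same chromosome: one pair
  l1 <- loci_tbl("a", "Chr01", 100000, 110000, "+",
                 "b", "Chr01", 140000, 150000, "+")
  expect_equal(nrow(find_tandem(l1)), 1)
  expect_equal(find_tandem(l1)$distance_bp, 30000)
  # 60 kb apart: none
  l2 <- loci_tbl("a", "Chr01", 100000, 110000, "+",
                 "b", "Chr01", 170000, 180000, "+")
  expect_equal(nrow(find_tandem(l2)), 0)
  # same positions, different chromosomes: none
  l3 <- loci_tbl("a", "Chr01", 100000, 110000, "+",
                 "b", "Chr02", 100000, 110000, "+")
  expect_equal(nrow(find_tandem(l3)), 0)
  # symmetric in gene order and invariant under chromosome renaming
  l1r <- l1[2:1, ]
  l1r$chromosome <- "K"
  expect_equal(find_tandem(l1r)[, c("gene_a", "gene_b", "distance_bp")],
               find_tandem(l1)[, c("gene_a", "gene_b", "distance_bp")],
               ignore_attr = TRUE)
  # scaffold genes are excluded and reported
  l4 <- loci_tbl("a", "scaffold_1", 1000, 2000, "+",
                 "b", "Chr01", 1000, 2000, "+")
  td <- find_tandem(l4)
  expect_equal(nrow(td), 0)
  expect_equal(attr(td, "excluded"), "a")
})

test_that("flank extraction windows, truncation and coordinate maps agree", {
  genome <- c(ChrT = random_nt(200000))
  locus <- list(gene_id = "g", chromosome = "ChrT", start = 60000,
                end = 62000)
  fl <- extract_flanks(genome, locus, flank = 50000)
  expect_equal(nchar(fl$sequence), 100000)
  expect_equal(fl$map$gen_start, c(10000, 62000))
  expect_equal(fl$map$gen_end, c(60000, 112000))
  expect_false(fl$truncated_upstream)
  # gene body is excluded
  expect_equal(substr(fl$sequence, 1, 50000),
               substr(genome[["ChrT"]], 10001, 60000))

  # gene near the chromosome start: upstream truncated, flag set
  locus2 <- list(gene_id = "h", chromosome = "ChrT", start = 10000,
                 end = 12000)
  fl2 <- extract_flanks(genome, locus2, flank = 50000)
  expect_true(fl2$truncated_upstream)
  expect_equal(fl2$map$gen_start[1], 0)

  # round trip: window coordinates map back to the aligned substring
  pos <- c(0, 49999, 50000, 99999)
  mapped <- map_to_genomic(fl$map, pos)
  for (i in seq_along(pos)) {
    expect_equal(substr(fl$sequence, pos[i] + 1, pos[i] + 1),
                 substr(genome[["ChrT"]], mapped$genomic[i] + 1,
                        mapped$genomic[i] + 1))
  }
  expect_error(extract_flanks(genome, list(gene_id = "x",
                                           chromosome = "ChrZ",
                                           start = 1, end = 2)),
               "absent")
})

test_that("chaining applies the published per-block filters", {
  blk <- function(qs, len, id, ss = qs) {
    tibble::tibble(query_id = "q", subject_id = "s", qstart = qs,
                   qend = qs + len, sstart = ss, send = ss + len,
                   length = len, matches = round(id * len),
                   identity = id, score = len)
  }
  # one block of length 150: filtered out ("> 200 bp" is strict)
  expect_equal(chain_blocks(blk(0, 150, 0.95))$total_aligned, 0)
  # length 300 at 80% identity: filtered ("> 85%" is strict)
  expect_equal(chain_blocks(blk(0, 300, 0.80))$total_aligned, 0)
  # boundary cases stay excluded
  expect_equal(chain_blocks(blk(0, 200, 0.95))$total_aligned, 0)
  expect_equal(chain_blocks(blk(0, 300, 0.85))$total_aligned, 0)
  # a passing block survives
  ch <- chain_blocks(blk(0, 300, 0.90))
  expect_equal(ch$total_aligned, 300)
  expect_equal(ch$min_identity, 0.90)
  # empty input: empty chain, not an error
  expect_equal(chain_blocks(NULL)$total_aligned, 0)
})

test_that("chain dynamic programming equals brute-force enumeration", {
  set.seed(41)
  for (rep in 1:120) {
    nb <- sample(2:10, 1)
    qs <- sort(sample(0:5000, nb))
    blocks <- tibble::tibble(
      query_id = "q", subject_id = "s",
      qstart = qs,
      qend = qs + sample(150:900, nb, TRUE),
      sstart = sample(0:5000, nb),
      length = NA_integer_, identity = runif(nb, 0.8, 1)
    )
    blocks$length <- blocks$qend - blocks$qstart
    blocks$send <- blocks$sstart + blocks$length
    blocks$matches <- round(blocks$identity * blocks$length)
    blocks$score <- blocks$length
    got <- chain_blocks(blocks)$total_aligned
    expect_equal(got, chain_total_oracle(blocks))
  }
})

test_that("segmental calls recover the planted pairs and collapse loci", {
  scn <- noiseless_scenario()
  loci <- dplyr::select(scn$genome$gene_models, gene_id, chromosome,
                        start, end, strand)
  seg <- call_segmental(loci, scn$genome$genome)
  truth <- scn$genome$truth$duplications
  expect_equal(nrow(seg), nrow(truth))
  expect_setequal(paste(seg$gene_a, seg$gene_b),
                  paste(truth$gene_a, truth$gene_b))
  # same-locus transcript records were collapsed before pairing
  collapsed <- attr(seg, "collapsed")
  expect_equal(length(collapsed),
               length(scn$genome$truth$same_locus_pairs))
  # scaffold-bound genes excluded and reported
  expect_setequal(attr(seg, "excluded"), scn$genome$truth$scaffold_genes)
  # every chain block satisfies the published filters
  for (ch in attr(seg, "chains")) {
    expect_true(all(ch$blocks$length > 200))
    expect_true(all(ch$blocks$identity > 0.85))
  }
  # and no tandem pairs were planted or found
  expect_equal(nrow(find_tandem(loci)), 0)
})
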