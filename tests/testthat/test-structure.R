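make_models <- function(df) {
  # df: gene_id, chromosome, strand, exon bounds as list of c(start, end)
  purrr::pmap(df, function(gene_id, chromosome, strand, exons) {
    es <- vapply(exons, `[`, numeric(1), 1)
    ee <- vapply(exons, `[`, numeric(1), 2)
    tibble::tibble(
      gene_id = gene_id, chromosome = chromosome, strand = strand,
      start = min(es), end = max(ee),
      cds_start = if (strand == "+") min(es) else max(ee),
      exon_starts = list(es), exon_ends = list(ee)
    )
  }) |> dplyr::bind_rows()
}

test_that("exon and intron counts follow the gene models", {
  models <- make_models(tibble::tibble(
    gene_id = c("g1", "g2"), chromosome = "Chr01", strand = "+",
    exons = list(list(c(100, 400)),
                 list(c(100, 200), c(300, 400), c(500, 650)))
  ))
  st <- exon_stats(models, c(g1 = "I", g2 = "I", g9 = "II"))
  expect_equal(st$per_gene$n_exons, c(1, 3))
  expect_equal(st$per_gene$n_introns, c(0, 2))
  # genes missing from the annotation are listed, not dropped silently
  expect_equal(st$missing, "g9")
  # empty subfamilies are absent from the summary, not zero rows
  expect_false("II" %in% st$per_subfamily$subfamily)
})

test_that("a uniform 18-exon subfamily summarizes to mean 18", {
  exons18 <- lapply(0:17, function(i) c(1000 * i, 1000 * i + 80))
  models <- make_models(tibble::tibble(
    gene_id = sprintf("m%02d", 1:9), chromosome = "Chr02", strand = "+",
    exons = rep(list(exons18), 9)
  ))
  sf <- setNames(rep("III", 9), models$gene_id)
  st <- exon_stats(models, sf)
  smry <- st$per_subfamily
  expect_equal(smry$mean_exons, 18)
  expect_equal(smry$min_exons, 18)
  expect_equal(smry$max_exons, 18)
})

test_that("exon statistics survive a GFF3 round trip in any feature order", {
  scn <- noiseless_scenario()
  gm <- scn$genome$gene_models
  sf <- setNames(scn$proteome$truth$members$subfamily,
                 scn$proteome$truth$members$gene_id)
  direct <- exon_stats(gm, sf)

  path <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(gm, path)
  reread <- exon_stats(read_gene_models(path), sf)
  expect_equal(reread$per_gene, direct$per_gene)

  # shuffle feature lines (keeping the header first): order-invariant
  lines <- readLines(path)
  set.seed(2)
  shuffled <- c(lines[1], sample(lines[-1]))
  path2 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(shuffled, path2)
  reread2 <- exon_stats(read_gene_models(path2), sf)
  expect_equal(dplyr::arrange(reread2$per_gene, gene_id),
               dplyr::arrange(direct$per_gene, gene_id))
})

test_that("overlapping exons in one gene are a malformed-annotation error", {
  models <- make_models(tibble::tibble(
    gene_id = "bad", chromosome = "Chr01", strand = "+",
    exons = list(list(c(100, 300), c(250, 400)))
  ))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(models, path)
  expect_error(read_gene_models(path), "overlapping exons")
})
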