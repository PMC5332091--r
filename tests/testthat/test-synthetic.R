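test_that("degenerate and noiseless configurations behave as documented", {
  # all counts zero: empty proteome, empty truth
  empty <- scenario_config(
    archetype_counts = c(I = 0, II = 0, III = 0, IV = 0),
    decoy_counts = c(hd_only = 0, lz_only = 0, redundant = 0),
    duplication_plan = tibble::tibble(subfamily = character(),
                                      flank_identity = double(),
                                      span = double()))
  pe <- generate_proteome(empty)
  expect_length(pe$proteome, 0)
  expect_equal(nrow(pe$truth$members), 0)

  # mutation rate 0: members carry their subfamily consensus verbatim,
  # and subfamily divergence 0 collapses that to the packaged consensus
  pristine <- scenario_config(
    seed = 5, mutation_rate = 0, subfamily_divergence = 0,
    archetype_counts = c(I = 1, II = 0, III = 0, IV = 0),
    decoy_counts = c(hd_only = 0, lz_only = 0, redundant = 0),
    duplication_plan = tibble::tibble(subfamily = character(),
                                      flank_identity = double(),
                                      span = double()),
    n_scaffold_genes = 0, n_same_locus_pairs = 0)
  pp <- generate_proteome(pristine)
  seq1 <- pp$proteome[[1]]
  expect_true(grepl(domain_consensus()[["HD"]], seq1, fixed = TRUE))
  expect_true(grepl(domain_consensus()[["LZ"]], seq1, fixed = TRUE))

  # invalid configurations error out
  expect_error(scenario_config(archetype_counts = c(I = -1, II = 0,
                                                    III = 0, IV = 0)),
               "counts")
  expect_error(scenario_config(chromosome_length = 0), "zero-length")
  expect_error(scenario_config(duplication_plan = tibble::tibble(
    subfamily = "I", flank_identity = 1.2, span = 1000)),
    "flank_identity")
  expect_error(scenario_config(duplication_plan = tibble::tibble(
    subfamily = "I", flank_identity = 0.9, span = 2e5)), "span")
  expect_error(scenario_config(qpcr_plan = list(
    n_targets = 1, timepoints = "NTC", ratios = 1, ct_sd = -1,
    baseline_ct = 24, reference_ct = 18)), "sd")
})

test_that("a fixed seed reproduces byte-identical scenario files", {
  cfg <- noiseless_config(seed = 77)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_scenario(generate_scenario(cfg), d1)
  write_scenario(generate_scenario(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 2e7),
                     readBin(file.path(d2, f), "raw", 2e7),
                     label = f)
  }
})

test_that("planted flank windows match the configured identity", {
  # flank_identity = 1: gene B's window is a verbatim copy of gene A's
  scn <- noiseless_scenario()
  tru <- scn$genome$truth$duplications
  loci <- scn$genome$gene_models
  for (r in seq_len(nrow(tru))) {
    la <- loci[loci$gene_id == tru$gene_a[r], ]
    lb <- loci[loci$gene_id == tru$gene_b[r], ]
    h <- min(tru$span[r] %/% 2, 50000)
    fa <- extract_flanks(scn$genome$genome, la, flank = h)
    fb <- extract_flanks(scn$genome$genome, lb, flank = h)
    expect_identical(fa$sequence, fb$sequence)
  }

  # mutated copy: mismatch fraction within 3 SD of Binomial(len, 1 - id)
  cfg <- scenario_config(
    seed = 31, archetype_counts = c(I = 3, II = 2, III = 2, IV = 2),
    decoy_counts = c(hd_only = 0, lz_only = 0, redundant = 0),
    n_chromosomes = 4, n_scaffold_genes = 0, n_same_locus_pairs = 0,
    duplication_plan = tibble::tibble(subfamily = "I",
                                      flank_identity = 0.9,
                                      span = 60000))
  g <- generate_genome(cfg)
  tru <- g$truth$duplications
  la <- g$gene_models[g$gene_models$gene_id == tru$gene_a, ]
  lb <- g$gene_models[g$gene_models$gene_id == tru$gene_b, ]
  h <- 30000
  fa <- strsplit(extract_flanks(g$genome, la, flank = h)$sequence, "")[[1]]
  fb <- strsplit(extract_flanks(g$genome, lb, flank = h)$sequence, "")[[1]]
  mism <- mean(fa != fb)
  expect_lt(abs(mism - 0.1), 3 * sqrt(0.1 * 0.9 / length(fa)))

  # placement plan keeps same-chromosome genes > 50 kb apart: no tandems
  expect_equal(nrow(g$truth$tandem), 0)
  loci_tbl <- dplyr::select(g$gene_models, gene_id, chromosome, start,
                            end, strand)
  expect_equal(nrow(find_tandem(loci_tbl)), 0)

  # truth ids all exist in the emitted objects
  expect_true(all(tru$gene_a %in% g$gene_models$gene_id))
  expect_true(all(g$truth$exon_counts$gene_id %in% g$gene_models$gene_id))
})

test_that("noiseless expression generation hits its documented cases", {
  # 5 constitutive genes at sd = 0: min FPKM across samples > 1
  cfg <- scenario_config(
    seed = 9, archetype_counts = c(I = 5, II = 0, III = 0, IV = 0),
    decoy_counts = c(hd_only = 0, lz_only = 0, redundant = 0),
    duplication_plan = tibble::tibble(subfamily = character(),
                                      flank_identity = double(),
                                      span = double()),
    n_scaffold_genes = 0, n_same_locus_pairs = 0,
    expression_plan = list(
      samples = c("leaf", "stem", "root"), tissue_groups = list(),
      class_counts = c(constitutive = 5, non_expressed = 0,
                       tissue_specific = 0, partial = 0),
      noise_sd = 0, leaf_changed = 0, root_changed = 0, change_ratio = 8),
    qpcr_plan = list(n_targets = 2, timepoints = c("NTC", "t1"),
                     ratios = c(1, 1), ct_sd = 0, baseline_ct = 24,
                     reference_ct = 18))
  ex <- generate_expression(cfg)
  mat <- as.matrix(ex$fpkm[, -1])
  expect_true(all(apply(mat, 1, min) > 1))

  # true ratio 1 everywhere, sd = 0: downstream 2^-ddCt is exactly 1
  res <- qpcr_analysis(ex$ct)
  expect_true(all(abs(res$relative_expression - 1) < 1e-12))

  # true ratio 4, sd = 0: target Ct sits 2 cycles below the calibrator
  cfg4 <- scenario_config(
    seed = 9, archetype_counts = c(I = 2, II = 0, III = 0, IV = 0),
    decoy_counts = c(hd_only = 0, lz_only = 0, redundant = 0),
    duplication_plan = tibble::tibble(subfamily = character(),
                                      flank_identity = double(),
                                      span = double()),
    n_scaffold_genes = 0, n_same_locus_pairs = 0,
    qpcr_plan = list(n_targets = 1, timepoints = c("NTC", "t1"),
                     ratios = c(1, 4), ct_sd = 0, baseline_ct = 24,
                     reference_ct = 18))
  ct <- generate_expression(cfg4)$ct
  tgt <- ct[ct$target != "ACT", ]
  expect_equal(mean(tgt$ct[tgt$sample == "NTC"]) -
                 mean(tgt$ct[tgt$sample == "t1"]), 2)
  refs <- ct[ct$target == "ACT", ]
  expect_true(all(refs$ct == 18))
})
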