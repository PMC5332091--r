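# End-to-end orchestration: identify -> classify -> structure/motifs |
# duplication | cis-elements -> expression/qPCR, with a run manifest
# recording the configuration, input checksums and per-stage counts.

#' Default pipeline configuration
#'
#' All thresholds default to the study's stated values: E-value 0.01,
#' FPKM 1, fold change 2, tandem window 50 kb, flank 50 kb, block length
#' 200 bp, block identity 85%, promoter 1500 bp, 1000 bootstrap
#' replicates, alpha 0.05.
#'
#' @param ... Overrides for any field.
#' @return An `hdz_pipeline_config` list with fields: `inputs` (named
#'   paths: proteome, genome, gff3, fpkm, fpkm_drought, qpcr, catalog,
#'   alignment, anchors), `synthetic` (NULL or an
#'   [scenario_config()]), `evalue`, `fpkm_threshold`, `fold_change`,
#'   `tandem_window`, `flank`, `block_length`, `block_identity`,
#'   `min_chain_span`, `promoter_length`, `bootstrap`, `alpha`,
#'   `null_shuffles`, `seed`, `out_dir`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    inputs = list(proteome = NULL, genome = NULL, gff3 = NULL,
                  fpkm = NULL, fpkm_drought = NULL, qpcr = NULL,
                  catalog = NULL, alignment = NULL, anchors = NULL),
    synthetic = NULL,
    evalue = 0.01,
    fpkm_threshold = 1,
    fold_change = 2,
    tandem_window = 50000,
    flank = 50000,
    block_length = 200,
    block_identity = 0.85,
    min_chain_span = 2000,
    promoter_length = 1500,
    bootstrap = 1000,
    alpha = 0.05,
    null_shuffles = 199,
    seed = 1,
    out_dir = tempfile("hdzipr_run_")
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) abort(sprintf("unknown config field '%s'", nm))
    cfg[[nm]] <- dots[[nm]]
  }
  validate_pipeline_config(cfg)
  structure(cfg, class = "hdz_pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  num_fields <- c("evalue", "fpkm_threshold", "fold_change",
                  "tandem_window", "flank", "block_length",
                  "block_identity", "min_chain_span", "promoter_length",
                  "bootstrap", "alpha", "null_shuffles")
  for (nm in num_fields) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0) {
      abort(sprintf("invalid configuration value for field '%s'", nm))
    }
  }
  if (cfg$bootstrap < 1) abort("invalid configuration value for field 'bootstrap'")
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys mirror
#'   [pipeline_config()] fields.
#' @return An `hdz_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full characterization pipeline
#'
#' Stages run in dependency order: identification, subfamily
#' classification (tree + architecture), exon-intron structure, motif
#' discovery, duplication calling, promoter cis-element enrichment, and
#' expression/qPCR analysis. Any stage failure halts the run with the
#' stage name; the partial manifest is still written. With
#' `config$synthetic` set, inputs are generated from that scenario and
#' written alongside the outputs.
#'
#' @param config An [pipeline_config()].
#' @return An `hdz_manifest` list: `timestamp`, `config`, `checksums`,
#'   `counts` (per-stage record counts), `warnings`, `out_dir`.
#'   All stage outputs are written as TSV/newick under `config$out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "hdz_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  warn_log <- character(0)
  note <- function(msg) warn_log <<- c(warn_log, msg)
  counts <- list()
  stage <- "setup"
  result <- tryCatch({
    # ---- inputs ---------------------------------------------------------
    if (!is.null(config$synthetic)) {
      scn <- generate_scenario(config$synthetic)
      sdir <- file.path(config$out_dir, "synthetic_inputs")
      write_scenario(scn, sdir)
      proteome <- scn$proteome$proteome
      genome <- scn$genome$genome
      gene_models <- scn$genome$gene_models
      fpkm <- scn$expression$fpkm
      fpkm_drought <- scn$expression$fpkm_drought
      ct <- scn$expression$ct
      alignment <- scn$proteome$truth$alignment
      anchors <- scn$proteome$truth$anchors
      catalog <- read_element_catalog()
      input_files <- list.files(sdir, full.names = TRUE)
    } else {
      req <- c("proteome", "genome", "gff3", "fpkm")
      missing <- req[vapply(req, function(f) {
        is.null(config$inputs[[f]]) || !file.exists(config$inputs[[f]])
      }, logical(1))]
      if (length(missing) > 0) {
        abort(sprintf("missing input(s): %s",
                      paste(missing, collapse = ", ")))
      }
      proteome <- read_proteome(config$inputs$proteome)
      genome <- read_genome(config$inputs$genome)
      gene_models <- read_gene_models(config$inputs$gff3)
      fpkm <- read_fpkm(config$inputs$fpkm)
      fpkm_drought <- if (!is.null(config$inputs$fpkm_drought)) {
        read_fpkm(config$inputs$fpkm_drought)
      } else NULL
      ct <- if (!is.null(config$inputs$qpcr)) {
        read_ct_table(config$inputs$qpcr)
      } else NULL
      alignment <- if (!is.null(config$inputs$alignment)) {
        read_proteome(config$inputs$alignment)
      } else NULL
      anchors <- if (!is.null(config$inputs$anchors)) {
        unlist(yaml::read_yaml(config$inputs$anchors))
      } else NULL
      catalog <- read_element_catalog(config$inputs$catalog)
      input_files <- unlist(config$inputs)
    }
    checksums <- vapply(input_files, function(f) {
      if (!is.null(f) && file.exists(f)) digest::digest(file = f)
      else NA_character_
    }, character(1))

    # ---- identify -------------------------------------------------------
    stage <- "identify"
    profiles <- default_profiles()
    calls <- identify_family(proteome, profiles,
                             evalue_threshold = config$evalue,
                             null_shuffles = config$null_shuffles,
                             seed = config$seed)
    readr::write_tsv(calls, file.path(config$out_dir, "family_calls.tsv"))
    counts$identify <- nrow(calls)
    retained <- calls$protein_id[calls$retained]

    # ---- classify -------------------------------------------------------
    stage <- "classify"
    assignments <- NULL
    if (!is.null(alignment) && !is.null(anchors)) {
      keep <- intersect(names(alignment), c(retained, names(anchors)))
      aln <- alignment[keep]
      tree <- bootstrap_support(aln, n_replicates = config$bootstrap,
                                seed = config$seed)
      ape::write.tree(tree, file.path(config$out_dir, "family_tree.nwk"))
      arch <- domain_architecture(proteome[retained], profiles,
                                  evalue_threshold = config$evalue,
                                  null_shuffles = config$null_shuffles,
                                  seed = config$seed)
      arch_map <- architecture_calls(arch)
      assignments <- withCallingHandlers(
        assign_subfamily(tree, anchors, arch_map),
        warning = function(w) {
          note(conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      readr::write_tsv(assignments,
                       file.path(config$out_dir, "subfamilies.tsv"))
      counts$classify <- nrow(assignments)
    } else {
      note("classification skipped: no alignment/anchors supplied")
    }
    sf_map <- if (!is.null(assignments)) {
      setNames(assignments$subfamily, assignments$gene_id)
    } else {
      setNames(rep("I", length(retained)), retained)
    }

    # ---- structure ------------------------------------------------------
    stage <- "structure"
    fam_models <- filter(gene_models, .data$gene_id %in% retained)
    es <- exon_stats(gene_models, sf_map[intersect(names(sf_map),
                                                   gene_models$gene_id)])
    readr::write_tsv(es$per_gene,
                     file.path(config$out_dir, "exon_stats.tsv"))
    readr::write_tsv(es$per_subfamily,
                     file.path(config$out_dir, "exon_summary.tsv"))
    counts$structure <- nrow(es$per_gene)

    # ---- motifs ---------------------------------------------------------
    stage <- "motifs"
    motifs <- discover_motifs(proteome[retained], seed = config$seed)
    write_meme(motifs, proteome[retained],
               file.path(config$out_dir, "motifs.txt"))
    counts$motifs <- length(motifs)

    # ---- duplication ----------------------------------------------------
    stage <- "duplication"
    loci <- select(fam_models, "gene_id", "chromosome", "start", "end",
                   "strand")
    tandem <- find_tandem(loci, window = config$tandem_window)
    segmental <- call_segmental(
      loci, genome, flank = config$flank,
      min_length = config$block_length,
      min_identity = config$block_identity,
      min_chain_span = config$min_chain_span,
      tandem_window = config$tandem_window)
    dup <- bind_rows(
      select(tandem, "gene_a", "gene_b", "type"),
      select(segmental, "gene_a", "gene_b", "type")
    )
    readr::write_tsv(bind_rows(tandem, segmental) |>
                       select(-dplyr::any_of("distance_bp")),
                     file.path(config$out_dir, "duplications.tsv"))
    counts$duplication <- nrow(dup)

    # ---- cis-elements ---------------------------------------------------
    stage <- "cisreg"
    promoters <- setNames(purrr::map_chr(seq_len(nrow(fam_models)),
      function(i) {
        as.character(extract_promoter(genome, fam_models[i, ],
                                      config$promoter_length))
      }), fam_models$gene_id)
    write_fasta(promoters, file.path(config$out_dir, "promoters.fa"),
                "DNA")
    hits <- scan_elements(promoters, catalog)
    readr::write_tsv(hits, file.path(config$out_dir, "element_hits.tsv"))
    enr <- withCallingHandlers(
      enrichment_test(hits, sf_map[names(promoters)]),
      warning = function(w) {
        note(conditionMessage(w)); invokeRestart("muffleWarning")
      })
    readr::write_tsv(enr, file.path(config$out_dir, "enrichment.tsv"))
    counts$cisreg <- nrow(enr)

    # ---- expression -----------------------------------------------------
    stage <- "expression"
    fam_fpkm <- filter(fpkm, .data$gene_id %in% retained)
    tg <- if (!is.null(config$synthetic)) {
      config$synthetic$expression_plan$tissue_groups
    } else list()
    cls <- classify_expression(fam_fpkm, threshold = config$fpkm_threshold,
                               tissue_groups = tg)
    readr::write_tsv(select(cls, -"expressed_samples"),
                     file.path(config$out_dir, "expression_class.tsv"))
    counts$expression <- nrow(cls)
    if (!is.null(fpkm_drought)) {
      fd <- filter(fpkm_drought, .data$gene_id %in% retained)
      fc <- bind_rows(
        mutate(fold_change(fd$leaf_drought, fd$leaf_control,
                           gene_id = fd$gene_id), tissue = "leaf"),
        mutate(fold_change(fd$root_drought, fd$root_control,
                           gene_id = fd$gene_id), tissue = "root")
      )
      readr::write_tsv(fc, file.path(config$out_dir, "fold_change.tsv"))
      counts$fold_change <- nrow(fc)
    }

    # ---- qPCR -----------------------------------------------------------
    stage <- "qpcr"
    if (!is.null(ct) && nrow(ct) > 0) {
      qres <- qpcr_analysis(ct, alpha = config$alpha)
      readr::write_tsv(qres, file.path(config$out_dir, "qpcr.tsv"))
      counts$qpcr <- nrow(qres)
    }
    stage <- "done"
    list(counts = counts, checksums = checksums)
  }, error = function(e) {
    abort(sprintf("pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)))
  })

  manifest <- structure(
    list(
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config = unclass(config),
      checksums = as.list(result$checksums),
      counts = result$counts,
      warnings = warn_log,
      out_dir = config$out_dir
    ),
    class = "hdz_manifest"
  )
  jsonlite::write_json(
    manifest[setdiff(names(manifest), "timestamp")],
    file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  writeLines(manifest$timestamp,
             file.path(config$out_dir, "timestamp.txt"))
  manifest
}

#' @export
print.hdz_manifest <- function(x, ...) {
  cat("<hdz_manifest>", x$timestamp, "\n")
  cat("output:", x$out_dir, "\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-12s %d records\n", nm, x$counts[[nm]]))
  }
  if (length(x$warnings)) {
    cat("warnings:\n")
    for (w in x$warnings) cat("  -", w, "\n")
  }
  invisible(x)
}
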