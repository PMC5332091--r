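# Synthetic scenario generator. Produces proteomes, genomes with GFF3 gene
# models, promoters with planted cis-elements, FPKM matrices and qPCR Ct
# tables -- all with a known truth table so every downstream stage can be
# validated exactly. Defaults emulate the study design the pipeline
# targets: 57 family genes in subfamilies of 23/14/9/11, a candidate pool
# of 125, 18 chromosomes plus 3 scaffold-bound genes and two same-locus
# transcript pairs, five segmental duplication pairs (two in subfamily II,
# one in each other subfamily) and no tandem pairs.

#' Build a synthetic scenario configuration
#'
#' All downstream generator behaviour flows from this object; a fixed
#' `seed` implies byte-identical outputs.
#'
#' @param seed Integer seed.
#' @param archetype_counts Named counts of true members per subfamily
#'   (architectures: I = HD+LZ, II = +CPSCE, III = +START+MEKHLA,
#'   IV = +START).
#' @param decoy_counts Named counts per decoy class: `hd_only`, `lz_only`
#'   (single-domain) and `redundant` (exact duplicates of true members).
#' @param mutation_rate Per-position mutation rate of member domains
#'   relative to their subfamily consensus (0 = noiseless).
#' @param subfamily_divergence Per-position divergence of each subfamily
#'   consensus from the packaged base consensus.
#' @param n_chromosomes Number of chromosomes (default 18).
#' @param chromosome_length Optional minimum chromosome length in bp;
#'   `NULL` sizes each chromosome from its gene count.
#' @param n_scaffold_genes Family genes placed on unanchored scaffolds.
#' @param n_same_locus_pairs Same-coordinate transcript pairs (default 2).
#' @param duplication_plan Tibble with one row per planted segmental pair:
#'   `subfamily`, `flank_identity` in (0, 1], `span` <= 100000.
#' @param exon_plan Named list: subfamily -> candidate exon counts.
#' @param promoter_plan Named character: subfamily -> element planted at
#'   `planted_freq`; all catalog elements are planted at
#'   `background_freq` everywhere else.
#' @param planted_freq,background_freq Per-promoter planting
#'   probabilities.
#' @param expression_plan List with `samples`, `tissue_groups`,
#'   `class_counts` (constitutive / non_expressed / tissue_specific /
#'   partial), `noise_sd` (log2-scale), `leaf_changed`, `root_changed`
#'   (planted drought-responsive gene counts), `change_ratio`.
#' @param qpcr_plan List with `n_targets`, `timepoints`, `ratios` (true
#'   fold levels per timepoint, calibrator first = 1), `ct_sd` (cycles),
#'   `baseline_ct`, `reference_ct`.
#' @return An `hdz_scenario_config` list.
#' @export
scenario_config <- function(
    seed = 1,
    archetype_counts = c(I = 23, II = 14, III = 9, IV = 11),
    decoy_counts = c(hd_only = 30, lz_only = 28, redundant = 10),
    mutation_rate = 0.05,
    subfamily_divergence = 0.15,
    n_chromosomes = 18,
    chromosome_length = NULL,
    n_scaffold_genes = 3,
    n_same_locus_pairs = 2,
    duplication_plan = tibble(
      subfamily = c("II", "II", "I", "III", "IV"),
      flank_identity = 0.92,
      span = 100000
    ),
    exon_plan = list(I = 1:3, II = 3:4, III = 18, IV = c(9, 10)),
    promoter_plan = c(I = "ABRE", II = "HSE", III = "GARE-motif",
                      IV = "MBS"),
    planted_freq = 0.9,
    background_freq = 0.15,
    expression_plan = list(
      samples = c("leaf", "stem", "ESR", "MSR", "LSR"),
      tissue_groups = list(root = c("ESR", "MSR", "LSR")),
      class_counts = c(constitutive = 25, non_expressed = 8,
                       tissue_specific = 12, partial = 12),
      noise_sd = 0.1,
      leaf_changed = 18, root_changed = 24,
      change_ratio = 8
    ),
    qpcr_plan = list(
      n_targets = 12,
      timepoints = c("NTC", "5h", "15h", "48h"),
      ratios = c(1, 4, 0.25, 2),
      ct_sd = 0.15, baseline_ct = 24, reference_ct = 18
    )) {
  cfg <- list(
    seed = seed, archetype_counts = archetype_counts,
    decoy_counts = decoy_counts, mutation_rate = mutation_rate,
    subfamily_divergence = subfamily_divergence,
    n_chromosomes = n_chromosomes,
    chromosome_length = chromosome_length,
    n_scaffold_genes = n_scaffold_genes,
    n_same_locus_pairs = n_same_locus_pairs,
    duplication_plan = duplication_plan, exon_plan = exon_plan,
    promoter_plan = promoter_plan, planted_freq = planted_freq,
    background_freq = background_freq,
    expression_plan = expression_plan, qpcr_plan = qpcr_plan
  )
  validate_scenario_config(cfg)
  structure(cfg, class = "hdz_scenario_config")
}

validate_scenario_config <- function(cfg) {
  if (any(cfg$archetype_counts < 0) || any(cfg$decoy_counts < 0)) {
    abort("configuration error: counts must be >= 0")
  }
  if (!setequal(names(cfg$archetype_counts), SUBFAMILIES)) {
    abort("archetype_counts must cover subfamilies I-IV")
  }
  if (!is.null(cfg$chromosome_length) && cfg$chromosome_length <= 0) {
    abort("configuration error: zero-length chromosome")
  }
  dp <- cfg$duplication_plan
  if (nrow(dp) > 0) {
    if (any(dp$flank_identity <= 0 | dp$flank_identity > 1)) {
      abort("flank_identity must lie in (0, 1]")
    }
    if (any(dp$span > 100000 | dp$span <= 0)) {
      abort("duplicated span must lie in (0, 100000]")
    }
  }
  if (cfg$mutation_rate < 0 || cfg$mutation_rate >= 1) {
    abort("mutation_rate must lie in [0, 1)")
  }
  if (length(cfg$expression_plan$samples) < 1) {
    abort("expression_plan must name at least one sample")
  }
  if (cfg$expression_plan$noise_sd < 0 || cfg$qpcr_plan$ct_sd < 0) {
    abort("configuration error: noise sd must be >= 0")
  }
  invisible(cfg)
}

# Per-run subfamily consensus: each subfamily's alleles of each domain,
# diverged from the packaged base consensus.
subfamily_consensus <- function(cfg) {
  with_seed(child_seed(cfg$seed, 11L), {
    out <- lapply(SUBFAMILIES, function(sf) {
      doms <- SUBFAMILY_ARCHITECTURE[[sf]]
      setNames(lapply(doms, function(d) {
        mutate_sequence(DOMAIN_CONSENSUS[[d]], cfg$subfamily_divergence)
      }), doms)
    })
    setNames(out, SUBFAMILIES)
  })
}

# Family member table: ids in subfamily blocks, matching the default
# subfamily sizes.
member_table <- function(cfg) {
  n <- sum(cfg$archetype_counts)
  if (n == 0) {
    return(tibble(gene_id = character(), subfamily = character()))
  }
  tibble(
    gene_id = sprintf("HDZ%02d", seq_len(n)),
    subfamily = rep(SUBFAMILIES, cfg$archetype_counts[SUBFAMILIES])
  )
}

#' Generate a synthetic candidate proteome with planted truth
#'
#' True members carry their subfamily's domain alleles (mutated at
#' `mutation_rate` per position) embedded in random background; decoys
#' carry exactly one of HD or LZ, or are exact duplicates of a true
#' member. True members precede decoys in the output so the
#' first-occurrence redundancy rule retains the planted member.
#'
#' @param config An [scenario_config()].
#' @return List: `proteome` (named character), `truth` (list with
#'   `members`, `decoys`, `domain_layout`, `alignment`, `anchors`).
#'   `alignment` is the domain-block concatenation (gaps where a domain is
#'   absent) used for tree building; `anchors` maps the four subfamily
#'   exemplar taxa (`ANCHOR_I` ...) to their subfamily.
#' @export
generate_proteome <- function(config) {
  validate_scenario_config(config)
  cons <- subfamily_consensus(config)
  members <- member_table(config)
  dom_w <- nchar(DOMAIN_CONSENSUS)
  gap_block <- function(d) strrep("-", dom_w[[d]])
  all_doms <- names(DOMAIN_CONSENSUS)
  proteome <- character(0)
  layout <- list()
  aln <- character(0)
  with_seed(child_seed(config$seed, 12L), {
    for (i in seq_len(nrow(members))) {
      sf <- members$subfamily[i]
      doms <- SUBFAMILY_ARCHITECTURE[[sf]]
      nterm <- random_aa(sample(10:40, 1))
      segs <- nterm
      pos <- nchar(nterm)
      dom_seqs <- list()
      for (d in doms) {
        dseq <- mutate_sequence(cons[[sf]][[d]], config$mutation_rate)
        dom_seqs[[d]] <- dseq
        layout[[length(layout) + 1]] <- tibble(
          gene_id = members$gene_id[i], domain = d,
          start = pos, end = pos + nchar(dseq)
        )
        segs <- c(segs, dseq)
        pos <- pos + nchar(dseq)
        if (d != doms[length(doms)]) {
          linker <- random_aa(sample(5:20, 1))
          segs <- c(segs, linker)
          pos <- pos + nchar(linker)
        }
      }
      cterm <- random_aa(sample(20:80, 1))
      segs <- c(segs, cterm)
      proteome[members$gene_id[i]] <- paste(segs, collapse = "")
      aln[members$gene_id[i]] <- paste(vapply(all_doms, function(d) {
        if (d %in% doms) dom_seqs[[d]] else gap_block(d)
      }, character(1)), collapse = "")
    }
    # anchors: the subfamily consensus exemplars themselves
    for (sf in SUBFAMILIES) {
      aln[paste0("ANCHOR_", sf)] <- paste(vapply(all_doms, function(d) {
        if (d %in% SUBFAMILY_ARCHITECTURE[[sf]]) cons[[sf]][[d]]
        else gap_block(d)
      }, character(1)), collapse = "")
    }
    # decoys
    decoys <- list()
    dc <- config$decoy_counts
    mk_id <- function(cls, i) sprintf("DECOY_%s_%02d", toupper(cls), i)
    count_of <- function(nm) if (nm %in% names(dc)) dc[[nm]] else 0
    for (i in seq_len(count_of("hd_only"))) {
      id <- mk_id("hd", i)
      proteome[id] <- paste0(
        random_aa(sample(20:60, 1)),
        mutate_sequence(DOMAIN_CONSENSUS[["HD"]], config$mutation_rate),
        random_aa(sample(30:90, 1)))
      decoys[[length(decoys) + 1]] <- tibble(
        gene_id = id, class = "hd_only", source = NA_character_)
    }
    for (i in seq_len(count_of("lz_only"))) {
      id <- mk_id("lz", i)
      proteome[id] <- paste0(
        random_aa(sample(20:60, 1)),
        mutate_sequence(DOMAIN_CONSENSUS[["LZ"]], config$mutation_rate),
        random_aa(sample(30:90, 1)))
      decoys[[length(decoys) + 1]] <- tibble(
        gene_id = id, class = "lz_only", source = NA_character_)
    }
    n_red <- count_of("redundant")
    if (n_red > 0 && nrow(members) == 0) {
      abort("redundant decoys require at least one true member")
    }
    for (i in seq_len(n_red)) {
      src <- members$gene_id[((i - 1) %% nrow(members)) + 1]
      id <- mk_id("dup", i)
      proteome[id] <- proteome[[src]]
      decoys[[length(decoys) + 1]] <- tibble(
        gene_id = id, class = "redundant", source = src)
    }
  })
  decoys <- if (length(decoys)) bind_rows(decoys) else
    tibble(gene_id = character(), class = character(),
           source = character())
  list(
    proteome = proteome,
    truth = list(
      members = members,
      decoys = decoys,
      domain_layout = if (length(layout)) bind_rows(layout) else
        tibble(gene_id = character(), domain = character(),
               start = integer(), end = integer()),
      alignment = aln,
      anchors = setNames(SUBFAMILIES, paste0("ANCHOR_", SUBFAMILIES))
    )
  )
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# raw-byte helpers for building chromosome sequences -----------------------

DNA_RAW <- charToRaw("ACGT")

raw_dna <- function(n) sample(DNA_RAW, n, replace = TRUE)

# point-mutate raw bases at a per-base rate (uniform over the other bases)
mutate_raw <- function(x, rate) {
  if (rate <= 0 || length(x) == 0) return(x)
  hit <- which(runif(length(x)) < rate)
  if (length(hit) > 0) {
    shift <- sample(1:3, length(hit), replace = TRUE)
    cur <- match(x[hit], DNA_RAW)
    x[hit] <- DNA_RAW[((cur - 1 + shift) %% 4) + 1]
  }
  x
}

revcomp_chars <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(x), "", fixed = TRUE)[[1]]]),
        collapse = "")
}

# realize an IUPAC pattern into a concrete sequence
realize_iupac <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    opts <- IUPAC_CODES[[ch]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

#' Generate a synthetic genome with planted duplications and promoters
#'
#' Places the family genes of a scenario on chromosomes (plus unanchored
#' scaffolds and same-locus transcript pairs), builds exon-intron
#' structures per the subfamily exon plan, plants cis-elements into the
#' 1500-bp promoters (each subfamily's focal element at `planted_freq`,
#' every element at `background_freq`), and for each planned segmental
#' pair copies gene A's flanking windows over gene B's at a per-base
#' mutation rate of `1 - flank_identity`. Gene spacing keeps all
#' same-chromosome pairs more than 50 kb apart, so the planted tandem
#' truth is empty.
#'
#' @param config An [scenario_config()].
#' @param proteome Optional result of [generate_proteome()] for the same
#'   config (regenerated when NULL).
#' @return List: `genome` (named character), `gene_models` tibble
#'   (as [read_gene_models()]), `truth` list with `loci`, `duplications`,
#'   `tandem`, `planted_elements`, `exon_counts`, `scaffold_genes`,
#'   `same_locus_pairs`.
#' @export
generate_genome <- function(config, proteome = NULL) {
  validate_scenario_config(config)
  if (is.null(proteome)) proteome <- generate_proteome(config)
  members <- proteome$truth$members
  n <- nrow(members)
  if (n == 0) {
    return(list(genome = character(0),
                gene_models = tibble(),
                truth = list(loci = tibble(), duplications = tibble(),
                             tandem = tibble(), planted_elements = tibble(),
                             exon_counts = tibble(),
                             scaffold_genes = character(0),
                             same_locus_pairs = list())))
  }
  catalog <- read_element_catalog()
  with_seed(child_seed(config$seed, 13L), {
    # --- choose special genes -------------------------------------------
    scaffold_idx <- integer(0)
    if (config$n_scaffold_genes > 0) {
      preferred <- c(31L, 47L, 53L)
      scaffold_idx <- head(preferred[preferred <= n],
                           config$n_scaffold_genes)
      extra_needed <- config$n_scaffold_genes - length(scaffold_idx)
      if (extra_needed > 0) {
        scaffold_idx <- c(scaffold_idx,
                          tail(setdiff(seq_len(n), scaffold_idx),
                               extra_needed))
      }
    }
    same_pairs <- list()
    if (config$n_same_locus_pairs > 0) {
      pref <- list(c(1L, 6L), c(38L, 41L))
      avail <- setdiff(seq_len(n), scaffold_idx)
      for (pp in pref) {
        if (length(same_pairs) >= config$n_same_locus_pairs) break
        if (all(pp %in% avail) &&
            members$subfamily[pp[1]] == members$subfamily[pp[2]]) {
          same_pairs[[length(same_pairs) + 1]] <- pp
          avail <- setdiff(avail, pp)
        }
      }
      while (length(same_pairs) < config$n_same_locus_pairs) {
        cand <- split(avail, members$subfamily[avail])
        cand <- cand[lengths(cand) >= 2]
        if (length(cand) == 0) break
        pp <- cand[[1]][1:2]
        same_pairs[[length(same_pairs) + 1]] <- pp
        avail <- setdiff(avail, pp)
      }
    }
    same_secondary <- vapply(same_pairs, `[`, integer(1), 2)
    # slots = loci; a same-locus pair shares one slot
    slot_of <- setNames(seq_len(n), members$gene_id)
    for (pp in same_pairs) slot_of[pp[2]] <- slot_of[pp[1]]
    chrom_genes <- setdiff(seq_len(n), scaffold_idx)
    slot_leader <- setdiff(chrom_genes, same_secondary)
    # --- assign slots to chromosomes ------------------------------------
    nchr <- config$n_chromosomes
    chrom_names <- sprintf("Chr%02d", seq_len(nchr))
    slot_chrom <- setNames(rep(NA_character_, length(slot_leader)),
                           members$gene_id[slot_leader])
    singles <- intersect(c(7L, 10L, 18L), seq_len(nchr))
    if (nchr < 4) singles <- integer(0)
    remaining <- members$gene_id[slot_leader]
    # same-locus pair slots pinned first (pair 1 -> Chr03, pair 2 -> Chr01)
    pin_chr <- c(min(3L, nchr), 1L)
    for (i in seq_along(same_pairs)) {
      lead <- members$gene_id[same_pairs[[i]][1]]
      slot_chrom[lead] <- chrom_names[pin_chr[min(i, length(pin_chr))]]
      remaining <- setdiff(remaining, lead)
    }
    # one gene on each "single" chromosome
    for (s in singles) {
      if (length(remaining) == 0) break
      slot_chrom[remaining[1]] <- chrom_names[s]
      remaining <- remaining[-1]
    }
    # fill Chr01 up to 7 slots (8 gene records with its same-locus pair)
    target_chr1 <- 7L
    while (sum(slot_chrom == chrom_names[1], na.rm = TRUE) < target_chr1 &&
           length(remaining) > 0 && nchr > 1) {
      slot_chrom[remaining[1]] <- chrom_names[1]
      remaining <- remaining[-1]
    }
    # round-robin the rest over the other, non-single chromosomes
    pool <- setdiff(seq_len(nchr), c(1L, singles))
    if (length(pool) == 0) pool <- seq_len(nchr)
    ci <- 1L
    for (g in remaining) {
      slot_chrom[g] <- chrom_names[pool[ci]]
      ci <- ci %% length(pool) + 1L
    }
    # --- gene structures -------------------------------------------------
    aa_len <- nchar(proteome$proteome[members$gene_id])
    structures <- vector("list", n)
    for (i in seq_len(n)) {
      sf <- members$subfamily[i]
      n_ex <- if (length(config$exon_plan[[sf]]) == 1) {
        config$exon_plan[[sf]]
      } else {
        sample(config$exon_plan[[sf]], 1)
      }
      cds_len <- 3L * (aa_len[i] + 1L)
      n_ex <- min(n_ex, cds_len %/% 3L)
      base_sz <- cds_len %/% n_ex
      sizes <- rep(base_sz, n_ex)
      sizes[seq_len(cds_len - base_sz * n_ex)] <-
        sizes[seq_len(cds_len - base_sz * n_ex)] + 1L
      introns <- if (n_ex > 1) sample(200:1500, n_ex - 1, replace = TRUE)
      else integer(0)
      offs <- cumsum(c(0L, head(sizes, -1) + introns))
      structures[[i]] <- list(n_ex = n_ex, sizes = sizes, introns = introns,
                              rel_starts = offs,
                              span = sum(sizes) + sum(introns))
    }
    # same-locus secondaries share their leader's span
    for (pp in same_pairs) {
      structures[[pp[2]]]$span <- structures[[pp[1]]]$span
    }
    # --- positions -------------------------------------------------------
    pitch <- 130000L
    margin <- 60000L
    loci <- members
    loci$chromosome <- NA_character_
    loci$start <- NA_real_
    loci$end <- NA_real_
    loci$strand <- NA_character_
    chrom_slots <- split(names(slot_chrom), slot_chrom)
    chrom_len <- setNames(rep(0, nchr), chrom_names)
    for (chr in names(chrom_slots)) {
      ids <- chrom_slots[[chr]]
      for (si in seq_along(ids)) {
        gi <- match(ids[si], members$gene_id)
        start <- margin + (si - 1) * pitch
        span <- structures[[gi]]$span
        strand <- sample(c("+", "-"), 1)
        loci$chromosome[gi] <- chr
        loci$start[gi] <- start
        loci$end[gi] <- start + span
        loci$strand[gi] <- strand
      }
      chrom_len[chr] <- margin + length(ids) * pitch
    }
    if (!is.null(config$chromosome_length)) {
      chrom_len <- pmax(chrom_len, config$chromosome_length)
    }
    # same-locus secondaries copy the leader's locus
    for (pp in same_pairs) {
      loci$chromosome[pp[2]] <- loci$chromosome[pp[1]]
      loci$start[pp[2]] <- loci$start[pp[1]]
      loci$end[pp[2]] <- loci$end[pp[1]]
      loci$strand[pp[2]] <- loci$strand[pp[1]]
    }
    # scaffolds
    scaffold_names <- sprintf("scaffold_%d", seq_along(scaffold_idx))
    scaffold_len <- numeric(length(scaffold_idx))
    for (k in seq_along(scaffold_idx)) {
      gi <- scaffold_idx[k]
      span <- structures[[gi]]$span
      loci$chromosome[gi] <- scaffold_names[k]
      loci$start[gi] <- 4000
      loci$end[gi] <- 4000 + span
      loci$strand[gi] <- sample(c("+", "-"), 1)
      scaffold_len[k] <- span + 8000
    }
    # collision check (same-locus pairs excluded by construction)
    leaders <- setdiff(seq_len(n), same_secondary)
    ll <- loci[leaders, ]
    for (chr in unique(ll$chromosome)) {
      sub <- arrange(filter(ll, .data$chromosome == chr), .data$start)
      if (nrow(sub) > 1) {
        ov <- which(sub$start[-1] < sub$end[-nrow(sub)])
        if (length(ov) > 0) {
          abort(sprintf("overlapping placements: %s and %s",
                        sub$gene_id[ov[1]], sub$gene_id[ov[1] + 1]))
        }
      }
    }
    # --- segmental duplication pairing ----------------------------------
    dp <- config$duplication_plan
    used <- c(scaffold_idx, unlist(same_pairs))
    dup_pairs <- list()
    if (nrow(dp) > 0) {
      for (r in seq_len(nrow(dp))) {
        sf <- dp$subfamily[r]
        cand <- setdiff(which(members$subfamily == sf), used)
        # prefer genes on different chromosomes
        if (length(cand) < 2) {
          abort(sprintf("not enough free genes in subfamily %s for the
duplication plan", sf))
        }
        a <- cand[1]
        b_cand <- cand[loci$chromosome[cand] != loci$chromosome[a]]
        b <- if (length(b_cand) > 0) b_cand[1] else cand[2]
        used <- c(used, a, b)
        dup_pairs[[r]] <- list(a = a, b = b,
                               identity = dp$flank_identity[r],
                               span = dp$span[r])
        # shared strand so the duplicated promoter keeps its orientation
        loci$strand[b] <- loci$strand[a]
      }
    }
    # --- build sequences -------------------------------------------------
    seqs <- lapply(chrom_len, function(L) raw_dna(L))
    for (k in seq_along(scaffold_idx)) {
      seqs[[scaffold_names[k]]] <- raw_dna(scaffold_len[k])
    }
    # --- plant promoter elements (leaders only; pairs share promoters) --
    planted <- list()
    promoter_len <- 1500L
    for (gi in leaders) {
      sf <- members$subfamily[gi]
      focal <- unname(config$promoter_plan[sf])
      chr <- loci$chromosome[gi]
      used_iv <- matrix(numeric(0), ncol = 2)
      for (r in seq_len(nrow(catalog))) {
        el <- catalog$name[r]
        p_plant <- if (!is.na(focal) && identical(el, focal)) {
          config$planted_freq
        } else {
          config$background_freq
        }
        if (runif(1) >= p_plant) next
        pat <- realize_iupac(catalog$pattern[r])
        w <- nchar(pat)
        ok <- FALSE
        for (try in 1:20) {
          off <- sample(0:(promoter_len - w), 1)
          clash <- nrow(used_iv) > 0 &&
            any(off < used_iv[, 2] & (off + w) > used_iv[, 1])
          if (!clash) { ok <- TRUE; break }
        }
        if (!ok) next
        used_iv <- rbind(used_iv, c(off, off + w))
        # genomic write, strand-aware
        if (loci$strand[gi] == "+") {
          gpos <- loci$start[gi] - promoter_len + off
          if (gpos < 0) next
          seqs[[chr]][(gpos + 1):(gpos + w)] <- charToRaw(pat)
        } else {
          gpos <- loci$end[gi] + promoter_len - off - w
          if (gpos + w > length(seqs[[chr]])) next
          seqs[[chr]][(gpos + 1):(gpos + w)] <- charToRaw(revcomp_chars(pat))
        }
        ids_here <- members$gene_id[which(vapply(
          seq_len(n), function(x) slot_of[x] == slot_of[gi], logical(1)))]
        for (idh in ids_here) {
          planted[[length(planted) + 1]] <- tibble(
            gene_id = idh, element = el, offset = off,
            strand = loci$strand[gi])
        }
      }
    }
    # --- copy flank windows for segmental pairs -------------------------
    half <- function(span) min(span %/% 2, 50000L)
    for (pp in dup_pairs) {
      a <- pp$a; b <- pp$b
      h <- half(pp$span)
      rate <- 1 - pp$identity
      ca <- loci$chromosome[a]; cb <- loci$chromosome[b]
      # upstream
      a_up <- seqs[[ca]][(loci$start[a] - h + 1):loci$start[a]]
      seqs[[cb]][(loci$start[b] - h + 1):loci$start[b]] <-
        mutate_raw(a_up, rate)
      # downstream
      a_dn <- seqs[[ca]][(loci$end[a] + 1):(loci$end[a] + h)]
      seqs[[cb]][(loci$end[b] + 1):(loci$end[b] + h)] <-
        mutate_raw(a_dn, rate)
    }
    genome <- vapply(seqs, rawToChar, character(1))
    # the flank copy overwrote each pair-B promoter with A's planted
    # elements; the truth table must reflect the copied layout
    planted_tbl <- if (length(planted)) bind_rows(planted) else
      tibble(gene_id = character(), element = character(),
             offset = integer(), strand = character())
    for (pp in dup_pairs) {
      ga <- members$gene_id[pp$a]
      gb <- members$gene_id[pp$b]
      a_rows <- filter(planted_tbl, .data$gene_id == ga)
      planted_tbl <- bind_rows(
        filter(planted_tbl, .data$gene_id != gb),
        mutate(a_rows, gene_id = gb, strand = loci$strand[pp$b])
      )
    }
    # --- gene models ------------------------------------------------------
    gm <- purrr::map(seq_len(n), function(gi) {
      st <- structures[[gi]]
      estarts <- loci$start[gi] + st$rel_starts
      eends <- estarts + st$sizes
      tibble(
        gene_id = members$gene_id[gi],
        chromosome = loci$chromosome[gi],
        strand = loci$strand[gi],
        start = loci$start[gi], end = loci$end[gi],
        cds_start = if (loci$strand[gi] == "+") loci$start[gi]
        else loci$end[gi],
        exon_starts = list(estarts), exon_ends = list(eends)
      )
    }) |> bind_rows()
    dup_truth <- purrr::map(dup_pairs, function(pp) {
      ab <- sort(members$gene_id[c(pp$a, pp$b)])
      tibble(gene_a = ab[1], gene_b = ab[2], type = "segmental",
             flank_identity = pp$identity, span = pp$span)
    }) |> bind_rows()
    list(
      genome = genome,
      gene_models = gm,
      truth = list(
        loci = select(gm, "gene_id", "chromosome", "strand", "start",
                      "end"),
        duplications = dup_truth,
        tandem = tibble(gene_a = character(), gene_b = character()),
        planted_elements = planted_tbl,
        exon_counts = tibble(
          gene_id = members$gene_id,
          subfamily = members$subfamily,
          n_exons = vapply(structures, function(s) as.integer(s$n_ex),
                           integer(1))
        ),
        scaffold_genes = members$gene_id[scaffold_idx],
        same_locus_pairs = lapply(same_pairs, function(pp)
          members$gene_id[pp])
      )
    )
  })
}

#' Generate synthetic expression and qPCR data with planted truth
#'
#' Produces (1) a tissue FPKM matrix in which each gene belongs to a
#' planted class -- constitutive genes exceed 1 FPKM everywhere,
#' non-expressed genes never do, tissue-specific genes only within their
#' tissue group, partial genes in an arbitrary other subset; (2) a
#' drought contrast matrix with planted up/down regulated genes at the
#' configured fold ratio (`leaf_changed` and `root_changed` genes); and
#' (3) a triplicate qPCR Ct table where the target Ct is
#' `baseline - log2(true ratio) + Normal(0, ct_sd)` against a
#' constant-Ct reference gene.
#'
#' @param config An [scenario_config()].
#' @param members Optional member table (regenerated when NULL).
#' @return List: `fpkm` (tissue matrix tibble), `fpkm_drought`
#'   (leaf/root control-drought columns), `ct` (Ct tibble), `truth` list
#'   with `expression_class`, `drought`, `qpcr`.
#' @export
generate_expression <- function(config, members = NULL) {
  validate_scenario_config(config)
  if (is.null(members)) members <- generate_proteome(config)$truth$members
  ep <- config$expression_plan
  qp <- config$qpcr_plan
  n <- nrow(members)
  samples <- ep$samples
  groups <- lapply(ep$tissue_groups, function(g) sort(intersect(g, samples)))
  groups <- groups[lengths(groups) > 0]
  with_seed(child_seed(config$seed, 14L), {
    # --- class assignment ----------------------------------------------
    cc <- ep$class_counts
    classes <- rep(names(cc), cc)
    if (length(classes) < n) {
      classes <- c(classes, rep("constitutive", n - length(classes)))
    }
    classes <- classes[seq_len(n)]
    if (length(groups) == 0) {
      classes[classes == "tissue_specific"] <- "partial"
    }
    noise <- function(k) 2^rnorm(k, 0, ep$noise_sd)
    expressed_value <- function(k) (2 + rlnorm(k, log(10), 0.6)) * noise(k)
    silent_value <- function(k) runif(k, 0, 0.95)
    mat <- matrix(0, n, length(samples),
                  dimnames = list(members$gene_id, samples))
    expressed_sets <- vector("list", n)
    for (i in seq_len(n)) {
      cl <- classes[i]
      if (cl == "constitutive") {
        mat[i, ] <- expressed_value(length(samples))
        expressed_sets[[i]] <- samples
      } else if (cl == "non_expressed") {
        mat[i, ] <- silent_value(length(samples))
        expressed_sets[[i]] <- character(0)
      } else if (cl == "tissue_specific") {
        grp <- groups[[(i %% length(groups)) + 1]]
        mat[i, ] <- silent_value(length(samples))
        mat[i, grp] <- expressed_value(length(grp))
        expressed_sets[[i]] <- grp
      } else { # partial: a subset that is not a group union
        union_sets <- list()
        if (length(groups) > 0) {
          for (mask in seq_len(2^length(groups) - 1)) {
            mem <- which(bitwAnd(mask, 2^(seq_along(groups) - 1)) > 0)
            union_sets[[length(union_sets) + 1]] <-
              sort(unique(unlist(groups[mem])))
          }
        }
        repeat {
          sz <- sample(seq_len(length(samples) - 1), 1)
          sub <- sort(sample(samples, sz))
          bad <- any(vapply(union_sets, function(u) identical(u, sub),
                            logical(1)))
          if (!bad) break
        }
        mat[i, ] <- silent_value(length(samples))
        mat[i, sub] <- expressed_value(length(sub))
        expressed_sets[[i]] <- sub
      }
    }
    fpkm <- bind_cols(tibble(gene_id = members$gene_id),
                      as_tibble(mat))
    # --- drought contrasts ----------------------------------------------
    n_leaf <- min(ep$leaf_changed, n)
    root_pool <- setdiff(seq_len(n), seq_len(n_leaf))
    n_root <- min(ep$root_changed, length(root_pool))
    leaf_idx <- seq_len(n_leaf)
    root_idx <- root_pool[seq_len(n_root)]
    ratio_vec <- function(idx) {
      r <- rep(1, n)
      if (length(idx) > 0) {
        up <- idx[seq_len(ceiling(length(idx) / 2))]
        dn <- setdiff(idx, up)
        r[up] <- ep$change_ratio
        r[dn] <- 1 / ep$change_ratio
      }
      r
    }
    leaf_ratio <- ratio_vec(leaf_idx)
    root_ratio <- ratio_vec(root_idx)
    base_leaf <- runif(n, 5, 50)
    base_root <- runif(n, 5, 50)
    fpkm_drought <- tibble(
      gene_id = members$gene_id,
      leaf_control = base_leaf,
      leaf_drought = base_leaf * leaf_ratio * noise(n),
      root_control = base_root,
      root_drought = base_root * root_ratio * noise(n)
    )
    drought_truth <- bind_rows(
      tibble(gene_id = members$gene_id, tissue = "leaf",
             true_ratio = leaf_ratio, changed = leaf_ratio != 1),
      tibble(gene_id = members$gene_id, tissue = "root",
             true_ratio = root_ratio, changed = root_ratio != 1)
    )
    # --- qPCR ------------------------------------------------------------
    n_targets <- min(qp$n_targets, n)
    targets <- character(0)
    if (n_targets > 0 && n > 0) {
      per_sf <- split(members$gene_id, members$subfamily)
      take <- ceiling(n_targets / length(per_sf))
      targets <- head(unlist(lapply(per_sf, head, take),
                             use.names = FALSE), n_targets)
    }
    tp <- qp$timepoints
    ratios <- qp$ratios
    if (length(ratios) != length(tp)) {
      abort("qpcr_plan ratios must match timepoints")
    }
    ct_rows <- list()
    for (tg in targets) {
      for (s in seq_along(tp)) {
        for (rep_i in 1:3) {
          ct_rows[[length(ct_rows) + 1]] <- tibble(
            sample = tp[s], target = tg, reference = "ACT",
            replicate = rep_i,
            ct = qp$baseline_ct - log2(ratios[s]) + rnorm(1, 0, qp$ct_sd)
          )
        }
      }
    }
    # constant-Ct reference wells
    for (s in seq_along(tp)) {
      for (rep_i in 1:3) {
        ct_rows[[length(ct_rows) + 1]] <- tibble(
          sample = tp[s], target = "ACT", reference = "ACT",
          replicate = rep_i, ct = qp$reference_ct
        )
      }
    }
    ct <- if (length(ct_rows)) bind_rows(ct_rows) else
      tibble(sample = character(), target = character(),
             reference = character(), replicate = integer(),
             ct = double())
    qpcr_truth <- if (length(targets)) {
      tidyr::expand_grid(target = targets,
                         timepoint = tp) |>
        mutate(true_ratio = ratios[match(.data$timepoint, tp)])
    } else {
      tibble(target = character(), timepoint = character(),
             true_ratio = double())
    }
    list(
      fpkm = fpkm,
      fpkm_drought = fpkm_drought,
      ct = ct,
      truth = list(
        expression_class = tibble(
          gene_id = members$gene_id, class = classes,
          expressed_samples = expressed_sets
        ),
        drought = drought_truth,
        qpcr = qpcr_truth
      )
    )
  })
}

#' Generate a complete synthetic scenario
#'
#' Convenience wrapper running [generate_proteome()], [generate_genome()]
#' and [generate_expression()] coherently from one config.
#'
#' @param config An [scenario_config()].
#' @return List `config`, `proteome`, `genome`, `expression` (each as the
#'   respective generator returns).
#' @export
generate_scenario <- function(config = scenario_config()) {
  prot <- generate_proteome(config)
  gen <- generate_genome(config, proteome = prot)
  expr <- generate_expression(config, members = prot$truth$members)
  list(config = config, proteome = prot, genome = gen, expression = expr)
}

#' Write a synthetic scenario to disk
#'
#' Emits proteome.faa, alignment.faa, genome.fa, genes.gff3, fpkm.tsv,
#' fpkm_drought.tsv, qpcr_ct.csv and truth.json under `dir`.
#'
#' @param scenario Result of [generate_scenario()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(scenario$proteome$proteome, file.path(dir, "proteome.faa"),
              "AA")
  write_fasta(scenario$proteome$truth$alignment,
              file.path(dir, "alignment.faa"), "AA")
  if (length(scenario$genome$genome) > 0) {
    write_fasta(scenario$genome$genome, file.path(dir, "genome.fa"), "DNA")
    write_gene_models(scenario$genome$gene_models,
                      file.path(dir, "genes.gff3"))
  }
  readr::write_tsv(scenario$expression$fpkm, file.path(dir, "fpkm.tsv"))
  readr::write_tsv(scenario$expression$fpkm_drought,
                   file.path(dir, "fpkm_drought.tsv"))
  readr::write_csv(scenario$expression$ct, file.path(dir, "qpcr_ct.csv"))
  truth <- list(
    members = scenario$proteome$truth$members,
    decoys = scenario$proteome$truth$decoys,
    anchors = as.list(scenario$proteome$truth$anchors),
    duplications = scenario$genome$truth$duplications,
    planted_elements = scenario$genome$truth$planted_elements,
    exon_counts = scenario$genome$truth$exon_counts,
    scaffold_genes = scenario$genome$truth$scaffold_genes,
    expression_class = dplyr::select(
      scenario$expression$truth$expression_class, -"expressed_samples"),
    drought = scenario$expression$truth$drought,
    qpcr = scenario$expression$truth$qpcr
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
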