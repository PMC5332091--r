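# Tandem and segmental duplication calling. Tandem: same chromosome and
# nearest-boundary distance <= 50 kb. Segmental: the two genes' 100-kb
# flanking windows (50 kb upstream + 50 kb downstream, gene body excluded)
# share a collinear chain of alignment blocks, each > 200 bp and > 85%
# identity, totalling at least `min_chain_span` aligned bases.

#' Find tandem duplication pairs
#'
#' A pair is tandem when both genes sit on the same chromosome and the gap
#' between their nearest boundaries is at most `window` (overlapping genes
#' count as distance zero). Genes without a resolved chromosome (scaffold
#' entries, see `scaffold_pattern`) are excluded and reported in the
#' `"excluded"` attribute, and records mapped to identical coordinates
#' (alternative transcripts of one locus) are collapsed to a single
#' representative first. Symmetric in gene order and invariant under
#' chromosome renaming.
#'
#' @param loci Tibble with `gene_id`, `chromosome`, `start`, `end`
#'   (0-based half-open).
#' @param family_ids Gene ids to consider (default: all loci).
#' @param window Maximum boundary-to-boundary distance in bp
#'   (default 50000).
#' @param scaffold_pattern Regex marking unanchored scaffolds
#'   (default `"^scaffold"`, case-insensitive).
#' @return Tibble: `gene_a`, `gene_b` (unordered, `gene_a < gene_b`),
#'   `type = "tandem"`, `distance_bp`; attribute `excluded` lists
#'   scaffold-bound genes.
#' @export
find_tandem <- function(loci, family_ids = loci$gene_id, window = 50000,
                        scaffold_pattern = "^scaffold") {
  loci <- filter(loci, .data$gene_id %in% family_ids)
  on_scaffold <- grepl(scaffold_pattern, loci$chromosome, ignore.case = TRUE)
  excluded <- loci$gene_id[on_scaffold]
  loci <- loci[!on_scaffold, ]
  # same-coordinate records are alternative transcripts of one locus
  loci <- arrange(loci, .data$chromosome, .data$start, .data$gene_id)
  loci <- loci[!duplicated(loci[, c("chromosome", "start", "end")]), ]
  pairs <- list()
  if (nrow(loci) >= 2) {
    for (i in seq_len(nrow(loci) - 1)) {
      for (j in (i + 1):nrow(loci)) {
        if (loci$chromosome[i] != loci$chromosome[j]) next
        gap <- max(0, max(loci$start[i], loci$start[j]) -
                     min(loci$end[i], loci$end[j]))
        if (gap <= window) {
          ab <- sort(c(loci$gene_id[i], loci$gene_id[j]))
          pairs[[length(pairs) + 1]] <- tibble(
            gene_a = ab[1], gene_b = ab[2], type = "tandem",
            distance_bp = gap
          )
        }
      }
    }
  }
  out <- if (length(pairs)) {
    bind_rows(pairs) |> distinct() |> arrange(.data$gene_a, .data$gene_b)
  } else {
    tibble(gene_a = character(), gene_b = character(),
           type = character(), distance_bp = double())
  }
  attr(out, "excluded") <- excluded
  out
}

#' Extract the 100-kb flanking window of a gene
#'
#' Concatenates up to `flank` bases upstream and `flank` bases downstream
#' of the gene body (the body itself is excluded), truncating at
#' chromosome edges, together with a coordinate map that converts window
#' offsets back to genomic positions.
#'
#' @param genome Named character vector of chromosome sequences (or a
#'   `DNAStringSet`).
#' @param locus One-row tibble (or list) with `gene_id`, `chromosome`,
#'   `start`, `end`.
#' @param flank Bases per side (default 50000).
#' @return List: `sequence` (window string), `map` tibble (`segment`
#'   upstream/downstream, `win_start`, `win_end`, `gen_start`, `gen_end`,
#'   0-based half-open), `truncated_upstream`, `truncated_downstream`.
#' @export
extract_flanks <- function(genome, locus, flank = 50000) {
  genome <- as_named_character(genome)
  chrom <- locus$chromosome
  if (!chrom %in% names(genome)) {
    abort(sprintf("chromosome '%s' absent from genome", chrom))
  }
  clen <- nchar(genome[[chrom]])
  if (locus$end > clen || locus$start < 0) {
    abort(sprintf("locus '%s' lies beyond chromosome end", locus$gene_id))
  }
  up_start <- max(0, locus$start - flank)
  up_end <- locus$start
  down_start <- locus$end
  down_end <- min(clen, locus$end + flank)
  up_seq <- substr(genome[[chrom]], up_start + 1, up_end)
  down_seq <- substr(genome[[chrom]], down_start + 1, down_end)
  map <- tibble(
    segment = c("upstream", "downstream"),
    win_start = c(0L, nchar(up_seq)),
    win_end = c(nchar(up_seq), nchar(up_seq) + nchar(down_seq)),
    gen_start = c(up_start, down_start),
    gen_end = c(up_end, down_end)
  )
  list(
    sequence = paste0(up_seq, down_seq),
    map = map,
    truncated_upstream = (up_end - up_start) < flank,
    truncated_downstream = (down_end - down_start) < flank
  )
}

#' Convert window coordinates back to genomic coordinates
#'
#' @param map Coordinate map from [extract_flanks()].
#' @param win_pos 0-based window positions.
#' @return Tibble `segment`, `genomic` for each position (NA if a position
#'   falls outside the window).
#' @export
map_to_genomic <- function(map, win_pos) {
  purrr::map(win_pos, function(p) {
    seg <- filter(map, .data$win_start <= p, p < .data$win_end)
    if (nrow(seg) == 0) {
      tibble(segment = NA_character_, genomic = NA_real_)
    } else {
      tibble(segment = seg$segment[1],
             genomic = seg$gen_start[1] + (p - seg$win_start[1]))
    }
  }) |> bind_rows()
}

#' Chain alignment blocks under the published filters
#'
#' Blocks failing the per-block filters (`length > min_length` and
#' `identity > min_identity`, both strict) are discarded; the
#' maximum-total-aligned-length strictly collinear chain over the
#' survivors is then found by dynamic programming on blocks sorted by
#' query start. Ties break toward the higher minimum identity within the
#' chain, then toward the earlier block order.
#'
#' @param blocks Tibble of alignment blocks for one ordered window pair.
#' @param min_length Per-block length filter, strict (default 200).
#' @param min_identity Per-block identity filter, strict (default 0.85).
#' @return An `hdz_chain`: list with `blocks` (tibble, chain order),
#'   `total_aligned` (bp), `min_identity`. Empty input or no surviving
#'   blocks give an empty chain with `total_aligned = 0`.
#' @export
chain_blocks <- function(blocks, min_length = 200, min_identity = 0.85) {
  empty <- structure(
    list(blocks = blocks[0, ], total_aligned = 0, min_identity = NA_real_),
    class = "hdz_chain"
  )
  if (is.null(blocks) || nrow(blocks) == 0) return(empty)
  surv <- filter(blocks, .data$length > min_length,
                 .data$identity > min_identity)
  if (nrow(surv) == 0) return(empty)
  surv <- arrange(surv, .data$qstart, .data$sstart)
  nb <- nrow(surv)
  total <- surv$length # best chain total ending at block i
  minid <- surv$identity
  prev <- rep(0L, nb)
  for (i in seq_len(nb)) {
    for (j in seq_len(i - 1)) {
      ok <- surv$qstart[i] >= surv$qend[j] &&
        surv$sstart[i] >= surv$send[j]
      if (!ok) next
      cand_total <- total[j] + surv$length[i]
      cand_minid <- min(minid[j], surv$identity[i])
      better <- cand_total > total[i] ||
        (cand_total == total[i] && cand_minid > minid[i])
      if (better) {
        total[i] <- cand_total
        minid[i] <- cand_minid
        prev[i] <- j
      }
    }
  }
  best <- which.max(total) # ties: which.max takes the first (lexicographic)
  chain_idx <- integer(0)
  at <- best
  while (at != 0L) {
    chain_idx <- c(at, chain_idx)
    at <- prev[at]
  }
  structure(
    list(blocks = surv[chain_idx, ], total_aligned = total[best],
         min_identity = min(surv$identity[chain_idx])),
    class = "hdz_chain"
  )
}

#' @export
print.hdz_chain <- function(x, ...) {
  cat(sprintf("<hdz_chain> %d blocks, %d bp aligned, min identity %s\n",
              nrow(x$blocks), x$total_aligned,
              ifelse(is.na(x$min_identity), "NA",
                     sprintf("%.3f", x$min_identity))))
  invisible(x)
}

#' Call segmental duplications among family genes
#'
#' All-vs-all over family gene loci: gene records mapped to identical
#' coordinates (alternative transcripts of one locus) are collapsed to a
#' single representative first; scaffold-bound genes are excluded and
#' reported; pairs already called tandem are skipped. For each remaining
#' pair the 100-kb flank windows are aligned by [seeded_local_align()],
#' blocks are chained under the published filters, and the pair is called
#' segmental when the chain's total aligned length reaches
#' `min_chain_span`.
#'
#' @param loci Tibble `gene_id`, `chromosome`, `start`, `end`.
#' @param genome Named character vector of chromosome sequences.
#' @param flank Flank size per side (default 50000).
#' @param min_length,min_identity Per-block chain filters (strict;
#'   defaults 200 bp, 0.85).
#' @param min_chain_span Minimum chained aligned length to call a pair
#'   (default 2000 bp).
#' @param k,xdrop Seed-and-extend parameters.
#' @param tandem_window Tandem exclusion window (default 50000).
#' @param scaffold_pattern Regex marking unanchored scaffolds.
#' @return Tibble: `gene_a`, `gene_b`, `type = "segmental"`,
#'   `chain_total_bp`, `n_blocks`, `mean_identity`, `min_identity`.
#'   Attributes: `excluded` (scaffold genes), `collapsed` (same-locus
#'   duplicate records dropped), `chains` (named list of `hdz_chain`).
#' @export
call_segmental <- function(loci, genome, flank = 50000,
                           min_length = 200, min_identity = 0.85,
                           min_chain_span = 2000, k = 12, xdrop = 20,
                           tandem_window = 50000,
                           scaffold_pattern = "^scaffold") {
  genome <- as_named_character(genome)
  on_scaffold <- grepl(scaffold_pattern, loci$chromosome, ignore.case = TRUE)
  excluded <- loci$gene_id[on_scaffold]
  loci <- loci[!on_scaffold, ]
  # collapse same-locus records (alternative transcripts)
  loci <- arrange(loci, .data$chromosome, .data$start, .data$gene_id)
  dup <- duplicated(loci[, c("chromosome", "start", "end")])
  collapsed <- loci$gene_id[dup]
  loci <- loci[!dup, ]
  tandem <- find_tandem(loci, window = tandem_window,
                        scaffold_pattern = scaffold_pattern)
  tandem_key <- paste(tandem$gene_a, tandem$gene_b)
  pairs <- list()
  chains <- list()
  n <- nrow(loci)
  if (n >= 2) {
    flanks <- lapply(seq_len(n), function(i) {
      extract_flanks(genome, loci[i, ], flank)
    })
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ab <- sort(c(loci$gene_id[i], loci$gene_id[j]))
        if (paste(ab[1], ab[2]) %in% tandem_key) next
        blocks <- seeded_local_align(
          flanks[[i]]$sequence, flanks[[j]]$sequence, k = k,
          xdrop = xdrop,
          query_id = loci$gene_id[i], subject_id = loci$gene_id[j])
        chain <- chain_blocks(blocks, min_length, min_identity)
        if (chain$total_aligned >= min_chain_span) {
          pairs[[length(pairs) + 1]] <- tibble(
            gene_a = ab[1], gene_b = ab[2], type = "segmental",
            chain_total_bp = chain$total_aligned,
            n_blocks = nrow(chain$blocks),
            mean_identity = mean(chain$blocks$identity),
            min_identity = chain$min_identity
          )
          chains[[paste(ab[1], ab[2], sep = "|")]] <- chain
        }
      }
    }
  }
  out <- if (length(pairs)) {
    bind_rows(pairs) |> arrange(.data$gene_a, .data$gene_b)
  } else {
    tibble(gene_a = character(), gene_b = character(), type = character(),
           chain_total_bp = double(), n_blocks = integer(),
           mean_identity = double(), min_identity = double())
  }
  attr(out, "excluded") <- excluded
  attr(out, "collapsed") <- collapsed
  attr(out, "chains") <- chains
  out
}
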