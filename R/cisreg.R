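# Promoter extraction, IUPAC cis-element scanning and per-subfamily
# exact-binomial overrepresentation.

#' Read a cis-element catalog
#'
#' The packaged catalog (`system.file("extdata", "cis_elements.tsv",
#' package = "hdzipr")`) lists common plant stress/hormone/light elements
#' with editable IUPAC patterns; the patterns are package fixtures.
#'
#' @param path Catalog TSV (`name`, `pattern`, `class`); default the
#'   packaged catalog.
#' @return Tibble with unique names and validated IUPAC patterns.
#' @export
read_element_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cis_elements.tsv", package = "hdzipr")
  }
  cat_tbl <- readr::read_tsv(path, show_col_types = FALSE)
  if (anyDuplicated(cat_tbl$name)) abort("catalog names must be unique")
  for (i in seq_len(nrow(cat_tbl))) {
    chars <- strsplit(toupper(cat_tbl$pattern[i]), "", fixed = TRUE)[[1]]
    bad <- setdiff(chars, names(IUPAC_CODES))
    if (length(bad) > 0) {
      abort(sprintf("invalid IUPAC code '%s' in catalog entry '%s'",
                    bad[1], cat_tbl$name[i]))
    }
  }
  cat_tbl
}

#' Extract the promoter upstream of the translation start
#'
#' Plus strand: bases `[cds_start - length, cds_start)`; minus strand: the
#' reverse complement of `[cds_end, cds_end + length)` (so the returned
#' string always reads 5' to 3' toward the start codon). Truncated at the
#' contig edge with a flag. The translation start (ATG) stands in for the
#' transcription start site, mirroring common practice when 5' UTR models
#' are unreliable.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param gene One-row gene model (needs `chromosome`, `strand`, `start`,
#'   `end`).
#' @param length Promoter length in bp (default 1500).
#' @return Character scalar with attribute `truncated` (logical).
#' @export
extract_promoter <- function(genome, gene, length = 1500) {
  genome <- as_named_character(genome)
  chrom <- gene$chromosome
  if (!chrom %in% names(genome)) {
    abort(sprintf("chromosome '%s' absent from genome", chrom))
  }
  clen <- nchar(genome[[chrom]])
  if (gene$strand == "+") {
    from <- max(0, gene$start - length)
    to <- gene$start
    seq <- substr(genome[[chrom]], from + 1, to)
  } else {
    from <- gene$end
    to <- min(clen, gene$end + length)
    seq <- substr(genome[[chrom]], from + 1, to)
    seq <- reverse_complement(seq)
  }
  attr(seq, "truncated") <- nchar(seq) < length
  seq
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# IUPAC pattern -> regex character classes; N in the scanned sequence must
# never match, so the expansion never includes N.
iupac_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    bases <- IUPAC_CODES[[ch]]
    if (is.null(bases)) abort(sprintf("invalid IUPAC code '%s'", ch))
    if (length(bases) == 1) bases else
      paste0("[", paste(bases, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Scan a promoter for catalog elements
#'
#' Reports every offset where an IUPAC pattern matches (overlapping
#' occurrences included; `N` in the sequence never matches). With
#' `both_strands`, reverse-strand matches are reported at the forward
#' offset of the matched stretch. A palindromic pattern then matches both
#' strands at the same offset; `dedupe_palindromes` collapses those to the
#' forward hit. Case-insensitive.
#'
#' @param promoter Promoter sequence over ACGTN (any case), or a named
#'   character vector of promoters.
#' @param catalog Element catalog tibble (see [read_element_catalog()]).
#' @param both_strands Scan the reverse strand too (default TRUE).
#' @param dedupe_palindromes Drop reverse hits coinciding with a forward
#'   hit of the same element at the same offset (default TRUE).
#' @return Tibble: `gene_id`, `element`, `offset` (0-based, forward
#'   coordinates), `strand`, `match` (forward-strand stretch).
#' @export
scan_elements <- function(promoter, catalog, both_strands = TRUE,
                          dedupe_palindromes = TRUE) {
  proms <- as_named_character(promoter)
  purrr::imap(proms, function(p, id) {
    scan_one_promoter(p, id, catalog, both_strands, dedupe_palindromes)
  }) |> bind_rows()
}

scan_one_promoter <- function(promoter, gene_id, catalog, both_strands,
                              dedupe_palindromes) {
  seq <- toupper(promoter)
  if (grepl("[^ACGTN]", seq)) abort("promoter must be over ACGTN")
  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    pat <- toupper(catalog$pattern[i])
    rx <- iupac_regex(pat)
    fwd <- find_all_matches(seq, rx)
    if (length(fwd) > 0) {
      rows[[length(rows) + 1]] <- tibble(
        gene_id = gene_id, element = catalog$name[i],
        offset = fwd - 1L, strand = "+",
        match = substring(seq, fwd, fwd + nchar(pat) - 1L)
      )
    }
    if (both_strands) {
      rx_rc <- iupac_regex(reverse_complement_iupac(pat))
      rev <- find_all_matches(seq, rx_rc)
      if (length(rev) > 0) {
        hits <- tibble(
          gene_id = gene_id, element = catalog$name[i],
          offset = rev - 1L, strand = "-",
          match = substring(seq, rev, rev + nchar(pat) - 1L)
        )
        if (dedupe_palindromes && length(fwd) > 0) {
          hits <- filter(hits, !.data$offset %in% (fwd - 1L))
        }
        rows[[length(rows) + 1]] <- hits
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(gene_id = character(), element = character(),
                  offset = integer(), strand = character(),
                  match = character()))
  }
  bind_rows(rows) |> arrange(.data$element, .data$offset)
}

# all (overlapping) match start positions, 1-based, via zero-width lookahead
find_all_matches <- function(seq, rx) {
  m <- gregexpr(paste0("(?=", rx, ")"), seq, perl = TRUE)[[1]]
  if (length(m) == 1 && m == -1L) integer(0) else as.integer(m)
}

reverse_complement_iupac <- function(pattern) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  chars <- rev(strsplit(toupper(pattern), "", fixed = TRUE)[[1]])
  paste(comp[chars], collapse = "")
}

#' Per-subfamily cis-element overrepresentation (exact binomial)
#'
#' The unit is presence/absence per promoter. For each element x
#' subfamily cell: `k` = promoters in the subfamily containing at least
#' one hit, `n` = subfamily size, `p0` = proportion of all family
#' promoters containing the element, and the p-value is the exact
#' upper-tail binomial probability `P(X >= k)` with `X ~ Binomial(n, p0)`.
#' q-values are Benjamini-Hochberg, adjusted within each subfamily.
#' Empty subfamilies are omitted with a warning.
#'
#' @param hits Element hit tibble from [scan_elements()].
#' @param subfamily_map Named character vector: gene id -> subfamily. All
#'   mapped genes count as scanned promoters (a gene with no hits still
#'   contributes to `n` and `p0`).
#' @param elements Elements to test (default: all in `hits`).
#' @return An `hdz_enrichment` tibble: `element`, `subfamily`, `k`, `n`,
#'   `p0`, `p_value`, `q_value`.
#' @export
enrichment_test <- function(hits, subfamily_map, elements = NULL) {
  genes <- names(subfamily_map)
  if (is.null(elements)) elements <- sort(unique(hits$element))
  n_total <- length(genes)
  if (n_total == 0) abort("subfamily_map is empty")
  subs <- split(genes, unname(subfamily_map[genes]))
  empty <- setdiff(SUBFAMILIES, names(subs))
  if (length(empty) > 0) {
    warn(sprintf("empty subfamily omitted: %s",
                 paste(empty, collapse = ", ")))
  }
  rows <- list()
  for (el in elements) {
    with_el <- unique(hits$gene_id[hits$element == el])
    p0 <- sum(genes %in% with_el) / n_total
    for (sf in names(subs)) {
      members <- subs[[sf]]
      n <- length(members)
      k <- sum(members %in% with_el)
      p <- pbinom(k - 1, n, p0, lower.tail = FALSE) # P(X >= k); k=0 -> 1
      rows[[length(rows) + 1]] <- tibble(
        element = el, subfamily = sf, k = k, n = n, p0 = p0, p_value = p
      )
    }
  }
  out <- bind_rows(rows) |>
    group_by(.data$subfamily) |>
    mutate(q_value = p.adjust(.data$p_value, method = "BH")) |>
    ungroup() |>
    arrange(.data$subfamily, .data$p_value)
  class(out) <- c("hdz_enrichment", class(out))
  out
}

#' Plot cis-element enrichment
#'
#' Dot plot of -log10 q-value per element x subfamily, sized by the
#' subfamily hit fraction.
#'
#' @param object An `hdz_enrichment` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hdz_enrichment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$subfamily, y = .data$element,
    size = .data$k / pmax(.data$n, 1),
    colour = -log10(pmax(.data$q_value, 1e-16)))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "subfamily", y = NULL, size = "hit fraction",
                  colour = expression(-log[10] ~ q))
}
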