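# Format plumbing: FASTA via Biostrings, GFF3 via rtracklayer, flat tables
# via readr. Internally all genomic coordinates are 0-based half-open;
# GFF3's 1-based inclusive convention is converted at the boundary.

as_named_character <- function(x) {
  if (methods::is(x, "XStringSet")) {
    setNames(as.character(x), names(x))
  } else if (is.character(x)) {
    if (is.null(names(x)) && length(x) > 0) {
      names(x) <- paste0("seq", seq_along(x))
    }
    x
  } else {
    abort("expected a character vector or Biostrings XStringSet")
  }
}

#' Read a protein FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_proteome <- function(path) {
  x <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) abort(sprintf("unreadable FASTA '%s': %s",
                                      path, conditionMessage(e)))
  )
  nm <- sub("\\s.*$", "", names(x))
  setNames(as.character(x), nm)
}

#' Read a nucleotide FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  setNames(as.character(x), nm)
}

#' Write sequences to FASTA (60-column wrapped)
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @param type `"AA"` or `"DNA"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") {
    Biostrings::AAStringSet(sequences)
  } else {
    Biostrings::DNAStringSet(sequences)
  }
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS features and assembles one record per gene with
#' 0-based half-open coordinates. Exons are taken from the first mRNA of
#' each gene (alternative transcripts at the same locus are separate gene
#' records in this pipeline).
#'
#' @param path GFF3 file path.
#' @return Tibble with columns `gene_id`, `chromosome`, `strand`, `start`,
#'   `end`, `cds_start`, `exon_starts`, `exon_ends` (list-columns of 0-based
#'   half-open exon intervals, sorted).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- tibble(
    type = as.character(gr$type),
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    parent = vapply(
      if (!is.null(gr$Parent)) as.list(gr$Parent) else
        rep(list(character(0)), length(gr)),
      function(p) if (length(p)) p[[1]] else NA_character_, character(1)
    )
  )
  genes <- filter(df, .data$type == "gene")
  mrnas <- filter(df, .data$type == "mRNA")
  exons <- filter(df, .data$type == "exon")
  purrr::pmap(
    list(genes$id, genes$chromosome, genes$strand, genes$start, genes$end),
    function(gid, chrom, strand, gstart, gend) {
      mr <- filter(mrnas, .data$parent == gid)
      ex <- if (nrow(mr) > 0) {
        filter(exons, .data$parent == mr$id[1])
      } else {
        filter(exons, .data$parent == gid)
      }
      ex <- arrange(ex, .data$start)
      if (nrow(ex) == 0) {
        ex <- tibble(start = gstart, end = gend)
      }
      if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
        abort(sprintf("overlapping exons in gene '%s'", gid))
      }
      tibble(
        gene_id = gid, chromosome = chrom, strand = strand,
        start = gstart, end = gend,
        cds_start = if (strand == "+") gstart else gend,
        exon_starts = list(ex$start), exon_ends = list(ex$end)
      )
    }
  ) |> bind_rows()
}

#' Write gene models to GFF3
#'
#' Emits gene/mRNA/exon/CDS rows (CDS mirrors exons) in 1-based inclusive
#' GFF3 coordinates.
#'
#' @param models Tibble as returned by [read_gene_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  rows <- purrr::pmap(
    list(models$gene_id, models$chromosome, models$strand,
         models$start, models$end, models$exon_starts, models$exon_ends),
    function(gid, chrom, strand, gstart, gend, estarts, eends) {
      g <- sprintf("%s\thdzipr\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   chrom, gstart + 1L, gend, strand, gid)
      m <- sprintf("%s\thdzipr\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                   chrom, gstart + 1L, gend, strand, gid, gid)
      e <- sprintf(
        "%s\thdzipr\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s.t1",
        chrom, estarts + 1L, eends, strand, gid, seq_along(estarts), gid)
      cds <- sprintf(
        "%s\thdzipr\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.c%d;Parent=%s.t1",
        chrom, estarts + 1L, eends, strand, gid, seq_along(estarts), gid)
      c(g, m, e, cds)
    }
  )
  writeLines(c("##gff-version 3", unlist(rows)), path)
  invisible(path)
}

#' Read an FPKM expression matrix
#'
#' @param path TSV with a `gene_id` column followed by one column per sample.
#' @return Tibble.
#' @export
read_fpkm <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read a qPCR Ct table
#'
#' @param path CSV with columns `sample`, `target`, `reference`, `replicate`,
#'   `ct` -- one row per well. `target` is the gene measured in the well and
#'   `reference` names the experiment's internal-control gene; wells that
#'   measure the internal control itself have `target == reference`.
#' @return Tibble.
#' @export
read_ct_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
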