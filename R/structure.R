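# Exon-intron structure statistics per gene and per subfamily.

#' Exon and intron counts with per-subfamily summaries
#'
#' Computes per-gene exon/intron counts from gene models (intron count =
#' exon count - 1) and per-subfamily minimum, maximum and mean. Genes in
#' the subfamily map but absent from the annotation are listed separately,
#' never silently dropped. Empty subfamilies are absent from the summary
#' rather than reported as zero.
#'
#' @param gene_models Tibble from [read_gene_models()] (or a GFF3 path).
#' @param subfamily_map Named character vector: gene id -> subfamily.
#' @return An `hdz_exon_stats` list: `per_gene` tibble (`gene_id`,
#'   `subfamily`, `n_exons`, `n_introns`), `per_subfamily` tibble
#'   (`subfamily`, `n_genes`, `min_exons`, `max_exons`, `mean_exons`),
#'   `missing` character vector.
#' @export
exon_stats <- function(gene_models, subfamily_map) {
  if (is.character(gene_models) && length(gene_models) == 1) {
    gene_models <- read_gene_models(gene_models)
  }
  present <- intersect(names(subfamily_map), gene_models$gene_id)
  missing <- setdiff(names(subfamily_map), gene_models$gene_id)
  per_gene <- gene_models |>
    filter(.data$gene_id %in% present) |>
    mutate(
      subfamily = unname(subfamily_map[.data$gene_id]),
      n_exons = lengths(.data$exon_starts),
      n_introns = .data$n_exons - 1L
    ) |>
    select("gene_id", "subfamily", "n_exons", "n_introns") |>
    arrange(.data$subfamily, .data$gene_id)
  per_subfamily <- per_gene |>
    group_by(.data$subfamily) |>
    summarise(
      n_genes = n(),
      min_exons = min(.data$n_exons),
      max_exons = max(.data$n_exons),
      mean_exons = mean(.data$n_exons),
      .groups = "drop"
    )
  structure(
    list(per_gene = per_gene, per_subfamily = per_subfamily,
         missing = missing),
    class = "hdz_exon_stats"
  )
}

#' @export
print.hdz_exon_stats <- function(x, ...) {
  cat(sprintf("<hdz_exon_stats> %d genes, %d missing from annotation\n",
              nrow(x$per_gene), length(x$missing)))
  print(x$per_subfamily)
  invisible(x)
}

#' @export
tidy.hdz_exon_stats <- function(x, ...) x$per_gene

#' @export
glance.hdz_exon_stats <- function(x, ...) x$per_subfamily

#' Plot exon-intron gene structure
#'
#' Draws each gene as a horizontal intron line with exon boxes, lengths to
#' scale, grouped by subfamily.
#'
#' @param gene_models Tibble from [read_gene_models()].
#' @param subfamily_map Optional named character vector gene -> subfamily.
#' @return A ggplot object.
#' @export
plot_gene_structure <- function(gene_models, subfamily_map = NULL) {
  exons <- purrr::pmap(
    list(gene_models$gene_id, gene_models$start,
         gene_models$exon_starts, gene_models$exon_ends),
    function(gid, gstart, es, ee) {
      tibble(gene_id = gid, xstart = es - gstart, xend = ee - gstart)
    }
  ) |> bind_rows()
  spans <- gene_models |>
    mutate(len = .data$end - .data$start) |>
    select("gene_id", "len")
  if (!is.null(subfamily_map)) {
    exons$subfamily <- unname(subfamily_map[exons$gene_id])
    spans$subfamily <- unname(subfamily_map[spans$gene_id])
  }
  p <- ggplot2::ggplot(spans) +
    ggplot2::geom_segment(ggplot2::aes(
      x = 0, xend = .data$len, y = .data$gene_id, yend = .data$gene_id)) +
    ggplot2::geom_rect(
      data = exons,
      ggplot2::aes(xmin = .data$xstart, xmax = .data$xend,
                   ymin = as.numeric(factor(.data$gene_id)) - 0.35,
                   ymax = as.numeric(factor(.data$gene_id)) + 0.35),
      fill = "steelblue") +
    ggplot2::labs(x = "position in gene (bp)", y = NULL)
  if (!is.null(subfamily_map)) {
    p <- p + ggplot2::facet_grid(rows = ggplot2::vars(.data$subfamily),
                                 scales = "free_y", space = "free_y")
  }
  p
}
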