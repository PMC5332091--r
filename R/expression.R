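# FPKM expression classification and fold-change calling.

#' Classify expression profiles from an FPKM matrix
#'
#' A gene is expressed in a sample when FPKM is strictly greater than
#' `threshold`. Classes: `constitutive` (expressed in every sample),
#' `non_expressed` (in none), `tissue_specific` (the expressed set is
#' exactly the union of one or more configured tissue groups), otherwise
#' `partial`.
#'
#' @param fpkm Tibble with `gene_id` and one numeric column per sample.
#' @param threshold Expression threshold, strict (default 1 FPKM).
#' @param tissue_groups Named list of sample-name vectors defining tissue
#'   groups (e.g. `list(root = c("ESR", "MSR"))`).
#' @return Tibble: `gene_id`, `class`, `expressed_samples` (list-column),
#'   `n_expressed`.
#' @export
classify_expression <- function(fpkm, threshold = 1.0,
                                tissue_groups = list()) {
  samples <- setdiff(names(fpkm), "gene_id")
  if (length(samples) < 1) abort("need at least one sample column")
  vals <- as.matrix(fpkm[, samples])
  if (any(vals < 0)) abort("FPKM values must be >= 0")
  group_sets <- lapply(tissue_groups, function(g) sort(intersect(g, samples)))
  # all unions of non-empty subsets of tissue groups
  union_sets <- list()
  if (length(group_sets) > 0) {
    for (mask in seq_len(2^length(group_sets) - 1)) {
      members <- which(bitwAnd(mask, 2^(seq_along(group_sets) - 1)) > 0)
      union_sets[[length(union_sets) + 1]] <-
        sort(unique(unlist(group_sets[members])))
    }
  }
  purrr::map(seq_len(nrow(fpkm)), function(i) {
    expr <- samples[vals[i, ] > threshold]
    cls <- if (length(expr) == length(samples)) {
      "constitutive"
    } else if (length(expr) == 0) {
      "non_expressed"
    } else if (any(vapply(union_sets, function(u) identical(sort(expr), u),
                          logical(1)))) {
      "tissue_specific"
    } else {
      "partial"
    }
    tibble(gene_id = fpkm$gene_id[i], class = cls,
           expressed_samples = list(expr), n_expressed = length(expr))
  }) |> bind_rows()
}

#' Log2 fold change between treatment and control
#'
#' `log2_fc = log2((treatment + pseudocount) / (control + pseudocount))`;
#' a gene is `changed` when the absolute fold change exceeds 2, i.e.
#' `|log2_fc| > 1`.
#'
#' @param treatment,control Non-negative FPKM vectors of equal length.
#' @param pseudocount Added to both sides before the ratio (default 0.1;
#'   0 reproduces the raw ratio but leaves zero-FPKM genes undefined).
#' @param gene_id Optional gene ids.
#' @return Tibble: `gene_id`, `treatment`, `control`, `log2_fc`,
#'   `changed`.
#' @export
#' @examples
#' fold_change(4, 1, pseudocount = 0)$log2_fc # 2
fold_change <- function(treatment, control, pseudocount = 0.1,
                        gene_id = NULL) {
  if (any(treatment < 0, na.rm = TRUE) || any(control < 0, na.rm = TRUE)) {
    abort("FPKM inputs must be >= 0")
  }
  if (length(treatment) != length(control)) {
    abort("treatment and control must have equal length")
  }
  if (is.null(gene_id)) gene_id <- paste0("gene", seq_along(treatment))
  lfc <- log2((treatment + pseudocount) / (control + pseudocount))
  tibble(gene_id = gene_id, treatment = treatment, control = control,
         log2_fc = lfc, changed = abs(lfc) > 1)
}

#' Heatmap-ready expression matrices
#'
#' Exports the two standard panels: log2(FPKM + pseudocount) per sample,
#' and log2 fold change for configured treatment/control column pairs.
#'
#' @param fpkm FPKM tibble (`gene_id` + samples).
#' @param contrasts Named list of `c(treatment, control)` sample-name
#'   pairs.
#' @param pseudocount Pseudocount for both panels (default 0.1).
#' @return List of tibbles `log2_fpkm` and `log2_fc`.
#' @export
expression_panels <- function(fpkm, contrasts = list(), pseudocount = 0.1) {
  samples <- setdiff(names(fpkm), "gene_id")
  lf <- fpkm
  for (s in samples) lf[[s]] <- log2(fpkm[[s]] + pseudocount)
  fc <- tibble(gene_id = fpkm$gene_id)
  for (nm in names(contrasts)) {
    pair <- contrasts[[nm]]
    fc[[nm]] <- fold_change(fpkm[[pair[1]]], fpkm[[pair[2]]],
                            pseudocount)$log2_fc
  }
  list(log2_fpkm = lf, log2_fc = fc)
}

#' Expression heatmap
#'
#' Tile plot of a heatmap-ready matrix (genes x samples).
#'
#' @param panel Tibble with `gene_id` plus numeric columns.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_expression_heatmap <- function(panel, title = "log2 expression") {
  long <- tidyr::pivot_longer(panel, -"gene_id", names_to = "sample",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$gene_id,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
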