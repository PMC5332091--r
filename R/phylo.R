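# Distance-based subfamily classification: Poisson-corrected distances with
# partial deletion, neighbor-joining, column-resampling bootstrap, and
# anchored-clade subfamily assignment cross-checked against domain
# architecture.

# alignment (named character vector, '-' gaps) -> list(mat = char matrix,
# kept = indices of columns passing the partial-deletion coverage cutoff)
alignment_matrix <- function(alignment, coverage = 0.95) {
  alignment <- as_named_character(alignment)
  if (length(alignment) < 3) abort("need >= 3 sequences")
  L <- unique(nchar(alignment))
  if (length(L) != 1) abort("alignment sequences must have equal length")
  mat <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  rownames(mat) <- names(alignment)
  nongap <- colMeans(mat != "-" & mat != ".")
  kept <- which(nongap >= coverage)
  if (length(kept) == 0) abort("no alignment columns pass the coverage cutoff")
  list(mat = mat, kept = kept)
}

# Distances from a column matrix over chosen column indices (shared by
# pairwise_distance and the bootstrap replicates). p capped just below 1 so
# the Poisson correction stays finite.
dist_from_columns <- function(mat, cols, correction) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  sub <- mat[, cols, drop = FALSE]
  isgap <- sub == "-" | sub == "."
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- !isgap[i, ] & !isgap[j, ]
      nc <- sum(comp)
      if (nc == 0) {
        abort(sprintf("no comparable columns between '%s' and '%s'",
                      rownames(mat)[i], rownames(mat)[j]))
      }
      p <- sum(sub[i, comp] != sub[j, comp]) / nc
      dij <- if (correction == "poisson") -log(1 - min(p, 0.999)) else p
      d[i, j] <- dij
      d[j, i] <- dij
    }
  }
  d
}

#' Pairwise distances from a protein alignment
#'
#' Applies partial deletion first (columns with non-gap coverage below
#' `coverage` are dropped), then computes per-pair p-distances over columns
#' where neither sequence is gapped. The Poisson correction
#' `d = -ln(1 - p)` accounts for multiple substitutions (p is capped at
#' 0.999 to keep the correction finite).
#'
#' @param alignment Named character vector (or `AAStringSet`) of
#'   equal-length aligned sequences with `-` gaps.
#' @param correction `"poisson"` (default) or `"p"`.
#' @param coverage Partial-deletion site-coverage cutoff (default 0.95).
#' @return Symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
#' @examples
#' a <- c(x = "AAAA", y = "AAAT", z = "TTTT")
#' pairwise_distance(a, correction = "p")["x", "y"] # 0.25
pairwise_distance <- function(alignment, correction = c("poisson", "p"),
                              coverage = 0.95) {
  correction <- match.arg(correction)
  am <- alignment_matrix(alignment, coverage)
  dist_from_columns(am$mat, am$kept, correction)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor-joining agglomeration (via ape). Negative branch-length
#' estimates are clamped to zero; the affected edge count is recorded in the
#' `"clamped_edges"` attribute.
#'
#' @param dm Symmetric nonnegative distance matrix with zero diagonal and
#'   taxa as dimnames (>= 3 taxa).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) abort("dm must be square")
  if (nrow(dm) < 3) abort("need >= 3 taxa")
  if (any(abs(dm - t(dm)) > 1e-8)) abort("distance matrix is not symmetric")
  if (any(!is.finite(dm))) abort("distance matrix has non-finite entries")
  # canonical taxon order: agglomeration tie-breaks then depend only on
  # the taxa, not on input order, so bootstrap supports are invariant
  # under permutation
  if (!is.null(rownames(dm))) {
    ord <- order(rownames(dm))
    dm <- dm[ord, ord, drop = FALSE]
  }
  tree <- ape::nj(dm)
  clamped <- sum(tree$edge.length < 0)
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "clamped_edges") <- clamped
  tree
}

# Canonical bipartition keys for every internal node of an unrooted tree:
# each internal node's descendant tip set defines a split; the key is the
# sorted label set on the side NOT containing the reference taxon, so the
# key is invariant to rooting and taxon order.
split_keys <- function(tree, ref = NULL) {
  labs <- tree$tip.label
  if (is.null(ref)) ref <- sort(labs)[1]
  parts <- ape::prop.part(tree)
  ntip <- length(labs)
  keys <- character(0)
  nodes <- integer(0)
  for (i in seq_along(parts)) {
    tips <- labs[parts[[i]]]
    node <- ntip + i
    size <- length(tips)
    if (size < 2 || size > ntip - 2) next # trivial split
    side <- if (ref %in% tips) setdiff(labs, tips) else tips
    keys <- c(keys, paste(sort(side), collapse = "\r"))
    nodes <- c(nodes, node)
  }
  setNames(keys, nodes)
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples alignment columns (those passing partial deletion) with
#' replacement, rebuilds the NJ tree per replicate, and reports for each
#' internal edge of the full-data tree the percentage of replicates
#' containing the same bipartition. Supports are stored in `node.label`
#' (empty for trivial splits).
#'
#' @inheritParams pairwise_distance
#' @param n_replicates Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return A `phylo` tree with `node.label` percentages and attribute
#'   `n_replicates`.
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000, seed = 1,
                              correction = c("poisson", "p"),
                              coverage = 0.95) {
  correction <- match.arg(correction)
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  am <- alignment_matrix(alignment, coverage)
  main <- nj_tree(dist_from_columns(am$mat, am$kept, correction))
  keys <- split_keys(main)
  counts <- setNames(numeric(length(keys)), keys)
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      cols <- sample(am$kept, length(am$kept), replace = TRUE)
      rep_tree <- tryCatch(
        nj_tree(dist_from_columns(am$mat, cols, correction)),
        error = function(e) NULL
      )
      if (is.null(rep_tree)) next
      rk <- unique(split_keys(rep_tree))
      hit <- keys %in% rk
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- round(100 * counts / n_replicates, 1)
  nl <- rep("", main$Nnode)
  idx <- as.integer(names(keys)) - length(main$tip.label)
  nl[idx] <- as.character(support)
  main$node.label <- nl
  attr(main, "n_replicates") <- n_replicates
  main
}

#' Assign subfamilies from an anchored tree and architecture calls
#'
#' The tree label of a gene is the subfamily of the anchors in the smallest
#' split side (over all internal edges) that contains the gene and at least
#' one anchor. If that side contains anchors of more than one subfamily the
#' gene is labelled `"ambiguous"` and the competing labels are recorded.
#' The architecture label comes from the rule table (HD+LZ only -> I;
#' +CPSCE -> II; +START+MEKHLA -> III; +START without MEKHLA -> IV) and
#' disagreement with the tree raises a logged warning, never an overwrite.
#'
#' @param tree A `phylo` tree containing both genes and anchor taxa.
#' @param anchors Named character vector: anchor taxon id -> subfamily.
#' @param architecture Named character vector: gene id -> architecture
#'   subfamily (e.g. from [architecture_calls()]); may be missing genes.
#' @return Tibble: `gene_id`, `subfamily`, `tree_support`,
#'   `architecture`, `architecture_agrees`, `competing`.
#' @export
assign_subfamily <- function(tree, anchors, architecture = NULL) {
  labs <- tree$tip.label
  if (!all(names(anchors) %in% labs)) {
    abort("all anchors must be taxa of the tree")
  }
  if (!all(SUBFAMILIES %in% anchors)) {
    abort("every subfamily needs at least one anchor in the tree")
  }
  ntip <- length(labs)
  parts <- ape::prop.part(tree)
  support <- if (!is.null(tree$node.label)) tree$node.label else
    rep(NA_character_, tree$Nnode)
  # enumerate both sides of every internal edge
  sides <- list(); side_support <- numeric(0)
  for (i in seq_along(parts)) {
    tips <- labs[parts[[i]]]
    size <- length(tips)
    if (size < 1 || size > ntip - 1) next
    sup <- suppressWarnings(as.numeric(support[i]))
    sides <- c(sides, list(tips), list(setdiff(labs, tips)))
    side_support <- c(side_support, sup, sup)
  }
  genes <- setdiff(labs, names(anchors))
  rows <- purrr::map(genes, function(g) {
    in_side <- vapply(sides, function(s) g %in% s, logical(1))
    has_anchor <- vapply(sides, function(s) any(names(anchors) %in% s),
                         logical(1))
    cand <- which(in_side & has_anchor)
    if (length(cand) == 0) {
      return(tibble(gene_id = g, subfamily = "ambiguous",
                    tree_support = NA_real_, competing = ""))
    }
    sizes <- vapply(sides[cand], length, integer(1))
    best <- cand[which.min(sizes)]
    anchor_subs <- unique(anchors[intersect(names(anchors), sides[[best]])])
    if (length(anchor_subs) == 1) {
      tibble(gene_id = g, subfamily = unname(anchor_subs),
             tree_support = side_support[best], competing = "")
    } else {
      tibble(gene_id = g, subfamily = "ambiguous",
             tree_support = side_support[best],
             competing = paste(sort(anchor_subs), collapse = ","))
    }
  }) |> bind_rows()
  if (!is.null(architecture)) {
    rows <- mutate(
      rows,
      architecture = unname(architecture[.data$gene_id]),
      architecture_agrees = !is.na(.data$architecture) &
        .data$architecture == .data$subfamily
    )
    n_dis <- sum(!rows$architecture_agrees, na.rm = TRUE)
    if (n_dis > 0) {
      warn(sprintf(
        "tree and architecture subfamily disagree for %d gene(s)", n_dis))
    }
  } else {
    rows <- mutate(rows, architecture = NA_character_,
                   architecture_agrees = NA)
  }
  select(rows, "gene_id", "subfamily", "tree_support",
         "architecture", "architecture_agrees", "competing")
}

#' Architecture subfamily labels from a domain scan
#'
#' Collapses the per-protein x per-domain presence table of
#' [domain_architecture()] to one architecture-rule subfamily label per
#' protein (`NA` when the pattern matches no archetype).
#'
#' @param arch_scan Output of [domain_architecture()].
#' @return Named character vector: protein id -> subfamily.
#' @export
architecture_calls <- function(arch_scan) {
  wide <- arch_scan |>
    select("protein_id", "domain", "present") |>
    tidyr::pivot_wider(names_from = "domain", values_from = "present")
  for (dom in c("HD", "LZ", "CPSCE", "START", "MEKHLA")) {
    if (!dom %in% names(wide)) wide[[dom]] <- FALSE
  }
  setNames(
    architecture_subfamily(wide$HD, wide$LZ, wide$CPSCE, wide$START,
                           wide$MEKHLA),
    wide$protein_id
  )
}
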