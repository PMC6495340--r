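#' UPGMA (average-linkage) hierarchical clustering
#'
#' Builds the ultrametric dendrogram used to group genes with similar
#' expression profiles within each regulon. Merge heights follow the
#' classical UPGMA convention (half the average pairwise distance between the
#' merged groups), so the cophenetic distance between two leaves --
#' recoverable with [cophenetic_matrix()] -- is the average pairwise distance
#' itself.
#'
#' @param d a symmetric, zero-diagonal distance matrix (or `dist` object).
#' @return an object of class `upgma_tree` wrapping the merge table, heights,
#'   leaf order and labels.
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12))
    abort("Distance matrix must be square and symmetric.")
  if (any(diag(d) != 0)) abort("Distance matrix must have a zero diagonal.")
  if (any(d < 0)) abort("Distances must be non-negative.")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("g", seq_len(nrow(d)))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  structure(
    list(merge = hc$merge, height = hc$height / 2, order = hc$order,
         labels = hc$labels, hclust = hc),
    class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("<upgma_tree> %d leaves, %d merges, root height %.4g\n",
              length(x$labels), length(x$height), max(x$height)))
  invisible(x)
}

#' Cophenetic distance matrix of a UPGMA tree
#'
#' Entry (i, j) is the average pairwise distance at which leaves i and j were
#' merged (twice the merge height); an ultrametric.
#'
#' @param tree an [upgma()] tree.
#' @return symmetric numeric matrix with the tree's leaf labels.
#' @export
cophenetic_matrix <- function(tree) {
  stopifnot(inherits(tree, "upgma_tree"))
  as.matrix(stats::cophenetic(tree$hclust))
}

#' Number expression clusters on a UPGMA tree
#'
#' Cuts the tree into the maximal subtrees whose cophenetic diameter does not
#' exceed `height`, then numbers the groups of at least `min_size` leaves
#' sequentially in leaf order; smaller groups are left unnumbered (`NA`).
#' This automates the manual step of assigning numbers to groups of five or
#' more genes with similar expression patterns distinct from their neighbors.
#'
#' @param tree an [upgma()] tree.
#' @param min_size smallest group that receives a cluster number (default 5).
#' @param height cut value on the cophenetic-distance scale.
#' @return tibble: `gene_id`, `cluster_id` (integer or `NA`), `leaf_order`.
#' @export
assign_cluster_numbers <- function(tree, min_size = 5, height) {
  stopifnot(inherits(tree, "upgma_tree"), min_size >= 1)
  grp <- stats::cutree(tree$hclust, h = height)
  ord <- tree$labels[tree$order]
  grp_in_order <- grp[ord]
  sizes <- table(grp)
  big_in_leaf_order <- unique(grp_in_order[sizes[as.character(grp_in_order)] >= min_size])
  renum <- setNames(seq_along(big_in_leaf_order), big_in_leaf_order)
  tibble(gene_id = ord,
         cluster_id = unname(renum[as.character(grp_in_order)]),
         leaf_order = seq_along(ord))
}

#' Cluster gene expression profiles within regulon categories
#'
#' Concatenates each gene's mean log2 trajectories across the four strains
#' into one profile vector, computes Euclidean distances within each regulon
#' category, and runs [upgma()] + [assign_cluster_numbers()] per category.
#'
#' @param profiles mean-profile tibble from [mean_profiles()].
#' @param labels regulon labels from [assign_regulons()].
#' @param min_size,height passed to [assign_cluster_numbers()].
#' @param categories which categories to cluster (default: the DE ones).
#' @return tibble: `gene_id`, `category`, `cluster_id`, `leaf_order` (within
#'   category). Trees are attached as the `"trees"` attribute (a named list).
#' @export
cluster_regulons <- function(profiles, labels, min_size = 5, height = 2,
                             categories = .regulons) {
  pm <- profile_matrix(profiles)
  out <- list(); trees <- list()
  for (cat in categories) {
    genes <- labels$gene_id[labels$category == cat]
    genes <- intersect(genes, rownames(pm))
    if (length(genes) < 2) next
    tr <- upgma(as.matrix(stats::dist(pm[genes, , drop = FALSE])))
    cl <- assign_cluster_numbers(tr, min_size = min_size, height = height)
    cl$category <- cat
    out[[cat]] <- cl
    trees[[cat]] <- tr
  }
  res <- bind_rows(out)
  res <- res[, c("gene_id", "category", "cluster_id", "leaf_order")]
  attr(res, "trees") <- trees
  res
}

#' Gene x (strain:time) profile matrix
#'
#' Heat-map-ready layout: one row per gene, columns ordered strain-major
#' (WT, dsigJ, dsigC, dsigF) then time.
#'
#' @param profiles mean-profile tibble from [mean_profiles()].
#' @return numeric matrix with `strain:time` column names.
#' @export
profile_matrix <- function(profiles) {
  wide <- profiles |>
    mutate(strain = factor(.data$strain, levels = .strains)) |>
    arrange(.data$strain, .data$time_h) |>
    mutate(col = paste0(.data$strain, ":", .data$time_h)) |>
    select("gene_id", "col", "log2_ratio") |>
    pivot_wider(names_from = "col", values_from = "log2_ratio")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene_id
  m
}
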