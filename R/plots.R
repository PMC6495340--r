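#' Heat-map of expression profiles grouped by regulon
#'
#' The standard four-strain time-course layout: one tile per gene x
#' strain:time cell, genes grouped by regulon category.
#'
#' @param profiles mean-profile tibble from [mean_profiles()].
#' @param labels regulon labels from [assign_regulons()] (optional; genes
#'   are ordered by category when given).
#' @param max_genes cap on genes drawn (highest-|ratio| genes kept).
#' @return a ggplot object.
#' @export
plot_regulon_heatmap <- function(profiles, labels = NULL, max_genes = 200) {
  df <- profiles
  if (!is.null(labels)) {
    df <- left_join(df, labels[, c("gene_id", "category")], by = "gene_id")
  } else df$category <- "all"
  keep <- df |>
    group_by(.data$gene_id) |>
    summarise(span = max(abs(.data$log2_ratio)), .groups = "drop") |>
    arrange(dplyr::desc(.data$span)) |>
    utils::head(max_genes) |>
    pull("gene_id")
  df <- df |>
    filter(.data$gene_id %in% keep) |>
    mutate(strain = factor(.data$strain, levels = .strains),
           gene_id = factor(.data$gene_id, levels = rev(sort(unique(.data$gene_id)))))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$time_h), y = .data$gene_id,
                                   fill = .data$log2_ratio)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(category ~ strain, scales = "free_y", space = "free_y") +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "black", high = "yellow") +
    ggplot2::labs(x = "time (h)", y = NULL, fill = "log2 ratio") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Trajectories of selected genes across strains
#'
#' @param profiles mean-profile tibble from [mean_profiles()].
#' @param genes gene ids to draw.
#' @return a ggplot object.
#' @export
plot_profiles <- function(profiles, genes) {
  df <- profiles |>
    filter(.data$gene_id %in% genes) |>
    mutate(strain = factor(.data$strain, levels = .strains))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$log2_ratio,
                                   colour = .data$strain)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~gene_id) +
    ggplot2::labs(x = "time (h)", y = "log2 ratio to wild-type 0 h") +
    ggplot2::theme_minimal(base_size = 10)
}

#' Sequence-logo-style view of a consensus promoter
#'
#' Letters scaled by per-column information content (bits), the usual logo
#' presentation of the J-Box / extended -10 consensus.
#'
#' @param object a [build_consensus()] object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.consensus_promoter <- function(object, ...) {
  td <- tidy(object)
  long <- td |>
    pivot_longer(c("A", "C", "G", "T"), names_to = "base",
                 values_to = "freq") |>
    filter(.data$freq > 0) |>
    mutate(bits = .data$freq * .data$ic) |>
    arrange(.data$column, .data$freq) |>
    group_by(.data$column) |>
    mutate(ymax = cumsum(.data$bits), ymin = .data$ymax - .data$bits,
           ymid = (.data$ymin + .data$ymax) / 2) |>
    ungroup()
  base_cols <- c(A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rel)) +
    ggplot2::geom_text(ggplot2::aes(y = .data$ymid, label = .data$base,
                                    colour = .data$base, size = .data$bits),
                       fontface = "bold", show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = base_cols) +
    ggplot2::scale_size_continuous(range = c(0.5, 6)) +
    ggplot2::labs(x = "position relative to +1", y = "information (bits)") +
    ggplot2::ylim(0, 2) +
    ggplot2::theme_minimal(base_size = 10)
}

#' Dendrogram of a UPGMA tree
#'
#' @param object an [upgma()] tree.
#' @param ... unused.
#' @return a ggplot object drawn from the merge table.
#' @export
autoplot.upgma_tree <- function(object, ...) {
  n <- length(object$labels)
  xpos <- setNames(seq_len(n), object$labels[object$order])
  leaf_x <- xpos[object$labels]
  node_x <- numeric(n - 1); node_h <- object$height
  segs <- list()
  getx <- function(idx) if (idx < 0) leaf_x[-idx] else node_x[idx]
  geth <- function(idx) if (idx < 0) 0 else node_h[idx]
  for (k in seq_len(n - 1)) {
    x1 <- getx(object$merge[k, 1]); x2 <- getx(object$merge[k, 2])
    h1 <- geth(object$merge[k, 1]); h2 <- geth(object$merge[k, 2])
    node_x[k] <- (x1 + x2) / 2
    segs[[k]] <- tibble(
      x = c(x1, x2, x1), xend = c(x1, x2, x2),
      y = c(h1, h2, node_h[k]), yend = c(node_h[k], node_h[k], node_h[k]))
  }
  segs <- bind_rows(segs)
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = seq_len(n),
                                labels = object$labels[object$order]) +
    ggplot2::labs(x = NULL, y = "UPGMA merge height") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
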