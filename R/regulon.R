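#' Assign genes to sigma-factor regulons
#'
#' Implements the four-category classification of knockout time-course data.
#' Genes not differentially expressed in the wild-type course are `not_de`.
#' Wild-type-DE genes whose trajectory differs in no deletion strain are
#' `shared` (expressed similarly in all strains). The remainder are assigned
#' to the regulon of the sigma factor whose deletion produced the greatest
#' change, by ranking the L2 norms of the strains whose difference test is
#' significant. Exact L2 ties are broken by the fixed precedence
#' sigJ > sigC > sigF (with `tie_broken` set and a warning), so assignment is
#' deterministic.
#'
#' @param de per-gene wide tibble from [de_analysis()].
#' @return tibble: `gene_id`, `category`
#'   (`not_de`/`shared`/`sigJ`/`sigC`/`sigF`), `direction` (from the
#'   wild-type course), `l2_dsigJ`, `l2_dsigC`, `l2_dsigF`, `tie_broken`.
#' @export
assign_regulons <- function(de) {
  req <- c("gene_id", "wt_de", "wt_direction",
           "flag_dsigJ", "flag_dsigC", "flag_dsigF",
           "l2_dsigJ", "l2_dsigC", "l2_dsigF")
  miss <- setdiff(req, names(de))
  if (length(miss))
    abort(paste0("`de` is missing column(s): ", paste(miss, collapse = ", ")))
  flags <- as.matrix(de[, c("flag_dsigJ", "flag_dsigC", "flag_dsigF")])
  l2 <- as.matrix(de[, c("l2_dsigJ", "l2_dsigC", "l2_dsigF")])
  if (anyNA(flags) || anyNA(l2))
    abort("Every gene needs flags and L2 norms for all three deletion strains.")
  cat_sigma <- c("sigJ", "sigC", "sigF")  # column order = tie precedence
  n <- nrow(de)
  category <- character(n)
  tie_broken <- logical(n)
  for (i in seq_len(n)) {
    if (!isTRUE(de$wt_de[i])) {
      category[i] <- "not_de"
    } else if (!any(flags[i, ])) {
      category[i] <- "shared"
    } else {
      l2i <- ifelse(flags[i, ], l2[i, ], -Inf)
      best <- which(l2i == max(l2i))
      category[i] <- cat_sigma[best[1]]  # ties: earlier column wins
      tie_broken[i] <- length(best) > 1
    }
  }
  if (any(tie_broken))
    warn(sprintf("%d gene(s) had tied L2 norms; precedence sigJ > sigC > sigF applied.",
                 sum(tie_broken)))
  tibble(gene_id = de$gene_id, category = category,
         direction = de$wt_direction,
         l2_dsigJ = l2[, 1], l2_dsigC = l2[, 2], l2_dsigF = l2[, 3],
         tie_broken = tie_broken)
}

#' Cross-tabulate regulon labels
#'
#' @param labels tibble from [assign_regulons()] (or any tibble with
#'   `category` and `direction` columns).
#' @return tibble with one row per category (`not_de`, `shared`, `sigJ`,
#'   `sigC`, `sigF`), columns `up`, `down`, `total`; totals conserve the gene
#'   count.
#' @export
regulon_summary <- function(labels) {
  cats <- c("not_de", .regulons)
  base <- tidyr::expand_grid(category = cats, direction = c("up", "down"))
  labels |>
    count(.data$category, .data$direction) |>
    dplyr::right_join(base, by = c("category", "direction")) |>
    mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    pivot_wider(names_from = "direction", values_from = "n") |>
    mutate(total = .data$up + .data$down,
           category = factor(.data$category, levels = cats)) |>
    arrange(.data$category) |>
    mutate(category = as.character(.data$category))
}
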